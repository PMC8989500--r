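# ggplot2 views of the main result types.

#' Plot a Marey map with its fitted spline
#'
#' @param marey A `marey_map` tibble.
#' @param spline Optional `marey_spline` overlay.
#' @param n_grid Evaluation points per chromosome for the overlay.
#' @return A ggplot.
#' @export
plot_marey <- function(marey, spline = NULL, n_grid = 200) {
  p <- ggplot2::ggplot(marey,
                       ggplot2::aes(x = .data$bp / 1e6, y = .data$cM,
                                    colour = .data$kept)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_wrap(~chrom, scales = "free") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey25",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "physical position (Mbp)", y = "genetic position (cM)",
                  colour = "retained")
  if (!is.null(spline)) {
    curves <- purrr::imap_dfr(spline$fits, function(f, ch) {
      x <- seq(f$support[1], f$support[2], length.out = n_grid)
      tibble::tibble(chrom = ch, bp = x * 1e6,
                     cM = predict(f$fit, x)$y)
    })
    p <- p + ggplot2::geom_line(data = curves,
                                ggplot2::aes(x = .data$bp / 1e6, y = .data$cM),
                                colour = "steelblue", inherit.aes = FALSE)
  }
  p
}

#' @describeIn window_recombination_rates Landscape plot of window rates
#'   (one line per population, faceted by chromosome).
#' @param object A `window_rates` tibble.
#' @param ... Unused.
#' @export
autoplot.window_rates <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$rate, group = .data$pop_id)) +
    ggplot2::geom_line(alpha = 0.4, colour = "grey30") +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::labs(x = "window midpoint (Mbp)",
                  y = "recombination rate (cM/Mbp)")
}

#' @describeIn fit_gre_sre Dot plot of GRE estimates with the SRE spread.
#' @export
autoplot.gre_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$term,
                                                     .data$estimate),
                                  y = .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~effect, scales = "free") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "effect on recombination rate (cM/Mbp)")
}

#' @describeIn cv_fivefold Boxplots of per-run prediction abilities by
#'   scenario.
#' @param object A `cv_result` tibble.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("r_pg", "r_gre"),
                           names_to = "ability", values_to = "r")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scenario, y = .data$r)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~ability) +
    ggplot2::labs(x = NULL, y = "prediction ability (Pearson r)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
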