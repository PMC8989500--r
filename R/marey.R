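# Marey maps, monotone smoothing splines, windowed recombination rates,
# consensus map and landscape summaries.

#' Assemble a Marey map from a linkage map
#'
#' Pairs each bin's anchor physical position with its genetic position and
#' removes points that break the monotone increase by more than the stated
#' tolerance relative to the running maximum of retained points. Points
#' within the tolerance are retained unmodified.
#'
#' @param linkmap Linkage map tibble from [build_linkage_map()].
#' @param tolerance_cm Tolerated downward diversion in cM.
#' @param min_points Minimum retained points per chromosome for a spline.
#' @return A `marey_map` tibble: `chrom`, `bp`, `cM`, `kept`.
#' @export
assemble_marey <- function(linkmap, tolerance_cm = 2, min_points = 4) {
  out <- linkmap |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$anchor_bp, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      kept <- logical(nrow(d))
      run_max <- -Inf
      for (i in seq_len(nrow(d))) {
        if (d$cM[i] >= run_max - tolerance_cm) {
          kept[i] <- TRUE
          run_max <- max(run_max, d$cM[i])
        }
      }
      tibble::tibble(bp = d$anchor_bp, cM = d$cM, kept = kept)
    }) |>
    dplyr::ungroup()
  short <- out |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n = sum(.data$kept), .groups = "drop") |>
    dplyr::filter(.data$n < min_points)
  if (nrow(short) > 0)
    abort(paste("too few Marey points for a spline on:",
                paste(short$chrom, collapse = ", ")),
          class = "recombkit_spline_infeasible")
  class(out) <- c("marey_map", class(out))
  attr(out, "tolerance_cm") <- tolerance_cm
  out
}

fit_one_spline <- function(x, y, max_clip_cm = 2, spar_max = 1.5,
                           df_band = c(8, 25), n_grid = 4001) {
  grid <- seq(min(x), max(x), length.out = n_grid)
  dx <- grid[2] - grid[1]
  clip_area <- function(f) # cM removed by clipping negative derivatives
    sum(pmax(-predict(f, grid, deriv = 1)$y, 0)) * dx
  fit <- smooth.spline(x, y, cv = FALSE) # GCV smoothing
  # GCV's equivalent df is erratic across noisy Marey maps (interpolating on
  # one chromosome, near-linear on the next), which makes the boundary
  # behaviour population-specific; clamp into a stable band when violated
  band <- pmin(df_band, length(unique(x)) - 1)
  if (band[2] > band[1] && (fit$df < band[1] || fit$df > band[2]))
    fit <- smooth.spline(x, y, df = max(band[1], min(band[2], fit$df)))
  area <- clip_area(fit)
  if (area > max_clip_cm) {
    # escalate smoothing until the monotonized curve stays within
    # max_clip_cm of the raw spline; keep the least-smoothed such fit
    best <- fit; best_area <- area
    for (s in seq(min(max(fit$spar, 0), spar_max) + 0.05, spar_max,
                  by = 0.05)) {
      cand <- smooth.spline(x, y, spar = s)
      a <- clip_area(cand)
      if (a < best_area) { best <- cand; best_area <- a }
      if (a <= max_clip_cm) break
    }
    fit <- best; area <- best_area
    if (!is.finite(area))
      abort("smoothing search failed to produce a finite fit",
            class = "recombkit_spline_nonconvergent")
  }
  # monotone evaluation curve: integral of the derivative clipped at 0
  d <- pmax(predict(fit, grid, deriv = 1)$y, 0)
  mono_y <- predict(fit, grid[1])$y +
    c(0, cumsum((d[-1] + d[-length(d)]) / 2 * dx))
  list(fit = fit, mono_x = grid, mono_y = mono_y, clip_cm = area)
}

#' Fit monotone cubic smoothing splines to a Marey map
#'
#' Per chromosome, a cubic smoothing spline of genetic position (cM) on
#' physical position (Mbp) is fitted with the smoothing parameter chosen by
#' generalized cross-validation; negative derivatives are clipped to 0 on
#' evaluation, making the evaluated curve monotone by construction. When
#' the clipping would remove more than `max_clip_cm` of genetic length, the
#' smoothing parameter is increased automatically until the monotonized
#' curve stays within that budget of the raw spline (escalating smoothing
#' all the way to exact monotonicity systematically shrinks the map ends,
#' biasing total genetic length down).
#'
#' @param marey A `marey_map` tibble (only `kept` points are used).
#' @param max_clip_cm Largest tolerated genetic length (cM) removed by
#'   derivative clipping before smoothing is escalated.
#' @return A `marey_spline` object: per-chromosome fit, monotone evaluation
#'   grid, support (Mbp) and retained point positions.
#' @export
fit_marey_spline <- function(marey, max_clip_cm = 2) {
  pts <- marey[marey$kept, ]
  fits <- lapply(split(pts, pts$chrom), function(d) {
    if (nrow(d) < 4)
      abort("need >= 4 Marey points per chromosome",
            class = "recombkit_spline_infeasible")
    x <- d$bp / 1e6
    fit <- fit_one_spline(x, d$cM, max_clip_cm = max_clip_cm)
    c(fit, list(support = range(x), points_mbp = x, n = nrow(d)))
  })
  structure(list(fits = fits), class = "marey_spline")
}

#' @export
print.marey_spline <- function(x, ...) {
  cat(sprintf("<marey_spline> %d chromosome(s): %s\n", length(x$fits),
              paste(names(x$fits), collapse = ", ")))
  invisible(x)
}

#' Evaluate a Marey spline
#'
#' @param spline A `marey_spline`.
#' @param chrom Chromosome name.
#' @param bp Physical positions (bp).
#' @param deriv 0 for cM, 1 for the local rate (cM/Mbp, clipped at 0).
#' @return Numeric vector.
#' @export
predict_marey <- function(spline, chrom, bp, deriv = 0) {
  f <- spline$fits[[chrom]]
  if (is.null(f)) abort(paste("no spline for chromosome", chrom))
  if (deriv == 1) {
    pmax(predict(f$fit, bp / 1e6, deriv = 1)$y, 0)
  } else {
    stats::approx(f$mono_x, f$mono_y, xout = bp / 1e6, rule = 2)$y
  }
}

#' Windowed recombination rates from a fitted Marey spline
#'
#' The default rate of a window is the mean slope of the fitted curve,
#' `(spline(end) - spline(start)) / width`, evaluated within the spline's
#' support; mean slopes are exactly additive to the chromosome's genetic
#' length. A terminal window with no Marey points takes the spline
#' derivative at the mean physical position of the 5 nearest points. The
#' last partial window is normalized by its true width. All rates are
#' clipped at 0.
#'
#' @param spline A `marey_spline`.
#' @param chrom_spec Chromosome tibble (`chrom`, `length_bp`).
#' @param window_bp Window width in bp (half-open `[k*w, (k+1)*w)` grid).
#' @param method `"mean_slope"` (default) or `"midpoint"` (pointwise
#'   derivative at the window midpoint).
#' @param pop_id Optional population id recorded in the output.
#' @return A `window_rates` tibble: `pop_id`, `chrom`, `start`, `end`,
#'   `width_mbp`, `rate`, `edge` (filled by the nearest-points rule).
#' @export
window_recombination_rates <- function(spline, chrom_spec, window_bp = 1e7,
                                       method = c("mean_slope", "midpoint"),
                                       pop_id = NA_character_) {
  method <- match.arg(method)
  chroms <- intersect(chrom_spec$chrom, names(spline$fits))
  if (length(chroms) == 0) abort("empty window grid: no fitted chromosomes",
                                 class = "recombkit_validation")
  purrr::map_dfr(chroms, function(ch) {
    len <- chrom_spec$length_bp[chrom_spec$chrom == ch]
    f <- spline$fits[[ch]]
    start <- seq(0, len - 1, by = window_bp)
    end <- pmin(start + window_bp, len)
    width <- (end - start) / 1e6
    sup <- f$support * 1e6
    b1 <- pmax(start, sup[1]); b2 <- pmin(end, sup[2])
    rate <- numeric(length(start))
    edge <- b2 <= b1
    inside <- !edge
    if (any(inside)) {
      if (method == "mean_slope") {
        rate[inside] <- (predict_marey(spline, ch, b2[inside]) -
                           predict_marey(spline, ch, b1[inside])) /
          width[inside]
      } else {
        rate[inside] <- predict_marey(spline, ch,
                                      (b1[inside] + b2[inside]) / 2, deriv = 1)
      }
    }
    if (any(edge)) {
      for (k in which(edge)) {
        mid <- (start[k] + end[k]) / 2e6
        near <- f$points_mbp[order(abs(f$points_mbp - mid))][seq_len(
          min(5, length(f$points_mbp)))]
        rate[k] <- predict_marey(spline, ch, mean(near) * 1e6, deriv = 1)
      }
    }
    tibble::tibble(pop_id = pop_id, chrom = ch, start = start, end = end,
                   width_mbp = width, rate = pmax(rate, 0), edge = edge)
  }) |>
    structure(class = c("window_rates", class(tibble::tibble())))
}

#' Aggregate window rates to chromosome and genome level
#'
#' Chromosome rate = arithmetic mean of that chromosome's window rates;
#' genome-wide rate = unweighted mean of the chromosome means. `NA` windows
#' are excluded and counted.
#'
#' @param wr A `window_rates` tibble (one or many populations).
#' @return List of tibbles `chromosome` (`pop_id`, `chrom`, `rate`, `n_na`)
#'   and `genome` (`pop_id`, `rate`).
#' @export
aggregate_rates <- function(wr) {
  chromosome <- wr |>
    dplyr::group_by(.data$pop_id, .data$chrom) |>
    dplyr::summarise(n_na = sum(is.na(.data$rate)),
                     rate = mean(.data$rate, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::select("pop_id", "chrom", "rate", "n_na")
  genome <- chromosome |>
    dplyr::group_by(.data$pop_id) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop")
  list(chromosome = chromosome, genome = genome)
}

#' Cross-population mean rate per window
#'
#' @param wr A `window_rates` tibble over populations.
#' @return Tibble `chrom`, `start`, `end`, `rate` (mean across populations).
#' @export
mean_window_rates <- function(wr) {
  wr |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(rate = mean(.data$rate, na.rm = TRUE), .groups = "drop")
}

#' Consensus genetic map from cross-population average window rates
#'
#' Physical distances between adjacent markers are converted to cM using the
#' mean window rate across populations (piecewise-linear cumulative map,
#' integrating the window rates over bp), cumulative from 0 per chromosome.
#'
#' @param wr A `window_rates` tibble over populations.
#' @param markers Marker tibble (`marker`, `chrom`, `pos`).
#' @return Tibble `marker`, `chrom`, `pos`, `cM`.
#' @export
consensus_map <- function(wr, markers) {
  mw <- mean_window_rates(wr)
  markers |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      w <- mw[mw$chrom == key$chrom, ]
      w <- w[order(w$start), ]
      if (nrow(w) == 0) abort(paste("no window rates for", key$chrom))
      cum <- c(0, cumsum(w$rate * (w$end - w$start) / 1e6))
      bounds <- c(w$start, w$end[nrow(w)])
      d <- d[order(d$pos), ]
      cM <- stats::approx(bounds, cum, xout = pmin(pmax(d$pos, bounds[1]),
                                                   bounds[length(bounds)]),
                          rule = 2)$y
      tibble::tibble(marker = d$marker, pos = d$pos, cM = cM)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("marker", "chrom", "pos", "cM")
}

#' Delineate the pericentromeric region of each chromosome
#'
#' The pericentromere is the maximal contiguous run of windows containing
#' the centromere whose mean cross-population rate is at most the
#' genome-wide mean divided by `fold`.
#'
#' @param wr A `window_rates` tibble over populations.
#' @param chrom_spec Chromosome tibble with `centromere_bp`.
#' @param fold Suppression factor (default 20).
#' @return Tibble `chrom`, `start`, `end`, `n_windows`; chromosomes whose
#'   centromere window is above the threshold yield no row (with a warning).
#' @export
pericentromeric_region <- function(wr, chrom_spec, fold = 20) {
  mw <- mean_window_rates(wr)
  agg <- aggregate_rates(dplyr::mutate(mw, pop_id = "consensus"))
  threshold <- agg$genome$rate / fold
  purrr::map_dfr(unique(mw$chrom), function(ch) {
    w <- mw[mw$chrom == ch, ]
    w <- w[order(w$start), ]
    cent <- chrom_spec$centromere_bp[chrom_spec$chrom == ch]
    k <- which(w$start <= cent & cent < w$end)
    if (length(k) != 1)
      abort(paste("centromere position outside window grid on", ch))
    if (w$rate[k] > threshold) {
      warn(paste("centromere window above threshold on", ch,
                 "- empty pericentromere"))
      return(NULL)
    }
    lo <- k; while (lo > 1 && w$rate[lo - 1] <= threshold) lo <- lo - 1
    hi <- k; while (hi < nrow(w) && w$rate[hi + 1] <= threshold) hi <- hi + 1
    tibble::tibble(chrom = ch, start = w$start[lo], end = w$end[hi],
                   n_windows = hi - lo + 1L)
  })
}

#' Fold range of window rates across populations
#'
#' Per window, `fold = max / max(min, floor)` across populations, with the
#' floor guarding near-zero minima; the coefficient of variation is returned
#' alongside. The median fold across windows is attached as attribute
#' `"median_fold"`.
#'
#' @param wr A `window_rates` tibble with >= 2 populations.
#' @param floor Minimum denominator in cM/Mbp.
#' @return Tibble `chrom`, `start`, `end`, `fold`, `floored`, `cv`.
#' @export
window_fold_range <- function(wr, floor = 0.001) {
  if (length(unique(wr$pop_id)) < 2)
    abort("fold range needs >= 2 populations", class = "recombkit_validation")
  out <- wr |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      fold = max(.data$rate, na.rm = TRUE) /
        max(min(.data$rate, na.rm = TRUE), floor),
      floored = min(.data$rate, na.rm = TRUE) < floor,
      cv = sd(.data$rate, na.rm = TRUE) / mean(.data$rate, na.rm = TRUE),
      .groups = "drop")
  attr(out, "median_fold") <- median(out$fold, na.rm = TRUE)
  out
}

#' Shared-allele fraction of two parents per physical window
#'
#' @param founders A `founder_set`.
#' @param parent_i,parent_j Parent ids.
#' @param window_bp Window width in bp.
#' @param min_markers Windows with fewer markers yield `NA`.
#' @return Tibble `chrom`, `start`, `end`, `n_markers`, `similarity`.
#' @export
parental_similarity_windows <- function(founders, parent_i, parent_j,
                                        window_bp = 1e7, min_markers = 5) {
  hp <- founders$haplotypes
  same <- hp[parent_i, ] == hp[parent_j, ]
  founders$markers |>
    dplyr::mutate(same = same[.data$marker],
                  start = floor(.data$pos / window_bp) * window_bp) |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     similarity = ifelse(dplyr::n() >= min_markers,
                                         mean(.data$same), NA_real_),
                     .groups = "drop") |>
    dplyr::mutate(end = .data$start + window_bp) |>
    dplyr::select("chrom", "start", "end", "n_markers", "similarity")
}

#' Correlate parental similarity with recombination rates
#'
#' On a genome basis, per-window values averaged across populations are
#' correlated across windows; on a population basis, per-population values
#' averaged across windows are correlated across populations.
#'
#' @param similarity Tibble from [parental_similarity_windows()] with an
#'   added `pop_id` column (one set of windows per population).
#' @param wr A `window_rates` tibble for the same populations and grid.
#' @param basis `"genome"` or `"population"`.
#' @return Pearson correlation (single number).
#' @export
similarity_rate_correlation <- function(similarity, wr,
                                        basis = c("genome", "population")) {
  basis <- match.arg(basis)
  joined <- dplyr::inner_join(
    similarity, wr,
    by = c("pop_id", "chrom", "start", "end"))
  if (basis == "genome") {
    d <- joined |>
      dplyr::group_by(.data$chrom, .data$start) |>
      dplyr::summarise(similarity = mean(.data$similarity, na.rm = TRUE),
                       rate = mean(.data$rate, na.rm = TRUE), .groups = "drop")
  } else {
    d <- joined |>
      dplyr::group_by(.data$pop_id) |>
      dplyr::summarise(similarity = mean(.data$similarity, na.rm = TRUE),
                       rate = mean(.data$rate, na.rm = TRUE), .groups = "drop")
  }
  cor(d$similarity, d$rate, use = "complete.obs")
}
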