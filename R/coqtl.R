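# Crossover counting per RIL, the histogram-gap outlier rule, and a
# simplified multi-population cross-specific QTL scan with a permutation
# threshold.

count_xo_vector <- function(v) {
  v <- v[!is.na(v) & v != 1] # skip missing and heterozygous calls
  if (length(v) < 2) return(NA_integer_)
  sum(diff(v) != 0)
}

#' Count crossovers per RIL and chromosome
#'
#' A crossover is a transition between opposite homozygous states scanning
#' markers in physical order; missing and heterozygous calls are skipped
#' (a residual heterozygote at S4 is ambiguous between 0 and 1 extra
#' crossover, so the minimal-transition convention is used). Chromosomes
#' with fewer than 2 informative markers yield `NA`.
#'
#' @param geno A cleaned, parental-coded `genotype_table`.
#' @return A `co_counts` tibble: `id`, `pop_id`, `chrom`, `n_co`, plus
#'   `chrom = "genome"` rows with the genome-wide sum.
#' @export
count_crossovers <- function(geno) {
  mk <- geno$markers[order(geno$markers$chrom, geno$markers$pos), ]
  by_chrom <- purrr::map_dfr(unique(mk$chrom), function(ch) {
    cols <- mk$marker[mk$chrom == ch]
    G <- geno$calls[, cols, drop = FALSE]
    tibble::tibble(id = rownames(G), chrom = ch,
                   n_co = unname(apply(G, 1, count_xo_vector)))
  })
  genome <- by_chrom |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(chrom = "genome", n_co = sum(.data$n_co), .groups = "drop")
  out <- dplyr::bind_rows(by_chrom, genome) |>
    dplyr::left_join(geno$individuals, by = "id") |>
    dplyr::select("id", "pop_id", "chrom", "n_co")
  class(out) <- c("co_counts", class(out))
  out
}

#' Flag crossover-count outliers within a population
#'
#' A unit-width integer histogram is built from the minimum count; `K` is
#' the last bin of the first maximal run of consecutive non-empty bins, and
#' any RIL whose count exceeds `K + slack` is flagged.
#'
#' @param counts Numeric vector of per-RIL counts (one population, one
#'   scale), or a `co_counts` tibble, in which case flags are computed per
#'   population for the chosen `chrom` level.
#' @param slack Allowed excess over the last consecutive bin (2 crossovers).
#' @param chrom Count level used when `counts` is a tibble.
#' @param min_n Minimum population size.
#' @return Logical flags (vector input) or the tibble with an `outlier`
#'   column.
#' @export
filter_co_outliers <- function(counts, slack = 2, chrom = "genome",
                               min_n = 5) {
  flag_one <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) < min_n)
      abort(sprintf("need >= %d RILs per population for the outlier rule",
                    min_n), class = "recombkit_validation")
    vals <- x[ok]
    bins <- seq(min(vals), max(vals))
    occupied <- bins %in% vals
    gap <- which(!occupied)
    K <- if (length(gap) == 0) bins[length(bins)] else bins[gap[1] - 1]
    out <- rep(NA, length(x))
    out[ok] <- vals > K + slack
    out
  }
  if (is.numeric(counts)) return(flag_one(counts))
  counts |>
    dplyr::filter(.data$chrom == !!chrom) |>
    dplyr::group_by(.data$pop_id) |>
    dplyr::mutate(outlier = flag_one(.data$n_co)) |>
    dplyr::ungroup()
}

# -log10 p of the cross-specific marker F test at one position, for the
# observed phenotype and all permutations at once (columns of Y).
scan_stat <- function(Y, X0, X1) {
  q0 <- qr(X0); q1 <- qr(X1)
  df1 <- q1$rank - q0$rank
  df2 <- nrow(Y) - q1$rank
  if (df1 < 1 || df2 < 1) return(rep(NA_real_, ncol(Y)))
  tot <- colSums(Y^2)
  rss0 <- tot - colSums(qr.qty(q0, Y)[seq_len(q0$rank), , drop = FALSE]^2)
  rss1 <- tot - colSums(qr.qty(q1, Y)[seq_len(q1$rank), , drop = FALSE]^2)
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  -pf(f, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Multi-population cross-specific QTL scan of crossover counts
#'
#' At each scan position the crossover count is modelled as
#' `CO ~ population + population:dose` with the marker dose taken from the
#' physically nearest marker within each population; the joint F test of the
#' cross-specific dose terms gives `-log10 p`. The genome-wide threshold is
#' the 0.95 quantile of the maximum statistic over within-population
#' phenotype permutations. Positions monomorphic in every population are
#' `NA`.
#'
#' @param counts A `co_counts` tibble (outliers already removed), filtered
#'   to one `chrom` level via `phenotype`.
#' @param geno_list Named list of parental-coded `genotype_table`s keyed by
#'   population.
#' @param positions Tibble `chrom`, `pos` of scan positions.
#' @param phenotype Count level used as phenotype (`"genome"` or a
#'   chromosome name).
#' @param n_perm Number of permutations (1,000 in the full analysis).
#' @param alpha Genome-wide significance level.
#' @param seed Integer seed.
#' @return A `qtl_scan` list: `scan` tibble (`chrom`, `pos`, `stat`,
#'   `significant`), `threshold`, `qtl` (merged significant intervals) and
#'   `perm_max` (null maxima).
#' @export
multipop_qtl_scan <- function(counts, geno_list, positions,
                              phenotype = "genome", n_perm = 1000,
                              alpha = 0.05, seed = 1L) {
  ph <- counts[counts$chrom == phenotype & !is.na(counts$n_co), ]
  ph <- ph[ph$pop_id %in% names(geno_list), ]
  y <- ph$n_co
  pop <- factor(ph$pop_id)
  n <- length(y)
  set.seed(seed)
  # within-population permutations of the phenotype
  idx <- seq_len(n)
  Y <- matrix(0, n, n_perm + 1)
  Y[, 1] <- y
  for (b in seq_len(n_perm)) {
    perm <- unlist(lapply(split(idx, pop), sample), use.names = FALSE)
    ord <- unlist(split(idx, pop), use.names = FALSE)
    Y[ord, b + 1] <- y[perm]
  }
  X0 <- stats::model.matrix(~pop)
  dose_at <- function(ch, p) {
    d <- rep(NA_real_, n)
    for (pid in levels(pop)) {
      g <- geno_list[[pid]]
      mk <- g$markers[g$markers$chrom == ch, ]
      if (nrow(mk) == 0) next
      nearest <- mk$marker[which.min(abs(mk$pos - p))]
      rows <- which(pop == pid)
      v <- g$calls[match(ph$id[rows], rownames(g$calls)), nearest]
      v[is.na(v)] <- mean(v, na.rm = TRUE) # neutral dose for missing calls
      d[rows] <- v
    }
    d
  }
  stats_mat <- matrix(NA_real_, nrow(positions), n_perm + 1)
  for (k in seq_len(nrow(positions))) {
    d <- dose_at(positions$chrom[k], positions$pos[k])
    d[is.na(d)] <- 0
    # per-population dose columns, dropping monomorphic populations
    cols <- lapply(levels(pop), function(pid) {
      v <- ifelse(pop == pid, d, 0)
      if (var(v[pop == pid]) == 0) NULL else v
    })
    cols <- cols[!vapply(cols, is.null, logical(1))]
    if (length(cols) == 0) next
    X1 <- cbind(X0, do.call(cbind, cols))
    stats_mat[k, ] <- scan_stat(Y, X0, X1)
  }
  perm_max <- apply(stats_mat[, -1, drop = FALSE], 2, max, na.rm = TRUE)
  threshold <- quantile(perm_max, 1 - alpha, names = FALSE, type = 7)
  scan <- tibble::tibble(chrom = positions$chrom, pos = positions$pos,
                         stat = stats_mat[, 1],
                         significant = !is.na(stats_mat[, 1]) &
                           stats_mat[, 1] > threshold)
  qtl <- if (!any(scan$significant)) {
    tibble::tibble(chrom = character(), start = numeric(),
                   end = numeric(), peak_stat = numeric())
  } else {
    scan |>
      dplyr::group_by(.data$chrom) |>
      dplyr::arrange(.data$pos, .by_group = TRUE) |>
      dplyr::mutate(run = cumsum(c(1, abs(diff(.data$significant))))) |>
      dplyr::filter(.data$significant) |>
      dplyr::group_by(.data$chrom, .data$run) |>
      dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                       peak_stat = max(.data$stat), .groups = "drop") |>
      dplyr::select(-"run")
  }
  structure(list(scan = scan, threshold = threshold, qtl = qtl,
                 perm_max = perm_max, phenotype = phenotype, alpha = alpha),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("<qtl_scan> %s phenotype, %d positions, threshold %.2f: %d QTL\n",
              x$phenotype, nrow(x$scan), x$threshold, nrow(x$qtl)))
  invisible(x)
}
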