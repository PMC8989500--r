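# Genotype cleaning, segregation distortion scan and anchored linkage maps.

#' Recode a biparental population to parental-origin genotypes
#'
#' Converts allele-count codes to population-local parental-origin codes:
#' 0 = homozygous for the `parent_i` allele, 2 = homozygous for the
#' `parent_j` allele, 1 = heterozygous. Markers where the two parents carry
#' the same allele, or where either parent is heterozygous or missing, are
#' uninformative in this population and are dropped.
#'
#' @param geno A `genotype_table` in allele coding.
#' @param founders A `founder_set` holding the parental haplotypes.
#' @return A `genotype_table` in parental coding.
#' @export
recode_by_parents <- function(geno, founders) {
  if (geno$coding == "parental") return(geno)
  if (is.null(geno$parents))
    abort("genotype table has no recorded parents", class = "recombkit_design")
  hp <- founders$haplotypes
  if (!all(geno$parents %in% rownames(hp)))
    abort("parents not present in founder set", class = "recombkit_design")
  keep_mk <- intersect(geno$markers$marker, colnames(hp))
  gi <- hp[geno$parents[1], keep_mk]
  gj <- hp[geno$parents[2], keep_mk]
  informative <- keep_mk[gi != gj]
  idx <- match(informative, geno$markers$marker)
  calls <- geno$calls[, idx, drop = FALSE]
  # dose of the "2" allele -> dose of the parent_j allele
  flip <- gi[informative] == 2
  calls[, flip] <- 2L - calls[, flip]
  new_genotype_table(calls, geno$individuals, geno$markers[idx, ],
                     coding = "parental", parents = geno$parents,
                     truth_co = geno$truth_co, origins = geno$origins)
}

#' Clean a RIL population's genotypes
#'
#' Filters are applied markers-first, then individuals: markers with a
#' quality score strictly below `quality_min` or with missingness strictly
#' above `marker_missing_max`; then RILs with missingness or residual
#' heterozygosity strictly above their thresholds.
#'
#' @param geno A `genotype_table`.
#' @param quality_min Minimum per-marker quality score retained.
#' @param marker_missing_max Maximum tolerated per-marker missing fraction.
#' @param ril_missing_max,ril_het_max Maximum tolerated per-RIL missing and
#'   heterozygous fractions.
#' @return List with the filtered `genotype_table` (`$geno`) and a
#'   `CleanReport` tibble (`$report`) of removal counts by axis and reason.
#' @export
clean_population <- function(geno, quality_min = 0.7,
                             marker_missing_max = 0.10,
                             ril_missing_max = 0.10, ril_het_max = 0.10) {
  thr <- c(quality_min, marker_missing_max, ril_missing_max, ril_het_max)
  if (any(thr < 0 | thr > 1))
    abort("thresholds must be in [0, 1]", class = "recombkit_validation")
  n_mk0 <- ncol(geno$calls); n_id0 <- nrow(geno$calls)
  low_q <- geno$markers$quality < quality_min
  calls <- geno$calls[, !low_q, drop = FALSE]
  markers <- geno$markers[!low_q, ]
  mk_miss <- colMeans(is.na(calls)) > marker_missing_max
  calls <- calls[, !mk_miss, drop = FALSE]
  markers <- markers[!mk_miss, ]
  if (ncol(calls) == 0) {
    report <- tibble::tibble(
      axis = "marker", reason = c("quality", "missingness"),
      n_removed = c(sum(low_q), sum(mk_miss)))
    abort("all markers removed during cleaning",
          class = "recombkit_empty_population", report = report)
  }
  id_miss <- rowMeans(is.na(calls)) > ril_missing_max
  id_het <- rowMeans(calls == 1, na.rm = TRUE) > ril_het_max
  id_drop <- id_miss | id_het
  report <- tibble::tibble(
    axis = c("marker", "marker", "ril", "ril"),
    reason = c("quality", "missingness", "missingness", "heterozygosity"),
    n_removed = c(sum(low_q), sum(mk_miss), sum(id_miss), sum(id_het & !id_miss)),
    n_input = c(n_mk0, n_mk0, n_id0, n_id0))
  out <- new_genotype_table(
    calls[!id_drop, , drop = FALSE],
    geno$individuals[!id_drop, ], markers, coding = geno$coding,
    parents = geno$parents,
    truth_co = if (!is.null(geno$truth_co))
      geno$truth_co[geno$truth_co$id %in% geno$individuals$id[!id_drop], ]
    else NULL)
  list(geno = out, report = report)
}

#' Scan a biparental population for segregation distortion
#'
#' For every marker, the count of the two parental homozygous classes among
#' non-missing homozygous calls is tested against the Mendelian 1:1
#' expectation with an exact two-sided binomial test. Contiguous significant
#' markers (in physical order per chromosome) are merged into regions.
#'
#' @param geno A cleaned, parental-coded `genotype_table`.
#' @param alpha Per-marker significance level (no multiplicity correction).
#' @return Tibble of regions: `chrom`, `start`, `end`, `favoured_parent`
#'   (1 or 2, the majority-allele parent), `min_p`, `n_markers`. Per-marker
#'   results are attached as attribute `"markers"`.
#' @export
segregation_distortion_scan <- function(geno, alpha = 0.05) {
  n0 <- colSums(geno$calls == 0, na.rm = TRUE)
  n2 <- colSums(geno$calls == 2, na.rm = TRUE)
  n <- n0 + n2
  p <- vapply(seq_along(n), function(k) {
    if (n[k] == 0) return(NA_real_)
    binom.test(n2[k], n[k], p = 0.5)$p.value
  }, numeric(1))
  mk <- geno$markers |>
    dplyr::mutate(n0 = n0, n2 = n2, p_value = p,
                  flagged = !is.na(p) & p < alpha)
  n_skip <- sum(n == 0)
  if (n_skip > 0)
    inform(sprintf(
      "segregation scan: %d marker(s) without homozygous calls skipped",
      n_skip))
  regions <- mk |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(c(1, abs(diff(.data$flagged))))) |>
    dplyr::filter(.data$flagged) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos),
      favoured_parent = ifelse(sum(.data$n2) > sum(.data$n0), 2L, 1L),
      min_p = min(.data$p_value), n_markers = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"run")
  attr(regions, "markers") <- mk
  regions
}

#' Recombination fractions between adjacent markers
#'
#' The observed recombinant fraction `R` between physically adjacent markers
#' is computed on fully informative RIL pairs (both calls homozygous) and
#' converted to the per-meiosis recombination fraction by inverting the
#' selfing-RIL map expansion `R = 2r / (1 + 2r)`, i.e. `r = R / (2 - 2R)`,
#' clamped to `[0, 0.5)`.
#'
#' @param geno A parental-coded `genotype_table`.
#' @param chromosome Optional chromosome name; default all.
#' @param min_informative Pairs with fewer informative RILs get `r = NA`.
#' @return Tibble: `chrom`, `marker_left`, `marker_right`, `pos_left`,
#'   `pos_right`, `n_informative`, `R_obs`, `r`.
#' @export
pairwise_recombination_fraction <- function(geno, chromosome = NULL,
                                            min_informative = 10) {
  mk <- geno$markers
  if (!is.null(chromosome)) mk <- mk[mk$chrom %in% chromosome, ]
  out <- mk |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(d, key) {
      d <- d[order(d$pos), ]
      m <- nrow(d)
      if (m < 2) return(NULL)
      G <- geno$calls[, d$marker, drop = FALSE]
      L <- G[, -m, drop = FALSE]
      Rm <- G[, -1, drop = FALSE]
      inf <- !is.na(L) & !is.na(Rm) & L != 1 & Rm != 1
      n_inf <- colSums(inf)
      n_rec <- colSums(inf & L != Rm)
      R_obs <- ifelse(n_inf > 0, n_rec / n_inf, NA_real_)
      r <- pmin(pmax(R_obs / (2 - 2 * R_obs), 0), 0.5 - 1e-9)
      r[n_inf < min_informative] <- NA_real_
      tibble::tibble(chrom = key$chrom,
                     marker_left = d$marker[-m], marker_right = d$marker[-1],
                     pos_left = d$pos[-m], pos_right = d$pos[-1],
                     n_informative = unname(n_inf),
                     R_obs = unname(R_obs), r = unname(r))
    }) |>
    dplyr::bind_rows()
  n_na <- sum(is.na(out$r))
  if (n_na > 0)
    warn(sprintf("%d adjacent pair(s) with < %d informative RILs set to NA",
                 n_na, min_informative))
  out
}

haldane_cM <- function(r) -50 * log(1 - 2 * r)
kosambi_cM <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

#' Build an anchored linkage map for one population
#'
#' Marker order is anchored to the physical map; cosegregating adjacent
#' markers (`r = 0`) are collapsed into bins and cumulative genetic
#' positions follow the chosen map function (Haldane by default,
#' `d = -50 ln(1 - 2r)` cM). Adjacent pairs with too few informative RILs
#' are chained through the nearest informative neighbour: the gap distance is
#' computed between the flanking markers that do have enough informative
#' pairs and distributed over the intervening intervals proportionally to
#' physical length. If no informative chain exists, an error lists the gap.
#'
#' @param geno A cleaned, parental-coded `genotype_table`.
#' @param map_function `"haldane"` or `"kosambi"`.
#' @param min_informative Minimum informative RILs per pair.
#' @param max_chain Maximum number of markers skipped when chaining.
#' @return Tibble: `chrom`, `bin`, `cM`, `anchor_bp`, `n_markers`,
#'   `markers` (list column of member marker ids).
#' @export
build_linkage_map <- function(geno, map_function = c("haldane", "kosambi"),
                              min_informative = 10, max_chain = 10) {
  map_function <- match.arg(map_function)
  mf <- if (map_function == "haldane") haldane_cM else kosambi_cM
  pair_r <- function(a, b) {
    inf <- !is.na(a) & !is.na(b) & a != 1 & b != 1
    n <- sum(inf)
    if (n < min_informative) return(NA_real_)
    R_obs <- sum(a[inf] != b[inf]) / n
    pmin(pmax(R_obs / (2 - 2 * R_obs), 0), 0.5 - 1e-9)
  }
  purrr::map_dfr(unique(geno$markers$chrom), function(ch) {
    d <- geno$markers[geno$markers$chrom == ch, ]
    d <- d[order(d$pos), ]
    m <- nrow(d)
    if (m < 2)
      return(tibble::tibble(chrom = ch, bin = 1L, cM = 0,
                            anchor_bp = d$pos, n_markers = 1L,
                            markers = list(d$marker)))
    G <- geno$calls[, d$marker, drop = FALSE]
    # vectorized adjacent-pair recombination fractions
    L <- G[, -m, drop = FALSE]; Rm <- G[, -1, drop = FALSE]
    inf <- !is.na(L) & !is.na(Rm) & L != 1 & Rm != 1
    n_inf <- colSums(inf)
    R_obs <- colSums(inf & L != Rm) / pmax(n_inf, 1)
    r_adj <- pmin(pmax(R_obs / (2 - 2 * R_obs), 0), 0.5 - 1e-9)
    r_adj[n_inf < min_informative] <- NA_real_
    gap <- numeric(m - 1) # cM between consecutive markers
    i <- 1L
    while (i < m) {
      r <- r_adj[i]
      if (!is.na(r)) {
        gap[i] <- mf(r)
        i <- i + 1L
      } else {
        j <- i + 2L
        r_span <- NA_real_
        while (j <= min(m, i + max_chain)) {
          r_span <- pair_r(G[, i], G[, j])
          if (!is.na(r_span)) break
          j <- j + 1L
        }
        if (is.na(r_span))
          abort(sprintf(
            "chromosome %s disconnects after %s (bp %.0f): no informative pair",
            ch, d$marker[i], d$pos[i]), class = "recombkit_map_gap")
        w <- diff(d$pos[i:j]); w <- w / sum(w)
        gap[i:(j - 1)] <- mf(r_span) * w
        i <- j
      }
    }
    cM <- c(0, cumsum(gap))
    bin_id <- cumsum(c(1, gap > 0))
    tibble::tibble(chrom = ch, marker = d$marker, pos = d$pos,
                   cM = cM, bin = bin_id) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(chrom = ch, cM = .data$cM[1],
                       anchor_bp = mean(.data$pos),
                       n_markers = dplyr::n(),
                       markers = list(.data$marker), .groups = "drop") |>
      dplyr::select("chrom", "bin", "cM", "anchor_bp", "n_markers", "markers")
  })
}
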