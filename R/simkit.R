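# Synthetic double round-robin (DRR) experiment generator with known
# general/specific recombination effect (GRE/SRE) ground truth.

seed_stream <- function(master, k) {
  # deterministic per-population seed below 2^31
  as.integer((as.numeric(master) + 7919 * as.numeric(k)) %% 2147483629L)
}

#' Chromosome layout preset for a barley-like genome
#'
#' Seven metacentric chromosomes of equal physical length with the centromere
#' at the midpoint. Chromosome sizes in barley range roughly 560-770 Mbp; a
#' common 600 Mbp length keeps window grids aligned across chromosomes.
#'
#' @param n_chrom Number of chromosomes.
#' @param length_bp Physical length of each chromosome in bp.
#' @param centromere_frac Centromere position as a fraction of the length.
#' @return A tibble with columns `chrom`, `length_bp`, `centromere_bp`.
#' @export
barley_chrom_spec <- function(n_chrom = 7, length_bp = 600e6,
                              centromere_frac = 0.5) {
  tibble::tibble(
    chrom = paste0(seq_len(n_chrom), "H"),
    length_bp = rep(length_bp, n_chrom)[seq_len(n_chrom)],
    centromere_bp = round(length_bp * centromere_frac)
  )
}

new_genotype_table <- function(calls, individuals, markers,
                               coding = c("allele", "parental"),
                               parents = NULL, truth_co = NULL,
                               origins = NULL) {
  coding <- match.arg(coding)
  stopifnot(is.matrix(calls), nrow(calls) == nrow(individuals),
            ncol(calls) == nrow(markers))
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
    abort("genotype calls must be coded 0/1/2/NA", class = "recombkit_validation")
  dimnames(calls) <- list(individuals$id, markers$marker)
  structure(
    list(calls = calls, individuals = individuals, markers = markers,
         coding = coding, parents = parents, truth_co = truth_co,
         origins = origins),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d markers (%s coding)\n",
              nrow(x$calls), ncol(x$calls), x$coding))
  if (!is.null(x$parents))
    cat("  cross:", x$parents[1], "x", x$parents[2], "\n")
  pops <- unique(x$individuals$pop_id)
  cat("  populations:", paste(head(pops, 6), collapse = ", "),
      if (length(pops) > 6) "..." else "", "\n")
  invisible(x)
}

#' Generate a panel of fully homozygous founder inbreds
#'
#' Founders carry biallelic markers on a regular physical grid (positions
#' `0, s, 2s, ...` up to and including the chromosome end). Alleles (coded
#' 0 or 2) are drawn independently per founder and marker with frequency 1/2,
#' so nearly all markers segregate in the panel.
#'
#' @param n_parents Number of founder inbreds (>= 2).
#' @param chrom_spec Tibble as from [barley_chrom_spec()].
#' @param marker_spacing Distance between adjacent markers in bp.
#' @param seed Integer seed.
#' @return A `founder_set`: list with `haplotypes` (parents x markers matrix
#'   of 0/2), `markers` (tibble: marker, chrom, pos) and `chrom`.
#' @export
generate_founders <- function(n_parents, chrom_spec, marker_spacing, seed = 1L) {
  if (n_parents < 2) abort("need at least 2 parents", class = "recombkit_config")
  if (any(chrom_spec$length_bp <= 0))
    abort("chromosome lengths must be > 0", class = "recombkit_config")
  if (marker_spacing <= 0) abort("marker_spacing must be > 0",
                                 class = "recombkit_config")
  if (any(marker_spacing >= chrom_spec$length_bp))
    abort("marker_spacing must be smaller than every chromosome",
          class = "recombkit_too_few_markers")
  set.seed(seed)
  markers <- purrr::pmap_dfr(chrom_spec, function(chrom, length_bp, centromere_bp) {
    pos <- seq(0, length_bp, by = marker_spacing)
    tibble::tibble(
      marker = sprintf("%s_%010.0f", chrom, pos),
      chrom = chrom, pos = pos)
  })
  ids <- sprintf("P%02d", seq_len(n_parents))
  hap <- matrix(2L * rbinom(n_parents * nrow(markers), 1L, 0.5),
                nrow = n_parents,
                dimnames = list(ids, markers$marker))
  structure(list(haplotypes = hap, markers = markers, chrom = chrom_spec),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf("<founder_set> %d parents, %d chromosomes, %d markers\n",
              nrow(x$haplotypes), nrow(x$chrom), nrow(x$markers)))
  invisible(x)
}

#' Build a (double) round-robin crossing design
#'
#' In the single-ring layout each parent is crossed to its next ring
#' neighbour (`n` crosses). The double layout adds the second ring
#' neighbours (`2n` crosses). The 23-parent study layout keeps 45 of the 46
#' double-ring crosses (the last second-ring cross is omitted), which is the
#' default cap when `n_parents == 23`.
#'
#' @param founders A `founder_set`.
#' @param n_rils_range Integer range `(min, max)` for population sizes.
#' @param layout `"double"` or `"single"` ring.
#' @param max_crosses Keep only the first `max_crosses` crosses.
#' @param seed Integer seed (draws the population sizes).
#' @return A tibble with columns `parent_i`, `parent_j`, `pop_id`, `n_rils`.
#' @export
simulate_drr_design <- function(founders, n_rils_range = c(35, 146),
                                layout = c("double", "single"),
                                max_crosses = NULL, seed = 1L) {
  layout <- match.arg(layout)
  ids <- rownames(founders$haplotypes)
  n <- length(ids)
  if (n < 3) abort("a round-robin design needs >= 3 parents",
                   class = "recombkit_design")
  ring1 <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  pairs <- ring1
  if (layout == "double") {
    ring2 <- cbind(seq_len(n), c(seq_len(n)[-(1:2)], 1L, 2L))
    pairs <- rbind(ring1, ring2)
  }
  if (is.null(max_crosses))
    max_crosses <- if (layout == "double" && n == 23) 45L else nrow(pairs)
  pairs <- pairs[seq_len(min(max_crosses, nrow(pairs))), , drop = FALSE]
  set.seed(seed)
  sizes <- seq(n_rils_range[1], n_rils_range[2])
  n_rils <- sizes[sample.int(length(sizes), nrow(pairs), replace = TRUE)]
  tibble::tibble(
    parent_i = ids[pairs[, 1]],
    parent_j = ids[pairs[, 2]],
    pop_id = sprintf("POP%02d", seq_len(nrow(pairs))),
    n_rils = as.integer(n_rils))
}

#' Ground-truth recombination model for a DRR simulation
#'
#' The per-cross landscape is multiplicative on a shared baseline:
#' `L_ij(w) = L0(w) * exp(g_i + g_j + s_ij)`, with log-scale per-parent
#' effects `g` and per-cross effects `s ~ N(0, tau2_s)`. By default the
#' per-parent effects are polygenic -- a sum of small independent effects of
#' all founder marker alleles, scaled to variance `tau2_g` across parents --
#' so that general recombination effects are tagged by genome-wide SNPs and
#' genomic prediction of untested parents is possible, as the recombination
#' machinery's allelic variation implies; `gre_basis = "iid"` draws them
#' independently of the genotypes instead. Both `g` and `s` are rescaled so
#' their realized variances match `tau2_g` and `tau2_s` exactly, making the
#' simulated variance ratio a controlled condition rather than a draw.
#' The barley-like baseline is U-shaped along each chromosome
#' (`shape = d^shape_power + shape_floor` with `d` the relative distance from
#' the centromere), scaled so the genome-wide mean rate equals `mean_rate`;
#' the pericentromeric windows then sit more than 20-fold below the genome
#' mean. The default `tau2_g` is calibrated so that the variance of the
#' cross-level GRE contribution on the rate scale,
#' `mean_rate^2 * tau2_g`, is about 0.0023 (cM/Mbp)^2, with an 8:1 GRE:SRE
#' variance ratio.
#'
#' @param founders A `founder_set`.
#' @param design Crossing design tibble (see [simulate_drr_design()]).
#' @param window_bp Landscape window width in bp.
#' @param mean_rate Genome-wide mean recombination rate of the baseline
#'   (cM/Mbp).
#' @param tau2_g,tau2_s Log-scale variances of GRE and SRE.
#' @param shape_power,shape_floor Baseline U-shape parameters.
#' @param gre_basis `"markers"` (polygenic, default) or `"iid"`.
#' @param seed Integer seed (draws `g` and `s`).
#' @return A `recomb_truth`: baseline window tibble, `gre` and `sre` tibbles,
#'   and the variance parameters.
#' @export
true_recomb_model <- function(founders, design, window_bp = 1e7,
                              mean_rate = 0.45, tau2_g = 0.0113,
                              tau2_s = tau2_g / 8, shape_power = 3.5,
                              shape_floor = 0.002,
                              gre_basis = c("markers", "iid"), seed = 1L) {
  gre_basis <- match.arg(gre_basis)
  cs <- founders$chrom
  baseline <- purrr::pmap_dfr(cs, function(chrom, length_bp, centromere_bp) {
    start <- seq(0, length_bp - 1, by = window_bp)
    end <- pmin(start + window_bp, length_bp)
    mid <- (start + end) / 2
    d <- abs(mid - centromere_bp) / max(centromere_bp, length_bp - centromere_bp)
    tibble::tibble(chrom = chrom, start = start, end = end,
                   shape = d^shape_power + shape_floor)
  })
  chrom_mean <- baseline |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(m = mean(.data$shape), .groups = "drop")
  scale <- mean_rate / mean(chrom_mean$m)
  baseline$rate <- baseline$shape * scale
  baseline$shape <- NULL
  set.seed(seed)
  parents <- rownames(founders$haplotypes)
  rescale <- function(x, v) {
    if (v == 0 || sd(x) == 0) return(rep(0, length(x)))
    (x - mean(x)) * sqrt(v) / sd(x)
  }
  if (gre_basis == "markers") {
    W <- scale(founders$haplotypes, center = TRUE, scale = FALSE)
    g <- drop(W %*% rnorm(ncol(W))) # uniform polygenic marker effects
  } else {
    g <- rnorm(length(parents))
  }
  gre <- tibble::tibble(parent = parents, g = rescale(g, tau2_g))
  sre <- design |>
    dplyr::select("pop_id", "parent_i", "parent_j") |>
    dplyr::mutate(s = rescale(rnorm(dplyr::n()), tau2_s))
  structure(list(baseline = baseline, gre = gre, sre = sre,
                 tau2_g = tau2_g, tau2_s = tau2_s, window_bp = window_bp),
            class = "recomb_truth")
}

#' @export
print.recomb_truth <- function(x, ...) {
  cat(sprintf(
    "<recomb_truth> %d windows, %d parents, %d crosses; tau2_g/tau2_s = %.3g\n",
    nrow(x$baseline), nrow(x$gre), nrow(x$sre), x$tau2_g / x$tau2_s))
  invisible(x)
}

#' Per-cross recombination landscape implied by the ground truth
#'
#' @param truth A `recomb_truth`.
#' @param pop_id Population id present in the truth's cross table.
#' @return The baseline window tibble with `rate` scaled by
#'   `exp(g_i + g_j + s_ij)`.
#' @export
cross_landscape <- function(truth, pop_id) {
  cr <- truth$sre[truth$sre$pop_id == pop_id, ]
  if (nrow(cr) != 1) abort(paste("unknown population:", pop_id),
                           class = "recombkit_design")
  g <- setNames(truth$gre$g, truth$gre$parent)
  mult <- exp(g[[cr$parent_i]] + g[[cr$parent_j]] + cr$s)
  out <- truth$baseline
  out$rate <- out$rate * mult
  out
}

#' True genome-wide recombination rate per cross
#'
#' Genome-wide rate of a cross = mean over chromosomes of the mean window
#' rate of its true landscape (same aggregation as the estimation side).
#'
#' @param truth A `recomb_truth`.
#' @return Tibble with `pop_id`, `g_sum` (`g_i + g_j + s_ij`) and `rate`.
#' @export
true_genome_rates <- function(truth) {
  g <- setNames(truth$gre$g, truth$gre$parent)
  base_genome <- truth$baseline |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(m = mean(.data$rate), .groups = "drop")
  base_rate <- mean(base_genome$m)
  truth$sre |>
    dplyr::mutate(g_sum = g[.data$parent_i] + g[.data$parent_j] + .data$s,
                  rate = base_rate * exp(.data$g_sum)) |>
    dplyr::select("pop_id", "g_sum", "rate")
}

#' Simulate one RIL population of a cross to generation S(n)
#'
#' Meiosis follows the Haldane (no-interference) model: the crossover count
#' of each gamete is Poisson with mean equal to the cross landscape's genetic
#' length in Morgans, and crossover positions are sampled proportionally to
#' the landscape. Lines descend by single-seed descent: the F1 is selfed to
#' give an F2 plant, which is selfed `generations - 1` further times
#' (`generations = 5` corresponds to S4, residual heterozygosity
#' `0.5^5` per locus). The true number of observable crossovers per RIL and
#' chromosome (transitions between opposite homozygous origin states at
#' marker resolution) is recorded in `$truth_co`.
#'
#' @param cross One row of a crossing design tibble.
#' @param founders A `founder_set`.
#' @param truth A `recomb_truth` whose windows cover all chromosomes.
#' @param generations Number of meiosis rounds from the F1 (>= 1).
#' @param obligate_co If `TRUE`, every gamete receives at least one
#'   crossover per chromosome (`max(1, draw)`).
#' @param seed Integer seed.
#' @param keep_origins Keep the founder-origin matrices (for breakpoint
#'   oracles); off by default to save memory.
#' @return A `genotype_table` in allele coding (0/1/2 counts of the "2"
#'   allele), with per-marker `quality = 1`.
#' @export
simulate_population <- function(cross, founders, truth, generations = 5,
                                obligate_co = FALSE, seed = 1L,
                                keep_origins = FALSE) {
  stopifnot(generations >= 1)
  ids <- rownames(founders$haplotypes)
  if (!(cross$parent_i %in% ids) || !(cross$parent_j %in% ids))
    abort("cross references unknown parent", class = "recombkit_design")
  land <- cross_landscape(truth, cross$pop_id)
  set.seed(seed)
  n <- cross$n_rils
  ril_ids <- sprintf("%s_R%03d", cross$pop_id, seq_len(n))
  chroms <- founders$chrom$chrom
  calls <- matrix(NA_integer_, n, nrow(founders$markers))
  truth_co <- vector("list", length(chroms))
  origins <- if (keep_origins) vector("list", length(chroms)) else NULL
  if (keep_origins) names(origins) <- chroms
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    mk <- which(founders$markers$chrom == ch)
    pos <- founders$markers$pos[mk]
    lw <- land[land$chrom == ch, ]
    if (nrow(lw) == 0 || max(lw$end) < max(pos))
      abort("truth windows do not cover all chromosomes",
            class = "recombkit_config")
    bounds <- c(lw$start, lw$end[nrow(lw)])
    cum_cM <- c(0, cumsum(lw$rate * (lw$end - lw$start) / 1e6))
    sim <- .sim_ril_chromosome(n, as.integer(generations), pos, bounds,
                               cum_cM, obligate_co)
    hi <- founders$haplotypes[cross$parent_i, mk] / 2 # 0/1 dose of allele "2"
    hj <- founders$haplotypes[cross$parent_j, mk] / 2
    S <- sim$origin1 + sim$origin2 # copies inherited from parent_j
    Mi <- matrix(hi, n, length(mk), byrow = TRUE)
    Mj <- matrix(hj, n, length(mk), byrow = TRUE)
    calls[, mk] <- as.integer(S * Mj + (2 - S) * Mi)
    truth_co[[k]] <- tibble::tibble(id = ril_ids, chrom = ch,
                                    n_co = as.integer(sim$true_co))
    if (keep_origins)
      origins[[ch]] <- list(origin1 = sim$origin1, origin2 = sim$origin2,
                            pos = pos)
  }
  markers <- founders$markers
  markers$quality <- 1
  new_genotype_table(
    calls,
    individuals = tibble::tibble(id = ril_ids, pop_id = cross$pop_id),
    markers = markers, coding = "allele",
    parents = c(cross$parent_i, cross$parent_j),
    truth_co = dplyr::bind_rows(truth_co),
    origins = origins)
}

#' Simulate all populations of a crossing design
#'
#' Population-level seeds are derived deterministically from the master seed
#' and the population index, so individual populations are reproducible in
#' isolation.
#'
#' @inheritParams simulate_population
#' @param design Crossing design tibble.
#' @param seed Master seed.
#' @param ... Passed to [simulate_population()].
#' @return Named list of `genotype_table`s, one per population.
#' @export
simulate_drr_genotypes <- function(founders, design, truth, generations = 5,
                                   seed = 1L, ...) {
  out <- vector("list", nrow(design))
  names(out) <- design$pop_id
  for (k in seq_len(nrow(design))) {
    out[[k]] <- simulate_population(design[k, ], founders, truth,
                                    generations = generations,
                                    seed = seed_stream(seed, k), ...)
  }
  out
}

#' Add missing calls and per-marker quality scores to a genotype table
#'
#' Emulates assay artefacts so that downstream quality filters have
#' something to act on. The input table is not modified.
#'
#' @param geno A `genotype_table`.
#' @param missing_rate Fraction of calls set to `NA`.
#' @param quality_dist Function of `n` returning `n` scores in `[0, 1]`;
#'   the default concentrates mass near 1 (mean about 0.93).
#' @param seed Integer seed.
#' @return A new `genotype_table`.
#' @export
inject_assay_noise <- function(geno, missing_rate = 0.02,
                               quality_dist = function(n) rbeta(n, 40, 3),
                               seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1)
    abort("missing_rate must be in [0, 1]", class = "recombkit_validation")
  set.seed(seed)
  calls <- geno$calls
  if (missing_rate > 0) {
    drop <- runif(length(calls)) < missing_rate
    calls[drop] <- NA_integer_
  }
  markers <- geno$markers
  markers$quality <- pmin(pmax(quality_dist(nrow(markers)), 0), 1)
  new_genotype_table(calls, geno$individuals, markers, coding = geno$coding,
                     parents = geno$parents, truth_co = geno$truth_co,
                     origins = geno$origins)
}
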