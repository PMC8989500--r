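# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default run stays fast.

tiny_chrom_spec <- function(n_chrom = 2, length_bp = 100e6) {
  barley_chrom_spec(n_chrom = n_chrom, length_bp = length_bp)
}

# founders whose two first parents are fully complementary: every marker is
# informative in a P01 x P02 cross, which makes crossover counting exact
complementary_founders <- function(chrom_spec = tiny_chrom_spec(),
                                   spacing = 1e6, n_parents = 2, seed = 1) {
  f <- generate_founders(max(n_parents, 2), chrom_spec, spacing, seed = seed)
  f$haplotypes[1, ] <- 0L
  f$haplotypes[2, ] <- 2L
  f
}

# a flat landscape of the given rate (cM/Mbp) with no GRE/SRE variation
flat_truth <- function(founders, design, rate = 1, window_bp = 1e7) {
  tr <- true_recomb_model(founders, design, window_bp = window_bp,
                          mean_rate = rate, tau2_g = 0, tau2_s = 0,
                          seed = 1)
  tr$baseline$rate <- rate
  tr
}

linkmap_from <- function(cM, bp = NULL, chrom = "1A") {
  if (is.null(bp)) bp <- seq_along(cM) * 1e6
  tibble::tibble(chrom = chrom, bin = seq_along(cM), cM = cM,
                 anchor_bp = bp, n_markers = 1L,
                 markers = as.list(sprintf("m%02d", seq_along(cM))))
}

single_cross_design <- function(n_rils) {
  tibble::tibble(parent_i = "P01", parent_j = "P02", pop_id = "POP01",
                 n_rils = as.integer(n_rils))
}

# small multi-population experiment reused across test files (lazy cache)
.small_exp_cache <- new.env()
small_experiment <- function() {
  if (is.null(.small_exp_cache$ex)) {
    .small_exp_cache$ex <- simulate_drr_experiment(
      n_parents = 10, chrom_spec = tiny_chrom_spec(2, 150e6),
      marker_spacing = 1e6, n_rils = 80, seed = 401)
  }
  .small_exp_cache$ex
}
small_experiment_rates <- function() {
  if (is.null(.small_exp_cache$wr)) {
    ex <- small_experiment()
    .small_exp_cache$wr <- estimate_window_rates(ex$genotypes, ex$founders)
  }
  .small_exp_cache$wr
}
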