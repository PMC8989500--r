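# End-to-end drivers: simulate a DRR experiment, estimate window rates for
# every population, and run replicate parameter-recovery studies.

#' Simulate a complete DRR experiment
#'
#' Bundles founder generation, design construction, ground-truth drawing and
#' population simulation with one master seed. The defaults reproduce the
#' study-scale preset: 23 parents, 45 double round-robin crosses, seven
#' 600 Mbp chromosomes, S4 RILs.
#'
#' @param n_parents Number of founder inbreds.
#' @param chrom_spec Chromosome tibble (default [barley_chrom_spec()]).
#' @param marker_spacing Marker grid spacing in bp.
#' @param n_rils_range Population size range.
#' @param n_rils Optional fixed population size (overrides the range).
#' @param tau2_g,tau2_s GRE/SRE log-scale variances (see
#'   [true_recomb_model()]).
#' @param mean_rate Genome-wide mean baseline rate (cM/Mbp).
#' @param generations Meiosis rounds from the F1 (5 = S4).
#' @param seed Master seed.
#' @param ... Passed to [simulate_population()].
#' @return List: `founders`, `design`, `truth`, `genotypes` (list of
#'   `genotype_table`s).
#' @export
simulate_drr_experiment <- function(n_parents = 23,
                                    chrom_spec = barley_chrom_spec(),
                                    marker_spacing = 4e5,
                                    n_rils_range = c(35, 146),
                                    n_rils = NULL,
                                    tau2_g = 0.0113, tau2_s = tau2_g / 8,
                                    mean_rate = 0.45,
                                    generations = 5, seed = 1L, ...) {
  founders <- generate_founders(n_parents, chrom_spec, marker_spacing,
                                seed = seed_stream(seed, 1))
  design <- simulate_drr_design(founders, n_rils_range = n_rils_range,
                                seed = seed_stream(seed, 2))
  if (!is.null(n_rils)) design$n_rils <- as.integer(n_rils)
  truth <- true_recomb_model(founders, design, tau2_g = tau2_g,
                             tau2_s = tau2_s, mean_rate = mean_rate,
                             seed = seed_stream(seed, 3))
  genotypes <- simulate_drr_genotypes(founders, design, truth,
                                      generations = generations,
                                      seed = seed_stream(seed, 4), ...)
  list(founders = founders, design = design, truth = truth,
       genotypes = genotypes)
}

#' Window recombination rates for every population of an experiment
#'
#' Chains, per population: parental-origin recoding, cleaning, anchored
#' linkage map, Marey-map assembly, monotone spline fit and windowed rates.
#'
#' @param genotypes Named list of `genotype_table`s (allele or parental
#'   coding).
#' @param founders The `founder_set` (for recoding and chromosome lengths).
#' @param window_bp Window width in bp.
#' @param tolerance_cm Marey monotonicity tolerance in cM.
#' @param map_function Map function for the linkage maps.
#' @param quality_min,marker_missing_max,ril_missing_max,ril_het_max
#'   Cleaning thresholds (see [clean_population()]).
#' @return A `window_rates` tibble over all populations.
#' @export
estimate_window_rates <- function(genotypes, founders, window_bp = 1e7,
                                  tolerance_cm = 2,
                                  map_function = "haldane",
                                  quality_min = 0.7,
                                  marker_missing_max = 0.10,
                                  ril_missing_max = 0.10,
                                  ril_het_max = 0.10) {
  purrr::imap_dfr(genotypes, function(geno, pop_id) {
    geno <- recode_by_parents(geno, founders)
    geno <- clean_population(geno, quality_min = quality_min,
                             marker_missing_max = marker_missing_max,
                             ril_missing_max = ril_missing_max,
                             ril_het_max = ril_het_max)$geno
    lm <- build_linkage_map(geno, map_function = map_function)
    marey <- assemble_marey(lm, tolerance_cm = tolerance_cm)
    spl <- fit_marey_spline(marey)
    window_recombination_rates(spl, founders$chrom, window_bp = window_bp,
                               pop_id = pop_id)
  })
}

#' Genome-wide rates per population
#'
#' @param wr A `window_rates` tibble.
#' @return Tibble `pop_id`, `rate` (mean of chromosome means).
#' @export
genome_rates <- function(wr) aggregate_rates(wr)$genome

#' Replicate parameter recovery of the GRE:SRE variance ratio
#'
#' Repeats the whole chain -- simulate a DRR experiment with a known
#' `tau2_g : tau2_s` ratio, estimate genome-wide rates through the Marey
#' pipeline, fit the identity-mode GRE/SRE model -- and records the
#' estimated variance ratio per replicate.
#'
#' @param n_replicates Number of independent replicate experiments.
#' @param seed Master seed.
#' @param n_rils RILs per population (fixed across populations).
#' @param marker_spacing Marker grid spacing in bp.
#' @param ... Passed to [simulate_drr_experiment()].
#' @return Tibble `replicate`, `sigma2_a`, `sigma2_d`, `ratio`.
#' @export
gre_sre_recovery <- function(n_replicates = 20, seed = 1L, n_rils = 100,
                             marker_spacing = 4e5, ...) {
  purrr::map_dfr(seq_len(n_replicates), function(k) {
    ex <- simulate_drr_experiment(n_rils = n_rils,
                                  marker_spacing = marker_spacing,
                                  seed = seed_stream(seed, 100 + k), ...)
    wr <- estimate_window_rates(ex$genotypes, ex$founders)
    fit <- fit_gre_sre(genome_rates(wr), ex$design)
    tibble::tibble(replicate = k, sigma2_a = fit$vc$sigma2_a,
                   sigma2_d = fit$vc$sigma2_d,
                   ratio = gre_sre_variance_ratio(fit))
  })
}
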