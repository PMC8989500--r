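test_that("Marey assembly tolerates 2 cM diversions and removes larger ones", {
  keep_all <- assemble_marey(linkmap_from(c(0, 5, 3, 10)), min_points = 3)
  expect_true(all(keep_all$kept)) # diversion exactly 2 is tolerated
  drop_one <- assemble_marey(linkmap_from(c(0, 5, 1, 10)), min_points = 3)
  expect_equal(sum(drop_one$kept), 3)
  expect_equal(drop_one$kept, c(TRUE, TRUE, FALSE, TRUE)) # diversion 4
  mono <- assemble_marey(linkmap_from(c(0, 2, 4, 9)), min_points = 3)
  expect_true(all(mono$kept))
  expect_error(assemble_marey(linkmap_from(c(0, 50, 3, 4))),
               class = "recombkit_spline_infeasible")
})

test_that("the Marey spline reproduces linear and constant maps", {
  bp <- seq(0, 100e6, by = 5e6)
  line <- assemble_marey(linkmap_from(0.5 * bp / 1e6, bp = bp))
  sp <- fit_marey_spline(line)
  grid <- seq(5e6, 95e6, by = 5e6)
  expect_equal(predict_marey(sp, "1A", grid, deriv = 1),
               rep(0.5, length(grid)), tolerance = 1e-6)
  flat <- linkmap_from(rep(1, 21), bp = bp)
  flat$cM <- rep(0, 21)
  sp0 <- fit_marey_spline(assemble_marey(flat))
  expect_equal(predict_marey(sp0, "1A", grid, deriv = 1),
               rep(0, length(grid)), tolerance = 1e-6)
})

test_that("the spline tracks a noisy sigmoid Marey curve within 2 cM RMS", {
  set.seed(5)
  n <- 250
  bp <- sort(runif(n, 0, 200e6))
  truth <- 150 * stats::plogis((bp - 100e6) / 25e6)
  noisy <- truth + rnorm(n, 0, 1.5)
  mm <- assemble_marey(linkmap_from(noisy, bp = bp))
  sp <- fit_marey_spline(mm)
  fitted <- predict_marey(sp, "1A", bp)
  expect_lt(sd(fitted - truth), 2)
})

test_that("window rates follow the grid arithmetic and the edge rule", {
  bp <- seq(0, 95e6, by = 2.5e6)
  sp <- fit_marey_spline(assemble_marey(linkmap_from(0.5 * bp / 1e6,
                                                     bp = bp)))
  cs <- tibble::tibble(chrom = "1A", length_bp = 95e6, centromere_bp = 45e6)
  wr <- window_recombination_rates(sp, cs)
  expect_equal(nrow(wr), 10)
  expect_equal(wr$width_mbp, c(rep(10, 9), 5))
  expect_equal(wr$rate, rep(0.5, 10), tolerance = 1e-6)
  expect_true(all(wr$rate >= 0))
  # an extreme window with no points uses the derivative at the mean of the
  # five nearest points
  bp2 <- seq(30e6, 95e6, by = 2.5e6)
  sp2 <- fit_marey_spline(assemble_marey(linkmap_from(0.5 * bp2 / 1e6,
                                                      bp = bp2)))
  wr2 <- window_recombination_rates(sp2, cs)
  expect_true(all(wr2$edge[1:3]))
  expect_equal(wr2$rate[1:3], rep(0.5, 3), tolerance = 1e-6)
})

test_that("window rates conserve the fitted genetic length", {
  ex <- small_experiment()
  wr <- small_experiment_rates()
  one <- wr[wr$pop_id == "POP03", ]
  geno <- clean_population(recode_by_parents(ex$genotypes$POP03,
                                             ex$founders))$geno
  sp <- fit_marey_spline(assemble_marey(build_linkage_map(geno)))
  for (ch in unique(one$chrom)) {
    w <- one[one$chrom == ch & !one$edge, ]
    f <- sp$fits[[ch]]
    span <- diff(stats::approx(f$mono_x, f$mono_y, xout = f$support)$y)
    expect_equal(sum(w$rate * w$width_mbp), span, tolerance = 0.02)
  }
})

test_that("rate aggregation is the unweighted mean of means", {
  wr <- tibble::tibble(pop_id = "P", chrom = rep(c("1A", "2A"), each = 2),
                       start = rep(c(0, 1e7), 2), end = rep(c(1e7, 2e7), 2),
                       width_mbp = 10, rate = c(0.4, 0.6, 0.2, 0.2),
                       edge = FALSE)
  ag <- aggregate_rates(wr)
  expect_equal(ag$chromosome$rate, c(0.5, 0.2))
  expect_equal(ag$genome$rate, 0.35)
  # independent summation order
  expect_equal(ag$genome$rate,
               sum(tapply(wr$rate, wr$chrom, mean)) / 2)
})

test_that("the consensus map integrates mean window rates", {
  wr <- tibble::tibble(pop_id = rep(c("A", "B"), each = 2),
                       chrom = "1A", start = rep(c(0, 1e7), 2),
                       end = rep(c(1e7, 2e7), 2), width_mbp = 10,
                       rate = c(0.2, 0.2, 0.6, 0.6), edge = FALSE)
  mk <- tibble::tibble(marker = sprintf("m%d", 1:11), chrom = "1A",
                       pos = seq(0, 20e6, by = 2e6))
  cm <- consensus_map(wr, mk)
  expect_equal(diff(cm$cM), rep(0.8, 10), tolerance = 1e-9) # 2 Mbp x 0.4
  expect_equal(max(cm$cM), 0.4 * 20, tolerance = 1e-9)
  expect_true(all(diff(cm$cM) >= 0))
})

test_that("the pericentromere is the contiguous suppressed run", {
  mkwr <- function(rates) tibble::tibble(
    pop_id = "A", chrom = "1A",
    start = (seq_along(rates) - 1) * 1e7, end = seq_along(rates) * 1e7,
    width_mbp = 10, rate = rates, edge = FALSE)
  cs <- tibble::tibble(chrom = "1A", length_bp = 9e7, centromere_bp = 4.5e7)
  wr <- mkwr(c(1, 1, 0.02, 0.01, 0.01, 0.02, 1, 1, 1))
  pc <- pericentromeric_region(wr, cs, fold = 20)
  gm <- mean(wr$rate)
  expect_true(all(wr$rate[wr$start >= pc$start & wr$end <= pc$end] <=
                    gm / 20))
  expect_equal(pc$start, 2e7)
  expect_equal(pc$end, 6e7)
  expect_true(pc$start <= 4.5e7 && 4.5e7 <= pc$end)
  expect_warning(empty <- pericentromeric_region(mkwr(rep(0.5, 9)), cs),
                 "empty pericentromere")
  expect_equal(nrow(empty), 0)
})

test_that("fold ranges guard the near-zero denominator", {
  wr <- tibble::tibble(pop_id = rep(c("A", "B"), each = 2), chrom = "1A",
                       start = rep(c(0, 1e7), 2), end = rep(c(1e7, 2e7), 2),
                       width_mbp = 10, rate = c(0.2, 0.0001, 0.9, 0.5),
                       edge = FALSE)
  fr <- window_fold_range(wr)
  expect_equal(fr$fold[fr$start == 0], 4.5)
  expect_false(fr$floored[fr$start == 0])
  expect_equal(fr$fold[fr$start == 1e7], 0.5 / 0.001)
  expect_true(fr$floored[fr$start == 1e7])
  same <- dplyr::mutate(wr, rate = 0.3)
  expect_equal(window_fold_range(same)$fold, c(1, 1))
  expect_error(window_fold_range(wr[wr$pop_id == "A", ]),
               class = "recombkit_validation")
})

test_that("parental similarity counts shared alleles per window", {
  cs <- tibble::tibble(chrom = "1A", length_bp = 20e6, centromere_bp = 1e7)
  f <- generate_founders(3, cs, 1e6, seed = 41)
  f$haplotypes[2, ] <- f$haplotypes[1, ]                 # identical
  f$haplotypes[3, ] <- 2L - f$haplotypes[1, ]            # complementary
  s_same <- parental_similarity_windows(f, "P01", "P02")
  expect_true(all(s_same$similarity == 1, na.rm = TRUE))
  expect_true(all(is.na(s_same$similarity) == (s_same$n_markers < 5)))
  s_opp <- parental_similarity_windows(f, "P01", "P03")
  expect_true(all(s_opp$similarity == 0, na.rm = TRUE))
  f$haplotypes[3, 1:10] <- f$haplotypes[1, 1:10]
  f$haplotypes[3, 11:21] <- 2L - f$haplotypes[1, 11:21]
  s_mix <- parental_similarity_windows(f, "P01", "P03")
  expect_equal(s_mix$similarity[1], 10 / 10)
})

test_that("pericentromeric windows vary more across populations", {
  wr <- small_experiment_rates()
  ex <- small_experiment()
  fr <- window_fold_range(wr)
  pc <- pericentromeric_region(wr, ex$founders$chrom)
  skip_if(nrow(pc) == 0, "no pericentromere delineated on this draw")
  in_pc <- logical(nrow(fr))
  for (k in seq_len(nrow(pc)))
    in_pc <- in_pc | (fr$chrom == pc$chrom[k] & fr$start >= pc$start[k] &
                        fr$end <= pc$end[k])
  expect_gt(median(fr$cv[in_pc], na.rm = TRUE),
            median(fr$cv[!in_pc], na.rm = TRUE))
})
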