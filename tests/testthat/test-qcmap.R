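make_parental_table <- function(calls, pos = NULL, quality = NULL,
                                chrom = "1A") {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1e6
  markers <- tibble::tibble(marker = sprintf("%s_%03d", chrom, seq_len(m)),
                            chrom = chrom, pos = pos,
                            quality = if (is.null(quality)) rep(1, m)
                                      else quality)
  recombkit:::new_genotype_table(
    calls, tibble::tibble(id = sprintf("R%03d", seq_len(n)),
                          pop_id = "POP01"),
    markers, coding = "parental")
}

test_that("cleaning applies the quality and missingness boundaries strictly", {
  calls <- matrix(0L, 10, 4)
  g <- make_parental_table(calls, quality = c(0.69, 0.70, 0.95, 1))
  cl <- clean_population(g)
  expect_equal(ncol(cl$geno$calls), 3) # 0.69 removed, 0.70 retained
  expect_false("1A_001" %in% cl$geno$markers$marker)

  calls <- matrix(0L, 40, 100)
  calls[1, 1:11] <- NA # 11% missing -> removed
  calls[2, 1:10] <- NA # exactly 10% -> retained
  g <- make_parental_table(calls)
  cl <- clean_population(g)
  expect_equal(nrow(cl$geno$calls), 39)
  expect_false("R001" %in% cl$geno$individuals$id)
  expect_true("R002" %in% cl$geno$individuals$id)
  # conservation: removed + retained = input, per axis
  rep_mk <- cl$report[cl$report$axis == "marker", ]
  expect_equal(sum(rep_mk$n_removed) + ncol(cl$geno$calls), 100)
  rep_id <- cl$report[cl$report$axis == "ril", ]
  expect_equal(sum(rep_id$n_removed) + nrow(cl$geno$calls), 40)
})

test_that("cleaning is idempotent and can empty a population", {
  calls <- matrix(sample(c(0L, 2L), 200, TRUE), 10, 20)
  calls[, 1] <- NA
  g <- make_parental_table(calls)
  cl1 <- clean_population(g)
  cl2 <- clean_population(cl1$geno)
  expect_equal(sum(cl2$report$n_removed), 0)
  bad <- make_parental_table(matrix(0L, 5, 3), quality = rep(0.1, 3))
  expect_error(clean_population(bad), class = "recombkit_empty_population")
})

test_that("segregation distortion uses the exact two-sided binomial test", {
  calls <- rbind(matrix(0L, 50, 3), matrix(2L, 50, 3))
  calls[, 2] <- c(rep(0L, 35), rep(2L, 65)) # 65 of 100 carry one allele
  calls[, 3] <- 2L                          # 100 of 100
  g <- make_parental_table(calls)
  res <- segregation_distortion_scan(g, alpha = 0.05)
  mk <- attr(res, "markers")
  expect_false(mk$flagged[1])              # 50:50
  expect_equal(mk$p_value[2], 0.0035176, tolerance = 1e-4)
  expect_true(mk$flagged[2])
  expect_lt(mk$p_value[3], 1e-6)
  expect_true(mk$flagged[3])
})

test_that("contiguous distorted markers merge into one region", {
  calls <- cbind(matrix(c(rep(0L, 50), rep(2L, 50)), 100, 2),
                 matrix(2L, 100, 3),
                 matrix(c(rep(0L, 50), rep(2L, 50)), 100, 1))
  g <- make_parental_table(calls)
  res <- segregation_distortion_scan(g)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_markers, 3L)
  expect_equal(res$favoured_parent, 2L)
  expect_equal(res$start, 3e6)
  expect_equal(res$end, 5e6)
})

test_that("distortion scan keeps its type-I error at alpha", {
  set.seed(11)
  calls <- matrix(2L * rbinom(200 * 120, 1, 0.5), 200, 120)
  g <- make_parental_table(calls)
  mk <- attr(segregation_distortion_scan(g), "markers")
  frac <- mean(mk$flagged)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("recombination fractions invert the selfing-RIL map expansion", {
  # oracle: independent two-locus selfing recurrence simulated directly
  set.seed(21)
  r <- 0.2; n <- 4000; gens <- 12
  sim_pair <- function() {
    h <- rbind(c(0L, 0L), c(1L, 1L)) # rows homologs, cols loci
    for (g in seq_len(gens)) {
      gam <- function() {
        co <- runif(1) < r
        i <- sample(2, 1)
        c(h[i, 1], h[if (co) 3 - i else i, 2])
      }
      h <- rbind(gam(), gam())
    }
    colSums(h)
  }
  pairs <- t(replicate(n, sim_pair()))
  inf <- pairs[, 1] != 1 & pairs[, 2] != 1
  R_obs <- mean(pairs[inf, 1] != pairs[inf, 2])
  r_hat <- R_obs / (2 - 2 * R_obs)
  se <- sqrt(R_obs * (1 - R_obs) / sum(inf)) / (2 * (1 - R_obs)^2)
  expect_lt(abs(r_hat - r), 3 * se)

  # the same inversion applied by the package on simulated RILs
  cs <- tibble::tibble(chrom = "1A", length_bp = 60e6, centromere_bp = 30e6)
  f <- complementary_founders(cs, spacing = 2e6)
  d <- single_cross_design(800)
  tr <- flat_truth(f, d, rate = 1)
  g <- simulate_population(d[1, ], f, tr, generations = 12, seed = 3)
  gp <- recode_by_parents(g, f)
  rf <- pairwise_recombination_fraction(gp)
  # true adjacent r over 2 Mbp at 1 cM/Mbp: Haldane r = (1 - exp(-2d))/2
  r_true <- (1 - exp(-2 * 0.02)) / 2
  expect_equal(mean(rf$r), r_true, tolerance = 0.15)
})

test_that("recombination fraction handles its boundary cases", {
  calls <- cbind(rep(0L, 20), rep(0L, 20), c(rep(0L, 10), rep(2L, 10)))
  g <- make_parental_table(calls)
  rf <- pairwise_recombination_fraction(g)
  expect_equal(rf$r[1], 0)           # R = 0 -> r = 0
  expect_equal(rf$R_obs[2], 0.5)
  expect_lt(rf$r[2], 0.5)            # clamped below 0.5
  few <- make_parental_table(matrix(c(rep(NA, 15), rep(0L, 5),
                                      rep(0L, 20)), 20, 2))
  expect_warning(rf2 <- pairwise_recombination_fraction(few), "informative")
  expect_true(is.na(rf2$r[1]))
})

test_that("linkage maps collapse cosegregating bins and use Haldane", {
  expect_equal(recombkit:::haldane_cM(0.2), 25.54128, tolerance = 1e-5)
  # numeric check against the defining integral of the Haldane intensity:
  # d(r) = -50 log(1 - 2 r) inverts r(d) = (1 - exp(-2 d/100)) / 2
  expect_equal((1 - exp(-2 * recombkit:::haldane_cM(0.2) / 100)) / 2, 0.2,
               tolerance = 1e-10)
  calls <- matrix(c(rep(0L, 10), rep(2L, 10)), 20, 5) # identical columns
  g <- make_parental_table(calls)
  lm0 <- build_linkage_map(g)
  expect_equal(nrow(lm0), 1)   # one bin
  expect_equal(lm0$cM, 0)      # zero-length map
  expect_equal(lm0$n_markers, 5L)
})

test_that("anchored maps recover order and length on clean simulations", {
  cs <- tibble::tibble(chrom = "1A", length_bp = 100e6, centromere_bp = 50e6)
  f <- complementary_founders(cs, spacing = 1e6)
  d <- single_cross_design(150)
  tr <- flat_truth(f, d, rate = 1)
  # near-complete inbreeding so the fully-inbred inversion applies
  g <- simulate_population(d[1, ], f, tr, generations = 12, seed = 13)
  gp <- recode_by_parents(g, f)
  lmp <- build_linkage_map(gp)
  expect_true(all(diff(lmp$anchor_bp) > 0))
  expect_true(all(diff(lmp$cM) >= 0))
  expect_lt(abs(max(lmp$cM) - 100) / 100, 0.10)
  # kosambi gives a shorter map than haldane on the same data
  lmk <- build_linkage_map(gp, map_function = "kosambi")
  expect_lt(max(lmk$cM), max(lmp$cM))
})

test_that("parental recoding keeps only informative homozygous markers", {
  cs <- tiny_chrom_spec(1, 20e6)
  f <- generate_founders(4, cs, 1e6, seed = 31)
  d <- tibble::tibble(parent_i = "P01", parent_j = "P03",
                      pop_id = "POP01", n_rils = 10L)
  tr <- flat_truth(f, d, rate = 0.5)
  g <- simulate_population(d[1, ], f, tr, seed = 32)
  gp <- recode_by_parents(g, f)
  informative <- f$haplotypes["P01", ] != f$haplotypes["P03", ]
  expect_equal(ncol(gp$calls), sum(informative))
  # parent_i homozygote must be coded 0 regardless of the allele it carries
  hi <- f$haplotypes["P01", gp$markers$marker]
  raw <- g$calls[, gp$markers$marker]
  expect_true(all(gp$calls[, hi == 2][raw[, hi == 2] == 2] == 0))
})
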