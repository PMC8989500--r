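founder_doses <- function(n = 12, seed = 51) {
  f <- generate_founders(n, tiny_chrom_spec(2, 60e6), 1e6, seed = seed)
  f$haplotypes
}

test_that("the additive GRM matches its defining sum", {
  M <- founder_doses()
  A <- additive_grm(M, ridge = 0)
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  # brute-force entry-by-entry oracle
  oracle <- matrix(0, nrow(M), nrow(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(nrow(M))) {
    oracle[i, j] <- sum((M[i, ] - 2 * p) * (M[j, ] - 2 * p)) / denom
  }
  expect_equal(unclass(A), oracle, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(unclass(additive_grm(M[, sample(ncol(M))], ridge = 0)),
               unclass(A), tolerance = 1e-10, ignore_attr = TRUE)
  M2 <- rbind(M, M[1, , drop = FALSE])
  A2 <- additive_grm(M2, ridge = 0)
  expect_equal(A2[nrow(M2), 1], A2[1, 1], tolerance = 1e-10)
  expect_error(additive_grm(matrix(2, 3, 5)), class = "recombkit_validation")
})

test_that("the cross dominance matrix reduces to identity for unrelated A", {
  d <- tibble::tibble(parent_i = c("P01", "P03"), parent_j = c("P02", "P04"),
                      pop_id = c("X1", "X2"))
  A <- diag(4); dimnames(A) <- list(sprintf("P%02d", 1:4),
                                    sprintf("P%02d", 1:4))
  D <- dominance_grm(d, A)
  expect_equal(unclass(D), diag(2), ignore_attr = TRUE)
  # crosses sharing no parents among unrelated founders are unrelated
  expect_equal(D["X1", "X2"], 0)
  M <- founder_doses()
  Ag <- additive_grm(M)
  dd <- tibble::tibble(parent_i = c("P01", "P01"), parent_j = c("P02", "P03"),
                       pop_id = c("Y1", "Y2"))
  Dg <- dominance_grm(dd, Ag)
  expect_equal(mean(diag(Dg)), 1, tolerance = 1e-12)
  expect_error(dominance_grm(tibble::tibble(parent_i = "P99",
                                            parent_j = "P01",
                                            pop_id = "Z"), Ag),
               class = "recombkit_lookup")
})

test_that("GBLUP with identity matrices reduces to the identity-mode fit", {
  ex <- small_experiment()
  gr <- genome_rates(small_experiment_rates())
  parents <- sort(unique(c(ex$design$parent_i, ex$design$parent_j)))
  A <- diag(length(parents)); dimnames(A) <- list(parents, parents)
  D <- diag(nrow(ex$design)); dimnames(D) <- list(ex$design$pop_id,
                                                  ex$design$pop_id)
  f1 <- fit_gre_sre(gr, ex$design)
  f2 <- fit_gblup(gr, ex$design, A, D)
  expect_equal(f2$mu, f1$mu, tolerance = 1e-6)
  expect_equal(f2$gre$u, f1$gre$u, tolerance = 1e-5)
  expect_equal(f2$vc$sigma2_a, f1$vc$sigma2_a, tolerance = 1e-4)
})

test_that("marker-tagged GRE beats a permuted relationship baseline", {
  # discriminating setting: each parent's GRE is predicted with all of its
  # own crosses held out, so only the marker relationships can carry
  # signal; a sparse panel keeps the per-marker tagging strong enough for
  # a 15-parent training set
  f <- generate_founders(16, tiny_chrom_spec(2, 150e6), 5e6, seed = 62)
  d <- simulate_drr_design(f, n_rils_range = c(60, 60), seed = 63)
  tr <- true_recomb_model(f, d, seed = 64)
  set.seed(65)
  tg <- true_genome_rates(tr)
  gr <- tibble::tibble(pop_id = tg$pop_id,
                       rate = tg$rate + rnorm(nrow(tg), 0, 0.01))
  A <- additive_grm(f$haplotypes)
  g_true <- setNames(tr$gre$g, tr$gre$parent)
  lpo_gre <- function(A) {
    D <- dominance_grm(d, A)
    vapply(rownames(A), function(p) {
      ts <- d$pop_id[d$parent_i != p & d$parent_j != p]
      fit <- fit_gblup(gr[gr$pop_id %in% ts, ],
                       d[d$pop_id %in% ts, ], A, D)
      fit$gre$u[fit$gre$parent == p]
    }, numeric(1))
  }
  r_real <- cor(lpo_gre(A), g_true[rownames(A)])
  set.seed(61)
  idx <- sample(nrow(A))
  Ap <- unclass(A)[idx, idx]; dimnames(Ap) <- dimnames(A)
  attr(Ap, "p") <- attr(A, "p")
  r_perm <- cor(lpo_gre(Ap), g_true[rownames(A)])
  expect_gt(r_real, r_perm)
})

test_that("GBLUP and RR-BLUP give identical predictions", {
  M <- founder_doses(16, seed = 52)
  set.seed(53)
  beta <- rnorm(ncol(M), 0, 0.02)
  y <- setNames(drop(scale(M, scale = FALSE) %*% beta) + rnorm(16, 0, 0.3),
                rownames(M))
  K <- additive_grm(M)
  # the identity holds at any variance components, so fix an interior pair
  gb <- gblup_values(y, K, vc = c(0.05, 0.08))
  me <- rrblup_marker_effects(y, M, vc = gb$vc)
  pred_rr <- predict_marker_effects(me, M)
  expect_lt(max(abs(pred_rr - (gb$mu + gb$u[names(y)]))), 1e-6)
})

test_that("single-marker RR-BLUP recovers the shrunken slope in closed form", {
  x <- c(0, 0, 2, 2, 0, 2)
  y <- 0.1 * x + 1
  M <- matrix(x, ncol = 1, dimnames = list(sprintf("I%d", 1:6), "m1"))
  lambda <- 3
  me <- rrblup_marker_effects(y, M, lambda = lambda)
  w <- x - mean(x)
  expect_equal(me$effects$effect, sum(w * y) / (sum(w^2) + lambda),
               tolerance = 1e-10)
  expect_equal(unname(rrblup_marker_effects(rep(0, 6), M,
                                            lambda = 1)$effects$effect), 0)
})

test_that("BLUP extension through relationships behaves at its limits", {
  M <- founder_doses()
  A <- additive_grm(M)
  u <- setNames(rnorm(nrow(A), 0, 0.05), rownames(A))
  # duplicate of a training parent
  self_rows <- unclass(A)[1:2, , drop = FALSE]
  rownames(self_rows) <- c("dup", "dup2")
  pred <- predict_gre_new(u, A, self_rows)
  expect_equal(unname(pred), unname(u[1:2]), tolerance = 1e-8)
  # orthogonal individual drops to the prior mean
  zero_row <- matrix(0, 1, nrow(A), dimnames = list("new", rownames(A)))
  expect_equal(unname(predict_gre_new(u, A, zero_row)), 0)
  # algebraic midpoint: relationships averaging two parents average the BLUPs
  mid <- (unclass(A)[3, , drop = FALSE] + unclass(A)[4, , drop = FALSE]) / 2
  rownames(mid) <- "ril"
  expect_equal(unname(predict_gre_new(u, A, mid)),
               unname((u[3] + u[4]) / 2), tolerance = 1e-8)
})

test_that("a simulated RIL predicts near the mean of its parents", {
  ex <- small_experiment()
  A <- additive_grm(ex$founders$haplotypes)
  gr <- genome_rates(small_experiment_rates())
  fit <- fit_gblup(gr, ex$design, A, dominance_grm(ex$design, A))
  u <- setNames(fit$gre$u, fit$gre$parent)
  pid <- ex$design$pop_id[1]
  geno <- ex$genotypes[[pid]]
  p <- attr(A, "p")[geno$markers$marker]
  W_ril <- sweep(geno$calls, 2, 2 * p)
  W_par <- sweep(ex$founders$haplotypes[, geno$markers$marker], 2, 2 * p)
  A_cross <- tcrossprod(W_ril, W_par) / attr(A, "denominator")
  colnames(A_cross) <- rownames(ex$founders$haplotypes)
  pred <- predict_gre_new(u, A, A_cross[, rownames(A)])
  target <- mean(u[c(ex$design$parent_i[1], ex$design$parent_j[1])])
  expect_lt(abs(mean(pred) - target), 0.1 * max(abs(u)))
})

test_that("hybrid combination counts and GEBVs follow the model", {
  expect_equal(n_hybrid_combinations(3959), 7838820)
  gre <- c(a = 0.1, b = -0.1, c = 0)
  gb <- predict_cross_gebv(gre, mu = 0.45)
  expect_equal(nrow(gb), 6) # 3 pairs + 3 self-pairs
  expect_equal(gb$gebv[gb$id_i == "a" & gb$id_j == "b"], 0.45)
  gb0 <- predict_cross_gebv(c(a = 0, b = 0, c = 0), mu = 0.45)
  expect_true(all(gb0$gebv == 0.45))
  shifted <- predict_cross_gebv(gre + 5, mu = 0.45)
  expect_equal(rank(round(shifted$gebv - 10, 9)), rank(round(gb$gebv, 9)))
})

test_that("prediction ability is a guarded Pearson correlation", {
  x <- c(0.31, 0.45, 0.52, 0.61, 0.73)
  y <- c(0.35, 0.40, 0.58, 0.60, 0.70)
  # textbook formula computed by hand
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(prediction_ability(x, y), manual)
  expect_equal(prediction_ability(x, x), 1)
  expect_equal(prediction_ability(x, -x), -1)
  expect_warning(na <- prediction_ability(x, rep(1, 5)), "zero variance")
  expect_true(is.na(na))
  expect_error(prediction_ability(1:2, 2:1), class = "recombkit_validation")
  # invariance to positive affine transforms of the predictions
  expect_equal(prediction_ability(x, 3 * y + 2), prediction_ability(x, y))
})

test_that("Zou intervals separate correlations as a bootstrap oracle does", {
  eq <- zou_correlation_diff(0.5, 0.5, 50)
  expect_true(eq$lower < 0 && eq$upper > 0)
  ci <- zou_correlation_diff(0.9, 0.1, 100, 100)
  expect_true(ci$significant)
  expect_true(ci$lower > -2 && ci$upper < 2)
  # oracle: sampling distribution of r1 - r2 for independent bivariate
  # normal samples with the same true correlations
  set.seed(71)
  sim_r <- function(rho, n) {
    x <- rnorm(n); z <- rnorm(n)
    cor(x, rho * x + sqrt(1 - rho^2) * z)
  }
  boot <- replicate(1500, sim_r(0.9, 100) - sim_r(0.1, 100))
  q <- quantile(boot, c(0.025, 0.975))
  expect_lt(abs(ci$lower - q[[1]]), 0.08)
  expect_lt(abs(ci$upper - q[[2]]), 0.08)
  expect_error(zou_correlation_diff(1, 0.5, 50),
               class = "recombkit_validation")
  # the overlapping-dependent variant tightens with high r12
  dep <- zou_correlation_diff(0.6, 0.5, 80, dependence = "overlapping",
                              r12 = 0.9)
  ind <- zou_correlation_diff(0.6, 0.5, 80)
  expect_lt(dep$upper - dep$lower, ind$upper - ind$lower)
})

test_that("marker thinning keeps one marker per non-empty bin", {
  mk <- tibble::tibble(marker = sprintf("m%04d", 1:1400), chrom = "1A",
                       pos = seq(0, 700e6 - 5e5, by = 5e5))
  kept <- thin_markers(mk, 10, seed = 1)
  expect_equal(length(kept), 70)
  kept2 <- thin_markers(mk, 10, seed = 2)
  expect_false(identical(sort(kept), sort(kept2)))
  bins1 <- table(floor(mk$pos[match(kept, mk$marker)] / 1e7))
  bins2 <- table(floor(mk$pos[match(kept2, mk$marker)] / 1e7))
  expect_equal(as.vector(bins1), as.vector(bins2))
  # empty bins are skipped silently
  sparse <- mk[mk$pos < 5e6 | mk$pos > 650e6, ]
  expect_lt(length(thin_markers(sparse, 10, seed = 1)), 70)
})

test_that("fivefold folds exhaust the populations and are reproducible", {
  ex <- small_experiment()
  gr <- genome_rates(small_experiment_rates())
  cv <- cv_fivefold(gr, ex$design, ex$founders$haplotypes, repeats = 1,
                    seed = 5)
  expect_equal(nrow(cv), 5)
  expect_equal(cv$fold, 1:5) # every subset serves once as validation set
  expect_equal(cv$n_ts, rep(16, 5))
  cv2 <- cv_fivefold(gr, ex$design, ex$founders$haplotypes, repeats = 1,
                     seed = 5)
  expect_equal(cv, cv2)
  cv3 <- cv_fivefold(gr, ex$design, ex$founders$haplotypes, repeats = 1,
                     seed = 6)
  expect_false(isTRUE(all.equal(cv$r_pg, cv3$r_pg)))
})

test_that("leave-parents-out holds the selected parents fully out", {
  ex <- small_experiment()
  gr <- genome_rates(small_experiment_rates())
  cv <- cv_leave_parents_out(gr, ex$design, ex$founders$haplotypes,
                             n_par = 3, repeats = 4, seed = 9)
  expect_equal(nrow(cv), 4)
  expect_true(all(cv$n_ts < nrow(ex$design)))
  expect_error(cv_leave_parents_out(gr, ex$design, ex$founders$haplotypes,
                                    n_par = 10, repeats = 1, seed = 1),
               class = "recombkit_design")
})
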