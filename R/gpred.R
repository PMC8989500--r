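# Genomic relationship matrices, GBLUP/RR-BLUP prediction, prediction
# ability, Zou's correlation comparison, and the two cross-validation
# designs.

#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' `A = W W' / (2 * sum p (1 - p))` with `W` the genotype matrix (0/1/2
#' allele doses) centred by twice the allele frequencies of the supplied
#' individuals.
#'
#' @param M Individuals x markers dose matrix (0/1/2; inbreds are 0/2).
#' @param ridge Small value added to the diagonal to keep the matrix
#'   numerically positive semidefinite.
#' @return Relationship matrix with individual ids as dimnames and
#'   attributes `kind = "additive"`, `p` (allele frequencies) and
#'   `denominator`.
#' @export
additive_grm <- function(M, ridge = 1e-8) {
  if (nrow(M) < 2) abort("need >= 2 individuals", class = "recombkit_validation")
  p <- colMeans(M, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    abort("all markers monomorphic: zero denominator",
          class = "recombkit_validation")
  W <- sweep(M, 2, 2 * p)
  W[is.na(W)] <- 0
  A <- tcrossprod(W) / denom
  diag(A) <- diag(A) + ridge
  structure(A, kind = "additive", p = p, denominator = denom,
            n_markers = ncol(M))
}

#' Dominance-type relationship matrix among crosses
#'
#' Relates the SRE effects of crosses through the parental additive
#' relationships: `D[(i,j),(k,l)] = (A_ik A_jl + A_il A_jk) / 4`, scaled so
#' the mean diagonal equals 1. With `A = I` (all parents unrelated) this
#' reduces to the identity over crosses.
#'
#' @param design Crossing design tibble.
#' @param A Parent relationship matrix covering all design parents.
#' @return Cross x cross relationship matrix (`kind = "dominance"`).
#' @export
dominance_grm <- function(design, A) {
  miss <- setdiff(unique(c(design$parent_i, design$parent_j)), rownames(A))
  if (length(miss) > 0)
    abort(paste("cross parent(s) missing from A:", paste(miss, collapse = ", ")),
          class = "recombkit_lookup")
  i <- match(design$parent_i, rownames(A))
  j <- match(design$parent_j, rownames(A))
  D <- (A[i, i, drop = FALSE] * A[j, j, drop = FALSE] +
          A[i, j, drop = FALSE] * A[j, i, drop = FALSE]) / 4
  D <- D / mean(diag(D))
  dimnames(D) <- list(design$pop_id, design$pop_id)
  structure(D, kind = "dominance")
}

#' GBLUP fit of the GRE/SRE model
#'
#' [fit_gre_sre()] with genomic relationship matrices, returning the genomic
#' estimates GRE_G/SRE_G.
#'
#' @inheritParams fit_gre_sre
#' @param A Additive genomic relationship matrix of the parents
#'   (see [additive_grm()]).
#' @param D Cross relationship matrix (see [dominance_grm()]).
#' @return A `gre_fit` in genomic mode.
#' @export
fit_gblup <- function(rates, design, A, D, reml_opts = list()) {
  fit_gre_sre(rates, design, A = A, D = D, mode = "genomic",
              reml_opts = reml_opts)
}

#' Single-trait GBLUP of individual-level values
#'
#' Fits `y = mu + u + e`, `u ~ N(0, K s2_g)`, by REML and returns the BLUPs.
#' Used for parent-level prediction of general recombination effects and as
#' one side of the GBLUP/RR-BLUP equivalence.
#'
#' @param y Named numeric vector of phenotypes.
#' @param K Relationship matrix covering (at least) the phenotyped ids.
#' @param vc Optional fixed variance components `c(s2_g, s2_e)`; estimated
#'   by REML when `NULL`.
#' @return List: `mu`, `u` (named, all ids of `K`), `vc`.
#' @export
gblup_values <- function(y, K, vc = NULL) {
  ids <- names(y)
  if (!all(ids %in% rownames(K)))
    abort("phenotyped ids missing from K", class = "recombkit_lookup")
  Z <- matrix(0, length(y), nrow(K), dimnames = list(ids, rownames(K)))
  Z[cbind(seq_along(y), match(ids, rownames(K)))] <- 1
  X <- matrix(1, length(y), 1)
  if (is.null(vc)) {
    fit <- reml_fit(y, X, list(Z), list(unclass(K)))
    vc <- fit$theta
    mu <- fit$beta
    u <- setNames(fit$u[[1]], rownames(K))
  } else {
    V <- vc[1] * Z %*% K %*% t(Z) + vc[2] * diag(length(y))
    Vi <- solve(V)
    mu <- drop(solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y)))
    Py <- Vi %*% (y - X %*% mu)
    u <- setNames(drop(vc[1] * K %*% t(Z) %*% Py), rownames(K))
  }
  list(mu = unname(mu), u = u, vc = unname(vc))
}

#' RR-BLUP marker effects
#'
#' Ridge-regression BLUP of per-marker additive effects: solves the
#' mixed-model equations for `y = 1 mu + W b + e` with `W` the 2p-centred
#' dose matrix and ridge `lambda = s2_e / s2_marker`. With
#' `s2_marker = s2_g / (2 sum p (1 - p))` the predictions equal GBLUP
#' breeding values computed from the VanRaden matrix of the same genotypes.
#'
#' @param y Named numeric vector of phenotypes (one per genotyped line).
#' @param M Dose matrix of the same lines.
#' @param lambda Ridge parameter; when `NULL`, computed from `vc`.
#' @param vc Variance components `c(s2_g, s2_e)` on the genomic-value scale
#'   (as from [gblup_values()]).
#' @return A `marker_effects` object: `intercept`, tibble `effects`,
#'   `lambda`, training allele frequencies `p`.
#' @export
rrblup_marker_effects <- function(y, M, lambda = NULL, vc = NULL) {
  stopifnot(length(y) == nrow(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  if (is.null(lambda)) {
    if (is.null(vc)) abort("supply lambda or vc")
    lambda <- vc[2] / (vc[1] / denom)
  }
  W <- sweep(M, 2, 2 * p)
  W[is.na(W)] <- 0
  n <- length(y); m <- ncol(M)
  C <- rbind(cbind(n, t(colSums(W))),
             cbind(colSums(W), crossprod(W) + lambda * diag(m)))
  rhs <- c(sum(y), crossprod(W, y))
  sol <- solve(C, rhs)
  structure(list(
    intercept = unname(sol[1]),
    effects = tibble::tibble(marker = colnames(M),
                             effect = unname(sol[-1])),
    lambda = lambda, p = p, denominator = denom),
    class = "marker_effects")
}

#' Predict genomic values from RR-BLUP marker effects
#'
#' @param me A `marker_effects` object.
#' @param M Dose matrix of the lines to predict (same markers).
#' @return Named numeric vector `intercept + W b` with training-set
#'   centring.
#' @export
predict_marker_effects <- function(me, M) {
  W <- sweep(M[, me$effects$marker, drop = FALSE], 2, 2 * me$p)
  W[is.na(W)] <- 0
  setNames(drop(me$intercept + W %*% me$effects$effect), rownames(M))
}

#' Extend GRE BLUPs to new individuals through relationships
#'
#' Standard BLUP extension `u_new = A_cross A_train^-1 u_train`, usable for
#' RILs or a diversity panel related to the training parents.
#'
#' @param u_train Named vector of training BLUPs (e.g. `fit$gre$u` named by
#'   parent).
#' @param A_train Relationship matrix among training individuals.
#' @param A_cross New x training relationship matrix (columns matching
#'   `A_train`).
#' @return Named numeric vector of predicted effects for the new rows.
#' @export
predict_gre_new <- function(u_train, A_train, A_cross) {
  if (!all(colnames(A_cross) == rownames(A_train)))
    abort("A_cross columns must match training individuals",
          class = "recombkit_lookup")
  u <- u_train[rownames(A_train)]
  setNames(drop(A_cross %*% solve(unclass(A_train), u)), rownames(A_cross))
}

#' Number of unordered hybrid combinations with self-pairs
#'
#' @param n Number of lines.
#' @return `n (n + 1) / 2`.
#' @export
n_hybrid_combinations <- function(n) n * (n + 1) / 2

#' Genomic estimated breeding values of cross combinations
#'
#' `GEBV(i, j) = mu + GRE(i) + GRE(j)` for unordered pairs including
#' self-pairs; an SRE term is added when a cross relationship predictor is
#' supplied.
#'
#' @param gre Tibble (`parent`/`id`, `u`) or named vector of GRE values.
#' @param mu Intercept added to every pair.
#' @param pairs Optional two-column structure of id pairs; by default all
#'   `n (n + 1) / 2` unordered pairs with self-pairs are enumerated.
#' @param sre Optional function `(id_i, id_j) -> numeric` supplying a
#'   specific-effect term.
#' @return Tibble `id_i`, `id_j`, `gebv`; GEBV ranking is invariant to
#'   adding a constant to all GRE values.
#' @export
predict_cross_gebv <- function(gre, mu = 0, pairs = NULL, sre = NULL) {
  if (is.data.frame(gre)) {
    idcol <- intersect(c("parent", "id"), names(gre))[1]
    gre <- setNames(gre$u, gre[[idcol]])
  }
  ids <- names(gre)
  if (is.null(pairs)) {
    idx <- which(upper.tri(matrix(0, length(ids), length(ids)), diag = TRUE),
                 arr.ind = TRUE)
    pairs <- cbind(ids[idx[, 1]], ids[idx[, 2]])
  } else pairs <- as.matrix(pairs)
  if (!all(pairs %in% ids)) abort("pair ids missing GRE values",
                                  class = "recombkit_lookup")
  gebv <- mu + gre[pairs[, 1]] + gre[pairs[, 2]]
  if (!is.null(sre)) gebv <- gebv + sre(pairs[, 1], pairs[, 2])
  tibble::tibble(id_i = pairs[, 1], id_j = pairs[, 2], gebv = unname(gebv))
}

#' Prediction ability (Pearson correlation)
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3 pairs).
#' @return Pearson correlation; `NA` with a warning if either vector has
#'   zero variance.
#' @export
prediction_ability <- function(observed, predicted) {
  ok <- stats::complete.cases(observed, predicted)
  if (sum(ok) < 3) abort("need >= 3 complete pairs",
                         class = "recombkit_validation")
  if (sd(observed[ok]) == 0 || sd(predicted[ok]) == 0) {
    warn("zero variance: prediction ability undefined")
    return(NA_real_)
  }
  cor(observed[ok], predicted[ok])
}

#' Confidence interval for a difference of correlations (Zou's method)
#'
#' Modified asymptotic interval for `r1 - r2` built from the Fisher-z
#' confidence limits of each correlation; the `overlapping` variant accounts
#' for the dependence of two correlations sharing one variable through the
#' correlation `r12` of the two non-shared variables.
#'
#' @param r1,r2 Sample correlations in (-1, 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @param conf Confidence level.
#' @param dependence `"independent"` or `"overlapping"`.
#' @param r12 Correlation between the two non-shared variables (needed for
#'   the overlapping variant).
#' @return Tibble `diff`, `lower`, `upper`, `significant` (CI excludes 0).
#' @export
zou_correlation_diff <- function(r1, r2, n1, n2 = n1, conf = 0.95,
                                 dependence = c("independent", "overlapping"),
                                 r12 = NULL) {
  dependence <- match.arg(dependence)
  if (any(abs(c(r1, r2)) >= 1) || min(n1, n2) < 4)
    abort("need |r| < 1 and n >= 4", class = "recombkit_validation")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci_r <- function(r, n) tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
  c1 <- ci_r(r1, n1); c2 <- ci_r(r2, n2)
  if (dependence == "independent") {
    corr_r <- 0
  } else {
    if (is.null(r12)) abort("overlapping variant needs r12")
    corr_r <- ((r12 - 0.5 * r1 * r2) * (1 - r1^2 - r2^2 - r12^2) + r12^3) /
      ((1 - r1^2) * (1 - r2^2))
  }
  lower <- r1 - r2 - sqrt((r1 - c1[1])^2 + (c2[2] - r2)^2 -
                            2 * corr_r * (r1 - c1[1]) * (c2[2] - r2))
  upper <- r1 - r2 + sqrt((c1[2] - r1)^2 + (r2 - c2[1])^2 -
                            2 * corr_r * (c1[2] - r1) * (r2 - c2[1]))
  tibble::tibble(diff = r1 - r2, lower = lower, upper = upper,
                 significant = lower > 0 | upper < 0)
}

#' Thin markers to one per physical spacing bin
#'
#' One marker is sampled uniformly at random from each non-empty bin of the
#' given width along every chromosome; empty bins are skipped.
#'
#' @param markers Marker tibble (`marker`, `chrom`, `pos`).
#' @param spacing_mbp Bin width in Mbp (1, 5 or 10 in the thinning
#'   scenarios).
#' @param seed Optional integer seed.
#' @return Character vector of retained marker ids.
#' @export
thin_markers <- function(markers, spacing_mbp, seed = NULL) {
  if (spacing_mbp <= 0) abort("spacing must be > 0",
                              class = "recombkit_validation")
  if (!is.null(seed)) set.seed(seed)
  markers |>
    dplyr::mutate(bin = floor(.data$pos / (spacing_mbp * 1e6))) |>
    dplyr::group_by(.data$chrom, .data$bin) |>
    dplyr::slice_sample(n = 1) |>
    dplyr::pull(.data$marker)
}

grm_pair <- function(M_parents, design, thin = NULL, markers = NULL) {
  if (!is.null(thin)) {
    keep <- thin_markers(markers, thin)
    M_parents <- M_parents[, keep, drop = FALSE]
  }
  A <- additive_grm(M_parents)
  D <- dominance_grm(design, A)
  list(A = A, D = D)
}

cv_fit_predict <- function(rates, design, A, D, ts_pops, vs_pops,
                           gre_p_full, gre_parents = NULL) {
  fit <- fit_gblup(rates[rates$pop_id %in% ts_pops, ],
                   design[design$pop_id %in% ts_pops, ], A = A, D = D)
  vs <- design[design$pop_id %in% vs_pops, ]
  u <- setNames(fit$gre$u, fit$gre$parent)
  s <- setNames(fit$sre$u, fit$sre$pop_id)
  gebv <- fit$mu + u[vs$parent_i] + u[vs$parent_j] + s[vs$pop_id]
  obs <- setNames(rates$rate, rates$pop_id)[vs$pop_id]
  if (is.null(gre_parents))
    gre_parents <- unique(c(vs$parent_i, vs$parent_j))
  r_pg <- prediction_ability(obs, gebv)
  r_gre <- prediction_ability(gre_p_full[gre_parents], u[gre_parents])
  c(r_pg = r_pg, r_gre = r_gre)
}

#' Fivefold cross-validation of GBLUP prediction ability
#'
#' Populations are randomly split into five disjoint near-equal subsets per
#' repeat; each subset serves once as validation set (VS) while
#' `n_subsets_ts` of the remaining four subsets form the training set (TS):
#' 36, 27 or 18 populations for a 45-population design. Reported per run
#' are `r_PG` (correlation between observed rates and GEBVs over the VS
#' populations) and `r_GRE` (correlation between the full-data phenotypic
#' GRE and the TS genomic GRE over the VS parents).
#'
#' @param rates Tibble `pop_id`, `rate` for all populations.
#' @param design Crossing design tibble.
#' @param M_parents Parent dose matrix (rows = parents).
#' @param n_subsets_ts Number of the four remaining subsets used as TS
#'   (4, 3 or 2).
#' @param repeats Number of repeated partitions (100 in the full design).
#' @param seed Integer seed.
#' @param thin_spacing_mbp Optional marker thinning (1, 5 or 10), re-sampled
#'   per run.
#' @param markers Marker tibble (`marker`, `chrom`, `pos`); required when
#'   thinning.
#' @return A `cv_result` tibble: `scenario`, `rep`, `fold`, `n_ts`, `r_pg`,
#'   `r_gre`. Summarise with [cv_summary()].
#' @export
cv_fivefold <- function(rates, design, M_parents, n_subsets_ts = 4,
                        repeats = 100, seed = 1L, thin_spacing_mbp = NULL,
                        markers = NULL) {
  stopifnot(n_subsets_ts %in% 1:4)
  pops <- rates$pop_id
  if (length(pops) < 5) abort("fivefold CV needs >= 5 populations",
                              class = "recombkit_validation")
  gre_p_full <- with(fit_gre_sre(rates, design), setNames(gre$u, gre$parent))
  if (is.null(thin_spacing_mbp)) {
    gp <- grm_pair(M_parents, design)
  }
  set.seed(seed)
  out <- purrr::map_dfr(seq_len(repeats), function(rep_k) {
    fold_of <- sample(rep(1:5, length.out = length(pops)))
    purrr::map_dfr(1:5, function(f) {
      if (!is.null(thin_spacing_mbp))
        gp <- grm_pair(M_parents, design, thin = thin_spacing_mbp,
                       markers = markers)
      vs <- pops[fold_of == f]
      ts_folds <- sample(setdiff(1:5, f), n_subsets_ts)
      ts <- pops[fold_of %in% ts_folds]
      r <- cv_fit_predict(rates, design, gp$A, gp$D, ts, vs, gre_p_full)
      tibble::tibble(scenario = sprintf("fivefold_ts%d", n_subsets_ts),
                     rep = rep_k, fold = f, n_ts = length(ts),
                     r_pg = r[["r_pg"]], r_gre = r[["r_gre"]])
    })
  })
  class(out) <- c("cv_result", class(out))
  out
}

#' Leave-parents-out cross-validation
#'
#' Per repeat, `n_par` parents are selected at random; every population
#' involving a selected parent forms the validation set and the remainder
#' the training set, so the held-out parents appear in no training
#' population. `r_GRE` is computed over the selected parents.
#'
#' @inheritParams cv_fivefold
#' @param n_par Number of held-out parents (3 or 5 in the full design).
#' @param repeats Number of repeats (1000 in the full design).
#' @return A `cv_result` tibble (`fold` is `NA`).
#' @export
cv_leave_parents_out <- function(rates, design, M_parents, n_par = 3,
                                 repeats = 1000, seed = 1L,
                                 thin_spacing_mbp = NULL, markers = NULL) {
  parents <- sort(unique(c(design$parent_i, design$parent_j)))
  gre_p_full <- with(fit_gre_sre(rates, design), setNames(gre$u, gre$parent))
  if (is.null(thin_spacing_mbp)) gp <- grm_pair(M_parents, design)
  set.seed(seed)
  out <- purrr::map_dfr(seq_len(repeats), function(rep_k) {
    if (!is.null(thin_spacing_mbp))
      gp <- grm_pair(M_parents, design, thin = thin_spacing_mbp,
                     markers = markers)
    sel <- sample(parents, n_par)
    vs <- design$pop_id[design$parent_i %in% sel | design$parent_j %in% sel]
    ts <- setdiff(design$pop_id, vs)
    if (length(ts) == 0)
      abort("empty training set: too many parents held out",
            class = "recombkit_design")
    stopifnot(!any(sel %in% c(design$parent_i[design$pop_id %in% ts],
                              design$parent_j[design$pop_id %in% ts])))
    r <- cv_fit_predict(rates, design, gp$A, gp$D, ts, vs,
                        gre_p_full, gre_parents = sel)
    tibble::tibble(scenario = sprintf("leave%dparents", n_par),
                   rep = rep_k, fold = NA_integer_, n_ts = length(ts),
                   r_pg = r[["r_pg"]], r_gre = r[["r_gre"]])
  })
  class(out) <- c("cv_result", class(out))
  out
}

#' Median prediction abilities per CV scenario
#'
#' @param cv A `cv_result` tibble (scenarios may be row-bound).
#' @return Tibble `scenario`, `runs`, `median_r_pg`, `median_r_gre`,
#'   `median_n_ts`.
#' @export
cv_summary <- function(cv) {
  cv |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(runs = dplyr::n(),
                     median_r_pg = median(.data$r_pg, na.rm = TRUE),
                     median_r_gre = median(.data$r_gre, na.rm = TRUE),
                     median_n_ts = median(.data$n_ts),
                     .groups = "drop")
}
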