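# GRE/SRE decomposition: incidence matrices, average-information REML with
# EM fallback, BLUP extraction and broad-sense heritability.

#' Incidence matrices for the GRE/SRE model
#'
#' The model is `c = 1 mu + Z_GRE u_GRE + Z_SRE u_SRE + e`: the GRE row for
#' cross `(i, j)` has a 1 in columns `i` and `j` (row sum 2); the SRE
#' incidence selects each phenotyped cross.
#'
#' @param design Crossing design tibble (`parent_i`, `parent_j`, `pop_id`).
#' @param parents Optional full parent id vector (columns of `Z_gre`);
#'   defaults to parents appearing in the design.
#' @param crosses Optional full cross id vector (columns of `Z_sre`).
#' @param warn_unused Warn about parents absent from every cross.
#' @return List with matrices `Z_gre`, `Z_sre` and the id vectors.
#' @export
build_incidence <- function(design, parents = NULL, crosses = NULL,
                            warn_unused = TRUE) {
  if (any(design$parent_i == design$parent_j))
    abort("a cross needs two distinct parents", class = "recombkit_design")
  if (anyDuplicated(design$pop_id))
    abort("population ids must be unique", class = "recombkit_design")
  if (is.null(parents))
    parents <- sort(unique(c(design$parent_i, design$parent_j)))
  if (is.null(crosses)) crosses <- design$pop_id
  n <- nrow(design)
  Z_gre <- matrix(0, n, length(parents),
                  dimnames = list(design$pop_id, parents))
  Z_gre[cbind(seq_len(n), match(design$parent_i, parents))] <- 1
  Z_gre[cbind(seq_len(n), match(design$parent_j, parents))] <- 1
  unused <- setdiff(parents, c(design$parent_i, design$parent_j))
  if (length(unused) > 0 && warn_unused)
    warn(paste("parent(s) absent from all crosses:",
               paste(unused, collapse = ", ")))
  Z_sre <- matrix(0, n, length(crosses),
                  dimnames = list(design$pop_id, crosses))
  Z_sre[cbind(seq_len(n), match(design$pop_id, crosses))] <- 1
  list(Z_gre = Z_gre, Z_sre = Z_sre, parents = parents, crosses = crosses)
}

check_psd <- function(M, name) {
  if (!isSymmetric(unname(M), tol = 1e-8))
    abort(paste(name, "must be symmetric"), class = "recombkit_decomposition")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    abort(sprintf("%s is not positive semidefinite (eigenvalue %.3g)",
                  name, min(ev)), class = "recombkit_decomposition")
  invisible(ev)
}

# Restricted maximum likelihood for y = X b + sum_k Z_k u_k + e,
# u_k ~ N(0, G_k s2_k), e ~ N(0, I s2_e). Average-information updates with
# an EM fallback whenever the AI step leaves the parameter space or lowers
# the restricted likelihood; components are kept >= 0 by projection.
reml_fit <- function(y, X, Zlist, Glist, init = NULL, tol = 1e-8,
                     max_iter = 200) {
  n <- length(y)
  K <- length(Zlist)
  Vk <- lapply(seq_len(K), function(k)
    Zlist[[k]] %*% Glist[[k]] %*% t(Zlist[[k]]))
  Vk <- c(Vk, list(diag(n))) # residual last
  vy <- var(y)
  theta <- init %||% rep(vy / (K + 1), K + 1)
  floor_v <- 1e-10 * vy
  loglik_of <- function(theta) {
    V <- Reduce(`+`, Map(`*`, Vk, theta))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    chx <- chol(XtViX)
    P <- Vi - Vi %*% X %*% chol2inv(chx) %*% t(X) %*% Vi
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(ll = ll, P = P, Py = Py, Vi = Vi)
  }
  st <- loglik_of(theta)
  ll_trace <- st$ll
  grad <- rep(NA_real_, K + 1)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    PVk <- lapply(Vk, function(M) st$P %*% M)
    yPVkPy <- vapply(Vk, function(M)
      drop(crossprod(st$Py, M %*% st$Py)), numeric(1))
    trPVk <- vapply(PVk, function(M) sum(diag(M)), numeric(1))
    grad <- -0.5 * (trPVk - yPVkPy)
    at_bound <- theta <= floor_v & grad < 0
    free <- !at_bound
    if (sqrt(sum(grad[free]^2)) < 1e-6) { converged <- TRUE; break }
    # average-information step on the free components
    AI <- matrix(0, K + 1, K + 1)
    VkPy <- lapply(Vk, function(M) M %*% st$Py)
    for (a in seq_len(K + 1)) for (b in a:(K + 1)) {
      AI[a, b] <- AI[b, a] <-
        0.5 * drop(crossprod(VkPy[[a]], st$P %*% VkPy[[b]]))
    }
    proposal <- theta
    accepted <- FALSE
    step <- if (sum(free) > 0)
      tryCatch(solve(AI[free, free, drop = FALSE], grad[free]),
               error = function(e) NULL) else NULL
    if (!is.null(step)) {
      # AI step with halving towards the current point
      fac <- 1
      for (h in 1:6) {
        proposal <- theta
        proposal[free] <- pmax(theta[free] + fac * step, floor_v)
        proposal[at_bound] <- floor_v
        st_new <- loglik_of(proposal)
        if (st_new$ll >= tail(ll_trace, 1) - 1e-12) { accepted <- TRUE; break }
        fac <- fac / 2
      }
    }
    if (!accepted) {
      # EM-type update (Johnson & Thompson), guaranteed direction of ascent;
      # halve towards the current point if needed
      q <- c(vapply(Zlist, ncol, integer(1)), n)
      em <- pmax(theta + theta^2 * (yPVkPy - trPVk) / q, floor_v)
      em[at_bound] <- floor_v
      proposal <- em
      st_new <- loglik_of(proposal)
      tries <- 0
      while (st_new$ll < tail(ll_trace, 1) - 1e-10 && tries < 30) {
        proposal <- (proposal + theta) / 2
        st_new <- loglik_of(proposal)
        tries <- tries + 1
      }
      if (st_new$ll < tail(ll_trace, 1) - 1e-10) { converged <- TRUE; break }
    }
    delta <- max(abs(proposal - theta) / pmax(theta, floor_v))
    theta <- proposal
    st <- st_new
    # pin near-boundary components whose likelihood does not object
    tiny <- which(theta > floor_v & theta < 1e-5 * vy)
    for (k in tiny) {
      pin <- theta; pin[k] <- floor_v
      st_pin <- loglik_of(pin)
      if (st_pin$ll >= st$ll - 1e-9) { theta <- pin; st <- st_pin }
    }
    ll_trace <- c(ll_trace, st$ll)
    if (delta < tol) { converged <- TRUE; break }
    if (length(ll_trace) > 3 &&
        diff(tail(ll_trace, 2)) < 1e-9 &&
        diff(range(tail(ll_trace, 3))) < 1e-8) { converged <- TRUE; break }
  }
  if (!converged) {
    # ridge-shaped likelihoods (e.g. a cross relationship matrix close to
    # the identity) make the AI/EM iteration creep; polish on the log scale
    obj <- function(lt) -loglik_of(pmax(exp(lt), floor_v))$ll
    opt <- optim(log(pmax(theta, floor_v)), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    theta_new <- pmax(exp(opt$par), floor_v)
    st_new <- loglik_of(theta_new)
    if (!is.finite(st_new$ll) || st_new$ll < tail(ll_trace, 1) - 1e-8)
      abort(sprintf("REML did not converge in %d iterations (|grad| %.3g)",
                    max_iter, sqrt(sum(grad^2, na.rm = TRUE))),
            class = "recombkit_reml_nonconvergent",
            ll_trace = ll_trace)
    theta <- theta_new
    # try pinning near-boundary components after the polish
    for (k in which(theta < 1e-5 * vy)) {
      pin <- theta; pin[k] <- floor_v
      st_pin <- loglik_of(pin)
      if (st_pin$ll >= st_new$ll - 1e-9) { theta <- pin; st_new <- st_pin }
    }
    st <- loglik_of(theta)
    ll_trace <- c(ll_trace, st$ll)
    converged <- TRUE
  }
  beta <- drop(solve(crossprod(X, st$Vi %*% X), crossprod(X, st$Vi %*% y)))
  u <- lapply(seq_len(K), function(k)
    drop(theta[k] * Glist[[k]] %*% t(Zlist[[k]]) %*% st$Py))
  theta[theta <= floor_v] <- 0
  list(theta = theta, beta = beta, u = u, loglik = tail(ll_trace, 1),
       ll_trace = ll_trace, iterations = iter,
       gradient = grad, converged = converged)
}

#' Fit the GRE/SRE mixed model by REML
#'
#' Decomposes cross-level recombination rates into a general effect per
#' parent (GRE) and a specific effect per cross (SRE) with variance
#' components estimated by average-information REML (EM fallback, components
#' constrained non-negative). With identity relationship matrices the fit
#' yields the phenotypic estimates GRE_P/SRE_P; with genomic matrices
#' (see [fit_gblup()]) the genomic estimates GRE_G/SRE_G.
#'
#' Identifiability: when each cross is phenotyped once and `D` is the
#' identity, the SRE covariance equals the residual covariance, so their
#' variances are estimable only through their sum. The fit then drops the
#' separate residual, attributes the whole cross-level variance to the SRE
#' (`sigma2_e = NA`, `confounded = TRUE`); the SRE values are the
#' cross-level deviations from the GRE fit. Heritability is not informative
#' in that mode.
#'
#' @param rates Tibble with `pop_id` and `rate` (or a named numeric vector).
#' @param design Crossing design tibble covering the phenotyped crosses.
#' @param A Parent relationship matrix (default identity).
#' @param D Cross relationship matrix (default identity).
#' @param mode `"identity"` or `"genomic"` (controls labelling; matrices
#'   rule the fit).
#' @param reml_opts List: `tol`, `max_iter`, `init`.
#' @return A `gre_fit`: `mu`, tibbles `gre` and `sre`, variance components
#'   `vc`, `H2`, fitted values and metadata. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
fit_gre_sre <- function(rates, design, A = NULL, D = NULL,
                        mode = c("identity", "genomic"),
                        reml_opts = list()) {
  mode <- match.arg(mode)
  if (is.data.frame(rates)) {
    y <- setNames(rates$rate, rates$pop_id)
  } else y <- rates
  design <- design[match(names(y), design$pop_id), ]
  if (any(is.na(design$pop_id)))
    abort("rates contain populations absent from the design",
          class = "recombkit_design")
  parents <- if (!is.null(A)) rownames(A) else NULL
  crosses <- if (!is.null(D)) rownames(D) else NULL
  inc <- build_incidence(design, parents = parents, crosses = crosses,
                         warn_unused = FALSE)
  n <- length(y)
  if (is.null(A)) A <- diag(length(inc$parents))
  if (is.null(D)) D <- diag(length(inc$crosses))
  check_psd(A, "A"); check_psd(D, "D")
  X <- matrix(1, n, 1)
  ZDZ <- inc$Z_sre %*% D %*% t(inc$Z_sre)
  confounded <- max(abs(ZDZ - diag(n))) < 1e-10
  opts <- utils::modifyList(list(tol = 1e-8, max_iter = 200, init = NULL),
                            reml_opts)
  if (confounded) {
    fit <- reml_fit(y, X, list(inc$Z_gre), list(A), init = opts$init,
                    tol = opts$tol, max_iter = opts$max_iter)
    s2 <- c(a = fit$theta[1], d = fit$theta[2], e = NA_real_)
    u_gre <- setNames(fit$u[[1]], inc$parents)
    # cross-level deviations, attributed to the SRE (see Details)
    u_sre_full <- setNames(drop(y - X %*% fit$beta - inc$Z_gre %*% u_gre),
                           design$pop_id)
    u_sre <- setNames(rep(0, length(inc$crosses)), inc$crosses)
    u_sre[names(u_sre_full)] <- u_sre_full
    resid <- rep(0, n)
  } else {
    fit <- reml_fit(y, X, list(inc$Z_gre, inc$Z_sre), list(A, D),
                    init = opts$init, tol = opts$tol, max_iter = opts$max_iter)
    s2 <- c(a = fit$theta[1], d = fit$theta[2], e = fit$theta[3])
    u_gre <- setNames(fit$u[[1]], inc$parents)
    u_sre <- setNames(fit$u[[2]], inc$crosses)
    resid <- drop(y - X %*% fit$beta - inc$Z_gre %*% u_gre -
                    inc$Z_sre %*% u_sre)
  }
  vc <- list(sigma2_a = unname(s2["a"]), sigma2_d = unname(s2["d"]),
             sigma2_e = unname(s2["e"]), confounded = confounded,
             iterations = fit$iterations,
             gradient_norm = sqrt(sum(fit$gradient^2, na.rm = TRUE)),
             loglik = fit$loglik, ll_trace = fit$ll_trace)
  H2 <- if (confounded) NA_real_ else
    (s2[["a"]] + s2[["d"]]) / (s2[["a"]] + s2[["d"]] + s2[["e"]])
  structure(list(
    mu = unname(fit$beta),
    gre = tibble::tibble(parent = inc$parents, u = unname(u_gre)),
    sre = tibble::tibble(pop_id = inc$crosses, u = unname(u_sre)),
    vc = vc, H2 = unname(H2), mode = mode,
    fitted = tibble::tibble(pop_id = design$pop_id, rate = unname(y),
                            fitted = unname(y - resid),
                            residual = unname(resid)),
    design = design, A = A, D = D, y = y),
    class = "gre_fit")
}

#' @export
print.gre_fit <- function(x, ...) {
  cat(sprintf("<gre_fit> %s mode, %d crosses, %d parents\n",
              x$mode, nrow(x$fitted), nrow(x$gre)))
  cat(sprintf("  mu = %.4g; sigma2_a = %.4g, sigma2_d = %.4g, sigma2_e = %s%s\n",
              x$mu, x$vc$sigma2_a, x$vc$sigma2_d,
              ifelse(is.na(x$vc$sigma2_e), "NA",
                     sprintf("%.4g", x$vc$sigma2_e)),
              ifelse(x$vc$confounded, " (SRE absorbs residual)", "")))
  invisible(x)
}

#' @rdname fit_gre_sre
#' @param x,object A `gre_fit`.
#' @param ... Unused.
#' @export
tidy.gre_fit <- function(x, ...) {
  dplyr::bind_rows(
    x$gre |> dplyr::transmute(term = .data$parent, effect = "GRE",
                              estimate = .data$u),
    x$sre |> dplyr::transmute(term = .data$pop_id, effect = "SRE",
                              estimate = .data$u))
}

#' @rdname fit_gre_sre
#' @export
glance.gre_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, sigma2_a = x$vc$sigma2_a, sigma2_d = x$vc$sigma2_d,
    sigma2_e = x$vc$sigma2_e, H2 = x$H2,
    gre_sre_ratio = gre_sre_variance_ratio(x),
    confounded = x$vc$confounded, mode = x$mode,
    iterations = x$vc$iterations, loglik = x$vc$loglik)
}

#' Broad-sense heritability of the recombination rate
#'
#' `H2 = (sigma2_GRE + sigma2_SRE) / (sigma2_GRE + sigma2_SRE + sigma2_e)`.
#'
#' @param vc A `gre_fit`, its `vc` list, or a numeric vector
#'   `(sigma2_a, sigma2_d, sigma2_e)`.
#' @return Heritability in `[0, 1]` (`NA` with a warning for a confounded
#'   identity-mode fit).
#' @export
heritability <- function(vc) {
  if (inherits(vc, "gre_fit")) vc <- vc$vc
  if (is.list(vc)) {
    if (isTRUE(vc$confounded)) {
      warn("SRE and residual are confounded in this fit; H2 not informative")
      return(NA_real_)
    }
    vc <- c(vc$sigma2_a, vc$sigma2_d, vc$sigma2_e)
  }
  if (any(vc < 0) || all(vc == 0))
    abort("components must be >= 0 and not all zero",
          class = "recombkit_validation")
  (vc[1] + vc[2]) / sum(vc[1:3])
}

#' Ratio of GRE to SRE variance
#'
#' @param fit A `gre_fit` or numeric `(sigma2_a, sigma2_d)`.
#' @return `sigma2_a / sigma2_d`; `Inf` with a warning when the SRE
#'   component is at the zero boundary.
#' @export
gre_sre_variance_ratio <- function(fit) {
  if (inherits(fit, "gre_fit"))
    fit <- c(fit$vc$sigma2_a, fit$vc$sigma2_d)
  if (fit[2] <= 0) {
    warn("SRE variance at the zero boundary; ratio is infinite")
    return(Inf)
  }
  fit[1] / fit[2]
}
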