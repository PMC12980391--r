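# Random-intercept linear mixed model, fit by REML with the variance-ratio
# profiled out. The covariance of observation vector y is
#   V = sigma_e^2 (W^-1 + theta Z Z^T),  theta = sigma_u^2 / sigma_e^2,
# with Z the participant indicator matrix and W fixed precision weights.
# Because Z Z^T is block diagonal in participants, every V^-1 quantity is
# computed per cluster by Sherman-Morrison in O(n p + q p^2), which is what
# lets the benchmark fit tens of thousands of replicates.

# Per-theta core quantities. ord: observations sorted by cluster.
ri_core <- function(theta, X, y, w, id_sw, id_m, id_r, XtWX, XtWy, ytWy, sum_log_w) {
  cfac <- theta / (1 + theta * id_sw)             # per-cluster SM factor
  XtVX <- XtWX - crossprod(id_m * cfac, id_m)
  XtVy <- XtWy - drop(crossprod(id_m * cfac, id_r))
  ytVy <- ytWy - sum(cfac * id_r^2)
  logdetV0 <- sum(log1p(theta * id_sw)) - sum_log_w
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
  rss <- ytVy - sum(XtVy * beta)
  list(beta = beta, rss = max(rss, 1e-300), chol = ch,
       logdetV0 = logdetV0, logdetXtVX = 2 * sum(log(diag(ch))))
}

#' Fit a participant random-intercept linear mixed model by REML
#'
#' The per-feature engine of the differential pipeline: REML estimation of
#' `y = X b + u_participant + e` with optional fixed per-observation
#' precision weights on `e`. The random-intercept-to-residual variance
#' ratio is profiled and optimised on the log scale with a fixed grid plus
#' golden-section refinement, so fits are deterministic in the data.
#'
#' @param y numeric response vector.
#' @param X design matrix (full rank on the observed rows), typically from
#'   [build_cell_means_design()].
#' @param participant cluster identifier vector.
#' @param weights optional positive precision weights (larger = more
#'   precise); invariant to overall rescaling.
#' @return an object of class `lmm_fit`: coefficients, their covariance,
#'   variance components, and cached structures for [test_contrast()].
#' @export
fit_feature_lmm <- function(y, X, participant, weights = NULL) {
  keep <- !is.na(y)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  participant <- as.character(participant)[keep]
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("fewer observations than fixed-effect parameters")
  if (is.null(weights)) weights <- rep(1, n) else weights <- weights[keep]
  if (any(weights <= 0)) stop("precision weights must be positive")
  if (qr(X)$rank < p)
    stop("design matrix rank deficient on observed rows")
  id <- factor(participant)
  # cluster-level sufficient statistics
  wX <- X * weights
  wy <- y * weights
  id_sw <- drop(rowsum(weights, id))
  id_m <- rowsum(wX, id)
  id_r <- drop(rowsum(wy, id))
  XtWX <- crossprod(X, wX)
  XtWy <- drop(crossprod(X, wy))
  ytWy <- sum(y * wy)
  sum_log_w <- sum(log(weights))
  m2ll_prof <- function(log_theta) {
    core <- ri_core(exp(log_theta), X, y, weights, id_sw, id_m, id_r,
                    XtWX, XtWy, ytWy, sum_log_w)
    if (is.null(core)) return(1e10)
    (n - p) * log(core$rss) + core$logdetV0 + core$logdetXtVX
  }
  # coarse deterministic grid, then golden-section refinement
  grid <- seq(-14, 8, by = 2)
  vals <- vapply(grid, m2ll_prof, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- optimize(m2ll_prof, c(lo, hi), tol = 1e-7)
  theta <- exp(opt$minimum)
  # boundary: essentially zero random-intercept variance
  if (m2ll_prof(-14) <= opt$objective + 1e-10) theta <- exp(-14)
  core <- ri_core(theta, X, y, weights, id_sw, id_m, id_r,
                  XtWX, XtWy, ytWy, sum_log_w)
  sigma_e2 <- core$rss / (n - p)
  sigma_u2 <- theta * sigma_e2
  Cinv <- chol2inv(core$chol)               # (X' V0^-1 X)^-1
  vcov_beta <- sigma_e2 * Cinv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  structure(list(
    beta = setNames(drop(core$beta), colnames(X)),
    vcov = vcov_beta,
    sigma_u2 = if (theta <= exp(-13.9)) 0 else sigma_u2,
    sigma_e2 = sigma_e2,
    theta = theta,
    n = n, p = p,
    converged = is.finite(opt$objective),
    m2ll = opt$objective,
    cache = list(X = X, y = y, w = weights, id_sw = id_sw, id_m = id_m,
                 id_r = id_r, XtWX = XtWX, XtWy = XtWy, ytWy = ytWy,
                 sum_log_w = sum_log_w)),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("random-intercept LMM: n=%d, p=%d, sigma_u^2=%.4g, sigma_e^2=%.4g\n",
              x$n, x$p, x$sigma_u2, x$sigma_e2))
  print(x$beta)
  invisible(x)
}

# -2 REML log-likelihood as a function of (sigma_u2, sigma_e2); used for
# the Satterthwaite Hessian.
ri_m2ll_var <- function(su2, se2, fit) {
  ca <- fit$cache
  n <- fit$n; p <- fit$p
  theta <- su2 / se2
  core <- ri_core(theta, ca$X, ca$y, ca$w, ca$id_sw, ca$id_m, ca$id_r,
                  ca$XtWX, ca$XtWy, ca$ytWy, ca$sum_log_w)
  if (is.null(core)) return(1e10)
  (n - p) * log(se2) + core$logdetV0 + core$logdetXtVX + core$rss / se2
}

# Var(L beta) as a function of the variance components.
ri_varL <- function(su2, se2, fit, L) {
  ca <- fit$cache
  theta <- su2 / se2
  core <- ri_core(theta, ca$X, ca$y, ca$w, ca$id_sw, ca$id_m, ca$id_r,
                  ca$XtWX, ca$XtWy, ca$ytWy, ca$sum_log_w)
  if (is.null(core)) return(NA_real_)
  u <- backsolve(core$chol, forwardsolve(t(core$chol), L))
  se2 * sum(L * u)
}

#' Test a linear contrast of an LMM fit with Satterthwaite df
#'
#' Computes the contrast estimate, its standard error from the
#' fixed-effect covariance, Satterthwaite-approximated denominator degrees
#' of freedom (delta method on Var(Lb) over the REML variance components,
#' with the component covariance taken as twice the inverse Hessian of the
#' -2 REML log-likelihood), and the two-sided t p-value.
#'
#' @param fit an `lmm_fit` from [fit_feature_lmm()].
#' @param contrast a `contrast_spec` (weights over design cells) or a
#'   numeric vector of length `ncol(X)`.
#' @return list: estimate, se, df, p.
#' @export
test_contrast <- function(fit, contrast) {
  p <- fit$p
  nm <- names(fit$beta)
  if (inherits(contrast, "contrast_spec")) {
    missing_cells <- setdiff(names(contrast$weights), nm)
    if (length(missing_cells))
      stop("contrast touches cell(s) absent from the fit: ",
           paste(missing_cells, collapse = ", "))
    L <- setNames(numeric(p), nm)
    L[names(contrast$weights)] <- contrast$weights
  } else {
    stopifnot(length(contrast) == p)
    L <- as.numeric(contrast)
  }
  est <- sum(L * fit$beta)
  varL <- drop(L %*% fit$vcov %*% L)
  se <- sqrt(varL)
  df <- satterthwaite_df(fit, L)
  tval <- est / se
  list(estimate = est, se = se, df = df,
       p = 2 * pt(-abs(tval), df))
}

satterthwaite_df <- function(fit, L) {
  su2 <- max(fit$sigma_u2, 1e-8 * fit$sigma_e2)
  se2 <- fit$sigma_e2
  g0 <- ri_varL(su2, se2, fit, L)
  # numerical gradient of Var(L beta) wrt (su2, se2)
  hu <- max(su2 * 1e-4, 1e-10); he <- se2 * 1e-4
  grad <- c((ri_varL(su2 + hu, se2, fit, L) - ri_varL(max(su2 - hu, 0), se2, fit, L)) /
              (hu + min(su2, hu)),
            (ri_varL(su2, se2 + he, fit, L) - ri_varL(su2, se2 - he, fit, L)) / (2 * he))
  # Hessian of -2 REML loglik wrt (su2, se2), central differences
  Hu <- max(su2 * 1e-3, 1e-9); He <- se2 * 1e-3
  f <- function(a, b) ri_m2ll_var(max(a, 0), b, fit)
  H <- matrix(0, 2, 2)
  H[1, 1] <- (f(su2 + Hu, se2) - 2 * f(su2, se2) + f(su2 - Hu, se2)) / Hu^2
  H[2, 2] <- (f(su2, se2 + He) - 2 * f(su2, se2) + f(su2, se2 - He)) / He^2
  H[1, 2] <- H[2, 1] <- (f(su2 + Hu, se2 + He) - f(su2 + Hu, se2 - He) -
                           f(su2 - Hu, se2 + He) + f(su2 - Hu, se2 - He)) /
    (4 * Hu * He)
  df_fallback <- fit$n - fit$p
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(A)) return(df_fallback)
  denom <- drop(grad %*% A %*% grad)
  if (!is.finite(denom) || denom <= 0) return(df_fallback)
  df <- 2 * g0^2 / denom
  if (!is.finite(df) || df < 1) df <- 1
  min(df, 1e6)
}
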