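#' Fleishman power-method coefficients for a target skewness and kurtosis
#'
#' Solves for (a, b, c, d) with a = -c such that Y = a + bZ + cZ^2 + dZ^3,
#' Z ~ N(0,1), has mean 0, variance 1, skewness `skew` and excess kurtosis
#' `exkurt`. The three moment equations are solved by Newton iteration with
#' a fixed starting point, so the result is deterministic in the inputs.
#'
#' @param skew target marginal skewness (gamma1).
#' @param exkurt target marginal excess kurtosis (gamma2).
#' @param tol residual tolerance on the moment equations.
#' @return list of class `fleishman_coeffs` with elements a, b, c, d.
#' @details Attainability requires `exkurt >= skew^2 - 2`; infeasible pairs
#'   error. Within that bound the power method covers most but not all
#'   pairs; non-convergence of the moment equations also errors.
#' @export
fleishman_solve <- function(skew, exkurt, tol = 1e-8) {
  if (exkurt < skew^2 - 2)
    stop(sprintf(paste("(skew=%.3g, exkurt=%.3g) is infeasible:",
                       "attainability requires exkurt >= skew^2 - 2 = %.3g"),
                 skew, exkurt, skew^2 - 2))
  if (abs(skew) < 1e-12 && abs(exkurt) < 1e-12) {
    out <- list(a = 0, b = 1, c = 0, d = 0)
    class(out) <- "fleishman_coeffs"
    return(out)
  }
  g1 <- skew; g2 <- exkurt
  fn <- function(par) {
    b <- par[1]; c <- par[2]; d <- par[3]
    c(b^2 + 6 * b * d + 2 * c^2 + 15 * d^2 - 1,
      2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2) - g1,
      24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
              d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2)) - g2)
  }
  # fixed starting point (Fleishman's recommendation)
  par <- c(1, 0.15 * sign(g1) * min(abs(g1), 2), 0.05 * sign(g2 + 1e-12) * min(abs(g2), 2) / 4)
  if (abs(g1) < 1e-12) par[2] <- 0
  conv <- FALSE
  for (it in 1:200) {
    f <- fn(par)
    if (max(abs(f)) < tol) { conv <- TRUE; break }
    # numerical Jacobian
    J <- matrix(0, 3, 3)
    h <- 1e-7
    for (j in 1:3) {
      pj <- par; pj[j] <- pj[j] + h
      J[, j] <- (fn(pj) - f) / h
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) stop("Fleishman solve failed: singular Jacobian")
    # damped Newton
    lam <- 1
    repeat {
      cand <- par - lam * step
      if (sum(fn(cand)^2) < sum(f^2) || lam < 1e-4) break
      lam <- lam / 2
    }
    par <- par - lam * step
  }
  if (!conv && max(abs(fn(par))) >= tol)
    stop(sprintf("Fleishman moment equations did not converge for skew=%.3g exkurt=%.3g", g1, g2))
  out <- list(a = -par[2], b = par[1], c = par[2], d = par[3])
  class(out) <- "fleishman_coeffs"
  out
}

#' Theoretical moments of a Fleishman polynomial transform
#'
#' Closed-form mean/variance/skewness/excess kurtosis of
#' a + bZ + cZ^2 + dZ^3 for standard normal Z; used to verify solved
#' coefficients without simulation.
#'
#' @param coeffs a `fleishman_coeffs` object.
#' @return named numeric vector (mean, var, skew, exkurt).
#' @export
fleishman_moments <- function(coeffs) {
  b <- coeffs$b; c <- coeffs$c; d <- coeffs$d
  v <- b^2 + 6 * b * d + 2 * c^2 + 15 * d^2
  g1 <- 2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2)
  g2 <- 24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
                d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2))
  c(mean = coeffs$a + c, var = v, skew = g1, exkurt = g2)
}

#' Vale-Maurelli intermediate correlation
#'
#' Given Fleishman coefficients of two margins and a target (post-transform)
#' correlation, finds the latent normal correlation rho_Z whose transformed
#' pair attains the target: the cubic
#' rho_Y = rho_Z (b_i b_j + 3 b_i d_j + 3 d_i b_j + 9 d_i d_j)
#'       + 2 rho_Z^2 c_i c_j + 6 rho_Z^3 d_i d_j
#' is inverted by root bracketing on \\[-1, 1\\].
#'
#' @param coeffs_i,coeffs_j `fleishman_coeffs` of the two margins.
#' @param target_rho desired correlation of the transformed variables.
#' @param tol root tolerance.
#' @export
intermediate_correlation <- function(coeffs_i, coeffs_j, target_rho, tol = 1e-8) {
  stopifnot(abs(target_rho) <= 1)
  bi <- coeffs_i$b; ci <- coeffs_i$c; di <- coeffs_i$d
  bj <- coeffs_j$b; cj <- coeffs_j$c; dj <- coeffs_j$d
  k1 <- bi * bj + 3 * bi * dj + 3 * di * bj + 9 * di * dj
  k2 <- 2 * ci * cj
  k3 <- 6 * di * dj
  f <- function(r) r * k1 + r^2 * k2 + r^3 * k3 - target_rho
  lo <- f(-1); hi <- f(1)
  if (sign(lo) == sign(hi) && lo != 0 && hi != 0)
    stop(sprintf("target correlation %.3f unattainable for this margin pair; attainable range [%.3f, %.3f]",
                 target_rho, -1 * k1 + k2 - k3, k1 + k2 + k3))
  if (abs(target_rho) < 1e-14) return(0)
  uniroot(f, c(-1, 1), tol = tol)$root
}

# Compile a Vale-Maurelli generator for one subgroup: per-margin Fleishman
# coefficients and the Cholesky factor of the intermediate correlation
# matrix, so repeated draws are cheap.
vm_compile <- function(mean, cov, skew, exkurt) {
  T_ <- length(mean)
  stopifnot(nrow(cov) == T_, ncol(cov) == T_,
            length(skew) == T_, length(exkurt) == T_)
  if (max(abs(cov - t(cov))) > 1e-8) stop("covariance must be symmetric")
  sds <- sqrt(diag(cov))
  if (any(sds <= 0)) stop("zero-variance timepoint in covariance")
  R <- cov / tcrossprod(sds)
  coeffs <- lapply(seq_len(T_), function(t) fleishman_solve(skew[t], exkurt[t]))
  Rz <- diag(T_)
  for (i in seq_len(T_)) for (j in seq_len(T_)) if (i < j) {
    r <- intermediate_correlation(coeffs[[i]], coeffs[[j]], R[i, j])
    Rz[i, j] <- Rz[j, i] <- r
  }
  # guard PSD of the intermediate matrix (VM can push it slightly out)
  ev <- eigen(Rz, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    vals <- pmax(ev$values, 1e-8)
    Rz <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    D <- 1 / sqrt(diag(Rz))
    Rz <- Rz * tcrossprod(D)
  }
  list(mean = mean, sds = sds, coeffs = coeffs, chol = chol(Rz), T = T_)
}

# Draw n participant trajectories (n x T) from a compiled generator.
vm_draw <- function(gen, n) {
  Z <- matrix(rnorm(n * gen$T), n, gen$T) %*% gen$chol
  Y <- Z
  for (t in seq_len(gen$T)) {
    co <- gen$coeffs[[t]]
    z <- Z[, t]
    Y[, t] <- co$a + co$b * z + co$c * z^2 + co$d * z^3
  }
  sweep(sweep(Y, 2, gen$sds, "*"), 2, gen$mean, "+")
}
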