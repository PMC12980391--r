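# Clusters sharing an observation pattern (timepoint positions) and design
# rows can be processed as one matrix block; the benchmark's cell-means
# designs make such bundles large, which is what keeps the GEE and MMRM
# fitters fast enough for 20k-replicate simulation runs.
cluster_bundles <- function(X, y, cluster, pos) {
  idx <- split(seq_along(y), cluster)
  # cheap bundle key when X is a pure indicator design (one 1 per row):
  # the ordered column-index sequence determines both pattern and design
  indicator <- all(rowSums(X != 0) == 1) && all(X %in% c(0, 1))
  keys <- vapply(idx, function(ii) {
    o <- ii[order(pos[ii])]
    if (indicator)
      paste(c(pos[o], max.col(X[o, , drop = FALSE])), collapse = "|")
    else
      paste(c(pos[o], as.vector(X[o, , drop = FALSE])), collapse = "|")
  }, character(1))
  out <- lapply(split(seq_along(idx), keys), function(which_cl) {
    ii1 <- idx[[which_cl[1]]]
    o1 <- ii1[order(pos[ii1])]
    Y <- matrix(vapply(which_cl, function(ci) {
      ii <- idx[[ci]]
      y[ii[order(pos[ii])]]
    }, numeric(length(o1))), ncol = length(o1), byrow = TRUE)
    list(pos = pos[o1], Xc = X[o1, , drop = FALSE], Y = Y,
         n_c = length(which_cl), YtY = crossprod(Y), sy = colSums(Y))
  })
  attr(out, "n_clusters") <- length(idx)
  out
}

#' Gaussian GEE with AR(1) working correlation and sandwich covariance
#'
#' Identity-link generalized estimating equations for repeated measures:
#' the working correlation between two observations of a cluster is
#' `alpha^|pos_s - pos_t|` on the timepoint grid, with `alpha` estimated by
#' the usual lag-1 moment estimator of Pearson residuals. Inference uses
#' the robust (Liang-Zeger) sandwich covariance; by default no
#' small-sample correction is applied, so with few clusters the estimator
#' shows the anti-conservatism this family is known for. A Mancl-DeRouen
#' bias-corrected variant is available.
#'
#' @param y response vector (`NA` dropped).
#' @param X design matrix.
#' @param cluster cluster (participant) identifiers.
#' @param pos integer timepoint positions (AR distance = position
#'   difference).
#' @param correction `"none"` (default) or `"mancl-derouen"`.
#' @param max_iter,tol iteration control.
#' @param bundles optional precomputed [cluster_bundles()] (e.g. shared
#'   with the MMRM fit on the same replicate).
#' @return list: `beta`, `vcov` (sandwich), `vcov_model`, `alpha`, `phi`,
#'   `converged`, `n_clusters`.
#' @export
gee_ar1 <- function(y, X, cluster, pos, correction = c("none", "mancl-derouen"),
                    max_iter = 25, tol = 1e-6, bundles = NULL) {
  correction <- match.arg(correction)
  keep <- !is.na(y)
  if (is.null(bundles)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    cluster <- as.character(cluster)[keep]; pos <- pos[keep]
    bundles <- cluster_bundles(X, y, cluster, pos)
  } else {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
  }
  p <- ncol(X)
  q <- attr(bundles, "n_clusters")
  n <- length(y)
  beta <- qr.coef(qr(X), y)
  alpha <- 0; conv <- FALSE
  for (iter in seq_len(max_iter)) {
    # residual matrices per bundle
    phi_num <- 0; lag_num <- 0; n1 <- 0
    for (b in bundles) {
      mu <- drop(b$Xc %*% beta)
      E <- sweep(b$Y, 2, mu)
      phi_num <- phi_num + sum(E^2)
      d <- diff(b$pos)
      l1 <- which(d == 1)
      if (length(l1)) {
        lag_num <- lag_num + sum(E[, l1, drop = FALSE] * E[, l1 + 1, drop = FALSE])
        n1 <- n1 + length(l1) * b$n_c
      }
    }
    phi <- phi_num / (n - p)
    alpha <- if (n1 > 0) lag_num / (max(n1 - p, 1) * phi) else 0
    alpha <- max(min(alpha, 0.99), -0.99)
    A <- matrix(0, p, p); bvec <- numeric(p)
    rcache <- list()
    for (b in bundles) {
      pk <- paste(b$pos, collapse = ",")
      Rinv <- rcache[[pk]]
      if (is.null(Rinv)) {
        Rinv <- solve(alpha^abs(outer(b$pos, b$pos, "-")))
        rcache[[pk]] <- Rinv
      }
      XtRi <- crossprod(b$Xc, Rinv) / phi
      A <- A + b$n_c * XtRi %*% b$Xc
      bvec <- bvec + drop(XtRi %*% b$sy)
    }
    beta_new <- solve(A, bvec)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new; conv <- TRUE; break
    }
    beta <- beta_new
  }
  Ainv <- solve(A)
  meat <- matrix(0, p, p)
  rcache <- list()
  for (b in bundles) {
    pk <- paste(b$pos, collapse = ",")
    Rinv <- rcache[[pk]]
    if (is.null(Rinv)) {
      Rinv <- solve(alpha^abs(outer(b$pos, b$pos, "-")))
      rcache[[pk]] <- Rinv
    }
    Vinv <- Rinv / phi
    mu <- drop(b$Xc %*% beta)
    E <- sweep(b$Y, 2, mu)
    if (correction == "mancl-derouen") {
      H <- b$Xc %*% Ainv %*% crossprod(b$Xc, Vinv)
      E <- t(solve(diag(nrow = length(b$pos)) - H, t(E)))
    }
    U <- E %*% Vinv %*% b$Xc            # n_c x p, rows u_j^T
    meat <- meat + crossprod(U)
  }
  vcov_sand <- Ainv %*% meat %*% Ainv
  dimnames(vcov_sand) <- list(colnames(X), colnames(X))
  list(beta = setNames(drop(beta), colnames(X)), vcov = vcov_sand,
       vcov_model = Ainv, alpha = alpha, phi = phi, converged = conv,
       n_clusters = q)
}

# duplication map for vech: columns of pairs (a >= b)
vech_pairs <- function(m) {
  idx <- which(lower.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

#' Mixed model for repeated measures (unstructured covariance)
#'
#' Multivariate-normal likelihood fit of `y_i = X_i b + e_i`,
#' `e_i ~ N(0, Sigma[obs_i, obs_i])` with a fully unstructured
#' timepoint-by-timepoint covariance. The mean is profiled out by GLS and
#' `Sigma` is updated by Fisher scoring on its distinct elements with
#' step-halving to maintain positive definiteness, started from the
#' pairwise-complete residual covariance. By default the covariance is
#' estimated by REML (the standard for repeated-measures mixed models,
#' and essential with as few as ~30 participants carrying ~10 mean
#' parameters); `reml = FALSE` gives plain ML.
#'
#' @param y response vector (`NA` dropped).
#' @param X design matrix.
#' @param cluster cluster identifiers.
#' @param pos integer timepoint index (1..T) of each observation.
#' @param n_time total number of timepoints T.
#' @param max_iter scoring iteration cap.
#' @param tol relative log-likelihood convergence tolerance.
#' @param reml use the restricted likelihood (default) or plain ML.
#' @param bundles optional precomputed [cluster_bundles()].
#' @return list: `beta`, `vcov` (model-based GLS covariance), `Sigma`,
#'   `logLik`, `converged`, `n_clusters`.
#' @export
mmrm_unstructured <- function(y, X, cluster, pos, n_time = max(pos),
                              max_iter = 30, tol = 1e-9, bundles = NULL,
                              reml = TRUE) {
  keep <- !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  if (is.null(bundles)) {
    cluster <- as.character(cluster)[keep]; pos <- pos[keep]
    bundles <- cluster_bundles(X, y, cluster, pos)
  }
  p <- ncol(X)
  q <- attr(bundles, "n_clusters")
  beta0 <- qr.coef(qr(X), y)
  # warm start: pairwise-complete covariance of OLS residuals, PD-floored
  Cpw <- matrix(0, n_time, n_time); Np <- matrix(0, n_time, n_time)
  for (b in bundles) {
    mu <- drop(b$Xc %*% beta0)
    sm <- tcrossprod(b$sy, mu)
    Cb <- b$YtY - sm - t(sm) + b$n_c * tcrossprod(mu)
    Cpw[b$pos, b$pos] <- Cpw[b$pos, b$pos] + Cb
    Np[b$pos, b$pos] <- Np[b$pos, b$pos] + b$n_c
  }
  Cpw <- (Cpw + t(Cpw)) / 2 / pmax(Np, 1)
  ev <- eigen(Cpw, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-3 * max(ev$values, 1e-10))
  Sigma <- ev$vectors %*% (lam * t(ev$vectors))
  pr_glob <- vech_pairs(n_time)
  nv <- nrow(pr_glob)
  glob_of <- matrix(0L, n_time, n_time)
  glob_of[cbind(pr_glob[, 1], pr_glob[, 2])] <- seq_len(nv)
  glob_of[cbind(pr_glob[, 2], pr_glob[, 1])] <- seq_len(nv)
  # profiled nll, matrix gradient G = d loglik/d Sigma, and GLS pieces
  evaluate <- function(Sigma) {
    nb <- length(bundles)
    Ws <- vector("list", nb); logdets <- numeric(nb)
    A <- matrix(0, p, p); bvec <- numeric(p)
    for (k in seq_len(nb)) {
      b <- bundles[[k]]
      ch <- tryCatch(chol(Sigma[b$pos, b$pos, drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      W <- chol2inv(ch)
      Ws[[k]] <- W; logdets[k] <- 2 * sum(log(diag(ch)))
      XtW <- crossprod(b$Xc, W)
      A <- A + b$n_c * XtW %*% b$Xc
      bvec <- bvec + drop(XtW %*% b$sy)
    }
    beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    Ainv <- if (reml) tryCatch(solve(A), error = function(e) NULL) else NULL
    if (reml && is.null(Ainv)) return(NULL)
    nll <- 0
    G <- matrix(0, n_time, n_time)
    for (k in seq_len(nb)) {
      b <- bundles[[k]]; W <- Ws[[k]]
      mu <- drop(b$Xc %*% beta)
      sm <- tcrossprod(b$sy, mu)
      C <- b$YtY - sm - t(sm) + b$n_c * tcrossprod(mu)
      nll <- nll + 0.5 * b$n_c * logdets[k] + 0.5 * sum(W * C)
      Gb <- 0.5 * (W %*% C %*% W - b$n_c * W)
      if (reml) {
        WX <- W %*% b$Xc
        Gb <- Gb + 0.5 * b$n_c * WX %*% Ainv %*% t(WX)
      }
      G[b$pos, b$pos] <- G[b$pos, b$pos] + Gb
    }
    if (reml) nll <- nll + 0.5 * determinant(A)$modulus[1]
    list(nll = nll, G = G, beta = beta, A = A, Ws = Ws)
  }
  pinfo <- lapply(bundles, function(b) {
    m <- length(b$pos)
    pr_loc <- vech_pairs(m)
    a <- pr_loc[, 1]; b_ <- pr_loc[, 2]
    sv <- ifelse(a == b_, 1 / sqrt(2), sqrt(2))
    list(a = a, b = b_, ss = tcrossprod(sv),
         gl = glob_of[cbind(b$pos[a], b$pos[b_])])
  })
  st <- evaluate(Sigma)
  if (is.null(st)) stop("initial covariance not positive definite")
  conv <- FALSE
  for (iter in seq_len(max_iter)) {
    # score over vech(Sigma)
    sc <- ifelse(pr_glob[, 1] == pr_glob[, 2],
                 st$G[pr_glob], 2 * st$G[pr_glob])
    Info <- matrix(0, nv, nv)
    for (k in seq_along(bundles)) {
      b <- bundles[[k]]; W <- st$Ws[[k]]
      pi_ <- pinfo[[k]]
      # closed-form information entries:
      # I[(ab),(cd)] = 0.5 n_c s_ab s_cd (W_ac W_bd + W_ad W_bc),
      # s = sqrt(2) off-diagonal, 1/sqrt(2) diagonal
      term <- W[pi_$a, pi_$a] * W[pi_$b, pi_$b] +
        W[pi_$a, pi_$b] * W[pi_$b, pi_$a]
      Il <- 0.5 * b$n_c * pi_$ss * term
      Info[pi_$gl, pi_$gl] <- Info[pi_$gl, pi_$gl] + Il
    }
    step_v <- tryCatch(solve(Info + diag(1e-10 * max(diag(Info)), nv), sc),
                       error = function(e) NULL)
    if (is.null(step_v)) break
    Delta <- matrix(0, n_time, n_time)
    Delta[cbind(pr_glob[, 1], pr_glob[, 2])] <- step_v
    Delta[cbind(pr_glob[, 2], pr_glob[, 1])] <- step_v
    s <- 1; improved <- FALSE
    for (half in 1:12) {
      cand <- evaluate(Sigma + s * Delta)
      if (!is.null(cand) && cand$nll < st$nll) {
        Sigma <- Sigma + s * Delta
        improved <- TRUE
        dll <- st$nll - cand$nll
        st <- cand
        break
      }
      s <- s / 2
    }
    if (!improved) { conv <- TRUE; break }   # no ascent direction left
    if (dll < tol * (abs(st$nll) + 1)) { conv <- TRUE; break }
  }
  vcov <- tryCatch(solve(st$A), error = function(e) matrix(NA_real_, p, p))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(beta = setNames(drop(st$beta), colnames(X)), vcov = vcov,
       Sigma = Sigma, logLik = -st$nll,
       converged = conv, n_clusters = q)
}
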