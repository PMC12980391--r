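# Sparse CCA by rank-1 penalized matrix decomposition of the
# cross-product matrix: alternate soft-thresholded power iterations with
# the L1 budgets enforced by bisection on the threshold.

soft_threshold <- function(x, delta) sign(x) * pmax(abs(x) - delta, 0)

# normalize(soft(a, delta)) with delta chosen so the L1 norm of the
# normalized vector is <= c1 (binary search; delta = 0 if already inside)
l1_projected_unit <- function(a, c1) {
  if (all(a == 0)) return(a)
  u <- a / sqrt(sum(a^2))
  if (sum(abs(u)) <= c1) return(u)
  lo <- 0; hi <- max(abs(a))
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    su <- soft_threshold(a, mid)
    if (all(su == 0)) { hi <- mid; next }
    su <- su / sqrt(sum(su^2))
    if (sum(abs(su)) > c1) lo <- mid else hi <- mid
  }
  su <- soft_threshold(a, hi)
  su / sqrt(sum(su^2))
}

#' Rank-1 sparse canonical pair (penalized matrix decomposition)
#'
#' Finds sparse unit vectors u, v maximizing `u' X' Z v` subject to
#' `||u||_1 <= c_x`, `||v||_1 <= c_z` by alternating soft-thresholded
#' updates (`u <- normalize(soft(X'Z v, delta_u))` and symmetrically for
#' v), each threshold chosen by bisection to meet its L1 budget. With
#' penalties at `sqrt(p)`/`sqrt(q)` no thresholding occurs and the
#' solution is the leading singular pair of `X'Z`.
#'
#' @param X,Z column-standardized matrices (samples x features), same row
#'   count.
#' @param c_x,c_z L1 budgets in `[1, sqrt(ncol(.))]`.
#' @param tol convergence tolerance on successive u.
#' @param max_iter iteration cap.
#' @return list: `u`, `v`, `r` (canonical correlation `cor(Xu, Zv)`),
#'   `objective` (trajectory of `u'X'Zv`, non-decreasing), `converged`.
#' @export
pmd_rank1 <- function(X, Z, c_x, c_z, tol = 1e-8, max_iter = 200) {
  stopifnot(nrow(X) == nrow(Z))
  p <- ncol(X); q <- ncol(Z)
  stopifnot(c_x >= 1, c_x <= sqrt(p) + 1e-9, c_z >= 1, c_z <= sqrt(q) + 1e-9)
  M <- crossprod(X, Z)
  if (all(abs(M) < 1e-14)) stop("cross-product of X and Z is zero")
  pmd_rank1_M(M, c_x, c_z, tol, max_iter, X = X, Z = Z)
}

# core on a (possibly deflated) cross-product matrix
pmd_rank1_M <- function(M, c_x, c_z, tol = 1e-8, max_iter = 200,
                        X = NULL, Z = NULL) {
  sv <- svd(M, nu = 1, nv = 1)
  v <- drop(sv$v)
  v <- v / sqrt(sum(v^2))
  u <- numeric(nrow(M))
  obj_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u_new <- l1_projected_unit(drop(M %*% v), c_x)
    v <- l1_projected_unit(drop(crossprod(M, u_new)), c_z)
    obj_trace <- c(obj_trace, drop(u_new %*% M %*% v))
    if (it > 1 && sqrt(sum((u_new - u)^2)) < tol) {
      u <- u_new; converged <- TRUE; break
    }
    u <- u_new
  }
  names(u) <- rownames(M); names(v) <- colnames(M)
  r <- if (!is.null(X) && !is.null(Z)) {
    xu <- drop(X %*% u); zv <- drop(Z %*% v)
    if (sd(xu) < 1e-12 || sd(zv) < 1e-12) 0 else cor(xu, zv)
  } else NA_real_
  # sign convention: the largest-|loading| v entry is positive (flipping
  # both vectors leaves the canonical correlation unchanged)
  if (sign(v[which.max(abs(v))]) < 0) { u <- -u; v <- -v }
  list(u = u, v = v, r = r, objective = obj_trace, converged = converged)
}

#' Permutation tuning of the sparsity penalties
#'
#' For each penalty pair on the grid, compares the Fisher-z of the real
#' canonical correlation with its null distribution over row-permuted X
#' (mean/SD of the permuted Fisher-z), and selects the pair with the
#' largest standardized gap. Deterministic given the seed.
#'
#' @param X,Z column-standardized matrices.
#' @param grid data.frame with columns `c_x`, `c_z` (or `NULL` for a
#'   default geometric grid over the feasible range).
#' @param n_perm permutations (minimum 50 enforced).
#' @param seed RNG seed.
#' @return list: `best` (row of `grid`), `table` (grid with r, z per
#'   point), `n_perm`.
#' @export
permutation_tune <- function(X, Z, grid = NULL, n_perm = 1000, seed = 1) {
  if (n_perm < 50) stop("at least 50 permutations are required")
  p <- ncol(X); q <- ncol(Z)
  if (is.null(grid)) {
    fx <- seq(0.1, 0.7, by = 0.1)
    grid <- data.frame(c_x = pmax(1, fx * sqrt(p)), c_z = pmax(1, fx * sqrt(q)))
  }
  stopifnot(nrow(grid) >= 1, all(c("c_x", "c_z") %in% names(grid)))
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(nrow(X)), simplify = FALSE)
  fisher_z <- function(r) atanh(pmin(pmax(r, -0.999999), 0.999999))
  zs <- rs <- numeric(nrow(grid))
  skipped <- logical(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fit <- pmd_rank1(X, Z, grid$c_x[g], grid$c_z[g])
    rs[g] <- fit$r
    zp <- vapply(perms, function(pm) {
      f <- tryCatch(pmd_rank1(X[pm, , drop = FALSE], Z,
                              grid$c_x[g], grid$c_z[g], max_iter = 50),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else fisher_z(f$r)
    }, numeric(1))
    zp <- zp[is.finite(zp)]
    if (length(zp) < 2 || sd(zp) < 1e-12) { skipped[g] <- TRUE; next }
    zs[g] <- (fisher_z(fit$r) - mean(zp)) / sd(zp)
  }
  tab <- cbind(grid, r = rs, z = zs, skipped = skipped)
  usable <- which(!skipped)
  if (!length(usable)) stop("no usable grid point (all permutation SDs zero)")
  best <- usable[which.max(zs[usable])]
  list(best = grid[best, ], table = tab, n_perm = n_perm)
}

#' Extract successive sparse canonical variates
#'
#' Fits K rank-1 sparse pairs, deflating the cross-product matrix after
#' each (`M <- M - d * u v'` with `d = u' M v`, the PMD convention), and
#' reports each variate's weights and canonical correlation with a
#' largest-|trait-loading|-positive sign convention.
#'
#' @param X,Z column-standardized matrices.
#' @param c_x,c_z penalties (e.g. from [permutation_tune()]).
#' @param K number of variates.
#' @return object of class `cca_model`: lists `u`, `v`, vector `r`,
#'   `penalties`, and a long-format `loadings` data.frame.
#' @export
extract_variates <- function(X, Z, c_x, c_z, K = 3) {
  M <- crossprod(X, Z)
  if (all(abs(M) < 1e-14)) stop("cross-product of X and Z is zero")
  us <- vs <- list(); rsv <- numeric(0)
  for (k in seq_len(K)) {
    if (max(abs(M)) < 1e-12) {
      warning("cross-product numerically zero after ", k - 1,
              " variates; returning fewer")
      break
    }
    fit <- pmd_rank1_M(M, c_x, c_z, X = X, Z = Z)
    us[[k]] <- fit$u; vs[[k]] <- fit$v
    rsv[k] <- fit$r
    d <- drop(fit$u %*% M %*% fit$v)
    M <- M - d * tcrossprod(fit$u, fit$v)
  }
  loadings <- do.call(rbind, lapply(seq_along(us), function(k) {
    rbind(data.frame(variate = k, domain = "x", feature = names(us[[k]]),
                     weight = unname(us[[k]]), stringsAsFactors = FALSE),
          data.frame(variate = k, domain = "z", feature = names(vs[[k]]),
                     weight = unname(vs[[k]]), stringsAsFactors = FALSE))
  }))
  structure(list(u = us, v = vs, r = rsv,
                 penalties = c(c_x = c_x, c_z = c_z),
                 loadings = loadings[loadings$weight != 0, ]),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("sparse CCA: %d variate(s), penalties (%.2f, %.2f)\n",
              length(x$r), x$penalties[1], x$penalties[2]))
  for (k in seq_along(x$r))
    cat(sprintf("  variate %d: r = %.3f, nnz(u) = %d, nnz(v) = %d\n",
                k, x$r[k], sum(x$u[[k]] != 0), sum(x$v[[k]] != 0)))
  invisible(x)
}

#' Standardize columns to mean 0, SD 1
#'
#' Constant columns are dropped with a warning; missing values are
#' mean-imputed (i.e. set to 0 after centering) with an attribute noting
#' the count.
#'
#' @param X numeric matrix.
#' @export
standardize_columns <- function(X) {
  X <- as.matrix(X)
  n_imputed <- sum(is.na(X))
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2, mu)
  Xc[is.na(Xc)] <- 0
  sds <- apply(Xc, 2, sd)
  keep <- sds > 1e-12
  if (!all(keep))
    warning("dropping constant column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  out <- sweep(Xc[, keep, drop = FALSE], 2, sds[keep], "/")
  attr(out, "n_imputed") <- n_imputed
  out
}
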