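planted_xz <- function(n = 80, p = 30, q = 8, seed = 80, noise = 0.5,
                       trait_noise = noise) {
  set.seed(seed)
  f <- rnorm(n)
  X <- matrix(rnorm(n * p, sd = 1), n, p)
  Z <- matrix(rnorm(n * q, sd = 1), n, q)
  active_x <- 1:5; active_z <- 1:2
  X[, active_x] <- X[, active_x] * noise + f
  Z[, active_z] <- Z[, active_z] * trait_noise + f
  colnames(X) <- paste0("met", seq_len(p))
  colnames(Z) <- paste0("trait", seq_len(q))
  list(X = standardize_columns(X), Z = standardize_columns(Z),
       active_x = paste0("met", active_x), active_z = paste0("trait", active_z))
}

test_that("without sparsity the fit equals the leading singular pair", {
  d <- planted_xz()
  p <- ncol(d$X); q <- ncol(d$Z)
  fit <- pmd_rank1(d$X, d$Z, sqrt(p), sqrt(q))
  sv <- svd(crossprod(d$X, d$Z), nu = 1, nv = 1)
  align <- sign(sum(fit$u * sv$u))
  expect_equal(unname(fit$u), align * drop(sv$u), tolerance = 1e-6)
  expect_equal(unname(fit$v), align * drop(sv$v), tolerance = 1e-6)
  expect_true(all(diff(fit$objective) >= -1e-9))   # non-decreasing
})

test_that("duplicated domains give canonical correlation one", {
  set.seed(81)
  X <- standardize_columns(matrix(rnorm(200), 40, 5,
                                  dimnames = list(NULL, paste0("a", 1:5))))
  fit <- pmd_rank1(X, X, sqrt(5), sqrt(5))
  expect_equal(fit$r, 1, tolerance = 1e-6)
})

test_that("an L1 budget of one selects exactly one feature", {
  d <- planted_xz()
  fit <- pmd_rank1(d$X, d$Z, 1, sqrt(ncol(d$Z)))
  expect_equal(sum(fit$u != 0), 1)
  expect_equal(sum(abs(fit$u)), 1, tolerance = 1e-9)
})

test_that("constraints hold at every return", {
  d <- planted_xz()
  for (cx in c(1.5, 2.5, 4)) {
    fit <- pmd_rank1(d$X, d$Z, cx, 1.8)
    expect_lte(sum(fit$u^2), 1 + 1e-9)
    expect_lte(sum(abs(fit$u)), cx + 1e-6)
    expect_lte(sum(abs(fit$v)), 1.8 + 1e-6)
  }
})

test_that("permutation tuning recovers a planted sparse support", {
  # active metabolites individually weak, jointly strong: the tuned
  # penalty must open the support beyond a single feature
  d <- planted_xz(n = 120, noise = 1.5, trait_noise = 0.7)
  tune <- permutation_tune(d$X, d$Z, n_perm = 60, seed = 5)
  fit <- pmd_rank1(d$X, d$Z, tune$best$c_x, tune$best$c_z)
  support <- names(fit$u)[fit$u != 0]
  expect_gte(length(intersect(support, d$active_x)), 4)
  expect_error(permutation_tune(d$X, d$Z, n_perm = 1), "at least 50")
})

test_that("pure noise yields no confident permutation statistic", {
  set.seed(83)
  X <- standardize_columns(matrix(rnorm(50 * 20), 50, 20,
                                  dimnames = list(NULL, paste0("x", 1:20))))
  Z <- standardize_columns(matrix(rnorm(50 * 5), 50, 5,
                                  dimnames = list(NULL, paste0("z", 1:5))))
  tune <- permutation_tune(X, Z, n_perm = 60, seed = 6)
  best_z <- max(tune$table$z[!tune$table$skipped])
  expect_lt(best_z, 3)
})

test_that("successive variates recover two orthogonally planted factors", {
  set.seed(84)
  n <- 120
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- matrix(rnorm(n * 20, sd = 0.4), n, 20)
  Z <- matrix(rnorm(n * 8, sd = 0.4), n, 8)
  X[, 1:4] <- X[, 1:4] + f1;  X[, 5:8] <- X[, 5:8] + f2
  Z[, 1:2] <- Z[, 1:2] + f1;  Z[, 3:4] <- Z[, 3:4] + f2
  colnames(X) <- paste0("m", 1:20); colnames(Z) <- paste0("t", 1:8)
  Xs <- standardize_columns(X); Zs <- standardize_columns(Z)
  mod <- extract_variates(Xs, Zs, c_x = 2.5, c_z = 1.6, K = 2)
  scores1 <- cbind(drop(Xs %*% mod$u[[1]]), drop(Zs %*% mod$v[[1]]))
  scores2 <- cbind(drop(Xs %*% mod$u[[2]]), drop(Zs %*% mod$v[[2]]))
  r11 <- max(abs(cor(scores1[, 1], f1)), abs(cor(scores1[, 1], f2)))
  r22 <- max(abs(cor(scores2[, 1], f1)), abs(cor(scores2[, 1], f2)))
  expect_gt(r11, 0.9)
  expect_gt(r22, 0.9)
  # the two variates pick up different factors
  which1 <- which.max(c(abs(cor(scores1[, 1], f1)), abs(cor(scores1[, 1], f2))))
  which2 <- which.max(c(abs(cor(scores2[, 1], f1)), abs(cor(scores2[, 1], f2))))
  expect_false(which1 == which2)
})

test_that("K = 1 extraction equals the rank-1 fit and domains swap", {
  d <- planted_xz()
  m1 <- extract_variates(d$X, d$Z, 2.5, 1.8, K = 1)
  f1 <- pmd_rank1(d$X, d$Z, 2.5, 1.8)
  expect_equal(m1$u[[1]], f1$u, tolerance = 1e-8)
  expect_equal(m1$r[1], f1$r, tolerance = 1e-8)
  swapped <- pmd_rank1(d$Z, d$X, 1.8, 2.5)
  expect_equal(abs(swapped$u), abs(f1$v), tolerance = 1e-5)
  expect_equal(abs(swapped$v), abs(f1$u), tolerance = 1e-5)
})

test_that("column standardization drops constants and flags imputation", {
  X <- cbind(a = c(1, 2, 3, NA), b = c(5, 5, 5, 5), c = rnorm(4))
  expect_warning(out <- standardize_columns(X), "constant")
  expect_equal(colnames(out), c("a", "c"))
  expect_equal(attr(out, "n_imputed"), 1)
  expect_equal(unname(colMeans(out)), c(0, 0), tolerance = 1e-12)
})
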