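fake_da <- function(fids, est, se, genes = NULL) {
  df <- data.frame(feature_id = fids, contrast = "difference_in_changes",
                   group = "EE", timepoint = "post10",
                   estimate = est, se = se, df = 30,
                   p = 2 * pnorm(-abs(est / se)),
                   stratum_id = "x", stringsAsFactors = FALSE)
  df
}

test_that("z-score matrix keeps the most extreme z per gene with a tie rule", {
  da <- fake_da(c("t1", "t2", "t3"), est = c(1.2, -2.5, 0.4), se = 1)
  map <- data.frame(feature_id = c("t1", "t2", "t3"),
                    gene_symbol = c("G1", "G1", "G2"),
                    stringsAsFactors = FALSE)
  zm <- zscore_matrix(da, map)
  expect_equal(zm["G1", 1], -2.5)
  expect_equal(zm["G2", 1], 0.4)
  # tie on |z|: first feature id wins
  da2 <- fake_da(c("a2", "a1"), est = c(2, -2), se = 1)
  map2 <- data.frame(feature_id = c("a1", "a2"),
                     gene_symbol = c("G", "G"), stringsAsFactors = FALSE)
  expect_equal(unname(zscore_matrix(da2, map2)["G", 1]), -2)
  # unmapped features are dropped and counted
  map3 <- data.frame(feature_id = "t1", gene_symbol = "G1",
                     stringsAsFactors = FALSE)
  zm3 <- zscore_matrix(da, map3)
  expect_equal(attr(zm3, "n_unmapped"), 2)
})

test_that("set filtering enforces size and retention boundaries inclusively", {
  universe <- paste0("g", 1:100)
  coll <- list(keep70 = c(paste0("g", 1:7), paste0("x", 1:3)),   # 7/10 = 70%
               drop60 = c(paste0("g", 1:6), paste0("x", 1:4)),   # 6/10
               small = paste0("g", 1:4),                         # < 5
               full = paste0("g", 11:20))
  out <- filter_sets(coll, universe)
  expect_setequal(names(out), c("keep70", "full"))
  expect_equal(out$keep70, paste0("g", 1:7))
})

test_that("camera with rho = 0 reduces to the two-sample t-test", {
  set.seed(60)
  z <- setNames(rnorm(200), paste0("g", 1:200))
  members <- paste0("g", 1:20)
  r <- camera_pr(z, members, rho = 0)
  tt <- t.test(z[members], z[!(names(z) %in% members)], var.equal = TRUE)
  expect_equal(r$p, tt$p.value, tolerance = 1e-9)
})

test_that("camera agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(61)
  z <- setNames(rnorm(300), paste0("g", 1:300))
  idx <- list(set = paste0("g", sample(300, 40)))
  mine <- camera_pr(z, idx$set, rho = 0.01)
  ref <- limma::cameraPR(z, idx, inter.gene.cor = 0.01, sort = FALSE)
  expect_equal(mine$p, ref$PValue, tolerance = 1e-9)
  expect_equal(mine$direction, ref$Direction)
})

test_that("camera enrichment shrinks monotonically in rho", {
  set.seed(62)
  z <- setNames(c(rnorm(30, 1), rnorm(170)), paste0("g", 1:200))
  members <- paste0("g", 1:30)
  zs <- vapply(c(0, 0.01, 0.05, 0.2), function(r)
    abs(camera_pr(z, members, rho = r)$z_enrich), numeric(1))
  expect_true(all(diff(zs) < 0))
})

test_that("camera p-values are uniform under label permutation", {
  set.seed(63)
  z <- setNames(rnorm(150), paste0("g", 1:150))
  ps <- replicate(500, camera_pr(z, sample(names(z), 25), rho = 0)$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("hypergeometric ORA matches the exact combinatorial count", {
  universe <- paste0("g", 1:20)
  set <- paste0("g", 1:5)
  hits <- paste0("g", 1:5)
  r <- ora(hits, universe, set)
  expect_equal(r$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$overlap, 5L)
  far <- ora(paste0("g", 18:20), universe, set)
  expect_gt(far$p, 0.4)
  expect_equal(ora(character(), universe, set)$p, 1)
})

test_that("ORA equals brute-force enumeration over all hit subsets", {
  universe <- paste0("u", 1:8)
  set <- c("u1", "u2", "u3")
  combs <- combn(universe, 3, simplify = FALSE)
  for (hits in combs) {
    k <- length(intersect(hits, set))
    # P(X >= k) by enumerating equally likely 3-subsets
    exceed <- mean(vapply(combs, function(h)
      length(intersect(h, set)) >= k, TRUE))
    expect_equal(ora(hits, universe, set)$p, exceed, tolerance = 1e-12)
  }
})

test_that("collection adjustment stays within its stratum", {
  res <- data.frame(collection = rep(c("c1", "c2"), each = 3),
                    tissue = "blood", ome = "metabolite_intensity",
                    contrast = "dd", set = paste0("s", 1:6),
                    m = 10, direction = "Up",
                    statistic = 1, p = rep(c(0.01, 0.02, 0.03), 2),
                    stringsAsFactors = FALSE)
  adj <- adjust_collections(res)
  expect_equal(adj$p_adj[1:3], adj$p_adj[4:6])
  expect_equal(adj$p_adj[1:3], brute_bh(c(0.01, 0.02, 0.03)))
})

test_that("GMT collections round-trip", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  gmt <- read_gmt(path)
  expect_equal(gmt, list(setA = c("g1", "g2", "g3"), setB = c("g2", "g4")))
})
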