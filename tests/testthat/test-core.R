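test_that("cell-means design partitions samples and appends covariates", {
  meta <- make_meta(4, groups = c("EE", "RE", "CON"))
  d <- build_cell_means_design(meta)
  expect_equal(ncol(d$X), 6)                        # 3 groups x 2 timepoints
  expect_true(all(rowSums(d$X) == 1))               # indicator partition
  d2 <- build_cell_means_design(meta, covariates = c("sex", "age"))
  expect_equal(ncol(d2$X), 8)                       # 6 cells + 1 + 1
  expect_lt(abs(sum(d2$X[, "age"])), 1e-9)          # centered
})

test_that("cells with no samples are dropped with a warning", {
  meta <- make_meta(4, groups = c("EE", "CON"),
                    timepoints = c("pre", "post10"))
  extra <- make_meta(3, groups = "CON", timepoints = "dur20")
  extra$participant_id <- paste0("x", extra$participant_id)
  extra$sample_id <- paste0("x", extra$sample_id)
  meta <- rbind(meta, extra)
  expect_warning(d <- build_cell_means_design(meta), "EE.dur20")
  expect_false("EE.dur20" %in% colnames(d$X))
  expect_true("CON.dur20" %in% colnames(d$X))
})

test_that("metadata invariants are enforced", {
  meta <- make_meta(3)
  bad <- meta
  bad$group[1] <- "RE"; bad$timepoint[1] <- "dur20"
  expect_error(validate_sample_meta(bad), "during-exercise")
  bad2 <- rbind(meta, meta[1, ])
  bad2$sample_id[nrow(bad2)] <- "dup"
  expect_error(validate_sample_meta(bad2), "duplicate")
  no_pre <- meta[meta$timepoint != "pre" | meta$participant_id != "p001", ]
  expect_warning(validate_sample_meta(no_pre), "unpaired")
})

test_that("delta-delta contrast algebra matches direct arithmetic", {
  meta <- make_meta(4)
  d <- build_cell_means_design(meta)
  ct <- delta_delta_contrast(d$cell_map, "EE", "post10")
  expect_equal(sort(unname(ct$weights)), c(-1, -1, 1, 1))
  expect_equal(sum(ct$weights), 0)
  mu_equal <- setNames(rep(3.7, 4), names(ct$weights))
  expect_equal(sum(ct$weights * mu_equal), 0)
  mu <- setNames(c(2, 1, 0.5, 0.5),
                 c("EE.post10", "EE.pre", "CON.post10", "CON.pre"))
  expect_equal(sum(ct$weights[names(mu)] * mu), 1.0)
  set.seed(7)
  for (i in 1:25) {
    mu <- setNames(rnorm(4), c("EE.post10", "EE.pre", "CON.post10", "CON.pre"))
    expect_equal(sum(ct$weights[names(mu)] * mu),
                 (mu[1] - mu[2]) - (mu[3] - mu[4]),
                 ignore_attr = TRUE)
  }
  expect_error(delta_delta_contrast(d$cell_map, "EE", "post24h"),
               "not present")
})

test_that("group-specific and mode-vs-mode contrasts sum to zero per group", {
  meta <- make_meta(4, groups = c("EE", "RE", "CON"))
  d <- build_cell_means_design(meta)
  gs <- group_specific_contrast(d$cell_map, "CON", "post10")
  expect_equal(sum(gs$weights), 0)
  mm <- mode_vs_mode_contrast(d$cell_map, "post10")
  expect_equal(sum(mm$weights), 0)
  # within-group weight sums are zero for the change-based contrasts
  for (ct in list(delta_delta_contrast(d$cell_map, "RE", "post10"), mm)) {
    grp_of <- sub("\\..*$", "", names(ct$weights))
    expect_true(all(abs(tapply(ct$weights, grp_of, sum)) < 1e-12))
  }
})

test_that("stratified BH matches a brute-force step-up oracle", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # stratum independence: identical strata give identical adjustments
  p <- c(0.01, 0.2, 0.8, 0.01, 0.2, 0.8)
  s <- rep(c("a", "b"), each = 3)
  adj <- bh_adjust(p, s)
  expect_equal(adj[1:3], adj[4:6])
  set.seed(42)
  for (i in 1:8) {
    n <- sample(3:12, 1)
    p <- runif(n)
    p[sample(n, 1)] <- NA
    expect_equal(bh_adjust(p), brute_bh(p))
    strat <- sample(c("s1", "s2"), n, replace = TRUE)
    expected <- rep(NA_real_, n)
    for (st in unique(strat))
      expected[strat == st] <- brute_bh(p[strat == st])
    expect_equal(bh_adjust(p, strat), expected)
  }
})

test_that("OLS on a balanced covariate-free design recovers cell means", {
  meta <- make_meta(5)
  d <- build_cell_means_design(meta)
  set.seed(3)
  y <- rnorm(nrow(meta), mean = match(meta$group, c("EE", "RE", "CON")))
  beta <- qr.coef(qr(d$X), y)
  cells <- paste(meta$group, meta$timepoint, sep = ".")
  expect_equal(unname(beta), unname(c(tapply(y, cells, mean)[names(beta)])))
})

test_that("feature table round-trips through TSV", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  m[2, 3] <- NA
  ft <- feature_table(m, ome = "protein_log")
  path <- tempfile(fileext = ".tsv")
  write_feature_tsv(ft, path)
  back <- read_feature_tsv(path, ome = "protein_log")
  expect_equal(back$values, m)
  expect_error(feature_table(matrix(c(-1, 2, 3, 4), 2,
                                    dimnames = list(NULL, c("a", "b"))),
                             ome = "transcript_counts"),
               "non-negative")
})
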