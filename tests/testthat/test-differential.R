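test_that("pairing filter counts complete pre/post pairs per group", {
  # 2 groups x 4 participants, drop observations to hit the boundary
  meta <- make_meta(4)
  m <- matrix(rnorm(2 * nrow(meta)), 2,
              dimnames = list(c("f_ok", "f_short"), meta$sample_id))
  # f_short: only 2 EE participants observed at post10
  post_ee <- meta$sample_id[meta$group == "EE" & meta$timepoint == "post10"]
  m["f_short", post_ee[1:2]] <- NA
  ft <- feature_table(m, ome = "protein_log")
  d <- build_cell_means_design(meta)
  ct <- delta_delta_contrast(d$cell_map, "EE", "post10")
  elig <- min_pairing_filter(meta, ft, list(ct), min_n = 3)
  expect_true(elig["f_ok", 1])
  expect_false(elig["f_short", 1])
  # exactly 3 pairs is eligible (boundary)
  m2 <- m
  m2["f_short", post_ee[1:2]] <- 0
  m2["f_short", post_ee[1]] <- NA
  elig2 <- min_pairing_filter(meta, feature_table(m2, ome = "protein_log"),
                              list(ct), min_n = 3)
  expect_true(elig2["f_short", 1])
})

test_that("pairing eligibility equals brute-force pair counting", {
  prep <- small_null_prep()
  set.seed(90)
  ps <- sim_preset("adipose")
  ps$scenario$n_features <- 12L
  ps$scenario$seed <- 91L
  ps$scenario$mcar_rate <- 0.3          # aggressive, to stress the filter
  sim <- simulate_longitudinal(ps$moments, ps$scenario)
  d <- build_cell_means_design(sim$meta)
  cts <- list(delta_delta_contrast(d$cell_map, "EE", "post10"),
              delta_delta_contrast(d$cell_map, "EE", "post24h"))
  elig <- min_pairing_filter(sim$meta, sim$table, cts, min_n = 3)
  v <- sim$table$values
  for (i in seq_len(nrow(v))) for (j in seq_along(cts)) {
    ok <- TRUE
    for (g in c("EE", "CON")) {
      npairs <- 0
      for (pid in unique(sim$meta$participant_id[sim$meta$group == g])) {
        s_pre <- sim$meta$sample_id[sim$meta$participant_id == pid &
                                      sim$meta$timepoint == "pre"]
        s_tp <- sim$meta$sample_id[sim$meta$participant_id == pid &
                                     sim$meta$timepoint == cts[[j]]$timepoint]
        if (length(s_pre) && length(s_tp) &&
            !is.na(v[i, s_pre]) && !is.na(v[i, s_tp]))
          npairs <- npairs + 1
      }
      if (npairs < 3) ok <- FALSE
    }
    expect_identical(unname(elig[i, j]), ok)
  }
})

test_that("precision weights are flat for homoscedastic data and trend down for counts", {
  set.seed(92)
  meta <- make_meta(20)
  design <- build_cell_means_design(meta)$X
  # homoscedastic on the log scale: constant log-variance across genes
  mu_g <- runif(1000, 6, 12)
  logc <- mu_g + matrix(rnorm(1000 * nrow(meta), 0, 0.4), 1000)
  counts_flat <- round(2^logc)
  dimnames(counts_flat) <- list(paste0("g", 1:1000), meta$sample_id)
  w <- precision_weights(counts_flat, design)
  expect_lt((max(w) - min(w)) / mean(w), 0.1)
  # NB counts with a strong trend: weight decreasing in mean at low means
  cnt <- simulate_counts(500, meta, disp_asymp = 0.05, disp_scale = 5,
                         seed = 93)$values
  keep <- rowMeans(cnt) > 0
  w2 <- precision_weights(cnt[keep, ], design)
  mlog <- log2(rowMeans(cnt[keep, ]) + 0.5)
  gw <- rowMeans(w2)
  low <- mlog < quantile(mlog, 0.3); high <- mlog > quantile(mlog, 0.7)
  expect_lt(mean(gw[low]), mean(gw[high]))
  expect_error(precision_weights(counts_flat[1:5, ], design), "at least 10")
})

test_that("voom-style weights track the limma reference", {
  skip_if_not_installed("limma")
  set.seed(94)
  meta <- make_meta(15)
  design <- build_cell_means_design(meta)$X
  cnt <- simulate_counts(400, meta, seed = 95)$values
  cnt <- cnt[rowSums(cnt) > 10, ]
  w <- precision_weights(cnt, design)
  ref <- limma::voom(cnt, design)$weights
  expect_gt(cor(log(as.vector(w)), log(as.vector(ref))), 0.95)
})

test_that("planted effects are recovered and the null controls FDR", {
  ps <- sim_preset("blood", effect_size = 1)
  ps$scenario$n_features <- 60L
  ps$scenario$seed <- 96L
  sim <- simulate_longitudinal(ps$moments, ps$scenario)
  res <- run_da(sim$table, sim$meta, contrasts = "delta_delta")
  dd10 <- res[res$timepoint == "post10" & res$contrast == "difference_in_changes", ]
  expect_gt(mean(dd10$significant), 0.8)            # power at delta = 1
  expect_equal(mean(dd10$estimate), 1, tolerance = 0.15)
  # other timepoints carry no effect: few discoveries expected
  other <- res[res$timepoint != "post10", ]
  expect_lt(mean(other$significant), 0.1)
  # pure null
  ps0 <- sim_preset("blood")
  ps0$scenario$n_features <- 80L
  ps0$scenario$seed <- 97L
  sim0 <- simulate_longitudinal(ps0$moments, ps0$scenario)
  res0 <- run_da(sim0$table, sim0$meta, contrasts = "delta_delta")
  expect_lt(mean(res0$significant), 0.05)
})

test_that("a shared time trend is group-significant but delta-delta null", {
  ps <- sim_preset("blood")
  ps$scenario$n_features <- 40L
  ps$scenario$seed <- 98L
  sim <- simulate_longitudinal(ps$moments, ps$scenario)
  # add the same post10 drift to every participant (circadian-style)
  drift <- sim$meta$timepoint == "post10"
  sim$table$values[, drift] <- sim$table$values[, drift] + 1.5
  res <- run_da(sim$table, sim$meta,
                contrasts = c("delta_delta", "group_specific"),
                timepoints = "post10")
  gs_con <- res[res$contrast == "group_specific" & res$group == "CON", ]
  dd <- res[res$contrast == "difference_in_changes", ]
  expect_gt(mean(gs_con$significant), 0.8)
  expect_lt(mean(dd$significant), 0.1)
})

test_that("results are invariant to sample-column permutation", {
  ps <- sim_preset("adipose")
  ps$scenario$n_features <- 8L
  ps$scenario$seed <- 99L
  sim <- simulate_longitudinal(ps$moments, ps$scenario)
  res1 <- run_da(sim$table, sim$meta, contrasts = "delta_delta")
  perm <- sample(ncol(sim$table$values))
  tbl2 <- feature_table(sim$table$values[, perm], ome = sim$table$ome)
  res2 <- run_da(tbl2, sim$meta, contrasts = "delta_delta")
  key <- function(r) r[order(r$feature_id, r$timepoint), ]
  expect_equal(key(res1)$estimate, key(res2)$estimate, tolerance = 1e-6)
  expect_equal(key(res1)$p, key(res2)$p, tolerance = 1e-6)
})
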