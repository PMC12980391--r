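mk <- function(..., ids = NULL) {
  m <- rbind(...)
  rownames(m) <- if (is.null(ids)) paste0("f", seq_len(nrow(m))) else ids
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("duplicate rows are averaged entrywise, missing-aware", {
  m <- mk(c(1, 3), c(3, 1), ids = c("a", "a"))
  expect_equal(unname(average_duplicates(m)), rbind(c(2, 2)))
  m2 <- mk(c(1, NA), c(3, NA), ids = c("a", "a"))
  expect_equal(unname(average_duplicates(m2)), rbind(c(2, NA)))
  m3 <- mk(c(1, 2), c(3, 4))
  expect_identical(average_duplicates(m3), m3)
})

test_that("non-positive intensities are masked", {
  m <- mk(c(-1, 0, 0.5))
  expect_equal(unname(mask_nonpositive(m)), rbind(c(NA, NA, 0.5)))
})

test_that("missingness filter is strict at the boundary", {
  m <- matrix(1, 3, 10, dimnames = list(c("keep20", "drop30", "full"),
                                        paste0("s", 1:10)))
  m[1, 1:2] <- NA          # exactly 20%
  m[2, 1:3] <- NA          # 30%
  fl <- filter_missing(m, 0.20)
  expect_setequal(rownames(fl$values), c("keep20", "full"))
  expect_equal(fl$removed, "drop30")
  complete <- matrix(1, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_identical(filter_missing(complete)$values, complete)
})

test_that("small panels use half-minimum imputation", {
  m <- mk(c(4, 8, NA, 6), c(1, 2, 3, 4), c(5, 5, 5, NA),
          c(9, 9, 9, 9), c(2, 4, 6, 8))
  out <- impute_missing(m)
  expect_equal(out["f1", 3], 2.0)          # half of min 4
  expect_equal(out["f3", 4], 2.5)
  expect_equal(out[!is.na(m)], m[!is.na(m)])  # observed untouched
  expect_identical(impute_missing(out), out)  # idempotent
  bad <- mk(c(NA, NA), c(1, 2))
  expect_error(impute_missing(bad), "no observed")
})

test_that("KNN imputation restores a perfectly duplicated profile", {
  set.seed(33)
  base <- matrix(rnorm(48 * 20, 10), 48, 20)
  twin <- base[1, ] + 0          # exact duplicate of feature 1
  m <- rbind(base, twin)
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  colnames(m) <- paste0("s", 1:20)
  truth <- m["f1", 5]
  m["f1", 5] <- NA
  out <- impute_missing(m)
  expect_equal(out["f1", 5], truth, tolerance = 1e-9)
})

test_that("log2(x+1) boundary values and error path", {
  m <- mk(c(0, 1, 3, NA))
  expect_equal(unname(log2_plus1(m)), rbind(c(0, 1, 2, NA)))
  expect_error(log2_plus1(mk(c(-0.5))), "negative")
})

test_that("median-MAD normalization gates on sex/group association", {
  set.seed(34)
  meta <- make_meta(10)
  m <- matrix(rnorm(40 * nrow(meta), 8), 40,
              dimnames = list(NULL, meta$sample_id))
  nm <- median_mad_normalize(m, meta)
  expect_true(nm$normalized)
  expect_equal(unname(apply(nm$values, 2, median)), rep(0, ncol(m)),
               tolerance = 1e-12)
  expect_equal(unname(apply(nm$values, 2, mad)), rep(1, ncol(m)),
               tolerance = 1e-12)
  # location-scale equivariance: per-sample affine input changes nothing
  resc <- sweep(sweep(m, 2, runif(ncol(m), 0.5, 2), "*"), 2,
                rnorm(ncol(m)), "+")
  expect_equal(median_mad_normalize(resc, meta)$values, nm$values,
               tolerance = 1e-10)
  # a strong sex shift in sample medians trips the gate
  shifted <- m
  shifted[, meta$sex == "F"] <- shifted[, meta$sex == "F"] + 5
  nm2 <- median_mad_normalize(shifted, meta)
  expect_false(nm2$normalized)
  expect_identical(nm2$values, shifted)
  expect_true(any(nm2$gate$p < 0.01, na.rm = TRUE))
  const <- matrix(1, 5, nrow(meta), dimnames = list(NULL, meta$sample_id))
  expect_error(median_mad_normalize(const, meta), "MAD")
})

test_that("PC outlier flags find a planted extreme and only it", {
  set.seed(35)
  m <- matrix(rnorm(60 * 40), 60, 40,
              dimnames = list(paste0("f", 1:60), paste0("s", 1:40)))
  m[, 7] <- m[, 7] + 20           # 20-sigma offset along many features
  flags <- pc_outlier_flags(m, multiplier = 5, n_pcs = 5)
  expect_equal(flags, "s7")
  expect_length(pc_outlier_flags(m, multiplier = 1e6, n_pcs = 5), 0)
  expect_error(pc_outlier_flags(m, n_pcs = 50), "rank")
  expect_error(pc_outlier_flags(cbind(m[, 1:3], NA_s = NA), 5, 2),
               "complete")
})

test_that("proteomics preset flags planted extremes among 300 samples", {
  set.seed(36)
  m <- matrix(rnorm(50 * 300), 50, 300,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:300)))
  planted <- c("s10", "s50", "s150", "s299")
  m[, planted] <- m[, planted] + 12
  flags <- pc_outlier_flags(m, preset = "proteomics")
  expect_setequal(flags, planted)
})

test_that("platform redundancy resolves to the lowest-CV platform", {
  meta <- make_meta(60, groups = "CON", timepoints = "pre")
  sim <- simulate_metabolite_platforms(
    n_features = 25, n_shared = 10,
    platform_cvs = c(A = 0.05, B = 0.25),
    censor_quantile = 0, meta = meta, mcar_rate = 0, seed = 40)
  res <- resolve_redundancy(sim$tables)
  shared <- sim$truth$refmet_id
  chosen <- res$provenance$chosen_platform[
    match(shared, res$provenance$refmet_id)]
  expect_true(all(chosen == sim$truth$best_platform))
  # ids unique to one platform are kept from it regardless of CV
  uniq_b <- grep("^REFMET:B", res$provenance$refmet_id, value = TRUE)
  expect_true(all(res$provenance$chosen_platform[
    res$provenance$refmet_id %in% uniq_b] == "B"))
  # platform without standards competing for an id errors
  nostd <- sim$tables
  nostd$A$feature_meta$is_internal_standard <- FALSE
  expect_error(resolve_redundancy(nostd), "internal standards")
})

test_that("the full chain runs in order and logs feature counts", {
  set.seed(41)
  meta <- make_meta(12)
  n_feat <- 30
  m <- matrix(rlnorm(n_feat * nrow(meta), log(1e3), 1), n_feat,
              dimnames = list(paste0("f", seq_len(n_feat)), meta$sample_id))
  m[1, ] <- -m[1, ]                                  # all non-positive
  m[2, 1:10] <- NA                                   # > 20% missing
  m[5, 3] <- NA                                      # imputable
  ft <- feature_table(m, ome = "metabolite_intensity")
  out <- prep_metabolomics(ft, meta)
  steps <- vapply(out$log$steps, `[[`, "", "step")
  expect_equal(steps, c("average_duplicates", "mask_nonpositive",
                        "filter_missing", "impute", "log2_plus1",
                        "median_mad_normalize", "pc_outlier_flags"))
  counts <- vapply(out$log$steps, `[[`, 0, "features_out")
  expect_true(all(diff(counts) <= 0 | counts[-1] == counts[-length(counts)]))
  expect_equal(nrow(out$table$values), n_feat - 2)   # f1 and f2 removed
  expect_false(anyNA(out$table$values))
})

test_that("prep logs serialise to JSON", {
  set.seed(42)
  meta <- make_meta(8)
  m <- matrix(rlnorm(20 * nrow(meta), log(100), 1), 20,
              dimnames = list(paste0("f", 1:20), meta$sample_id))
  out <- prep_metabolomics(feature_table(m, ome = "metabolite_intensity"),
                           meta)
  path <- tempfile(fileext = ".json")
  write_prep_log_json(out$log, path)
  back <- jsonlite::read_json(path)
  expect_equal(length(back), length(out$log$steps))
  expect_equal(back[[1]]$step, "average_duplicates")
})
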