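# Metabolomics/lipidomics cleaning chain. Fixed order:
# average duplicates -> mask non-positives -> missingness filter ->
# imputation -> log2(x+1) -> (gated) median-MAD normalization ->
# PC outlier flags. Every step appends one record to the prep log.

new_prep_log <- function() {
  structure(list(steps = list()), class = "prep_log")
}

log_step <- function(plog, step, n_in, n_out, flagged = character(),
                     params = list()) {
  plog$steps[[length(plog$steps) + 1L]] <-
    list(step = step, features_in = n_in, features_out = n_out,
         samples_flagged = flagged, parameters = params)
  plog
}

#' @export
print.prep_log <- function(x, ...) {
  for (s in x$steps)
    cat(sprintf("%-22s %5d -> %5d features%s\n", s$step, s$features_in,
                s$features_out,
                if (length(s$samples_flagged))
                  paste0(" [", length(s$samples_flagged), " samples flagged]")
                else ""))
  invisible(x)
}

#' @export
as.data.frame.prep_log <- function(x, ...) {
  do.call(rbind, lapply(x$steps, function(s)
    data.frame(step = s$step, features_in = s$features_in,
               features_out = s$features_out,
               n_samples_flagged = length(s$samples_flagged),
               stringsAsFactors = FALSE)))
}

#' Average rows sharing a metabolite identifier
#'
#' Entry-wise mean over duplicate feature ids, ignoring missing values;
#' cells missing in every duplicate stay missing.
#'
#' @param m numeric matrix with feature ids as rownames.
#' @export
average_duplicates <- function(m) {
  ids <- rownames(m)
  if (!anyDuplicated(ids)) return(m)
  grp <- factor(ids, levels = unique(ids))
  obs <- !is.na(m)
  m0 <- m; m0[!obs] <- 0
  sums <- rowsum(m0, grp)
  cnts <- rowsum(obs + 0, grp)
  out <- sums / cnts               # 0/0 -> NaN where all missing
  out[cnts == 0] <- NA_real_
  rownames(out) <- levels(grp)
  out
}

#' Mask non-positive intensities as missing
#'
#' Raw intensities at or below zero are artefacts of peak integration and
#' are converted to missing before filtering and imputation.
#'
#' @param m intensity matrix.
#' @export
mask_nonpositive <- function(m) {
  m[!is.na(m) & m <= 0] <- NA_real_
  m
}

#' Remove features with excessive missingness
#'
#' A feature is kept iff its missing fraction is at most `threshold`
#' (removal is strictly "greater than", so exactly 20% missing survives
#' the default).
#'
#' @param m matrix.
#' @param threshold maximum tolerated missing fraction, in (0, 1).
#' @return list: `values` (filtered matrix), `removed` (dropped ids).
#' @export
filter_missing <- function(m, threshold = 0.20) {
  stopifnot(threshold > 0, threshold < 1)
  frac <- rowMeans(is.na(m))
  keep <- frac <= threshold
  list(values = m[keep, , drop = FALSE], removed = rownames(m)[!keep])
}

#' Impute remaining missing intensities
#'
#' Datasets with more than `knn_min` features use K-nearest-neighbour
#' imputation in feature space: a missing entry is the
#' correlation-distance-weighted mean of the `k` most similar feature
#' profiles (Pearson correlation over pairwise-complete samples, at least
#' `min_shared` shared observations per pair) observed in that sample.
#' Small panels fall back to half-minimum imputation (each missing entry
#' set to half the feature's minimum observed value). Observed entries are
#' never altered.
#'
#' @param m matrix with every feature observed at least once.
#' @param k neighbours for the KNN branch.
#' @param knn_min feature count above which KNN is used (panels of exactly
#'   `knn_min` features or fewer use half-minimum).
#' @param min_shared minimum pairwise-complete samples for a usable
#'   neighbour.
#' @export
impute_missing <- function(m, k = 10, knn_min = 12, min_shared = 3) {
  if (any(rowSums(!is.na(m)) == 0))
    stop("feature(s) with no observed values; filter before imputing")
  if (!anyNA(m)) return(m)
  if (nrow(m) <= knn_min) return(impute_half_min(m))
  impute_knn(m, k = k, min_shared = min_shared)
}

impute_half_min <- function(m) {
  half_min <- apply(m, 1, function(x) min(x, na.rm = TRUE)) / 2
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- half_min[idx[, 1]]
  m
}

impute_knn <- function(m, k = 10, min_shared = 3) {
  cors <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  shared <- tcrossprod(!is.na(m) + 0)
  cors[shared < min_shared] <- NA
  diag(cors) <- NA
  out <- m
  need <- which(rowSums(is.na(m)) > 0)
  for (i in need) {
    sim <- cors[i, ]
    cand <- which(!is.na(sim))
    if (!length(cand)) { out[i, is.na(m[i, ])] <- impute_half_min(m[i, , drop = FALSE])[is.na(m[i, ])]; next }
    # correlation distance; weights = inverse distance
    dist_i <- 1 - sim[cand]
    ord <- cand[order(dist_i)]
    for (j in which(is.na(m[i, ]))) {
      donors <- ord[!is.na(m[ord, j])]
      donors <- head(donors, k)
      if (!length(donors)) {
        out[i, j] <- min(m[i, ], na.rm = TRUE) / 2
      } else {
        w <- 1 / pmax(1 - cors[i, donors], 1e-12)
        out[i, j] <- sum(w * m[donors, j]) / sum(w)
      }
    }
  }
  out
}

#' Shifted log2 transform
#'
#' `x -> log2(x + 1)`, so intensities in (0, 1) keep positive logs;
#' missing entries stay missing.
#'
#' @param m non-negative matrix.
#' @export
log2_plus1 <- function(m) {
  if (any(m < 0, na.rm = TRUE)) stop("negative values; mask before log transform")
  log2(m + 1)
}

#' Gated per-sample median-MAD normalization
#'
#' Normalizes each sample to median 0 / MAD 1 (MAD scaled by 1.4826) --
#' but only if the gate passes: Kruskal-Wallis tests of per-sample medians
#' and upper quartiles against sex and against sex-stratified training
#' group must all be non-significant at `gate_p`, otherwise apparent
#' technical variation could be biology and the table is returned
#' untouched with the reason recorded.
#'
#' @param m log-scale matrix (samples in columns).
#' @param meta sample metadata with `sex` and `group` columns.
#' @param gate_p gate threshold on the Kruskal-Wallis p-values.
#' @return list: `values`, `normalized` (logical), `gate` (data.frame of
#'   the four tests).
#' @export
median_mad_normalize <- function(m, meta, gate_p = 0.01) {
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  med <- apply(m, 2, median, na.rm = TRUE)
  uq <- apply(m, 2, quantile, probs = 0.75, na.rm = TRUE)
  sexgrp <- interaction(meta$sex, meta$group, drop = TRUE)
  kw <- function(x, g) {
    if (length(unique(g)) < 2) return(NA_real_)
    kruskal.test(x, factor(g))$p.value
  }
  gate <- data.frame(
    statistic = rep(c("median", "upper_quartile"), each = 2),
    factor = rep(c("sex", "sex_group"), 2),
    p = c(kw(med, meta$sex), kw(med, sexgrp),
          kw(uq, meta$sex), kw(uq, sexgrp)),
    stringsAsFactors = FALSE)
  if (any(gate$p < gate_p, na.rm = TRUE))
    return(list(values = m, normalized = FALSE, gate = gate))
  mads <- apply(m, 2, mad, na.rm = TRUE)     # 1.4826 scaling is mad()'s default
  if (any(mads == 0))
    stop("zero MAD for sample(s): ",
         paste(colnames(m)[mads == 0], collapse = ", "))
  list(values = sweep(sweep(m, 2, med), 2, mads, "/"),
       normalized = TRUE, gate = gate)
}

#' Flag outlying samples on principal components
#'
#' PCA on the complete (post-imputation) table; a sample is flagged iff
#' any of its first `n_pcs` PC scores falls outside the boxplot fence
#' `[Q1 - m IQR, Q3 + m IQR]`. Presets follow the QC conventions of the
#' two omes: metabolomics `multiplier = 5, n_pcs = 5`, proteomics
#' `multiplier = 3, n_pcs = 3`.
#'
#' @param m complete matrix (features x samples).
#' @param multiplier IQR fence multiplier.
#' @param n_pcs number of leading components examined.
#' @param preset `"metabolomics"`, `"proteomics"` or `NULL` to use the
#'   explicit parameters.
#' @return character vector of flagged sample ids.
#' @export
pc_outlier_flags <- function(m, multiplier = 5, n_pcs = 5, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("metabolomics", "proteomics"))
    if (preset == "metabolomics") { multiplier <- 5; n_pcs <- 5 }
    else { multiplier <- 3; n_pcs <- 3 }
  }
  if (anyNA(m)) stop("outlier detection requires a complete (imputed) table")
  pca <- prcomp(t(m), center = TRUE, scale. = FALSE)
  if (n_pcs > ncol(pca$x))
    stop(sprintf("n_pcs = %d exceeds the rank (%d)", n_pcs, ncol(pca$x)))
  flagged <- logical(ncol(m))
  for (j in seq_len(n_pcs)) {
    sc <- pca$x[, j]
    qs <- quantile(sc, c(0.25, 0.75))
    fence <- multiplier * (qs[2] - qs[1])
    flagged <- flagged | sc < qs[1] - fence | sc > qs[2] + fence
  }
  colnames(m)[flagged]
}

#' Resolve metabolites measured on multiple platforms
#'
#' For each RefMet id measured on two or more platforms, keeps the
#' measurement from the platform whose internal standards have the lowest
#' coefficient of variation (mean over that platform's standards of
#' sd/mean on the raw intensity scale); ids unique to a platform are kept
#' regardless. Provenance records the losing platforms per id.
#'
#' @param tables named list of [feature_table()]s, one per platform, each
#'   carrying `refmet_id` and `is_internal_standard` feature metadata.
#' @return list: `table` (merged [feature_table()], internal standards
#'   removed), `platform_cv` (named numeric), `provenance` (data.frame:
#'   refmet_id, chosen_platform, losing_platforms).
#' @export
resolve_redundancy <- function(tables) {
  stopifnot(length(tables) >= 2, !is.null(names(tables)))
  cvs <- vapply(names(tables), function(p) {
    ft <- tables[[p]]
    std <- ft$feature_meta$is_internal_standard
    if (!any(std))
      stop("platform '", p, "' has no internal standards")
    vals <- ft$values[std, , drop = FALSE]
    mean(apply(vals, 1, function(x) sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE)))
  }, numeric(1))
  id_map <- lapply(tables, function(ft) {
    keep <- !ft$feature_meta$is_internal_standard &
      !is.na(ft$feature_meta$refmet_id)
    setNames(ft$feature_meta$feature_id[keep], ft$feature_meta$refmet_id[keep])
  })
  all_ids <- unique(unlist(lapply(id_map, names)))
  chosen <- character(length(all_ids)); losers <- character(length(all_ids))
  rows <- list()
  for (i in seq_along(all_ids)) {
    id <- all_ids[i]
    present <- names(id_map)[vapply(id_map, function(x) id %in% names(x), TRUE)]
    best <- present[which.min(cvs[present])]
    chosen[i] <- best
    losers[i] <- paste(setdiff(present, best), collapse = ",")
    ft <- tables[[best]]
    rows[[i]] <- ft$values[id_map[[best]][[id]], , drop = FALSE]
  }
  merged <- do.call(rbind, rows)
  rownames(merged) <- all_ids
  fm <- data.frame(feature_id = all_ids, refmet_id = all_ids,
                   platform = chosen, is_internal_standard = FALSE,
                   stringsAsFactors = FALSE)
  list(table = feature_table(merged, ome = "metabolite_intensity",
                             feature_meta = fm),
       platform_cv = cvs,
       provenance = data.frame(refmet_id = all_ids, chosen_platform = chosen,
                               losing_platforms = losers,
                               stringsAsFactors = FALSE))
}

#' Full metabolomics preprocessing chain
#'
#' Runs the cleaning steps in their fixed order on one platform table and
#' returns the normalized table together with the prep log and outlier
#' flags. Normalization is gated (see [median_mad_normalize()]) for
#' untargeted data and skipped for targeted panels.
#'
#' @param table a [feature_table()] with ome `metabolite_intensity`.
#' @param meta sample metadata (needs `sex` and `group` for the gate).
#' @param untargeted gate-and-normalize when `TRUE`.
#' @param missing_threshold see [filter_missing()].
#' @param outlier_multiplier,outlier_n_pcs see [pc_outlier_flags()].
#' @return list: `table` (processed [feature_table()]), `log` (a
#'   `prep_log`), `outliers`, `normalized`.
#' @export
prep_metabolomics <- function(table, meta, untargeted = TRUE,
                              missing_threshold = 0.20,
                              outlier_multiplier = 5, outlier_n_pcs = 5) {
  m <- table$values
  plog <- new_prep_log()
  n0 <- nrow(m)
  m <- average_duplicates(m)
  plog <- log_step(plog, "average_duplicates", n0, nrow(m))
  n1 <- nrow(m)
  m <- mask_nonpositive(m)
  plog <- log_step(plog, "mask_nonpositive", n1, nrow(m))
  fl <- filter_missing(m, missing_threshold)
  plog <- log_step(plog, "filter_missing", n1, nrow(fl$values),
                   params = list(threshold = missing_threshold,
                                 removed = fl$removed))
  m <- fl$values
  m <- impute_missing(m)
  plog <- log_step(plog, "impute", nrow(m), nrow(m))
  m <- log2_plus1(m)
  plog <- log_step(plog, "log2_plus1", nrow(m), nrow(m))
  normalized <- FALSE
  if (untargeted) {
    nm <- median_mad_normalize(m, meta)
    m <- nm$values
    normalized <- nm$normalized
    plog <- log_step(plog, "median_mad_normalize", nrow(m), nrow(m),
                     params = list(applied = nm$normalized,
                                   gate = nm$gate))
  }
  n_pcs_use <- min(outlier_n_pcs, ncol(m) - 1, nrow(m))
  outliers <- pc_outlier_flags(m, outlier_multiplier, n_pcs_use)
  plog <- log_step(plog, "pc_outlier_flags", nrow(m), nrow(m),
                   flagged = outliers,
                   params = list(multiplier = outlier_multiplier,
                                 n_pcs = n_pcs_use))
  out <- feature_table(m, ome = "metabolite_intensity")
  list(table = out, log = plog, outliers = outliers, normalized = normalized)
}

#' Write a preprocessing log to JSON
#'
#' Serialises a `prep_log` (step names, feature counts in/out, flagged
#' samples, parameters) for provenance alongside the processed table.
#'
#' @param plog a `prep_log` from [prep_metabolomics()].
#' @param path output file path.
#' @export
write_prep_log_json <- function(plog, path) {
  jsonlite::write_json(plog$steps, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
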