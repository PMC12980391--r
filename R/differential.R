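#' Minimum paired-participant eligibility filter
#'
#' A contrast at a during/post timepoint is eligible for a feature only if
#' every group entering the contrast has at least `min_n` participants with
#' observed values at both pre-exercise and that timepoint. Ineligible
#' (feature, contrast) pairs are excluded from modelling and from the BH
#' test count of their stratum.
#'
#' @param meta sample metadata.
#' @param table a [feature_table()] (missing entries count as unobserved).
#' @param contrasts list of `contrast_spec` objects.
#' @param min_n minimum complete pre/timepoint pairs per group.
#' @return logical matrix, features x contrasts, `TRUE` = eligible.
#' @export
min_pairing_filter <- function(meta, table, contrasts, min_n = 3) {
  v <- table$values
  stopifnot(all(colnames(v) %in% meta$sample_id))
  ord <- match(colnames(v), meta$sample_id)
  grp <- meta$group[ord]; tp <- meta$timepoint[ord]
  pid <- meta$participant_id[ord]
  obs <- !is.na(v)
  elig <- matrix(FALSE, nrow(v), length(contrasts),
                 dimnames = list(rownames(v),
                                 vapply(contrasts, contrast_label, "")))
  for (j in seq_along(contrasts)) {
    ct <- contrasts[[j]]
    groups <- unique(c(ct$group_a, ct$group_b))
    ok <- rep(TRUE, nrow(v))
    for (g in groups) {
      pre_cols <- which(grp == g & tp == "pre")
      tp_cols <- which(grp == g & tp == ct$timepoint)
      pre_pid <- pid[pre_cols]; tp_pid <- pid[tp_cols]
      both <- intersect(pre_pid, tp_pid)
      if (length(both) < min_n) { ok[] <- FALSE; break }
      # per-feature count of participants observed at both ends
      pre_obs <- obs[, pre_cols[match(both, pre_pid)], drop = FALSE]
      tp_obs <- obs[, tp_cols[match(both, tp_pid)], drop = FALSE]
      ok <- ok & (rowSums(pre_obs & tp_obs) >= min_n)
    }
    elig[, j] <- ok
  }
  elig
}

contrast_label <- function(ct) {
  paste(ct$kind, ct$group_a, ct$timepoint, sep = ":")
}

#' Count precision weights from the mean-variance trend
#'
#' voom-style observation weights for transcript counts: per-gene
#' square-root residual standard deviations from an unweighted log-CPM fit
#' are smoothed against mean log2 count (lowess, span 0.5) and each
#' observation's weight is the predicted fourth inverse power of the trend
#' at its fitted log-count. Genes below the trend's support are clamped to
#' the boundary.
#'
#' @param counts count matrix (genes x samples).
#' @param design design matrix for the unweighted first-pass fit.
#' @param lib_size optional library sizes (default column sums).
#' @param span lowess span.
#' @return matrix of positive weights, same dimension as `counts`.
#' @export
precision_weights <- function(counts, design, lib_size = colSums(counts),
                              span = 0.5) {
  if (nrow(counts) < 10)
    stop("need at least 10 genes to estimate a mean-variance trend")
  n <- ncol(counts)
  y <- t(log2(t(counts + 0.5) / (lib_size + 1) * 1e6))
  fit <- lm.fit(design, t(y))
  res <- t(fit$residuals)
  df_res <- n - fit$rank
  if (df_res < 1) stop("no residual degrees of freedom for the trend fit")
  sqrt_sd <- sqrt(sqrt(rowSums(res^2) / df_res))
  mean_logc <- rowMeans(y) + mean(log2(lib_size + 1)) - log2(1e6)
  if (sd(mean_logc) < 1e-10 || all(sqrt_sd < 1e-12))
    stop("degenerate mean-variance trend (all counts identical?)")
  lo <- lowess(mean_logc, sqrt_sd, f = span)
  # fitted log-count per observation, clamped into the trend's support
  beta <- fit$coefficients
  fitted_y <- t(design %*% beta)
  fitted_logc <- t(t(fitted_y) + log2(lib_size + 1) - log2(1e6))
  fitted_logc[fitted_logc < min(lo$x)] <- min(lo$x)
  fitted_logc[fitted_logc > max(lo$x)] <- max(lo$x)
  pred <- approx(lo$x, lo$y, xout = as.vector(fitted_logc), ties = mean)$y
  pred <- pmax(pred, 1e-6)
  w <- matrix(pred^-4, nrow(counts), ncol(counts))
  dimnames(w) <- dimnames(counts)
  w
}

#' Run the difference-in-changes differential-abundance analysis
#'
#' The primary analysis engine: for every eligible feature x contrast, fit
#' the cell-means random-intercept linear mixed model (with count
#' precision weights for the transcript ome), test the contrast with
#' Satterthwaite df, and adjust p-values by Benjamini-Hochberg within each
#' contrast-group-tissue-ome-timepoint stratum.
#'
#' @param table a [feature_table()] (preprocessed: normalized log-scale
#'   values, or filtered raw counts for `transcript_counts`).
#' @param meta sample metadata covering the table's columns.
#' @param contrasts `"delta_delta"`, `"group_specific"`, `"mode_vs_mode"`
#'   or any subset; contrasts whose cells are absent are skipped with a
#'   message in the `skipped` attribute.
#' @param covariates covariate columns of `meta` to adjust for.
#' @param timepoints during/post timepoints to test (default: all
#'   observed).
#' @param tissue tissue label used in the stratum id.
#' @param min_n minimum paired participants per group (see
#'   [min_pairing_filter()]).
#' @param fdr significance threshold applied to the adjusted p-values.
#' @return data.frame of class `da_result`: feature_id, contrast fields,
#'   estimate (log2-scale effect), se, df, p, p_adj, stratum_id,
#'   significant; failures are collected in the `failures` attribute.
#' @export
run_da <- function(table, meta, contrasts = "delta_delta",
                   covariates = character(), timepoints = NULL,
                   tissue = "blood", min_n = 3, fdr = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  meta <- meta[match(colnames(table$values), meta$sample_id), , drop = FALSE]
  design <- build_cell_means_design(meta, covariates)
  tps <- intersect(TIMEPOINTS, unique(meta$timepoint))
  tps <- setdiff(tps, "pre")
  if (!is.null(timepoints)) tps <- intersect(tps, timepoints)
  specs <- list()
  for (tp in tps) {
    for (kind in contrasts) {
      make <- switch(kind,
        delta_delta = function(g) delta_delta_contrast(design$cell_map, g, tp),
        group_specific = function(g) group_specific_contrast(design$cell_map, g, tp),
        mode_vs_mode = function(g) mode_vs_mode_contrast(design$cell_map, tp),
        stop("unknown contrast kind: ", kind))
      groups <- switch(kind,
        delta_delta = intersect(c("EE", "RE"), unique(meta$group)),
        group_specific = unique(meta$group),
        mode_vs_mode = "RE")
      for (g in groups) {
        ct <- tryCatch(make(g), error = function(e) e)
        if (inherits(ct, "error")) next
        specs[[length(specs) + 1L]] <- ct
      }
    }
  }
  if (!length(specs)) stop("no estimable contrasts for this design")
  elig <- min_pairing_filter(meta, table, specs, min_n = min_n)
  weights <- NULL
  values <- table$values
  if (table$ome == "transcript_counts") {
    weights <- precision_weights(values, design$X)
    values <- t(log2(t(values + 0.5) / (colSums(values) + 1) * 1e6))
  }
  rows <- vector("list", nrow(values) * length(specs))
  failures <- list()
  k <- 0L
  for (i in seq_len(nrow(values))) {
    y <- values[i, ]
    if (!any(elig[i, ])) next
    fit <- tryCatch(
      fit_feature_lmm(y, design$X, meta$participant_id,
                      weights = if (!is.null(weights)) weights[i, ] else NULL),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[rownames(values)[i]]] <- conditionMessage(fit)
      next
    }
    for (j in seq_along(specs)) {
      if (!elig[i, j]) next
      ct <- specs[[j]]
      tc <- tryCatch(test_contrast(fit, ct), error = function(e) e)
      if (inherits(tc, "error")) {
        failures[[paste(rownames(values)[i], contrast_label(ct), sep = "|")]] <-
          conditionMessage(tc)
        next
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        feature_id = rownames(values)[i],
        contrast = ct$kind, group = ct$group_a,
        timepoint = ct$timepoint,
        estimate = tc$estimate, se = tc$se, df = tc$df, p = tc$p,
        stratum_id = stratum_id(ct$kind, ct$group_a, tissue, table$ome,
                                ct$timepoint),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) stop("no feature x contrast passed the pairing filter")
  res <- do.call(rbind, rows[seq_len(k)])
  res$p_adj <- bh_adjust(res$p, res$stratum_id)
  res$significant <- !is.na(res$p_adj) & res$p_adj < fdr
  res <- res[order(res$stratum_id, res$p), ]
  rownames(res) <- NULL
  attr(res, "failures") <- failures
  class(res) <- c("da_result", "data.frame")
  res
}
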