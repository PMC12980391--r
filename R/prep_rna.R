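#' RNA integrity filter
#'
#' Excludes samples whose RIN score is below the threshold (strictly
#' "below": a sample at exactly the threshold is retained). Samples with
#' no RIN value are excluded with a warning.
#'
#' @param meta sample metadata with a `rin` column.
#' @param threshold minimum acceptable RIN.
#' @return character vector of retained sample ids.
#' @export
rin_filter <- function(meta, threshold = 5) {
  if (!"rin" %in% names(meta)) {
    warning("no 'rin' column in metadata; all samples excluded with warning")
    return(character())
  }
  rin <- meta$rin
  no_rin <- is.na(rin)
  if (any(no_rin))
    warning("samples without RIN excluded: ",
            paste(meta$sample_id[no_rin], collapse = ", "))
  meta$sample_id[!no_rin & rin >= threshold]
}

#' Filter lowly expressed genes
#'
#' Default `mode = "keep_expressed"` keeps a gene iff it has CPM above
#' `cpm_cut` in at least `frac` of samples (the edgeR-style reading of
#' "0.5 or fewer counts per million in at least 10% of samples" as the
#' low-expression definition). `mode = "literal"` removes a gene iff the
#' number of samples with CPM at or below `cpm_cut` is at least
#' `frac * N`, the sentence read verbatim -- which discards nearly every
#' gene and is provided for auditability only.
#'
#' @param counts count matrix.
#' @param cpm_cut CPM threshold defining low expression.
#' @param frac sample fraction.
#' @param mode `"keep_expressed"` or `"literal"`.
#' @return filtered count matrix with a `removed` attribute.
#' @export
filter_low_expression <- function(counts, cpm_cut = 0.5, frac = 0.10,
                                  mode = c("keep_expressed", "literal")) {
  mode <- match.arg(mode)
  lib <- colSums(counts)
  stopifnot(all(lib > 0))
  cpm <- t(t(counts) / lib * 1e6)
  n <- ncol(counts)
  keep <- if (mode == "keep_expressed") {
    rowSums(cpm > cpm_cut) >= frac * n
  } else {
    rowSums(cpm <= cpm_cut) < frac * n
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}

#' TMM library-composition scaling factors
#'
#' Trimmed mean of M-values normalization (reference sample chosen by
#' closeness of the 75th-percentile CPM to the mean; 30%/5% trimming on
#' M/A values; inverse asymptotic binomial variance weights; factors
#' rescaled to geometric mean 1), delegated to edgeR's implementation.
#'
#' @param counts count matrix with at least 2 samples and nonzero library
#'   sizes.
#' @return numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts) {
  stopifnot(ncol(counts) >= 2, all(colSums(counts) > 0))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  setNames(as.numeric(f), colnames(counts))
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (factor * libsize + 2 * prior) * 1e6)` using
#' TMM-adjusted effective library sizes.
#'
#' @param counts count matrix.
#' @param factors scaling factors from [tmm_factors()] (default all 1).
#' @param prior prior count added to the numerator (twice to the
#'   denominator).
#' @return log2-CPM matrix.
#' @export
log_cpm <- function(counts, factors = rep(1, ncol(counts)), prior = 0.5) {
  eff_lib <- colSums(counts) * factors
  t(log2((t(counts) + prior) / (eff_lib + 2 * prior) * 1e6))
}

#' Regress technical batch effects out of a normalized table
#'
#' Jointly fits the protected biological design (age, sex and the
#' group-by-timepoint cell means by default) together with the batch
#' columns, then subtracts only the fitted batch component, so variance
#' attributable to the protected design is preserved exactly. Refuses to
#' run when a batch covariate is confounded with the protected design
#' (e.g. an assay batch perfectly collinear with exercise modality).
#'
#' @param logtable normalized features x samples matrix.
#' @param meta sample metadata.
#' @param batch_covariates names of technical covariate columns in `meta`.
#' @param protected names of protected biological covariates (the
#'   group-by-timepoint interaction is always protected).
#' @return adjusted matrix.
#' @export
remove_batch_effects <- function(logtable, meta,
                                 batch_covariates,
                                 protected = c("age", "sex")) {
  if (!length(batch_covariates)) return(logtable)
  meta <- meta[match(colnames(logtable), meta$sample_id), , drop = FALSE]
  protected <- intersect(protected, names(meta))
  design <- build_cell_means_design(meta, covariates = protected)
  cov_mat <- function(cols) {
    pieces <- lapply(cols, function(cv) {
      v <- meta[[cv]]
      if (is.numeric(v)) matrix(v - mean(v), ncol = 1, dimnames = list(NULL, cv))
      else {
        f <- factor(v)
        mm <- model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(f)[-1])
        mm
      }
    })
    do.call(cbind, pieces)
  }
  B <- cov_mat(batch_covariates)
  full <- cbind(design$X, B)
  qr_full <- qr(full)
  if (qr_full$rank < ncol(full)) {
    stop("batch covariate(s) confounded with the protected design; ",
         "removing them would delete biological variance. Aliased: ",
         paste(colnames(full)[qr_full$pivot[(qr_full$rank + 1):ncol(full)]],
               collapse = ", "))
  }
  # joint fit, subtract only the batch component (limma's approach)
  limma::removeBatchEffect(logtable, covariates = B, design = design$X)
}
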