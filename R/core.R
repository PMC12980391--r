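#' @importFrom stats coef complete.cases cor lm lm.fit lowess mad median model.matrix
#'   optimize p.adjust pchisq phyper pnorm pt qnorm quantile rbinom rlnorm rnbinom
#'   rnorm runif sd setNames t.test uniroot var approx kruskal.test prcomp optim
#'   IQR na.omit aggregate
#' @importFrom utils head read.delim write.table
NULL

# Canonical factor levels for the randomized 3-arm acute bout design.
GROUPS <- c("EE", "RE", "CON")
TIMEPOINTS <- c("pre", "dur20", "dur40", "post10", "post30", "post3.5h", "post24h")
TEMPORAL_PROFILES <- c("early", "middle", "late", "all")

#' Assemble sample metadata for a group-by-timepoint repeated-measures design
#'
#' Builds and validates the per-sample metadata table that drives design
#' matrices, contrasts and missingness handling. One row per collected
#' sample; a participant appears once per timepoint.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param participant_id character vector; the clustering unit.
#' @param group one of `"EE"` (endurance), `"RE"` (resistance), `"CON"`
#'   (non-exercise control).
#' @param timepoint one of `"pre"`, `"dur20"`, `"dur40"`, `"post10"`,
#'   `"post30"`, `"post3.5h"`, `"post24h"`. During-exercise draws
#'   (`dur20`/`dur40`) are only valid for EE and CON.
#' @param temporal_profile optional early/middle/late/all randomization label.
#' @param ... further per-sample covariates (sex, age, bmi, site, RIN, batch,
#'   ...), recycled to length.
#' @return A `data.frame` of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, participant_id, group, timepoint,
                        temporal_profile = NULL, ...) {
  meta <- data.frame(sample_id = as.character(sample_id),
                     participant_id = as.character(participant_id),
                     group = as.character(group),
                     timepoint = as.character(timepoint),
                     stringsAsFactors = FALSE)
  if (!is.null(temporal_profile)) meta$temporal_profile <- as.character(temporal_profile)
  extra <- list(...)
  for (nm in names(extra)) meta[[nm]] <- rep(extra[[nm]], length.out = nrow(meta))
  validate_sample_meta(meta)
  class(meta) <- c("sample_meta", "data.frame")
  meta
}

#' Validate sample metadata invariants
#'
#' Checks factor levels, uniqueness of (participant, timepoint), the rule
#' that during-exercise blood exists only for EE and CON, and flags
#' participants lacking a pre-exercise sample.
#'
#' @param meta a data.frame with at least sample_id, participant_id, group,
#'   timepoint columns.
#' @return `meta`, invisibly, with an `unpaired` attribute listing
#'   participants that have no `pre` record.
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "participant_id", "group", "timepoint")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("sample metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id values")
  bad_g <- setdiff(unique(meta$group), GROUPS)
  if (length(bad_g)) stop("unknown group label(s): ", paste(bad_g, collapse = ", "))
  bad_t <- setdiff(unique(meta$timepoint), TIMEPOINTS)
  if (length(bad_t)) stop("unknown timepoint label(s): ", paste(bad_t, collapse = ", "))
  key <- paste(meta$participant_id, meta$timepoint, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (participant_id, timepoint) records")
  dur_bad <- meta$timepoint %in% c("dur20", "dur40") & !(meta$group %in% c("EE", "CON"))
  if (any(dur_bad))
    stop("during-exercise timepoints are collected only for EE and CON; offending samples: ",
         paste(head(meta$sample_id[dur_bad]), collapse = ", "))
  if ("temporal_profile" %in% names(meta)) {
    bad_p <- setdiff(unique(na.omit(meta$temporal_profile)), TEMPORAL_PROFILES)
    if (length(bad_p)) stop("unknown temporal_profile value(s): ", paste(bad_p, collapse = ", "))
  }
  has_pre <- tapply(meta$timepoint == "pre", meta$participant_id, any)
  unpaired <- names(has_pre)[!has_pre]
  if (length(unpaired))
    warning("participants without a pre-exercise sample (unpaired): ",
            paste(head(unpaired), collapse = ", "))
  attr(meta, "unpaired") <- unpaired
  invisible(meta)
}

#' Construct a feature-by-sample abundance table
#'
#' Light container pairing an abundance matrix with its ome type and
#' per-feature annotation. Transcript counts must be complete non-negative
#' integers; intensity/log omes may contain `NA` for missing.
#'
#' @param values numeric matrix, features in rows, samples in columns
#'   (dimnames required).
#' @param ome `"transcript_counts"`, `"protein_log"` or
#'   `"metabolite_intensity"`.
#' @param feature_meta optional data.frame keyed by `feature_id` with
#'   columns such as `gene_symbol`, `refmet_id`, `platform`,
#'   `is_internal_standard`.
#' @return An object of class `feature_table`: a list with elements
#'   `values`, `ome`, `feature_meta`.
#' @export
feature_table <- function(values,
                          ome = c("metabolite_intensity", "protein_log", "transcript_counts"),
                          feature_meta = NULL) {
  ome <- match.arg(ome)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feat", seq_len(nrow(values)))
  if (is.null(colnames(values))) stop("feature table needs sample column names")
  if (ome == "transcript_counts") {
    if (anyNA(values)) stop("transcript counts may not contain missing values")
    if (any(values < 0) || any(values != round(values)))
      stop("transcript counts must be non-negative integers")
  }
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(feature_id = rownames(values), stringsAsFactors = FALSE)
  } else {
    if (!"feature_id" %in% names(feature_meta)) stop("feature_meta needs a feature_id column")
    if (!all(rownames(values) %in% feature_meta$feature_id))
      stop("feature_meta does not cover all features")
    feature_meta <- feature_meta[match(rownames(values), feature_meta$feature_id), , drop = FALSE]
    rownames(feature_meta) <- NULL
  }
  structure(list(values = values, ome = ome, feature_meta = feature_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d features x %d samples, %.1f%% missing\n",
              x$ome, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

cell_name <- function(group, timepoint) paste(group, timepoint, sep = ".")

#' Cell-means design matrix for group-by-timepoint data
#'
#' One indicator column per observed (group, timepoint) cell and no
#' intercept, so every fixed-effect hypothesis is a linear contrast of cell
#' means. Continuous covariates are mean-centered (cell-mean estimates keep
#' their interpretation as adjusted cell means); categorical covariates are
#' one-hot encoded dropping the first level.
#'
#' @param meta sample metadata (see [sample_meta()]).
#' @param covariates character vector of covariate column names in `meta`.
#' @return list with `X` (design matrix, rows named by sample_id),
#'   `cell_map` (named character vector: design column for each observed
#'   cell), `covariate_cols`, and `dropped_cells` (cells of the full
#'   group-by-timepoint grid with no samples, dropped with a warning).
#' @export
build_cell_means_design <- function(meta, covariates = character()) {
  stopifnot(all(covariates %in% names(meta)))
  for (cv in covariates)
    if (anyNA(meta[[cv]]))
      stop("covariate '", cv, "' has missing values; complete covariates are required")
  cells <- cell_name(meta$group, meta$timepoint)
  observed <- unique(cells)
  # deterministic cell order: group major, timepoint minor, canonical levels
  grid <- as.vector(outer(TIMEPOINTS, GROUPS, function(tp, g) cell_name(g, tp)))
  grid <- grid[!(grid %in% cell_name(c("RE", "RE"), c("dur20", "dur40")))]
  observed <- grid[grid %in% observed]
  dropped <- setdiff(intersect(grid, possible_cells(meta)), observed)
  if (length(dropped))
    warning("design cells with no samples dropped: ", paste(dropped, collapse = ", "))
  X_cells <- sapply(observed, function(cl) as.numeric(cells == cl))
  X_cells <- matrix(X_cells, nrow = nrow(meta),
                    dimnames = list(meta$sample_id, observed))
  X_cov <- NULL
  cov_cols <- character()
  if (length(covariates)) {
    pieces <- lapply(covariates, function(cv) {
      v <- meta[[cv]]
      if (is.numeric(v)) {
        m <- matrix(v - mean(v), ncol = 1, dimnames = list(NULL, cv))
      } else {
        f <- factor(v)
        if (nlevels(f) < 2) stop("categorical covariate '", cv, "' has a single level")
        m <- model.matrix(~f)[, -1, drop = FALSE]
        colnames(m) <- paste0(cv, levels(f)[-1])
      }
      m
    })
    X_cov <- do.call(cbind, pieces)
    cov_cols <- colnames(X_cov)
    rownames(X_cov) <- meta$sample_id
  }
  X <- if (is.null(X_cov)) X_cells else cbind(X_cells, X_cov)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  list(X = X,
       cell_map = setNames(observed, observed),
       covariate_cols = cov_cols,
       dropped_cells = dropped)
}

# Cells that could in principle exist for the groups present in meta
# (RE never has during-exercise draws).
possible_cells <- function(meta) {
  out <- character()
  for (g in intersect(GROUPS, unique(meta$group))) {
    tps <- intersect(TIMEPOINTS, unique(meta$timepoint))
    if (g == "RE") tps <- setdiff(tps, c("dur20", "dur40"))
    out <- c(out, cell_name(g, tps))
  }
  out
}

new_contrast <- function(kind, weights, group_a = NA, group_b = NA, timepoint = NA) {
  stopifnot(abs(sum(weights)) < 1e-12)
  structure(list(kind = kind, group_a = group_a, group_b = group_b,
                 timepoint = timepoint, weights = weights),
            class = "contrast_spec")
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat(sprintf("contrast [%s] %s vs %s @ %s\n", x$kind, x$group_a, x$group_b, x$timepoint))
  print(x$weights[x$weights != 0])
  invisible(x)
}

require_cells <- function(design_map, cells) {
  missing_cells <- setdiff(cells, names(design_map))
  if (length(missing_cells))
    stop("contrast requires design cell(s) not present: ",
         paste(missing_cells, collapse = ", "))
}

#' Difference-in-changes (delta-delta) contrast
#'
#' The primary exercise-effect contrast: the change from pre-exercise to a
#' during/post timepoint in an exercise arm, minus the same change in the
#' non-exercising control. Applied to estimated cell means it returns
#' (post - pre in exercise) - (post - pre in control), isolating the
#' exercise response from circadian, fasting and procedural drift.
#'
#' @param design_map the `cell_map` from [build_cell_means_design()].
#' @param exercise_group `"EE"` or `"RE"`.
#' @param timepoint a during/post timepoint present in the design.
#' @param control control arm label, default `"CON"`.
#' @return a `contrast_spec` whose weights are +1 (ex, tp), -1 (ex, pre),
#'   -1 (con, tp), +1 (con, pre).
#' @export
delta_delta_contrast <- function(design_map, exercise_group, timepoint, control = "CON") {
  stopifnot(timepoint != "pre")
  cells <- c(cell_name(exercise_group, timepoint), cell_name(exercise_group, "pre"),
             cell_name(control, timepoint), cell_name(control, "pre"))
  require_cells(design_map, cells)
  w <- setNames(c(1, -1, -1, 1), cells)
  new_contrast("difference_in_changes", w,
               group_a = exercise_group, group_b = control, timepoint = timepoint)
}

#' Group-specific change contrast
#'
#' Post (or during) minus pre within one group, without reference to
#' control; used for effect-size description, not as a primary endpoint.
#'
#' @inheritParams delta_delta_contrast
#' @param group the group whose within-arm change is estimated.
#' @export
group_specific_contrast <- function(design_map, group, timepoint) {
  stopifnot(timepoint != "pre")
  cells <- c(cell_name(group, timepoint), cell_name(group, "pre"))
  require_cells(design_map, cells)
  new_contrast("group_specific", setNames(c(1, -1), cells),
               group_a = group, group_b = group, timepoint = timepoint)
}

#' Resistance-vs-endurance contrast (difference of the two delta-deltas)
#'
#' Compares the pre-to-timepoint change between the two exercise modes:
#' (post - pre in RE) - (post - pre in EE). Control cancels, so this equals
#' the difference of the two difference-in-changes contrasts.
#'
#' @inheritParams delta_delta_contrast
#' @param direct if `TRUE`, compare the two modes' timepoint cell means
#'   directly instead of their changes from pre.
#' @export
mode_vs_mode_contrast <- function(design_map, timepoint, direct = FALSE) {
  stopifnot(timepoint != "pre")
  if (direct) {
    cells <- c(cell_name("RE", timepoint), cell_name("EE", timepoint))
    require_cells(design_map, cells)
    return(new_contrast("mode_vs_mode", setNames(c(1, -1), cells),
                        group_a = "RE", group_b = "EE", timepoint = timepoint))
  }
  cells <- c(cell_name("RE", timepoint), cell_name("RE", "pre"),
             cell_name("EE", timepoint), cell_name("EE", "pre"))
  require_cells(design_map, cells)
  new_contrast("mode_vs_mode", setNames(c(1, -1, -1, 1), cells),
               group_a = "RE", group_b = "EE", timepoint = timepoint)
}

#' Benjamini-Hochberg adjustment within strata
#'
#' Step-up BH FDR adjustment applied independently within each stratum
#' (e.g. each contrast-group-tissue-ome-timepoint combination), never
#' pooling across strata. `NA` p-values propagate `NA` and are excluded
#' from their stratum's test count.
#'
#' @param p numeric vector of p-values in \\[0, 1\\] (NA allowed).
#' @param stratum vector (same length) assigning each p to one stratum;
#'   a single stratum if `NULL`.
#' @return adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p, stratum = NULL) {
  if (is.null(stratum)) stratum <- rep(1L, length(p))
  stopifnot(length(stratum) == length(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    out[idx] <- p.adjust(p[idx], method = "BH")
  }
  out
}

#' Canonical stratum identifier
#'
#' Builds the "contrast|group|tissue|ome|timepoint" string under which BH
#' adjustment is performed, making the per-stratum rule auditable.
#'
#' @param contrast,group,tissue,ome,timepoint character scalars/vectors.
#' @export
stratum_id <- function(contrast, group, tissue, ome, timepoint) {
  paste(contrast, group, tissue, ome, timepoint, sep = "|")
}

#' Read/write helpers for the package's TSV interchange formats
#'
#' `read_feature_tsv`/`write_feature_tsv` exchange feature-by-sample
#' matrices (first column `feature_id`); `read_meta_tsv` reads sample
#' metadata with the mandated column names.
#'
#' @param path file path.
#' @name io_tsv
NULL

#' @rdname io_tsv
#' @export
read_meta_tsv <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_meta(meta)
  class(meta) <- c("sample_meta", "data.frame")
  meta
}

#' @rdname io_tsv
#' @param ome ome tag for the resulting [feature_table()].
#' @export
read_feature_tsv <- function(path, ome = "metabolite_intensity") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  feature_table(m, ome = ome)
}

#' @rdname io_tsv
#' @param x a [feature_table()] or matrix.
#' @export
write_feature_tsv <- function(x, path) {
  m <- if (inherits(x, "feature_table")) x$values else x
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
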