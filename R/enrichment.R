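#' Z-score matrix from differential-analysis results
#'
#' Converts a [run_da()] result table to a genes x contrasts matrix of
#' signed z-scores for set-level enrichment. Per result, z = estimate/se
#' when the SE is available (avoiding p-value underflow), otherwise the
#' signed normal quantile of the two-sided p. When several features map to
#' one gene, only the most extreme z per (gene, contrast) is retained;
#' ties keep the first feature in feature-id order.
#'
#' @param da a `da_result` data.frame.
#' @param feature_map optional data.frame (feature_id, gene_symbol);
#'   features without a mapping are dropped (count recorded in the
#'   `n_unmapped` attribute). `NULL` uses feature ids as gene ids.
#' @param from_se use estimate/se (`TRUE`) or back-transform the p-value.
#' @return numeric matrix, genes x contrasts (contrast label =
#'   "kind:group:timepoint").
#' @export
zscore_matrix <- function(da, feature_map = NULL, from_se = TRUE) {
  z <- if (from_se && all(is.finite(da$se)) && all(da$se > 0)) {
    da$estimate / da$se
  } else {
    p <- pmax(da$p, 1e-300)
    -qnorm(p / 2) * sign(da$estimate)
  }
  gene <- if (is.null(feature_map)) {
    da$feature_id
  } else {
    feature_map$gene_symbol[match(da$feature_id, feature_map$feature_id)]
  }
  contrast <- paste(da$contrast, da$group, da$timepoint, sep = ":")
  ok <- !is.na(gene) & is.finite(z)
  n_unmapped <- sum(!ok)
  gene <- gene[ok]; contrast <- contrast[ok]; z <- z[ok]
  fid <- da$feature_id[ok]
  ord <- order(contrast, gene, -abs(z), fid)
  gene <- gene[ord]; contrast <- contrast[ord]; z <- z[ord]
  first <- !duplicated(paste(contrast, gene, sep = "\r"))
  gene <- gene[first]; contrast <- contrast[first]; z <- z[first]
  genes <- sort(unique(gene)); contrasts <- unique(contrast)
  out <- matrix(NA_real_, length(genes), length(contrasts),
                dimnames = list(genes, contrasts))
  out[cbind(match(gene, genes), match(contrast, contrasts))] <- z
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, tab-separated members).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Filter gene sets against the measured universe
#'
#' Intersects each set with the universe and keeps it iff the intersection
#' has at least `min_size` members AND retains at least `min_frac` of the
#' set's original members (so the surviving members still describe the set
#' label). Both boundaries are inclusive.
#'
#' @param collection named list of character vectors.
#' @param universe measured feature/gene identifiers.
#' @param min_size minimum intersected size.
#' @param min_frac minimum retained fraction of the original set.
#' @return named list of filtered sets (subset of `collection`).
#' @export
filter_sets <- function(collection, universe, min_size = 5, min_frac = 0.70) {
  out <- lapply(collection, function(s) intersect(unique(s), universe))
  orig <- vapply(collection, function(s) length(unique(s)), 1L)
  keep <- vapply(out, length, 1L) >= min_size &
    vapply(out, length, 1L) / orig >= min_frac
  out[keep]
}

#' Correlation-adjusted mean-rank competitive set test (parametric)
#'
#' Pre-ranked competitive test of whether a set's statistics run higher or
#' lower than the rest of the universe: a two-sample comparison of in-set
#' versus out-of-set z-scores whose in-set variance is inflated by
#' VIF = 1 + (m - 1) * rho to account for inter-feature correlation rho.
#' The two-sided p comes from a t reference with G - 2 degrees of freedom
#' (G = universe size). With rho = 0 this reduces to the ordinary equal-
#' variance two-sample t-test.
#'
#' @param z named numeric vector of per-feature statistics (the universe).
#' @param set character vector of member ids (or logical/integer index).
#' @param rho assumed inter-feature correlation within the set.
#' @return list: `z_enrich` (signed standardized enrichment), `direction`
#'   ("Up"/"Down"), `p`, `m` (set size used).
#' @export
camera_pr <- function(z, set, rho = 0.01) {
  stopifnot(is.numeric(z), !is.null(names(z)) || !is.character(set))
  G <- length(z)
  in_set <- if (is.character(set)) names(z) %in% set else {
    tmp <- rep(FALSE, G); tmp[set] <- TRUE; tmp
  }
  m <- sum(in_set)
  if (m == G) stop("set covers the whole universe; no competitive comparison")
  if (m < 2) stop("need at least 2 set members present in the universe")
  m2 <- G - m
  mean_in <- mean(z[in_set]); mean_out <- mean(z[!in_set])
  df <- G - 2
  s2 <- ((m - 1) * var(z[in_set]) + (m2 - 1) * var(z[!in_set])) / df
  vif <- 1 + (m - 1) * rho
  se <- sqrt(s2 * (vif / m + 1 / m2))
  t_stat <- (mean_in - mean_out) / se
  list(z_enrich = t_stat,
       direction = if (t_stat >= 0) "Up" else "Down",
       p = 2 * pt(-abs(t_stat), df),
       m = m)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and a
#' set within a measured universe: P(X >= k) with population `|universe|`,
#' successes `|set n universe|`, draws `|hits|`.
#'
#' @param hits significant feature ids (must lie in `universe`).
#' @param universe background ids (all measured).
#' @param set the gene set.
#' @return list: `overlap`, `expected`, `fold`, `p`.
#' @export
ora <- function(hits, universe, set) {
  universe <- unique(universe)
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  set_u <- intersect(unique(set), universe)
  k <- length(intersect(hits, set_u))
  if (length(hits) == 0)
    return(list(overlap = 0L, expected = 0, fold = NA_real_, p = 1))
  expected <- length(hits) * length(set_u) / length(universe)
  p <- phyper(k - 1, length(set_u), length(universe) - length(set_u),
              length(hits), lower.tail = FALSE)
  list(overlap = k, expected = expected,
       fold = if (expected > 0) k / expected else NA_real_, p = p)
}

#' Enrichment of a collection against a z-score matrix
#'
#' Runs [camera_pr()] (or [ora()] on the significant features) for every
#' set of a filtered collection against every contrast column.
#'
#' @param zmat matrix from [zscore_matrix()].
#' @param collection named list of sets (pre-filter with [filter_sets()]).
#' @param method `"camera"` or `"ora"`.
#' @param rho inter-feature correlation for camera.
#' @param hit_threshold two-sided |z| threshold defining ORA hits.
#' @param collection_name,tissue,ome labels carried into the stratum used
#'   by [adjust_collections()].
#' @return data.frame: collection, tissue, ome, contrast, set, m,
#'   direction, statistic, p.
#' @export
enrich_collection <- function(zmat, collection, method = c("camera", "ora"),
                              rho = 0.01, hit_threshold = qnorm(0.975),
                              collection_name = "sets", tissue = "blood",
                              ome = "metabolite_intensity") {
  method <- match.arg(method)
  rows <- list()
  for (ct in colnames(zmat)) {
    z <- zmat[, ct]
    z <- z[is.finite(z)]
    universe <- names(z)
    for (s in names(collection)) {
      members <- intersect(collection[[s]], universe)
      if (length(members) < 2) next
      if (method == "camera") {
        r <- camera_pr(z, members, rho = rho)
        rows[[length(rows) + 1L]] <- data.frame(
          collection = collection_name, tissue = tissue, ome = ome,
          contrast = ct, set = s, m = r$m, direction = r$direction,
          statistic = r$z_enrich, p = r$p, stringsAsFactors = FALSE)
      } else {
        hits <- universe[abs(z) >= hit_threshold]
        r <- ora(hits, universe, members)
        rows[[length(rows) + 1L]] <- data.frame(
          collection = collection_name, tissue = tissue, ome = ome,
          contrast = ct, set = s, m = length(members),
          direction = NA_character_, statistic = r$fold, p = r$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' BH adjustment within tissue-ome-contrast-collection strata
#'
#' @param results data.frame from [enrich_collection()] (rows from several
#'   collections may be concatenated).
#' @param fdr significance threshold.
#' @return `results` with `p_adj` and `significant` columns.
#' @export
adjust_collections <- function(results, fdr = 0.05) {
  stratum <- paste(results$tissue, results$ome, results$contrast,
                   results$collection, sep = "|")
  results$p_adj <- bh_adjust(results$p, stratum)
  results$significant <- !is.na(results$p_adj) & results$p_adj < fdr
  results
}
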