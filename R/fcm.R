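#' Standardize per-feature temporal trajectories
#'
#' Builds feature x timepoint mean profiles for one group (mean of the
#' normalized values over that group's samples at each timepoint) and
#' z-scores each feature's profile (temporal mean 0, SD 1), so clustering
#' sees shapes, not magnitudes. Constant profiles are dropped and listed
#' in the `dropped` attribute.
#'
#' @param table a [feature_table()] of normalized values.
#' @param meta sample metadata.
#' @param group group whose trajectory is summarized (`NULL` = all
#'   samples).
#' @param timepoints timepoint order (default: observed canonical order).
#' @return features x timepoints matrix of z-profiles.
#' @export
standardize_trajectories <- function(table, meta, group = NULL,
                                     timepoints = NULL) {
  meta <- meta[match(colnames(table$values), meta$sample_id), , drop = FALSE]
  keep <- if (is.null(group)) rep(TRUE, nrow(meta)) else meta$group == group
  v <- table$values[, keep, drop = FALSE]
  tp <- meta$timepoint[keep]
  if (is.null(timepoints)) timepoints <- intersect(TIMEPOINTS, unique(tp))
  prof <- vapply(timepoints, function(t)
    rowMeans(v[, tp == t, drop = FALSE], na.rm = TRUE), numeric(nrow(v)))
  prof <- matrix(prof, nrow = nrow(v),
                 dimnames = list(rownames(v), timepoints))
  ctr <- prof - rowMeans(prof)
  sds <- sqrt(rowSums(ctr^2) / (ncol(prof) - 1))
  const <- sds < 1e-12 | !is.finite(sds)
  out <- ctr[!const, , drop = FALSE] / sds[!const]
  attr(out, "dropped") <- rownames(prof)[const]
  out
}

#' Fuzzy c-means clustering of trajectory profiles
#'
#' Standard Bezdek alternating optimization: memberships
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and centroids
#' `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`, iterated until the objective
#' decreases by less than `tol`. Initialization is k-means++-style
#' (greedy farthest-point seeding on a deterministic RNG stream), so
#' results are reproducible per seed. A feature coinciding with a
#' centroid gets crisp membership 1 there.
#'
#' @param profiles features x timepoints matrix (e.g. from
#'   [standardize_trajectories()]).
#' @param c number of clusters (>= 2).
#' @param m fuzzifier (> 1); `NULL` uses the dimension-based
#'   Schwaemmle-Jensen estimate via [estimate_fuzzifier()].
#' @param seed RNG seed for the initialization.
#' @param tol objective-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `fcm_model`: `centroids` (c x T),
#'   `membership` (features x c, rows sum to 1), `m`, `objective`
#'   (trajectory of values, non-increasing), `iterations`.
#' @export
fcm_fit <- function(profiles, c, m = NULL, seed = 1, tol = 1e-7,
                    max_iter = 500) {
  stopifnot(c >= 2, nrow(profiles) > c)
  if (is.null(m)) m <- estimate_fuzzifier(nrow(profiles), ncol(profiles))
  stopifnot(m > 1)
  X <- as.matrix(profiles)
  n <- nrow(X)
  set.seed(seed)
  # k-means++ seeding
  cent <- matrix(0, c, ncol(X))
  first <- sample.int(n, 1)
  cent[1, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2, cent[1, ])^2)
  for (k in 2:c) {
    prob <- d2 / sum(d2)
    pick <- sample.int(n, 1, prob = prob)
    cent[k, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, cent[k, ])^2))
  }
  expo <- 2 / (m - 1)
  obj_trace <- numeric(0)
  U <- NULL
  for (it in seq_len(max_iter)) {
    D2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(cent) +
      outer(rep(1, n), rowSums(cent^2))
    D2[D2 < 1e-300] <- 1e-300
    U <- 1 / (D2^(expo / 2) * rowSums((1 / D2)^(expo / 2)))
    # crisp assignment for coincident points
    zero <- D2 < 1e-12
    if (any(zero)) {
      hit <- which(rowSums(zero) > 0)
      U[hit, ] <- 0
      U[cbind(hit, max.col(-D2[hit, , drop = FALSE]))] <- 1
    }
    Um <- U^m
    obj <- sum(Um * D2)
    obj_trace <- c(obj_trace, obj)
    cent_new <- (t(Um) %*% X) / colSums(Um)
    if (it > 1 && obj_trace[it - 1] - obj < tol) { cent <- cent_new; break }
    cent <- cent_new
  }
  rownames(cent) <- paste0("cluster", seq_len(c))
  colnames(cent) <- colnames(X)
  dimnames(U) <- list(rownames(X), rownames(cent))
  structure(list(centroids = cent, membership = U, m = m,
                 objective = obj_trace, iterations = length(obj_trace)),
            class = "fcm_model")
}

#' @export
print.fcm_model <- function(x, ...) {
  cat(sprintf("fuzzy c-means: %d clusters, m=%.2f, %d features, %d iterations\n",
              nrow(x$centroids), x$m, nrow(x$membership), x$iterations))
  invisible(x)
}

#' Dimension-based fuzzifier estimate
#'
#' The Schwaemmle-Jensen rule of thumb relating a suitable fuzzifier to
#' feature count N and dimension D:
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#'
#' @param n_features number of clustered features.
#' @param n_dims profile dimension (number of timepoints).
#' @export
estimate_fuzzifier <- function(n_features, n_dims) {
  N <- n_features; D <- n_dims
  1 + (1418 / N + 22.05) * D^-2 +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Choose the cluster number by the minimum-centroid-distance elbow
#'
#' Fits [fcm_fit()] across `c_range`, records the minimum pairwise
#' centroid distance per c (non-increasing in c), and proposes the elbow
#' as the last c before the curve's largest proportional drop -- the
#' second-difference corner of the log-scale curve, which also works when
#' the corner sits at the first candidate. The full curve is returned so
#' the choice can be inspected or overridden.
#'
#' @param profiles see [fcm_fit()].
#' @param c_range candidate cluster numbers (within 2..12).
#' @param m fuzzifier (`NULL` = estimated).
#' @param seed base seed; each candidate c is fit `n_starts` times from
#'   seeds `seed .. seed + n_starts - 1` and the best-objective fit kept.
#' @param n_starts restarts per candidate c.
#' @param override manually chosen c (honoured verbatim when not `NULL`).
#' @return list: `c` (chosen), `curve` (data.frame c / min_dist),
#'   `override` flag.
#' @export
choose_c <- function(profiles, c_range = 2:8, m = NULL, seed = 1,
                     n_starts = 5, override = NULL) {
  stopifnot(all(c_range >= 2), all(c_range <= 12), length(c_range) >= 3)
  c_range <- sort(c_range)
  md <- vapply(c_range, function(cc) {
    fits <- lapply(seq_len(n_starts) - 1L, function(s)
      fcm_fit(profiles, cc, m = m, seed = seed + s))
    objs <- vapply(fits, function(f) min(f$objective), numeric(1))
    min(dist(fits[[which.min(objs)]]$centroids))
  }, numeric(1))
  curve <- data.frame(c = c_range, min_dist = md)
  if (!is.null(override)) {
    return(list(c = override, curve = curve, override = TRUE))
  }
  # elbow: last c before the largest proportional drop of the curve
  ratio <- md[-length(md)] / pmax(md[-1], 1e-12)
  elbow <- c_range[which.max(ratio)]
  list(c = elbow, curve = curve, override = FALSE)
}

#' Metabolite-class enrichment within trajectory clusters
#'
#' For each cluster, tests whether a feature class (e.g. a RefMet
#' chemical subclass) is concentrated in that cluster: the cluster's
#' membership column is the ranking statistic for [camera_pr()] (fallback
#' [ora()] on the cluster core = features assigned to the cluster with
#' membership at least `alpha_core`). BH adjustment within cluster.
#'
#' @param model an `fcm_model`.
#' @param classes named character vector: class label per feature (names =
#'   feature ids).
#' @param alpha_core core membership threshold.
#' @param method `"camera"` or `"ora"`.
#' @param rho camera's inter-feature correlation.
#' @return data.frame: cluster, class, n_core, statistic, p, p_adj.
#' @export
cluster_class_enrichment <- function(model, classes, alpha_core = 0.7,
                                     method = c("camera", "ora"),
                                     rho = 0.01) {
  method <- match.arg(method)
  U <- model$membership
  feats <- rownames(U)
  classes <- classes[feats]
  assigned <- max.col(U)
  rows <- list()
  for (k in seq_len(ncol(U))) {
    core <- feats[assigned == k & U[, k] >= alpha_core]
    if (!length(core)) next
    for (cl in unique(na.omit(classes))) {
      members <- feats[!is.na(classes) & classes == cl]
      if (length(members) < 2) next
      if (method == "camera") {
        stat <- setNames(U[, k], feats)
        r <- tryCatch(camera_pr(stat, members, rho = rho),
                      error = function(e) NULL)
        if (is.null(r)) next
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = k, class = cl, n_core = sum(members %in% core),
          statistic = r$z_enrich, p = r$p, stringsAsFactors = FALSE)
      } else {
        r <- ora(core, feats, members)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = k, class = cl, n_core = r$overlap,
          statistic = r$fold, p = r$p, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p, out$cluster)
  out
}
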