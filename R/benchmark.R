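STRATEGIES <- c("paired_t", "ols", "lmm_ri_weighted", "lmm_ri",
                "mmrm_unstructured", "gee_ar1")

#' Package one simulated replicate for the strategy benchmark
#'
#' Converts a [sim_draw()] replicate into the long-format pieces every
#' analytic strategy consumes: response, cell-means design over observed
#' (group, timepoint) cells, cluster ids, timepoint positions, and the
#' difference-in-changes contrast vector at the tested timepoint.
#'
#' @param draw a replicate from [sim_draw()].
#' @param feature which feature of the replicate to analyse.
#' @param exercise_group,control,timepoint the delta-delta cells tested.
#' @param weights optional per-observation precision weights.
#' @return list used by [apply_strategy()].
#' @export
bench_dataset <- function(draw, feature = 1, exercise_group = "EE",
                          control = "CON", timepoint = "post10",
                          weights = NULL) {
  v <- draw$values[[feature]]
  obs <- which(!is.na(v), arr.ind = TRUE)
  y <- v[obs]
  row_i <- obs[, 1]; col_t <- obs[, 2]
  group <- draw$group[row_i]
  tpname <- draw$timepoints[col_t]
  cells <- paste(group, tpname, sep = ".")
  lev <- sort(unique(cells))
  X <- matrix(0, length(y), length(lev), dimnames = list(NULL, lev))
  X[cbind(seq_along(y), match(cells, lev))] <- 1
  need <- paste(rep(c(exercise_group, control), each = 2),
                c(timepoint, "pre"), sep = ".")
  if (!all(need %in% lev))
    stop("delta-delta cells missing from replicate: ",
         paste(setdiff(need, lev), collapse = ", "))
  L <- setNames(numeric(length(lev)), lev)
  L[need] <- c(1, -1, -1, 1)
  id <- draw$participant[row_i]
  list(y = y, X = X, id = id, pos = col_t,
       tpname = tpname, group = group, n_time = length(draw$timepoints),
       L = L, exercise_group = exercise_group, control = control,
       timepoint = timepoint, weights = weights,
       bundles = cluster_bundles(X, y, id, col_t))
}

#' Apply one analytic strategy to a simulated repeated-measures dataset
#'
#' The six strategies compared by the model-selection benchmark, each
#' producing one p-value for the difference-in-changes hypothesis:
#' `paired_t` (Welch two-sample t on per-participant change scores between
#' the exercise and control arms), `ols` (cell-means least squares ignoring
#' clustering), `lmm_ri` / `lmm_ri_weighted` (random-intercept REML with
#' Satterthwaite df, the weighted flavour carrying count precision
#' weights when supplied), `mmrm_unstructured` (ML multivariate normal
#' with unstructured timepoint covariance, Wald t with between-within df),
#' and `gee_ar1` (AR(1) working-correlation GEE with robust sandwich
#' covariance, Wald z).
#'
#' @param strategy one of `r paste(STRATEGIES, collapse=", ")`.
#' @param dataset a [bench_dataset()].
#' @return list: `p`, `estimate`, `converged`.
#' @export
apply_strategy <- function(strategy = STRATEGIES, dataset) {
  strategy <- match.arg(strategy)
  d <- dataset
  switch(strategy,
    paired_t = {
      pre_idx <- d$tpname == "pre"
      tp_idx <- d$tpname == d$timepoint
      pre <- setNames(d$y[pre_idx], d$id[pre_idx])
      post <- setNames(d$y[tp_idx], d$id[tp_idx])
      common <- intersect(names(pre), names(post))
      ch <- post[common] - pre[common]
      grp <- setNames(d$group[match(common, d$id)], common)
      a <- ch[grp == d$exercise_group]; b <- ch[grp == d$control]
      if (length(a) < 2 || length(b) < 2)
        return(list(p = NA_real_, estimate = NA_real_, converged = FALSE))
      tt <- t.test(a, b)
      list(p = tt$p.value, estimate = unname(diff(rev(tt$estimate))),
           converged = TRUE)
    },
    ols = {
      fit <- lm.fit(d$X, d$y)
      p_ <- fit$rank
      s2 <- sum(fit$residuals^2) / (length(d$y) - p_)
      XtXi <- chol2inv(chol(crossprod(d$X)))
      est <- sum(d$L * fit$coefficients)
      se <- sqrt(s2 * drop(d$L %*% XtXi %*% d$L))
      df <- length(d$y) - p_
      list(p = 2 * pt(-abs(est / se), df), estimate = est, converged = TRUE)
    },
    lmm_ri = ,
    lmm_ri_weighted = {
      w <- if (strategy == "lmm_ri_weighted") d$weights else NULL
      res <- tryCatch({
        fit <- fit_feature_lmm(d$y, d$X, d$id, weights = w)
        tc <- test_contrast(fit, d$L)
        list(p = tc$p, estimate = tc$estimate, converged = fit$converged)
      }, error = function(e) list(p = NA_real_, estimate = NA_real_,
                                  converged = FALSE))
      res
    },
    mmrm_unstructured = {
      res <- tryCatch({
        fit <- mmrm_unstructured(d$y, d$X, d$id, d$pos, n_time = d$n_time,
                                 bundles = d$bundles)
        if (is.null(fit$beta)) stop("singular covariance")
        est <- sum(d$L * fit$beta)
        se <- sqrt(drop(d$L %*% fit$vcov %*% d$L))
        df <- fit$n_clusters - ncol(d$X)
        if (df < 1) df <- 1
        list(p = 2 * pt(-abs(est / se), df), estimate = est,
             converged = fit$converged)
      }, error = function(e) list(p = NA_real_, estimate = NA_real_,
                                  converged = FALSE))
      res
    },
    gee_ar1 = {
      res <- tryCatch({
        fit <- gee_ar1(d$y, d$X, d$id, d$pos, bundles = d$bundles)
        est <- sum(d$L * fit$beta)
        se <- sqrt(drop(d$L %*% fit$vcov %*% d$L))
        list(p = 2 * pnorm(-abs(est / se)), estimate = est,
             converged = fit$converged)
      }, error = function(e) list(p = NA_real_, estimate = NA_real_,
                                  converged = FALSE))
      res
    })
}

#' Type-I error / power benchmark of the analytic strategies
#'
#' Replicates the model-selection simulation: draws `n_reps` feature
#' datasets per scenario from the moment-matched non-normal longitudinal
#' simulator and reports each strategy's rejection rate at `alpha` with
#' its Monte-Carlo standard error and the bias of the delta-delta
#' estimate. Under a null scenario the rate is the empirical type-I error;
#' under an alternative it is power. Non-convergent fits are counted and
#' excluded from the rate denominator, never resampled. Results are
#' streamed into running tallies, so memory does not grow with `n_reps`.
#'
#' @param scenarios named list; each element a list with `moments` and
#'   `scenario` (e.g. from [sim_preset()]).
#' @param strategies subset of `r paste(STRATEGIES, collapse=", ")`.
#' @param n_reps Monte-Carlo replicates per scenario.
#' @param seed RNG seed (one stream for the whole benchmark).
#' @param alpha nominal test level.
#' @param timepoint,exercise_group tested delta-delta cells.
#' @return data.frame of class `benchmark_report`: one row per
#'   (scenario, strategy) with `rate`, `mc_se`, `bias`, `n_used`,
#'   `n_nonconv`, `n_reps`, `seed`.
#' @export
run_benchmark <- function(scenarios, strategies = STRATEGIES,
                          n_reps = 1000, seed = 1, alpha = 0.05,
                          timepoint = "post10", exercise_group = "EE") {
  stopifnot(n_reps >= 1)
  strategies <- match.arg(strategies, STRATEGIES, several.ok = TRUE)
  set.seed(seed)
  out <- list()
  for (sc_name in names(scenarios)) {
    sc <- scenarios[[sc_name]]
    prep <- sim_prepare(sc$moments, sc$scenario)
    true_effect <- if (timepoint %in% sc$scenario$effect_timepoints &&
                       exercise_group == sc$scenario$effect_group)
      sc$scenario$effect_size else 0
    # population delta-delta on the data scale (unit marginal SDs assumed
    # equal across the effect cells is not required: bias uses the planted
    # standardized effect times the exercise subgroup SD average)
    rej <- used <- nonconv <- setNames(numeric(length(strategies)), strategies)
    est_sum <- setNames(numeric(length(strategies)), strategies)
    for (r in seq_len(n_reps)) {
      draw <- sim_draw(prep, n_features = 1L)
      d <- bench_dataset(draw, timepoint = timepoint,
                         exercise_group = exercise_group)
      for (s in strategies) {
        res <- apply_strategy(s, d)
        if (is.na(res$p)) {
          nonconv[s] <- nonconv[s] + 1
        } else {
          used[s] <- used[s] + 1
          rej[s] <- rej[s] + (res$p < alpha)
          est_sum[s] <- est_sum[s] + res$estimate
        }
      }
    }
    rate <- rej / pmax(used, 1)
    # planted population value of the contrast on the data scale
    target <- planted_delta_delta(prep, exercise_group, timepoint)
    out[[sc_name]] <- data.frame(
      scenario = sc_name, strategy = strategies,
      rate = unname(rate),
      mc_se = unname(sqrt(rate * (1 - rate) / pmax(used, 1))),
      bias = unname(est_sum / pmax(used, 1) - target),
      true_value = target,
      n_used = unname(used), n_nonconv = unname(nonconv),
      n_reps = n_reps, alpha = alpha, seed = seed,
      stringsAsFactors = FALSE)
  }
  rep_df <- do.call(rbind, out)
  rownames(rep_df) <- NULL
  class(rep_df) <- c("benchmark_report", "data.frame")
  rep_df
}

# Population value of the delta-delta contrast implied by a compiled
# simulation (mixes subgroups by their sample share within each group).
planted_delta_delta <- function(prep, exercise_group, timepoint) {
  tps <- prep$tps
  it <- match(timepoint, tps); ip <- match("pre", tps)
  cellmean <- function(group, ti) {
    keys <- prep$keys[subgroup_group(prep$keys) == group]
    ns <- prep$scenario$n[keys]
    mus <- vapply(keys, function(k)
      prep$gens[[k]]$mean[ti] + prep$effects[[k]][ti], numeric(1))
    sum(mus * ns) / sum(ns)
  }
  (cellmean(exercise_group, it) - cellmean(exercise_group, ip)) -
    (cellmean("CON", it) - cellmean("CON", ip))
}

#' Analytic power of the two-sided two-sample t-test
#'
#' Exact noncentral-t computation of the power to detect a standardized
#' mean difference `delta` (difference in means over the common SD) with
#' `n_per_group` participants per arm.
#'
#' @param n_per_group per-arm sample size.
#' @param delta standardized effect size.
#' @param alpha two-sided level.
#' @return power in \\[0, 1\\].
#' @export
power_two_sample_t <- function(n_per_group, delta, alpha = 0.05) {
  df <- 2 * n_per_group - 2
  ncp <- delta * sqrt(n_per_group / 2)
  crit <- stats::qt(1 - alpha / 2, df)
  pt(-crit, df, ncp = ncp) + 1 - pt(crit, df, ncp = ncp)
}
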