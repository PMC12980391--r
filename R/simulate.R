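# Blood collection schedule by temporal-randomization profile: every
# participant is drawn pre-exercise and 10 min post; the randomized
# early/middle/late/all profiles add the later draws.
PROFILE_MASKS <- list(
  early  = c("pre", "post10", "post30"),
  middle = c("pre", "post10", "post3.5h"),
  late   = c("pre", "post10", "post24h"),
  all    = c("pre", "post10", "post30", "post3.5h", "post24h")
)

#' Per-subgroup moment summary for the longitudinal simulator
#'
#' Bundles the sufficient statistics the simulator matches within one
#' sex-by-group subgroup: a mean vector over timepoints, a timepoint
#' covariance, and marginal skewness / excess kurtosis.
#'
#' @param mean numeric vector over timepoints.
#' @param cov symmetric PSD matrix (timepoints x timepoints).
#' @param skew,exkurt marginal skewness and excess kurtosis; scalars are
#'   recycled over timepoints. Feasibility (`exkurt >= skew^2 - 2`) is
#'   checked when the generator is compiled.
#' @export
moment_summary <- function(mean, cov, skew = 0, exkurt = 0) {
  T_ <- length(mean)
  out <- list(mean = mean, cov = as.matrix(cov),
              skew = rep(skew, length.out = T_),
              exkurt = rep(exkurt, length.out = T_))
  class(out) <- "moment_summary"
  out
}

#' Simulation scenario for the repeated-measures design
#'
#' @param n named integer vector of participants per sex-by-group subgroup,
#'   names like `"M.EE"`, `"F.CON"`.
#' @param timepoints timepoints simulated (must include `"pre"`).
#' @param profile_fractions allocation over the early/middle/late/all
#'   temporal profiles (default uniform quarters).
#' @param effect_size standardized mean shift added to the exercise arm's
#'   affected cells (0 under the null).
#' @param effect_group,effect_timepoints where the effect is planted.
#' @param mcar_rate extra completely-at-random sample dropout applied after
#'   the temporal-profile masks.
#' @param n_features number of iid features drawn on the shared design.
#' @param seed optional seed (set once per call when not `NULL`).
#' @export
sim_scenario <- function(n,
                         timepoints = c("pre", "post10", "post30", "post3.5h", "post24h"),
                         profile_fractions = c(early = 0.25, middle = 0.25,
                                               late = 0.25, all = 0.25),
                         effect_size = 0,
                         effect_group = "EE",
                         effect_timepoints = "post10",
                         mcar_rate = 0.05,
                         n_features = 1L,
                         seed = NULL) {
  stopifnot(!is.null(names(n)), all(n >= 2), "pre" %in% timepoints)
  stopifnot(abs(sum(profile_fractions) - 1) < 1e-8)
  structure(list(n = n, timepoints = timepoints,
                 profile_fractions = profile_fractions,
                 effect_size = effect_size, effect_group = effect_group,
                 effect_timepoints = effect_timepoints,
                 mcar_rate = mcar_rate, n_features = as.integer(n_features),
                 seed = seed),
            class = "sim_scenario")
}

#' Timepoint covariance builders
#'
#' `cs_cov` builds an exchangeable (compound-symmetric) covariance -- the
#' within-participant structure a random-intercept analysis assumes --
#' and `ar1_cov` a first-order autoregressive decay, for use as the `cov`
#' of a [moment_summary()].
#'
#' @param n_time number of timepoints.
#' @param rho correlation (lag-1 correlation for `ar1_cov`).
#' @param sd marginal standard deviation.
#' @export
cs_cov <- function(n_time, rho, sd = 1) {
  R <- matrix(rho, n_time, n_time)
  diag(R) <- 1
  R * sd^2
}

#' @rdname cs_cov
#' @export
ar1_cov <- function(n_time, rho, sd = 1) {
  rho^abs(outer(seq_len(n_time), seq_len(n_time), "-")) * sd^2
}

subgroup_sex <- function(key) sub("\\..*$", "", key)
subgroup_group <- function(key) sub("^[^.]*\\.", "", key)

#' Compile a longitudinal simulation for repeated drawing
#'
#' Solves the Fleishman systems and intermediate correlations once per
#' subgroup so that the benchmark can draw tens of thousands of replicate
#' datasets cheaply via [sim_draw()].
#'
#' @param moments named list of [moment_summary()] objects, one per
#'   subgroup named in `scenario$n`.
#' @param scenario a [sim_scenario()].
#' @return an opaque compiled-simulation object.
#' @export
sim_prepare <- function(moments, scenario) {
  keys <- names(scenario$n)
  stopifnot(all(keys %in% names(moments)))
  tps <- scenario$timepoints
  gens <- lapply(keys, function(k) {
    mo <- moments[[k]]
    stopifnot(length(mo$mean) == length(tps))
    vm_compile(mo$mean, mo$cov, mo$skew, mo$exkurt)
  })
  names(gens) <- keys
  # effect vector on the standardized scale, per subgroup
  effects <- lapply(keys, function(k) {
    e <- numeric(length(tps))
    if (scenario$effect_size != 0 && subgroup_group(k) == scenario$effect_group) {
      idx <- match(scenario$effect_timepoints, tps)
      e[idx] <- scenario$effect_size * gens[[k]]$sds[idx]
    }
    e
  })
  names(effects) <- keys
  masks <- lapply(PROFILE_MASKS, function(m) tps %in% m)
  list(scenario = scenario, keys = keys, gens = gens, effects = effects,
       masks = masks, tps = tps)
}

#' Draw one replicate dataset from a compiled simulation
#'
#' All features of the replicate share one sample-collection mask (the
#' temporal-profile allocation plus MCAR dropout are properties of the
#' blood draw, not of the assay), and are otherwise iid.
#'
#' @param prep object from [sim_prepare()].
#' @param n_features number of iid features to draw (default from the
#'   scenario).
#' @return list with `values` (a list of participants x timepoints
#'   matrices, one per feature, `NA` where a sample was not collected),
#'   `participant`, `group`, `sex`, `profile` vectors, and `timepoints`.
#' @export
sim_draw <- function(prep, n_features = prep$scenario$n_features) {
  sc <- prep$scenario
  ntot <- sum(sc$n)
  T_ <- length(prep$tps)
  values <- lapply(seq_len(n_features), function(i) matrix(NA_real_, ntot, T_))
  group <- sex <- profile <- character(ntot)
  pos <- 0L
  prof_names <- names(sc$profile_fractions)
  for (k in prep$keys) {
    n_k <- sc$n[[k]]
    idx <- pos + seq_len(n_k)
    # one big draw covering every feature of this subgroup
    Y <- vm_draw(prep$gens[[k]], n_k * n_features)
    Y <- sweep(Y, 2, prep$effects[[k]], "+")
    for (f in seq_len(n_features))
      values[[f]][idx, ] <- Y[(f - 1L) * n_k + seq_len(n_k), , drop = FALSE]
    # balanced profile allocation within subgroup, order randomized
    target <- rep(prof_names, times = round(sc$profile_fractions * n_k))
    if (length(target) < n_k)
      target <- c(target, sample(prof_names, n_k - length(target), replace = TRUE))
    target <- sample(target[seq_len(n_k)])
    group[idx] <- subgroup_group(k)
    sex[idx] <- subgroup_sex(k)
    profile[idx] <- target
    pos <- pos + n_k
  }
  # shared collection mask
  keep <- t(vapply(profile, function(p) prep$masks[[p]], logical(T_)))
  if (sc$mcar_rate > 0)
    keep <- keep & (matrix(runif(ntot * T_), ntot, T_) >= sc$mcar_rate)
  for (f in seq_len(n_features)) values[[f]][!keep] <- NA_real_
  list(values = values,
       participant = sprintf("P%03d", seq_len(ntot)),
       group = group, sex = sex, profile = profile,
       timepoints = prep$tps)
}

#' Simulate a longitudinal multi-feature dataset
#'
#' Generates participant trajectories whose subgroup-wise mean, covariance,
#' skewness and excess kurtosis match the supplied moment summaries
#' (Fleishman polynomial margins coupled through Vale-Maurelli intermediate
#' correlations), applies the temporal-profile collection masks and extra
#' MCAR dropout, and plants the scenario's standardized effect in the
#' exercise arm. All features are iid given the shared collection design.
#'
#' @inheritParams sim_prepare
#' @return list with `table` (a [feature_table()], one column per collected
#'   sample), `meta` (a [sample_meta()] with sex and temporal profile), and
#'   `truth` (the planted effect description).
#' @export
simulate_longitudinal <- function(moments, scenario) {
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  prep <- sim_prepare(moments, scenario)
  d1 <- sim_draw(prep)
  obs <- !is.na(d1$values[[1]])
  sample_rows <- which(obs, arr.ind = TRUE)
  ord <- order(sample_rows[, 1], sample_rows[, 2])
  sample_rows <- sample_rows[ord, , drop = FALSE]
  sid <- sprintf("S%04d", seq_len(nrow(sample_rows)))
  meta <- data.frame(
    sample_id = sid,
    participant_id = d1$participant[sample_rows[, 1]],
    group = d1$group[sample_rows[, 1]],
    timepoint = d1$timepoints[sample_rows[, 2]],
    temporal_profile = d1$profile[sample_rows[, 1]],
    sex = d1$sex[sample_rows[, 1]],
    stringsAsFactors = FALSE)
  vals <- t(vapply(d1$values, function(v) v[obs][ord], numeric(nrow(sample_rows))))
  rownames(vals) <- sprintf("feature%04d", seq_len(nrow(vals)))
  colnames(vals) <- sid
  suppressWarnings(validate_sample_meta(meta))
  class(meta) <- c("sample_meta", "data.frame")
  list(table = feature_table(vals, ome = "protein_log"),
       meta = meta,
       truth = list(effect_size = scenario$effect_size,
                    effect_group = scenario$effect_group,
                    effect_timepoints = scenario$effect_timepoints))
}

#' Tissue-flavoured simulation presets
#'
#' Named moment/sample-size presets spanning the design space the analysis
#' must tolerate: subgroup sizes down to 4, marginal skewness up to |1.5|,
#' excess kurtosis up to 6, and AR-decaying timepoint correlation between
#' 0.3 and 0.8. The presets are configuration for the simulator, not
#' estimates of any real cohort; `adipose` is the stress preset (smallest
#' subgroups, strongest non-normality), `blood` the large-cohort preset,
#' `muscle` intermediate.
#'
#' @param name `"adipose"`, `"blood"` or `"muscle"`.
#' @param effect_size planted standardized effect (0 gives the null
#'   scenario).
#' @return list with `moments` (per-subgroup [moment_summary()]s) and
#'   `scenario` (a [sim_scenario()]).
#' @export
sim_preset <- function(name = c("adipose", "blood", "muscle"), effect_size = 0) {
  name <- match.arg(name)
  tps <- c("pre", "post10", "post30", "post3.5h", "post24h")
  T_ <- length(tps)
  cfg <- switch(name,
    adipose = list(
      n = c(M.EE = 4, F.EE = 10, M.CON = 5, F.CON = 12),
      skew = c(M.EE = 1.5, F.EE = 0.8, M.CON = -0.5, F.CON = 0.3),
      exkurt = c(M.EE = 6, F.EE = 2.5, M.CON = 1.0, F.CON = 0.8),
      rho = c(M.EE = 0.7, F.EE = 0.5, M.CON = 0.6, F.CON = 0.4),
      mu = c(M.EE = 0.5, F.EE = 0, M.CON = 0.5, F.CON = 0)),
    blood = list(
      n = c(M.EE = 20, F.EE = 50, M.CON = 10, F.CON = 25),
      skew = c(M.EE = 1.0, F.EE = 0.5, M.CON = -0.3, F.CON = 0.2),
      exkurt = c(M.EE = 3, F.EE = 1.5, M.CON = 0.8, F.CON = 0.5),
      rho = c(M.EE = 0.6, F.EE = 0.5, M.CON = 0.45, F.CON = 0.35),
      mu = c(M.EE = 0.5, F.EE = 0, M.CON = 0.5, F.CON = 0)),
    muscle = list(
      n = c(M.EE = 8, F.EE = 18, M.CON = 6, F.CON = 15),
      skew = c(M.EE = 1.2, F.EE = 0.6, M.CON = -0.4, F.CON = 0.2),
      exkurt = c(M.EE = 4, F.EE = 2, M.CON = 1.0, F.CON = 0.6),
      rho = c(M.EE = 0.8, F.EE = 0.6, M.CON = 0.5, F.CON = 0.3),
      mu = c(M.EE = 0.5, F.EE = 0, M.CON = 0.5, F.CON = 0)))
  moments <- lapply(names(cfg$n), function(k)
    moment_summary(rep(cfg$mu[[k]], T_), cs_cov(T_, cfg$rho[[k]]),
                   cfg$skew[[k]], cfg$exkurt[[k]]))
  names(moments) <- names(cfg$n)
  list(moments = moments,
       scenario = sim_scenario(cfg$n, timepoints = tps,
                               effect_size = effect_size))
}

#' Simulate transcript counts with a mean-variance trend
#'
#' Negative-binomial counts with gene-wise dispersion decreasing in the
#' mean (phi = disp_asymp + disp_scale / mu), log-normal library sizes, and
#' an optional multiplicative batch shift tied to a metadata column.
#'
#' @param n_genes number of genes.
#' @param meta sample metadata; one count column per row of `meta`.
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters.
#' @param disp_asymp,disp_scale dispersion trend parameters (dispersion
#'   `disp_asymp + disp_scale/mu`; both 0 gives Poisson).
#' @param batch_col optional metadata column; samples at `batch_level` get
#'   counts scaled by `batch_fc`.
#' @param batch_level,batch_fc see `batch_col`.
#' @param seed optional RNG seed.
#' @return a [feature_table()] with ome `"transcript_counts"`.
#' @export
simulate_counts <- function(n_genes, meta,
                            lib_meanlog = log(2e6), lib_sdlog = 0.3,
                            disp_asymp = 0.05, disp_scale = 2,
                            batch_col = NULL, batch_level = NULL, batch_fc = 1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_samp <- nrow(meta)
  lib <- rlnorm(n_samp, lib_meanlog, lib_sdlog)
  rel <- rlnorm(n_genes, meanlog = log(50), sdlog = 1.5)
  rel <- rel / sum(rel)
  mu <- outer(rel, lib)                       # expected counts
  phi <- disp_asymp + disp_scale / rowMeans(mu)
  if (!is.null(batch_col)) {
    hit <- meta[[batch_col]] == batch_level
    mu[, hit] <- mu[, hit] * batch_fc
  }
  counts <- matrix(0L, n_genes, n_samp)
  for (g in seq_len(n_genes)) {
    counts[g, ] <- if (phi[g] <= 1e-12) stats::rpois(n_samp, mu[g, ])
                   else rnbinom(n_samp, size = 1 / phi[g], mu = mu[g, ])
  }
  dimnames(counts) <- list(sprintf("gene%05d", seq_len(n_genes)), meta$sample_id)
  feature_table(counts, ome = "transcript_counts")
}

#' Simulate multi-platform metabolite tables with internal standards
#'
#' Builds two or more platform tables sharing `n_shared` RefMet identities,
#' each platform carrying internal-standard features with a specified
#' coefficient of variation, log-normal intensities, left-censoring (MNAR)
#' below a quantile, and extra MCAR missingness. The returned truth record
#' names, per shared id, the platform with the lower internal-standard CV
#' (the platform redundancy resolution should pick it).
#'
#' @param n_features features per platform (excluding internal standards).
#' @param n_shared number of RefMet ids measured on every platform.
#' @param platform_cvs named numeric vector of nominal internal-standard
#'   CVs (raw intensity scale), one per platform; >= 2 platforms.
#' @param censor_quantile left-censoring quantile in \\[0, 1); intensities
#'   below this platform-wise quantile become missing.
#' @param meta sample metadata (columns of the tables).
#' @param n_standards internal standards per platform (>= 3).
#' @param mcar_rate extra random missingness among non-standard features.
#' @param seed optional RNG seed.
#' @return list of [feature_table()]s (one per platform) plus `truth`.
#' @export
simulate_metabolite_platforms <- function(n_features, n_shared, platform_cvs,
                                          censor_quantile = 0.05, meta,
                                          n_standards = 3, mcar_rate = 0.02,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(platform_cvs) < 2) stop("need at least two platforms")
  if (n_standards < 3) stop("need at least 3 internal standards per platform")
  if (censor_quantile < 0 || censor_quantile >= 1)
    stop("censor_quantile must lie in [0, 1)")
  stopifnot(n_shared <= n_features)
  n_samp <- nrow(meta)
  platforms <- names(platform_cvs)
  shared_ids <- sprintf("REFMET:%04d", seq_len(n_shared))
  tables <- list()
  for (p in platforms) {
    n_own <- n_features - n_shared
    ids <- c(shared_ids,
             if (n_own > 0) sprintf("REFMET:%s%04d", p, seq_len(n_own)))
    base <- rlnorm(n_features, meanlog = log(1e4), sdlog = 1)
    sdlog_feat <- 0.4
    vals <- exp(matrix(rnorm(n_features * n_samp, 0, sdlog_feat), n_features) +
                  log(base))
    # internal standards: tight lognormal with the platform's nominal CV
    cv <- platform_cvs[[p]]
    sig <- sqrt(log(1 + cv^2))
    std_vals <- exp(matrix(rnorm(n_standards * n_samp, 0, sig), n_standards) +
                      log(rlnorm(n_standards, log(5e4), 0.2)))
    std_ids <- sprintf("IS_%s_%d", p, seq_len(n_standards))
    all_vals <- rbind(vals, std_vals)
    rownames(all_vals) <- c(sprintf("%s_%s", p, ids), std_ids)
    colnames(all_vals) <- meta$sample_id
    if (censor_quantile > 0) {
      thr <- quantile(vals, censor_quantile)
      all_vals[seq_len(n_features), ][vals < thr] <- NA_real_
    }
    if (mcar_rate > 0) {
      m <- matrix(runif(n_features * n_samp) < mcar_rate, n_features)
      all_vals[seq_len(n_features), ][m] <- NA_real_
    }
    fm <- data.frame(feature_id = rownames(all_vals),
                     refmet_id = c(ids, rep(NA_character_, n_standards)),
                     platform = p,
                     is_internal_standard = c(rep(FALSE, n_features),
                                              rep(TRUE, n_standards)),
                     stringsAsFactors = FALSE)
    tables[[p]] <- feature_table(all_vals, ome = "metabolite_intensity",
                                 feature_meta = fm)
  }
  best <- platforms[which.min(platform_cvs)]
  truth <- data.frame(refmet_id = shared_ids,
                      best_platform = best,
                      stringsAsFactors = FALSE)
  list(tables = tables, truth = truth)
}
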