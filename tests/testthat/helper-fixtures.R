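# Shared fixture builders. Everything is generated in code; no files.

# balanced two-group pre/post metadata
make_meta <- function(n_per_group = 6, groups = c("EE", "CON"),
                      timepoints = c("pre", "post10"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  pid <- 0
  for (g in groups) for (i in seq_len(n_per_group)) {
    pid <- pid + 1
    for (tp in timepoints) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("s_%s_%02d_%s", g, i, tp),
        participant_id = sprintf("p%03d", pid),
        group = g, timepoint = tp,
        sex = if (i %% 2 == 0) "F" else "M",
        age = 30 + (pid %% 20), stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)
  class(meta) <- c("sample_meta", "data.frame")
  meta
}

# independent step-up BH reference used as the oracle for bh_adjust
brute_bh <- function(p) {
  ok <- !is.na(p)
  out <- rep(NA_real_, length(p))
  ps <- p[ok]
  m <- length(ps)
  if (m == 0) return(out)
  o <- order(ps)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    val <- min(prev, m / i * ps[o[i]], 1)
    adj[o[i]] <- val
    prev <- val
  }
  out[ok] <- adj
  out
}

# tiny compiled null simulation shared by several tests
small_null_prep <- function() {
  ps <- sim_preset("adipose")
  sim_prepare(ps$moments, ps$scenario)
}
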