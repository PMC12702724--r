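# programmatic fixtures shared across test files

# a perfect ramp test: work rate 25 W/min through the origin, all metrics
# linear in time, breaths every `dt` seconds; no noise unless added
make_ramp_series <- function(n = 100, duration = NULL, dt = 2,
                             meta = participant_meta("T01", "male", 12)) {
  t <- seq_len(n) * dt
  if (is.null(duration)) duration <- max(t)
  cmin <- t / 60
  breaths <- data.frame(
    time_s = t,
    vo2 = 0.5 + 0.2 * cmin,
    vco2 = 0.45 + 0.22 * cmin,
    ve = 12 + 7 * cmin,
    hr = 95 + 9 * cmin,
    rr = 20 + 3 * cmin,
    vt = 0.55 + 0.12 * cmin,
    work_rate = 25 * cmin)
  cpet_series(breaths, meta = meta, duration_s = duration)
}

# tiny cohort spec for fast end-to-end runs
small_spec <- function(n = 2, ...) {
  cohort_spec(n_per_group = c(male_younger = n, male_older = n,
                              female_younger = n, female_older = n), ...)
}

fast_sampler <- function() sampler_config(chains = 2, draws_per_chain = 400,
                                          warmup = 400)

# independent step-down Holm-Sidak, written as a literal loop over the
# sorted p-values (oracle for the vectorized implementation)
holm_sidak_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    step_val <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, step_val)
    adj[ord[i]] <- min(running, 1)
  }
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (adj[ord[i]] < alpha) reject[ord[i]] <- TRUE else break
  }
  list(adjusted = adj, reject = reject)
}
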