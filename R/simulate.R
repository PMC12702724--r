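#' Specification for a synthetic ramp-CPET cohort
#'
#' Describes a cohort of simulated progressive (ramp) cardiopulmonary
#' exercise tests.  Each participant's breath times accumulate as
#' \code{60/RR(t)} increments under a linearly rising respiratory rate, each
#' metric follows a linear ramp plus a slowly mean-reverting fluctuation
#' whose per-breath increments follow the configured innovation process, and
#' the work-rate channel is an ergometer-style ramp through the origin with a
#' short unloaded lead-in.  Signal complexity is controlled through the
#' innovation process of the differenced signal: white (iid) increments give
#' a high-entropy differenced signal, AR(1)-correlated increments a lower
#' one, which is the knob used to realize group- and half-specific entropy
#' structure.
#'
#' @param n_per_group Named counts for the four sex-by-age cells
#'   (\code{male_younger}, \code{male_older}, \code{female_younger},
#'   \code{female_older}).  Default \code{c(40, 45, 40, 45)}.
#' @param duration_range_s Test duration bounds in seconds (ramp tests run
#'   8--12 min).
#' @param duration_mean_s,duration_sd_s Mean and SD of the truncated-normal
#'   duration draw, seconds.
#' @param rr_start,rr_end Respiratory-rate ramp endpoints, breaths/min.
#' @param metric_ramps Named list of \code{c(start, end)} levels per metric,
#'   in each metric's own units.
#' @param noise_model Named list per metric with elements \code{scale}
#'   (marginal SD of the per-breath innovation, metric units),
#'   \code{phi_pre} and \code{phi_post} (AR(1) coefficient of the innovation
#'   process before/after the test midpoint; 0 = iid).
#' @param entropy_effects Named numeric complexity multipliers per sex-age
#'   cell.  A multiplier \code{c} divides the innovation AR(1) coefficient
#'   (\code{phi/c}), so larger values mean less autocorrelated increments and
#'   hence higher Sample Entropy.
#' @param hr_repeat_prob Length-2 vector: probability that a breath repeats
#'   the previous recorded HR value, pre and post midpoint (emulates
#'   per-breath assignment of a continuously measured HR).
#' @param wr_slope_w_min Work-rate ramp slope, Watts per minute.
#' @param unloaded_phase_s Unloaded lead-in during which work rate is zero,
#'   seconds.
#' @param time_jitter_sd Log-normal jitter SD on breath intervals.
#' @param artifact_rate Fraction of breaths receiving an injected
#'   out-of-physiological-range value.
#' @param spike_rate Fraction of breaths receiving an injected in-range
#'   6-sigma spike.
#' @param gap_metric,gap_length_s If \code{n_gap_participants > 0}, that many
#'   participants get a run of missing values spanning at least
#'   \code{gap_length_s} seconds in \code{gap_metric}.
#' @param n_gap_participants Number of participants given an injected gap.
#' @param seed RNG seed for \code{\link{generate_cohort}}.
#'
#' @return A list of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_per_group = c(male_younger = 40, male_older = 45,
                                        female_younger = 40, female_older = 45),
                        duration_range_s = c(480, 720),
                        duration_mean_s = 582, duration_sd_s = 57,
                        rr_start = 20, rr_end = 50,
                        metric_ramps = list(
                          vo2 = c(0.5, 2.5), vco2 = c(0.45, 2.8),
                          ve = c(12, 80), hr = c(95, 190),
                          rr = c(20, 50), vt = c(0.55, 1.8)),
                        noise_model = list(
                          vo2 = list(scale = 0.020, phi_pre = 0.30, phi_post = 0.70),
                          vco2 = list(scale = 0.022, phi_pre = 0.30, phi_post = 0.70),
                          ve = list(scale = 0.70, phi_pre = 0.30, phi_post = 0.70),
                          hr = list(scale = 1.10, phi_pre = 0.30, phi_post = 0.70),
                          rr = list(scale = 0.80, phi_pre = 0.30, phi_post = 0.40),
                          vt = list(scale = 0.022, phi_pre = 0.30, phi_post = 0.40)),
                        entropy_effects = c(male_younger = 1.10,
                                            male_older = 1.00,
                                            female_younger = 1.15,
                                            female_older = 1.25),
                        hr_repeat_prob = c(pre = 0.3, post = 0.5),
                        wr_slope_w_min = 25, unloaded_phase_s = 15,
                        time_jitter_sd = 0.04,
                        artifact_rate = 0, spike_rate = 0,
                        gap_metric = "vo2", gap_length_s = 35,
                        n_gap_participants = 0,
                        seed = 1L) {
  cells <- c("male_younger", "male_older", "female_younger", "female_older")
  if (is.null(names(n_per_group))) names(n_per_group) <- cells
  stopifnot(setequal(names(n_per_group), cells),
            all(n_per_group >= 0),
            length(duration_range_s) == 2,
            duration_range_s[1] < duration_range_s[2],
            rr_end > 0, rr_start > 0)
  for (m in cpet_metrics()) {
    nm <- noise_model[[m]]
    if (is.null(nm)) stop("noise_model missing metric ", m)
    if (nm$scale < 0) stop("noise scale must be non-negative for ", m)
    if (abs(nm$phi_pre) >= 1 || abs(nm$phi_post) >= 1) {
      stop("AR(1) phi must lie in (-1, 1) for ", m)
    }
  }
  structure(
    list(n_per_group = n_per_group[cells],
         duration_range_s = duration_range_s,
         duration_mean_s = duration_mean_s, duration_sd_s = duration_sd_s,
         rr_start = rr_start, rr_end = rr_end,
         metric_ramps = metric_ramps, noise_model = noise_model,
         entropy_effects = entropy_effects,
         hr_repeat_prob = hr_repeat_prob,
         wr_slope_w_min = wr_slope_w_min,
         unloaded_phase_s = unloaded_phase_s,
         time_jitter_sd = time_jitter_sd,
         artifact_rate = artifact_rate, spike_rate = spike_rate,
         gap_metric = gap_metric, gap_length_s = gap_length_s,
         n_gap_participants = n_gap_participants,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

# AR(1) innovation series with marginal SD `scale`; phi = 0 gives iid.
.ar1_innovations <- function(n, phi, scale) {
  z <- stats::rnorm(n)
  if (phi == 0 || n == 1) return(scale * z)
  e <- numeric(n)
  e[1] <- scale * z[1]
  w <- scale * sqrt(1 - phi^2)
  for (t in 2:n) e[t] <- phi * e[t - 1] + w * z[t]
  e
}

#' Simulate one ramp-CPET participant
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param sex \code{"male"} or \code{"female"}.
#' @param age_years Decimal age.
#' @param participant_id Identifier for the generated series.
#' @param seed Per-participant RNG seed.
#'
#' @return List with elements \code{series} (a \code{\link{cpet_series}})
#'   and \code{truth} (noise parameters, cell label, artifact bookkeeping).
#' @export
generate_participant <- function(spec, sex, age_years,
                                 participant_id = "P000", seed = 1L) {
  if (spec$rr_end <= 0) stop("infeasible spec: rr_end must be positive")
  sex <- match.arg(sex, c("male", "female"))
  set.seed(as.integer(seed))
  dur <- stats::rnorm(1, spec$duration_mean_s, spec$duration_sd_s)
  dur <- min(max(dur, spec$duration_range_s[1]), spec$duration_range_s[2])

  # breath times: cumulative 60/RR(t) increments with log-normal jitter
  rr_at <- function(t) spec$rr_start + (spec$rr_end - spec$rr_start) * t / dur
  times <- numeric(0)
  t <- 60 / rr_at(0)
  while (t <= dur) {
    times <- c(times, t)
    dt <- 60 / rr_at(t) * exp(stats::rnorm(1, 0, spec$time_jitter_sd))
    t <- t + dt
  }
  n <- length(times)
  half <- ifelse(times < dur / 2, "pre", "post")

  cell <- paste(sex,
                if (age_group_of(sex, age_years) == "older") "older"
                else "younger", sep = "_")
  cmult <- spec$entropy_effects[[cell]]
  if (is.null(cmult) || is.na(cmult)) cmult <- 1

  breaths <- data.frame(time_s = times)
  noise_par <- list()
  phi_level <- 0.98  # slow mean reversion keeps the level bounded while
                     # passing the innovation structure through to the diffs
  for (m in cpet_metrics()) {
    ramp <- spec$metric_ramps[[m]]
    base <- ramp[1] + (ramp[2] - ramp[1]) * times / dur
    nm <- spec$noise_model[[m]]
    phi_pre <- nm$phi_pre / cmult
    phi_post <- nm$phi_post / cmult
    e <- numeric(n)
    idx_pre <- which(half == "pre")
    idx_post <- which(half == "post")
    if (length(idx_pre)) {
      e[idx_pre] <- .ar1_innovations(length(idx_pre), phi_pre, nm$scale)
    }
    if (length(idx_post)) {
      e[idx_post] <- .ar1_innovations(length(idx_post), phi_post, nm$scale)
    }
    u <- numeric(n)
    u[1] <- e[1]
    for (tt in seq_len(n)[-1]) u[tt] <- phi_level * u[tt - 1] + e[tt]
    vals <- base + u
    if (m == "hr") {
      vals <- round(vals)
      p_rep <- ifelse(half == "pre", spec$hr_repeat_prob[["pre"]],
                      spec$hr_repeat_prob[["post"]])
      rep_draw <- stats::runif(n) < p_rep
      for (tt in seq_len(n)[-1]) if (rep_draw[tt]) vals[tt] <- vals[tt - 1]
    }
    breaths[[m]] <- vals
    noise_par[[m]] <- list(scale = nm$scale, phi_pre = phi_pre,
                           phi_post = phi_post)
  }
  breaths$work_rate <- ifelse(times < spec$unloaded_phase_s, 0,
                              spec$wr_slope_w_min * times / 60)

  meta <- participant_meta(participant_id, sex, age_years)
  series <- cpet_series(breaths, meta = meta, duration_s = dur)
  truth <- list(participant_id = participant_id, sex = sex,
                age_years = age_years, cell = cell,
                complexity_multiplier = cmult, duration_s = dur,
                noise = noise_par,
                artifacts = data.frame(kind = character(0),
                                       metric = character(0),
                                       index = integer(0),
                                       time_s = numeric(0),
                                       value = numeric(0)))
  out <- list(series = series, truth = truth)
  if (spec$artifact_rate > 0 || spec$spike_rate > 0) {
    inj <- inject_artifacts(series, spec, seed = as.integer(seed) + 1L)
    out$series <- inj$series
    out$truth$artifacts <- inj$positions
  }
  out
}

# metric -> an out-of-physiological-range replacement value
.out_of_range_value <- function(metric) {
  switch(metric,
         vo2 = 0.1, vco2 = 0.05, hr = 240, rr = 80, vt = 4.0,
         stop("no absolute bound exists for metric ", metric))
}

#' Inject artifacts into a breath series
#'
#' Adds (a) absolute-bound violations (e.g. HR 240 bpm, VO2 0.1 L/min) for
#' metrics that have physiological bounds, (b) isolated in-range spikes six
#' local standard deviations from the 15-breath window mean, sized to trip
#' the moving-window outlier rule, and (c) optionally a run of missing
#' values spanning at least \code{spec$gap_length_s} seconds.  Artifacts are
#' placed in the middle 80\% of the test so they cannot hide inside the
#' warm-up removals.  Every injected position is returned.
#'
#' @param series A \code{\link{cpet_series}}.
#' @param spec A \code{\link{cohort_spec}} (uses \code{artifact_rate},
#'   \code{spike_rate}, and the gap settings).
#' @param seed RNG seed.
#' @param inject_gap Force a gap regardless of \code{n_gap_participants}.
#'
#' @return List with \code{series} (modified) and \code{positions}
#'   (data.frame: kind, metric, index, time_s, value).
#' @export
inject_artifacts <- function(series, spec, seed = 1L, inject_gap = FALSE) {
  set.seed(as.integer(seed))
  br <- series$breaths
  n <- nrow(br)
  mid <- seq.int(max(1L, ceiling(n * 0.1)), floor(n * 0.9))
  pos <- list()
  bounded <- c("vo2", "vco2", "hr", "rr", "vt")

  n_art <- stats::rbinom(1, length(mid), spec$artifact_rate)
  if (n_art > 0) {
    idx <- sample(mid, n_art)
    mets <- sample(bounded, n_art, replace = TRUE)
    for (k in seq_len(n_art)) {
      val <- .out_of_range_value(mets[k])
      br[[mets[k]]][idx[k]] <- val
      pos[[length(pos) + 1L]] <- data.frame(
        kind = "out_of_range", metric = mets[k], index = idx[k],
        time_s = br$time_s[idx[k]], value = val)
    }
  }

  n_spk <- stats::rbinom(1, length(mid), spec$spike_rate)
  if (n_spk > 0) {
    # keep spikes off breaths already carrying an out-of-range artifact so
    # the truth record stays one-artifact-per-position
    taken <- if (length(pos)) {
      unique(do.call(rbind, pos)$index)
    } else integer(0)
    ok <- setdiff(mid[mid > 7 & mid <= n - 7], taken)
    idx <- sample(ok, min(n_spk, length(ok)))
    for (i in idx) {
      m <- sample(cpet_metrics(), 1)
      w <- br[[m]][(i - 7):(i + 7)]
      mu <- mean(w, na.rm = TRUE)
      sd_loc <- stats::sd(w, na.rm = TRUE)
      if (!is.finite(sd_loc) || sd_loc == 0) sd_loc <- abs(mu) * 0.02 + 1e-3
      # spike away from the nearer physiological bound so the moving-window
      # rule, not the absolute-bounds rule, is what catches it
      b <- switch(m, vo2 = c(0.2, Inf), vco2 = c(0.2, Inf),
                  hr = c(50, 230), rr = c(8, 75), vt = c(0.1, 3.5),
                  c(-Inf, Inf))
      val <- mu + 6 * sd_loc
      if (val >= b[2]) val <- mu - 6 * sd_loc
      if (val <= b[1]) val <- mu + 6 * sd_loc
      br[[m]][i] <- val
      pos[[length(pos) + 1L]] <- data.frame(
        kind = "spike6sigma", metric = m, index = i,
        time_s = br$time_s[i], value = val)
    }
  }

  if (inject_gap) {
    gm <- spec$gap_metric
    t0 <- br$time_s[mid[1]] +
      stats::runif(1, 0, diff(range(br$time_s[mid])) * 0.5)
    in_gap <- which(br$time_s > t0 - 1 & br$time_s < t0 + spec$gap_length_s + 1)
    br[[gm]][in_gap] <- NA_real_
    for (i in in_gap) {
      pos[[length(pos) + 1L]] <- data.frame(
        kind = "gap", metric = gm, index = i,
        time_s = br$time_s[i], value = NA_real_)
    }
  }

  positions <- if (length(pos)) do.call(rbind, pos) else
    data.frame(kind = character(0), metric = character(0),
               index = integer(0), time_s = numeric(0), value = numeric(0))
  list(series = cpet_series(br, meta = series$meta,
                            duration_s = series$duration_s),
       positions = positions)
}

#' Generate a synthetic CPET cohort
#'
#' Draws participants per sex-by-age cell (ages uniform inside each cell's
#' band), simulates each with \code{\link{generate_participant}}, and
#' optionally injects a long missing-data gap into the first
#' \code{n_gap_participants} participants.  Deterministic under
#' \code{spec$seed}.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A list of class \code{"cpet_cohort"} with \code{series} (list of
#'   \code{\link{cpet_series}}) and \code{truth} (one record per
#'   participant).
#' @export
generate_cohort <- function(spec) {
  cells <- list(
    male_younger = list(sex = "male", age_lo = 8, age_hi = 12.99),
    male_older = list(sex = "male", age_lo = 13, age_hi = 18),
    female_younger = list(sex = "female", age_lo = 8, age_hi = 11.99),
    female_older = list(sex = "female", age_lo = 12, age_hi = 18))
  set.seed(spec$seed)
  series <- list()
  truth <- list()
  k <- 0L
  for (cell in names(cells)) {
    info <- cells[[cell]]
    n_cell <- spec$n_per_group[[cell]]
    if (n_cell == 0) next
    ages <- stats::runif(n_cell, info$age_lo, info$age_hi)
    for (j in seq_len(n_cell)) {
      k <- k + 1L
      pid <- sprintf("%s%03d", toupper(substr(info$sex, 1, 1)), k)
      pseed <- (spec$seed * 7919L + k * 104729L) %% 2147483587L + 1L
      p <- generate_participant(spec, info$sex, ages[j],
                                participant_id = pid, seed = pseed)
      if (k <= spec$n_gap_participants) {
        inj <- inject_artifacts(p$series, spec, seed = pseed + 13L,
                                inject_gap = TRUE)
        p$series <- inj$series
        p$truth$artifacts <- rbind(p$truth$artifacts, inj$positions)
      }
      series[[pid]] <- p$series
      truth[[pid]] <- p$truth
    }
  }
  structure(list(series = series, truth = truth, spec = spec),
            class = "cpet_cohort")
}

#' @export
print.cpet_cohort <- function(x, ...) {
  cat("Synthetic CPET cohort:", length(x$series), "participants\n")
  cells <- table(vapply(x$truth, `[[`, "", "cell"))
  for (nm in names(cells)) cat(sprintf("  %-15s %d\n", nm, cells[[nm]]))
  nb <- vapply(x$series, function(s) nrow(s$breaths), integer(1))
  cat(sprintf("  breaths/test: mean %.1f (range %d-%d)\n",
              mean(nb), min(nb), max(nb)))
  invisible(x)
}
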