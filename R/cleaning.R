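#' Cleaning configuration
#'
#' Parameters of the breath-removal rules: the work-rate ramp filter, the
#' absolute physiological bounds, the 15-breath moving-window 3-sigma
#' outlier rule, and the 30-second missing-data participant exclusion.
#'
#' Bounds are strict as stated for the source rules: values exactly on a
#' bound (HR 50 or 230 bpm, RR 8 or 75 breaths/min, VT 0.1 or 3.5 L, VO2
#' 0.2 L/min) are kept.  Minute ventilation has no absolute bound.
#'
#' @param bounds Named list of \code{c(min, max)} per bounded metric;
#'   \code{-Inf}/\code{Inf} for open sides.
#' @param window_halfwidth Moving-window halfwidth in breaths; the window
#'   length is \code{2 * halfwidth + 1} (15 by default, matching the 1/15
#'   divisor of the moving mean and SD).
#' @param sigma_mult Outlier threshold in window SDs (default 3).
#' @param wr_percentiles Percentiles of work rate and time used to fit the
#'   ramp line (default 5th and 95th).
#' @param gap_exclusion_s Participants with any metric missing for at least
#'   this many consecutive seconds are excluded (default 30).
#' @param eq1_variant Placement of the "- 1" in the work-rate criterion,
#'   which is typographically ambiguous in its source:
#'   \code{"subtract_after_product"} flags breath t when
#'   \code{WR_t < S * c_t - 1} (1 Watt below the percentile-fit ramp line);
#'   \code{"subtract_inside"} flags when \code{WR_t < S * (c_t - 1)} (the
#'   line shifted right by one minute).
#'
#' @return A list of class \code{"cleaning_config"}.
#' @export
cleaning_config <- function(bounds = list(vo2 = c(0.2, Inf),
                                          vco2 = c(0.2, Inf),
                                          hr = c(50, 230),
                                          rr = c(8, 75),
                                          vt = c(0.1, 3.5)),
                            window_halfwidth = 7, sigma_mult = 3,
                            wr_percentiles = c(0.05, 0.95),
                            gap_exclusion_s = 30,
                            eq1_variant = c("subtract_after_product",
                                            "subtract_inside")) {
  eq1_variant <- match.arg(eq1_variant)
  for (m in names(bounds)) {
    b <- bounds[[m]]
    if (length(b) != 2 || !(b[1] < b[2])) {
      stop("bounds for ", m, " must be c(min, max) with min < max")
    }
  }
  structure(list(bounds = bounds, window_halfwidth = window_halfwidth,
                 sigma_mult = sigma_mult, wr_percentiles = wr_percentiles,
                 gap_exclusion_s = gap_exclusion_s,
                 eq1_variant = eq1_variant),
            class = "cleaning_config")
}

#' Work-rate ramp filter
#'
#' Fits a ramp line through the participant's own work-rate/time percentiles
#' (slope \code{S = (WR_95 - WR_5) / (c_95 - c_5)} with time \code{c} in
#' minutes) and flags breaths whose work rate falls below that line, which
#' removes warm-up breaths and ergometer dropouts.  Flagged breaths are
#' removed across all metrics (a breath is one observation event).
#'
#' @param series A \code{\link{cpet_series}}.
#' @param cfg A \code{\link{cleaning_config}}.
#' @return Integer vector of flagged breath indices (possibly empty).
#' @export
filter_workrate_ramp <- function(series, cfg = cleaning_config()) {
  br <- series$breaths
  ok <- which(!is.na(br$work_rate))
  if (length(ok) < 2) {
    warning("work-rate filter skipped: fewer than 2 work-rate observations")
    return(integer(0))
  }
  wr <- br$work_rate[ok]
  cmin <- br$time_s[ok] / 60
  q <- cfg$wr_percentiles
  wr_q <- stats::quantile(wr, q, names = FALSE)
  c_q <- stats::quantile(cmin, q, names = FALSE)
  if (wr_q[2] == wr_q[1] || c_q[2] == c_q[1]) {
    warning("work-rate filter skipped: degenerate percentiles")
    return(integer(0))
  }
  S <- (wr_q[2] - wr_q[1]) / (c_q[2] - c_q[1])
  line <- if (cfg$eq1_variant == "subtract_after_product") {
    S * cmin - 1
  } else {
    S * (cmin - 1)
  }
  ok[wr < line]
}

#' Absolute physiological bounds filter
#'
#' Flags metric observations strictly outside their configured bounds.
#' Boundary values are kept (strict inequalities).
#'
#' @inheritParams filter_workrate_ramp
#' @return data.frame with columns \code{metric} and \code{index}.
#' @export
filter_absolute_bounds <- function(series, cfg = cleaning_config()) {
  out <- list()
  for (m in intersect(cpet_metrics(), names(cfg$bounds))) {
    b <- cfg$bounds[[m]]
    v <- series$breaths[[m]]
    bad <- which(!is.na(v) & (v < b[1] | v > b[2]))
    if (length(bad)) {
      out[[m]] <- data.frame(metric = m, index = bad)
    }
  }
  if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
  else data.frame(metric = character(0), index = integer(0))
}

#' Moving mean and standard deviation
#'
#' Centered moving window of \code{2 * halfwidth + 1} breaths; the SD uses
#' the population divisor (the full window length).  Positions within
#' \code{halfwidth} of either end have no full window and return \code{NA}.
#'
#' @param values Numeric signal (ordinal over surviving breaths).
#' @param halfwidth Window halfwidth in breaths.
#' @return List with numeric vectors \code{mu} and \code{sigma}, same length
#'   as \code{values}; \code{NULL} (with a warning) if the signal is shorter
#'   than one full window.
#' @export
moving_stats <- function(values, halfwidth = 7) {
  w <- 2 * halfwidth + 1
  n <- length(values)
  if (n < w) {
    warning("signal shorter than one full window (", w, "); skipped")
    return(NULL)
  }
  kern <- rep(1 / w, w)
  # center on the global mean before squaring to avoid catastrophic
  # cancellation in mean(x^2) - mean(x)^2 (constant windows must give 0)
  ctr <- values - mean(values)
  mu_c <- as.numeric(stats::filter(ctr, kern, sides = 2))
  m2_c <- as.numeric(stats::filter(ctr^2, kern, sides = 2))
  sigma <- sqrt(pmax(m2_c - mu_c^2, 0))
  list(mu = mu_c + mean(values), sigma = sigma)
}

#' Moving-window 3-sigma outlier filter
#'
#' Flags position t when \code{|b_t - mu_t| > sigma_mult * sigma_t} using
#' the full-window moving statistics of \code{\link{moving_stats}}.
#' Constant windows (sigma 0) flag nothing, edge positions are not
#' evaluated, and the rule is applied in a single pass.
#'
#' @param values Numeric signal.
#' @param cfg A \code{\link{cleaning_config}}.
#' @return Integer vector of flagged positions within \code{values}.
#' @export
filter_moving_3sigma <- function(values, cfg = cleaning_config()) {
  ms <- suppressWarnings(moving_stats(values, cfg$window_halfwidth))
  if (is.null(ms)) return(integer(0))
  dev <- abs(values - ms$mu)
  which(!is.na(ms$sigma) & dev > cfg$sigma_mult * ms$sigma)
}

#' 30-second missing-data exclusion
#'
#' A participant is excluded when, for any metric, the elapsed time between
#' consecutive present observations -- or from test start to the first, or
#' from the last to the end of the test -- reaches
#' \code{cfg$gap_exclusion_s}.  Applied after cleaning, since removals
#' create the gaps the rule guards against.
#'
#' @inheritParams filter_workrate_ramp
#' @return List with \code{excluded} (logical), and when excluded,
#'   \code{metric}, \code{gap_s} and \code{gap_start_s} describing the
#'   widest offending gap.
#' @export
exclude_by_gap <- function(series, cfg = cleaning_config()) {
  worst <- list(excluded = FALSE)
  for (m in cpet_metrics()) {
    sig <- extract_signal(series, m)
    t_pres <- sig$time_s
    edges <- c(0, t_pres, series$duration_s)
    gaps <- diff(edges)
    j <- which.max(gaps)
    if (gaps[j] >= cfg$gap_exclusion_s) {
      if (!worst$excluded || gaps[j] > worst$gap_s) {
        worst <- list(excluded = TRUE, metric = m, gap_s = gaps[j],
                      gap_start_s = edges[j])
      }
    }
  }
  worst
}

#' Clean a breath-by-breath series
#'
#' Applies the removal rules in order -- work-rate ramp filter, absolute
#' bounds, moving-window 3-sigma (each operating on the survivors of the
#' previous rule) -- then the 30-second gap exclusion.  Removed values
#' become \code{NA} so gap durations remain computable; no interpolation is
#' performed.
#'
#' @inheritParams filter_workrate_ramp
#' @return A list of class \code{"cleaning_report"} with elements
#'   \code{surviving} (the cleaned \code{\link{cpet_series}}),
#'   \code{removed_by_rule} (data.frame rule, metric, count),
#'   \code{removed_positions} (data.frame rule, metric, index),
#'   \code{excluded}, \code{exclusion} and \code{original_present}.
#' @export
clean_series <- function(series, cfg = cleaning_config()) {
  br <- series$breaths
  metrics <- cpet_metrics()
  original_present <- vapply(metrics, function(m) sum(!is.na(br[[m]])),
                             integer(1))
  positions <- list()

  # rule 1: work-rate ramp filter removes whole breaths
  eq1_idx <- filter_workrate_ramp(series, cfg)
  if (length(eq1_idx)) {
    for (m in metrics) {
      present <- eq1_idx[!is.na(br[[m]][eq1_idx])]
      if (length(present)) {
        positions[[length(positions) + 1L]] <- data.frame(
          rule = "eq1_workrate", metric = m, index = present)
      }
      br[[m]][eq1_idx] <- NA_real_
    }
    br$work_rate[eq1_idx] <- NA_real_
  }

  # rule 2: absolute physiological bounds on survivors
  tmp <- cpet_series(br, meta = series$meta, duration_s = series$duration_s)
  ab <- filter_absolute_bounds(tmp, cfg)
  if (nrow(ab)) {
    for (m in unique(ab$metric)) {
      idx <- ab$index[ab$metric == m]
      positions[[length(positions) + 1L]] <- data.frame(
        rule = "absolute_bounds", metric = m, index = idx)
      br[[m]][idx] <- NA_real_
    }
  }

  # rule 3: moving-window 3-sigma on the surviving signal of each metric
  for (m in metrics) {
    present <- which(!is.na(br[[m]]))
    flagged <- filter_moving_3sigma(br[[m]][present], cfg)
    if (length(flagged)) {
      idx <- present[flagged]
      positions[[length(positions) + 1L]] <- data.frame(
        rule = "moving_3sigma", metric = m, index = idx)
      br[[m]][idx] <- NA_real_
    }
  }

  surviving <- cpet_series(br, meta = series$meta,
                           duration_s = series$duration_s)
  exclusion <- exclude_by_gap(surviving, cfg)

  removed_positions <- if (length(positions)) {
    do.call(rbind, c(positions, list(make.row.names = FALSE)))
  } else {
    data.frame(rule = character(0), metric = character(0),
               index = integer(0))
  }
  removed_by_rule <- if (nrow(removed_positions)) {
    stats::aggregate(index ~ rule + metric, removed_positions, length)
  } else {
    data.frame(rule = character(0), metric = character(0),
               index = integer(0))
  }
  names(removed_by_rule)[names(removed_by_rule) == "index"] <- "count"

  structure(list(surviving = surviving,
                 removed_by_rule = removed_by_rule,
                 removed_positions = removed_positions,
                 excluded = exclusion$excluded,
                 exclusion = exclusion,
                 original_present = original_present),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("CPET cleaning report\n")
  if (nrow(x$removed_by_rule)) {
    tot <- stats::aggregate(count ~ rule, x$removed_by_rule, sum)
    for (i in seq_len(nrow(tot))) {
      cat(sprintf("  %-16s %d removed\n", tot$rule[i], tot$count[i]))
    }
  } else {
    cat("  no removals\n")
  }
  if (x$excluded) {
    cat(sprintf("  EXCLUDED: %.1f s gap in %s starting at %.1f s\n",
                x$exclusion$gap_s, x$exclusion$metric,
                x$exclusion$gap_start_s))
  } else {
    cat("  participant retained\n")
  }
  invisible(x)
}
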