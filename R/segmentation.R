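#' Split a test at its midpoint
#'
#' The midpoint is half the participant's total CPET time.  Breaths strictly
#' before it are "pre-midpoint"; breaths at or after it are "post-midpoint".
#'
#' @param series A \code{\link{cpet_series}} with positive duration.
#' @return List with \code{pre} and \code{post}, both
#'   \code{\link{cpet_series}} sharing the parent's metadata and duration.
#' @export
split_midpoint <- function(series) {
  if (series$duration_s <= 0) stop("duration_s must be positive")
  half <- series$duration_s / 2
  pre_rows <- series$breaths$time_s < half
  mk <- function(rows) {
    cpet_series(series$breaths[rows, , drop = FALSE], meta = series$meta,
                duration_s = series$duration_s)
  }
  list(pre = mk(pre_rows), post = mk(!pre_rows))
}

# age-group cutoffs: males 13 y, females 12 y (boundary age -> older)
age_group_of <- function(sex, age_years, scheme = "primary") {
  cutoff <- switch(scheme,
                   primary = if (sex == "male") 13 else 12,
                   female_cutoff_11 = if (sex == "male") 13 else 11,
                   exclusion_bands = if (sex == "male") 13 else 12,
                   stop("unknown scheme: ", scheme))
  if (age_years >= cutoff) "older" else "younger"
}

#' Assign age/sex groups to participants
#'
#' Primary scheme: males are "older" at age 13 and above, females at 12 and
#' above (boundary ages go to the older group).  Two sensitivity schemes are
#' available: \code{"female_cutoff_11"} moves the female cutoff to 11 years,
#' and \code{"exclusion_bands"} drops males aged [12.5, 13.5) and females
#' aged [11, 12) to sharpen the contrast between groups.
#'
#' @param meta_list List of \code{\link{participant_meta}} objects (or
#'   \code{\link{cpet_series}}, whose metadata is used).
#' @param scheme One of \code{"primary"}, \code{"female_cutoff_11"},
#'   \code{"exclusion_bands"}.
#' @return data.frame: participant_id, sex, age_years, age_group, scheme.
#'   Participants dropped by \code{exclusion_bands} are omitted (their ids
#'   are in \code{attr(, "dropped")}).
#' @export
assign_groups <- function(meta_list, scheme = c("primary",
                                                "female_cutoff_11",
                                                "exclusion_bands")) {
  scheme <- match.arg(scheme)
  metas <- lapply(meta_list, function(x) {
    if (inherits(x, "cpet_series")) x$meta else x
  })
  rows <- list()
  dropped <- character(0)
  for (m in metas) {
    if (!m$sex %in% c("male", "female")) {
      stop("unknown sex value: ", m$sex)
    }
    if (scheme == "exclusion_bands") {
      in_band <- (m$sex == "male" && m$age_years >= 12.5 &&
                    m$age_years < 13.5) ||
        (m$sex == "female" && m$age_years >= 11 && m$age_years < 12)
      if (in_band) {
        dropped <- c(dropped, m$participant_id)
        next
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = m$participant_id, sex = m$sex,
      age_years = m$age_years,
      age_group = age_group_of(m$sex, m$age_years, scheme),
      scheme = scheme)
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(participant_id = character(0), sex = character(0),
               age_years = numeric(0), age_group = character(0),
               scheme = character(0))
  }
  attr(out, "dropped") <- dropped
  out
}

# max over 20-s rolling windows, stepped every 5 s across the last 2 min
.rolling_tail_max <- function(series, window_value) {
  dur <- series$duration_s
  if (dur < 140) stop("test too short for the rolling-peak window scheme")
  starts <- seq(dur - 120, dur - 20, by = 5)
  vals <- vapply(starts, function(s0) {
    window_value(s0, s0 + 20)
  }, numeric(1))
  if (all(is.na(vals))) {
    stop("no breaths fall inside any rolling window")
  }
  max(vals, na.rm = TRUE)
}

#' Peak oxygen uptake
#'
#' VO2 peak is the maximum 20-second rolling average of breath VO2,
#' computed every 5 seconds over the last 2 minutes of exercise.  Windows
#' are half-open \code{[start, start + 20)}; windows containing no breath
#' are skipped.
#'
#' @param series A \code{\link{cpet_series}}.
#' @return VO2 peak in L/min.
#' @export
vo2_peak <- function(series) {
  sig <- extract_signal(series, "vo2")
  .rolling_tail_max(series, function(lo, hi) {
    sel <- sig$time_s >= lo & sig$time_s < hi
    if (!any(sel)) NA_real_ else mean(sig$values[sel])
  })
}

#' Peak respiratory exchange ratio
#'
#' Maximal-effort check: the maximum 20-second rolling average of the
#' per-breath respiratory exchange ratio (VCO2/VO2), using the same window
#' scheme as \code{\link{vo2_peak}}.  Tests are conventionally considered
#' maximal when this exceeds 1.0; the value is reported, not used to drop
#' participants.
#'
#' @param series A \code{\link{cpet_series}}.
#' @return Peak RER (dimensionless).
#' @export
rer_peak <- function(series) {
  vo2 <- series$breaths$vo2
  vco2 <- series$breaths$vco2
  t <- series$breaths$time_s
  ok <- !is.na(vo2) & !is.na(vco2) & vo2 > 0
  rer <- vco2[ok] / vo2[ok]
  tt <- t[ok]
  .rolling_tail_max(series, function(lo, hi) {
    sel <- tt >= lo & tt < hi
    if (!any(sel)) NA_real_ else mean(rer[sel])
  })
}
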