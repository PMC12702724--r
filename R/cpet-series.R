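#' CPET metric identifiers
#'
#' The six breath-by-breath metrics analyzed by the package: oxygen uptake
#' (\code{vo2}, L/min), carbon-dioxide output (\code{vco2}, L/min), minute
#' ventilation (\code{ve}, L/min), heart rate (\code{hr}, beats/min),
#' respiratory rate (\code{rr}, breaths/min) and tidal volume (\code{vt},
#' L/breath).
#'
#' @return Character vector of the six metric ids.
#' @export
cpet_metrics <- function() {
  c("vo2", "vco2", "ve", "hr", "rr", "vt")
}

# canonical CSV header <-> internal column names
.breath_columns <- c(
  time_s = "time_s",
  vo2 = "vo2_l_min",
  vco2 = "vco2_l_min",
  ve = "ve_l_min",
  hr = "hr_bpm",
  rr = "rr_br_min",
  vt = "vt_l",
  work_rate = "work_rate_w"
)

#' Participant metadata
#'
#' @param participant_id Opaque identifier string.
#' @param sex \code{"male"} or \code{"female"}.
#' @param age_years Decimal age in years; must lie inside \code{age_bounds}.
#' @param height_cm,weight_kg,bmi_percentile Optional anthropometrics.
#' @param age_bounds Sanity bounds on age (years).
#'
#' @return A list of class \code{"participant_meta"}.
#' @export
participant_meta <- function(participant_id, sex, age_years,
                             height_cm = NA_real_, weight_kg = NA_real_,
                             bmi_percentile = NA_real_,
                             age_bounds = c(5, 25)) {
  sex <- match.arg(sex, c("male", "female"))
  age_years <- as.numeric(age_years)
  if (!is.finite(age_years) || age_years < age_bounds[1] ||
      age_years > age_bounds[2]) {
    stop("age_years must be a finite value in [", age_bounds[1], ", ",
         age_bounds[2], "], got ", age_years)
  }
  structure(
    list(participant_id = as.character(participant_id), sex = sex,
         age_years = age_years, height_cm = height_cm,
         weight_kg = weight_kg, bmi_percentile = bmi_percentile),
    class = "participant_meta"
  )
}

#' A participant's breath-by-breath series
#'
#' Container for one CPET: ordered breath records plus metadata and total
#' test duration.  Each row of \code{breaths} is one breath; metric cells may
#' be \code{NA}, which marks a removed or missing observation while keeping
#' the breath's position in time (gap-duration rules need this).
#'
#' @param breaths \code{data.frame} with columns \code{time_s}, \code{vo2},
#'   \code{vco2}, \code{ve}, \code{hr}, \code{rr}, \code{vt},
#'   \code{work_rate}.  \code{time_s} is seconds since test start and must be
#'   strictly increasing, finite, non-negative.
#' @param meta A \code{\link{participant_meta}} or \code{NULL}.
#' @param duration_s Total test time in seconds; defaults to the last breath
#'   time.  Must be \eqn{\ge} the last breath time.
#'
#' @return An object of class \code{"cpet_series"}.
#' @export
cpet_series <- function(breaths, meta = NULL, duration_s = NULL) {
  cols <- names(.breath_columns)
  breaths <- as.data.frame(breaths)
  missing_cols <- setdiff(cols, names(breaths))
  if (length(missing_cols)) {
    stop("breaths is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  breaths <- breaths[, cols, drop = FALSE]
  for (cl in cols) breaths[[cl]] <- as.numeric(breaths[[cl]])
  t <- breaths$time_s
  if (nrow(breaths)) {
    if (anyNA(t) || any(!is.finite(t)) || any(t < 0)) {
      stop("time_s must be finite and non-negative")
    }
    if (is.unsorted(t, strictly = FALSE)) {
      breaths <- breaths[order(t), , drop = FALSE]
      t <- breaths$time_s
    }
    dup <- which(duplicated(t))
    if (length(dup)) {
      stop("duplicate time_s at row ", dup[1], " (t = ", t[dup[1]], " s)")
    }
    for (cl in setdiff(cols, "time_s")) {
      v <- breaths[[cl]]
      if (any(!is.na(v) & !is.finite(v))) {
        stop("non-finite values in column ", cl)
      }
    }
  }
  rownames(breaths) <- NULL
  if (is.null(duration_s)) {
    duration_s <- if (nrow(breaths)) t[length(t)] else 0
  }
  duration_s <- as.numeric(duration_s)
  if (nrow(breaths) && duration_s < t[length(t)] - 1e-9) {
    stop("duration_s (", duration_s, ") is before the last breath (",
         t[length(t)], ")")
  }
  structure(list(meta = meta, breaths = breaths, duration_s = duration_s),
            class = "cpet_series")
}

#' @export
print.cpet_series <- function(x, ...) {
  id <- if (is.null(x$meta)) "<unlabelled>" else x$meta$participant_id
  cat("CPET breath-by-breath series\n")
  cat("  participant:", id)
  if (!is.null(x$meta)) {
    cat(sprintf(" (%s, %.1f y)", x$meta$sex, x$meta$age_years))
  }
  cat("\n")
  cat(sprintf("  %d breaths over %.1f s (%.1f min)\n",
              nrow(x$breaths), x$duration_s, x$duration_s / 60))
  present <- vapply(cpet_metrics(), function(m) sum(!is.na(x$breaths[[m]])),
                    integer(1))
  cat("  present observations:",
      paste(sprintf("%s=%d", names(present), present), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.cpet_series <- function(x) nrow(x$breaths)

#' Extract one metric's signal from a series
#'
#' Returns the observed (non-missing) values of one metric, with their breath
#' times, order preserved.  Each breath is one observation in the signal.
#'
#' @param series A \code{\link{cpet_series}}.
#' @param metric One of \code{\link{cpet_metrics}()}.
#'
#' @return List with \code{time_s} and \code{values}, equal-length numeric
#'   vectors containing only present observations.
#' @export
extract_signal <- function(series, metric) {
  metric <- match.arg(metric, cpet_metrics())
  v <- series$breaths[[metric]]
  keep <- !is.na(v)
  list(time_s = series$breaths$time_s[keep], values = v[keep])
}

#' Read a breath-by-breath table from CSV
#'
#' Expects the canonical header \code{time_s, vo2_l_min, vco2_l_min,
#' ve_l_min, hr_bpm, rr_br_min, vt_l, work_rate_w}; alternative headers can
#' be mapped via \code{dialect}.  Empty cells become \code{NA} (a missing or
#' removed breath value).  A JSON sidecar \code{<path>.json} holding
#' \code{duration_s} is honoured when present, since the last breath can
#' underestimate total test time.
#'
#' @param path CSV file path.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names actually used in the file, e.g.
#'   \code{c(hr_bpm = "HR")}.
#' @param meta Optional \code{\link{participant_meta}} to attach.
#' @param duration_s Optional duration override (takes precedence over the
#'   sidecar).
#'
#' @return A \code{\link{cpet_series}}, sorted by time.
#' @export
read_breath_table <- function(path, dialect = NULL, meta = NULL,
                              duration_s = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = c("", "NA"))
  wanted <- unname(.breath_columns)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), wanted)
    if (length(bad)) stop("unknown dialect keys: ", paste(bad, collapse = ", "))
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
  }
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols)) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(lapply(df[wanted], as.numeric))
  names(out) <- names(.breath_columns)
  if (is.null(duration_s)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      side <- jsonlite::read_json(sidecar)
      if (!is.null(side$duration_s)) duration_s <- as.numeric(side$duration_s)
    }
  }
  cpet_series(out, meta = meta, duration_s = duration_s)
}

#' Write a breath-by-breath table to CSV
#'
#' Inverse of \code{\link{read_breath_table}}: numeric fields round-trip to
#' within 1e-9, \code{NA} cells are written as empty cells, and
#' \code{duration_s} goes to a JSON sidecar \code{<path>.json}.
#'
#' @param series A \code{\link{cpet_series}}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_breath_table <- function(series, path) {
  df <- series$breaths
  out <- df
  names(out) <- unname(.breath_columns[names(df)])
  # format() at 15 significant digits keeps the round-trip inside 1e-9
  chr <- as.data.frame(lapply(out, function(v) {
    s <- vapply(v, function(x) {
      if (is.na(x)) "" else format(x, digits = 15, scientific = FALSE)
    }, character(1))
    s
  }), check.names = FALSE)
  utils::write.csv(chr, path, row.names = FALSE, quote = FALSE, na = "")
  jsonlite::write_json(list(duration_s = series$duration_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns \code{participant_id}, \code{sex},
#' \code{age_years}, \code{file} (breath-table path relative to the manifest)
#' and optionally \code{height_cm}, \code{weight_kg}, \code{bmi_percentile}.
#'
#' @param manifest Path to the manifest CSV.
#' @return List of \code{\link{cpet_series}}, one per manifest row.
#' @export
read_cohort <- function(manifest) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("participant_id", "sex", "age_years", "file")
  missing_cols <- setdiff(need, names(mf))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  base <- dirname(manifest)
  lapply(seq_len(nrow(mf)), function(i) {
    meta <- participant_meta(
      mf$participant_id[i], mf$sex[i], mf$age_years[i],
      height_cm = if ("height_cm" %in% names(mf)) mf$height_cm[i] else NA_real_,
      weight_kg = if ("weight_kg" %in% names(mf)) mf$weight_kg[i] else NA_real_,
      bmi_percentile = if ("bmi_percentile" %in% names(mf))
        mf$bmi_percentile[i] else NA_real_
    )
    read_breath_table(file.path(base, mf$file[i]), meta = meta)
  })
}

#' Write a cohort to a directory
#'
#' Writes one breath table per participant plus a manifest CSV, readable by
#' \code{\link{read_cohort}}.
#'
#' @param cohort List of \code{\link{cpet_series}} (all with metadata).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    if (is.null(s$meta)) stop("write_cohort requires participant metadata")
    fn <- paste0(s$meta$participant_id, ".csv")
    write_breath_table(s, file.path(dir, fn))
    data.frame(participant_id = s$meta$participant_id, sex = s$meta$sex,
               age_years = s$meta$age_years, height_cm = s$meta$height_cm,
               weight_kg = s$meta$weight_kg,
               bmi_percentile = s$meta$bmi_percentile, file = fn,
               stringsAsFactors = FALSE)
  })
  mf <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(mf, path, row.names = FALSE)
  invisible(path)
}
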