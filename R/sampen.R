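#' Brute-force Sample Entropy (reference implementation)
#'
#' Direct enumeration of every ordered template pair \code{(i, j)}, i != j,
#' with \code{i, j in 1:(N - m)}: templates of length m are compared under
#' the Chebyshev (max-norm) distance against the similarity radius r
#' (inclusive), self-matches excluded, and the same index range is reused
#' for the (m+1)-length templates (the final (m+1)-template ends exactly at
#' the last observation).  Both match probabilities share the normalization
#' \code{Z = (N - m) * (N - m - 1)}, so A and B always lie in [0, 1], and
#' \code{SampEn = -log(A / B)}.
#'
#' This implementation is the package's oracle: it is deliberately a plain
#' double loop over pairs.  \code{\link{sampen}} must return identical match
#' counts on every input.
#'
#' @param x Numeric signal (conventionally already differenced and
#'   standardized, so r is in SD units).
#' @param m Embedding dimension (template length), positive integer.
#' @param r Similarity radius, > 0.
#' @return An object of class \code{"sampen_result"}: \code{value} (nats;
#'   \code{Inf} when no (m+1)-matches exist), \code{a_prob}, \code{b_prob},
#'   \code{a_count}, \code{b_count}, \code{n}, \code{m}, \code{r},
#'   \code{defined}.
#' @export
sampen_bruteforce <- function(x, m = 2, r = 0.2) {
  .check_sampen_args(x, m, r)
  n <- length(x)
  ntmpl <- n - m
  a_count <- 0L
  b_count <- 0L
  for (i in seq_len(ntmpl)) {
    for (j in seq_len(ntmpl)) {
      if (i == j) next
      db <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (db <= r) {
        b_count <- b_count + 1L
        da <- max(db, abs(x[i + m] - x[j + m]))
        if (da <= r) a_count <- a_count + 1L
      }
    }
  }
  .sampen_result(a_count, b_count, n, m, r)
}

.check_sampen_args <- function(x, m, r) {
  if (m < 1 || m != as.integer(m)) stop("m must be a positive integer")
  if (!is.finite(r) || r <= 0) stop("r must be positive")
  if (length(x) < m + 2) {
    stop("signal too short: need N >= m + 2 (= ", m + 2, "), got ",
         length(x))
  }
  if (anyNA(x)) stop("signal contains missing values")
  invisible(TRUE)
}

.sampen_result <- function(a_count, b_count, n, m, r) {
  z <- as.numeric(n - m) * (n - m - 1)
  a_prob <- a_count / z
  b_prob <- b_count / z
  defined <- a_count > 0 && b_count > 0
  value <- if (defined) -log(a_prob / b_prob) else Inf
  structure(list(value = value, a_prob = a_prob, b_prob = b_prob,
                 a_count = as.integer(a_count), b_count = as.integer(b_count),
                 n = as.integer(n), m = as.integer(m), r = r,
                 defined = defined),
            class = "sampen_result")
}

#' @export
print.sampen_result <- function(x, ...) {
  cat(sprintf("SampEn(m = %d, r = %g, N = %d) = %s\n", x$m, x$r, x$n,
              if (x$defined) sprintf("%.4f nats", x$value) else
                "undefined (no template matches)"))
  cat(sprintf("  B = %.6g (%d matches), A = %.6g (%d matches)\n",
              x$b_prob, x$b_count, x$a_prob, x$a_count))
  invisible(x)
}

#' Sample Entropy
#'
#' Production implementation of Sample Entropy; reorganizes the computation
#' around cumulative Chebyshev distance matrices but counts exactly the same
#' template pairs as \code{\link{sampen_bruteforce}}, to which it is
#' bit-for-bit equivalent.
#'
#' The similarity radius r is interpreted in units of the signal's SD;
#' signals entering from the stationarity stage are already standardized,
#' so no rescaling happens here.
#'
#' @inheritParams sampen_bruteforce
#' @return A \code{"sampen_result"}; see \code{\link{sampen_bruteforce}}.
#' @export
sampen <- function(x, m = 2, r = 0.2) {
  .check_sampen_args(x, m, r)
  n <- length(x)
  ntmpl <- n - m
  # D holds the Chebyshev distance between length-k templates at each
  # (i, j); grow k by folding in the next shifted element-wise distance
  d1 <- abs(outer(x, x, "-"))
  D <- d1
  for (k in seq_len(m - 1)) {
    sz <- n - k
    D <- pmax(D[seq_len(sz), seq_len(sz), drop = FALSE],
              d1[k + seq_len(sz), k + seq_len(sz), drop = FALSE])
  }
  Dm <- D[seq_len(ntmpl), seq_len(ntmpl), drop = FALSE]
  b_count <- sum(Dm <= r) - sum(diag(Dm) <= r)
  Dm1 <- pmax(Dm, d1[m + seq_len(ntmpl), m + seq_len(ntmpl), drop = FALSE])
  a_count <- sum(Dm1 <= r) - sum(diag(Dm1) <= r)
  .sampen_result(a_count, b_count, n, m, r)
}

#' Penalized (m, r) selection for Sample Entropy
#'
#' Searches a grid of embedding dimensions and similarity radii and picks
#' the point minimizing the median, across the supplied signals, of the
#' estimated relative error of SampEn plus a penalty \code{lam * r}.  The
#' relative error uses a delta-method (quadratic) approximation of the
#' template match-count variance: treating the A- and B-counts as binomial
#' over their \code{Z} comparisons,
#' \code{var(log p) ~ (1 - p) / (p Z)}, so
#' \code{rel_err = sqrt(var(log A) + var(log B)) / SampEn}.  Signals where a
#' grid point yields an undefined SampEn contribute an infinite error there;
#' grid points undefined (or too short) for more than half the signals are
#' effectively dropped.  Ties break toward smaller m, then smaller r.
#'
#' This objective is a documented surrogate for variance-aware parameter
#' selection; it is not a reimplementation of any specific published
#' optimizer, and the selected values need not match any particular study.
#'
#' @param signals List of numeric vectors (differenced, standardized
#'   signals for one metric across participants).
#' @param m_grid Candidate embedding dimensions.
#' @param r_grid Candidate radii (SD units).
#' @param lam Penalty weight on r (larger values push the search toward
#'   small radii; used to guarantee exploration for low-variability metrics
#'   such as per-breath HR).
#' @return List of class \code{"sampen_selection"}: \code{m}, \code{r},
#'   and \code{trace} (data.frame of the objective over the grid).
#' @export
select_sampen_params <- function(signals, m_grid = 1:3,
                                 r_grid = seq(0.05, 0.50, by = 0.05),
                                 lam = 0.2) {
  if (!length(signals)) stop("need at least one signal")
  grid <- expand.grid(m = m_grid, r = r_grid)
  obj <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    m <- grid$m[g]
    r <- grid$r[g]
    errs <- vapply(signals, function(x) {
      if (length(x) < m + 2) return(NA_real_)
      res <- sampen(x, m, r)
      if (!res$defined || res$value <= 0) return(Inf)
      z <- (res$n - res$m) * (res$n - res$m - 1)
      va <- (1 - res$a_prob) / (res$a_prob * z)
      vb <- (1 - res$b_prob) / (res$b_prob * z)
      sqrt(va + vb) / res$value
    }, numeric(1))
    usable <- errs[!is.na(errs)]
    obj[g] <- if (length(usable)) stats::median(usable) + lam * r else Inf
  }
  trace <- cbind(grid, objective = obj)
  feasible <- which(is.finite(obj))
  if (!length(feasible)) stop("no feasible (m, r) grid point")
  # ties break toward smaller m then smaller r
  ord <- feasible[order(obj[feasible], grid$m[feasible], grid$r[feasible])]
  best <- ord[1]
  structure(list(m = grid$m[best], r = grid$r[best], lam = lam,
                 trace = trace),
            class = "sampen_selection")
}

#' @export
print.sampen_selection <- function(x, ...) {
  cat(sprintf("Selected SampEn parameters: m = %d, r = %.2f (lam = %g)\n",
              x$m, x$r, x$lam))
  invisible(x)
}

#' Per-participant entropy table
#'
#' Computes SampEn for every analyzable (participant x metric x segment)
#' combination.  Signals are differenced and standardized via
#' \code{\link{prepare_stationary}}; rows whose SampEn is undefined (no
#' (m+1)-template matches) are carried with \code{defined = FALSE} so the
#' group-comparison stage can exclude rather than impute them.  When a
#' stationarity verdict table is supplied, non-stationary signals are
#' marked non-analyzable.
#'
#' @param cohort List of cleaned \code{\link{cpet_series}} (excluded
#'   participants already dropped).
#' @param params Named list per metric with elements \code{m} and \code{r}.
#' @param segments Which segments to tabulate.
#' @param stationarity Optional data.frame with columns
#'   \code{participant_id}, \code{metric}, \code{segment},
#'   \code{stationary}; rows whose verdict is \code{FALSE} are skipped.
#' @param adf ADF configuration forwarded to
#'   \code{\link{prepare_stationary}}.
#' @return data.frame: participant_id, metric, segment, n, m, r, sampen,
#'   a_prob, b_prob, defined.
#' @export
entropy_table <- function(cohort, params,
                          segments = c("pre", "post", "full"),
                          stationarity = NULL, adf = adf_config()) {
  rows <- list()
  for (s in cohort) {
    pid <- if (is.null(s$meta)) NA_character_ else s$meta$participant_id
    for (metric in cpet_metrics()) {
      pr <- params[[metric]]
      if (is.null(pr)) stop("no SampEn parameters for metric ", metric)
      for (seg in segments) {
        if (!is.null(stationarity)) {
          hit <- stationarity$participant_id == pid &
            stationarity$metric == metric & stationarity$segment == seg
          if (any(hit) && isFALSE(all(stationarity$stationary[hit]))) next
        }
        st <- prepare_stationary(s, metric, seg, cfg = adf)
        if (!st$analyzable || st$n < pr$m + 2) next
        res <- sampen(st$values, pr$m, pr$r)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, metric = metric, segment = seg,
          n = res$n, m = res$m, r = res$r,
          sampen = if (res$defined) res$value else NA_real_,
          a_prob = res$a_prob, b_prob = res$b_prob, defined = res$defined)
      }
    }
  }
  if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(participant_id = character(0), metric = character(0),
                  segment = character(0), n = integer(0), m = integer(0),
                  r = numeric(0), sampen = numeric(0), a_prob = numeric(0),
                  b_prob = numeric(0), defined = logical(0))
}
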