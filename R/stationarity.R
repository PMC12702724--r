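#' First-difference a signal
#'
#' \code{x[t+1] - x[t]}; removes the ramp-driven trend from CPET metrics and
#' is the transformation applied before Sample Entropy is computed.
#'
#' @param values Numeric vector, length at least 2.
#' @return Numeric vector of length \code{length(values) - 1}.
#' @export
difference <- function(values) {
  if (length(values) < 2) stop("difference() needs at least 2 observations")
  diff(values)
}

#' Standardize a signal to zero mean and unit variance
#'
#' Sample standard deviation (divisor n - 1).  Constant signals are
#' degenerate: entropy is undefined on them, so an error is raised.
#'
#' @param values Numeric vector, length at least 2, non-constant.
#' @return Standardized numeric vector.
#' @export
standardize <- function(values) {
  if (length(values) < 2) stop("standardize() needs at least 2 observations")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate signal: zero variance, cannot standardize")
  }
  (values - mean(values)) / s
}

#' ADF test configuration
#'
#' @param alpha Significance level for the stationarity verdict.
#' @param lag_policy \code{"aic"} (select the augmentation lag by AIC up to
#'   \code{max_lag}) or a fixed non-negative integer lag.
#' @param regression \code{"constant"} (default; differencing has already
#'   removed the trend) or \code{"constant+trend"}.
#' @param max_lag Upper bound for AIC lag selection; \code{NULL} uses the
#'   Schwert rule \code{floor(12 * (n/100)^0.25)}.
#' @param correction Multiple-testing correction applied across the family
#'   of ADF tests; only \code{"holm_sidak"} is supported.
#' @return A list of class \code{"adf_config"}.
#' @export
adf_config <- function(alpha = 0.05, lag_policy = "aic",
                       regression = c("constant", "constant+trend"),
                       max_lag = NULL, correction = "holm_sidak") {
  regression <- match.arg(regression)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!identical(lag_policy, "aic")) {
    lag_policy <- as.integer(lag_policy)
    if (is.na(lag_policy) || lag_policy < 0) {
      stop("lag_policy must be \"aic\" or a non-negative integer")
    }
  }
  structure(list(alpha = alpha, lag_policy = lag_policy,
                 regression = regression, max_lag = max_lag,
                 correction = correction),
            class = "adf_config")
}

# MacKinnon (1994) response-surface coefficients for the approximate
# asymptotic p-value of the ADF tau statistic (single unit root).
.mackinnon <- list(
  constant = list(max = 2.74, min = -18.83, star = -1.61,
                  small = c(2.1659, 1.4412, 0.038269),
                  large = c(1.7339, 0.93202, -0.12745, -0.010368)),
  `constant+trend` = list(max = 0.7, min = -16.18, star = -2.89,
                          small = c(3.2512, 1.6047, 0.049588),
                          large = c(2.5261, 0.61654, -0.37956, -0.060285)))

.mackinnon_p <- function(tau, regression) {
  tab <- .mackinnon[[regression]]
  if (tau > tab$max) return(1)
  if (tau < tab$min) return(0)
  coefs <- if (tau <= tab$star) tab$small else tab$large
  stats::pnorm(sum(coefs * tau^(seq_along(coefs) - 1)))
}

#' Augmented Dickey-Fuller unit-root test
#'
#' OLS regression of \code{diff(y)} on the lagged level, an intercept
#' (optionally a linear trend) and \code{k} lagged differences, with
#' \code{k} chosen by AIC over a common estimation sample (then refit on the
#' full usable sample).  The p-value of the tau statistic uses the MacKinnon
#' (1994) response-surface approximation.  Small p-values reject the unit
#' root, supporting stationarity.
#'
#' @param values Numeric signal.
#' @param cfg An \code{\link{adf_config}}.
#' @return List with \code{statistic} (tau), \code{p_value},
#'   \code{used_lag} and \code{n}.  Signals shorter than 20 observations
#'   return the conservative \code{p_value = 1} with a warning.
#' @export
adf_test <- function(values, cfg = adf_config()) {
  n <- length(values)
  if (n < 20) {
    warning("ADF test needs >= 20 observations; returning conservative p = 1")
    return(list(statistic = NA_real_, p_value = 1, used_lag = NA_integer_,
                n = n))
  }
  y <- as.numeric(values)
  dy <- diff(y)
  nd <- length(dy)

  fit_one <- function(k, rows) {
    X <- cbind(level = y[rows], intercept = 1)
    if (cfg$regression == "constant+trend") X <- cbind(X, trend = rows)
    if (k > 0) {
      lagmat <- sapply(seq_len(k), function(j) dy[rows - j])
      X <- cbind(X, lagmat)
    }
    fit <- stats::lm.fit(X, dy[rows])
    rss <- sum(fit$residuals^2)
    list(fit = fit, rss = rss, X = X, nobs = length(rows),
         npar = ncol(X))
  }

  if (identical(cfg$lag_policy, "aic")) {
    maxlag <- cfg$max_lag
    if (is.null(maxlag)) maxlag <- floor(12 * (n / 100)^0.25)
    maxlag <- max(0L, min(maxlag, nd - 8L))
    rows_sel <- (maxlag + 1):nd
    aics <- vapply(0:maxlag, function(k) {
      f <- fit_one(k, rows_sel)
      f$nobs * log(f$rss / f$nobs) + 2 * f$npar
    }, numeric(1))
    used_lag <- which.min(aics) - 1L
  } else {
    used_lag <- cfg$lag_policy
  }

  rows <- (used_lag + 1):nd
  f <- fit_one(used_lag, rows)
  dfree <- f$nobs - f$npar
  s2 <- f$rss / dfree
  XtX_inv <- chol2inv(chol(crossprod(f$X)))
  se_level <- sqrt(s2 * XtX_inv[1, 1])
  tau <- f$fit$coefficients[["level"]] / se_level
  list(statistic = tau, p_value = .mackinnon_p(tau, cfg$regression),
       used_lag = used_lag, n = n)
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' Sort the p-values ascending; the i-th adjusted value is
#' \code{max over j <= i of 1 - (1 - p_(j))^(m - j + 1)}, capped at 1.
#' Hypotheses are rejected while the adjusted value stays below
#' \code{alpha} (the decisions form a prefix of the sorted list).
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param alpha Family-wise error level.
#' @return List with \code{adjusted} (in the input order) and \code{reject}
#'   (logical, input order).
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(list(adjusted = numeric(0), reject = logical(0)))
  ord <- order(p)
  step <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj_sorted <- pmin(cummax(step), 1)
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  reject_sorted <- adj_sorted < alpha
  # step-down: once a hypothesis fails, all later ones fail too
  if (any(!reject_sorted)) {
    first_fail <- which(!reject_sorted)[1]
    reject_sorted[first_fail:m] <- FALSE
  }
  reject <- logical(m)
  reject[ord] <- reject_sorted
  list(adjusted = adjusted, reject = reject)
}

#' Prepare one metric segment for entropy analysis
#'
#' Extracts the metric's signal on a segment (\code{"pre"}, \code{"post"},
#' or \code{"full"}), first-differences it, standardizes to zero mean and
#' unit variance, and runs the ADF unit-root test.  The cohort-level
#' stationarity verdict is filled in later, once all tests in a pipeline
#' run are corrected together with \code{\link{holm_sidak}}.
#'
#' @param series A cleaned \code{\link{cpet_series}}.
#' @param metric One of \code{\link{cpet_metrics}()}.
#' @param segment \code{"full"}, \code{"pre"} or \code{"post"} (relative to
#'   the test midpoint).
#' @param cfg An \code{\link{adf_config}}.
#' @return A list of class \code{"stationary_signal"}: \code{values}
#'   (differenced, standardized), \code{metric}, \code{segment},
#'   \code{adf_p}, \code{stationary} (\code{NA} until corrected),
#'   \code{n}, and \code{analyzable}.  Degenerate or too-short signals come
#'   back with \code{analyzable = FALSE}.
#' @export
prepare_stationary <- function(series, metric, segment = "full",
                               cfg = adf_config()) {
  segment <- match.arg(segment, c("full", "pre", "post"))
  sub <- if (segment == "full") series else {
    halves <- split_midpoint(series)
    halves[[segment]]
  }
  sig <- extract_signal(sub, metric)
  base <- list(metric = metric, segment = segment, analyzable = FALSE,
               values = numeric(0), adf_p = NA_real_, stationary = NA,
               n = 0L)
  if (length(sig$values) < 3) {
    base$reason <- "too short"
    return(structure(base, class = "stationary_signal"))
  }
  d <- difference(sig$values)
  s <- stats::sd(d)
  # relative floor: a noiseless ramp differences to a constant up to
  # floating-point residue, which must not masquerade as signal
  if (!is.finite(s) || s <= 1e-9 * (abs(mean(d)) + 1e-30)) {
    base$reason <- "degenerate (constant after differencing)"
    return(structure(base, class = "stationary_signal"))
  }
  z <- standardize(d)
  adf <- suppressWarnings(adf_test(z, cfg))
  structure(list(metric = metric, segment = segment, analyzable = TRUE,
                 values = z, adf_p = adf$p_value, stationary = NA,
                 n = length(z), used_lag = adf$used_lag),
            class = "stationary_signal")
}
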