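test_that("moving window statistics match direct arithmetic", {
  # constant signal
  ms <- moving_stats(rep(1, 30))
  expect_equal(ms$mu[8:23], rep(1, 16))
  expect_equal(ms$sigma[8:23], rep(0, 16), tolerance = 1e-12)
  expect_true(all(is.na(ms$mu[1:7])))

  # a single 100 among fourteen 1.0s: mu and sigma from the definition
  w <- c(rep(1, 7), 100, rep(1, 7))
  ms <- moving_stats(w)
  expect_equal(ms$mu[8], 114 / 15)                 # 7.6
  expect_equal(ms$sigma[8], sqrt((14 * (1 - 7.6)^2 + (100 - 7.6)^2) / 15))
  expect_equal(ms$sigma[8], sqrt(609.84))

  # linear signal: window symmetry makes mu_t = t
  lin <- as.numeric(1:40)
  ms <- moving_stats(lin)
  expect_equal(ms$mu[8:33], lin[8:33])

  expect_warning(moving_stats(rep(1, 10)), "shorter")
})

test_that("the 3-sigma rule flags an isolated spike but not constants", {
  x <- c(rep(1, 20), 100, rep(1, 20))
  flagged <- filter_moving_3sigma(x)
  expect_equal(flagged, 21L)          # |100 - 7.6| = 92.4 > 3 * 24.69
  expect_length(filter_moving_3sigma(rep(2, 40)), 0)

  # two-sided 3-sigma on iid noise flags almost nothing
  set.seed(31)
  expect_lte(length(filter_moving_3sigma(rnorm(300))), 4)
})

test_that("work-rate filter keeps a perfect ramp and flags a warm-up", {
  s <- make_ramp_series(200, dt = 3)
  expect_length(filter_workrate_ramp(s), 0)

  # unloaded phase below the percentile-fit line: evaluate the criterion
  # independently and compare index sets
  p <- generate_participant(cohort_spec(), "male", 12, seed = 21)
  s2 <- p$series
  flagged <- filter_workrate_ramp(s2)
  wr <- s2$breaths$work_rate
  cmin <- s2$breaths$time_s / 60
  S <- diff(quantile(wr, c(0.05, 0.95), names = FALSE)) /
    diff(quantile(cmin, c(0.05, 0.95), names = FALSE))
  expect_identical(flagged, which(wr < S * cmin - 1))
  expect_gt(length(flagged), 0)
  expect_true(all(s2$breaths$time_s[flagged] < 30))

  # degenerate: constant work rate
  s3 <- make_ramp_series(20)
  s3$breaths$work_rate <- 50
  expect_warning(f <- filter_workrate_ramp(s3), "degenerate")
  expect_length(f, 0)
})

test_that("eq1 variants place the 1-unit offset differently", {
  s <- make_ramp_series(100, dt = 3)
  # shift one mid-test breath 2 W below the ramp: caught by the
  # after-product variant (line minus 1 W), not by the shifted-line variant
  s$breaths$work_rate[50] <- s$breaths$work_rate[50] - 2
  f_a <- filter_workrate_ramp(s, cleaning_config(
    eq1_variant = "subtract_after_product"))
  f_b <- filter_workrate_ramp(s, cleaning_config(
    eq1_variant = "subtract_inside"))
  expect_true(50 %in% f_a)
  expect_false(50 %in% f_b)
})

test_that("absolute bounds are strict: boundary values are kept", {
  s <- make_ramp_series(12)
  s$breaths$hr[1] <- 240    # outside 50-230
  s$breaths$hr[2] <- 230    # boundary, kept
  s$breaths$hr[3] <- 50
  s$breaths$vo2[4] <- 0.2   # boundary, kept
  s$breaths$vo2[5] <- 0.19
  s$breaths$rr[6] <- 7.9
  s$breaths$rr[7] <- 8
  s$breaths$vt[8] <- 3.6
  s$breaths$vt[9] <- 3.5
  fl <- filter_absolute_bounds(s)
  got <- paste(fl$metric, fl$index)
  expect_setequal(got, c("hr 1", "vo2 5", "rr 6", "vt 8"))
})

test_that("gap exclusion measures elapsed time between present breaths", {
  s <- make_ramp_series(100, dt = 2)   # 200 s test
  # carve a 36 s hole in vo2
  s$breaths$vo2[s$breaths$time_s > 100 & s$breaths$time_s < 136] <- NA
  g <- exclude_by_gap(s)
  expect_true(g$excluded)
  expect_equal(g$metric, "vo2")
  expect_gte(g$gap_s, 30)

  expect_false(exclude_by_gap(make_ramp_series(100, dt = 2))$excluded)

  # a fully missing metric is one gap spanning the whole test
  s2 <- make_ramp_series(30, dt = 2)
  s2$breaths$hr <- NA_real_
  g2 <- exclude_by_gap(s2)
  expect_true(g2$excluded)
  expect_equal(g2$metric, "hr")
})

test_that("cleaning a clean ramp removes nothing", {
  rep <- clean_series(make_ramp_series(200, dt = 3))
  expect_equal(nrow(rep$removed_positions), 0)
  expect_false(rep$excluded)
})

test_that("cleaning accounting conserves observations per metric", {
  spec <- cohort_spec(artifact_rate = 0.02, spike_rate = 0.005)
  p <- generate_participant(spec, "female", 16, seed = 17)
  rep <- clean_series(p$series)
  for (m in cpet_metrics()) {
    removed <- sum(rep$removed_positions$metric == m)
    surviving <- sum(!is.na(rep$surviving$breaths[[m]]))
    expect_equal(removed + surviving, rep$original_present[[m]])
  }
  # rule order: no position is removed twice
  key <- paste(rep$removed_positions$metric, rep$removed_positions$index)
  expect_false(any(duplicated(key)))
})

test_that("the bounds filter is idempotent on cleaned data", {
  spec <- cohort_spec(artifact_rate = 0.03)
  p <- generate_participant(spec, "male", 13, seed = 23)
  cleaned <- clean_series(p$series)$surviving
  expect_equal(nrow(filter_absolute_bounds(cleaned)), 0)
})

test_that("injected 6-sigma spikes are flagged by the moving-window rule", {
  spec <- cohort_spec(spike_rate = 0.01)
  found <- 0
  for (seed in 1:3) {
    p <- generate_participant(spec, "male", 14, seed = 40 + seed)
    rep <- clean_series(p$series)
    spikes <- p$truth$artifacts[p$truth$artifacts$kind == "spike6sigma", ]
    mv <- rep$removed_positions[rep$removed_positions$rule ==
                                  "moving_3sigma", ]
    for (k in seq_len(nrow(spikes))) {
      found <- found + 1
      expect_true(any(mv$metric == spikes$metric[k] &
                        mv$index == spikes$index[k]),
                  label = sprintf("spike at %s[%d] flagged",
                                  spikes$metric[k], spikes$index[k]))
    }
  }
  expect_gt(found, 0)
})
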