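test_that("SampEn analytic limits hold", {
  # constant signal: every template pair matches at m and m+1
  res <- sampen(rep(1, 50), 2, 0.2)
  expect_equal(res$value, 0)
  expect_equal(res$a_prob, 1)
  expect_equal(res$b_prob, 1)
  expect_identical(sampen_bruteforce(rep(1, 50), 2, 0.2)$value, 0)

  # huge radius on a standardized signal: all pairs match, entropy 0
  set.seed(3)
  z <- standardize(rnorm(100))
  expect_equal(sampen(z, 2, 10)$value, 0)

  # too-short signals error
  expect_error(sampen(c(1, 2, 3), 2, 0.2), "too short")
  expect_error(sampen_bruteforce(c(1, 2), 1, 0.2), "too short")
  expect_error(sampen(rnorm(20), 0, 0.2), "positive integer")
  expect_error(sampen(rnorm(20), 2, -1), "positive")

  # zero (m+1)-matches: undefined, +Inf sentinel
  x <- c(0, 0, 10, 20, -10)
  res0 <- sampen(x, 1, 0.1)
  expect_false(res0$defined)
  expect_identical(res0$value, Inf)
  expect_gt(res0$b_count, 0)
  expect_equal(res0$a_count, 0L)
})

test_that("brute-force enumeration reproduces frozen exact values", {
  # alternating 1,2: same-phase templates match exactly -> A = B = 24/56
  res <- sampen_bruteforce(c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2), 2, 0.5)
  expect_identical(res$a_count, 24L)
  expect_identical(res$b_count, 24L)
  expect_equal(res$b_prob, 24 / 56)
  expect_equal(res$value, 0)

  y <- c(0.5, 1.2, 0.3, 1.4, 0.6, 1.1, 0.2, 1.3, 0.7, 1.0, 0.4, 1.5)
  r2 <- sampen_bruteforce(y, 1, 0.3)
  expect_identical(r2$a_count, 28L)
  expect_identical(r2$b_count, 40L)
  expect_equal(r2$value, -log(28 / 40))
})

test_that("production SampEn is bit-identical to the brute-force oracle", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(20:120, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                as.numeric(arima.sim(list(ar = 0.6), n)),
                round(rnorm(n), 1))   # ties stress the inclusive radius
    m <- sample(1:3, 1)
    r <- sample(c(0.1, 0.2, 0.35), 1)
    a <- sampen(x, m, r)
    b <- sampen_bruteforce(x, m, r)
    expect_identical(a$a_count, b$a_count)
    expect_identical(a$b_count, b$b_count)
    expect_identical(a$value, b$value)
  }
})

test_that("match probabilities are monotone in r and satisfy A <= B", {
  set.seed(12)
  x <- rnorm(150)
  rs <- c(0.05, 0.1, 0.2, 0.35, 0.5, 1)
  b_probs <- vapply(rs, function(r) sampen(x, 2, r)$b_prob, numeric(1))
  expect_true(all(diff(b_probs) >= 0))
  for (r in rs) {
    res <- sampen(x, 2, r)
    expect_lte(res$a_prob, res$b_prob)
    expect_gte(res$a_prob, 0)
    expect_lte(res$b_prob, 1)
  }
})

test_that("iid noise sits in the expected entropy range; periodic below it", {
  set.seed(21)
  vals <- replicate(20, sampen(rnorm(300), 2, 0.2)$value)
  expect_true(all(vals > 1.5 & vals < 3.0))

  per <- sampen(standardize(sin(1:300)), 2, 0.2)$value
  expect_true(all(per < vals))
})

test_that("shuffling an autocorrelated signal raises SampEn", {
  set.seed(14)
  diffs <- replicate(20, {
    x <- standardize(as.numeric(arima.sim(list(ar = 0.7), 200)))
    set.seed(sample.int(1e6, 1))
    xs <- sample(x)
    sampen(xs, 2, 0.2)$value - sampen(x, 2, 0.2)$value
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("parameter selection respects the penalty and feasibility", {
  set.seed(25)
  sigs <- replicate(8, standardize(rnorm(150)), simplify = FALSE)

  # an overwhelming penalty drives r to the smallest feasible grid value
  sel_big <- select_sampen_params(sigs, lam = 1e6)
  feasible_r <- min(sel_big$trace$r[is.finite(sel_big$trace$objective)])
  expect_equal(sel_big$r, feasible_r)

  # deterministic on fixed input
  sel_a <- select_sampen_params(sigs, lam = 0.2)
  sel_b <- select_sampen_params(sigs, lam = 0.2)
  expect_identical(sel_a[c("m", "r")], sel_b[c("m", "r")])
  expect_true(sel_a$m %in% 1:3)
  expect_true(sel_a$r %in% seq(0.05, 0.5, by = 0.05))

  # short noisy signals make tiny radii undefined; selection avoids them
  set.seed(26)
  short <- replicate(10, standardize(rnorm(40)), simplify = FALSE)
  sel_s <- select_sampen_params(short, lam = 0.2)
  expect_gte(sel_s$r, 0.15)
})

test_that("entropy_table enumerates analyzable participant-metric-segments", {
  co <- generate_cohort(small_spec(1, seed = 12))
  cleaned <- lapply(co$series, function(s) clean_series(s)$surviving)
  params <- stats::setNames(rep(list(list(m = 2, r = 0.2)), 6),
                            cpet_metrics())
  tab <- entropy_table(cleaned, params)
  expect_lte(nrow(tab), 4 * 6 * 3)
  expect_gt(nrow(tab), 0)
  expect_true(all(tab$segment %in% c("pre", "post", "full")))
  expect_true(all(tab$sampen[tab$defined] >= 0))

  # a participant dropped before tabulation contributes no rows
  tab2 <- entropy_table(cleaned[-1], params)
  expect_false(names(co$series)[1] %in% tab2$participant_id)
})
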