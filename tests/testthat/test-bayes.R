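# hand-built posterior sets for arithmetic checks on the delta statistics
fake_ps <- function(mu, key = list()) {
  structure(list(mu = mu, sigma = rep(0.2, length(mu)),
                 nu = rep(10, length(mu)), key = key, group = "g",
                 D = length(mu)),
            class = "posterior_set")
}

test_that("delta statistics follow their defining arithmetic", {
  key <- list(metric = "vo2", sex = "male", age_group = "younger")

  d <- delta_midpoint(fake_ps(rep(1, 100), c(key, half = "post")),
                      fake_ps(rep(0, 100), c(key, half = "pre")))
  expect_equal(d$draws, rep(1, 100))
  expect_equal(d$p_ge_zero, 1)

  # identical draws: ties count as >= 0 (documented convention)
  d0 <- delta_midpoint(fake_ps(rep(0.7, 50), c(key, half = "post")),
                       fake_ps(rep(0.7, 50), c(key, half = "pre")))
  expect_equal(d0$draws, rep(0, 50))
  expect_equal(d0$p_ge_zero, 1)

  a <- delta_age(fake_ps(rep(2, 10), list(metric = "ve", sex = "male",
                                          age_group = "older")),
                 fake_ps(rep(1, 10), list(metric = "ve", sex = "male",
                                          age_group = "younger")))
  expect_equal(unique(a$draws), 50)
  a2 <- delta_age(fake_ps(rep(1, 10), list(metric = "ve", sex = "male",
                                           age_group = "older")),
                  fake_ps(rep(2, 10), list(metric = "ve", sex = "male",
                                           age_group = "younger")))
  expect_equal(unique(a2$draws), -100)

  s0 <- delta_sex(fake_ps(rep(1.5, 10), list(metric = "hr",
                                             age_group = "older",
                                             sex = "male")),
                  fake_ps(rep(1.5, 10), list(metric = "hr",
                                             age_group = "older",
                                             sex = "female")))
  expect_equal(unique(s0$draws), 0)
  expect_equal(s0$p_ge_zero, 1)
  s1 <- delta_sex(fake_ps(rep(1.1, 10), list(metric = "hr",
                                             age_group = "older",
                                             sex = "male")),
                  fake_ps(rep(1.0, 10), list(metric = "hr",
                                             age_group = "older",
                                             sex = "female")))
  expect_equal(unique(s1$draws), 10)

  # the reported probability equals an explicit loop over draws
  set.seed(4)
  dd <- delta_midpoint(fake_ps(rnorm(500, 0.02, 0.1),
                               c(key, half = "post")),
                       fake_ps(rnorm(500, 0, 0.1), c(key, half = "pre")))
  count <- 0
  for (k in seq_along(dd$draws)) if (dd$draws[k] >= 0) count <- count + 1
  expect_equal(dd$p_ge_zero, count / length(dd$draws))
})

test_that("mismatched comparisons are rejected", {
  expect_error(
    delta_midpoint(fake_ps(rep(1, 10), list(metric = "vo2", half = "post")),
                   fake_ps(rep(0, 10), list(metric = "hr", half = "pre"))),
    "mismatched")
  expect_error(
    delta_midpoint(fake_ps(rep(1, 10), list(metric = "vo2")),
                   fake_ps(rep(0, 20), list(metric = "vo2"))),
    "unequal draw")
})

test_that("significance labels follow the 0.05/0.95 thresholds", {
  mk <- function(p, comparison) {
    structure(list(comparison = comparison, p_ge_zero = p,
                   draws = numeric(0), mean = 0, sd = 0,
                   context = list()),
              class = "delta_result")
  }
  expect_equal(classify_significance(mk(0.03, "midpoint")),
               "higher pre-midpoint")
  expect_equal(classify_significance(mk(0.97, "midpoint")),
               "higher post-midpoint")
  expect_equal(classify_significance(mk(0.97, "age")), "higher for older")
  expect_equal(classify_significance(mk(0.03, "sex")), "higher for female")
  expect_equal(classify_significance(mk(0.5, "age")), "none")
  expect_equal(classify_significance(mk(0.05, "sex")), "none")
  expect_equal(classify_significance(mk(0.95, "sex")), "none")
})

test_that("the Student-t fit recovers known parameters deterministically", {
  set.seed(61)
  y <- 2.0 + 0.2 * rt(85, df = 10)
  fit <- fit_t_groups(list(g = y), sampler = fast_sampler(), seed = 5)
  mu_mean <- mean(fit$mu[, 1])
  mu_sd <- sd(fit$mu[, 1])
  expect_lt(abs(mu_mean - 2.0), 3 * mu_sd)
  expect_true(all(fit$sigma >= 0.05 & fit$sigma <= 0.50))
  expect_true(all(fit$nu > 0))
  expect_equal(fit$D, 800)

  fit2 <- fit_t_groups(list(g = y), sampler = fast_sampler(), seed = 5)
  expect_identical(fit$mu, fit2$mu)
  expect_identical(fit$nu, fit2$nu)
  fit3 <- fit_t_groups(list(g = y), sampler = fast_sampler(), seed = 6)
  expect_false(identical(fit$mu, fit3$mu))
})

test_that("tiny data variance pins sigma at its prior floor", {
  set.seed(62)
  y <- rnorm(40, 2.0, 0.01)
  fit <- fit_t_groups(list(g = y), sampler = fast_sampler(), seed = 2)
  expect_lt(mean(fit$sigma[, 1]), 0.07)
})

test_that("degenerate group data is refused", {
  expect_error(fit_t_groups(list(g = numeric(0))), "insufficient")
  expect_error(fit_t_groups(list(g = 2.0)), "insufficient")
  expect_error(fit_t_groups(list(a = c(1, 2), b = c(NA, NA, Inf))),
               "insufficient")
})

test_that("swapping groups reflects the direction probability", {
  set.seed(63)
  y1 <- 2.1 + 0.2 * rt(40, 10)
  y0 <- 2.0 + 0.2 * rt(40, 10)
  key <- list(metric = "vo2", sex = "male", age_group = "older")
  fit <- fit_t_groups(list(post = y1, pre = y0), sampler = fast_sampler(),
                      seed = 9)
  ps1 <- posterior_set(fit, "post", c(key, half = "post"))
  ps0 <- posterior_set(fit, "pre", c(key, half = "pre"))
  d_fwd <- delta_midpoint(ps1, ps0)
  d_rev <- delta_midpoint(ps0, ps1)
  expect_equal(d_rev$draws, -d_fwd$draws)
  expect_equal(d_rev$p_ge_zero, 1 - d_fwd$p_ge_zero)  # continuous draws
})

test_that("the likelihood dominates a moved prior at n = 85", {
  set.seed(64)
  y <- 2.0 + 0.2 * rt(85, 10)
  f1 <- fit_t_groups(list(g = y), spec = tgroup_spec(mu_mean = 2),
                     sampler = fast_sampler(), seed = 3)
  f2 <- fit_t_groups(list(g = y), spec = tgroup_spec(mu_mean = 2.5),
                     sampler = fast_sampler(), seed = 3)
  expect_lt(abs(mean(f1$mu) - mean(f2$mu)), 0.05)
})
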