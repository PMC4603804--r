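test_that("rankit scores are antisymmetric and average over ties", {
  x <- c(3.2, -1, 0.5, 7, 2, 2, -4)
  s <- rankit_scores(x)
  expect_equal(rankit_scores(-x), -s)
  # the two tied values share the mean of their positional rankits
  expect_identical(s[5], s[6])
  n <- length(x)
  blom <- qnorm((1:n - 3 / 8) / (n + 1 / 4))
  expect_equal(sort(s)[4:5], rep(mean(blom[4:5]), 2))
  expect_error(rankit_scores(c(1, NA)), "missing")
})

test_that("estimate_d matches an independent partial-likelihood maximisation", {
  dat <- draw_survival_times(80, beta = 0.8, censoring_rate = 0.3, seed = 101)
  est <- estimate_d(dat$time, dat$status, dat$pi)
  expect_equal(est$d, oracle_d(dat$time, dat$status, dat$pi),
               tolerance = 1e-6)
  # and on a dataset with tied prognostic-index values
  dat$pi2 <- round(dat$pi, 1)
  est2 <- estimate_d(dat$time, dat$status, dat$pi2)
  expect_equal(est2$d, oracle_d(dat$time, dat$status, dat$pi2),
               tolerance = 1e-4)
})

test_that("D is rank-invariant and sign-antisymmetric in the prognostic index", {
  dat <- draw_survival_times(150, beta = 1, censoring_rate = 0.2, seed = 7)
  est <- estimate_d(dat$time, dat$status, dat$pi)
  # any strictly increasing transform leaves the ranks, hence D, unchanged
  expect_identical(est$d,
                   estimate_d(dat$time, dat$status, exp(dat$pi))$d)
  expect_identical(est$d,
                   estimate_d(dat$time, dat$status, 100 + 3 * dat$pi)$d)
  expect_equal(estimate_d(dat$time, dat$status, -dat$pi)$d, -est$d,
               tolerance = 1e-8)
})

test_that("degenerate inputs are handled", {
  dat <- draw_survival_times(50, beta = 1, seed = 3)
  expect_warning(est <- estimate_d(dat$time, dat$status, rep(2, 50)),
                 "constant")
  expect_identical(est$d, 0)
  expect_error(estimate_d(dat$time, rep(0, 50), dat$pi), "events")
  expect_error(estimate_d(dat$time, dat$status), "pi")
  expect_error(estimate_d(c(-1, dat$time[-1]), dat$status, dat$pi),
               "positive")
})

test_that("a prognostic index can be derived from covariate columns", {
  set.seed(5)
  n <- 120
  x <- cbind(a = rnorm(n), b = rnorm(n))
  lp <- 0.8 * x[, 1] - 0.5 * x[, 2]
  tt <- rexp(n, exp(lp))
  st <- rep(1L, n)
  fit <- survival::coxph(survival::Surv(tt, st) ~ x, ties = "efron")
  expect_equal(estimate_d(tt, st, x = x)$d,
               estimate_d(tt, st, pi = unname(fit$linear.predictors))$d)
})

test_that("large samples recover D = beta * kappa", {
  dat <- exact_event_dataset(events = 2000, censoring = 0, beta = 1,
                             seed = 17)
  est <- estimate_d(dat$time, dat$status, dat$pi)
  # sampling SD is about sqrt(lambda/e) ~ 0.05; allow 4 of them
  expect_equal(est$d, kappa_d(), tolerance = 0.2 / kappa_d())
})

test_that("bootstrap SE is deterministic under a seed and tracks the sampling SD", {
  dat <- exact_event_dataset(events = 150, censoring = 0.2, d = 1.6,
                             seed = 23)
  b1 <- bootstrap_se_d(dat$time, dat$status, dat$pi, reps = 100, seed = 9)
  b2 <- bootstrap_se_d(dat$time, dat$status, dat$pi, reps = 100, seed = 9)
  expect_identical(b1$se, b2$se)
  expect_identical(b1$skipped, 0L)
  expect_error(bootstrap_se_d(dat$time, dat$status, dat$pi, reps = 1),
               "reps")

  # empirical-SD oracle: SD of D over independent replicate datasets
  set.seed(31)
  dhat <- replicate(250, {
    d <- exact_event_dataset(events = 150, censoring = 0.2, d = 1.6)
    estimate_d(d$time, d$status, d$pi)$d
  })
  emp_sd <- sd(dhat)
  boot_se <- mean(replicate(5, {
    d <- exact_event_dataset(events = 150, censoring = 0.2, d = 1.6)
    bootstrap_se_d(d$time, d$status, d$pi, reps = 200)$se
  }))
  expect_equal(boot_se, emp_sd, tolerance = 0.25)
})

test_that("estimate_d(boot =) reports both standard errors", {
  dat <- exact_event_dataset(events = 120, censoring = 0.1, d = 1.3,
                             seed = 4)
  est <- estimate_d(dat$time, dat$status, dat$pi, boot = 50, seed = 2)
  expect_true(est$se > 0)
  expect_true(est$se_boot > 0)
  expect_identical(est$n_boot, 50L)
})
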