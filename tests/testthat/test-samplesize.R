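lam_s <- lambda_from_study(se_d1 = 0.09, events = 502)
lam_m <- lambda_from_model(1.3, 0.10)

test_that("quantile sums match standard-normal reference values", {
  expect_equal(zz_quantile(0.05, sided = 1, power = 0.90), 2.9264052,
               tolerance = 1e-6)
  expect_equal(zz_quantile(0.05, sided = 2, power = 0.50), 1.9599640,
               tolerance = 1e-6)
  expect_equal(zz_quantile(0.05, sided = 2, power = 0.90), 3.2415155,
               tolerance = 1e-6)
  expect_error(zz_quantile(0, sided = 1, power = 0.9), "alpha")
  expect_error(zz_quantile(0.05, sided = 1, power = 1), "power")
  expect_error(zz_quantile(0.05, sided = 3, power = 0.9), "sided")
})

test_that("significance designs reproduce the liver-cancer worked examples", {
  expect_identical(
    events_significance(lam_s, 0.25, alpha = 0.05, sided = 1,
                        power = 0.9)$events, 558L)
  expect_identical(
    events_significance(lam_s, 0.25, alpha = 0.05, sided = 2,
                        power = 0.9)$events, 684L)
  expect_identical(
    events_significance(lam_m, 0.25, alpha = 0.05, sided = 1,
                        power = 0.9)$events, 633L)
  expect_identical(
    events_significance(lam_m, 0.25, alpha = 0.05, sided = 2,
                        power = 0.9)$events, 777L)
  # the displayed 1-dp lambda of 4.1 would give 562, not 558: intermediates
  # must stay at full precision
  expect_identical(
    events_significance(4.1, 0.25, alpha = 0.05, sided = 1,
                        power = 0.9)$events, 562L)
})

test_that("precision designs reproduce the worked examples", {
  expect_identical(events_ci(lam_s, 0.2, alpha = 0.05)$events, 391L)
  expect_identical(events_ci(lam_m, 0.2, alpha = 0.05,
                             censoring = 0.10)$events, 444L)
  expect_identical(
    events_ci(lambda_from_model(1.5, 0.30), 0.2, censoring = 0.30)$events,
    461L)
})

test_that("events are the ceiling of the raw value; patients inflate by censoring", {
  res <- events_significance(lam_s, 0.25, alpha = 0.05, sided = 1,
                             power = 0.9, censoring = 0.10)
  expect_equal(res$events, as.integer(ceiling(res$raw_events)))
  expect_identical(res$patients,
                   patients_from_events(res$events, 0.10))
  expect_true(res$patients >= res$events)
  # exact ratio: lambda = 1 and margin = zz gives exactly one event
  zz <- zz_quantile(0.05, 1, 0.9)
  expect_identical(events_significance(1, zz, alpha = 0.05, sided = 1,
                                       power = 0.9)$events, 1L)
})

test_that("patient counts match the published grid and handle edge cases", {
  expect_identical(patients_from_events(392, 0.10), 436L)
  expect_identical(patients_from_events(504, 0.10), 560L)
  expect_identical(patients_from_events(461, 0.30), 659L)
  expect_identical(patients_from_events(100, 0), 100L)
  expect_error(patients_from_events(100, 1), "censoring")
  expect_error(patients_from_events(0, 0.1), "events")
})

test_that("event counts fall with the margin/width and scale linearly in lambda", {
  margins <- seq(0.1, 0.6, by = 0.05)
  raw <- vapply(margins, function(m)
    events_significance(lam_m, m, 0.05, 2, 0.9)$raw_events, numeric(1))
  expect_true(all(diff(raw) < 0))
  widths <- seq(0.1, 0.6, by = 0.05)
  rawc <- vapply(widths, function(w)
    events_ci(lam_m, w, 0.05)$raw_events, numeric(1))
  expect_true(all(diff(rawc) < 0))
  # linearity in lambda before rounding
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(events_significance(k * lam_m$value, 0.25, 0.05, 2,
                                     0.9)$raw_events,
                 k * events_significance(lam_m$value, 0.25, 0.05, 2,
                                         0.9)$raw_events)
  }
  # doubling the margin quarters the raw event count
  expect_equal(events_significance(lam_m, 0.5, 0.05, 2, 0.9)$raw_events,
               events_significance(lam_m, 0.25, 0.05, 2, 0.9)$raw_events / 4)
})

test_that("a precision design is a 50%-power two-sided significance design", {
  set.seed(11)
  for (i in 1:20) {
    lam <- runif(1, 0.5, 12)
    w <- runif(1, 0.05, 0.8)
    a <- runif(1, 0.005, 0.2)
    expect_equal(events_ci(lam, w, a)$raw_events,
                 events_significance(lam, w, a, sided = 2,
                                     power = 0.5)$raw_events)
  }
})

test_that("designs carrying prior uncertainty reduce to the fixed-target forms at sigma1 = 0", {
  ps <- prior_study(se_d1 = 0.09, events = 502)
  for (m in c(0.15, 0.25, 0.4)) {
    expect_equal(
      events_with_prior(ps, margin = m, alpha = 0.05, sided = 1, power = 0.9,
                        sigma1 = 0)$raw_events,
      events_significance(lam_s, m, 0.05, 1, 0.9)$raw_events)
    expect_equal(
      events_with_prior(ps, width = m, alpha = 0.05, sigma1 = 0)$raw_events,
      events_ci(lam_s, m, 0.05)$raw_events)
  }
})

test_that("prior-uncertainty designs match direct arithmetic and enforce feasibility", {
  ps <- prior_study(se_d1 = 0.09, events = 502)
  zz <- qnorm(0.95) + qnorm(0.90)
  # margin 0.4 is comfortably above the feasibility bound of 0.09 * zz
  raw_expected <- (502 * 0.09^2) / ((0.4 / zz)^2 - 0.09^2)
  res <- events_with_prior(ps, margin = 0.4, alpha = 0.05, sided = 1,
                           power = 0.9)
  expect_equal(res$raw_events, raw_expected)
  expect_identical(res$events, as.integer(ceiling(raw_expected)))
  expect_true(res$raw_events > events_significance(lam_s, 0.4, 0.05, 1,
                                                   0.9)$raw_events)

  # margins at or below SE(D1) * zz are infeasible and report the bound
  expect_error(events_with_prior(ps, margin = 0.09 * zz, alpha = 0.05,
                                 sided = 1, power = 0.9), "infeasible")
  expect_error(events_with_prior(ps, margin = 0.2, alpha = 0.05, sided = 1,
                                 power = 0.9), "0.2634")
  z <- qnorm(0.975)
  expect_error(events_with_prior(ps, width = 0.09 * z, alpha = 0.05),
               "infeasible")
  expect_error(events_with_prior(ps, margin = 0.25, width = 0.2),
               "exactly one")
})

test_that("composite absolute/relative design peaks where the curves cross", {
  cmp <- composite_events(delta_abs = 0.25, p = 0.20, alpha = 0.05,
                          sided = 2, power = 0.90, censoring = 0.10)
  expect_equal(cmp$peak_d, 1.25)
  expect_equal(round(cmp$lambda$value, 2), 4.47)
  expect_identical(cmp$events, 753L)
  # the peak equals the absolute-margin calculation at the crossing D
  expect_identical(cmp$events,
                   events_significance(lambda_from_model(1.25, 0.10), 0.25,
                                       0.05, 2, 0.9)$events)
  # lower envelope: composite <= both curves everywhere, and never exceeds
  # the peak by construction of the crossing point
  prof <- cmp$profile
  expect_true(all(prof$events_composite <= prof$events_abs))
  expect_true(all(prof$events_composite <= prof$events_rel))
  expect_true(all(prof$events_composite <= cmp$events))
  expect_error(composite_events(0.25, 1.2), "'p'")
  expect_error(composite_events(-1, 0.2), "delta_abs")
})

test_that("achieved margin inverts the significance design", {
  expect_equal(round(achieved_margin(753, d = 2, censoring = 0.10,
                                     alpha = 0.05, sided = 2, power = 0.90),
                     2), 0.32)
  # round trip: ceiling only ever adds events, so the achieved margin is
  # no worse than the designed one
  set.seed(21)
  for (i in 1:15) {
    d <- runif(1, 0.5, 3); cens <- runif(1, 0, 0.6)
    delta <- runif(1, 0.1, 0.5)
    ev <- events_significance(lambda_from_model(d, cens), delta, 0.05, 2,
                              0.9)$events
    expect_lte(achieved_margin(ev, d, cens, 0.05, 2, 0.9), delta)
  }
  # more events, tighter margin
  margins <- vapply(c(100, 400, 1600, 6400), achieved_margin, numeric(1),
                    d = 1.3, censoring = 0.1)
  expect_true(all(diff(margins) < 0))
  expect_error(achieved_margin(0, d = 1.3), "events")
})
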