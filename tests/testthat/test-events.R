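test_that("event identities hold and simple cases are exact", {
  # monotone ramp: full-series event, endpoints at the series ends
  ser <- temperature_series("T1", age = seq(252.2, 247.2, length.out = 21),
                            sst = seq(20, 28, length.out = 21))
  e <- detect_largest_event(ser)
  expect_equal(e$delta_T, 8)
  expect_equal(e$t0, 252.2)
  expect_equal(e$t1, 247.2)
  expect_equal(e$delta_t, 5)
  expect_identical(e$direction, "warming")
  # the delta_T / delta_t / rate identities hold to machine precision
  expect_equal(e$delta_T, e$T1 - e$T0)
  expect_equal(e$rate, e$delta_T / e$delta_t)

  # constant series: degenerate zero event
  cs <- temperature_series("T1", age = seq(252.2, 247.2, length.out = 11),
                           sst = rep(22, 11))
  ec <- detect_largest_event(cs)
  expect_identical(ec$delta_T, 0)
  expect_true(ec$degenerate)

  # too few samples: no event
  short <- temperature_series("T1", age = c(252, 251), sst = c(20, 25))
  expect_null(detect_largest_event(short))
})

test_that("event rate is the signed quotient and rejects non-positive durations", {
  expect_equal(event_rate(8, 0.4), 20)
  expect_equal(event_rate(10, 0.06), 166.6667, tolerance = 1e-4)
  expect_identical(event_rate(0, 3), 0)
  expect_equal(event_rate(-6, 2), -3)
  expect_error(event_rate(5, 0), "positive")
  expect_error(event_rate(5, -1), "positive")
})

test_that("detection recovers injected excursions and respects invariants", {
  cfg0 <- synthetic_config(events = data.frame(bin_id = "P5", magnitude = 8,
                                               duration = 0.5),
                           noise_sd = 0, sampling_density = 10, seed = 1)
  g0 <- generate_climate_series(cfg0)
  e0 <- detect_largest_event(g0$series[["P5"]])
  # noise-free: exact up to sampling discretisation (one inter-sample step)
  step <- 8 / cfg0$event_oversampling
  expect_lt(abs(e0$delta_T - 8), step + 1e-9)
  expect_lt(abs(e0$delta_t - 0.5), 2 * 0.5 / cfg0$event_oversampling + 1e-9)

  # noisy recovery: bias within 3 Monte Carlo SDs, duration within 30%
  # (median over seeds); detected magnitude never exceeds the data range
  res <- t(vapply(1:60, function(s) {
    cfg <- synthetic_config(events = data.frame(bin_id = "P5", magnitude = -6,
                                                duration = 1),
                            noise_sd = 0.5, sampling_density = 4, seed = s)
    gen <- generate_climate_series(cfg)
    ser <- gen$series[["P5"]]
    e <- detect_largest_event(ser)
    e <- event_uncertainty_mc(ser, e, event_config(mc_draws = 200, seed = s))
    c(dT = e$delta_T, dt = e$delta_t, sd = e$delta_T_sd,
      rng = diff(range(ser$sst)))
  }, numeric(4)))
  expect_lt(abs(median(res[, "dT"]) + 6), 3 * median(res[, "sd"]))
  expect_lt(abs(median(res[, "dt"]) - 1), 0.3)
  expect_true(all(abs(res[, "dT"]) <= res[, "rng"] + 1e-9))
})

test_that("detection is invariant under time translation and temperature offset", {
  set.seed(5)
  age <- sort(runif(40, 247.2, 252.2), decreasing = TRUE)
  sst <- 24 + 6 * plogis((250 - age) * 8) + rnorm(40, 0, 0.3)
  e1 <- detect_largest_event(temperature_series("T1", age, sst))
  e2 <- detect_largest_event(temperature_series("T1", age - 100, sst))
  e3 <- detect_largest_event(temperature_series("T1", age, sst + 11.5))
  expect_equal(e1$rate, e2$rate)
  expect_equal(e1$delta_t, e2$delta_t)
  expect_equal(e1$delta_T, e3$delta_T)
  expect_equal(e1$t0 - 100, e2$t0)
})

test_that("Monte Carlo event uncertainty matches the group-mean expectation", {
  # all sst_sd = 0 with k = 1: both SDs collapse to zero
  ser <- temperature_series("T1", age = seq(252, 248, length.out = 20),
                            sst = c(rep(20, 10), rep(28, 10)))
  e <- detect_largest_event(ser, event_config(endpoint_group_size = 1))
  e0 <- event_uncertainty_mc(ser, e, event_config(endpoint_group_size = 1,
                                                  mc_draws = 100, seed = 2))
  expect_identical(e0$delta_T_sd, 0)
  expect_identical(e0$delta_t_sd, 0)

  # endpoint groups with sample SD s: sd(delta_T) ~ s * sqrt(2/k)
  set.seed(3)
  k <- 25
  s <- 1.2
  age <- seq(260, 250, length.out = 2 * k)
  sst <- c(rnorm(k, 20, s), rnorm(k, 30, s))
  ser2 <- temperature_series("P3", age, sst)
  cfgk <- event_config(endpoint_group_size = k, mc_draws = 3000, seed = 4,
                       max_reversal_frac = 1)
  e2 <- detect_largest_event(ser2, cfgk)
  e2 <- event_uncertainty_mc(ser2, e2, cfgk)
  expect_equal(e2$delta_T_sd, s * sqrt(2 / k), tolerance = 0.2)

  # seed reproducibility
  ea <- event_uncertainty_mc(ser2, e2, cfgk)
  eb <- event_uncertainty_mc(ser2, e2, cfgk)
  expect_identical(ea$delta_T_sd, eb$delta_T_sd)
  expect_identical(ea$rate_sd, eb$rate_sd)
})

test_that("events are assigned to the onset bin with the boundary convention", {
  bins <- load_bin_scheme()
  mk <- function(t0, t1) {
    structure(list(t0 = t0, t1 = t1, T0 = 20, T1 = 30, delta_T = 10,
                   delta_t = t0 - t1, rate = 10 / (t0 - t1),
                   direction = "warming", degenerate = FALSE,
                   timespan_flag = FALSE, delta_T_sd = NA_real_,
                   rate_sd = NA_real_, delta_t_sd = NA_real_,
                   group0 = 1L, group1 = 2L, source_label = ""),
              class = "climate_event")
  }
  # crossing the P5/T1 boundary (251.9-ish): onset in P5 -> P5, flagged
  e <- assign_event_bin(mk(252.3, 252.0), bins)
  expect_identical(e$bin_id, "P5")
  expect_true(e$timespan_flag)
  # wholly inside one bin
  e2 <- assign_event_bin(mk(255, 254), bins)
  expect_identical(e2$bin_id, "P5")
  expect_false(e2$timespan_flag)
  # onset exactly on a shared boundary age belongs to the older bin
  e3 <- assign_event_bin(mk(252.2, 252.0), bins)
  expect_identical(e3$bin_id, "P5")
  expect_error(assign_event_bin(mk(500, 499), bins), "outside")
})

test_that("threshold classification uses strict inequalities on |dT| and |R|", {
  mk <- function(dT, dt) {
    structure(list(delta_T = dT, delta_t = dt, rate = dT / dt),
              class = "climate_event")
  }
  expect_identical(classify_event(mk(10.4, 0.06))$class, "big_five_regime")
  expect_identical(classify_event(mk(-8.4, 0.35))$class, "big_five_regime")
  expect_identical(classify_event(mk(5.2, 0.1))$class, "background")   # at mag cut
  expect_identical(classify_event(mk(8, 0.8))$class, "background")     # |R| = 10 exactly
  expect_identical(classify_event(mk(8, 0.5))$class, "big_five_regime")
  expect_identical(classify_event(mk(8, 8 / 9))$class, "background")   # |R| = 9
  expect_true(classify_event(mk(10.4, 0.06))$short_timespan)
  expect_false(classify_event(mk(8, 0.8))$short_timespan)
})

test_that("averaging events across series pools the signed quantities", {
  mk <- function(dT, dt, sd = 0.5) {
    structure(list(bin_id = "P5", t0 = 255, t1 = 255 - dt, T0 = 24,
                   T1 = 24 + dT, delta_T = dT, delta_t = dt, rate = dT / dt,
                   direction = if (dT > 0) "warming" else "cooling",
                   degenerate = FALSE, timespan_flag = FALSE,
                   delta_T_sd = sd, rate_sd = sd, delta_t_sd = 0.1,
                   group0 = 1L, group1 = 2L, source_label = "x"),
              class = "climate_event")
  }
  one <- mk(6, 0.5)
  expect_identical(average_events(list(one)), one)
  avg <- average_events(list(mk(6, 0.4), mk(8, 0.6)))
  expect_equal(avg$delta_T, 7)
  expect_equal(avg$delta_t, 0.5)
  expect_equal(avg$rate, (6 / 0.4 + 8 / 0.6) / 2)
  expect_equal(avg$delta_T_sd, sqrt(0.5^2 + 0.5^2) / 2)
  expect_warning(average_events(list(mk(6, 0.5), mk(-5, 0.5))), "conflicting")

  # variance reduction: two proxies of one event beat either alone in RMSE
  err <- t(vapply(1:60, function(s) {
    cfg1 <- synthetic_config(events = data.frame(bin_id = "P5", magnitude = 7,
                                                 duration = 0.8),
                             noise_sd = 0.7, sampling_density = 4, seed = s)
    cfg2 <- synthetic_config(events = cfg1$events, noise_sd = 0.7,
                             sampling_density = 4, seed = s + 5000)
    e1 <- detect_largest_event(generate_climate_series(cfg1)$series[["P5"]])
    e2 <- detect_largest_event(generate_climate_series(cfg2)$series[["P5"]])
    c(single = e1$delta_T - 7,
      paired = average_events(list(e1, e2))$delta_T - 7)
  }, numeric(2)))
  rmse <- sqrt(colMeans(err^2))
  expect_lt(rmse["paired"], rmse["single"])
})
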