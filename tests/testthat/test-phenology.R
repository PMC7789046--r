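test_that("effective temperature is floored at 0 and capped at t_max_eff", {
  expect_equal(effective_temperature(20, 0, 30), 20)
  expect_equal(effective_temperature(-5, 0, 30), 0)   # negative -> 0
  expect_equal(effective_temperature(35, 0, 30), 30)  # constant above the cap
  expect_equal(effective_temperature(c(-5, 10, 40), 2, 25), c(0, 8, 25))
  expect_error(effective_temperature(10, 30, 30),
               class = "agroclim_validation_error")
})

test_that("vernalization and photoperiod factors are clamped-linear", {
  vp <- vernalization_params(v_base = 10, v_sat = 50)
  expect_equal(vernalization_factor(60, vp), 1)
  expect_equal(vernalization_factor(5, vp), 0)
  expect_equal(vernalization_factor(30, vp), 0.5)
  # effectiveness curve: peak between 3 and 10, zero outside [-4, 17]
  expect_equal(vernalization_increment(c(-10, -4, 3, 7, 10, 17, 20)),
               c(0, 0, 1, 1, 1, 0, 0))
  expect_equal(vernalization_increment(-0.5), 0.5)   # midway up the ramp
  pp <- photoperiod_params(d_critical = 8, d_optimal = 16)
  expect_equal(photoperiod_factor(17, pp), 1)
  expect_equal(photoperiod_factor(8, pp), 0)
  expect_equal(photoperiod_factor(12, pp), 0.5)
  expect_error(photoperiod_params(16, 8), class = "agroclim_validation_error")
  expect_error(vernalization_params(v_base = 5, v_sat = 5),
               class = "agroclim_validation_error")
})

test_that("two-phase arithmetic: 600 GDD at 20 degC gives 30-day phases", {
  s <- make_constant_series(tavg = 20, days = 120)
  p <- variety_params(tsum1 = 600, tsum2 = 600, vern = NULL, photo = NULL,
                      sowing_date = s$date[1])
  tr <- simulate_2phase(s, p)
  expect_equal(tr$dvs[1], 0)                        # DVS 0 at sowing
  expect_equal(tr$dvs[31], 1)                       # day 30 after sowing
  expect_equal(tr$dvs[61], 2)                       # day 60 after sowing
  sd <- stage_dates(tr)
  expect_equal(as.numeric(sd[["flowering"]] - sd[["sowing"]]), 30)
  expect_equal(as.numeric(sd[["maturity"]] - sd[["sowing"]]), 60)
  expect_true(attr(tr, "complete"))
  expect_error(simulate_2phase(s, variety_params(sowing_date = "1990-01-01")),
               class = "agroclim_validation_error")
})

test_that("multi-phase arithmetic hits each boundary on schedule", {
  s <- make_constant_series(tavg = 20, days = 100)
  p <- variety_params_multi(tsum = c(200, 100, 200, 200, 100, 500),
                            t_base = rep(0, 6), vern = NULL, photo = NULL,
                            sowing_date = s$date[1])
  tr <- simulate_multiphase(s, p)
  # cumulative boundary days at 20 GDD/day: 10, 15, 25, 35, 40, 65
  for (b in seq_len(6)) {
    day <- c(10, 15, 25, 35, 40, 65)[b]
    expect_equal(tr$dvs[day + 1], b)
  }
  expect_equal(max(tr$dvs), 6)
  # a sub-phase with base temperature 9 makes no progress at tavg 8
  cold <- variety_params_multi(tsum = c(100, 50, 50, 50, 50, 450),
                               t_base = c(2, -2, -2, 0, 0, 9),
                               vern = NULL, photo = NULL,
                               sowing_date = s$date[1])
  s8 <- make_constant_series(tavg = 8, days = 400)
  cold$sowing_date <- s8$date[1]
  tr8 <- simulate_multiphase(s8, cold)
  expect_lt(max(tr8$dvs), 6)          # stuck in flowering-ripening
  expect_gte(max(tr8$dvs), 5)         # earlier phases do progress
  expect_false(attr(tr8, "complete"))
})

test_that("both simulators match independent day-loop oracles", {
  # random synthetic seasons with active vernalization/photoperiod factors
  set.seed(101)
  for (rep in 1:25) {
    s <- make_long_series(seed = 200 + rep, n_years = 3)
    for (force_off in c(TRUE, FALSE)) {
      p2 <- random_params_2phase(s, force_factors_off = force_off)
      tr <- simulate_2phase(s, p2)
      expect_equal(tr$dvs, oracle_2phase(s, p2), tolerance = 1e-12)
      pm <- random_params_multi(s, force_factors_off = force_off)
      trm <- simulate_multiphase(s, pm)
      expect_equal(trm$dvs, oracle_multiphase(s, pm), tolerance = 1e-12)
    }
  }
})

test_that("DVS is non-decreasing and insensitive to temperature above the cap", {
  s <- make_long_series(seed = 55, n_years = 2)
  p <- random_params_2phase(s)
  tr <- simulate_2phase(s, p)
  expect_true(all(diff(tr$dvs) >= 0))
  # raise all temperatures above the cap to a fixed level: identical track
  hot <- s
  hot$tmin <- pmax(s$tmin, 35); hot$tmax <- pmax(s$tmax, 45)
  hot$tavg <- (hot$tmin + hot$tmax) / 2
  hot2 <- s
  hot2$tmin <- pmax(s$tmin, 45); hot2$tmax <- pmax(s$tmax, 55)
  hot2$tavg <- (hot2$tmin + hot2$tmax) / 2
  p0 <- p; p0$vern <- NULL; p0$photo <- NULL
  # every day sits above the cap in both series, so the tracks are identical
  d1 <- simulate_2phase(hot, p0)$dvs
  d2 <- simulate_2phase(hot2, p0)$dvs
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("multi-phase with proportional tsums reproduces two-phase flowering", {
  # common base temperature, factors off: sub-phases 1..5 summing to TSUM1
  # and phase 6 = TSUM2 reach flowering/maturity on the two-phase days
  s <- make_long_series(seed = 77, n_years = 2)
  sow <- as.Date("2000-10-20")
  t1 <- 750; t2 <- 680
  p2 <- variety_params(tsum1 = t1, tsum2 = t2, t_base = 0, vern = NULL,
                       photo = NULL, sowing_date = sow)
  pm <- variety_params_multi(tsum = c(t1 * c(0.2, 0.1, 0.25, 0.25, 0.2), t2),
                             t_base = rep(0, 6), vern = NULL, photo = NULL,
                             sowing_date = sow)
  f2 <- stage_dates(simulate_2phase(s, p2))
  fm <- stage_dates(simulate_multiphase(s, pm))
  expect_equal(fm[["flowering"]], f2[["flowering"]])
  expect_equal(fm[["maturity"]], f2[["maturity"]])
})

test_that("windows resolve statically and dynamically", {
  w <- stage_window_static("2001-03-01", "2001-03-31")
  r <- resolve_window(w)
  expect_equal(r$start, as.Date("2001-03-01"))
  expect_equal(r$end, as.Date("2001-03-31"))

  s <- make_constant_series(tavg = 20, days = 120)
  p <- variety_params(tsum1 = 600, tsum2 = 600, vern = NULL, photo = NULL,
                      sowing_date = s$date[1])
  tr <- simulate_2phase(s, p)
  rd <- resolve_window(stage_window_dynamic(1, 2), tr)
  expect_equal(as.numeric(rd$start - s$date[1]), 30)
  expect_equal(as.numeric(rd$end - s$date[1]), 60)

  # track that never flowers -> incomplete error carrying max DVS
  short <- make_constant_series(tavg = 20, days = 20)
  p$sowing_date <- short$date[1]
  tr_short <- simulate_2phase(short, p)
  err <- tryCatch(resolve_window(stage_window_dynamic(1, 2), tr_short),
                  error = function(e) e)
  expect_s3_class(err, "agroclim_incomplete_error")
  expect_lt(err$max_dvs, 1)
  expect_error(stage_window_dynamic(2, 1), class = "agroclim_validation_error")
})

test_that("a warmer preceding period advances the resolved flowering window", {
  base <- make_long_series(seed = 42, n_years = 2, t_mean_annual = 13)
  warm <- make_long_series(seed = 42, n_years = 2, t_mean_annual = 15)
  p <- variety_params(tsum1 = 800, tsum2 = 800, vern = NULL, photo = NULL,
                      sowing_date = "2000-10-25")
  w_base <- resolve_window(stage_window_dynamic(1, 2), simulate_2phase(base, p))
  w_warm <- resolve_window(stage_window_dynamic(1, 2), simulate_2phase(warm, p))
  expect_lt(w_warm$start, w_base$start)
})
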