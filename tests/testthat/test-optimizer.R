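# shared season for the optimizer tests
opt_series <- make_long_series(seed = 11)
opt_balance <- climatic_water_balance(opt_series)
opt_template <- variety_params_multi(sowing_date = "2011-10-25")
opt_template2 <- variety_params(tsum1 = 800, tsum2 = 800,
                                sowing_date = "2011-10-25")

test_that("a 1x1 grid scan equals a direct indicator call", {
  g <- grid_scan(opt_series, opt_template2, 750, 700, ids = c(10, 16),
                 spei_warn = FALSE)
  p <- opt_template2; p$tsum1 <- 750; p$tsum2 <- 700
  direct <- compute_indicators(opt_series, p, ids = c(10, 16),
                               spei_warn = FALSE)
  expect_equal(g$value, direct$value)
  expect_equal(nrow(g), 2)
})

test_that("grid scans cover the full cross-product with unique keys", {
  g <- grid_scan(opt_series, opt_template2, c(600, 800, 1000),
                 c(600, 800, 1000), ids = 16, spei_warn = FALSE)
  expect_equal(nrow(g), 9)
  expect_equal(nrow(unique(g[c("tsum1", "tsum2")])), 9)
  expect_true(all(g$season_complete))
})

test_that("heat exposure grows with longer reproductive requirements", {
  # later maturity pushes grain filling into hotter weather: indicator 16 is
  # non-decreasing along tsum2 at fixed tsum1
  g <- grid_scan(opt_series, opt_template2, 700, seq(600, 1000, 100),
                 ids = 16, spei_warn = FALSE)
  g <- g[order(g$tsum2), ]
  expect_true(all(diff(g$value) >= 0))
  expect_true(all(diff(as.numeric(g$maturity)) > 0))
})

test_that("fitness equals an independent penalty-by-penalty recomputation", {
  cfg <- ga_config(indicator_ids = c(4, 5, 15, 16), weights = c(1, 2, 1, 0.5))
  for (tsum in list(c(160, 90, 160, 150, 100, 500),
                    c(120, 35, 100, 100, 50, 450),
                    c(200, 140, 220, 200, 150, 550))) {
    f <- variety_fitness(tsum, opt_series, opt_template, cfg,
                         balance = opt_balance)
    p <- opt_template; p$tsum <- tsum
    res <- compute_indicators(opt_series, p, ids = cfg$indicator_ids,
                              spei_warn = FALSE, balance = opt_balance)
    hand <- 0
    for (j in seq_len(nrow(res))) {
      w <- cfg$weights[j]
      if (res$statistic[j] == "spei") {
        hand <- hand + w * max(0, abs(res$value[j]) - 1)
      } else {
        len <- as.numeric(res$window_end[j] - res$window_start[j]) + 1
        hand <- hand + w * res$value[j] / len
      }
    }
    expect_equal(f$total, -hand, tolerance = 1e-12)
    expect_true(f$total <= 0)
  }
})

test_that("zero penalties give the maximum attainable fitness of 0", {
  # cold-stress indicator in a season with no frost at all after booting
  cfg <- ga_config(indicator_ids = 14)
  warm <- generate_series(climate_spec(t_mean_annual = 18, t_noise_sd = 1,
                                       n_years = 13, seed = 4))
  tmpl <- variety_params_multi(vern = NULL, photo = NULL,
                               sowing_date = "2011-10-25")
  f <- variety_fitness(c(160, 90, 160, 150, 100, 500), warm, tmpl, cfg)
  expect_equal(f$total, 0)
  expect_true(f$complete)
})

test_that("non-maturing chromosomes take the fixed incomplete penalty", {
  cfg <- ga_config(indicator_ids = 16, incomplete_penalty = 10)
  cold <- generate_series(climate_spec(t_mean_annual = 4, t_amplitude = 6,
                                       n_years = 13, seed = 6))
  tmpl <- variety_params_multi(vern = NULL, photo = NULL,
                               sowing_date = "2011-10-25")
  f <- variety_fitness(c(200, 140, 220, 200, 150, 550), cold, tmpl, cfg)
  expect_equal(f$total, -10)
  expect_false(f$complete)
  expect_error(variety_fitness(rep(1000, 6), opt_series, opt_template, cfg),
               class = "agroclim_validation_error")
})

test_that("GA is deterministic, elitist and honours degenerate bounds", {
  cfg <- ga_config(population_size = 12, n_generations = 8, seed = 5,
                   indicator_ids = c(15, 16))
  # collapsed search space returns the unique chromosome
  single <- list(lower = c(160, 90, 160, 150, 100, 500),
                 upper = c(160, 90, 160, 150, 100, 500))
  out <- ga_optimize(opt_series, opt_template, bounds = single, config = cfg)
  expect_equal(out$best_tsum, single$lower)
  direct <- variety_fitness(single$lower, opt_series, opt_template, cfg,
                            balance = opt_balance)
  expect_equal(out$best_fitness, direct$total)

  out1 <- ga_optimize(opt_series, opt_template, config = cfg)
  out2 <- ga_optimize(opt_series, opt_template, config = cfg)
  expect_identical(out1$best_tsum, out2$best_tsum)
  expect_identical(out1$trace, out2$trace)
  # elitism: the best-fitness trace never decreases
  expect_true(all(diff(out1$trace$best) >= 0))
  expect_equal(nrow(out1$trace), 8)
  expect_error(ga_optimize(opt_series, opt_template,
                           bounds = list(lower = rep(200, 6),
                                         upper = rep(100, 6)), config = cfg),
               class = "agroclim_validation_error")
})

test_that("GA beats random search on a matched evaluation budget", {
  cfg_base <- ga_config(population_size = 16, n_generations = 10,
                        indicator_ids = c(4, 5, 15, 16))
  b <- subphase_bounds()
  ga_best <- random_best <- numeric(6)
  for (r in 1:6) {
    cfg <- cfg_base; cfg$seed <- 400 + r
    out <- ga_optimize(opt_series, opt_template, config = cfg,
                       balance = opt_balance)
    ga_best[r] <- out$best_fitness
    random_best[r] <- withr::with_seed(500 + r, {
      cand <- replicate(out$n_evaluations,
                        runif(6, b$lower, b$upper), simplify = FALSE)
      max(vapply(cand, function(g)
        variety_fitness(g, opt_series, opt_template, cfg,
                        balance = opt_balance)$total, numeric(1)))
    })
  }
  expect_gte(median(ga_best), median(random_best))
})

test_that("ensemble optimization averages member fitness equally", {
  ens <- generate_ensemble(climate_spec(n_years = 13, seed = 11), 3)
  tmpl <- variety_params_multi(sowing_date = "2011-10-25")
  cfg <- ga_config(population_size = 10, n_generations = 5, seed = 9,
                   indicator_ids = c(15, 16))
  # spot-check: ensemble fitness is the hand-averaged per-member fitness
  # (collapsed bounds make the GA evaluate exactly that chromosome)
  for (tsum in list(c(160, 90, 160, 150, 100, 500),
                    c(130, 60, 120, 120, 70, 470))) {
    per_member <- vapply(ens$members, function(m)
      variety_fitness(tsum, m, tmpl, cfg)$total, numeric(1))
    out <- ga_optimize_ensemble(ens, tmpl,
                                bounds = list(lower = tsum, upper = tsum),
                                config = cfg)
    expect_equal(out$best_fitness, mean(per_member), tolerance = 1e-12)
  }
  # single-member ensemble reduces to the plain optimizer (same seed)
  one <- weather_ensemble(ens$members[1])
  a <- ga_optimize_ensemble(one, tmpl, config = cfg)
  b2 <- ga_optimize(ens$members[[1]], tmpl, config = cfg)
  expect_equal(a$best_tsum, b2$best_tsum)
  expect_equal(a$best_fitness, b2$best_fitness)
  # identical members: mean fitness equals single-member fitness
  twin <- weather_ensemble(ens$members[c(1, 1)])
  c2 <- ga_optimize_ensemble(twin, tmpl, config = cfg)
  expect_equal(c2$best_fitness, b2$best_fitness)
  expect_equal(c2$best_tsum, b2$best_tsum)
})
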