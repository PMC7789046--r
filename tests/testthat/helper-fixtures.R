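# Fixture builders shared across test files. Everything is generated in code.

make_constant_series <- function(tavg = 20, days = 400,
                                 start = as.Date("2000-01-01"),
                                 latitude = 44, precip = 0,
                                 diurnal_range = 10) {
  dates <- seq(start, by = "day", length.out = days)
  weather_series(dates, rep(tavg - diurnal_range / 2, days),
                 rep(tavg + diurnal_range / 2, days),
                 rep(precip, days), latitude = latitude, site_id = "const")
}

# a multi-year Mediterranean series long enough for SPEI references and an
# autumn-sown season ending inside the record
make_long_series <- function(seed = 11, n_years = 13, start_year = 2000,
                             ...) {
  generate_series(climate_spec(n_years = n_years, start_year = start_year,
                               seed = seed, ...))
}

random_params_2phase <- function(series, force_factors_off = FALSE) {
  sow_year <- as.integer(format(series$date[1], "%Y")) + 1L
  variety_params(
    tsum1 = runif(1, 600, 1000), tsum2 = runif(1, 600, 1000),
    t_base = runif(1, -1, 2), t_max_eff = 30,
    vern = if (force_factors_off) NULL else vernalization_params(),
    photo = if (force_factors_off) NULL else photoperiod_params(),
    sowing_date = as.Date(sprintf("%d-10-%02d", sow_year,
                                  sample(15:31, 1))))
}

random_params_multi <- function(series, force_factors_off = FALSE) {
  b <- subphase_bounds()
  sow_year <- as.integer(format(series$date[1], "%Y")) + 1L
  variety_params_multi(
    tsum = runif(6, b$lower, b$upper),
    vern = if (force_factors_off) NULL else vernalization_params(),
    photo = if (force_factors_off) NULL else photoperiod_params(),
    sowing_date = as.Date(sprintf("%d-10-%02d", sow_year,
                                  sample(15:31, 1))))
}
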