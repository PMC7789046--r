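#' Climate specification for the stochastic weather generator
#'
#' Defines the statistical structure of a generated site: an annual sinusoidal
#' temperature cycle with additive Gaussian noise and a fixed diurnal range,
#' plus an occurrence/amount precipitation process (Bernoulli wet days, gamma
#' wet-day amounts). Defaults emulate a Mediterranean lowland site suitable for
#' October-sown durum wheat: 15 degC annual mean, 9 degC seasonal amplitude
#' (coldest in mid-January), 10 degC diurnal range, 25% wet days averaging
#' 8 mm.
#'
#' @param t_mean_annual Annual mean temperature, degC.
#' @param t_amplitude Seasonal half-amplitude of the daily-mean cycle, degC
#'   (>= 0).
#' @param t_noise_sd SD of additive day-to-day temperature noise, degC.
#' @param diurnal_range tmax - tmin, degC.
#' @param wet_day_prob Probability a day is wet; scalar or length-12 monthly
#'   vector, each in \[0, 1\].
#' @param precip_mean_wet Mean precipitation on wet days, mm (> 0).
#' @param gamma_shape Shape of the gamma wet-day amount distribution
#'   (right-skewed daily rainfall; scale is `precip_mean_wet / gamma_shape`).
#' @param latitude Site latitude, degrees.
#' @param n_years Number of calendar years generated (>= 1).
#' @param start_year First calendar year.
#' @param t_min_doy Day of year of the coldest day (default 15 = mid-January,
#'   northern hemisphere).
#' @param seed Integer seed; the same spec always generates the same series.
#' @return A `climate_spec` object.
#' @export
climate_spec <- function(t_mean_annual = 15, t_amplitude = 9, t_noise_sd = 2,
                         diurnal_range = 10, wet_day_prob = 0.25,
                         precip_mean_wet = 8, gamma_shape = 0.8,
                         latitude = 44, n_years = 3, start_year = 2000,
                         t_min_doy = 15, seed = 1L) {
  if (t_amplitude < 0) val_err("t_amplitude must be >= 0")
  if (any(wet_day_prob < 0 | wet_day_prob > 1))
    val_err("wet_day_prob must be in [0, 1]")
  if (!length(wet_day_prob) %in% c(1L, 12L))
    val_err("wet_day_prob must be scalar or monthly (length 12)")
  if (precip_mean_wet <= 0) val_err("precip_mean_wet must be > 0")
  if (n_years < 1) val_err("n_years must be >= 1")
  if (abs(latitude) > 90) val_err("latitude must be in [-90, 90]")
  structure(list(t_mean_annual = t_mean_annual, t_amplitude = t_amplitude,
                 t_noise_sd = t_noise_sd, diurnal_range = diurnal_range,
                 wet_day_prob = wet_day_prob, precip_mean_wet = precip_mean_wet,
                 gamma_shape = gamma_shape, latitude = latitude,
                 n_years = as.integer(n_years), start_year = as.integer(start_year),
                 t_min_doy = t_min_doy, seed = as.integer(seed)),
            class = "climate_spec")
}

#' Generate a synthetic daily weather series
#'
#' Daily mean temperature is
#' `t_mean_annual - t_amplitude * cos(2*pi*(doy - t_min_doy)/365) + noise`,
#' with `tmin/tmax = tavg -/+ diurnal_range/2`. Precipitation is a Bernoulli
#' occurrence process with gamma-distributed wet-day amounts. Fully
#' reproducible from `spec$seed`; the caller's RNG state is left untouched.
#'
#' @param spec A [climate_spec()].
#' @return A validated [weather_series()].
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "climate_spec"))
  dates <- seq(as.Date(sprintf("%04d-01-01", spec$start_year)),
               as.Date(sprintf("%04d-12-31", spec$start_year + spec$n_years - 1L)),
               by = "day")
  n <- length(dates)
  doy <- day_of_year(dates)
  month <- as.integer(format(dates, "%m"))
  p_wet <- if (length(spec$wet_day_prob) == 12L) spec$wet_day_prob[month]
           else rep(spec$wet_day_prob, n)
  with_local_seed(spec$seed, {
    tavg <- spec$t_mean_annual -
      spec$t_amplitude * cos(2 * pi * (doy - spec$t_min_doy) / 365) +
      stats::rnorm(n, 0, spec$t_noise_sd)
    wet <- stats::runif(n) < p_wet
    amount <- stats::rgamma(n, shape = spec$gamma_shape,
                            scale = spec$precip_mean_wet / spec$gamma_shape)
    precip <- ifelse(wet, amount, 0)
    weather_series(dates, tavg - spec$diurnal_range / 2,
                   tavg + spec$diurnal_range / 2, precip,
                   latitude = spec$latitude,
                   site_id = sprintf("synthetic-%d", spec$seed))
  })
}

#' Generate a synthetic weather ensemble
#'
#' Members share the climate specification and date range but use per-member
#' seeds `spec$seed + member index`, so they are distinct, reproducible
#' realizations of the same climate (the structure of a seasonal-prediction
#' ensemble).
#'
#' @param spec A [climate_spec()].
#' @param n_members Number of members (>= 1).
#' @return A [weather_ensemble()].
#' @export
generate_ensemble <- function(spec, n_members) {
  if (n_members < 1) val_err("n_members must be >= 1")
  members <- lapply(seq_len(n_members), function(i) {
    s <- spec
    s$seed <- spec$seed + i
    generate_series(s)
  })
  weather_ensemble(members, sprintf("m%02d", seq_len(n_members)))
}
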