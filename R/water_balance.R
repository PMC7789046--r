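#' Extraterrestrial radiation (FAO-56)
#'
#' Daily extraterrestrial solar radiation from solar declination, inverse
#' relative Earth-Sun distance and sunset hour angle (FAO-56 formulation,
#' solar constant 0.0820 MJ m-2 min-1). The sunset-hour-angle argument is
#' clamped to \[-1, 1\] so polar night yields exactly 0 and polar day the
#' 24-hour maximum.
#'
#' @param latitude Degrees, in \[-90, 90\]. Vectorized.
#' @param day_of_year Integer 1..366. Vectorized.
#' @return Ra in MJ m-2 day-1 (>= 0).
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year) {
  if (any(day_of_year < 1 | day_of_year > 366))
    val_err("day_of_year must be in 1..366")
  if (any(abs(latitude) > 90)) val_err("latitude must be in [-90, 90]")
  gsc <- 0.0820                       # MJ m-2 min-1
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * day_of_year / 365)
  delta <- 0.409 * sin(2 * pi * day_of_year / 365 - 1.39)
  ws <- acos(clamp(-tan(phi) * tan(delta), -1, 1))
  ra <- (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  pmax(ra, 0)
}

#' Daylength from standard solar geometry
#'
#' `N = 24/pi * ws` with the same declination and sunset hour angle used by
#' [extraterrestrial_radiation()]; clamping handles polar night (0 h) and
#' polar day (24 h).
#'
#' @param latitude Degrees, in \[-90, 90\]. Vectorized.
#' @param day_of_year Integer 1..366. Vectorized.
#' @return Hours in \[0, 24\].
#' @export
daylength <- function(latitude, day_of_year) {
  if (any(abs(latitude) > 90)) val_err("latitude must be in [-90, 90]")
  phi <- latitude * pi / 180
  delta <- 0.409 * sin(2 * pi * day_of_year / 365 - 1.39)
  ws <- acos(clamp(-tan(phi) * tan(delta), -1, 1))
  24 / pi * ws
}

#' Reference evapotranspiration, modified Hargreaves-Samani
#'
#' Droogers & Allen (2002) precipitation-modified Hargreaves:
#' `ET0 = 0.0013 * 0.408 * Ra * (Tavg + t_offset) * max(TD - 0.0123*P, 0)^0.76`
#' with `TD = tmax - tmin`, Ra from [extraterrestrial_radiation()], result in
#' mm/day. A negative radicand is clamped to 0 and ET0 is floored at 0
#' (physical non-negativity when `Tavg < -t_offset`).
#'
#' @param series A [weather_series()].
#' @param t_offset Temperature offset, degC; 17.0 as printed in Droogers &
#'   Allen (a 17.8 variant circulates; configurable).
#' @return A `water_balance` data.frame with columns `date`, `et0`, `balance`
#'   (balance is NA until [climatic_water_balance()] fills it; this function
#'   returns it populated too, as `precip - et0`).
#' @export
et0_hargreaves <- function(series, t_offset = 17.0) {
  validate_weather_series(series)
  lat <- attr(series, "latitude")
  ra <- extraterrestrial_radiation(lat, day_of_year(series$date))
  td <- series$tmax - series$tmin
  rad <- pmax(td - 0.0123 * series$precip, 0)
  et0 <- 0.0013 * 0.408 * ra * (series$tavg + t_offset) * rad^0.76
  pmax(et0, 0)
}

#' Daily climatic water balance
#'
#' `D = precip - ET0`: the difference between water availability and
#' atmospheric water demand, the quantity standardized by the SPEI.
#'
#' @inheritParams et0_hargreaves
#' @return A `water_balance` data.frame: `date`, `et0` (mm/day), `balance`
#'   (mm/day).
#' @export
climatic_water_balance <- function(series, t_offset = 17.0) {
  et0 <- et0_hargreaves(series, t_offset)
  bal <- series$precip - et0
  structure(data.frame(date = series$date, et0 = et0, balance = bal),
            cumsum = c(0, cumsum(bal)),   # O(1) window aggregation
            class = c("water_balance", "data.frame"))
}
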