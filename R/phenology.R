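#' Vernalization response parameters
#'
#' Vernalization is tracked as accumulated "effective vernalization days":
#' each day contributes between 0 and 1 depending on its mean temperature,
#' through a piecewise-linear effectiveness curve. The vernalization factor
#' rises linearly from 0 (at `v_base` accumulated days) to 1 (at `v_sat`).
#' Defaults (0 -> 40 effective days; effectiveness peaking between 3 and
#' 10 degC, zero outside \[-4, 17\] degC) are package defaults for a
#' winter-wheat-like response, not calibrated values.
#'
#' @param v_base Accumulated effective days at which the factor starts rising.
#' @param v_sat Accumulated effective days at which the factor reaches 1.
#' @param t_breaks,effectiveness Breakpoints (degC) and values (0..1) of the
#'   daily effectiveness curve; linear between breakpoints, 0 outside.
#' @return A `vernalization_params` object.
#' @export
vernalization_params <- function(v_base = 0, v_sat = 40,
                                 t_breaks = c(-4, 3, 10, 17),
                                 effectiveness = c(0, 1, 1, 0)) {
  if (v_base < 0 || v_base >= v_sat) val_err("need 0 <= v_base < v_sat")
  if (length(t_breaks) != length(effectiveness) || is.unsorted(t_breaks))
    val_err("t_breaks must be sorted and match effectiveness in length")
  structure(list(v_base = v_base, v_sat = v_sat, t_breaks = t_breaks,
                 effectiveness = effectiveness), class = "vernalization_params")
}

#' Photoperiod response parameters
#'
#' The photoperiod factor is 0 at daylengths at or below `d_critical`, 1 at or
#' above `d_optimal`, linear in between. Defaults (8 h / 16 h) are package
#' defaults for a long-day response.
#'
#' @param d_critical Daylength (h) below which development stops.
#' @param d_optimal Daylength (h) at which development is unconstrained.
#' @return A `photoperiod_params` object.
#' @export
photoperiod_params <- function(d_critical = 8, d_optimal = 16) {
  if (d_critical >= d_optimal) val_err("d_critical must be < d_optimal")
  structure(list(d_critical = d_critical, d_optimal = d_optimal),
            class = "photoperiod_params")
}

#' Two-phase variety parameters
#'
#' Thermal requirements of the vegetative (sowing to flowering, `tsum1`) and
#' reproductive (flowering to maturity, `tsum2`) periods, in growing degree
#' days, with a common base temperature (0 degC for winter wheat) and a cap on
#' the daily effective temperature (30 degC). Vernalization and photoperiod
#' corrections apply only during the vegetative phase; pass `vern = NULL` /
#' `photo = NULL` to force the corresponding factor to 1.
#'
#' @param tsum1,tsum2 Thermal requirements, GDD (> 0). Mediterranean durum
#'   varieties typically fall in 600-1000 GDD for each.
#' @param t_base Base temperature, degC.
#' @param t_max_eff Maximum effective daily temperature, degC (> t_base).
#' @param vern [vernalization_params()] or NULL (factor fixed at 1).
#' @param photo [photoperiod_params()] or NULL (factor fixed at 1).
#' @param sowing_date Sowing date (Date or ISO string).
#' @return A `variety_params_2phase` object.
#' @export
variety_params <- function(tsum1 = 800, tsum2 = 800, t_base = 0,
                           t_max_eff = 30, vern = vernalization_params(),
                           photo = photoperiod_params(), sowing_date) {
  if (tsum1 <= 0 || tsum2 <= 0) val_err("tsum1 and tsum2 must be > 0")
  if (t_base >= t_max_eff) val_err("t_base must be < t_max_eff")
  structure(list(tsum1 = tsum1, tsum2 = tsum2, t_base = t_base,
                 t_max_eff = t_max_eff, vern = vern, photo = photo,
                 sowing_date = as.Date(sowing_date)),
            class = "variety_params_2phase")
}

#' Default sub-phase parameter table for the multi-phase model
#'
#' Typical ranges (GDD) and base temperatures (degC) for Italian durum wheat
#' sub-phases: sowing-emergence 120-200 (Tb 2), emergence-tillering 35-140
#' (Tb -2), tillering-stem elongation 100-220 (Tb -2), stem elongation-booting
#' 100-200 (Tb 0), booting-flowering 50-150 (Tb 0), flowering-ripening 450-550
#' (Tb 9).
#'
#' @return data.frame with columns `phase`, `tsum_min`, `tsum_max`, `t_base`.
#' @export
subphase_parameter_table <- function() {
  data.frame(
    phase = c("sowing-emergence", "emergence-tillering",
              "tillering-stem_elongation", "stem_elongation-booting",
              "booting-flowering", "flowering-ripening"),
    tsum_min = c(120, 35, 100, 100, 50, 450),
    tsum_max = c(200, 140, 220, 200, 150, 550),
    t_base = c(2, -2, -2, 0, 0, 9))
}

#' Multi-phase (six sub-phase) variety parameters
#'
#' Per-sub-phase thermal requirements and base temperatures; vernalization and
#' photoperiod corrections apply to sub-phases 2-5 (emergence-tillering
#' through booting-flowering).
#'
#' @param tsum Length-6 thermal requirements, GDD (each > 0); defaults are the
#'   midpoints of [subphase_parameter_table()] ranges.
#' @param t_base Length-6 base temperatures, degC.
#' @param t_max_eff Cap on daily effective temperature, degC.
#' @inheritParams variety_params
#' @return A `variety_params_multi` object.
#' @export
variety_params_multi <- function(tsum = NULL, t_base = NULL, t_max_eff = 30,
                                 vern = vernalization_params(),
                                 photo = photoperiod_params(), sowing_date) {
  tab <- subphase_parameter_table()
  tsum <- tsum %||% ((tab$tsum_min + tab$tsum_max) / 2)
  t_base <- t_base %||% tab$t_base
  if (length(tsum) != 6 || length(t_base) != 6)
    val_err("tsum and t_base must have length 6")
  if (any(tsum <= 0)) val_err("all tsum must be > 0")
  if (any(t_base >= t_max_eff)) val_err("t_base must be < t_max_eff")
  structure(list(tsum = as.numeric(tsum), t_base = as.numeric(t_base),
                 t_max_eff = t_max_eff, vern = vern, photo = photo,
                 sowing_date = as.Date(sowing_date)),
            class = "variety_params_multi")
}

#' Daily effective temperature
#'
#' `clamp(tavg - t_base, 0, t_max_eff)`: the daily development rate driver is
#' the excess of mean temperature over the base temperature, floored at 0 and
#' held constant above the maximum effective temperature.
#'
#' @param tavg Daily mean temperature, degC. Vectorized.
#' @param t_base Base temperature, degC.
#' @param t_max_eff Maximum effective temperature, degC.
#' @return Effective temperature, GDD/day.
#' @export
effective_temperature <- function(tavg, t_base = 0, t_max_eff = 30) {
  if (t_base >= t_max_eff) val_err("t_base must be < t_max_eff")
  clamp(tavg - t_base, 0, t_max_eff)
}

#' Daily vernalization effectiveness of a given mean temperature
#' @param tavg Daily mean temperature, degC. Vectorized.
#' @param params [vernalization_params()].
#' @return Effective vernalization day fraction in \[0, 1\].
#' @export
vernalization_increment <- function(tavg, params = vernalization_params()) {
  stats::approx(params$t_breaks, params$effectiveness, xout = tavg,
                yleft = 0, yright = 0, ties = "ordered")$y
}

#' Vernalization factor from accumulated effective vernalization days
#' @param state Accumulated effective vernalization days (>= 0). Vectorized.
#' @param params [vernalization_params()].
#' @return Factor in \[0, 1\].
#' @export
vernalization_factor <- function(state, params = vernalization_params()) {
  clamp((state - params$v_base) / (params$v_sat - params$v_base), 0, 1)
}

#' Photoperiod factor from daylength
#' @param daylength_h Daylength in hours (0..24). Vectorized.
#' @param params [photoperiod_params()].
#' @return Factor in \[0, 1\].
#' @export
photoperiod_factor <- function(daylength_h, params = photoperiod_params()) {
  clamp((daylength_h - params$d_critical) /
          (params$d_optimal - params$d_critical), 0, 1)
}

#' Stage-to-DVS lookup tables
#'
#' Maps named growth stages to DVS thresholds, used to resolve dynamic
#' indicator windows. For the two-phase model the intermediate stages follow
#' the WOFOST-convention ordering and are recalibratable; `end_of_flowering`
#' is flowering plus a configurable offset (flowering duration is not a model
#' output). For the multi-phase model integer DVS values are the sub-phase
#' boundaries; `heading` (not a sub-phase boundary) is placed inside
#' booting-flowering.
#'
#' @param model_kind `"2phase"` or `"multiphase"`.
#' @param end_flowering_offset DVS offset added to the flowering threshold to
#'   mark the end of flowering (default 0.15, on the model's own DVS scale).
#' @return Named numeric vector of DVS thresholds (includes `sowing = NA`,
#'   resolved to the sowing date directly).
#' @export
stage_dvs_map <- function(model_kind = c("2phase", "multiphase"),
                          end_flowering_offset = 0.15) {
  model_kind <- match.arg(model_kind)
  if (model_kind == "2phase") {
    c(emergence = 0, tillering = 0.15, stem_elongation = 0.35, booting = 0.75,
      heading = 0.90, flowering = 1.0,
      end_of_flowering = 1.0 + end_flowering_offset, maturity = 2.0)
  } else {
    c(emergence = 1, tillering = 2, stem_elongation = 3, booting = 4,
      heading = 4.6, flowering = 5,
      end_of_flowering = 5 + end_flowering_offset, maturity = 6)
  }
}

factor_series <- function(series, params, idx) {
  # per-day Vf and Pf for the simulated day indices (idx into series rows);
  # vernalization state accumulates from the first simulated day
  n <- length(idx)
  if (is.null(params$vern)) {
    vf <- rep(1, n)
  } else {
    state <- cumsum(vernalization_increment(series$tavg[idx], params$vern))
    vf <- vernalization_factor(state, params$vern)
  }
  if (is.null(params$photo)) {
    pf <- rep(1, n)
  } else {
    dl <- daylength(attr(series, "latitude"), day_of_year(series$date[idx]))
    pf <- photoperiod_factor(dl, params$photo)
  }
  list(vf = vf, pf = pf)
}

new_phenology_track <- function(dates, dvs, model_kind, params, max_stage,
                                stage_map) {
  complete <- max(dvs) >= max_stage - 1e-9
  stage_dates <- as.Date(vapply(names(stage_map), function(s) {
    thr <- stage_map[[s]]
    hit <- if (thr <= 0) which(dvs > 0) else which(dvs >= thr - 1e-9)
    if (length(hit) == 0) NA_character_ else as.character(dates[hit[1]])
  }, character(1)))
  stage_dates <- c(sowing = dates[1], stage_dates)
  structure(data.frame(date = dates, dvs = dvs),
            model_kind = model_kind, params = params, complete = complete,
            stage_map = stage_map, stage_dates = stage_dates,
            class = c("phenology_track", "data.frame"))
}

#' @export
print.phenology_track <- function(x, ...) {
  sd <- attr(x, "stage_dates")
  cat(sprintf("<phenology_track> %s, %d days from %s, max DVS %.3f (%s)\n",
              attr(x, "model_kind"), nrow(x), x$date[1], max(x$dvs),
              if (attr(x, "complete")) "complete" else "incomplete"))
  for (s in names(sd)) cat(sprintf("  %-17s %s\n", s, sd[[s]]))
  invisible(x)
}

#' Stage dates of a phenology track
#' @param track A `phenology_track`.
#' @return Named Date vector (NA for stages not reached).
#' @export
stage_dates <- function(track) attr(track, "stage_dates")

#' Simulate phenology with the two-phase thermal-time model
#'
#' Daily development stage (DVS, 0 at sowing, 1 at flowering, 2 at maturity)
#' accumulates the capped daily effective temperature, divided by `tsum1`
#' during the vegetative phase (where it is multiplied by the vernalization
#' and photoperiod factors) and by `tsum2`, uncorrected, during the
#' reproductive phase. DVS starts at 0 on the sowing day; accumulation begins
#' the following day. When a day's increment crosses DVS = 1 the residual
#' fraction of the day accrues under `tsum2`. Seasons that do not reach
#' maturity by the end of the series return a track flagged incomplete, not an
#' error.
#'
#' @param series A [weather_series()] containing the sowing date.
#' @param params A [variety_params()] object.
#' @param stage_map Stage-to-DVS thresholds, see [stage_dvs_map()].
#' @return A `phenology_track` data.frame (`date`, `dvs`) with stage dates,
#'   completeness flag and model metadata as attributes.
#' @export
simulate_2phase <- function(series, params,
                            stage_map = stage_dvs_map("2phase")) {
  stopifnot(inherits(params, "variety_params_2phase"))
  validate_weather_series(series)
  i0 <- match(params$sowing_date, series$date)
  if (is.na(i0)) val_err("sowing_date outside the weather series")
  idx <- i0:nrow(series)
  n <- length(idx)
  fac <- factor_series(series, params, idx)
  eff <- effective_temperature(series$tavg[idx], params$t_base, params$t_max_eff)
  dvs <- numeric(n)  # dvs[1] = 0 at sowing
  d <- 0
  for (i in seq_len(n)[-1]) {
    if (d < 1) {
      corrected <- eff[i] * fac$vf[i] * fac$pf[i]
      if (corrected > 0 && d + corrected / params$tsum1 >= 1) {
        frac <- (1 - d) * params$tsum1 / corrected
        d <- min(1 + (1 - frac) * eff[i] / params$tsum2, 2)
      } else {
        d <- d + corrected / params$tsum1
      }
    } else if (d < 2) {
      d <- min(d + eff[i] / params$tsum2, 2)
    }
    dvs[i] <- d
  }
  new_phenology_track(series$date[idx], dvs, "2phase", params, 2, stage_map)
}

#' Simulate phenology with the six-sub-phase thermal-time model
#'
#' DVS runs 0 (sowing) to 6 (maturity); each integer interval is one sub-phase
#' with its own thermal requirement and base temperature. Vernalization and
#' photoperiod factors apply to sub-phases 2-5 only. When a day's increment
#' crosses an integer boundary the residual day fraction accrues under the
#' next sub-phase's requirement and base temperature; DVS advances at most one
#' integer boundary per day.
#'
#' @inheritParams simulate_2phase
#' @param params A [variety_params_multi()] object.
#' @return A `phenology_track` (see [simulate_2phase()]).
#' @export
simulate_multiphase <- function(series, params,
                                stage_map = stage_dvs_map("multiphase")) {
  stopifnot(inherits(params, "variety_params_multi"))
  validate_weather_series(series)
  i0 <- match(params$sowing_date, series$date)
  if (is.na(i0)) val_err("sowing_date outside the weather series")
  idx <- i0:nrow(series)
  n <- length(idx)
  fac <- factor_series(series, params, idx)
  tavg <- series$tavg[idx]
  tsum <- params$tsum; tb <- params$t_base; cap <- params$t_max_eff
  dvs <- numeric(n)
  d <- 0
  for (i in seq_len(n)[-1]) {
    if (d >= 6) { dvs[i] <- 6; next }
    k <- floor(d + 1e-12) + 1
    eff_k <- clamp(tavg[i] - tb[k], 0, cap)
    f_k <- if (k >= 2 && k <= 5) fac$vf[i] * fac$pf[i] else 1
    rate <- eff_k * f_k
    if (rate > 0 && d + rate / tsum[k] >= k) {
      frac <- (k - d) * tsum[k] / rate       # fraction of the day to finish k
      if (k == 6) {
        d <- 6
      } else {
        k2 <- k + 1
        eff_2 <- clamp(tavg[i] - tb[k2], 0, cap)
        f_2 <- if (k2 >= 2 && k2 <= 5) fac$vf[i] * fac$pf[i] else 1
        d <- min(k + (1 - frac) * eff_2 * f_2 / tsum[k2], k + 1)
      }
    } else {
      d <- d + rate / tsum[k]
    }
    dvs[i] <- d
  }
  new_phenology_track(series$date[idx], dvs, "multiphase", params, 6, stage_map)
}

#' Static or dynamic aggregation window
#'
#' Static windows are fixed calendar intervals; dynamic windows are DVS
#' intervals resolved against a simulated [simulate_2phase()] /
#' [simulate_multiphase()] track, so their calendar position follows the
#' season's thermal conditions.
#'
#' @param start,end Calendar bounds (static mode).
#' @param start_dvs,end_dvs DVS bounds (dynamic mode).
#' @return A `stage_window` object.
#' @export
stage_window_static <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) val_err("window start after end")
  structure(list(mode = "static", start = start, end = end),
            class = "stage_window")
}

#' @rdname stage_window_static
#' @export
stage_window_dynamic <- function(start_dvs, end_dvs) {
  if (start_dvs >= end_dvs) val_err("start_dvs must be < end_dvs")
  structure(list(mode = "dynamic", start_dvs = start_dvs, end_dvs = end_dvs),
            class = "stage_window")
}

#' Resolve a stage window to calendar dates
#'
#' Static windows are returned unchanged. Dynamic windows map `start_dvs` /
#' `end_dvs` to the first dates on which the track's DVS reaches them. If the
#' track never reaches a bound an `agroclim_incomplete_error` is signalled,
#' carrying the maximum DVS reached (`max_dvs` field of the condition).
#'
#' @param window A [stage_window_static()] / [stage_window_dynamic()].
#' @param track A `phenology_track` (required in dynamic mode).
#' @return List with Date elements `start`, `end`.
#' @export
resolve_window <- function(window, track = NULL) {
  stopifnot(inherits(window, "stage_window"))
  if (window$mode == "static")
    return(list(start = window$start, end = window$end))
  if (is.null(track)) val_err("dynamic window needs a phenology track")
  list(start = dvs_date(track, window$start_dvs),
       end = dvs_date(track, window$end_dvs))
}

dvs_date <- function(track, thr) {
  hit <- if (thr <= 0) which(track$dvs > 0) else which(track$dvs >= thr - 1e-9)
  if (length(hit) == 0) {
    stop(errorCondition(
      sprintf("season incomplete: DVS never reaches %.3f (max %.3f)",
              thr, max(track$dvs)),
      max_dvs = max(track$dvs),
      class = c("agroclim_incomplete_error", "agroclim_validation_error", "error")))
  }
  track$date[hit[1]]
}
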