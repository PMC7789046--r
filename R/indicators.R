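#' Built-in registry of the 16 agro-climate indicators
#'
#' Four groups, each tied to a sensitive period of winter-wheat growth:
#' hydrological balance (ids 1-6, non-parametric SPEI of the climatic water
#' balance), excessive wetness (7-13, rainfall cumulate / wet-day counts /
#' longest wet spell), cold stress (14, days with tmin below 2 degC) and heat
#' stress (15-16, days with tmax above 28 degC). Window bounds are named
#' growth stages, resolved either dynamically from a simulated phenology
#' track or from a static stage calendar.
#'
#' @param wet_thresholds Named list overriding the rainfall thresholds (mm):
#'   `light` (5), `moderate` (10), `heavy` (40).
#' @param cold_threshold tmin threshold for cold stress, degC (default 2).
#' @param heat_threshold tmax threshold for heat stress, degC (default 28).
#' @return data.frame with one row per indicator: `id`, `group`, `statistic`,
#'   `variable`, `threshold`, `direction`, `start_stage`, `end_stage`,
#'   `description`.
#' @export
indicator_registry <- function(wet_thresholds = list(light = 5, moderate = 10,
                                                     heavy = 40),
                               cold_threshold = 2, heat_threshold = 28) {
  w <- wet_thresholds
  reg <- rbind(
    data.frame(id = 1:6, group = "hydrological", statistic = "spei",
               variable = NA_character_, threshold = NA_real_,
               direction = NA_character_,
               start_stage = c("pre_sowing", "sowing", "tillering",
                               "stem_elongation", "heading", "sowing"),
               end_stage = c("sowing", "emergence", "stem_elongation",
                             "booting", "maturity", "maturity"),
               description = c("SPEI pre-sowing", "SPEI sowing-emergence",
                               "SPEI tillering", "SPEI stem elongation-booting",
                               "SPEI heading-maturity", "SPEI whole season")),
    data.frame(id = 7, group = "wetness", statistic = "cumulate",
               variable = "precip", threshold = NA_real_,
               direction = NA_character_,
               start_stage = "pre_sowing", end_stage = "sowing",
               description = "Rainfall cumulate pre-sowing"),
    data.frame(id = c(8, 9, 10, 11), group = "wetness",
               statistic = "count_above", variable = "precip",
               threshold = c(w$moderate, w$heavy, w$light, w$heavy),
               direction = "above",
               start_stage = c("tillering", "tillering", "heading", "heading"),
               end_stage = c("stem_elongation", "stem_elongation",
                             "maturity", "maturity"),
               description = c("Days rainfall > 10 mm, tillering",
                               "Days rainfall > 40 mm, tillering",
                               "Days rainfall > 5 mm, heading-maturity",
                               "Days rainfall > 40 mm, heading-maturity")),
    data.frame(id = c(12, 13), group = "wetness",
               statistic = "max_consecutive_above", variable = "precip",
               threshold = w$light, direction = "above",
               start_stage = c("heading", "flowering"),
               end_stage = c("flowering", "maturity"),
               description = c("Longest wet spell (> 5 mm), heading-flowering",
                               "Longest wet spell (> 5 mm), flowering-maturity")),
    data.frame(id = 14, group = "cold", statistic = "count_below",
               variable = "tmin", threshold = cold_threshold,
               direction = "below",
               start_stage = "booting", end_stage = "flowering",
               description = "Days tmin < 2 degC, booting-flowering"),
    data.frame(id = c(15, 16), group = "heat", statistic = "count_above",
               variable = "tmax", threshold = heat_threshold,
               direction = "above",
               start_stage = c("booting", "end_of_flowering"),
               end_stage = c("end_of_flowering", "maturity"),
               description = c("Days tmax > 28 degC, booting-end of flowering",
                               "Days tmax > 28 degC, end of flowering-maturity")))
  reg
}

slice_window <- function(series, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) val_err("window start after end")
  if (start < min(series$date) || end > max(series$date))
    val_err("window outside the weather series")
  series[series$date >= start & series$date <= end, , drop = FALSE]
}

#' Count days beyond a threshold in a window
#'
#' Strict inequality by default ("above 5 mm" means > 5 mm exactly).
#'
#' @param series A [weather_series()].
#' @param start,end Window bounds (inclusive).
#' @param variable `"precip"`, `"tmin"`, `"tmax"` or `"tavg"`.
#' @param threshold Threshold in the variable's units.
#' @param direction `"above"` or `"below"`.
#' @param strict Use strict inequality (default TRUE).
#' @return Integer day count.
#' @export
count_days <- function(series, start, end, variable, threshold,
                       direction = c("above", "below"), strict = TRUE) {
  direction <- match.arg(direction)
  v <- slice_window(series, start, end)[[variable]]
  if (length(v) == 0) val_err("empty window")
  hit <- switch(direction,
                above = if (strict) v > threshold else v >= threshold,
                below = if (strict) v < threshold else v <= threshold)
  sum(hit)
}

#' Longest run of consecutive days beyond a threshold in a window
#'
#' @inheritParams count_days
#' @return Integer length of the longest qualifying run (0 if none).
#' @export
max_consecutive <- function(series, start, end, variable, threshold,
                            direction = c("above", "below"), strict = TRUE) {
  direction <- match.arg(direction)
  v <- slice_window(series, start, end)[[variable]]
  if (length(v) == 0) val_err("empty window")
  hit <- switch(direction,
                above = if (strict) v > threshold else v >= threshold,
                below = if (strict) v < threshold else v <= threshold)
  r <- rle(hit)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else max(runs)
}

#' Default static stage calendar (Mediterranean October sowing)
#'
#' Month-day anchors for each growth stage when no phenology simulation is
#' used; sowing-side stages fall in the year before harvest. Package defaults
#' for an Italian durum-wheat calendar; override to recalibrate.
#'
#' @return Named character vector of `"mm-dd"` anchors in stage order.
#' @export
default_static_stages <- function() {
  c(sowing = "10-25", emergence = "11-15", tillering = "12-10",
    stem_elongation = "03-05", booting = "04-10", heading = "04-20",
    flowering = "05-01", end_of_flowering = "05-10", maturity = "06-25")
}

static_stage_dates <- function(harvest_year, mmdd = default_static_stages(),
                               presowing_days = 30) {
  out <- as.Date(character(0))
  prev <- as.Date(sprintf("%d-01-01", harvest_year - 1))
  for (s in names(mmdd)) {
    cand <- as.Date(sprintf("%d-%s", harvest_year - 1, mmdd[[s]]))
    if (cand < prev) cand <- shift_years(cand, 1)
    out <- c(out, cand)
    prev <- cand
  }
  names(out) <- names(mmdd)
  c(pre_sowing = out[["sowing"]] - presowing_days, out)
}

dynamic_stage_dates <- function(track, presowing_days = 30) {
  sd <- stage_dates(track)
  c(pre_sowing = sd[["sowing"]] - presowing_days, sd)
}

#' Compute phenology-linked agro-climate indicators
#'
#' The end-to-end indicator pipeline: resolves each selected indicator's
#' growth-stage window (dynamically, by simulating the crop's development
#' from the supplied variety parameters, or statically from a stage calendar),
#' then routes hydrological indicators through the water balance and
#' non-parametric SPEI and wetness/temperature indicators through day-count
#' statistics. SPEI indicators standardize the current window against
#' same-window aggregates across all years of `series`, so a multi-year
#' series (>= `spei_min_n` + 1 years) is required for ids 1-6.
#'
#' @param series A multi-year [weather_series()].
#' @param params [variety_params()] or [variety_params_multi()] (dynamic
#'   mode); may be NULL in static mode if `harvest_year` is given.
#' @param ids Indicator ids to compute (subset of 1..16).
#' @param mode `"dynamic"` (simulate phenology) or `"static"` (stage
#'   calendar).
#' @param registry Indicator registry, see [indicator_registry()].
#' @param presowing_days Length of the pre-sowing window, days (default 30).
#' @param static_stages Month-day stage anchors for static mode.
#' @param harvest_year Harvest year for static mode (derived from
#'   `params$sowing_date` when omitted).
#' @param track Optional precomputed phenology track (skips simulation).
#' @param balance Optional precomputed [climatic_water_balance()] for
#'   `series`.
#' @param spei_min_n Minimum SPEI reference years (default 10).
#' @param spei_warn Warn when the SPEI reference has fewer than 30 years.
#' @return data.frame with one row per requested indicator: `id`, `group`,
#'   `statistic`, `window_start`, `window_end`, `value`, `risk_class`,
#'   `season_complete`. Indicators whose window the season never reached have
#'   `value = NA` and `season_complete = FALSE`.
#' @export
compute_indicators <- function(series, params = NULL, ids = 1:16,
                               mode = c("dynamic", "static"),
                               registry = indicator_registry(),
                               presowing_days = 30,
                               static_stages = default_static_stages(),
                               harvest_year = NULL, track = NULL,
                               balance = NULL, spei_min_n = 10,
                               spei_warn = TRUE) {
  mode <- match.arg(mode)
  if (!all(ids %in% registry$id))
    val_err(paste0("unknown indicator id(s): ",
                   paste(setdiff(ids, registry$id), collapse = ", ")))
  if (mode == "dynamic") {
    if (is.null(track)) {
      if (is.null(params)) val_err("dynamic mode needs variety params or a track")
      track <- if (inherits(params, "variety_params_multi"))
        simulate_multiphase(series, params) else simulate_2phase(series, params)
    }
    stages <- dynamic_stage_dates(track, presowing_days)
    complete <- attr(track, "complete")
  } else {
    hy <- harvest_year %||%
      (if (!is.null(params)) as.integer(format(params$sowing_date, "%Y")) + 1L
       else val_err("static mode needs harvest_year or params"))
    stages <- static_stage_dates(hy, static_stages, presowing_days)
    complete <- TRUE
  }
  rows <- lapply(ids, function(i) {
    spec <- registry[registry$id == i, ]
    w_start <- stages[[spec$start_stage]]
    w_end <- stages[[spec$end_stage]]
    if (is.na(w_start) || is.na(w_end)) {
      return(data.frame(id = i, group = spec$group, statistic = spec$statistic,
                        window_start = as.Date(NA), window_end = as.Date(NA),
                        value = NA_real_, risk_class = NA_character_,
                        season_complete = FALSE))
    }
    if (spec$statistic == "spei") {
      if (is.null(balance)) balance <<- climatic_water_balance(series)
      agg <- aggregate_balance(balance, w_start, w_end)
      ref <- if (spei_warn)
        reference_sample(balance, w_start, w_end, min_n = spei_min_n)
      else suppressWarnings(
        reference_sample(balance, w_start, w_end, min_n = spei_min_n))
      value <- spei_nonparametric(agg, ref, min_n = spei_min_n)
      risk <- classify_spei(value)
    } else {
      value <- switch(spec$statistic,
        cumulate = sum(slice_window(series, w_start, w_end)[[spec$variable]]),
        count_above = count_days(series, w_start, w_end, spec$variable,
                                 spec$threshold, "above"),
        count_below = count_days(series, w_start, w_end, spec$variable,
                                 spec$threshold, "below"),
        max_consecutive_above = max_consecutive(series, w_start, w_end,
                                                spec$variable, spec$threshold,
                                                "above"))
      risk <- NA_character_
    }
    data.frame(id = i, group = spec$group, statistic = spec$statistic,
               window_start = w_start, window_end = w_end,
               value = as.numeric(value), risk_class = risk,
               season_complete = complete)
  })
  do.call(rbind, rows)
}
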