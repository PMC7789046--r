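#' Daily weather series
#'
#' A `weather_series` is a data.frame with one row per calendar day and columns
#' `date` (Date), `tmin`, `tmax` (degrees C), `precip` (mm, non-negative) and a
#' derived `tavg = (tmin + tmax)/2`. The site latitude (degrees, used for solar
#' geometry) and an optional site label travel as attributes. Dates must be
#' strictly consecutive with no gaps; `tmin <= tmax` on every day.
#'
#' @param date Date vector, strictly consecutive days.
#' @param tmin,tmax Daily minimum / maximum air temperature, degrees C.
#' @param precip Daily precipitation, mm (>= 0).
#' @param latitude Site latitude in degrees, in \[-90, 90\].
#' @param site_id Optional site label.
#' @return A `weather_series` object.
#' @export
weather_series <- function(date, tmin, tmax, precip, latitude, site_id = "site") {
  date <- as.Date(date)
  df <- data.frame(date = date, tmin = as.numeric(tmin), tmax = as.numeric(tmax),
                   precip = as.numeric(precip))
  df$tavg <- (df$tmin + df$tmax) / 2
  structure(df, latitude = as.numeric(latitude), site_id = site_id,
            class = c("weather_series", "data.frame")) |>
    validate_weather_series()
}

#' Validate a weather series
#'
#' Checks the structural invariants of a [weather_series()]: required columns,
#' parsable and strictly consecutive dates, `tmin <= tmax`, non-negative
#' precipitation, no missing values, latitude within \[-90, 90\]. Errors are
#' classed (`agroclim_format_error`, `agroclim_validation_error`) and name the
#' first offending date.
#'
#' @param x A `weather_series` (or data.frame shaped like one).
#' @return `x`, invisibly validated (returned unchanged on success).
#' @export
validate_weather_series <- function(x) {
  needed <- c("date", "tmin", "tmax", "precip")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop(errorCondition(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
                        class = c("agroclim_format_error", "error")))
  }
  if (nrow(x) < 1) val_err("weather series must contain at least one day")
  if (anyNA(x$date)) val_err("unparsable or missing dates present")
  if (anyNA(x$tmin) || anyNA(x$tmax) || anyNA(x$precip))
    val_err("missing values in tmin/tmax/precip are not supported")
  lat <- attr(x, "latitude")
  if (is.null(lat) || is.na(lat) || abs(lat) > 90)
    val_err("latitude must be given and within [-90, 90]")
  d <- diff(as.integer(x$date))
  if (any(d != 1)) {
    i <- which(d != 1)[1]
    if (d[i] < 1) val_err(paste0("dates not strictly increasing at ", x$date[i + 1]))
    val_err(paste0("gap in daily dates: missing ", x$date[i] + 1))
  }
  bad <- which(x$tmin > x$tmax)
  if (length(bad) > 0)
    val_err(paste0("tmin > tmax on ", x$date[bad[1]]))
  if (any(x$precip < 0))
    val_err(paste0("negative precipitation on ", x$date[which(x$precip < 0)[1]]))
  x
}

val_err <- function(msg) {
  stop(errorCondition(msg, class = c("agroclim_validation_error", "error")))
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> %s: %d days (%s .. %s), latitude %.2f\n",
              attr(x, "site_id"), nrow(x), min(x$date), max(x$date),
              attr(x, "latitude")))
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE)
  if (nrow(x) > 4) cat(sprintf("... %d more days\n", nrow(x) - 4))
  invisible(x)
}

#' Read a daily weather series from CSV
#'
#' Expects columns `date` (ISO-8601), `tmin`, `tmax`, `precip`; comma separated
#' with a header row and `.` decimal. Units are fixed (degrees C, mm).
#'
#' @param path CSV file path.
#' @param latitude Site latitude, degrees.
#' @param site_id Optional site label (defaults to the file name).
#' @return A validated [weather_series()].
#' @export
read_weather_csv <- function(path, latitude, site_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("date", "tmin", "tmax", "precip")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop(errorCondition(paste0("CSV ", path, " missing column(s): ",
                               paste(missing_cols, collapse = ", ")),
                        class = c("agroclim_format_error", "error")))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop(errorCondition(paste0("unparsable date at row ", which(is.na(dates))[1]),
                        class = c("agroclim_format_error", "error")))
  weather_series(dates, df$tmin, df$tmax, df$precip, latitude, site_id)
}

#' Write a weather series to CSV (round-trip safe)
#' @param x A `weather_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("date", "tmin", "tmax", "precip")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Weather ensemble
#'
#' Container for an ensemble of realizations of the same season (e.g. members
#' of a seasonal prediction). All members must share the identical date range
#' and latitude.
#'
#' @param members List of [weather_series()].
#' @param member_ids Optional character ids, one per member.
#' @return A `weather_ensemble` object.
#' @export
weather_ensemble <- function(members, member_ids = NULL) {
  if (length(members) < 1) val_err("ensemble must have at least one member")
  member_ids <- member_ids %||% sprintf("m%02d", seq_along(members))
  if (length(member_ids) != length(members))
    val_err("member_ids length must match members")
  lapply(members, validate_weather_series)
  ref <- members[[1]]
  for (m in members[-1]) {
    if (!identical(range(m$date), range(ref$date)))
      val_err("ensemble members must share an identical date range")
    if (!identical(attr(m, "latitude"), attr(ref, "latitude")))
      val_err("ensemble members must share the same latitude")
  }
  structure(list(members = members, member_ids = member_ids),
            class = "weather_ensemble")
}

#' @export
print.weather_ensemble <- function(x, ...) {
  cat(sprintf("<weather_ensemble> %d members, %s .. %s\n",
              length(x$members), min(x$members[[1]]$date),
              max(x$members[[1]]$date)))
  invisible(x)
}

#' Read a long-format ensemble CSV (columns date,tmin,tmax,precip,member_id)
#' @param path CSV path.
#' @param latitude Site latitude, degrees.
#' @return A [weather_ensemble()].
#' @export
read_weather_ensemble_csv <- function(path, latitude) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"member_id" %in% names(df))
    stop(errorCondition("ensemble CSV needs a member_id column",
                        class = c("agroclim_format_error", "error")))
  ids <- unique(df$member_id)
  members <- lapply(ids, function(id) {
    sub <- df[df$member_id == id, , drop = FALSE]
    weather_series(as.Date(sub$date), sub$tmin, sub$tmax, sub$precip,
                   latitude, site_id = as.character(id))
  })
  weather_ensemble(members, as.character(ids))
}

#' Read an ensemble from a directory of per-member CSV files
#' @param dir Directory containing one weather CSV per member.
#' @param latitude Site latitude, degrees.
#' @return A [weather_ensemble()].
#' @export
read_weather_ensemble_dir <- function(dir, latitude) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) val_err(paste0("no CSV files in ", dir))
  members <- lapply(files, read_weather_csv, latitude = latitude)
  weather_ensemble(members, sub("\\.csv$", "", basename(files)))
}

#' Write an ensemble to a long-format CSV with a member_id column
#' @param x A `weather_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather_ensemble_csv <- function(x, path) {
  long <- do.call(rbind, Map(function(m, id) {
    df <- as.data.frame(m)[c("date", "tmin", "tmax", "precip")]
    df$member_id <- id
    df
  }, x$members, x$member_ids))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply a computation independently to each ensemble member
#'
#' Phenology, indicators and any other per-series computation are applied to
#' each member separately; the result list is aligned with `member_ids`.
#'
#' @param ensemble A [weather_ensemble()].
#' @param fn Function taking a `weather_series`.
#' @param ... Further arguments passed to `fn`.
#' @return Named list of per-member results.
#' @export
map_over_ensemble <- function(ensemble, fn, ...) {
  if (!inherits(ensemble, "weather_ensemble")) val_err("not a weather_ensemble")
  if (length(ensemble$members) == 0) val_err("empty ensemble")
  stats::setNames(lapply(ensemble$members, fn, ...), ensemble$member_ids)
}

#' Summarize per-member numeric results of an ensemble computation
#'
#' @param values Numeric vector (or list) of per-member results; NaN/NA members
#'   are excluded and counted.
#' @return List with `mean`, `median`, `q10`, `q90`, `min`, `max`, `n`, `n_na`.
#' @export
summarize_ensemble <- function(values) {
  v <- as.numeric(unlist(values))
  n_na <- sum(!is.finite(v))
  v <- v[is.finite(v)]
  if (length(v) == 0) val_err("all ensemble values are missing/NaN")
  q <- unname(stats::quantile(v, c(0.1, 0.9), type = 7))
  list(mean = mean(v), median = stats::median(v), q10 = q[1], q90 = q[2],
       min = min(v), max = max(v), n = length(v), n_na = n_na)
}
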