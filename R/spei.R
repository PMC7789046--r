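#' Aggregate the climatic water balance over a window
#'
#' Sum of daily balance `D` between two dates, inclusive of both endpoints.
#'
#' @param balance A `water_balance` data.frame from [climatic_water_balance()].
#' @param start,end Dates (coercible with `as.Date`).
#' @return Aggregate balance in mm.
#' @export
aggregate_balance <- function(balance, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) val_err("window start is after end")
  d0 <- balance$date[1]; n <- nrow(balance)
  i1 <- as.numeric(start - d0) + 1
  i2 <- as.numeric(end - d0) + 1
  if (i1 < 1 || i2 > n) val_err("window outside the balance series")
  cs <- attr(balance, "cumsum") %||% c(0, cumsum(balance$balance))
  cs[i2 + 1] - cs[i1]
}

#' Build a cross-year reference sample of same-window aggregates
#'
#' For a window `start..end` (possibly spanning a year boundary), computes the
#' same month-day window shifted by every whole number of years that keeps it
#' inside the series, and aggregates the balance over each. This is the
#' empirical climatology against which the evaluated window is standardized.
#' The evaluated year is left in the reference by default (leave-current-in);
#' set `leave_one_out = TRUE` to exclude it.
#'
#' @inheritParams aggregate_balance
#' @param min_n Minimum number of reference years (default 10; a warning is
#'   issued below 30, where the empirical standardization is noisy).
#' @param leave_one_out Exclude the evaluated window's own year.
#' @return A `reference_sample` list: `aggregates` (mm), `years`, `n`.
#' @export
reference_sample <- function(balance, start, end, min_n = 10,
                             leave_one_out = FALSE) {
  start <- as.Date(start); end <- as.Date(end)
  lo <- min(balance$date); hi <- max(balance$date)
  k_lo <- as.integer(format(lo, "%Y")) - as.integer(format(start, "%Y")) - 1L
  k_hi <- as.integer(format(hi, "%Y")) - as.integer(format(end, "%Y")) + 1L
  years <- integer(0); aggs <- numeric(0)
  for (k in seq(k_lo, k_hi)) {
    s <- shift_years(start, k); e <- shift_years(end, k)
    if (s < lo || e > hi) next
    if (leave_one_out && k == 0) next
    years <- c(years, as.integer(format(s, "%Y")))
    aggs <- c(aggs, aggregate_balance(balance, s, e))
  }
  if (length(aggs) < min_n)
    val_err(sprintf("reference sample too small (%d < %d years)",
                    length(aggs), min_n))
  if (length(aggs) < 30)
    warning(sprintf("reference sample has only %d years; SPEI is noisy below 30",
                    length(aggs)), call. = FALSE)
  structure(list(aggregates = aggs, years = years, n = length(aggs)),
            class = "reference_sample")
}

#' Non-parametric SPEI standardization
#'
#' Maps an aggregate water balance to standard-normal units through the
#' empirical distribution of the reference aggregates: the value is ranked
#' among `reference U {value}` (ties share the mean rank), converted to an
#' empirical probability by a plotting position, and passed through the
#' standard-normal quantile function. No parametric distribution is fitted.
#'
#' Plotting positions: Gringorten `p = (r - 0.44)/(n + 0.12)` (default; the
#' standard choice for non-parametric standardized drought indices, whose
#' self-referenced standardization stays close to unit variance) or Weibull
#' `p = r/(n+1)`.
#'
#' @param value Aggregate balance to standardize, mm.
#' @param reference A [reference_sample()] or numeric vector of reference
#'   aggregates, mm.
#' @param plotting_position `"gringorten"` or `"weibull"`.
#' @param min_n Minimum reference size.
#' @return SPEI in standard-normal units (finite).
#' @export
spei_nonparametric <- function(value, reference,
                               plotting_position = c("gringorten", "weibull"),
                               min_n = 10) {
  plotting_position <- match.arg(plotting_position)
  ref <- if (inherits(reference, "reference_sample")) reference$aggregates
         else as.numeric(reference)
  if (length(ref) < min_n)
    val_err(sprintf("reference too small (%d < %d)", length(ref), min_n))
  pooled <- c(value, ref)
  r <- rank(pooled, ties.method = "average")[1]
  n <- length(pooled)
  p <- switch(plotting_position,
              weibull = r / (n + 1),
              gringorten = (r - 0.44) / (n + 0.12))
  stats::qnorm(p)
}

#' Classify an SPEI value into the seven-band risk scheme
#'
#' Drought: moderate (-1.5, -1\], severe (-2, -1.5\], extreme <= -2; wetness
#' mirrored: moderately wet \[1, 1.5), very wet \[1.5, 2), extremely wet >= 2;
#' `normal` between -1 and 1 (exclusive). Band edges belong to the more severe
#' class.
#'
#' @param spei Finite SPEI value(s), standard-normal units. Vectorized.
#' @return Character risk class(es).
#' @export
classify_spei <- function(spei) {
  if (any(!is.finite(spei))) val_err("SPEI must be finite")
  cls <- character(length(spei))
  cls[spei <= -2] <- "extreme_drought"
  cls[spei > -2 & spei <= -1.5] <- "severe_drought"
  cls[spei > -1.5 & spei <= -1] <- "moderate_drought"
  cls[spei > -1 & spei < 1] <- "normal"
  cls[spei >= 1 & spei < 1.5] <- "moderately_wet"
  cls[spei >= 1.5 & spei < 2] <- "very_wet"
  cls[spei >= 2] <- "extremely_wet"
  cls
}
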