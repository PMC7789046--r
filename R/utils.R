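#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
with_local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Shift a date by whole calendar years, mapping Feb 29 to Feb 28
#' @keywords internal
shift_years <- function(date, k) {
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900 + k
  m <- lt$mon + 1
  d <- lt$mday
  leap <- (y %% 4 == 0 & y %% 100 != 0) | (y %% 400 == 0)
  d <- ifelse(m == 2 & d == 29 & !leap, 28, d)
  as.Date(sprintf("%04d-%02d-%02d", y, m, d))
}

#' Day of year (Feb 29 = 60 in leap years)
#' @keywords internal
day_of_year <- function(date) as.integer(format(date, "%j"))

`%||%` <- function(a, b) if (is.null(a)) b else a
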