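# Independent day-loop transcriptions of the thermal-time recurrences and
# naive recomputations of the indicator statistics. Deliberately written as
# plain scalar loops with inlined formulas, not calls into the package's
# computational path.

oracle_vern_eff <- function(t) {
  if (t < -4 || t > 17) return(0)
  if (t < 3) return((t + 4) / 7)
  if (t <= 10) return(1)
  (17 - t) / 7
}

oracle_daylength <- function(lat, doy) {
  phi <- lat * pi / 180
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  arg <- -tan(phi) * tan(delta)
  arg <- max(-1, min(1, arg))
  24 / pi * acos(arg)
}

oracle_factors <- function(series, params, idx) {
  lat <- attr(series, "latitude")
  n <- length(idx)
  vf <- pf <- rep(1, n)
  state <- 0
  for (i in seq_len(n)) {
    t <- series$tavg[idx[i]]
    if (!is.null(params$vern)) {
      state <- state + oracle_vern_eff(t)
      v <- (state - params$vern$v_base) /
        (params$vern$v_sat - params$vern$v_base)
      vf[i] <- max(0, min(1, v))
    }
    if (!is.null(params$photo)) {
      dl <- oracle_daylength(lat, as.integer(format(series$date[idx[i]], "%j")))
      p <- (dl - params$photo$d_critical) /
        (params$photo$d_optimal - params$photo$d_critical)
      pf[i] <- max(0, min(1, p))
    }
  }
  list(vf = vf, pf = pf)
}

oracle_2phase <- function(series, params) {
  i0 <- which(series$date == params$sowing_date)
  idx <- i0:nrow(series)
  fac <- oracle_factors(series, params, idx)
  dvs <- numeric(length(idx))
  d <- 0
  for (i in seq_along(idx)[-1]) {
    t <- series$tavg[idx[i]]
    eff <- max(0, min(t - params$t_base, params$t_max_eff))
    if (d < 1) {
      corr <- eff * fac$vf[i] * fac$pf[i]
      if (corr > 0 && d + corr / params$tsum1 >= 1) {
        frac <- (1 - d) * params$tsum1 / corr
        d <- min(1 + (1 - frac) * eff / params$tsum2, 2)
      } else {
        d <- d + corr / params$tsum1
      }
    } else if (d < 2) {
      d <- min(d + eff / params$tsum2, 2)
    }
    dvs[i] <- d
  }
  dvs
}

oracle_multiphase <- function(series, params) {
  i0 <- which(series$date == params$sowing_date)
  idx <- i0:nrow(series)
  fac <- oracle_factors(series, params, idx)
  dvs <- numeric(length(idx))
  d <- 0
  for (i in seq_along(idx)[-1]) {
    if (d >= 6) { dvs[i] <- 6; next }
    t <- series$tavg[idx[i]]
    k <- floor(d + 1e-12) + 1
    eff <- max(0, min(t - params$t_base[k], params$t_max_eff))
    f <- if (k >= 2 && k <= 5) fac$vf[i] * fac$pf[i] else 1
    rate <- eff * f
    if (rate > 0 && d + rate / params$tsum[k] >= k) {
      frac <- (k - d) * params$tsum[k] / rate
      if (k == 6) {
        d <- 6
      } else {
        eff2 <- max(0, min(t - params$t_base[k + 1], params$t_max_eff))
        f2 <- if (k + 1 >= 2 && k + 1 <= 5) fac$vf[i] * fac$pf[i] else 1
        d <- min(k + (1 - frac) * eff2 * f2 / params$tsum[k + 1], k + 1)
      }
    } else {
      d <- d + rate / params$tsum[k]
    }
    dvs[i] <- d
  }
  dvs
}

# independent per-day ET0/climatic-balance chain (inlined formulas)
oracle_balance <- function(series) {
  lat <- attr(series, "latitude")
  doys <- as.integer(format(series$date, "%j"))
  bal <- numeric(nrow(series))
  for (i in seq_len(nrow(series))) {
    doy <- doys[i]
    phi <- lat * pi / 180
    dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
    delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
    ws <- acos(max(-1, min(1, -tan(phi) * tan(delta))))
    ra <- max(0, 24 * 60 / pi * 0.0820 * dr *
                (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws)))
    td <- series$tmax[i] - series$tmin[i]
    rad <- max(td - 0.0123 * series$precip[i], 0)
    et0 <- max(0, 0.0013 * 0.408 * ra * (series$tavg[i] + 17) * rad^0.76)
    bal[i] <- series$precip[i] - et0
  }
  bal
}

# naive per-day recomputation of an indicator value over resolved window
# dates, including an independent ET0/balance/SPEI chain for hydrological ids
oracle_indicator_value <- function(series, spec, w_start, w_end,
                                   naive_balance = NULL) {
  days <- which(series$date >= w_start & series$date <= w_end)
  if (spec$statistic == "cumulate") {
    tot <- 0
    for (i in days) tot <- tot + series$precip[i]
    return(tot)
  }
  if (spec$statistic %in% c("count_above", "count_below")) {
    cnt <- 0
    for (i in days) {
      v <- series[[spec$variable]][i]
      if (spec$direction == "above" && v > spec$threshold) cnt <- cnt + 1
      if (spec$direction == "below" && v < spec$threshold) cnt <- cnt + 1
    }
    return(cnt)
  }
  if (spec$statistic == "max_consecutive_above") {
    best <- 0; run <- 0
    for (i in days) {
      if (series[[spec$variable]][i] > spec$threshold) {
        run <- run + 1
        best <- max(best, run)
      } else run <- 0
    }
    return(best)
  }
  # SPEI: independent ET0 + balance + cross-year rank standardization
  nb <- naive_balance
  if (is.null(nb)) nb <- oracle_balance(series)
  win_sum <- function(s, e) {
    tot <- 0
    for (i in which(series$date >= s & series$date <= e)) tot <- tot + nb[i]
    tot
  }
  value <- win_sum(w_start, w_end)
  shift_mmdd <- function(date, k) {
    y <- as.integer(format(date, "%Y")) + k
    md <- format(date, "%m-%d")
    if (md == "02-29" && !((y %% 4 == 0 && y %% 100 != 0) || y %% 400 == 0))
      md <- "02-28"
    as.Date(paste0(y, "-", md))
  }
  ref <- numeric(0)
  for (k in -40:40) {
    s <- shift_mmdd(w_start, k); e <- shift_mmdd(w_end, k)
    if (s >= min(series$date) && e <= max(series$date))
      ref <- c(ref, win_sum(s, e))
  }
  pooled <- c(value, ref)
  r <- sum(pooled < value) + (sum(pooled == value) + 1) / 2
  qnorm((r - 0.44) / (length(pooled) + 0.12))
}
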