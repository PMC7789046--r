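#' Rank-based pseudo-observations
#'
#' Maps paired observations to the unit square by the empirical margins:
#' `u_i = rank(x_i)/(n+1)` (ties get average ranks), likewise for `v`. The
#' copula fitted on these is invariant to any strictly monotone transform of
#' either margin.
#'
#' @param x,y Paired numeric vectors (indicator value, disease severity).
#' @return data.frame with columns `u`, `v` in (0, 1).
#' @export
pseudo_observations <- function(x, y) {
  if (length(x) != length(y)) val_err("x and y must have equal length")
  n <- length(x)
  if (n < 2) val_err("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) val_err("missing values in observation pairs")
  data.frame(u = rank(x, ties.method = "average") / (n + 1),
             v = rank(y, ties.method = "average") / (n + 1))
}

#' Fit a bivariate kernel copula density
#'
#' Probit-transformation estimator: the pseudo-observations are mapped to
#' normal scores `z = qnorm(u)`, `w = qnorm(v)`, a Gaussian product-kernel
#' density with Silverman bandwidths (`sd * n^(-1/6)` per margin) is fitted
#' there, and the copula density is the back-transformed
#' `c(u,v) = f(qnorm(u), qnorm(v)) / (dnorm(qnorm(u)) dnorm(qnorm(v)))`.
#' This construction is boundary-consistent (no mass leaks outside the unit
#' square) and integrates to 1 by change of variables.
#'
#' @param x,y Paired observations: indicator values and disease severities
#'   (severity in percent, 0..100). At least 5 pairs; a fully tied margin is
#'   degenerate and rejected.
#' @param bw_factor Multiplier on the Silverman bandwidths (default 1).
#' @return A `copula_model` list: `x`, `y`, `u`, `v`, `z`, `w`, bandwidths
#'   `h1`, `h2`, `n`; use [copula_density()], [conditional_exceedance()],
#'   [risk_threshold()] on it.
#' @export
fit_copula_density <- function(x, y, bw_factor = 1) {
  if (length(x) < 5) val_err("need at least 5 pairs to fit")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    val_err("degenerate margin: all values tied")
  po <- pseudo_observations(x, y)
  z <- stats::qnorm(po$u); w <- stats::qnorm(po$v)
  n <- length(z)
  h1 <- bw_factor * stats::sd(z) * n^(-1 / 6)
  h2 <- bw_factor * stats::sd(w) * n^(-1 / 6)
  structure(list(x = x, y = y, u = po$u, v = po$v, z = z, w = w,
                 h1 = h1, h2 = h2, n = n), class = "copula_model")
}

#' @export
print.copula_model <- function(x, ...) {
  cat(sprintf("<copula_model> n = %d pairs, bandwidths (%.3f, %.3f)\n",
              x$n, x$h1, x$h2))
  invisible(x)
}

#' Evaluate the fitted copula density
#' @param model A [fit_copula_density()] model.
#' @param u,v Points in (0, 1) (vectorized, recycled).
#' @return Copula density values (>= 0).
#' @export
copula_density <- function(model, u, v) {
  zu <- stats::qnorm(u); wv <- stats::qnorm(v)
  f <- mapply(function(a, b) {
    mean(stats::dnorm(a, model$z, model$h1) * stats::dnorm(b, model$w, model$h2))
  }, zu, wv)
  f / (stats::dnorm(zu) * stats::dnorm(wv))
}

# empirical margin mapping: observed value -> u in (0,1), by interpolating the
# (sorted value, sorted pseudo-observation) pairs; warns outside the range
margin_to_u <- function(values, obs, pobs, what = "value") {
  rng <- range(obs)
  if (any(values < rng[1] | values > rng[2]))
    warning(sprintf("%s outside the observed range [%g, %g]: extrapolating",
                    what, rng[1], rng[2]), call. = FALSE)
  o <- order(obs)
  ux <- stats::approx(obs[o], pobs[o], xout = values, rule = 2,
                      ties = "ordered")$y
  clamp(ux, 1e-6, 1 - 1e-6)
}

#' Conditional probability of exceeding a severity threshold
#'
#' `P(severity > threshold | indicator = value)`, computed from the fitted
#' copula: the conditioning value is mapped through the empirical indicator
#' margin to `u0`, the severity threshold through the empirical severity
#' margin to `v_t`, and the conditional tail mass is the closed-form Gaussian
#' mixture integral of the kernel density above `qnorm(v_t)` along the slice
#' `z = qnorm(u0)` (no numeric quadrature error in v).
#'
#' @param model A [fit_copula_density()] model.
#' @param indicator_value Conditioning indicator value(s); values outside the
#'   observed range trigger an extrapolation warning.
#' @param severity_threshold Severity threshold, percent.
#' @return Probability in \[0, 1\] (vectorized over `indicator_value`).
#' @export
conditional_exceedance <- function(model, indicator_value, severity_threshold) {
  u0 <- margin_to_u(indicator_value, model$x, model$u, "indicator value")
  # severity threshold below/above everything observed: tail mass 1/0 up to
  # the smoothing of the kernel; mapped through the same empirical margin
  vt <- margin_to_u(severity_threshold, model$y, model$v, "severity threshold")
  # but a threshold strictly below all severities must give ~1, handle by rule=2
  z0 <- stats::qnorm(u0); wt <- stats::qnorm(vt)
  vapply(z0, function(z) {
    wgt <- stats::dnorm(z, model$z, model$h1)
    tail <- stats::pnorm((wt - model$w) / model$h2, lower.tail = FALSE)
    sum(wgt * tail) / sum(wgt)
  }, numeric(1))
}

#' Smallest indicator value reaching a conditional risk level
#'
#' Scans a grid of indicator values over the observed range and returns the
#' smallest one whose conditional exceedance probability
#' ([conditional_exceedance()]) reaches `prob_level`. If the probability
#' never reaches the level an explicit `NA` sentinel is returned (with the
#' maximum probability attained as attribute `max_prob`).
#'
#' @param model A [fit_copula_density()] model.
#' @param severity_threshold Severity threshold, percent.
#' @param prob_level Required conditional probability in \[0, 1\].
#' @param grid Indicator evaluation grid (default: the distinct observed
#'   indicator values — day-count indicators take whole-day thresholds).
#' @return The threshold indicator value, or `NA` if the level is never
#'   reached.
#' @export
risk_threshold <- function(model, severity_threshold, prob_level,
                           grid = NULL) {
  rng <- range(model$x)
  if (prob_level <= 0) return(rng[1])
  grid <- grid %||% sort(unique(model$x))
  p <- conditional_exceedance(model, grid, severity_threshold)
  hit <- which(p >= prob_level)
  if (length(hit) == 0)
    return(structure(NA_real_, max_prob = max(p)))
  grid[hit[1]]
}

#' Synthetic indicator/severity pairs with a dependence switch-point
#'
#' Generates observation pairs with the qualitative structure of wet-day
#' driven fungal disease data: below `switch_point` wet days the severity is
#' low (a few percent); at or above it the severity jumps to a high regime
#' and keeps rising with the indicator. Used to test that the copula risk
#' chain recovers a known threshold; the generator is synthetic machinery,
#' not observed data.
#'
#' @param n Number of pairs.
#' @param switch_point Indicator value (wet days) where severity jumps.
#' @param indicator_max Maximum indicator value generated.
#' @param low_severity,high_severity Mean severity (percent) below/above the
#'   switch-point.
#' @param noise_sd Severity noise SD, percent.
#' @param seed Integer seed.
#' @return data.frame with columns `indicator`, `severity` (severity clamped
#'   to \[0, 100\]).
#' @export
generate_impact_observations <- function(n = 60, switch_point = 5,
                                         indicator_max = 15,
                                         low_severity = 5,
                                         high_severity = 50,
                                         noise_sd = 5, seed = 1L) {
  with_local_seed(seed, {
    ind <- sample.int(indicator_max + 1, n, replace = TRUE) - 1
    base <- ifelse(ind < switch_point, low_severity,
                   high_severity + 2 * (ind - switch_point))
    sev <- clamp(base + stats::rnorm(n, 0, noise_sd), 0, 100)
    data.frame(indicator = ind, severity = sev)
  })
}
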