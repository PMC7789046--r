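#' Exhaustive TSUM1/TSUM2 grid scan
#'
#' Evaluates every combination of vegetative and reproductive thermal
#' requirements with the two-phase model and computes the selected indicators
#' for each, returning a long-format table suitable for hazard maps.
#' Combinations whose season does not complete are flagged, not fatal.
#'
#' @param series A multi-year [weather_series()].
#' @param template A [variety_params()] carrying sowing date, base
#'   temperatures and factor settings; its `tsum1`/`tsum2` are overwritten.
#' @param tsum1_values,tsum2_values Numeric GDD values to cross (e.g.
#'   `seq(600, 1000, 50)`).
#' @param ids Indicator ids to compute per combination.
#' @param ... Passed to [compute_indicators()] (e.g. `balance`, `spei_warn`).
#' @return data.frame: `tsum1`, `tsum2`, `id`, `value`, `risk_class`,
#'   `season_complete`, `flowering`, `maturity` (one row per combination and
#'   indicator).
#' @export
grid_scan <- function(series, template, tsum1_values, tsum2_values,
                      ids = c(5, 16), ...) {
  stopifnot(inherits(template, "variety_params_2phase"))
  if (length(tsum1_values) == 0 || length(tsum2_values) == 0)
    val_err("tsum value lists must be non-empty")
  out <- list()
  for (t1 in tsum1_values) for (t2 in tsum2_values) {
    p <- template; p$tsum1 <- t1; p$tsum2 <- t2
    track <- simulate_2phase(series, p)
    res <- compute_indicators(series, ids = ids, track = track, ...)
    sd <- stage_dates(track)
    res$tsum1 <- t1; res$tsum2 <- t2
    res$flowering <- sd[["flowering"]]; res$maturity <- sd[["maturity"]]
    out[[length(out) + 1]] <- res
  }
  df <- do.call(rbind, out)
  df[c("tsum1", "tsum2", "id", "value", "risk_class", "season_complete",
       "flowering", "maturity")]
}

#' Genetic-algorithm configuration
#'
#' Defaults follow common practice for small real-valued problems: population
#' 50, 200 generations, tournament selection (size 3), uniform crossover
#' (probability 0.9), per-gene Gaussian mutation (probability 0.1, SD 10% of
#' the gene range) and elitism 1 (the best individual always survives, so the
#' best fitness is non-decreasing across generations).
#'
#' @param population_size Individuals per generation (>= 2).
#' @param n_generations Number of generations.
#' @param crossover_prob Probability a child is formed by uniform crossover.
#' @param mutation_prob Per-gene mutation probability.
#' @param mutation_sd_frac Mutation SD as a fraction of each gene's range.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism Number of best individuals copied unchanged.
#' @param seed Integer RNG seed; same seed and inputs give identical results.
#' @param indicator_ids Indicators entering the fitness (default 4, 5, 15,
#'   16: pre-flowering hydrological balance and heat stress around grain
#'   filling).
#' @param weights Named or positional weights per indicator (default 1 each).
#' @param spei_band Half-width of the no-penalty SPEI band (default 1:
#'   hydrological indicators between -1 and 1 are unpenalized).
#' @param incomplete_penalty Penalty when the season does not reach maturity
#'   (default 10, dominating any feasible penalty).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50, n_generations = 200,
                      crossover_prob = 0.9, mutation_prob = 0.1,
                      mutation_sd_frac = 0.1, tournament_size = 3,
                      elitism = 1, seed = 1L,
                      indicator_ids = c(4, 5, 15, 16), weights = NULL,
                      spei_band = 1, incomplete_penalty = 10) {
  if (population_size < 2) val_err("population_size must be >= 2")
  if (any(c(crossover_prob, mutation_prob) < 0 |
            c(crossover_prob, mutation_prob) > 1))
    val_err("probabilities must be in [0, 1]")
  weights <- weights %||% rep(1, length(indicator_ids))
  if (length(weights) != length(indicator_ids))
    val_err("weights must match indicator_ids in length")
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 mutation_sd_frac = mutation_sd_frac,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism), seed = as.integer(seed),
                 indicator_ids = indicator_ids, weights = weights,
                 spei_band = spei_band,
                 incomplete_penalty = incomplete_penalty),
            class = "ga_config")
}

#' Default per-sub-phase TSUM search bounds
#' @return List with numeric `lower` and `upper` (length 6, GDD), the ranges
#'   of [subphase_parameter_table()].
#' @export
subphase_bounds <- function() {
  tab <- subphase_parameter_table()
  list(lower = tab$tsum_min, upper = tab$tsum_max)
}

#' Fitness of a six-sub-phase thermal-requirement chromosome
#'
#' Simulates the multi-phase phenology for the candidate TSUMs and scores the
#' season: each selected hydrological indicator contributes a hinge penalty
#' `max(0, |SPEI| - spei_band)`; each day-count indicator contributes its
#' count divided by its window length (fraction of the window under stress);
#' a rainfall cumulate contributes its value divided by the window length in
#' mm/day. Penalties are weighted and summed; the fitness is their negated
#' sum, so 0 is the best attainable score. A season that does not reach
#' maturity scores `-incomplete_penalty`.
#'
#' @param tsum Numeric length-6 chromosome, GDD; must lie within `bounds`.
#' @param series A multi-year [weather_series()].
#' @param template A [variety_params_multi()] providing sowing date, base
#'   temperatures and factor settings; its `tsum` is overwritten.
#' @param config A [ga_config()].
#' @param bounds List with `lower`/`upper` (length 6); chromosomes outside
#'   are an error. NULL skips the check.
#' @param balance Optional precomputed [climatic_water_balance()].
#' @return List: `total` (scalar fitness, <= 0), `penalties` (data.frame id,
#'   penalty), `complete` (logical).
#' @export
variety_fitness <- function(tsum, series, template, config = ga_config(),
                            bounds = subphase_bounds(), balance = NULL) {
  stopifnot(inherits(template, "variety_params_multi"))
  if (!is.null(bounds) &&
      (any(tsum < bounds$lower - 1e-9) || any(tsum > bounds$upper + 1e-9)))
    val_err("chromosome outside bounds")
  p <- template; p$tsum <- as.numeric(tsum)
  track <- simulate_multiphase(series, p)
  if (!attr(track, "complete")) {
    return(list(total = -config$incomplete_penalty,
                penalties = data.frame(id = NA_integer_,
                                       penalty = config$incomplete_penalty),
                complete = FALSE))
  }
  res <- compute_indicators(series, ids = config$indicator_ids, track = track,
                            balance = balance, spei_warn = FALSE)
  pen <- mapply(function(i, w) {
    row <- res[res$id == i, ]
    if (is.na(row$value)) return(config$incomplete_penalty)
    wlen <- as.numeric(row$window_end - row$window_start) + 1
    p0 <- if (row$statistic == "spei") max(0, abs(row$value) - config$spei_band)
          else row$value / wlen
    w * p0
  }, config$indicator_ids, config$weights)
  list(total = -sum(pen),
       penalties = data.frame(id = config$indicator_ids, penalty = pen),
       complete = TRUE)
}

snap_to_levels <- function(x, levels_list) {
  vapply(seq_along(x), function(j) {
    lv <- levels_list[[j]]
    lv[which.min(abs(lv - x[j]))]
  }, numeric(1))
}

ga_engine <- function(eval_fn, bounds, config, discretize = NULL) {
  lower <- bounds$lower; upper <- bounds$upper
  if (any(lower > upper)) val_err("infeasible bounds (lower > upper)")
  ng <- length(lower)
  levels_list <- if (!is.null(discretize))
    lapply(seq_len(ng), function(j) seq(lower[j], upper[j],
                                        length.out = discretize))
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fit1 <- function(genes) {
    key <- paste(signif(genes, 10), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    v <- eval_fn(genes)
    cache[[key]] <- v
    v
  }
  with_local_seed(config$seed, {
    np <- config$population_size
    pop <- t(vapply(seq_len(np), function(i) {
      g <- stats::runif(ng, lower, upper)
      if (!is.null(levels_list)) g <- snap_to_levels(g, levels_list)
      g
    }, numeric(ng)))
    trace <- data.frame(generation = integer(0), best = numeric(0),
                        mean = numeric(0), median = numeric(0))
    best_genes <- NULL; best_fit <- -Inf
    for (gen in seq_len(config$n_generations)) {
      fit <- apply(pop, 1, fit1)
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_genes <- pop[which.max(fit), ]
      }
      trace <- rbind(trace, data.frame(generation = gen, best = best_fit,
                                       mean = mean(fit),
                                       median = stats::median(fit)))
      if (gen == config$n_generations) break
      ord <- order(fit, decreasing = TRUE)
      newpop <- matrix(NA_real_, np, ng)
      ne <- min(config$elitism, np)
      if (ne > 0) newpop[seq_len(ne), ] <- pop[ord[seq_len(ne)], , drop = FALSE]
      for (i in if (ne < np) (ne + 1):np else integer(0)) {
        pick <- function() {
          cand <- sample.int(np, config$tournament_size, replace = TRUE)
          cand[which.max(fit[cand])]
        }
        p1 <- pop[pick(), ]
        child <- if (stats::runif(1) < config$crossover_prob) {
          p2 <- pop[pick(), ]
          mask <- stats::runif(ng) < 0.5
          ifelse(mask, p1, p2)
        } else p1
        mut <- stats::runif(ng) < config$mutation_prob
        if (any(mut)) {
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0,
                         config$mutation_sd_frac * (upper[mut] - lower[mut]))
          child <- clamp(child, lower, upper)
        }
        if (!is.null(levels_list)) child <- snap_to_levels(child, levels_list)
        newpop[i, ] <- child
      }
      pop <- newpop
    }
    list(best = best_genes, best_fitness = best_fit, trace = trace,
         n_evaluations = n_eval)
  })
}

#' Genetic-algorithm search for optimal sub-phase thermal requirements
#'
#' Searches the six-dimensional TSUM space for the variety whose simulated
#' season minimizes the selected climate-impact penalties ([variety_fitness()]
#' is the objective). Real-valued genes within `bounds`; tournament
#' selection, uniform crossover, Gaussian mutation, elitism. Fully
#' deterministic given `config$seed`.
#'
#' @inheritParams variety_fitness
#' @param bounds List with `lower`/`upper` per gene (default the
#'   [subphase_parameter_table()] ranges).
#' @param discretize Optional integer: restrict each gene to this many evenly
#'   spaced levels between its bounds (used to compare against exhaustive
#'   enumeration).
#' @return List: `best_tsum`, `best_fitness`, `best_params`, `track` (the
#'   best variety's phenology), `trace` (per-generation best/mean/median
#'   fitness), `n_evaluations` (distinct chromosomes evaluated).
#' @export
ga_optimize <- function(series, template, bounds = subphase_bounds(),
                        config = ga_config(), discretize = NULL,
                        balance = NULL) {
  if (is.null(balance) &&
      any(indicator_registry()$statistic[
        indicator_registry()$id %in% config$indicator_ids] == "spei"))
    balance <- climatic_water_balance(series)
  eval_fn <- function(genes)
    variety_fitness(genes, series, template, config, bounds = NULL,
                    balance = balance)$total
  out <- ga_engine(eval_fn, bounds, config, discretize)
  p <- template; p$tsum <- out$best
  list(best_tsum = out$best, best_fitness = out$best_fitness,
       best_params = p, track = simulate_multiphase(series, p),
       trace = out$trace, n_evaluations = out$n_evaluations)
}

#' GA search over a weather ensemble
#'
#' Identical to [ga_optimize()] but the objective is the unweighted mean of
#' the per-member fitness: every ensemble member counts equally when
#' searching for the optimal variety.
#'
#' @param ensemble A [weather_ensemble()].
#' @inheritParams ga_optimize
#' @return As [ga_optimize()], with `track` computed on the first member.
#' @export
ga_optimize_ensemble <- function(ensemble, template,
                                 bounds = subphase_bounds(),
                                 config = ga_config(), discretize = NULL) {
  if (!inherits(ensemble, "weather_ensemble")) val_err("not a weather_ensemble")
  needs_spei <- any(indicator_registry()$statistic[
    indicator_registry()$id %in% config$indicator_ids] == "spei")
  balances <- if (needs_spei)
    lapply(ensemble$members, climatic_water_balance) else
    vector("list", length(ensemble$members))
  eval_fn <- function(genes) {
    mean(vapply(seq_along(ensemble$members), function(m)
      variety_fitness(genes, ensemble$members[[m]], template, config,
                      bounds = NULL, balance = balances[[m]])$total,
      numeric(1)))
  }
  out <- ga_engine(eval_fn, bounds, config, discretize)
  p <- template; p$tsum <- out$best
  list(best_tsum = out$best, best_fitness = out$best_fitness,
       best_params = p,
       track = simulate_multiphase(ensemble$members[[1]], p),
       trace = out$trace, n_evaluations = out$n_evaluations)
}
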