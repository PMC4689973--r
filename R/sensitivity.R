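#' Specify a one-way deterministic sensitivity parameter
#'
#' @param path Parameter path (see [param_get()]).
#' @param low,high Bound values; if omitted they default to 25% below and
#'   above the base-case value at run time.
#' @param label Display label (defaults to the path).
#' @return Object of class `osteo_dsa_spec`.
#' @export
dsa_spec <- function(path, low = NULL, high = NULL, label = path) {
  structure(list(path = path, low = low, high = high, label = label),
            class = "osteo_dsa_spec")
}

# Default tornado parameters for a pairwise comparison: efficacy of both
# strategies, their drug costs, fracture and nursing-home costs, the LTC
# admission fraction, utility multipliers, and the injectable
# discontinuation hazard ratio.
default_dsa_specs <- function(config,
                              comparison = c("generic_alendronate",
                                             "denosumab")) {
  paths <- character()
  for (s in comparison) {
    paths <- c(paths,
               paste0("strategies.", s, ".rr.", FRACTURE_SITES),
               paste0("strategies.", s, ".annual_drug_cost"))
    if (config$strategies[[s]]$persistence_class ==
        "injectable_hr_adjusted") {
      paths <- c(paths, paste0("strategies.", s, ".hazard_ratio"))
    }
  }
  paths <- c(paths,
             paste0("costs.fracture_year1.", FRACTURE_SITES),
             "costs.hip_subsequent_annual",
             "costs.ltc_daily",
             "costs.ltc_admission_fraction",
             paste0("utilities.multiplier_year1.", FRACTURE_SITES),
             "utilities.multiplier_later.hip",
             "utilities.multiplier_later.vertebral")
  lapply(paths, dsa_spec)
}

# Pairwise incremental result between two strategies under a configuration.
pairwise_icer <- function(config, comparison) {
  ref <- run_strategy(config, comparison[1])
  alt <- run_strategy(config, comparison[2])
  dc <- alt$cost - ref$cost
  dq <- alt$qalys - ref$qalys
  note <- if (dq > 0 && dc <= 0) {
    "comparator_dominates"
  } else if (dq <= 0 && dc >= 0) {
    "comparator_dominated"
  } else if (dq < 0 && dc < 0) {
    "southwest"
  } else {
    ""
  }
  ratio <- if (dq == 0) sign(dc) * Inf else dc / dq
  list(icer = ratio, note = note, delta_cost = dc, delta_qalys = dq)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the pairwise comparison with each parameter at its low and high
#' bound, all else fixed at base case, and records the resulting ICER of
#' `comparison[2]` versus `comparison[1]`.  Rows are sorted by ICER range
#' width, widest first.  Dominance cases are annotated: the raw cost/QALY
#' ratio is always reported, with a `note` column flagging quadrants in
#' which it is not interpretable as a conventional ICER.
#'
#' @param config Model configuration.
#' @param specs List of [dsa_spec()]s (defaults to a standard tornado set).
#' @param comparison Character vector of two strategy names,
#'   reference first.
#' @return Data frame of class `osteo_tornado`: parameter, bounds,
#'   ICERs and notes at each bound, base ICER, and range width.
#' @export
one_way_dsa <- function(config, specs = default_dsa_specs(config),
                        comparison = c("generic_alendronate", "denosumab")) {
  for (s in comparison) {
    if (is.null(config$strategies[[s]])) {
      stop("unknown strategy in comparison: ", s, call. = FALSE)
    }
  }
  base <- pairwise_icer(config, comparison)
  rows <- lapply(specs, function(spec) {
    base_val <- param_get(config, spec$path)
    lo <- spec$low %||% (0.75 * base_val)
    hi <- spec$high %||% (1.25 * base_val)
    at <- function(v) {
      pairwise_icer(param_set(config, spec$path, v), comparison)
    }
    r_lo <- at(lo)
    r_hi <- at(hi)
    data.frame(parameter = spec$label, base_value = base_val,
               low_value = lo, high_value = hi,
               icer_low = r_lo$icer, icer_high = r_hi$icer,
               note_low = r_lo$note, note_high = r_hi$note,
               icer_base = base$icer,
               width = abs(r_hi$icer - r_lo$icer))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("osteo_tornado", "data.frame")
  out
}

#' Rerun the analysis under named parameter overrides
#'
#' @param config Model configuration.
#' @param overrides Named list: parameter paths mapped to replacement
#'   values.  Empty overrides reproduce the base-case analysis.
#' @return An `osteo_cea` (see [run_cea()]).
#' @export
scenario <- function(config, overrides = list()) {
  for (path in names(overrides)) {
    config <- param_set(config, path, overrides[[path]])
  }
  run_cea(validate_config(config))
}

#' Packaged scenario analyses
#'
#' Override sets mirroring the standard scenario analyses: generic pricing
#' of zoledronate (65% of base cost) and risedronate (35% of base cost),
#' long offset times (5 years for bisphosphonates, 2.5 for teriparatide,
#' 2 for denosumab), and a 1-year denosumab offset.
#'
#' @param config Model configuration (base prices are read from it).
#' @return Named list of override lists, each usable with [scenario()].
#' @export
preset_scenarios <- function(config) {
  price <- function(s) config$strategies[[s]]$annual_drug_cost
  list(
    generic_zoledronate = list(
      "strategies.zoledronate.annual_drug_cost" = 0.65 * price("zoledronate")
    ),
    generic_risedronate = list(
      "strategies.risedronate.annual_drug_cost" = 0.35 * price("risedronate")
    ),
    long_offset = list(
      "strategies.generic_alendronate.offset_years" = 5,
      "strategies.risedronate.offset_years" = 5,
      "strategies.ibandronate.offset_years" = 5,
      "strategies.zoledronate.offset_years" = 5,
      "strategies.teriparatide.offset_years" = 2.5,
      "strategies.denosumab.offset_years" = 2
    ),
    short_denosumab_offset = list(
      "strategies.denosumab.offset_years" = 1
    )
  )
}

#' Specify a probabilistic sensitivity parameter
#'
#' Distribution families follow parameter support: lognormal for relative
#' risks and hazard ratios, gamma for costs, beta for utilities and
#' proportions.  Dispersion defaults to a standard error of 25% of the
#' central value when no CI is given; a lognormal spec may instead give a
#' 95% CI from which the log-scale moments are derived.
#'
#' @param path Parameter path, or a character vector of paths that share a
#'   single draw (e.g. one discontinuation hazard ratio applied to every
#'   injectable strategy).
#' @param family `"lognormal"`, `"gamma"` or `"beta"`.
#' @param mean Central value (defaults at build time to the configuration
#'   value via [default_psa_specs()]).
#' @param se Standard error (0 gives a degenerate, point-mass parameter).
#' @param ci Optional 95% CI `c(low, high)` (lognormal only).
#' @param label Display label.
#' @return Object of class `osteo_psa_spec`.
#' @export
psa_spec <- function(path, family = c("lognormal", "gamma", "beta"),
                     mean, se = NULL, ci = NULL, label = path[1]) {
  family <- match.arg(family)
  if (!is.null(ci)) {
    if (family != "lognormal" || length(ci) != 2L || any(ci <= 0) ||
        ci[1] >= ci[2]) {
      stop("ci must be an increasing positive pair, lognormal family only",
           call. = FALSE)
    }
  }
  if (is.null(se)) se <- if (is.null(ci)) 0.25 * mean else NA_real_
  if (!is.null(ci)) se <- NA_real_
  if (family %in% c("lognormal", "gamma") && mean <= 0) {
    stop("mean must be positive for ", family, " parameters", call. = FALSE)
  }
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) {
      stop("beta parameters need mean in (0, 1)", call. = FALSE)
    }
    if (!is.na(se) && se > 0 && se^2 >= mean * (1 - mean)) {
      stop("invalid dispersion: se^2 must be below mean * (1 - mean)",
           call. = FALSE)
    }
  }
  if (!is.na(se) && se < 0) stop("invalid dispersion: se must be >= 0",
                                 call. = FALSE)
  structure(list(path = path, family = family, mean = mean, se = se,
                 ci = ci, label = label),
            class = "osteo_psa_spec")
}

# Draw n values from a PSA spec (moment-matched to mean/se, or CI-derived
# on the log scale).
sample_psa_spec <- function(spec, n) {
  if (!is.null(spec$ci)) {
    meanlog <- mean(log(spec$ci))
    sdlog <- (log(spec$ci[2]) - log(spec$ci[1])) / (2 * qnorm(0.975))
    return(rlnorm(n, meanlog, sdlog))
  }
  m <- spec$mean
  s <- spec$se
  if (s == 0) return(rep(m, n))
  switch(spec$family,
    lognormal = {
      sdlog <- sqrt(log(1 + (s / m)^2))
      rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
    },
    gamma = rgamma(n, shape = (m / s)^2, rate = m / s^2),
    beta = {
      nu <- m * (1 - m) / s^2 - 1
      rbeta(n, m * nu, (1 - m) * nu)
    }
  )
}

#' Default probabilistic sensitivity parameter set
#'
#' The parameters sampled in the packaged PSA: on-treatment fracture
#' relative risks of every strategy (lognormal), first-year fracture and
#' subsequent-year hip costs (gamma), fracture utility multipliers (beta),
#' the injectable discontinuation hazard ratio (lognormal, one draw shared
#' by all injectable strategies), and the long-term-care admission fraction
#' (beta).  All dispersions default to 25% of the central value.
#'
#' @param config Model configuration supplying central values.
#' @return List of [psa_spec()]s.
#' @export
default_psa_specs <- function(config) {
  specs <- list()
  for (s in names(config$strategies)) {
    for (site in FRACTURE_SITES) {
      specs <- c(specs, list(psa_spec(
        paste0("strategies.", s, ".rr.", site), "lognormal",
        mean = config$strategies[[s]]$rr[[site]]
      )))
    }
  }
  for (site in FRACTURE_SITES) {
    specs <- c(specs, list(psa_spec(
      paste0("costs.fracture_year1.", site), "gamma",
      mean = config$costs$fracture_year1[[site]]
    )))
  }
  specs <- c(specs, list(psa_spec(
    "costs.hip_subsequent_annual", "gamma",
    mean = config$costs$hip_subsequent_annual
  )))
  for (site in FRACTURE_SITES) {
    specs <- c(specs, list(psa_spec(
      paste0("utilities.multiplier_year1.", site), "beta",
      mean = config$utilities$multiplier_year1[[site]]
    )))
  }
  for (site in c("hip", "vertebral")) {
    specs <- c(specs, list(psa_spec(
      paste0("utilities.multiplier_later.", site), "beta",
      mean = config$utilities$multiplier_later[[site]]
    )))
  }
  injectables <- names(config$strategies)[vapply(
    config$strategies,
    function(s) s$persistence_class == "injectable_hr_adjusted", logical(1)
  )]
  if (length(injectables)) {
    specs <- c(specs, list(psa_spec(
      paste0("strategies.", injectables, ".hazard_ratio"), "lognormal",
      mean = config$strategies[[injectables[1]]]$hazard_ratio,
      label = "discontinuation_hazard_ratio"
    )))
  }
  specs <- c(specs, list(psa_spec(
    "costs.ltc_admission_fraction", "beta",
    mean = config$costs$ltc_admission_fraction
  )))
  specs
}

#' Probabilistic sensitivity analysis
#'
#' Draws all parameters jointly and independently (parameter-major
#' sampling from a single seeded generator, so draw `i` of one parameter
#' does not depend on how many other parameters are in the spec list),
#' reruns the full model for each draw, and returns per-draw strategy
#' totals.
#'
#' @param config Model configuration.
#' @param specs List of [psa_spec()]s.
#' @param n_draws Number of PSA iterations.
#' @param seed Integer seed (reproducible: the same seed yields the same
#'   draw matrix and totals).
#' @param strategies Optional subset of strategy names.
#' @return Data frame of class `osteo_psa` (`draw`, `strategy`, `cost`,
#'   `qalys`, `lys`), with the draw matrix in attribute `"draws"`.
#' @export
psa <- function(config, specs = default_psa_specs(config),
                n_draws = config$run_settings$psa_draws,
                seed = config$run_settings$psa_seed,
                strategies = NULL) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  strategies <- strategies %||% names(config$strategies)
  set.seed(seed)
  draws <- vapply(specs, sample_psa_spec, numeric(n_draws), n = n_draws)
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- vapply(specs, `[[`, "", "label")

  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    cfg <- config
    for (j in seq_along(specs)) {
      for (path in specs[[j]]$path) {
        cfg <- param_set(cfg, path, draws[i, j])
      }
    }
    tot <- lapply(strategies, function(s) run_strategy(cfg, s))
    rows[[i]] <- data.frame(
      draw = i,
      strategy = vapply(tot, `[[`, "", "strategy"),
      cost = vapply(tot, `[[`, numeric(1), "cost"),
      qalys = vapply(tot, `[[`, numeric(1), "qalys"),
      lys = vapply(tot, `[[`, numeric(1), "lys")
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  class(out) <- c("osteo_psa", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws in
#' which each strategy attains the maximal net monetary benefit (ties split
#' equally).  Probabilities partition to 1 at every threshold.
#'
#' @param draws An `osteo_psa` data frame (or any data frame with `draw`,
#'   `strategy`, `cost`, `qalys`).
#' @param thresholds Numeric vector of thresholds (USD/QALY).
#' @return Data frame (`threshold`, `strategy`, `probability`).
#' @export
ceac <- function(draws, thresholds = seq(0, 2e5, by = 1e4)) {
  strategies <- unique(draws$strategy)
  cost <- matrix(draws$cost[order(draws$draw, match(draws$strategy,
                                                    strategies))],
                 ncol = length(strategies), byrow = TRUE)
  qaly <- matrix(draws$qalys[order(draws$draw, match(draws$strategy,
                                                     strategies))],
                 ncol = length(strategies), byrow = TRUE)
  out <- lapply(thresholds, function(th) {
    benefit <- th * qaly - cost
    best <- apply(benefit, 1L, max)
    win <- benefit >= best - 1e-9
    win <- win / rowSums(win)
    data.frame(threshold = th, strategy = strategies,
               probability = colMeans(win))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
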