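#' Six-month discontinuation probability for a strategy
#'
#' Oral-reference strategies follow the discontinuation schedule directly.
#' Injectable strategies (denosumab, zoledronate, teriparatide) transform
#' each oral probability through proportional hazards,
#' \eqn{p' = 1 - (1 - p)^{HR}}, using the strategy's discontinuation hazard
#' ratio (0.5 for the packaged injectables, from the denosumab-vs-oral
#' adherence trial).  Beyond cycle 6 (year 3) discontinuation before
#' planned termination is assumed not to occur, so the probability is 0.
#'
#' @param strategy An `osteo_strategy`.
#' @param schedule Numeric vector of six oral 6-month discontinuation
#'   probabilities (cycles 1-6).
#' @param cycle Cycle index (vectorised), 1-based.
#' @return 6-month discontinuation probability per cycle.
#' @export
discontinuation_probability <- function(strategy, schedule, cycle) {
  if (any(cycle < 1)) stop("cycle must be >= 1", call. = FALSE)
  p <- numeric(length(cycle))
  in_sched <- cycle <= length(schedule)
  p[in_sched] <- schedule[cycle[in_sched]]
  if (strategy$persistence_class == "injectable_hr_adjusted") {
    p <- 1 - (1 - p)^strategy$hazard_ratio
  }
  p
}

#' Partition a strategy's cohort into discontinuation subcohorts
#'
#' Because discontinuation is assumed independent of health state, the
#' cohort can be decomposed exactly into subcohorts by discontinuation
#' time: one per possible discontinuation cycle (1-6, applied at cycle
#' start) plus a completer subcohort that stays on treatment until planned
#' termination (`2 * max_treatment_years` cycles).  Weights are the exact
#' probabilities of each discontinuation time and sum to 1.
#'
#' Each subcohort carries its effective offset duration: the residual
#' efficacy period after stopping equals the strategy's offset duration
#' capped at the time actually spent on treatment (rounded up to whole
#' years); patients who drop out in the very first cycle receive no offset.
#'
#' @inheritParams discontinuation_probability
#' @param n_cycles Model horizon in cycles (on-treatment flags are filled
#'   to this length).
#' @return List of subcohort profiles (class `osteo_subcohort`): `id`,
#'   `weight`, `stop_cycle` (first cycle off treatment), `on` (logical per
#'   cycle), `years_on`, `offset_years`.
#' @export
build_subcohorts <- function(strategy, schedule, n_cycles = 64L) {
  n_sched <- length(schedule)
  p <- discontinuation_probability(strategy, schedule, seq_len(n_sched))
  persist <- cumprod(1 - p)
  weights <- c(p[1], p[-1] * persist[-n_sched])
  planned_stop <- 2L * strategy$max_treatment_years + 1L

  make <- function(id, weight, stop_cycle) {
    stop_cycle <- min(stop_cycle, planned_stop)
    years_on <- 0.5 * (stop_cycle - 1L)
    offset <- if (years_on == 0) 0 else {
      min(strategy$offset_years, ceiling(years_on))
    }
    structure(list(id = id, weight = weight, stop_cycle = stop_cycle,
                   on = seq_len(n_cycles) < stop_cycle,
                   years_on = years_on, offset_years = offset),
              class = "osteo_subcohort")
  }

  subs <- lapply(seq_len(n_sched), function(d) {
    make(paste0("dropout_cycle_", d), weights[d], d)
  })
  subs[[n_sched + 1L]] <- make("completer", persist[n_sched], planned_stop)
  subs
}

#' Effective fracture relative risk for a subcohort at a cycle
#'
#' While on treatment the strategy's on-treatment RR applies.  After
#' stopping, the RR decays linearly from the treatment value to 1 over the
#' subcohort's effective offset duration (evaluated at cycle start), and is
#' exactly 1 once the offset has elapsed (immediately, for first-cycle
#' dropouts who receive no offset).
#'
#' @param strategy An `osteo_strategy`.
#' @param subcohort A profile from [build_subcohorts()].
#' @param cycle Cycle index (vectorised).
#' @param site Fracture site.
#' @return Effective relative risk in `[rr, 1]`.
#' @export
effective_rr <- function(strategy, subcohort, cycle, site) {
  site <- match.arg(site, FRACTURE_SITES)
  rr <- strategy$rr[[site]]
  on <- cycle < subcohort$stop_cycle
  t_since <- pmax(0, 0.5 * (cycle - subcohort$stop_cycle))
  O <- subcohort$offset_years
  waned <- if (O <= 0) rep(1, length(cycle)) else pmin(1, t_since / O)
  ifelse(on, rr, ifelse(waned >= 1, 1, rr + (1 - rr) * waned))
}

# Effective RR paths for all sites: n_cycles x 3 matrix.
rr_path <- function(strategy, subcohort, n_cycles) {
  vapply(FRACTURE_SITES, function(site) {
    effective_rr(strategy, subcohort, seq_len(n_cycles), site)
  }, numeric(n_cycles))
}

#' One-year treatment persistence
#'
#' Probability of still being on treatment after two 6-month cycles:
#' the product of (1 - discontinuation probability) over cycles 1-2.  For
#' the packaged denosumab strategy (hazard ratio 0.5 applied to the oral
#' schedule) this is 73.6%.
#'
#' @inheritParams discontinuation_probability
#' @return Proportion persistent at one year.
#' @export
one_year_persistence <- function(strategy, schedule) {
  prod(1 - discontinuation_probability(strategy, schedule, 1:2))
}
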