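DAYS_PER_CYCLE <- 365.25 / 2

#' Discount factor at a cycle
#'
#' Half-yearly compounding of an annual rate: `(1 + rate)^(-cycle / 2)`.
#'
#' @param cycle Cycle index (0 = model start; vectorised).
#' @param annual_rate Annual discount rate (e.g. 0.03).
#' @return Discount factor(s).
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (annual_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle / 2)
}

# Per-state utility multipliers implied by the fracture-state structure:
# year-1 multipliers in the tunnels, later-year multipliers in the post
# states (1 for post-NHNV), 1 in `well`, 0 when dead.
state_utility_multipliers <- function(utilities, space) {
  m1 <- utilities$multiplier_year1
  m2 <- utilities$multiplier_later
  mult <- setNames(rep(1, space$n), space$states)
  for (site in FRACTURE_SITES) {
    y1a <- space$y1a[[site]]
    y1b <- space$residual[[y1a]]
    post <- space$residual[[y1b]]
    mult[c(y1a, y1b)] <- m1[[site]]
    mult[post] <- m2[[site]]
  }
  mult["dead"] <- 0
  mult
}

#' Quality-adjusted life-years accrued in one cycle
#'
#' Half a year weighted by age-specific baseline utility and the
#' state-specific fracture multiplier, summed over live-state occupancy.
#'
#' @param occupancy Named occupancy vector over the state space.
#' @param age Age used for the baseline-utility lookup.
#' @param config Model configuration.
#' @param space State space (rebuilt if omitted).
#' @return Undiscounted QALYs for the cycle.
#' @export
cycle_qalys <- function(occupancy, age, config,
                        space = build_state_space()) {
  u <- baseline_utility_at(config$utilities$baseline, age)
  mult <- state_utility_multipliers(config$utilities, space)
  0.5 * u * sum(occupancy * mult[names(occupancy)])
}

# Internal per-subcohort simulation: trace, incident events, long-term-care
# occupancy, and undiscounted per-cycle cost components / QALYs / LYs.
simulate_subcohort <- function(strategy, sub, shared) {
  n <- shared$n
  space <- shared$space
  rrs <- rr_path(strategy, sub, n)

  builder <- function(k) {
    rr3 <- rrs[k, ]
    if (all(rr3 == 1)) {
      if (is.null(shared$env$untreated[[k]])) {
        shared$env$untreated[[k]] <- assemble_matrix(
          space, shared$p_death_states[k, ], shared$p6[k, ])
      }
      shared$env$untreated[[k]]
    } else {
      assemble_matrix(space, shared$p_death_states[k, ], rr3 * shared$p6[k, ])
    }
  }

  run <- run_cohort(shared$initial, builder, n,
                    event_cols = shared$event_cols,
                    event_sources = shared$event_sources)
  trace <- run$trace
  events <- run$events

  i_dead <- space$idx[["dead"]]
  i_post_hip <- space$idx[["post_hip"]]
  occ_start <- trace[seq_len(n), , drop = FALSE]
  occ_end <- trace[seq_len(n) + 1L, , drop = FALSE]
  hcc <- isTRUE(shared$half_cycle_correction)
  occ_rew <- if (hcc) (occ_start + occ_end) / 2 else occ_end
  alive_pay <- if (hcc) {
    1 - (occ_start[, i_dead] + occ_end[, i_dead]) / 2
  } else {
    1 - occ_start[, i_dead]
  }

  # long-term-care occupancy: permanent admissions from incident hip
  # fractures, depleted by post-hip-state mortality
  ltc <- numeric(n)
  prev <- 0
  for (k in seq_len(n)) {
    prev <- prev * (1 - shared$p_death_posthip[k]) +
      shared$ltc_fraction * events[k, "hip"]
    ltc[k] <- prev
  }

  on <- sub$on
  drug <- on * alive_pay * strategy$annual_drug_cost / 2
  admin_rate <- sum(strategy$admin_events$unit_cost *
                      strategy$admin_events$events_per_year) +
    shared$monitoring_rate
  admin <- on * alive_pay * admin_rate / 2
  frac_y1 <- as.numeric(events %*% shared$cost_year1)
  hip_sub <- occ_rew[, i_post_hip] * shared$hip_subsequent_annual / 2
  ltc_cost <- ltc * shared$ltc_daily * DAYS_PER_CYCLE

  qalys <- 0.5 * shared$u_age * as.numeric(occ_rew %*% shared$state_mult)
  lys <- 0.5 * (1 - occ_rew[, i_dead])

  list(trace = trace, events = events, ltc = ltc,
       drug = drug, admin = admin, frac_y1 = frac_y1,
       hip_sub = hip_sub, ltc_cost = ltc_cost,
       qalys = qalys, lys = lys)
}

# Precompute everything shared across subcohorts of one model run.
make_shared <- function(config, space) {
  pop <- config$population
  n <- as.integer(round((pop$max_age - pop$start_age) / 0.5))
  ages <- pop$start_age + 0.5 * (seq_len(n) - 1L)   # age at cycle start
  terminal <- ages + 0.5 >= pop$max_age

  q_ann <- vapply(ages, life_table_q, numeric(1),
                  life_table = config$mortality$life_table,
                  max_age = pop$max_age)
  p_death_base <- ifelse(terminal | q_ann >= 1, 1,
                         1 - (1 - q_ann)^0.5)
  rr_mort <- state_mortality_rr(config$mortality, space)
  p_death_states <- pmin(outer(p_death_base, rr_mort), 1)
  colnames(p_death_states) <- space$states

  p6 <- vapply(FRACTURE_SITES, function(site) {
    vapply(ages, function(a) {
      prob_rate_convert(incidence_for_age(config$epidemiology, a, site),
                        1, 0.5)
    }, numeric(1))
  }, numeric(n))

  initial <- setNames(numeric(space$n), space$states)
  initial["post_vert"] <- pop$prevalent_vertebral_fraction
  initial["well"] <- 1 - pop$prevalent_vertebral_fraction

  event_cols <- space$idx[space$y1a]
  names(event_cols) <- FRACTURE_SITES
  event_sources <- if (isTRUE(config$run_settings$count_all_events)) {
    NULL
  } else {
    lapply(FRACTURE_SITES, function(site) {
      which(is.na(space$site_of) & space$states != "dead" |
              (!is.na(space$site_of) & space$site_of != site))
    })
  }

  ages_end <- pop$start_age + 0.5 * seq_len(n)
  u_age <- vapply(ages_end, baseline_utility_at, numeric(1),
                  baseline = config$utilities$baseline)

  list(
    n = n, space = space, initial = initial,
    p_death_states = p_death_states,
    p_death_posthip = p_death_states[, "post_hip"],
    p6 = p6,
    event_cols = event_cols, event_sources = event_sources,
    u_age = u_age,
    state_mult = state_utility_multipliers(config$utilities, space),
    cost_year1 = config$costs$fracture_year1[FRACTURE_SITES],
    hip_subsequent_annual = config$costs$hip_subsequent_annual,
    ltc_daily = config$costs$ltc_daily,
    ltc_fraction = config$costs$ltc_admission_fraction,
    monitoring_rate = sum(config$costs$monitoring$unit_cost *
                            config$costs$monitoring$events_per_year),
    half_cycle_correction = config$run_settings$half_cycle_correction,
    df_costs = discount_factor(seq_len(n),
                               config$run_settings$discount_rate_costs),
    df_effects = discount_factor(seq_len(n),
                                 config$run_settings$discount_rate_effects),
    env = local({
      e <- new.env(parent = emptyenv())
      e$untreated <- vector("list", n)
      e
    })
  )
}

#' Run one treatment strategy through the lifetime model
#'
#' Builds the discontinuation subcohorts, simulates each through the Markov
#' engine with its own effective-RR path, and accumulates weight-averaged
#' discounted lifetime costs (by component), QALYs, life-years, and
#' undiscounted 10-year fracture risks.
#'
#' @param config Model configuration.
#' @param strategy Strategy name (looked up in the configuration) or an
#'   `osteo_strategy`.
#' @param keep_trace If `TRUE`, attach the weight-averaged occupancy trace
#'   and incident-event matrix.
#' @return An object of class `osteo_totals`: `strategy`, discounted `cost`
#'   with a `components` breakdown (drug, administration + monitoring,
#'   first-year fracture, subsequent-year hip, long-term care), discounted
#'   `qalys` and `lys`, and `risk10` (cumulative incident fracture events
#'   per initial cohort member over the first 20 cycles, by site).
#' @export
run_strategy <- function(config, strategy, keep_trace = FALSE) {
  if (is.character(strategy)) {
    if (is.null(config$strategies[[strategy]])) {
      stop("unknown strategy: ", strategy, call. = FALSE)
    }
    strategy <- config$strategies[[strategy]]
  }
  space <- build_state_space()
  shared <- make_shared(config, space)
  n <- shared$n
  subs <- build_subcohorts(strategy, config$persistence, n)
  weights <- vapply(subs, `[[`, numeric(1), "weight")

  runs <- lapply(subs, simulate_subcohort, strategy = strategy,
                 shared = shared)

  wavg <- function(field) {
    out <- 0
    for (i in seq_along(runs)) out <- out + weights[i] * runs[[i]][[field]]
    out
  }
  drug <- wavg("drug"); admin <- wavg("admin"); frac_y1 <- wavg("frac_y1")
  hip_sub <- wavg("hip_sub"); ltc_cost <- wavg("ltc_cost")
  qalys <- wavg("qalys"); lys <- wavg("lys")
  events <- wavg("events")

  dfc <- shared$df_costs
  dfe <- shared$df_effects
  components <- c(
    drug = sum(drug * dfc),
    admin_monitoring = sum(admin * dfc),
    fracture_year1 = sum(frac_y1 * dfc),
    fracture_subsequent = sum(hip_sub * dfc),
    long_term_care = sum(ltc_cost * dfc)
  )
  horizon10 <- seq_len(min(20L, n))
  risk10 <- colSums(events[horizon10, , drop = FALSE])

  out <- list(strategy = strategy$name,
              cost = sum(components),
              components = components,
              qalys = sum(qalys * dfe),
              lys = sum(lys * dfe),
              risk10 = risk10,
              weights = setNames(weights,
                                 vapply(subs, `[[`, "", "id")))
  if (keep_trace) {
    out$trace <- wavg("trace")
    out$events <- events
    out$ltc <- wavg("ltc")
  }
  class(out) <- "osteo_totals"
  out
}

#' @export
print.osteo_totals <- function(x, ...) {
  cat("<osteo_totals> ", x$strategy, "\n", sep = "")
  cat(sprintf("  discounted cost $%.0f  (QALYs %.4f, LYs %.4f)\n",
              x$cost, x$qalys, x$lys))
  comp <- paste(sprintf("%s $%.0f", names(x$components), x$components),
                collapse = ", ")
  cat("  components:", comp, "\n")
  cat(sprintf("  10-year fracture risks: hip %.3f, vertebral %.3f, NHNV %.3f\n",
              x$risk10[["hip"]], x$risk10[["vertebral"]],
              x$risk10[["nhnv"]]))
  invisible(x)
}

#' Collect strategy totals into a data frame
#'
#' @param totals List of `osteo_totals` (one per strategy).
#' @return Data frame with one row per strategy: cost, QALYs, LYs, cost
#'   components and 10-year fracture risks.
#' @export
totals_table <- function(totals) {
  out <- do.call(rbind, lapply(totals, function(t) {
    data.frame(strategy = t$strategy, cost = t$cost,
               qalys = t$qalys, lys = t$lys,
               cost_drug = t$components[["drug"]],
               cost_admin_monitoring = t$components[["admin_monitoring"]],
               cost_fracture_year1 = t$components[["fracture_year1"]],
               cost_fracture_subsequent =
                 t$components[["fracture_subsequent"]],
               cost_long_term_care = t$components[["long_term_care"]],
               risk10_hip = t$risk10[["hip"]],
               risk10_vertebral = t$risk10[["vertebral"]],
               risk10_nhnv = t$risk10[["nhnv"]],
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full multiway cost-effectiveness analysis
#'
#' Runs every strategy (or a subset) through the lifetime model and builds
#' the incremental cost-effectiveness frontier.
#'
#' @param config Model configuration.
#' @param strategies Optional character vector restricting the comparison.
#' @param keep_trace Passed through to [run_strategy()].
#' @return Object of class `osteo_cea`: `totals` (data frame),
#'   `frontier` (the [frontier()] table), `runs` (per-strategy
#'   `osteo_totals`), and the configuration used.
#' @export
run_cea <- function(config, strategies = NULL, keep_trace = FALSE) {
  strategies <- strategies %||% names(config$strategies)
  runs <- lapply(strategies, function(s) {
    run_strategy(config, s, keep_trace = keep_trace)
  })
  names(runs) <- strategies
  tot <- totals_table(runs)
  structure(list(totals = tot, frontier = frontier(tot), runs = runs,
                 config = config),
            class = "osteo_cea")
}

#' @export
print.osteo_cea <- function(x, ...) {
  cat("<osteo_cea> ", nrow(x$totals), " strategies\n", sep = "")
  print(x$frontier, ...)
  invisible(x)
}

#' Tidy per-cycle occupancy trace
#'
#' @param run An `osteo_totals` from `run_strategy(..., keep_trace = TRUE)`.
#' @param config The configuration the run used.
#' @return Long data frame (`cycle`, `age`, `state`, `occupancy`).
#' @export
trace_table <- function(run, config) {
  if (is.null(run$trace)) {
    stop("run was not kept with keep_trace = TRUE", call. = FALSE)
  }
  tr <- run$trace
  cycles <- seq_len(nrow(tr)) - 1L
  data.frame(
    cycle = rep(cycles, times = ncol(tr)),
    age = config$population$start_age + 0.5 * rep(cycles, times = ncol(tr)),
    state = rep(colnames(tr), each = nrow(tr)),
    occupancy = as.vector(tr)
  )
}

#' Tidy per-cycle incident-event table
#'
#' @inheritParams trace_table
#' @return Long data frame (`cycle`, `site`, `incident_fraction`).
#' @export
event_table <- function(run, config) {
  if (is.null(run$events)) {
    stop("run was not kept with keep_trace = TRUE", call. = FALSE)
  }
  ev <- run$events
  data.frame(
    cycle = rep(seq_len(nrow(ev)), times = ncol(ev)),
    site = rep(colnames(ev), each = nrow(ev)),
    incident_fraction = as.vector(ev)
  )
}
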