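#' Build the hierarchical fracture state space
#'
#' Eleven states: `well`, two-cycle first-year tunnels and a post-fracture
#' state for each fracture site (`hip_y1a`, `hip_y1b`, `post_hip`, likewise
#' `vert_*` and `nhnv_*`), and absorbing `dead`.  The hierarchy forbids
#' moving to a milder fracture type: from the hip states only further hip
#' fractures are possible; from the vertebral states hip or vertebral; from
#' `well` and the NHNV states any site.  A new fracture restarts the
#' first-year clock in the new site's `*_y1a` tunnel.
#'
#' @return An object of class `osteo_state_space`: state names, index
#'   helpers, per-state allowed fracture sites, residual-transition targets,
#'   and the allowed-transition mask.
#' @export
build_state_space <- function() {
  states <- c("well",
              "hip_y1a", "hip_y1b", "post_hip",
              "vert_y1a", "vert_y1b", "post_vert",
              "nhnv_y1a", "nhnv_y1b", "post_nhnv",
              "dead")
  n <- length(states)
  idx <- setNames(seq_len(n), states)

  # fracture sites reachable from each live state (hierarchy mask)
  allowed <- list(
    well      = FRACTURE_SITES,
    hip_y1a   = "hip",
    hip_y1b   = "hip",
    post_hip  = "hip",
    vert_y1a  = c("hip", "vertebral"),
    vert_y1b  = c("hip", "vertebral"),
    post_vert = c("hip", "vertebral"),
    nhnv_y1a  = FRACTURE_SITES,
    nhnv_y1b  = FRACTURE_SITES,
    post_nhnv = FRACTURE_SITES
  )

  # where residual (no new fracture, no death) mass goes
  residual <- c(
    well = "well",
    hip_y1a = "hip_y1b", hip_y1b = "post_hip", post_hip = "post_hip",
    vert_y1a = "vert_y1b", vert_y1b = "post_vert", post_vert = "post_vert",
    nhnv_y1a = "nhnv_y1b", nhnv_y1b = "post_nhnv", post_nhnv = "post_nhnv"
  )

  y1a <- c(hip = "hip_y1a", vertebral = "vert_y1a", nhnv = "nhnv_y1a")
  live <- setdiff(states, "dead")

  mask <- matrix(FALSE, n, n, dimnames = list(states, states))
  mask["dead", "dead"] <- TRUE
  for (s in live) {
    mask[s, "dead"] <- TRUE
    mask[s, residual[[s]]] <- TRUE
    mask[s, y1a[allowed[[s]]]] <- TRUE
  }

  # which fracture site a state belongs to (NA for well/dead)
  site_of <- c(well = NA_character_,
               hip_y1a = "hip", hip_y1b = "hip", post_hip = "hip",
               vert_y1a = "vertebral", vert_y1b = "vertebral",
               post_vert = "vertebral",
               nhnv_y1a = "nhnv", nhnv_y1b = "nhnv", post_nhnv = "nhnv",
               dead = NA_character_)

  space <- list(states = states, n = n, idx = idx, live = live,
                allowed = allowed, residual = residual, y1a = y1a,
                site_of = site_of, mask = mask)
  class(space) <- "osteo_state_space"
  space
}

#' Convert a probability between time scales under a constant hazard
#'
#' `1 - (1 - p)^(t_to / t_from)`: the probability over `t_to` implied by a
#' constant hazard that yields probability `p` over `t_from`.  Used to
#' convert annual incidence and death probabilities to 6-month cycles.
#'
#' @param p Probability observed over `t_from` (in `[0, 1)`).
#' @param t_from,t_to Durations in consistent units (both positive).
#' @return Probability over `t_to`.
#' @export
prob_rate_convert <- function(p, t_from, t_to) {
  if (any(p < 0 | p >= 1)) {
    stop("probability must lie in [0, 1) for rate conversion", call. = FALSE)
  }
  if (t_from <= 0 || t_to <= 0) stop("durations must be positive",
                                     call. = FALSE)
  1 - (1 - p)^(t_to / t_from)
}

# Annual death probability for a whole-year age, with death certain from
# max_age onward.
life_table_q <- function(life_table, age, max_age) {
  a <- floor(age)
  if (a >= max_age) return(1)
  a <- min(max(a, min(life_table$age)), max(life_table$age))
  life_table$qx[match(a, life_table$age)]
}

# Baseline utility for a whole-year age (clamped to the tabulated range).
baseline_utility_at <- function(baseline, age) {
  a <- min(max(floor(age), min(baseline$age)), max(baseline$age))
  baseline$utility[match(a, baseline$age)]
}

# Per-state mortality relative risks implied by the state structure:
# first-year RRs in the two-cycle tunnels, subsequent-year RRs in the
# post-fracture states (1 for post-NHNV), 1 in `well`.
state_mortality_rr <- function(mortality, space) {
  rrf <- mortality$rr_first_year
  rrs <- mortality$rr_subsequent
  rr <- setNames(rep(1, space$n), space$states)
  for (site in FRACTURE_SITES) {
    y1a <- space$y1a[[site]]
    y1b <- space$residual[[y1a]]
    post <- space$residual[[y1b]]
    rr[c(y1a, y1b)] <- rrf[[site]]
    rr[post] <- rrs[[site]]
  }
  rr["dead"] <- 0
  rr
}

# Core matrix assembly from per-state death probabilities and per-site
# 6-month fracture probabilities.  Death is assigned first; fracture
# probabilities are scaled by (1 - p_death) so rows are exactly stochastic.
assemble_matrix <- function(space, p_death_states, p_frac_sites) {
  P <- matrix(0, space$n, space$n,
              dimnames = list(space$states, space$states))
  P["dead", "dead"] <- 1
  for (s in space$live) {
    pd <- p_death_states[[s]]
    sites <- space$allowed[[s]]
    pf <- p_frac_sites[sites]
    tot <- sum(pf)
    if (tot > 1 + 1e-12) {
      stop("fracture probabilities from state '", s, "' sum to ", tot,
           " (> 1); inputs are pathological", call. = FALSE)
    }
    P[s, "dead"] <- pd
    targets <- space$y1a[sites]
    P[s, targets] <- P[s, targets] + pf * (1 - pd)
    P[s, space$residual[[s]]] <-
      P[s, space$residual[[s]]] + (1 - pd) * (1 - tot)
  }
  P
}

#' One-cycle transition matrix
#'
#' Builds the 6-month transition matrix for a cohort of the given age under
#' the given effective fracture relative risks.  Death probability is the
#' 6-month baseline from the life table scaled by the state-appropriate
#' post-fracture mortality relative risk (capped at 1); fracture
#' probabilities are the RR-scaled constant-hazard 6-month incidences for
#' the sites the hierarchy allows, scaled by cycle survival; residual mass
#' follows the tunnel structure (`y1a` to `y1b`, `y1b` to the post state,
#' others stay).
#'
#' @param age Age at the start of the cycle (years).
#' @param rr_by_site Named numeric vector of effective fracture relative
#'   risks (`hip`, `vertebral`, `nhnv`) for this cycle.
#' @param config Model configuration.
#' @param terminal If `TRUE`, death is certain this cycle (used for the
#'   final cycle reaching `max_age`).
#' @param space State space from [build_state_space()] (rebuilt if omitted).
#' @return Row-stochastic matrix over the 11 states.
#' @export
transition_matrix <- function(age, rr_by_site, config, terminal = FALSE,
                              space = build_state_space()) {
  q <- life_table_q(config$mortality$life_table, age,
                    config$population$max_age)
  p_death_base <- if (terminal || q >= 1) 1 else prob_rate_convert(q, 1, 0.5)
  rr_mort <- state_mortality_rr(config$mortality, space)
  p_death_states <- pmin(p_death_base * rr_mort, 1)

  p6 <- vapply(FRACTURE_SITES, function(site) {
    prob_rate_convert(incidence_for_age(config$epidemiology, age, site),
                      1, 0.5)
  }, numeric(1))
  p_frac <- rr_by_site[FRACTURE_SITES] * p6
  assemble_matrix(space, p_death_states, p_frac)
}

#' Propagate a cohort through a sequence of transition matrices
#'
#' Generic cohort engine: works over any state space (the acceptance
#' oracles use it with reduced 3-state chains).  Optionally counts incident
#' events as the transition mass flowing into designated columns, possibly
#' restricted to a subset of source states.
#'
#' @param initial Initial occupancy vector (sums to 1).
#' @param matrix_provider Function `(cycle) -> transition matrix`.
#' @param n_cycles Number of cycles to simulate.
#' @param event_cols Optional named integer vector of target-state columns
#'   whose inflow is counted per cycle (e.g. the three `*_y1a` tunnels).
#' @param event_sources Optional list (parallel to `event_cols`) of source
#'   row indices to include; defaults to all states.
#' @return Object of class `osteo_trace`: `trace` is a
#'   `(n_cycles + 1) x n_states` occupancy matrix (row 1 = initial
#'   distribution), `events` a `n_cycles x length(event_cols)` matrix of
#'   incident transition mass.
#' @export
run_cohort <- function(initial, matrix_provider, n_cycles,
                       event_cols = NULL, event_sources = NULL) {
  S <- length(initial)
  if (abs(sum(initial) - 1) > 1e-8) {
    stop("initial distribution must sum to 1", call. = FALSE)
  }
  trace <- matrix(0, n_cycles + 1L, S)
  colnames(trace) <- names(initial)
  trace[1L, ] <- initial
  events <- NULL
  if (!is.null(event_cols)) {
    events <- matrix(0, n_cycles, length(event_cols),
                     dimnames = list(NULL, names(event_cols)))
  }
  for (k in seq_len(n_cycles)) {
    P <- matrix_provider(k)
    occ <- trace[k, ]
    trace[k + 1L, ] <- occ %*% P
    if (!is.null(event_cols)) {
      for (j in seq_along(event_cols)) {
        src <- if (is.null(event_sources)) seq_len(S) else event_sources[[j]]
        events[k, j] <- sum(occ[src] * P[src, event_cols[[j]]])
      }
    }
  }
  structure(list(trace = trace, events = events), class = "osteo_trace")
}
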