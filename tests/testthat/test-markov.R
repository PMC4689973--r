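test_that("probability-rate conversion follows the constant-hazard closed form", {
  expect_identical(prob_rate_convert(0, 1, 0.5), 0)
  # annual hip incidence at 78 converted to a 6-month cycle
  expect_equal(prob_rate_convert(0.0053, 1, 0.5), 0.00265352,
               tolerance = 1e-6)
  # round trip annual -> 6-month -> annual
  for (p in c(0.0053, 0.05, 0.3, 0.9)) {
    expect_equal(prob_rate_convert(prob_rate_convert(p, 1, 0.5), 0.5, 1), p,
                 tolerance = 1e-12)
  }
  expect_error(prob_rate_convert(1, 1, 0.5), "\\[0, 1\\)")
  expect_error(prob_rate_convert(0.2, 0, 0.5), "positive")
})

test_that("state space encodes the fracture hierarchy", {
  space <- build_state_space()
  expect_length(space$states, 11L)
  m <- space$mask
  # post-hip patients can only refracture at the hip
  expect_true(m["post_hip", "hip_y1a"])
  expect_false(m["post_hip", "vert_y1a"])
  expect_false(m["post_hip", "nhnv_y1a"])
  # vertebral states cannot move to the milder NHNV tunnel
  expect_false(m["post_vert", "nhnv_y1a"])
  expect_false(m["vert_y1a", "nhnv_y1a"])
  expect_true(m["post_vert", "vert_y1a"])
  # well and NHNV states can fracture anywhere
  for (s in c("well", "post_nhnv", "nhnv_y1a")) {
    expect_true(all(m[s, c("hip_y1a", "vert_y1a", "nhnv_y1a")]),
                label = paste("fracture targets from", s))
  }
  # tunnels pass through: y1a -> y1b -> post
  expect_identical(space$residual[["hip_y1a"]], "hip_y1b")
  expect_identical(space$residual[["hip_y1b"]], "post_hip")
  # dead is absorbing
  expect_identical(unname(m["dead", ]),
                   space$states == "dead")
})

test_that("transition matrices are stochastic and honour the hierarchy mask", {
  cfg <- base_cfg()
  space <- build_state_space()
  rr1 <- c(hip = 1, vertebral = 1, nhnv = 1)
  for (age in c(78, 84.5, 93, 105)) {
    P <- transition_matrix(age, rr1, cfg, space = space)
    expect_equal(unname(rowSums(P)), rep(1, 11), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(P[!space$mask] == 0),
                label = paste("structural zeros at age", age))
  }
  expect_identical(unname(transition_matrix(78, rr1, cfg,
                                            terminal = TRUE)[, "dead"]),
                   rep(1, 11))

  # death first, fractures scaled by cycle survival (competing risks)
  P <- transition_matrix(78, rr1, cfg, space = space)
  q78 <- cfg$mortality$life_table$qx[cfg$mortality$life_table$age == 78]
  pd <- 1 - (1 - q78)^0.5
  p_hip6 <- 1 - (1 - 0.0053)^0.5
  expect_equal(P["well", "dead"], pd, tolerance = 1e-12)
  expect_equal(P["well", "hip_y1a"], p_hip6 * (1 - pd), tolerance = 1e-12)
  # first-year mortality RR applies inside the tunnels
  rr_hip_y1 <- cfg$mortality$rr_first_year[["hip"]]
  expect_equal(P["hip_y1a", "dead"], min(1, pd * rr_hip_y1),
               tolerance = 1e-12)

  # pathological inputs refuse to renormalize silently
  bad <- flat_cfg(q_annual = 0.01, hip = 0.9, vert = 0.9, nhnv = 0.9)
  expect_error(transition_matrix(80, rr1, bad, space = space), "sum to")
})

test_that("cohort propagation conserves mass and handles degenerate inputs", {
  space <- build_state_space()
  ident <- diag(space$n)
  dimnames(ident) <- list(space$states, space$states)
  init <- setNames(numeric(space$n), space$states)
  init["well"] <- 0.6
  init["post_vert"] <- 0.4
  run <- run_cohort(init, function(k) ident, 5L)
  for (k in 1:6) expect_identical(unname(run$trace[k, ]), unname(init))

  dead_start <- setNames(numeric(space$n), space$states)
  dead_start["dead"] <- 1
  cfg <- base_cfg()
  P <- transition_matrix(80, c(hip = 1, vertebral = 1, nhnv = 1), cfg,
                         space = space)
  run <- run_cohort(dead_start, function(k) P, 10L,
                    event_cols = space$idx[space$y1a])
  expect_identical(unname(run$trace[11, "dead"]), 1)
  expect_identical(sum(run$events), 0)

  expect_error(run_cohort(init * 2, function(k) ident, 2L), "sum to 1")

  # 64-cycle default run conserves probability mass
  tot <- run_strategy(cfg, "denosumab", keep_trace = TRUE)
  expect_equal(unname(rowSums(tot$trace)), rep(1, 65), tolerance = 1e-10)
  expect_true(all(tot$trace >= -1e-15))
})

test_that("a 3-state constant-hazard reduction matches the closed form", {
  # well -> fractured -> dead with constant per-cycle probabilities;
  # independent closed-form oracle for the occupancy of each compartment
  pf <- 0.02   # well -> fractured
  pd <- 0.03   # well -> dead
  pd2 <- 0.06  # fractured -> dead (distinct from 1 - pf - pd)
  P <- rbind(well = c(1 - pf - pd, pf, pd),
             frac = c(0, 1 - pd2, pd2),
             dead = c(0, 0, 1))
  colnames(P) <- rownames(P)
  run <- run_cohort(c(well = 1, frac = 0, dead = 0),
                    function(k) P, 40L)
  a <- 1 - pf - pd
  s <- 1 - pd2
  for (k in c(1, 5, 17, 40)) {
    w_k <- a^k
    f_k <- pf * (a^k - s^k) / (a - s)
    expect_equal(unname(run$trace[k + 1, "well"]), w_k, tolerance = 1e-8)
    expect_equal(unname(run$trace[k + 1, "frac"]), f_k, tolerance = 1e-8)
    expect_equal(unname(run$trace[k + 1, "dead"]), 1 - w_k - f_k,
                 tolerance = 1e-8)
  }
})

test_that("post-hip mass never enters vertebral or NHNV tunnels", {
  cfg <- base_cfg()
  space <- build_state_space()
  ages <- 78 + 0.5 * (0:63)
  for (age in ages[c(1, 10, 30, 63)]) {
    P <- transition_matrix(age, c(hip = 0.38, vertebral = 0.36,
                                  nhnv = 0.84), cfg, space = space)
    expect_identical(P["post_hip", "vert_y1a"], 0)
    expect_identical(P["post_hip", "nhnv_y1a"], 0)
    expect_identical(P["hip_y1a", "vert_y1a"], 0)
    expect_identical(P["hip_y1b", "nhnv_y1a"], 0)
  }
})

test_that("lowering the hip relative risk never increases hip events", {
  cfg <- base_cfg()
  risks <- vapply(c(1.0, 0.62, 0.38, 0.10), function(rr) {
    cfg <- param_set(cfg, "strategies.denosumab.rr.hip", rr)
    run <- run_strategy(cfg, "denosumab", keep_trace = TRUE)
    sum(run$events[, "hip"])
  }, numeric(1))
  expect_true(all(diff(risks) < 0))
})
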