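test_that("discount factors compound half-yearly", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_identical(discount_factor(0:10, 0), rep(1, 11))
  expect_equal(discount_factor(2, 0.03), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(1, 0.03), 1.03^-0.5, tolerance = 1e-15)
  expect_error(discount_factor(1, -0.01), ">= 0")
})

test_that("cycle QALYs weight occupancy by baseline utility and state multiplier", {
  cfg <- base_cfg()
  space <- build_state_space()
  u <- cfg$utilities$baseline$utility[cfg$utilities$baseline$age == 80]
  occ <- setNames(numeric(space$n), space$states)

  occ["well"] <- 1
  expect_equal(cycle_qalys(occ, 80, cfg, space), 0.5 * u, tolerance = 1e-12)
  occ["well"] <- 0
  occ["dead"] <- 1
  expect_identical(cycle_qalys(occ, 80, cfg, space), 0)
  occ["dead"] <- 0
  occ["vert_y1b"] <- 1
  expect_equal(cycle_qalys(occ, 80, cfg, space), 0.5 * u * 0.590,
               tolerance = 1e-12)
})

test_that("QALYs equal LYs when every utility is 1", {
  cfg <- flat_cfg(hip = 0.0053, vert = 0.0045, nhnv = 0.0076)
  cfg$utilities$multiplier_year1 <- c(hip = 1, vertebral = 1, nhnv = 1)
  cfg$utilities$multiplier_later <- c(hip = 1, vertebral = 1, nhnv = 1)
  cfg <- validate_config(cfg)
  for (s in pair) {
    tot <- run_strategy(cfg, s)
    expect_equal(tot$qalys, tot$lys, tolerance = 1e-12)
  }
})

test_that("QALYs never exceed LYs and discounting never inflates totals", {
  cfg <- base_cfg()
  tot <- run_strategy(cfg, "denosumab")
  expect_lt(tot$qalys, tot$lys)
  cfg0 <- cfg
  cfg0$run_settings$discount_rate_costs <- 0
  cfg0$run_settings$discount_rate_effects <- 0
  tot0 <- run_strategy(cfg0, "denosumab")
  expect_lt(tot$cost, tot0$cost)
  expect_lt(tot$qalys, tot0$qalys)
})

test_that("cost accounting is linear in unit costs", {
  cfg <- base_cfg()
  doubled <- cfg
  doubled$costs$fracture_year1 <- 2 * cfg$costs$fracture_year1
  doubled$costs$hip_subsequent_annual <- 2 * cfg$costs$hip_subsequent_annual
  doubled$costs$ltc_daily <- 2 * cfg$costs$ltc_daily
  doubled$costs$monitoring$unit_cost <- 2 * cfg$costs$monitoring$unit_cost
  for (s in names(cfg$strategies)) {
    doubled$strategies[[s]]$annual_drug_cost <-
      2 * cfg$strategies[[s]]$annual_drug_cost
    doubled$strategies[[s]]$admin_events$unit_cost <-
      2 * cfg$strategies[[s]]$admin_events$unit_cost
  }
  t1 <- run_strategy(cfg, "denosumab")
  t2 <- run_strategy(doubled, "denosumab")
  expect_equal(t2$cost, 2 * t1$cost, tolerance = 1e-12)
  expect_equal(t2$components, 2 * t1$components, tolerance = 1e-12)
})

test_that("cost components cross-foot to the total", {
  cfg <- base_cfg()
  for (s in pair) {
    tot <- run_strategy(cfg, s)
    expect_equal(sum(tot$components), tot$cost, tolerance = 1e-9)
    expect_true(all(tot$components >= 0))
  }
})

test_that("zero incidence zeroes fracture costs and equalizes QALYs", {
  cfg <- base_cfg()
  cfg$epidemiology$hip <- rep(0, 3)
  cfg$epidemiology$vertebral <- rep(0, 3)
  cfg$epidemiology$nhnv <- rep(0, 3)
  cfg <- validate_config(cfg)
  cea <- run_cea(cfg)
  expect_true(all(cea$totals$cost_fracture_year1 == 0))
  expect_true(all(cea$totals$cost_fracture_subsequent == 0))
  expect_true(all(cea$totals$cost_long_term_care == 0))
  expect_equal(diff(range(cea$totals$qalys)), 0, tolerance = 1e-12)
  expect_true(all(cea$totals$risk10_hip == 0))
})

test_that("10-year fracture risk matches the constant-hazard closed form", {
  # flat mortality, hip-only incidence, no treatment effect: per-cycle
  # incident events are p6 * (1 - pd) * alive, with alive = (1 - pd)^k
  cfg <- flat_cfg(q_annual = 0.05, hip = 0.0053)
  cfg <- param_set(cfg, "strategies.generic_alendronate.rr",
                   c(hip = 1, vertebral = 1, nhnv = 1))
  tot <- run_strategy(cfg, "generic_alendronate", keep_trace = TRUE)
  pd <- 1 - (1 - 0.05)^0.5
  p6 <- 1 - (1 - 0.0053)^0.5
  sv <- 1 - pd
  oracle <- p6 * sv * (1 - sv^20) / (1 - sv)
  expect_equal(tot$risk10[["hip"]], oracle, tolerance = 1e-10)
  expect_identical(tot$risk10[["vertebral"]], 0)
  # and the trace-level event counters agree cycle by cycle
  expect_equal(tot$events[1:20, "hip"], p6 * sv * sv^(0:19),
               tolerance = 1e-10)
})

test_that("drug and monitoring costs stop at discontinuation", {
  cfg <- flat_cfg()
  # (almost) everyone discontinues at the start of cycle 2, after half a
  # year on treatment (discontinuation applies at cycle start)
  cfg$persistence <- c(0, 0.999999999999, 0, 0, 0, 0)
  cfg <- validate_config(cfg)
  # make it an oral strategy so the schedule applies unadjusted
  tot <- run_strategy(cfg, "risedronate")
  alive1 <- 1  # everyone alive at the start of cycle 1
  dfc <- discount_factor(1, 0.03)
  expected_drug <- 1708 / 2 * alive1 * dfc
  expect_equal(tot$components[["drug"]], expected_drug, tolerance = 1e-6)
  mon_rate <- sum(cfg$costs$monitoring$unit_cost *
                    cfg$costs$monitoring$events_per_year)
  expect_equal(tot$components[["admin_monitoring"]],
               mon_rate / 2 * alive1 * dfc, tolerance = 1e-6)
})

test_that("trace and event exports are tidy", {
  cfg <- base_cfg()
  run <- run_strategy(cfg, "denosumab", keep_trace = TRUE)
  tr <- trace_table(run, cfg)
  expect_identical(nrow(tr), 65L * 11L)
  expect_identical(unique(tr$age[tr$cycle == 0]), 78)
  ev <- event_table(run, cfg)
  expect_identical(sort(unique(ev$site)), sort(fracture_sites()))
  agg <- tapply(ev$incident_fraction, ev$site, sum)
  expect_equal(unname(agg[fracture_sites()][1]), sum(run$events[, "hip"]),
               tolerance = 1e-12)
})
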