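test_that("degenerate DSA bounds reproduce the base-case ICER", {
  cfg <- base_cfg()
  base_cost <- cfg$strategies$denosumab$annual_drug_cost
  specs <- list(dsa_spec("strategies.denosumab.annual_drug_cost",
                         low = base_cost, high = base_cost))
  tor <- one_way_dsa(cfg, specs, comparison = pair)
  expect_equal(tor$icer_low, tor$icer_base, tolerance = 1e-12)
  expect_equal(tor$icer_high, tor$icer_base, tolerance = 1e-12)
  expect_equal(tor$width, 0, tolerance = 1e-12)
})

test_that("the pairwise ICER responds monotonically to key drivers", {
  cfg <- base_cfg()
  specs <- list(
    dsa_spec("strategies.denosumab.annual_drug_cost"),  # +/- 25%
    dsa_spec("strategies.denosumab.rr.hip")
  )
  tor <- one_way_dsa(cfg, specs, comparison = pair)
  drug <- tor[tor$parameter == "strategies.denosumab.annual_drug_cost", ]
  # costlier denosumab: strictly higher ICER versus generic alendronate
  expect_gt(drug$icer_high, drug$icer_base)
  expect_lt(drug$icer_low, drug$icer_base)
  # better hip protection: strictly lower ICER (toward dominance)
  rrh <- tor[tor$parameter == "strategies.denosumab.rr.hip", ]
  expect_lt(rrh$icer_low, rrh$icer_base)
  expect_gt(rrh$icer_high, rrh$icer_base)
  # widest bar first
  expect_true(!is.unsorted(rev(tor$width)))
  expect_error(one_way_dsa(cfg, list(dsa_spec("no.such.parameter")),
                           comparison = pair),
               "unknown parameter path")
  expect_error(one_way_dsa(cfg, comparison = c("generic_alendronate",
                                               "moon_dust")),
               "unknown strategy")
})

test_that("scenario reruns apply overrides exactly", {
  cfg <- base_cfg()
  cfg$strategies <- cfg$strategies[pair]
  base <- run_cea(cfg)
  same <- scenario(cfg, list())
  expect_equal(same$totals, base$totals, tolerance = 1e-12)

  # drug-price cuts flow linearly through the discounted drug component
  cut <- scenario(cfg, list("strategies.denosumab.annual_drug_cost" =
                              0.65 * cfg$strategies$denosumab$annual_drug_cost))
  i <- match("denosumab", base$totals$strategy)
  expect_equal(base$totals$cost[i] - cut$totals$cost[i],
               0.35 * base$totals$cost_drug[i], tolerance = 1e-9)
  # the untouched strategy is unchanged
  j <- match("generic_alendronate", base$totals$strategy)
  expect_equal(cut$totals$cost[j], base$totals$cost[j], tolerance = 1e-12)

  presets <- preset_scenarios(base_cfg())
  expect_setequal(names(presets),
                  c("generic_zoledronate", "generic_risedronate",
                    "long_offset", "short_denosumab_offset"))
  expect_equal(presets$generic_zoledronate[[1]], 0.65 * 1084,
               tolerance = 1e-12)
})

test_that("PSA is seed-reproducible and degenerate draws recover the base case", {
  cfg <- base_cfg()
  specs <- list(
    psa_spec("strategies.denosumab.rr.hip", "lognormal", mean = 0.38,
             se = 0.05),
    psa_spec("costs.fracture_year1.hip", "gamma", mean = 28112, se = 2000),
    psa_spec("costs.ltc_admission_fraction", "beta", mean = 0.2, se = 0.04)
  )
  d1 <- psa(cfg, specs, n_draws = 3, seed = 7, strategies = pair)
  d2 <- psa(cfg, specs, n_draws = 3, seed = 7, strategies = pair)
  expect_identical(d1, d2)
  d3 <- psa(cfg, specs, n_draws = 3, seed = 8, strategies = pair)
  expect_false(identical(attr(d1, "draws"), attr(d3, "draws")))

  # zero dispersion: every draw equals the deterministic result exactly
  degenerate <- list(
    psa_spec("strategies.denosumab.rr.hip", "lognormal", mean = 0.38,
             se = 0),
    psa_spec("costs.ltc_admission_fraction", "beta", mean = 0.2, se = 0)
  )
  dd <- psa(cfg, degenerate, n_draws = 2, seed = 1, strategies = pair)
  base <- run_cea(cfg, strategies = pair)
  for (i in 1:2) {
    sub <- dd[dd$draw == i, ]
    expect_equal(sub$cost, base$totals$cost, tolerance = 1e-12)
    expect_equal(sub$qalys, base$totals$qalys, tolerance = 1e-12)
  }
})

test_that("PSA distributions match their stated moments and intervals", {
  set.seed(99)
  # lognormal spec from a 95% CI: empirical quantiles approach the CI
  ci <- c(0.25, 0.60)
  spec <- psa_spec("strategies.denosumab.rr.hip", "lognormal",
                   mean = 0.38, ci = ci)
  x <- osteocea:::sample_psa_spec(spec, 50000)
  q <- unname(quantile(x, c(0.025, 0.975)))
  expect_equal(q, ci, tolerance = 0.02)

  # moment-matched gamma and beta reproduce mean and SE
  g <- osteocea:::sample_psa_spec(
    psa_spec("costs.ltc_daily", "gamma", mean = 236, se = 30), 50000)
  expect_equal(mean(g), 236, tolerance = 0.005)
  expect_equal(sd(g), 30, tolerance = 0.05)
  b <- osteocea:::sample_psa_spec(
    psa_spec("costs.ltc_admission_fraction", "beta", mean = 0.2,
             se = 0.05), 50000)
  expect_equal(mean(b), 0.2, tolerance = 0.01)

  # invalid dispersions fail at spec construction
  expect_error(psa_spec("x", "beta", mean = 0.5, se = 0.7),
               "invalid dispersion")
  expect_error(psa_spec("x", "gamma", mean = -5), "positive")
  expect_error(psa_spec("x", "beta", mean = 1.2), "\\(0, 1\\)")
})

test_that("CEAC probabilities partition to one and respect NMB", {
  draws <- data.frame(
    draw = rep(1:2, each = 2),
    strategy = rep(c("cheap", "better"), 2),
    cost = c(100, 200, 100, 400),
    qalys = c(1.0, 1.1, 1.0, 1.05),
    lys = 1
  )
  cc <- ceac(draws, thresholds = c(0, 1000, 10000))
  sums <- tapply(cc$probability, cc$threshold, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-12)
  # at threshold 0 the cheaper strategy wins every draw
  expect_identical(cc$probability[cc$threshold == 0 &
                                    cc$strategy == "cheap"], 1)
  # at a high threshold the more effective strategy wins both draws
  expect_identical(cc$probability[cc$threshold == 10000 &
                                    cc$strategy == "better"], 1)
  # single draw: indicator probabilities
  one <- ceac(draws[draws$draw == 1, ], thresholds = c(0, 5000))
  expect_setequal(one$probability, c(0, 1))
  # exact NMB ties are split equally
  tie <- data.frame(draw = 1, strategy = c("a", "b"),
                    cost = c(100, 100), qalys = c(1, 1), lys = 1)
  ct <- ceac(tie, thresholds = 500)
  expect_equal(ct$probability, c(0.5, 0.5), tolerance = 1e-12)
})
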