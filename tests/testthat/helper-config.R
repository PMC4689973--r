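# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

base_cfg <- function() {
  if (is.null(.cache$base)) .cache$base <- generate_config(1L)
  .cache$base
}

# A deliberately simple configuration for closed-form oracles: constant
# annual death probability, a single open-ended incidence band, no excess
# post-fracture mortality, flat utilities.
flat_cfg <- function(q_annual = 0.05, hip = 0.0053, vert = 0, nhnv = 0) {
  cfg <- base_cfg()
  ages <- 60:110
  cfg$mortality$life_table <- data.frame(
    age = ages, qx = c(rep(q_annual, length(ages) - 1L), 1)
  )
  cfg$mortality$rr_first_year <- c(hip = 1, vertebral = 1, nhnv = 1)
  cfg$mortality$rr_subsequent <- c(hip = 1, vertebral = 1, nhnv = 1)
  cfg$epidemiology <- data.frame(lower = 60, upper = NA,
                                 hip = hip, vertebral = vert, nhnv = nhnv)
  cfg$utilities$baseline <- data.frame(age = ages, utility = 1)
  validate_config(cfg)
}

# Restrict a CEA run to two strategies for speed.
pair <- c("generic_alendronate", "denosumab")
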