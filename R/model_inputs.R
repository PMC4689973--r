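#' Construct a treatment strategy
#'
#' A strategy bundles everything that distinguishes one treatment arm:
#' site-specific fracture relative risks while on treatment, drug and
#' administration costs, planned treatment duration, post-discontinuation
#' offset duration, and how persistence is modelled.
#'
#' @param name Strategy label (unique within a configuration).
#' @param rr Named numeric vector of fracture relative risks on treatment,
#'   with names `hip`, `vertebral`, `nhnv`.  An RR of exactly 1 encodes
#'   "no demonstrated risk reduction at this site".
#' @param annual_drug_cost Drug acquisition cost, USD per year on treatment.
#' @param admin_events Data frame (`label`, `unit_cost`, `events_per_year`)
#'   of strategy-specific administration resources (e.g. nurse visits for a
#'   subcutaneous injectable); may have zero rows.
#' @param max_treatment_years Planned treatment duration in years.
#' @param offset_years Maximum residual-efficacy (offset) duration in years
#'   after stopping treatment; the effective offset is further capped by the
#'   time actually spent on treatment.
#' @param persistence_class `"oral_reference"` for strategies that follow
#'   the oral-bisphosphonate discontinuation schedule directly, or
#'   `"injectable_hr_adjusted"` for strategies whose discontinuation hazard
#'   is scaled by `hazard_ratio`.
#' @param hazard_ratio Discontinuation hazard ratio versus the oral
#'   reference schedule (used only by the injectable class).
#' @return An object of class `osteo_strategy`.
#' @export
new_strategy <- function(name, rr, annual_drug_cost,
                         admin_events = NULL,
                         max_treatment_years = 5,
                         offset_years = 2,
                         persistence_class = c("oral_reference",
                                               "injectable_hr_adjusted"),
                         hazard_ratio = 1) {
  persistence_class <- match.arg(persistence_class)
  if (is.null(admin_events) || length(admin_events) == 0L ||
      (is.data.frame(admin_events) && nrow(admin_events) == 0L)) {
    admin_events <- data.frame(label = character(), unit_cost = numeric(),
                               events_per_year = numeric())
  }
  s <- list(name = name,
            rr = rr[FRACTURE_SITES],
            annual_drug_cost = annual_drug_cost,
            admin_events = admin_events,
            max_treatment_years = max_treatment_years,
            offset_years = offset_years,
            persistence_class = persistence_class,
            hazard_ratio = hazard_ratio)
  class(s) <- "osteo_strategy"
  s
}

validate_strategy <- function(s, field) {
  if (is.null(s$name) || !nzchar(s$name)) config_error(field, "needs a name")
  rr <- s$rr
  if (length(rr) != 3L || !all(FRACTURE_SITES %in% names(rr))) {
    config_error(paste0(field, ".rr"),
                 "must give relative risks for hip, vertebral and nhnv")
  }
  for (site in FRACTURE_SITES) {
    check_number(rr[[site]], paste0(field, ".rr.", site),
                 lower = 0, open_lower = TRUE)
  }
  check_number(s$annual_drug_cost, paste0(field, ".annual_drug_cost"),
               lower = 0)
  check_number(s$max_treatment_years, paste0(field, ".max_treatment_years"),
               lower = 0, open_lower = TRUE)
  check_number(s$offset_years, paste0(field, ".offset_years"), lower = 0)
  if (!s$persistence_class %in% c("oral_reference",
                                  "injectable_hr_adjusted")) {
    config_error(paste0(field, ".persistence_class"),
                 "must be 'oral_reference' or 'injectable_hr_adjusted'")
  }
  check_number(s$hazard_ratio, paste0(field, ".hazard_ratio"),
               lower = 0, open_lower = TRUE)
  ae <- s$admin_events
  if (!is.data.frame(ae) ||
      !all(c("label", "unit_cost", "events_per_year") %in% names(ae))) {
    config_error(paste0(field, ".admin_events"),
                 "must be a data frame with label, unit_cost, events_per_year")
  }
  invisible(s)
}

#' Assemble and validate a model configuration
#'
#' Low-level constructor used by [load_config()] and [generate_config()].
#' All invariants (probability ranges, contiguous age bands, terminal
#' life-table entry, structural constraints on mortality and utility
#' parameters) are checked here; violations raise an error naming the field.
#'
#' @param population List with `start_age`, `max_age`,
#'   `prevalent_vertebral_fraction` and `cycle_length` (fixed at 0.5 years).
#' @param strategies List of [new_strategy()] objects (at least two).
#' @param epidemiology Data frame of age-banded annual fracture incidence
#'   (`lower`, `upper`, `hip`, `vertebral`, `nhnv`); `upper = NA` marks the
#'   open-ended last band.
#' @param mortality List with `life_table` (data frame `age`, `qx`),
#'   `rr_first_year` and `rr_subsequent` (named vectors by site).
#' @param utilities List with `baseline` (data frame `age`, `utility`),
#'   `multiplier_year1` and `multiplier_later` (named vectors by site).
#' @param costs List with `fracture_year1` (named by site),
#'   `hip_subsequent_annual`, `ltc_daily`, `ltc_admission_fraction` and
#'   `monitoring` (data frame `label`, `unit_cost`, `events_per_year`).
#' @param persistence Numeric vector of six 6-month discontinuation
#'   probabilities for the oral reference schedule (years 0-3).
#' @param run_settings List with discount rates, PSA settings,
#'   willingness-to-pay threshold and run flags.
#' @param provenance Named character vector flagging each tabular input as
#'   `"published"` or `"placeholder"`.
#' @return A validated object of class `osteo_config`.
#' @export
new_config <- function(population, strategies, epidemiology, mortality,
                       utilities, costs, persistence, run_settings,
                       provenance = character()) {
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  strip <- function(df) {
    attr(df, "provenance") <- NULL
    rownames(df) <- NULL
    df
  }
  epidemiology <- strip(epidemiology)
  mortality$life_table <- strip(mortality$life_table)
  utilities$baseline <- strip(utilities$baseline)
  config <- list(population = population,
                 strategies = strategies,
                 epidemiology = epidemiology,
                 mortality = mortality,
                 utilities = utilities,
                 costs = costs,
                 persistence = persistence,
                 run_settings = run_settings,
                 provenance = provenance)
  class(config) <- "osteo_config"
  validate_config(config)
}

#' Validate a model configuration
#'
#' @param config An `osteo_config` object (possibly modified by hand or via
#'   [param_set()]).
#' @return The configuration, invisibly returned visible; errors name the
#'   offending field.
#' @export
validate_config <- function(config) {
  pop <- config$population
  check_number(pop$start_age, "population.start_age", lower = 0)
  check_number(pop$max_age, "population.max_age", lower = 0)
  if (pop$start_age >= pop$max_age) {
    config_error("population.start_age", "must be below max_age")
  }
  check_number(pop$prevalent_vertebral_fraction,
               "population.prevalent_vertebral_fraction", 0, 1)
  if (!isTRUE(all.equal(pop$cycle_length, 0.5))) {
    config_error("population.cycle_length", "must be 0.5 years")
  }

  if (length(config$strategies) < 2L) {
    config_error("strategies", "needs at least 2 strategies")
  }
  nm <- names(config$strategies)
  if (anyDuplicated(nm)) config_error("strategies", "has duplicate names")
  for (i in seq_along(config$strategies)) {
    validate_strategy(config$strategies[[i]], paste0("strategies.", nm[i]))
  }

  epi <- config$epidemiology
  if (!is.data.frame(epi) ||
      !all(c("lower", "upper", FRACTURE_SITES) %in% names(epi))) {
    config_error("epidemiology", "must tabulate lower, upper, hip, vertebral, nhnv")
  }
  if (!is.na(epi$upper[nrow(epi)])) {
    config_error("epidemiology.upper", "last age band must be open-ended (NA)")
  }
  if (nrow(epi) > 1L &&
      !all(epi$upper[-nrow(epi)] + 1 == epi$lower[-1])) {
    config_error("epidemiology", "age bands must be contiguous")
  }
  for (site in FRACTURE_SITES) {
    p <- epi[[site]]
    if (any(p < 0 | p >= 1)) {
      config_error(paste0("epidemiology.", site),
                   "annual probabilities must lie in [0, 1)")
    }
  }

  lt <- config$mortality$life_table
  if (!is.data.frame(lt) || !all(c("age", "qx") %in% names(lt))) {
    config_error("mortality.life_table", "must tabulate age and qx")
  }
  if (min(lt$age) > pop$start_age || max(lt$age) < pop$max_age) {
    config_error("mortality.life_table",
                 "must cover ages from start_age to max_age")
  }
  if (any(lt$qx < 0 | lt$qx > 1)) {
    config_error("mortality.life_table.qx", "must lie in [0, 1]")
  }
  q_max <- lt$qx[lt$age == pop$max_age]
  if (length(q_max) != 1L || q_max != 1) {
    config_error("mortality.life_table.qx", "must equal 1 at max_age")
  }
  if (mean(diff(lt$qx)) < 0) {
    config_error("mortality.life_table.qx",
                 "must be nondecreasing on average")
  }
  for (blk in c("rr_first_year", "rr_subsequent")) {
    rr <- config$mortality[[blk]]
    if (!all(FRACTURE_SITES %in% names(rr))) {
      config_error(paste0("mortality.", blk), "must name hip, vertebral, nhnv")
    }
    if (any(rr[FRACTURE_SITES] < 1)) {
      config_error(paste0("mortality.", blk), "must be >= 1")
    }
  }
  if (config$mortality$rr_subsequent[["nhnv"]] != 1) {
    config_error("mortality.rr_subsequent.nhnv",
                 "must be 1 (NHNV excess mortality is first-year only)")
  }

  ut <- config$utilities
  ub <- ut$baseline
  if (!is.data.frame(ub) || !all(c("age", "utility") %in% names(ub))) {
    config_error("utilities.baseline", "must tabulate age and utility")
  }
  if (any(ub$utility <= 0 | ub$utility > 1)) {
    config_error("utilities.baseline.utility", "must lie in (0, 1]")
  }
  for (blk in c("multiplier_year1", "multiplier_later")) {
    m <- ut[[blk]]
    if (!all(FRACTURE_SITES %in% names(m))) {
      config_error(paste0("utilities.", blk), "must name hip, vertebral, nhnv")
    }
    if (any(m[FRACTURE_SITES] <= 0 | m[FRACTURE_SITES] > 1)) {
      config_error(paste0("utilities.", blk), "must lie in (0, 1]")
    }
  }
  if (ut$multiplier_later[["nhnv"]] != 1) {
    config_error("utilities.multiplier_later.nhnv",
                 "must be 1 (NHNV fractures affect quality of life in year 1 only)")
  }

  cs <- config$costs
  for (site in FRACTURE_SITES) {
    check_number(cs$fracture_year1[[site]],
                 paste0("costs.fracture_year1.", site), lower = 0)
  }
  check_number(cs$hip_subsequent_annual, "costs.hip_subsequent_annual",
               lower = 0)
  check_number(cs$ltc_daily, "costs.ltc_daily", lower = 0)
  check_number(cs$ltc_admission_fraction, "costs.ltc_admission_fraction",
               0, 1)
  mon <- cs$monitoring
  if (!is.data.frame(mon) ||
      !all(c("label", "unit_cost", "events_per_year") %in% names(mon))) {
    config_error("costs.monitoring",
                 "must be a data frame with label, unit_cost, events_per_year")
  }

  pers <- config$persistence
  if (length(pers) != 6L) {
    config_error("persistence", "must give 6 half-year probabilities")
  }
  if (any(pers < 0 | pers >= 1)) {
    config_error("persistence", "probabilities must lie in [0, 1)")
  }

  rs <- config$run_settings
  check_number(rs$discount_rate_costs, "run_settings.discount_rate_costs",
               lower = 0)
  check_number(rs$discount_rate_effects, "run_settings.discount_rate_effects",
               lower = 0)
  check_number(rs$psa_draws, "run_settings.psa_draws", lower = 1)
  check_number(rs$wtp_threshold, "run_settings.wtp_threshold", lower = 0)

  config
}

# Read a fixture CSV, honouring "# provenance: ..." header comments.
read_fixture_csv <- function(path) {
  if (!file.exists(path)) {
    stop("fixture file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  prov <- if (grepl("^#\\s*provenance:", first)) {
    trimws(sub("^#\\s*provenance:", "", first))
  } else {
    NA_character_
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "provenance") <- prov
  df
}

#' Load a model configuration from a YAML file
#'
#' The YAML document holds scalar parameters and strategy definitions, and
#' references CSV tables (relative to its own directory) for the life table,
#' fracture incidence, persistence schedule, post-fracture mortality
#' relative risks and baseline utilities, so that externally sourced tables
#' can be dropped in without code changes.
#'
#' @param path Path to the YAML configuration.
#' @return A validated `osteo_config`.
#' @seealso [default_config()], [write_config()], [generate_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))
  resolve <- function(f) if (file.exists(f)) f else file.path(dir, f)

  files <- raw$files
  for (f in c("life_table", "fracture_incidence", "persistence_schedule",
              "mortality_rr", "baseline_utility")) {
    if (is.null(files[[f]])) config_error(paste0("files.", f), "is missing")
  }
  lt <- read_fixture_csv(resolve(files$life_table))
  epi <- read_fixture_csv(resolve(files$fracture_incidence))
  pers_tbl <- read_fixture_csv(resolve(files$persistence_schedule))
  mrr <- read_fixture_csv(resolve(files$mortality_rr))
  ub <- read_fixture_csv(resolve(files$baseline_utility))
  epi$upper <- suppressWarnings(as.numeric(epi$upper))

  strategies <- lapply(raw$strategies, function(s) {
    ae <- if (length(s$admin_events)) {
      do.call(rbind, lapply(s$admin_events, function(e) {
        data.frame(label = e$label, unit_cost = e$unit_cost,
                   events_per_year = e$events_per_year)
      }))
    } else {
      NULL
    }
    new_strategy(name = s$name,
                 rr = unlist(s$rr),
                 annual_drug_cost = s$annual_drug_cost,
                 admin_events = ae,
                 max_treatment_years = s$max_treatment_years,
                 offset_years = s$offset_years,
                 persistence_class = s$persistence_class,
                 hazard_ratio = s$hazard_ratio %||% 1)
  })

  mon <- if (length(raw$costs$monitoring)) {
    do.call(rbind, lapply(raw$costs$monitoring, function(e) {
      data.frame(label = e$label, unit_cost = e$unit_cost,
                 events_per_year = e$events_per_year)
    }))
  } else {
    data.frame(label = character(), unit_cost = numeric(),
               events_per_year = numeric())
  }

  provenance <- c(
    life_table = attr(lt, "provenance") %||% NA_character_,
    fracture_incidence = attr(epi, "provenance") %||% NA_character_,
    persistence_schedule = attr(pers_tbl, "provenance") %||% NA_character_,
    mortality_rr = attr(mrr, "provenance") %||% NA_character_,
    baseline_utility = attr(ub, "provenance") %||% NA_character_
  )

  new_config(
    population = raw$population,
    strategies = strategies,
    epidemiology = epi[c("lower", "upper", FRACTURE_SITES)],
    mortality = list(
      life_table = lt[c("age", "qx")],
      rr_first_year = setNames(mrr$rr_first_year, mrr$site)[FRACTURE_SITES],
      rr_subsequent = setNames(mrr$rr_subsequent, mrr$site)[FRACTURE_SITES]
    ),
    utilities = list(
      baseline = ub[c("age", "utility")],
      multiplier_year1 = unlist(raw$utilities$multiplier_year1)[FRACTURE_SITES],
      multiplier_later = unlist(raw$utilities$multiplier_later)[FRACTURE_SITES]
    ),
    costs = list(
      fracture_year1 = unlist(raw$costs$fracture_year1)[FRACTURE_SITES],
      hip_subsequent_annual = raw$costs$hip_subsequent_annual,
      ltc_daily = raw$costs$ltc_daily,
      ltc_admission_fraction = raw$costs$ltc_admission_fraction,
      monitoring = mon
    ),
    persistence = pers_tbl$discontinuation_probability,
    run_settings = modifyList(
      list(discount_rate_costs = 0.03, discount_rate_effects = 0.03,
           psa_draws = 1000, psa_seed = 1, wtp_threshold = 1e5,
           half_cycle_correction = FALSE, count_all_events = TRUE),
      raw$run_settings %||% list()
    ),
    provenance = provenance
  )
}

#' Write a model configuration to disk
#'
#' Writes the YAML document plus the five CSV tables it references
#' (provenance flags preserved as `# provenance:` header comments).
#' [load_config()] on the result reproduces the configuration.
#'
#' @param config An `osteo_config`.
#' @param dir Output directory (created if needed).
#' @param basename File name for the YAML document.
#' @return The path to the YAML file, invisibly.
#' @export
write_config <- function(config, dir, basename = "config.yaml") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- config$provenance

  write_tbl <- function(df, file, key) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    on.exit(close(con))
    p <- prov[[key]] %||% NA_character_
    if (!is.na(p)) writeLines(paste0("# provenance: ", p), con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
    file
  }

  files <- list(
    life_table = write_tbl(config$mortality$life_table,
                           "life_table.csv", "life_table"),
    fracture_incidence = write_tbl(config$epidemiology,
                                   "fracture_incidence.csv",
                                   "fracture_incidence"),
    persistence_schedule = write_tbl(
      data.frame(cycle = seq_along(config$persistence),
                 discontinuation_probability = config$persistence),
      "persistence_schedule.csv", "persistence_schedule"),
    mortality_rr = write_tbl(
      data.frame(site = FRACTURE_SITES,
                 rr_first_year = unname(
                   config$mortality$rr_first_year[FRACTURE_SITES]),
                 rr_subsequent = unname(
                   config$mortality$rr_subsequent[FRACTURE_SITES])),
      "mortality_rr.csv", "mortality_rr"),
    baseline_utility = write_tbl(config$utilities$baseline,
                                 "baseline_utility.csv", "baseline_utility")
  )

  as_events <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(label = df$label[i], unit_cost = df$unit_cost[i],
           events_per_year = df$events_per_year[i])
    })
  }
  doc <- list(
    population = config$population,
    run_settings = config$run_settings,
    files = files,
    strategies = lapply(unname(config$strategies), function(s) {
      list(name = s$name, rr = as.list(s$rr),
           annual_drug_cost = s$annual_drug_cost,
           admin_events = as_events(s$admin_events),
           max_treatment_years = s$max_treatment_years,
           offset_years = s$offset_years,
           persistence_class = s$persistence_class,
           hazard_ratio = s$hazard_ratio)
    }),
    utilities = list(
      multiplier_year1 = as.list(config$utilities$multiplier_year1),
      multiplier_later = as.list(config$utilities$multiplier_later)
    ),
    costs = list(
      fracture_year1 = as.list(config$costs$fracture_year1),
      hip_subsequent_annual = config$costs$hip_subsequent_annual,
      ltc_daily = config$costs$ltc_daily,
      ltc_admission_fraction = config$costs$ltc_admission_fraction,
      monitoring = as_events(config$costs$monitoring)
    )
  )
  path <- file.path(dir, basename)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' The packaged default configuration
#'
#' Loads the base-case configuration shipped with the package: a cohort of
#' 78-year-old US men with 23% prevalent vertebral fracture, six treatment
#' strategies, published incidence / efficacy / utility / cost tables, and
#' placeholder fixtures (life table, persistence schedule, post-fracture
#' mortality relative risks, baseline utilities) whose provenance flags mark
#' them as synthetic stand-ins for unprinted sources.
#'
#' @return A validated `osteo_config`.
#' @export
default_config <- function() {
  load_config(system.file("extdata", "default", "config.yaml",
                          package = "osteocea", mustWork = TRUE))
}

#' Annual fracture incidence at a given age
#'
#' Looks up the age band containing `age` (bands are closed-open in whole
#' years, e.g. 75-79 covers ages in \[75, 80); the last band is open-ended).
#'
#' @param epi Epidemiology table from a configuration
#'   (`config$epidemiology`).
#' @param age Age in years.
#' @param site One of `"hip"`, `"vertebral"`, `"nhnv"`.
#' @return Annual fracture probability for untreated men of that age.
#' @export
incidence_for_age <- function(epi, age, site) {
  site <- match.arg(site, FRACTURE_SITES)
  if (age < epi$lower[1]) {
    stop("age ", age, " is below the first incidence band (",
         epi$lower[1], ")", call. = FALSE)
  }
  band <- findInterval(age, epi$lower)
  epi[[site]][band]
}

#' Published base-case totals for the six packaged strategies
#'
#' Reference discounted lifetime cost, life-year and QALY totals for the six
#' strategies of the packaged base case, as published for this model.  Used
#' to exercise frontier arithmetic independently of the simulation engine.
#'
#' @return Data frame with columns `strategy`, `cost`, `lys`, `qalys`.
#' @export
load_reference_totals <- function() {
  read_fixture_csv(system.file("extdata", "reference_base_case_totals.csv",
                               package = "osteocea", mustWork = TRUE))
}

#' @export
print.osteo_config <- function(x, ...) {
  cat("<osteo_config>\n")
  cat("  cohort: age", x$population$start_age, "to", x$population$max_age,
      "| prevalent vertebral fracture",
      x$population$prevalent_vertebral_fraction, "\n")
  cat("  strategies:", paste(names(x$strategies), collapse = ", "), "\n")
  cat("  discounting:", x$run_settings$discount_rate_costs, "(costs),",
      x$run_settings$discount_rate_effects, "(effects)\n")
  invisible(x)
}
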