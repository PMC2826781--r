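# Model parameters: arm-level trial summaries, unit costs, utilities and
# economic settings, loaded from a JSON configuration file and validated
# against the documented schema.

cea_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_prop <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    cea_error(field, "must be a proportion in [0, 1]")
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    cea_error(field, "must be a finite non-negative number")
  }
  invisible(x)
}

check_count <- function(x, field) {
  check_nonneg(x, field)
  if (any(x != round(x))) cea_error(field, "must be an integer count")
  invisible(x)
}

#' @keywords internal
validate_arm_summary <- function(arm, label = arm$arm_label) {
  required <- c("arm_label", "n_treated", "n_recurrences", "n_deaths",
                "ae_rates", "prophylaxis_patients", "prophylaxis_cycles")
  missing <- setdiff(required, names(arm))
  if (length(missing)) {
    cea_error(paste0("arms.", label),
              paste("missing field(s):", paste(missing, collapse = ", ")))
  }
  pre <- function(f) paste0("arms.", label, ".", f)
  check_count(arm$n_treated, pre("n_treated"))
  if (arm$n_treated < 1) cea_error(pre("n_treated"), "must be >= 1")
  check_count(arm$n_recurrences, pre("n_recurrences"))
  check_count(arm$n_deaths, pre("n_deaths"))
  check_count(arm$prophylaxis_patients, pre("prophylaxis_patients"))
  check_count(arm$prophylaxis_cycles, pre("prophylaxis_cycles"))
  if (arm$n_recurrences > arm$n_treated) {
    cea_error(pre("n_recurrences"), "exceeds n_treated")
  }
  if (arm$n_deaths > arm$n_treated) {
    cea_error(pre("n_deaths"), "exceeds n_treated")
  }
  if (arm$prophylaxis_patients > arm$n_treated) {
    cea_error(pre("prophylaxis_patients"), "exceeds n_treated")
  }
  for (ev in names(arm$ae_rates)) {
    check_prop(arm$ae_rates[[ev]], pre(paste0("ae_rates.", ev)))
  }
  arm$ae_rates <- lapply(arm$ae_rates, as.numeric)
  class(arm) <- "cea_arm_summary"
  arm
}

#' Construct an arm-level trial summary
#'
#' Bundles the 5-year outcome counts, grade 3/4 adverse-event rates and
#' secondary-prophylaxis counts observed for one trial arm.
#'
#' @param arm_label arm name, e.g. "TAC".
#' @param n_treated number of patients treated in the arm.
#' @param n_recurrences number of recurrences (any site) over the trial
#'   horizon.
#' @param n_deaths number of deaths over the trial horizon.
#' @param ae_rates named list of adverse-event proportions in [0, 1].
#' @param prophylaxis_patients number of patients who received any
#'   secondary G-CSF prophylaxis.
#' @param prophylaxis_cycles total chemotherapy cycles under secondary
#'   prophylaxis across those patients.
#' @return An object of class \code{cea_arm_summary}.
#' @export
arm_trial_summary <- function(arm_label, n_treated, n_recurrences, n_deaths,
                              ae_rates = list(),
                              prophylaxis_patients = 0,
                              prophylaxis_cycles = 0) {
  validate_arm_summary(list(
    arm_label = arm_label, n_treated = n_treated,
    n_recurrences = n_recurrences, n_deaths = n_deaths,
    ae_rates = ae_rates,
    prophylaxis_patients = prophylaxis_patients,
    prophylaxis_cycles = prophylaxis_cycles
  ), label = arm_label)
}

# documented defaults for optional configuration fields
config_defaults <- function() {
  list(
    costs = list(
      her2_positive_fraction = 0.20,
      line_utilization = list(line1 = 0.80, line2 = 0.50, line3 = 0.25)
    ),
    settings = list(
      discount_rate_annual = 0.05,
      cycle_length = 0.5,
      trial_horizon_cycles = 10L,
      gcsf_days_per_cycle = 7L,
      patient_weight_kg = 60,
      treatment_phase_cycles = 6L
    ),
    transitions = list(
      percent_met_relapse = 0.80,
      p_met_relapse = 0.065,
      death_allocation = list(no_recurrence = 0.5, locoregional = 0.1,
                              distant = 0.4),
      relapse_scale = list()
    )
  )
}

fill_defaults <- function(section, defaults, section_name, quiet) {
  for (f in names(defaults)) {
    if (is.null(section[[f]])) {
      section[[f]] <- defaults[[f]]
      if (!quiet) {
        message(sprintf("config: '%s.%s' not given, using default %s",
                        section_name, f,
                        paste(deparse(defaults[[f]], width.cutoff = 120),
                              collapse = "")))
      }
    }
  }
  section
}

validate_costs <- function(costs) {
  scalar_fields <- c("gcsf_cost_per_event", "antibiotic_prophylaxis",
                     "supportive_care_average", "diagnostics_at_diagnosis",
                     "lab_tests", "followup_metastatic_annual")
  for (f in scalar_fields) {
    if (is.null(costs[[f]])) cea_error(paste0("costs.", f), "is required")
    check_nonneg(costs[[f]], paste0("costs.", f))
  }
  for (f in c("drug_acquisition", "chemo_administration")) {
    if (is.null(costs[[f]])) cea_error(paste0("costs.", f), "is required")
    for (arm in names(costs[[f]])) {
      check_nonneg(costs[[f]][[arm]], paste0("costs.", f, ".", arm))
    }
  }
  for (ev in names(costs$ae_unit_costs)) {
    check_nonneg(costs$ae_unit_costs[[ev]],
                 paste0("costs.ae_unit_costs.", ev))
  }
  fu <- costs$followup_no_recurrence
  if (is.null(fu$years_1_3) || is.null(fu$after_year_3)) {
    cea_error("costs.followup_no_recurrence",
              "needs 'years_1_3' and 'after_year_3'")
  }
  check_nonneg(fu$years_1_3, "costs.followup_no_recurrence.years_1_3")
  check_nonneg(fu$after_year_3, "costs.followup_no_recurrence.after_year_3")
  if (!is.null(costs$followup_locoregional_schedule)) {
    check_nonneg(unlist(costs$followup_locoregional_schedule),
                 "costs.followup_locoregional_schedule")
    if (is.null(costs$followup_locoregional_annual)) {
      costs$followup_locoregional_annual <-
        mean(unlist(costs$followup_locoregional_schedule))
    }
  }
  if (is.null(costs$followup_locoregional_annual)) {
    cea_error("costs.followup_locoregional_annual",
              "is required (directly or via followup_locoregional_schedule)")
  }
  check_nonneg(costs$followup_locoregional_annual,
               "costs.followup_locoregional_annual")
  check_prop(costs$her2_positive_fraction, "costs.her2_positive_fraction")
  for (ln in names(costs$line_utilization)) {
    check_prop(costs$line_utilization[[ln]],
               paste0("costs.line_utilization.", ln))
  }
  for (arm in names(costs$met_chemo_line_costs)) {
    lines <- costs$met_chemo_line_costs[[arm]]
    for (ln in names(lines)) {
      rng <- unlist(lines[[ln]])
      check_nonneg(rng, paste0("costs.met_chemo_line_costs.", arm, ".", ln))
      if (length(rng) != 2 || rng[2] < rng[1]) {
        cea_error(paste0("costs.met_chemo_line_costs.", arm, ".", ln),
                  "must be a non-decreasing [her2-, her2+] cost pair")
      }
    }
  }
  if (!is.null(costs$supportive_care_components)) {
    for (comp in names(costs$supportive_care_components)) {
      check_nonneg(unlist(costs$supportive_care_components[[comp]]),
                   paste0("costs.supportive_care_components.", comp))
    }
  }
  costs
}

validate_utilities <- function(util) {
  for (f in c("u_no_recurrence", "u_locoregional", "u_adjuvant_fac")) {
    if (is.null(util[[f]])) cea_error(paste0("utilities.", f), "is required")
    check_prop(util[[f]], paste0("utilities.", f))
  }
  rng <- unlist(util$u_distant_range)
  if (length(rng) != 2) {
    cea_error("utilities.u_distant_range", "must be a (low, high) pair")
  }
  check_prop(rng, "utilities.u_distant_range")
  if (rng[2] < rng[1]) {
    cea_error("utilities.u_distant_range", "low exceeds high")
  }
  check_prop(util$disutility_tac, "utilities.disutility_tac")
  check_prop(util$disutility_fac, "utilities.disutility_fac")
  if (util$disutility_tac < util$disutility_fac) {
    cea_error("utilities.disutility_tac",
              "must be >= disutility_fac (taxane arm carries more toxicity)")
  }
  util
}

validate_settings <- function(st) {
  check_nonneg(st$discount_rate_annual, "settings.discount_rate_annual")
  check_nonneg(st$cycle_length, "settings.cycle_length")
  if (st$cycle_length <= 0) {
    cea_error("settings.cycle_length", "must be > 0")
  }
  check_count(st$trial_horizon_cycles, "settings.trial_horizon_cycles")
  if (st$trial_horizon_cycles < 1) {
    cea_error("settings.trial_horizon_cycles", "must be >= 1")
  }
  check_count(st$gcsf_days_per_cycle, "settings.gcsf_days_per_cycle")
  check_nonneg(st$patient_weight_kg, "settings.patient_weight_kg")
  check_count(st$treatment_phase_cycles, "settings.treatment_phase_cycles")
  le <- st$remaining_life_expectancy
  if (is.null(le)) {
    cea_error("settings.remaining_life_expectancy", "is required")
  }
  for (s in alive_states()) {
    if (is.null(le[[s]])) {
      cea_error(paste0("settings.remaining_life_expectancy.", s),
                "is required")
    }
    check_nonneg(le[[s]], paste0("settings.remaining_life_expectancy.", s))
  }
  st
}

validate_transitions <- function(tr) {
  check_prop(tr$percent_met_relapse, "transitions.percent_met_relapse")
  check_prop(tr$p_met_relapse, "transitions.p_met_relapse")
  w <- unlist(tr$death_allocation[alive_states()])
  if (length(w) != 3 || any(is.na(w))) {
    cea_error("transitions.death_allocation",
              "must give a weight for each non-absorbing state")
  }
  check_nonneg(w, "transitions.death_allocation")
  if (abs(sum(w) - 1) > 1e-8) {
    cea_error("transitions.death_allocation", "weights must sum to 1")
  }
  for (arm in names(tr$relapse_scale)) {
    check_nonneg(tr$relapse_scale[[arm]],
                 paste0("transitions.relapse_scale.", arm))
  }
  tr
}

validate_primary_prophylaxis <- function(pp) {
  if (is.null(pp)) return(NULL)
  for (blk in c("ae_rates_pre", "ae_rates_post", "ae_rates_fac")) {
    for (ev in names(pp[[blk]])) {
      check_prop(pp[[blk]][[ev]],
                 paste0("primary_prophylaxis.", blk, ".", ev))
    }
  }
  fn_pre <- pp$ae_rates_pre$febrile_neutropenia
  fn_post <- pp$ae_rates_post$febrile_neutropenia
  if (!is.null(fn_pre) && !is.null(fn_post) && fn_post > fn_pre) {
    cea_error("primary_prophylaxis.ae_rates_post.febrile_neutropenia",
              "post-prophylaxis rate exceeds pre-prophylaxis rate")
  }
  check_nonneg(pp$gcsf_cost_all_cycles,
               "primary_prophylaxis.gcsf_cost_all_cycles")
  pp
}

#' Validate a full model configuration
#'
#' Applies every schema invariant and fills documented defaults. Called by
#' \code{\link{load_model_config}}; exposed so programmatically built
#' configurations can be checked the same way.
#'
#' @param config nested list following the configuration schema.
#' @param quiet suppress messages about defaults being applied.
#' @return The validated configuration, class \code{cea_config}.
#' @export
validate_model_config <- function(config, quiet = FALSE) {
  defs <- config_defaults()
  if (is.null(config$arms) || length(config$arms) < 1) {
    cea_error("arms", "at least one arm is required")
  }
  for (a in names(config$arms)) {
    if (is.null(config$arms[[a]]$arm_label)) {
      config$arms[[a]]$arm_label <- a
    }
    config$arms[[a]] <- validate_arm_summary(config$arms[[a]], label = a)
  }
  config$costs <- fill_defaults(config$costs, defs$costs, "costs", quiet)
  config$costs <- validate_costs(config$costs)
  config$utilities <- validate_utilities(config$utilities)
  config$settings <- fill_defaults(config$settings, defs$settings,
                                   "settings", quiet)
  config$settings <- validate_settings(config$settings)
  config$transitions <- fill_defaults(config$transitions, defs$transitions,
                                      "transitions", quiet)
  config$transitions <- validate_transitions(config$transitions)
  config$primary_prophylaxis <-
    validate_primary_prophylaxis(config$primary_prophylaxis)
  class(config) <- "cea_config"
  config
}

#' Load a model configuration file
#'
#' Reads a JSON configuration holding the arm-level trial summaries, unit
#' costs (2006 CAD), utility weights, economic settings and transition
#' parameters, validates every schema invariant and fills documented
#' defaults. The bundled base-case configuration is available via
#' \code{system.file("extdata", "tacfac_2006.json", package = "oncoMarkov")}.
#'
#' @param path path to a JSON configuration file.
#' @param quiet suppress messages echoing applied defaults.
#' @return A validated configuration object of class \code{cea_config} with
#'   elements \code{arms}, \code{costs}, \code{utilities}, \code{settings},
#'   \code{transitions} and (optionally) \code{primary_prophylaxis}.
#' @export
#' @examples
#' cfg <- load_model_config(system.file("extdata", "tacfac_2006.json",
#'                                      package = "oncoMarkov"), quiet = TRUE)
#' cfg$arms$TAC$n_treated
load_model_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_model_config(raw, quiet = quiet)
}

#' Serialize a configuration back to JSON
#'
#' Round-trips with \code{\link{load_model_config}}: saving and reloading a
#' validated configuration yields identical parameter values.
#'
#' @param config a \code{cea_config} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_model_config <- function(config, path) {
  out <- unclass(config)
  out$arms <- lapply(out$arms, unclass)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.cea_config <- function(x, ...) {
  cat("Cost-effectiveness model configuration\n")
  for (a in names(x$arms)) {
    arm <- x$arms[[a]]
    cat(sprintf("  arm %-4s n=%d, recurrences=%d (%.1f%%), deaths=%d (%.1f%%)\n",
                a, arm$n_treated, arm$n_recurrences,
                100 * arm$n_recurrences / arm$n_treated, arm$n_deaths,
                100 * arm$n_deaths / arm$n_treated))
  }
  cat(sprintf("  discount %.1f%%/yr, cycle %.2g yr, trial horizon %d cycles\n",
              100 * x$settings$discount_rate_annual, x$settings$cycle_length,
              x$settings$trial_horizon_cycles))
  invisible(x)
}

# ---- derived per-patient cost and utility aggregates -----------------------

#' Adjuvant treatment cost for an arm
#'
#' Drug acquisition plus chemotherapy administration for the full 6-cycle
#' course, applied once at time 0.
#'
#' @param costs the \code{costs} section of a configuration.
#' @param arm arm label present in the cost tables.
#' @return Cost in CAD.
#' @export
#' @examples
#' cfg <- load_model_config(system.file("extdata", "tacfac_2006.json",
#'                                      package = "oncoMarkov"), quiet = TRUE)
#' treatment_cost(cfg$costs, "TAC")  # 10546.08
treatment_cost <- function(costs, arm) {
  acq <- costs$drug_acquisition[[arm]]
  adm <- costs$chemo_administration[[arm]]
  if (is.null(acq) || is.null(adm)) {
    stop("unknown arm label: ", arm, call. = FALSE)
  }
  acq + adm
}

#' Expected adverse-event management cost per patient
#'
#' Sum over grade 3/4 events of (rate x unit cost), plus the prophylactic
#' antibiotic course every patient receives. Applied once at time 0.
#'
#' @param arm a \code{cea_arm_summary}.
#' @param costs the \code{costs} section of a configuration.
#' @param include_antibiotics add the per-patient antibiotic prophylaxis
#'   cost (default TRUE).
#' @return Cost in CAD.
#' @export
average_ae_cost <- function(arm, costs, include_antibiotics = TRUE) {
  total <- 0
  for (ev in names(arm$ae_rates)) {
    unit <- costs$ae_unit_costs[[ev]]
    if (is.null(unit)) {
      stop("adverse event '", ev, "' has a rate but no unit cost",
           call. = FALSE)
    }
    total <- total + arm$ae_rates[[ev]] * unit
  }
  if (include_antibiotics) total <- total + costs$antibiotic_prophylaxis
  total
}

#' Expected secondary G-CSF prophylaxis cost per patient
#'
#' Cost per prophylaxis event multiplied by the proportion of patients who
#' received any secondary prophylaxis and by the average number of cycles
#' under prophylaxis among them; algebraically
#' \code{gcsf_cost_per_event * prophylaxis_cycles / n_treated}. Applied once
#' at time 0.
#'
#' @inheritParams average_ae_cost
#' @return Cost in CAD.
#' @export
secondary_prophylaxis_cost <- function(arm, costs) {
  if (arm$prophylaxis_patients == 0) return(0)
  p_any <- arm$prophylaxis_patients / arm$n_treated
  mean_cycles <- arm$prophylaxis_cycles / arm$prophylaxis_patients
  costs$gcsf_cost_per_event * p_any * mean_cycles
}

#' Per-state utility weights for an arm
#'
#' State utilities are shared across arms; only the treatment-phase weight
#' differs, by the incremental adverse-event disutility of the taxane arm
#' relative to the reference arm.
#'
#' @param util the \code{utilities} section of a configuration.
#' @param arm arm label; the arm named \code{taxane_arm} carries the
#'   incremental disutility.
#' @param taxane_arm which arm label receives the extra disutility
#'   (default \code{"TAC"}).
#' @return Named list with \code{treatment} (weight while on chemotherapy,
#'   applied to No Recurrence occupancy during the treatment phase),
#'   \code{no_recurrence}, \code{locoregional}, \code{distant} (midpoint of
#'   the configured range) and \code{dead} (0).
#' @export
#' @examples
#' cfg <- load_model_config(system.file("extdata", "tacfac_2006.json",
#'                                      package = "oncoMarkov"), quiet = TRUE)
#' arm_utilities(cfg$utilities, "TAC")$treatment  # 0.7163
arm_utilities <- function(util, arm, taxane_arm = "TAC") {
  inc_dis <- if (identical(arm, taxane_arm)) {
    util$disutility_tac - util$disutility_fac
  } else {
    0
  }
  treatment <- util$u_adjuvant_fac - inc_dis
  rng <- unlist(util$u_distant_range)
  out <- list(
    treatment     = treatment,
    no_recurrence = util$u_no_recurrence,
    locoregional  = util$u_locoregional,
    distant       = mean(rng),
    dead          = 0
  )
  bad <- vapply(out, function(u) u < 0 || u > 1, logical(1))
  if (any(bad)) {
    cea_error("utilities", "derived utility weight outside [0, 1]")
  }
  out
}

#' Annual follow-up cost by health state
#'
#' No Recurrence follows the declining schedule (one value for years 1-3,
#' a lower one thereafter); Locoregional uses the single 6-year average;
#' Distant uses the flat annual value.
#'
#' @param state one of the non-absorbing health-state keys.
#' @param year 1-based year since entering the model phase.
#' @param costs the \code{costs} section of a configuration.
#' @return Cost in CAD per year.
#' @export
annual_followup_cost <- function(state, year, costs) {
  if (identical(state, "dead")) {
    stop("follow-up cost requested for the absorbing state", call. = FALSE)
  }
  switch(state,
    no_recurrence = if (year <= 3) costs$followup_no_recurrence$years_1_3
                    else costs$followup_no_recurrence$after_year_3,
    locoregional  = costs$followup_locoregional_annual,
    distant       = costs$followup_metastatic_annual,
    stop("unknown health state: ", state, call. = FALSE)
  )
}

#' Expected metastatic chemotherapy cost per patient entering Distant
#'
#' Per-line expected cost is the HER2-prevalence-weighted value of the
#' configured [HER2-, HER2+] cost pair; lines are weighted by their
#' utilization proportions and summed. Fourth and later lines are priced
#' as line 3 and folded into its utilization. Charged once on the
#' transition into the Distant state.
#'
#' @param costs the \code{costs} section of a configuration.
#' @param arm arm label present in \code{met_chemo_line_costs}.
#' @return Cost in CAD.
#' @export
expected_met_chemo_cost <- function(costs, arm) {
  lines <- costs$met_chemo_line_costs[[arm]]
  if (is.null(lines)) stop("unknown arm label: ", arm, call. = FALSE)
  f <- costs$her2_positive_fraction
  total <- 0
  for (ln in names(lines)) {
    rng <- unlist(lines[[ln]])
    util <- costs$line_utilization[[ln]]
    if (is.null(util)) {
      cea_error(paste0("costs.line_utilization.", ln), "is required")
    }
    total <- total + util * ((1 - f) * rng[1] + f * rng[2])
  }
  total
}

#' Undiscounted cost applied at model start for one arm
#'
#' Adjuvant drug and administration, expected adverse-event management,
#' antibiotic prophylaxis, secondary G-CSF prophylaxis, average supportive
#' care, diagnostics at diagnosis and laboratory work-up. All are applied
#' once at time 0 and therefore undiscounted.
#'
#' @param config a \code{cea_config}.
#' @param arm arm label.
#' @return Cost in CAD.
#' @export
time_zero_cost <- function(config, arm) {
  costs <- config$costs
  summ <- config$arms[[arm]]
  if (is.null(summ)) stop("unknown arm label: ", arm, call. = FALSE)
  treatment_cost(costs, arm) +
    average_ae_cost(summ, costs) +
    secondary_prophylaxis_cost(summ, costs) +
    costs$supportive_care_average +
    costs$diagnostics_at_diagnosis +
    costs$lab_tests
}
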