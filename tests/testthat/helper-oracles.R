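# Shared fixtures and independent oracles for the test suite.

base_config_path <- function() {
  system.file("extdata", "tacfac_2006.json", package = "oncoMarkov")
}

base_config <- function() {
  load_model_config(base_config_path(), quiet = TRUE)
}

oneway_catalogue_path <- function() {
  system.file("extdata", "scenarios_oneway.json", package = "oncoMarkov")
}

# Independent oracle: exhaustive enumeration of all state paths, weighted
# by path probability. Start state is the first row.
brute_force_occupancy <- function(P, n_cycles) {
  n_s <- nrow(P)
  occ <- matrix(0, n_cycles + 1, n_s, dimnames = list(NULL, rownames(P)))
  occ[1, 1] <- 1
  grid <- expand.grid(rep(list(seq_len(n_s)), n_cycles))
  for (i in seq_len(nrow(grid))) {
    path <- c(1L, as.integer(grid[i, ]))
    w <- prod(P[cbind(path[-length(path)], path[-1])])
    if (w > 0) {
      for (t in seq_len(n_cycles)) {
        occ[t + 1, path[t + 1]] <- occ[t + 1, path[t + 1]] + w
      }
    }
  }
  occ
}

# a small, fully valid transition model built by hand
toy_model <- function(p_relapse = 0.05, percent_met_relapse = 0.6,
                      p_met_relapse = 0.1,
                      p_death = c(no_recurrence = 0.02,
                                  locoregional = 0.04, distant = 0.2)) {
  arm <- arm_trial_summary("toy", 100, 0, 0)
  m <- derive_transition_model(arm, percent_met_relapse,
                               list(no_recurrence = 0.2, locoregional = 0.2,
                                    distant = 0.6),
                               n_cycles = 10, p_met_relapse = p_met_relapse)
  # overwrite the derived scalars with the requested ones
  m$p_relapse <- p_relapse
  m$p_death_from <- p_death
  m$matrix <- oncoMarkov:::build_transition_matrix(
    p_relapse, percent_met_relapse, p_met_relapse, p_death)
  m
}

toy_costs <- function(scale = 1) {
  list(
    followup_no_recurrence = list(years_1_3 = 100 * scale,
                                  after_year_3 = 50 * scale),
    followup_locoregional_annual = 200 * scale,
    followup_metastatic_annual = 400 * scale
  )
}

toy_utils <- function(all_one = FALSE) {
  if (all_one) {
    list(treatment = 1, no_recurrence = 1, locoregional = 1, distant = 1,
         dead = 0)
  } else {
    list(treatment = 0.7, no_recurrence = 0.9, locoregional = 0.8,
         distant = 0.5, dead = 0)
  }
}

toy_settings <- function(r = 0.05, n_cycles = 4, le = c(10, 5, 1)) {
  list(
    discount_rate_annual = r, cycle_length = 0.5,
    trial_horizon_cycles = n_cycles, treatment_phase_cycles = 2,
    gcsf_days_per_cycle = 7, patient_weight_kg = 60,
    remaining_life_expectancy = list(no_recurrence = le[1],
                                     locoregional = le[2], distant = le[3])
  )
}
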