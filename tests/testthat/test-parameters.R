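test_that("bundled configuration loads with the published arm summaries", {
  cfg <- base_config()
  expect_s3_class(cfg, "cea_config")
  expect_identical(cfg$arms$TAC$n_treated, 744L)
  expect_identical(cfg$arms$FAC$n_treated, 736L)
  expect_identical(cfg$arms$TAC$n_recurrences, 141L)
  expect_identical(cfg$arms$FAC$n_deaths, 246L)
  expect_equal(cfg$arms$TAC$ae_rates$febrile_neutropenia, 0.247)
  expect_equal(cfg$arms$TAC$prophylaxis_patients, 217L)
})

test_that("configuration validation names the offending field", {
  cfg <- base_config()
  bad <- unclass(cfg)
  bad$arms$TAC$ae_rates$febrile_neutropenia <- 1.2
  expect_error(validate_model_config(bad, quiet = TRUE),
               "arms.TAC.ae_rates.febrile_neutropenia")

  bad <- unclass(cfg)
  bad$costs$gcsf_cost_per_event <- -1
  expect_error(validate_model_config(bad, quiet = TRUE),
               "costs.gcsf_cost_per_event")

  bad <- unclass(cfg)
  bad$arms$FAC$prophylaxis_patients <- 9999L
  expect_error(validate_model_config(bad, quiet = TRUE),
               "prophylaxis_patients")

  bad <- unclass(cfg)
  bad$utilities$disutility_fac <- 0.05  # above the taxane disutility
  expect_error(validate_model_config(bad, quiet = TRUE), "disutility_tac")
})

test_that("omitted optional fields get documented defaults, with a message", {
  raw <- jsonlite::read_json(base_config_path(), simplifyVector = FALSE)
  raw$costs$her2_positive_fraction <- NULL
  expect_message(cfg <- validate_model_config(raw),
                 "her2_positive_fraction")
  expect_equal(cfg$costs$her2_positive_fraction, 0.20)

  raw$settings$discount_rate_annual <- NULL
  cfg <- validate_model_config(raw, quiet = TRUE)
  expect_equal(cfg$settings$discount_rate_annual, 0.05)
})

test_that("configurations round-trip through serialization", {
  cfg <- base_config()
  path <- withr::local_tempfile(fileext = ".json")
  save_model_config(cfg, path)
  cfg2 <- load_model_config(path, quiet = TRUE)
  expect_equal(cfg2$arms, cfg$arms)
  expect_equal(cfg2$costs, cfg$costs)
  expect_equal(cfg2$utilities, cfg$utilities)
  expect_equal(cfg2$settings, cfg$settings)
  expect_equal(cfg2$transitions, cfg$transitions)
})

test_that("treatment cost is drug acquisition plus administration", {
  cfg <- base_config()
  expect_equal(treatment_cost(cfg$costs, "TAC"), 10546.08)
  expect_equal(treatment_cost(cfg$costs, "FAC"), 1215.18)
  expect_error(treatment_cost(cfg$costs, "XYZ"), "unknown arm")
  zero <- list(drug_acquisition = list(Z = 0), chemo_administration = list(Z = 0))
  expect_equal(treatment_cost(zero, "Z"), 0)
})

test_that("average adverse-event cost is the rate-weighted sum plus antibiotics", {
  cfg <- base_config()
  # hand sum: 0.247*2367.23 + 0.071*3151.18 + 0.038*2760.30 + 0.039*2367.30
  expect_equal(average_ae_cost(cfg$arms$TAC, cfg$costs,
                               include_antibiotics = FALSE), 1005.65569)
  expect_equal(average_ae_cost(cfg$arms$TAC, cfg$costs),
               1005.65569 + 314.10)
  expect_equal(average_ae_cost(cfg$arms$FAC, cfg$costs,
                               include_antibiotics = FALSE), 223.97035)

  none <- arm_trial_summary("none", 100, 0, 0,
                            ae_rates = list(febrile_neutropenia = 0))
  expect_equal(average_ae_cost(none, cfg$costs), 314.10)

  orphan <- arm_trial_summary("o", 100, 0, 0, ae_rates = list(rash = 0.1))
  expect_error(average_ae_cost(orphan, cfg$costs), "rash")
})

test_that("average adverse-event cost is linear in each rate", {
  cfg <- base_config()
  full <- average_ae_cost(cfg$arms$TAC, cfg$costs)
  for (ev in names(cfg$arms$TAC$ae_rates)) {
    arm <- cfg$arms$TAC
    rate <- arm$ae_rates[[ev]]
    arm$ae_rates[[ev]] <- 0
    expect_equal(average_ae_cost(arm, cfg$costs),
                 full - rate * cfg$costs$ae_unit_costs[[ev]])
  }
})

test_that("secondary prophylaxis cost follows the three-factor product", {
  cfg <- base_config()
  expect_equal(secondary_prophylaxis_cost(cfg$arms$TAC, cfg$costs),
               1239.77 * (217 / 744) * (799 / 217))
  expect_equal(round(secondary_prophylaxis_cost(cfg$arms$TAC, cfg$costs), 2),
               1331.42)
  expect_equal(secondary_prophylaxis_cost(cfg$arms$FAC, cfg$costs),
               1239.77 * 126 / 736)
  none <- arm_trial_summary("none", 100, 0, 0)
  expect_equal(secondary_prophylaxis_cost(none, cfg$costs), 0)
})

test_that("three-factor prophylaxis form cancels to cycles over n", {
  cfg <- base_config()
  set.seed(11)
  for (i in 1:25) {
    n <- sample(50:1000, 1)
    pts <- sample(1:n, 1)
    cyc <- pts + stats::rpois(1, 2 * pts)
    arm <- arm_trial_summary("x", n, 0, 0, prophylaxis_patients = pts,
                             prophylaxis_cycles = cyc)
    expect_equal(secondary_prophylaxis_cost(arm, cfg$costs),
                 cfg$costs$gcsf_cost_per_event * cyc / n)
  }
})

test_that("utility construction subtracts the incremental disutility", {
  cfg <- base_config()
  u_tac <- arm_utilities(cfg$utilities, "TAC")
  u_fac <- arm_utilities(cfg$utilities, "FAC")
  expect_equal(u_tac$treatment, 0.7163)
  expect_equal(u_fac$treatment, 0.72)
  expect_equal(u_tac$distant, 0.57)  # midpoint of 0.49-0.65
  # state utilities identical across arms
  for (s in c("no_recurrence", "locoregional", "distant", "dead")) {
    expect_identical(u_tac[[s]], u_fac[[s]])
  }
  # equal disutilities collapse the treatment-phase difference
  util <- cfg$utilities
  util$disutility_tac <- util$disutility_fac
  expect_equal(arm_utilities(util, "TAC")$treatment, 0.72)
})

test_that("derived utilities stay in [0, 1] for valid inputs", {
  set.seed(21)
  for (i in 1:50) {
    util <- list(
      u_no_recurrence = runif(1), u_locoregional = runif(1),
      u_distant_range = sort(runif(2)),
      u_adjuvant_fac = runif(1, 0.3, 1),
      disutility_fac = runif(1, 0, 0.1)
    )
    util$disutility_tac <- util$disutility_fac + runif(1, 0, 0.2)
    for (u in unlist(arm_utilities(util, "TAC"))) {
      expect_gte(u, 0)
      expect_lte(u, 1)
    }
  }
})

test_that("annual follow-up costs follow the published schedules", {
  cfg <- base_config()
  # 6-year average of (1032.76 x2, 764.27 x2, 620.65 x2)
  expect_equal(annual_followup_cost("locoregional", 1, cfg$costs),
               805.89, tolerance = 1e-4)
  expect_equal(annual_followup_cost("no_recurrence", 2, cfg$costs), 582.82)
  expect_equal(annual_followup_cost("no_recurrence", 5, cfg$costs), 356.93)
  expect_equal(annual_followup_cost("distant", 3, cfg$costs), 1729.10)
  expect_error(annual_followup_cost("dead", 1, cfg$costs), "absorbing")
})

test_that("expected metastatic line costs weight utilization and HER2 mix", {
  cfg <- base_config()
  # frozen hand computation with her2+ fraction 0.2, utilization .8/.5/.25
  expect_equal(expected_met_chemo_cost(cfg$costs, "TAC"), 22427.88)
  expect_equal(expected_met_chemo_cost(cfg$costs, "FAC"), 19725.72)
  expect_error(expected_met_chemo_cost(cfg$costs, "XYZ"), "unknown arm")
})

test_that("time-zero cost assembles every once-only component", {
  cfg <- base_config()
  expect_equal(
    time_zero_cost(cfg, "TAC"),
    10546.08 + (1005.65569 + 314.10) + 1239.77 * 799 / 744 +
      65.08 + 643.04 + 41.95
  )
})
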