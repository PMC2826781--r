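test_that("discount factors follow the annual rate and cycle length", {
  s <- list(discount_rate_annual = 0.05, cycle_length = 0.5)
  expect_equal(discount_factor(0, s), 1)
  expect_equal(discount_factor(2, s), 1 / 1.05)
  expect_equal(discount_factor(4, s), 1 / 1.05^2)
  s0 <- list(discount_rate_annual = 0, cycle_length = 0.5)
  expect_equal(discount_factor(0:20, s0), rep(1, 21))
  expect_error(discount_factor(-1, s), ">= 0")
})

test_that("a cohort that never moves accrues the discounted trial annuity", {
  still <- toy_model(p_relapse = 0, p_death = c(no_recurrence = 0,
                                                locoregional = 0,
                                                distant = 0))
  st <- toy_settings(r = 0.05, n_cycles = 10, le = c(0, 0, 0))
  tr <- run_cohort(still, toy_costs(), toy_utils(all_one = TRUE), st)
  # closed form: sum over 10 half-year cycles of 0.5 * 1.05^(-t/2)
  expect_equal(tr$total_lys, sum(0.5 * 1.05^(-(0:9) * 0.5)))
  expect_equal(tr$total_lys, 4.49117196639741)
  expect_equal(unname(tr$occupancy[11, ]), c(1, 0, 0, 0))
})

test_that("unit utilities make QALYs equal LYs exactly", {
  m <- toy_model()
  st <- toy_settings()
  tr <- run_cohort(m, toy_costs(), toy_utils(all_one = TRUE), st)
  expect_identical(tr$total_qalys, tr$total_lys)
})

test_that("two-state toy matches the path-enumeration life-years", {
  half <- toy_model(p_relapse = 0, p_death = c(no_recurrence = 0.5,
                                               locoregional = 0,
                                               distant = 0))
  st <- toy_settings(r = 0, n_cycles = 3, le = c(0, 0, 0))
  tr <- run_cohort(half, toy_costs(0), toy_utils(all_one = TRUE), st)
  # exhaustive paths: alive fractions 1, 1/2, 1/4 at cycle starts
  expect_equal(tr$total_lys, 0.5 * (1 + 0.5 + 0.25))
})

test_that("trial phase equals brute-force path enumeration to 1e-12", {
  m <- toy_model()
  st <- toy_settings(r = 0.05, n_cycles = 4)
  tr <- run_cohort(m, toy_costs(), toy_utils(), st,
                   time0_cost = 123, met_entry_cost = 1000)
  oracle_occ <- brute_force_occupancy(m$matrix, 4)
  expect_equal(unname(tr$occupancy), unname(oracle_occ), tolerance = 1e-12)

  # recompute the accumulators from the oracle occupancy
  cl <- 0.5
  u <- toy_utils()
  lys <- qalys <- costs <- 0
  for (t in 0:3) {
    d <- 1.05^(-t * cl)
    occ <- unname(oracle_occ[t + 1, ])
    lys <- lys + cl * d * sum(occ[1:3])
    u_nr <- if (t < st$treatment_phase_cycles) u$treatment else u$no_recurrence
    qalys <- qalys + cl * d * (occ[1] * u_nr + occ[2] * 0.8 + occ[3] * 0.5)
    year <- ceiling((t + 1) * cl)
    fu_nr <- if (year <= 3) 100 else 50
    costs <- costs + cl * d * (occ[1] * fu_nr + occ[2] * 200 + occ[3] * 400) +
      1000 * 1.05^(-(t + 1) * cl) *
        (occ[1] * m$matrix[1, 3] + occ[2] * m$matrix[2, 3])
  }
  expect_equal(sum(tr$cycle_lys), lys, tolerance = 1e-12)
  expect_equal(sum(tr$cycle_qalys), qalys, tolerance = 1e-12)
  expect_equal(sum(tr$cycle_costs), costs, tolerance = 1e-12)
})

test_that("QALYs never exceed LYs under sub-unit utilities", {
  set.seed(33)
  for (i in 1:20) {
    m <- toy_model(p_relapse = runif(1, 0, 0.2),
                   percent_met_relapse = runif(1),
                   p_met_relapse = runif(1, 0, 0.3),
                   p_death = c(no_recurrence = runif(1, 0, 0.1),
                               locoregional = runif(1, 0, 0.2),
                               distant = runif(1, 0, 0.5)))
    st <- toy_settings(r = runif(1, 0, 0.1), n_cycles = sample(2:10, 1),
                       le = runif(3, 0, 20))
    tr <- run_cohort(m, toy_costs(), toy_utils(), st)
    expect_lte(tr$total_qalys, tr$total_lys)
  }
})

test_that("totals are nonincreasing in the discount rate", {
  m <- toy_model()
  prev <- NULL
  for (r in c(0, 0.03, 0.05, 0.1, 0.2)) {
    tr <- run_cohort(m, toy_costs(), toy_utils(), toy_settings(r = r),
                     time0_cost = 100, met_entry_cost = 500)
    if (!is.null(prev)) {
      expect_lte(tr$total_cost, prev$total_cost)
      expect_lte(tr$total_lys, prev$total_lys)
      expect_lte(tr$total_qalys, prev$total_qalys)
    }
    prev <- tr
  }
})

test_that("doubling all unit costs exactly doubles total cost", {
  m <- toy_model()
  st <- toy_settings()
  t1 <- run_cohort(m, toy_costs(1), toy_utils(), st,
                   time0_cost = 250, met_entry_cost = 800)
  t2 <- run_cohort(m, toy_costs(2), toy_utils(), st,
                   time0_cost = 500, met_entry_cost = 1600)
  expect_equal(t2$total_cost, 2 * t1$total_cost, tolerance = 1e-12)
  expect_identical(t2$total_lys, t1$total_lys)
})

test_that("the trace satisfies its occupancy invariants", {
  cfg <- base_config()
  res <- run_base_case(cfg)
  for (tr in res$traces) {
    expect_equal(rowSums(tr$occupancy), rep(1, 11), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(diff(tr$occupancy[, "dead"]) >= 0))
    acc <- c(tr$cycle_costs, tr$cycle_lys, tr$cycle_qalys, tr$ext_cost,
             tr$ext_lys, tr$ext_qalys, tr$total_cost, tr$total_lys,
             tr$total_qalys)
    expect_true(all(is.finite(acc)))
    expect_true(all(acc >= 0))
  }
})

test_that("extrapolation phase assigns discounted state life expectancies", {
  still <- toy_model(p_relapse = 0, p_death = c(no_recurrence = 0,
                                                locoregional = 0,
                                                distant = 0))
  st <- toy_settings(r = 0, n_cycles = 4, le = c(10, 5, 1))
  tr <- run_cohort(still, toy_costs(), toy_utils(all_one = TRUE), st)
  expect_equal(tr$ext_lys, 10)  # whole cohort still in no recurrence
  expect_equal(tr$total_lys, 2 + 10)
  # with discounting, the annuity is strictly below the undiscounted LE
  st5 <- toy_settings(r = 0.05, n_cycles = 4, le = c(10, 5, 1))
  tr5 <- run_cohort(still, toy_costs(), toy_utils(all_one = TRUE), st5)
  expect_lt(tr5$ext_lys, 10)
})

test_that("missing utility entries are reported", {
  m <- toy_model()
  u <- toy_utils()
  u$distant <- NULL
  expect_error(run_cohort(m, toy_costs(), u, toy_settings()), "distant")
})

test_that("trace tables carry one row per cycle plus extrapolation", {
  cfg <- base_config()
  tr <- run_arm(cfg, "TAC")
  tab <- trace_table(tr)
  expect_equal(nrow(tab), 11)
  expect_equal(tab$cycle[11], "extrapolation")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  expect_equal(nrow(utils::read.csv(path, check.names = FALSE)), 11)
})
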