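# Discounted cohort simulation over the two-phase horizon: a trial phase
# of matrix iteration (6-month cycles) followed by an extrapolation phase
# that assigns each surviving state a configurable remaining life
# expectancy.

#' Discount factor at the start of a model cycle
#'
#' \code{(1 + r)^(-cycle_index * cycle_length)} with \code{r} the annual
#' discount rate applied to costs and outcomes alike.
#'
#' @param cycle_index 0-based cycle index.
#' @param settings the \code{settings} section of a configuration.
#' @return Dimensionless discount factor in (0, 1].
#' @export
#' @examples
#' s <- list(discount_rate_annual = 0.05, cycle_length = 0.5)
#' discount_factor(2, s)  # 1/1.05
discount_factor <- function(cycle_index, settings) {
  if (any(cycle_index < 0)) {
    stop("cycle_index must be >= 0", call. = FALSE)
  }
  (1 + settings$discount_rate_annual) ^
    (-cycle_index * settings$cycle_length)
}

# Present value at time 0 of a continuous stream of 1/year over L years
# starting at year `start`, discounted at annual rate r.
discounted_annuity <- function(L, r, start = 0) {
  if (L <= 0) return(0)
  base <- if (r > 0) (1 - (1 + r)^(-L)) / log(1 + r) else L
  base * (1 + r)^(-start)
}

#' Run the discounted cohort simulation for one arm
#'
#' The cohort starts fully in No Recurrence. Time-0 costs are applied once,
#' undiscounted. Each trial-phase cycle accrues discounted life-years
#' (cycle length times the fraction alive), utility-weighted QALYs and
#' per-state follow-up costs, with state membership evaluated at cycle
#' start (no half-cycle correction); the expected metastatic chemotherapy
#' cost is charged on each transition into Distant. After
#' \code{trial_horizon_cycles} cycles, survivors in each state receive the
#' configured remaining life expectancy for that state as a continuous
#' discounted annuity of life-years, utility-weighted QALYs and
#' state-appropriate follow-up costs.
#'
#' While on chemotherapy (the first \code{treatment_phase_cycles} cycles)
#' No Recurrence occupancy is valued at the treatment-phase utility rather
#' than the No Recurrence state utility.
#'
#' @param model a \code{cea_transition_model}.
#' @param costs the \code{costs} section of a configuration (used for
#'   follow-up costs).
#' @param utils per-state utility map from \code{\link{arm_utilities}}.
#' @param settings the \code{settings} section of a configuration.
#' @param arm arm label recorded in the trace.
#' @param time0_cost undiscounted cost applied once at model start
#'   (assembled by \code{\link{time_zero_cost}}; default 0).
#' @param met_entry_cost expected metastatic chemotherapy cost charged per
#'   transition into Distant (default 0).
#' @return An object of class \code{cea_cohort_trace} with per-cycle
#'   occupancy, discounted cost/LY/QALY accumulators, the extrapolation
#'   phase contributions and phase totals.
#' @export
run_cohort <- function(model, costs, utils, settings, arm = model$arm_label,
                       time0_cost = 0, met_entry_cost = 0) {
  st <- health_states()
  for (s in st) {
    if (is.null(utils[[s]])) {
      stop("utility map missing state: ", s, call. = FALSE)
    }
  }
  if (is.null(utils$treatment)) {
    stop("utility map missing treatment-phase weight", call. = FALSE)
  }
  n <- settings$trial_horizon_cycles
  cl <- settings$cycle_length
  m <- model$matrix

  occupancy <- matrix(0, n + 1, 4, dimnames = list(0:n, st))
  occupancy[1, "no_recurrence"] <- 1
  cycle_costs <- cycle_lys <- cycle_qalys <- numeric(n)

  for (t in 0:(n - 1)) {
    occ <- occupancy[t + 1, ]
    d <- discount_factor(t, settings)
    u_nr <- if (t < settings$treatment_phase_cycles) utils$treatment
            else utils$no_recurrence
    alive <- sum(occ[alive_states()])
    cycle_lys[t + 1] <- cl * alive * d
    cycle_qalys[t + 1] <- cl * d *
      (occ[["no_recurrence"]] * u_nr +
       occ[["locoregional"]] * utils$locoregional +
       occ[["distant"]] * utils$distant)
    year <- ceiling((t + 1) * cl)
    fu <- sum(vapply(alive_states(), function(s) {
      occ[[s]] * annual_followup_cost(s, year, costs)
    }, numeric(1)))
    met_inflow <- occ[["no_recurrence"]] * m["no_recurrence", "distant"] +
      occ[["locoregional"]] * m["locoregional", "distant"]
    cycle_costs[t + 1] <- cl * fu * d +
      met_inflow * met_entry_cost * discount_factor(t + 1, settings)
    occupancy[t + 2, ] <- as.vector(occ %*% m)
  }

  # extrapolation phase: fixed remaining life expectancy by state at the
  # end of the trial horizon, discounted as a continuous annuity
  r <- settings$discount_rate_annual
  horizon_years <- n * cl
  le <- settings$remaining_life_expectancy
  final <- occupancy[n + 1, ]
  ext_cost <- ext_lys <- ext_qalys <- 0
  for (s in alive_states()) {
    a <- discounted_annuity(as.numeric(le[[s]]), r, start = horizon_years)
    ext_lys <- ext_lys + final[[s]] * a
    ext_qalys <- ext_qalys + final[[s]] * utils[[s]] * a
    ext_cost <- ext_cost + final[[s]] *
      annual_followup_cost(s, year = ceiling(horizon_years) + 1, costs) * a
  }

  trace <- list(
    arm = arm,
    occupancy = occupancy,
    cycle_costs = cycle_costs,
    cycle_lys = cycle_lys,
    cycle_qalys = cycle_qalys,
    time0_cost = time0_cost,
    ext_cost = ext_cost,
    ext_lys = ext_lys,
    ext_qalys = ext_qalys,
    total_cost = time0_cost + sum(cycle_costs) + ext_cost,
    total_lys = sum(cycle_lys) + ext_lys,
    total_qalys = sum(cycle_qalys) + ext_qalys,
    settings = settings
  )
  class(trace) <- "cea_cohort_trace"
  trace
}

#' @export
print.cea_cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace%s: %d trial cycles + extrapolation\n",
              if (!is.null(x$arm)) paste0(" (", x$arm, ")") else "",
              length(x$cycle_costs)))
  cat(sprintf("  total cost  %12.2f (time0 %.2f, trial %.2f, extrapolation %.2f)\n",
              x$total_cost, x$time0_cost, sum(x$cycle_costs), x$ext_cost))
  cat(sprintf("  total LYs   %12.4f (trial %.4f, extrapolation %.4f)\n",
              x$total_lys, sum(x$cycle_lys), x$ext_lys))
  cat(sprintf("  total QALYs %12.4f (trial %.4f, extrapolation %.4f)\n",
              x$total_qalys, sum(x$cycle_qalys), x$ext_qalys))
  invisible(x)
}

#' Tabulate a cohort trace
#'
#' One row per trial cycle (state occupancies at cycle start plus the
#' discounted cost/LY/QALY accrued over that cycle) and a final
#' extrapolation row.
#'
#' @param trace a \code{cea_cohort_trace}.
#' @return A \code{data.frame}.
#' @export
trace_table <- function(trace) {
  n <- length(trace$cycle_costs)
  df <- data.frame(
    cycle = c(0:(n - 1), "extrapolation"),
    trace$occupancy[c(seq_len(n), n + 1), , drop = FALSE],
    cost = c(trace$cycle_costs, trace$ext_cost),
    lys = c(trace$cycle_lys, trace$ext_lys),
    qalys = c(trace$cycle_qalys, trace$ext_qalys),
    row.names = NULL,
    check.names = FALSE
  )
  df
}

#' Write a cohort trace as a delimited table
#'
#' @param trace a \code{cea_cohort_trace}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace_table(trace), path, row.names = FALSE)
  invisible(path)
}
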