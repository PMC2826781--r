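# One-way scenario analyses, bootstrap resampling of the trial outcome
# counts, and the primary G-CSF prophylaxis alternative model.

#' Construct a sensitivity scenario
#'
#' A scenario is a named list of perturbations applied to a copy of the
#' base configuration. Each perturbation addresses a parameter by its
#' dotted path into the configuration (e.g.
#' \code{"arms.TAC.ae_rates.febrile_neutropenia"}) and either scales the
#' value by a positive factor or sets it outright.
#'
#' @param name scenario label.
#' @param perturbations list of perturbations, each a list with
#'   \code{path}, \code{op} (\code{"scale"} or \code{"set"}) and
#'   \code{value}.
#' @param model which model the scenario runs against: \code{"base"} or
#'   \code{"primary_prophylaxis"}.
#' @return An object of class \code{cea_scenario}.
#' @export
scenario <- function(name, perturbations = list(), model = "base") {
  model <- match.arg(model, c("base", "primary_prophylaxis"))
  for (p in perturbations) {
    if (is.null(p$path) || is.null(p$op) || is.null(p$value)) {
      stop("scenario '", name,
           "': each perturbation needs path, op and value", call. = FALSE)
    }
    if (!p$op %in% c("scale", "set")) {
      stop("scenario '", name, "': unknown op '", p$op, "'", call. = FALSE)
    }
    if (p$op == "scale" &&
        (!is.numeric(p$value) || length(p$value) != 1 || p$value <= 0)) {
      stop("scenario '", name, "': scale factor must be a positive number",
           call. = FALSE)
    }
  }
  structure(list(name = name, perturbations = perturbations, model = model),
            class = "cea_scenario")
}

resolve_path <- function(config, path, scenario_name) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop("scenario '", scenario_name,
           "': unresolvable parameter path '", path, "'", call. = FALSE)
    }
    node <- node[[k]]
  }
  keys
}

assign_path <- function(config, keys, value) {
  config[[keys]] <- value
  config
}

#' Apply a scenario to a configuration
#'
#' Returns a modified, re-validated deep copy; the base configuration is
#' untouched. Scale operations multiply the addressed numeric value (or
#' every element of an addressed numeric vector); set operations replace
#' it.
#'
#' @param base_config a \code{cea_config}.
#' @param scenario a \code{cea_scenario}.
#' @return A validated \code{cea_config}.
#' @export
apply_scenario <- function(base_config, scenario) {
  cfg <- base_config
  for (p in scenario$perturbations) {
    keys <- resolve_path(cfg, p$path, scenario$name)
    current <- cfg[[keys]]
    new_value <- if (p$op == "scale") {
      if (!is.numeric(unlist(current))) {
        stop("scenario '", scenario$name, "': path '", p$path,
             "' is not numeric and cannot be scaled", call. = FALSE)
      }
      if (is.list(current)) {
        rapply(current, function(v) v * p$value, how = "replace")
      } else {
        current * p$value
      }
    } else {
      p$value
    }
    cfg <- assign_path(cfg, keys, new_value)
  }
  validate_model_config(unclass(cfg), quiet = TRUE)
}

#' Load a scenario catalogue from JSON
#'
#' The bundled catalogue reproducing the published one-way analyses is at
#' \code{system.file("extdata", "scenarios_oneway.json",
#' package = "oncoMarkov")}.
#'
#' @param path path to a JSON file holding an array of scenario objects.
#' @return List of \code{cea_scenario}.
#' @export
load_scenarios <- function(path) {
  if (!file.exists(path)) {
    stop("scenario file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    scenario(s$name, s$perturbations,
             model = if (is.null(s$model)) "base" else s$model)
  })
}

#' Run a one-way sensitivity suite
#'
#' Runs the base case plus each scenario and tabulates the incremental
#' ratios. Deterministic given the configuration.
#'
#' @param base_config a \code{cea_config}.
#' @param scenarios list of \code{cea_scenario} (may be empty: base case
#'   only).
#' @return A \code{data.frame} with one row per analysis: \code{name},
#'   \code{icer}, \code{icur}, \code{delta_cost}, \code{delta_lys},
#'   \code{delta_qalys}.
#' @export
run_one_way_suite <- function(base_config, scenarios = list()) {
  run_one <- function(name, cfg, model) {
    res <- if (model == "primary_prophylaxis") {
      primary_prophylaxis_model(cfg)
    } else {
      run_base_case(cfg)
    }
    data.frame(name = name, icer = res$icer, icur = res$icur,
               delta_cost = res$delta_cost, delta_lys = res$delta_lys,
               delta_qalys = res$delta_qalys)
  }
  rows <- list(run_one("Base case", base_config, "base"))
  for (sc in scenarios) {
    cfg <- apply_scenario(base_config, sc)
    rows[[length(rows) + 1]] <- run_one(sc$name, cfg, sc$model)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap the incremental ratios by resampling trial outcome counts
#'
#' For each replicate the recurrence and death counts of each arm are
#' redrawn as binomials at the observed proportions with the trial arm
#' sizes, the transition models re-derived and re-calibrated, and the full
#' model re-run. Reports the replicate ratios, the sample extremes
#' (best/worst case) and percentile bounds. Reproducible under a fixed
#' seed.
#'
#' @param base_config a \code{cea_config}.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param level confidence level for the percentile interval.
#' @return A list with \code{samples} (data.frame of \code{icer},
#'   \code{icur}), \code{best_case}, \code{worst_case} (rows of the
#'   extreme ICER replicates), and \code{ci_icer}, \code{ci_icur}
#'   percentile bounds.
#' @export
bootstrap_icer <- function(base_config, n_boot, seed, level = 0.95) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  set.seed(seed)
  arms <- default_arm_pair(base_config)
  samples <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    cfg <- base_config
    for (a in arms) {
      summ <- cfg$arms[[a]]
      cfg$arms[[a]]$n_recurrences <-
        stats::rbinom(1, summ$n_treated, summ$n_recurrences / summ$n_treated)
      cfg$arms[[a]]$n_deaths <-
        stats::rbinom(1, summ$n_treated, summ$n_deaths / summ$n_treated)
    }
    res <- run_base_case(cfg, arms = arms)
    samples[[b]] <- data.frame(icer = res$icer, icur = res$icur)
  }
  samples <- do.call(rbind, samples)
  alpha <- (1 - level) / 2
  finite <- samples[is.finite(samples$icer), , drop = FALSE]
  best <- finite[which.min(finite$icer), , drop = FALSE]
  worst <- finite[which.max(finite$icer), , drop = FALSE]
  list(
    samples = samples,
    best_case = best,
    worst_case = worst,
    ci_icer = stats::quantile(samples$icer, c(alpha, 1 - alpha),
                              na.rm = TRUE, names = FALSE),
    ci_icur = stats::quantile(samples$icur, c(alpha, 1 - alpha),
                              na.rm = TRUE, names = FALSE)
  )
}

#' Primary G-CSF prophylaxis alternative model
#'
#' Re-runs the incremental analysis under primary (every-cycle) G-CSF
#' prophylaxis in the taxane arm: the taxane arm's adverse-event rates are
#' replaced by the with-prophylaxis rates, the full-course G-CSF
#' acquisition cost is added at time 0, and the secondary-prophylaxis cost
#' is removed (all febrile-neutropenia episodes are pre-empted); the
#' comparator arm uses its corresponding observed rates.
#'
#' @param base_config a \code{cea_config} whose \code{primary_prophylaxis}
#'   section (or the \code{pp} argument) supplies the with/without
#'   prophylaxis rates and the full-course G-CSF cost.
#' @param pp a primary-prophylaxis input list with \code{ae_rates_post},
#'   \code{ae_rates_fac} and \code{gcsf_cost_all_cycles}; defaults to
#'   \code{base_config$primary_prophylaxis}.
#' @param remove_secondary drop the taxane arm's secondary-prophylaxis
#'   cost (default TRUE, the primary-prophylaxis assumption).
#' @return A \code{cea_result}.
#' @export
primary_prophylaxis_model <- function(base_config,
                                      pp = base_config$primary_prophylaxis,
                                      remove_secondary = TRUE) {
  if (is.null(pp)) {
    stop("no primary_prophylaxis inputs configured", call. = FALSE)
  }
  pp <- validate_primary_prophylaxis(pp)
  arms <- default_arm_pair(base_config)
  intervention <- arms[1]
  comparator <- arms[2]
  cfg <- base_config
  if (!is.null(pp$ae_rates_post) && length(pp$ae_rates_post)) {
    cfg$arms[[intervention]]$ae_rates <- lapply(pp$ae_rates_post, as.numeric)
  }
  if (!is.null(pp$ae_rates_fac) && length(pp$ae_rates_fac)) {
    cfg$arms[[comparator]]$ae_rates <- lapply(pp$ae_rates_fac, as.numeric)
  }
  if (remove_secondary) {
    cfg$arms[[intervention]]$prophylaxis_patients <- 0
    cfg$arms[[intervention]]$prophylaxis_cycles <- 0
  }
  extra <- stats::setNames(c(pp$gcsf_cost_all_cycles, 0),
                           c(intervention, comparator))
  run_base_case(cfg, arms = arms, time0_extra = extra)
}
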