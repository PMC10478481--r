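# End-to-end orchestration: generate -> estimate -> fit -> simulate ->
# counterfactual -> ci -> report, driven by a YAML-style config. Every
# stage reads/writes only its declared files, writes atomically, and
# derives its randomness from the single top-level seed, so stages can be
# rerun independently with stable results.

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Mandatory top-level seed; each stage derives a sub-seed.
#' @param n_participants Synthetic cohort size.
#' @param n_per_group Simulated individuals per stratum in the main run.
#' @param ensemble List with `n_reps` and `n_individuals_per_rep` (`NULL`
#'   disables the ci stage).
#' @param scenarios Counterfactual scenario list: names become report keys,
#'   values are factor subsets (`"all"` for the joint effect).
#' @param sensitivity_threshold Episode-merging threshold in years.
#' @param grid_step Age step of the reported age-prevalence curve.
#' @return Config list (class `"metsim_config"`).
#' @export
metsim_config <- function(out_dir = "metsim_out",
                          seed = 1,
                          n_participants = 93249,
                          n_per_group = 125000,
                          ensemble = list(n_reps = 1000,
                                          n_individuals_per_rep = 50000),
                          scenarios = list(
                            counterfactual_smoking = "smoking",
                            counterfactual_alcohol = "alcohol",
                            counterfactual_health_literacy =
                              "health_literacy",
                            counterfactual_diet = "diet",
                            counterfactual_joint = "all"
                          ),
                          sensitivity_threshold = 0.5,
                          grid_step = 1) {
  config <- list(
    out_dir = out_dir, seed = seed, n_participants = n_participants,
    n_per_group = n_per_group, ensemble = ensemble, scenarios = scenarios,
    sensitivity_threshold = sensitivity_threshold, grid_step = grid_step,
    paths = list(
      cohort = "cohort.csv", rates = "rates.csv", curves = "curves.json",
      prevalence18 = "prevalence18.csv", life_courses = "life_courses.csv",
      intervals = "intervals.csv", report = "report.json"
    )
  )
  class(config) <- "metsim_config"
  config
}

#' Read a pipeline configuration file
#'
#' YAML document mirroring [metsim_config()]; missing fields take the
#' defaults. `seed` is mandatory.
#'
#' @param path Config file path.
#' @return A `metsim_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) stop("config ", path, " must set a seed")
  config <- metsim_config()
  for (field in names(user)) {
    if (field == "paths") {
      for (p in names(user$paths)) config$paths[[p]] <- user$paths[[p]]
    } else {
      config[[field]] <- user[[field]]
    }
  }
  class(config) <- "metsim_config"
  config
}

#' Write a pipeline configuration file
#'
#' @param config A `metsim_config`.
#' @param path Destination YAML path.
#' @export
write_config <- function(config, path) {
  atomic_write(path, function(tmp) {
    yaml::write_yaml(unclass(config), tmp)
  })
}

config_path <- function(config, key) {
  file.path(config$out_dir, config$paths[[key]])
}

scenario_factors <- function(value) {
  if (identical(value, "all")) MEDIATORS else
    match.arg(value, MEDIATORS, several.ok = TRUE)
}

#' Run pipeline stages
#'
#' Stages: `generate` (synthetic cohort CSV), `estimate` (rates CSV and
#' baseline-prevalence CSV), `fit` (curves JSON), `simulate` (life-course
#' CSV of the observed scenario), `counterfactual` (per-scenario summaries,
#' kept in memory for the report), `ci` (ensemble intervals CSV), `report`
#' (inequality report JSON). `"all"` chains every stage. Identical config
#' and seed give identical JSON/CSV outputs.
#'
#' @param command One of `generate`, `estimate`, `fit`, `simulate`,
#'   `counterfactual`, `ci`, `report`, `all`.
#' @param config A `metsim_config` (or path to a YAML config).
#' @param verbose Log stage progress.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(command = "all", config = metsim_config(),
                         verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  command <- match.arg(command, c("generate", "estimate", "fit", "simulate",
                                  "counterfactual", "ci", "report", "all"))
  stages <- if (command == "all") {
    c("generate", "estimate", "fit", "simulate", "counterfactual", "ci",
      "report")
  } else {
    command
  }
  if (is.null(config$ensemble)) stages <- setdiff(stages, "ci")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message("[metsim] ", ...)
  results <- list()

  if ("generate" %in% stages) {
    gc_cfg <- default_generator_config(
      n_participants = config$n_participants,
      seed = derive_seed(config$seed, "generate")
    )
    cohort <- generate_cohort(gc_cfg)
    write_cohort(cohort, config_path(config, "cohort"))
    log_msg("generate: ", nrow(cohort), " participants (seed ",
            config$seed, ")")
    results$cohort <- cohort
  }
  need_cohort <- function() {
    if (is.null(results$cohort)) {
      results$cohort <<- read_cohort(config_path(config, "cohort"))
    }
    results$cohort
  }

  if ("estimate" %in% stages) {
    cohort <- need_cohort()
    rates <- rbind(estimate_rates(cohort, "incidence"),
                   estimate_rates(cohort, "recovery"))
    prev18 <- estimate_prevalence_at_18(cohort)
    write_rates(rates, config_path(config, "rates"))
    atomic_write(config_path(config, "prevalence18"), function(tmp) {
      write.csv(prev18, tmp, row.names = FALSE)
    })
    log_msg("estimate: ", sum(!rates$absent), " non-absent rate cells")
    results$rates <- rates
    results$prev18 <- prev18
  }
  need_rates <- function() {
    if (is.null(results$rates)) {
      results$rates <<- read_rates(config_path(config, "rates"))
    }
    results$rates
  }
  need_prev18 <- function() {
    if (is.null(results$prev18)) {
      results$prev18 <<- read.csv(config_path(config, "prevalence18"),
                                  stringsAsFactors = FALSE)
    }
    results$prev18
  }

  if ("fit" %in% stages) {
    curves <- fit_all_curves(need_rates())
    write_curves(curves, config_path(config, "curves"))
    log_msg("fit: 8 curves")
    results$curves <- curves
  }
  need_curves <- function() {
    if (is.null(results$curves)) {
      results$curves <<- read_curves(config_path(config, "curves"))
    }
    results$curves
  }

  if ("simulate" %in% stages) {
    lcs <- simulate_cohort(need_curves(), need_prev18(),
                           config$n_per_group,
                           derive_seed(config$seed, "simulate"))
    write_life_courses(lcs, config_path(config, "life_courses"))
    grid <- seq(AGE_MIN, AGE_MAX - config$grid_step, by = config$grid_step)
    results$observed_summary <- summarize_by_stratum(lcs, grid = grid)
    if (config$sensitivity_threshold > 0) {
      results$sensitivity_summary <- summarize_by_stratum(
        merge_short_episodes(lcs, config$sensitivity_threshold)
      )
    }
    log_msg("simulate: ", 4 * config$n_per_group, " life courses")
  }

  if ("counterfactual" %in% stages && length(config$scenarios) > 0) {
    cohort <- need_cohort()
    rates <- need_rates()
    prev18 <- need_prev18()
    results$counterfactual_summaries <- list()
    for (name in names(config$scenarios)) {
      factors <- scenario_factors(config$scenarios[[name]])
      cf <- run_counterfactual_pipeline(
        cohort, factors, config$n_per_group,
        derive_seed(config$seed, "simulate"),
        observed_rates = rates, prev18 = prev18
      )
      results$counterfactual_summaries[[name]] <- cf$summary
      log_msg("counterfactual ", name, ": done")
    }
  }

  if ("ci" %in% stages) {
    iv <- run_ensemble(
      need_rates(), need_prev18(),
      n_reps = config$ensemble$n_reps,
      n_individuals_per_rep = config$ensemble$n_individuals_per_rep,
      n_main_per_group = config$n_per_group,
      seed = derive_seed(config$seed, "ci")
    )
    atomic_write(config_path(config, "intervals"), function(tmp) {
      write.csv(iv, tmp, row.names = FALSE)
    })
    log_msg("ci: ", config$ensemble$n_reps, " repetitions (",
            attr(iv, "n_failed"), " failed)")
    results$intervals <- iv
  }

  if ("report" %in% stages) {
    if (is.null(results$observed_summary)) {
      lcs <- read_life_courses(config_path(config, "life_courses"))
      results$observed_summary <- summarize_by_stratum(lcs)
    }
    report <- build_report(
      results$observed_summary,
      counterfactuals = results$counterfactual_summaries %||% list(),
      intervals = results$intervals
    )
    write_report(report, config_path(config, "report"))
    log_msg("report: written to ", config_path(config, "report"))
    results$report <- report
  }

  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
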