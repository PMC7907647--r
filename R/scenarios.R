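# Scenario configuration: YAML schema, packaged scenario matrix, and the
# run-to-disk pipeline with an effective-config echo.

scenario_fields <- c("name", "population", "regimen", "ddi", "n_trials",
                     "n_subjects_per_trial", "seed", "auc_window_h",
                     "compare_to_baseline")

#' Load and validate a scenario configuration file
#'
#' A scenario YAML names a population spec, a regimen (the keyword
#' `regimen_A` or an explicit `times_h`/`amounts_mg_salt` pair), an optional
#' built-in DDI perpetrator, and trial-design overrides.  All defaults are
#' resolved here so the returned object is a frozen effective configuration.
#'
#' @param path scenario YAML path (see `inst/scenarios/` for the packaged
#'   simulation matrix).
#' @return object of class `scenario_config`.
#' @export
load_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), scenario_fields)
  if (length(unknown))
    stop("unknown scenario key(s) in ", basename(path), ": ",
         paste(unknown, collapse = ", "))
  if (is.null(raw$name)) stop("scenario needs a name")
  pop <- raw$population %||% list()
  spec <- population_spec(
    category = pop$category %||% "healthy",
    age_range = unlist(pop$age_range %||% c(20, 50)),
    sex_ratio = pop$sex_ratio %||% if ((pop$category %||% "") == "pregnant") 0 else 0.5,
    gestational_week = pop$gestational_week %||% NA_real_,
    variability = pop$variability %||% TRUE)
  reg <- raw$regimen %||% "regimen_A"
  reg <- if (identical(reg, "regimen_A")) regimen_a()
  else regimen(unlist(reg$times_h), unlist(reg$amounts_mg_salt),
               label = raw$name)
  if (is.null(raw$seed)) stop("seed is mandatory for population scenarios")
  ddi <- if (!is.null(raw$ddi)) ddi_scenario(raw$ddi)
  structure(list(
    name = raw$name, population = spec, regimen = reg, ddi = ddi,
    n_trials = raw$n_trials %||% 10,
    n_subjects_per_trial = raw$n_subjects_per_trial %||% 10,
    seed = as.integer(raw$seed),
    auc_window_h = raw$auc_window_h %||% 240,
    compare_to_baseline = raw$compare_to_baseline %||% TRUE
  ), class = "scenario_config")
}

effective_config_list <- function(sc) {
  list(name = sc$name,
       population = list(category = sc$population$category,
                         age_range = sc$population$age_range,
                         sex_ratio = sc$population$sex_ratio,
                         gestational_week =
                           if (is.na(sc$population$gestational_week)) NULL
                           else sc$population$gestational_week,
                         variability = sc$population$variability),
       regimen = if (identical(sc$regimen$label, "Regimen A")) "regimen_A"
       else list(times_h = sc$regimen$events$time_h,
                 amounts_mg_salt = sc$regimen$events$amount_mg_salt),
       ddi = if (is.null(sc$ddi)) NULL else sc$ddi$perpetrator$name,
       n_trials = sc$n_trials,
       n_subjects_per_trial = sc$n_subjects_per_trial,
       seed = sc$seed, auc_window_h = sc$auc_window_h,
       compare_to_baseline = sc$compare_to_baseline)
}

#' List the packaged scenario files
#'
#' One file per row of the study's simulation matrix (baseline, geriatric
#' bands, Child-Pugh grades, renal bands, pregnancy weeks, pediatric bands,
#' and the three perpetrator scenarios).
#'
#' @return named character vector of file paths.
#' @export
packaged_scenarios <- function() {
  dir <- system.file("scenarios", package = "hcqpbpk")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  stats::setNames(files, sub("\\.yaml$", "", basename(files)))
}

#' Run a scenario to disk
#'
#' Executes the virtual trial for the scenario, optionally computes
#' baseline-relative exposure ratios, and writes per-subject metrics, the
#' summary, the ratio table, and the frozen effective configuration
#' (sufficient metadata to reproduce the run) into `out_dir`.
#'
#' @param config a `scenario_config` from [load_scenario()] (or a path).
#' @param out_dir output directory (created if missing).
#' @param baseline optional precomputed baseline `trial_result` (computed on
#'   the fly with the scenario's seed when comparison is requested and none
#'   is supplied).
#' @param drugs drug set (default packaged HCQ).
#' @return list with the `trial_result` and, when computed, the
#'   `ratio_result`; invisibly.
#' @export
run_scenario <- function(config, out_dir, baseline = NULL, drugs = NULL) {
  if (is.character(config)) config <- load_scenario(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- trial_design(config$population, config$regimen, drugs = drugs,
                         ddi = config$ddi, n_trials = config$n_trials,
                         n_subjects_per_trial = config$n_subjects_per_trial,
                         seed = config$seed,
                         auc_window_h = config$auc_window_h)
  result <- run_trials(design)
  utils::write.table(result$metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ratios <- NULL
  if (isTRUE(config$compare_to_baseline)) {
    if (is.null(baseline)) {
      base_design <- trial_design(population_spec(variability = TRUE),
                                  regimen_a(), drugs = drugs,
                                  n_trials = config$n_trials,
                                  n_subjects_per_trial = config$n_subjects_per_trial,
                                  seed = config$seed,
                                  auc_window_h = config$auc_window_h)
      baseline <- run_trials(base_design)
    }
    ratios <- exposure_ratio(result, baseline)
    rt <- data.frame(metric = c("R_Cmax_plasma", "R_AUC_plasma",
                                "R_Cmax_lung", "R_AUC_lung"),
                     ratio = c(ratios$R_Cmax_plasma, ratios$R_AUC_plasma,
                               ratios$R_Cmax_lung, ratios$R_AUC_lung))
    utils::write.table(rt, file.path(out_dir, "ratios.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(effective_config_list(config),
                   file.path(out_dir, "effective_config.yaml"))
  invisible(list(result = result, ratios = ratios))
}
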