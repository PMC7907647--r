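# Virtual clinical-trial layer: PK metrics, 10x10 trial simulation,
# baseline-relative exposure ratios, lung-uptake calibration and pediatric
# weight-based dose matching.

#' Non-compartmental PK metrics of a concentration-time profile
#'
#' Cmax/Tmax over the grid, AUC by linear trapezoid over `[0, auc_window_h]`,
#' and troughs (concentrations at the stated pre-dose times).
#'
#' @param profile data.frame with `time_h` and `conc`.
#' @param auc_window_h AUC integration window, h; must be covered by the
#'   profile.
#' @param trough_times_h optional times at which troughs are read.
#' @return list with `cmax`, `tmax`, `auc`, `troughs`.
#' @export
pk_metrics <- function(profile, auc_window_h, trough_times_h = NULL) {
  t <- profile$time_h
  y <- profile$conc
  if (auc_window_h > max(t) + 1e-9)
    stop("auc window (", auc_window_h, " h) extends beyond simulated span")
  sel <- t <= auc_window_h + 1e-9
  tt <- t[sel]; yy <- y[sel]
  auc <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  troughs <- NULL
  if (!is.null(trough_times_h))
    troughs <- stats::approx(t, y, xout = trough_times_h, rule = 2)$y
  list(cmax = max(yy), tmax = tt[which.max(yy)], auc = auc, troughs = troughs)
}

#' Virtual-trial design
#'
#' The study design used throughout: `n_trials` trials of
#' `n_subjects_per_trial` subjects each (default 10 x 10, n = 100), a shared
#' regimen, and an AUC window of 240 h (10 days) from the first victim dose.
#'
#' @param population a [population_spec()].
#' @param regimen a [regimen()].
#' @param drugs drug set passed to [build_pbpk_model()]; defaults to the
#'   packaged HCQ parameters alone (the metabolite does not feed back on the
#'   parent and is omitted from ratio runs for speed).
#' @param ddi optional [ddi_scenario()].
#' @param n_trials,n_subjects_per_trial trial structure (> 0).
#' @param seed integer master seed; each subject derives a substream.
#' @param auc_window_h exposure window, h.
#' @param config engine settings.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(population, regimen = regimen_a(), drugs = NULL,
                         ddi = NULL, n_trials = 10, n_subjects_per_trial = 10,
                         seed = 1L, auc_window_h = 240,
                         config = engine_config()) {
  stopifnot(n_trials > 0, n_subjects_per_trial > 0, auc_window_h > 0)
  drugs <- drugs %||% list(hcq_parameters())
  structure(list(population = population, regimen = regimen, drugs = drugs,
                 ddi = ddi, n_trials = n_trials,
                 n_subjects_per_trial = n_subjects_per_trial,
                 seed = as.integer(seed), auc_window_h = auc_window_h,
                 config = config),
            class = "trial_design")
}

subject_seed <- function(master, trial, subject) {
  (master + 7919L * trial + 104729L * subject) %% .Machine$integer.max
}

#' Run a virtual trial
#'
#' Samples each subject from the population spec on a per-subject seed
#' substream, simulates the regimen, and collects Cmax and windowed AUC for
#' plasma and lung tissue (parent analyte).  Fully reproducible given the
#' design; solver failures are caught and reported per subject.
#'
#' @param design a [trial_design()].
#' @param t_end_h simulation horizon (defaults to the AUC window).
#' @return object of class `trial_result`: per-subject `metrics` data.frame,
#'   summary statistics, and the design.
#' @export
run_trials <- function(design, t_end_h = NULL) {
  t_end_h <- t_end_h %||% design$auc_window_h
  rows <- list()
  failures <- list()
  for (tr in seq_len(design$n_trials)) {
    for (su in seq_len(design$n_subjects_per_trial)) {
      sd <- subject_seed(design$seed, tr, su)
      ind <- sample_individual(design$population, sd)
      res <- tryCatch({
        model <- build_pbpk_model(design$drugs, ind, design$regimen,
                                  interactions = design$ddi,
                                  config = design$config)
        sim <- simulate(model, t_end_h = t_end_h)
        parent <- model$parent$name
        for (mx in c("plasma", "lung_tissue")) {
          pm <- pk_metrics(observable(sim, parent, mx), design$auc_window_h)
          rows[[length(rows) + 1]] <- data.frame(
            trial = tr, subject = su, analyte = parent, matrix = mx,
            cmax = pm$cmax, auc = pm$auc, body_weight = ind$body_weight)
        }
        TRUE
      }, error = function(e) e)
      if (inherits(res, "error"))
        failures[[length(failures) + 1]] <-
          list(trial = tr, subject = su, message = conditionMessage(res))
    }
  }
  metrics <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(metrics, metrics$matrix), function(d) {
    data.frame(matrix = d$matrix[1],
               mean_cmax = mean(d$cmax), sd_cmax = stats::sd(d$cmax),
               gm_cmax = exp(mean(log(d$cmax))),
               mean_auc = mean(d$auc), sd_auc = stats::sd(d$auc),
               gm_auc = exp(mean(log(d$auc))),
               n = nrow(d))
  }))
  trial_means <- stats::aggregate(cbind(cmax, auc) ~ trial + matrix,
                                  data = metrics, FUN = mean)
  structure(list(metrics = metrics, summary = summ,
                 trial_means = trial_means, failures = failures,
                 auc_window_h = design$auc_window_h, design = design),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result> ", x$design$n_trials, "x",
      x$design$n_subjects_per_trial, " subjects, population ",
      x$design$population$category, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (length(x$failures))
    cat("  WARNING:", length(x$failures), "subject simulations failed\n")
  invisible(x)
}

#' Baseline-relative exposure ratios
#'
#' Ratios of arithmetic means of individual PK parameters (the tables'
#' reading of "mean ratio"); geometric-mean ratios are carried alongside for
#' transparency.  Windows must match.
#'
#' @param test,baseline `trial_result` objects with matching AUC windows.
#' @return object of class `ratio_result` with `R_Cmax_plasma`,
#'   `R_AUC_plasma`, `R_Cmax_lung`, `R_AUC_lung` (and `geomean` variants).
#' @export
exposure_ratio <- function(test, baseline) {
  if (abs(test$auc_window_h - baseline$auc_window_h) > 1e-9)
    stop("AUC window mismatch between test and baseline")
  g <- function(res, mx, col) res$summary[res$summary$matrix == mx, col]
  out <- list(
    R_Cmax_plasma = g(test, "plasma", "mean_cmax") /
      g(baseline, "plasma", "mean_cmax"),
    R_AUC_plasma = g(test, "plasma", "mean_auc") /
      g(baseline, "plasma", "mean_auc"),
    R_Cmax_lung = g(test, "lung_tissue", "mean_cmax") /
      g(baseline, "lung_tissue", "mean_cmax"),
    R_AUC_lung = g(test, "lung_tissue", "mean_auc") /
      g(baseline, "lung_tissue", "mean_auc"),
    geomean = c(
      R_Cmax_plasma = g(test, "plasma", "gm_cmax") /
        g(baseline, "plasma", "gm_cmax"),
      R_AUC_plasma = g(test, "plasma", "gm_auc") /
        g(baseline, "plasma", "gm_auc"))
  )
  structure(out, class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat("<ratio_result>\n")
  for (k in c("R_Cmax_plasma", "R_AUC_plasma", "R_Cmax_lung", "R_AUC_lung"))
    cat(sprintf("  %-14s %.3f\n", k, x[[k]]))
  invisible(x)
}

#' Calibrate the lung active-uptake clearance to a partition target
#'
#' Scalar root finding on `CLint_T` so that the lung:plasma partition
#' coefficient at the stated trough time under the given regimen matches the
#' target (default: day-6 trough, 120 h, target 200).  The passive-only
#' partition must lie below the target; Kp is monotone increasing in
#' `CLint_T` (verified during bracketing).
#'
#' @param target_kp target lung:plasma ratio (dimensionless).
#' @param drug HCQ parameter set to calibrate (its `lung_uptake_clint_T`
#'   field is replaced).
#' @param individual the calibration subject; defaults to the baseline
#'   typical adult (variability off).
#' @param regimen regimen used for calibration (default Regimen A).
#' @param trough_h evaluation time, h (default 120: day-6 pre-dose trough).
#' @param tol relative tolerance on the achieved Kp.
#' @param config engine settings.
#' @return object of class `lung_calibration`: `clint_T` (L/h),
#'   `achieved_kp`, `passive_kp`, and the calibrated `drug`.
#' @export
calibrate_lung_uptake <- function(target_kp = 200,
                                  drug = hcq_parameters(),
                                  individual = NULL,
                                  regimen = regimen_a(),
                                  trough_h = 120,
                                  tol = 0.005,
                                  config = engine_config()) {
  individual <- individual %||%
    sample_individual(population_spec(variability = FALSE), 1L)
  kp_at <- function(clt) {
    d <- drug
    d$lung_uptake_clint_T <- clt
    m <- build_pbpk_model(list(d), individual, regimen, config = config)
    s <- simulate(m, t_end_h = trough_h + 1)
    lung_kp(s, trough_h)
  }
  passive <- kp_at(0)
  if (target_kp <= passive)
    stop("target Kp (", target_kp, ") is not above the passive-only Kp (",
         signif(passive, 4), "): active uptake cannot be negative")
  lo <- 0; hi <- 8; kp_hi <- kp_at(hi); kp_lo <- passive
  while (kp_hi < target_kp) {
    if (kp_hi <= kp_lo + 1e-9)
      stop("lung Kp is not increasing in CLint_T; calibration aborted")
    lo <- hi; kp_lo <- kp_hi
    hi <- hi * 2
    if (hi > 1e5) stop("calibration bracket exceeded 1e5 L/h")
    kp_hi <- kp_at(hi)
  }
  root <- stats::uniroot(function(clt) kp_at(clt) - target_kp,
                         lower = lo, upper = hi,
                         tol = tol * max(1, hi - lo) / 100)
  achieved <- kp_at(root$root)
  if (abs(achieved - target_kp) / target_kp > 2 * tol)
    warning("achieved Kp ", signif(achieved, 4), " misses target by > ",
            200 * tol, "%")
  d <- drug
  d$lung_uptake_clint_T <- root$root
  structure(list(clint_T = root$root, achieved_kp = achieved,
                 passive_kp = passive, target_kp = target_kp,
                 trough_h = trough_h, drug = d),
            class = "lung_calibration")
}

#' @export
print.lung_calibration <- function(x, ...) {
  cat(sprintf(
    "<lung_calibration> CLint_T = %.3f L/h (passive Kp %.1f -> achieved %.1f at %g h, target %g)\n",
    x$clint_T, x$passive_kp, x$achieved_kp, x$trough_h, x$target_kp))
  invisible(x)
}

first_dose_cmax <- function(drugs, individual, reg, config,
                            window_h = 12) {
  ev <- reg$events[1, ]
  first <- regimen(ev$time_h, ev$amount_mg_salt, ev$route,
                   paste(reg$label, "(first dose)"))
  model <- build_pbpk_model(drugs, individual, first, config = config)
  sim <- simulate(model, t_end_h = window_h + 1)
  pl <- observable(sim, model$parent$name, "plasma")
  max(pl$conc[pl$time_h <= window_h])
}

#' Solve the weight-based pediatric loading dose
#'
#' Finds the per-kilogram loading dose whose typical-individual first-dose
#' plasma Cmax matches the adult reference (600 mg salt in the 70 kg
#' baseline adult under Regimen A).  The model is linear in dose, so the
#' solution is obtained by scaling a probe simulation and verified by
#' re-simulation to within 1%.  The full regimen is loading BID on day 1 and
#' loading/3 BID on days 2-5.
#'
#' @param band pediatric [population_spec()] (its age midpoint defines the
#'   typical child) or a numeric age in years.
#' @param drugs drug set (default packaged HCQ).
#' @param adult_reference_cmax optional precomputed reference Cmax, mg/L.
#' @param config engine settings.
#' @return object of class `pediatric_dose`: `loading_mg_per_kg`,
#'   `maintenance_mg_per_kg` (= loading / 3), the achieved Cmax ratio and the
#'   solved regimen.
#' @export
optimize_pediatric_dose <- function(band, drugs = NULL,
                                    adult_reference_cmax = NULL,
                                    config = engine_config()) {
  drugs <- drugs %||% list(hcq_parameters())
  if (is.numeric(band)) {
    lo <- max(band - 0.01, 0); hi <- band + 0.01
    band <- population_spec("pediatric", age_range = c(lo, hi),
                            variability = FALSE)
  }
  if (band$category != "pediatric") stop("band must be a pediatric spec")
  spec_off <- band; spec_off$variability <- FALSE
  child <- sample_individual(spec_off, 1L)
  ref <- adult_reference_cmax %||% first_dose_cmax(
    drugs, sample_individual(population_spec(variability = FALSE), 1L),
    regimen_a(), config)
  probe <- 8
  cmax_probe <- first_dose_cmax(drugs, child,
                                weight_based_regimen(probe, child$body_weight),
                                config)
  dose <- probe * ref / cmax_probe
  achieved <- first_dose_cmax(drugs, child,
                              weight_based_regimen(dose, child$body_weight),
                              config)
  if (abs(achieved / ref - 1) > 0.01)
    stop("pediatric dose solve failed to converge (ratio ",
         signif(achieved / ref, 4), ")")
  structure(list(loading_mg_per_kg = dose,
                 maintenance_mg_per_kg = dose / 3,
                 cmax_ratio = achieved / ref,
                 adult_reference_cmax = ref,
                 child_weight_kg = child$body_weight,
                 regimen = weight_based_regimen(dose, child$body_weight)),
            class = "pediatric_dose")
}

#' @export
print.pediatric_dose <- function(x, ...) {
  cat(sprintf(
    "<pediatric_dose> loading %.2f mg/kg (maintenance %.2f mg/kg), child %.1f kg, Cmax ratio %.3f\n",
    x$loading_mg_per_kg, x$maintenance_mg_per_kg, x$child_weight_kg,
    x$cmax_ratio))
  invisible(x)
}
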