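test_that("PK metrics match hand-computed trapezoids", {
  prof <- data.frame(time_h = c(0, 1, 2), conc = c(0, 10, 5))
  pm <- pk_metrics(prof, 2)
  expect_equal(pm$cmax, 10)
  expect_equal(pm$tmax, 1)
  expect_equal(pm$auc, 12.5)
  zero <- data.frame(time_h = 0:5, conc = numeric(6))
  pm0 <- pk_metrics(zero, 5, trough_times_h = c(1, 3))
  expect_equal(pm0$cmax, 0); expect_equal(pm0$auc, 0)
  expect_equal(pm0$troughs, c(0, 0))
  expect_error(pk_metrics(prof, 10), "beyond")
  # grid refinement changes the trapezoid by < 0.2%
  f <- function(t) 10 * (exp(-t / 8) - exp(-t))
  coarse <- data.frame(time_h = seq(0, 24, 0.25), conc = f(seq(0, 24, 0.25)))
  fine <- data.frame(time_h = seq(0, 24, 0.05), conc = f(seq(0, 24, 0.05)))
  expect_lt(abs(pk_metrics(coarse, 24)$auc / pk_metrics(fine, 24)$auc - 1),
            0.002)
})

test_that("trials are reproducible and collapse correctly without variability", {
  off <- trial_design(population_spec(variability = FALSE), n_trials = 2,
                      n_subjects_per_trial = 3, seed = 5)
  r <- run_trials(off)
  expect_equal(nrow(r$metrics), 2 * 3 * 2)   # two matrices per subject
  sds <- tapply(r$metrics$auc, r$metrics$matrix, stats::sd)
  expect_true(all(sds == 0))
  on <- trial_design(population_spec(variability = TRUE), n_trials = 2,
                     n_subjects_per_trial = 3, seed = 5)
  a <- run_trials(on); b <- run_trials(on)
  expect_identical(a$summary, b$summary)
  c2 <- run_trials(trial_design(population_spec(variability = TRUE),
                                n_trials = 2, n_subjects_per_trial = 3,
                                seed = 6))
  expect_false(identical(a$summary, c2$summary))
  # mean of per-trial means equals the grand mean
  pl <- a$metrics[a$metrics$matrix == "plasma", ]
  tm <- a$trial_means[a$trial_means$matrix == "plasma", ]
  expect_equal(mean(tm$auc), mean(pl$auc), tolerance = 1e-12)
})

test_that("exposure ratios are exact for self-comparison and dose-invariant", {
  d <- trial_design(population_spec(variability = TRUE), n_trials = 2,
                    n_subjects_per_trial = 3, seed = 11)
  r <- run_trials(d)
  self <- exposure_ratio(r, r)
  expect_identical(self$R_Cmax_plasma, 1)
  expect_identical(self$R_AUC_plasma, 1)
  expect_identical(self$R_AUC_lung, 1)
  # common dose scaling cancels in the ratio (linear kinetics)
  reg2 <- regimen(seq(0, 108, 12), 2 * c(600, 600, rep(200, 8)))
  pop <- population_spec("renal_GFR_lt_30", variability = TRUE)
  r_t1 <- run_trials(trial_design(pop, n_trials = 2,
                                  n_subjects_per_trial = 3, seed = 11))
  r_t2 <- run_trials(trial_design(pop, regimen = reg2, n_trials = 2,
                                  n_subjects_per_trial = 3, seed = 11))
  r_b2 <- run_trials(trial_design(population_spec(variability = TRUE),
                                  regimen = reg2, n_trials = 2,
                                  n_subjects_per_trial = 3, seed = 11))
  expect_equal(exposure_ratio(r_t2, r_b2)$R_AUC_plasma,
               exposure_ratio(r_t1, r)$R_AUC_plasma, tolerance = 1e-9)
  d2 <- trial_design(population_spec(), auc_window_h = 120)
  expect_error(exposure_ratio(r, run_trials(trial_design(
    population_spec(variability = FALSE), n_trials = 1,
    n_subjects_per_trial = 1, auc_window_h = 120))), "window")
})

test_that("lung partition accumulates over days and calibrates monotonically", {
  ind <- typical_adult()
  s <- simulate(build_pbpk_model(list(hcq_parameters()), ind, regimen_a()),
                t_end_h = 121)
  kps <- vapply(c(24, 48, 72, 96, 120), function(t) lung_kp(s, t), numeric(1))
  expect_true(all(diff(kps) > 0))
  cal200 <- calibrate_lung_uptake(200, trough_h = 120)
  cal400 <- calibrate_lung_uptake(400, trough_h = 120)
  expect_gt(cal400$clint_T, cal200$clint_T)
  expect_lt(abs(cal200$achieved_kp / 200 - 1), 0.01)
  expect_error(calibrate_lung_uptake(cal200$passive_kp * 0.5),
               "passive")
})

test_that("pediatric dose solving is self-consistent and age-monotone", {
  near_adult <- optimize_pediatric_dose(17.9)
  expect_equal(near_adult$loading_mg_per_kg, 600 / 70, tolerance = 0.05)
  expect_equal(near_adult$maintenance_mg_per_kg,
               near_adult$loading_mg_per_kg / 3)
  expect_lt(abs(near_adult$cmax_ratio - 1), 0.01)
  doses <- vapply(list(c(0, 0.085), c(2, 6), c(6, 12)), function(ar)
    optimize_pediatric_dose(population_spec("pediatric", age_range = ar,
                                            variability = FALSE))$loading_mg_per_kg,
    numeric(1))
  expect_true(all(diff(doses) > 0))
})
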