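make_obs_file <- function(path, extra = NULL) {
  d <- data.frame(
    time_h = c(1, 4, 12, 1, 4, 12),
    conc = c(50, 120, 60, 0.05, 0.12, 0.06),
    unit = c("ng/mL", "ng/mL", "ng/mL", "mg/L", "mg/L", "mg/L"),
    analyte = "HCQ",
    matrix = c(rep("blood", 3), rep("plasma", 3)),
    study = c(rep("S1", 3), rep("S2", 3)),
    lloq_flag = FALSE)
  if (!is.null(extra)) d <- rbind(d, extra)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

test_that("observed profiles parse, normalize units and reject serum", {
  f <- make_obs_file(tempfile(fileext = ".tsv"))
  profs <- read_observed_profiles(f)
  expect_length(profs, 2L)
  blood <- profs[[which(vapply(profs, attr, "", "matrix") == "blood")]]
  expect_equal(blood$conc, c(50, 120, 60) / 1000)  # ng/mL -> mg/L
  serum_row <- data.frame(time_h = 2, conc = 1, unit = "mg/L",
                          analyte = "HCQ", matrix = "serum", study = "S3",
                          lloq_flag = FALSE)
  f2 <- make_obs_file(tempfile(fileext = ".tsv"), serum_row)
  p2 <- read_observed_profiles(f2)
  expect_length(p2, 2L)
  rej <- attr(p2, "rejected")
  expect_length(rej, 1L)
  expect_match(rej[[1]]$reason, "serum")
  bad <- data.frame(time_h = 2, conc = 1, unit = "furlongs",
                    analyte = "HCQ", matrix = "plasma", study = "S4",
                    lloq_flag = FALSE)
  expect_error(read_observed_profiles(
    make_obs_file(tempfile(fileext = ".tsv"), bad)), "unknown unit")
})

test_that("profile write/read round-trips losslessly", {
  f <- make_obs_file(tempfile(fileext = ".tsv"))
  profs <- read_observed_profiles(f)
  out <- tempfile(fileext = ".tsv")
  write_observed_profiles(profs, out)
  back <- read_observed_profiles(out)
  for (i in seq_along(profs)) {
    expect_equal(back[[i]]$time_h, profs[[i]]$time_h, tolerance = 1e-12)
    expect_equal(back[[i]]$conc, profs[[i]]$conc, tolerance = 1e-12)
  }
})

test_that("fold checks are inclusive at the boundary and symmetric", {
  expect_true(fold_check(1, 1)$pass)
  expect_true(fold_check(2, 1, 2)$pass)
  expect_true(fold_check(1, 2, 2)$pass)
  expect_false(fold_check(2.01, 1, 2)$pass)
  for (p in c(0.3, 0.9, 1.7)) for (o in c(0.5, 1.2))
    expect_equal(fold_check(p, o, 2)$pass, fold_check(o, p, 2)$pass)
  expect_error(fold_check(0, 1), "positive")
})

test_that("interval coverage brackets the simulated population", {
  set.seed(41)
  n <- 60; times <- 1:8
  pred <- matrix(exp(rnorm(n * length(times), 0, 0.3)), n) *
    rep(10 * exp(-times / 6), each = n)
  med <- apply(pred, 2, stats::median)
  obs_med <- data.frame(time_h = times, conc = med)
  expect_equal(interval_coverage(pred, obs_med), 1.0)
  expect_equal(interval_coverage(pred, transform(obs_med, conc = conc * 10)),
               0.0)
  expect_error(interval_coverage(pred[1:5, ], obs_med), ">= 20")
  # drawing observations from the population itself recovers ~90% coverage
  reps <- vapply(1:200, function(i) {
    draw <- pred[cbind(sample(n, length(times), TRUE), seq_along(times))]
    interval_coverage(pred, data.frame(time_h = times, conc = draw))
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.9), 0.03)
})

test_that("self-coverage of the PBPK population is near the nominal 90%", {
  times <- c(2, 6, 12, 24, 48, 72)
  spec <- population_spec(variability = TRUE)
  pred <- population_predictions(spec, times, n = 40, seed = 8,
                                 regimen = regimen_a())
  reps <- vapply(1:100, function(i) {
    draw <- pred[cbind(sample(nrow(pred), length(times), TRUE),
                       seq_along(times))]
    interval_coverage(pred, data.frame(time_h = times, conc = draw))
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.9), 0.07)
})

test_that("metabolite clearance fitting recovers known truth", {
  ind <- typical_adult()
  truth <- 30
  dh <- dhcq_parameters()
  renal <- dh$fm_map[["renal"]] * dh$reference_plasma_clearance
  total <- truth + renal
  dh_true <- dhcq_parameters(
    fm_map = list(hepatic = truth / total, renal = renal / total),
    reference_plasma_clearance = total)
  m <- build_pbpk_model(list(hcq_parameters(), dh_true), ind, regimen_a())
  s <- simulate(m, t_end_h = 240)
  ob <- observable(s, "DHCQ", "plasma")
  pick <- ob$time_h %in% c(4, 12, 24, 48, 72, 96, 120, 144, 168, 192, 216, 240)
  clean <- data.frame(time_h = ob$time_h[pick], conc = ob$conc[pick])
  fit <- fit_dhcq_hepatic_clint(clean, regimen_a(), individual = ind,
                                profile_ci = TRUE)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$clh_hepatic / truth - 1), 0.01)
  # with noise-free data the interval collapses onto the optimum
  expect_true(fit$ci90[1] <= truth * 1.001 && truth * 0.999 <= fit$ci90[2])
  # censored-only input is flagged non-identifiable
  cens <- transform(clean, lloq_flag = TRUE)
  expect_false(fit_dhcq_hepatic_clint(cens, regimen_a(),
                                      individual = ind)$identifiable)
})

test_that("fit recovery tolerates proportional noise across seeds", {
  ind <- typical_adult()
  truth <- 30
  dh <- dhcq_parameters()
  renal <- dh$fm_map[["renal"]] * dh$reference_plasma_clearance
  total <- truth + renal
  dh_true <- dhcq_parameters(
    fm_map = list(hepatic = truth / total, renal = renal / total),
    reference_plasma_clearance = total)
  s <- simulate(build_pbpk_model(list(hcq_parameters(), dh_true), ind,
                                 regimen_a()), t_end_h = 240)
  ob <- observable(s, "DHCQ", "plasma")
  pick <- ob$time_h %in% c(4, 12, 24, 48, 72, 96, 120, 144, 168, 192, 216, 240)
  clean <- data.frame(time_h = ob$time_h[pick], conc = ob$conc[pick])
  ests <- vapply(1:8, function(sd) {
    noisy <- generate_noisy_profile(clean, error_model(0.10, seed = sd))
    fit_dhcq_hepatic_clint(noisy, regimen_a(), individual = ind,
                           profile_ci = FALSE)$clh_hepatic
  }, numeric(1))
  expect_true(all(abs(ests / truth - 1) < 0.15))
  expect_lt(abs(mean(ests) / truth - 1), 0.05)
})
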