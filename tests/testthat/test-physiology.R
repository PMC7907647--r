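test_that("typical healthy adult is deterministic at 70 kg with balanced flows", {
  spec <- population_spec(variability = FALSE)
  ind <- sample_individual(spec, 1L)
  expect_equal(ind$body_weight, 70)
  expect_equal(ind$sex, "male")
  expect_equal(sum(ind$organ_blood_flows), ind$cardiac_output,
               tolerance = 1e-9)
  expect_identical(sample_individual(spec, 99L), ind)  # no RNG dependence
})

test_that("sampling is seed-reproducible and respects configured variability", {
  spec <- population_spec(variability = TRUE)
  a <- sample_individual(spec, 42L)
  b <- sample_individual(spec, 42L)
  expect_identical(a, b)
  expect_false(identical(a, sample_individual(spec, 43L)))
  ws <- vapply(1:3000, function(i)
    sample_individual(spec, i)$body_weight, numeric(1))
  # sexes mix 1:1, so compare against the sex-averaged typical weight
  typ <- mean(c(70, 61))
  expect_lt(abs(mean(ws) / typ - 1), 0.02)
  cv <- stats::sd(ws) / mean(ws)
  # weight CV 15% plus the male/female split's bimodal spread
  expect_gt(cv, 0.12); expect_lt(cv, 0.22)
})

test_that("every category produces individuals satisfying the invariants", {
  specs <- list(
    population_spec("healthy"),
    population_spec("geriatric", c(85, 95)),
    population_spec("cirrhosis_CP_C"),
    population_spec("renal_GFR_lt_30"),
    population_spec("pregnant", gestational_week = 25),
    population_spec("pediatric", c(2, 6))
  )
  for (spec in specs) for (seed in c(1L, 7L, 123L)) {
    ind <- sample_individual(spec, seed)
    expect_silent(validate_individual(ind))
    expect_equal(sum(ind$organ_blood_flows), ind$cardiac_output,
                 tolerance = 1e-6 * ind$cardiac_output)
  }
  expect_error(population_spec("martian"), "unsupported")
})

test_that("pediatric ontogeny matures monotonically to the adult limit", {
  for (e in c("CYP2C8", "CYP2D6", "CYP3A4")) {
    fr <- ontogeny_fraction(seq(0, 18, by = 0.25), e)
    expect_true(all(diff(fr) >= 0))
    expect_lt(abs(ontogeny_fraction(17.99, e) - 1), 0.05)
  }
  expect_lt(ontogeny_fraction(0.04, "CYP3A4"), 0.5)
  expect_lt(abs(gfr_maturation(17.99) - 1), 0.05)
  adult <- typical_adult()
  nearly <- apply_pediatric_scaling(adult, 17.99)
  expect_true(all(abs(nearly$enzyme_abundance_scalars - 1) < 0.05))
  young <- apply_pediatric_scaling(adult, 0.04)
  expect_lt(young$enzyme_abundance_scalars[["CYP3A4"]], 0.5)
  expect_lt(young$body_weight, 5)
  expect_error(apply_pediatric_scaling(adult, -1), ">= 0")
})

test_that("geriatric decline is monotone with a 40-year identity anchor", {
  adult <- typical_adult()
  expect_identical(apply_geriatric_scaling(adult, 40), adult)
  g65 <- apply_geriatric_scaling(adult, 65)
  g95 <- apply_geriatric_scaling(adult, 95)
  expect_lt(g95$gfr, g65$gfr)
  expect_lt(g95$cardiac_output, g65$cardiac_output)
  expect_lt(g95$organ_volumes[["liver"]], g65$organ_volumes[["liver"]])
})

test_that("Child-Pugh factors are severity-ordered and idempotent", {
  f <- hepatic_impairment_factors()
  for (col in c("cyp", "liver_mass", "hepatic_flow", "albumin"))
    expect_true(all(diff(f[[col]]) < 0))
  expect_lte(f$cyp[f$grade == "CP-C"], 0.5)
  adult <- typical_adult()
  c1 <- apply_hepatic_impairment(adult, "CP-C")
  expect_identical(apply_hepatic_impairment(c1, "CP-C"), c1)
  expect_error(apply_hepatic_impairment(c1, "CP-A"), "already carries")
  expect_lt(c1$albumin_scalar, adult$albumin_scalar)
})

test_that("renal bands set GFR-proportional clearance multipliers", {
  adult <- typical_adult()
  lo <- apply_renal_impairment(adult, "GFR_lt_30")
  mid <- apply_renal_impairment(adult, "GFR_30_60")
  expect_equal(lo$gfr / 120, 20 / 120, tolerance = 1e-9)
  expect_equal(mid$gfr / 120, 45 / 120, tolerance = 1e-9)
  expect_gt(mid$gfr, lo$gfr)
  expect_error(apply_renal_impairment(adult, "GFR_0"), "unknown")
})

test_that("gestational changes are smooth, anchored and female-only", {
  f <- sample_individual(population_spec(sex_ratio = 0, variability = FALSE), 1L)
  expect_identical(apply_pregnancy(f, 0), f)
  w13 <- apply_pregnancy(f, 13); w25 <- apply_pregnancy(f, 25)
  w37 <- apply_pregnancy(f, 37)
  for (field in c("gfr", "body_weight", "cardiac_output")) {
    vals <- c(f[[field]], w13[[field]], w25[[field]], w37[[field]])
    expect_true(all(diff(vals) > 0), info = field)
  }
  e <- sapply(list(f, w13, w25, w37),
              function(i) i$enzyme_abundance_scalars[["CYP3A4"]])
  expect_true(all(diff(e) > 0))
  alb <- sapply(list(f, w13, w25, w37), function(i) i$albumin_scalar)
  expect_true(all(diff(alb) < 0))
  male <- typical_adult()
  expect_error(apply_pregnancy(male, 20), "female")
})

test_that("noisy-profile generation is exact at zero noise and calibrated", {
  prof <- data.frame(time_h = 0:10, conc = exp(-(0:10) / 5))
  em0 <- error_model(proportional_cv = 0, additive_sd = 0, seed = 1)
  expect_equal(generate_noisy_profile(prof, em0)$conc, prof$conc)
  em <- error_model(proportional_cv = 0.2, seed = 7)
  n1 <- generate_noisy_profile(prof, em)
  expect_identical(generate_noisy_profile(prof, em), n1)
  # Monte-Carlo: empirical CV of the multiplicative deviates
  flat <- data.frame(time_h = 1:1000, conc = rep(1, 1000))
  noisy <- generate_noisy_profile(flat, error_model(0.2, seed = 3))
  cv_emp <- stats::sd(noisy$conc) / mean(noisy$conc)
  expect_lt(abs(cv_emp / 0.2 - 1), 0.10)
  # censoring flags, not drops
  low <- generate_noisy_profile(data.frame(time_h = 1, conc = 1e-6),
                                error_model(0, 0, lloq = 0.01, seed = 1))
  expect_true(low$lloq_flag)
  expect_equal(nrow(low), 1L)
})
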