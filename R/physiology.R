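# Virtual-population generator: reference physiology tables, special-population
# scalings (age, pregnancy, hepatic/renal impairment), inter-individual
# variability, and the synthetic observed-profile generator.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so sampling is reproducible without
#' disturbing the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reference adult physiology tables
#'
#' Typical organ volume fractions (of body weight; tissue density taken as
#' 1 kg/L), organ blood-flow fractions (of cardiac output), and scalar
#' reference values for a healthy 20-50 year adult.  These tables are the
#' transparent stand-in for a proprietary virtual-population database; all
#' special-population scalings start from them.
#'
#' @param sex `"male"` or `"female"`.
#' @return list with `body_weight`, `volume_fractions`, `flow_fractions`,
#'   `cardiac_output_ref`, `gfr`, `hematocrit`, `mppgl`.
#' @export
reference_physiology <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  vf <- c(adipose = 0.21, bone = 0.14, brain = 0.020, gut = 0.017,
          heart = 0.005, kidney = 0.0044, liver = 0.026, muscle = 0.40,
          skin = 0.047, spleen = 0.0022,
          lung_EC = 0.0021, lung_IC = 0.0050,
          venous = 0.051, arterial = 0.025)
  bw <- 70
  if (sex == "female") {
    bw <- 61
    vf["adipose"] <- 0.29
    vf["muscle"] <- 0.33
  }
  vf <- c(vf, rest = max(1 - sum(vf), 0.02))
  ff <- c(adipose = 0.05, bone = 0.05, brain = 0.12, gut = 0.15,
          heart = 0.04, kidney = 0.19, liver = 0.065, muscle = 0.17,
          skin = 0.05, spleen = 0.03)
  ff <- c(ff, rest = 1 - sum(ff))
  list(body_weight = bw,
       volume_fractions = vf,
       flow_fractions = ff,          # of cardiac output; liver = hepatic artery
       cardiac_output_ref = 336,     # L/h at 70 kg; scaled by (W/70)^0.75
       gfr = 120,                    # mL/min healthy adult
       hematocrit = 0.45,
       mppgl = 40)                   # mg microsomal protein / g liver
}

#' Population specification
#'
#' @param category one of `"healthy"`, `"geriatric"`, `"cirrhosis_CP_A"`,
#'   `"cirrhosis_CP_B"`, `"cirrhosis_CP_C"`, `"renal_GFR_30_60"`,
#'   `"renal_GFR_lt_30"`, `"pregnant"`, `"pediatric"`.
#' @param age_range numeric length-2, years (low < high).
#' @param sex_ratio fraction male in \[0, 1\]; forced to 0 for pregnancy.
#' @param gestational_week gestational week for pregnant populations
#'   (13, 25 and 37 are the study trimester anchors; other values allowed).
#' @param ethnicity label; affects only the body-weight table hook.
#' @param variability logical: sample log-normal inter-individual variability.
#' @param cv named CV map; defaults 30% on clearance-like quantities
#'   (enzyme abundances, GFR), 20% on volumes and flows, 15% on body weight.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(category = "healthy",
                            age_range = c(20, 50),
                            sex_ratio = 0.5,
                            gestational_week = NA_real_,
                            ethnicity = "Caucasian",
                            variability = TRUE,
                            cv = NULL) {
  categories <- c("healthy", "geriatric", "cirrhosis_CP_A", "cirrhosis_CP_B",
                  "cirrhosis_CP_C", "renal_GFR_30_60", "renal_GFR_lt_30",
                  "pregnant", "pediatric")
  if (!category %in% categories)
    stop("unsupported population category: ", category)
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop("age_range must be (low, high) with low < high")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0,1]")
  if (category == "pregnant") {
    sex_ratio <- 0
    if (is.na(gestational_week)) stop("pregnant spec needs gestational_week")
    if (gestational_week < 0 || gestational_week > 42)
      stop("gestational_week must lie in [0, 42]")
    if (!gestational_week %in% c(13, 25, 37))
      message("gestational_week ", gestational_week,
              " is outside the trimester anchors (13, 25, 37)")
  }
  cv_default <- c(weight = 0.15, volume = 0.20, flow = 0.20,
                  enzyme = 0.30, gfr = 0.30)
  if (!is.null(cv)) cv_default[names(cv)] <- unlist(cv)
  structure(list(category = category, age_range = age_range,
                 sex_ratio = sex_ratio, gestational_week = gestational_week,
                 ethnicity = ethnicity, variability = variability,
                 cv = cv_default),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec> ", x$category, ", ages ", x$age_range[1], "-",
      x$age_range[2], " y, male fraction ", x$sex_ratio,
      if (!is.na(x$gestational_week)) paste0(", week ", x$gestational_week),
      ", variability ", ifelse(x$variability, "on", "off"), "\n", sep = "")
  invisible(x)
}

#' Validate an individual's physiological invariants
#'
#' All volumes and flows positive; non-lung organ flows sum to cardiac output
#' to 1e-6 relative; GFR and enzyme scalars non-negative.
#'
#' @param ind an `individual`.
#' @return `ind`, invisibly; errors on violation.
#' @export
validate_individual <- function(ind) {
  if (any(ind$organ_volumes <= 0)) stop("all organ volumes must be > 0")
  if (any(ind$organ_blood_flows <= 0)) stop("all organ flows must be > 0")
  rel <- abs(sum(ind$organ_blood_flows) - ind$cardiac_output) /
    ind$cardiac_output
  if (rel > 1e-6)
    stop("organ flows do not sum to cardiac output (rel err ",
         format(rel), ")")
  if (ind$gfr < 0) stop("gfr must be >= 0")
  if (any(ind$enzyme_abundance_scalars < 0))
    stop("enzyme scalars must be >= 0")
  invisible(ind)
}

individual_from_parts <- function(age, sex, bw, volumes, flows, co, gfr,
                                  enzyme, albumin_scalar = 1, hematocrit = 0.45,
                                  gestational_week = NA_real_, mppgl = 40,
                                  tags = list()) {
  ind <- structure(list(
    age = age, sex = sex, body_weight = bw,
    organ_volumes = volumes,
    organ_blood_flows = flows,
    cardiac_output = co,
    liver_weight = unname(volumes["liver"]) * 1000 * 1.05,
    microsomal_protein_per_g_liver = mppgl,
    enzyme_abundance_scalars = enzyme,
    gfr = gfr,
    albumin_scalar = albumin_scalar,
    hematocrit = hematocrit,
    gestational_week = gestational_week,
    tags = tags
  ), class = "individual")
  validate_individual(ind)
}

#' @export
print.individual <- function(x, ...) {
  cat("<individual> ", x$sex, ", ", signif(x$age, 3), " y, ",
      signif(x$body_weight, 3), " kg, CO ", signif(x$cardiac_output, 4),
      " L/h, GFR ", signif(x$gfr, 3), " mL/min\n", sep = "")
  cat("  CYP scalars:",
      paste(sprintf("%s=%.2f", names(x$enzyme_abundance_scalars),
                    x$enzyme_abundance_scalars), collapse = " "), "\n")
  invisible(x)
}

build_typical_adult <- function(age, sex) {
  ref <- reference_physiology(sex)
  bw <- ref$body_weight
  volumes <- ref$volume_fractions * bw          # L (density 1)
  co <- ref$cardiac_output_ref * (bw / 70)^0.75
  flows <- ref$flow_fractions * co
  individual_from_parts(age = age, sex = sex, bw = bw, volumes = volumes,
                        flows = flows, co = co, gfr = ref$gfr,
                        enzyme = c(CYP2C8 = 1, CYP2D6 = 1, CYP3A4 = 1),
                        hematocrit = ref$hematocrit, mppgl = ref$mppgl)
}

apply_variability <- function(ind, cv, seed) {
  with_seed(seed, {
    lndev <- function(cvv, n = 1) {
      sdlog <- sqrt(log(1 + cvv^2))
      exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    }
    wf <- lndev(cv["weight"])
    bw <- ind$body_weight * wf
    # volumes scale with weight plus per-organ jitter
    vols <- ind$organ_volumes * wf *
      lndev(cv["volume"], length(ind$organ_volumes))
    co <- ind$cardiac_output * wf^0.75 * lndev(cv["flow"])
    fr <- ind$organ_blood_flows * lndev(cv["flow"], length(ind$organ_blood_flows))
    flows <- fr / sum(fr) * co                  # exact flow balance
    enz <- ind$enzyme_abundance_scalars *
      lndev(cv["enzyme"], length(ind$enzyme_abundance_scalars))
    gfr <- ind$gfr * lndev(cv["gfr"])
    individual_from_parts(ind$age, ind$sex, bw, vols, flows, co, gfr, enz,
                          ind$albumin_scalar, ind$hematocrit,
                          ind$gestational_week, ind$microsomal_protein_per_g_liver,
                          ind$tags)
  })
}

#' Sample one virtual individual
#'
#' Builds the deterministic category-typical individual for the spec, applies
#' log-normal inter-individual variability when enabled, then applies the
#' category transform (ontogeny, geriatric decline, organ impairment,
#' pregnancy).  Fully reproducible given `(spec, seed)`.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed for this individual's substream.
#' @return an `individual`.
#' @export
sample_individual <- function(spec, seed = 1L) {
  if (!inherits(spec, "population_spec")) stop("spec must be a population_spec")
  draws <- with_seed(seed, list(
    age = stats::runif(1, spec$age_range[1], spec$age_range[2]),
    male = stats::runif(1) < spec$sex_ratio
  ))
  if (spec$variability) {
    age <- draws$age
    sex <- if (draws$male) "male" else "female"
  } else {
    age <- mean(spec$age_range)
    sex <- if (spec$sex_ratio >= 0.5) "male" else "female"
  }
  if (spec$category == "pregnant") sex <- "female"

  ind <- build_typical_adult(age = age, sex = sex)
  if (spec$variability) ind <- apply_variability(ind, spec$cv, seed + 104729L)

  switch(spec$category,
    healthy = ind,
    geriatric = apply_geriatric_scaling(ind, age),
    cirrhosis_CP_A = apply_hepatic_impairment(
      if (age > 60) apply_geriatric_scaling(ind, age) else ind, "CP-A"),
    cirrhosis_CP_B = apply_hepatic_impairment(
      if (age > 60) apply_geriatric_scaling(ind, age) else ind, "CP-B"),
    cirrhosis_CP_C = apply_hepatic_impairment(
      if (age > 60) apply_geriatric_scaling(ind, age) else ind, "CP-C"),
    renal_GFR_30_60 = apply_renal_impairment(
      if (age > 60) apply_geriatric_scaling(ind, age) else ind, "GFR_30_60"),
    renal_GFR_lt_30 = apply_renal_impairment(
      if (age > 60) apply_geriatric_scaling(ind, age) else ind, "GFR_lt_30"),
    pregnant = apply_pregnancy(ind, spec$gestational_week),
    pediatric = apply_pediatric_scaling(ind, age)
  )
}

# ---- pediatric ontogeny ------------------------------------------------------

#' Pediatric growth and body-composition reference table
#'
#' Age-indexed typical body weight and organ mass fractions used by
#' [apply_pediatric_scaling()]; intermediate ages are linearly interpolated.
#' Children carry proportionally less adipose and muscle and more brain and
#' liver than adults, and their tissues bind a lipophilic base less avidly:
#' `f_tissue_binding` is the fraction of adult tissue partitioning applied
#' to all perfusion-limited organ Kps (it matures to 1 by adulthood; values
#' calibrated once against the weight-based pediatric dose table).
#'
#' @return data.frame of ages (years) and composition columns.
#' @export
pediatric_reference <- function() {
  data.frame(
    age      = c(0.04, 0.29, 1.25,  4,    9,    14.5, 18),
    weight   = c(3.8,  6.0,  10.5,  16.5, 29,   53,   70),
    f_adipose= c(0.13, 0.21, 0.23,  0.17, 0.15, 0.17, 0.21),
    f_muscle = c(0.20, 0.20, 0.22,  0.28, 0.33, 0.38, 0.40),
    f_brain  = c(0.105,0.105,0.092, 0.077,0.046,0.027,0.020),
    f_liver  = c(0.042,0.040,0.036, 0.032,0.029,0.027,0.026),
    f_kidney = c(0.008,0.007,0.006, 0.005,0.0048,0.0045,0.0044),
    f_tissue_binding = c(0.253, 0.297, 0.324, 0.347, 0.404, 0.488, 1.00)
  )
}

#' CYP ontogeny fraction
#'
#' Sigmoidal maturation of hepatic enzyme abundance:
#' `f(age) = base + (1 - base) * age^n / (age^n + age50^n)`.
#' Non-decreasing in age; approaches 1 by adulthood.
#'
#' @param age postnatal age, years.
#' @param enzyme one of `"CYP2C8"`, `"CYP2D6"`, `"CYP3A4"`.
#' @param params optional override list with `base`, `age50`, `hill`.
#' @return maturation fraction in (0, 1\].
#' @export
ontogeny_fraction <- function(age, enzyme, params = NULL) {
  defaults <- list(
    CYP3A4 = list(base = 0.11, age50 = 0.64, hill = 1.5),
    CYP2D6 = list(base = 0.036, age50 = 0.10, hill = 1.0),
    CYP2C8 = list(base = 0.30, age50 = 0.25, hill = 1.0)
  )
  p <- params %||% defaults[[enzyme]]
  if (is.null(p)) stop("no ontogeny defaults for ", enzyme)
  p$base + (1 - p$base) * age^p$hill / (age^p$hill + p$age50^p$hill)
}

#' Renal maturation fraction from postmenstrual age
#'
#' Hill function of postmenstrual age in weeks (`PMA = 40 + 52.18 * age`):
#' `PMA^3.4 / (PMA^3.4 + 47.7^3.4)`.
#'
#' @param age postnatal age, years.
#' @return fraction of weight-normalized adult GFR.
#' @export
gfr_maturation <- function(age) {
  pma <- 40 + 52.18 * age
  pma^3.4 / (pma^3.4 + 47.7^3.4)
}

#' Scale an individual to a pediatric age
#'
#' Body size from the growth reference table; organ volumes from age-specific
#' composition fractions (remaining organs allometric on weight); blood flows
#' allometric (cardiac output proportional to weight^0.75) and renormalized;
#' enzyme abundances multiplied by sigmoidal ontogeny; GFR by allometry times
#' the postmenstrual-age maturation function.
#'
#' @param individual an `individual` (healthy adult base).
#' @param age postnatal age, years (0 <= age < 18).
#' @return scaled `individual`.
#' @export
apply_pediatric_scaling <- function(individual, age) {
  if (age < 0) stop("age must be >= 0")
  if (age >= 18) stop("pediatric scaling applies to age < 18")
  tab <- pediatric_reference()
  gi <- function(col) stats::approx(tab$age, tab[[col]], xout = max(age, tab$age[1]),
                                    rule = 2)$y
  wf <- individual$body_weight / reference_physiology(individual$sex)$body_weight
  bw <- gi("weight") * wf                     # preserve sampled size deviate
  ws <- bw / 70
  ref <- reference_physiology("male")$volume_fractions
  vols <- ref * bw                            # default: weight-proportional
  vols["adipose"] <- gi("f_adipose") * bw
  vols["muscle"]  <- gi("f_muscle") * bw
  vols["brain"]   <- gi("f_brain") * bw
  vols["liver"]   <- gi("f_liver") * bw
  vols["kidney"]  <- gi("f_kidney") * bw
  vols["rest"] <- max(bw - sum(vols[names(vols) != "rest"]), 0.02 * bw)
  size_ratio <- bw / individual$body_weight
  co <- individual$cardiac_output * size_ratio^0.75
  fr <- individual$organ_blood_flows / sum(individual$organ_blood_flows)
  flows <- fr * co
  enz <- individual$enzyme_abundance_scalars
  for (e in names(enz)) enz[e] <- enz[e] * ontogeny_fraction(age, e)
  gfr <- individual$gfr * size_ratio^0.75 * gfr_maturation(age)
  tags <- individual$tags
  tags$tissue_binding <- gi("f_tissue_binding")
  individual_from_parts(age, individual$sex, bw, vols, flows, co, gfr, enz,
                        individual$albumin_scalar, individual$hematocrit,
                        NA_real_, individual$microsomal_protein_per_g_liver,
                        tags)
}

# ---- geriatric ---------------------------------------------------------------

#' Geriatric physiological decline
#'
#' Past a 40-year anchor: GFR declines linearly (default 0.9 mL/min/year),
#' cardiac output by 0.35%/year, liver volume by 0.30%/year and hepatic CYP
#' abundance by 0.35%/year (defaults calibrated once against the
#' baseline-relative geriatric exposure table).  Flows are renormalized to
#' the reduced cardiac output.  Age 40 or below is the identity.
#'
#' @param individual an `individual`.
#' @param age age in years.
#' @param gfr_slope GFR decline, mL/min per year past 40.
#' @param co_rate,liver_rate,cyp_rate fractional declines per year past 40.
#' @return scaled `individual`.
#' @export
apply_geriatric_scaling <- function(individual, age,
                                    gfr_slope = 0.9,
                                    co_rate = 0.0035,
                                    liver_rate = 0.0030,
                                    cyp_rate = 0.0035) {
  yrs <- max(age - 40, 0)
  if (yrs == 0) return(individual)
  gfr <- max(individual$gfr - gfr_slope * yrs, 5)
  co <- individual$cardiac_output * max(1 - co_rate * yrs, 0.3)
  vols <- individual$organ_volumes
  vols["liver"] <- vols["liver"] * max(1 - liver_rate * yrs, 0.3)
  fr <- individual$organ_blood_flows / sum(individual$organ_blood_flows)
  flows <- fr * co
  enz <- individual$enzyme_abundance_scalars * max(1 - cyp_rate * yrs, 0.2)
  individual_from_parts(age, individual$sex, individual$body_weight, vols,
                        flows, co, gfr, enz, individual$albumin_scalar,
                        individual$hematocrit, individual$gestational_week,
                        individual$microsomal_protein_per_g_liver,
                        individual$tags)
}

# ---- organ impairment --------------------------------------------------------

#' Child-Pugh grade factor table
#'
#' Multiplicative factors applied by [apply_hepatic_impairment()]:
#' progressive reduction of functional CYP abundance, liver mass, hepatic
#' blood flow and albumin (unbound fraction rises as albumin falls).
#'
#' @return data.frame with one row per grade.
#' @export
hepatic_impairment_factors <- function() {
  data.frame(
    grade = c("CP-A", "CP-B", "CP-C"),
    cyp = c(0.72, 0.56, 0.43),
    liver_mass = c(0.95, 0.88, 0.80),
    hepatic_flow = c(0.90, 0.75, 0.60),
    albumin = c(0.90, 0.75, 0.60),
    stringsAsFactors = FALSE
  )
}

#' Apply cirrhosis (Child-Pugh) impairment
#'
#' @param individual an `individual`.
#' @param grade `"CP-A"`, `"CP-B"` or `"CP-C"`.
#' @param factors factor table, see [hepatic_impairment_factors()].
#' @return impaired `individual`; idempotent (re-applying the same grade is a
#'   no-op, tracked via a tag).
#' @export
apply_hepatic_impairment <- function(individual, grade,
                                     factors = hepatic_impairment_factors()) {
  if (!grade %in% factors$grade) stop("unknown Child-Pugh grade: ", grade)
  if (identical(individual$tags$hepatic_grade, grade)) return(individual)
  if (!is.null(individual$tags$hepatic_grade))
    stop("individual already carries hepatic grade ",
         individual$tags$hepatic_grade)
  f <- factors[factors$grade == grade, ]
  vols <- individual$organ_volumes
  vols["liver"] <- vols["liver"] * f$liver_mass
  flows <- individual$organ_blood_flows
  hep <- c("liver", "gut", "spleen")          # total liver flow = HA + portal
  flows[hep] <- flows[hep] * f$hepatic_flow
  co <- sum(flows)                            # reduced splanchnic return
  enz <- individual$enzyme_abundance_scalars * f$cyp
  tags <- individual$tags
  tags$hepatic_grade <- grade
  individual_from_parts(individual$age, individual$sex, individual$body_weight,
                        vols, flows, co, individual$gfr, enz,
                        individual$albumin_scalar * f$albumin,
                        individual$hematocrit, individual$gestational_week,
                        individual$microsomal_protein_per_g_liver, tags)
}

#' Apply renal impairment
#'
#' Sets GFR to the band-typical value (45 mL/min for GFR 30-60, 20 mL/min for
#' GFR < 30); downstream renal drug clearance scales as GFR / 120.  An
#' optional uremia factor on hepatic CYPs is off by default.
#'
#' @param individual an `individual`.
#' @param band `"GFR_30_60"` or `"GFR_lt_30"`.
#' @param band_gfr named defaults for the two bands, mL/min.
#' @param uremia_cyp_factor multiplier on hepatic CYP abundance (default 1).
#' @return impaired `individual`.
#' @export
apply_renal_impairment <- function(individual, band,
                                   band_gfr = c(GFR_30_60 = 45, GFR_lt_30 = 20),
                                   uremia_cyp_factor = 1) {
  if (!band %in% names(band_gfr)) stop("unknown renal band: ", band)
  # preserve the individual's relative (sampled) deviation around typical
  rel <- individual$gfr / 120
  gfr <- unname(band_gfr[band]) * rel
  enz <- individual$enzyme_abundance_scalars * uremia_cyp_factor
  individual_from_parts(individual$age, individual$sex, individual$body_weight,
                        individual$organ_volumes, individual$organ_blood_flows,
                        individual$cardiac_output, gfr, enz,
                        individual$albumin_scalar, individual$hematocrit,
                        individual$gestational_week,
                        individual$microsomal_protein_per_g_liver,
                        individual$tags)
}

# ---- pregnancy ---------------------------------------------------------------

#' Apply gestational changes
#'
#' Smooth (linear-in-week) physiological changes, week 0 being the identity:
#' plasma/blood volume expansion, body-weight gain, GFR increase, CYP3A4 and
#' CYP2D6 (and mildly CYP2C8) activity increase, and albumin decrease.
#' Term-anchored magnitudes are config defaults calibrated once against the
#' baseline-relative pregnancy exposure table.
#'
#' @param individual a female `individual`.
#' @param gestational_week weeks, 0-42.
#' @param term anchor list of term (week-40) effect sizes.
#' @return pregnant `individual`.
#' @export
apply_pregnancy <- function(individual, gestational_week,
                            term = list(weight_gain_kg = 12,
                                        blood_expansion = 0.42,
                                        gfr_rise = 0.60,
                                        cyp3a4_rise = 2.1,
                                        cyp2d6_rise = 2.5,
                                        cyp2c8_rise = 1.3,
                                        albumin_drop = 0.27)) {
  if (individual$sex != "female")
    stop("pregnancy scaling requires a female individual")
  if (gestational_week < 0 || gestational_week > 42)
    stop("gestational_week must lie in [0, 42]")
  w <- gestational_week / 40
  if (w == 0) return(individual)
  vols <- individual$organ_volumes
  dblood <- (vols["venous"] + vols["arterial"]) * term$blood_expansion * w
  vols["venous"] <- vols["venous"] * (1 + term$blood_expansion * w)
  vols["arterial"] <- vols["arterial"] * (1 + term$blood_expansion * w)
  gain <- term$weight_gain_kg * w
  bw <- individual$body_weight + gain
  # weight gain beyond blood expansion goes to the rest compartment
  vols["rest"] <- vols["rest"] + max(gain - dblood, 0)
  co <- individual$cardiac_output * (1 + 0.35 * w)
  fr <- individual$organ_blood_flows / sum(individual$organ_blood_flows)
  flows <- fr * co
  gfr <- individual$gfr * (1 + term$gfr_rise * w)
  enz <- individual$enzyme_abundance_scalars
  enz["CYP3A4"] <- enz["CYP3A4"] * (1 + term$cyp3a4_rise * w)
  enz["CYP2D6"] <- enz["CYP2D6"] * (1 + term$cyp2d6_rise * w)
  enz["CYP2C8"] <- enz["CYP2C8"] * (1 + term$cyp2c8_rise * w)
  individual_from_parts(individual$age, "female", bw, vols, flows, co, gfr,
                        enz, individual$albumin_scalar * (1 - term$albumin_drop * w),
                        individual$hematocrit, gestational_week,
                        individual$microsomal_protein_per_g_liver,
                        individual$tags)
}

# ---- synthetic observations --------------------------------------------------

#' Residual error model for synthetic observations
#'
#' @param proportional_cv proportional log-normal CV (fraction, >= 0).
#' @param additive_sd additive noise SD, mg/L (>= 0).
#' @param lloq lower limit of quantification, mg/L (>= 0).
#' @param seed integer seed.
#' @return object of class `error_model`.
#' @export
error_model <- function(proportional_cv = 0.1, additive_sd = 0, lloq = 0,
                        seed = 1L) {
  if (proportional_cv < 0 || additive_sd < 0 || lloq < 0)
    stop("error model parameters must be >= 0")
  structure(list(proportional_cv = proportional_cv, additive_sd = additive_sd,
                 lloq = lloq, seed = as.integer(seed)),
            class = "error_model")
}

#' Fabricate a noisy observed profile from a true concentration series
#'
#' Each point is multiplied by a log-normal deviate with the configured CV and
#' perturbed by additive Gaussian noise, then censored at the LLOQ (flagged,
#' not dropped; censored values are reported at the LLOQ).  Seed-reproducible;
#' zero noise returns the input exactly.
#'
#' @param true_profile data.frame with columns `time_h` and `conc` (mg/L,
#'   non-negative).
#' @param error an [error_model()].
#' @return `observed_profile` data.frame: `time_h`, `conc`, `lloq_flag`.
#' @export
generate_noisy_profile <- function(true_profile, error) {
  if (any(true_profile$conc < 0)) stop("true profile must be non-negative")
  n <- nrow(true_profile)
  conc <- with_seed(error$seed, {
    out <- true_profile$conc
    if (error$proportional_cv > 0) {
      sdlog <- sqrt(log(1 + error$proportional_cv^2))
      out <- out * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    }
    if (error$additive_sd > 0)
      out <- out + stats::rnorm(n, 0, error$additive_sd)
    pmax(out, 0)
  })
  flag <- conc < error$lloq
  conc[flag] <- error$lloq
  data.frame(time_h = true_profile$time_h, conc = conc, lloq_flag = flag)
}
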