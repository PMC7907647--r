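# Perpetrator pharmacokinetics and enzyme-activity dynamics for drug-drug
# interaction scenarios: competitive inhibition scales intrinsic clearance
# instantaneously; mechanism-based inactivation is a turnover state per CYP.

#' Perpetrator parameter bundle
#'
#' One-compartment first-order-absorption PK plus per-enzyme inhibition
#' constants.  An enzyme may carry competitive (`ki_u`) and/or
#' mechanism-based (`KI_u` + `kinact`) terms.
#'
#' @param name perpetrator label.
#' @param molecular_weight g/mol.
#' @param dose_mg dose per administration, mg.
#' @param interval_h dosing interval, h.
#' @param n_doses number of doses.
#' @param start_h time of first perpetrator dose relative to the first victim
#'   dose, h (negative = pretreatment).
#' @param ka absorption rate constant, 1/h.
#' @param v_f apparent volume V/F, L.
#' @param cl_f apparent clearance CL/F, L/h.
#' @param fu_plasma unbound fraction.
#' @param ki_u named list: unbound competitive Ki per enzyme, uM.
#' @param KI_u,kinact named lists: unbound MBI concentration (uM) and maximal
#'   inactivation rate (1/h) per enzyme.
#' @param kdeg named list of enzyme turnover rates, 1/h; `kdeg_default`
#'   applies to enzymes without an entry (36 h turnover half-life).
#' @param kdeg_default default turnover rate, 1/h.
#' @return object of class `perpetrator_params`.
#' @export
perpetrator_parameters <- function(name, molecular_weight, dose_mg, interval_h,
                                   n_doses, start_h = -48, ka, v_f, cl_f,
                                   fu_plasma, ki_u = list(), KI_u = list(),
                                   kinact = list(), kdeg = list(),
                                   kdeg_default = log(2) / 36) {
  stopifnot(molecular_weight > 0, dose_mg > 0, interval_h > 0, n_doses >= 1,
            ka > 0, v_f > 0, cl_f > 0, fu_plasma > 0, fu_plasma <= 1)
  if (!setequal(names(KI_u), names(kinact)))
    stop("KI_u and kinact must cover the same enzymes")
  listed <- union(names(ki_u), names(kinact))
  if (!length(listed)) stop("a perpetrator must inhibit at least one enzyme")
  for (v in c(unlist(ki_u), unlist(KI_u), unlist(kinact), unlist(kdeg)))
    if (v <= 0) stop("all kinetic constants must be > 0")
  structure(list(name = name, molecular_weight = molecular_weight,
                 dose_mg = dose_mg, interval_h = interval_h,
                 n_doses = n_doses, start_h = start_h, ka = ka, v_f = v_f,
                 cl_f = cl_f, fu_plasma = fu_plasma, ki_u = ki_u,
                 KI_u = KI_u, kinact = kinact, kdeg = kdeg,
                 kdeg_default = kdeg_default),
            class = "perpetrator_params")
}

#' @export
print.perpetrator_params <- function(x, ...) {
  cat("<perpetrator_params> ", x$name, ": ", x$dose_mg, " mg q", x$interval_h,
      "h x", x$n_doses, " from t=", x$start_h, " h\n", sep = "")
  if (length(x$ki_u))
    cat("  competitive Ki_u:",
        paste(sprintf("%s=%.3g uM", names(x$ki_u), unlist(x$ki_u)),
              collapse = " "), "\n")
  if (length(x$kinact))
    cat("  MBI:", paste(sprintf("%s KI=%.3g uM kinact=%.3g/h",
                                names(x$kinact), unlist(x$KI_u),
                                unlist(x$kinact)), collapse = "; "), "\n")
  invisible(x)
}

#' Built-in interaction perpetrators
#'
#' Literature-informed defaults for the three scenario perpetrators:
#' gemfibrozil 600 mg BID (strong CYP2C8 inhibitor; the acyl-glucuronide's
#' mechanism-based CYP2C8 inactivation is folded into the parent's MBI
#' terms), quinidine 200 mg QD (strong CYP2D6 inhibitor) and ritonavir
#' 100 mg QD (strong CYP3A4, weak CYP2D6 inhibitor).  Each is dosed for 12
#' days starting two days before the victim's first dose.
#'
#' @param name one of `"gemfibrozil"`, `"quinidine"`, `"ritonavir"`.
#' @return a `perpetrator_params`.
#' @export
builtin_perpetrator <- function(name = c("gemfibrozil", "quinidine",
                                         "ritonavir")) {
  name <- match.arg(name)
  switch(name,
    gemfibrozil = perpetrator_parameters(
      name = "gemfibrozil", molecular_weight = 250.34,
      dose_mg = 600, interval_h = 12, n_doses = 24, start_h = -48,
      ka = 2.0, v_f = 16, cl_f = 7.0, fu_plasma = 0.03,
      ki_u = list(CYP2C8 = 9.3),
      KI_u = list(CYP2C8 = 20), kinact = list(CYP2C8 = 0.40)),
    quinidine = perpetrator_parameters(
      name = "quinidine", molecular_weight = 324.42,
      dose_mg = 200, interval_h = 24, n_doses = 12, start_h = -48,
      ka = 1.5, v_f = 190, cl_f = 18, fu_plasma = 0.13,
      ki_u = list(CYP2D6 = 0.06)),
    ritonavir = perpetrator_parameters(
      name = "ritonavir", molecular_weight = 720.95,
      dose_mg = 100, interval_h = 24, n_doses = 12, start_h = -48,
      ka = 1.0, v_f = 96, cl_f = 8.8, fu_plasma = 0.015,
      ki_u = list(CYP3A4 = 0.019, CYP2D6 = 2.5),
      KI_u = list(CYP3A4 = 0.17), kinact = list(CYP3A4 = 20))
  )
}

#' Unbound perpetrator concentration at a time point
#'
#' One-compartment first-order-absorption superposition over all administered
#' doses, converted to an unbound molar concentration (uM) via the unbound
#' fraction and molecular weight.  Used as the liver-inlet inhibitor
#' concentration.
#'
#' @param params a `perpetrator_params`.
#' @param t_h time, h (same clock as the victim regimen); values before the
#'   first perpetrator dose give 0.
#' @return unbound concentration, uM (vectorized over `t_h`).
#' @export
perpetrator_concentration <- function(params, t_h) {
  ke <- params$cl_f / params$v_f
  ka <- params$ka
  if (abs(ka - ke) < 1e-9) ka <- ka * (1 + 1e-6)
  dose_times <- params$start_h + params$interval_h * (seq_len(params$n_doses) - 1)
  conc <- vapply(t_h, function(t) {
    tau <- t - dose_times
    tau <- tau[tau >= 0]
    if (!length(tau)) return(0)
    sum(params$dose_mg * ka / (params$v_f * (ka - ke)) *
          (exp(-ke * tau) - exp(-ka * tau)))
  }, numeric(1))
  params$fu_plasma * conc / params$molecular_weight * 1000
}

#' Competitive inhibition activity multiplier
#'
#' `1 / (1 + Iu / Ki_u)`, in (0, 1].
#'
#' @param Iu unbound inhibitor concentration, uM (>= 0).
#' @param Ki_u unbound inhibition constant, uM (> 0; `Inf` = no inhibition).
#' @return activity multiplier.
#' @export
competitive_multiplier <- function(Iu, Ki_u) {
  if (any(Iu < 0)) stop("Iu must be >= 0")
  if (any(Ki_u <= 0)) stop("Ki_u must be > 0")
  1 / (1 + Iu / Ki_u)
}

#' Mechanism-based inactivation turnover derivative
#'
#' `dE/dt = kdeg (1 - E) - kinact Iu / (KI_u + Iu) E`; the steady state is
#' `E* = kdeg / (kdeg + kinact Iu / (KI_u + Iu))`, decreasing in Iu with
#' limit `kdeg / (kdeg + kinact)`.
#'
#' @param E active enzyme fraction (>= 0).
#' @param Iu unbound inhibitor concentration, uM.
#' @param KI_u unbound concentration of half-maximal inactivation, uM.
#' @param kinact maximal inactivation rate, 1/h.
#' @param kdeg enzyme turnover rate, 1/h.
#' @return dE/dt, 1/h.
#' @export
mbi_turnover <- function(E, Iu, KI_u, kinact, kdeg) {
  if (any(E < 0)) stop("E must be >= 0")
  kdeg * (1 - E) - kinact * Iu / (KI_u + Iu) * E
}

#' Static complete-inhibition AUC-ratio ceiling
#'
#' `1 / (1 - fm)`: the exposure-ratio upper bound if the affected pathway
#' were fully ablated.  Dynamic simulations must stay below it; with
#' fm = 0.373 (CYP2C8) the ceiling is ~1.595.
#'
#' @param fm fraction of total clearance through the inhibited pathway,
#'   in \[0, 1).
#' @return AUC ratio upper bound.
#' @export
static_aucr_bound <- function(fm) {
  if (any(fm < 0) || any(fm >= 1)) stop("fm must lie in [0, 1)")
  1 / (1 - fm)
}

#' Drug-drug interaction scenario
#'
#' @param perpetrator a `perpetrator_params` (or a [builtin_perpetrator()]
#'   name).
#' @param label scenario label.
#' @return object of class `ddi_scenario`.
#' @export
ddi_scenario <- function(perpetrator, label = NULL) {
  if (is.character(perpetrator)) perpetrator <- builtin_perpetrator(perpetrator)
  stopifnot(inherits(perpetrator, "perpetrator_params"))
  structure(list(perpetrator = perpetrator,
                 label = label %||% perpetrator$name),
            class = "ddi_scenario")
}
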