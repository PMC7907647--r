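# Whole-body PBPK model assembly.
#
# The model is linear in drug amounts: transit-chain absorption, perfusion-
# limited organs, a permeability-limited lung with apparent active uptake for
# the parent, well-stirred enzyme-resolved hepatic elimination, renal
# elimination proportional to GFR, and liver-side metabolite formation.  The
# assembled system is a constant coefficient matrix except when a perpetrator
# makes enzyme activity time-varying (see simulate.pbpk_model).

#' Engine configuration defaults
#'
#' @param n_gut_segments number of small-intestinal transit segments.
#' @param gastric_emptying_t12_h gastric emptying half-life, h.
#' @param small_intestinal_transit_h mean small-intestinal transit time, h.
#' @param gut_radius_cm effective segment radius, cm (`ka = 2 Peff / r`).
#' @param lung_area_cm2 lung epithelial exchange area at 70 kg, cm^2 (scaled
#'   with lung volume).
#' @param ref_liver_volume_l,ref_gfr reference healthy-adult liver volume (L)
#'   and GFR (mL/min) used to scale intrinsic and renal clearances.
#' @param plasma_ph plasma pH.
#' @param peff_slope,peff_intercept Caco-2 to jejunal-Peff log-log correlation.
#' @param dt_h output grid step, h.
#' @param rtol,atol solver tolerances for the ODE-integrator path.
#' @return named list of engine settings.
#' @export
engine_config <- function(n_gut_segments = 7,
                          gastric_emptying_t12_h = 0.25,
                          small_intestinal_transit_h = 3.32,
                          gut_radius_cm = 1.25,
                          lung_area_cm2 = 7e5,
                          ref_liver_volume_l = 1.82,
                          ref_gfr = 120,
                          plasma_ph = 7.4,
                          peff_slope = 0.6795,
                          peff_intercept = -0.3360,
                          dt_h = 0.25,
                          rtol = 1e-8,
                          atol = 1e-10) {
  as.list(environment())
}

#' Fraction absorbed through the transit chain
#'
#' Closed form for the stomach + N-segment transit/absorption chain:
#' `fa = 1 - prod(kt / (kt + ka_n))` with `ka_n = 2 Peff / r_n`.
#'
#' @param drug a `drug_params` object (Caco-2 permeability used).
#' @param config engine configuration.
#' @return fraction of an oral dose absorbed into the portal vein.
#' @export
fraction_absorbed <- function(drug, config = engine_config()) {
  if (drug$papp_caco2 <= 0) return(0)
  peff <- caco2_to_human_peff(drug$papp_caco2, config$peff_slope,
                              config$peff_intercept)
  ka <- 2 * peff / config$gut_radius_cm * 3600
  kt <- config$n_gut_segments / config$small_intestinal_transit_h
  1 - (kt / (kt + ka))^config$n_gut_segments
}

organ_names <- function() {
  c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
    "muscle", "skin", "spleen", "rest")
}

#' Build the whole-body PBPK model for one individual
#'
#' Assembles a single linear ODE system covering the parent analyte (and, if
#' supplied, its metabolite): gut transit chain, all organs, the two-pool
#' permeability-limited lung, balance accumulators, and the dose-event
#' schedule in base equivalents.  Per-enzyme intrinsic clearances are derived
#' by inverting the well-stirred liver model against the configured pathway
#' clearances, then scaled to the individual (enzyme abundance, liver mass,
#' GFR).
#'
#' @param drugs a `drug_params` object or list of them; the analyte carrying
#'   `metabolite_links` is the parent.
#' @param individual an `individual` from [sample_individual()].
#' @param regimen a [regimen()].
#' @param interactions optional `ddi_scenario` (see [ddi_scenario()]).
#' @param config engine settings from [engine_config()].
#' @return object of class `pbpk_model`.
#' @export
build_pbpk_model <- function(drugs, individual, regimen,
                             interactions = NULL,
                             config = engine_config()) {
  if (inherits(drugs, "drug_params")) drugs <- list(drugs)
  has_links <- vapply(drugs, function(d) length(d$metabolite_links) > 0,
                      logical(1))
  parent <- if (any(has_links)) drugs[[which(has_links)[1]]] else drugs[[1]]
  metab <- NULL
  if (length(drugs) > 1) {
    others <- drugs[!vapply(drugs, identical, logical(1), parent)]
    if (length(others)) {
      metab <- others[[1]]
      linked <- vapply(parent$metabolite_links, function(l) l$product,
                       character(1))
      if (length(linked) && !metab$name %in% linked)
        stop("metabolite ", metab$name,
             " is not a product of any metabolite_link of ", parent$name)
    }
  }
  validate_individual(individual)
  # hypoalbuminemia raises the unbound fraction (affects binding-sensitive
  # clearance and partitioning); fu' = fu / (alb + fu (1 - alb))
  if (individual$albumin_scalar != 1) {
    adjust_fu <- function(d) {
      a <- individual$albumin_scalar
      d$fu_plasma <- min(d$fu_plasma / (a + d$fu_plasma * (1 - a)), 1)
      d
    }
    drugs <- lapply(drugs, adjust_fu)
    has_links <- vapply(drugs, function(d) length(d$metabolite_links) > 0,
                        logical(1))
    parent <- if (any(has_links)) drugs[[which(has_links)[1]]] else drugs[[1]]
    if (!is.null(metab))
      metab <- drugs[[which(vapply(drugs, function(d)
        identical(d$name, metab$name), logical(1)))[1]]]
  }
  vols <- individual$organ_volumes
  flows <- individual$organ_blood_flows
  co <- individual$cardiac_output
  organs <- organ_names()
  ns <- config$n_gut_segments

  # --- state index map -------------------------------------------------------
  p_states <- c("p_stomach", paste0("p_gi", seq_len(ns)), "p_sink",
                "p_art", "p_ven", "p_lungEC", "p_lungIC",
                paste0("p_", organs),
                paste0("p_elim_", c("CYP2C8", "CYP2D6", "CYP3A4", "renal")))
  m_states <- character()
  if (!is.null(metab))
    m_states <- c("m_art", "m_ven", "m_lung", paste0("m_", organs),
                  "m_elim_hepatic", "m_elim_renal", "m_formed")
  states <- c(p_states, m_states)
  ix <- stats::setNames(seq_along(states), states)
  n <- length(states)
  A <- matrix(0, n, n, dimnames = list(states, states))

  comp <- tissue_composition_table()
  rownames(comp) <- comp$tissue

  # --- absorption chain ------------------------------------------------------
  kga <- log(2) / config$gastric_emptying_t12_h
  kt <- ns / config$small_intestinal_transit_h
  ka <- if (parent$papp_caco2 > 0) {
    peff <- caco2_to_human_peff(parent$papp_caco2, config$peff_slope,
                                config$peff_intercept)
    rep(2 * peff / config$gut_radius_cm * 3600, ns)
  } else rep(0, ns)
  A[ix["p_gi1"], ix["p_stomach"]] <- kga
  A[ix["p_stomach"], ix["p_stomach"]] <- -kga
  for (s in seq_len(ns)) {
    gi <- ix[paste0("p_gi", s)]
    A[gi, gi] <- -(kt + ka[s])
    nxt <- if (s < ns) ix[paste0("p_gi", s + 1)] else ix["p_sink"]
    A[nxt, gi] <- A[nxt, gi] + kt
    A[ix["p_liver"], gi] <- A[ix["p_liver"], gi] + ka[s]
  }

  # --- distribution for one analyte -----------------------------------------
  tissue_binding <- individual$tags$tissue_binding %||% 1
  add_distribution <- function(drug, pre, lung_mode) {
    bp <- drug$blood_plasma_ratio
    kp <- predict_all_kps(drug, comp, config$plasma_ph) * tissue_binding
    art <- ix[paste0(pre, "art")]; ven <- ix[paste0(pre, "ven")]
    out_coef <- function(org) {  # blood conc leaving organ, per unit amount
      flows[org] * bp / (kp[org] * vols[org])
    }
    nonsplanchnic <- setdiff(organs, c("gut", "spleen", "liver"))
    for (org in c(nonsplanchnic, "gut", "spleen")) {
      oi <- ix[paste0(pre, org)]
      A[oi, art] <<- A[oi, art] + flows[org] / vols["arterial"]
      A[art, art] <<- A[art, art] - flows[org] / vols["arterial"]
      dest <- if (org %in% c("gut", "spleen")) ix[paste0(pre, "liver")] else ven
      A[oi, oi] <<- A[oi, oi] - out_coef(org)
      A[dest, oi] <<- A[dest, oi] + out_coef(org)
    }
    # liver: hepatic artery inflow, total outflow to venous
    li <- ix[paste0(pre, "liver")]
    A[li, art] <<- A[li, art] + flows["liver"] / vols["arterial"]
    A[art, art] <<- A[art, art] - flows["liver"] / vols["arterial"]
    q_li_tot <- flows["liver"] + flows["gut"] + flows["spleen"]
    li_out <- q_li_tot * bp / (kp["liver"] * vols["liver"])
    A[li, li] <<- A[li, li] - li_out
    A[ven, li] <<- A[ven, li] + li_out
    if (lung_mode == "permeability") {
      ec <- ix[paste0(pre, "lungEC")]; ic <- ix[paste0(pre, "lungIC")]
      A[ec, ven] <<- A[ec, ven] + co / vols["venous"]
      A[ven, ven] <<- A[ven, ven] - co / vols["venous"]
      A[ec, ec] <<- A[ec, ec] - co * bp / vols["lung_EC"]
      A[art, ec] <<- A[art, ec] + co * bp / vols["lung_EC"]
      lung_scale <- (vols["lung_EC"] + vols["lung_IC"]) / 0.497
      ps <- caco2_to_calu3(parent$papp_caco2 / 1e-7) * 1e-7 *
        config$lung_area_cm2 * lung_scale * 3600 / 1000   # L/h
      clt <- drug$lung_uptake_clint_T * lung_scale
      trap <- drug$lung_trapping
      uptake <- (ps + clt) * drug$fu_plasma / vols["lung_EC"]
      efflux <- ps / (vols["lung_IC"] * trap)
      A[ic, ec] <<- A[ic, ec] + uptake
      A[ec, ec] <<- A[ec, ec] - uptake
      A[ec, ic] <<- A[ec, ic] + efflux
      A[ic, ic] <<- A[ic, ic] - efflux
      lung_info <<- list(ps = unname(ps), clint_T = unname(clt), trap = trap,
                         v_ec = unname(vols["lung_EC"]),
                         v_ic = unname(vols["lung_IC"]))
    } else {
      lu <- ix[paste0(pre, "lung")]
      v_lung <- vols["lung_EC"] + vols["lung_IC"]
      A[lu, ven] <<- A[lu, ven] + co / vols["venous"]
      A[ven, ven] <<- A[ven, ven] - co / vols["venous"]
      lout <- co * bp / (kp["lung"] * v_lung)
      A[lu, lu] <<- A[lu, lu] - lout
      A[art, lu] <<- A[art, lu] + lout
    }
    list(bp = bp, kp = kp, q_li_tot = q_li_tot)
  }

  lung_info <- NULL
  pinfo <- add_distribution(parent, "p_", "permeability")
  minfo <- if (!is.null(metab)) add_distribution(metab, "m_", "perfusion")

  # --- parent elimination ----------------------------------------------------
  pcomp <- derive_clearance_components(parent)
  enzymes <- intersect(c("CYP2C8", "CYP2D6", "CYP3A4"), names(parent$fm_map))
  fm_hep <- sum(parent$fm_map[enzymes])
  clh_blood_target <- fm_hep * pcomp$total / pinfo$bp
  fu_b_p <- parent$fu_plasma / pinfo$bp
  q_ref <- pinfo$q_li_tot
  clu_tot <- invert_well_stirred(clh_blood_target, q_ref, fu_b_p)
  liver_scale <- unname(vols["liver"]) / config$ref_liver_volume_l
  li_p <- ix["p_liver"]
  li_conc_coef <- pinfo$bp / (pinfo$kp["liver"] * vols["liver"])
  enz_coef <- numeric(0)
  for (e in enzymes) {
    clu_e <- clu_tot * parent$fm_map[[e]] / fm_hep *
      individual$enzyme_abundance_scalars[[e]] * liver_scale
    coef <- unname(fu_b_p * clu_e * li_conc_coef)  # flux per unit liver amount
    enz_coef[e] <- coef
    A[li_p, li_p] <- A[li_p, li_p] - coef
    A[ix[paste0("p_elim_", e)], li_p] <-
      A[ix[paste0("p_elim_", e)], li_p] + coef
    if (!is.null(metab)) {
      ff <- 0
      for (lk in parent$metabolite_links)
        if (lk$enzyme == e && lk$product == metab$name)
          ff <- lk$formation_fraction
      mw_ratio <- metab$molecular_weight_base / parent$molecular_weight_base
      A[ix["m_liver"], li_p] <- A[ix["m_liver"], li_p] + ff * mw_ratio * coef
      A[ix["m_formed"], li_p] <- A[ix["m_formed"], li_p] + ff * mw_ratio * coef
    }
  }
  # renal: glomerular filtration of arterial plasma, scaled by GFR
  clr_p <- pcomp$components[["renal"]] * individual$gfr / config$ref_gfr
  art_p <- ix["p_art"]
  renal_coef <- unname(clr_p / (pinfo$bp * vols["arterial"]))
  A[art_p, art_p] <- A[art_p, art_p] - renal_coef
  A[ix["p_elim_renal"], art_p] <- A[ix["p_elim_renal"], art_p] + renal_coef

  # --- metabolite elimination ------------------------------------------------
  if (!is.null(metab)) {
    mcomp <- derive_clearance_components(metab)
    fu_b_m <- metab$fu_plasma / minfo$bp
    if ("hepatic" %in% names(metab$fm_map) && metab$fm_map[["hepatic"]] > 0) {
      clh_m <- metab$fm_map[["hepatic"]] * mcomp$total / minfo$bp
      clu_m <- invert_well_stirred(clh_m, minfo$q_li_tot, fu_b_m) * liver_scale
      li_m <- ix["m_liver"]
      coef_m <- unname(fu_b_m * clu_m * minfo$bp /
                         (minfo$kp["liver"] * vols["liver"]))
      A[li_m, li_m] <- A[li_m, li_m] - coef_m
      A[ix["m_elim_hepatic"], li_m] <- A[ix["m_elim_hepatic"], li_m] + coef_m
    }
    if ("renal" %in% names(metab$fm_map) && metab$fm_map[["renal"]] > 0) {
      clr_m <- mcomp$components[["renal"]] * individual$gfr / config$ref_gfr
      art_m <- ix["m_art"]
      rc_m <- unname(clr_m / (minfo$bp * vols["arterial"]))
      A[art_m, art_m] <- A[art_m, art_m] - rc_m
      A[ix["m_elim_renal"], art_m] <- A[ix["m_elim_renal"], art_m] + rc_m
    }
  }

  # --- dose events in base equivalents --------------------------------------
  ev <- regimen$events
  target <- ifelse(ev$route == "oral", ix["p_stomach"], ix["p_ven"])
  amounts <- vapply(seq_len(nrow(ev)), function(i) {
    if (ev$route[i] == "oral" || !is.na(parent$molecular_weight_salt))
      salt_to_base_amount(ev$amount_mg_salt[i], parent)
    else ev$amount_mg_salt[i]
  }, numeric(1))
  events <- data.frame(time_h = ev$time_h, state = target,
                       amount_mg = amounts)

  structure(list(
    A = A, states = states, index = ix,
    parent = parent, metabolite = metab,
    individual = individual, regimen = regimen,
    events = events,
    interactions = interactions,
    enzyme_flux_coef = enz_coef,
    lung = lung_info,
    config = config,
    info = list(parent = pinfo, metabolite = minfo,
                clu_int_total = clu_tot, fu_blood = fu_b_p)
  ), class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("<pbpk_model> ", x$parent$name,
      if (!is.null(x$metabolite)) paste0(" + ", x$metabolite$name),
      ": ", length(x$states), " states, ",
      nrow(x$events), " dose events",
      if (!is.null(x$interactions)) paste0(", DDI: ",
                                           x$interactions$perpetrator$name),
      "\n", sep = "")
  print(x$individual)
  invisible(x)
}

#' @export
summary.pbpk_model <- function(object, ...) {
  cc <- derive_clearance_components(object$parent)
  cat("Model for", object$parent$name, "in a",
      object$individual$sex, "of", signif(object$individual$age, 3), "y\n")
  print(cc)
  if (!is.null(object$lung))
    cat(sprintf("Lung: PS %.3g L/h, CLint_T %.3g L/h, trapping %.0f\n",
                object$lung$ps, object$lung$clint_T, object$lung$trap))
  cat(sprintf("Fraction absorbed (transit chain): %.3f\n",
              fraction_absorbed(object$parent, object$config)))
  invisible(object)
}
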