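# Structural, conservation and analytic-limit checks on the assembled ODE
# system.

test_that("model assembly has the expected structure", {
  ind <- typical_adult()
  hcq <- hcq_parameters()
  m1 <- build_pbpk_model(list(hcq), ind, regimen_a())
  # stomach + 7 segments + sink + art/ven + lung EC/IC + 11 organs + 4 ledgers
  expect_length(m1$states, 28L)
  m2 <- build_pbpk_model(list(hcq, dhcq_parameters()), ind, regimen_a())
  expect_length(m2$states, 28L + 17L)
  expect_equal(nrow(m1$events), 10L)
  expect_equal(m1$events$amount_mg[1], salt_to_base_amount(600, hcq))
})

test_that("null metabolite coupling leaves all metabolite states at zero", {
  ind <- typical_adult()
  hcq <- hcq_parameters()
  hcq$metabolite_links <- lapply(hcq$metabolite_links, function(l) {
    l$formation_fraction <- 0; l
  })
  m <- build_pbpk_model(list(hcq, dhcq_parameters()), ind, regimen_a())
  s <- simulate(m, t_end_h = 120)
  mcols <- grep("^m_", m$states, value = TRUE)
  expect_true(all(abs(s$amounts[, mcols]) < 1e-12))
})

test_that("transit-chain absorption has the right limits", {
  expect_equal(fraction_absorbed(hcq_parameters(papp_caco2 = 0)), 0)
  big <- fraction_absorbed(hcq_parameters(papp_caco2 = 1e-3))
  expect_gt(big, 0.999)
  fa <- fraction_absorbed(hcq_parameters())
  expect_gt(fa, 0.6); expect_lte(fa, 1)
  # simulated unabsorbed fraction matches the closed form
  ind <- typical_adult()
  s <- simulate(build_pbpk_model(list(hcq_parameters()), ind,
                                 regimen(0, 600)), t_end_h = 400)
  dose <- salt_to_base_amount(600, hcq_parameters())
  sink_frac <- unname(s$amounts[nrow(s$amounts), "p_sink"]) / dose
  expect_equal(sink_frac, 1 - fa, tolerance = 1e-3)
})

test_that("a closed system conserves mass and dosing is linear", {
  ind <- typical_adult()
  inert <- renal_only_drug(cl = 1e-9)
  s <- simulate(build_pbpk_model(list(inert), ind, regimen(0, 400, route = "iv")),
                t_end_h = 48)
  tot <- rowSums(s$amounts[-1, grep("^p_", colnames(s$amounts))])
  expect_lt(max(abs(tot / 300 - 1)), 1e-8)
  # dose linearity: doubling every dose doubles every concentration
  hcq <- hcq_parameters()
  s1 <- simulate(build_pbpk_model(list(hcq), ind, regimen_a()), t_end_h = 240)
  reg2 <- regimen(seq(0, 108, 12), 2 * c(600, 600, rep(200, 8)))
  s2 <- simulate(build_pbpk_model(list(hcq), ind, reg2), t_end_h = 240)
  c1 <- observable(s1, matrix = "plasma")$conc
  c2 <- observable(s2, matrix = "plasma")$conc
  expect_equal(c2[-1], 2 * c1[-1], tolerance = 1e-9)
})

test_that("default simulations satisfy the mass-balance invariant", {
  ind <- typical_adult()
  drugs <- list(hcq_parameters(), dhcq_parameters())
  s <- simulate(build_pbpk_model(drugs, ind, regimen_a()), t_end_h = 240)
  expect_lt(mass_balance(s), 1e-6)
  sl <- simulate(build_pbpk_model(drugs, ind, regimen_a()), t_end_h = 240,
                 method = "lsoda")
  expect_lt(mass_balance(sl), 1e-6)
  # zero-dose: nothing anywhere (single distant dose, observed before it)
  s0 <- simulate(build_pbpk_model(list(hcq_parameters()), ind,
                                  regimen(300, 600)), t_end_h = 301)
  expect_true(all(s0$amounts[s0$time_h < 300, ] == 0))
})

test_that("the two integration paths agree and converge in tolerance", {
  ind <- typical_adult()
  m <- build_pbpk_model(list(hcq_parameters()), ind, regimen_a())
  se <- simulate(m, t_end_h = 120)
  sl <- simulate(m, t_end_h = 120, method = "lsoda")
  ce <- observable(se, matrix = "plasma")$conc
  cl_ <- observable(sl, matrix = "plasma")$conc
  expect_lt(max(abs(cl_[-1] - ce[-1]) / max(ce)), 1e-4)
  cm_tight <- pk_metrics(observable(
    simulate(m, t_end_h = 120, method = "lsoda", rtol = 1e-8), matrix = "plasma"),
    120)$cmax
  cm_loose <- pk_metrics(observable(
    simulate(m, t_end_h = 120, method = "lsoda", rtol = 1e-6), matrix = "plasma"),
    120)$cmax
  expect_lt(abs(cm_loose / cm_tight - 1), 0.001)
})

test_that("steady-state accumulation equals single-dose superposition", {
  ind <- typical_adult()
  hcq <- hcq_parameters()
  reg_bid <- regimen(seq(0, 228, by = 12), 200)
  s_bid <- simulate(build_pbpk_model(list(hcq), ind, reg_bid), t_end_h = 240)
  s_one <- simulate(build_pbpk_model(list(hcq), ind, regimen(0, 200)),
                    t_end_h = 240)
  grid <- s_one$time_h
  single <- observable(s_one, matrix = "plasma")$conc
  super <- numeric(length(grid))
  for (t0 in seq(0, 228, by = 12)) {
    shift <- stats::approx(grid + t0, single, xout = grid, yleft = 0,
                           rule = 2)$y
    super <- super + shift
  }
  bid <- observable(s_bid, matrix = "plasma")$conc
  at_ss <- grid >= 200 & grid <= 239
  expect_lt(max(abs(bid[at_ss] / super[at_ss] - 1)), 0.005)
})

test_that("venous-plasma AUC matches the one-compartment analytic limit", {
  ind <- typical_adult()
  d <- renal_only_drug(cl = 10)   # low renal extraction
  s <- simulate(build_pbpk_model(list(d), ind, regimen(0, 400)),
                t_end_h = 2000, dt_h = 1)
  pl <- observable(s, matrix = "plasma")
  tail_auc <- pl$conc[nrow(pl)] * 100   # bounded remainder, conc ~ 0
  auc <- pk_metrics(pl, 2000)$auc
  dose_base <- salt_to_base_amount(400, d)
  fa <- fraction_absorbed(d)
  expect_lt(abs((auc + tail_auc) / (dose_base * fa / 10) - 1), 0.005)
})

test_that("lung two-pool steady state matches its closed form", {
  ind <- typical_adult()
  # near-inert analyte: the closed system relaxes to true equilibrium
  hcq <- hcq_parameters(reference_plasma_clearance = 1e-6)
  m <- build_pbpk_model(list(hcq), ind, regimen(0, 600, route = "iv"))
  s <- simulate(m, t_end_h = 4000, dt_h = 4)
  am <- s$amounts[nrow(s$amounts), ]
  cu_ec <- am[["p_lungEC"]] / m$lung$v_ec * hcq$fu_plasma
  c_ic <- am[["p_lungIC"]] / m$lung$v_ic
  closed <- m$lung$trap * (m$lung$ps + m$lung$clint_T) / m$lung$ps
  expect_lt(abs(c_ic / cu_ec / closed - 1), 0.005)
  # passive equilibrium: CLint_T = 0, trapping = 1 gives a unit ratio
  passive <- hcq_parameters(reference_plasma_clearance = 1e-6,
                            lung_uptake_clint_T = 0, lung_trapping = 1)
  mp <- build_pbpk_model(list(passive), ind, regimen(0, 600, route = "iv"))
  sp <- simulate(mp, t_end_h = 4000, dt_h = 4)
  amp <- sp$amounts[nrow(sp$amounts), ]
  ratio <- (amp[["p_lungIC"]] / mp$lung$v_ic) /
    (amp[["p_lungEC"]] / mp$lung$v_ec * passive$fu_plasma)
  expect_equal(unname(ratio), 1, tolerance = 0.005)
  # doubling the uptake clearance strictly increases lung Kp
  k1 <- lung_kp(simulate(build_pbpk_model(
    list(hcq_parameters(lung_uptake_clint_T = 10)), ind, regimen_a()),
    t_end_h = 121), 120)
  k2 <- lung_kp(simulate(build_pbpk_model(
    list(hcq_parameters(lung_uptake_clint_T = 20)), ind, regimen_a()),
    t_end_h = 121), 120)
  expect_gt(k2, k1)
})

test_that("hepatic pathway fluxes split in the configured fm proportions", {
  ind <- typical_adult()
  s <- simulate(build_pbpk_model(list(hcq_parameters()), ind, regimen_a()),
                t_end_h = 240)
  fin <- s$amounts[nrow(s$amounts), ]
  fluxes <- fin[paste0("p_elim_", c("CYP2C8", "CYP2D6", "CYP3A4"))]
  expect_equal(unname(fluxes / sum(fluxes)),
               c(0.373, 0.193, 0.167) / 0.733, tolerance = 1e-8)
  # abundance scalars scale all fluxes proportionally
  ind2 <- apply_hepatic_impairment(ind, "CP-C")
  s2 <- simulate(build_pbpk_model(list(hcq_parameters()), ind2, regimen_a()),
                 t_end_h = 240)
  f2 <- s2$amounts[nrow(s2$amounts),
                   paste0("p_elim_", c("CYP2C8", "CYP2D6", "CYP3A4"))]
  expect_equal(unname(f2 / sum(f2)), c(0.373, 0.193, 0.167) / 0.733,
               tolerance = 1e-8)
})

test_that("the well-stirred construction reproduces the hepatic target", {
  ind <- typical_adult()
  m <- build_pbpk_model(list(hcq_parameters()), ind, regimen_a())
  q_li <- sum(ind$organ_blood_flows[c("liver", "gut", "spleen")])
  clh_target <- 0.733 * 69 / hcq_parameters()$blood_plasma_ratio
  expect_equal(unname(well_stirred_clearance(m$info$clu_int_total, q_li,
                                             m$info$fu_blood)),
               clh_target, tolerance = 1e-6)
})

test_that("simulation export is a parseable tidy table with metadata", {
  ind <- typical_adult()
  s <- simulate(build_pbpk_model(list(hcq_parameters()), ind, regimen(0, 200)),
                t_end_h = 24)
  path <- tempfile(fileext = ".tsv")
  write_simulation(s, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#")
  expect_setequal(unique(back$matrix), c("plasma", "blood", "lung_tissue"))
  expect_equal(nrow(back), nrow(s$observables))
})
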