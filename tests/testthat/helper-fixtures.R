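# Shared fixtures: typical subjects and small drug sets, built in code.

typical_adult <- function() {
  sample_individual(population_spec(variability = FALSE), 1L)
}

# molecular weights recomputed from atomic composition as an independent
# oracle for the salt conversion (C18H26ClN3O and its sulfate)
atomic_mw <- function(counts) {
  w <- c(C = 12.011, H = 1.008, Cl = 35.453, N = 14.007, O = 15.999, S = 32.06)
  sum(w[names(counts)] * counts)
}
mw_hcq_base <- atomic_mw(c(C = 18, H = 26, Cl = 1, N = 3, O = 1))
mw_hcq_salt <- mw_hcq_base + atomic_mw(c(H = 2, S = 1, O = 4))

# minimal renal-only test analyte (low renal extraction so the venous-sampled
# AUC matches the one-compartment identity closely)
renal_only_drug <- function(cl = 10) {
  drug_parameters("X", molecular_weight_base = 300,
                  molecular_weight_salt = 400, pKa_values = 9, logP = 2,
                  fu_plasma = 1, blood_plasma_ratio = 7.2,
                  papp_caco2 = 3.68e-6, fm_map = c(renal = 1),
                  reference_plasma_clearance = cl)
}

plasma_auc <- function(sim, t_end) {
  pk_metrics(observable(sim, matrix = "plasma"), t_end)$auc
}
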