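# Desethylhydroxychloroquine (DHCQ) analyte parameters.
# DHCQ is never dosed; it is formed hepatically from HCQ via CYP2C8/2D6/3A4.
# Physicochemistry is an in-silico-informed default; renal clearance from
# published data; the hepatic component is the packaged fit result (see
# fit_dhcq_hepatic_clint).  All values are config stand-ins, not printed
# constants.
name: DHCQ
molecular_weight_base: 307.82      # C16H22ClN3O (N-desethyl HCQ)
pKa_values: [9.4, 8.1]
logP: 3.0
fu_plasma: 0.55
blood_plasma_ratio: 7.0
papp_caco2: 0.0                    # not orally dosed in this model
fm_map:
  hepatic: 0.75
  renal: 0.25
reference_plasma_clearance: 45.0   # L/h plasma
kp_scalar: 25.0
metabolite_links: []
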