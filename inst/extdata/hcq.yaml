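# Hydroxychloroquine (HCQ) analyte parameters.
# Units: molecular weights g/mol; permeability cm/s; clearance L/h (plasma).
# fm_map fractions are the measured pathway contributions; fu_plasma,
# blood_plasma_ratio, reference_plasma_clearance and kp_scalar are
# literature-informed defaults (flagged: not printed in the primary source).
name: HCQ
molecular_weight_base: 335.87      # C18H26ClN3O
molecular_weight_salt: 433.95      # C18H26ClN3O . H2SO4 (sulfate)
pKa_values: [9.67, 8.27]           # diprotic base
logP: 3.58
fu_plasma: 0.50                    # literature stand-in
blood_plasma_ratio: 7.2            # red-cell partitioning; literature stand-in
papp_caco2: 3.68e-6                # measured Caco-2 Papp, cm/s
fm_map:
  CYP2C8: 0.373
  CYP2D6: 0.193
  CYP3A4: 0.167
  renal: 0.267
reference_plasma_clearance: 69.0   # L/h plasma (~9.6 L/h blood x B/P)
lung_uptake_clint_T: 10.223        # L/h; packaged day-6 trough Kp=200 calibration
lung_trapping: 200.0               # intracellular binding/trapping capacity
kp_scalar: 35.0                    # uniform Kp scalar (Vss calibration)
metabolite_links:
  - enzyme: CYP2C8
    formation_fraction: 1.0
    product: DHCQ
  - enzyme: CYP2D6
    formation_fraction: 1.0
    product: DHCQ
  - enzyme: CYP3A4
    formation_fraction: 1.0
    product: DHCQ
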