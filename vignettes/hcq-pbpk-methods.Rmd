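---
title: "Model and methods: whole-body PBPK for hydroxychloroquine and its metabolite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: whole-body PBPK for hydroxychloroquine and its metabolite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
structural model and its assumptions, the parameters that matter and their
defaults, what the virtual-population generator does and does not emulate,
the numerical choices, and the design decisions taken where the design was
genuinely open.

## Structural model

Each virtual subject is simulated with one linear ODE system in drug
amounts (mg base equivalents, time in hours, concentrations in mg/L).

**Absorption.** Oral doses of hydroxychloroquine sulfate are converted to
base equivalents (salt factor `335.87 / 433.95 = 0.774`) and enter the
stomach, which empties first-order (half-life 0.25 h) into a chain of seven
small-intestinal transit segments (mean transit 3.32 h).  Each segment
absorbs into the portal circulation with `ka = 2 Peff / r` (segment radius
1.25 cm); drug leaving the last segment is unabsorbed and accumulates in a
sink.  `Peff` comes from the measured Caco-2 permeability through a
log-log correlation.  This transit chain is a deliberately spare stand-in
for a full segmented dissolution-absorption model: the drug is an
immediate-release tablet of a soluble salt, so dissolution is not rate
limiting and no gut-wall metabolism is claimed; the contractual quantities
are the permeability-driven absorption rate and the fraction absorbed
(`fa ~ 0.85` at the measured permeability).

**Distribution.** All organs except the lung are perfusion limited.
Tissue:plasma partition coefficients are predicted from tissue composition
for a diprotic base with ion trapping:

$$Kp = fu_p\left(f_w \frac{I(\mathrm{pH}_t)}{I(\mathrm{pH}_p)} +
       f_l \frac{10^{\log P}}{I(\mathrm{pH}_p)}\right) \times s$$

where $I$ is the total:neutral ionization factor, $f_w$/$f_l$ are tissue
water and neutral-lipid fractions, and $s$ is a single uniform scalar
(default 35 for HCQ) calibrated once so the steady-state distribution
volume is of the literature order for this extremely tissue-avid drug.
Only the scalar, not the per-tissue mechanism, is tuned.

**Lung.** The lung is the sole permeability-limited tissue: an
extracellular pool perfused by the whole cardiac output exchanges with an
intracellular pool by passive permeability `PS` (Calu-3-scaled
permeability x an exchange area of 7e5 cm^2 at 70 kg, scaled with lung
size) plus an apparent active-uptake clearance `CLint_T`; intracellular
drug is held by a binding/trapping capacity scalar (default 200) that lumps
lysosomal sequestration and binding, because the mechanism (lysosomal vs
binding) and the true exchange area are not separately identifiable — any
residual misfit is absorbed by `CLint_T` during calibration.  The
steady-state intracellular:unbound-extracellular ratio has the closed form
`trapping x (PS + CLint_T)/PS`, which the test suite verifies against long
simulations.  `calibrate_lung_uptake()` root-finds `CLint_T` so the
lung:plasma ratio at the day-6 pre-dose trough (120 h) under Regimen A is
200; the packaged default (10.22 L/h) is that calibration result, and it is
held fixed across adult populations.  Pediatric lung exposure is not
predicted: the permeability-limited parameters are not assumed to scale to
children.

**Elimination.** Total reference plasma clearance (default 69 L/h,
consistent with a whole-blood clearance near 9.6 L/h at a blood:plasma
ratio of 7.2) is split by the pathway-fraction map — CYP2C8 37.3%, CYP2D6
19.3%, CYP3A4 16.7%, renal 26.7% — and the hepatic part is realized by
inverting the well-stirred liver model to an unbound intrinsic clearance,
apportioned across the three CYPs in their fm proportions.  The fractions,
not the absolute intrinsic clearances, are the contract: per-subject
scaling multiplies each CYP's intrinsic clearance by its abundance scalar
and the liver-mass ratio, and renal clearance scales as GFR/120.  Renal
elimination filters arterial plasma, which makes the one-compartment
analytic limit (`AUC = dose x fa / CL_R`) hold exactly for a renal-only
analyte.  Metabolite formation feeds each CYP flux (formation fraction
default 1.0 per pathway, exposed in config; the true overall conversion
fraction is unknown) into the metabolite's liver compartment with the
molecular-weight ratio.  The metabolite distributes with its own predicted
partition coefficients and is cleared by a fitted hepatic component plus a
literature renal clearance.

**Interactions.** Perpetrators (gemfibrozil 600 mg BID, quinidine 200 mg
QD, ritonavir 100 mg QD; 12 days, starting two days before the victim's
first dose) follow closed-form one-compartment superposition kinetics.
Competitive inhibition multiplies the affected intrinsic clearance by
`1/(1 + Iu/Ki_u)` instantaneously; mechanism-based inactivation evolves an
active-enzyme fraction per CYP with `dE/dt = kdeg (1 - E) - kinact
Iu/(KI_u + Iu) E` (turnover half-life 36 h).  Gemfibrozil's acyl
glucuronide — the actual CYP2C8 inactivator — is not modelled explicitly;
its inactivation is folded into the parent's MBI terms with
correspondingly weaker apparent constants.  The exposure-ratio ceiling
`1/(1 - fm)` (1.595 for CYP2C8) bounds every dynamic simulation and is
asserted in the tests.

## Virtual populations

The generator samples subjects from transparent physiology tables: organ
volume fractions, flow fractions summing exactly to cardiac output
(`CO = 336 (W/70)^{0.75}` L/h), GFR 120 mL/min, and unit CYP abundance
scalars for the healthy 20-50-year adult (70 kg male / 61 kg female,
mixed 1:1 unless specified).  Inter-individual variability is log-normal:
CV 30% on enzyme abundances and GFR, 20% on volumes and flows, 15% on body
weight; one integer seed drives a per-subject substream, and flow jitter is
renormalized so the flow-balance invariant holds exactly.

Special populations are deterministic transforms applied after sampling:

* **Geriatric** — past age 40: GFR -0.9 mL/min/yr, cardiac output
  -0.35%/yr, liver volume -0.30%/yr, CYP abundance -0.35%/yr, flows
  renormalized.
* **Cirrhosis** — Child-Pugh factor table (CYP abundance 0.72/0.56/0.43,
  liver mass 0.95/0.88/0.80, hepatic flow 0.90/0.75/0.60, albumin
  0.90/0.75/0.60 for grades A/B/C).  Hypoalbuminemia raises the unbound
  fraction as `fu' = fu/(alb + fu (1 - alb))`, which feeds both clearance
  and partitioning.
* **Renal impairment** — band-typical GFR (45, 20 mL/min); renal drug
  clearance scales proportionally; an optional uremia factor on hepatic
  CYPs is off by default.
* **Pregnancy** — linear-in-week changes anchored at term: blood volume
  +42%, weight +12 kg, GFR +60%, CYP3A4 x2.1-fold rise, CYP2D6 x2.5,
  CYP2C8 x1.3, albumin -27%; week 0 is the identity and weeks 13/25/37 are
  the trimester anchors.
* **Pediatric** — growth and body-composition tables (weight, adipose,
  muscle, brain, liver, kidney fractions by age), allometric flows and
  GFR, sigmoidal CYP ontogeny (CYP3A4 from 11% at birth, age-50 0.64 y;
  CYP2D6 from 3.6%, age-50 0.10 y; CYP2C8 from 30%, age-50 0.25 y), a
  postmenstrual-age Hill function for renal maturation, and an
  age-indexed tissue-binding fraction applied to all organ partition
  coefficients (0.25 at two weeks rising to 1 by adulthood), reflecting
  the lower tissue binding of a lipophilic base in infant tissues.

A proprietary virtual-population database cannot be reproduced, so these
factor tables are declared calibration surfaces: where literature ranges
permitted, the geriatric decline rates, Child-Pugh factors, pregnancy term
anchors, the gemfibrozil MBI constants and the pediatric tissue-binding
column were each tuned once — against the published baseline-relative
exposure-ratio tables and the weight-based pediatric dose table — and then
frozen.  They are stated in output metadata and never adjusted at run
time.  Consequently, agreement with those tables demonstrates internal
consistency of the re-implementation under its declared calibration, not
blind prediction of the original study; the clearance fractions, the
Calu-3 equation, the lung calibration target and all property-based
invariants are reproduced without any table-level tuning.

What the generator deliberately does not emulate: disease-progression or
infection pathophysiology, ethnicity beyond body-weight tables, organ-level
covariance structure between sampled quantities (deviates are independent
apart from the shared size factor), and pediatric lung exposure.  Passing
tests therefore show correct mechanistic plumbing and calibrated
population scaling, not validated prediction for real patient cohorts.

## Trial simulation and metrics

The study design is 10 trials x 10 subjects.  Exposure metrics are Cmax
(grid maximum) and AUC by linear trapezoid over 240 h (ten days) from the
first victim dose — the table convention — even though dosing spans five
days.  "Mean ratio" is read as the ratio of arithmetic means of individual
parameters, matching the tables' labelling; geometric-mean ratios are
carried alongside for transparency.  Lung tissue concentration is total
(extracellular + intracellular) amount over total lung tissue volume,
excluding vascular blood.  Weight-based pediatric dosing exploits dose
linearity: one probe simulation per band fixes the per-kg loading dose
whose typical-individual first-dose Cmax (0-12 h) matches the 600 mg/70 kg
adult reference, verified by re-simulation to within 1%; maintenance is
one third of loading, per the regimen convention.

## Numerics

Between dose events the system is linear and time invariant, so the
default integrator computes one matrix exponential per distinct grid step
(0.25 h output grid) and propagates states exactly; mass balance on every
shipped scenario holds to better than 1e-8.  Interaction scenarios make
the hepatic coefficients time varying, so they integrate with `lsoda`
(rtol 1e-8, atol 1e-10 mg) with an analytic Jacobian; the two paths agree
to < 0.01% on identical problems.  Dose events are discontinuities: grid
values at an event time are pre-dose, which is also the trough convention.
Doses scheduled beyond the simulated horizon are simply not administered.
Root finding (lung calibration) brackets upward from zero uptake and
verifies monotonicity; the fit of the metabolite's hepatic clearance is a
scalar least-squares on log concentrations with a profile-likelihood-style
interval from an objective grid, flagged non-identifiable when the
objective is flat or all points are censored.

Problem sizes used in the shipped tests — 10x10 trials for ratio checks,
40 subjects for interval-coverage checks, 6-8 seeds for
parameter-recovery checks, and a 240 h sampling window for the metabolite
fit (the washout phase is what identifies its clearance) — were chosen as
the smallest designs at which the respective statistical checks are
stable.

## Known limitations

* Absolute concentrations inherit literature stand-in values (fu,
  blood:plasma ratio, reference clearance); the printed pathway fractions
  and calibration targets, not absolute exposure, are the reproducible
  contract.
* The blood:plasma ratio is a fixed scalar; no explicit red-cell kinetics.
* Linear (non-saturable) enzyme kinetics are assumed at simulated doses.
* The metabolite's hepatic pathway is not enzyme resolved, so perpetrators
  do not alter metabolite elimination (only its formation).
* The pediatric tissue-binding maturation column is a calibrated
  surrogate; it should be replaced if age-resolved tissue composition or
  binding data become available.
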