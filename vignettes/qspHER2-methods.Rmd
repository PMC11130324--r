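---
title: "qspHER2: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qspHER2: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qspHER2)
```

## What the model is

`qspHER2` is a mechanistic quantitative-systems-pharmacology (QSP) model of
HER2-positive breast cancer. One ODE system (58 species, 79 reactions,
compiled C right-hand side driven by `deSolve`) couples four layers:

1. **ErbB receptor signaling.** EGFR, HER2, HER3 and HER4 with their
   ligands (EGF for EGFR; NRG1 for HER3/HER4). Ligand binding, five
   dimerization routes — EGF:EGFR–HER2, HER2–HER2, the spontaneous
   (ligand-independent) HER2–HER3, NRG1:HER3–HER2 and NRG1:HER4–HER2 —
   transphosphorylation/dephosphorylation, receptor synthesis and
   degradation, ligand-induced internalization, and a FOXO-type negative
   feedback in which low pAKT de-represses HER3 synthesis. HER3 is
   kinase-dead, so HER3 homodimers are absent and HER3 phosphorylation
   requires an active partner kinase.
2. **Downstream cascades.** A weighted phospho-dimer pool drives PI3K→AKT
   and a lumped two-tier Raf→ERK cascade (MEK folded into the Raf→ERK
   step) through Hill transfer functions. HER3/HER4-containing dimers are
   weighted strongly (`w_her3 = 30` for NRG1-bound dimers,
   `w_her3_basal = 6` for the spontaneous HER2–HER3 dimer, `w22 = 0.2`
   per HER2 monomer in homodimers): the HER2–HER3 unit is the dominant
   oncogenic driver, and ligand-bound dimers signal more strongly than
   spontaneous ones.
3. **Drug pharmacology.** Lapatinib (reversible, EGFR+HER2), pyrotinib
   (covalent, EGFR+HER2+HER4) — both block transphosphorylation of their
   occupied targets and enhance receptor degradation; T-DM1 and T-DXd bind
   HER2, internalize (`kint_ADC`), undergo lysosomal processing
   (`kdeg_ADC_2`, competing with recycling/expulsion `krec_ADC`) and
   release DAR payload molecules; DM1 is effluxed irreversibly
   (`kout_PL`, no re-entry), DXd permeates the membrane in both directions
   (`kper_PL`). Capecitabine acts through its metabolite 5-FU. Payload and
   5-FU feed death Hill terms; TKIs act indirectly by removing the
   pro-growth signal.
4. **Tumor growth.** `dN/dt = N [umax Hill(S; km13, n13)(1 − V/Vmax) −
   dmax (1 + Σ w14 Hill(payload) + w15 Hill(5-FU))]`, with the growth
   signal `S` a normalized weighted sum of Hill-transformed pERK and pAKT
   plus a small basal survival weight. In vitro the logistic factor is 1;
   in vivo `Vmax = 2000` mm³.

Mouse PK uses standard one/two-compartment models (oral first-order
absorption for the TKIs and capecitabine, IV bolus for the ADCs), an ADC
deconjugation + payload-catabolite disposition branch, and the sequential
capecitabine → 5'DFCR → 5'DFUR → 5-FU cascade. Tumor exposure is
`Kp ×` plasma concentration for TKIs and 5-FU, and first-order entry from
the central compartment (`k_tu`, no back-flux) for the ADCs.

## How the TKIs are represented

Rather than enumerating drug-bound species for every receptor form (which
would blow the species budget), TKI action is an occupancy: lapatinib
occupancy is the instantaneous equilibrium `C/(Kd + C)`; pyrotinib
occupancy is a covalent state with inactivation rate `kinact × C` and slow
recovery. Each dimer's transphosphorylation flux is scaled by the
probability that at least one competent kinase in the pair is unoccupied,
and occupied receptors degrade faster (`degfold`). Ligand-bound dimers
protect against lapatinib (effective Kd × `prot_lap`, default 100) — the
active-conformation protection reported for lapatinib — but not against
covalent pyrotinib. This single assumption reproduces, with one parameter
set: complete pathway shutdown by 100 nM lapatinib alone, persistent
signaling at 1000 nM lapatinib when NRG1 is present, and pyrotinib's
retained potency under NRG1.

## Calibration philosophy

No kinetic parameter values are printed in the source material for this
model class; every default in `paramTemplate()` is the package's own
calibration, chosen once so that the model reproduces the qualitative and
quantitative behaviors that define the system: constitutive
HER2-driven signaling at steady state, receptor copy numbers per cell line
(SKBR3: 150,000 / 1,500,000 / 40,000 / 2,000 for EGFR/HER2/HER3/HER4;
IHC 3+/2+/1+ = 1.5e6/0.5e6/0.1e6 HER2), TKI dose–response and receptor
up/downregulation (pyrotinib lowers total HER2; lapatinib and pyrotinib
raise total HER3 through FOXO feedback; NRG1 lowers total HER3 through
ligand-induced internalization), single-agent viability curves with
realistic IC50 ranges, xenograft growth from 80 mm³ toward the 2000 mm³
cap, moderate single-agent TGI for capecitabine and the ADCs, near-complete
TGI for the TKI+ADC combinations, and the PRCC driver rankings. The
in vitro→in vivo translation keeps all signaling/drug-processing parameters
bit-identical and re-estimates only growth/death parameters (`umax`,
`dmax`, `w14*`, `w15` and their Hill constants); in vivo values are smaller
than in vitro ones, as expected for the slower microenvironment-limited
growth of xenografts.

Parameters worth knowing (units; defaults):

* `umax`, `dmax` (1/day; 0.6/0.15 in vitro, 0.25/0.05 in vivo) — maximum
  proliferation and basal death rates.
* `km13`, `n13` (0.5, 2) — Hill constants of the growth signal; `km13` is
  re-estimated per cell line (`ihcPreset()` uses 0.5/0.10/0.07 for
  3+/2+/1+) because lower-HER2 lines proliferate at a lower signaling tone.
* `Kd_lap` (3 nM), `prot_lap` (100), `kinact_pyr` (0.06 /nM/h) — TKI
  binding; `Kp_lap = 0.003` reflects the small free fraction of the highly
  protein-bound lapatinib, which is what leaves in vivo suppression strong
  but not absolute.
* `kint_ADC` (0.1/h), `kdeg_ADC_2` (0.02/h), `krec_ADC` (0.04/h),
  `DAR` (3.5 T-DM1 / 8 T-DXd), `kout_PL` (1/h), `kper_PL` (2/h) — ADC
  processing. Lysosomal processing competes with recycling, so the
  processing rate genuinely controls how much payload is delivered.
* `w14_*`, `km14_*` (max fold-stimulation of death and payload
  half-saturation); `w15`, `km10` (5-FU death stimulus, `km10 = 5` µM,
  `n10 = 1`).

## The synthetic-data generator

`fixtureSpec()`/`generateFixture()` emulate every modality the calibration
pipeline consumes: densitometry-style phospho time courses and
dose–responses (n = 3 replicates, multiplicative lognormal noise —
densitometry is ratio-scale — normalized to series maximum or control),
viability curves (normalized to untreated wells of the same duration),
plasma concentration–time samples (proportional error), and xenograft
volume series measured every 3 days from an 80 mm³ start (Gaussian 10% cv).
Fixtures carry their generating truth, so calibration, bootstrap and
recovery machinery are testable end to end. What the generator does *not*
emulate: between-lab batch effects, non-Gaussian outliers, censoring of
large tumors, or inter-animal growth-rate heterogeneity — so green recovery
tests demonstrate correctness of the estimation machinery on
well-specified data, not robustness to real-world artifacts.

## Numerical choices

* **Integration.** `lsoda` (stiff-capable) with `atol = rtol = 1e-8` for
  cell-level work, `1e-6` for xenograft studies, `1e-10` for PK oracle
  comparisons. Small negative excursions below solver tolerance are
  clamped to zero; non-negativity is not enforced by reflection.
* **Steady state.** Drug- and ligand-free integration in 500 h chunks until
  the maximum relative derivative over signaling species drops below
  1e-8/h (the tumor cell count is excluded — it grows); a convergence
  error is raised beyond 10,000 h.
* **Compiled/interpreted equivalence.** The symbolic `ReactionNetwork`
  (rate closures + stoichiometry matrix) is the reference form; the test
  suite requires the compiled derivatives to match a naive per-reaction
  interpretation to 1e-10 at random states.
* **Pattern search.** Derivative-free mesh/poll in log-parameter space,
  starting mesh 25% of the box, contraction ×0.5, convergence at 1e-6 of
  the box width, with an accelerating pattern move along the last
  successful direction. The mesh is *not* re-expanded after successful
  sweeps (compass variant): with re-expansion the search oscillates across
  the narrow correlated valleys typical of ODE least-squares objectives
  and stalls far from the optimum, while the compass variant recovers
  noiseless ground truth to <0.1%. Multi-start (seeded Latin hypercube)
  guards against local minima.
* **Staged translation fits.** Joint estimation of
  {`umax`, `dmax`, `w14`, `w15`} from a single study is ill-conditioned
  (`dmax` trades almost exactly against the death stimuli over one cycle).
  `xenograftRecovery()` therefore fits in stages — growth parameters from
  the 60-day control curve, whose logistic plateau identifies `umax` and
  `dmax` separately, then each death stimulus from its own treatment
  arm — the same order used for the in vivo translation. Bootstrap refits
  resample datapoint means under the 10%-of-mean dispersion convention.
* **Sensitivity analyses.** PRCC follows the rank-regression methodology
  (rank-transform, partial out all other inputs, correlate residuals,
  t-test p-values); significance requires |PRCC| > 0.05 *and* Bonferroni
  p < 0.01. Sobol total-order indices use Saltelli A/B/AB designs with the
  Jansen estimator and bootstrap CIs. Tumor volume at day 20 is the
  output, parameters vary over [0.5×, 2×] baseline. The no-stimulus and
  drug conditions are run at n = 500 (scaled down from the full 5000-run
  design; the rankings are unambiguous at that size), while the NRG1
  overexpression condition is run at the full n = 5000: the
  NRG1–HER3 binding rate `k8on` has a consistent but small positive
  partial effect (PRCC ≈ 0.1), which clears the strict significance rule
  only at the full design. The NRG1 overexpression condition uses a
  1 ng/mL autocrine-level bath — at tens of ng/mL every synthesized HER3
  is ligand-bound regardless of the binding rate, so `k8on` can only
  retain leverage where binding is rate-limiting.
* **Problem sizes.** Default test-suite problem sizes: 500-sample PRCC
  (5000 for the NRG1 condition), 50 bootstrap resamples, 60-day recovery
  fixtures, 63-day three-cycle combination studies. These are the
  package's chosen desk-scale defaults; all are arguments.

## Design choices where the design was genuinely open

* **TGI formula.** Baseline-corrected
  `100 (1 − (V_t − V0)/(V_c − V0))`, clipped at 100, so regression to (or
  below) baseline scores 100; the ratio-of-volumes form is available via
  `baselineCorrected = FALSE`.
* **Bliss effect scale in vivo.** Fractional TGI/100 clipped to [0, 1];
  cells are synergistic when the model effect exceeds the Bliss
  expectation by more than the additive tolerance (±0.01).
* **ADC tumor entry.** First-order in central amount (a literal zero-order
  "constant rate" would be dose-independent).
* **Ligand unit conversion.** EGF 6.2 kDa, NRG1 active domain 7.5 kDa for
  ng/mL → nM.
* **Pyrotinib-induced degradation** applies equally to EGFR, HER2 and
  HER4.
* **BTK-C node.** Available as an NRG1-gated additive survival weight
  (`w_btk`), default off.
* **Acquired resistance.** `simulateAcquiredResistance()` implements an
  optional per-cycle exposure-driven potency decay; off in all standard
  protocols.
* **Phenotype multipliers.** The resistance presets
  (`kout_PL ×50`; `umax ×1.5/×2` with `kon_Raf ×8`; `kon_PI3K ×0.2`;
  NRG1 bath 50 ng/mL; `k8on → 0`) are calibrated so the four response
  patterns and the rescue experiments reproduce qualitatively; no
  published multiplier values exist. The MAPK-lesion multiplier needs to
  be as large as ×8 because daily lapatinib exposure peaks suppress the
  suppressed-drive Raf activation multiplicatively.

## Worked example

```{r example, eval = FALSE}
net <- buildNetwork(cellLineConfig("SKBR3"))
ss <- initializeSteadyState(net)

## pathway shutdown and NRG1 rescue
tr <- simulateTimecourse(net, ss, stimulus(lapatinib = 100), 24)
readout(tr, "pERK")[c(1, 5)]        # baseline vs 1 h

## three-cycle combination study
vivo <- buildNetwork(
  cellLineConfig("SKBR3", growth = growthDeathParams(inVivo = TRUE)),
  inVitro = FALSE)
ctl <- runXenograft(vivo, regimen(), 63)
combo <- runXenograft(vivo, regimen(regimenArm("pyrotinib", 6, "qd"),
                                    regimenArm("tdm1", 6, "q3w")), 63)
computeTGI(combo, ctl, 62)

## sensitivity analysis
sens <- tumorSensitivity("TDM1", n = 500, seed = 1)
head(sens$prcc)
```

## Known limitations

* All kinetic defaults are calibrated to reproduce described behaviors,
  not fitted to raw experimental readouts; absolute intracellular scales
  (molecules/cell of phospho-species, payload) matter only through
  ratios and Hill constants.
* PK parameters are provisional shape-level calibrations (mouse oral TKI
  half-lives of hours, biexponential antibody decline over weeks, a fast
  sequential capecitabine cascade), not fits to digitized concentration
  data.
* Drug–drug PK interactions, toxicity, immune biology, ER cross-talk,
  STAT/PLC-γ branches, spatial tumor structure and subclonal evolution are
  out of scope.
* The k8on sensitivity under NRG1 overexpression depends on the NRG1 tone:
  at saturating ligand levels the binding rate is immaterial by
  construction, in the model as in the biology.
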