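---
title: "A multi-compartmental model of CNS drug distribution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-compartmental model of CNS drug distribution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnspk)
```

## The problem

Drug effect in the central nervous system is driven by the unbound
concentration at the target site — usually the brain extracellular fluid
(ECF) — not by the plasma concentration that clinical studies measure. The
blood-brain barrier (BBB), the fluid spaces of the brain (ECF, intracellular
fluid, and the cerebrospinal fluid ventricles and cisterns in series) and
active transporters all separate the two. `cnspk` implements a
physiologically structured compartmental model of this system, the
estimation machinery to fit it to rat microdialysis data, and the
translation workflow that predicts human brain and CSF concentration-time
profiles from a rat fit.

## Model structure

The core model is a set of mass-balance ODEs over compartments

> plasma (± one or two peripheral compartments) → brain ECF → CSF in the
> lateral ventricle → third+fourth ventricle → cisterna magna →
> subarachnoid space → back to plasma,

with amounts in ng, volumes in mL and flows in mL/min. Three ideas shape it:

* **One dispersion flow.** A single flow `Q_DIFF` (mL/min) carries drug
  from the ECF through the four CSF compartments in series and returns it
  to plasma from the subarachnoid space. It lumps bulk CSF flow and
  turbulence-like mixing into one identifiable parameter.
* **BBB exchange dominates.** Transfer between plasma and ECF is a single
  symmetric clearance `Q_PL_ECF` acting on the unbound plasma
  concentration (`f_p * C_PL`). Exchange across the blood-CSF barrier is
  omitted by default — its surface area is several-fold smaller — and is
  enabled only as an efflux term (`Q_LV_PL`, lateral ventricle to plasma)
  for drugs whose data demand it (methotrexate among the built-in
  presets).
* **System vs drug parameters.** Compartment volumes are species
  properties (`system_parameters()`: rat 0.29/1.44/0.05/0.05/0.017/0.18 mL
  for ECF/ICF/LV/TFV/CM/SAS; human 240/22.5/22.5/7.5/90 mL), fixed and
  never estimated. Clearances, flows and distribution volumes are drug
  properties (`drug_parameters()`), estimated in the rat.

Optional features per drug: peripheral compartments (`per1`, `per2`), brain
ICF exchange (`icf`), BCSFB efflux (`bcsfb_efflux`), enterohepatic
recirculation (`enterohepatic`), and — in humans only — an external
ventricular drain (`evd`) that samples the lateral ventricle with a
one-way flow `Q_LV_EVD` into a drain reservoir `V_EVD`. The full equations
are in `?ode_rhs`; `solve_profile()` integrates them with a compiled
right-hand side (deSolve/lsoda, relative tolerance 1e-10) and treats every
infusion start and stop as an exact event boundary, so no discontinuity
falls inside an integrator step.

Two closed forms anchor the numerics and are enforced in the tests: at
constant-rate steady state a plasma-only model gives `C_ss = rate / CL_PL`,
and the reduced brain model gives
`C_ECF / (f_p C_PL) = Q_PL_ECF / (Q_PL_ECF + Q_DIFF)`
(`steady_state_ecf_ratio()`), with all four CSF compartments equilibrated
to the ECF.

### Enterohepatic recirculation and identifiability

Acetaminophen's preset carries a recirculated `fraction` (93.3%). The
recirculation sub-model is implemented as a net-clearance reduction
`CL_PL (1 - fraction)` — a static approximation without gallbladder lag,
because no rate constants are available for the lag process. Under this
approximation `CL_PL` and `fraction` enter the equations only through
their product, so they are jointly unidentifiable: fits therefore keep
`fraction` fixed and estimate `CL_PL`.

### Covariates

Transporter inhibition (and the morphine dose-group effect) are
categorical: `P = P * (1 + theta * Cov)` (`apply_covariate()`). The
built-in presets carry the coefficients on `Q_PL_ECF` (and for
methotrexate also on `Q_LV_PL`). Continuous concentration-dependent
transport saturation is deliberately not modelled; the morphine
nonlinearity is expressed as a dose-group covariate (the 4 mg/kg group has
its own BBB clearance).

## Preprocessing

Microdialysis measures the unbound concentration in tissue fluid, but the
dialysate understates it by the probe recovery. The package implements the
standard chain: `free_fraction()` (ultrafiltrate / pooled plasma),
`in_vivo_recovery()` (retrodialysis loss `(C_in - C_dial)/C_in`), and
`correct_dialysate()` (division by recovery). `assemble_dataset()` turns an
event-record table (one dosing row per infusion, one row per observation)
into a model-ready dataset: doses mg/kg → ng via body weight, dialysate
rows recovery-corrected, total plasma converted to unbound via `f_p`
(phenytoin 91% bound → `f_p` 0.09; remoxipride 26% → 0.74), below-LLOQ
rows excluded (or LLOQ/2-substituted on request).

## Estimation

Fitting is naive-pooled extended least squares: all animals are treated as
one subject (the experimental designs are highly standardised), and the
objective is

    OFV = sum_i [ (y_i - f_i)^2 / v_i + log v_i ],

with `v_i = sigma_s^2 f_i^2` per observation stream `s` (proportional
error; a mixed model adds `sigma_add^2`). This is -2 log likelihood up to a
constant, so nested models are compared by a chi-square likelihood-ratio
test with the conventional 3.84 threshold at one degree of freedom
(`lrt_compare()`).

Numerical choices that matter:

* Optimisation runs in log-parameter space (coefficients `theta` as
  `log(1 + theta)`), with three jittered starts and BFGS restarts until no
  further progress; a smooth ±6 log-unit trust region around the starting
  values keeps line searches inside a physiologically conceivable range.
* For the proportional model the per-stream `sigma` maximising the
  likelihood has the closed form `mean(res^2 / pred^2)` and is profiled
  out of the objective at every evaluation; `els_objective()` retains the
  explicit-sigma form and serves as the independent oracle in the tests.
* Variances are floored at `(1e-6 * max(y))^2` so predictions approaching
  zero cannot drive `log v` to minus infinity; parameters hitting extreme
  values and streams with data but near-zero predictions are reported as
  diagnostics, never silently clipped.
* Relative standard errors come from the inverse Hessian at the optimum
  (the log-scale standard error is the relative standard error to first
  order), together with the parameter correlation matrix for
  identifiability assessment.
* A caveat worth knowing: with a *fixed* assumed `sigma`, the `log v` term
  rewards lower predictions, shifting the prediction scale by about
  `sigma^2`. With the profiled (estimated) `sigma` the estimator is the
  regular MLE and the effect disappears; the zero-noise recovery tests
  therefore fix a small `sigma`.

Inter-individual variability (IIV) is log-normal, `theta_i = theta *
exp(eta)`, `eta ~ N(0, omega^2)` (`iiv_realize()`). Full nonlinear
mixed-effects estimation (FOCE-like linearisation) is not implemented;
where IIV is needed — plasma-only fits feeding the translation — the
package uses a two-stage approach (`fit_human_plasma()`): a pooled fit
selects the compartment number by LRT and provides starting values, each
subject is refitted, and the subject estimates are pooled in the log
domain (`theta = exp(mean log theta_i)`, `omega = sd(log theta_i)`). Only
the population means feed the translation, which is what the two-stage
estimator targets; its `omega` estimates include estimation noise and
should be read as upper bounds with few subjects.

## Validation

Prediction quality is scored with the symmetric prediction error
`PE = (y - f) / ((y + f)/2)` and `SMAPE = 100 * mean |PE|`, which is
bounded by 200%, symmetric and scale-invariant. (The symmetric denominator
`(y + f)/2` is the defining property of this metric; the package uses it
throughout.) `simulate_prediction_interval()` implements the
simulation-based 95% prediction interval: 200 replicates by default, each
drawing subject parameters from the IIV model and residual noise from the
error model, summarised as empirical 2.5/50/97.5 percentiles per time
point and compartment (linear interpolation between order statistics, so
bands are bit-reproducible given a seed). `external_validation()` runs the
three-step external workflow: re-estimate plasma parameters on the
external plasma data, hold the brain parameters fixed, predict the
brain/CSF observations and report SMAPE per compartment.

## Translation to humans

`build_human_model()` performs the five translation steps: (1) human
plasma parameters from `fit_human_plasma()`; (2) system volumes replaced
by the human values; (3) the drug-specific brain parameters `Q_PL_ECF` and
`Q_DIFF` allometrically scaled,
`P_human = P_rat * (BW_human / BW_rat)^0.75` with 70 kg and 0.25 kg
reference weights (`allometric_scale()`), fixed, and reported at 3
significant figures (full precision is a few parts in 10^3 away; the
rounded value is the reporting convention and is what the fixed parameter
carries); (4) the EVD compartment attached per patient where drain records
exist; (5) prediction with `predict_human_profiles()`. For morphine the
4 mg/kg dose-group BBB clearance (no inhibitor) is the one scaled — the
low-dose estimate is the least affected by the dose-group nonlinearity.
Human brain ICF volume is not part of the translational set; the ICF
feature stays off for human predictions (neither translated drug needs
it).

## The synthetic-data generators

No raw animal or patient data are distributed with the package, so
`default_design()` + `generate_rat_study()` / `generate_human_study()`
realise the published study designs as simulation designs: the printed
dose levels, infusion durations, animal/patient counts, observed
compartments, inhibitor arms, residual-error SDs and (for humans) IIV SDs.
Sampling times are not published; the package realises them as:

* plasma — a geometric grid from 2 min to the window end (serial arterial
  sampling with a front-loaded schedule, as rich rat PK designs use);
* dialysate — contiguous collection bins stamped at the bin midpoint (the
  usual microdialysis convention), with shorter bins over the first third
  of the window and longer bins after.

The early-sample placement is not cosmetic: the brain/CSF equilibration
time constant `V_ECF / (Q_PL_ECF + Q_DIFF)` is a few minutes, and the
magnitudes of `Q_PL_ECF` and `Q_DIFF` (as opposed to their ratio, which
the steady state fixes) are identified almost entirely by samples inside
that transient. Uniform end-stamped grids leave the magnitudes
near-unidentifiable — parameter-recovery simulations then show ridge-like
likelihood surfaces with >100% relative standard errors.

Probe recoveries default to 0.4 (ECF) and 0.5 (CSF), inside the plausible
in-vivo microdialysis range, and are recorded in the design so the
preprocessing correction is exactly invertible in tests. Inhibitor arms
are generated as separate animals. Residual noise follows the
proportional-error model with the published SDs; at the largest published
SDs this model produces occasional negative concentrations, and the
generator keeps them — truncating or censoring them would inflate the
observed stream means (by up to ~90% at SD 1.88) and bias every downstream
fit. Real assay data never contain negative values; this is a property of
the assumed error model at high noise, and it is the price of keeping the
generate → preprocess → fit loop exactly self-consistent.

What the generators do *not* emulate: per-animal sampling irregularities,
LLOQ censoring mechanics beyond a simple threshold, circadian variation,
between-batch assay effects, and pathological BBB changes (the "injured"
tissue of trauma patients). Passing the recovery tests therefore
demonstrates the estimator works under the model's own assumptions at the
published design sizes — not that the model is correct for any real
dataset.

## Problem sizes used in the tests

Unit tests run scaled-down designs (2-4 animals, a handful of samples per
stream). The study-scale checks use the published acetaminophen design (16
animals, 67 plasma + 576 dialysate samples) for the ten-seed
parameter-recovery study, 200-replicate prediction intervals checked
against 1000 freshly simulated observations for coverage, and the 7-patient
human acetaminophen and 2-patient human morphine designs for the
translation loop. These sizes keep the full suite to a few minutes while
matching the printed study dimensions where it matters.

## Known limitations

* Naive pooling ignores between-animal variability in the rat fits, as the
  original estimation strategy does; rat RSEs are conditional on that
  choice.
* The two-stage IIV estimator is not FOCE; `omega` estimates with n < 10
  subjects are noisy and upwardly biased.
* The enterohepatic sub-model is a static net-clearance reduction.
* The EVD drain parameters are synthetic defaults (0.15 mL/min, 10 mL) of
  a plausible clinical magnitude, not patient records.
* Allometric body-weight scaling is one defensible translation rule among
  several (brain weight and endothelial surface area scaling are
  alternatives); the package implements only the body-weight rule.
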