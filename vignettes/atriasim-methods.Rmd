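---
title: "Methods: virtual atrial fibrillation cohorts and in-silico therapy trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual atrial fibrillation cohorts and in-silico therapy trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`atriasim` is a desk-scale pipeline for in-silico trials of persistent
atrial fibrillation (AF) therapy. It builds a cohort of virtual patients
that vary in three clinically motivated dimensions — ionic-current
expression, atrial size, and the presence of low-voltage areas (LVAs) —
simulates re-entrant arrhythmia on synthetic atrial tissue with a
monodomain reaction–diffusion model, applies catheter-ablation lesion sets
and pore-block antiarrhythmic drugs, and tabulates which treatments
terminate the arrhythmia in which patients. A feature-based decision
cascade (`stratify()`) condenses the trial logic into a bedside-style rule
on LVA status, chamber volumes and the effective refractory period (ERP).

The pipeline emulates, at greatly reduced computational scale, the design
of large published in-silico AF trials that used volumetric bi-atrial
anatomies and tens of thousands of CPU hours. Everything here runs on one
core in minutes; the correspondence is at the level of mechanisms and
protocol structure, not of full-cohort statistics.

## Cellular electrophysiology

The reaction term is the Courtemanche–Ramirez–Nattel (CRN) human atrial
action-potential model (21 state variables). The trial baseline applies a
persistent-AF electrical remodelling set on top of the original
parameters:

| parameter | remodelling | rationale |
|---|---|---|
| g(ICaL) | x 0.35 | reduced L-type calcium density in chronic AF |
| g(Ito) | x 0.35 | transient-outward down-regulation |
| g(IKur) | x 0.50 | ultrarapid delayed-rectifier down-regulation |
| g(IK1) | x 2.0 | inward-rectifier up-regulation, hyperpolarized rest |

This is a standard remodelling set for CRN-based AF work; the original
parameters remain available (`cell_params(af_remodelled = FALSE)`) and the
resulting action potential reproduces published CRN biomarkers (APD90 at
1 Hz near 300 ms, resting potential near -81 mV). The remodelled baseline
has APD90 near 150 ms and a rest of -84 mV; its quiescent state was
settled numerically for 4 s and frozen into
`cell_initial_state()` so unstimulated tissue is exactly at rest.

Nine currents are scalable per virtual patient (`ionic_profile()`):
INa, ICaL, IK1, IKr, IKs, Ito, IKur, INaK, INCX. Effective conductance is
the product `baseline x profile x region x (1 - drug block) x LVA
remodelling`; the factors commute by construction. Seven region classes
carry multiplicative adjustment tables (`region_adjustments()`). The six
heterogeneous regions' default adjustments (shorter pulmonary-vein and
left-atrial action potentials, longer crista-terminalis ones) are
package assumptions chosen to reproduce the qualitative regional APD
ordering reported for human atria; users can supply their own tables.

Drugs are simple pore blocks: current X keeps `1 - block[X]` of its
conductance, with no dose–response or state-dependent kinetics. Three
presets are shipped (amiodarone 1.5 and 3.0 uM, vernakalant 30 uM) with
their catalogued block fractions; concentrations are bookkeeping tags.

## Tissue model and numerics

The monodomain equation is solved on a masked structured grid of edge
length h (400 um by default) with membrane capacitance 1 uF/cm^2 and
surface-to-volume ratio 1400 cm^-1 fixed; only conductivity is calibrated.
Geometry is a 2D manifold (planar-unfolded chambers): the re-entrant
phenomena of interest are surface-dominated, and the dimensional reduction
is the key desk-scale enabler. "Chamber volume" maps to sheet area through
a fixed documented convention of 40 mm^2 per mL
(`chamber_area_mm2()`), preserving monotonicity of size effects.

Numerical scheme, chosen as the standard stable combination at this h:

* operator splitting (diffusion, then reaction) at a shared dt = 0.02 ms;
* diffusion: conservative flux-form 5/9-point stencil with the
  fiber-rotated anisotropic tensor; cross-derivative terms use averaged
  masked gradients at faces, so the scheme conserves total voltage exactly
  under no-flux boundaries (this is tested);
* reaction: Rush–Larsen for the 12 voltage-gated variables, forward Euler
  for concentrations and the calcium-release gates;
* voltage-dependent kinetics are evaluated through lookup tables on
  [-120, 90] mV at 0.05 mV resolution with linear interpolation, rebuilt
  per dt — the standard cardiac-solver speed optimization. The tabulated
  integrator tracks the exact one to ~1e-3 mV over a full action
  potential (tested);
* an explicit stability check `dt <= h^2 / (2 max(Dxx + Dyy))` runs
  before each simulation and aborts with the violated bound;
* integration aborts with diagnostics if |Vm| leaves +-200 mV.

Baseline longitudinal conductivity is calibrated by bisection (geometric
midpoint, since CV ~ sqrt(sigma)) until the measured plane-wave velocity
on a 30 mm strip hits 80 cm/s; the bulk anisotropy ratio defaults to 4:1,
a package assumption. LVA elements receive 30% lower longitudinal
conductivity, an 8:1 anisotropy ratio and ionic reductions of 50/40/50% in
ICaL/INa/IK1, applied after any regional conductivity scaling (the order
is a documented choice) and guarded to be idempotent.

Ablation removes elements from the mesh; removed element boundaries become
no-flux, which eliminates electrotonic loading by the lesion, and the
conduction graph (4-connectivity) updates accordingly.

## Synthetic anatomy and LVA maps

`make_idealized_atria()` builds two square unfolded chambers (right atrium
left, left atrium right) joined by two inter-atrial bridges, with a fixed
landmark template: four pulmonary-vein discs with ostium rings, posterior
and anterior walls, roof, appendages, annulus holes with their isthmus
corridors (mitral and cavo-tricuspid), an anterior-line path, and a crista
strip. The template stands in for imaging-derived anatomy that the
pipeline deliberately does not require; it preserves the topological
features the lesion sets rely on (isolatable veins and posterior wall,
corridors that lines of block can transect, two chambers with a
well-defined bridge set).

The probabilistic LVA map is a Gaussian-smoothed random field rescaled to
[0, 1], with an additive bias toward the anterior and posterior walls
mimicking where low voltage concentrates clinically. Thresholding labels
elements per chamber in order of decreasing probability (ties broken by
element index) until coverage reaches the 15% target. The smoothed-field
surrogate reproduces the compactness of clinical LVA patches — compact
patches are what anchors rotors — but no attempt is made to copy any
patient-derived spatial distribution.

## Cohort construction

Profiles are sampled uniformly and independently per current on
[1 - spread, 1 + spread] with spread 0.5 — the +-50% variation documented
for sodium-current density is applied to all nine scaled currents, a
generalization the sampling module exposes per current. Profiles are then
calibrated by rejection against single-cell biomarker windows
(`calibration_ranges()`): APD90 70–330 ms, rest -90 to -70 mV, peak 0–50
mV, max upstroke 50–400 V/s — broad literature-informed persistent-AF
ranges shipped as editable defaults. Rejection sampling (rather than
curated fitting) is assumed for the population-of-models step.

Anatomy scales are truncated-normal draws (RA 127 +- 51 mL, LA 105 +- 39
mL, truncated above 20 mL). `build_cohort()` forms the full profiles x
anatomies cross, optionally duplicated into LVA-absent/LVA-present twins:
40 profiles x 10 anatomies x 2 LVA states = 800 virtual patients, and the
planned-run accounting `cohort + sustained x therapies` reproduces the
full-scale trial arithmetic (800 + 522 x 12 = 7064).

## Protocols

* **CV**: plane wave from one strip edge (stimulated edge width scales
  with the electrotonic space constant so capture survives strong
  coupling); activation marked at maximum upstroke velocity; velocity from
  two sites >= 10 mm apart. Conduction failure returns an explicit block
  result, never a number.
* **ERP**: S1 train of 4 beats at 600 ms cycle length (a documented
  convention), then binary search over the S1–S2 coupling interval to 5 ms
  resolution; S2 must propagate >= 10 mm. The S1 conditioning state is
  checkpointed and reused across the search.
* **PVI**: per vein, the smallest circumferential annulus (width 1.5 h,
  which provably blocks 4-connected crossings) lying wholly outside the
  vein whose removal graph-disconnects the vein interior from the
  left-atrial body. Already-isolated veins are skipped, making
  re-application a no-op.
* **Induction**: the phase-distribution method. A single-cell limit cycle
  (250 ms, recorded at 1 ms resolution after conditioning) is laid out
  spatially with phase equal to the summed polar angles about the
  requested cores. The default trial spec imposes 3 cores at fixed
  landmark-relative sites with seed-controlled jitter, consistent with the
  reported mean of about 3 simultaneous rotors. Determinism: identical
  specs yield identical initial states.
* **Sustainment**: a trajectory is sustained if any element activates
  (upstroke > 10 V/s) during the final 500 ms of the analysis window
  (7 s at full scale; shorter in the reduced demos). The verdict is a pure
  function of the voltage trajectory and is robust to +-20% threshold
  changes (tested).

## Arrhythmia metrics

Phase is the analytic-signal angle of the mean-subtracted voltage;
elements with < 1 mV variability are flagged undefined. Phase
singularities are plaquette winding numbers (+-1). Tracking is
frame-to-frame nearest-neighbour linking with a 4 mm gate; a track is
stationary below 5 mm tip excursion; anchoring to LVAs requires 80% of
tip samples within 2 mm of labelled elements; break-up is declared above
a mean of 4 simultaneous tips. These taxonomy thresholds are not
literature constants; they are package defaults exposed as arguments.
Macro-re-entry (peri-annular flutter and flutter around ablated islands)
carries no exposed phase singularity, so it is identified structurally:
`detect_macro_reentry()` tests for a consistent unit phase winding along a
closed loop of conducting elements encircling the obstacle.
The pseudo-ECG is the infinite-volume-conductor dipole sum over element
voltage gradients (a deliberate reduction of torso-resolved 12-lead
ECGs), and dominant frequency is the argmax of a Welch periodogram in
1–15 Hz, requiring >= 4 s of signal.

## Trial engine and stratification

Therapies are named lesion sets and/or drugs: PWI (box isolation of the
posterior wall's perimeter), mitral-isthmus and cavo-tricuspid lines,
anterior mitral line, Marshall-PLAN (mitral line + CTI + an extra lesion
along the mitral-isthmus corridor standing in for the ethanol-infused
Marshall bundle — a flagged approximation, since the venous ethanol
effect has no faithful in-silico counterpart here), staged LVA ablation,
and the two drug arms; low-dose amiodarone can be added to any ablation
as synergistic therapy. Composites union their parts. Driver location is
the majority chamber/LVA residence of tracked tips, an operationalization
chosen because the source analyses do not define one algorithmically.

The stratification cascade and its boundary conventions (values exactly
at 60 mL / 90 mL / 170 ms take the big/long branch) are implemented as a
total deterministic function; the (no-LVA, small-RA, small-LA) corner
returns a `flutter-circuit` placeholder because flutter-specific circuit
ablation has no single lesion set — the user must choose. The low-dose
amiodarone adjunct attaches in the LVA-absent arm when ERP < 170 ms,
matching where synergistic therapy was needed.

## Desk-scale choices and what the tests show

Problem sizes used by the shipped tests and the acceptance script, chosen
so the whole suite runs on one core:

* CV/ERP strips: 30 mm x 1.2 mm at h = 400 um;
* re-entry demonstration sheet: 42 x 42 mm at h = 600 um, conductivity
  at one quarter of the calibrated bulk value and a short-APD demo
  profile (IKr x 2.2, ICaL x 0.4) so that the re-entrant wavelength fits
  the sheet — a constructed fixture, not a sampled patient;
* LVA-therapy demonstration: the same sheet with a compact 12 mm LVA
  patch, which anchors a meandering rotor. Ablating the patch alone
  leaves a macro-re-entry around the lesion island (detected by loop
  winding), and adding a lesion-to-boundary line — the cavo-tricuspid
  manoeuvre transplanted to the sheet — terminates it. This is the
  desk-scale counterpart of the staged LVA-ablation arms and of the
  incremental benefit of CTI block; the full two-chamber version is not
  reproducible at these mesh sizes because coarse atria cannot sustain
  re-entry at all;
* reduced trial: idealized atria at h = 1.3–2 mm, analysis windows well
  under the full 7 s.

Passing tests therefore demonstrate mechanism-level correctness
(calibration, remodelling arithmetic, lesion topology, detector
properties, determinism), not reproduction of full-cohort statistics.
Numerically, the explicit 400 um lattice slows the bulk plane wave by
about 8% relative to a 200 um grid (the gap closes as conductivity
rises), so convergence checks assert that measured figure rather than a
tighter bound, and the continuum CV-vs-sqrt(conductivity) law is verified
on the finer grid. Two
known model-level limitations are documented rather than hidden: the
CRN-based formulation's conduction velocity depends more strongly on
sodium-current density than the (uncited-parameter) baseline model of the
emulated trials, so the extreme slow-profile velocities land below their
reported counterparts; and with the slowest sodium profile, transversally
remodelled LVA tissue at h = 400 um sits past the discrete propagation
limit and blocks, so "slowest conducting" quantities are scanned over the
sampling range rather than evaluated at its lower bound.
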