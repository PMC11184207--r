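# atriasim

Desk-scale in-silico trials of catheter-ablation and drug therapy for
persistent atrial fibrillation (AF), for computational cardiac
electrophysiologists and methods researchers who want a fully scripted,
single-machine counterpart of large virtual-cohort AF trials.

The package builds cohorts of *virtual patients* that differ in ionic-current
expression, atrial size, and low-voltage-area (LVA) structural remodelling;
simulates re-entrant arrhythmia with a monodomain reaction–diffusion model
coupled to a human atrial action-potential model; applies virtual pulmonary
vein isolation, eight further lesion sets, and pore-block antiarrhythmic
drugs; and tabulates per-therapy freedom from arrhythmia, stratified by LVA
status.

## The model

Tissue voltage follows the monodomain equation

```
chi * Cm * dV/dt = div( sigma(x) grad V ) - chi * I_ion(V, s; p)
```

with `chi = 1400 cm^-1`, `Cm = 1 uF/cm^2`, a fiber-aligned anisotropic
conductivity tensor `sigma`, and the Courtemanche–Ramirez–Nattel human
atrial model (with a persistent-AF remodelling parameter set) as the
reaction term `I_ion`. A virtual patient's electrophysiology is a vector of
nine conductance multipliers `p` (INa, ICaL, IK1, IKr, IKs, Ito, IKur,
INaK, INCX); drugs act as pore blocks, `g_X -> g_X * (1 - b_X)`; LVA tissue
receives 30% lower longitudinal conductivity, 8:1 anisotropy, and
50/40/50% reductions of ICaL/INa/IK1. Baseline conductivity is calibrated
by bisection so a planar wave travels at 80 cm/s in bulk tissue. Re-entry
is imposed with phase-distribution initial conditions, tracked via
analytic-signal phase maps and topological-charge rotor detection, and
summarized as pseudo-ECG dominant frequency and per-therapy efficacy
tables. A decision cascade (`stratify()`) maps patient features (LVA
status, chamber volumes, tissue ERP) to a recommended therapy.

See the methods vignette (`vignettes/atriasim-methods.Rmd`) for model
assumptions, parameter defaults, numerical choices and known limitations.

## Worked example

```r
library(atriasim)

# 1. calibrate tissue conductivity to the 80 cm/s bulk target
strip <- make_sheet(75, 3, h_um = 400)
cal <- calibrate_baseline_conductivity(strip, target_cv_cm_s = 80)
glance(cal)
#> # A tibble: 1 x 5
#>   sigma_l_ms_mm cv_cm_s target_cv_cm_s iterations anisotropy
#>           <dbl>   <dbl>          <dbl>      <int>      <dbl>
#> 1         0.458      80             80          3          4

# 2. sample an ionic-profile population, calibrate it against single-cell
#    biomarkers, and cross it with anatomies into a cohort
profiles <- sample_profiles(n = 12, spread = 0.5, seed = 42)
accepted <- calibrate_profiles(profiles, calibration_ranges(), n_beats = 2)
anatomies <- sample_anatomy_scales(n = 3, seed = 42)
cohort <- build_cohort(accepted, anatomies, with_and_without_lva = TRUE)
dplyr::count(cohort, has_lva)
#> # A tibble: 2 x 2
#>   has_lva     n
#>   <lgl>   <int>
#> 1 FALSE      36
#> 2 TRUE       36

# 3. drug worked example: amiodarone 3.0 uM removes 70% of peak IKr
clamp_block_assay("IKr", drug_preset("amiodarone_3.0"))
#> # A tibble: 1 x 4
#>   current peak_control peak_drug reduction_pct
#>   <chr>          <dbl>     <dbl>         <dbl>
#> 1 IKr            0.983     0.295          70.0

# 4. stratify two virtual patients to therapy
features <- tibble::tibble(has_lva = c(TRUE, FALSE),
                           ra_volume_ml = c(55, 80),
                           la_volume_ml = c(100, 85),
                           erp_ms = c(200, 160))
stratify(features)[, c("has_lva", "therapy", "adjunct")]
#> # A tibble: 2 x 3
#>   has_lva therapy       adjunct
#>   <lgl>   <chr>         <chr>
#> 1 TRUE    LVA_LA        <NA>
#> 2 FALSE   Marshall-PLAN amiodarone_1.5
```

The first patient has LVAs and a small right atrium (55 mL), so left-atrial
LVA ablation alone is recommended; the second has no LVAs, a large right
atrium and a small left atrium, pointing to Marshall-PLAN, with low-dose
amiodarone added because the ERP is short (160 ms < 170 ms).

A miniature end-to-end trial (`run_trial()`) chains anatomy construction,
LVA mapping, pulmonary vein isolation, re-entry induction, sustainment
assessment and per-therapy treatment into a record table that
`efficacy_table()` summarizes; `autoplot()` methods visualize meshes, LVA
maps, voltage frames and efficacy tables.

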