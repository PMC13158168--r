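# bnctdose

Patient-specific whole-body **out-of-field dosimetry** for accelerator-based
boron neutron capture therapy (BNCT).

In BNCT the patient is positioned against the collimator wall, so the whole
body receives a leakage dose from neutrons and gamma rays. Gamma dose is
measured directly with TLDs, but activation foils (Au, Mn, Al) measure only
reaction rates — spectrum integrals that cannot be converted to dose without
a spectrum model. `bnctdose` implements the integrated
measurement–simulation workflow used clinically for this problem:

1. **Activation**: HPGe net peak counts → reaction rate per unit beam charge
   per atom (n/C/atom), via the standard saturation/decay/counting
   correction.
2. **Unfolding**: per body location, solve the 3×3 linear system
   `R_sim · N = R_meas` for the per-energy-region normalization factors
   `N = (N_thermal, N_epi, N_fast)` — the ratios of measured to reference
   foil response (thermal ≤ 5.3×10⁻⁷ MeV, epithermal ≤ 10⁻² MeV, fast
   ≤ 30 MeV).
3. **Dose synthesis**: scale the reference per-region dose components into
   the biologically weighted neutron dose
   `D_n = Σ_j N_j [CBE·D_B,j·(C_B/25) + RBE_N·D_N,j + RBE_H·D_H,j]`
   (CBE 2.5, RBE_N 2.9, RBE_H 2.4), add the measured gamma dose (weight 1),
   and evaluate ambient dose equivalent H\*(10) = `Σ_j N_j H_ref,j + D_γ`.
4. **Reporting**: cohort mean ± SD per location, dose-component fractions
   by treatment-site group, primary/secondary gamma-origin ratios, and
   EQD2-normalized dose-versus-distance profiles (H\*(10) per tumor EQD2 of
   D95%, and EQD2-converted weighted dose per tumor EQD2) for
   inter-modality comparison.

Because the reference quantities come from a Monte Carlo room model that is
site-specific, the package ships a **parametric synthetic reference**
(Maxwellian + 1/E + fast-tail spectra with per-component distance
attenuation) and a **cohort generator with ground truth**, so the entire
pipeline is testable end to end; a genuine Monte Carlo library can be
substituted through the same JSON schema (`readReferenceLibrary()`).

## Worked example

```r
library(bnctdose)

lib <- buildReferenceLibrary()                       # parametric reference
coh <- generateCohort(cohortSpec(nPatients = 50, seed = 1), lib)
de  <- analyzeCohort(coh$measurements, lib)          # DoseExperiment
summarizeCohort(de)
```

which prints (weighted dose in Gy-eq, H\*(10) in Sv, gamma in Gy):

```
 location      weighted         hstar gamma
     neck 1.82 +/- 0.34 5.39 +/- 0.58  0.64
    chest 0.57 +/- 0.12 1.57 +/- 0.17  0.32
  abdomen 0.25 +/- 0.06 0.71 +/- 0.09  0.14
    waist 0.13 +/- 0.03 0.42 +/- 0.05  0.07
     knee 0.04 +/- 0.01 0.11 +/- 0.02  0.03
    ankle 0.02 +/- 0.00 0.03 +/- 0.01  0.01
```

i.e. the weighted out-of-field dose falls from ~1.8 Gy-eq at the neck to
~0.02 Gy-eq at the ankle, gamma-dominated everywhere beyond the neck. A
single unfolding step looks like:

```r
solveNormalization(c(3, 6.5, 1), matrix(c(2,1,0, 1,3,0, 0,0,4), 3, 3))
#> NormalizationFactors 'unknown': thermal=0.50, epithermal=2.00, fast=0.25  (cond 2.42)
```

A thin CLI over the same functions is installed at
`system.file("cli/bnctdose.R", package = "bnctdose")` with subcommands
`gen-reference`, `gen-cohort`, `analyze`, `report`.

See `vignettes/whole-body-dosimetry.Rmd` for the model, its assumptions,
numerical conventions and limitations.

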