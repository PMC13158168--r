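---
title: "Whole-body out-of-field dosimetry for BNCT: methods and design"
author: "bnctdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body out-of-field dosimetry for BNCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnctdose)
```

## The problem

In accelerator-based boron neutron capture therapy (BNCT) the patient sits
directly against the collimator wall, so the whole body receives a
non-negligible out-of-field dose from leaked neutrons and gamma rays. The
gamma dose can be measured directly with thermoluminescent dosimeters
(TLDs), but foil activation measurements of neutrons yield only reaction
rates — integrals of the neutron spectrum over each foil's sensitive energy
range — which cannot be converted to dose without knowledge of the local
spectrum. `bnctdose` implements the integrated measurement–simulation
workflow that resolves this: a reference room model supplies, per body
location, the expected foil reaction rates and the per-energy-region dose
components; the measured-to-reference ratios (normalization factors) then
scale the reference doses to the individual patient.

## The dose model

Three activation foils bracket the spectrum: Au (thermal + epithermal
capture, with a large epithermal resonance), Mn (predominantly thermal
capture), and Al via the threshold reaction Al-27(n,α)Na-24, which responds
only to fast neutrons above an effective threshold of 3.4 MeV. The neutron
energy axis is partitioned into three regions with upper-inclusive cuts:

* thermal: E ≤ 5.3×10⁻⁷ MeV
* epithermal: 5.3×10⁻⁷ < E ≤ 10⁻² MeV
* fast: 10⁻² < E ≤ 30 MeV

Per location, the reference library carries a 3×3 response matrix
`R_sim[foil, region]` (n/C/atom). Given the measured rate vector `R_meas`,
the per-region normalization factors **N** solve the linear system
`R_sim · N = R_meas` — a direct 3×3 solve, not a regularized many-group
unfolding, because three foils support exactly three degrees of freedom.

The reference weighted dose per region combines the boron, nitrogen and
hydrogen physical components:

D_sim,j = CBE_skin · D_B,j · (C_B / 25 ppm) + RBE_N · D_N,j + RBE_H · D_H,j

with CBE_skin = 2.5, RBE_N = 2.9, RBE_H = 2.4, and the boron component
rescaled linearly from the 25 ppm reference concentration to the patient's
measured blood concentration C_B. The patient neutron dose is
D_n = Σ_j N_j D_sim,j; the measured gamma dose is added with weight 1.
Ambient dose equivalent uses the same per-region scaling,
H\*(10) = Σ_j N_j H_ref,j + D_γ (1 Gy = 1 Sv for gamma rays). For
inter-modality comparison, results are normalized to the EQD2 of the
prescription (D95%, α/β = 10 Gy); the location weighted dose is itself
EQD2-converted with α/β = 2 Gy before normalization, treating the single
BNCT session as one fraction.

## Key parameters

| parameter | default | unit | role |
|---|---|---|---|
| region cuts | 5.3e-7, 1e-2 | MeV | thermal/epithermal/fast partition |
| CBE_skin, RBE_N, RBE_H | 2.5, 2.9, 2.4 | – | component weights |
| reference boron | 25 | ppm | boron-dose normalization point |
| tumor/blood ratio × CBE_tumor | 2.5 × 3.8 | – | synthetic D95 only |
| α/β tumor / normal | 10 / 2 | Gy | EQD2 conversions |
| condition threshold | 1e6 | – | ill-conditioning flag |
| cohort size preset | 271 | patients | default study conditions |

## Numerical choices

* **H\*(10) and kerma interpolation** is log–log between tabulated points,
  the standard convention for neutron conversion coefficients; it is exact
  at table nodes and monotone between them. Energies outside the table are
  an error — never silently clamped. The shipped coefficient table is
  therefore extended (flat below 10⁻⁹ MeV, smoothly above 20 MeV) to cover
  the full grid, so folding never extrapolates.
* **Group-average cross sections** use a flat lethargy weighting:
  ∫σ(E) dE/E over the group divided by the group lethargy width, evaluated
  analytically per power-law segment of the log–log-interpolated pointwise
  table. Segments touching zero (the Al threshold) switch to linear-in-E
  interpolation, so groups entirely below threshold average to exactly
  zero.
* **Energy grid**: 60 log-spaced edges over 10⁻²⁰–30 MeV with the two
  edges nearest the region cuts snapped exactly onto them, so region
  boundaries land on the printed cut energies; group membership uses the
  geometric-mean midpoint and upper-inclusive intervals.
* **Kerma and H\* folding** evaluate coefficients at group midpoints (not
  group-averaged); at the default 59-group resolution the difference is
  negligible against the parametric-spectrum approximation itself.
* **Condition number** is computed on the row-equilibrated response matrix
  (each foil row scaled by its largest entry). The raw matrix mixes foil
  sensitivities spanning seven decades, so its raw condition number
  reflects units rather than solvability; the equilibrated diagnostic is
  scale-invariant and measures the genuine failure mode — shape degeneracy
  between foil responses (e.g. Au/Mn thermal similarity).
* **Negative unfolded factors** are preserved, flagged and propagated;
  zero-clamping is an explicit opt-in (`clampNegative = TRUE`).
  Transparency beats silent truncation, and negative components are a
  useful QA signal for background over-subtraction.
* **Measurement uncertainty** propagates to N by first-order linear
  propagation (covariance `A⁻¹ Σ A⁻ᵀ` with Σ diagonal from counting
  statistics, 1/√counts). Per-patient uncertainties are a package
  addition: the clinical workflow reports cohort SDs only.

## The synthetic reference and cohort generator

The original workflow obtains `R_sim`, the dose components and H\*(10)
from a validated Monte Carlo model of the treatment room. That transport
calculation is out of scope here; the package ships a parametric stand-in
whose *schema* is the integration contract (`writeReferenceLibrary()` /
`readReferenceLibrary()`), so genuine Monte Carlo output can be dropped in
without code changes.

The parametric model builds each location spectrum as a thermal Maxwellian
(kT = 2.53×10⁻⁸ MeV) + 1/E epithermal slope + exponential fast tail
(E₀ = 0.5 MeV), each amplitude decaying exponentially with lateral
distance from the field center with its own attenuation length (thermal
shortest — 15, 19, 23 cm — so the field hardens with distance). The
amplitudes and the per-location gamma doses/primary fractions were
calibrated once so that a unit-factor patient reproduces the reported
magnitude and distance trend of clinical out-of-field doses (neck ≈ 1.9
Gy-eq weighted, gamma-dominated beyond the neck, primary gamma fraction
91.6 % at the knee and 27.2 % at the ankle where the shutter shields the
beam-line component). Only the waist lateral offset (~65 cm) is anchored
by the clinical installation; the other distances are flagged placeholders
in `reference_config.json`.

The cohort generator draws, per patient: blood boron (log-normal, mean
25 ppm), a single-fraction D95 prescription (log-normal, median 22 Gy-eq),
a treatment-site category, and per location a true factor vector **N**
(log-normal). Noiseless measurements are the exact forward map
`R_sim · N`; noise is multiplicative log-normal with unit mean ("relative
SD" exactly), largest by default on Al (15 %), whose counts are near
background far from the field. Ground truth is always emitted next to the
measurements; analysis functions never read it.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: room-scatter structure beyond smooth
exponential decay, foil self-shielding and flux perturbation, HPGe peak
fitting and dead time, patient-geometry deformation, and any systematic
simulation–reality offset in `R_sim` (which in the clinical workflow is
absorbed into **N** only to first order). Recovery tests validate the
*pipeline algebra*, not the room model.

## Test and validation sizes

The suite exercises: oracle equivalence of the 3×3 unfolding on 1000
random well-conditioned systems (recovery < 10⁻¹⁰ relative); end-to-end
zero-noise recovery of factors, doses and H\*(10) on a 50-patient cohort
(< 10⁻⁹ relative); stochastic mean recovery on the full 271-patient
preset with 5 % reaction-rate noise (cohort means within 3 SE of truth at
all six locations); hand-derived closed forms for the activation equation,
the weighted dose model (0.443 Gy-eq example) and EQD2 (16.667 and
6.0 Gy); and report integrity (component fractions summing to 1,
primary + secondary gamma = 1, monotone dose–distance decay). These sizes
keep the full suite under a minute while leaving the statistical checks
well-powered.

## Worked example

```{r example, eval = FALSE}
lib <- buildReferenceLibrary()
coh <- generateCohort(cohortSpec(nPatients = 50, seed = 1), lib)
de  <- analyzeCohort(coh$measurements, lib)
summarizeCohort(de)[, c("location", "weightedDose_mean", "weightedDose_sd")]
exportDistanceProfile(de, lib)
```

## Known limitations

* Surface-mounted dosimetry overestimates organ doses; no depth
  conversion is attempted.
* The constant-current assumption underlies the per-charge activation
  normalization; a beam-current profile would require the charge-weighted
  generalization.
* H\*(10) per-region scaling by **N** is a modeling default (an
  `scaled = FALSE` mode preserves the unscaled reference alternative),
  since the clinical convention is not fully specified.
* No resonance self-shielding or foil-thickness corrections; detector
  efficiency is an input, not a calibration.
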