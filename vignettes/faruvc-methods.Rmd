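---
title: "Methods: far-UVC skin dosimetry, radiative transfer and colorimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: far-UVC skin dosimetry, radiative transfer and colorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the models it implements, the
defaults it chooses where the underlying study leaves the design open, and
what its tests do and do not demonstrate.

## The problem

Krypton-chloride excimer lamps emit principally at 222 nm — a wavelength so
strongly absorbed by proteins and nucleic acids that it barely penetrates
the stratum corneum — but also emit low-power longer-wavelength UVC
(230–280 nm) that penetrates much deeper. Whether such a lamp is safe for
skin therefore depends on its whole spectrum, not its peak. The package
quantifies this in three coupled ways: surface dosimetry against the ICNIRP
actinic-hazard limits, Monte Carlo photon transport to the depth of the
proliferating basal keratinocytes, and reflectance colorimetry of the
skin's visible response.

## Dosimetry

Radiant exposure is the exact product `H = E · t` (mW cm⁻² × s = mJ cm⁻²).
Exposure tables report this exact value alongside a 2-significant-figure
display value, matching how such studies print doses; we deliberately do
not guess a "nominal" irradiance when the rounded product differs from a
printed dose (6.1 mW cm⁻² × 1000 s = 6100, displayed 6100 — a study
quoting 6000 evidently planned at a nominal 6.0; `run_exposure_report()`
keeps the exact arithmetic).

The ICNIRP table (200–400 nm 8-h limits and relative spectral effectiveness
S(λ), anchored at S = 1, 3 mJ cm⁻² at 270 nm) ships as a package constant
with its citation. Two interpolation conventions matter:

* **Limits** interpolate **linearly in wavelength**; this is what makes the
  222 nm limit exactly 23 mJ cm⁻² from the 220 nm (25) and 225 nm (20)
  entries, the value universally quoted for KrCl lamps.
* **S(λ)** interpolates **log-linearly**, the standard convention for
  actinic weighting curves that span five orders of magnitude.

Germicidal timing assumes single-exponential (first-order) inactivation,
`S(H) = 10^(−H/D₉₀)`, so `t = n_logs · D₉₀ / E`. The packaged constants are
taken from the cited aerosol-chamber (HCoV-229E k = 4.1, HCoV-OC43
k = 5.9 cm² mJ⁻¹) and surface-disinfection (SARS-CoV-2, 99.7% at
3.0 mJ cm⁻², i.e. D₉₀ ≈ 1.19 mJ cm⁻²) studies; shoulders and multi-hit
kinetics are out of scope. Zero irradiance yields an infinite-time sentinel
with a warning rather than an error.

## Monte Carlo radiative transfer

The transport core (compiled, `src/mcrt.cpp`) is a standard layered-medium
photon-packet walk in the MCML lineage:

* **Geometry.** Laterally infinite plane-parallel layers; a normally
  incident collimated broad beam is modeled as a pencil beam with
  translational invariance, so tallies depend on depth `z` only (the
  irradiated field, centimetres wide, is vastly wider than UV penetration
  depths). Depth bins are half-open `[lo, hi)` in µm, surface at `z = 0`.
* **Sampling.** Free paths are exponential, `s = −ln(u)/µ_t`; scattering is
  Henyey–Greenstein via its inverse CDF with uniform azimuth; boundaries
  use the unpolarized Fresnel average with total internal reflection beyond
  the critical angle. All tissue layers share `n = 1.38` and the ambient is
  `n = 1.0`, so Fresnel acts only at the air–skin surface — internal
  mismatches are second-order for fluence-versus-depth and no reliable
  per-layer UV indices exist.
* **Variance reduction.** Implicit capture deposits `w · µ_a/µ_t` at each
  interaction; Russian roulette triggers below weight 10⁻⁴ with survival
  probability 0.1. The roulette bookkeeping is ledger-exact: a surviving
  packet's weight boost is debited from the absorbed tally and a killed
  packet's residual weight credited to it. This is unbiased in expectation
  and makes `reflected + transmitted + absorbed = 1` hold to floating-point
  precision at every wavelength, which the tests assert at 10⁻⁶.
* **Estimator.** Fluence is the track-length estimator: per depth bin,
  `Σ w·ℓ / (N · Δz)`, normalized per unit incident irradiance per
  wavelength. Standard errors come from the per-photon contribution
  variance. Wavelengths are transported independently on a 2 nm grid
  (no fluorescence or other wavelength coupling); the source spectrum
  enters only as a per-wavelength weight at tally time, so one transport
  solution serves any source on the same grid.

**Validation strategy.** With scattering off and matched boundaries the
walk must reproduce Beer–Lambert attenuation; the suite compares every
depth bin of a 10⁵-photon run against the analytic bin-averaged
`exp(−µ_a z)` at 3 Monte Carlo standard errors, and checks the
fluence-weighted mean depth against the slab-truncated exponential mean.
Refinement consistency is asserted on a fixed depth support: the average of
two 50 µm bins must agree with the covering 100 µm bin from an independent
photon stream within combined MC error (bin estimates at *different*
supports legitimately differ by the attenuation across the bin, so
comparing them directly would conflate discretization with error).

**The skin preset is synthetic.** The study this package models defers its
layer thicknesses and optical-property tables to external references that
are not reproduced; `inst/extdata/skin_default.yaml` is therefore an
explicit stand-in: five layers (stratum corneum 20 µm, living epidermis
80 µm, papillary dermis 150 µm, reticular dermis 1000 µm, subcutis
backstop), markers at 20/60/100 µm, `µ_a(λ)` a decreasing double
exponential (protein/nucleic-acid-dominated below ~240 nm; ~90 mm⁻¹ at
222 nm falling to a few mm⁻¹ by 300 nm in the epidermis) plus a small
melanin-like `λ⁻³` term, `µ_s(λ)` a `λ⁻¹·⁵` power law (tens of mm⁻¹),
`g = 0.9`. Every constant lives in that one config file (the YAML dialect
spells the index `refractive_index`, since a bare `n` is a YAML boolean)
and round-trips through `write_skin_config()`. Consequences that depend
only on the preset's qualitative shape — 222 nm extinguished above the
epidermis while 280–320 nm reaches the basal layer, and a filtered source
delivering ~10² times less 240–320 nm basal fluence than an unfiltered
one — are robust; absolute fluence values are not, and the fold-difference
is checked as an order of magnitude (within [10, 1000]), never as an exact
number.

## Colorimetry

Tristimulus integration uses shipped D65 × standard-observer weight tables
(400–700 nm, 10 nm pitch — the range and pitch of handheld sphere
instruments), followed by the CIELAB transform with its cube-root/linear
switch at (6/29)³. Defaults: **D65 illuminant, 1964 10° observer**,
specular component included (no gloss correction) — the instrument class's
typical settings, which the study does not state; both are switchable, and
every delta-based result is insensitive to the choice for neutral
baselines because Δ-values subtract the baseline under the same weights.
The white-point identity (perfect diffuser → L\* = 100, a\* = b\* = 0) holds
exactly by construction, and the XYZ→Lab transform is cross-checked against
`grDevices::convertColor` as an independent oracle.

Response classification calls erythema/yellowing when Δa/Δb exceeds
**1.0 CIELAB unit for ≥ 2 consecutive post-baseline time points**. The
study reports presence/absence only, so the threshold is explicit
configuration: 1 unit is roughly a just-noticeable difference, and the
two-point persistence requirement rejects single noisy excursions.

## The synthetic-data generator

The generator produces every input the pipeline needs, with known ground
truth:

* **Lamp spectra.** Gaussian 222 nm peak (FWHM 2 nm), weak Gaussian lines
  at 237/258/270 nm (amplitudes 0.03/0.05/0.02) and a 0.004 continuum
  confined to 230–280 nm — the qualitative structure of published KrCl
  spectra, whose numeric tables exist only as figures. "Filtered"
  multiplies the 230–280 nm band by 10⁻², "additional" filtering by 10⁻⁴;
  because every component in that band scales together, the filtered:
  unfiltered band-integral ratio equals the suppression factor to 10⁻⁶,
  which the tests exploit.
* **Yellowing kinetics.** Phenomenological only (the study's single
  mechanistic statement is negative — not photo-oxidation of melanin): a
  blue-band Gaussian absorber (centre 445 nm, width 55 nm) on a pale-skin
  baseline rising linearly 0.3→0.6 over 400–700 nm, with amplitude
  `A(dose) = A_max (1 − e^{−(dose−thr)/D₀})` above threshold and clearance
  `e^{−t/τ}`. Defaults: `A_max = 0.06` (peak Δb ≈ 3–4.6 across the study
  doses, the scale seen in such measurements), `D₀ = 6000 mJ cm⁻²`,
  `τ = 6 h` (chosen so the 6000 mJ cm⁻² response is below the noise floor
  by 24 h), threshold 3000 mJ cm⁻² — the true threshold is only bracketed
  in (1500, 6000] by the study, and 3000 is an explicit, arbitrary choice
  within that bracket. Tape stripping multiplies the remaining amplitude by
  `1 − strip_factor` (default 0.8, "initially reduced" being the only
  guidance). Measurement noise is Gaussian per band (sd 0.002 reflectance).
* **What it does not emulate.** Erythema dose-response (none was observed
  at any tested dose, so none is simulated), site-to-site baseline
  variation, instrument drift, and any fit to the study's actual figure
  curves. Passing tests therefore demonstrate the *pipeline's* correctness
  and identifiability under the stated kinetics, not agreement with the
  unpublished figure values.

**Parameter recovery.** Δb is not linear in chromophore amplitude (the
CIELAB cube root intervenes), so `fit_yellowing_tau()` inverts the monotone
amplitude→Δb map per time point by root finding (tolerance 10⁻¹²) and
regresses `log A` on time; `fit_dose_response()` then fits the saturating
dose curve by `nls` (with `scaleOffset` so the zero-residual noise-free
problem has a well-defined convergence test). Noise-free series recover τ
to 10⁻⁶ relative and D₀ to well under 5% across four doses.

## Orchestration and reproducibility

`read_run_config()` reads a flat YAML mapping; one file drives all stages.
A single master seed yields fixed-offset child seeds per stage (MCRT
unfiltered/filtered, one per dose series), so any stage can be reproduced
in isolation; `write_report_table()` stamps every output with the config
hash and stage seed. Identical config + seed reproduces every output
bit for bit, which the suite asserts.

Problem sizes used by the packaged runs: 10⁴ photons per wavelength on a
2 nm, 200–400 nm grid with 5 µm depth bins for the headline comparison
(the basal-layer ratio then carries ~0.6% MC error); unit tests use
10³–2×10⁴ photons on coarser grids, and the Beer–Lambert oracle 10⁵
photons at a single pair of wavelengths.

## Known limitations

* Skin optics are a documented stand-in, not measured tissue data; only
  order-of-magnitude transport conclusions should be drawn.
* Single-exponential germicidal kinetics; no shoulder, no repair.
* No ocular dosimetry, no polarization, no fluorescence, no time-resolved
  transport, no CPD action-spectrum convolution.
* The colorimetric tables are truncated to 400–700 nm; absolute L\*a\*b\*
  of strongly chromatic non-skin samples would need the full-range tables,
  but baseline-relative deltas of skin-like spectra are unaffected.
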