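---
title: "Methods: multispectroscopic estimation of protein-ligand binding parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectroscopic estimation of protein-ligand binding parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

# The problem

When a small-molecule drug binds a transport protein such as serum albumin,
the protein's intrinsic tryptophan/tyrosine fluorescence is quenched, its UV
absorbance grows, and its far-UV circular dichroism (CD) loses helical
signal. Each of these titration experiments carries a classical linearised
estimator, and together they answer: how strongly does the ligand bind
(K, K~b~), how many sites (n), where (site-marker competition), by what
mechanism (static vs dynamic quenching), driven by which forces
(sign pattern of ΔH, ΔS), and with what structural consequence
(α-helix change). `specbind` implements that full inference chain, plus
forward-model generators for every input so that each estimator is
verifiable by parameter recovery.

# Models and estimators

## Stern-Volmer quenching

For fluorescence intensity F at quencher concentration [Q] with ligand-free
reference F₀:

$$F_0/F = 1 + K_{SV}[Q] = 1 + k_q \tau_0 [Q]$$

`stern_volmer_fit()` performs ordinary least squares of y = F₀/F on x = [Q].
The intercept is fitted freely rather than pinned at 1: on clean data it
lands on 1 anyway, and on real data a displaced intercept is a visible
baseline diagnostic rather than a silently absorbed error. `R` is the
Pearson correlation of (x, y) and `SD` the residual standard deviation of
F₀/F about the line. The bimolecular rate constant is k~q~ = K~SV~/τ₀ — an
exact identity in every returned object, with τ₀ defaulting to 1e-8 s, the
canonical average lifetime of albumin intrinsic fluorescence (overridable).

Intensities enter via `extract_quench_table()`, which reads every spectrum
at one fixed wavelength: the emission maximum of the ligand-free spectrum.
Using per-spectrum maxima would conflate the complexation blue shift with
quenching. The maximum is *located* on a 5-point running-mean smooth of the
reference trace; intensities are then read from the raw spectra at that
fixed wavelength. The smoothing exists because an arg-max taken on a noisy
trace preferentially lands on upward noise excursions, inflating F₀ — and
with it every fitted constant — by several percent at 1% multiplicative
noise; locating the peak on the smoothed trace removes that selection bias
while leaving noiseless symmetric bands untouched.

## Double-logarithmic binding isotherm

$$\lg\frac{F_0 - F}{F} = \lg K + n \lg [Q]$$

`double_log_fit()` uses base-10 logs throughout; K = 10^intercept^, n =
slope. Rows with F ≥ F₀ at [Q] > 0 carry no quenching signal and make the
log argument non-positive; they are dropped with a warning rather than
clamped. When n = 1 this model coincides with the linear Stern-Volmer law,
and the two fitted constants agree to numerical precision on shared data —
a property the test suite asserts.

[Q] is the total ligand concentration; no free-ligand correction is applied,
matching the implicit convention of the quenching literature.

## Mechanism and site rules

`classify_mechanism()` applies two rules: K~SV~ strictly decreasing with
temperature supports static quenching (ground-state complex dissociating on
heating), strictly increasing supports dynamic (collisional); and k~q~
uniformly above the diffusion-controlled limit (default 2.0e10 L/mol/s)
supports static, since collisions cannot quench faster than diffusion
delivers them. Agreement (or a single fired rule) yields the call;
conflict or silence yields `indeterminate`.

`displacement_call()` compares K~SV~ with and without a site-specific probe.
The competition threshold is a ratio of 0.7 — at least a 30% drop. No
published cutoff exists; in practice the two regimes are far apart (the
worked example shows a 77% drop for the competing probe versus a 7% rise
for the non-competing one), so any threshold in a wide band gives the same
call. Warfarin marks Sudlow site I, ibuprofen site II.

## Van't Hoff thermodynamics

$$\ln K = -\frac{\Delta H}{RT} + \frac{\Delta S}{R}, \qquad
\Delta G = \Delta H - T\Delta S$$

`vant_hoff_fit()` regresses ln K on 1/T (R = 8.314 J/mol/K; energies stored
in J/mol, rendered in kJ/mol). Reported ΔG comes from ΔH − TΔS; the
−RT ln K value is attached as a labelled cross-check (`dG_lnK_by_T`) and
never substituted — the two agree exactly when the K values lie on the
model, and their gap grows as the fit correlation drops below 1. The linear
(constant-ΔH) form is used; a heat-capacity term is out of scope for three
closely spaced temperatures.

A reproducibility caveat the package makes explicit: binding constants
printed to 3 significant figures limit the precision of the derived
thermodynamics. Refitting on such rounded inputs shifts ΔH and ΔS by a few
tenths of a percent relative to values computed from unrounded constants,
so the acceptance tests compare at 0.5% relative rather than at 2 printed
decimals.

`classify_forces()` maps the (ΔH, ΔS) signs: both negative → hydrogen
bonding + van der Waals; both positive → hydrophobic; ΔH < 0, ΔS > 0 →
electrostatic. Boundary zeros are decided by the ΔS sign with a warning
(the doubly degenerate origin falls to electrostatic); the non-canonical
quadrant ΔH > 0, ΔS < 0 is likewise decided by the ΔS sign, with a warning,
since no canonical rule covers it.

## UV Benesi-Hildebrand

$$\frac{1}{A_{obs} - A_0} = \frac{1}{A_c - A_0} +
\frac{1}{K_b (A_c - A_0)[L]}$$

`benesi_hildebrand_fit()` fits the double-reciprocal line by unweighted OLS
— deliberately, because that is the procedure the published constants come
from, even though reciprocal transformation is heteroscedastic. The direct
nonlinear fit of the underlying 1:1 isotherm is exposed as
`isotherm_fit()`; the suite asserts the two agree on noiseless data. A0 is
the measured free-protein absorbance, never fitted. Non-positive slope or
intercept flags the fit non-physical instead of returning a silently
negative K~b~.

## CD helix content

$$MRE = \frac{\theta_{obs}(\mathrm{mdeg})}{10\, n\, l\, C_p}, \qquad
\alpha\%_{helix} = \frac{-MRE_{208} - 4000}{33000 - 4000} \times 100$$

`mre()` and `helix_percent()` implement the single-wavelength 208-nm
estimator; `helix_change()` interpolates θ at 208 nm linearly on the
wavelength grid for free and complexed spectra. Defaults: n = 583 residues
(mature bovine serum albumin), path length l = 0.1 cm (a 1-mm cell — "cell
diameter" is interpreted as optical path length, and expressing it in cm is
what puts MRE on the deg·cm²/dmol scale where the 4000/33000 anchors are
meaningful), C~p~ = 1e-6 M. Values outside [0, 100] are returned unclamped
but flagged. No CONTIN/BeStSel-style deconvolution is attempted: one
wavelength estimates one secondary-structure fraction, nothing more.

## Spectral features

`peak_max()` is a plain arg-max on the grid (ties to the shorter
wavelength, boundary maxima flagged) — scan increments of 1-10 nm do not
support sub-grid claims. `shift_report()` tracks the emission maximum along
the ladder; net shifts under 1 nm are classified as no shift.
`sfs_slice()` cuts S(λ~ex~) = EEM(λ~ex~, λ~ex~ + Δλ) with linear
interpolation on the emission axis; Δλ = 15 nm is the tyrosine channel,
60 nm the tryptophan channel, and `sfs_attribution()` compares the
quench fractions 1 − S(q~max~)/S(0) at the ligand-free slice maximum
(difference below 0.02 → "mixed"). `eem_peaks()` masks the Rayleigh ridge
(|λ~em~ − λ~ex~| < 20 nm) and returns intensity-sorted grid-local maxima
with their geometric Stokes differences λ~em~ − λ~ex~ in nm.

# The synthetic world

The generators state, once, the world the estimators are tested in:

- `gen_quench_titration()`: a Gaussian emission band (centre 348 nm, sd
  25 nm, the albumin tryptophan band) whose peak follows F₀/(1 + K~SV~q)
  or F₀/(1 + Kqⁿ) on the 11-point ladder 0–1e-4 mol/L in 1e-5 steps. Band
  shape is irrelevant to the fitted constants because the estimators read a
  single wavelength. The centre can drift linearly (the complexation blue
  shift); quantitative-recovery presets use zero drift, shift demonstrations
  use −6 nm. Noise is multiplicative Gaussian (detector-like), seed
  mandatory when active.
- `gen_uv_series()`: the 1:1 isotherm with A0 = 0.5, Ac = 0.6,
  K~b~ = 7.12e5 on the ladder 1e-7–4e-7 M; additive noise.
- `gen_cd()`: MRE is a convex helix/coil mixture. The helix basis is a
  smooth double minimum at 208/222 nm scaled to MRE(208) = −33000 exactly;
  the coil basis is a broad shallow band with MRE(208) = −4000 exactly. The
  anchors make the 208-nm formula return 100·h for helix fraction h by
  construction, so the CD round trip is exact — a consistency check of the
  formula chain, not evidence about real deconvolution accuracy. Additive
  noise in mdeg.
- `gen_eem()`: anisotropic Gaussian peaks on the 10-nm scan grids
  (ex 200–500, em 200–600 nm). The free preset has peaks at
  (280, 348) and (230, 340) with amplitudes 4500 and 2218; the complex
  preset 3791/1750 with the backbone peak emission moved to 330 nm.
- `make_study_fixtures()` writes clean and 1%-noise versions of everything
  plus a JSON manifest of generating constants.

What a green test establishes: that the estimators invert their stated
forward models exactly at zero noise, remain within stated error at 1%
noise, and reproduce published constants when fed the published inputs.
What it does not establish: robustness to real-instrument artifacts the
generators deliberately omit — inner-filter effects (none are simulated,
and no correction is applied), Raman scatter, baseline drift, wavelength
miscalibration, or deviations from Gaussian band shapes.

# Numerical choices

- All linear fits are `stats::lm`; the tests compare them against an
  explicit normal-equation solver at 1e-10 relative on ≤ 12 points.
- Stored results keep full double precision; rounding to 2 decimals happens
  only in `render_report()`. Structured JSON uses 17 significant digits so
  write→read round-trips are bit-identical.
- The Stern-Volmer fit accepts two points total (the q = 0 row enters the
  regression as y = 1); residual SD is 0 by convention when there are no
  residual degrees of freedom.
- `stern_volmer_fit` returns K~SV~ = 0 with a warning when nothing quenches,
  and flags negative slopes as anti-quenching rather than failing.
- Degenerate inputs fail loudly at construction: non-monotone wavelength
  axes, ladders not starting at 0, flat reference spectra, non-positive
  binding constants.

# Limitations

Modified (Lehrer) Stern-Volmer analysis, fluorescence lifetime fitting,
FRET distances, curved Van't Hoff, bootstrap error propagation, PARAFAC
decomposition of EEMs and multi-component CD deconvolution are all out of
scope. The package trusts its inputs to be background-subtracted,
inner-filter-corrected spectra.

# A worked run

```{r, eval = FALSE}
dir <- tempfile(); out <- tempfile()
make_study_fixtures(dir, seed = 1)
bundle <- run_study(study_config(
  quench_titrations = c("293" = file.path(dir, "quench_dl_293K_clean.csv"),
                        "298" = file.path(dir, "quench_dl_298K_clean.csv"),
                        "303" = file.path(dir, "quench_dl_303K_clean.csv")),
  displacement_free = file.path(dir, "displacement_free.csv"),
  displacement_probes = c(warfarin = file.path(dir, "displacement_warfarin.csv"),
                          ibuprofen = file.path(dir, "displacement_ibuprofen.csv")),
  uv_pairs = file.path(dir, "uv_clean.csv"), uv_A0 = 0.5,
  cd_free = file.path(dir, "cd_free_clean.csv"),
  cd_complex = file.path(dir, "cd_complex_clean.csv"),
  out_dir = out))
bundle$conclusions
```
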