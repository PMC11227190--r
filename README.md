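# specbind

Protein–ligand binding analysis from titration spectroscopy, in R.

When a small molecule binds a transport protein such as serum albumin, the
protein's intrinsic fluorescence is quenched, its UV absorbance grows and
its far-UV CD loses helical signal. Each experiment has a classical
linearised estimator, and `specbind` implements the full chain for
spectroscopists who run such titrations:

- **Stern–Volmer quenching**: F₀/F = 1 + K_SV[Q] = 1 + k_q τ₀[Q], fitted by
  OLS; mechanism classification (static vs dynamic) from the temperature
  trend of K_SV and the diffusion limit on k_q.
- **Double-log binding isotherm**: lg[(F₀−F)/F] = lg K + n lg[Q], giving the
  binding constant K and site number n.
- **Van't Hoff thermodynamics**: ln K = −ΔH/(RT) + ΔS/R and ΔG = ΔH − TΔS,
  with Ross–Subramanian classification of the dominant force from the
  (ΔH, ΔS) signs.
- **Site-marker displacement**: K_SV with/without warfarin (site I) or
  ibuprofen (site II); competition called below a 0.7 K_SV ratio.
- **UV Benesi–Hildebrand**: 1/(A_obs−A₀) vs 1/[L] double-reciprocal fit,
  K_b = intercept/slope, with a nonlinear-isotherm cross-check.
- **CD helix content**: MRE = θ_obs/(10 n l C_p) and
  α-helix % = 100·(−MRE₂₀₈ − 4000)/29000 for free vs complexed protein.
- **Spectral features**: emission-maximum shift tracking, synchronous
  fluorescence slices (Δλ = 15/60 nm, Tyr/Trp channels) with residue
  attribution, and EEM peak picking with Rayleigh-ridge masking.
- **Synthetic generators** (`gen_quench_titration`, `gen_uv_series`,
  `gen_cd`, `gen_eem`, `make_study_fixtures`) forward-model every input, so
  each estimator is testable by exact parameter recovery.

## Worked example

Generate the bundled study fixtures (the oseltamivir-phosphate /
bovine-serum-albumin constants) and run the whole pipeline:

```r
library(specbind)
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
print(bundle)
```

prints (abridged):

```
## Binding constants and thermodynamics

| T (K) | K (10^4 L/mol) | R | n | SD | dG (kJ/mol) | dS (J/mol/K) | dH (kJ/mol) |
|---|---|---|---|---|---|---|---|
| 293 | 4.03 | 1.00 | 1.28 | 0.00 | -25.73 | -177.07 | -77.62 |
| 298 | 2.09 | 1.00 | 1.24 | 0.00 | -24.85 | -177.07 | -77.62 |
| 303 | 1.41 | 1.00 | 1.22 | 0.00 | -23.96 | -177.07 | -77.62 |

## Site-marker displacement

| probe | K_SV free | K_SV with probe | ratio | competes |
|---|---|---|---|---|
| warfarin | 3.06e+03 | 715 | 0.23 | yes |
| ibuprofen | 3.06e+03 | 3.26e+03 | 1.07 | no |

## UV binding constant

K_b = 7.12 x 10^5 1/M (R = 1.00, A0 = 0.5, Ac = 0.6)

## Circular dichroism

Alpha-helix: free 48.08%, complex 40.95% (delta -7.13 points)

## Conclusions

- Fluorescence quenching is static.
- The binding-site number is close to 1 (a single site).
- The ligand competes with warfarin: binding near site I.
- No competition with ibuprofen.
- Dominant interaction forces: hydrogen bonding and van der Waals.
- Binding is spontaneous (dG < 0 at all temperatures).
- Alpha-helix content decreased on complexation (48.08% to 40.95%).
```

Read: the binding constant falls from 4.03×10⁴ to 1.41×10⁴ L/mol between
293 and 303 K (a ground-state complex dissociating on heating → static
quenching), one binding site, both ΔH and ΔS negative → hydrogen bonding
and van der Waals contacts drive binding, the warfarin probe is displaced
(site I, subdomain IIA), and complexation costs the protein about 7
percentage points of α-helix.

Each stage is also available alone: `stern_volmer_fit()`,
`double_log_fit()`, `classify_mechanism()`, `displacement_call()`,
`vant_hoff_fit()`, `benesi_hildebrand_fit()`, `helix_change()`,
`shift_report()`, `sfs_attribution()`, `eem_peaks()`. See the vignette in
`vignettes/binding-spectroscopy.Rmd` for models, assumptions and numerical
choices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the noiseless UV and CD presets from scratch with the installed
package, refits them (`benesi_hildebrand_fit` on the 1:1 isotherm ladder;
θ(208 nm) → MRE → helix % for the free and complexed CD spectra) and writes
the recovered constants as JSON.
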