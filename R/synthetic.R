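## Forward-model generators. Every estimator in the package has a matching
## generator here so parameter recovery can be tested; the "study presets"
## bundle the constants of the serum-albumin / oseltamivir-phosphate study
## the package ships as its worked example.

## run expr with a local RNG state seeded by `seed` (NULL = no randomness
## allowed downstream); restores the caller's .Random.seed
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic fluorescence quenching titration
#'
#' Each spectrum is a Gaussian emission band whose peak intensity follows the
#' chosen quenching law: `"sv_linear"` gives F = F0 / (1 + K_SV q) (the
#' linear Stern-Volmer law), `"double_log"` gives F = F0 / (1 + K q^n) (the
#' law whose log-log linearisation yields K and n). The band centre can drift
#' linearly across the ladder to emulate the blue shift seen on complexation;
#' noise is multiplicative Gaussian (detector-like), applied per sample
#' point.
#'
#' @param q_ladder Quencher molarities, starting at 0; default the 11-point
#'   ladder 0 to 1e-4 mol/L in 1e-5 steps used by the worked example.
#' @param law `"sv_linear"` or `"double_log"`.
#' @param K_SV Stern-Volmer constant (L/mol) for `law = "sv_linear"`.
#' @param K,n Binding constant (L/mol) and site number for
#'   `law = "double_log"`.
#' @param F0_peak Unquenched peak intensity (arbitrary units).
#' @param lambda0_nm Band centre of the ligand-free spectrum; default 348 nm,
#'   the serum-albumin tryptophan emission maximum.
#' @param band_sigma_nm Gaussian band width (sd); default 25 nm.
#' @param shift_total_nm Signed drift of the band centre from the first to
#'   the last spectrum (negative = blue shift); default 0.
#' @param temperature_K Temperature recorded on the series.
#' @param axis_nm Wavelength axis; default 300-500 nm in 1-nm steps.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   noise; 0 disables noise.
#' @param seed RNG seed, mandatory when `noise_cv > 0`; the caller's RNG
#'   state is left untouched.
#' @param kind Spectrum kind to stamp on the output (default `"emission"`;
#'   use `"synchronous"` to emulate constant-offset scans).
#' @return A [titration_series()].
#' @export
gen_quench_titration <- function(q_ladder = seq(0, 1e-4, by = 1e-5),
                                 law = c("sv_linear", "double_log"),
                                 K_SV = NULL, K = NULL, n = NULL,
                                 F0_peak = 1000, lambda0_nm = 348,
                                 band_sigma_nm = 25, shift_total_nm = 0,
                                 temperature_K = 298,
                                 axis_nm = seq(300, 500, by = 1),
                                 noise_cv = 0, seed = NULL,
                                 kind = "emission") {
  law <- match.arg(law)
  if (F0_peak <= 0) stop("gen_quench_titration: F0_peak must be positive",
                         call. = FALSE)
  if (noise_cv < 0) stop("gen_quench_titration: noise_cv must be >= 0",
                         call. = FALSE)
  if (noise_cv > 0 && is.null(seed))
    stop("gen_quench_titration: seed is mandatory when noise_cv > 0",
         call. = FALSE)
  peak <- switch(law,
    sv_linear = {
      if (is.null(K_SV) || K_SV < 0)
        stop("gen_quench_titration: sv_linear law needs K_SV >= 0", call. = FALSE)
      F0_peak / (1 + K_SV * q_ladder)
    },
    double_log = {
      if (is.null(K) || is.null(n) || K <= 0 || n <= 0)
        stop("gen_quench_titration: double_log law needs K > 0 and n > 0",
             call. = FALSE)
      F0_peak / (1 + K * q_ladder^n)
    })
  m <- length(q_ladder)
  centre <- lambda0_nm + shift_total_nm * (seq_len(m) - 1) / max(1L, m - 1L)
  .with_seed(seed, {
    spectra <- lapply(seq_len(m), function(i) {
      sig <- peak[i] * exp(-(axis_nm - centre[i])^2 / (2 * band_sigma_nm^2))
      if (noise_cv > 0)
        sig <- sig * (1 + stats::rnorm(length(sig), sd = noise_cv))
      spectrum(axis_nm, sig, kind)
    })
    titration_series(spectra, q_ladder, temperature_K,
                     meta = list(generator = "gen_quench_titration", law = law))
  })
}

#' Generate a synthetic UV absorbance titration
#'
#' Absorbances follow the 1:1 binding isotherm
#' A = A0 + (Ac - A0) Kb q / (1 + Kb q), with additive Gaussian noise.
#' Defaults are the worked example's UV preset: A0 = 0.5, Ac = 0.6,
#' Kb = 7.12e5 1/M on the ladder 1e-7 to 4e-7 mol/L.
#'
#' @param op_ladder Ligand molarities (may include 0, which returns A0).
#' @param A0 Free-protein absorbance.
#' @param Ac Saturated-complex absorbance (`Ac != A0`).
#' @param K_b Intrinsic binding constant (1/M), positive.
#' @param noise_sd Additive Gaussian noise sd in absorbance units.
#' @param seed RNG seed, mandatory when `noise_sd > 0`.
#' @return A data frame `(op_molar, a_obs)`.
#' @export
gen_uv_series <- function(op_ladder = seq(1e-7, 4e-7, by = 1e-7),
                          A0 = 0.5, Ac = 0.6, K_b = 7.12e5,
                          noise_sd = 0, seed = NULL) {
  if (Ac == A0) stop("gen_uv_series: Ac must differ from A0", call. = FALSE)
  if (K_b <= 0) stop("gen_uv_series: K_b must be positive", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("gen_uv_series: seed is mandatory when noise_sd > 0", call. = FALSE)
  A <- A0 + (Ac - A0) * K_b * op_ladder / (1 + K_b * op_ladder)
  .with_seed(seed, {
    if (noise_sd > 0) A <- A + stats::rnorm(length(A), sd = noise_sd)
    data.frame(op_molar = op_ladder, a_obs = A)
  })
}

## Smooth two-component CD basis curves, anchored exactly at 208 nm:
## basis_helix(208) = -33000, basis_coil(208) = -4000, so a mixture with
## helix fraction h has MRE(208) = -4000 - 29000 h and the 208-nm helix
## formula returns exactly 100 h.
cd_basis_helix <- function(lambda_nm) {
  g <- function(l, mu, s) exp(-(l - mu)^2 / (2 * s^2))
  raw <- function(l) g(l, 208, 7) + 0.95 * g(l, 222, 8)
  -33000 * raw(lambda_nm) / raw(208)
}

cd_basis_coil <- function(lambda_nm) {
  g <- function(l, mu, s) exp(-(l - mu)^2 / (2 * s^2))
  -4000 * g(lambda_nm, 200, 18) / g(208, 200, 18)
}

#' Generate a synthetic CD spectrum of a helix/coil mixture
#'
#' The mean-residue-ellipticity trace is a convex mixture of a helix basis
#' (double minimum at 208 and 222 nm, MRE(208) = -33000) and a coil basis
#' (MRE(208) = -4000); the observed ellipticity is then
#' theta = MRE x 10 n l Cp plus additive noise in mdeg. By construction the
#' 208-nm helix formula recovers `100 * helix_fraction` exactly at zero
#' noise.
#'
#' @param helix_fraction Helix fraction h in \[0, 1\].
#' @param config A [cd_config()] (residue count, path length, molarity).
#' @param wavelength_nm Wavelength grid; default 200-260 nm in 0.5-nm steps.
#' @param noise_sd_mdeg Additive Gaussian noise sd in mdeg.
#' @param seed RNG seed, mandatory when `noise_sd_mdeg > 0`.
#' @return A [spectrum()] of kind `"cd_mdeg"`.
#' @export
gen_cd <- function(helix_fraction, config = cd_config(),
                   wavelength_nm = seq(200, 260, by = 0.5),
                   noise_sd_mdeg = 0, seed = NULL) {
  if (helix_fraction < 0 || helix_fraction > 1)
    stop("gen_cd: helix_fraction must lie in [0, 1]", call. = FALSE)
  stopifnot(inherits(config, "cd_config"))
  if (noise_sd_mdeg > 0 && is.null(seed))
    stop("gen_cd: seed is mandatory when noise_sd_mdeg > 0", call. = FALSE)
  mre_trace <- helix_fraction * cd_basis_helix(wavelength_nm) +
    (1 - helix_fraction) * cd_basis_coil(wavelength_nm)
  theta <- mre_trace * 10 * config$n_residues * config$path_cm * config$Cp_molar
  .with_seed(seed, {
    if (noise_sd_mdeg > 0)
      theta <- theta + stats::rnorm(length(theta), sd = noise_sd_mdeg)
    spectrum(wavelength_nm, theta, "cd_mdeg")
  })
}

#' Generate a synthetic excitation-emission matrix
#'
#' Sum of anisotropic Gaussian peaks on a rectangular scan grid, optionally
#' with a Rayleigh scatter ridge along lambda_em = lambda_ex and additive
#' noise.
#'
#' @param peaks Data frame with columns `ex_nm`, `em_nm`, `amplitude`, and
#'   optionally `ex_sigma`, `em_sigma` (defaults 15 and 20 nm). An empty
#'   frame yields a zero matrix.
#' @param ex_nm Excitation grid; default 200-500 nm, 10-nm increment.
#' @param em_nm Emission grid; default 200-600 nm, 10-nm increment.
#' @param rayleigh_amplitude Amplitude of a scatter ridge along the diagonal
#'   (sd 6 nm); default 0 (no ridge).
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed RNG seed, mandatory when `noise_sd > 0`.
#' @return An [eem()].
#' @export
gen_eem <- function(peaks, ex_nm = seq(200, 500, by = 10),
                    em_nm = seq(200, 600, by = 10),
                    rayleigh_amplitude = 0, noise_sd = 0, seed = NULL) {
  if (noise_sd > 0 && is.null(seed))
    stop("gen_eem: seed is mandatory when noise_sd > 0", call. = FALSE)
  z <- matrix(0, length(ex_nm), length(em_nm))
  if (nrow(peaks)) {
    if (any(peaks$ex_nm < min(ex_nm) | peaks$ex_nm > max(ex_nm) |
            peaks$em_nm < min(em_nm) | peaks$em_nm > max(em_nm)))
      stop("gen_eem: peak centres must lie inside the scan grids", call. = FALSE)
    if (is.null(peaks$ex_sigma)) peaks$ex_sigma <- 15
    if (is.null(peaks$em_sigma)) peaks$em_sigma <- 20
    for (k in seq_len(nrow(peaks))) {
      z <- z + peaks$amplitude[k] *
        outer(exp(-(ex_nm - peaks$ex_nm[k])^2 / (2 * peaks$ex_sigma[k]^2)),
              exp(-(em_nm - peaks$em_nm[k])^2 / (2 * peaks$em_sigma[k]^2)))
    }
  }
  if (rayleigh_amplitude > 0) {
    z <- z + rayleigh_amplitude *
      outer(ex_nm, em_nm, function(ex, em) exp(-(em - ex)^2 / (2 * 6^2)))
  }
  .with_seed(seed, {
    if (noise_sd > 0)
      z <- z + matrix(stats::rnorm(length(z), sd = noise_sd),
                      nrow(z), ncol(z))
    eem(ex_nm, em_nm, z)
  })
}

#' Study presets: the constants of the worked serum-albumin example
#'
#' Bundles the published constants of the oseltamivir-phosphate /
#' bovine-serum-albumin study that the package reproduces end to end:
#' Stern-Volmer constants at three temperatures, double-log binding constants
#' and site numbers, site-marker displacement constants at 303 K, the UV
#' isotherm parameters, the CD helix states, and the two-peak EEM geometries
#' of the free protein and the complex.
#'
#' @return A nested list of generating constants.
#' @export
study_presets <- function() {
  list(
    q_ladder = seq(0, 1e-4, by = 1e-5),
    tau0_s = 1e-8,
    quench = list(
      "293" = list(K_SV = 3.06e3, K = 4.03e4, n = 1.28),
      "298" = list(K_SV = 2.36e3, K = 2.09e4, n = 1.24),
      "303" = list(K_SV = 1.86e3, K = 1.41e4, n = 1.22)
    ),
    displacement = list(temperature_K = 303, ksv_free = 3.06e3,
                        ksv_ibuprofen = 3.26e3, ksv_warfarin = 7.15e2),
    uv = list(A0 = 0.5, Ac = 0.6, K_b = 7.12e5,
              op_ladder = seq(1e-7, 4e-7, by = 1e-7)),
    cd = list(helix_free = 0.4808, helix_complex = 0.4095,
              n_residues = 583, path_cm = 0.1, Cp_molar = 1e-6),
    eem = list(
      free = data.frame(ex_nm = c(280, 230), em_nm = c(348, 340),
                        amplitude = c(4500, 2218)),
      complex = data.frame(ex_nm = c(280, 230), em_nm = c(348, 330),
                           amplitude = c(3791, 1750))
    )
  )
}

#' Write the full synthetic fixture set for the worked example
#'
#' Generates noiseless and low-noise versions of every input the pipeline
#' consumes — three-temperature quench titrations under both quenching laws,
#' probe-displacement quench tables, the UV pairs, free/complex CD spectra
#' and free/complex EEMs — using the [study_presets()] constants, and writes
#' them as the package's delimited-text formats plus a JSON manifest of all
#' generating parameters.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Seed for the low-noise variants.
#' @param noise_cv Coefficient of variation for the low-noise fluorescence
#'   variants (additive-noise sds for UV/CD are scaled analogously);
#'   default 0.01.
#' @return Invisibly, a character vector of the files written.
#' @export
make_study_fixtures <- function(out_dir, seed = 1, noise_cv = 0.01) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- study_presets()
  written <- character(0)
  put <- function(fname) { f <- file.path(out_dir, fname); written <<- c(written, f); f }

  i <- 0L
  for (tt in names(p$quench)) {
    cfg <- p$quench[[tt]]
    for (nz in c(FALSE, TRUE)) {
      i <- i + 1L
      tag <- if (nz) "noisy" else "clean"
      sv <- gen_quench_titration(q_ladder = p$q_ladder, law = "sv_linear",
                                 K_SV = cfg$K_SV,
                                 temperature_K = as.numeric(tt),
                                 noise_cv = if (nz) noise_cv else 0,
                                 seed = if (nz) seed + i else NULL)
      write_titration(sv, put(sprintf("quench_sv_%sK_%s.csv", tt, tag)))
      dl <- gen_quench_titration(q_ladder = p$q_ladder, law = "double_log",
                                 K = cfg$K, n = cfg$n,
                                 temperature_K = as.numeric(tt),
                                 noise_cv = if (nz) noise_cv else 0,
                                 seed = if (nz) seed + 100L + i else NULL)
      write_titration(dl, put(sprintf("quench_dl_%sK_%s.csv", tt, tag)))
    }
  }

  # displacement: quench tables generated from the 303 K constants
  d <- p$displacement
  for (nm in c("free", "ibuprofen", "warfarin")) {
    ksv <- switch(nm, free = d$ksv_free, ibuprofen = d$ksv_ibuprofen,
                  warfarin = d$ksv_warfarin)
    ser <- gen_quench_titration(q_ladder = p$q_ladder, law = "sv_linear",
                                K_SV = ksv, temperature_K = d$temperature_K)
    write_quench_table(extract_quench_table(ser),
                       put(sprintf("displacement_%s.csv", nm)))
  }

  uv0 <- gen_uv_series(op_ladder = p$uv$op_ladder, A0 = p$uv$A0, Ac = p$uv$Ac,
                       K_b = p$uv$K_b)
  .write_csv_full(uv0, put("uv_clean.csv"))
  uvn <- gen_uv_series(op_ladder = p$uv$op_ladder, A0 = p$uv$A0, Ac = p$uv$Ac,
                       K_b = p$uv$K_b, noise_sd = noise_cv * 0.02,
                       seed = seed + 201L)
  .write_csv_full(uvn, put("uv_noisy.csv"))

  cdc <- cd_config(p$cd$n_residues, p$cd$path_cm, p$cd$Cp_molar)
  write_cd(gen_cd(p$cd$helix_free, cdc), put("cd_free_clean.csv"))
  write_cd(gen_cd(p$cd$helix_complex, cdc), put("cd_complex_clean.csv"))
  write_cd(gen_cd(p$cd$helix_free, cdc, noise_sd_mdeg = noise_cv,
                  seed = seed + 301L), put("cd_free_noisy.csv"))
  write_cd(gen_cd(p$cd$helix_complex, cdc, noise_sd_mdeg = noise_cv,
                  seed = seed + 302L), put("cd_complex_noisy.csv"))

  write_eem(gen_eem(p$eem$free), put("eem_free.csv"))
  write_eem(gen_eem(p$eem$complex), put("eem_complex.csv"))

  manifest <- list(presets = p, seed = seed, noise_cv = noise_cv,
                   files = basename(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, file.path(out_dir, "manifest.json"))
  invisible(written)
}
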