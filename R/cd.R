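#' Circular-dichroism measurement configuration
#'
#' Parameters that normalise an observed ellipticity (mdeg) to mean residue
#' ellipticity: MRE = theta / (10 n l Cp).
#'
#' @param n_residues Number of amino-acid residues of the protein; default
#'   583, mature bovine serum albumin.
#' @param path_cm Optical path length of the cuvette in cm; default 0.1
#'   (a 1-mm cell), so MRE lands in the deg cm^2/dmol range where the
#'   helix-formula anchors (-4000, -33000) apply.
#' @param Cp_molar Protein molar concentration (mol/L); default 1e-6.
#' @return An object of class `cd_config`.
#' @export
cd_config <- function(n_residues = 583, path_cm = 0.1, Cp_molar = 1e-6) {
  if (n_residues <= 0 || path_cm <= 0 || Cp_molar <= 0)
    stop("cd_config: all parameters must be positive", call. = FALSE)
  structure(list(n_residues = n_residues, path_cm = path_cm,
                 Cp_molar = Cp_molar), class = "cd_config")
}

#' Mean residue ellipticity from an observed ellipticity
#'
#' MRE = theta_obs(mdeg) / (10 n l Cp), in deg cm^2/dmol. Linear in theta
#' and inverse-linear in each of n, l, Cp.
#'
#' @param theta_mdeg Observed ellipticity in millidegrees (scalar or vector).
#' @param config A [cd_config()].
#' @return Mean residue ellipticity, same length as `theta_mdeg`.
#' @export
mre <- function(theta_mdeg, config = cd_config()) {
  stopifnot(inherits(config, "cd_config"))
  theta_mdeg / (10 * config$n_residues * config$path_cm * config$Cp_molar)
}

#' Alpha-helix percentage from the 208-nm mean residue ellipticity
#'
#' helix \% = 100 (-MRE208 - 4000) / (33000 - 4000), the single-wavelength
#' estimator anchored at MRE208 = -4000 for pure coil and -33000 for pure
#' helix. Values outside \[0, 100\] are returned unclamped with attribute
#' `out_of_range = TRUE`.
#'
#' @param mre_208 Mean residue ellipticity at 208 nm (deg cm^2/dmol).
#' @return Helix percentage (possibly flagged out of range).
#' @export
helix_percent <- function(mre_208) {
  if (!all(is.finite(mre_208)))
    stop("helix_percent: mre_208 must be finite", call. = FALSE)
  pct <- 100 * (-mre_208 - 4000) / (33000 - 4000)
  if (any(pct < 0 | pct > 100)) {
    warning("helix_percent: value outside [0, 100]; returned unclamped and flagged")
    attr(pct, "out_of_range") <- TRUE
  }
  pct
}

#' Ellipticity of a spectrum at one wavelength (linear interpolation)
#' @param spec A [spectrum()].
#' @param lambda_nm Wavelength to evaluate at; must lie inside the axis.
#' @return Interpolated signal value.
#' @export
theta_at <- function(spec, lambda_nm) {
  stopifnot(inherits(spec, "spectrum"))
  if (lambda_nm < min(spec$axis_nm) || lambda_nm > max(spec$axis_nm))
    stop(sprintf("theta_at: %g nm outside the spectrum axis [%g, %g]",
                 lambda_nm, min(spec$axis_nm), max(spec$axis_nm)),
         call. = FALSE)
  stats::approx(spec$axis_nm, spec$signal, xout = lambda_nm)$y
}

#' Helix-content change between free and complexed protein
#'
#' Reads theta at 208 nm from each CD trace by linear interpolation, converts
#' to mean residue ellipticity, and applies the 208-nm helix formula to both.
#'
#' @param spectrum_free CD [spectrum()] (kind `"cd_mdeg"`) of the free
#'   protein; must cover 208 nm.
#' @param spectrum_complex CD spectrum of the protein-ligand complex.
#' @param config A [cd_config()] shared by both measurements.
#' @return An object of class `cd_result`: `helix_free`, `helix_complex`,
#'   `delta` (complex minus free, percentage points), plus the underlying
#'   `theta_208_mdeg` and `mre_208` pairs.
#' @export
helix_change <- function(spectrum_free, spectrum_complex, config = cd_config()) {
  stopifnot(inherits(spectrum_free, "spectrum"),
            inherits(spectrum_complex, "spectrum"))
  th_f <- theta_at(spectrum_free, 208)
  th_c <- theta_at(spectrum_complex, 208)
  mre_f <- mre(th_f, config)
  mre_c <- mre(th_c, config)
  h_f <- helix_percent(mre_f)
  h_c <- helix_percent(mre_c)
  structure(list(helix_free = as.numeric(h_f), helix_complex = as.numeric(h_c),
                 delta = as.numeric(h_c) - as.numeric(h_f),
                 theta_208_mdeg = c(free = th_f, complex = th_c),
                 mre_208 = c(free = mre_f, complex = mre_c),
                 config = unclass(config)),
            class = "cd_result")
}

#' @export
print.cd_result <- function(x, ...) {
  cat(sprintf("Alpha-helix content: free %.2f%%, complex %.2f%% (delta %+.2f points)\n",
              x$helix_free, x$helix_complex, x$delta))
  invisible(x)
}
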