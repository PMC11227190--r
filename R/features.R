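#' Locate the maximum of a spectrum within a wavelength window
#'
#' Plain arg-max over the sampled grid — no sub-grid refinement, since typical
#' scan increments do not support finer claims. Ties are broken toward the
#' shorter wavelength and flagged ambiguous; a maximum sitting on the window
#' boundary is flagged, because the true band may lie outside.
#'
#' @param spec A [spectrum()].
#' @param window_nm Optional `c(lo, hi)` window; default the full axis.
#' @return An object of class `peak_call`: `lambda_nm`, `intensity`,
#'   `prominence` (intensity as a fraction of the window maximum of
#'   `abs(signal)` — 1 at the peak itself), `ambiguous`, `at_boundary`.
#' @export
peak_max <- function(spec, window_nm = NULL) {
  stopifnot(inherits(spec, "spectrum"))
  axis <- spec$axis_nm
  keep <- if (is.null(window_nm)) rep(TRUE, length(axis)) else {
    if (length(window_nm) != 2L || window_nm[1L] >= window_nm[2L])
      stop("peak_max: window_nm must be c(lo, hi)", call. = FALSE)
    axis >= window_nm[1L] & axis <= window_nm[2L]
  }
  if (!any(keep))
    stop("peak_max: window does not intersect the axis", call. = FALSE)
  wl <- axis[keep]; sig <- spec$signal[keep]
  i <- which.max(sig)                      # first max = shortest wavelength
  ambiguous <- sum(sig == sig[i]) > 1L
  structure(list(lambda_nm = wl[i], intensity = sig[i],
                 prominence = if (max(abs(sig)) > 0) sig[i] / max(abs(sig)) else NA_real_,
                 ambiguous = ambiguous,
                 at_boundary = i == 1L || i == length(wl)),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("<peak %.1f nm, intensity %.4g%s%s>\n", x$lambda_nm, x$intensity,
              if (x$ambiguous) ", ambiguous" else "",
              if (x$at_boundary) ", at window boundary" else ""))
  invisible(x)
}

#' Emission-maximum shift across a titration
#'
#' Tracks the emission-maximum wavelength of each spectrum along the quencher
#' ladder. The net shift is the last minus the first maximum (negative =
#' blue shift, toward shorter wavelengths, the signature of a fluorophore
#' microenvironment becoming more hydrophobic).
#'
#' @param series A [titration_series()].
#' @param threshold_nm Shifts smaller in magnitude than this are classified
#'   `"none"`; default 1 nm.
#' @param window_nm Optional window passed to [peak_max()].
#' @return An object of class `shift_report`: `lambda_max_nm` (per-q trace),
#'   `q_molar`, `net_shift_nm`, `classification` (`"blue"`, `"red"`,
#'   `"none"`), `threshold_nm`.
#' @export
shift_report <- function(series, threshold_nm = 1, window_nm = NULL) {
  stopifnot(inherits(series, "titration_series"))
  lam <- vapply(series$spectra,
                function(s) peak_max(s, window_nm)$lambda_nm, numeric(1))
  net <- lam[length(lam)] - lam[1L]
  cls <- if (abs(net) < threshold_nm) "none" else if (net < 0) "blue" else "red"
  structure(list(lambda_max_nm = lam, q_molar = series$q_molar,
                 net_shift_nm = net, classification = cls,
                 threshold_nm = threshold_nm),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("Emission-maximum shift: %+.2f nm across the ladder => %s (threshold %g nm)\n",
              x$net_shift_nm, x$classification, x$threshold_nm))
  invisible(x)
}

#' Synchronous-fluorescence slice of an excitation-emission matrix
#'
#' Extracts S(lambda_ex) = EEM(lambda_ex, lambda_ex + delta_lambda), the
#' constant-offset scan. Offsets of 15 nm and 60 nm select the tyrosine and
#' tryptophan channels respectively. Emission values off the grid are
#' obtained by linear interpolation along the emission axis.
#'
#' @param x An [eem()].
#' @param delta_lambda_nm Fixed offset lambda_em - lambda_ex in nm.
#' @return A [spectrum()] of kind `"synchronous"` whose axis is the
#'   excitation grid (restricted to points where lambda_ex + delta lies on
#'   the emission grid).
#' @export
sfs_slice <- function(x, delta_lambda_nm) {
  stopifnot(inherits(x, "eem"))
  target <- x$ex_nm + delta_lambda_nm
  ok <- target >= min(x$em_nm) & target <= max(x$em_nm)
  if (sum(ok) < 3L)
    stop("sfs_slice: fewer than 3 excitation points fall on the emission grid at this offset",
         call. = FALSE)
  vals <- vapply(which(ok), function(i) {
    stats::approx(x$em_nm, x$intensity[i, ], xout = target[i])$y
  }, numeric(1))
  spectrum(x$ex_nm[ok], vals, "synchronous")
}

#' Residue attribution from paired synchronous-fluorescence titrations
#'
#' Compares quenching depth in the tyrosine (offset 15 nm) and tryptophan
#' (offset 60 nm) synchronous channels. For each channel the quench fraction
#' is 1 - S(q_max)/S(0), read at the wavelength of the ligand-free slice
#' maximum. A clearly deeper tryptophan-channel quench attributes the binding
#' perturbation to tryptophan residues, the reverse to tyrosine; fractions
#' within `tolerance` of each other are called mixed.
#'
#' @param series15 [titration_series()] of synchronous slices at offset 15 nm
#'   (tyrosine channel), or a bare numeric quench fraction.
#' @param series60 Same at offset 60 nm (tryptophan channel), or a bare
#'   numeric quench fraction.
#' @param tolerance Fraction difference below which the call is `"mixed"`;
#'   default 0.02.
#' @return An object of class `sfs_attribution`: `fraction15`, `fraction60`,
#'   `attribution` (`"tryptophan"`, `"tyrosine"`, `"mixed"`).
#' @export
sfs_attribution <- function(series15, series60, tolerance = 0.02) {
  f15 <- .quench_fraction(series15)
  f60 <- .quench_fraction(series60)
  attribution <- if (abs(f60 - f15) <= tolerance) "mixed"
                 else if (f60 > f15) "tryptophan" else "tyrosine"
  structure(list(fraction15 = f15, fraction60 = f60, tolerance = tolerance,
                 attribution = attribution),
            class = "sfs_attribution")
}

.quench_fraction <- function(x) {
  if (is.numeric(x) && length(x) == 1L) return(x)
  stopifnot(inherits(x, "titration_series"))
  ref <- x$spectra[[1L]]
  pk <- peak_max(ref)
  s0 <- pk$intensity
  if (s0 == 0)
    stop("sfs_attribution: zero baseline intensity at the slice maximum",
         call. = FALSE)
  idx <- match(pk$lambda_nm, ref$axis_nm)
  s_last <- x$spectra[[length(x$spectra)]]$signal[idx]
  1 - s_last / s0
}

#' @export
print.sfs_attribution <- function(x, ...) {
  cat(sprintf("SFS quench fractions: offset-15 %.3f (Tyr), offset-60 %.3f (Trp) => %s\n",
              x$fraction15, x$fraction60, x$attribution))
  invisible(x)
}

#' Peak picking on an excitation-emission matrix
#'
#' Finds grid-local maxima of the EEM after masking the first-order Rayleigh
#' scatter ridge (|lambda_em - lambda_ex| < `mask_width_nm`), and returns the
#' strongest `n_peaks` sorted by intensity. A cell is a local maximum when it
#' strictly exceeds zero and is >= all of its up-to-8 unmasked neighbours.
#'
#' @param x An [eem()].
#' @param n_peaks Number of peaks requested (>= 1).
#' @param mask_width_nm Half-width of the Rayleigh exclusion ridge; default
#'   20 nm.
#' @return A data frame with columns `ex_nm`, `em_nm`, `intensity`,
#'   `stokes_nm` (= em - ex), ordered by decreasing intensity. Fewer rows
#'   than `n_peaks` are returned, with a warning, when the surface has fewer
#'   maxima.
#' @export
eem_peaks <- function(x, n_peaks = 2, mask_width_nm = 20) {
  stopifnot(inherits(x, "eem"), n_peaks >= 1)
  nex <- length(x$ex_nm); nem <- length(x$em_nm)
  masked <- outer(x$ex_nm, x$em_nm, function(ex, em) abs(em - ex) < mask_width_nm)
  z <- x$intensity
  z[masked] <- NA_real_
  found <- list()
  for (i in seq_len(nex)) for (j in seq_len(nem)) {
    v <- z[i, j]
    if (is.na(v) || v <= 0) next
    nb <- z[max(1L, i - 1L):min(nex, i + 1L), max(1L, j - 1L):min(nem, j + 1L)]
    if (v >= max(nb, na.rm = TRUE)) {
      found[[length(found) + 1L]] <- c(x$ex_nm[i], x$em_nm[j], v)
    }
  }
  if (!length(found)) {
    warning("eem_peaks: no unmasked local maxima found")
    return(data.frame(ex_nm = numeric(0), em_nm = numeric(0),
                      intensity = numeric(0), stokes_nm = numeric(0)))
  }
  m <- do.call(rbind, found)
  out <- data.frame(ex_nm = m[, 1L], em_nm = m[, 2L], intensity = m[, 3L])
  out <- out[order(-out$intensity), , drop = FALSE]
  if (nrow(out) < n_peaks)
    warning(sprintf("eem_peaks: only %d of %d requested peaks found",
                    nrow(out), n_peaks))
  out <- utils::head(out, n_peaks)
  out$stokes_nm <- out$em_nm - out$ex_nm
  rownames(out) <- NULL
  out
}
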