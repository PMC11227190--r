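#' Construct a single spectrum
#'
#' A `spectrum` is a wavelength-indexed trace: fluorescence emission,
#' a synchronous-fluorescence slice, a UV absorbance scan, or a CD trace in
#' millidegrees.
#'
#' @param axis_nm Numeric wavelength grid in nanometres, strictly increasing,
#'   length >= 3. Values are band centres; no binning is assumed.
#' @param signal Numeric intensities on `axis_nm`: arbitrary fluorescence
#'   units, absorbance units, or mdeg depending on `kind`.
#' @param kind One of `"emission"`, `"synchronous"`, `"uv_absorbance"`,
#'   `"cd_mdeg"`.
#' @return An object of class `spectrum` with elements `axis_nm`, `signal`,
#'   `kind`.
#' @export
spectrum <- function(axis_nm, signal, kind = c("emission", "synchronous",
                                               "uv_absorbance", "cd_mdeg")) {
  kind <- match.arg(kind)
  axis_nm <- as.numeric(axis_nm)
  signal <- as.numeric(signal)
  if (length(axis_nm) < 3L)
    stop("spectrum: axis must have at least 3 points", call. = FALSE)
  if (length(axis_nm) != length(signal))
    stop("spectrum: axis and signal lengths differ", call. = FALSE)
  if (!all(is.finite(axis_nm)) || !all(is.finite(signal)))
    stop("spectrum: non-finite values in axis or signal", call. = FALSE)
  if (any(diff(axis_nm) <= 0))
    stop("spectrum: wavelength axis must be strictly increasing", call. = FALSE)
  structure(list(axis_nm = axis_nm, signal = signal, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum kind=%s, %d points, %.1f-%.1f nm>\n",
              x$kind, length(x$axis_nm), min(x$axis_nm), max(x$axis_nm)))
  invisible(x)
}

#' Construct a quencher titration series
#'
#' An ordered set of spectra recorded at one temperature along a ladder of
#' quencher (ligand) concentrations. The first spectrum must be the
#' ligand-free reference (q = 0); all spectra share one wavelength axis.
#'
#' @param spectra List of [spectrum()] objects, one per quencher level.
#' @param q_molar Quencher concentration per spectrum (mol/L); non-negative,
#'   strictly increasing, first entry 0.
#' @param temperature_K Temperature of the whole series (K).
#' @param meta Optional named list of free-text provenance.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(spectra, q_molar, temperature_K, meta = list()) {
  q_molar <- as.numeric(q_molar)
  if (!is.list(spectra) || !all(vapply(spectra, inherits, logical(1), "spectrum")))
    stop("titration_series: 'spectra' must be a list of spectrum objects",
         call. = FALSE)
  if (length(spectra) != length(q_molar))
    stop("titration_series: one spectrum per q value required", call. = FALSE)
  if (any(q_molar < 0) || any(diff(q_molar) <= 0))
    stop("titration_series: q_molar must be non-negative and strictly increasing",
         call. = FALSE)
  if (q_molar[1L] != 0)
    stop("titration_series: first q must be 0 (ligand-free reference)",
         call. = FALSE)
  axis <- spectra[[1L]]$axis_nm
  same <- vapply(spectra, function(s) length(s$axis_nm) == length(axis) &&
                   all(s$axis_nm == axis), logical(1))
  if (!all(same))
    stop("titration_series: all spectra must share one wavelength axis",
         call. = FALSE)
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("titration_series: temperature_K must be positive", call. = FALSE)
  structure(list(spectra = spectra, q_molar = q_molar,
                 temperature_K = as.numeric(temperature_K), meta = meta),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series: %d spectra, q = 0 .. %.3g mol/L, T = %g K>\n",
              length(x$spectra), max(x$q_molar), x$temperature_K))
  invisible(x)
}

#' Construct an excitation-emission matrix
#'
#' @param ex_nm Excitation wavelength grid (nm), strictly increasing.
#' @param em_nm Emission wavelength grid (nm), strictly increasing.
#' @param intensity Matrix of intensities, `length(ex_nm)` rows by
#'   `length(em_nm)` columns, all finite.
#' @return An object of class `eem`.
#' @export
eem <- function(ex_nm, em_nm, intensity) {
  ex_nm <- as.numeric(ex_nm); em_nm <- as.numeric(em_nm)
  intensity <- as.matrix(intensity)
  if (any(diff(ex_nm) <= 0) || any(diff(em_nm) <= 0))
    stop("eem: wavelength grids must be strictly increasing", call. = FALSE)
  if (nrow(intensity) != length(ex_nm) || ncol(intensity) != length(em_nm))
    stop("eem: intensity dimensions must match grids", call. = FALSE)
  if (!all(is.finite(intensity)))
    stop("eem: non-finite intensities", call. = FALSE)
  structure(list(ex_nm = ex_nm, em_nm = em_nm, intensity = intensity),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem: %d ex x %d em points>\n", length(x$ex_nm), length(x$em_nm)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Wide-CSV titration reader/writer
##
## Dialect: header `wavelength_nm,q=<molar>,q=<molar>,...`, q in scientific
## notation, UTF-8, '.' decimal separator.  Column order defines q order.
## ---------------------------------------------------------------------------

#' Read a fluorescence titration from a wide CSV file
#'
#' Expected header: `wavelength_nm,q=<molar>,q=<molar>,...` with one column
#' per quencher concentration (mol/L, scientific notation accepted). The
#' concentration ladder must start at 0 and increase strictly.
#'
#' @param path Path to the CSV file.
#' @param temperature_K Temperature to attach to the series (K); the file
#'   format does not carry it.
#' @return A [titration_series()].
#' @export
read_titration <- function(path, temperature_K = 298) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  if (nm[1L] != "wavelength_nm")
    stop(sprintf("read_titration: first column must be 'wavelength_nm', got '%s'",
                 nm[1L]), call. = FALSE)
  qcols <- nm[-1L]
  if (!all(grepl("^q=", qcols)))
    stop("read_titration: data columns must be labelled 'q=<molar>'",
         call. = FALSE)
  q <- suppressWarnings(as.numeric(sub("^q=", "", qcols)))
  if (any(is.na(q)))
    stop(sprintf("read_titration: non-numeric q label in column(s): %s",
                 paste(qcols[is.na(q)], collapse = ", ")), call. = FALSE)
  if (anyDuplicated(q))
    stop("read_titration: duplicated q labels", call. = FALSE)
  if (any(diff(q) <= 0))
    stop("read_titration: q columns must be in strictly increasing order",
         call. = FALSE)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]))
      stop(sprintf("read_titration: non-numeric cells in column '%s'", nm[j]),
           call. = FALSE)
    bad <- which(!is.finite(df[[j]]))
    if (length(bad))
      stop(sprintf("read_titration: non-finite value at row %d, column '%s'",
                   bad[1L], nm[j]), call. = FALSE)
  }
  wl <- df[[1L]]
  if (any(diff(wl) <= 0))
    stop("read_titration: wavelength axis must be strictly increasing",
         call. = FALSE)
  spectra <- lapply(seq_along(q), function(i) spectrum(wl, df[[i + 1L]], "emission"))
  titration_series(spectra, q, temperature_K, meta = list(source = path))
}

#' Write a titration series to the wide CSV dialect
#'
#' Inverse of [read_titration()]: full-precision floats, so
#' `read_titration(write_titration(x))` round-trips bit-identically.
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  df <- data.frame(wavelength_nm = series$spectra[[1L]]$axis_nm,
                   check.names = FALSE)
  for (i in seq_along(series$q_molar)) {
    df[[sprintf("q=%.17g", series$q_molar[i])]] <- series$spectra[[i]]$signal
  }
  .write_csv_full(df, path)
  invisible(path)
}

## centred running mean with shrinking windows at the edges
.running_mean <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) stop("smooth_pts must be odd", call. = FALSE)
  h <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

## full-precision CSV writer shared by all formats (17 significant digits
## guarantees double round-trip)
.write_csv_full <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(cbind, lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
}

## ---------------------------------------------------------------------------
## Quench table
## ---------------------------------------------------------------------------

#' Extract the quenching table from a titration series
#'
#' Locates the emission maximum of the ligand-free (q = 0) spectrum inside
#' `window_nm` and reads the intensity of every spectrum at that one fixed
#' wavelength. Reading at the fixed reference maximum (rather than
#' per-spectrum maxima) keeps a band shift from masquerading as quenching.
#'
#' The maximum is *located* on a short running-mean smooth of the reference
#' (`smooth_pts` grid points): picking the arg-max of a noisy trace selects
#' upward noise and would bias F0 — and with it every fitted quenching
#' constant — upward. Intensities are still read from the raw spectra at the
#' selected wavelength, so a noiseless symmetric band is unaffected.
#'
#' @param series A [titration_series()].
#' @param window_nm Optional `c(lo, hi)` wavelength window restricting the
#'   search for the reference maximum; default is the full axis.
#' @param smooth_pts Odd number of grid points in the running mean used for
#'   peak location (1 = no smoothing); default 5.
#' @return A `data.frame` of class `quench_table` with columns
#'   `temperature_K`, `q_molar`, `F`, and attribute `lambda_F_nm` (the fixed
#'   read-out wavelength).
#' @export
extract_quench_table <- function(series, window_nm = NULL, smooth_pts = 5) {
  stopifnot(inherits(series, "titration_series"))
  ref <- series$spectra[[1L]]
  axis <- ref$axis_nm
  keep <- if (is.null(window_nm)) rep(TRUE, length(axis)) else {
    if (length(window_nm) != 2L || window_nm[1L] >= window_nm[2L])
      stop("extract_quench_table: window_nm must be c(lo, hi)", call. = FALSE)
    axis >= window_nm[1L] & axis <= window_nm[2L]
  }
  if (!any(keep))
    stop("extract_quench_table: window does not intersect the axis", call. = FALSE)
  smoothed <- .running_mean(ref$signal, smooth_pts)
  sig <- smoothed[keep]
  if (diff(range(ref$signal[keep])) == 0)
    stop("extract_quench_table: reference spectrum is flat in the window; no unique maximum",
         call. = FALSE)
  idx <- which(keep)[which.max(sig)]   # which.max takes the first (shortest wavelength) tie
  lambda <- axis[idx]
  F <- vapply(series$spectra, function(s) s$signal[idx], numeric(1))
  out <- data.frame(temperature_K = series$temperature_K,
                    q_molar = series$q_molar, F = F)
  out <- out[order(out$q_molar), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda_F_nm") <- lambda
  class(out) <- c("quench_table", "data.frame")
  out
}

#' Read a quench table from a long CSV file
#'
#' Expected header: `temperature_K,q_molar,F`. Within each temperature the
#' q ladder must increase strictly from 0 and intensities must be positive.
#'
#' @param path Path to the CSV file.
#' @return A `quench_table` data frame.
#' @export
read_quench_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_K", "q_molar", "F")
  if (!identical(names(df)[seq_along(need)], need))
    stop("read_quench_table: header must be 'temperature_K,q_molar,F'",
         call. = FALSE)
  validate_quench_table(df)
  class(df) <- c("quench_table", "data.frame")
  df
}

validate_quench_table <- function(df) {
  for (tt in unique(df$temperature_K)) {
    sub <- df[df$temperature_K == tt, , drop = FALSE]
    if (any(diff(sub$q_molar) <= 0))
      stop(sprintf("quench_table: q not strictly increasing at T = %g K", tt),
           call. = FALSE)
    if (sum(sub$q_molar == 0) != 1L)
      stop(sprintf("quench_table: exactly one q = 0 row required at T = %g K", tt),
           call. = FALSE)
    if (any(sub$F <= 0))
      stop(sprintf("quench_table: F must be positive at T = %g K", tt),
           call. = FALSE)
  }
  invisible(df)
}

#' Write a quench table to long CSV
#' @param table A `quench_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quench_table <- function(table, path) {
  .write_csv_full(as.data.frame(table)[c("temperature_K", "q_molar", "F")], path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## EEM and CD formats
## ---------------------------------------------------------------------------

#' Read an excitation-emission matrix from CSV
#'
#' Layout: first row is the emission grid (first cell blank or a label),
#' first column the excitation grid, matrix body the intensities.
#'
#' @param path Path to the CSV file.
#' @return An [eem()].
#' @export
read_eem <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  em <- suppressWarnings(as.numeric(raw[1L, -1L]))
  ex <- suppressWarnings(as.numeric(raw[-1L, 1L]))
  if (any(is.na(em)) || any(is.na(ex)))
    stop("read_eem: non-numeric wavelength grid", call. = FALSE)
  body <- as.matrix(raw[-1L, -1L, drop = FALSE])
  storage.mode(body) <- "double"
  dimnames(body) <- NULL
  eem(ex, em, body)
}

#' Write an excitation-emission matrix to CSV
#' @param x An [eem()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eem <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("ex_nm\\em_nm", sprintf("%.17g", x$em_nm)), collapse = ","), con)
  for (i in seq_along(x$ex_nm)) {
    writeLines(paste(sprintf("%.17g", c(x$ex_nm[i], x$intensity[i, ])),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read a CD spectrum (`wavelength_nm,theta_mdeg`) from CSV
#' @param path Path to the CSV file.
#' @return A [spectrum()] of kind `"cd_mdeg"`.
#' @export
read_cd <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:2], c("wavelength_nm", "theta_mdeg")))
    stop("read_cd: header must be 'wavelength_nm,theta_mdeg'", call. = FALSE)
  spectrum(df$wavelength_nm, df$theta_mdeg, "cd_mdeg")
}

#' Write a CD spectrum to CSV
#' @param x A [spectrum()] of kind `"cd_mdeg"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cd <- function(x, path) {
  stopifnot(inherits(x, "spectrum"), x$kind == "cd_mdeg")
  .write_csv_full(data.frame(wavelength_nm = x$axis_nm, theta_mdeg = x$signal),
                  path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Structured result output
## ---------------------------------------------------------------------------

#' Write any fitted result to structured JSON
#'
#' Stored values keep full precision; rounding happens only in the
#' human-readable report (see [render_report()]). Round-trips through
#' [read_results()] bit-identically.
#'
#' @param results A fitted result object (`sv_fit`, `binding_fit`,
#'   `thermo_result`, `uv_fit`, ...) or any list of numeric scalars/vectors.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  x <- unclass(results)
  x[["schema"]] <- paste0("specbind/", class(results)[1L], "/1")
  # digits = 17 guarantees bit-identical double round-trips
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 17, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read back a structured result written by [write_results()]
#' @param path Path to the JSON file.
#' @return A named list (the `schema` field identifies the original class).
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
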