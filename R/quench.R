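#' Stern-Volmer fit of a fluorescence quenching table
#'
#' Fits the linear quenching law F0/F = 1 + Ksv \[Q\] by ordinary least
#' squares of y = F0/F on x = \[Q\], with the intercept fitted freely (a
#' pinned intercept of 1 would hide baseline errors). The bimolecular
#' quenching rate constant is kq = Ksv / tau0.
#'
#' @param table A `quench_table` (see [extract_quench_table()]) restricted to
#'   a single temperature; must contain the q = 0 reference row.
#' @param tau0_s Unquenched fluorophore lifetime in seconds. Default 1e-8 s,
#'   the canonical average lifetime of serum-albumin intrinsic fluorescence.
#' @return An object of class `sv_fit` with elements `temperature_K`, `K_SV`
#'   (L/mol), `k_q` (L/mol/s), `tau0_s`, `intercept`, `R` (Pearson
#'   correlation of x and y), `SD` (residual standard deviation of F0/F about
#'   the line), `n_points`, and `warnings` (character vector, possibly empty).
#' @examples
#' tab <- data.frame(temperature_K = 298, q_molar = c(0, 1e-4), F = c(100, 50))
#' stern_volmer_fit(tab)$K_SV   # 1e4
#' @export
stern_volmer_fit <- function(table, tau0_s = 1e-8) {
  tab <- .one_temperature(table, "stern_volmer_fit")
  F0 <- tab$F[tab$q_molar == 0]
  if (length(F0) != 1L)
    stop("stern_volmer_fit: exactly one q = 0 reference row required",
         call. = FALSE)
  if (any(tab$F <= 0))
    stop("stern_volmer_fit: intensities must be positive", call. = FALSE)
  if (nrow(tab) < 2L)
    stop("stern_volmer_fit: at least 2 points required", call. = FALSE)
  x <- tab$q_molar
  y <- F0 / tab$F
  warnings <- character(0)
  if (all(y == y[1L])) {
    # no quenching at all: slope is identically zero, report it, don't fail
    warnings <- c(warnings, "no quenching: all F equal F0, K_SV = 0")
    ksv <- 0; intercept <- y[1L]; R <- NA_real_; SD <- 0
  } else {
    fit <- stats::lm(y ~ x)
    ksv <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    R <- stats::cor(x, y)
    SD <- .residual_sd(fit)
    if (ksv < 0)
      warnings <- c(warnings, "anti-quenching: fitted slope is negative")
  }
  structure(list(temperature_K = tab$temperature_K[1L],
                 K_SV = ksv, k_q = ksv / tau0_s, tau0_s = tau0_s,
                 intercept = intercept, R = R, SD = SD,
                 n_points = nrow(tab), warnings = warnings),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit @ %g K: K_SV = %.4g L/mol, k_q = %.4g L/mol/s (tau0 = %g s)\n",
              x$temperature_K, x$K_SV, x$k_q, x$tau0_s))
  cat(sprintf("  R = %.4f, SD = %.4g, n = %d\n",
              if (is.na(x$R)) NA else x$R, x$SD, x$n_points))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Double-logarithmic binding fit
#'
#' Fits lg((F0 - F)/F) = lg K + n lg\[Q\] (base-10 logs throughout) by
#' ordinary least squares, giving the binding constant K = 10^intercept and
#' the binding-site number n = slope. The q = 0 reference only supplies F0;
#' rows with F >= F0 at q > 0 carry no quenching signal and are dropped with
#' a warning (the log of a non-positive argument is undefined).
#'
#' @param table A `quench_table` at a single temperature including the q = 0
#'   row.
#' @return An object of class `binding_fit` with elements `temperature_K`,
#'   `K` (L/mol), `n_sites`, `R`, `SD`, `n_points`, `warnings`.
#' @export
double_log_fit <- function(table) {
  tab <- .one_temperature(table, "double_log_fit")
  F0 <- tab$F[tab$q_molar == 0]
  if (length(F0) != 1L)
    stop("double_log_fit: exactly one q = 0 reference row required",
         call. = FALSE)
  pos <- tab[tab$q_molar > 0, , drop = FALSE]
  warnings <- character(0)
  usable <- pos$F < F0
  if (any(!usable)) {
    warnings <- c(warnings, sprintf(
      "%d row(s) with F >= F0 dropped (no quenching signal)", sum(!usable)))
    pos <- pos[usable, , drop = FALSE]
  }
  if (nrow(pos) < 2L)
    stop("double_log_fit: fewer than 2 usable rows with q > 0 and F < F0",
         call. = FALSE)
  x <- log10(pos$q_molar)
  y <- log10((F0 - pos$F) / pos$F)
  fit <- stats::lm(y ~ x)
  structure(list(temperature_K = tab$temperature_K[1L],
                 K = 10^unname(stats::coef(fit)[1L]),
                 n_sites = unname(stats::coef(fit)[2L]),
                 R = stats::cor(x, y), SD = .residual_sd(fit),
                 n_points = nrow(pos), warnings = warnings),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit @ %g K: K = %.4g L/mol, n = %.3f\n",
              x$temperature_K, x$K, x$n_sites))
  cat(sprintf("  R = %.4f, SD = %.4g, n_points = %d\n", x$R, x$SD, x$n_points))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Classify the quenching mechanism from multi-temperature fits
#'
#' Two rules distinguish static (ground-state complex) from dynamic
#' (collisional) quenching: (1) Ksv strictly decreasing with temperature
#' supports static, strictly increasing supports dynamic; (2) every kq above
#' the diffusion-controlled limit supports static, because collisions alone
#' cannot quench that fast. The call is made when the fired rules agree and
#' is `indeterminate` otherwise.
#'
#' @param fits List of `sv_fit` objects at two or more distinct temperatures.
#' @param diffusion_limit Diffusion-limited collisional rate constant
#'   (L/mol/s); default 2.0e10.
#' @return An object of class `mechanism_call` with elements `mechanism`
#'   (`"static"`, `"dynamic"` or `"indeterminate"`) and `evidence` (named
#'   logical-ish list of rule outcomes).
#' @export
classify_mechanism <- function(fits, diffusion_limit = 2.0e10) {
  if (!is.list(fits) || !all(vapply(fits, inherits, logical(1), "sv_fit")))
    stop("classify_mechanism: 'fits' must be a list of sv_fit objects",
         call. = FALSE)
  Tk <- vapply(fits, `[[`, numeric(1), "temperature_K")
  if (length(unique(Tk)) < 2L)
    stop("classify_mechanism: at least 2 distinct temperatures required",
         call. = FALSE)
  ord <- order(Tk)
  ksv <- vapply(fits, `[[`, numeric(1), "K_SV")[ord]
  kq <- vapply(fits, `[[`, numeric(1), "k_q")[ord]
  trend <- if (all(diff(ksv) < 0)) "decreasing"
           else if (all(diff(ksv) > 0)) "increasing"
           else "non-monotone"
  exceeds <- all(kq > diffusion_limit)
  support_static <- (trend == "decreasing") || exceeds
  support_dynamic <- (trend == "increasing")
  mechanism <- if (support_static && !support_dynamic) "static"
               else if (support_dynamic && !support_static) "dynamic"
               else "indeterminate"
  structure(list(mechanism = mechanism,
                 evidence = list(ksv_trend_with_T = trend,
                                 all_kq_above_diffusion_limit = exceeds,
                                 diffusion_limit = diffusion_limit)),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s (K_SV %s with T; k_q %s diffusion limit %.2g)\n",
              x$mechanism, x$evidence$ksv_trend_with_T,
              if (x$evidence$all_kq_above_diffusion_limit) "above" else "not above",
              x$evidence$diffusion_limit))
  invisible(x)
}

#' Site-marker displacement call
#'
#' Compares the Stern-Volmer constant of the ligand with and without a
#' site-specific competitive probe. A substantial drop of Ksv in the presence
#' of the probe means the ligand and the probe compete for the same site;
#' warfarin marks Sudlow site I (subdomain IIA), ibuprofen site II
#' (subdomain IIIA).
#'
#' @param fit_free `sv_fit` of the ligand-protein system alone.
#' @param fit_probe `sv_fit` with the probe present, same temperature.
#' @param probe_name Probe identity; `"warfarin"` and `"ibuprofen"` map to a
#'   site assignment, other names are kept verbatim without one.
#' @param competition_threshold Ksv ratio below which competition is called
#'   (default 0.7, i.e. at least a 30 percent drop).
#' @return An object of class `displacement_call` with `ksv_free`,
#'   `ksv_with_probe`, `ratio`, `competes`, `probe_name`, `site` (the site
#'   the probe marks, or `NA`), and `assigned_site` (`site` if competing,
#'   else `NA`).
#' @export
displacement_call <- function(fit_free, fit_probe, probe_name,
                              competition_threshold = 0.7) {
  stopifnot(inherits(fit_free, "sv_fit"), inherits(fit_probe, "sv_fit"))
  if (fit_free$temperature_K != fit_probe$temperature_K)
    stop("displacement_call: fits must share one temperature", call. = FALSE)
  if (fit_free$K_SV <= 0)
    stop("displacement_call: K_SV of the probe-free system must be positive",
         call. = FALSE)
  ratio <- fit_probe$K_SV / fit_free$K_SV
  if (ratio <= 0)
    stop("displacement_call: K_SV ratio must be positive", call. = FALSE)
  site <- switch(tolower(probe_name), warfarin = "site I",
                 ibuprofen = "site II", NA_character_)
  competes <- ratio < competition_threshold
  structure(list(probe_name = probe_name,
                 ksv_free = fit_free$K_SV, ksv_with_probe = fit_probe$K_SV,
                 ratio = ratio, competes = competes,
                 competition_threshold = competition_threshold,
                 site = site,
                 assigned_site = if (competes) site else NA_character_),
            class = "displacement_call")
}

#' @export
print.displacement_call <- function(x, ...) {
  cat(sprintf("Displacement by %s: K_SV %.4g -> %.4g (ratio %.3f) => %s\n",
              x$probe_name, x$ksv_free, x$ksv_with_probe, x$ratio,
              if (x$competes) sprintf("competes (%s)",
                                      if (is.na(x$site)) "unknown site" else x$site)
              else "no competition"))
  invisible(x)
}

## restrict a quench table to one temperature, coercing plain data frames
.one_temperature <- function(table, fn) {
  tab <- as.data.frame(table)
  need <- c("temperature_K", "q_molar", "F")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: table must have columns %s", fn,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (length(unique(tab$temperature_K)) != 1L)
    stop(sprintf("%s: table spans several temperatures; subset first", fn),
         call. = FALSE)
  tab[order(tab$q_molar), , drop = FALSE]
}

.residual_sd <- function(fit) {
  res <- stats::residuals(fit)
  df <- fit$df.residual
  if (df <= 0) return(0)
  sqrt(sum(res^2) / df)
}
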