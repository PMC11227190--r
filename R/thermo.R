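#' Universal gas constant (J/mol/K)
#' @export
R_GAS <- 8.314

#' Van't Hoff estimation of binding thermodynamics
#'
#' Regresses ln K on 1/T: the slope is -dH/R and the intercept dS/R, under
#' the usual assumption that dH and dS are constant over the (narrow)
#' temperature range. Gibbs energies are then dG(T) = dH - T dS at each input
#' temperature, and the (dH, dS) sign pattern is mapped to the dominant
#' non-covalent force via [classify_forces()].
#'
#' ln K is taken on the numeric value of K in L/mol with no standard-state
#' correction, which is the convention of the quenching literature this
#' package serves.
#'
#' @param K_by_T Named numeric vector of binding constants (L/mol), names the
#'   temperatures in K; or supply `temperature_K` separately.
#' @param temperature_K Optional numeric vector of temperatures matching
#'   `K_by_T` when the latter is unnamed.
#' @return An object of class `thermo_result` with `dH` (J/mol), `dS`
#'   (J/mol/K), `dG_by_T` (named, J/mol, from dH - T dS), `dG_lnK_by_T`
#'   (named, J/mol, the -RT ln K cross-check, never substituted for
#'   `dG_by_T`), `fit_R` (Pearson correlation of ln K vs 1/T), `R_gas`,
#'   `spontaneous` (TRUE iff every dG_by_T entry is negative), and
#'   `force_class`.
#' @examples
#' vant_hoff_fit(c("293" = 4.03e4, "298" = 2.09e4, "303" = 1.41e4))
#' @export
vant_hoff_fit <- function(K_by_T, temperature_K = NULL) {
  K <- as.numeric(K_by_T)
  Tk <- if (!is.null(temperature_K)) as.numeric(temperature_K)
        else as.numeric(names(K_by_T))
  if (length(Tk) != length(K) || any(is.na(Tk)))
    stop("vant_hoff_fit: temperatures missing; name K_by_T or pass temperature_K",
         call. = FALSE)
  if (length(unique(Tk)) < 2L)
    stop("vant_hoff_fit: at least 2 distinct temperatures required", call. = FALSE)
  if (any(!is.finite(K)) || any(K <= 0))
    stop("vant_hoff_fit: binding constants must be positive and finite",
         call. = FALSE)
  if (any(Tk <= 0))
    stop("vant_hoff_fit: temperatures must be positive (K)", call. = FALSE)
  x <- 1 / Tk
  y <- log(K)
  if (stats::sd(y) == 0) {
    # flat line: K independent of T, so dH = 0 and dS = R ln K
    dH <- 0; dS <- R_GAS * y[1L]; fit_R <- NA_real_
  } else {
    fit <- stats::lm(y ~ x)
    dH <- -unname(stats::coef(fit)[2L]) * R_GAS
    dS <- unname(stats::coef(fit)[1L]) * R_GAS
    fit_R <- stats::cor(x, y)
  }
  ord <- order(Tk)
  Tk <- Tk[ord]; K <- K[ord]
  dG <- dH - Tk * dS
  names(dG) <- as.character(Tk)
  dG_lnK <- -R_GAS * Tk * log(K)
  names(dG_lnK) <- as.character(Tk)
  structure(list(dH = dH, dS = dS, dG_by_T = dG, dG_lnK_by_T = dG_lnK,
                 fit_R = fit_R, R_gas = R_GAS,
                 spontaneous = all(dG < 0),
                 force_class = classify_forces(dH, dS)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Van't Hoff: dH = %.2f kJ/mol, dS = %.2f J/mol/K (fit R = %s)\n",
              x$dH / 1000, x$dS,
              if (is.na(x$fit_R)) "NA" else sprintf("%.4f", x$fit_R)))
  for (tt in names(x$dG_by_T))
    cat(sprintf("  dG(%s K) = %.2f kJ/mol  [-RT ln K cross-check: %.2f]\n",
                tt, x$dG_by_T[[tt]] / 1000, x$dG_lnK_by_T[[tt]] / 1000))
  cat(sprintf("  %sspontaneous; dominant forces: %s\n",
              if (x$spontaneous) "" else "not ", x$force_class))
  invisible(x)
}

#' Gibbs energy from a single binding constant
#'
#' Returns -R T ln K (J/mol). Reported alongside the Van't Hoff dH - T dS
#' values as a consistency cross-check, never substituted for them.
#'
#' @param K Binding constant (L/mol), positive.
#' @param temperature_K Temperature (K), positive.
#' @return Gibbs energy in J/mol.
#' @export
gibbs_from_K <- function(K, temperature_K) {
  if (any(K <= 0) || any(temperature_K <= 0))
    stop("gibbs_from_K: K and temperature must be positive", call. = FALSE)
  -R_GAS * temperature_K * log(K)
}

#' Ross-Subramanian interaction-force classification
#'
#' Maps the signs of the enthalpy and entropy changes of binding to the
#' dominant non-covalent force: dH < 0 and dS < 0 indicate hydrogen bonding
#' plus van der Waals contacts; dH > 0 and dS > 0 indicate hydrophobic
#' association; dH < 0 with dS > 0 indicates electrostatic interactions.
#' A zero on either axis sits on a rule boundary: the sign of dS decides
#' (with a warning), and the doubly-degenerate origin falls to electrostatic.
#'
#' @param dH Enthalpy change (J/mol).
#' @param dS Entropy change (J/mol/K).
#' @return One of `"hydrogen_bond_vdw"`, `"hydrophobic"`, `"electrostatic"`.
#' @export
classify_forces <- function(dH, dS) {
  if (!is.finite(dH) || !is.finite(dS))
    stop("classify_forces: dH and dS must be finite", call. = FALSE)
  if (dH < 0 && dS < 0) return("hydrogen_bond_vdw")
  if (dH > 0 && dS > 0) return("hydrophobic")
  if (dH < 0 && dS > 0) return("electrostatic")
  if (dH > 0 && dS < 0) {
    warning("classify_forces: dH > 0 with dS < 0 matches no canonical sign rule; ",
            "classifying by the dS sign as hydrogen_bond_vdw")
    return("hydrogen_bond_vdw")
  }
  # at least one exact zero: boundary case
  warning("classify_forces: dH or dS is exactly zero (rule boundary); ",
          "classifying by the dS sign")
  if (dS < 0) "hydrogen_bond_vdw" else if (dS > 0) "hydrophobic" else "electrostatic"
}
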