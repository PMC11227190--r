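#' Benesi-Hildebrand fit of a UV absorbance titration
#'
#' Double-reciprocal estimation of the intrinsic 1:1 binding constant: with
#' A0 the absorbance of the free protein and Ac that of the saturated
#' complex, 1/(Aobs - A0) is linear in 1/\[L\] with slope 1/(Kb (Ac - A0))
#' and intercept 1/(Ac - A0), so Kb = intercept/slope. The reciprocal-space
#' line is fitted by unweighted ordinary least squares — the procedure of the
#' classical plot, kept despite its known heteroscedasticity; a direct
#' nonlinear fit of the same isotherm is available as a cross-check via
#' [isotherm_fit()].
#'
#' @param op_molar Ligand concentrations (mol/L), all positive; or a
#'   two-column data frame `(op_molar, a_obs)`.
#' @param a_obs Observed absorbances at each concentration.
#' @param A0 Absorbance of the ligand-free protein (measured, not fitted).
#' @return An object of class `uv_fit` with `K_b` (1/M), `A0`, `Ac`
#'   (back-computed as A0 + 1/intercept), `slope`, `intercept`, `R`,
#'   `n_points`, `nonphysical` (TRUE when slope or intercept is
#'   non-positive, leaving K_b meaningless), `warnings`.
#' @examples
#' p <- gen_uv_series(noise_sd = 0)
#' benesi_hildebrand_fit(p$op_molar, p$a_obs, A0 = 0.5)$K_b  # 7.12e5
#' @export
benesi_hildebrand_fit <- function(op_molar, a_obs = NULL, A0) {
  if (is.data.frame(op_molar)) {
    a_obs <- op_molar[[2L]]
    op_molar <- op_molar[[1L]]
  }
  if (length(op_molar) != length(a_obs))
    stop("benesi_hildebrand_fit: concentration and absorbance lengths differ",
         call. = FALSE)
  if (any(op_molar <= 0))
    stop("benesi_hildebrand_fit: ligand concentrations must be positive",
         call. = FALSE)
  warnings <- character(0)
  flat <- a_obs == A0
  if (all(flat))
    stop("benesi_hildebrand_fit: no signal (all A_obs equal A0)", call. = FALSE)
  if (any(flat)) {
    warnings <- c(warnings, sprintf("%d point(s) with A_obs == A0 dropped",
                                    sum(flat)))
    op_molar <- op_molar[!flat]; a_obs <- a_obs[!flat]
  }
  if (length(op_molar) < 2L)
    stop("benesi_hildebrand_fit: fewer than 2 usable pairs", call. = FALSE)
  x <- 1 / op_molar
  y <- 1 / (a_obs - A0)
  fit <- stats::lm(y ~ x)
  intercept <- unname(stats::coef(fit)[1L])
  slope <- unname(stats::coef(fit)[2L])
  nonphysical <- !(slope > 0 && intercept > 0)
  if (nonphysical)
    warnings <- c(warnings,
                  "non-physical fit: slope or intercept not positive, K_b unreliable")
  structure(list(K_b = intercept / slope, A0 = A0,
                 Ac = A0 + 1 / intercept,
                 slope = slope, intercept = intercept,
                 R = stats::cor(x, y), n_points = length(x),
                 nonphysical = nonphysical, warnings = warnings),
            class = "uv_fit")
}

#' @export
print.uv_fit <- function(x, ...) {
  cat(sprintf("Benesi-Hildebrand fit: K_b = %.4g 1/M, Ac = %.4g (A0 = %.4g), R = %.4f, n = %d\n",
              x$K_b, x$Ac, x$A0, x$R, x$n_points))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Direct nonlinear fit of the 1:1 UV binding isotherm
#'
#' Least-squares fit of A = A0 + (Ac - A0) Kb \[L\] / (1 + Kb \[L\]) with A0
#' fixed, used as an independent cross-check of the double-reciprocal
#' linearization (the two agree exactly on noiseless data).
#'
#' @inheritParams benesi_hildebrand_fit
#' @param start Optional named list with starting values `K_b` and `Ac`;
#'   defaults to the Benesi-Hildebrand estimates.
#' @return A list with `K_b`, `Ac`, `A0`, and the underlying `nls` fit.
#' @export
isotherm_fit <- function(op_molar, a_obs = NULL, A0, start = NULL) {
  if (is.data.frame(op_molar)) {
    a_obs <- op_molar[[2L]]
    op_molar <- op_molar[[1L]]
  }
  if (is.null(start)) {
    bh <- benesi_hildebrand_fit(op_molar, a_obs, A0)
    start <- list(K_b = bh$K_b, Ac = bh$Ac)
  }
  dat <- data.frame(q = op_molar, A = a_obs)
  fit <- stats::nls(A ~ A0 + (Ac - A0) * K_b * q / (1 + K_b * q),
                    data = dat, start = start,
                    control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                                 scaleOffset = 1))
  co <- stats::coef(fit)
  list(K_b = unname(co[["K_b"]]), Ac = unname(co[["Ac"]]), A0 = A0, fit = fit)
}
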