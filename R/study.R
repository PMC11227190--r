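#' Configuration for a full binding study
#'
#' Collects the input paths and tunable parameters for [run_study()]. Any
#' input class may be omitted; the orchestrator runs whatever subset the
#' available inputs support.
#'
#' @param quench_titrations Named character vector of wide-CSV titration
#'   paths, names = temperature in K (e.g. `c("293" = "...")`), used for the
#'   Stern-Volmer and double-log stages.
#' @param displacement_free,displacement_probes Long-CSV quench-table paths
#'   for the probe-free system and (named by probe) with each site marker.
#' @param uv_pairs Path to a `op_molar,a_obs` CSV.
#' @param uv_A0 Free-protein absorbance for the UV stage.
#' @param cd_free,cd_complex Paths to `wavelength_nm,theta_mdeg` CSVs.
#' @param eem_free,eem_complex Paths to EEM CSVs.
#' @param sfs15,sfs60 Paths to wide-CSV synchronous titrations at offsets 15
#'   and 60 nm.
#' @param tau0_s Fluorophore lifetime (s) for k_q; default 1e-8.
#' @param diffusion_limit Diffusion-limited rate constant (L/mol/s).
#' @param competition_threshold K_SV ratio below which probe competition is
#'   called.
#' @param cd CD normalisation, a [cd_config()].
#' @param out_dir Optional directory: each stage's structured JSON plus a
#'   human-readable `report.md` are written there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(quench_titrations = NULL,
                         displacement_free = NULL, displacement_probes = NULL,
                         uv_pairs = NULL, uv_A0 = NULL,
                         cd_free = NULL, cd_complex = NULL,
                         eem_free = NULL, eem_complex = NULL,
                         sfs15 = NULL, sfs60 = NULL,
                         tau0_s = 1e-8, diffusion_limit = 2.0e10,
                         competition_threshold = 0.7,
                         cd = cd_config(), out_dir = NULL) {
  paths <- c(quench_titrations, displacement_free, displacement_probes,
             uv_pairs, cd_free, cd_complex, eem_free, eem_complex,
             sfs15, sfs60)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("study_config: input file(s) not found: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (tau0_s <= 0 || diffusion_limit <= 0 || competition_threshold <= 0)
    stop("study_config: parameters must be positive", call. = FALSE)
  structure(list(quench_titrations = quench_titrations,
                 displacement_free = displacement_free,
                 displacement_probes = displacement_probes,
                 uv_pairs = uv_pairs, uv_A0 = uv_A0,
                 cd_free = cd_free, cd_complex = cd_complex,
                 eem_free = eem_free, eem_complex = eem_complex,
                 sfs15 = sfs15, sfs60 = sfs60,
                 tau0_s = tau0_s, diffusion_limit = diffusion_limit,
                 competition_threshold = competition_threshold,
                 cd = cd, out_dir = out_dir),
            class = "study_config")
}

#' Run the full binding-study pipeline
#'
#' Executes, for whichever inputs the configuration provides:
#' quenching fits per temperature (Stern-Volmer and double-log), mechanism
#' classification, Van't Hoff thermodynamics with force classification,
#' site-marker displacement, the UV Benesi-Hildebrand fit, the CD helix
#' change, emission-shift reports and EEM peak extraction, and the
#' synchronous-fluorescence residue attribution. A failing stage is recorded
#' in `$errors` and does not stop independent stages. With `out_dir` set,
#' each stage's full-precision JSON and a rounded human-readable `report.md`
#' are written.
#'
#' @param config A [study_config()].
#' @return An object of class `study_bundle`: stage results (`sv_fits`,
#'   `binding_fits`, `mechanism`, `thermo`, `displacement`, `uv`, `cd`,
#'   `shifts`, `eem_peaks`, `sfs`), `warnings`, `errors`, and `conclusions`
#'   (from [summarize_conclusions()]).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  bundle <- list(sv_fits = NULL, binding_fits = NULL, mechanism = NULL,
                 thermo = NULL, displacement = NULL, uv = NULL, cd = NULL,
                 shifts = NULL, eem_peaks = NULL, sfs = NULL,
                 warnings = character(0), errors = character(0))
  note_err <- function(stage, e) {
    bundle$errors <<- c(bundle$errors, sprintf("%s: %s", stage, conditionMessage(e)))
  }

  if (!is.null(config$quench_titrations)) {
    tryCatch({
      temps <- as.numeric(names(config$quench_titrations))
      series <- lapply(seq_along(temps), function(i)
        read_titration(config$quench_titrations[[i]], temperature_K = temps[i]))
      tables <- lapply(series, extract_quench_table)
      bundle$sv_fits <- lapply(tables, stern_volmer_fit, tau0_s = config$tau0_s)
      bundle$binding_fits <- lapply(tables, double_log_fit)
      bundle$shifts <- lapply(series, shift_report)
      if (length(bundle$sv_fits) >= 2L)
        bundle$mechanism <- classify_mechanism(bundle$sv_fits,
                                               config$diffusion_limit)
      K_by_T <- stats::setNames(
        vapply(bundle$binding_fits, `[[`, numeric(1), "K"),
        vapply(bundle$binding_fits, function(f) as.character(f$temperature_K), ""))
      if (length(K_by_T) >= 2L) bundle$thermo <- vant_hoff_fit(K_by_T)
    }, error = function(e) note_err("quench", e))
  }

  if (!is.null(config$displacement_free) && length(config$displacement_probes)) {
    tryCatch({
      fit_free <- stern_volmer_fit(read_quench_table(config$displacement_free),
                                   tau0_s = config$tau0_s)
      bundle$displacement <- lapply(names(config$displacement_probes), function(pn) {
        fit_p <- stern_volmer_fit(read_quench_table(config$displacement_probes[[pn]]),
                                  tau0_s = config$tau0_s)
        displacement_call(fit_free, fit_p, pn, config$competition_threshold)
      })
      names(bundle$displacement) <- names(config$displacement_probes)
    }, error = function(e) note_err("displacement", e))
  }

  if (!is.null(config$uv_pairs)) {
    tryCatch({
      pairs <- utils::read.csv(config$uv_pairs)
      A0 <- if (is.null(config$uv_A0)) {
        if (!any(pairs$op_molar == 0))
          stop("uv_A0 not given and no q = 0 row in the UV pairs")
        pairs$a_obs[pairs$op_molar == 0][1L]
      } else config$uv_A0
      use <- pairs$op_molar > 0
      bundle$uv <- benesi_hildebrand_fit(pairs$op_molar[use], pairs$a_obs[use], A0)
    }, error = function(e) note_err("uv", e))
  }

  if (!is.null(config$cd_free) && !is.null(config$cd_complex)) {
    tryCatch({
      bundle$cd <- helix_change(read_cd(config$cd_free),
                                read_cd(config$cd_complex), config$cd)
    }, error = function(e) note_err("cd", e))
  }

  if (!is.null(config$eem_free)) {
    tryCatch({
      pk_free <- eem_peaks(read_eem(config$eem_free), n_peaks = 2)
      bundle$eem_peaks <- list(free = pk_free)
      if (!is.null(config$eem_complex))
        bundle$eem_peaks$complex <- eem_peaks(read_eem(config$eem_complex),
                                              n_peaks = 2)
    }, error = function(e) note_err("eem", e))
  }

  if (!is.null(config$sfs15) && !is.null(config$sfs60)) {
    tryCatch({
      s15 <- read_titration(config$sfs15)
      s60 <- read_titration(config$sfs60)
      bundle$sfs <- sfs_attribution(s15, s60)
    }, error = function(e) note_err("sfs", e))
  }

  for (f in c(bundle$sv_fits, bundle$binding_fits))
    bundle$warnings <- c(bundle$warnings, f$warnings)
  class(bundle) <- "study_bundle"
  bundle$conclusions <- summarize_conclusions(bundle)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_stage <- function(obj, fname) {
      if (!is.null(obj)) write_results(obj, file.path(config$out_dir, fname))
    }
    for (f in bundle$sv_fits)
      save_stage(f, sprintf("sv_fit_%gK.json", f$temperature_K))
    for (f in bundle$binding_fits)
      save_stage(f, sprintf("binding_fit_%gK.json", f$temperature_K))
    save_stage(bundle$mechanism, "mechanism.json")
    save_stage(bundle$thermo, "thermo.json")
    for (nm in names(bundle$displacement))
      save_stage(bundle$displacement[[nm]], sprintf("displacement_%s.json", nm))
    save_stage(bundle$uv, "uv_fit.json")
    save_stage(bundle$cd, "cd_result.json")
    if (!is.null(bundle$sfs)) save_stage(bundle$sfs, "sfs_attribution.json")
    writeLines(render_report(bundle), file.path(config$out_dir, "report.md"))
  }
  bundle
}

#' Rule-derived study conclusions
#'
#' Emits only sentences that follow mechanically from the fitted results:
#' the quenching-mechanism call, the site assignment, the dominant-force
#' class, spontaneity, the helix change, and the residue attribution. No
#' free-form inference. An empty bundle yields an empty character vector.
#'
#' @param bundle A `study_bundle` from [run_study()].
#' @return Character vector of findings.
#' @export
summarize_conclusions <- function(bundle) {
  out <- character(0)
  if (!is.null(bundle$mechanism))
    out <- c(out, sprintf("Fluorescence quenching is %s.",
                          bundle$mechanism$mechanism))
  if (!is.null(bundle$binding_fits) && length(bundle$binding_fits)) {
    n_mean <- mean(vapply(bundle$binding_fits, `[[`, numeric(1), "n_sites"))
    if (abs(n_mean - 1) < 0.5)
      out <- c(out, "The binding-site number is close to 1 (a single site).")
  }
  for (d in bundle$displacement) {
    out <- c(out, if (d$competes)
      sprintf("The ligand competes with %s: binding near %s.", d$probe_name,
              if (is.na(d$site)) "its site" else d$site)
      else sprintf("No competition with %s.", d$probe_name))
  }
  if (!is.null(bundle$thermo)) {
    tr <- bundle$thermo
    out <- c(out, sprintf("Dominant interaction forces: %s.",
                          switch(tr$force_class,
                                 hydrogen_bond_vdw = "hydrogen bonding and van der Waals",
                                 hydrophobic = "hydrophobic",
                                 electrostatic = "electrostatic")))
    out <- c(out, if (tr$spontaneous)
      "Binding is spontaneous (dG < 0 at all temperatures)."
      else "Binding is not spontaneous at every temperature.")
  }
  if (!is.null(bundle$cd)) {
    out <- c(out, sprintf(
      "Alpha-helix content %s on complexation (%.2f%% to %.2f%%).",
      if (bundle$cd$delta < 0) "decreased" else if (bundle$cd$delta > 0)
        "increased" else "did not change",
      bundle$cd$helix_free, bundle$cd$helix_complex))
  }
  if (!is.null(bundle$sfs))
    out <- c(out, sprintf("Quenching acts mainly on %s residues.",
                          bundle$sfs$attribution))
  out
}

#' Render a human-readable report of a study bundle
#'
#' Markdown tables mirror the conventional presentation: constants rounded
#' to 2 decimals against powers-of-ten column headers. Rounding happens only
#' here; stored results keep full precision.
#'
#' @param bundle A `study_bundle`.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(bundle) {
  L <- c("# Binding study report", "")
  if (!is.null(bundle$sv_fits)) {
    L <- c(L, "## Stern-Volmer quenching constants", "",
           "| T (K) | R | K_SV (10^3 L/mol) | k_q (10^11 L/mol/s) | SD |",
           "|---|---|---|---|---|")
    for (f in bundle$sv_fits)
      L <- c(L, sprintf("| %g | %.2f | %.2f | %.2f | %.2f |", f$temperature_K,
                        f$R, f$K_SV / 1e3, f$k_q / 1e11, f$SD))
    L <- c(L, "")
  }
  if (!is.null(bundle$binding_fits)) {
    L <- c(L, "## Binding constants and thermodynamics", "",
           "| T (K) | K (10^4 L/mol) | R | n | SD | dG (kJ/mol) | dS (J/mol/K) | dH (kJ/mol) |",
           "|---|---|---|---|---|---|---|---|")
    for (f in bundle$binding_fits) {
      tt <- as.character(f$temperature_K)
      dG <- if (!is.null(bundle$thermo)) bundle$thermo$dG_by_T[[tt]] else NA
      L <- c(L, sprintf("| %g | %.2f | %.2f | %.2f | %.2f | %s | %s | %s |",
                        f$temperature_K, f$K / 1e4, f$R, f$n_sites, f$SD,
                        if (is.null(dG) || is.na(dG)) "" else sprintf("%.2f", dG / 1000),
                        if (is.null(bundle$thermo)) "" else sprintf("%.2f", bundle$thermo$dS),
                        if (is.null(bundle$thermo)) "" else sprintf("%.2f", bundle$thermo$dH / 1000)))
    }
    L <- c(L, "")
  }
  if (!is.null(bundle$displacement)) {
    L <- c(L, "## Site-marker displacement", "",
           "| probe | K_SV free | K_SV with probe | ratio | competes |",
           "|---|---|---|---|---|")
    for (d in bundle$displacement)
      L <- c(L, sprintf("| %s | %.3g | %.3g | %.2f | %s |", d$probe_name,
                        d$ksv_free, d$ksv_with_probe, d$ratio,
                        if (d$competes) "yes" else "no"))
    L <- c(L, "")
  }
  if (!is.null(bundle$uv)) {
    L <- c(L, "## UV binding constant", "",
           sprintf("K_b = %.2f x 10^5 1/M (R = %.2f, A0 = %.3g, Ac = %.3g)",
                   bundle$uv$K_b / 1e5, bundle$uv$R, bundle$uv$A0, bundle$uv$Ac), "")
  }
  if (!is.null(bundle$cd)) {
    L <- c(L, "## Circular dichroism", "",
           sprintf("Alpha-helix: free %.2f%%, complex %.2f%% (delta %+.2f points)",
                   bundle$cd$helix_free, bundle$cd$helix_complex, bundle$cd$delta), "")
  }
  if (length(bundle$conclusions)) {
    L <- c(L, "## Conclusions", "", paste0("- ", bundle$conclusions), "")
  }
  if (length(bundle$warnings)) {
    L <- c(L, "## Warnings", "", paste0("- ", bundle$warnings), "")
  }
  if (length(bundle$errors)) {
    L <- c(L, "## Stage errors", "", paste0("- ", bundle$errors), "")
  }
  L
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
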