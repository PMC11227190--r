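test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(spectrum(1:5, rnorm(5), "emission"), "spectrum")
  expect_error(spectrum(c(1, 2), c(1, 2), "emission"), "at least 3")
  expect_error(spectrum(c(1, 3, 2), c(1, 2, 3), "emission"), "increasing")
  expect_error(spectrum(1:3, c(1, NA, 3), "emission"), "non-finite")
  expect_error(spectrum(1:4, 1:3, "emission"), "lengths differ")
  expect_error(spectrum(1:3, 1:3, "nonsense"))
})

test_that("titration_series enforces the concentration-ladder contract", {
  sp <- lapply(1:3, function(i) spectrum(1:5, rep(i, 5), "emission"))
  expect_s3_class(titration_series(sp, c(0, 1e-5, 2e-5), 298), "titration_series")
  expect_error(titration_series(sp, c(1e-5, 0, 2e-5), 298), "increasing")
  expect_error(titration_series(sp, c(1e-5, 2e-5, 3e-5), 298), "first q must be 0")
  sp2 <- sp; sp2[[2]] <- spectrum(2:6, rep(1, 5), "emission")
  expect_error(titration_series(sp2, c(0, 1e-5, 2e-5), 298), "share one")
})

test_that("titration wide-CSV round-trips bit-identically and rejects malformed files", {
  ser <- gen_quench_titration(law = "sv_linear", K_SV = 3.06e3,
                              noise_cv = 0.05, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration(ser, path)
  back <- read_titration(path, temperature_K = ser$temperature_K)
  expect_identical(back$q_molar, ser$q_molar)
  expect_identical(back$spectra[[1]]$axis_nm, ser$spectra[[1]]$axis_nm)
  for (i in seq_along(ser$spectra))
    expect_identical(back$spectra[[i]]$signal, ser$spectra[[i]]$signal)

  # 11-column ladder 0..1e-4 step 1e-5 parses into 11 spectra
  expect_length(back$spectra, 11L)

  # shuffled q columns are a format error
  lines <- readLines(path)
  hdr <- strsplit(lines[1], ",")[[1]]
  bad <- paste(hdr[c(1, 3, 2, 4:12)], collapse = ",")
  bad_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(bad, lines[-1]), bad_path)
  expect_error(read_titration(bad_path), "increasing order")

  # wrong first column name
  writeLines(c(sub("wavelength_nm", "wl", lines[1]), lines[-1]), bad_path)
  expect_error(read_titration(bad_path), "wavelength_nm")

  # non-numeric cell named by row/column
  broken <- lines
  broken[3] <- sub("^([^,]*),[^,]*", "\\1,oops", broken[3])
  writeLines(broken, bad_path)
  expect_error(read_titration(bad_path), "non-")
})

test_that("quench-table extraction reads every F at the fixed reference maximum", {
  ser <- gen_quench_titration(law = "sv_linear", K_SV = 3.06e3)
  tab <- extract_quench_table(ser)
  expect_equal(attr(tab, "lambda_F_nm"), 348)
  # oracle: direct lookup in the spectra at the q=0 maximum
  idx <- which.max(ser$spectra[[1]]$signal)
  for (i in seq_along(ser$q_molar))
    expect_identical(tab$F[i], ser$spectra[[i]]$signal[idx])

  # identical spectra: all F equal
  sp <- replicate(3, spectrum(300:320, dnorm(300:320, 310, 5), "emission"),
                  simplify = FALSE)
  same <- titration_series(sp, c(0, 1e-5, 2e-5), 298)
  expect_true(all(extract_quench_table(same)$F == extract_quench_table(same)$F[1]))

  # two-point series with F halved
  f <- function(pk) spectrum(300:400, pk * dnorm(300:400, 348, 25) / dnorm(348, 348, 25),
                             "emission")
  two <- titration_series(list(f(100), f(50)), c(0, 1e-4), 298)
  t2 <- extract_quench_table(two)
  expect_equal(t2$F, c(100, 50))

  # flat reference spectrum is ambiguous
  flat <- titration_series(replicate(2, spectrum(1:5, rep(1, 5), "emission"),
                                     simplify = FALSE), c(0, 1e-5), 298)
  expect_error(extract_quench_table(flat), "flat|unique maximum")
})

test_that("quench-table extraction ignores wavelength samples outside the window", {
  ser <- gen_quench_titration(law = "sv_linear", K_SV = 2e3,
                              axis_nm = seq(300, 500, 1))
  wide <- gen_quench_titration(law = "sv_linear", K_SV = 2e3,
                               axis_nm = seq(200, 600, 1))
  a <- extract_quench_table(ser, window_nm = c(320, 380))
  b <- extract_quench_table(wide, window_nm = c(320, 380))
  expect_equal(a$F, b$F)
  expect_equal(attr(a, "lambda_F_nm"), attr(b, "lambda_F_nm"))
  expect_error(extract_quench_table(ser, window_nm = c(600, 700)), "window")
})

test_that("long quench-table CSV round-trips and validates", {
  tab <- make_quench_table(seq(0, 1e-4, 1e-5), K_SV = 3.06e3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_quench_table(tab, path)
  back <- read_quench_table(path)
  expect_identical(back$F, tab$F)
  expect_identical(back$q_molar, tab$q_molar)

  bad <- tab[nrow(tab):1, ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, p2, row.names = FALSE)
  expect_error(read_quench_table(p2), "increasing")
})

test_that("EEM and CD CSV formats round-trip bit-identically", {
  e <- gen_eem(study_presets()$eem$free, noise_sd = 0.5, seed = 3)
  pe <- withr::local_tempfile(fileext = ".csv")
  write_eem(e, pe)
  be <- read_eem(pe)
  expect_identical(be$ex_nm, e$ex_nm)
  expect_identical(be$em_nm, e$em_nm)
  expect_identical(be$intensity, e$intensity)

  cd <- gen_cd(0.48, noise_sd_mdeg = 0.02, seed = 4)
  pc <- withr::local_tempfile(fileext = ".csv")
  write_cd(cd, pc)
  bc <- read_cd(pc)
  expect_identical(bc$axis_nm, cd$axis_nm)
  expect_identical(bc$signal, cd$signal)
})

test_that("structured results round-trip with full float precision", {
  fit <- stern_volmer_fit(make_quench_table(seq(0, 1e-4, 1e-5), K_SV = 1234.56789))
  path <- withr::local_tempfile(fileext = ".json")
  write_results(fit, path)
  back <- read_results(path)
  expect_identical(back$K_SV, fit$K_SV)
  expect_identical(back$k_q, fit$k_q)
  expect_identical(back$SD, fit$SD)
  expect_match(back$schema, "sv_fit")

  tr <- vant_hoff_fit(c("293" = 4.03e4, "298" = 2.09e4, "303" = 1.41e4))
  write_results(tr, path)
  back <- read_results(path)
  expect_identical(unname(unlist(back$dG_by_T)), unname(tr$dG_by_T))
  expect_identical(back$dH, tr$dH)
})
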