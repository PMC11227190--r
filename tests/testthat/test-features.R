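test_that("peak_max finds the band maximum with documented tie and boundary handling", {
  band <- gen_quench_titration(law = "sv_linear", K_SV = 0)$spectra[[1]]
  pk <- peak_max(band)
  expect_equal(pk$lambda_nm, 348)
  expect_identical(pk$intensity, band$signal[band$axis_nm == 348])
  expect_false(pk$ambiguous)

  flat <- spectrum(300:310, rep(5, 11), "emission")
  pf <- peak_max(flat, window_nm = c(302, 308))
  expect_equal(pf$lambda_nm, 302)          # tie broken toward shorter wavelength
  expect_true(pf$ambiguous)

  off <- peak_max(band, window_nm = c(400, 450))  # window excludes the band
  expect_true(off$at_boundary)
  expect_equal(off$lambda_nm, 400)

  expect_error(peak_max(band, window_nm = c(600, 700)), "window")
  expect_error(peak_max(band, window_nm = c(450, 400)), "window")
})

test_that("shift_report classifies blue, red and negligible drifts", {
  blue <- shift_report(gen_quench_titration(law = "sv_linear", K_SV = 3e3,
                                            shift_total_nm = -6))
  expect_equal(blue$net_shift_nm, -6)
  expect_identical(blue$classification, "blue")

  none <- shift_report(gen_quench_titration(law = "sv_linear", K_SV = 3e3))
  expect_identical(none$classification, "none")
  expect_identical(none$net_shift_nm, 0)

  # sub-threshold drift (finer axis so a 0.5 nm drift is resolvable)
  tiny <- shift_report(gen_quench_titration(law = "sv_linear", K_SV = 3e3,
                                            shift_total_nm = -0.5,
                                            axis_nm = seq(300, 500, 0.25)))
  expect_identical(tiny$classification, "none")

  red <- shift_report(gen_quench_titration(law = "sv_linear", K_SV = 3e3,
                                           shift_total_nm = 4))
  expect_identical(red$classification, "red")
})

test_that("net shift is additive over splitting the ladder", {
  ser <- gen_quench_titration(law = "sv_linear", K_SV = 3e3,
                              shift_total_nm = -6)
  k <- 6L
  first <- titration_series(ser$spectra[1:k], ser$q_molar[1:k], ser$temperature_K)
  qr <- ser$q_molar[k:length(ser$q_molar)] - ser$q_molar[k]
  second <- titration_series(ser$spectra[k:length(ser$spectra)], qr,
                             ser$temperature_K)
  expect_equal(shift_report(first)$net_shift_nm + shift_report(second)$net_shift_nm,
               shift_report(ser)$net_shift_nm)
})

test_that("sfs_slice extracts the constant-offset diagonal of an EEM", {
  grid <- seq(200, 400, 10)
  sym <- eem(grid, grid, outer(grid, grid, function(a, b) exp(-(a - b)^2 / 200)))
  d0 <- sfs_slice(sym, 0)
  expect_equal(d0$signal, rep(1, length(grid)))   # the diagonal itself
  expect_identical(d0$kind, "synchronous")

  pk <- gen_eem(data.frame(ex_nm = 280, em_nm = 340, amplitude = 100))
  s60 <- sfs_slice(pk, 60)
  expect_equal(peak_max(s60)$lambda_nm, 280)      # slice passes through the peak

  expect_error(sfs_slice(pk, 1000), "emission grid")
})

test_that("sfs_slice commutes with intensity scaling", {
  e <- gen_eem(study_presets()$eem$free)
  scaled <- eem(e$ex_nm, e$em_nm, 5 * e$intensity)
  expect_equal(sfs_slice(scaled, 60)$signal, 5 * sfs_slice(e, 60)$signal)
})

test_that("sfs_attribution compares tyrosine- and tryptophan-channel quench depths", {
  expect_identical(sfs_attribution(0.30, 0.45)$attribution, "tryptophan")
  expect_identical(sfs_attribution(0.45, 0.30)$attribution, "tyrosine")
  expect_identical(sfs_attribution(0.40, 0.41)$attribution, "mixed")

  # from full synchronous titrations: deeper quench in the 60-nm channel
  ax <- seq(250, 350, 1)
  s15 <- gen_quench_titration(q_ladder = seq(0, 9e-5, 1e-5), law = "sv_linear",
                              K_SV = 1.2e3, lambda0_nm = 285, axis_nm = ax,
                              kind = "synchronous")
  s60 <- gen_quench_titration(q_ladder = seq(0, 9e-5, 1e-5), law = "sv_linear",
                              K_SV = 3.0e3, lambda0_nm = 282, axis_nm = ax,
                              kind = "synchronous")
  call <- sfs_attribution(s15, s60)
  expect_gt(call$fraction60, call$fraction15)
  expect_identical(call$attribution, "tryptophan")

  zero <- titration_series(replicate(2, spectrum(1:5, c(0, 0, 0, 0, 0), "synchronous"),
                                     simplify = FALSE), c(0, 1e-5), 298)
  expect_error(sfs_attribution(zero, s60), "zero baseline")
})

test_that("eem_peaks recovers the two-peak geometry and the complexation blue shift", {
  p <- study_presets()
  free <- eem_peaks(gen_eem(p$eem$free), n_peaks = 2)
  expect_equal(free$ex_nm, c(280, 230))            # sorted by intensity
  expect_lt(abs(free$em_nm[1] - 348), 10)          # on the 10-nm grid
  expect_equal(free$em_nm[2], 340)
  expect_equal(free$stokes_nm, free$em_nm - free$ex_nm)

  complx <- eem_peaks(gen_eem(p$eem$complex), n_peaks = 2)
  expect_equal(complx$em_nm[2], 330)
  expect_equal(free$em_nm[2] - complx$em_nm[2], 10)  # 10 nm blue shift of peak 2

  zeros <- eem(seq(200, 300, 10), seq(200, 400, 10),
               matrix(0, 11, 21))
  expect_warning(none <- eem_peaks(zeros, 1), "no unmasked")
  expect_identical(nrow(none), 0L)
})

test_that("eem_peaks positions are invariant to adding the masked Rayleigh ridge", {
  p <- study_presets()$eem$free
  clean <- eem_peaks(gen_eem(p), n_peaks = 2)
  ridged <- eem_peaks(gen_eem(p, rayleigh_amplitude = 1e4), n_peaks = 2)
  expect_equal(ridged$ex_nm, clean$ex_nm)
  expect_equal(ridged$em_nm, clean$em_nm)
})
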