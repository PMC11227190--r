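test_that("Stern-Volmer fit recovers generating constants exactly on noiseless data", {
  q <- seq(0, 1e-4, by = 1e-5)
  for (ksv in c(3.06e3, 2.36e3, 1.86e3, 0.5, 1e6)) {
    fit <- stern_volmer_fit(make_quench_table(q, K_SV = ksv))
    expect_rel(fit$K_SV, ksv, 1e-9)
    expect_identical(fit$k_q, fit$K_SV / fit$tau0_s)   # identity holds exactly
    expect_equal(fit$intercept, 1, tolerance = 1e-9)
    expect_equal(fit$R, 1, tolerance = 1e-12)
  }
  # full generator path at the 293 K preset
  ser <- gen_quench_titration(law = "sv_linear", K_SV = 3.06e3,
                              temperature_K = 293)
  fit <- stern_volmer_fit(extract_quench_table(ser), tau0_s = 1e-8)
  expect_rel(fit$K_SV, 3.06e3, 1e-9)
  expect_rel(fit$k_q, 3.06e11, 1e-9)
})

test_that("Stern-Volmer edge cases: two points, no quenching, anti-quenching", {
  two <- data.frame(temperature_K = 298, q_molar = c(0, 1e-4), F = c(100, 50))
  expect_rel(stern_volmer_fit(two)$K_SV, 1e4, 1e-12)

  flat <- data.frame(temperature_K = 298, q_molar = c(0, 1e-5, 2e-5),
                     F = c(80, 80, 80))
  f0 <- stern_volmer_fit(flat)
  expect_identical(f0$K_SV, 0)
  expect_match(f0$warnings, "no quenching", all = FALSE)

  anti <- data.frame(temperature_K = 298, q_molar = c(0, 1e-5, 2e-5),
                     F = c(80, 90, 100))
  fa <- stern_volmer_fit(anti)
  expect_lt(fa$K_SV, 0)
  expect_match(fa$warnings, "anti-quenching", all = FALSE)

  expect_error(stern_volmer_fit(data.frame(temperature_K = 298, q_molar = 0,
                                           F = 10)), "2 points|reference")
})

test_that("double-log fit recovers K and n exactly on noiseless data", {
  q <- seq(0, 1e-4, by = 1e-5)
  cases <- list(c(4.03e4, 1.28), c(2.09e4, 1.24), c(1.41e4, 1.22), c(1e3, 0.9))
  for (cs in cases) {
    fit <- double_log_fit(make_quench_table(q, K = cs[1], n = cs[2]))
    expect_rel(fit$K, cs[1], 1e-9)
    expect_rel(fit$n_sites, cs[2], 1e-9)
  }
  # exact two-point solution of the log-linear system
  two <- data.frame(temperature_K = 298, q_molar = c(0, 1e-5, 1e-4),
                    F = c(100, 100 / 1.1, 50))
  fit <- double_log_fit(two)
  expect_rel(fit$K, 1e4, 1e-9)
  expect_rel(fit$n_sites, 1, 1e-9)
})

test_that("double-log and Stern-Volmer coincide when n = 1", {
  q <- seq(0, 1e-4, by = 1e-5)
  tab <- make_quench_table(q, K_SV = 2.5e3)  # 1/(1+Kq) is both laws at n = 1
  expect_rel(double_log_fit(tab)$K, stern_volmer_fit(tab)$K_SV, 1e-9)
})

test_that("double-log fit drops F >= F0 rows with a warning and needs 2 usable rows", {
  q <- seq(0, 5e-5, by = 1e-5)
  tab <- make_quench_table(q, K = 2e4, n = 1.1)
  tab$F[2] <- tab$F[1] * 1.01           # anti-quenching point
  fit <- double_log_fit(tab)
  expect_match(fit$warnings, "dropped", all = FALSE)
  expect_equal(fit$n_points, length(q) - 2L)

  small <- make_quench_table(c(0, 1e-5, 2e-5), K = 2e4, n = 1)
  small$F[2:3] <- small$F[1]
  expect_error(double_log_fit(small), "fewer than 2")
})

test_that("both linear fits match a brute-force normal-equation oracle", {
  set.seed(42)
  for (rep in 1:20) {
    npts <- sample(3:12, 1)
    q <- sort(runif(npts, 1e-6, 1e-4))
    q <- c(0, q)
    F0 <- runif(1, 100, 1000)
    F <- F0 / (1 + runif(1, 1e3, 1e5) * q) * (1 + rnorm(npts + 1, sd = 0.02))
    tab <- data.frame(temperature_K = 298, q_molar = q, F = abs(F))
    sv <- stern_volmer_fit(tab)
    o <- ols_oracle(q, abs(F[1]) / abs(F))
    expect_rel(sv$K_SV, o$slope, 1e-10)
    usable <- q > 0 & abs(F) < abs(F[1])
    if (sum(usable) >= 2) {
      dl <- double_log_fit(tab)
      o2 <- ols_oracle(log10(q[usable]),
                       log10((abs(F[1]) - abs(F)[usable]) / abs(F)[usable]))
      expect_rel(dl$n_sites, o2$slope, 1e-10)
      expect_rel(dl$K, 10^o2$intercept, 1e-10)
    }
  }
})

test_that("fitted constants are invariant to rescaling all intensities", {
  q <- seq(0, 1e-4, by = 1e-5)
  tab <- make_quench_table(q, K = 3e4, n = 1.2)
  tab$F <- tab$F * (1 + 0.01 * sin(seq_along(q)))  # mild structure, not exact law
  for (c_scale in c(0.01, 3, 1e4)) {
    scaled <- tab; scaled$F <- scaled$F * c_scale
    expect_rel(stern_volmer_fit(scaled)$K_SV, stern_volmer_fit(tab)$K_SV, 1e-12)
    expect_rel(double_log_fit(scaled)$K, double_log_fit(tab)$K, 1e-9)
    expect_rel(double_log_fit(scaled)$n_sites, double_log_fit(tab)$n_sites, 1e-9)
  }
})

test_that("mechanism classification follows the temperature-trend and diffusion-limit rules", {
  q <- seq(0, 1e-4, by = 1e-5)
  fit_at <- function(ksv, tk, tau0 = 1e-8)
    stern_volmer_fit(make_quench_table(q, K_SV = ksv, temperature_K = tk), tau0)

  # decreasing K_SV with T and k_q ~ 1e11 >> diffusion limit: static
  static_fits <- list(fit_at(3.06e3, 293), fit_at(2.36e3, 298), fit_at(1.86e3, 303))
  m <- classify_mechanism(static_fits)
  expect_identical(m$mechanism, "static")
  expect_identical(m$evidence$ksv_trend_with_T, "decreasing")
  expect_true(m$evidence$all_kq_above_diffusion_limit)

  # increasing K_SV, k_q below the limit (long lifetime): dynamic
  dyn_fits <- list(fit_at(50, 293, tau0 = 1e-6), fit_at(80, 298, tau0 = 1e-6),
                   fit_at(120, 303, tau0 = 1e-6))
  expect_identical(classify_mechanism(dyn_fits)$mechanism, "dynamic")

  # non-monotone trend without k_q support: indeterminate
  odd <- list(fit_at(100, 293, 1e-6), fit_at(150, 298, 1e-6), fit_at(120, 303, 1e-6))
  expect_identical(classify_mechanism(odd)$mechanism, "indeterminate")

  # conflicting rules (increasing K_SV but k_q above the limit): indeterminate
  confl <- list(fit_at(2e3, 293), fit_at(3e3, 298), fit_at(4e3, 303))
  expect_identical(classify_mechanism(confl)$mechanism, "indeterminate")

  expect_error(classify_mechanism(list(fit_at(3e3, 298), fit_at(2e3, 298))),
               "distinct temperatures")
})

test_that("displacement calls competition below the K_SV-ratio threshold", {
  q <- seq(0, 1e-4, by = 1e-5)
  free <- stern_volmer_fit(make_quench_table(q, K_SV = 3.06e3, temperature_K = 303))
  warf <- stern_volmer_fit(make_quench_table(q, K_SV = 7.15e2, temperature_K = 303))
  ibu <- stern_volmer_fit(make_quench_table(q, K_SV = 3.26e3, temperature_K = 303))

  dw <- displacement_call(free, warf, "warfarin")
  expect_equal(dw$ratio, 7.15e2 / 3.06e3, tolerance = 1e-6)
  expect_true(dw$competes)
  expect_identical(dw$assigned_site, "site I")

  di <- displacement_call(free, ibu, "ibuprofen")
  expect_equal(di$ratio, 3.26e3 / 3.06e3, tolerance = 1e-6)
  expect_false(di$competes)
  expect_identical(di$site, "site II")
  expect_true(is.na(di$assigned_site))

  dd <- displacement_call(free, free, "warfarin")
  expect_equal(dd$ratio, 1)
  expect_false(dd$competes)

  zero <- free; zero$K_SV <- 0
  expect_error(displacement_call(zero, warf, "warfarin"), "positive")
  wrongT <- stern_volmer_fit(make_quench_table(q, K_SV = 3e3, temperature_K = 298))
  expect_error(displacement_call(free, wrongT, "warfarin"), "temperature")
})
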