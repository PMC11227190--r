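# Independent oracles used across the suite.

# brute-force simple linear regression via explicit normal equations,
# independent of stats::lm
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# closed-form quench table at one temperature: F follows the named law
make_quench_table <- function(q, F0 = 1000, temperature_K = 298,
                              K_SV = NULL, K = NULL, n = NULL) {
  F <- if (!is.null(K_SV)) F0 / (1 + K_SV * q) else F0 / (1 + K * q^n)
  data.frame(temperature_K = temperature_K, q_molar = q, F = F)
}

# direct nonlinear inversion of the 1:1 UV isotherm (independent of any fit)
uv_isotherm <- function(q, A0, Ac, K_b) A0 + (Ac - A0) * K_b * q / (1 + K_b * q)

expect_rel <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = sprintf("%s within %g relative of %s",
                              paste(signif(object, 10), collapse = ","), tol,
                              paste(signif(expected, 10), collapse = ",")))
}
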