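# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force minimum quantization error over every (sign, fraction, code)
# triple of the dual-stage reference
brute_force_best <- function(target, n_bits = 10L, v_supply = 3.3,
                             fractions = c(0, 0.01, 0.02, 0.04, 0.06, 0.08,
                                           0.10, 0.12, 0.14, 0.16, 0.18,
                                           0.20, 0.22, 0.24),
                             denom = 2^n_bits - 1) {
  codes <- 0:(2^n_bits - 1)
  vref <- codes * v_supply / denom
  vals <- outer(vref, fractions)
  all_vals <- c(vals, -vals)
  min(abs(all_vals - target))
}

# Randles-Sevcik peak current for a reversible diffusive couple at 25 C
# (A in cm^2, D in cm^2/s, C in mol/cm^3, v in V/s)
randles_sevcik <- function(n, A, D, C, v) 2.69e5 * n^1.5 * A * sqrt(D) * C * sqrt(v)

# Cottrell current at time t after a diffusion-limited potential step
cottrell <- function(t, n, A, D, C) n * 96485.33212 * A * C * sqrt(D / (pi * t))

# ideal reversible surface-voltammetry CV peak height
surface_cv_peak <- function(n, v, A, gamma, T = 298.15) {
  F <- 96485.33212; R <- 8.314462618
  n^2 * F^2 * v * A * gamma / (4 * R * T)
}

# steady-state amplitude of a tone after first-order low-pass filtering
first_order_gain <- function(f, fc) 1 / sqrt(1 + (f / fc)^2)

# fit the amplitude of a known-frequency tone by least squares
fit_tone_amplitude <- function(x, t, f) {
  co <- stats::coef(stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  unname(sqrt(co[2]^2 + co[3]^2))
}
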