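# Signal-chain model of the miniaturized potentiostat: a microcontroller DAC
# drives the VREF pin of an LMP91000-style analog front end whose internal
# bias ladder outputs a fixed percentage of VREF as the cell potential. The
# working-electrode current is read out through a transimpedance amplifier
# (TIA) whose output rides on an "internal zero" that tracks VREF, with an
# optional RC network in the feedback loop acting as a first-order low-pass.

#' DAC description
#'
#' Ideal n-bit digital-to-analog converter running off the supply rail.
#' The default transfer is `code / (2^n_bits - 1) * v_supply`, the convention
#' of the SAMD21-class DACs in which the full-scale code reaches the supply
#' exactly; `full_scale = "pow2"` selects the `code / 2^n_bits * v_supply`
#' convention instead.
#'
#' @param n_bits resolution in bits (default 10).
#' @param v_supply supply/reference voltage in volts (default 3.3).
#' @param full_scale "max_code" (divisor `2^n - 1`, default) or "pow2"
#'   (divisor `2^n`).
#' @return an object of class `dac_spec`.
#' @examples
#' d <- dac_spec()
#' dac_output(d, 1023)  # 3.3 V at full scale
#' @export
dac_spec <- function(n_bits = 10L, v_supply = 3.3,
                     full_scale = c("max_code", "pow2")) {
  full_scale <- match.arg(full_scale)
  if (!is_number(n_bits) || n_bits < 1 || n_bits != round(n_bits))
    stop_picostat("n_bits must be a positive integer", "picostat_domain_error")
  if (!is_number(v_supply) || v_supply <= 0)
    stop_picostat("v_supply must be a positive voltage", "picostat_domain_error")
  n_bits <- as.integer(n_bits)
  denom <- if (full_scale == "max_code") 2^n_bits - 1 else 2^n_bits
  structure(list(n_bits = n_bits, v_supply = v_supply,
                 full_scale = full_scale, denom = denom),
            class = "dac_spec")
}

#' @export
print.dac_spec <- function(x, ...) {
  cat(sprintf("<dac_spec> %d-bit, %.4g V supply, LSB = %.4g mV (divisor %s)\n",
              x$n_bits, x$v_supply, 1e3 * x$v_supply / x$denom, x$full_scale))
  invisible(x)
}

#' DAC output voltage for a code
#'
#' @param spec a [dac_spec()].
#' @param code integer code(s) in `[0, 2^n_bits - 1]`.
#' @return output voltage(s) in volts.
#' @export
dac_output <- function(spec, code) {
  stopifnot(inherits(spec, "dac_spec"))
  max_code <- 2^spec$n_bits - 1
  if (any(!is.finite(code)) || any(code < 0) || any(code > max_code) ||
      any(code != round(code)))
    stop_picostat(sprintf("DAC code must be an integer in [0, %d]", max_code),
                  "picostat_domain_error")
  code * spec$v_supply / spec$denom
}

#' Bias-ladder description
#'
#' The analog front end's internal reference generator outputs a fixed
#' fraction of the VREF-pin voltage; the stock part exposes 14 fractions
#' between 0 and 24 percent. Cell polarity is modeled as a sign attribute.
#'
#' @param fractions dimensionless divider fractions, sorted ascending.
#' @param signs allowed polarities.
#' @return an object of class `bias_ladder`.
#' @export
bias_ladder <- function(fractions = c(0, 0.01, 0.02, 0.04, 0.06, 0.08, 0.10,
                                      0.12, 0.14, 0.16, 0.18, 0.20, 0.22, 0.24),
                        signs = c(1, -1)) {
  if (!is.numeric(fractions) || length(fractions) < 1 ||
      any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 0.24 + 1e-12))
    stop_picostat("fractions must be finite values in [0, 0.24]",
                  "picostat_domain_error")
  fractions <- sort(unique(fractions))
  if (!all(signs %in% c(-1, 1)))
    stop_picostat("signs must be a subset of {-1, +1}", "picostat_domain_error")
  structure(list(fractions = fractions, signs = sort(unique(signs), decreasing = TRUE)),
            class = "bias_ladder")
}

#' @export
print.bias_ladder <- function(x, ...) {
  cat(sprintf("<bias_ladder> %d fractions: %s\n", length(x$fractions),
              paste0(100 * x$fractions, "%", collapse = ", ")))
  invisible(x)
}

# maximum attainable |v_bias| for a dac/ladder pair
max_bias <- function(dac, ladder) {
  max(ladder$fractions) * dac_output(dac, 2^dac$n_bits - 1)
}

#' Quantize a requested cell potential onto the dual-stage reference
#'
#' The instrument realizes a requested bias as `sign * fraction * v_ref`,
#' where `v_ref` is the DAC output and `fraction` one of the ladder taps.
#' Strategy `"fixed_max_fraction"` pins the ladder at its largest tap and
#' only moves the DAC (constant setpoint spacing of `max_fraction * LSB`);
#' `"exhaustive"` searches every (sign, fraction, code) triple for the global
#' minimum absolute error. Ties are broken by smaller DAC-code change from
#' `prev_code`, then smaller fraction, then positive sign.
#'
#' @param target requested potential, volts.
#' @param dac a [dac_spec()].
#' @param ladder a [bias_ladder()].
#' @param strategy "exhaustive" or "fixed_max_fraction".
#' @param prev_code DAC code of the previous setpoint, used only to break
#'   exact ties (default 0).
#' @return an object of class `bias_setting` with fields `dac_code`,
#'   `fraction`, `sign`, `v_ref`, `v_bias`, `abs_error`.
#' @examples
#' quantize_bias(0.25, dac_spec(), bias_ladder())
#' @export
quantize_bias <- function(target, dac = dac_spec(), ladder = bias_ladder(),
                          strategy = c("exhaustive", "fixed_max_fraction"),
                          prev_code = 0L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(dac, "dac_spec"), inherits(ladder, "bias_ladder"))
  if (!is_number(target))
    stop_picostat("target must be a single finite voltage", "picostat_domain_error")
  lim <- max_bias(dac, ladder)
  if (abs(target) > lim + 1e-12)
    stop_picostat(sprintf(
      "target %.6g V outside the attainable range of +/- %.6g V", target, lim),
      "picostat_range_error")
  max_code <- 2^dac$n_bits - 1
  lsb <- dac$v_supply / dac$denom

  if (strategy == "fixed_max_fraction") {
    frac <- max(ladder$fractions)
    if (frac == 0) {
      cand <- data.frame(code = 0L, fraction = 0, sign = 1)
    } else {
      sgn <- if (target < 0 && -1 %in% ladder$signs) -1 else 1
      ideal <- abs(target) / (frac * lsb)
      codes <- unique(pmin(pmax(c(floor(ideal), ceiling(ideal)), 0), max_code))
      cand <- expand.grid(code = codes, fraction = frac, sign = sgn)
    }
  } else {
    codes <- 0:max_code
    cand <- expand.grid(code = codes, fraction = ladder$fractions,
                        sign = ladder$signs)
  }
  achieved <- cand$sign * cand$fraction * (cand$code * dac$v_supply / dac$denom)
  err <- abs(achieved - target)
  best <- which(err <= min(err) + .Machine$double.eps * abs(target))
  if (length(best) > 1L) {
    o <- order(abs(cand$code[best] - prev_code), cand$fraction[best],
               -cand$sign[best])
    best <- best[o]
  }
  k <- best[1L]
  structure(list(
    dac_code = as.integer(cand$code[k]),
    fraction = cand$fraction[k],
    sign = cand$sign[k],
    v_ref = cand$code[k] * dac$v_supply / dac$denom,
    v_bias = achieved[k],
    abs_error = err[k],
    strategy = strategy
  ), class = "bias_setting")
}

#' @export
print.bias_setting <- function(x, ...) {
  cat(sprintf(
    "<bias_setting> code %d, fraction %.2f, sign %+d -> %.6f V (|err| = %.4g mV)\n",
    x$dac_code, x$fraction, x$sign, x$v_bias, 1e3 * x$abs_error))
  invisible(x)
}

#' Enumerate all achievable cell-potential setpoints
#'
#' @inheritParams quantize_bias
#' @param strategy "exhaustive" (full sign x fraction x code grid),
#'   "fixed_max_fraction" (ladder pinned at its top tap), or "stock"
#'   (DAC pinned at full scale: the unmodified 14-point front end).
#' @return sorted, deduplicated vector of attainable potentials (volts).
#' @export
achievable_setpoints <- function(dac = dac_spec(), ladder = bias_ladder(),
                                 strategy = c("exhaustive", "fixed_max_fraction",
                                              "stock")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(dac, "dac_spec"), inherits(ladder, "bias_ladder"))
  max_code <- 2^dac$n_bits - 1
  vals <- switch(strategy,
    exhaustive = {
      pos <- as.vector(outer(dac_output(dac, 0:max_code), ladder$fractions))
      as.vector(outer(pos, ladder$signs))
    },
    fixed_max_fraction = {
      pos <- max(ladder$fractions) * dac_output(dac, 0:max_code)
      as.vector(outer(pos, ladder$signs))
    },
    stock = as.vector(outer(ladder$fractions * dac$v_supply, ladder$signs))
  )
  sort(unique(vals))
}

#' Voltage resolution of the unmodified front end
#'
#' With the VREF pin held at the supply rail, the only attainable biases are
#' the ladder fractions of the supply; the resolution is the largest gap
#' between adjacent taps.
#'
#' @param ladder a [bias_ladder()].
#' @param v_supply supply voltage, volts.
#' @return worst-case setpoint spacing in volts (0.066 V at 3.3 V).
#' @export
stock_resolution <- function(ladder = bias_ladder(), v_supply = 3.3) {
  stopifnot(inherits(ladder, "bias_ladder"))
  if (!is_number(v_supply) || v_supply <= 0)
    stop_picostat("v_supply must be positive", "picostat_domain_error")
  if (length(ladder$fractions) < 2) return(0)
  max(diff(ladder$fractions)) * v_supply
}

#' Transimpedance amplifier description
#'
#' @param r_feedback feedback resistance, ohms.
#' @param c_feedback feedback capacitance, farads (0 disables the RC filter).
#' @param zero_fraction internal zero as a fraction of VREF; the TIA output
#'   rides on `zero_fraction * v_ref` so bidirectional currents fit a
#'   single-supply range.
#' @param v_rail_low,v_rail_high output rails, volts.
#' @param gain_error multiplicative TIA gain error (datasheet tolerance up to
#'   about 5 percent); default 1 (ideal).
#' @return an object of class `tia_spec`.
#' @export
tia_spec <- function(r_feedback, c_feedback = 0, zero_fraction = 0.5,
                     v_rail_low = 0, v_rail_high = 3.3, gain_error = 1) {
  if (!is_number(r_feedback) || r_feedback <= 0)
    stop_picostat("r_feedback must be positive", "picostat_config_error")
  if (!is_number(c_feedback) || c_feedback < 0)
    stop_picostat("c_feedback must be >= 0", "picostat_domain_error")
  if (!is_number(zero_fraction) || zero_fraction < 0 || zero_fraction > 1)
    stop_picostat("zero_fraction must lie in [0, 1]", "picostat_domain_error")
  if (v_rail_low >= v_rail_high)
    stop_picostat("rails must satisfy v_rail_low < v_rail_high",
                  "picostat_domain_error")
  structure(list(r_feedback = r_feedback, c_feedback = c_feedback,
                 zero_fraction = zero_fraction, v_rail_low = v_rail_low,
                 v_rail_high = v_rail_high, gain_error = gain_error),
            class = "tia_spec")
}

#' TIA output voltage for a cell current
#'
#' `v_out = zero_fraction * v_ref + i_cell * r_feedback`, clipped to the
#' rails. Saturation is flagged in the `"saturated"` attribute, not raised
#' as an error.
#'
#' @param i_cell working-electrode current, amperes (vectorized).
#' @param tia a [tia_spec()].
#' @param v_ref VREF-pin voltage, volts.
#' @return voltages with logical attribute `saturated`.
#' @export
tia_output <- function(i_cell, tia, v_ref) {
  stopifnot(inherits(tia, "tia_spec"))
  if (any(!is.finite(i_cell)))
    stop_picostat("currents must be finite", "picostat_domain_error")
  v <- tia$zero_fraction * v_ref + i_cell * tia$r_feedback * tia$gain_error
  sat <- v < tia$v_rail_low | v > tia$v_rail_high
  v <- pmin(pmax(v, tia$v_rail_low), tia$v_rail_high)
  attr(v, "saturated") <- sat
  v
}

#' Recover the cell current from the TIA output
#'
#' Subtracts the internal zero and divides by the feedback impedance; the
#' exact inverse of [tia_output()] in the unsaturated region.
#'
#' @param v_out TIA output voltage(s).
#' @param tia a [tia_spec()].
#' @param v_ref VREF-pin voltage, volts.
#' @return currents in amperes.
#' @export
current_from_output <- function(v_out, tia, v_ref) {
  stopifnot(inherits(tia, "tia_spec"))
  if (tia$r_feedback == 0)
    stop_picostat("r_feedback must be nonzero to recover a current",
                  "picostat_config_error")
  (as.numeric(v_out) - tia$zero_fraction * v_ref) /
    (tia$r_feedback * tia$gain_error)
}

#' Cutoff frequency of the feedback RC network
#'
#' @param r resistance, ohms.
#' @param c capacitance, farads.
#' @return `1 / (2 pi R C)` in hertz.
#' @examples
#' rc_cutoff(2.2e6, 15e-9)  # ~4.8 Hz
#' rc_cutoff(180e3, 10e-9)  # ~88 Hz
#' @export
rc_cutoff <- function(r, c) {
  if (!is_number(r) || r <= 0 || !is_number(c) || c <= 0)
    stop_picostat("r and c must be positive", "picostat_domain_error")
  1 / (2 * pi * r * c)
}

#' First-order low-pass filter of a sampled current series
#'
#' Exact step-invariant discretization of the single-pole RC response:
#' `y[k] = y[k-1] + (1 - exp(-2 pi fc / fs)) * (x[k] - y[k-1])`, initialized
#' at the first sample so there is no startup transient. DC gain is exactly 1.
#'
#' @param samples input series (e.g. currents in amperes).
#' @param fc cutoff frequency, hertz (`Inf` returns the input unchanged).
#' @param fs sampling rate, hertz.
#' @return filtered series of the same length.
#' @export
lowpass_first_order <- function(samples, fc, fs) {
  if (length(samples) == 0)
    stop_picostat("series must be nonempty", "picostat_domain_error")
  if (!is_number(fs) || fs <= 0)
    stop_picostat("fs must be positive", "picostat_domain_error")
  if (is.infinite(fc)) return(samples)
  if (!is_number(fc) || fc <= 0)
    stop_picostat("fc must be positive (or Inf for no filtering)",
                  "picostat_domain_error")
  a <- 1 - exp(-2 * pi * fc / fs)
  as.numeric(stats::filter(a * samples, 1 - a, method = "recursive",
                           init = samples[1]))
}

#' Additive noise description
#'
#' @param sigma_white standard deviation of white current noise, amperes.
#' @param amp_60hz amplitude of the 60 Hz line tone, amperes.
#' @param seed integer seed; a fixed seed reproduces the realization exactly.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_white = 0, amp_60hz = 0, seed = 1L) {
  if (!is_number(sigma_white) || sigma_white < 0)
    stop_picostat("sigma_white must be >= 0", "picostat_domain_error")
  if (!is_number(amp_60hz) || amp_60hz < 0)
    stop_picostat("amp_60hz must be >= 0", "picostat_domain_error")
  structure(list(sigma_white = sigma_white, amp_60hz = amp_60hz,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Add white and 60 Hz line noise to a current series
#'
#' Emulates the ambient mains coupling and input-referred noise of the
#' physical instrument: `samples + N(0, sigma_white) + amp_60hz *
#' sin(2 pi 60 t)`.
#'
#' @param samples currents, amperes.
#' @param times sample times, seconds (same length).
#' @param spec a [noise_spec()].
#' @return noisy series, reproducible under the spec's seed.
#' @export
add_noise <- function(samples, times, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (length(samples) != length(times))
    stop_picostat("samples and times must have the same length",
                  "picostat_domain_error")
  if (length(samples) == 0) return(samples)
  white <- if (spec$sigma_white > 0)
    with_seed(spec$seed, stats::rnorm(length(samples), 0, spec$sigma_white))
  else 0
  samples + white + spec$amp_60hz * sin(2 * pi * 60 * times)
}
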