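# Excitation waveform synthesis. A waveform is a timed staircase of
# potential setpoints: `times[k]` is the sampling instant at the END of the
# k-th dwell, during which `potential[k]` is applied. `sample_idx` marks the
# points at which the instrument records current; square wave voltammetry
# additionally carries (forward, reverse) index pairs and the base-potential
# axis of its difference current.

# staircase from `from` to `to` in increments of `step` (> 0); includes both
# endpoints, appending a short final step with a warning when the span is not
# an integer multiple of step.
stair_seq <- function(from, to, step, include_from = TRUE) {
  if (isTRUE(all.equal(from, to))) return(if (include_from) from else numeric(0))
  dir <- sign(to - from)
  n <- floor(abs(to - from) / step + 1e-9)
  pts <- from + dir * step * seq_len(n)
  if (n == 0 || abs(pts[n] - to) > step * 1e-9) {
    warning(sprintf(
      "span %.6g V is not a multiple of the %.6g V step; final short step added",
      abs(to - from), step), call. = FALSE)
    pts <- c(pts, to)
  } else {
    pts[n] <- to  # snap to the exact endpoint
  }
  if (include_from) c(from, pts) else pts
}

new_waveform <- function(technique, times, potential, sample_idx,
                         params, extra = list()) {
  stopifnot(length(times) == length(potential),
            all(diff(times) > 0), all(sample_idx >= 1),
            all(sample_idx <= length(times)))
  structure(c(list(technique = technique, times = times, potential = potential,
                   sample_idx = as.integer(sample_idx), params = params,
                   quantized = NULL), extra),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s: %d points over %.4g s, %.4g to %.4g V%s\n",
              toupper(x$technique), length(x$times), max(x$times),
              min(x$potential), max(x$potential),
              if (!is.null(x$quantized)) " (quantized)" else ""))
  invisible(x)
}

#' @export
as.data.frame.waveform <- function(x, ...) {
  data.frame(
    time_s = x$times,
    potential_ideal_V = x$potential,
    potential_quantized_V = if (!is.null(x$quantized)) x$quantized$v_bias
                            else NA_real_,
    sample_flag = seq_along(x$times) %in% x$sample_idx
  )
}

#' Cyclic voltammetry parameters
#'
#' @param v_start start (and stop) potential, volts; must lie inside the
#'   vertex interval.
#' @param v_vertex1 first vertex, volts; the initial sweep runs toward it.
#' @param v_vertex2 second vertex, volts.
#' @param step staircase step, volts (> 0).
#' @param scan_rate sweep rate, volts per second.
#' @param n_cycles number of full triangular cycles.
#' @return an object of class `cv_params`.
#' @export
cv_params <- function(v_start, v_vertex1, v_vertex2, step = 1e-3,
                      scan_rate = 0.05, n_cycles = 1L) {
  if (!is_number(step) || step <= 0) stop_picostat("step must be > 0",
                                                   "picostat_domain_error")
  if (!is_number(scan_rate) || scan_rate <= 0)
    stop_picostat("scan_rate must be > 0", "picostat_domain_error")
  if (!is_number(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles))
    stop_picostat("n_cycles must be a positive integer", "picostat_domain_error")
  lo <- min(v_vertex1, v_vertex2); hi <- max(v_vertex1, v_vertex2)
  if (v_start < lo - 1e-12 || v_start > hi + 1e-12)
    stop_picostat("v_start must lie within the vertex interval",
                  "picostat_domain_error")
  structure(list(v_start = v_start, v_vertex1 = v_vertex1,
                 v_vertex2 = v_vertex2, step = step, scan_rate = scan_rate,
                 n_cycles = as.integer(n_cycles)), class = "cv_params")
}

#' Square wave voltammetry parameters
#'
#' @param v_start,v_stop sweep limits of the base staircase, volts.
#' @param step base staircase step, volts (> 0).
#' @param pulse_amp square pulse amplitude, volts (> 0).
#' @param frequency square wave frequency, hertz: one staircase period lasts
#'   `1/frequency`.
#' @param pulse_first "along" (default: first half-pulse oriented along the
#'   sweep direction) or "against".
#' @return an object of class `swv_params`.
#' @export
swv_params <- function(v_start, v_stop, step = 1e-3, pulse_amp = 0.05,
                       frequency = 62.5, pulse_first = c("along", "against")) {
  pulse_first <- match.arg(pulse_first)
  if (!is_number(step) || step <= 0) stop_picostat("step must be > 0",
                                                   "picostat_domain_error")
  if (!is_number(pulse_amp) || pulse_amp <= 0)
    stop_picostat("pulse_amp must be > 0", "picostat_domain_error")
  if (!is_number(frequency) || frequency <= 0)
    stop_picostat("frequency must be > 0", "picostat_domain_error")
  if (isTRUE(all.equal(v_start, v_stop)))
    stop_picostat("v_start and v_stop must differ", "picostat_domain_error")
  structure(list(v_start = v_start, v_stop = v_stop, step = step,
                 pulse_amp = pulse_amp, frequency = frequency,
                 pulse_first = pulse_first), class = "swv_params")
}

#' Normal pulse voltammetry parameters
#'
#' @param v_base baseline potential held between pulses, volts.
#' @param v_stop final pulse potential, volts.
#' @param step pulse-height increment, volts (> 0).
#' @param pulse_width pulse duration, seconds.
#' @param pulse_period time between pulse starts, seconds (> pulse_width).
#' @return an object of class `npv_params`.
#' @export
npv_params <- function(v_base, v_stop, step = 0.01, pulse_width = 0.05,
                       pulse_period = 0.2) {
  if (!is_number(step) || step <= 0) stop_picostat("step must be > 0",
                                                   "picostat_domain_error")
  if (!is_number(pulse_width) || !is_number(pulse_period) ||
      pulse_width <= 0 || pulse_width >= pulse_period)
    stop_picostat("need 0 < pulse_width < pulse_period",
                  "picostat_domain_error")
  structure(list(v_base = v_base, v_stop = v_stop, step = step,
                 pulse_width = pulse_width, pulse_period = pulse_period),
            class = "npv_params")
}

#' Chronoamperometry parameters
#'
#' @param v_initial holding potential before the step, volts.
#' @param v_step potential applied at t = 0 and held, volts.
#' @param duration hold time, seconds.
#' @param sample_rate sampling rate, hertz.
#' @return an object of class `ca_params`.
#' @export
ca_params <- function(v_initial, v_step, duration = 40, sample_rate = 10) {
  if (!is_number(duration) || duration <= 0)
    stop_picostat("duration must be > 0", "picostat_domain_error")
  if (!is_number(sample_rate) || sample_rate <= 0)
    stop_picostat("sample_rate must be > 0", "picostat_domain_error")
  structure(list(v_initial = v_initial, v_step = v_step, duration = duration,
                 sample_rate = sample_rate), class = "ca_params")
}

#' Generate a cyclic voltammetry staircase
#'
#' Triangular staircase from `v_start` toward `v_vertex1`, then to
#' `v_vertex2`, then back to `v_start`, repeated `n_cycles` times. Each
#' setpoint dwells for `step / scan_rate`; current is sampled at the end of
#' every dwell.
#'
#' @param p a [cv_params()].
#' @return a `waveform`.
#' @export
generate_cv <- function(p) {
  stopifnot(inherits(p, "cv_params"))
  one_cycle <- c(stair_seq(p$v_start, p$v_vertex1, p$step, include_from = FALSE),
                 stair_seq(p$v_vertex1, p$v_vertex2, p$step, include_from = FALSE),
                 stair_seq(p$v_vertex2, p$v_start, p$step, include_from = FALSE))
  pot <- c(p$v_start, rep(one_cycle, p$n_cycles))
  dwell <- p$step / p$scan_rate
  times <- dwell * seq_along(pot)
  cycle_id <- c(1L, rep(seq_len(p$n_cycles), each = length(one_cycle)))
  new_waveform("cv", times, pot, seq_along(pot), p,
               extra = list(cycle = cycle_id, dwell = dwell))
}

#' Generate a square wave voltammetry waveform
#'
#' Base staircase from `v_start` to `v_stop`; in each period of duration
#' `1/frequency`, the first half holds `base + pulse_amp` and the second half
#' `base - pulse_amp`, the pulse sign oriented along the sweep direction (see
#' `pulse_first`). Current is sampled at the end of each half-cycle; the
#' difference current `i_forward - i_reverse` is plotted against the base
#' potential (see [swv_difference_current()]).
#'
#' @param p a [swv_params()].
#' @return a `waveform` with a `sample_pairs` matrix (columns `fwd`, `rev`)
#'   and `base` potential axis.
#' @export
generate_swv <- function(p) {
  stopifnot(inherits(p, "swv_params"))
  bases <- stair_seq(p$v_start, p$v_stop, p$step, include_from = TRUE)
  dir <- sign(p$v_stop - p$v_start)
  pa <- if (p$pulse_first == "along") dir * p$pulse_amp else -dir * p$pulse_amp
  n <- length(bases)
  pot <- as.vector(rbind(bases + pa, bases - pa))
  period <- 1 / p$frequency
  times <- as.vector(rbind(period * (seq_len(n) - 0.5), period * seq_len(n)))
  fwd <- 2L * seq_len(n) - 1L
  rev <- 2L * seq_len(n)
  new_waveform("swv", times, pot, seq_along(pot), p,
               extra = list(sample_pairs = cbind(fwd = fwd, rev = rev),
                            base = bases, period = period))
}

#' Generate a normal pulse voltammetry waveform
#'
#' Pulse train: the baseline `v_base` is held between pulses; the k-th pulse
#' (k = 0, 1, ...) steps to `v_base + k * step` (signed toward `v_stop`) for
#' `pulse_width` seconds out of every `pulse_period`. Current is sampled at
#' the end of each pulse.
#'
#' @param p a [npv_params()].
#' @return a `waveform`.
#' @export
generate_npv <- function(p) {
  stopifnot(inherits(p, "npv_params"))
  levels <- stair_seq(p$v_base, p$v_stop, p$step, include_from = TRUE)
  n <- length(levels)
  pot <- as.vector(rbind(rep(p$v_base, n), levels))
  times <- as.vector(rbind(
    p$pulse_period * (seq_len(n) - 1) + (p$pulse_period - p$pulse_width),
    p$pulse_period * seq_len(n)))
  sample_idx <- 2L * seq_len(n)
  new_waveform("npv", times, pot, sample_idx, p,
               extra = list(base = levels,
                            duty = p$pulse_width / p$pulse_period))
}

#' Generate a chronoamperometry waveform
#'
#' One pre-step sample at `v_initial` (t = 0), then the potential steps to
#' `v_step` and is held for `duration` seconds, sampled at `sample_rate`.
#'
#' @param p a [ca_params()].
#' @return a `waveform`; the pre-step point is index 1.
#' @export
generate_ca <- function(p) {
  stopifnot(inherits(p, "ca_params"))
  n <- round(p$duration * p$sample_rate)
  dt <- 1 / p$sample_rate
  times <- c(0, dt * seq_len(n))
  pot <- c(p$v_initial, rep(p$v_step, n))
  # times[1] = 0 marks the pre-step instant; the step occurs at t = 0
  w <- structure(list(technique = "ca", times = times, potential = pot,
                      sample_idx = seq_along(pot), params = p,
                      quantized = NULL, step_index = 2L),
                 class = "waveform")
  w
}

#' Map a waveform's ideal setpoints onto hardware-achievable ones
#'
#' Runs [quantize_bias()] on every setpoint and stores the achieved settings
#' in the waveform's `quantized` field.
#'
#' @param w a `waveform`.
#' @param dac a [dac_spec()].
#' @param ladder a [bias_ladder()].
#' @param strategy quantization strategy, see [quantize_bias()].
#' @return the waveform with `quantized` filled in (data frame with columns
#'   `dac_code`, `fraction`, `sign`, `v_bias`, `abs_error`).
#' @export
quantize_waveform <- function(w, dac = dac_spec(), ladder = bias_ladder(),
                              strategy = c("exhaustive", "fixed_max_fraction")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(w, "waveform"))
  lim <- max_bias(dac, ladder)
  bad <- which(abs(w$potential) > lim + 1e-12)
  if (length(bad))
    stop_picostat(sprintf(
      "setpoint %.6g V (index %d) outside the attainable range of +/- %.6g V",
      w$potential[bad[1]], bad[1], lim), "picostat_range_error")
  uniq <- unique(w$potential)
  prev <- 0L
  cache <- vector("list", length(uniq))
  for (i in seq_along(uniq)) {
    s <- quantize_bias(uniq[i], dac, ladder, strategy, prev_code = prev)
    cache[[i]] <- s
    prev <- s$dac_code
  }
  idx <- match(w$potential, uniq)  # exact: setpoints repeat bit-identically
  w$quantized <- data.frame(
    dac_code = vapply(cache, `[[`, integer(1), "dac_code")[idx],
    fraction = vapply(cache, `[[`, numeric(1), "fraction")[idx],
    sign = vapply(cache, `[[`, numeric(1), "sign")[idx],
    v_ref = vapply(cache, `[[`, numeric(1), "v_ref")[idx],
    v_bias = vapply(cache, `[[`, numeric(1), "v_bias")[idx],
    abs_error = vapply(cache, `[[`, numeric(1), "abs_error")[idx],
    row.names = NULL
  )
  w
}
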