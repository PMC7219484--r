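# Onboard voltammogram analyst: least-squares baseline tangent, peak current
# measured relative to the tangent, noise statistics with a 3-sigma limit of
# detection, and instrument-comparison metrics.

#' Voltammogram container
#'
#' @param potential potentials, volts (need not be monotone: CV cycles).
#' @param current currents, amperes.
#' @param technique technique tag ("cv", "swv", "npv", "ca", ...), optional.
#' @param metadata named list (units, reference electrode, seed, ...).
#' @return an object of class `voltammogram`.
#' @export
voltammogram <- function(potential, current, technique = NA_character_,
                         metadata = list()) {
  if (length(potential) != length(current))
    stop_picostat("potential and current must have the same length",
                  "picostat_domain_error")
  if (length(potential) < 2)
    stop_picostat("a voltammogram needs at least 2 points",
                  "picostat_domain_error")
  structure(list(potential = as.numeric(potential),
                 current = as.numeric(current),
                 n = length(potential), technique = technique,
                 metadata = metadata),
            class = "voltammogram")
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf("<voltammogram> %s%d points, E in [%.4g, %.4g] V, |i| max %s\n",
              if (is.na(x$technique)) "" else paste0(x$technique, ", "),
              x$n, min(x$potential), max(x$potential),
              format_current(max(abs(x$current)))))
  invisible(x)
}

#' @export
as.data.frame.voltammogram <- function(x, ...) {
  data.frame(potential_V = x$potential, current_A = x$current)
}

#' @export
plot.voltammogram <- function(x, ...) {
  plot(x$potential, x$current * 1e6, type = "l",
       xlab = "Potential (V)", ylab = "Current (uA)", ...)
  invisible(x)
}

#' Baseline and peak potential windows
#'
#' Interval endpoints may be given in either order; they are normalized to
#' `lo < hi` on construction.
#'
#' @param baseline length-2 potential window used for the tangent fit, volts.
#' @param peak length-2 potential window searched for the peak, volts.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(baseline, peak) {
  if (length(baseline) != 2 || length(peak) != 2 ||
      any(!is.finite(c(baseline, peak))))
    stop_picostat("baseline and peak must be finite length-2 windows",
                  "picostat_domain_error")
  structure(list(baseline = sort(baseline), peak = sort(peak)),
            class = "region_spec")
}

#' Standard analysis regions for the bundled chemistries
#'
#' Potential windows (vs. Ag/AgCl) for the ferricyanide oxidation and
#' reduction peaks and for the methylene-blue reduction peak of the cocaine
#' aptamer sensor.
#'
#' @param species one of "ferricyanide_ox", "ferricyanide_red",
#'   "cocaine_aptamer".
#' @return a [region_spec()].
#' @export
default_regions <- function(species = c("ferricyanide_ox", "ferricyanide_red",
                                        "cocaine_aptamer")) {
  species <- tryCatch(match.arg(species),
                      error = function(e) stop_picostat(
                        "unknown species; see ?default_regions",
                        "picostat_usage_error"))
  switch(species,
    ferricyanide_ox  = region_spec(baseline = c(-0.185, -0.03),
                                   peak = c(0.14, 0.30)),
    ferricyanide_red = region_spec(baseline = c(0.30, 0.40),
                                   peak = c(0.03, 0.17)),
    cocaine_aptamer  = region_spec(baseline = c(-0.20, -0.05),
                                   peak = c(-0.375, -0.315))
  )
}

# split a (possibly cyclic) voltammogram into monotone sweep segments;
# returns a list of index vectors in time order
sweep_segments <- function(potential) {
  d <- sign(diff(potential))
  d[d == 0] <- NA
  # carry the previous direction across flat runs
  for (k in seq_along(d)) if (is.na(d[k])) d[k] <- if (k > 1) d[k - 1] else NA
  d[is.na(d)] <- 1
  brk <- c(0, which(diff(d) != 0), length(potential) - 1)
  segs <- list()
  for (k in seq_len(length(brk) - 1)) {
    idx <- (brk[k] + 1):(brk[k + 1] + 1)
    segs[[k]] <- list(idx = idx, dir = d[brk[k] + 1])
  }
  segs
}

# restrict a cyclic voltammogram to the sweep segment relevant for the
# requested peak direction: the LAST full-span anodic (increasing E) segment
# for anodic peaks, the last full-span cathodic segment for cathodic peaks.
# Short closing stubs (the return to the start potential) are excluded by a
# span filter.
select_sweep <- function(vg, direction) {
  if (all(diff(vg$potential) >= 0) || all(diff(vg$potential) <= 0))
    return(seq_len(vg$n))
  segs <- sweep_segments(vg$potential)
  want <- if (direction == "anodic") 1 else -1
  dirs <- vapply(segs, `[[`, numeric(1), "dir")
  hit <- which(dirs == want)
  if (!length(hit)) return(seq_len(vg$n))
  spans <- vapply(hit, function(k) {
    e <- vg$potential[segs[[k]]$idx]
    max(e) - min(e)
  }, numeric(1))
  full <- hit[spans >= 0.9 * max(spans)]
  segs[[full[length(full)]]]$idx
}

#' Least-squares baseline tangent
#'
#' Fits the straight line `y = b0 + b1 x` to the points whose potential lies
#' in the baseline window, using the textbook closed-form least-squares sums
#' (as implemented in the instrument firmware).
#'
#' @param vg a [voltammogram()].
#' @param region a [region_spec()].
#' @param idx optional index subset to fit within (e.g. one CV sweep).
#' @return an object of class `baseline_fit` with slope `b1` (A/V),
#'   intercept `b0` (A) and `n_used`.
#' @export
fit_baseline <- function(vg, region, idx = seq_len(vg$n)) {
  stopifnot(inherits(vg, "voltammogram"), inherits(region, "region_spec"))
  sel <- idx[vg$potential[idx] >= region$baseline[1] &
             vg$potential[idx] <= region$baseline[2]]
  x <- vg$potential[sel]; y <- vg$current[sel]
  n <- length(x)
  if (n < 2)
    stop_picostat(sprintf(
      "baseline window [%g, %g] V contains %d point(s); need >= 2",
      region$baseline[1], region$baseline[2], n), "picostat_region_error")
  if (max(x) - min(x) <= 0)
    stop_picostat("all baseline potentials are identical: singular fit",
                  "picostat_region_error")
  sx <- sum(x); sy <- sum(y)
  b1 <- (sum(x * y) - sx * sy / n) / (sum(x * x) - sx^2 / n)
  b0 <- (sy - b1 * sx) / n
  structure(list(b0 = b0, b1 = b1, n_used = n, region = region),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> i = %.6g + %.6g * E (A; %d points in [%g, %g] V)\n",
              x$b0, x$b1, x$n_used, x$region$baseline[1], x$region$baseline[2]))
  invisible(x)
}

#' Peak current relative to the baseline tangent
#'
#' Extrapolates the baseline tangent under the peak window and reports the
#' maximal deviation of the measured current from it:
#' `i_peak = max_i s (y_i - (b0 + b1 x_i))` with `s = +1` for anodic and
#' `s = -1` for cathodic peaks. Cyclic inputs are first restricted to the
#' final sweep in the relevant direction (forward sweep for anodic, reverse
#' for cathodic).
#'
#' @param vg a [voltammogram()].
#' @param regions a [region_spec()].
#' @param direction "anodic" or "cathodic".
#' @return an object of class `peak_result` with `i_peak` (A, nonnegative for
#'   a true peak in the stated direction), `v_peak` (V) and the
#'   `baseline_fit`.
#' @export
find_peak <- function(vg, regions, direction = c("anodic", "cathodic")) {
  direction <- match.arg(direction)
  stopifnot(inherits(vg, "voltammogram"), inherits(regions, "region_spec"))
  idx <- if (identical(vg$technique, "cv")) select_sweep(vg, direction)
         else seq_len(vg$n)
  fit <- fit_baseline(vg, regions, idx)
  sel <- idx[vg$potential[idx] >= regions$peak[1] &
             vg$potential[idx] <= regions$peak[2]]
  if (!length(sel))
    stop_picostat(sprintf("peak window [%g, %g] V contains no points",
                          regions$peak[1], regions$peak[2]),
                  "picostat_region_error")
  s <- if (direction == "anodic") 1 else -1
  dev <- s * (vg$current[sel] - (fit$b0 + fit$b1 * vg$potential[sel]))
  k <- which.max(dev)
  structure(list(i_peak = dev[k], v_peak = vg$potential[sel][k],
                 direction = direction, fit = fit),
            class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("<peak_result> %s peak %s at %.4g V (tangent-relative)\n",
              x$direction, format_current(x$i_peak), x$v_peak))
  invisible(x)
}

#' Noise statistics and 3-sigma limit of detection
#'
#' `sigma` is the sample standard deviation (n - 1 denominator) of the
#' series; the limit of detection is defined as exactly `3 * sigma`.
#'
#' @param samples current series, amperes.
#' @param fs sampling rate, hertz.
#' @return an object of class `noise_result` with `sigma`, `lod`
#'   (= 3 sigma), `n` and `duration` (s).
#' @export
noise_stats <- function(samples, fs) {
  if (length(samples) < 2)
    stop_picostat("need at least 2 samples", "picostat_domain_error")
  if (!is_number(fs) || fs <= 0)
    stop_picostat("fs must be positive", "picostat_domain_error")
  sigma <- stats::sd(samples)
  structure(list(sigma = sigma, lod = 3 * sigma, n = length(samples),
                 duration = length(samples) / fs), class = "noise_result")
}

#' @export
print.noise_result <- function(x, ...) {
  cat(sprintf("<noise_result> sigma = %s, LOD (3 sigma) = %s over %d samples (%.3g s)\n",
              format_current(x$sigma), format_current(x$lod), x$n, x$duration))
  invisible(x)
}

#' Compare a voltammogram against a reference instrument's trace
#'
#' Linearly interpolates `a` onto the reference `b`'s potential grid over the
#' common potential support and reports the root-mean-square deviation; when
#' analysis regions are supplied, also reports the percent error of the
#' tangent-relative peak currents (reference in the denominator).
#'
#' @param a voltammogram under test.
#' @param b reference voltammogram.
#' @param regions optional [region_spec()] for peak-based comparison.
#' @param direction peak direction if `regions` is given.
#' @return list with `rmse` (A), `n` (compared points) and, with regions,
#'   `percent_error_peak`.
#' @export
compare_voltammograms <- function(a, b, regions = NULL,
                                  direction = c("anodic", "cathodic")) {
  direction <- match.arg(direction)
  stopifnot(inherits(a, "voltammogram"), inherits(b, "voltammogram"))
  lo <- max(min(a$potential), min(b$potential))
  hi <- min(max(a$potential), max(b$potential))
  if (lo >= hi)
    stop_picostat("voltammograms share no potential range",
                  "picostat_domain_error")
  same_grid <- a$n == b$n &&
    max(abs(a$potential - b$potential)) < 1e-12
  if (same_grid) {
    ai <- a$current; bi <- b$current; n <- b$n
  } else {
    mono <- function(v) all(diff(v$potential) > 0) || all(diff(v$potential) < 0)
    if (!mono(a) || !mono(b))
      stop_picostat(paste("grids differ and potentials are not monotone;",
                          "extract a single sweep segment first"),
                    "picostat_usage_error")
    keep <- b$potential >= lo & b$potential <= hi
    ai <- stats::approx(a$potential, a$current, xout = b$potential[keep],
                        ties = mean)$y
    bi <- b$current[keep]
    n <- sum(keep)
  }
  out <- list(rmse = sqrt(mean((ai - bi)^2)), n = n)
  if (!is.null(regions)) {
    pa <- find_peak(a, regions, direction)$i_peak
    pb <- find_peak(b, regions, direction)$i_peak
    out$percent_error_peak <- abs(pa - pb) / pb * 100
  }
  out
}

#' Percent signal gain of a target measurement over a blank
#'
#' @param i_target peak current with target bound, amperes.
#' @param i_blank blank peak current, amperes (> 0).
#' @return gain in percent: `(i_target - i_blank) / i_blank * 100`.
#' @examples
#' signal_gain(1.44e-6, 1.04e-6)  # ~38.5 %
#' @export
signal_gain <- function(i_target, i_blank) {
  if (!is_number(i_blank) || i_blank <= 0)
    stop_picostat("blank peak current must be positive",
                  "picostat_domain_error")
  (i_target - i_blank) / i_blank * 100
}
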