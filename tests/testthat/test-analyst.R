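# Baseline-tangent peak extraction, noise statistics, comparison metrics

test_that("baseline fit reproduces exact and symmetric cases", {
  x <- seq(-0.2, -0.05, by = 0.01)
  vg <- voltammogram(c(x, 0.1, 0.2), c(2 * x + 1, 5, 7))
  fit <- fit_baseline(vg, region_spec(c(-0.2, -0.05), c(0.05, 0.25)))
  expect_equal(fit$b1, 2)
  expect_equal(fit$b0, 1)
  expect_equal(fit$n_used, length(x))
  vg2 <- voltammogram(c(-1, 1), c(1, 1))
  fit2 <- fit_baseline(vg2, region_spec(c(-1, 1), c(0, 1)))
  expect_equal(fit2$b1, 0)
  expect_equal(fit2$b0, 1)
})

test_that("baseline fit agrees with a normal-equations oracle to 1e-10", {
  for (k in 1:20) {
    n <- 30 + k
    x <- with_seed(k, stats::runif(n, -0.3, 0.3))
    y <- with_seed(100 + k, 2e-6 * x + 5e-7 + stats::rnorm(n, 0, 1e-7))
    vg <- voltammogram(x, y)
    fit <- fit_baseline(vg, region_spec(c(-0.3, 0.3), c(0, 0.1)))
    # independent oracle: solve the normal equations directly
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$b0, beta[1], tolerance = 1e-10)
    expect_equal(fit$b1, beta[2], tolerance = 1e-10)
  }
})

test_that("baseline slope is recovered from noisy data within 3 SE", {
  n <- 50; sigma <- 0.5
  x <- seq(0, 1, length.out = n)
  y <- with_seed(31, 3 * x + stats::rnorm(n, 0, sigma))
  vg <- voltammogram(x, y)
  fit <- fit_baseline(vg, region_spec(c(0, 1), c(0, 1)))
  se <- sigma / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(fit$b1 - 3), 3 * se)
})

test_that("degenerate baseline regions are rejected", {
  vg <- voltammogram(c(0, 0.1, 0.2), c(1, 2, 3))
  expect_error(fit_baseline(vg, region_spec(c(0.5, 0.9), c(0, 0.1))),
               class = "picostat_region_error")
  vg_flat <- voltammogram(c(0.1, 0.1, 0.2), c(1, 2, 3))
  expect_error(fit_baseline(vg_flat, region_spec(c(0.05, 0.15), c(0, 0.1))),
               class = "picostat_region_error")
})

test_that("find_peak measures a constructed bump to 1% and a line to ~0", {
  E <- seq(-0.2, 0.4, by = 1e-3)
  line <- 2e-6 * E + 1e-6
  regions <- region_spec(baseline = c(-0.2, -0.05), peak = c(0.1, 0.3))
  vg_line <- voltammogram(E, line)
  expect_lt(find_peak(vg_line, regions, "anodic")$i_peak, 1e-15)
  bump <- 2e-6 * exp(-(E - 0.2)^2 / (2 * 0.03^2))
  vg <- voltammogram(E, line + bump)
  pk <- find_peak(vg, regions, "anodic")
  expect_equal(pk$i_peak, 2e-6, tolerance = 0.01)
  expect_equal(pk$v_peak, 0.2, tolerance = 0.01)
  # cathodic convention: sign-flipped deviation of a downward peak
  vgc <- voltammogram(E, line - bump)
  pkc <- find_peak(vgc, regions, "cathodic")
  expect_equal(pkc$i_peak, 2e-6, tolerance = 0.01)
})

test_that("peak measurement is invariant under affine offsets", {
  E <- seq(-0.2, 0.4, by = 1e-3)
  bump <- 2e-6 * exp(-(E - 0.2)^2 / (2 * 0.03^2))
  regions <- region_spec(c(-0.2, -0.05), c(0.1, 0.3))
  base <- find_peak(voltammogram(E, bump), regions, "anodic")$i_peak
  shifted <- find_peak(voltammogram(E, bump + 3e-6 - 4e-6 * E),
                       regions, "anodic")$i_peak
  expect_equal(shifted, base, tolerance = 1e-9)
})

test_that("peak recovery: median error < 3% over 100 noisy voltammograms", {
  E <- seq(-0.2, 0.4, by = 1e-3)
  regions <- region_spec(c(-0.2, -0.05), c(0.1, 0.3))
  amp <- 2e-6
  errs <- vapply(1:100, function(k) {
    y <- with_seed(1000 + k,
      5e-7 + 1e-6 * E + amp * exp(-(E - 0.2)^2 / (2 * 0.03^2)) +
        stats::rnorm(length(E), 0, 0.01 * amp))
    pk <- find_peak(voltammogram(E, y), regions, "anodic")
    abs(pk$i_peak - amp) / amp
  }, numeric(1))
  expect_lt(stats::median(errs), 0.03)
})

test_that("CV peak extraction uses the final full sweep in each direction", {
  # two-cycle triangular CV carrying a bump only on anodic sweeps
  p <- cv_params(0, -0.2, 0.4, step = 2e-3, scan_rate = 0.1, n_cycles = 2)
  w <- generate_cv(p)
  E <- w$potential
  dirs <- c(1, sign(diff(E)))
  bump <- ifelse(dirs > 0, 1e-6 * exp(-(E - 0.2)^2 / (2 * 0.03^2)), 0)
  vg <- voltammogram(E, bump, technique = "cv")
  pk <- find_peak(vg, region_spec(c(-0.185, -0.03), c(0.14, 0.3)), "anodic")
  expect_equal(pk$i_peak, 1e-6, tolerance = 0.02)
})

test_that("default regions match the instrument's documented windows", {
  ox <- default_regions("ferricyanide_ox")
  expect_equal(ox$baseline, c(-0.185, -0.03))
  expect_equal(ox$peak, c(0.14, 0.30))
  red <- default_regions("ferricyanide_red")
  expect_equal(red$baseline, c(0.30, 0.40))
  expect_equal(red$peak, c(0.03, 0.17))
  coc <- default_regions("cocaine_aptamer")
  expect_equal(coc$baseline, c(-0.20, -0.05))
  expect_equal(coc$peak, c(-0.375, -0.315))
  for (sp in c("ferricyanide_ox", "ferricyanide_red", "cocaine_aptamer")) {
    r <- default_regions(sp)
    expect_true(r$baseline[1] < r$baseline[2] && r$peak[1] < r$peak[2])
  }
  expect_error(default_regions("caffeine"), class = "picostat_usage_error")
})

test_that("noise statistics pin the sample-sd convention and the 3x LOD rule", {
  ns <- noise_stats(rep(1e-9, 10), fs = 10)
  expect_equal(ns$sigma, 0)
  expect_equal(ns$lod, 0)
  # two-point case fixes the n-1 convention: sd({-1, 1}) = sqrt(2)
  ns2 <- noise_stats(c(-1e-9, 1e-9), fs = 60)
  expect_equal(ns2$sigma, sqrt(2) * 1e-9)
  expect_equal(ns2$lod, 3 * sqrt(2) * 1e-9)
  x <- with_seed(8, stats::rnorm(3600, 0, 2e-9))
  ns3 <- noise_stats(x, fs = 60)
  expect_identical(ns3$lod, 3 * ns3$sigma)
  expect_equal(ns3$duration, 60)
  expect_error(noise_stats(1e-9, fs = 10), class = "picostat_domain_error")
})

test_that("comparison metrics: identity, constant offset, noise floor", {
  vg <- make_fixture("ferri_ca", seed = 2)
  self <- compare_voltammograms(vg, vg)
  expect_equal(self$rmse, 0)
  off <- vg; off$current <- vg$current + 1e-6
  expect_equal(compare_voltammograms(off, vg)$rmse, 1e-6)
  # rmse of two traces with independent noise sigma is ~ sqrt(2) sigma
  E <- seq(-0.5, 0.5, length.out = 3000)
  sig <- 1e-6 * exp(-E^2 / 0.02)
  a <- voltammogram(E, sig + with_seed(41, stats::rnorm(3000, 0, 5e-8)))
  b <- voltammogram(E, sig + with_seed(42, stats::rnorm(3000, 0, 5e-8)))
  expect_equal(compare_voltammograms(a, b)$rmse, sqrt(2) * 5e-8,
               tolerance = 0.05)
  # interpolation onto the reference grid
  a2 <- voltammogram(seq(-0.5, 0.5, length.out = 1777), rep(1e-6, 1777))
  b2 <- voltammogram(E, rep(0, 3000))
  expect_equal(compare_voltammograms(a2, b2)$rmse, 1e-6)
  expect_error(compare_voltammograms(
    voltammogram(c(0, 0.1), c(0, 0)), voltammogram(c(0.5, 0.6), c(0, 0))),
    class = "picostat_domain_error")
})

test_that("signal gain is the relative peak increase in percent", {
  expect_equal(signal_gain(1e-6, 1e-6), 0)
  expect_equal(signal_gain(2e-6, 1e-6), 100)
  expect_equal(signal_gain(1.44e-6, 1.04e-6), (1.44 - 1.04) / 1.04 * 100)
  expect_error(signal_gain(1e-6, 0), class = "picostat_domain_error")
})
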