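# Synthetic electrochemical cells against closed-form electrochemistry

test_that("zero concentration / coverage give identically zero current", {
  w <- generate_cv(cv_params(0, 0.2, -0.2, step = 5e-3, scan_rate = 0.05))
  cell0 <- nernstian_couple(e0 = 0, conc_bulk = 0)
  expect_identical(simulate_diffusive(w, cell0), rep(0, length(w$times)))
  ads0 <- adsorbed_species(e0 = 0, coverage = 0)
  expect_identical(simulate_adsorbed(w, ads0), rep(0, length(w$times)))
})

test_that("diffusive CV peak matches Randles-Sevcik within 5%", {
  cell <- nernstian_couple(e0 = 0.15, conc_bulk = 5e-6, init_state = "reduced")
  v <- 0.05
  w <- generate_cv(cv_params(-0.1, 0.4, -0.1, step = 1e-3, scan_rate = v))
  i <- simulate_diffusive(w, cell)
  ip <- max(i[seq_len(which.max(w$potential))])
  expect_equal(ip, randles_sevcik(1, cell$area, cell$diff_coeff,
                                  cell$conc_bulk, v),
               tolerance = 0.05)
})

test_that("diffusive CA matches the Cottrell decay within 5% over [0.1, 10] s", {
  cell <- nernstian_couple(e0 = 0.15, conc_bulk = 5e-6, init_state = "reduced")
  w <- generate_ca(ca_params(-0.2, 0.5, duration = 10, sample_rate = 10))
  i <- simulate_diffusive(w, cell)
  t <- w$times[-1]
  expected <- cottrell(t, 1, cell$area, cell$diff_coeff, cell$conc_bulk)
  expect_true(all(abs(i[-1] / expected - 1) < 0.05))
})

test_that("diffusive CV peak scales as sqrt(scan rate) over a decade", {
  cell <- nernstian_couple(e0 = 0.15, conc_bulk = 5e-6, init_state = "reduced")
  rates <- c(0.0125, 0.025, 0.05, 0.125)
  ip <- vapply(rates, function(v) {
    w <- generate_cv(cv_params(-0.1, 0.4, -0.1, step = 1e-3, scan_rate = v))
    i <- simulate_diffusive(w, cell)
    max(i[seq_len(which.max(w$potential))])
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(ip) ~ log(rates)))[[2]]
  expect_lt(abs(slope - 0.5), 0.03)
})

test_that("adsorbed CV: peaks at e0, zero separation, closed-form height", {
  ads <- adsorbed_species(e0 = -0.345, coverage = 1.8e-12)
  v <- 0.05
  w <- generate_cv(cv_params(-0.145, -0.545, -0.145, step = 2e-4,
                             scan_rate = v))
  i <- simulate_adsorbed(w, ads)
  turn <- which.min(w$potential)
  k_cath <- which.min(i[seq_len(turn)])
  k_anod <- turn - 1 + which.max(i[turn:length(i)])
  # both peak potentials sit at e0 (within one staircase step)
  expect_lt(abs(w$potential[k_cath] - ads$e0), 2 * 2e-4 + 1e-12)
  expect_lt(abs(w$potential[k_anod] - ads$e0), 2 * 2e-4 + 1e-12)
  expect_lt(abs(w$potential[k_anod] - w$potential[k_cath]), 2 * 2e-4 + 1e-12)
  # peak height within 2% of n^2 F^2 v A Gamma / (4 R T) at fine step size
  cf <- surface_cv_peak(1, v, ads$area, ads$coverage)
  expect_equal(abs(i[k_cath]), cf, tolerance = 0.02)
  expect_equal(i[k_anod], cf, tolerance = 0.02)
})

test_that("adsorbed CV peak scales linearly with scan rate", {
  ads <- adsorbed_species(e0 = -0.345, coverage = 1.8e-12)
  rates <- c(0.0125, 0.025, 0.05, 0.125)
  ip <- vapply(rates, function(v) {
    w <- generate_cv(cv_params(-0.145, -0.545, -0.145, step = 1e-3,
                               scan_rate = v))
    max(abs(simulate_adsorbed(w, ads)))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(ip) ~ log(rates)))[[2]]
  expect_lt(abs(slope - 1), 0.03)
})

test_that("SWV difference current isolates a single peak at e0", {
  ads <- adsorbed_species(e0 = -0.345, coverage = 1.8e-12)
  w <- generate_swv(swv_params(-0.03, -0.5, step = 1e-3, pulse_amp = 0.05,
                               frequency = 62.5))
  i <- simulate_adsorbed(w, ads)
  vg <- swv_difference_current(i, w)
  expect_equal(vg$n, length(w$base))
  k <- which.max(abs(vg$current))
  expect_lt(abs(vg$potential[k] - ads$e0), 5e-3)
  # constant raw current cancels exactly
  vg0 <- swv_difference_current(rep(4.2e-8, length(w$times)), w)
  expect_true(all(vg0$current == 0))
  # difference peak is linear in the coverage gain
  ads2 <- adsorbed_species(e0 = -0.345, coverage = 1.8e-12, gain_factor = 2)
  vg2 <- swv_difference_current(simulate_adsorbed(w, ads2), w)
  expect_equal(max(abs(vg2$current)), 2 * max(abs(vg$current)),
               tolerance = 1e-9)
  expect_error(swv_difference_current(i, generate_ca(ca_params(0, 0.1))),
               class = "picostat_usage_error")
})

test_that("capacitive background: closed-cycle charge cancels, offset shifts", {
  w <- generate_cv(cv_params(0, 0.2, -0.2, step = 2e-3, scan_rate = 0.05))
  i0 <- rep(0, length(w$times))
  expect_identical(add_background(i0, w, background_model(0, 0)), i0)
  icap <- add_background(i0, w, background_model(c_dl = 1e-6))
  dt <- diff(c(0, w$times))
  q <- sum(icap * dt)                     # net charge over the closed loop
  expect_lt(abs(q), 1e-6 * 0.2 * 0.02)    # << C * E_span
  ioff <- add_background(i0, w, background_model(0, i_offset = 1e-9))
  expect_equal(ioff, i0 + 1e-9)
  expect_error(add_background(i0[-1], w, background_model()),
               class = "picostat_domain_error")
})

test_that("fixtures are reproducible bit-for-bit under a fixed seed", {
  for (nm in c("ferri_ca", "aptamer_swv_blank")) {
    a <- make_fixture(nm, seed = 123)
    b <- make_fixture(nm, seed = 123)
    expect_identical(a$current, b$current, info = nm)
    expect_identical(a$potential, b$potential, info = nm)
    f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
    write_voltammogram(a, f1); write_voltammogram(b, f2)
    expect_identical(readLines(f1), readLines(f2), info = nm)
    unlink(c(f1, f2))
  }
  # a different seed changes the realization
  c1 <- make_fixture("ferri_ca", seed = 124)
  expect_false(identical(c1$current, make_fixture("ferri_ca", 123)$current))
  expect_error(make_fixture("nope"), class = "picostat_usage_error")
})

test_that("ferricyanide CV fixture has symmetric tangent-relative peaks", {
  vg <- make_fixture("ferri_cv", seed = 5)
  pa <- find_peak(vg, default_regions("ferricyanide_ox"), "anodic")
  pc <- find_peak(vg, default_regions("ferricyanide_red"), "cathodic")
  expect_gt(pa$i_peak, 1e-5)       # tens of microamps
  expect_equal(pa$i_peak / pc$i_peak, 1, tolerance = 0.02)
})

test_that("aptamer SWV fixtures encode the programmed cocaine signal gain", {
  blank <- make_fixture("aptamer_swv_blank", seed = 21)
  coc <- make_fixture("aptamer_swv_cocaine", seed = 22)
  regions <- default_regions("cocaine_aptamer")
  ib <- find_peak(blank, regions, "cathodic")$i_peak
  ic <- find_peak(coc, regions, "cathodic")$i_peak
  expect_equal(ib, 1e-6, tolerance = 0.15)          # ~1 uA scale
  programmed <- coc$metadata$truth$gain_factor - 1
  expect_equal(ic / ib - 1, programmed, tolerance = 0.05)
})
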