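# Deterministic synthetic datasets mirroring the instrument's two validation
# chemistries: 5 mM ferricyanide-like diffusing couple and a methylene-blue
# aptamer-like adsorbed monolayer with a cocaine-induced signal gain. Cell
# constants the underlying experiments do not pin down (electrode area,
# diffusion coefficient, coverage) are documented plausible defaults declared
# here, in one place; they are calibration knobs of the simulator, not
# measured claims.

.FIXTURE_CELLS <- list(
  ferri = list(
    e0 = 0.15,            # V vs Ag/AgCl, midway between the observed peaks
    n_e = 1L,
    diff_coeff = 7.6e-6,  # cm^2/s, ferro/ferricyanide in aqueous buffer
    conc_bulk = 5e-6,     # mol/cm^3 = 5 mM
    area = 0.0314         # cm^2, 2 mm diameter gold disc
  ),
  aptamer = list(
    e0 = -0.345,          # V vs Ag/AgCl, center of the MB reduction window
    n_e = 1L,
    coverage = 1.8e-12,   # mol/cm^2, calibrated to a ~1 uA SWV peak
    area = 0.0314,
    gain_cocaine = 1.44 / 1.04  # target-bound / blank peak ratio
  ),
  # instrument noise floor (white) plus a small residual of the 60 Hz line
  # tone; fixtures emulate recorded data, i.e. after the feedback RC filter
  # has removed most of the mains pickup
  noise = list(sigma_white = 1.5e-9, amp_60hz = 0.5e-9)
)

#' Generate a named synthetic voltammogram fixture
#'
#' Reproducible stand-in datasets for the instrument's validation
#' experiments, built by running the cell simulator under the corresponding
#' technique parameters and adding white + 60 Hz noise. Fixture names:
#' \describe{
#'   \item{ferri_cv}{5 mM diffusing couple, CV 0 V start/stop over
#'     -0.2..+0.45 V, 1 mV steps, 50 mV/s, 2 cycles (cathodic leg first).}
#'   \item{ferri_swv}{same cell, SWV -0.2 to +0.5 V, 1 mV step, 50 mV pulse,
#'     31.25 Hz (difference current vs. base potential).}
#'   \item{ferri_ca}{same cell, potential step -0.2 to +0.2 V held 40 s,
#'     sampled at 10 Hz.}
#'   \item{ferri_npv}{same cell, NPV -0.2 to +0.5 V, 10 mV steps, 50 ms
#'     pulses every 200 ms.}
#'   \item{aptamer_cv}{adsorbed monolayer, CV 7 cycles, -40 mV start/stop,
#'     -0.45..-0.02 V, 1 mV steps, 50 mV/s.}
#'   \item{aptamer_swv_blank}{adsorbed monolayer, SWV -0.03 to -0.5 V, 1 mV
#'     step, 50 mV pulse, 62.5 Hz.}
#'   \item{aptamer_swv_cocaine}{as the blank but with the effective coverage
#'     scaled by the target-binding gain factor (1.44/1.04).}
#' }
#'
#' @param name fixture name (see Details).
#' @param seed integer seed for the noise realization.
#' @return a [voltammogram()]; `metadata$truth` carries the ground-truth
#'   generator parameters for recovery tests.
#' @export
make_fixture <- function(name = c("ferri_cv", "ferri_swv", "ferri_ca",
                                  "ferri_npv", "aptamer_cv",
                                  "aptamer_swv_blank", "aptamer_swv_cocaine"),
                         seed = 1L) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop_picostat(
                     "unknown fixture name; see ?make_fixture",
                     "picostat_usage_error"))
  fc <- .FIXTURE_CELLS
  ns <- noise_spec(fc$noise$sigma_white, fc$noise$amp_60hz, seed = seed)

  if (startsWith(name, "ferri")) {
    cl <- fc$ferri
    cell <- nernstian_couple(e0 = cl$e0, n_e = cl$n_e,
                             diff_coeff = cl$diff_coeff,
                             conc_bulk = cl$conc_bulk, area = cl$area,
                             init_state = "equilibrium")
    truth <- c(cl, list(fixture = name, seed = seed))
    if (name == "ferri_cv") {
      # cathodic leg first, so the anodic sweep runs -0.2 -> +0.45 V and
      # covers both the oxidation baseline and peak windows; two cycles are
      # run and the analyst reads the second, quasi-reproducible one (the
      # first scan of a fresh cell is history-dependent)
      w <- generate_cv(cv_params(0, -0.2, 0.45, step = 1e-3, scan_rate = 0.05,
                                 n_cycles = 2))
      i <- simulate_diffusive(w, cell, quiet_time = 2)
      i <- add_noise(i, w$times, ns)
      vg <- voltammogram(w$potential, i, technique = "cv",
                         metadata = list(truth = truth))
    } else if (name == "ferri_swv") {
      w <- generate_swv(swv_params(-0.2, 0.5, step = 1e-3, pulse_amp = 0.05,
                                   frequency = 31.25))
      i <- simulate_diffusive(w, cell, quiet_time = 2)
      i <- add_noise(i, w$times, ns)
      vg <- swv_difference_current(i, w)
      vg$metadata <- list(truth = truth)
    } else if (name == "ferri_ca") {
      w <- generate_ca(ca_params(-0.2, 0.2, duration = 40, sample_rate = 10))
      i <- simulate_diffusive(w, cell, quiet_time = 2)
      i <- add_noise(i, w$times, ns)
      vg <- voltammogram(w$potential, i, technique = "ca",
                         metadata = list(truth = truth, time_s = w$times))
    } else { # ferri_npv
      w <- generate_npv(npv_params(-0.2, 0.5, step = 0.01, pulse_width = 0.05,
                                   pulse_period = 0.2))
      i <- simulate_diffusive(w, cell, quiet_time = 2)
      i <- add_noise(i, w$times, ns)
      sel <- w$sample_idx
      vg <- voltammogram(w$base, i[sel], technique = "npv",
                         metadata = list(truth = truth))
    }
    return(vg)
  }

  cl <- fc$aptamer
  gain <- if (name == "aptamer_swv_cocaine") cl$gain_cocaine else 1
  cell <- adsorbed_species(e0 = cl$e0, n_e = cl$n_e, coverage = cl$coverage,
                           area = cl$area, gain_factor = gain)
  truth <- c(cl, list(gain_factor = gain, fixture = name, seed = seed))
  if (name == "aptamer_cv") {
    w <- generate_cv(cv_params(-0.04, -0.45, -0.02, step = 1e-3,
                               scan_rate = 0.05, n_cycles = 7))
    i <- simulate_adsorbed(w, cell)
    i <- add_noise(i, w$times, ns)
    voltammogram(w$potential, i, technique = "cv",
                 metadata = list(truth = truth))
  } else {
    w <- generate_swv(swv_params(-0.03, -0.5, step = 1e-3, pulse_amp = 0.05,
                                 frequency = 62.5))
    i <- simulate_adsorbed(w, cell)
    i <- add_noise(i, w$times, ns)
    vg <- swv_difference_current(i, w)
    vg$metadata <- list(truth = truth)
    vg
  }
}
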