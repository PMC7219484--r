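# Synthetic electrochemical cells. These turn a waveform into a current
# trace so the full instrument chain can be exercised without laboratory
# data: a diffusing Nernstian redox couple (ferricyanide-like), a
# surface-adsorbed reversible species (methylene-blue aptamer-like) whose
# effective coverage scales with target binding, and a capacitive background.

#' Diffusing Nernstian redox couple
#'
#' Reversible (Nernstian) electron transfer with semi-infinite linear
#' diffusion and equal diffusion coefficients for both halves of the couple,
#' so the total concentration profile stays uniform and only one species
#' needs to be tracked.
#'
#' @param e0 formal potential vs. the reference electrode, volts.
#' @param n_e electrons transferred (integer >= 1).
#' @param diff_coeff diffusion coefficient, cm^2/s.
#' @param conc_bulk bulk concentration of the couple, mol/cm^3
#'   (5 mM = 5e-6 mol/cm^3).
#' @param area electrode area, cm^2 (default: 2 mm diameter disc).
#' @param temperature kelvin.
#' @param init_state which half of the couple the bulk solution contains at
#'   t = 0: "reduced", "oxidized", or "equilibrium" (Nernst partition at the
#'   waveform's first setpoint).
#' @return an object of class `nernstian_couple`.
#' @export
nernstian_couple <- function(e0, n_e = 1L, diff_coeff = 7.6e-6,
                             conc_bulk = 5e-6, area = 0.0314,
                             temperature = 298.15,
                             init_state = c("reduced", "oxidized",
                                            "equilibrium")) {
  init_state <- match.arg(init_state)
  if (!is_number(n_e) || n_e < 1 || n_e != round(n_e))
    stop_picostat("n_e must be a positive integer", "picostat_domain_error")
  for (v in c(diff_coeff = diff_coeff, area = area, temperature = temperature))
    if (!is_number(v) || v <= 0)
      stop_picostat("cell parameters must be positive", "picostat_domain_error")
  if (!is_number(conc_bulk) || conc_bulk < 0)
    stop_picostat("conc_bulk must be >= 0", "picostat_domain_error")
  structure(list(e0 = e0, n_e = as.integer(n_e), diff_coeff = diff_coeff,
                 conc_bulk = conc_bulk, area = area, temperature = temperature,
                 init_state = init_state), class = "nernstian_couple")
}

#' Surface-adsorbed reversible redox species
#'
#' An immobilized monolayer (e.g. a methylene-blue-labeled aptamer) whose
#' oxidized fraction follows the Nernst equation at every applied potential.
#' Target binding is emulated as a multiplicative gain on the electroactive
#' coverage.
#'
#' @param e0 formal potential vs. the reference electrode, volts.
#' @param n_e electrons transferred.
#' @param coverage surface concentration Gamma, mol/cm^2.
#' @param area electrode area, cm^2.
#' @param temperature kelvin.
#' @param gain_factor dimensionless scale on the effective coverage
#'   (>= 0; 1 = blank).
#' @return an object of class `adsorbed_species`.
#' @export
adsorbed_species <- function(e0, n_e = 1L, coverage = 1.8e-12, area = 0.0314,
                             temperature = 298.15, gain_factor = 1) {
  if (!is_number(coverage) || coverage < 0)
    stop_picostat("coverage must be >= 0", "picostat_domain_error")
  if (!is_number(gain_factor) || gain_factor < 0)
    stop_picostat("gain_factor must be >= 0", "picostat_domain_error")
  if (!is_number(n_e) || n_e < 1 || n_e != round(n_e))
    stop_picostat("n_e must be a positive integer", "picostat_domain_error")
  structure(list(e0 = e0, n_e = as.integer(n_e), coverage = coverage,
                 area = area, temperature = temperature,
                 gain_factor = gain_factor), class = "adsorbed_species")
}

#' Capacitive / offset background model
#'
#' @param c_dl double-layer capacitance, farads.
#' @param i_offset constant current offset, amperes.
#' @return an object of class `background_model`.
#' @export
background_model <- function(c_dl = 0, i_offset = 0) {
  if (!is_number(c_dl) || c_dl < 0)
    stop_picostat("c_dl must be >= 0", "picostat_domain_error")
  structure(list(c_dl = c_dl, i_offset = i_offset),
            class = "background_model")
}

# Nernst ratio theta = [O]/[R] at potential E
nernst_theta <- function(E, e0, n_e, temperature) {
  exp(n_e * .FARADAY * (E - e0) / (.GAS_R * temperature))
}

#' Simulate a diffusing Nernstian couple under a waveform
#'
#' Solves 1-D semi-infinite diffusion by explicit finite differences with an
#' equilibrium (Nernstian) surface boundary condition; the current follows
#' from the surface concentration gradient of the reduced species (anodic
#' positive). Time sub-stepping is chosen automatically to satisfy the
#' explicit-scheme stability bound `D dt / dx^2 <= lambda`.
#'
#' @param w a `waveform`.
#' @param cell a [nernstian_couple()].
#' @param n_sub sub-steps per shortest waveform dwell (temporal resolution).
#' @param lambda diffusion number cap (stability requires <= 0.5).
#' @param quiet_time equilibration hold at the first setpoint before the
#'   sweep, seconds (currents during the hold are not reported).
#' @param sample_point fraction of each dwell at which the reported current
#'   is evaluated. `NULL` (default) picks a per-technique convention: 0.25
#'   for CV staircases -- the sampling point at which a staircase reproduces
#'   the linear-sweep (Randles-Sevcik) response -- and 1 (end of dwell,
#'   definitional) for SWV, NPV and CA.
#' @return current in amperes at every waveform point.
#' @export
simulate_diffusive <- function(w, cell, n_sub = 25L, lambda = 0.45,
                               quiet_time = 0, sample_point = NULL) {
  stopifnot(inherits(w, "waveform"), inherits(cell, "nernstian_couple"))
  if (length(w$times) == 0)
    stop_picostat("waveform is empty", "picostat_domain_error")
  if (cell$conc_bulk == 0) return(rep(0, length(w$times)))
  if (lambda <= 0 || lambda > 0.5)
    stop_picostat("lambda must lie in (0, 0.5]", "picostat_config_error")
  if (is.null(sample_point))
    sample_point <- if (identical(w$technique, "cv")) 0.25 else 1
  if (!is_number(sample_point) || sample_point <= 0 || sample_point > 1)
    stop_picostat("sample_point must lie in (0, 1]", "picostat_config_error")

  E <- w$potential
  d_int <- diff(c(0, w$times))
  pos <- d_int > 0           # zero-length dwells (e.g. a pre-step sample)
  dt <- min(d_int[pos]) / n_sub
  D <- cell$diff_coeff

  # per-dwell sub-step counts; each dwell is split into a pre-sample chunk
  # (sample_point of the dwell) and a post-sample remainder chunk
  m_tot <- ifelse(pos, ceiling(d_int / dt), 0)
  dt_sub <- ifelse(pos, d_int / pmax(m_tot, 1), 0)
  m1 <- pmin(pmax(round(sample_point * m_tot), ifelse(pos, 1, 0)), m_tot)
  m2 <- m_tot - m1
  m <- as.vector(rbind(m1, m2))
  surf_E <- rep(E, each = 2)
  dt_chunk <- rep(dt_sub, each = 2)
  pick <- 2L * seq_along(E) - 1L

  t_tot <- max(w$times) + quiet_time
  if (quiet_time > 0) {
    mq <- ceiling(quiet_time / dt)
    m <- c(mq, m)
    surf_E <- c(E[1], surf_E)
    dt_chunk <- c(quiet_time / mq, dt_chunk)
    pick <- pick + 1L
  }

  dx <- sqrt(D * dt / lambda)
  L <- 6 * sqrt(D * t_tot)
  N <- as.integer(ceiling(L / dx)) + 1L
  if (!is.finite(N) || N > 2e5 || sum(as.numeric(m)) > 5e7)
    stop_picostat(sprintf(
      "grid too large (%s nodes, %.3g sub-steps); coarsen n_sub or the waveform",
      format(N), sum(as.numeric(m))), "picostat_config_error")
  lam <- ifelse(m > 0, D * dt_chunk / dx^2, 0)

  theta <- nernst_theta(surf_E, cell$e0, cell$n_e, cell$temperature)
  surf <- cell$conc_bulk / (1 + theta)   # reduced-species surface conc.
  bulk <- switch(cell$init_state,
                 reduced = cell$conc_bulk,
                 oxidized = 0,
                 equilibrium = cell$conc_bulk /
                   (1 + nernst_theta(E[1], cell$e0, cell$n_e,
                                     cell$temperature)))
  grad <- diffuse_fd(rep(bulk, N), surf, as.integer(m), lam, bulk)
  cell$n_e * .FARADAY * cell$area * D * grad[pick] / dx
}

#' Simulate a surface-adsorbed reversible species under a waveform
#'
#' The oxidized fraction of the monolayer equilibrates to the Nernst
#' equation at each setpoint; the reported current is the faradaic charge
#' passed during each dwell divided by the dwell time (the dwell-averaged
#' current, which is what a staircase instrument integrates):
#' `i_k = n F A Gamma_eff (f_k - f_{k-1}) / dt_k`, with
#' `Gamma_eff = coverage * gain_factor`. Anodic currents are positive. The
#' monolayer starts at equilibrium with the first setpoint.
#'
#' @param w a `waveform`.
#' @param cell an [adsorbed_species()].
#' @return current in amperes at every waveform point.
#' @export
simulate_adsorbed <- function(w, cell) {
  stopifnot(inherits(w, "waveform"), inherits(cell, "adsorbed_species"))
  if (length(w$times) == 0)
    stop_picostat("waveform is empty", "picostat_domain_error")
  g_eff <- cell$coverage * cell$gain_factor
  if (g_eff == 0) return(rep(0, length(w$times)))
  theta <- nernst_theta(w$potential, cell$e0, cell$n_e, cell$temperature)
  f <- theta / (1 + theta)             # oxidized fraction of the monolayer
  dt <- diff(c(0, w$times))
  df <- diff(c(f[1], f))               # start at equilibrium: i[1] = 0
  cell$n_e * .FARADAY * cell$area * g_eff * df / dt
}

#' Square wave difference current
#'
#' Pairs each period's forward and reverse half-cycle samples and returns
#' the background-suppressed difference current against the base potential.
#'
#' @param raw current series aligned with the waveform's points, amperes.
#' @param w a square-wave `waveform` from [generate_swv()].
#' @return a [voltammogram()] of `(base potential, i_forward - i_reverse)`.
#' @export
swv_difference_current <- function(raw, w) {
  stopifnot(inherits(w, "waveform"))
  if (is.null(w$sample_pairs))
    stop_picostat("waveform carries no square-wave sample schedule",
                  "picostat_usage_error")
  if (length(raw) != length(w$times))
    stop_picostat("current series and waveform lengths differ",
                  "picostat_domain_error")
  voltammogram(w$base, raw[w$sample_pairs[, "fwd"]] - raw[w$sample_pairs[, "rev"]],
               technique = "swv")
}

#' Add capacitive and offset background to a simulated current
#'
#' Adds the double-layer charging current `c_dl * dE/dt` (the staircase
#' derivative averaged over each dwell) plus a constant offset.
#'
#' @param i faradaic current series, amperes.
#' @param w the `waveform` that produced it.
#' @param bg a [background_model()].
#' @return current series with background, amperes.
#' @export
add_background <- function(i, w, bg) {
  stopifnot(inherits(w, "waveform"), inherits(bg, "background_model"))
  if (length(i) != length(w$times))
    stop_picostat("current series and waveform lengths differ",
                  "picostat_domain_error")
  dt <- diff(c(0, w$times))
  dE <- diff(c(w$potential[1], w$potential))
  i + bg$c_dl * dE / dt + bg$i_offset
}
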