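# Voltammogram exchange format and the end-to-end pipeline.
#
# The exchange format is a plain CSV with '#'-prefixed header lines:
#
#   # technique: cv
#   # potential_units: V
#   # current_units: A
#   # reference_electrode: Ag/AgCl
#   potential_V,current_A[,time_s]
#   ...
#
# Values are written with 17 significant digits so that
# read(write(x)) == x to full double precision.

#' Write a voltammogram to CSV
#'
#' @param vg a [voltammogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_voltammogram <- function(vg, path) {
  stopifnot(inherits(vg, "voltammogram"))
  meta <- vg$metadata
  hdr <- c(
    sprintf("# technique: %s", ifelse(is.na(vg$technique), "unknown",
                                      vg$technique)),
    "# potential_units: V",
    "# current_units: A",
    sprintf("# reference_electrode: %s",
            if (!is.null(meta$reference_electrode)) meta$reference_electrode
            else "Ag/AgCl")
  )
  if (!is.null(meta$truth$seed))
    hdr <- c(hdr, sprintf("# seed: %d", meta$truth$seed))
  has_time <- !is.null(meta$time_s)
  cols <- if (has_time) "potential_V,current_A,time_s"
          else "potential_V,current_A"
  fmt <- function(x) sprintf("%.17g", x)
  rows <- if (has_time)
    paste(fmt(vg$potential), fmt(vg$current), fmt(meta$time_s), sep = ",")
  else paste(fmt(vg$potential), fmt(vg$current), sep = ",")
  writeLines(c(hdr, cols, rows), path)
  invisible(path)
}

#' Read a voltammogram from CSV
#'
#' Accepts the format written by [write_voltammogram()]; '#'-prefixed header
#' lines are preserved as metadata. Currents labeled in mA/uA/nA are
#' converted to amperes (with a note); potentials must be in volts.
#'
#' @param path file path.
#' @return a [voltammogram()].
#' @export
read_voltammogram <- function(path) {
  if (!file.exists(path))
    stop_picostat(sprintf("no such file: %s", path), "picostat_io_error")
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  n_head <- match(FALSE, is_comment) - 1L
  if (is.na(n_head) || n_head >= length(lines) - 1L)
    stop_picostat(sprintf("%s: no data rows found", path), "picostat_io_error")
  meta <- list()
  for (ln in lines[seq_len(n_head)]) {
    kv <- sub("^\\s*#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (nzchar(key)) meta[[key]] <- val
  }
  header <- strsplit(lines[n_head + 1L], ",")[[1]]
  header <- trimws(header)
  # allow unit-suffixed current column names, e.g. current_uA
  cur_col <- grep("^current_", header)
  pot_col <- match("potential_V", header)
  if (is.na(pot_col) || length(cur_col) != 1L)
    stop_picostat(sprintf(
      "%s: expected columns potential_V and current_<unit> (got: %s)",
      path, paste(header, collapse = ", ")), "picostat_parse_error")
  body <- lines[-seq_len(n_head + 1L)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",")
  ncol <- length(header)
  bad_len <- which(lengths(parts) != ncol)
  if (length(bad_len))
    stop_picostat(sprintf("%s line %d: expected %d fields, found %d",
                          path, n_head + 1L + bad_len[1], ncol,
                          lengths(parts)[bad_len[1]]),
                  "picostat_parse_error")
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = ncol, byrow = TRUE)
  bad <- which(apply(is.na(mat), 1, any))
  if (length(bad))
    stop_picostat(sprintf("%s line %d: non-numeric value",
                          path, n_head + 1L + bad[1]), "picostat_parse_error")
  current <- mat[, cur_col]
  scales <- c(A = 1, mA = 1e-3, uA = 1e-6, nA = 1e-9, "µA" = 1e-6)
  # header metadata wins over the column-name suffix
  unit <- meta[["current_units"]] %||% sub("^current_", "", header[cur_col])
  if (!unit %in% names(scales))
    stop_picostat(sprintf("%s: unrecognized current units '%s'", path, unit),
                  "picostat_parse_error")
  if (scales[[unit]] != 1)
    message(sprintf("read_voltammogram: converting currents from %s to A",
                    unit))
  current <- current * scales[[unit]]
  if (ncol >= 3 && "time_s" %in% header)
    meta$time_s <- mat[, match("time_s", header)]
  technique <- if (!is.null(meta$technique) && meta$technique != "unknown")
    meta$technique else NA_character_
  voltammogram(mat[, pot_col], current, technique = technique,
               metadata = meta)
}

# ---- pipeline ---------------------------------------------------------------

default_hardware <- function() {
  list(v_supply = 3.3, dac_bits = 10L, full_scale = "max_code",
       bias_fractions = bias_ladder()$fractions,
       r_feedback_ohm = 2.2e6, c_feedback_f = 15e-9,
       zero_fraction = 0.5, rails = c(0, 3.3), gain_error = 1,
       noise = list(sigma_white_a = 0, amp_60hz_a = 0))
}

build_technique <- function(tech) {
  if (is.null(tech$type))
    stop_picostat("technique block needs a 'type'", "picostat_config_error")
  p <- tech[setdiff(names(tech), "type")]
  switch(tolower(tech$type),
    cv  = generate_cv(do.call(cv_params, p)),
    swv = generate_swv(do.call(swv_params, p)),
    npv = generate_npv(do.call(npv_params, p)),
    ca  = generate_ca(do.call(ca_params, p)),
    stop_picostat(sprintf("unknown technique '%s'", tech$type),
                  "picostat_config_error"))
}

build_cell <- function(cell) {
  if (is.null(cell$type))
    stop_picostat("cell block needs a 'type' (diffusive/adsorbed)",
                  "picostat_config_error")
  p <- cell[setdiff(names(cell), c("type", "quiet_time"))]
  switch(tolower(cell$type),
    diffusive = do.call(nernstian_couple, p),
    adsorbed  = do.call(adsorbed_species, p),
    stop_picostat(sprintf("unknown cell type '%s'", cell$type),
                  "picostat_config_error"))
}

#' Run the full virtual-instrument pipeline
#'
#' Excitation waveform -> dual-stage quantization -> cell simulation on the
#' achieved potentials -> readout (noise, feedback RC low-pass, TIA with
#' internal-zero subtraction) -> voltammogram -> baseline-tangent peak
#' analysis. Fully deterministic under the config seed.
#'
#' @param cfg a nested configuration list, or a path to a YAML file holding
#'   one. Blocks: `hardware` (see defaults in the vignette), `technique`
#'   (`type` = cv/swv/npv/ca plus the technique's parameters), `cell`
#'   (`type` = diffusive/adsorbed plus cell parameters, optional
#'   `quiet_time`), optional `background` (`c_dl`, `i_offset`), `analysis`
#'   (`species` or `baseline`/`peak` windows, `direction`), and `seed`.
#' @param quantize logical: route setpoints through the hardware quantizer
#'   (default TRUE).
#' @return an object of class `pipeline_report`: the voltammogram, the peak
#'   result (if an analysis block is present), quantization and saturation
#'   diagnostics, and the config.
#' @export
run_pipeline <- function(cfg, quantize = TRUE) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (!is.list(cfg))
    stop_picostat("cfg must be a list or a YAML path", "picostat_config_error")
  hw <- utils::modifyList(default_hardware(), cfg$hardware %||% list())
  seed <- cfg$seed %||% 1L

  w <- build_technique(cfg$technique)
  dac <- dac_spec(hw$dac_bits, hw$v_supply, hw$full_scale)
  ladder <- bias_ladder(hw$bias_fractions)

  if (quantize) {
    w <- quantize_waveform(w, dac, ladder, strategy = "exhaustive")
    applied <- w$quantized$v_bias
    v_ref <- w$quantized$v_ref
  } else {
    applied <- w$potential
    v_ref <- rep(hw$v_supply, length(w$potential))
  }

  w_sim <- w
  w_sim$potential <- applied
  cell <- build_cell(cfg$cell)
  i_cell <- if (inherits(cell, "nernstian_couple"))
    simulate_diffusive(w_sim, cell,
                       quiet_time = cfg$cell$quiet_time %||% 0)
  else simulate_adsorbed(w_sim, cell)

  if (!is.null(cfg$background))
    i_cell <- add_background(i_cell, w_sim,
                             do.call(background_model, cfg$background))

  ns <- noise_spec(hw$noise$sigma_white_a %||% 0, hw$noise$amp_60hz_a %||% 0,
                   seed = seed)
  i_noisy <- add_noise(i_cell, w$times, ns)

  tia <- tia_spec(hw$r_feedback_ohm, hw$c_feedback_f, hw$zero_fraction,
                  hw$rails[1], hw$rails[2], hw$gain_error %||% 1)
  if (tia$c_feedback > 0) {
    fs <- 1 / stats::median(diff(w$times))
    fc <- rc_cutoff(tia$r_feedback, tia$c_feedback)
    i_filtered <- lowpass_first_order(i_noisy, fc, fs)
  } else i_filtered <- i_noisy

  v_out <- tia_output(i_filtered, tia, v_ref)
  n_sat <- sum(attr(v_out, "saturated"))
  i_meas <- current_from_output(v_out, tia, v_ref)

  vg <- if (w$technique == "swv") swv_difference_current(i_meas, w)
  else if (w$technique == "npv")
    voltammogram(w$base, i_meas[w$sample_idx], technique = "npv")
  else voltammogram(w$potential, i_meas, technique = w$technique,
                    metadata = if (w$technique == "ca")
                      list(time_s = w$times) else list())

  peak <- NULL
  an <- cfg$analysis
  if (!is.null(an)) {
    regions <- if (!is.null(an$species)) default_regions(an$species)
               else region_spec(unlist(an$baseline), unlist(an$peak))
    peak <- find_peak(vg, regions, direction = an$direction %||% "anodic")
  }

  structure(list(voltammogram = vg, peak = peak,
                 quant_max_error = if (quantize) max(w$quantized$abs_error)
                                   else NA_real_,
                 n_saturated = n_sat, seed = seed, config = cfg),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$voltammogram)
  if (!is.na(x$quant_max_error))
    cat(sprintf("  max quantization error: %.4g mV\n", 1e3 * x$quant_max_error))
  if (x$n_saturated > 0)
    cat(sprintf("  WARNING: %d saturated TIA samples\n", x$n_saturated))
  if (!is.null(x$peak)) { cat("  "); print(x$peak) }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
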