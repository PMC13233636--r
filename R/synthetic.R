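#' Construct a recording object
#'
#' A recording is a tibble with `time` (ms) and `value` (pA in voltage
#' clamp, mV in current clamp) plus a metadata attribute describing how it
#' was (or should be) acquired, sufficient to re-simulate it.
#'
#' @param time,value Numeric vectors (uniform time grid, ms).
#' @param meta Named list: `id`, `cell`, `mode` ("vc"/"cc"), `v_hold`,
#'   `i_inj`, `compartments`, `condition` ("control"/"tboa"), `isolation`
#'   ("ampa"/"nmda"/"mixed"), `G_s`, `U_L`, `n_pulses`, `freq_hz`,
#'   `stim_start`, `noise_sigma`, `seed`, `units`.
#' @return A tibble of class `"synapse_recording"`.
#' @export
recording <- function(time, value, meta) {
  stopifnot(length(time) == length(value), length(time) >= 2)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    rlang::abort("recording requires a uniform time grid")
  }
  need <- c("id", "cell", "mode", "condition", "isolation", "G_s", "U_L",
            "n_pulses", "freq_hz", "stim_start")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    rlang::abort(paste("incomplete recording metadata:",
                       paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(time = as.numeric(time), value = as.numeric(value))
  attr(out, "meta") <- meta
  class(out) <- c("synapse_recording", class(out))
  out
}

.rec_meta <- function(id, cell, mode, v_hold, condition, isolation,
                      compartments = 2L, i_inj = 0, n_pulses = 5,
                      freq_hz = 50, stim_start = 10, noise_sigma = 0,
                      seed = NA_integer_) {
  row <- .cell_table[.cell_table$cell == cell, ]
  list(id = id, cell = cell, mode = mode, v_hold = v_hold, i_inj = i_inj,
       compartments = compartments, condition = condition,
       isolation = isolation, G_s = row$G_s, U_L = row$U_L,
       n_pulses = n_pulses, freq_hz = freq_hz, stim_start = stim_start,
       noise_sigma = noise_sigma, seed = seed,
       units = if (mode == "vc") "pA" else "mV")
}

#' Generate a synthetic patch-clamp dataset
#'
#' Forward-simulates the standard experimental design — four cells, 5-pulse
#' 50 Hz trains — and adds i.i.d. Gaussian noise. The set contains a
#' current-clamp/voltage-clamp pair from cell 1 (mixed receptors),
#' AMPA-isolated responses at -80 mV with and without transporter blockade
#' (cell 2), NMDA-isolated responses at -20 mV in control (cell 3) and
#' blockade (cell 4), and an NMDA response at +40 mV (cell 3). Receptor
#' isolation is modelled by zeroing the conductance scale of the blocked
#' receptor. Trains are separated by long (20 s) rest in the experiment, so
#' every trace starts from the resting state.
#'
#' @param params Shared model parameters ([synapse_params()]); per-cell
#'   `G_s`/`U_L` are taken from the built-in cell table.
#' @param noise_sigma Noise standard deviation as a fraction of the
#'   baseline-subtracted trace peak (default 0.05; 0 gives the noiseless
#'   forward solution).
#' @param seed Integer seed for the noise.
#' @param cc_vc_pair,ampa,nmda Logical switches selecting subsets.
#' @return Named list of [recording()] objects.
#' @export
#' @examples
#' recs <- generate_synthetic_dataset(noise_sigma = 0, ampa = TRUE,
#'                                    nmda = FALSE, cc_vc_pair = FALSE)
#' names(recs)
generate_synthetic_dataset <- function(params = synapse_params(),
                                       noise_sigma = 0.05, seed = 1,
                                       cc_vc_pair = TRUE, ampa = TRUE,
                                       nmda = TRUE) {
  set.seed(seed)
  specs <- list()
  if (cc_vc_pair) {
    specs$cell1_vc_control <- .rec_meta("cell1_vc_control", 1, "vc", -70,
                                        "control", "mixed")
    specs$cell1_cc_control <- .rec_meta("cell1_cc_control", 1, "cc", NA,
                                        "control", "mixed")
  }
  if (ampa) {
    specs$cell2_ampa_m80_control <- .rec_meta("cell2_ampa_m80_control", 2,
                                              "vc", -80, "control", "ampa")
    specs$cell2_ampa_m80_tboa <- .rec_meta("cell2_ampa_m80_tboa", 2, "vc",
                                           -80, "tboa", "ampa")
  }
  if (nmda) {
    specs$cell3_nmda_m20_control <- .rec_meta("cell3_nmda_m20_control", 3,
                                              "vc", -20, "control", "nmda")
    specs$cell4_nmda_m20_tboa <- .rec_meta("cell4_nmda_m20_tboa", 4, "vc",
                                           -20, "tboa", "nmda")
    specs$cell3_nmda_p40_control <- .rec_meta("cell3_nmda_p40_control", 3,
                                              "vc", 40, "control", "nmda")
  }

  t_end_for <- function(meta) {
    if (meta$isolation == "ampa") 300
    else if (meta$isolation == "nmda" && meta$condition == "tboa") 2000
    else if (meta$isolation == "nmda") 1200
    else 400
  }
  dt_for <- function(meta) {
    if (meta$isolation == "ampa") 0.2
    else if (meta$isolation == "nmda") 1
    else 0.5
  }

  purrr::imap(specs, function(meta, id) {
    meta$noise_sigma <- noise_sigma
    meta$seed <- seed
    p <- params
    if (meta$isolation == "ampa") p$receptor$gbar_nmda <- 0
    if (meta$isolation == "nmda") p$receptor$gbar_ampa <- 0
    p$neuron$G_s <- meta$G_s
    p$neuron$U_L <- meta$U_L
    clamp <- if (meta$mode == "vc") {
      clamp_spec("vc", v_hold = meta$v_hold,
                 compartments = meta$compartments)
    } else {
      clamp_spec("cc", i_inj = meta$i_inj,
                 compartments = meta$compartments)
    }
    cond <- condition(meta$condition, p)
    proto <- stim_train(n_pulses = meta$n_pulses, freq_hz = meta$freq_hz,
                        amplitude = p$transport$w_nu_pulse,
                        duration = p$transport$dt_pulse,
                        start = meta$stim_start)
    sim <- simulate_synapse(p, proto, clamp, cond, t_end = t_end_for(meta),
                            dt_out = dt_for(meta))
    signal <- if (meta$mode == "vc") sim$i_vc else sim$v_m
    if (noise_sigma > 0) {
      peak <- max(abs(signal - signal[1]))
      signal <- signal + stats::rnorm(length(signal), 0, noise_sigma * peak)
    }
    recording(sim$time, signal, meta)
  })
}
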