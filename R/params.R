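#' Electrotonic parameters of the two-compartment neuron
#'
#' The passive cell is a lumped soma coupled to a single equivalent dendrite.
#' All potentials are in mV, times in ms, conductances in nS, currents in pA.
#'
#' @param tau_m Membrane time constant, ms.
#' @param gamma Dendrite/soma membrane area ratio (dimensionless).
#' @param l Electrotonic parameter: squared ratio of dendritic length to the
#'   characteristic length (dimensionless).
#' @param G_s Somatic leak conductance, nS.
#' @param U_L Leak reversal potential, mV.
#'
#' @return A named list of class `"neuron_params"`.
#' @export
#' @examples
#' neuron_params()
#' neuron_params(G_s = 12, U_L = -69) # cell 2
neuron_params <- function(tau_m = 11, gamma = 2, l = 1.3, G_s = 8, U_L = -70) {
  stopifnot(tau_m > 0, G_s > 0, gamma >= 0, l > 0)
  structure(list(tau_m = tau_m, gamma = gamma, l = l, G_s = G_s, U_L = U_L),
            class = "neuron_params")
}

#' AMPA/NMDA receptor parameters
#'
#' Conductance scales, reversal potentials, magnesium level, the AMPA closing
#' time and the glutamate half-activation constants of the two receptor types.
#' The AMPA sensitivity is a Hill sigmoid (EC50 1000 uM, exponent 1.6), the
#' NMDA sensitivity a first-order saturation (EC50 4.7 uM), so NMDA receptors
#' respond to far lower glutamate than AMPA receptors.
#'
#' @param tau_A AMPA receptor closing (deactivation) time, ms.
#' @param ec50_ampa Glutamate concentration of half-maximal AMPA activation, uM.
#' @param hill_ampa Hill exponent of the AMPA sensitivity (dimensionless).
#' @param ec50_nmda Glutamate concentration of half-maximal NMDA activation, uM.
#' @param gbar_ampa Scale of the AMPA conductance, nS.
#' @param gbar_nmda Scale of the NMDA conductance, nS.
#' @param U_ampa_rev,U_nmda_rev Reversal potentials, mV.
#' @param mg_out Extracellular Mg2+ concentration, mM.
#'
#' @return A named list of class `"receptor_params"`.
#' @export
receptor_params <- function(tau_A = 2.5, ec50_ampa = 1000, hill_ampa = 1.6,
                            ec50_nmda = 4.7, gbar_ampa = 3040, gbar_nmda = 75,
                            U_ampa_rev = 0, U_nmda_rev = 0, mg_out = 1) {
  stopifnot(tau_A > 0, ec50_ampa > 0, ec50_nmda > 0, hill_ampa > 0,
            gbar_ampa >= 0, gbar_nmda >= 0, mg_out >= 0)
  structure(list(tau_A = tau_A, ec50_ampa = ec50_ampa, hill_ampa = hill_ampa,
                 ec50_nmda = ec50_nmda, gbar_ampa = gbar_ampa,
                 gbar_nmda = gbar_nmda, U_ampa_rev = U_ampa_rev,
                 U_nmda_rev = U_nmda_rev, mg_out = mg_out),
            class = "receptor_params")
}

#' Glutamate diffusion and EAAT2 uptake parameters
#'
#' Two extracellular compartments are tracked: the centre of the synaptic
#' cleft and a perisynaptic shell. Glutamate exchanges between them with time
#' constant `tau_glu` (scaled by the volume ratio `beta` on the way back),
#' leaks toward the bulk/perfusate level `c0_tboa` with time constant
#' `tau_diff`, and is removed from the perisynaptic shell by EAAT2 at maximal
#' rate `alpha_periph` with Michaelis constant `k_half_glu` and a
#' sodium-gradient factor. Concentrations are uM except sodium (mM); all
#' times in ms (1.17 s and 410 ms of the source table are stored as 1170 and
#' 410 ms).
#'
#' @param tau_glu Cleft-to-periphery diffusion time, ms.
#' @param tau_diff Periphery-to-bulk diffusion time, ms.
#' @param beta Extracellular-to-cleft volume ratio (dimensionless).
#' @param c0_tboa Background glutamate under transporter blockade, uM
#'   (control background is zero).
#' @param alpha_periph Maximal EAAT2 uptake rate, uM/ms.
#' @param k_half_glu Glutamate concentration of half-maximal uptake, uM.
#' @param na_ext Extracellular Na+, mM.
#' @param na_astro Astrocytic Na+, mM.
#' @param na_half Sodium gradient of half-maximal transport, mM.
#' @param na_exp Exponent of the sodium dependence (dimensionless).
#' @param w_nu_pulse Release amplitude: glutamate flux into the cleft during a
#'   stimulus pulse (the product of per-spike contribution and pulse flux,
#'   which only ever enter as a product), uM/ms.
#' @param dt_pulse Stimulus pulse duration, ms.
#'
#' @return A named list of class `"transport_params"`.
#' @export
transport_params <- function(tau_glu = 2.9, tau_diff = 1170, beta = 66,
                             c0_tboa = 2.0, alpha_periph = 0.31,
                             k_half_glu = 28, na_ext = 130, na_astro = 15,
                             na_half = 50, na_exp = 1.5,
                             w_nu_pulse = 200, dt_pulse = 1) {
  stopifnot(tau_glu > 0, tau_diff > 0, beta > 0, alpha_periph >= 0,
            na_ext > na_astro, c0_tboa >= 0, k_half_glu > 0,
            w_nu_pulse >= 0, dt_pulse > 0)
  structure(list(tau_glu = tau_glu, tau_diff = tau_diff, beta = beta,
                 c0_tboa = c0_tboa, alpha_periph = alpha_periph,
                 k_half_glu = k_half_glu, na_ext = na_ext,
                 na_astro = na_astro, na_half = na_half, na_exp = na_exp,
                 w_nu_pulse = w_nu_pulse, dt_pulse = dt_pulse),
            class = "transport_params")
}

#' Short-term plasticity parameters
#'
#' Facilitation F relaxes to `F0` with the (very fast) time constant `tau_F`
#' and grows toward 1 at rate `H_F` scaled by perisynaptic glutamate;
#' desensitization D recovers to 1 with `tau_D` and is depleted at rate `H_D`
#' in proportion to the instantaneous AMPA activation. `H_D` is stored per ms
#' (the source value 1.3 per second is 0.0013 per ms).
#'
#' @param tau_F Facilitation decay time, ms.
#' @param H_F Facilitation increment rate, 1/ms.
#' @param F0 Resting facilitation (fraction).
#' @param tau_D Recovery time from desensitization, ms.
#' @param H_D Desensitization rate, 1/ms.
#' @param k_half_glu Concentration scale of the facilitation drive, uM
#'   (shared with the transporter Michaelis constant).
#'
#' @return A named list of class `"plasticity_params"`.
#' @export
plasticity_params <- function(tau_F = 0.16, H_F = 64, F0 = 0.42,
                              tau_D = 410, H_D = 0.0013, k_half_glu = 28) {
  stopifnot(tau_F > 0, tau_D > 0, H_F >= 0, H_D >= 0, F0 > 0, F0 <= 1,
            k_half_glu > 0)
  structure(list(tau_F = tau_F, H_F = H_F, F0 = F0, tau_D = tau_D, H_D = H_D,
                 k_half_glu = k_half_glu),
            class = "plasticity_params")
}

#' Full model parameter set
#'
#' Bundles the four parameter groups. Defaults reproduce the reference
#' parameterization of the model (cell 1 electrotonics).
#'
#' @param neuron A [neuron_params()] object.
#' @param receptor A [receptor_params()] object.
#' @param transport A [transport_params()] object.
#' @param plasticity A [plasticity_params()] object.
#'
#' @return A list of class `"synapse_params"` with elements `neuron`,
#'   `receptor`, `transport`, `plasticity`.
#' @export
#' @examples
#' p <- synapse_params()
#' p$receptor$gbar_nmda
synapse_params <- function(neuron = neuron_params(),
                           receptor = receptor_params(),
                           transport = transport_params(),
                           plasticity = plasticity_params()) {
  stopifnot(inherits(neuron, "neuron_params"),
            inherits(receptor, "receptor_params"),
            inherits(transport, "transport_params"),
            inherits(plasticity, "plasticity_params"))
  structure(list(neuron = neuron, receptor = receptor, transport = transport,
                 plasticity = plasticity),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("<synapse_params>\n")
  for (g in names(x)) {
    cat(" ", g, ": ",
        paste(names(x[[g]]), signif(unlist(x[[g]]), 4), sep = "=",
              collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Per-cell fixed electrotonics of the four reference cells.
.cell_table <- data.frame(
  cell = 1:4,
  G_s = c(8, 12, 8.2, 9),
  U_L = c(-70, -69, -34, -4)
)

#' Fixed per-cell electrotonic constants
#'
#' Somatic conductance and leak reversal were measured per cell and held
#' fixed during fitting; all other parameters are shared across cells.
#'
#' @param params A [synapse_params()] object to specialize.
#' @param cell Integer cell id, 1-4.
#' @return `params` with `G_s` and `U_L` replaced by the cell's values.
#' @export
set_cell <- function(params, cell) {
  stopifnot(inherits(params, "synapse_params"),
            cell %in% .cell_table$cell)
  row <- .cell_table[.cell_table$cell == cell, ]
  params$neuron$G_s <- row$G_s
  params$neuron$U_L <- row$U_L
  params
}

#' Update parameters by flat name
#'
#' Convenience for fitting: sets fields addressed by their bare name in
#' whichever group they live (names are unique across groups).
#'
#' @param params A [synapse_params()] object.
#' @param values Named numeric vector or list, e.g. `c(tau_glu = 3.1)`.
#' @return The updated `synapse_params` object.
#' @export
update_params <- function(params, values) {
  stopifnot(inherits(params, "synapse_params"))
  for (nm in names(values)) {
    hit <- FALSE
    for (g in names(params)) {
      if (nm %in% names(params[[g]])) {
        params[[g]][[nm]] <- as.numeric(values[[nm]])
        hit <- TRUE
      }
    }
    if (!hit) {
      rlang::abort(paste0("unknown parameter: ", nm))
    }
  }
  params
}

#' Extract parameters by flat name
#' @param params A [synapse_params()] object.
#' @param names Character vector of field names.
#' @return Named numeric vector.
#' @export
get_params <- function(params, names) {
  flat <- unlist(unname(lapply(unclass(params), unclass)), recursive = FALSE)
  out <- unlist(flat[names])
  if (length(out) != length(names)) {
    rlang::abort("unknown parameter name(s)")
  }
  stats::setNames(as.numeric(out), names)
}

#' Convert a duration to milliseconds
#'
#' Parameter tables in the literature mix seconds and milliseconds; the
#' package stores everything in ms.
#'
#' @param x Numeric duration(s).
#' @param unit `"ms"` or `"s"`.
#' @return Duration in ms.
#' @export
#' @examples
#' to_ms(1.17, "s") # 1170
to_ms <- function(x, unit = c("ms", "s")) {
  unit <- match.arg(unit)
  if (unit == "s") x * 1000 else x
}
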