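#' Voltage-dependent magnesium block of NMDA channels
#'
#' Jahr-Stevens factor `1 / (1 + ([Mg]o / 3.57) exp(-0.062 V))`: near-total
#' block at hyperpolarized potentials, relieved by depolarization.
#'
#' @param V Membrane potential, mV.
#' @param mg_out Extracellular Mg2+ concentration, mM.
#' @return Unblocked fraction in (0, 1\].
#' @export
#' @examples
#' mg_block_factor(0, 3.57)  # 0.5
#' mg_block_factor(-80, 1)   # ~0.024
mg_block_factor <- function(V, mg_out = 1) {
  stopifnot(all(mg_out >= 0))
  1 / (1 + (mg_out / 3.57) * exp(-0.062 * V))
}

#' Recording mode specification
#'
#' @param mode `"vc"` (voltage clamp: soma held at `v_hold`, current
#'   recorded) or `"cc"` (current clamp: `i_inj` injected, voltage recorded).
#' @param v_hold Holding potential, mV (required for `"vc"`).
#' @param i_inj Constant injected somatic current, pA (`"cc"` only).
#' @param compartments 2 for the soma+dendrite model, 1 for the isopotential
#'   reduction (synaptic input arrives directly at the soma).
#' @return An object of class `"clamp_spec"`.
#' @export
clamp_spec <- function(mode = c("vc", "cc"), v_hold = NULL, i_inj = 0,
                       compartments = 2L) {
  mode <- match.arg(mode)
  if (mode == "vc" && is.null(v_hold)) {
    rlang::abort("voltage clamp requires v_hold")
  }
  if (mode == "cc") v_hold <- NA_real_
  stopifnot(compartments %in% c(1L, 2L))
  structure(list(mode = mode, v_hold = v_hold, i_inj = i_inj,
                 compartments = as.integer(compartments)),
            class = "clamp_spec")
}

#' Synaptic currents at given gate states and dendritic potential
#'
#' `I_AMPA = gbar m (U_rev - V)`; `I_NMDA` carries the additional magnesium
#' factor. Currents are positive inward (depolarizing) by this sign
#' convention. Driving force and Mg factor are evaluated at the potential of
#' the compartment carrying the receptors (the dendrite in the
#' two-compartment model).
#'
#' @param m_ampa,m_nmda Gating fractions in \[0, 1\].
#' @param U_d Potential at the receptors, mV.
#' @param p A [receptor_params()] object.
#' @param U_drive Optional separate potential for the driving force
#'   (defaults to `U_d`; the Mg factor always uses `U_d`).
#' @return Named list with `I_ampa` and `I_nmda`, pA.
#' @export
synaptic_currents <- function(m_ampa, m_nmda, U_d, p = receptor_params(),
                              U_drive = U_d) {
  stopifnot(all(m_ampa >= 0), all(m_ampa <= 1), all(m_nmda >= 0),
            all(m_nmda <= 1))
  list(
    I_ampa = p$gbar_ampa * m_ampa * (p$U_ampa_rev - U_drive),
    I_nmda = p$gbar_nmda * m_nmda * mg_block_factor(U_d, p$mg_out) *
      (p$U_nmda_rev - U_drive)
  )
}

#' Current-clamp membrane equations of the two-compartment neuron
#'
#' Soma: `tau_m dU/dt = -(U - U_L) + (2 gamma / l)(U_d - U) + I_inj / G_s`;
#' dendrite: `tau_m dU_d/dt = -(U_d - U_L) - (2 / l)(U_d - U) + I_d / (gamma G_s)`.
#'
#' @param U Somatic potential, mV.
#' @param U_d Dendritic potential, mV.
#' @param I_d Synaptic current delivered to the dendrite, pA.
#' @param I_inj Current injected at the soma, pA.
#' @param p A [neuron_params()] object.
#' @return Named list with `dU` and `dU_d`, mV/ms.
#' @export
cc_rhs <- function(U, U_d, I_d = 0, I_inj = 0, p = neuron_params()) {
  if (p$gamma == 0 && any(I_d != 0)) {
    rlang::abort("gamma = 0 (no dendrite) is inconsistent with nonzero dendritic current")
  }
  list(
    dU = (-(U - p$U_L) + (2 * p$gamma / p$l) * (U_d - U) + I_inj / p$G_s) /
      p$tau_m,
    dU_d = (-(U_d - p$U_L) - (2 / p$l) * (U_d - U) + I_d / (p$gamma * p$G_s)) /
      p$tau_m
  )
}

#' Input conductance seen by a somatically injected current
#'
#' Closed-form steady-state result `G_in = G_s (3 + 2 gamma) / (3 + gamma)`;
#' used to fix `G_s` from a measured input resistance.
#'
#' @param p A [neuron_params()] object.
#' @return Conductance, nS.
#' @export
input_conductance <- function(p = neuron_params()) {
  p$G_s * (3 + 2 * p$gamma) / (3 + p$gamma)
}

#' Dendritic membrane equation under somatic voltage clamp
#'
#' The dendritic equation with the somatic potential fixed at `V_h`.
#'
#' @param U_d Dendritic potential, mV.
#' @param I_d Dendritic synaptic current, pA.
#' @param V_h Holding potential, mV.
#' @param p A [neuron_params()] object.
#' @return dU_d/dt, mV/ms.
#' @export
vc_rhs <- function(U_d, I_d, V_h, p = neuron_params()) {
  (-(U_d - p$U_L) - (2 / p$l) * (U_d - V_h) + I_d / (p$gamma * p$G_s)) /
    p$tau_m
}

#' Resting dendritic potential under voltage clamp
#'
#' `U_d0 = (U_L + 2 V_h / l) / (1 + 2 / l)`.
#'
#' @param p A [neuron_params()] object.
#' @param V_h Holding potential, mV.
#' @return Potential, mV.
#' @export
resting_vc <- function(p = neuron_params(), V_h) {
  (p$U_L + 2 * V_h / p$l) / (1 + 2 / p$l)
}

#' Somatically recorded current under voltage clamp
#'
#' `I_VC = 2 (G_s gamma / l) (U_d - U_d0)`: proportional to the deviation of
#' the dendritic potential from its clamped resting value.
#'
#' @param U_d Dendritic potential, mV.
#' @param V_h Holding potential, mV.
#' @param p A [neuron_params()] object.
#' @return Current, pA.
#' @export
somatic_current_vc <- function(U_d, V_h, p = neuron_params()) {
  2 * (p$G_s * p$gamma / p$l) * (U_d - resting_vc(p, V_h))
}

#' Reconstruct the dendritic current from a somatic voltage-clamp trace
#'
#' Applies the first-order operator
#' `I_d = ((l/2) tau_m d/dt + 1 + l/2) I_VC` that exactly inverts the
#' clamped dendritic cable equation. The derivative is taken by
#' second-order central differences (one-sided at the endpoints), with
#' optional moving-average smoothing beforehand.
#'
#' @param i_vc Numeric vector: uniformly sampled somatic current, pA.
#' @param dt Sampling interval, ms (must be well below `tau_m`).
#' @param p A [neuron_params()] object.
#' @param smooth_window Odd integer moving-average window applied before
#'   differentiation; 0 (default) disables smoothing.
#' @return Numeric vector of reconstructed dendritic current, pA.
#' @export
reconstruct_dendritic_current <- function(i_vc, dt, p = neuron_params(),
                                          smooth_window = 0) {
  n <- length(i_vc)
  if (n < 3) rlang::abort("trace must have at least 3 samples")
  stopifnot(dt > 0)
  x <- i_vc
  if (smooth_window > 1) {
    k <- as.integer(smooth_window)
    if (k %% 2 == 0) rlang::abort("smooth_window must be odd")
    kern <- rep(1 / k, k)
    pad <- (k - 1) / 2
    xp <- c(rep(x[1], pad), x, rep(x[n], pad))
    x <- stats::filter(xp, kern, sides = 2)[(pad + 1):(pad + n)]
  }
  dxdt <- numeric(n)
  dxdt[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  dxdt[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
  dxdt[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  (p$l / 2) * p$tau_m * dxdt + (1 + p$l / 2) * x
}

#' Single-compartment membrane equation
#'
#' The isopotential reduction (`gamma -> 0`, `l -> 0`): synaptic and
#' injected currents act directly on the somatic membrane,
#' `tau_m dU/dt = -(U - U_L) + (I_syn + I_inj) / G_s`.
#'
#' @param U Membrane potential, mV.
#' @param I_syn Total synaptic current, pA.
#' @param I_inj Injected current, pA.
#' @param p A [neuron_params()] object.
#' @return dU/dt, mV/ms.
#' @export
one_compartment_rhs <- function(U, I_syn = 0, I_inj = 0, p = neuron_params()) {
  (-(U - p$U_L) + (I_syn + I_inj) / p$G_s) / p$tau_m
}
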