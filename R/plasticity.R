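#' Time derivative of presynaptic facilitation
#'
#' `dF/dt = (F0 - F)/tau_F + H_F (1 - F) c_periph / k_half_glu`:
#' relaxation to the resting level plus saturating growth toward 1 driven by
#' perisynaptic glutamate (a proxy for presynaptic depolarization via
#' metabotropic/extrasynaptic glutamate receptors).
#'
#' @param F Facilitation factor (fraction in \[0, 1\]).
#' @param c_periph Perisynaptic glutamate, uM.
#' @param p A [plasticity_params()] object.
#' @return dF/dt, 1/ms.
#' @export
facilitation_rhs <- function(F, c_periph, p = plasticity_params()) {
  stopifnot(all(F >= 0), all(F <= 1), all(c_periph >= 0))
  (p$F0 - F) / p$tau_F + p$H_F * (1 - F) * c_periph / p$k_half_glu
}

#' Quasi-steady-state facilitation
#'
#' `tau_F` is far smaller than every other time scale in the model, so F
#' tracks the fixed point of its own equation at the instantaneous
#' perisynaptic glutamate. Using this value in place of the F ODE reduces
#' the system order from 7 to 6.
#'
#' @param c_periph Perisynaptic glutamate, uM.
#' @param p A [plasticity_params()] object.
#' @return The fixed-point facilitation, fraction in \[F0, 1).
#' @export
#' @examples
#' facilitation_qss(0)   # F0
#' facilitation_qss(2)   # ~0.665 at default parameters
facilitation_qss <- function(c_periph, p = plasticity_params()) {
  stopifnot(all(c_periph >= 0))
  x <- p$tau_F * p$H_F * c_periph / p$k_half_glu
  (p$F0 + x) / (1 + x)
}

#' Time derivative of AMPA desensitization
#'
#' `dD/dt = (1 - D)/tau_D - H_D D S_AMPA(c_cleft)`: slow recovery toward 1
#' and depletion in proportion to the currently activatable AMPA fraction.
#'
#' @param D Desensitization factor (fraction in \[0, 1\]).
#' @param c_cleft Cleft glutamate, uM.
#' @param p A [plasticity_params()] object.
#' @param rp A [receptor_params()] object supplying the AMPA sensitivity.
#' @return dD/dt, 1/ms.
#' @export
desensitization_rhs <- function(D, c_cleft, p = plasticity_params(),
                                rp = receptor_params()) {
  stopifnot(all(D >= 0), all(D <= 1))
  (1 - D) / p$tau_D - p$H_D * D * s_ampa(c_cleft, rp)
}

#' Resting desensitization at a constant background glutamate
#'
#' Fixed point of the desensitization equation at frozen cleft glutamate.
#'
#' @inheritParams desensitization_rhs
#' @return Fraction in (0, 1\].
#' @export
desensitization_fixed_point <- function(c_cleft, p = plasticity_params(),
                                        rp = receptor_params()) {
  1 / (1 + p$tau_D * p$H_D * s_ampa(c_cleft, rp))
}
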