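#' AMPA receptor glutamate sensitivity
#'
#' Sigmoidal (Hill) activation as a function of cleft glutamate:
#' `S(c) = 1 / (1 + (ec50/c)^h)`. Returns 0 at `c = 0` (the limit).
#'
#' @param c Glutamate concentration, uM (vectorized, must be >= 0).
#' @param p A [receptor_params()] object.
#' @return Activation fraction in \[0, 1).
#' @export
#' @examples
#' s_ampa(1000, receptor_params()) # 0.5
s_ampa <- function(c, p = receptor_params()) {
  if (any(c < 0)) rlang::abort("glutamate concentration must be >= 0")
  out <- numeric(length(c))
  pos <- c > 0
  out[pos] <- 1 / (1 + (p$ec50_ampa / c[pos])^p$hill_ampa)
  out
}

#' NMDA receptor glutamate sensitivity
#'
#' First-order saturation `S(c) = 1 / (1 + ec50/c) = c / (c + ec50)`, i.e. a
#' much higher glutamate affinity than the AMPA sensitivity.
#'
#' @inheritParams s_ampa
#' @return Activation fraction in \[0, 1).
#' @export
#' @examples
#' s_nmda(4.7, receptor_params()) # 0.5
s_nmda <- function(c, p = receptor_params()) {
  if (any(c < 0)) rlang::abort("glutamate concentration must be >= 0")
  c / (c + p$ec50_nmda)
}

#' Time derivative of the AMPA gating variable
#'
#' First-order relaxation of the AMPA activation `m` toward the
#' desensitization-scaled sensitivity: `dm/dt = (S(c) D - m) / tau_A`.
#'
#' @param m Current AMPA activation (fraction in \[0, 1\]).
#' @param c_cleft Cleft glutamate concentration, uM.
#' @param D Desensitization factor (fraction in \[0, 1\]).
#' @param p A [receptor_params()] object.
#' @return dm/dt, 1/ms.
#' @export
ampa_gate_rhs <- function(m, c_cleft, D, p = receptor_params()) {
  stopifnot(all(m >= 0), all(m <= 1), all(D >= 0), all(D <= 1))
  (s_ampa(c_cleft, p) * D - m) / p$tau_A
}

#' Instantaneous NMDA gating variable
#'
#' NMDA activation follows perisynaptic glutamate without delay:
#' `m = S(c_periph) - S(c0)`, where the second term removes the fraction held
#' desensitized by the constant background `c0`. A transient dip of
#' `c_periph` below `c0` would make the difference negative; it is clipped at
#' zero (optionally with a warning) since it represents a desensitized
#' fraction, not a negative conductance.
#'
#' @param c_periph Perisynaptic glutamate, uM.
#' @param c0 Background glutamate, uM.
#' @param p A [receptor_params()] object.
#' @param warn Warn when clipping negative values (default TRUE).
#' @return Activation fraction in \[0, 1).
#' @export
#' @examples
#' nmda_gate(4.7, 0) # 0.5
nmda_gate <- function(c_periph, c0 = 0, p = receptor_params(), warn = TRUE) {
  if (any(c_periph < 0) || any(c0 < 0)) {
    rlang::abort("glutamate concentration must be >= 0")
  }
  m <- s_nmda(c_periph, p) - s_nmda(c0, p)
  if (any(m < 0)) {
    if (warn) {
      rlang::warn("NMDA gate clipped at 0 (perisynaptic glutamate below background)")
    }
    m <- pmax(m, 0)
  }
  m
}
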