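#' Stimulus train of presynaptic release pulses
#'
#' Release is a sequence of square glutamate flux pulses into the cleft.
#' Pulse windows are half-open `[onset, onset + duration)` so a train is
#' unambiguous at its edges.
#'
#' @param n_pulses Number of pulses.
#' @param freq_hz Train frequency, Hz.
#' @param amplitude Flux amplitude during a pulse, uM/ms (the release
#'   amplitude `w_nu_pulse`).
#' @param duration Pulse duration, ms.
#' @param start Onset of the first pulse, ms.
#' @param onsets Explicit onset times, ms (overrides `n_pulses`/`freq_hz`).
#' @return An object of class `"stim_train"`: list with `onsets`,
#'   `amplitude`, `duration`.
#' @export
#' @examples
#' stim_train() # the default protocol: 5 pulses at 50 Hz
stim_train <- function(n_pulses = 5, freq_hz = 50, amplitude = 200,
                       duration = 1, start = 10, onsets = NULL) {
  if (is.null(onsets)) {
    onsets <- if (n_pulses > 0) start + (seq_len(n_pulses) - 1) * 1000 / freq_hz else numeric(0)
  }
  stopifnot(duration > 0, amplitude >= 0,
            !is.unsorted(onsets, strictly = TRUE) || length(onsets) < 2)
  if (length(onsets) > 1 && any(diff(onsets) < duration)) {
    rlang::abort("pulses must not overlap")
  }
  structure(list(onsets = as.numeric(onsets), amplitude = amplitude,
                 duration = duration),
            class = "stim_train")
}

#' Release flux at given times
#'
#' @param t Time(s), ms.
#' @param s A [stim_train()] object.
#' @return Flux in uM/ms: `amplitude` inside a pulse window, 0 elsewhere.
#' @export
nu <- function(t, s) {
  stopifnot(inherits(s, "stim_train"))
  out <- numeric(length(t))
  for (on in s$onsets) {
    out[t >= on & t < on + s$duration] <- s$amplitude
  }
  out
}

#' Sodium-gradient factor of EAAT2 transport
#'
#' Transport is driven by the transmembrane sodium gradient with a Hill-type
#' dependence: `g^1.5 / (na_half^1.5 + g^1.5)` where `g = na_ext - na_astro`.
#' Constant for fixed sodium levels.
#'
#' @param p A [transport_params()] object.
#' @param gradient Optional sodium gradient in mM overriding
#'   `na_ext - na_astro` (used for half-max solving).
#' @return Fraction in \[0, 1).
#' @export
eaat2_sodium_factor <- function(p = transport_params(), gradient = NULL) {
  g <- if (is.null(gradient)) p$na_ext - p$na_astro else gradient
  stopifnot(all(g >= 0))
  g^p$na_exp / (p$na_half^p$na_exp + g^p$na_exp)
}

#' Normalized EAAT2 uptake rate
#'
#' Product of the constant sodium factor and a Michaelis-Menten glutamate
#' factor `c / (k_half_glu + c)`.
#'
#' @param c Glutamate concentration, uM.
#' @param p A [transport_params()] object.
#' @return Fraction in \[0, 1); multiply by `alpha_periph` for the uptake
#'   flux in uM/ms.
#' @export
#' @examples
#' eaat2_flux(28, transport_params()) # sodium factor * 0.5
eaat2_flux <- function(c, p = transport_params()) {
  if (any(c < 0)) rlang::abort("glutamate concentration must be >= 0")
  eaat2_sodium_factor(p) * c / (p$k_half_glu + c)
}

#' Time derivative of cleft glutamate
#'
#' Exchange with the perisynaptic compartment plus facilitation-scaled
#' release; no uptake term acts in the cleft centre (EAAT2 sits on
#' perisynaptic astrocytic membrane).
#'
#' @param c Cleft glutamate, uM.
#' @param c_periph Perisynaptic glutamate, uM.
#' @param F Facilitation factor (fraction).
#' @param t Time, ms.
#' @param s A [stim_train()] object.
#' @param p A [transport_params()] object.
#' @return dc/dt, uM/ms.
#' @export
cleft_rhs <- function(c, c_periph, F, t, s, p = transport_params()) {
  stopifnot(all(c >= 0), all(c_periph >= 0), all(F >= 0), all(F <= 1))
  (c_periph - c) / p$tau_glu + F * nu(t, s)
}

#' Time derivative of perisynaptic glutamate
#'
#' Back-diffusion from the cleft (volume-scaled), exchange with the bulk
#' level `c0`, and EAAT2 uptake (absent under transporter blockade).
#'
#' @param c Cleft glutamate, uM.
#' @param c_periph Perisynaptic glutamate, uM.
#' @param p A [transport_params()] object.
#' @param uptake_on Logical; FALSE models transporter blockade
#'   (`alpha_periph = 0`).
#' @param c0 Background/bulk glutamate, uM (0 in control).
#' @return dc_periph/dt, uM/ms.
#' @export
periph_rhs <- function(c, c_periph, p = transport_params(), uptake_on = TRUE,
                       c0 = 0) {
  stopifnot(all(c >= 0), all(c_periph >= 0), c0 >= 0)
  alpha <- if (uptake_on) p$alpha_periph else 0
  (c - c_periph) / (p$beta * p$tau_glu) - (c_periph - c0) / p$tau_diff -
    alpha * eaat2_flux(c_periph, p)
}
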