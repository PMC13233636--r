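#' Experimental condition: control or transporter blockade
#'
#' Transporter blockade (TFB-TBOA) is modelled by removing the EAAT2 uptake
#' term and raising the background glutamate to `c0_tboa`; control has
#' uptake on and zero background.
#'
#' @param name `"control"` or `"tboa"`.
#' @param params A [synapse_params()] object (supplies `c0_tboa`).
#' @param uptake_on,c0 Optional explicit overrides.
#' @return An object of class `"syn_condition"` with `uptake_on` and `c0`.
#' @export
#' @examples
#' condition("tboa")
condition <- function(name = c("control", "tboa"), params = synapse_params(),
                      uptake_on = NULL, c0 = NULL) {
  name <- match.arg(name)
  if (is.null(uptake_on)) uptake_on <- name == "control"
  if (is.null(c0)) c0 <- if (name == "control") 0 else params$transport$c0_tboa
  stopifnot(c0 >= 0)
  structure(list(name = name, uptake_on = uptake_on, c0 = c0),
            class = "syn_condition")
}

.mode_code <- function(clamp) {
  base <- if (clamp$mode == "cc") 0 else 1
  base + if (clamp$compartments == 1L) 2 else 0
}

# Flatten params + run configuration into the parameter vector consumed by
# the compiled derivative. Order must match src/synaptode.c.
.pack_parms <- function(params, clamp, cond, nu_now = 0, qss_F = FALSE,
                        drive_at_soma = FALSE) {
  n <- params$neuron; r <- params$receptor; tr <- params$transport
  pl <- params$plasticity
  alpha_eff <- if (cond$uptake_on) {
    tr$alpha_periph * eaat2_sodium_factor(tr)
  } else 0
  c(n$tau_m, n$gamma, n$l, n$G_s, n$U_L,
    r$gbar_ampa, r$gbar_nmda, r$U_ampa_rev, r$U_nmda_rev, r$mg_out,
    r$tau_A, r$ec50_ampa, r$hill_ampa, r$ec50_nmda,
    tr$tau_glu, tr$tau_diff, tr$beta, cond$c0, alpha_eff, tr$k_half_glu,
    pl$tau_F, pl$H_F, pl$F0, pl$tau_D, pl$H_D,
    nu_now, .mode_code(clamp),
    if (clamp$mode == "vc") clamp$v_hold else 0,
    clamp$i_inj,
    as.numeric(drive_at_soma), as.numeric(qss_F))
}

.state_names <- c("U", "U_d", "m_ampa", "c_glu", "c_periph", "F", "D")

# Reference R implementation of the full system, assembled from the exported
# module functions; used for cross-checking the compiled derivative and as
# the engine = "r" option.
.synapse_rhs_r <- function(t, y, ctx) {
  params <- ctx$params; clamp <- ctx$clamp; cond <- ctx$cond
  n <- params$neuron; r <- params$receptor; tr <- params$transport
  pl <- params$plasticity
  y <- stats::setNames(as.numeric(y), .state_names)
  cg <- max(y[["c_glu"]], 0); cp <- max(y[["c_periph"]], 0)
  onecomp <- clamp$compartments == 1L
  clamped <- clamp$mode == "vc"

  mN <- nmda_gate(cp, cond$c0, r, warn = FALSE)
  Feff <- if (ctx$qss_F) facilitation_qss(cp, pl) else y[["F"]]
  Usoma <- if (clamped) clamp$v_hold else y[["U"]]
  Ud <- if (onecomp) Usoma else y[["U_d"]]
  Udrive <- if (onecomp || ctx$drive_at_soma) Usoma else Ud
  cur <- synaptic_currents(y[["m_ampa"]], mN, Ud, r, U_drive = Udrive)
  Id <- cur$I_ampa + cur$I_nmda

  if (onecomp) {
    dU <- if (clamped) 0 else one_compartment_rhs(Usoma, Id, clamp$i_inj, n)
    dUd <- 0
  } else if (clamped) {
    dU <- 0
    dUd <- vc_rhs(Ud, Id, clamp$v_hold, n)
  } else {
    d <- cc_rhs(y[["U"]], Ud, Id, clamp$i_inj, n)
    dU <- d$dU; dUd <- d$dU_d
  }
  dm <- ampa_gate_rhs(min(max(y[["m_ampa"]], 0), 1), cg,
                      min(max(y[["D"]], 0), 1), r)
  dcg <- (cp - cg) / tr$tau_glu + Feff * ctx$nu_now
  dcp <- periph_rhs(cg, cp, tr, uptake_on = cond$uptake_on, c0 = cond$c0)
  dF <- if (ctx$qss_F) 0 else facilitation_rhs(min(max(y[["F"]], 0), 1), cp, pl)
  dD <- desensitization_rhs(min(max(y[["D"]], 0), 1), cg, pl, r)
  list(c(dU, dUd, dm, dcg, dcp, dF, dD))
}

#' Resting state of the full model
#'
#' Fixed point of all seven equations with no stimulation: concentrations at
#' the level set by the background/uptake balance, plasticity factors at
#' their fixed points, gates at their stationary activations, and membrane
#' potentials at the (current-dependent) electrical steady state, solved by
#' scalar root finding.
#'
#' @param params A [synapse_params()] object.
#' @param clamp A [clamp_spec()] object.
#' @param cond A [condition()] object.
#' @return Named numeric vector of the 7 state variables
#'   (`U`, `U_d`, `m_ampa`, `c_glu`, `c_periph`, `F`, `D`).
#' @export
resting_state <- function(params, clamp = clamp_spec("vc", v_hold = -70),
                          cond = condition("control", params)) {
  n <- params$neuron; r <- params$receptor; tr <- params$transport
  pl <- params$plasticity

  # concentrations: c_glu = c_periph = cp*, where cp* balances bulk exchange
  # against uptake (cp* = c0 exactly when uptake is off or c0 = 0)
  if (!cond$uptake_on || cond$c0 == 0) {
    cp <- cond$c0
  } else {
    g <- function(x) periph_rhs(x, x, tr, uptake_on = TRUE, c0 = cond$c0)
    cp <- stats::uniroot(g, c(0, cond$c0), tol = 1e-12)$root
  }
  Dst <- desensitization_fixed_point(cp, pl, r)
  Fst <- facilitation_qss(cp, pl)
  mA <- s_ampa(cp, r) * Dst
  mN <- nmda_gate(cp, cond$c0, r, warn = FALSE)

  syn_at <- function(Ud, Udrive) {
    cur <- synaptic_currents(mA, mN, Ud, r, U_drive = Udrive)
    cur$I_ampa + cur$I_nmda
  }
  if (clamp$compartments == 1L) {
    if (clamp$mode == "vc") {
      U <- clamp$v_hold
    } else {
      f <- function(U) one_compartment_rhs(U, syn_at(U, U), clamp$i_inj, n)
      U <- stats::uniroot(f, interval = c(-150, 60), tol = 1e-12,
                          extendInt = "yes")$root
    }
    Ud <- U
  } else if (clamp$mode == "vc") {
    U <- clamp$v_hold
    f <- function(Ud) vc_rhs(Ud, syn_at(Ud, Ud), clamp$v_hold, n)
    Ud <- stats::uniroot(f, interval = c(-150, 60), tol = 1e-12,
                         extendInt = "yes")$root
  } else {
    # steady soma potential given U_d from the somatic equation, then root
    # solve the dendritic one
    a <- 2 * n$gamma / n$l
    U_of <- function(Ud) (n$U_L + a * Ud + clamp$i_inj / n$G_s) / (1 + a)
    f <- function(Ud) {
      cc_rhs(U_of(Ud), Ud, syn_at(Ud, Ud), clamp$i_inj, n)$dU_d
    }
    Ud <- stats::uniroot(f, interval = c(-150, 60), tol = 1e-12,
                         extendInt = "yes")$root
    U <- U_of(Ud)
  }
  stats::setNames(c(U, Ud, mA, cp, cp, Fst, Dst), .state_names)
}

# Segment boundaries: pulse edges partition [0, t_end] into intervals on
# which the release flux is constant.
.segments <- function(protocol, t_end) {
  edges <- sort(unique(c(0, protocol$onsets, protocol$onsets + protocol$duration,
                         t_end)))
  edges <- edges[edges >= 0 & edges <= t_end]
  if (edges[length(edges)] < t_end) edges <- c(edges, t_end)
  edges
}

#' Simulate the full synaptic transmission model
#'
#' Integrates the coupled 7-ODE system from its resting state with lsoda
#' (automatic stiff/non-stiff switching). The release flux is a train of
#' square pulses; integration is restarted at every pulse edge so adaptive
#' steps cannot skip a pulse, and the maximal internal step during a pulse
#' is bounded.
#'
#' @param params A [synapse_params()] object.
#' @param protocol A [stim_train()] object (the default is the reference
#'   5-pulse 50 Hz protocol).
#' @param clamp A [clamp_spec()] object.
#' @param cond A [condition()] object.
#' @param t_end End of the simulated window, ms.
#' @param dt_out Output sampling interval, ms.
#' @param engine `"c"` (compiled, default) or `"r"` (reference R
#'   implementation).
#' @param rtol,atol Solver tolerances.
#' @param hmax_pulse Maximal internal step during a release pulse, ms.
#' @param qss_F If TRUE, replace the facilitation ODE by its quasi-steady
#'   state (6-ODE variant); the reported `F` column is then the QSS value.
#' @param drive_at_soma If TRUE, evaluate the synaptic driving force at the
#'   somatic potential (the literal printed form) instead of the dendritic
#'   one; the Mg factor always uses the dendritic potential.
#' @param y0 Optional initial state (named as the 7 state variables)
#'   overriding the resting state.
#'
#' @return A tibble of class `"synapse_sim"` with the time grid, the 7 state
#'   trajectories, and derived series `m_nmda`, `g_ampa`, `g_nmda`,
#'   `i_ampa`, `i_nmda` plus the recorded observable: `i_vc` (voltage
#'   clamp, pA) or `v_m` (current clamp, mV). Attributes `params`, `clamp`,
#'   `condition`, `protocol` carry the configuration.
#' @export
#' @examples
#' sim <- simulate_synapse(synapse_params(), t_end = 200)
#' dplyr::slice_max(sim, c_periph, n = 1)
simulate_synapse <- function(params,
                             protocol = stim_train(),
                             clamp = clamp_spec("vc", v_hold = -80),
                             cond = condition("control", params),
                             t_end = 500, dt_out = 0.2,
                             engine = c("c", "r"),
                             rtol = 1e-8, atol = 1e-8,
                             hmax_pulse = 0.1,
                             qss_F = FALSE, drive_at_soma = FALSE,
                             y0 = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "synapse_params"), inherits(clamp, "clamp_spec"),
            inherits(cond, "syn_condition"), t_end > 0, dt_out > 0)
  if (is.null(y0)) y0 <- resting_state(params, clamp, cond)
  y0 <- y0[.state_names]

  grid <- sort(unique(c(seq(0, t_end, by = dt_out), t_end,
                        .segments(protocol, t_end))))
  edges <- .segments(protocol, t_end)
  rows <- vector("list", length(edges) - 1)
  y <- y0
  for (k in seq_len(length(edges) - 1)) {
    t0 <- edges[k]; t1 <- edges[k + 1]
    in_pulse <- any(protocol$onsets <= t0 + 1e-12 &
                      t0 < protocol$onsets + protocol$duration - 1e-12)
    nu_now <- if (in_pulse) protocol$amplitude else 0
    times <- grid[grid >= t0 - 1e-12 & grid <= t1 + 1e-12]
    if (length(times) < 2) times <- c(t0, t1)
    hmax <- if (in_pulse) hmax_pulse else 0 # 0 = unrestricted for lsoda
    if (engine == "c") {
      pv <- .pack_parms(params, clamp, cond, nu_now = nu_now, qss_F = qss_F,
                        drive_at_soma = drive_at_soma)
      out <- deSolve::lsoda(y, times, func = "synaptode_deriv", parms = pv,
                            dllname = "synaptode",
                            initfunc = "synaptode_init",
                            rtol = rtol, atol = atol, hmax = hmax)
    } else {
      ctx <- list(params = params, clamp = clamp, cond = cond,
                  nu_now = nu_now, qss_F = qss_F,
                  drive_at_soma = drive_at_soma)
      out <- deSolve::lsoda(y, times, func = .synapse_rhs_r, parms = ctx,
                            rtol = rtol, atol = atol, hmax = hmax)
    }
    if (attr(out, "istate")[1] < 0) {
      rlang::abort(sprintf("solver failed in [%g, %g] ms", t0, t1))
    }
    y <- stats::setNames(as.numeric(out[nrow(out), -1]), .state_names)
    rows[[k]] <- out[if (k > 1) -1 else TRUE, , drop = FALSE]
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("time", .state_names)
  res <- tibble::as_tibble(as.data.frame(mat))

  # tiny solver undershoots below zero are clipped; anything larger is a bug
  low <- min(res$c_glu, res$c_periph)
  if (low < -1e3 * atol) {
    rlang::abort("negative glutamate concentration beyond solver tolerance")
  }
  res$c_glu <- pmax(res$c_glu, 0)
  res$c_periph <- pmax(res$c_periph, 0)
  res$m_ampa <- pmin(pmax(res$m_ampa, 0), 1)
  res$D <- pmin(pmax(res$D, 0), 1)
  if (qss_F) {
    res$F <- facilitation_qss(res$c_periph, params$plasticity)
  } else {
    res$F <- pmin(pmax(res$F, 0), 1)
  }

  res <- .add_derived(res, params, clamp, cond, drive_at_soma)
  attr(res, "params") <- params
  attr(res, "clamp") <- clamp
  attr(res, "condition") <- cond
  attr(res, "protocol") <- protocol
  class(res) <- c("synapse_sim", class(res))
  res
}

.add_derived <- function(res, params, clamp, cond, drive_at_soma) {
  r <- params$receptor; n <- params$neuron
  onecomp <- clamp$compartments == 1L
  clamped <- clamp$mode == "vc"
  Usoma <- if (clamped) rep(clamp$v_hold, nrow(res)) else res$U
  if (clamped) res$U <- Usoma
  Ud <- if (onecomp) Usoma else res$U_d
  if (onecomp) res$U_d <- Ud
  Udrive <- if (onecomp || drive_at_soma) Usoma else Ud

  res$m_nmda <- nmda_gate(res$c_periph, cond$c0, r, warn = FALSE)
  fmg <- mg_block_factor(Ud, r$mg_out)
  res$g_ampa <- r$gbar_ampa * res$m_ampa
  res$g_nmda <- r$gbar_nmda * res$m_nmda * fmg
  res$i_ampa <- res$g_ampa * (r$U_ampa_rev - Udrive)
  res$i_nmda <- res$g_nmda * (r$U_nmda_rev - Udrive)
  if (clamped) {
    res$i_vc <- if (onecomp) {
      res$i_ampa + res$i_nmda
    } else {
      somatic_current_vc(res$U_d, clamp$v_hold, n)
    }
  } else {
    res$v_m <- res$U
  }
  res
}

#' @export
print.synapse_sim <- function(x, ...) {
  clamp <- attr(x, "clamp"); cond <- attr(x, "condition")
  cat(sprintf("<synapse_sim> %s, %d compartment(s), %s, %d samples over %g ms\n",
              clamp$mode, clamp$compartments, cond$name, nrow(x),
              max(x$time)))
  NextMethod()
}
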