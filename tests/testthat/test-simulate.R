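test_that("resting state is a fixed point of the full system", {
  p <- synapse_params()
  for (cond_name in c("control", "tboa")) {
    for (mode in c("vc", "cc")) {
      clamp <- if (mode == "vc") clamp_spec("vc", v_hold = -40) else clamp_spec("cc")
      cond <- condition(cond_name, p)
      y0 <- resting_state(p, clamp, cond)
      sim <- simulate_synapse(p, stim_train(n_pulses = 0), clamp, cond,
                              t_end = 100, dt_out = 1)
      drift <- sapply(c("U", "U_d", "m_ampa", "c_glu", "c_periph", "F", "D"),
                      function(v) max(abs(sim[[v]] - y0[[v]])))
      expect_lt(max(drift), 1e-6)
    }
  }
})

test_that("blockade resting state carries the background glutamate", {
  p <- synapse_params()
  y0 <- resting_state(p, clamp_spec("vc", v_hold = -20), condition("tboa", p))
  expect_equal(unname(y0["c_periph"]), 2.0)
  expect_equal(unname(y0["c_glu"]), 2.0)
  expect_gt(unname(y0["F"]), p$plasticity$F0) # elevated resting facilitation
  y0c <- resting_state(p, clamp_spec("vc", v_hold = -20), condition("control", p))
  expect_equal(unname(y0c["F"]), p$plasticity$F0)
  expect_equal(unname(y0c["U_d"]),
               resting_vc(p$neuron, -20), tolerance = 1e-6)
})

test_that("compiled and reference R right-hand sides integrate to the same trajectories", {
  p <- synapse_params()
  for (cond_name in c("control", "tboa")) {
    cond <- condition(cond_name, p)
    a <- simulate_synapse(p, cond = cond, t_end = 150, dt_out = 0.5,
                          engine = "c")
    b <- simulate_synapse(p, cond = cond, t_end = 150, dt_out = 0.5,
                          engine = "r")
    scale <- max(abs(a$i_vc))
    expect_lt(max(abs(a$i_vc - b$i_vc)) / scale, 1e-4)
    expect_lt(max(abs(a$c_periph - b$c_periph)), 1e-4 * max(a$c_periph))
  }
})

test_that("halving solver tolerances leaves the peak current unchanged to 0.1%", {
  p <- synapse_params()
  coarse <- simulate_synapse(p, t_end = 200, rtol = 1e-8, atol = 1e-8)
  fine <- simulate_synapse(p, t_end = 200, rtol = 5e-9, atol = 5e-9)
  finest <- simulate_synapse(p, t_end = 200, rtol = 1e-10, atol = 1e-10)
  pk <- function(s) max(abs(s$i_vc))
  expect_lt(abs(pk(coarse) - pk(fine)) / pk(fine), 1e-3)
  expect_lt(abs(pk(fine) - pk(finest)) / pk(finest), 1e-3)
})

test_that("cleft glutamate peaks an order of magnitude above perisynaptic glutamate", {
  sim <- simulate_synapse(synapse_params(), t_end = 300)
  expect_gt(max(sim$c_glu) / max(sim$c_periph), 5)
})

test_that("without stimulation all trajectories return to rest after a train", {
  p <- synapse_params()
  sim <- simulate_synapse(p, t_end = 8000, dt_out = 10)
  y0 <- resting_state(p, clamp_spec("vc", v_hold = -80), condition("control", p))
  final <- sim[nrow(sim), ]
  expect_lt(abs(final$c_periph - y0["c_periph"]), 1e-2)
  expect_lt(abs(final$U_d - y0["U_d"]), 1e-2)
  expect_lt(abs(final$F - y0["F"]), 1e-2)
})

test_that("an empty protocol yields constant series and derived columns are consistent", {
  p <- synapse_params()
  clamp <- clamp_spec("vc", v_hold = -20)
  sim <- simulate_synapse(p, stim_train(n_pulses = 0), clamp,
                          condition("tboa", p), t_end = 50, dt_out = 1)
  expect_true(all(abs(sim$i_vc - sim$i_vc[1]) < 1e-8))
  # derived series recomputable from states and parameters
  r <- p$receptor
  expect_equal(sim$g_nmda,
               r$gbar_nmda * sim$m_nmda * mg_block_factor(sim$U_d, r$mg_out),
               tolerance = 1e-12)
  expect_equal(sim$i_vc, somatic_current_vc(sim$U_d, -20, p$neuron),
               tolerance = 1e-12)
})

test_that("voltage-clamp amplitudes at -20 and +40 mV are closer in the two-compartment model", {
  p <- nmda_only(3)
  amp <- function(compartments, v) {
    sim <- simulate_synapse(p, clamp = clamp_spec("vc", v_hold = v,
                                                  compartments = compartments),
                            t_end = 600, dt_out = 1)
    max(abs(sim$i_vc - sim$i_vc[1]))
  }
  gap <- function(compartments) {
    abs(log(amp(compartments, 40) / amp(compartments, -20)))
  }
  expect_lt(gap(2L), gap(1L))
})

test_that("the normalized NMDA response shapes differ between -20 and +40 mV", {
  p <- nmda_only(3)
  s20 <- simulate_synapse(p, clamp = clamp_spec("vc", v_hold = -20),
                          t_end = 800, dt_out = 1)
  s40 <- simulate_synapse(p, clamp = clamp_spec("vc", v_hold = 40),
                          t_end = 800, dt_out = 1)
  n20 <- abs(s20$i_vc - s20$i_vc[1]); n20 <- n20 / max(n20)
  n40 <- abs(s40$i_vc - s40$i_vc[1]); n40 <- n40 / max(n40)
  expect_gt(max(abs(n20 - n40)), 0.05)
})
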