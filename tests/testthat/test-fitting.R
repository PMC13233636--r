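test_that("trace MSE has the defining properties", {
  tr <- tibble::tibble(time = seq(0, 10, 0.5), value = sin(seq(0, 10, 0.5)))
  expect_equal(mse_loss(tr, tr), 0)
  shifted <- tr
  shifted$value <- tr$value + 3
  expect_equal(mse_loss(shifted, tr), 9, tolerance = 1e-12)
  # baseline subtraction removes a constant offset
  expect_equal(mse_loss(shifted, tr, t0 = 5), 0, tolerance = 1e-12)
  short <- tibble::tibble(time = seq(0, 5, 0.5), value = 0)
  expect_error(mse_loss(short, tr), "cover")
})

test_that("per-recording losses add with unit weights", {
  p <- synapse_params()
  recs <- generate_synthetic_dataset(p, noise_sigma = 0.05, seed = 7,
                                     cc_vc_pair = FALSE, nmda = FALSE)
  l1 <- synaptode:::.recording_loss(p, recs[1])
  l2 <- synaptode:::.recording_loss(p, recs[2])
  l12 <- synaptode:::.recording_loss(p, recs)
  expect_equal(l12, l1 + l2, tolerance = 1e-10)
  expect_equal(synaptode:::.recording_loss(p, recs, weights = c(2, 0)),
               2 * l1, tolerance = 1e-10)
})

test_that("a fit started at the generating parameters stays there with ~zero loss", {
  p <- synapse_params()
  recs <- generate_synthetic_dataset(p, noise_sigma = 0, cc_vc_pair = FALSE,
                                     nmda = FALSE)
  res <- fit_stage(recs, p, c("tau_glu", "gbar_ampa"), maxit = 60)
  expect_lt(res$loss, 1e-2) # pA^2 against traces peaking near 1000 pA
  est <- get_params(res$params, c("tau_glu", "gbar_ampa"))
  expect_equal(unname(est), c(2.9, 3040), tolerance = 1e-2)
})

test_that("a single perturbed parameter is recovered from noiseless traces", {
  p <- synapse_params()
  recs <- generate_synthetic_dataset(p, noise_sigma = 0, cc_vc_pair = FALSE,
                                     ampa = FALSE)
  p0 <- update_params(p, c(tau_glu = 2.9 * 1.5))
  res <- fit_stage(recs, p0, "tau_glu", maxit = 200)
  expect_equal(unname(get_params(res$params, "tau_glu")), 2.9,
               tolerance = 0.01)
})

test_that("recovery tolerates 5% Gaussian recording noise", {
  p <- synapse_params()
  recs <- generate_synthetic_dataset(p, noise_sigma = 0.05, seed = 11,
                                     cc_vc_pair = FALSE, nmda = FALSE)
  p0 <- update_params(p, c(tau_glu = 2.9 * 1.5))
  res <- fit_stage(recs, p0, "tau_glu", maxit = 200)
  expect_equal(unname(get_params(res$params, "tau_glu")), 2.9,
               tolerance = 0.10)
})

test_that("skipping the neuron stage degrades the fit on the same data and budget", {
  p <- synapse_params()
  recs <- generate_synthetic_dataset(p, noise_sigma = 0, nmda = FALSE)
  free <- c("tau_m", "gamma", "l", "gbar_ampa", "tau_glu")
  set.seed(8)
  start <- get_params(p, free) * runif(length(free), 0.7, 1.3)
  p0 <- update_params(p, setNames(start, free))
  schedule <- synaptode:::.default_stages()
  full <- staged_fit(recs, p0, free = free, maxit = 100, maxit_joint = 100)
  ablated <- staged_fit(recs, p0, free = free, stages = schedule[-1],
                        maxit = 100, maxit_joint = 100)
  expect_false(any(full$stages$skipped[full$stages$stage %in%
                                         c("neuron", "ampa", "joint")]))
  expect_true(full$stages$skipped[full$stages$stage == "nmda"])
  expect_lt(full$loss, ablated$loss)
  expect_lte(full$loss, synaptode:::.recording_loss(p0, recs))
})

test_that("tidy and glance summarize a staged fit", {
  p <- synapse_params()
  recs <- generate_synthetic_dataset(p, noise_sigma = 0, cc_vc_pair = FALSE,
                                     nmda = FALSE)
  fit <- staged_fit(recs, p, free = c("tau_glu", "gbar_ampa"), maxit = 30,
                    maxit_joint = 30)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("tau_glu", "gbar_ampa"))
  expect_true(all(c("start", "estimate", "rel_change") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_traces, 2L)
})

test_that("zero-dispersion restarts are identical and reporting is per parameter", {
  p <- synapse_params()
  recs <- generate_synthetic_dataset(p, noise_sigma = 0, cc_vc_pair = FALSE,
                                     nmda = FALSE)
  free <- c("tau_glu", "gbar_ampa")
  out <- perturb_and_recover(recs, p, free = free, n_restarts = 2,
                             dispersion = 0, seed = 5, maxit = 20,
                             maxit_joint = 20)
  expect_equal(nrow(out$by_parameter), length(free))
  r1 <- subset(out$runs, restart == 1)$estimate
  r2 <- subset(out$runs, restart == 2)$estimate
  expect_identical(r1, r2)
})
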