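# Shared fixtures: reference parameter set and small simulation helpers.

ref_params <- function() synapse_params()

# NMDA-isolated / AMPA-isolated parameter sets for a given cell
nmda_only <- function(cell = 3) {
  p <- set_cell(synapse_params(), cell)
  p$receptor$gbar_ampa <- 0
  p
}
ampa_only <- function(cell = 2) {
  p <- set_cell(synapse_params(), cell)
  p$receptor$gbar_nmda <- 0
  p
}

expect_rel_equal <- function(object, expected, tol = 1e-6) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-12), tol)
}
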