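# synaptode

Simulation and fitting of glutamatergic synaptic transmission at the
hippocampal CA3→CA1 (Schaffer collateral) synapse, for computational
neuroscientists and electrophysiologists who want a model that is richer
than a conductance kernel but cheap enough for network work.

The model is a system of seven ODEs coupling:

- a **passive two-compartment neuron** (soma `U`, dendrite `U_d`) usable in
  current clamp, voltage clamp, or as a one-compartment reduction —
  voltage clamp controls only the soma, so the dendritic driving force
  escapes the command potential (the space-clamp problem);
- **AMPA gating** `m_AMPA`, a first-order relaxation with closing time
  τ_A toward S_AMPA(C_glu)·D, with the low-affinity Hill sensitivity
  S_AMPA(c) = 1/(1+(1000 µM/c)^1.6);
- **instantaneous NMDA gating** m_NMDA = S_NMDA(C_periph) − S_NMDA(C₀)
  with the high-affinity S_NMDA(c) = 1/(1+4.7 µM/c) and Jahr–Stevens
  magnesium block 1/(1+([Mg]ₒ/3.57)·e^(−0.062V));
- **two glutamate compartments** — cleft centre `C_glu` and perisynaptic
  shell `C_periph` — with square release pulses W·F·ν(t), cleft↔shell
  exchange (τ_glu, volume ratio β), bulk leak (τ_diff) and saturable
  astrocytic **EAAT2 uptake** α·f(Na)·C/(k½+C) acting only perisynaptically;
  transporter blockade (TFB-TBOA) = uptake off + 2 µM background;
- **short-term plasticity**: glutamate-driven facilitation `F` and slow
  AMPA desensitization `D`.

This reproduces the signature observations: transporter blockade
prolongs NMDA-mediated currents while leaving per-pulse AMPA kinetics
unchanged, trains facilitate, and NMDA amplitudes at −20 and +40 mV are
nearly equal in the two-compartment model but far apart under an ideal
one-compartment clamp.

## Worked example

```r
library(synaptode)

p   <- synapse_params()                       # reference parameter set
sim <- simulate_synapse(p,
                        protocol = stim_train(),            # 5 pulses, 50 Hz
                        clamp    = clamp_spec("vc", v_hold = -80),
                        cond     = condition("control"),
                        t_end    = 300)
synapse_metrics(sim)$peaks
#> # A tibble: 5 × 4
#>   pulse t_peak  peak amplitude
#>   <int>  <dbl> <dbl>     <dbl>
#> 1     1   16    393.      393.
#> 2     2   36    637.      637.
#> 3     3   55.8  802.      802.
#> 4     4   75.8  909.      909.
#> 5     5   95.8  980.      980.
```

Each row is one stimulus in the train: `t_peak` is when the recorded
somatic current peaks (ms), `amplitude` its baseline-subtracted size in
pA. The first response is the smallest — the facilitation seen
experimentally — and the current is positive here because the package
keeps synaptic currents positive-inward (`--negate` in the CLI flips to
the display convention for recorded EPSCs). `autoplot(sim)` shows the
underlying glutamate, plasticity and conductance trajectories.

Fitting recovers parameters from recordings (here synthetic ones):

```r
recs <- generate_synthetic_dataset(p, noise_sigma = 0, cc_vc_pair = FALSE)
fit  <- staged_fit(recs, update_params(p, c(tau_glu = 4.4)))  # perturbed start
tidy(fit)     # term / start / estimate / rel_change
glance(fit)   # final loss, stage counts
```

A command-line interface wraps the same functions:

```sh
exec/synaptode simulate --out traces.csv --vhold -80
exec/synaptode generate --out data/ --seed 1
```

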