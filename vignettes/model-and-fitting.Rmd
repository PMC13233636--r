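---
title: "The synaptode model: glutamate dynamics, receptor kinetics and trace fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The synaptode model: glutamate dynamics, receptor kinetics and trace fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(synaptode)
```

## The model

`synaptode` simulates the population-averaged excitatory response of CA1
pyramidal neurons to Schaffer-collateral stimulation with seven coupled
ODEs. The state is

| variable | meaning | units |
|---|---|---|
| `U` | somatic membrane potential | mV |
| `U_d` | dendritic membrane potential | mV |
| `m_ampa` | AMPA receptor activation | – |
| `c_glu` | glutamate at the cleft centre | µM |
| `c_periph` | perisynaptic glutamate | µM |
| `F` | presynaptic facilitation | – |
| `D` | AMPA desensitization | – |

**Electrotonics.** The cell is a passive soma coupled to an equivalent
dendrite carrying all receptors:

$$\tau_m \dot U = -(U - U_L) + \frac{2\gamma}{l}(U_d - U) + I_{inj}/G_s,$$
$$\tau_m \dot U_d = -(U_d - U_L) - \frac{2}{l}(U_d - U) + I_d/(\gamma G_s),$$

with membrane time constant $\tau_m$, dendrite/soma area ratio $\gamma$,
electrotonic parameter $l$ (squared dendritic length over the
characteristic length), and somatic conductance $G_s$. In voltage clamp
the soma is held at $V_h$, the dendrite keeps its own dynamics (the
space-clamp problem), and the recorded current is
$I_{VC} = 2(G_s\gamma/l)(U_d - U_d^0)$ with
$U_d^0 = (U_L + 2V_h/l)/(1+2/l)$. The inverse operator
$I_d = ((l/2)\tau_m\,d/dt + 1 + l/2)\,I_{VC}$ recovers the dendritic
current from a somatic recording; `reconstruct_dendritic_current()`
applies it with central differences, and a test verifies the round trip on
a forward-simulated passive cell to 0.5% of peak. A one-compartment
reduction ($\gamma,l \to 0$) is available via
`clamp_spec(compartments = 1)` for space-clamp comparisons.

**Receptors.** AMPA activation relaxes with closing time $\tau_A$ toward
$S_{AMPA}(c_{glu})\,D$, with the Hill sensitivity
$S_{AMPA}(c) = 1/(1+(1000\,\mu M/c)^{1.6})$. NMDA activation is
instantaneous in perisynaptic glutamate,
$m_{NMDA} = S_{NMDA}(c_{periph}) - S_{NMDA}(c_0)$ with
$S_{NMDA}(c) = 1/(1+4.7\,\mu M/c)$; the subtracted term is the fraction
held desensitized by the standing background $c_0$, and a transient
negative difference is clipped at zero (it is a desensitized fraction, not
a negative conductance). NMDA currents carry the Jahr–Stevens magnesium
factor $1/(1 + ([Mg]_o/3.57)\,e^{-0.062 V})$ evaluated at the dendritic
potential. The driving force is also evaluated at the dendrite by default,
because the receptors sit there and this is what lets the two-compartment
model reproduce the near-equal NMDA amplitudes at −20 and +40 mV;
`drive_at_soma = TRUE` selects the literal somatic form for comparison.

**Glutamate.** Release is a train of square flux pulses (amplitude
$W\nu^{pulse}$ = 200 µM/ms, duration 1 ms — only the product of per-spike
contribution and flux is identifiable, so a single parameter
`w_nu_pulse` is used). The cleft exchanges with a perisynaptic shell with
time constant $\tau_{glu}$ (volume ratio $\beta$ on the way back), the
shell leaks toward the bulk level $c_0$ with $\tau_{diff}$ and is drained
by EAAT2 uptake
$\alpha^{periph} \cdot \frac{(Na^e-Na^a)^{1.5}}{(50\,mM)^{1.5}+(Na^e-Na^a)^{1.5}}
\cdot \frac{c}{k_{1/2}+c}$. No uptake acts in the cleft centre (EAAT2 is
perisynaptic/astrocytic). Transporter blockade (TFB-TBOA) is modelled by
`condition("tboa")`: uptake off and $c_0 = 2\,\mu M$.

**Plasticity.** Facilitation is driven by perisynaptic glutamate (a proxy
for presynaptic depolarization through metabotropic and extrasynaptic
receptors) and relaxes to $F_0$ with the very fast $\tau_F = 0.16$ ms;
desensitization recovers with $\tau_D = 410$ ms and is depleted in
proportion to the instantaneous AMPA activation. Because $\tau_F$ is far
below every other time scale, `facilitation_qss()` gives the algebraic
fixed point; `simulate_synapse(qss_F = TRUE)` uses it in place of the F
equation, reducing the order from 7 to 6, and a regression test keeps the
two variants within 2% of each other on the observable current.

## Parameters

Defaults are the reference parameterization: $\tau_m$ = 11 ms, $\gamma$ =
2, $l$ = 1.3; per-cell $G_s$ = 8/12/8.2/9 nS and $U_L$ = −70/−69/−34/−4 mV
(`set_cell()`; the unusual depolarized leak values of cells 3–4 are
accepted as measured cell properties); $\bar g_{AMPA}$ = 3040 nS,
$\bar g_{NMDA}$ = 75 nS, reversals 0 mV, $[Mg]_o$ = 1 mM; $\tau_{glu}$ =
2.9 ms, $\tau_{diff}$ = 1.17 s, $\beta$ = 66, $\alpha^{periph}$ = 0.31
µM/ms, $k_{1/2}$ = 28 µM, $Na^e$ = 130 mM, $Na^a$ = 15 mM; $\tau_F$ = 0.16
ms, $H_F$ = 64 ms⁻¹, $F_0$ = 0.42, $\tau_D$ = 410 ms, $H_D$ = 1.3 s⁻¹. All
durations are stored in ms (`to_ms()` converts), so $\tau_{diff}$ = 1170
ms and $H_D$ = 0.0013 ms⁻¹ internally.

The AMPA closing time $\tau_A$ has no tabulated reference value; the
package defaults to 2.5 ms, a typical deactivation time constant for
hippocampal AMPA receptors, and exposes it as an ordinary fitting
parameter. Both EC50s and the Hill exponent are parameters too, so
sensitivity analyses do not require code changes.

One deliberate inconsistency is preserved: `input_conductance()` returns
the closed form $G_{in} = G_s(3+2\gamma)/(3+\gamma)$, which is the
expression used to fix $G_s$ from a measured input resistance. The exact
steady state of the two-compartment equations implemented here is
$G_s(1 + 2\gamma/(l+2))$, which differs (the closed form descends from a
cable argument rather than the lumped two-compartment limit). The test
suite checks the simulated steady state against the exact expression and
the closed form against its defining values, keeping both facts visible.

## Simulating

```{r}
sim <- simulate_synapse(synapse_params(),
                        protocol = stim_train(), # 5 pulses at 50 Hz
                        clamp = clamp_spec("vc", v_hold = -80),
                        cond = condition("control"),
                        t_end = 300)
synapse_metrics(sim)$peaks
```

Integration uses `deSolve::lsoda` with rtol = atol = 1e-8. The release
flux is piecewise constant, so the integrator is restarted at every pulse
edge (adaptive steps can never skip a pulse) and the maximal internal step
during a pulse is 0.1 ms. The system is stiff by construction ($\tau_F$ =
0.16 ms against $\tau_{diff}$ = 1170 ms); lsoda's automatic stiff
switching handles it. The compiled C right-hand side (`engine = "c"`) is
the default; `engine = "r"` runs a reference implementation assembled from
the exported module functions, and a test holds the two to within 1e-4
relative on whole trajectories. Solver-refinement tests require the peak
current to move by less than 0.1% when tolerances are tightened 100-fold.
Simulations start from `resting_state()`, the numerically verified fixed
point; the 20-s inter-train interval of the recording protocol is
represented by starting every train at rest rather than integrating 20 s
of quiescence. Tiny negative concentration undershoots (within solver
tolerance) are clipped; anything larger raises an error.

The decay-time metric is the time for the final response to fall from its
peak to $1/e$ of the peak — chosen because no operational definition
accompanies the experimental metric — with 90→10% and log-linear
exponential-fit alternatives selectable in `synapse_metrics()`.

## The synthetic dataset

`generate_synthetic_dataset()` emulates the experimental design used for
fitting: a current-clamp/voltage-clamp pair from cell 1 (mixed
receptors), AMPA-isolated trains at −80 mV with and without transporter
blockade (cell 2), NMDA-isolated trains at −20 mV in control (cell 3) and
blockade (cell 4), and an NMDA train at +40 mV (cell 3) — all 5×50 Hz,
pharmacological isolation modelled by zeroing the blocked conductance.
Gaussian noise with σ = 5% of the trace peak is the default (recording
noise is not reported for the original data; 5% is a realistic figure for
evoked EPSCs of a few hundred pA). Trace windows are 300 ms (AMPA), 1200
ms (NMDA control), 2000 ms (NMDA blockade, whose decay is set by
$\tau_{diff}$) and 400 ms (mixed), long enough to contain the measured
decay phases while keeping a full staged fit around a minute.

What the generator does *not* emulate: stimulus artefacts, series
resistance and capacitance transients, baseline drift, correlated (1/f)
noise, trial-to-trial release variability, and failures. Passing
parameter-recovery tests on these traces therefore demonstrates the
identifiability and correctness of the fitting machinery, not performance
on raw patch-clamp data.

## Staged fitting

`staged_fit()` follows the four-step schedule: (1) neuron electrotonics
on the current-clamp trace, (2) AMPA parameters on AMPA-isolated traces,
(3) NMDA/transport parameters on NMDA-isolated traces, (4) joint
refinement on everything, each stage warm-starting the next. Losses are
trace MSEs after baseline subtraction (pre-stimulus mean), summed with
unit weights by default. Optimization is Nelder-Mead on log-transformed
parameters — all free parameters are positive scales, so the log
transform enforces positivity without hard bounds. Because a simplex can
collapse inside the narrow valley that couples $\bar g_{AMPA}$,
$\tau_{glu}$ and $\tau_A$, each stage re-runs Nelder-Mead from the
incumbent best (up to two extra runs, stopping when the gain drops below
0.1%); this restart is what makes recovery from ±50% perturbations
reliable. `perturb_and_recover()` packages the robustness check: refit
from starts independently perturbed within ±50% and report the maximum
relative deviation from the reference values — about 0.1–0.3% on the
noiseless synthetic dataset, well inside the 20% criterion.

```{r, eval = FALSE}
p <- synapse_params()
recs <- generate_synthetic_dataset(p, noise_sigma = 0, cc_vc_pair = FALSE)
fit <- staged_fit(recs, update_params(p, c(tau_glu = 4.4)))
tidy(fit)
plot_fit_overlay(fit)
```

## Known limitations

- With the reference parameters, the 5-pulse train accumulates
  perisynaptic glutamate to ≈7 µM in control (each pulse contributes
  1.3–2.4 µM and clearance takes longer than the 20-ms inter-pulse
  interval); the low-micromolar figure often quoted for perisynaptic
  transients applies to the single-release transient, not the
  train-accumulated peak.
- Receptors are two-state on/off with algebraic sensitivities; no Markov
  sub-states, no subunit-specific NMDA kinetics, no explicit vesicle-pool
  or residual-calcium presynaptic model (desensitization/depression is
  a single lumped factor).
- Diffusion is two-compartment; there is no spatial PDE and no
  electrodiffusion (voltage-dependent cleft escape), which the
  electrotonic mechanism makes unnecessary for the phenomena covered
  here.
- The neuron is passive: no spiking or active dendritic conductances.
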