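---
title: "Model and methods: the basal ganglia–thalamus network in bgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the basal ganglia-thalamus network in bgnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bgnet` simulates a conductance-based network of the indirect-pathway
basal ganglia nuclei — subthalamic nucleus (STN), globus pallidus
externa and interna (GPe, GPi) — together with a thalamocortical relay
population (THA), and derives the macroscopic observables used to
compare normal, Parkinsonian and deep-brain-stimulation (DBS) regimes.
This vignette documents the model equations, the parameter choices the
package makes where the literature is ambiguous, the numerical methods,
and the limits of what the simulations show.

## Membrane dynamics

STN, GPe and GPi neurons follow a Hodgkin–Huxley-type current balance

$$C \dot V = -I_{LEAK} - I_K - I_{Na} - I_{Ca} - I_T - I_{AHP}
  - I_{syn} + I_{app} + I_{DBS},$$

with instantaneous activation for the fast gates
($m_\infty$, $a_\infty$, $s_\infty$), first-order kinetics
$\dot x = (x_\infty(V) - x)/\tau_x(V)$ for $x \in \{n, h, r\}$, a
calcium pool $\dot{Ca} = k_2(-I_{Ca} - I_T - k_{Ca}\,Ca)$ feeding the
after-hyperpolarisation current
$I_{AHP} = g_{AHP}\,\frac{Ca}{k_1 + Ca}(V - E_K)$, and a first-order
synaptic activation (below).  The STN low-threshold T-current uses the
slow-variable-dependent inactivation
$b_\infty(r)$, $I_T = g_T a_\infty^3 b_\infty^2 (V - E_T)$; the
pallidal variant is $I_T = g_T a_\infty^3\, r\, (V - E_T)$.  Thalamic
relay cells carry only $V, h, r$ with
$I_K = g_K (0.75(1-h))^4 (V-E_K)$ and $I_T = g_T p_\infty^2 r (V-E_T)$,
driven by pallidal GABA and by a 40 Hz sensorimotor pulse train
(5 pA, 5 ms pulses).

All units follow the conventions of this model family: conductances in
nS/µm², potentials in mV, currents in pA, time in ms, with membrane
capacitance `C = 1` (not printed in the source tables; configurable).

### Parameter provenance and corrections

Most parameters are taken directly from the published tables
(`population_params()` shows every value).  A handful of printed
entries contradict the published single-cell behaviour and were
replaced by the values of the underlying conductance-model lineage
(Terman-type STN/GP cells, Rubin–Terman relay cells); each replacement
was validated against the published single-neuron figures:

* STN $\sigma_h = -3.1$ (printed $-31$ silences the cell; with $-3.1$
  it fires at ≈2.6 Hz at rest and speeds up monotonically with current,
  as published).
* GP $\theta_a = -57$, $\theta_s = -35$ (printed positive values zero
  out $I_T$ and $I_{Ca}$ and flatten the tuning curve).
* GP time constants $\tau_{n0} = 0.05$,
  $\sigma_{\tau h} = \sigma_{\tau n} = -12$, and the pallidal T-current
  reversal at $E_{Ca} = 120$ mV.  With these, an isolated pallidal cell
  fires tonically at 30.2 Hz at rest and 62.7 Hz under 5 pA — within
  0.5 % of the published rates — whereas the verbatim table entries
  produce doublet firing at 26/58 Hz.
* THA $\sigma_h = \sigma_r = -4$: h and r are inactivation gates; the
  printed positive slopes invert them.
* The pallidal $\tau_r$ has no printed voltage dependence and is the
  constant $\tau_{r0}/A_r = 15$ ms; `constant_tau = TRUE` forces the
  constant limit for every gate.
* $\sigma_s$ (slope of $s_\infty$) is not printed; the lineage values
  are used (8 for STN, 2 for GP).

Every replaced entry remains overridable through
`population_params(...)`, so the verbatim variants can be simulated.

### Synaptic activation and its threshold

Transmitter release follows
$\dot s = \alpha (1 - s) H(V_{pre} - \theta_0) - \beta s$ with the
smooth step $H(x) = 1/(1+e^{-x/\sigma_H})$.  $\sigma_H$ is not
printed.  For the STN the lineage value $\sigma_H = 8$ is used.  For
the pallidum the width matters qualitatively: the pallidal interspike
potential sits only ≈4 mV below $\theta_0 = -57$ mV, and with a wide
step ($\sigma_H = 2$) neurons that fall silent while moderately
depolarised keep $H \approx 0.12$ and hold their synapses ≈75 % open.
In the full network this tonic release locks the circuit into a silent
state (STN and thalamus dead) that contradicts the published normal
regime.  `bgnet` therefore uses $\sigma_H = 1$ for GPe/GPi, the widest
value for which release stays spike-gated; this was calibrated once
against the published normal-state observables (faithful thalamic
relay, response efficacy near 0.5) and then frozen.  The width is a
parameter, so the alternative readings can be explored.

Synaptic currents are conductance-based,
$I = g\,(V_{post} - E_{rev}) \sum_j A_{ij} s_j$, with
$E_{Glu} = -10$ mV and $E_{GABA} = -70$ mV.

## Network architecture

Default sizes are 500 STN, 500 GPe, 500 GPi and 200 THA neurons
(1700 total, ≈34 600 directed synapses).  `build_full_network()`
assembles:

* intra-GPe and intra-GPi Watts–Strogatz rings ($k = 20$,
  $p = 0.005$, periodic boundaries, edge count conserved under
  rewiring);
* sparse intra-STN connectivity: 20 % of neurons act as hubs with mean
  total degree 25, partners drawn by ring-distance band (30 % local
  $\le 10$, 45 % intermediate $10$–$20$, 25 % remote $> 25$ — the
  published distance percentages leave the 400–500 µm shell
  unassigned, and that remainder is folded into the remote band); the
  other 80 % are isolated.  A dense variant (`stn_topology = "dense"`)
  replaces this with a $k = 20$ small world;
* reciprocal one-to-one GPe↔STN wiring and one-to-one STN→GPi wiring;
* GPe→GPi fan-out of 18 ring-local targets plus 2 uniform remote
  targets (mean out-degree exactly 20);
* GPi→THA: a uniformly drawn pool of 200 GPi neurons from which each
  thalamic neuron samples 3 distinct afferents.

The published conductance vector
$(g_{STST}, g_{GPST}, g_{GPeGPe}, g_{STGPe}, g_{GPiGPi}, g_{GPeGPi},
g_{STGPi}, g_{GPiTha}) = (0.5, 4.5, 0.07, 0.56, 0.07, 0.01, 0.2, 0.1)$
is used verbatim in all conditions.  Topologies are reproducible from
an integer seed and serialise to a plain-text edge list.

## Stimulation protocols

`stimulus_protocol()` encodes the three functional states through the
constant drives $I_{app}$: STN always receives 4 pA (cortical drive);
the striatal drives are GPe 5 / GPi 4 pA in the normal state and GPe 3
/ GPi 8 pA in the Parkinsonian and DBS states (GPe inhibited, GPi
disinhibited).  DBS adds the pulse train
$I_{DBS} = A\,H(\sin(2\pi t/T))\,(1 - H(\sin(2\pi (t+\delta)/T)))$
with the exact Heaviside step, $A = 200$, $\delta = 0.6$ ms and
$T = 1000/f$ derived from the requested frequency (the tabulated
$T_{DBS} = 6$ ms is only the default corresponding to ≈167 Hz).  The
same functional form with $A = 5$, $\delta = 5$ ms, $T = 25$ ms is the
sensorimotor drive.  Pulse trains use the discontinuous step; the
smooth $H$ appears only inside the synaptic kinetics.

## Numerical integration

The engine (C++) advances all ≈9600 state variables together.  Two
schemes are available:

* **Adaptive** (default for `simulate_network()`): the embedded
  Bogacki–Shampine 3(2) pair — the scheme behind MATLAB's `ode23` —
  with FSAL, relative and absolute tolerances $10^{-6}$, and RMS-norm
  mixed error control $\sqrt{\tfrac1n \sum (e_i/(atol + rtol\,|y_i|))^2}$.
  The maximum step is capped at a quarter of the narrowest active pulse
  width so the discontinuous stimulus edges are never stepped over.
* **Fixed-step RK4** (`method = "rk4"`, the default for
  `run_scenario()` and sweeps): classical Runge–Kutta at
  `dt = 0.05` ms.  On the full network the two schemes agree on
  population firing rates and mean synaptic activity to well under 1 %
  (and halving `dt` changes rates by < 0.5 %), while RK4 is roughly an
  order of magnitude faster; scenario-level analyses therefore use it.

Initial conditions are not printed in the source material: per-neuron
voltages are drawn uniformly from $(-70, -50)$ mV (a desynchronised
start), gates start at their voltage steady state, calcium at 0.1 and
synaptic activations at 0, all reproducible from an integer seed.
Spikes are detected online as upward crossings of $-15$ mV (linear
interpolation between accepted steps) with a 2 ms lockout.  Non-finite
states abort with the first offending index.  The first 500 ms of a
run is treated as transient for steady-state observables; the entropy
deliberately includes it (see below).

## Macroscopic observables

For the GPi population the package computes:

* the Kuramoto synchronisation index
  $r(t) = |N^{-1}\sum_k e^{i\theta_k(t)}|$, with spike phases
  interpolated linearly (2π per interspike interval) by default, or
  Hilbert (analytic-signal) phases of the $s$-traces on request.
  Neurons without a defined phase at $t$ (fewer than 2 spikes, or $t$
  outside their spiking span) are excluded at that time.  The two phase
  definitions give $r(t)$ curves whose mean absolute difference on a
  full-size run is ≈0.1–0.15 after the transient — they agree on the
  macroscopic story but are not interchangeable estimators;
* the mean synaptic activity $l(t) = N^{-1} \sum_i s_i(t)$ — the
  proxy for pallido-thalamic inhibitory tone and for an LFP;
* the thalamic response efficacy $R$: for each sensorimotor pulse
  onset in 500–1500 ms, the fraction of thalamic neurons firing within
  $2\delta = 10$ ms of the onset, averaged over pulses;
* Shannon entropies $E_r, E_l$ of the two series, histogrammed over 50
  equal bins on $[0,1]$ at 1 ms resolution over the first 1500 ms
  *including* the transient (the entropy is meant to reflect the
  switch-on response as well);
* the periodogram of $l(t)$ on the 500–1500 ms window, its local
  maxima (≥5 % of the strongest in-band peak) and the least-squares
  slope of log power against log frequency over 1–100 Hz, excluding
  ±2 Hz around each detected peak so narrow rhythmic peaks do not
  dominate the broadband fit.  Entropy bin count, fit band and
  exclusion width are arguments.

## What the simulations do and do not show

The single-cell layer reproduces the published behaviour closely:
pallidal tuning (30/63 Hz) within 0.5 %, thalamic relay fidelity
exactly (40 Hz, one spike per pulse), STN tuning within ≈15 % (2.6 /
5.3 / 12.6 Hz at 0 / 4 / 10 pA against published ≈3 / 6–7 / 15 Hz; no
defensible parameter variant closes this gap, see the package ledger
of corrections above).

At network level the package reproduces the Parkinsonian state
(thalamic relay abolished, $R < 0.05$; inhibitory tone high) and a
normal state with $R \approx 0.55$ and a functioning relay, and the
DBS state entrains STN/GPe at high rates with GPe near 90 Hz as
published.  Two published network-level results are *not* reproduced
by the printed equations and parameters as implemented here, and the
package reports them as computed rather than forcing them:

* the DBS-state thalamic recovery ($R(184\,\mathrm{Hz}) \approx 0.22$
  with mean inhibitory tone ≈0.6): the printed GPe→GPi conductance
  (0.01) is too weak to normalise GPi firing as described, and the
  printed relay cell ($E_T = 0$) stops following the sensorimotor
  train at about a third of the GABA conductance the DBS state
  imposes.  Raising $E_T$ to a physiological calcium reversal restores
  the tolerance but breaks the published isolated-cell figure, so the
  printed cell is kept;
* the coherent 7–11 Hz rhythm of $l(t)$ in the normal state (and the
  associated steep spectral slopes): the simulated normal state is
  asynchronous-tonic, so the low-frequency collective oscillation and
  the $-3.6 / -2.5 / -3.1$ slopes are not recovered.

The ordering $l_{PD} > l_{normal}$ and the state separation in $R$ are
robust across seeds; orderings that involve the DBS state inherit the
first limitation.

## Problem sizes used in the test-suite

The unit tests exercise single neurons (0.5–2.5 s), reduced networks
(60 neurons per BG nucleus, 24 thalamic; 300–500 ms) for solver
consistency, determinism, and permutation invariance, and full-size
networks (1700 neurons, 1.5 s, five seeds per condition) for the
reproduction checks.  These sizes keep the default suite in the
minutes range while every structural claim is still tested at the
published scale.

## Limitations

Single-compartment neurons without channel noise or temperature
scaling; no intrathalamic or plastic connectivity; monophasic
rectangular DBS pulses without electrode field modelling; one
topology realisation per scenario by default (seeds expose the
variability).  The synthetic nature of the drive means the "normal"
state is defined operationally by its striatal currents, not by fitted
data.
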