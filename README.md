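# bgnet

Conductance-based simulation of the basal ganglia–thalamus circuit for
studying movement disorders and the frequency dependence of deep brain
stimulation (DBS).

The package is aimed at computational neuroscientists who want a
reproducible, scriptable implementation of the classic
subthalamo-pallidal network family (Terman-type STN/GPe/GPi cells,
Rubin–Terman thalamic relay cells) at population scale: 500 STN, 500
GPe, 500 GPi and 200 thalamic neurons wired through small-world
pallidal rings, sparse subthalamic hub connectivity and one-to-one
inter-nuclear projections (≈34 600 directed synapses).

## The model

Each basal ganglia neuron follows a Hodgkin–Huxley-type current
balance

```
C dV/dt = −I_LEAK − I_K − I_Na − I_Ca − I_T − I_AHP − I_syn + I_app + I_DBS
```

with first-order gating kinetics `dx/dt = (x∞(V) − x)/τ_x(V)` for
`x ∈ {n, h, r}`, a calcium pool driving the after-hyperpolarisation
current, and first-order synaptic activation
`ds/dt = α(1 − s)H(V − θ₀) − βs`.  Thalamic relay neurons carry
`(V, h, r)` and receive pallidal GABA plus a 40 Hz sensorimotor pulse
train.  Three functional states differ only in the constant striatal
drives (`I_app`): normal (GPe 5 / GPi 4 pA), Parkinsonian (GPe 3 /
GPi 8 pA — GPe inhibited, GPi disinhibited), and DBS (Parkinsonian
drives plus a high-frequency rectangular pulse train,
`A = 200`, `δ = 0.6` ms, injected into every STN neuron).

From each simulation the package derives the macroscopic observables
used to compare the states:

* the Kuramoto synchronisation index `r(t) = |⟨exp(iθ_k)⟩|` of GPi
  spiking,
* the mean GPi synaptic activity `l(t) = ⟨s_i(t)⟩` (the inhibitory
  tone onto thalamus, an LFP proxy),
* the thalamic response efficacy `R`: the mean fraction of thalamic
  neurons answering each sensorimotor pulse within 10 ms,
* Shannon entropies of `r` and `l`, and the log–log slope and peaks of
  the `l(t)` power spectrum.

The integrator (C++) is an adaptive Bogacki–Shampine 3(2) pair
(tolerances 1e-6) with a fixed-step RK4 mode used for scenario sweeps;
the two agree on population rates to well under 1 %.  See the methods
vignette (`vignettes/bgnet-methods.Rmd`) for the equations, parameter
provenance (including the handful of published table entries that had
to be corrected against the published single-cell figures), and known
limitations.

## Worked example

```r
library(bgnet)

# an isolated pallidal neuron: published tuning is 30 Hz at rest,
# 63 Hz under 5 pA
single_neuron_rate("GPe", I_app = 0, duration = 6000)
#> [1] 30.18182
single_neuron_rate("GPe", I_app = 5, duration = 6000)
#> [1] 62.72727

# a full normal-state network run (1700 neurons, 1.5 s) and its
# macroscopic summary
run <- run_scenario("normal", seed = 1)
glance(run)
#> # A tibble: 1 × 10
#>   condition dbs_frequency     R   E_r   E_l  slope peak1 peak2 mean_l mean_r
#>   <chr>             <dbl> <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl>  <dbl>  <dbl>
#> 1 normal               NA 0.556  2.48  1.29 -0.604     5    NA  0.374 0.0794
```

`R = 0.556` says that on average 56 % of thalamic neurons answer each
sensorimotor pulse — the intermediate coupling of the healthy state
(published value 0.518; a Parkinsonian run drops it to ≈0, the
inhibitory tone `mean_l` rising from ≈0.37 to ≈0.55).  `tidy(run)`
returns the `r(t)`/`l(t)` series as a tibble, and `plot_raster()`,
`plot_macro_series()`, `plot_spectrum()` and `plot_sweep()` draw the
standard figures.  A DBS frequency sweep is

```r
sweep <- frequency_sweep(seq(50, 250, by = 10), seed = 1)
find_response_peaks(sweep$f, sweep$R)
```

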