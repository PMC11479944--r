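# amparkin

Kinetic, fluctuation, FRAP and interface-stability analysis of AMPA
receptor gating under pH modulation.

## What problem this addresses

Extracellular acidification — as occurs transiently in the synaptic
cleft — inhibits AMPA-type glutamate receptors (AMPARs): it accelerates
entry into desensitization, slows recovery from it, reduces the peak
response, and, at the structural level, protonation of a histidine at
the N-terminal-domain (NTD) dimer-of-dimers interface ruptures that
interface and lets the NTD layer splay.  Quantifying this requires a
toolbox that spans patch-clamp kinetics, noise analysis, imaging and
molecular-dynamics trajectory metrics.  `amparkin` packages those
analyses for electrophysiologists and structural biologists, together
with seeded synthetic-data generators (currents, FRAP traces,
rupture trajectories) so that every estimator can be validated end to
end without access to raw recordings.

## The models at the core

* **Gating**: a continuous-time Markov scheme
  `C0 = C1 = C2 = O` with desensitized states `D1, D2` and a
  ligand-dependent recovery ladder `D2 = D1 = D0 -> C0`.  The master
  equation `dp/dt = Q(t)ᵀp` is solved with exact interval matrix
  exponentials; stochastic ensembles use multinomial count propagation
  (exact per sample interval).  pH enters as multiplicative factors on
  selected transitions.  Current is `N · Σ p_open · γ · V`.
* **Decay/rise kinetics**: `I(t) = I₀ + Σ Aᵢ exp(−t/τᵢ)` fitted from
  90% of peak; weighted `τ_w = Σ τᵢ|Aᵢ| / Σ|Aᵢ|`.
* **Recovery from desensitization**: paired-pulse fractions fitted with
  the Hodgkin–Huxley form `f(t) = y₀ + (y_max−y₀)(1−e^{−kt})^m`
  (`m = 2` for the steep GluA2 profile), `τ = 1/k`.
* **Dose–response**: Hill equation
  `I = I_max[A]^{n_H} / ([A]^{n_H} + EC₅₀^{n_H})`.
* **NSFA**: variance–mean parabola `σ² = iĪ − Ī²/N + σ_B²` over ten
  amplitude bins; `γ = i/V`.
* **FRAP**: double normalization
  `((ROI−bg)/(ref−bg)) / pre-bleach mean`, then
  `F(t) = F₀ + (plateau−F₀)(1−e^{−t/τ})`.
* **Protonation**: Henderson–Hasselbalch fraction
  `1/(1+10^{pH−pKa})` thresholded at 0.5.
* **Trajectory metrics**: Kabsch-superposed r.m.s.d. traces,
  windowed minimum heavy-atom contact distances, residue-pair distance
  s.d., encounter durations, and sustained-loss rupture-onset
  detection; static-structure COM/terminus distances, interface residue
  lists and two-fold tetramer construction.

## Worked example

Simulate an acidic-pH recording with the packaged GluA2-like scheme,
then run the three electrophysiology estimators:

```r
library(amparkin)
scheme <- glua2_scheme()                      # 20 pS, reference pH 7.4

## desensitization during a 200-ms 10 mM glutamate pulse at pH 5.5
prot  <- pulse_protocol(pulse = 200, sample_interval = 0.05)
sweep <- simulate_macroscopic(scheme, prot, pH = 5.5, n_channels = 100)
fit_decay(sweep)
#> Exponential decay fit (1 component)
#>   tau1 = 3.702 ms  (amplitude -49.32 pA)
#>   weighted tau = 3.702 ms, offset = -0.296 pA

## recovery from desensitization (paired-pulse, Hodgkin-Huxley m = 2)
ivs    <- c(5, 10, 15, 20, 30, 40, 60, 80, 120, 160, 220, 300)
sweeps <- lapply(paired_pulse_protocol(ivs), simulate_macroscopic,
                 scheme = scheme, pH = 5.5, n_channels = 100)
fit_recovery_hh(extract_recovery(sweeps), m = 2)
#> Hodgkin-Huxley recovery fit (m = 2)
#>   tau = 1/k = 28.76 ms  (k = 0.03477 /ms)
#>   y0 = -0.05611, ymax = 1.017

## NSFA on 100 stochastic sweeps of a 64-channel patch (reference pH)
sw <- simulate_stochastic(scheme, prot, n_channels = 64, n_sweeps = 100,
                          noise_sigma = 0.7, seed = 42)
fit_parabola(ensemble_variance(sw), voltage = -60)
#> Nonstationary fluctuation analysis (parabolic fit)
#>   i = -1.154 pA, N = 69.32 channels, sigma_B^2 = 0.6133 pA^2
#>   gamma = i/V = 19.23 pS at -60 mV (100 sweeps, 10 bins)
```

The decay time constant drops from ~14.3 ms at pH 7.4 to ~3.7 ms at
pH 5.5 while recovery slows from ~15.6 ms to ~28.8 ms — the acidic
phenotype the default scheme encodes.  The NSFA estimates scatter
around the generating truth (i = −1.2 pA, N = 64, γ = 20 pS); their
accuracy across replicates is quantified in the test suite.

FRAP and trajectory analyses follow the same pattern; see
`?generate_frap_trace`, `?fit_frap`, `?generate_rupture_trajectory`,
`?rupture_onset`, `?com_distance`, and the methods vignette
(`vignettes/amparkin-methods.Rmd`).

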