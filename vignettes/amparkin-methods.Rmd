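---
title: "Models and methods behind amparkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amparkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amparkin)
```

# Scope

`amparkin` implements the quantitative analyses used to characterize how
extracellular protons modulate AMPA-type glutamate receptor (AMPAR)
gating and destabilize the N-terminal-domain (NTD) dimer-of-dimers
interface: current-kinetics estimation (desensitization, deactivation,
recovery, dose-response), nonstationary fluctuation analysis (NSFA),
FRAP normalization and recovery fitting, protonation-state assignment,
MD-trajectory interface metrics, and static-structure measurements.
Because raw recordings and multi-hundred-gigabyte trajectories are not
redistributable, every analysis stage is paired with a seeded synthetic
generator that emulates the corresponding experiment; the generators are
first-class, tested code, not fixtures.

# The gating model

## Markov scheme

Channel gating is a continuous-time Markov chain.  The packaged default
(`glua2_scheme()`) has seven states:

    C0 = C1 = C2 = O          binding (x [glu]) and opening
    C1 -> D1, C2 -> D2, O -> D2   desensitization entry
    D2 = D1 = D0 -> C0        recovery via unbinding, then resensitization

The D-state ladder is the essential structural feature.  A two-state
desensitization picture cannot reconcile three observations that
co-occur experimentally: a ~14 ms desensitization time constant, a
steady-state current of only ~2% of peak at 10 mM glutamate, and
recovery on washout with a ~16 ms time constant.  If recovery proceeded
at 1/16 ms^-1 *during* the pulse, the steady state would be ~50% of
peak.  The resolution is ligand dependence of the recovery pathway:
desensitized channels must shed glutamate (`D2 -> D1 -> D0`) before
resensitizing (`D0 -> C0`).  At 10 mM the unbinding steps are reversed
by rapid rebinding (`D0 -> D1` and `D1 -> D2` scale with concentration),
trapping channels in the desensitized pool; at zero glutamate the same
ladder empties quickly.  The multi-step return is also what gives
recovery its sigmoidal onset, which is why the recovery curve is fitted
with a Hodgkin–Huxley form with slope `m = 2` rather than a plain
exponential.

Rates were fixed once, by numerical fitting of the simulator's own
outputs to the target phenomenology (weighted desensitization tau
14.3 ms, steady-state/peak 1.8%, recovery tau 15.6 ms at the reference
pH; 3.7 ms / 28.8 ms / 0.64x peak at pH 5.5), and are recorded with
that tuning note in `inst/extdata/glua2_scheme.cfg`.  Binding
(26, 13 /mM/ms), unbinding (3, 6 /ms) and gating (6, 1.8 /ms) rates are
generic fast-AMPAR values and were held fixed during tuning.

## pH modifiers

Protons are modeled phenomenologically as multiplicative factors on
selected transitions, tabulated per pH and anchored at factor 1 at the
reference pH 7.4 (log-linearly interpolated at intermediate pH).  The
default factors at pH 5.5 multiply desensitization entry by 3.72, slow
the recovery ladder to 0.557x and reduce the opening rate to 0.456x.
Whether the reduced peak at low pH reflects faster desensitization
entry, a lower opening rate, or both is not experimentally resolved;
the scheme exposes both knobs and the default uses both, which is a
modeling choice, not a mechanistic claim.

## Solution exchange and simulation

Fast perfusion is a first-order low-pass on the command concentration
with `exchange_tau = 0.12` ms (a ~120 µs exchange); the filtered
concentration is piecewise-analytic.  The master equation
`dp/dt = Q(t)' p` is propagated on the sample grid with the exact
interval matrix exponential, using the mid-step concentration; matrices
are cached per concentration value, and the filter tail is snapped to
its target below a 1e-9 relative threshold so the cache closes.
Occupancy conservation is asserted at 1e-9 at every sample.

The stochastic engine simulates channels with rates frozen per sample
interval.  Identical channels are aggregated by state counts and
propagated with multinomial draws from the same interval transition
matrix — distributionally identical to per-channel simulation but
O(states^2) per step, which is what makes 2x10^6 channel-sweep
ensembles cheap.  Within a sample interval the transition matrix is the
exact `expm(Q dt)`, so no first-order time-stepping error is incurred.
Every stochastic generator requires a seed and restores the caller's
RNG state.

# Estimators

**Exponential decay / rise.**  Decay fitting starts where the current
has fallen to 90% of peak (peak detection blanks the first 0.2 ms of
the pulse to skip the exchange artifact) and ends at the end of the
pulse.  One- vs two-component selection uses BIC with a margin of 10,
plus sanity constraints (separated time scales, common amplitude sign);
with two components the amplitude-weighted
`tau_w = sum(tau_i |A_i|) / sum(|A_i|)` is reported.  The steady state
is the mean of the final 10% of the pulse — a window definition chosen
here, since only the quantity itself is conventionally reported.  Rise
fitting uses a single exponential from the 20%-of-peak crossing to the
peak.  All nonlinear fits are bounded Levenberg–Marquardt
(`minpack.lm`) with a deterministic three-point multi-start on the time
constants (cost tolerance 1e-10); degenerate inputs (flat traces,
sub-sample rise times, windows under 10 samples) raise errors or flags,
never silent defaults.

**Recovery.**  `extract_recovery()` measures, per interpulse interval,
(test peak - baseline)/(conditioning peak - baseline), each pulse
against its own pre-pulse baseline (the tail of the interpulse gap for
the test pulse).  Fractions are not constrained to 1 (noise can
overshoot; the container allows [0, 1.2]).  `fit_recovery_hh()` fits
`y0 + (ymax - y0)(1 - exp(-kt))^m` with `m` fixed at 2 (or 1, which is
algebraically a single exponential) and reports `tau = 1/k` — the
standard reading of the rate constant, since only `k` is defined by the
fitting form.

**NSFA.**  The ensemble variance across >= 30 successive sweeps over
the desensitizing phase is grouped into ten equal-width mean-amplitude
bins (bins with fewer than 3 samples are dropped with a warning) and
fitted with `sigma^2 = i I - I^2/N + sigma_B^2`.  The fit is linear in
`(i, -1/N, sigma_B^2)` and solved by weighted least squares with
chi-squared-based weights (`2 sigma^4/(n-1)`, bin-averaged).  Within a
bin the design uses the bin mean of `I^2`, not the square of the bin
mean — binning must not distort the parabola's curvature, and this
makes recovery on noiseless bins exact.  `sigma_B^2` is free by
default (it is part of the fitted form) with an option to fix it from
the baseline; a successive-difference variance is available for
drift-affected data.  Conductance is `gamma = i/V`.  Fits with
non-negative curvature or a sign-inconsistent `i` are flagged invalid.

**FRAP.**  Double normalization divides the background-subtracted ROI
by the background-subtracted non-photobleached reference (removing
acquisition bleaching exactly, since it hits both equally) and scales
the pre-bleach mean to 1.  EasyFRAP-style full-scale normalization
(first post-bleach frame pinned to 0) is available as an option;
double is the default because it preserves the bleach depth.  The
recovery fit `F0 + (plateau - F0)(1 - exp(-t/tau))` takes the first
post-bleach frame as t = 0 and leaves `F0` free rather than pinning it
to a single noisy frame.  The plateau approximates the mobile
fraction; fitted recovered fractions at requested readout times (e.g.
630 s) are reported.

**Protonation.**  `assign_protonation()` evaluates the
Henderson–Hasselbalch protonated fraction `1/(1 + 10^(pH - pKa))` for
basic titration (histidine-like sites) from a consumed pKa table and
thresholds at 0.5 for fixed-state assignment.  pKa computation itself
is out of scope; the table is an input.

**Trajectory metrics.**  r.m.s.d. traces use optimal least-squares
(Kabsch) superposition per frame.  Contact evolution reports, per
cross-interface residue pair, the minimum heavy-atom distance
summarized as the minimum per time window.  The contact cutoff
defaults to 4.5 Å, a common van-der-Waals contact convention (no
cutoff is conventionally fixed for these analyses).  An "encounter" is
operationalized as a maximal run of consecutive below-cutoff frames;
mean encounter duration and fraction-of-frames-in-contact are both
reported so either reading of "encounter time" is available.  Rupture
onset is the earliest frame from which *all* pairs stay above cutoff
continuously for at least `sustain` ns (default 2), which suppresses
thermal flicker while reporting a single onset time.  Distance s.d.
matrices use residue heavy-atom centroids.

**Static structure.**  COM distances are mass-weighted over all heavy
atoms of the stated selection by default, with a C-alpha-only mode —
which atom set underlies conventionally reported "COM distances" is
ambiguous, and the ~Å-level tolerance of such measurements absorbs the
difference.  Terminus separations use the terminal C-alpha atoms.
Tetramer construction appends a copy rotated 180° about a given axis
through the center of mass (`R = 2uu' - I`, an involution), renaming
chains to free identifiers.

# Synthetic generators: what they emulate, and what they do not

* `simulate_stochastic()` reproduces macroscopic and per-channel
  currents with binomially distributed open counts and Gaussian
  background noise.  It does not model series-resistance artifacts,
  drift, rundown, or multiple conductance levels, so passing NSFA
  round trips show estimator correctness under the model's own
  assumptions, not robustness to recording pathologies (the
  successive-difference option addresses drift, but is tested only on
  synthetic drift-free data).
* `generate_frap_trace()` emulates the spine-FRAP acquisition (3
  pre-bleach and 20 post-bleach frames at 30-s intervals), per-frame
  acquisition bleaching applied equally to ROI and reference, and
  per-channel Gaussian noise.  Real FRAP additionally involves diffusive
  exchange during the bleach, reference-ROI selection error and focus
  drift, none of which are modeled.
* `generate_rupture_trajectory()` plants a controllable interface
  rupture (displacement along the separation axis at a set frame) on
  top of harmonic breathing and isotropic thermal noise over two small
  rigid domains.  It is a stand-in for real NTD-tetramer trajectories
  sufficient to validate the metrics' detection and invariance
  properties; it does not emulate side-chain rearrangements, partial
  contacts or force-field physics.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: 0.05–0.1 ms sampling
over 200-ms pulses; 2x10^6 channel-sweeps for the
stochastic-vs-deterministic comparison; 20 NSFA replicates of 100
sweeps x 64 channels; 25 FRAP repeats; 500-frame trajectories.  These
sizes give Monte-Carlo error comfortably below the assertion
tolerances while keeping the full suite under a minute of compute.
Matrix exponentials use `Matrix::expm`; the master-equation steady
state is cross-checked against the null space of `Q'` computed by SVD.
All tolerance values asserted in tests (1e-6 relative on noiseless
round trips, 2% on stochastic/deterministic agreement, 1e-8 Å on
rigid-transform invariance, 1e-12 on normalization identities) are
stated in the test files themselves.

# Known limitations

* The kinetic scheme is phenomenological: it reproduces macroscopic
  observables and their pH dependence but does not claim mechanistic
  identifiability of individual rate constants.
* The dose-response EC50 of the default scheme is an emergent property
  (~0.23 mM); it was not a tuning target.
* pH-factor interpolation between tabulated pH values is log-linear and
  intended for small excursions, not titration-curve modeling.
* Trajectory readers accept multi-model PDB only; binary trajectory
  formats should be converted upstream.
* FRAP fitting is single-exponential by design; reaction–diffusion
  models are out of scope.
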