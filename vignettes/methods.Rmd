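---
title: "Model-based resting-state EEG biomarkers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based resting-state EEG biomarkers: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictomark)
```

## The problem

Idiopathic generalized epilepsy (IGE) is usually confirmed by observing
epileptiform discharges on EEG, but such discharges are absent from many
recordings. This package implements a family of candidate biomarkers that
need only a short (~20 s) artifact-free segment of eyes-closed *resting*
EEG, i.e. background activity with no epileptiform events, and compares
them within a common classification framework:

1. **Occipital alpha-peak frequency** — the frequency of maximal normalized
   power over O1/O2 within 6–14 Hz. Alpha rhythms shift toward lower
   frequencies in IGE, so *lower* is the epilepsy-like direction.
2. **Functional-network mean degree** — the average node degree of the
   low-alpha (6–9 Hz) functional network inferred by phase-locking
   statistics; elevated at the group level in IGE.
3. **Local-coupling seizure likelihood** — the model-based biomarker: the
   inferred network is embedded in a phase-oscillator network model whose
   node-local coupling constants are the channel signal variances scaled by
   a uniform parameter *K*; each node in turn is driven into synchrony and
   the emergent whole-network synchrony is the subject's "seizure
   likelihood" at that node.

## Preprocessing

Segments are zero-phase Butterworth filtered: band-pass 0.5–70 Hz, then
band-stop 48–52 Hz (power-line removal), then optionally band-passed into
the alpha (8–13 Hz) or low-alpha (6–9 Hz) band. Order 4 is applied forward
and backward (effective magnitude order 8, zero phase). Zero-phase filtering
matters because instantaneous phase estimates feed the network inference.
Our filtfilt applies matched (steady-state) initial conditions with
even-reflection end padding sized to outlast the slowest transient (the
0.5 Hz corner); plain zero-state forward–backward filtering leaves large
edge transients, and odd reflection injects a spurious step whenever an
endpoint is far from zero.

Power spectra are Welch estimates (2-s Hann windows, 50% overlap, 0.5 Hz
grid; the underlying estimator is exposed as `welch_psd()`). Because
absolute amplitude varies between individuals for non-neural reasons
(cranium anatomy among them), every channel's spectrum is divided by one
constant per subject: the frequency-summed power averaged across channels.
The mean channel total is then exactly 1 while between-channel ratios are
preserved.

**Variance entering the model.** The node-local coupling uses the
per-channel variance of the **broadband-filtered** signal. The band is a
genuinely open choice; we use broadband because the low-alpha variance is
dominated by whether a subject's alpha peak happens to fall inside 6–9 Hz,
which would confound the model biomarker with the spectral comparator
rather than reflect the channel-amplitude quantity the uniform-*K* scaling
is meant to multiply.

## Functional network inference

Instantaneous phases come from the analytic signal (FFT Hilbert transform)
of the low-alpha segment; 5% of samples at each end are discarded against
end effects. For each channel pair the phase-locking factor
\(\mathrm{PLF} = |\langle e^{i(\phi_a - \phi_b)}\rangle_t|\) and the
circular mean phase difference (the lag) are computed.

Edges must pass two tests:

* **Surrogate significance.** Each pair's PLF is compared with the
  rank-based 95% point of 99 surrogate PLFs in which one channel's phase
  series is circularly shifted by a random offset of at least 1 s. The
  shift preserves each channel's marginal dynamics and spectrum but
  destroys inter-channel locking, so exceedance has false-positive
  probability `alpha_level` under exchangeability; the PLF of *every*
  circular shift is obtained at once by FFT cross-correlation of the unit
  phasors, and the ensemble is a random sample of those shifts. Thresholds
  are per pair by default; a pooled global threshold is available
  (`mode = "global"`) since the original group-level procedure does not
  record which was used.
* **Zero-lag exclusion.** Pairs whose lag lies within 0.1 rad of 0 or
  \(\pi\) are rejected: a single cortical source seen by two electrodes
  (volume conduction) produces exactly this near-instantaneous locking.

With 99 surrogates at the 0.05 level the quantile is the 5th-largest
surrogate PLF; fewer than 19 surrogates cannot support the 0.05 level and
raise an error.

## The dynamic network model

Each node (channel) is modelled as the complex order parameter \(z_i\) of a
within-node population of phase oscillators with Lorentzian frequency
spread \(\Delta\) around \(\omega_0\) — the mean-field (Ott–Antonsen-type)
reduction:

\[
\dot z_i = (i\omega_0 - \Delta) z_i + \tfrac{1}{2}\left(H_i - \bar H_i z_i^2\right),
\qquad
H_i = k_i z_i + g \sum_j A_{ji} e^{i\,\mathrm{lag}(j,i)} z_j .
\]

The reduction keeps the operative mechanism — an intra-node coupling
threshold, a switch into synchrony, spread along the inferred edges — while
being cheap and analytically checkable: an isolated node has
\(|z^*| = \sqrt{1 - 2\Delta/k}\) for \(k > k_c = 2\Delta\) and
\(|z^*| = 0\) below, which the test suite verifies against long
integrations to \(10^{-3}\).

Subject-specificity enters twice: the adjacency and lags come from the
subject's inferred network, and the local couplings are
\(k_i = K\,\sigma^2_i\) with \(\sigma^2_i\) the channel variance and *K* a
uniform scale optimized by the classifier.

**Seizure likelihood.** To score node *m*, its coupling is clamped at
`k_drive` (default \(2k_c\), which must exceed \(k_c\)), the model is
integrated past a burn-in, and \(S_m\) is the mean over the *other* nodes
of the fraction of sampled times their order parameter exceeds
\(\theta_\mathrm{sync} = 0.8\). The driven node is excluded from the
average because the quantity of interest is *emergent* spread; including it
(`exclude_driven = FALSE`) merely adds a constant offset and both modes are
exposed.

Numerical choices: fixed-step Heun integration (it extends directly to the
optional stochastic mode), `dt` = 1 ms, renormalization guard at
\(|z| = 1\), synchrony sampled every 10 ms after burn-in, deterministic by
default (`noise_amp = 0`), bit-reproducible given the seed. Halving `dt`
changes \(S\) by less than 0.01 at the defaults. \(\omega_0 = 2\pi\cdot
7.5\) rad/s (the low-alpha centre) is carried for completeness; a common
rotation, it provably does not affect \(|z|\).

**Calibrating the gain g.** The inter-node gain is the one free parameter
without a natural unit. `calibrate_g()` sweeps a grid and returns the
smallest gain for which a reference control cohort, with *K* placing the
mean node at criticality, yields a mean seizure likelihood in [0.1, 0.3] —
high enough that spread is measurable, low enough that controls do not
saturate. Running this routine on a 10-subject synthetic control cohort
(seed 42) selected g = 0.25, the package default.

## Classification: two thresholds, three outcomes

For a biomarker and a training set, two cuts are placed: `th1`, the most
sensitive cut with zero training false positives (highest sensitivity at
100% specificity), and `th2`, the most specific cut with zero training
false negatives. Cuts sit at the midpoint between the two order statistics
realizing each optimum; exact control/patient ties at a boundary push the
cut past the tied value, because the 100% requirement is absolute. A test
subject is **ige** when on the epilepsy side of both thresholds, **normal**
on the control side of both, and **uncertain** in between — the uncertain
band is the point of the design: a screening tool needs 100% sensitivity,
a specialist decision-support tool 100% specificity, and the same pair of
cuts serves both readings.

Evaluation is leave-one-out: all subjects are pooled, each in turn is held
out, thresholds (and, for the model biomarker, the channel and *K*
maximizing each objective — two independent optima re-fit inside every
fold, the stricter reading of the original procedure) are optimized on the
rest, and the held-out subject is classified. `local_coupling_table()`
precomputes the subject × channel × K array so the per-fold grid search is
a table lookup; the cached and direct paths agree exactly. Ties in the grid
go to the first cell in (channel, K) order, making folds deterministic.
Sensitivity counts only unequivocal **ige** outcomes among patients,
specificity only unequivocal **normal** among controls.

The default *K* grid is 20 log-spaced values spanning
\([0.1\,k_c/\max\sigma^2,\; 10\,k_c/\overline{\sigma^2}]\) (pooled over
subjects): from every node far subcritical to the mean node far
supercritical, with a grid ratio (~1.4) finer than the cohort-level
variance effects it must resolve.

## Comparing biomarkers

Per-subject outcomes are coded ordinally (correct = 2, uncertain = 1,
misclassified = 0; any strictly monotone coding gives identical ranks) and
compared across biomarkers with the Friedman test using within-subject
mid-ranks and the standard tie correction — essential here because
three-way outcomes are massively tied. A fully tied matrix leaves the
statistic undefined and raises an error rather than returning NaN. Patient
and control arms are never pooled. A Monte-Carlo permutation p-value
(permuting outcomes within subjects) is available as an alternative
reference distribution; the tie-corrected chi-squared is the default.

## The synthetic cohort generator

The clinical cohort is not public, so the generator produces surrogate
resting EEG with the three group-level effects under independent control —
each effect feeds a different biomarker, which is exactly what a testbed
needs:

* a **posterior-dominant alpha rhythm** at the subject's `alpha_peak`
  (independent phase per channel, posterior-weighted topography as in
  eyes-closed recordings);
* a **coupled phase-oscillator system** at 7.5 Hz (inside the low-alpha
  band) whose pairwise sine coupling at nonzero preferred lags defines the
  ground-truth functional network; only channels in the coupling graph
  carry this component;
* **1/f background noise**, with every channel rescaled exactly to its
  target variance.

Subject heterogeneity: alpha peak jittered (sd 1.25 Hz), variance scaled
lognormally (sd 0.2 on the log), and each subject receives an individually
drawn coupling graph (pair probability 0.06, strength 5 rad/s, lag
magnitudes 0.25–1.0 rad, clear of the zero-lag guard). The patient arm
additionally gets the three effects: alpha peak −1.0 Hz, coupling density
×1.25, variance ×1.6. The effect sizes are deliberately small against the
subject-level spread for the two comparator biomarkers — group-level
differences with substantial individual overlap, the regime reported for
real cohorts — while the variance effect, which only the model biomarker
exploits, is the strongest individual-level signal.

An earlier single-rhythm design (one oscillator per channel at the
subject's alpha peak, coupling on those oscillators) entangled the effects:
whoever's alpha fell inside 6–9 Hz showed dense low-alpha networks, so the
network biomarker mostly re-measured the spectral one and control networks
ranged from empty to near-clique. The three-component design removes that
artifact. Baseline graph sparsity matters for the same reason: Kuramoto
locking is transitive, so denser source graphs synchronize globally and the
detected network approaches a clique; pair probability 0.06 at strength 5
keeps detected control mean degrees in the single digits.

What the generator does **not** emulate: eye-blink/EMG artifacts, head
geometry and realistic lead fields (mixing is optional and purely linear
instantaneous), non-stationarity across the segment, and any morphology of
actual spike-wave discharges. Passing tests on this generator therefore
demonstrates that the pipeline recovers the structures it parameterizes —
not clinical performance on real EEG.

## Problem sizes in the tests and acceptance runs

The shipped experiments use 19-channel, 20-s, 256-Hz segments; cohorts of
20 subjects per arm over 5 cohort seeds; 99 surrogates per pair; a
20-point K grid; and model horizons of 5 s burn-in + 6 s scoring at
`dt` = 1 ms (the model reaches its attractor within ~2 s at these
parameters, and S changes by < 0.01 under halved `dt`). Longer horizons
(`t_sim = 30` s) are the `dnm()` default for interactive use; the cohort
driver passes shorter ones because the deterministic steady state makes
extra scoring time uninformative.

## Known limitations

* The surrogate scheme (circular phase shifts) and per-pair thresholds are
  one concrete choice among those compatible with the original group-level
  method; a pooled global threshold is provided as an option.
* The mean-field node model is a reduction chosen for checkability; the
  original computation used a finite Kuramoto population. The interface
  (`dnm()`, `seizure_likelihood()`) is unchanged under substitution of the
  node dynamics.
* Detected functional networks inherit transitivity from phase locking:
  indirect (two-step) locking can produce edges between nodes that are not
  directly coupled in the generator; these are genuine phase relations,
  not false positives of the significance test.
* With heavy volume-conduction-like mixing the zero-lag guard removes true
  zero-lag physiology along with the artifact; that trade-off is inherent
  to lag-based exclusion.
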