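---
title: "Methods: quantifying binocular matching of orientation tuning from intracellular recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying binocular matching of orientation tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binocmatch)
```

## The scientific problem

Neurons in layer 4 of binocular primary visual cortex respond to oriented
gratings shown to either eye. In mature animals each neuron prefers nearly
the same orientation through both eyes; before the critical period the two
eyes' preferences are unrelated. The circuit question is *where* this
binocular matching arises: in the feed-forward thalamic (dLGN) input, in the
recurrent intracortical excitation, or both. Experimentally the two sources
can be separated by optogenetically silencing the cortex (photoactivating
GABAergic interneurons): EPSCs recorded with the LED on are purely thalamic,
EPSCs with the LED off are the total excitation, and their difference is the
intracortical component.

`binocmatch` implements the complete analysis for such experiments:
preprocessing of raw current-clamp (membrane potential, Vm) and
voltage-clamp (EPSC) sweeps, tuning-curve construction, vector-sum
orientation statistics, the thalamic/cortical decomposition, and cohort
statistics — together with a synthetic-recording generator with known ground
truth that exercises every stage.

## Stimulus and data model

The assumed protocol is full-field drifting gratings at 12 directions
(30° apart), 1.5 s per presentation at 2 Hz temporal frequency (3 grating
cycles), plus blank (gray-screen) presentations, all sampled at 10 kHz.
Every sweep is labeled by cell, eye (contra/ipsi), LED state (off/on) and
stimulus (direction or blank). Datasets are stored as plain text — a JSON
protocol descriptor plus one CSV and one JSON sidecar per sweep — so every
preprocessing step can be re-run from the raw traces.

## Trace preprocessing

* **Spike detection** (current clamp): a spike onset is an upward crossing
  of dV/dt through a configurable threshold (default 10 mV/ms, typical for
  cortical spikes at 10 kHz), with a 2 ms refractory window. Detection is
  for QC counting only; it does not feed the tuning statistics.
* **Spike removal**: a 6 ms running median erases spike transients while
  leaving the subthreshold Vm intact. Spikes are removed per sweep *before*
  trial averaging — spike times differ across trials, and averaging first
  would smear transients beyond what a 6 ms window can remove.
* **Current smoothing** (voltage clamp): a 40 ms running mean. Trials are
  averaged first and then filtered; for a linear filter the order is
  immaterial. Both filters use reflect padding so output length equals
  input length and there is no startup bias.
* **Cycle averaging**: for each condition the windows 50–550 ms after each
  cycle onset are averaged. If the third cycle's peak-to-baseline amplitude
  falls below a threshold fraction (default 0.5) of the mean of the first
  two cycles, the cell is considered adapted for that condition and only
  cycles 1–2 are averaged. The criterion is deliberately explicit and
  configurable, and adaptation triggers are flagged per condition in the
  output.
* **Baselines**: blank sweeps are averaged and the mean and SD of the
  averaged trace over a stimulus-length window give the Vm (or holding
  current) baseline and the spontaneous-fluctuation SD. Because the LED
  changes the holding current, voltage-clamp baselines are computed
  separately per LED state; Vm analysis uses LED-off blanks.
* **Response magnitude**: baseline-subtracted peak of the cycle-averaged
  waveform — maximal depolarization for Vm, maximal inward current
  (reported positive) for EPSCs.

A 40 ms mean filter attenuates a 2 Hz sinusoid by sinc(0.08) ≈ 0.989, so
the full noiseless chain recovers amplitudes to ~1%, which is why the
end-to-end recovery checks use a 2% bound on amplitudes and scale factors.

## Orientation statistics

For a tuning curve $R(\theta)$ over the 12 directions the package computes

$$ z = \frac{\sum_\theta R(\theta)\, e^{2 i \theta}}{\sum_\theta R(\theta)} $$

with $\theta$ in radians. $|z|$ is the global orientation selectivity index
(gOSI); half the phase of $z$, shifted by −90° and wrapped into
$[-90°, 90°)$, is the preferred orientation (pref\_O) — the −90° converts
drift direction to grating orientation. Negative baseline-subtracted
magnitudes are clipped to zero before the sum (the vector average assumes
non-negative weights); the clipped fraction is reported per curve. The wrap
uses a half-open interval so each orientation has a unique representative;
a value landing exactly on +90° maps to −90°.

The inter-ocular difference
$\Delta O = \min(d, 180 - d)$, $d = |pref_c - pref_i| \bmod 180$,
lies in $[0°, 90°]$. If the two eyes' preferences were unrelated
(uniform), $\Delta O$ would be Uniform(0, 90) with mean 45° — the null
against which matching is tested. A curve with zero resultant (e.g. flat
or all clipped) has undefined pref\_O; such cells are excluded listwise
from difference and correlation statistics and counted in the QC report.

## Decomposition

Cortical EPSC traces are computed point by point as
(baseline-subtracted LED-off cycle average) − (baseline-subtracted LED-on
cycle average); each term uses its own LED-matched baseline because the
holding current differs between LED states. If the adaptation rule chose
different cycle counts for the two traces of one direction, both are
recomputed at the smaller count so the subtracted windows are commensurate.
The cortical tuning curve takes peaks of the subtracted traces (trace-level
subtraction, then peak). The scale factor — the thalamic fraction of
evoked excitation — is the mean of the thalamic tuning curve divided by
the mean of the total curve; the contra/ipsi ratio is the analogous ratio
of mean curve amplitudes across eyes. Linear subtraction inherits the
usual caveat that thalamo-cortical interactions could be non-linear; no
correction is attempted.

## Cohort statistics

Cohorts are summarized as mean ± SEM (sample SD / √n). The test battery
mirrors standard practice in this literature: two-sample
Kolmogorov–Smirnov between age groups on each ΔO metric, one-sample K-S of
each ΔO sample against Uniform(0, 90), paired t-tests within cohort (total
vs thalamic ΔO; ipsi vs contra thalamic-cortical difference), and Pearson
correlation between thalamic and total ΔO. All tests are two-sided with
asymptotic K-S p-values, and no multiple-testing correction is applied.
At the sample sizes involved (14–26 cells) the asymptotic one-sample K-S
test is mildly conservative: its empirical type-I error at α = 0.05 is
≈ 0.04 (verified by simulation in the test suite).

## The synthetic generator

`generate_cohort()` produces complete synthetic experiments with known
ground truth. Per cell and eye, a thalamic component
$T_e(\theta) = A_e s_e \cdot \mathrm{tune}(\theta)$ and a cortical component
$C_e(\theta) = A_e (1 - s_e) \cdot \mathrm{tune}(\theta)$ modulate a
half-rectified 2 Hz sinusoid over three cycles; LED-off sweeps carry
$T + C$, LED-on sweeps $T$ only, blanks only the holding level. The shared
modulation phase between components makes peak-of-sum equal sum-of-peaks,
so the decomposition's linearity is exactly testable; optional phase jitter
is available for robustness experiments. The tuning shape is a von-Mises
style bump on the 180° orientation cycle
($\mathrm{tune} = b + (1-b)\,e^{\kappa(\cos 2\Delta - 1)}$, defaults
$\kappa = 1$, $b = 0.1$, giving gOSI ≈ 0.33–0.45, typical of layer-4
synaptic tuning).

Cohort presets encode the study conditions: adult — inter-ocular thalamic
difference with mean 19.6°, thalamic-cortical differences 17.0°/22.4°
(contra/ipsi), scale factors 0.32/0.32; young — 30.9°, 35.8°/49.0°,
0.43/0.52. Orientation differences are drawn as $|N(0, \sigma)|$ folded
onto $[0°, 90°]$, with $\sigma$ root-solved so the analytic mean equals
the preset. This family's mean saturates at 45° (the uniform limit), so
preset means ≥ 45° — the young ipsilateral thalamic-cortical difference —
saturate to a uniform draw with mean 45°; the directional contra < ipsi
ordering is preserved, the exact 49° mean is not representable. The total
EPSC preference is *emergent*: it is the phase of the weighted vector sum
of the thalamic and cortical components, so young total ΔO
(≈ 38–41° across seeds) is a consequence of the drawn structure, not a
dialed parameter.

Other defaults, chosen once for realism: peak total EPSC 100 pA
(log-normal, sdlog 0.3) with contra/ipsi ratio 2; peak Vm depolarization
15 mV; per-cell scale factors normal around the preset with SD 0.1,
clipped to [0.02, 1]; two trials per condition; white Gaussian noise of
10 pA for voltage clamp. Current-clamp noise (SD 2 mV, matching typical
spontaneous Vm fluctuation) is low-pass filtered with a 15 ms running
mean: the membrane time constant makes real Vm noise slow, and white
noise at 10 kHz would produce unphysical derivatives that defeat any
dV/dt spike detector. Current-clamp cells get stereotyped 1.5 ms spike
waveforms injected where the noiseless Vm crosses a threshold (default
−50 mV), with injection times recorded, so spike detection and removal
are exercised against ground truth.

What the generator does *not* emulate: conductance-based spiking,
inhibition, series-resistance and space-clamp errors, slow drift,
adaptation beyond a single third-cycle factor, and any non-linear
thalamo-cortical interaction. Passing the recovery tests therefore shows
the *analysis* is correct under the stated generative assumptions, not
that real recordings satisfy those assumptions.

## Numerical choices and degenerate inputs

* Filter windows are `round(ms × rate)` samples, medians forced odd;
  reflect padding at both ends.
* The running mean uses cumulative sums (O(n), exact to double precision
  for these magnitudes); the running median uses the standard
  running-median algorithm on the padded trace.
* Cycle windows are indexed as `round(seconds × rate) + 1`, so windows are
  always sample-aligned.
* Zero tuning curves, all-clipped curves and zero resultants yield NA
  statistics and QC flags rather than errors; identical paired samples
  yield t = 0 with an NA p-value and a degenerate flag; zero-variance
  samples make the Pearson correlation an error.
* All randomness in the generator derives from one master seed; per-cell
  seeds are fixed integer offsets of it, so datasets are bit-reproducible.

## Problem sizes used in the validation suite

The packaged tests run cohorts of the study's sizes (young n = 26, adult
n = 15 voltage clamp; 25/14 current clamp) for the end-to-end checks, ten
replicate cohorts for noisy-recovery calibration, twenty replicates for
the directional cohort effects, and 1000 simulated samples of n = 25 for
K-S calibration. These sizes were chosen to match the study design while
keeping the full suite runnable in a few minutes on one core.

## Known limitations

* The paired contrast "thalamic ΔO < total ΔO" in young cohorts has
  limited power under this generative family at n = 26 (effect size
  d ≈ 0.33, ~30% power at α = 0.05 two-sided); single cohorts reproduce
  the direction reliably but its significance only sporadically — a
  property of the effect size itself, which the replicate tests document.
* Folded-normal presets cannot represent difference means above 45°.
* The adaptation criterion is a configurable stand-in; the appropriate
  threshold for real data is an empirical question.
* Only the standard 12-direction/2 Hz/3-cycle protocol family is
  supported; other direction counts work, but temporal parameters must
  satisfy the protocol invariants.
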