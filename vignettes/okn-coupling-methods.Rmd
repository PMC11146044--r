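---
title: "Decoding bistable percepts from the OKN and bounding audiovisual consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding bistable percepts from the OKN and bounding audiovisual consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okncouple)
```

# The problem

When a constant ambiguous stimulus is viewed or heard for minutes, perception
alternates spontaneously between interpretations. Two classical examples are
used here: the auditory ABA_ streaming sequence, heard either as one stream
(*integrated*) or two interleaved streams (*segregated*), and visual
pattern-component rivalry, where two overlaid drifting gratings are seen
either as one coherent plaid (integrated) or as separate gratings
(segregated). A central question is whether the alternations in the two
modalities are coupled moment by moment.

Asking observers to report both percepts at once creates a dual task with
response interference. The alternative implemented by this package is a
*no-report* readout of the visual percept: the drifting stimulus evokes an
optokinetic nystagmus (OKN), a reflexive sawtooth eye movement whose slow
phases track the *perceived* motion. Because the plaid moves horizontally
faster than a single grating, the slow-phase velocity — and the duration and
extent of the resetting fast phases — carry the current visual percept. A
linear support-vector machine decodes the percept from these eye-movement
signatures at 100 Hz, while the auditory percept is reported by button press.
Consistency between the decoded visual and the reported auditory percept,
scored with a class-adjusted accuracy, quantifies the coupling.

`okncouple` implements the full chain as testable code, together with a
synthetic-session generator that supplies ground truth for every stage, so
the statistical machinery can be validated without any recordings.

# The synthetic session generator

`build_session()` emulates a main experimental session: 3 unimodal visual,
2 unimodal auditory and 8 bimodal blocks, each a 180-s multistable part
followed by a 30-s disambiguated part in which the stimulus physically
suggests each percept twice for about 7.5 s (catch trials for response
verification).

**Percept dynamics.** Dominance phases are gamma distributed
(`shape = 3`, typical for multistability) with a mean of `mean_dom = 9` s;
with shape 3 this puts the median phase near 8 s, matching the magnitude
reported for these stimuli. The stationary segregated proportion `pi_seg`
defaults to 0.5 in both modalities: experiments of this kind titrate the
stimulus parameters (tone-frequency separation, grating opening angle)
toward balanced percepts, so balance is the design target the simulator
reproduces; individual asymmetries can be dialled in per modality.

**Coupling.** Both modalities derive from one shared alternating-renewal
trace. Each modality carries an independent *disagreement* renewal process;
inside a disagreement window the modality's state is the flipped common
state. With mean flip probability $\delta = (1-\kappa)/2$ per modality, the
stationary cross-modal match probability is $(1+\kappa_a\kappa_v)/2$: 1/2 at
independence ($\kappa=0$) and 1 at full coupling. Flip probabilities are
state-dependent (solved from the occupancy and mean-flip constraints) so
that each modality can hold its own `pi_seg` even under partial coupling;
in the symmetric case the construction reduces to plain unbiased flips.
This shape was chosen because it preserves realistic phase-duration
structure at every coupling strength.

**Reports.** The button trace is the latent trace delayed by
`lag_report = 0.35` s (a typical manual reaction time to an endogenous
perceptual switch), with each phase independently mislabeled with
probability `eps_report = 0.07`, and `none` gaps inserted around switches
(where button releases occur in practice) totalling `gamma_gap = 3%` of
time — reproducing the ~97% exclusive-report coverage and mid-80s-percent
catch-trial hit rates seen with real observers.

**OKN.** `simulate_okn()` integrates a sawtooth: slow drift at
`v_int = 1.9` deg/s (the stimulus speed) during integration and
`v_seg = 0.5` deg/s during segregation, a fast phase triggered at 2 deg
eccentricity with gamma-distributed duration (mean 40 ms integrated, 25 ms
segregated) at 60 deg/s — so fast phases are longer *and* larger during
integration — plus 0.01-deg position noise and Poisson blinks (12/min,
150 ms) during which samples are missing. Slow-phase velocities per percept
are not published for this paradigm; these defaults are simulator choices
producing a realistic ~0.8-Hz OKN.

What the generator deliberately does **not** emulate: smooth pursuit and
microsaccades, drift in tracker calibration, piecewise-gradual transition
periods (latent states switch instantaneously), and any dependence of
report errors on phase duration. Passing tests therefore validate the
analysis machinery, not the biology; empirical group numbers obtained from
real recordings are out of reach of the simulator by design.

# Preprocessing and features

`okn_variables()` turns a raw 1000-Hz gaze trace into the three decoding
signals:

1. **Blink handling** — every run of missing samples is padded by 50 ms per
   side (lid closure contaminates neighbouring samples).
2. **Fast-phase detection** — a velocity-threshold saccade detector:
   sample-to-sample velocity smoothed by a 10-ms centered moving average,
   events where it exceeds 22 deg/s for at least 4 ms, extended by
   hysteresis down to 10 deg/s, merged across gaps under 20 ms. The
   thresholds separate 1–2 deg/s slow drift from saccadic speeds by an
   order of magnitude; they are parameters, not dogma.
3. **Slow-phase velocity** — signed (positive = stimulus direction)
   differences between consecutive slow, valid samples; never bridged
   across excised fast phases or blinks; smoothed by a *trailing* 1-s mean
   over defined samples.
4. **Fast-phase run statistics** — for every sample, the length and
   absolute extent of the containing run of displacements in the fast-phase
   direction (0 if the sign differs), each smoothed by the trailing 1-s
   mean. Displacement signs are taken on a 20-ms boxcar-smoothed copy of
   the position by default: with raw 1000-Hz differences, sub-0.01-deg
   sensor noise flips nearly half of all slow-phase displacement signs,
   flooding the run statistics with one-sample runs; 20 ms of position
   smoothing removes those flips while leaving genuine fast phases (tens of
   samples, degrees of extent) intact. `smooth_ms = 0` restores raw signs.

All sliding means are trailing (causal): a feature at time *t* never uses
samples after *t*, which keeps the features usable for the real-time
decoding the method was designed for, and makes causality testable — the
suite truncates traces and asserts the past is unchanged. Whether the
original processing used centered or trailing windows is not documented;
trailing is the stricter choice and is exposed as the only mode.

`assemble_features()` samples the three signals at lags −2.0 … 0 s in
100-ms steps relative to each 100-Hz timepoint: 3 × 21 = 63 features per
timepoint. Rows whose lag window precedes the block or touches missing data
are flagged incomplete and dropped from training and evaluation rather than
zero-filled. Features are standardized by *training-block* statistics
(columns have incommensurate units — deg/s, samples, deg — and linear SVMs
are scale-sensitive); zero-variance columns pass through unchanged. Whether
the original analysis standardized is unknown; it is a config flag,
default on.

# Decoding

`train_svm()` fits a soft-margin linear SVM (libSVM via e1071) with class
weights inversely proportional to class frequency, so training matches the
class-adjusted evaluation objective. The decision rule is exported as an
explicit 63-vector and bias; decoding a block is one matrix product, and
ties on the decision boundary go to the positive class.

Accuracy is always **class-adjusted (balanced)**: per-class accuracies
(fraction of timepoints predicted *c* among timepoints reported *c*) are
averaged with equal weight, which pins random-guessing performance at 50%
regardless of percept asymmetry. A class absent from the labels leaves the
measure undefined and raises an error rather than silently degenerating.

`run_role_permutations()` implements the block-role scheme: the three
unimodal visual blocks take the roles (train, cost-optimization,
evaluation) in all 3! = 6 ordered assignments; for each assignment, 11
models (cost grid 0.0001 … 100) are trained, the cost with the highest
balanced accuracy on the optimization block is retained (ties toward the
smallest cost, i.e. stronger regularization), and the retained model is
scored on the evaluation block. All six models are kept and treated as
exchangeable; whether cost selection originally used balanced or raw
accuracy is undocumented — balanced is used for coherence with the
evaluation metric. An optional training-row `stride` decimates the 100-Hz
training rows (which are strongly autocorrelated); the default is 1.

# Consistency and its bounds

`compute_consistency()` scores, for each of the 6 models and 8 bimodal
blocks, the decoded visual percept against the simultaneous auditory report
(auditory integrated ↔ visual integrated, segregated ↔ segregated) with the
same balanced accuracy, and averages the 48 cells into the participant's
consistency. Blocks whose auditory report lacks a class leave their cells
undefined; they are excluded from the mean (not imputed) with a warning.

**Theoretical bounds.** With auditory/visual segregated proportions $a,v$,
the joint occupancy $x = P(\text{both segregated})$ is the single free
parameter, $\max(0, a+v-1) \le x \le \min(a,v)$, and the balanced
consistency $\tfrac12\left[x/a + (1-a-v+x)/(1-a)\right]$ is linear in $x$,
so the extremes sit at the interval endpoints:

$$\text{theo}_{\max} = \frac{1}{2}\left[\frac{\min(a,v)}{a} +
\frac{\min(1-a,1-v)}{1-a}\right],\qquad
\text{theo}_{\min} = \frac{1}{2}\left[\frac{\max(0,a+v-1)}{a} +
\frac{\max(0,1-a-v)}{1-a}\right].$$

The test suite certifies these closed forms against the endpoint
(linear-programming) oracle on a 20 × 20 grid to 1e-9; a failing
certification is treated as a release blocker.

**Expected bounds.** Imperfect visual decoding ($d$) and auditory reporting
($r$) attenuate what can be observed. With two classes, a true match is
transmitted when both channels are correct or both are wrong; under error
independence $q = dr + (1-d)(1-r)$. The per-class true-match proportions at
each theoretical extreme are mapped through $m \mapsto mq + (1-m)(1-q)$ and
averaged. The closed form approximates true-class proportions by
reported-class proportions (asymmetry is estimated from reports); the test
suite quantifies this approximation against a Monte-Carlo channel
simulation. For $d, r \ge 1/2$ the ordering
$\text{theo}_{\min} \le \text{exp}_{\min} \le 1/2 \le \text{exp}_{\max}
\le \text{theo}_{\max}$ holds, and chance stays at 50% for any $d, r$.

**Two estimators of $d$ and $r$.** The pipeline summary mirrors the
experimental plug-ins: $d$ from the unimodal-visual evaluation accuracy and
$r$ from the auditory catch-trial hit rate in bimodal blocks. Both are
deliberately conservative for bounding *observed* consistency: the catch
trials charge the full report latency and the 300-ms disambiguation
transition against $r$, whereas in the consistency measure the decoder —
trained on equally lagged labels — reproduces the report timing, so
symmetric lags cancel. The end-to-end parameter-recovery test therefore
brackets the pipeline output with bounds computed from the session's
*realized ground-truth* quantities, which only the simulator can provide:
latent occupancies for $a$ and $v$, the lag-compensated decode-vs-latent
balanced accuracy for $d$, and the lag-compensated report-vs-latent
accuracy (`report_accuracy()`) for $r$. With those plug-ins the realized
joint occupancy necessarily respects the realized marginals, so the bound
logic is exact up to channel-independence and finite-sample noise.

**Group statistics** are the unadjusted two-tailed tests of the field:
one-sample *t* against 50%, paired *t* for condition contrasts, Pearson
correlations across participants; no multiple-testing correction. A
zero-variance sample with mean at the reference returns $t = 0, p = 1$
with a warning; a zero-variance sample off the reference is an error.

# Pipeline, determinism and problem sizes

`run_pipeline()` stages the run on disk — simulate, preprocess, features,
train, decode, couple, report — with every stage consuming only the written
config and earlier outputs; deleting an intermediate file and re-running its
stage regenerates it byte-identically. A single master seed expands into
per-participant and per-block sub-seeds through a documented counter scheme
(`sub_seed()`), so any block is regenerable in isolation. The log records
per-stage row counts (timepoints extracted, labelled, trained) to keep
exclusions auditable. Inclusion mirrors the experimental criteria: visual
and auditory catch-trial hit rates and mean decoding accuracy all at least
70%, each failure flagged separately.

Numerical and degenerate-input choices worth knowing: decision ties go to
the positive class; cost-selection ties to the smallest cost; missing
samples break displacement runs and are excluded from (never interpolated
into) sliding means; empty smoothing windows yield missing values, not 0;
single-class blocks raise errors (accuracies) or undefined cells
(consistency); hit rates with no exclusive report are signalled as
undefined rather than returned as 0.

Problem sizes used by the shipped checks are the package's own choices to
keep a full run on a laptop scale: the end-to-end recovery experiment uses
8 synthetic participants, full-length 210-s blocks, coupling
$\kappa \in \{0, 0.3, 0.6, 0.9\}$, clean OKN (no position noise or blinks),
`eps_report = 0.05`, and SVM training decimated to stride 10 (10-Hz
effective training rate; selection and evaluation remain at 100 Hz).
Monte-Carlo recovery tests use 10,000-s traces at reduced sampling rates.

# Known limitations

* The bounds' independence assumption (decoding errors independent of
  reporting errors at each timepoint) is exactly true in the simulator and
  only plausible in experiments.
* The expected bounds use reported-class proportions in place of true-class
  proportions; the error is small for accuracies above ~0.8 but grows as
  either channel approaches chance.
* The generator's instantaneous latent switches make transition periods
  sharper than real perception; decoder accuracy on real data will be lower
  near switches than the synthetic tests suggest.
* No lead–lag or switch-time cross-correlation analysis is provided; the
  consistency measure is symmetric and says nothing about which modality
  drives the other.
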