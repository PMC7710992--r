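---
title: "Methods: odor-mixture coding analysis with pirimix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: odor-mixture coding analysis with pirimix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirimix)
```

## The scientific problem

A single sniff delivers a blend of odorants emitted by many objects at
once. The anterior piriform cortex is thought to be where the olfactory
system recognizes objects within such blends, which raises two coupled
questions this package addresses computationally: how do cortical
responses to odorant *mixtures* relate to the responses to their single
components, and how well can the presence of one target odorant be read
out from single neurons and from small populations despite variable
backgrounds?

The experimental design the package models presents all $2^4 - 1 = 15$
combinations of a 4-odorant panel (4 singles, 6 pairs, 4 triplets, 1
quadruple), roughly 30 trials each, while recording well-isolated single
units and the animal's respiration. Because breathing gates olfactory
input, every analysis is anchored to $t_0$, the first inhalation onset at
or after odor onset.

## The normalization model

For a unit with baseline-subtracted mean responses $R_i$ to the single
odorants, the *linear prediction* for a mixture $M$ is
$LP = \sum_{i \in M} R_i$. The mixture response is modeled with a
saturating logistic map

$$R \;=\; R_{max}\left(\frac{2}{1 + e^{-s\,LP}} - 1\right)
      \;=\; R_{max}\tanh\!\left(\frac{s\,LP}{2}\right),$$

with two free parameters per neuron: the saturating response $R_{max}$
(Hz) and the initial-slope parameter $s$ (1/Hz); the slope at $LP = 0$ is
$R_{max}\,s/2$. The map is odd, so suppressive (negative) drive is
mapped to suppression. We implement it in the algebraically identical
$\tanh$ form, which cannot overflow for extreme arguments.

Fitting (`fitNormModel()`) is bounded nonlinear least squares over the
11 multi-component mixtures only: single-odorant points define $LP$ and
would sit on the identity line by construction, so they carry no
information about the two parameters. Bounds are
$R_{max} \in [0, 3\max|R|]$ and $s \in [0, 10/\max|LP|]$; three starts at
$s_0 \in \{0.1, 1, 10\}/\max|LP|$ guard against the shallow SSE valley
that appears when responses saturate early, and ties are broken toward
the smaller $s$. $R^2$ is computed about the mean observed response and
reported as `NA` when the observations have zero variance (a flat unit
constrains neither parameter). A fit is called "good" at $R^2 > 0.5$.

## Analysis chain

1. **Respiration** (`smoothFlow`, `detectInhalationOnsets`,
   `spikePhase`): flow traces are low-pass filtered with a 250 ms boxcar
   (shrink-to-valid edges, so a constant trace is unchanged); inhalation
   onsets are negative-going zero crossings, linearly interpolated below
   the sample period because PSTHs use 1 ms bins; spike phase is the
   cycle fraction between consecutive onsets, in $[0, 2\pi)$.
2. **Responses** (`alignTrials`, `responseTable`): per (unit, stimulus),
   per-trial rates in the 3 s window from $t_0$ are compared against the
   3 s immediately preceding odor onset of the same trial (this placement
   controls slow drift) with a two-sided Wilcoxon rank-sum test at
   $\alpha = 0.01$. No multiple-comparison correction is applied, matching
   the single-test convention of the analysis this implements; test
   counts are visible in the table. Response latency scans 10 ms bins of
   per-trial counts from $t_0$ with a two-sample KS test per bin against
   the time-equivalent baseline bin (1 ms bins of a ~2 Hz unit are
   nearly binary, which degenerates the KS statistic). With heavily tied
   low counts the KS test is conservative: on null simulations the
   per-scan false-positive rate is near zero rather than the nominal
   $1 - 0.99^{300}$, and weak responses need many trials to yield a
   latency at all; latencies are therefore reported only for significant
   responses and may be `NA`.
3. **PSTHs** (`buildPsth`): 1 ms bins, trial-averaged, in Hz, smoothed
   with a unit-area Gaussian read off a "50 ms window": truncation at
   $\pm 25$ ms with $\sigma = 12.5$ ms (window $= 4\sigma$),
   renormalized so the smoothed rate integrates to the spike count.
4. **Population models** (`buildPseudopopulation`,
   `predictMixturePsths`, `modelErrors`): units recorded with the same
   panel are pooled into a units × 15 × time tensor of
   baseline-subtracted PSTHs; each unit is scaled by its SD over all
   bins and stimuli. Predicted mixture PSTHs are the bin-wise linear
   sum, mean, and max of the component PSTHs, and the normalization
   model applied bin-wise to the linear-sum PSTH with one $(R_{max}, s)$
   pair per unit fit jointly over all mixtures' odor-epoch bins
   (bin-wise because the product must itself be a PSTH). Model error is
   the Euclidean distance across units at each bin; epoch means use the
   odor presentation epoch, 0–1.5 s from $t_0$ (the full 6 s extent is
   kept for time-course plots). Across the 11 mixtures, models are
   compared with Wilcoxon signed-rank tests. The normalization errors
   are also compared with the 105 pairwise inter-stimulus distances;
   those samples are unpaired, so the primary test is a rank-sum test,
   with a paired signed-rank test against each mixture's nearest
   neighbor distance reported alongside.
5. **ROC detection** (`rocTable`, `shuffledControl`, sweeps): per unit
   and odorant, the auROC for discriminating target-present from
   target-absent trials (8 vs 7 stimuli), ties counting 1/2. auROC is
   reported as-is, not folded about 0.5, so suppressive coding is
   visible as values below chance. The control shuffles labels once per
   unit × odorant (seeded) and pools the values; a pair is "above
   control" only if it beats every pooled shuffled value. Growing
   windows (0.1–3 s) and sliding 200 ms windows stepped at 50 ms (the
   step is our choice; only the width is prescribed) characterize
   integration time.
6. **Decoding** (`crossValidate`, `prunePopulation`, sweeps): detectors
   are logistic regressions on pseudo-population vectors. Per iteration,
   one held-out response per unit per stimulus forms 15 test vectors;
   1,000 training pseudo-trials per stimulus are assembled by drawing
   one real trial per unit independently *with replacement* (unavoidable
   when drawing 1,000 from ~29 remaining trials, and it also removes
   noise correlations, which pseudo-populations lack anyway). Accuracy
   is scored per test vector and averaged over 100 iterations. Because
   the printed loss has no penalty but separable pseudo-trial sets make
   the unpenalized MLE diverge, the solver adds a small ridge
   ($\lambda = 1/n_{train}$ by default, exposed to 0) and fits by damped
   Newton iterations; chance level is estimated empirically by label
   permutation since class priors are 8/7, not 1/2. Population pruning
   removes the unit with the smallest $|w|$ in the current model,
   retrains on the same iteration's training set, and re-scores, down to
   one unit. The temporal-resolution analysis concatenates per-unit bin
   rates (units × bins features) and enlarges training to 10,000
   pseudo-trials per stimulus; both the 3 s and a 1 s response duration
   variant are supported via `responseDur`.

## The synthetic-data generator

No public recordings accompany the analysis, so `simulatePopulation()`
generates populations with the statistical structure the pipeline
assumes, and every dataset carries its ground truth for recovery tests:

- **Baseline firing**: per-unit rates from a gamma distribution (shape
  2) with mean 1.9 Hz — the observed cortical mean — modulated by
  respiratory phase as $b(1 + m\cos(\phi - \phi_0))$ with depth
  $m = 0.5$ and uniform preferred phases.
- **Respiration**: a phase-jittered sinusoid (default 2.5 Hz, cycle-SD
  40 ms, sampled at 200 Hz). Only the onsets and the phase they define
  matter downstream, so no biomechanical realism is attempted.
- **Tuning**: each unit responds to a given odorant with probability
  0.4 (most responding units are then tuned to more than one of the 4
  singles); amplitudes are uniform on 2–15 Hz, and 18% of responsive
  pairs are mildly suppressive (0.5–3 Hz decreases; the total rate is
  floored at 0). The amplitude distribution is a modeling choice, not a
  measured quantity — the source experiments report no such
  distribution — and is fully configurable.
- **Response kernel**: latency uniform on 150–400 ms (responses begin
  no earlier than 150 ms after $t_0$), a 50 ms linear rise, a sustained
  plateau while the odor is on (1.5 s), and exponential decay
  ($\tau = 200$ ms) after offset. This is the simplest shape consistent
  with example mixture PSTHs and is easy to invert in tests.
- **Mixture integration**: the evoked increment for a mixture is the
  normalization model applied instant-by-instant to the linear sum of
  the unit's single-component kernel drives, with per-unit
  $R_{max} \sim U(5, 30)$ Hz and $s \sim U(0.02, 0.2)$ /Hz; spikes are
  then drawn as an inhomogeneous Poisson process on 1 ms steps.
- **Design**: all 15 stimuli, randomized order, 30 trials each; trials
  span 3.2 s before odor onset (so a full 3 s baseline window exists)
  and 3.8 s after.

Because the model is applied to the instantaneous drive, the
window-averaged mixture response is attenuated by the kernel duty cycle
relative to the instantaneous saturation level; rate-level fits
therefore recover $R_{max}$ up to that factor, and recovery tests assert
fidelity on the response scale (predicted vs observed) rather than on
raw parameter ratios.

What passing on this generator does *not* show: the simulator has no
noise correlations, no adaptation across the 30 repetitions, no
concentration dynamics within the odor pulse, Poisson (not over- or
under-dispersed) count noise, and stationary sniffing typical of
anesthesia. Conclusions about real awake recordings require the real
data; the generator's role is to verify that each analysis recovers what
it is defined to recover under the assumptions it states.

## A high-signal-to-noise preset

The decoding benchmark uses a deliberately favorable population — every
unit responsive to 1–3 odorants at 5–20 Hz, no suppression — via
`nResponsiveRange = c(1, 3)`, `responseAmpRangeHz = c(5, 20)`,
`suppressedFraction = 0`. This matches the regime in which a 37-unit
pseudo-population supports high detection accuracy and serves as a floor
check for the full cross-validation protocol.

## Numerical choices and degenerate inputs

- Times are seconds; every counting window is half-open $[a, b)$, so a
  boundary spike is never double-counted.
- Onset interpolation is linear between samples; flat zero segments
  count once, at the segment start, with a warning.
- All-equal rank-sum samples return $p = 1$; all-zero response vectors
  give $R^2 =$ `NA` rather than a forced fit; zero-SD units are excluded
  from the population tensor with a warning naming them.
- Determinism: one master seed drives the generator; classifier
  iterations use derived child seeds, so identical configurations give
  bit-identical outputs.

## Problem sizes used in the test suite

Unit tests run on reduced populations (6–10 units, 8–12 trials per
stimulus) chosen so each statistical property is still measurable; the
end-to-end checks use the full 37-unit, 30-trials-per-stimulus design
for the population model comparison and the decoding protocol, a
50-unit population for the fit-quality fraction, and 10,000 null
replicates for the rank-sum calibration. These sizes are stated here so
results are reproducible exactly as tested.

## Worked example

```{r example, eval = FALSE}
cfg <- generatorConfig(nUnits = 12, nTrialsPerStimulus = 20, seed = 1)
report <- runPipeline(cfg,
                      protocol = classifierProtocol(nTrainPerStimulus = 200,
                                                    nIterations = 20))
report
```

The report prints the grand-mean baseline rate, the fraction of units
with $R^2 > 0.5$, the number of mixtures for which the normalization
model is the most accurate, the best single-neuron auROC per odorant,
and the mean decoding accuracy, each computed by the corresponding
exported function.

## Known limitations

- The latency estimator needs strong responses or many trials; with 30
  trials and a ~2 Hz baseline, mild responses legitimately return `NA`.
- The normalization-model PSTH fit assumes a single $(R_{max}, s)$ pair
  per unit across mixtures and time; slow within-trial gain changes are
  not modeled.
- Sniff-warped (phase-based rather than time-based) reanalysis is out of
  scope; the respiration module exposes onsets and phases, so the
  extension is straightforward.
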