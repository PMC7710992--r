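# pirimix

Analysis of single-unit odor-mixture responses in anterior piriform
cortex, for electrophysiologists and computational neuroscientists who
want a tested, reproducible implementation of the full chain from
respiration-locked spike trains to population readout:

1. **Respiration processing** — 250 ms moving-average filtering,
   inhalation-onset detection (negative-going zero crossings), spike
   phase assignment.
2. **Response statistics** — trials aligned to the first inhalation
   after odor onset, 1 ms PSTHs with 50 ms Gaussian smoothing, rank-sum
   response significance (p < 0.01), KS-scan response latencies, cosine
   phase tuning, observed-vs-linear-sum comparison.
3. **Normalization model** — per-neuron fit of the saturating logistic
   mixture model
   `R = Rmax * (2 / (1 + exp(-s * LP)) - 1)`,
   where `LP` is the linear sum of the neuron's single-odorant
   responses, `Rmax` its saturating response and `s` the initial-slope
   parameter (slope `Rmax*s/2` at `LP = 0`).
4. **Population model comparison** — pseudo-population PSTH tensors,
   PCA trajectories, and bin-wise linear / mean / max / normalization
   predicted PSTHs scored by Euclidean population distance against the
   observed responses and against inter-stimulus distances.
5. **ROC detection** — single-neuron detectability of each target
   odorant within mixtures (auROC, Mann–Whitney tie convention),
   shuffled-label controls, growing and sliding integration windows.
6. **Pseudo-population decoding** — cross-validated logistic-regression
   detectors (one held-out response per unit per stimulus, 1,000
   training pseudo-trials per stimulus, 100 iterations), weight-based
   population pruning, integration-time and temporal-resolution sweeps.

Because no public dataset accompanies the source experiments, the
package ships a first-class synthetic-data generator
(`simulatePopulation()`) producing respiration traces and
inhomogeneous-Poisson spike trains with known ground truth: 1.9 Hz mean
baselines, respiratory phase locking, sparse predominantly excitatory
tuning with latencies ≥ 150 ms, and mixture integration through the
normalization model. Every analysis stage is validated against it.

## Worked example

```r
library(pirimix)

cfg <- generatorConfig(nUnits = 12, nTrialsPerStimulus = 20, seed = 1)
report <- runPipeline(cfg,
                      protocol = classifierProtocol(nTrainPerStimulus = 200,
                                                    nIterations = 20))
report
#> Pipeline report (seed 1 ): 12 units, 300 trials
#>   mean baseline rate: 1.90 Hz
#>   normalization fits with R2 > 0.5: 75%
#>   normalization model best for 11 / 11 mixtures
#>   best single-neuron auROC per odorant: 0.95, 0.99, 1.00, 0.99
#>   mean decoding accuracy: 99.1%
```

Reading the output: the simulated population has a grand-mean baseline
at the 1.9 Hz calibration target; three quarters of the units are well
fit (R² > 0.5) by the two-parameter normalization model; at the
population level the normalization-predicted PSTHs are closer to the
observed mixture responses than the linear, mean, or max predictions for
all 11 mixtures; single neurons already detect their best odorant well
(auROC up to 1.0); and pooling the 12 units pushes detection of every
odorant's presence to ~99% correct.

Individual stages are plain functions if you want the pieces:

```r
sim <- simulatePopulation(cfg)
ds  <- alignTrials(sim$dataset)          # t0 = first inhalation after odor
rt  <- responseTable(ds)                 # per-(unit, stimulus) statistics
fits <- fitNormModels(rt)                # per-unit (Rmax, s, R2)
pt  <- buildPseudopopulation(ds)         # units x 15 x time tensor
roc <- rocTable(ds)                      # unit x odorant auROC grid
res <- crossValidate(ds)                 # population detection accuracy
```

Datasets round-trip through plain text (`writeDataset()` /
`readDataset()`: CSV tables plus a JSON header), so external recordings
in the documented schema can be analyzed with the same functions.

## Documentation

The methods vignette (`vignettes/mixture-coding-methods.Rmd`) describes
the model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, the
numerical choices (windows, kernels, bounds, tie-breaks, degenerate
inputs), and known limitations.
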