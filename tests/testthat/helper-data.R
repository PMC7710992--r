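## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(key, maker) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- maker()
  .fixtures[[key]]
}

## small default-condition simulation with ground truth
smallSim <- function() cachedFixture("small", function() {
  cfg <- generatorConfig(nUnits = 8, nTrialsPerStimulus = 10, seed = 21)
  sim <- simulatePopulation(cfg)
  list(cfg = cfg, truth = sim$truth, ds = alignTrials(sim$dataset))
})

## small high-SNR population (every unit responsive, strong amplitudes)
snrSim <- function() cachedFixture("snr", function() {
  cfg <- generatorConfig(nUnits = 10, nTrialsPerStimulus = 12, seed = 31,
                         nResponsiveRange = c(1, 3),
                         responseAmpRangeHz = c(8, 20),
                         suppressedFraction = 0)
  sim <- simulatePopulation(cfg)
  list(cfg = cfg, truth = sim$truth, ds = alignTrials(sim$dataset))
})

## deterministic toy experiment: known respiration (pure sinusoid, so the
## alignment anchor is analytic) and spike counts set by rateFun(unit,
## bitmask) -> Hz, spikes evenly spaced in the response window. With
## poisson = TRUE counts are Poisson draws instead.
makeToyDataset <- function(nUnits = 2L, nOdorants = 2L, reps = 4L,
                           rateFun = function(u, m) 2, poisson = FALSE,
                           baselineHz = 0, seed = 1L) {
  set.seed(seed)
  f <- 2.5; dur <- 7; onset <- 3.2; srate <- 200
  tt <- seq(0, dur - 1 / srate, by = 1 / srate)
  flow <- sin(2 * pi * f * tt + 0.01)
  phi0 <- (pi - 0.01) / (2 * pi * f)      # first negative-going crossing
  t0true <- phi0 + (1 / f) * ceiling((onset - phi0) * f)
  stim <- stimulusSet(nOdorants)
  masks <- rep(stim, each = reps)
  nTr <- length(masks)
  trials <- data.frame(trial_id = seq_len(nTr), stimulus_bitmask = masks,
                       odor_onset_s = onset)
  spk <- list()
  for (tr in seq_len(nTr)) for (u in seq_len(nUnits)) {
    r <- rateFun(u, masks[tr])
    n <- if (poisson) stats::rpois(1, r * 3) else round(r * 3)
    times <- if (n > 0) seq(t0true + 0.1, t0true + 2.9, length.out = n)
             else numeric(0)
    if (baselineHz > 0) {
      nb <- if (poisson) stats::rpois(1, baselineHz * dur)
            else round(baselineHz * dur)
      times <- sort(c(times, seq(0.05, dur - 0.05, length.out = nb)))
    }
    if (length(times))
      spk[[length(spk) + 1L]] <- data.frame(
        trial_id = tr, unit_id = u, spike_time_s = times)
  }
  spikes <- if (length(spk)) do.call(rbind, spk)
            else data.frame(trial_id = integer(0), unit_id = integer(0),
                            spike_time_s = numeric(0))
  resp <- matrix(rep(flow, nTr), nrow = nTr, byrow = TRUE)
  ds <- OdorExperiment(trials, spikes, resp, srate,
                       nOdorants = nOdorants)
  ds@unitIds <- seq_len(nUnits)
  attr(ds, "t0true") <- t0true
  ds
}

## hand-built population tensor for the model-prediction unit tests
makeTensor <- function(rates, time = NULL, nOdorants = 2L,
                       odorEpoch = c(0, 1.5)) {
  stopifnot(length(dim(rates)) == 3L)
  if (is.null(time))
    time <- seq(-1, by = 0.5, length.out = dim(rates)[3])
  usd <- pmax(apply(rates, 1, stats::sd), 1e-9)
  new("PopulationTensor", rates = rates, time = time,
      stimuli = as.integer(stimulusSet(nOdorants)),
      unitSd = usd, unitIds = seq_len(dim(rates)[1]),
      nOdorants = as.integer(nOdorants), odorEpoch = odorEpoch)
}

## brute-force auROC by pair counting (the independent oracle)
aurocBruteForce <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}
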