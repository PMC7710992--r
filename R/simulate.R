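#' Configuration for the synthetic piriform population generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: low-baseline units (mean 1.9 Hz) whose firing is modulated by
#' respiratory phase, sparse and predominantly excitatory odorant tuning
#' with latencies of at least 150 ms, mixture integration through the
#' saturating logistic normalization model, and Poisson trial-to-trial
#' variability with ~30 trials of each of the 15 stimuli.
#'
#' @param nUnits number of simulated units.
#' @param nOdorants odorant panel size (default 4, giving 15 stimuli).
#' @param nTrialsPerStimulus trials per stimulus (default 30).
#' @param respirationFreqHz mean respiration frequency (Hz).
#' @param respirationJitterSd SD of the cycle length (s); 0 gives a pure
#'   sinusoid.
#' @param respSampleRate flow-trace sampling rate (Hz).
#' @param baselineRateMeanHz mean baseline firing rate across units (Hz).
#' @param baselineShape gamma shape for the across-unit baseline-rate
#'   distribution (mean fixed at \code{baselineRateMeanHz}).
#' @param phaseModDepth respiratory modulation depth in \eqn{[0,1]}.
#' @param tuningSparsity probability that a unit responds to a given
#'   odorant (ignored when \code{nResponsiveRange} is given).
#' @param nResponsiveRange optional integer pair: each unit responds to a
#'   number of odorants drawn uniformly from this range (used for
#'   high-SNR populations where every unit is responsive).
#' @param responseAmpRangeHz range of excitatory response amplitudes (Hz).
#' @param suppressedFraction fraction of responsive unit-odorant pairs with
#'   a (mild) rate decrease instead of an increase.
#' @param suppressedAmpRangeHz amplitude range for suppressive responses
#'   (Hz, applied with negative sign; total rate floored at 0).
#' @param latencyRangeS response latency range (s); lower bound must be
#'   >= 0.15.
#' @param rmaxRangeHz per-unit range of the saturation parameter Rmax (Hz).
#' @param sRangePerHz per-unit range of the initial-slope parameter s
#'   (1/Hz).
#' @param odorDurationS odor presentation duration (s).
#' @param preOdorS recording time before odor onset (s); must be >= 3 so a
#'   full 3 s baseline window exists.
#' @param postOdorS recording time after odor onset (s); must leave >= 3 s
#'   after the first post-onset inhalation.
#' @param seed integer RNG seed; identical configs give bit-identical
#'   datasets.
#' @return A validated list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(nUnits = 37L,
                            nOdorants = 4L,
                            nTrialsPerStimulus = 30L,
                            respirationFreqHz = 2.5,
                            respirationJitterSd = 0.04,
                            respSampleRate = 200,
                            baselineRateMeanHz = 1.9,
                            baselineShape = 2,
                            phaseModDepth = 0.5,
                            tuningSparsity = 0.4,
                            nResponsiveRange = NULL,
                            responseAmpRangeHz = c(2, 15),
                            suppressedFraction = 0.18,
                            suppressedAmpRangeHz = c(0.5, 3),
                            latencyRangeS = c(0.15, 0.4),
                            rmaxRangeHz = c(5, 30),
                            sRangePerHz = c(0.02, 0.2),
                            odorDurationS = 1.5,
                            preOdorS = 3.2,
                            postOdorS = 3.8,
                            seed = 1L) {
  cfg <- list(nUnits = as.integer(nUnits), nOdorants = as.integer(nOdorants),
              nTrialsPerStimulus = as.integer(nTrialsPerStimulus),
              respirationFreqHz = respirationFreqHz,
              respirationJitterSd = respirationJitterSd,
              respSampleRate = respSampleRate,
              baselineRateMeanHz = baselineRateMeanHz,
              baselineShape = baselineShape,
              phaseModDepth = phaseModDepth,
              tuningSparsity = tuningSparsity,
              nResponsiveRange = if (is.null(nResponsiveRange)) NULL
                                 else as.integer(nResponsiveRange),
              responseAmpRangeHz = responseAmpRangeHz,
              suppressedFraction = suppressedFraction,
              suppressedAmpRangeHz = suppressedAmpRangeHz,
              latencyRangeS = latencyRangeS,
              rmaxRangeHz = rmaxRangeHz,
              sRangePerHz = sRangePerHz,
              odorDurationS = odorDurationS,
              preOdorS = preOdorS, postOdorS = postOdorS,
              seed = as.integer(seed))
  class(cfg) <- "GeneratorConfig"
  validateGeneratorConfig(cfg)
  cfg
}

validateGeneratorConfig <- function(cfg) {
  stopifnot(cfg$nUnits >= 1, cfg$nOdorants >= 1, cfg$nTrialsPerStimulus >= 1)
  if (cfg$respirationFreqHz <= 0) stop("respiration frequency must be > 0")
  if (cfg$respirationJitterSd < 0) stop("jitter SD must be >= 0")
  if (cfg$baselineRateMeanHz < 0) stop("baseline rate must be >= 0")
  if (cfg$phaseModDepth < 0 || cfg$phaseModDepth > 1)
    stop("phaseModDepth must be in [0, 1]")
  if (cfg$tuningSparsity < 0 || cfg$tuningSparsity > 1)
    stop("tuningSparsity must be in [0, 1]")
  if (cfg$suppressedFraction < 0 || cfg$suppressedFraction > 1)
    stop("suppressedFraction must be in [0, 1]")
  if (cfg$latencyRangeS[1] < 0.15)
    stop("latency lower bound must be >= 0.15 s")
  for (nm in c("responseAmpRangeHz", "suppressedAmpRangeHz",
               "latencyRangeS", "rmaxRangeHz", "sRangePerHz")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0)
      stop(nm, " must be a nonnegative increasing pair")
  }
  if (cfg$preOdorS < 3) stop("preOdorS must be >= 3 (full baseline window)")
  if (cfg$odorDurationS <= 0) stop("odor duration must be > 0")
  invisible(TRUE)
}

#' @export
print.GeneratorConfig <- function(x, ...) {
  cat("GeneratorConfig:", x$nUnits, "units,", x$nOdorants, "odorants x",
      x$nTrialsPerStimulus, "trials/stimulus, seed", x$seed, "\n")
  invisible(x)
}

#' Simulate a respiration flow trace
#'
#' A zero-mean quasi-sinusoidal flow: cycle lengths are drawn around the
#' mean period with Gaussian jitter, and each cycle is one sine period.
#' Inhalation onsets are the negative-going zero crossings, i.e. the
#' half-cycle points. Only the onsets and the phase they define matter
#' downstream, so no biomechanical detail is modeled.
#'
#' @param config a [generatorConfig()].
#' @param duration trace duration (s); must be > 0.
#' @return list with \code{flow} (numeric samples), \code{sampleRate},
#'   \code{onsets} (true inhalation onset times within \code{[0,
#'   duration)}), and \code{cycles} (data.frame of cycle start times and
#'   lengths, covering a margin beyond the trace for phase lookup).
#' @export
simulateRespiration <- function(config, duration) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0")
  f <- config$respirationFreqHz
  period <- 1 / f
  ## cover [-margin, duration + margin] so phase is defined everywhere
  nCyc <- ceiling((duration + 3 * period) * f * 1.5) + 3L
  lens <- stats::rnorm(nCyc, period, config$respirationJitterSd)
  lens <- pmax(lens, 0.2 * period)
  starts <- -period + c(0, cumsum(lens[-nCyc]))
  tt <- seq(0, duration - 1 / config$respSampleRate,
            by = 1 / config$respSampleRate)
  k <- findInterval(tt, starts)
  u <- (tt - starts[k]) / lens[k]
  ## one cycle = -sin(2*pi*u): flow turns negative (inhalation) at the
  ## cycle boundary, so onsets are the cycle starts and onset intervals
  ## equal the jittered cycle lengths
  flow <- -sin(2 * pi * u)
  onsets <- starts
  list(flow = flow, sampleRate = config$respSampleRate,
       onsets = onsets[onsets >= 0 & onsets < duration],
       cycles = data.frame(start = starts, length = lens))
}

## Respiratory phase (0..2pi from inhalation onset) at arbitrary times,
## from the generator's known cycle structure; onsets sit at cycle
## starts, so the phase is simply the cycle fraction.
simPhaseAt <- function(tt, cycles) {
  k <- findInterval(tt, cycles$start)
  k[k < 1] <- 1L
  u <- (tt - cycles$start[k]) / cycles$length[k]
  2 * pi * (u %% 1)
}

## Response kernel: zero before response start, linear 50 ms rise,
## sustained at 1 until odor offset, exponential decay (tau = 200 ms)
## afterwards. `tt` are absolute times, `tStart` = t0 + latency.
responseKernel <- function(tt, tStart, odorOff, riseS = 0.05, tauS = 0.2) {
  k <- numeric(length(tt))
  rise <- tt >= tStart & tt < tStart + riseS
  k[rise] <- (tt[rise] - tStart) / riseS
  sus <- tt >= tStart + riseS & tt < odorOff
  k[sus] <- 1
  dec <- tt >= odorOff
  if (odorOff < tStart + riseS) {
    ## odor ends during (or before) the rise: decay from the level reached
    lvl <- max(0, min(1, (odorOff - tStart) / riseS))
    k[dec] <- lvl * exp(-(tt[dec] - odorOff) / tauS)
  } else {
    k[dec] <- exp(-(tt[dec] - odorOff) / tauS)
  }
  k
}

#' Simulate a full mixture-coding experiment with known ground truth
#'
#' Generates every trial of the full stimulus set (all \code{2^n - 1}
#' odorant combinations, randomized order, \code{nTrialsPerStimulus}
#' each). Per unit, firing is an inhomogeneous Poisson process with rate
#' \deqn{b (1 + m \cos(\phi(t) - \phi_0)) + \Delta(t),}
#' where the odor-evoked increment \eqn{\Delta(t)} is the unit's response
#' kernel scaled by its single-odorant amplitude, and for mixtures the
#' saturating logistic normalization model applied to the linear sum of
#' the single-component increments. The total rate is floored at zero.
#'
#' @param config a [generatorConfig()].
#' @return list with \code{dataset} (an [OdorExperiment-class]) and
#'   \code{truth} (per-unit baseline rates, preferred phases, per-odorant
#'   amplitudes and latencies, and the (Rmax, s) pair each unit integrates
#'   mixtures with).
#' @export
simulatePopulation <- function(config) {
  validateGeneratorConfig(config)
  set.seed(config$seed)
  nU <- config$nUnits; nO <- config$nOdorants
  stim <- stimulusSet(nO)
  nTr <- config$nTrialsPerStimulus * length(stim)
  odorOnset <- config$preOdorS
  trialDur <- config$preOdorS + config$postOdorS
  dt <- 0.001
  tt <- seq(0, trialDur - dt, by = dt)

  ## ground truth
  baseline <- stats::rgamma(nU, shape = config$baselineShape,
                            scale = config$baselineRateMeanHz /
                              config$baselineShape)
  phase0 <- stats::runif(nU, 0, 2 * pi)
  amp <- matrix(0, nU, nO)
  if (is.null(config$nResponsiveRange)) {
    resp <- matrix(stats::runif(nU * nO) < config$tuningSparsity, nU, nO)
  } else {
    r <- config$nResponsiveRange
    resp <- matrix(FALSE, nU, nO)
    for (i in seq_len(nU)) {
      k <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
      resp[i, sample(nO, min(k, nO))] <- TRUE
    }
  }
  nResp <- sum(resp)
  a <- stats::runif(nResp, config$responseAmpRangeHz[1],
                    config$responseAmpRangeHz[2])
  neg <- stats::runif(nResp) < config$suppressedFraction
  a[neg] <- -stats::runif(sum(neg), config$suppressedAmpRangeHz[1],
                          config$suppressedAmpRangeHz[2])
  amp[resp] <- a
  latency <- matrix(NA_real_, nU, nO)
  latency[resp] <- stats::runif(nResp, config$latencyRangeS[1],
                                config$latencyRangeS[2])
  rmax <- stats::runif(nU, config$rmaxRangeHz[1], config$rmaxRangeHz[2])
  sPar <- stats::runif(nU, config$sRangePerHz[1], config$sRangePerHz[2])

  stimSeq <- sample(rep(stim, config$nTrialsPerStimulus))
  trials <- data.frame(trial_id = seq_len(nTr),
                       stimulus_bitmask = stimSeq,
                       odor_onset_s = odorOnset,
                       t0_s = NA_real_)

  respMat <- matrix(0, nTr, length(seq(0, trialDur - 1 / config$respSampleRate,
                                       by = 1 / config$respSampleRate)))
  spkTrial <- vector("list", nTr)
  spkUnit <- vector("list", nTr)
  odorOff <- odorOnset + config$odorDurationS
  cosP0 <- cos(phase0); sinP0 <- sin(phase0)
  m <- config$phaseModDepth

  for (tr in seq_len(nTr)) {
    resp1 <- simulateRespiration(config, trialDur)
    respMat[tr, ] <- resp1$flow
    phi <- simPhaseAt(tt, resp1$cycles)
    ## first inhalation at/after odor onset = true alignment anchor
    t0 <- resp1$onsets[resp1$onsets >= odorOnset][1]
    if (is.na(t0)) t0 <- odorOnset  # cannot happen with margins, but safe
    ## baseline rates: nU x nT via outer trig expansion
    cphi <- cos(phi); sphi <- sin(phi)
    rateMat <- (baseline %o% rep(1, length(tt))) *
      (1 + m * (cosP0 %o% cphi + sinP0 %o% sphi))
    comps <- stimulusComponents(stimSeq[tr])
    for (i in which(rowSums(resp[, comps, drop = FALSE]) > 0)) {
      lp <- numeric(length(tt))
      for (o in comps) {
        if (!resp[i, o]) next
        lp <- lp + amp[i, o] *
          responseKernel(tt, t0 + latency[i, o], odorOff)
      }
      incr <- if (length(comps) == 1L) lp
              else rmax[i] * tanh(sPar[i] * lp / 2)
      rateMat[i, ] <- rateMat[i, ] + incr
    }
    rateMat[rateMat < 0] <- 0
    nSpk <- matrix(stats::rpois(length(rateMat), rateMat * dt),
                   nrow = nU)
    hit <- which(nSpk > 0, arr.ind = TRUE)
    if (nrow(hit)) {
      cnt <- nSpk[hit]
      uu <- rep(hit[, 1], cnt)
      bb <- rep(hit[, 2], cnt)
      st <- tt[bb] + stats::runif(length(bb)) * dt
      o <- order(st)
      spkTrial[[tr]] <- st[o]
      spkUnit[[tr]] <- uu[o]
    } else {
      spkTrial[[tr]] <- numeric(0)
      spkUnit[[tr]] <- integer(0)
    }
  }

  nPerTrial <- lengths(spkTrial)
  spikes <- data.frame(trial_id = rep(seq_len(nTr), nPerTrial),
                       unit_id = unlist(spkUnit),
                       spike_time_s = unlist(spkTrial))
  ds <- OdorExperiment(trials, spikes, respMat, config$respSampleRate,
                       nOdorants = nO, odorDuration = config$odorDurationS)
  ds@unitIds <- seq_len(nU)
  truth <- list(baselineHz = baseline, preferredPhase = phase0,
                phaseModDepth = m, amplitudeHz = amp,
                latencyS = latency, rmaxHz = rmax, sPerHz = sPar,
                responsive = resp)
  list(dataset = ds, truth = truth)
}
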