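#' Align trials to the first inhalation onset after odor onset
#'
#' Smooths each trial's respiration trace (250 ms moving average), detects
#' inhalation onsets (negative-going zero crossings) and sets the
#' alignment anchor \code{t0} to the first onset at or after odor onset.
#' Trials without a post-onset inhalation are dropped with a warning.
#'
#' @param ds an [OdorExperiment-class] with respiration traces.
#' @param invert passed to [detectInhalationOnsets()].
#' @return The dataset with \code{t0_s} filled in the trial table and
#'   per-trial onset lists stored for phase analysis.
#' @export
alignTrials <- function(ds, invert = FALSE) {
  stopifnot(is(ds, "OdorExperiment"))
  if (nrow(ds@respiration) == 0L)
    stop("dataset has no respiration traces to align to")
  nTr <- nrow(ds@trials)
  t0 <- rep(NA_real_, nTr)
  ons <- vector("list", nTr)
  for (tr in seq_len(nTr)) {
    sm <- smoothFlow(ds@respiration[tr, ], ds@respSampleRate)
    o <- detectInhalationOnsets(sm, ds@respSampleRate, invert = invert)
    ons[[tr]] <- o
    hit <- o[o >= ds@trials$odor_onset_s[tr]]
    if (length(hit)) t0[tr] <- hit[1]
  }
  nDrop <- sum(is.na(t0))
  if (nDrop > 0) {
    warning(nDrop, " trial(s) without an inhalation after odor onset dropped")
    keep <- !is.na(t0)
    ds@trials <- ds@trials[keep, , drop = FALSE]
    ds@spikes <- ds@spikes[ds@spikes$trial_id %in% ds@trials$trial_id, ,
                           drop = FALSE]
    ds@respiration <- ds@respiration[keep, , drop = FALSE]
    t0 <- t0[keep]; ons <- ons[keep]
  }
  ds@trials$t0_s <- t0
  ds@onsets <- ons
  validObject(ds)
  ds
}

## split spike times by (trial, unit) once; returns a list indexed
## [[trialIdx]][[unitIdx]] of spike-time vectors
splitSpikes <- function(ds) {
  nTr <- nrow(ds@trials)
  uIdx <- match(ds@spikes$unit_id, ds@unitIds)
  tIdx <- match(ds@spikes$trial_id, ds@trials$trial_id)
  out <- vector("list", nTr)
  empty <- rep(list(numeric(0)), length(ds@unitIds))
  grp <- split(seq_len(nrow(ds@spikes)), tIdx)
  for (tr in seq_len(nTr)) out[[tr]] <- empty
  for (nm in names(grp)) {
    tr <- as.integer(nm)
    rows <- grp[[nm]]
    sub <- split(ds@spikes$spike_time_s[rows], uIdx[rows])
    for (un in names(sub)) out[[tr]][[as.integer(un)]] <- sub[[un]]
  }
  out
}

#' Per-trial firing rates in a window relative to the alignment anchor
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param window half-open window \code{[lo, hi)} in seconds relative to
#'   \code{t0} (default the 3 s response period).
#' @return numeric matrix trials x units of rates (Hz), with the trial
#'   table rows as rownames context (same order as \code{trialTable(ds)}).
#' @export
trialRates <- function(ds, window = c(0, 3)) {
  stopifnot(is(ds, "OdorExperiment"), length(window) == 2L,
            window[2] > window[1])
  if (anyNA(ds@trials$t0_s)) stop("dataset not aligned; run alignTrials()")
  lo <- ds@trials$t0_s + window[1]
  hi <- ds@trials$t0_s + window[2]
  countsInWindows(ds, lo, hi) / diff(window)
}

## spike counts per trial x unit in per-trial windows [lo, hi)
countsInWindows <- function(ds, lo, hi) {
  tIdx <- match(ds@spikes$trial_id, ds@trials$trial_id)
  keep <- ds@spikes$spike_time_s >= lo[tIdx] & ds@spikes$spike_time_s < hi[tIdx]
  uIdx <- match(ds@spikes$unit_id[keep], ds@unitIds)
  nTr <- nrow(ds@trials); nU <- length(ds@unitIds)
  cnt <- tabulate(tIdx[keep] + nTr * (uIdx - 1L), nbins = nTr * nU)
  matrix(cnt, nrow = nTr, ncol = nU)
}

#' Build a peri-stimulus time histogram
#'
#' Spike times (already aligned, i.e. relative to \code{t0}) are binned at
#' 1 ms, averaged over trials, converted to Hz, and smoothed with a
#' unit-area Gaussian kernel read off a "50 ms window": the kernel is
#' truncated at +/-25 ms with sigma = 12.5 ms and renormalized, so the
#' total spike count under the rate curve is conserved (edges use
#' shrink-to-valid renormalization).
#'
#' @param alignedSpikes list of per-trial spike-time vectors, relative to
#'   the alignment anchor.
#' @param window half-open \code{[lo, hi)} PSTH extent in seconds.
#' @param binS bin width (s), default 1 ms.
#' @param smoothS Gaussian window length (s); \code{0} disables smoothing.
#' @return list of class \code{"Psth"}: \code{time} (bin starts),
#'   \code{rate} (smoothed Hz), \code{raw} (unsmoothed Hz),
#'   \code{nTrials}, \code{binS}.
#' @export
buildPsth <- function(alignedSpikes, window = c(-3, 3), binS = 0.001,
                      smoothS = 0.05) {
  nTrials <- length(alignedSpikes)
  if (nTrials == 0L) stop("cannot build a PSTH from zero trials")
  nBins <- round(diff(window) / binS)
  allSpk <- unlist(alignedSpikes, use.names = FALSE)
  allSpk <- allSpk[allSpk >= window[1] & allSpk < window[2]]
  idx <- floor((allSpk - window[1]) / binS) + 1L
  idx[idx > nBins] <- nBins
  counts <- tabulate(idx, nbins = nBins)
  raw <- counts / (nTrials * binS)
  rate <- if (smoothS > 0) gaussSmooth(raw, binS, smoothS) else raw
  structure(list(time = window[1] + (seq_len(nBins) - 1L) * binS,
                 rate = rate, raw = raw, nTrials = nTrials, binS = binS),
            class = "Psth")
}

## unit-area truncated Gaussian smoothing; window = 4*sigma, truncated at
## +/- window/2, edge-renormalized so DC (and total area away from edges)
## is preserved
gaussSmooth <- function(x, binS, windowS) {
  half <- max(1L, round((windowS / 2) / binS))
  sigma <- windowS / 4
  kk <- stats::dnorm(seq(-half, half) * binS, sd = sigma)
  kk <- kk / sum(kk)
  n <- length(x)
  num <- stats::convolve(c(rep(0, half), x, rep(0, half)), kk,
                         type = "filter")
  den <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)), kk,
                         type = "filter")
  num / den
}

#' @export
print.Psth <- function(x, ...) {
  cat("PSTH:", length(x$time), "bins of", x$binS * 1000, "ms,",
      x$nTrials, "trials, peak", format(max(x$rate), digits = 4), "Hz\n")
  invisible(x)
}

#' Rank-sum response significance
#'
#' Two-sided Wilcoxon rank-sum test of per-trial response-window rates
#' against per-trial baseline-window rates. A response is called
#' significant at p < 0.01. Identical all-equal samples return p = 1 by
#' convention.
#'
#' @param responseRates,baselineRates numeric vectors of per-trial rates
#'   (Hz); at least 2 trials each.
#' @return the two-sided p-value.
#' @export
responseSignificance <- function(responseRates, baselineRates) {
  stopifnot(length(responseRates) >= 2L, length(baselineRates) >= 2L)
  if (length(unique(c(responseRates, baselineRates))) == 1L) return(1)
  suppressWarnings(
    stats::wilcox.test(responseRates, baselineRates, exact = FALSE)$p.value)
}

#' Response latency by per-bin Kolmogorov-Smirnov scan
#'
#' Scanning forward from the alignment anchor in \code{binS}-wide bins,
#' the latency is the start of the first bin whose across-trial
#' distribution of spike counts differs from the time-equivalent baseline
#' bin at p < 0.01 (two-sample KS). 1 ms bins of a low-rate unit are
#' nearly binary and KS-degenerate, so the scan uses 10 ms bins by
#' default. Returns \code{NA} when no bin qualifies. No multiple
#' comparison correction is applied (the per-scan false positive rate is
#' characterized on null simulations in the test suite).
#'
#' @param respSpikes list of per-trial spike times relative to t0 (s).
#' @param baseSpikes list of per-trial spike times relative to the start
#'   of the baseline epoch (s); same number of trials.
#' @param scanS how far to scan from t0 (s).
#' @param binS scan bin width (s).
#' @param alpha per-bin significance threshold.
#' @return latency in seconds (bin start) or \code{NA}.
#' @export
responseLatency <- function(respSpikes, baseSpikes, scanS = 3,
                            binS = 0.01, alpha = 0.01) {
  stopifnot(length(respSpikes) == length(baseSpikes))
  nBins <- floor(scanS / binS)
  nTr <- length(respSpikes)
  binOf <- function(spk, b) {
    lo <- (b - 1) * binS; hi <- b * binS
    vapply(spk, function(s) sum(s >= lo & s < hi), numeric(1))
  }
  for (b in seq_len(nBins)) {
    rc <- binOf(respSpikes, b)
    bc <- binOf(baseSpikes, b)
    if (all(rc == bc)) next
    p <- suppressWarnings(stats::ks.test(rc, bc)$p.value)
    if (is.finite(p) && p < alpha) return((b - 1) * binS)
  }
  NA_real_
}

#' Cosine fit of respiratory phase tuning
#'
#' Histogram of the fraction of spikes per phase bin, least-squares fit of
#' \eqn{a + b\cos(\phi - \phi_0)} with \eqn{b \ge 0}. The fit is linear in
#' \eqn{(a, b\cos\phi_0, b\sin\phi_0)} and solved in closed form.
#'
#' @param phases spike phases in \eqn{[0, 2\pi)}; at least 1.
#' @param nBins number of phase bins.
#' @return list: \code{preferredPhase} (\eqn{\phi_0} in \eqn{[0,2\pi)},
#'   NA when degenerate), \code{modDepth} (b), \code{offset} (a),
#'   \code{fraction} (per-bin spike fraction), \code{binCenters},
#'   \code{degenerate} flag.
#' @export
phaseTuning <- function(phases, nBins = 20L) {
  stopifnot(length(phases) >= 1L)
  edges <- seq(0, 2 * pi, length.out = nBins + 1L)
  idx <- findInterval(phases, edges, rightmost.closed = TRUE)
  idx[idx > nBins] <- nBins
  frac <- tabulate(idx, nbins = nBins) / length(phases)
  ctr <- (edges[-1] + edges[-(nBins + 1L)]) / 2
  if (sum(frac > 0) < 2L) {
    return(list(preferredPhase = NA_real_, modDepth = 0,
                offset = 1 / nBins, fraction = frac, binCenters = ctr,
                degenerate = TRUE))
  }
  X <- cbind(1, cos(ctr), sin(ctr))
  beta <- stats::lm.fit(X, frac)$coefficients
  b <- sqrt(beta[2]^2 + beta[3]^2)
  phi0 <- atan2(beta[3], beta[2]) %% (2 * pi)
  list(preferredPhase = unname(phi0), modDepth = unname(b),
       offset = unname(beta[1]), fraction = frac, binCenters = ctr,
       degenerate = FALSE)
}

#' Compute the per-(unit, stimulus) response table
#'
#' For every unit and stimulus: per-trial spike rates in the 3 s response
#' window starting at the alignment anchor, per-trial baseline rates in
#' the 3 s immediately preceding odor onset of the same trial, the mean
#' baseline-subtracted response R, rank-sum significance (p < 0.01), the
#' response sign, and (for significant responses) the KS-scan latency.
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param windowS response/baseline window length (s).
#' @param alpha significance threshold.
#' @param latency compute latencies (slower); default TRUE.
#' @return A [ResponseTable-class].
#' @export
responseTable <- function(ds, windowS = 3, alpha = 0.01, latency = TRUE) {
  stopifnot(is(ds, "OdorExperiment"))
  if (anyNA(ds@trials$t0_s)) stop("dataset not aligned; run alignTrials()")
  stim <- stimulusSet(ds@nOdorants)
  nU <- length(ds@unitIds); nS <- length(stim)
  respCnt <- countsInWindows(ds, ds@trials$t0_s,
                             ds@trials$t0_s + windowS) / windowS
  baseCnt <- countsInWindows(ds, ds@trials$odor_onset_s - windowS,
                             ds@trials$odor_onset_s) / windowS
  stimRows <- lapply(stim, function(s)
    which(ds@trials$stimulus_bitmask == s))
  maxTr <- max(lengths(stimRows))
  rr <- array(NA_real_, c(nU, nS, maxTr))
  br <- array(NA_real_, c(nU, nS, maxTr))
  spk <- if (latency) splitSpikes(ds) else NULL
  rows <- vector("list", nU * nS)
  k <- 0L
  for (si in seq_len(nS)) {
    tr <- stimRows[[si]]
    for (ui in seq_len(nU)) {
      k <- k + 1L
      rv <- respCnt[tr, ui]; bv <- baseCnt[tr, ui]
      rr[ui, si, seq_along(tr)] <- rv
      br[ui, si, seq_along(tr)] <- bv
      p <- if (length(tr) >= 2L) responseSignificance(rv, bv) else NA_real_
      R <- mean(rv) - mean(bv)
      sig <- !is.na(p) && p < alpha
      lat <- NA_real_
      if (latency && sig) {
        respS <- lapply(tr, function(t2)
          spk[[t2]][[ui]] - ds@trials$t0_s[t2])
        baseS <- lapply(tr, function(t2)
          spk[[t2]][[ui]] - (ds@trials$odor_onset_s[t2] - windowS))
        lat <- responseLatency(respS, baseS, scanS = windowS,
                               alpha = alpha)
      }
      rows[[k]] <- data.frame(
        unit_id = ds@unitIds[ui], stimulus_bitmask = stim[si],
        size = mixtureSize(stim[si]), n_trials = length(tr),
        R = R, p = p, significant = sig,
        sign = if (sig) sign(R) else 0, latency_s = lat)
    }
  }
  new("ResponseTable", summary = do.call(rbind, rows),
      responseRates = rr, baselineRates = br,
      unitIds = ds@unitIds, stimuli = stim,
      nOdorants = ds@nOdorants, window = windowS)
}

#' Fraction of significant responses as a function of mixture size
#'
#' @param rt a [ResponseTable-class].
#' @param alpha significance threshold used in the table.
#' @return list: \code{table} (per mixture size: n pairs, n significant,
#'   fraction, 95\% binomial CI), \code{r} and \code{p} from the Pearson
#'   correlation of fraction vs size (NA when the fractions are constant).
#' @export
fractionSignificantBySize <- function(rt, alpha = 0.01) {
  s <- responseSummary(rt)
  sizes <- sort(unique(s$size))
  tab <- do.call(rbind, lapply(sizes, function(sz) {
    sub <- s[s$size == sz, ]
    n <- nrow(sub); k <- sum(sub$significant)
    ci <- stats::binom.test(k, n)$conf.int
    data.frame(size = sz, n = n, nSignificant = k, fraction = k / n,
               ciLow = ci[1], ciHigh = ci[2])
  }))
  if (length(sizes) >= 3L && stats::sd(tab$fraction) > 0) {
    ct <- stats::cor.test(tab$size, tab$fraction)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_
  }
  list(table = tab, r = r, p = p)
}

#' Observed mixture responses vs the linear sum of component responses
#'
#' For every unit with all single-odorant responses measured, pairs each
#' multi-component stimulus's observed mean baseline-subtracted response
#' with its linear prediction LP (the sum of the unit's single-component
#' responses).
#'
#' @param rt a [ResponseTable-class].
#' @return data.frame with columns \code{unit_id},
#'   \code{stimulus_bitmask}, \code{size}, \code{LP}, \code{R_observed},
#'   \code{difference} (observed minus linear prediction).
#' @export
linearSumComparison <- function(rt) {
  s <- responseSummary(rt)
  singles <- s[s$size == 1L, ]
  out <- list()
  for (u in rt@unitIds) {
    su <- singles[singles$unit_id == u, ]
    if (nrow(su) < rt@nOdorants || anyNA(su$R)) {
      message("unit ", u, " lacks single-odorant responses; excluded")
      next
    }
    compR <- numeric(rt@nOdorants)
    for (o in seq_len(rt@nOdorants))
      compR[o] <- su$R[su$stimulus_bitmask == bitwShiftL(1L, o - 1L)]
    mix <- s[s$unit_id == u & s$size > 1L, ]
    lp <- vapply(mix$stimulus_bitmask,
                 function(m) sum(compR[stimulusComponents(m)]), numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      unit_id = u, stimulus_bitmask = mix$stimulus_bitmask,
      size = mix$size, LP = lp, R_observed = mix$R,
      difference = mix$R - lp)
  }
  do.call(rbind, out)
}
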