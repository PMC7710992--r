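#' Low-pass filter a flow trace with a 250 ms moving average
#'
#' Boxcar moving average with window \code{round(windowS * sampleRate)}
#' samples, centered. Edges use shrink-to-valid averaging (the mean over
#' the in-range part of the window), so the output has the same length as
#' the input and a constant trace passes through unchanged.
#'
#' @param flow numeric vector of raw flow samples.
#' @param sampleRate sampling rate (Hz), > 0.
#' @param windowS moving-average window length in seconds (default 0.25).
#' @return numeric vector, smoothed flow, same length as \code{flow}.
#' @export
smoothFlow <- function(flow, sampleRate, windowS = 0.25) {
  stopifnot(is.numeric(flow), sampleRate > 0)
  w <- max(1L, round(windowS * sampleRate))
  n <- length(flow)
  if (w > n) stop("smoothing window (", w, " samples) longer than trace (",
                  n, " samples)")
  half <- (w - 1) %/% 2
  halfUp <- w - 1 - half
  cs <- cumsum(c(0, flow))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + halfUp, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect inhalation onsets as negative-going zero crossings
#'
#' Inhalation onsets are the times where the (smoothed) flow signal
#' crosses zero from positive to negative, linearly interpolated between
#' samples so onsets are resolved below the sample period. Flat
#' zero-valued segments entered from positive values count as one onset
#' at the segment start (with a warning).
#'
#' @param flow numeric vector of (smoothed) flow samples.
#' @param sampleRate sampling rate (Hz).
#' @param invert set \code{TRUE} for sensors wired with the opposite sign
#'   convention; onsets are then the positive-going crossings of the
#'   recorded signal.
#' @return numeric vector of strictly increasing onset times (s, relative
#'   to the first sample).
#' @export
detectInhalationOnsets <- function(flow, sampleRate, invert = FALSE) {
  stopifnot(is.numeric(flow), sampleRate > 0)
  if (invert) flow <- -flow
  n <- length(flow)
  if (n < 2L) return(numeric(0))
  tt <- (seq_len(n) - 1L) / sampleRate
  s <- sign(flow)
  onsets <- numeric(0)
  ## ordinary crossings: positive sample followed by negative sample
  idx <- which(s[-n] > 0 & s[-1] < 0)
  if (length(idx)) {
    frac <- flow[idx] / (flow[idx] - flow[idx + 1L])
    onsets <- tt[idx] + frac / sampleRate
  }
  ## exact-zero hits and flat-zero segments entered from positive values
  zi <- which(s == 0)
  if (length(zi)) {
    segStart <- zi[c(TRUE, diff(zi) > 1L)]
    flat <- logical(0)
    for (st in segStart) {
      en <- st
      while (en < n && s[en + 1L] == 0) en <- en + 1L
      if (st > 1L && s[st - 1L] > 0 && en < n && s[en + 1L] < 0) {
        onsets <- c(onsets, tt[st])
        if (en > st) flat <- c(flat, TRUE)
      }
    }
    if (any(flat))
      warning("flat zero segment(s) in flow trace; onset taken at segment start")
  }
  sort(onsets)
}

#' Assign respiratory phase to spike times
#'
#' The phase of a spike at time \code{t} within the cycle bounded by
#' consecutive inhalation onsets \code{onset_i <= t < onset_{i+1}} is
#' \deqn{\phi = 2\pi (t - onset_i) / (onset_{i+1} - onset_i) \in [0, 2\pi).}
#' Spikes before the first or at/after the last onset are not inside a
#' covered cycle and are dropped (count reported via a message).
#'
#' @param spikeTimes numeric spike times (s), same clock as the onsets.
#' @param onsets strictly increasing inhalation onset times; at least 2.
#' @return numeric vector of phases in \eqn{[0, 2\pi)} for the retained
#'   spikes, with attribute \code{"dropped"} giving the number of spikes
#'   outside covered cycles.
#' @export
spikePhase <- function(spikeTimes, onsets) {
  if (length(onsets) < 2L)
    stop("need at least 2 inhalation onsets to define a cycle")
  if (is.unsorted(onsets, strictly = TRUE))
    stop("onsets must be strictly increasing")
  k <- findInterval(spikeTimes, onsets)
  ok <- k >= 1L & k < length(onsets)
  nDrop <- sum(!ok)
  if (nDrop > 0)
    message(nDrop, " spike(s) outside covered respiratory cycles dropped")
  k <- k[ok]
  ph <- 2 * pi * (spikeTimes[ok] - onsets[k]) / (onsets[k + 1L] - onsets[k])
  ph[ph >= 2 * pi] <- 0  # guard against rounding at the upper cycle edge
  structure(ph, dropped = nDrop)
}
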