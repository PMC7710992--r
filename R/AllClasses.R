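#' @import methods
NULL

#' OdorExperiment: spike trains, respiration and stimulus table for one
#' (real or simulated) recording set
#'
#' The central container of the package. Each trial is an independent
#' recording epoch with its own respiration trace; spike times are in
#' seconds from trial start. Alignment to the first inhalation after odor
#' onset (the anchor \code{t0}) is performed by [alignTrials()] and stored
#' in the trial table.
#'
#' @slot trials data.frame with columns \code{trial_id},
#'   \code{stimulus_bitmask}, \code{odor_onset_s} and (after alignment)
#'   \code{t0_s}.
#' @slot spikes data.frame with columns \code{trial_id}, \code{unit_id},
#'   \code{spike_time_s}, sorted by trial then time.
#' @slot respiration numeric matrix, one row per trial, of raw flow samples.
#' @slot respSampleRate sampling rate of the flow traces (Hz).
#' @slot onsets list of per-trial inhalation onset times (filled by
#'   [alignTrials()]).
#' @slot nOdorants number of odorants in the panel.
#' @slot unitIds integer ids of the recorded units.
#' @slot odorDuration odor presentation duration (s).
#'
#' @export
setClass("OdorExperiment",
  representation(
    trials = "data.frame",
    spikes = "data.frame",
    respiration = "matrix",
    respSampleRate = "numeric",
    onsets = "list",
    nOdorants = "integer",
    unitIds = "integer",
    odorDuration = "numeric"
  )
)

setValidity("OdorExperiment", function(object) {
  msg <- character(0)
  needT <- c("trial_id", "stimulus_bitmask", "odor_onset_s")
  if (!all(needT %in% names(object@trials)))
    msg <- c(msg, paste("trials must have columns:", paste(needT, collapse = ", ")))
  needS <- c("trial_id", "unit_id", "spike_time_s")
  if (!all(needS %in% names(object@spikes)))
    msg <- c(msg, paste("spikes must have columns:", paste(needS, collapse = ", ")))
  if (length(msg) == 0L) {
    full <- stimulusSet(object@nOdorants)
    bad <- setdiff(unique(object@trials$stimulus_bitmask), full)
    if (length(bad))
      msg <- c(msg, paste("unknown stimulus bitmask(s):", paste(bad, collapse = ", ")))
    if (anyDuplicated(object@trials$trial_id))
      msg <- c(msg, "duplicated trial_id in trials")
    orphan <- setdiff(unique(object@spikes$trial_id), object@trials$trial_id)
    if (length(orphan))
      msg <- c(msg, paste("spikes reference unknown trial_id(s):",
                          paste(utils::head(orphan, 3), collapse = ", ")))
    if (nrow(object@respiration) > 0 &&
        nrow(object@respiration) != nrow(object@trials))
      msg <- c(msg, "respiration must have one row per trial")
    if (nrow(object@spikes) > 0) {
      o <- order(object@spikes$trial_id, object@spikes$spike_time_s)
      if (is.unsorted(o))
        msg <- c(msg, "spikes must be sorted by trial_id then spike_time_s")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OdorExperiment
#'
#' @param trials,spikes data.frames as documented for the class slots.
#' @param respiration matrix of flow samples (one row per trial); may have
#'   zero rows when no respiration was recorded.
#' @param respSampleRate flow sampling rate in Hz.
#' @param nOdorants odorant panel size.
#' @param odorDuration odor presentation duration in seconds.
#' @return An [OdorExperiment-class] object.
#' @export
OdorExperiment <- function(trials, spikes, respiration,
                           respSampleRate, nOdorants = 4L,
                           odorDuration = 1.5) {
  spikes <- spikes[order(spikes$trial_id, spikes$spike_time_s), , drop = FALSE]
  rownames(spikes) <- NULL
  if (!("t0_s" %in% names(trials))) trials$t0_s <- NA_real_
  new("OdorExperiment",
      trials = trials, spikes = spikes,
      respiration = respiration, respSampleRate = respSampleRate,
      onsets = list(),
      nOdorants = as.integer(nOdorants),
      unitIds = sort(unique(as.integer(spikes$unit_id))),
      odorDuration = odorDuration)
}

#' PopulationTensor: pseudo-population PSTH array
#'
#' Trial-averaged, baseline-subtracted, smoothed PSTHs for every unit and
#' stimulus on a shared time grid, together with the per-unit normalization
#' standard deviation used for population distance computations.
#'
#' @slot rates numeric array, units x stimuli x time bins (Hz,
#'   baseline-subtracted).
#' @slot time bin start times relative to the alignment anchor t0 (s).
#' @slot stimuli integer stimulus bitmasks (third and second dims labels).
#' @slot unitSd per-unit standard deviation over all bins and stimuli.
#' @slot unitIds integer unit ids (rows of \code{rates}).
#' @slot nOdorants odorant panel size.
#' @slot odorEpoch two-element numeric, the odor presentation epoch
#'   \code{[start, end)} used for epoch-mean errors (s from t0).
#' @export
setClass("PopulationTensor",
  representation(
    rates = "array",
    time = "numeric",
    stimuli = "integer",
    unitSd = "numeric",
    unitIds = "integer",
    nOdorants = "integer",
    odorEpoch = "numeric"
  )
)

setValidity("PopulationTensor", function(object) {
  d <- dim(object@rates)
  msg <- character(0)
  if (length(d) != 3L) msg <- c(msg, "rates must be a 3-d array")
  else {
    if (d[2] != length(object@stimuli))
      msg <- c(msg, "dim 2 of rates must match stimuli")
    if (d[3] != length(object@time))
      msg <- c(msg, "dim 3 of rates must match time")
    if (d[1] != length(object@unitSd) || d[1] != length(object@unitIds))
      msg <- c(msg, "dim 1 of rates must match unitSd and unitIds")
    if (any(object@unitSd <= 0))
      msg <- c(msg, "unitSd must be > 0 for all included units")
  }
  if (length(object@odorEpoch) != 2L || diff(object@odorEpoch) <= 0)
    msg <- c(msg, "odorEpoch must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' ResponseTable: per-(unit, stimulus) trial rates and response statistics
#'
#' The substrate for the normalization-model fit, ROC analysis and
#' decoding: per-trial firing rates in the response window, per-trial
#' baseline rates, and derived statistics (mean baseline-subtracted
#' response R, rank-sum significance, response latency, sign).
#'
#' @slot summary data.frame, one row per (unit, stimulus) with columns
#'   \code{unit_id}, \code{stimulus_bitmask}, \code{size}, \code{n_trials},
#'   \code{R}, \code{p}, \code{significant}, \code{sign}, \code{latency_s}.
#' @slot responseRates array units x stimuli x max trials of response-window
#'   rates (Hz), NA-padded when trial counts differ.
#' @slot baselineRates matching array of baseline-window rates.
#' @slot unitIds,stimuli dimension labels.
#' @slot nOdorants odorant panel size.
#' @slot window length of the response/baseline windows (s).
#' @export
setClass("ResponseTable",
  representation(
    summary = "data.frame",
    responseRates = "array",
    baselineRates = "array",
    unitIds = "integer",
    stimuli = "integer",
    nOdorants = "integer",
    window = "numeric"
  )
)

setValidity("ResponseTable", function(object) {
  d <- dim(object@responseRates)
  msg <- character(0)
  if (length(d) != 3L || !all(d == dim(object@baselineRates)))
    msg <- c(msg, "responseRates and baselineRates must be matching 3-d arrays")
  else if (d[1] != length(object@unitIds) || d[2] != length(object@stimuli))
    msg <- c(msg, "array dims must match unitIds and stimuli")
  if (length(msg)) msg else TRUE
})
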