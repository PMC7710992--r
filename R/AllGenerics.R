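#' Number of units in a container
#' @param x An object holding per-unit data.
#' @return Integer count of units.
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' Stimulus bitmasks carried by a container
#' @param x An object holding per-stimulus data.
#' @return Integer vector of bitmasks.
#' @export
setGeneric("stimuli", function(x) standardGeneric("stimuli"))

#' Trial table accessor
#' @param x An [OdorExperiment-class].
#' @return The trial data.frame.
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))

#' Spike table accessor
#' @param x An [OdorExperiment-class].
#' @return The spike data.frame.
#' @export
setGeneric("spikeTable", function(x) standardGeneric("spikeTable"))

#' @rdname nUnits
#' @export
setMethod("nUnits", "OdorExperiment", function(x) length(x@unitIds))
#' @rdname nUnits
#' @export
setMethod("nUnits", "PopulationTensor", function(x) length(x@unitIds))
#' @rdname nUnits
#' @export
setMethod("nUnits", "ResponseTable", function(x) length(x@unitIds))

#' @rdname stimuli
#' @export
setMethod("stimuli", "OdorExperiment",
          function(x) stimulusSet(x@nOdorants))
#' @rdname stimuli
#' @export
setMethod("stimuli", "PopulationTensor", function(x) x@stimuli)
#' @rdname stimuli
#' @export
setMethod("stimuli", "ResponseTable", function(x) x@stimuli)

#' @rdname trialTable
#' @export
setMethod("trialTable", "OdorExperiment", function(x) x@trials)
#' @rdname spikeTable
#' @export
setMethod("spikeTable", "OdorExperiment", function(x) x@spikes)

#' Summary data.frame of a ResponseTable
#' @param x A [ResponseTable-class].
#' @return data.frame with one row per (unit, stimulus).
#' @export
responseSummary <- function(x) {
  stopifnot(is(x, "ResponseTable"))
  x@summary
}

setMethod("show", "OdorExperiment", function(object) {
  cat("OdorExperiment:", nrow(object@trials), "trials,",
      length(object@unitIds), "units,",
      object@nOdorants, "odorants (",
      length(stimulusSet(object@nOdorants)), "stimuli )\n")
  cat("  spikes:", nrow(object@spikes),
      "| respiration:", ncol(object@respiration), "samples/trial @",
      object@respSampleRate, "Hz\n")
  al <- sum(!is.na(object@trials$t0_s))
  cat("  aligned trials:", al, "/", nrow(object@trials), "\n")
})

setMethod("show", "PopulationTensor", function(object) {
  d <- dim(object@rates)
  cat("PopulationTensor:", d[1], "units x", d[2], "stimuli x", d[3],
      "time bins\n")
  cat("  time:", format(min(object@time), digits = 3), "to",
      format(max(object@time), digits = 3), "s; odor epoch [",
      object@odorEpoch[1], ",", object@odorEpoch[2], ") s\n")
})

setMethod("show", "ResponseTable", function(object) {
  cat("ResponseTable:", length(object@unitIds), "units x",
      length(object@stimuli), "stimuli;",
      sum(object@summary$significant), "significant responses (p < 0.01)\n")
})
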