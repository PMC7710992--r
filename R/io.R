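#' Write a dataset to a directory of plain-text files
#'
#' Writes \code{trials.csv}, \code{spikes.csv}, \code{respiration.csv}
#' (one row per trial: trial_id followed by flow samples) and
#' \code{meta.json}; optionally \code{truth.json} for simulated data.
#'
#' @param ds an [OdorExperiment-class].
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth list from [simulatePopulation()].
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(ds, dir, truth = NULL) {
  stopifnot(is(ds, "OdorExperiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ds@trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(ds@spikes, file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  resp <- cbind(trial_id = ds@trials$trial_id, as.data.frame(ds@respiration))
  utils::write.csv(resp, file.path(dir, "respiration.csv"),
                   row.names = FALSE)
  meta <- list(respSampleRate = ds@respSampleRate,
               nOdorants = ds@nOdorants,
               odorDuration = ds@odorDuration,
               unitIds = ds@unitIds)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset directory
#'
#' Reads the files written by [writeDataset()] with schema validation:
#' missing columns, unknown stimulus bitmasks and non-monotone spike
#' times (within a trial, in file order) are reported as errors naming
#' the offending column/trial; an empty spikes file is accepted with a
#' warning (zero-rate units).
#'
#' @param dir dataset directory.
#' @return an [OdorExperiment-class].
#' @export
readDataset <- function(dir) {
  need <- c("trials.csv", "spikes.csv", "meta.json")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("dataset directory is missing: ", paste(miss, collapse = ", "))
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  needT <- c("trial_id", "stimulus_bitmask", "odor_onset_s")
  if (!all(needT %in% names(trials)))
    stop("trials.csv missing column(s): ",
         paste(setdiff(needT, names(trials)), collapse = ", "))
  needS <- c("trial_id", "unit_id", "spike_time_s")
  if (!all(needS %in% names(spikes)))
    stop("spikes.csv missing column(s): ",
         paste(setdiff(needS, names(spikes)), collapse = ", "))
  full <- stimulusSet(meta$nOdorants)
  bad <- setdiff(unique(trials$stimulus_bitmask), full)
  if (length(bad))
    stop("unknown stimulus bitmask(s) in trials.csv: ",
         paste(bad, collapse = ", "))
  if (nrow(spikes) == 0L)
    warning("spikes.csv is empty; dataset has zero-rate units")
  for (tr in unique(spikes$trial_id)) {
    st <- spikes$spike_time_s[spikes$trial_id == tr]
    if (is.unsorted(st))
      stop("non-monotone spike times in trial ", tr)
  }
  respFile <- file.path(dir, "respiration.csv")
  respMat <- if (file.exists(respFile)) {
    r <- utils::read.csv(respFile)
    as.matrix(r[match(trials$trial_id, r$trial_id), -1, drop = FALSE])
  } else matrix(numeric(0), 0, 0)
  ds <- OdorExperiment(trials, spikes, respMat, meta$respSampleRate,
                       nOdorants = meta$nOdorants,
                       odorDuration = meta$odorDuration)
  if (!is.null(meta$unitIds)) ds@unitIds <- as.integer(meta$unitIds)
  ds
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a dataset, align it, and run the requested stages:
#' response statistics, normalization-model fits, population model
#' comparison, ROC detection and pseudo-population decoding. Fully
#' deterministic given the config seed. Optionally writes every stage's
#' tables as CSV.
#'
#' @param config a [generatorConfig()] (used when \code{dataset} is NULL).
#' @param dataset an existing [OdorExperiment-class] to analyze instead
#'   of simulating.
#' @param stages character subset of \code{c("respond", "fit",
#'   "popmodel", "roc", "decode")}.
#' @param protocol [classifierProtocol()] for the decode stage.
#' @param outDir optional output directory for CSV tables.
#' @return list of class \code{"PipelineReport"} with one element per
#'   executed stage plus \code{provenance}.
#' @export
runPipeline <- function(config = generatorConfig(),
                        dataset = NULL,
                        stages = c("respond", "fit", "popmodel", "roc",
                                   "decode"),
                        protocol = classifierProtocol(),
                        outDir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list()
  if (is.null(dataset)) {
    sim <- simulatePopulation(config)
    dataset <- sim$dataset
    report$truth <- sim$truth
  }
  ds <- alignTrials(dataset)
  report$provenance <- list(
    seed = config$seed,
    nUnits = length(ds@unitIds),
    nTrials = nrow(ds@trials),
    package = as.character(utils::packageVersion("pirimix")))
  saveCsv <- function(df, name) {
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(df, file.path(outDir, name), row.names = FALSE)
    }
  }
  rt <- NULL
  if (any(c("respond", "fit", "roc") %in% stages)) {
    rt <- responseTable(ds)
    report$responses <- list(
      table = responseSummary(rt),
      baselineMeanHz = mean(rt@baselineRates, na.rm = TRUE),
      fractionBySize = fractionSignificantBySize(rt),
      linearSum = linearSumComparison(rt))
    saveCsv(responseSummary(rt), "responses.csv")
  }
  if ("fit" %in% stages) {
    fits <- fitNormModels(rt)
    report$fits <- list(
      table = fits,
      fractionWellFit = mean(fits$r2 > 0.5, na.rm = TRUE),
      correlates = fitQualityCorrelates(fits))
    saveCsv(fits, "fits.csv")
  }
  if ("popmodel" %in% stages) {
    pt <- buildPseudopopulation(ds)
    preds <- lapply(c("linear", "mean", "max", "normalization"),
                    function(m) predictMixturePsths(pt, m))
    err <- modelErrors(preds, pt)
    dists <- interStimulusDistances(pt)
    normErr <- err$epochMean[err$epochMean$model == "normalization", ]
    report$popmodel <- list(
      epochMean = err$epochMean,
      winner = err$winner,
      nNormalizationBest = sum(err$winner$winner == "normalization"),
      pairwiseP = err$pairwiseP,
      interStimulus = dists,
      errorVsDistance = compareErrorsToDistances(normErr, dists),
      pca = pcaTrajectories(pt))
    saveCsv(err$epochMean, "model_errors.csv")
  }
  if ("roc" %in% stages) {
    sc <- shuffledControl(ds, seed = config$seed + 101L)
    report$roc <- list(
      table = sc$roc,
      bestPerNeuron = bestPerNeuron(sc$roc),
      bestPerOdorant = bestPerOdorant(sc$roc),
      nAboveControl = sum(bestPerNeuron(sc$roc)$auroc >
                            max(sc$shuffledValues)))
    saveCsv(sc$roc, "roc.csv")
  }
  if ("decode" %in% stages) {
    res <- crossValidate(ds, protocol)
    report$decoding <- list(
      accuracy = res$accuracy,
      perOdorant = res$perOdorant,
      bySize = res$bySize)
    saveCsv(data.frame(odorant = seq_along(res$perOdorant),
                       accuracy = res$perOdorant), "decoding.csv")
  }
  class(report) <- "PipelineReport"
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("Pipeline report (seed", x$provenance$seed, "):",
      x$provenance$nUnits, "units,", x$provenance$nTrials, "trials\n")
  if (!is.null(x$responses))
    cat(sprintf("  mean baseline rate: %.2f Hz\n",
                x$responses$baselineMeanHz))
  if (!is.null(x$fits))
    cat(sprintf("  normalization fits with R2 > 0.5: %.0f%%\n",
                100 * x$fits$fractionWellFit))
  if (!is.null(x$popmodel))
    cat("  normalization model best for",
        x$popmodel$nNormalizationBest, "/",
        nrow(x$popmodel$winner), "mixtures\n")
  if (!is.null(x$roc))
    cat(sprintf("  best single-neuron auROC per odorant: %s\n",
                paste(sprintf("%.2f", x$roc$bestPerOdorant$auroc),
                      collapse = ", ")))
  if (!is.null(x$decoding))
    cat(sprintf("  mean decoding accuracy: %.1f%%\n",
                100 * x$decoding$accuracy))
  invisible(x)
}
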