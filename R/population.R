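#' Assemble a pseudo-population PSTH tensor
#'
#' Pools units from one or more aligned experiments that used the same
#' odorant panel into a units x stimuli x time array of trial-averaged,
#' smoothed, baseline-subtracted PSTHs (baseline = each PSTH's own mean
#' over the pre-anchor window). Each unit's normalization SD is computed
#' over all bins and stimuli; units with zero SD carry no signal and are
#' excluded with a warning.
#'
#' @param datasets an aligned [OdorExperiment-class] or a list of them.
#' @param window PSTH extent \code{[lo, hi)} around the alignment anchor
#'   (s); must include pre-anchor time for baseline subtraction.
#' @param binS PSTH bin width (s).
#' @param smoothS Gaussian smoothing window (s).
#' @param odorEpoch odor presentation epoch \code{[start, end)} used for
#'   epoch-mean errors (s from the anchor).
#' @return A [PopulationTensor-class].
#' @export
buildPseudopopulation <- function(datasets, window = c(-3, 3),
                                  binS = 0.001, smoothS = 0.05,
                                  odorEpoch = c(0, 1.5)) {
  if (is(datasets, "OdorExperiment")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L)
  nOd <- datasets[[1]]@nOdorants
  stim <- stimulusSet(nOd)
  rateList <- list(); ids <- integer(0)
  unitOffset <- 0L
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    stopifnot(is(ds, "OdorExperiment"))
    if (ds@nOdorants != nOd)
      stop("dataset ", di, " uses a different odorant panel (",
           ds@nOdorants, " vs ", nOd, " odorants)")
    present <- sort(unique(ds@trials$stimulus_bitmask))
    if (!identical(as.integer(present), sort(stim)))
      stop("dataset ", di, " is missing stimuli: ",
           paste(setdiff(stim, present), collapse = ", "))
    if (anyNA(ds@trials$t0_s)) stop("dataset ", di, " is not aligned")
    spk <- splitSpikes(ds)
    nBins <- round(diff(window) / binS)
    for (ui in seq_along(ds@unitIds)) {
      mat <- matrix(0, length(stim), nBins)
      for (si in seq_along(stim)) {
        tr <- which(ds@trials$stimulus_bitmask == stim[si])
        aligned <- lapply(tr, function(t2)
          spk[[t2]][[ui]] - ds@trials$t0_s[t2])
        p <- buildPsth(aligned, window = window, binS = binS,
                       smoothS = smoothS)
        base <- mean(p$rate[p$time < 0])
        mat[si, ] <- p$rate - base
      }
      rateList[[length(rateList) + 1L]] <- mat
      ids <- c(ids, unitOffset + ds@unitIds[ui])
    }
    unitOffset <- unitOffset + max(ds@unitIds)
  }
  nU <- length(rateList)
  nBins <- ncol(rateList[[1]])
  rates <- array(0, c(nU, length(stim), nBins))
  for (ui in seq_len(nU)) rates[ui, , ] <- rateList[[ui]]
  unitSd <- apply(rates, 1, stats::sd)
  keep <- unitSd > 0
  if (any(!keep))
    warning(sum(!keep), " unit(s) with zero response SD excluded: ",
            paste(ids[!keep], collapse = ", "))
  if (!any(keep)) stop("no unit with nonzero response SD")
  new("PopulationTensor",
      rates = rates[keep, , , drop = FALSE],
      time = window[1] + (seq_len(nBins) - 1L) * binS,
      stimuli = as.integer(stim), unitSd = unitSd[keep],
      unitIds = ids[keep], nOdorants = as.integer(nOd),
      odorEpoch = odorEpoch)
}

## average consecutive bins to a coarser time grid
downsampleBins <- function(x, factor) {
  nb <- floor(length(x) / factor)
  colMeans(matrix(x[seq_len(nb * factor)], nrow = factor))
}

#' PCA trajectories of population responses
#'
#' PCA on SD-normalized responses: the data matrix has one row per
#' (stimulus, time bin) sample and one column per unit, each unit divided
#' by its normalization SD. PSTHs are downsampled (default 10 ms bins) to
#' control dimensionality; the projections trace each stimulus's
#' trajectory through PC space.
#'
#' @param pt a [PopulationTensor-class].
#' @param nComponents number of PCs to return; must not exceed the number
#'   of units.
#' @param downsampleS time resolution for the PCA (s).
#' @return list: \code{projections} (array stimuli x bins x components),
#'   \code{varExplained} (fraction per PC), \code{rotation} (units x
#'   components), \code{time}.
#' @export
pcaTrajectories <- function(pt, nComponents = 2L, downsampleS = 0.01) {
  stopifnot(is(pt, "PopulationTensor"))
  nU <- nUnits(pt)
  if (nComponents > nU)
    stop("requested ", nComponents, " components from ", nU, " units")
  binS <- pt@time[2] - pt@time[1]
  fac <- max(1L, round(downsampleS / binS))
  nS <- length(pt@stimuli)
  ds <- lapply(seq_len(nU), function(ui)
    t(apply(pt@rates[ui, , , drop = TRUE], 1, downsampleBins, factor = fac)) /
      pt@unitSd[ui])
  nb <- ncol(ds[[1]])
  X <- matrix(0, nS * nb, nU)
  for (ui in seq_len(nU)) X[, ui] <- as.vector(t(ds[[ui]])) # stim-major rows
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  proj <- array(0, c(nS, nb, nComponents))
  for (ci in seq_len(nComponents))
    proj[, , ci] <- matrix(pc$x[, ci], nS, nb, byrow = TRUE)
  tds <- pt@time[seq(1, fac * nb, by = fac)]
  list(projections = proj, varExplained = ve,
       rotation = pc$rotation[, seq_len(nComponents), drop = FALSE],
       time = tds)
}

#' Model-predicted mixture PSTHs
#'
#' Builds predicted PSTHs for every multi-component stimulus from the
#' observed single-odorant PSTHs: \describe{
#'   \item{linear}{bin-wise sum of the component PSTHs}
#'   \item{mean}{bin-wise sum divided by the mixture size}
#'   \item{max}{bin-wise maximum}
#'   \item{normalization}{the saturating logistic model applied bin-wise
#'     to the linear-sum PSTH, with a single (Rmax, s) pair per unit fit
#'     by least squares jointly over all mixtures' odor-epoch bins}
#' }
#'
#' @param pt a [PopulationTensor-class].
#' @param model one of \code{"linear"}, \code{"mean"}, \code{"max"},
#'   \code{"normalization"}.
#' @return list of class \code{"ModelPrediction"}: \code{model},
#'   \code{predicted} (units x mixtures x bins), \code{mixtures}
#'   (bitmasks), \code{time}; for the normalization model also
#'   \code{fits} (per-unit Rmax, s).
#' @export
predictMixturePsths <- function(pt, model = c("linear", "mean", "max",
                                              "normalization")) {
  stopifnot(is(pt, "PopulationTensor"))
  model <- match.arg(model)
  sz <- mixtureSize(pt@stimuli)
  singles <- pt@stimuli[sz == 1L]
  mixtures <- pt@stimuli[sz > 1L]
  nU <- nUnits(pt); nB <- length(pt@time)
  singleIdx <- match(singles, pt@stimuli)
  pred <- array(0, c(nU, length(mixtures), nB))
  linsum <- array(0, c(nU, length(mixtures), nB))
  for (mi in seq_along(mixtures)) {
    comps <- stimulusComponents(mixtures[mi])
    compIdx <- singleIdx[match(bitwShiftL(1L, comps - 1L), singles)]
    cube <- pt@rates[, compIdx, , drop = FALSE]
    linsum[, mi, ] <- apply(cube, c(1, 3), sum)
    pred[, mi, ] <- switch(model,
      linear = linsum[, mi, ],
      mean = linsum[, mi, ] / length(comps),
      max = apply(cube, c(1, 3), max),
      normalization = linsum[, mi, ])  # transformed below
  }
  fits <- NULL
  if (model == "normalization") {
    epoch <- pt@time >= pt@odorEpoch[1] & pt@time < pt@odorEpoch[2]
    obs <- pt@rates[, match(mixtures, pt@stimuli), , drop = FALSE]
    fits <- data.frame(unit_id = pt@unitIds, rmax = NA_real_, s = NA_real_)
    for (ui in seq_len(nU)) {
      f <- fitNormModel(as.vector(linsum[ui, , epoch]),
                        as.vector(obs[ui, , epoch]))
      fits$rmax[ui] <- f$rmax; fits$s[ui] <- f$s
      pred[ui, , ] <- evalNormModel(f$rmax, f$s, pred[ui, , ])
    }
  }
  structure(list(model = model, predicted = pred,
                 mixtures = as.integer(mixtures), time = pt@time,
                 fits = fits),
            class = "ModelPrediction")
}

#' @export
print.ModelPrediction <- function(x, ...) {
  cat("ModelPrediction (", x$model, "): ", dim(x$predicted)[1],
      " units x ", length(x$mixtures), " mixtures x ",
      dim(x$predicted)[3], " bins\n", sep = "")
  invisible(x)
}

## population Euclidean distance in SD-normalized space, per time bin:
## a, b are units x bins matrices
popDistance <- function(a, b, unitSd) {
  if (is.null(dim(a))) { a <- matrix(a, nrow = 1); b <- matrix(b, nrow = 1) }
  d <- (a - b) / unitSd
  sqrt(colSums(d * d))
}

#' Model errors against observed mixture responses
#'
#' For each prediction and mixture, the Euclidean distance between the
#' predicted and observed population vectors (SD-normalized) at every
#' time bin, the mean over the odor epoch, and pairwise Wilcoxon
#' signed-rank comparisons of the epoch-mean errors between models across
#' mixtures.
#'
#' @param predictions a \code{ModelPrediction} or a list of them.
#' @param pt the [PopulationTensor-class] the predictions came from.
#' @return list: \code{timecourse} (list per model of mixtures x bins
#'   error matrices), \code{epochMean} (data.frame model x mixture),
#'   \code{pairwiseP} (matrix of signed-rank p-values between models),
#'   \code{winner} (model with the lowest error per mixture),
#'   \code{time}.
#' @export
modelErrors <- function(predictions, pt) {
  if (is(predictions, "ModelPrediction")) predictions <- list(predictions)
  stopifnot(is(pt, "PopulationTensor"))
  models <- vapply(predictions, function(p) p$model, character(1))
  mix <- predictions[[1]]$mixtures
  obsIdx <- match(mix, pt@stimuli)
  epoch <- pt@time >= pt@odorEpoch[1] & pt@time < pt@odorEpoch[2]
  tc <- list(); em <- list()
  for (pi in seq_along(predictions)) {
    p <- predictions[[pi]]
    stopifnot(identical(p$mixtures, mix))
    errs <- matrix(0, length(mix), length(pt@time))
    for (mi in seq_along(mix))
      errs[mi, ] <- popDistance(p$predicted[, mi, ],
                                pt@rates[, obsIdx[mi], ], pt@unitSd)
    tc[[models[pi]]] <- errs
    em[[pi]] <- data.frame(model = models[pi], mixture = mix,
                           size = mixtureSize(mix),
                           meanError = rowMeans(errs[, epoch, drop = FALSE]))
  }
  em <- do.call(rbind, em)
  pw <- matrix(NA_real_, length(models), length(models),
               dimnames = list(models, models))
  if (length(models) > 1L) {
    for (i in seq_along(models)) for (j in seq_along(models)) {
      if (i == j) next
      ei <- em$meanError[em$model == models[i]]
      ej <- em$meanError[em$model == models[j]]
      pw[i, j] <- suppressWarnings(
        stats::wilcox.test(ei, ej, paired = TRUE, exact = FALSE)$p.value)
    }
  }
  wide <- matrix(em$meanError, nrow = length(mix))
  colnames(wide) <- models
  winner <- models[apply(wide, 1, which.min)]
  list(timecourse = tc, epochMean = em, pairwiseP = pw,
       winner = data.frame(mixture = mix, winner = winner),
       time = pt@time)
}

#' Pairwise distances between observed stimulus responses
#'
#' Odor-epoch mean Euclidean distances (SD-normalized space) between the
#' observed population responses to every pair of presented stimuli: 105
#' pairs for the 15-stimulus panel. Used as the yardstick the
#' normalization model's errors are compared against.
#'
#' @param pt a [PopulationTensor-class].
#' @return data.frame with columns \code{stimA}, \code{stimB},
#'   \code{distance}.
#' @export
interStimulusDistances <- function(pt) {
  stopifnot(is(pt, "PopulationTensor"))
  epoch <- pt@time >= pt@odorEpoch[1] & pt@time < pt@odorEpoch[2]
  nS <- length(pt@stimuli)
  out <- list()
  for (i in seq_len(nS - 1L)) for (j in (i + 1L):nS) {
    d <- popDistance(pt@rates[, i, ], pt@rates[, j, ], pt@unitSd)
    out[[length(out) + 1L]] <- data.frame(
      stimA = pt@stimuli[i], stimB = pt@stimuli[j],
      distance = mean(d[epoch]))
  }
  do.call(rbind, out)
}

#' Compare model errors with inter-stimulus distances
#'
#' The model's 11 epoch-mean errors against the 105 pairwise
#' inter-stimulus distances. The samples are unpaired, so the default
#' comparison is a rank-sum test; a paired signed-rank test of each
#' mixture's error against the smallest inter-stimulus distance involving
#' that mixture is also reported.
#'
#' @param errors epoch-mean errors for one model (the relevant subset of
#'   \code{modelErrors()$epochMean}).
#' @param distances output of [interStimulusDistances()].
#' @return list: \code{pRankSum}, \code{pPairedMin},
#'   \code{medianError}, \code{medianDistance}.
#' @export
compareErrorsToDistances <- function(errors, distances) {
  stopifnot(is.data.frame(errors), is.data.frame(distances))
  pRS <- suppressWarnings(
    stats::wilcox.test(errors$meanError, distances$distance,
                       exact = FALSE)$p.value)
  minD <- vapply(errors$mixture, function(m)
    min(distances$distance[distances$stimA == m | distances$stimB == m]),
    numeric(1))
  pPM <- suppressWarnings(
    stats::wilcox.test(errors$meanError, minD, paired = TRUE,
                       exact = FALSE)$p.value)
  list(pRankSum = pRS, pPairedMin = pPM,
       medianError = stats::median(errors$meanError),
       medianDistance = stats::median(distances$distance))
}
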