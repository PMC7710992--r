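#' Classifier protocol for pseudo-population decoding
#'
#' Bundles the cross-validation settings: per iteration one response per
#' unit per stimulus is held out as the test set, training pseudo-trials
#' are drawn (with replacement) from the remaining trials, one linear
#' detector is trained per target odorant, and the 15 held-out population
#' vectors are scored. Reported accuracy is the mean over iterations.
#'
#' @param nTrainPerStimulus training pseudo-trials per stimulus (1,000 by
#'   default; 10,000 for the temporal-resolution analysis).
#' @param nIterations cross-validation iterations (default 100).
#' @param window integration window \code{[lo, hi)} from the alignment
#'   anchor (s).
#' @param binWidthS temporal feature bin width (s); \code{NULL} = rate
#'   code (one feature per unit).
#' @param lambda ridge penalty on the logistic loss; \code{NULL} defaults
#'   to \code{1 / nTrainingRows} (kept small: the printed loss has no
#'   penalty, but separable pseudo-trial sets diverge without one).
#' @param seed master seed; per-iteration seeds are derived from it.
#' @return list of class \code{"ClassifierProtocol"}.
#' @export
classifierProtocol <- function(nTrainPerStimulus = 1000L,
                               nIterations = 100L,
                               window = c(0, 3),
                               binWidthS = NULL,
                               lambda = NULL,
                               seed = 1L) {
  stopifnot(nTrainPerStimulus >= 1, nIterations >= 1,
            length(window) == 2L, window[2] > window[1])
  structure(list(nTrainPerStimulus = as.integer(nTrainPerStimulus),
                 nIterations = as.integer(nIterations),
                 window = window, binWidthS = binWidthS,
                 lambda = lambda, seed = as.integer(seed)),
            class = "ClassifierProtocol")
}

#' Per-trial binned spike counts
#'
#' Spike counts per trial, unit and time bin, with bins defined relative
#' to the alignment anchor.
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param breaks bin edges (s from the anchor), length >= 2.
#' @return array trials x units x bins of rates (Hz).
#' @export
binnedRates <- function(ds, breaks) {
  stopifnot(is(ds, "OdorExperiment"), length(breaks) >= 2L)
  if (anyNA(ds@trials$t0_s)) stop("dataset not aligned; run alignTrials()")
  nTr <- nrow(ds@trials); nU <- length(ds@unitIds)
  nB <- length(breaks) - 1L
  tIdx <- match(ds@spikes$trial_id, ds@trials$trial_id)
  rel <- ds@spikes$spike_time_s - ds@trials$t0_s[tIdx]
  b <- findInterval(rel, breaks, left.open = FALSE)
  keep <- b >= 1L & b <= nB & rel < breaks[length(breaks)]
  uIdx <- match(ds@spikes$unit_id[keep], ds@unitIds)
  idx <- tIdx[keep] + nTr * (uIdx - 1L) + nTr * nU * (b[keep] - 1L)
  cnt <- tabulate(idx, nbins = nTr * nU * nB)
  arr <- array(cnt, c(nTr, nU, nB))
  sweep(arr, 3, diff(breaks), "/")
}

## per-stimulus feature pools: list over stimuli of reps x (units*bins)
## matrices; features ordered unit-major (unit 1 bins, unit 2 bins, ...)
featurePools <- function(ds, window, binWidthS = NULL) {
  if (is.null(binWidthS)) {
    breaks <- window
  } else {
    breaks <- seq(window[1], window[2], by = binWidthS)
    if (abs(breaks[length(breaks)] - window[2]) > 1e-9)
      breaks <- c(breaks, window[2])
  }
  arr <- binnedRates(ds, breaks)
  nU <- dim(arr)[2]; nB <- dim(arr)[3]
  stim <- stimulusSet(ds@nOdorants)
  flat <- matrix(arr, nrow = dim(arr)[1])  # trials x (units*bins), bin-major
  ## reorder columns to unit-major blocks
  ord <- as.vector(t(matrix(seq_len(nU * nB), nU, nB)))
  flat <- flat[, ord, drop = FALSE]
  pools <- lapply(stim, function(s)
    flat[ds@trials$stimulus_bitmask == s, , drop = FALSE])
  list(pools = pools, stimuli = stim, nUnits = nU, nBins = nB)
}

#' Ridge-penalized logistic regression (Newton/IRLS)
#'
#' Minimizes the logistic loss \eqn{\sum \log(1 + e^{-y f(x)})} plus
#' \eqn{\lambda/2 \|w\|^2} (intercept unpenalized) for a linear decision
#' function \eqn{f(x) = w^T x + b}, by damped Newton iterations.
#'
#' @param X numeric feature matrix (rows = trials).
#' @param y labels in \{-1, +1\} (or logical, coerced).
#' @param lambda ridge penalty (>= 0; a tiny ridge keeps separable
#'   problems bounded).
#' @param maxIter,tol Newton iteration controls.
#' @return list: \code{w} (weights), \code{b} (intercept),
#'   \code{converged}, \code{loss}.
#' @export
ridgeLogistic <- function(X, y, lambda = 1 / nrow(X), maxIter = 50L,
                          tol = 1e-8) {
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  stopifnot(all(y %in% c(-1, 1)), nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(X, 1)
  beta <- numeric(p + 1L)
  pen <- c(rep(lambda, p), 0)
  lossOf <- function(eta) {
    ## log(1 + exp(-y eta)), overflow-safe
    z <- -y * eta
    sum(ifelse(z > 30, z, log1p(exp(pmin(z, 30))))) +
      sum(pen * beta^2) / 2
  }
  eta <- as.vector(Xa %*% beta)
  curLoss <- lossOf(eta)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    mu <- stats::plogis(eta)            # P(y = +1 | x)
    y01 <- (y + 1) / 2
    grad <- crossprod(Xa, mu - y01) + pen * beta
    if (max(abs(grad)) < tol * n) { converged <- TRUE; break }
    wts <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xa, Xa * wts)
    diag(H) <- diag(H) + pen + 1e-12
    step <- solve(H, grad)
    ## backtracking to guarantee descent
    alpha <- 1
    repeat {
      betaNew <- beta - alpha * as.vector(step)
      etaNew <- as.vector(Xa %*% betaNew)
      penNew <- sum(pen * betaNew^2) / 2
      z <- -y * etaNew
      lossNew <- sum(ifelse(z > 30, z, log1p(exp(pmin(z, 30))))) + penNew
      if (lossNew <= curLoss + 1e-12 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    if (abs(curLoss - lossNew) < tol * (abs(curLoss) + 1)) {
      beta <- betaNew; eta <- etaNew; curLoss <- lossNew
      converged <- TRUE; break
    }
    beta <- betaNew; eta <- etaNew; curLoss <- lossNew
  }
  list(w = beta[seq_len(p)], b = beta[p + 1L], converged = converged,
       loss = curLoss)
}

#' Assemble training pseudo-trials for one stimulus
#'
#' Each pseudo-trial draws one real trial per unit independently, with
#' replacement, from the unit's trial pool for the stimulus (held-out
#' test trials excluded).
#'
#' @param pool reps x (units*bins) feature matrix for the stimulus.
#' @param n number of pseudo-trials.
#' @param exclude integer vector, per unit, of the held-out trial index
#'   (NA = none); length = number of units.
#' @param nBins features per unit.
#' @return n x (units*bins) matrix.
#' @export
assemblePseudotrials <- function(pool, n, exclude = NULL, nBins = 1L) {
  reps <- nrow(pool)
  nU <- ncol(pool) / nBins
  out <- matrix(0, n, ncol(pool))
  for (u in seq_len(nU)) {
    avail <- seq_len(reps)
    if (!is.null(exclude) && !is.na(exclude[u]))
      avail <- avail[-exclude[u]]
    if (length(avail) == 0L)
      stop("unit ", u, " has no remaining trials for this stimulus")
    idx <- avail[sample.int(length(avail), n, replace = TRUE)]
    cols <- (u - 1L) * nBins + seq_len(nBins)
    out[, cols] <- pool[idx, cols, drop = FALSE]
  }
  out
}

#' Train a linear detector for one target odorant
#'
#' @param X training matrix (pseudo-trials x features).
#' @param masks stimulus bitmask per training row.
#' @param targetOdorant 1-based odorant index; the label is presence of
#'   the target in the stimulus.
#' @param lambda ridge penalty (default \code{1/nrow(X)}).
#' @return a [ridgeLogistic()] fit with element \code{target} added.
#' @export
trainDetector <- function(X, masks, targetOdorant, lambda = 1 / nrow(X)) {
  y <- bitwAnd(as.integer(masks), bitwShiftL(1L, targetOdorant - 1L)) != 0L
  if (!any(y) || all(y)) stop("training set must contain both classes")
  fit <- ridgeLogistic(X, y, lambda = lambda)
  fit$target <- targetOdorant
  fit
}

#' Cross-validated pseudo-population detection of target odorants
#'
#' The full protocol: per iteration, one held-out response per unit per
#' stimulus forms 15 test population vectors; training pseudo-trials are
#' assembled from the remaining trials; one detector per odorant is
#' trained and scored on the 15 test vectors. Accuracy is the fraction of
#' correct presence/absence calls, averaged over iterations.
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param protocol a [classifierProtocol()].
#' @param unitSubset optional unit ids to restrict the population.
#' @param permuteLabels permute training labels each iteration (empirical
#'   chance level; class priors are 8/7 so chance is not 0.5).
#' @return list of class \code{"ClassifierResult"}: \code{accuracy}
#'   (grand mean), \code{perOdorant}, \code{bySize} (accuracy per mixture
#'   size), \code{iterations} (nIterations x nOdorants matrix),
#'   \code{meanAbsWeight} (per unit, averaged over odorants and
#'   iterations), \code{protocol}.
#' @export
crossValidate <- function(ds, protocol = classifierProtocol(),
                          unitSubset = NULL, permuteLabels = FALSE) {
  fp <- featurePools(ds, protocol$window, protocol$binWidthS)
  pools <- fp$pools; stim <- fp$stimuli
  nU <- fp$nUnits; nB <- fp$nBins
  if (!is.null(unitSubset)) {
    uKeep <- match(unitSubset, ds@unitIds)
    stopifnot(!anyNA(uKeep))
    cols <- as.vector(vapply(uKeep, function(u)
      (u - 1L) * nB + seq_len(nB), integer(nB)))
    pools <- lapply(pools, function(m) m[, cols, drop = FALSE])
    nU <- length(uKeep)
  }
  nS <- length(stim)
  nOd <- ds@nOdorants
  nTrain <- protocol$nTrainPerStimulus
  lambda <- if (is.null(protocol$lambda)) 1 / (nTrain * nS)
            else protocol$lambda
  seeds <- childSeeds(protocol$seed, protocol$nIterations)
  accIter <- matrix(NA_real_, protocol$nIterations, nOd)
  perStimCorrect <- matrix(0, nS, nOd)
  sumAbsW <- numeric(nU)
  trainMasks <- rep(stim, each = nTrain)
  for (it in seq_len(protocol$nIterations)) {
    set.seed(seeds[it])
    held <- matrix(NA_integer_, nU, nS)
    Xtest <- matrix(0, nS, nU * nB)
    Xtrain <- matrix(0, nTrain * nS, nU * nB)
    for (si in seq_len(nS)) {
      reps <- nrow(pools[[si]])
      held[, si] <- sample.int(reps, nU, replace = TRUE)
      for (u in seq_len(nU)) {
        cols <- (u - 1L) * nB + seq_len(nB)
        Xtest[si, cols] <- pools[[si]][held[u, si], cols]
      }
      rows <- (si - 1L) * nTrain + seq_len(nTrain)
      Xtrain[rows, ] <- assemblePseudotrials(pools[[si]], nTrain,
                                             exclude = held[, si],
                                             nBins = nB)
    }
    masksIt <- trainMasks
    if (permuteLabels) masksIt <- sample(trainMasks)
    for (o in seq_len(nOd)) {
      fit <- trainDetector(Xtrain, masksIt, o, lambda = lambda)
      predPresent <- as.vector(Xtest %*% fit$w + fit$b) > 0
      truth <- bitwAnd(stim, bitwShiftL(1L, o - 1L)) != 0L
      correct <- predPresent == truth
      accIter[it, o] <- mean(correct)
      perStimCorrect[, o] <- perStimCorrect[, o] + correct
      if (nB == 1L) sumAbsW <- sumAbsW + abs(fit$w)
      else sumAbsW <- sumAbsW +
        vapply(seq_len(nU), function(u)
          sum(abs(fit$w[(u - 1L) * nB + seq_len(nB)])), numeric(1))
    }
  }
  sz <- mixtureSize(stim)
  bySize <- vapply(sort(unique(sz)), function(s)
    mean(perStimCorrect[sz == s, ] / protocol$nIterations), numeric(1))
  structure(list(
    accuracy = mean(accIter),
    perOdorant = colMeans(accIter),
    bySize = data.frame(size = sort(unique(sz)), accuracy = bySize),
    iterations = accIter,
    meanAbsWeight = sumAbsW / (protocol$nIterations * nOd),
    protocol = protocol), class = "ClassifierResult")
}

#' @export
print.ClassifierResult <- function(x, ...) {
  cat(sprintf("ClassifierResult: mean accuracy %.1f%% over %d iterations\n",
              100 * x$accuracy, x$protocol$nIterations))
  cat("  per odorant:",
      paste(sprintf("%.1f%%", 100 * x$perOdorant), collapse = ", "), "\n")
  invisible(x)
}

#' Accuracy as a function of population size by weight pruning
#'
#' Per iteration and target odorant: train on the full population, then
#' repeatedly remove the unit with the smallest absolute weight, retrain
#' on the same training pseudo-trials (restricted to the remaining
#' units), and re-score the held-out vectors, down to a single unit.
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param protocol a [classifierProtocol()]; pruning retrains
#'   \code{nUnits} models per odorant and iteration, so moderate
#'   iteration counts are advisable.
#' @return list: \code{curve} (data.frame \code{n_units},
#'   \code{odorant}, \code{accuracy}), \code{nNinetyPercent} (per
#'   odorant, the smallest population size reaching >= 90\% of the
#'   full-population accuracy).
#' @export
prunePopulation <- function(ds, protocol = classifierProtocol()) {
  fp <- featurePools(ds, protocol$window, protocol$binWidthS)
  pools <- fp$pools; stim <- fp$stimuli
  nU <- fp$nUnits; nB <- fp$nBins
  nS <- length(stim); nOd <- ds@nOdorants
  nTrain <- protocol$nTrainPerStimulus
  lambda <- if (is.null(protocol$lambda)) 1 / (nTrain * nS)
            else protocol$lambda
  seeds <- childSeeds(protocol$seed + 7L, protocol$nIterations)
  trainMasks <- rep(stim, each = nTrain)
  acc <- array(0, c(nU, nOd))          # summed over iterations
  for (it in seq_len(protocol$nIterations)) {
    set.seed(seeds[it])
    held <- matrix(NA_integer_, nU, nS)
    Xtest <- matrix(0, nS, nU * nB)
    Xtrain <- matrix(0, nTrain * nS, nU * nB)
    for (si in seq_len(nS)) {
      reps <- nrow(pools[[si]])
      held[, si] <- sample.int(reps, nU, replace = TRUE)
      for (u in seq_len(nU)) {
        cols <- (u - 1L) * nB + seq_len(nB)
        Xtest[si, cols] <- pools[[si]][held[u, si], cols]
      }
      rows <- (si - 1L) * nTrain + seq_len(nTrain)
      Xtrain[rows, ] <- assemblePseudotrials(pools[[si]], nTrain,
                                             exclude = held[, si],
                                             nBins = nB)
    }
    for (o in seq_len(nOd)) {
      truth <- bitwAnd(stim, bitwShiftL(1L, o - 1L)) != 0L
      units <- seq_len(nU)
      while (length(units) >= 1L) {
        cols <- as.vector(vapply(units, function(u)
          (u - 1L) * nB + seq_len(nB), integer(nB)))
        fit <- trainDetector(Xtrain[, cols, drop = FALSE], trainMasks, o,
                             lambda = lambda)
        pred <- as.vector(Xtest[, cols, drop = FALSE] %*% fit$w + fit$b) > 0
        acc[length(units), o] <- acc[length(units), o] + mean(pred == truth)
        if (length(units) == 1L) break
        wUnit <- vapply(seq_along(units), function(k)
          sum(abs(fit$w[(k - 1L) * nB + seq_len(nB)])), numeric(1))
        units <- units[-which.min(wUnit)]
      }
    }
  }
  acc <- acc / protocol$nIterations
  curve <- data.frame(
    n_units = rep(seq_len(nU), nOd),
    odorant = rep(seq_len(nOd), each = nU),
    accuracy = as.vector(acc))
  n90 <- vapply(seq_len(nOd), function(o) {
    full <- acc[nU, o]
    ok <- which(acc[, o] >= 0.9 * full)
    min(ok)
  }, numeric(1))
  list(curve = curve, nNinetyPercent = n90)
}

#' Detection accuracy vs integration-window duration
#'
#' Reruns the cross-validation with rate features integrated over
#' \code{[0, d)} seconds from the alignment anchor for each duration d.
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param protocol base [classifierProtocol()].
#' @param durations window durations (s).
#' @return data.frame: \code{duration_s}, \code{accuracy}, plus one
#'   column per odorant.
#' @export
integrationTimeSweep <- function(ds, protocol = classifierProtocol(),
                                 durations = c(0.1, 0.2, 0.5, 1, 2, 3)) {
  rows <- lapply(durations, function(d) {
    p <- protocol
    p$window <- c(0, d)
    res <- crossValidate(ds, p)
    cbind(data.frame(duration_s = d, accuracy = res$accuracy),
          as.data.frame(as.list(stats::setNames(
            res$perOdorant, paste0("odorant", seq_along(res$perOdorant))))))
  })
  do.call(rbind, rows)
}

#' Detection accuracy vs temporal resolution
#'
#' Features are per-unit spike rates in time bins concatenated across the
#' population (units x bins features per pseudo-trial); the training set
#' is enlarged (10,000 pseudo-trials per stimulus in the reference
#' protocol). A single bin spanning the whole window reproduces the rate
#' code.
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param protocol base [classifierProtocol()]; its
#'   \code{nTrainPerStimulus} is used as-is, so pass the enlarged value.
#' @param binWidths bin widths to sweep (s).
#' @param responseDur total response duration (s).
#' @return data.frame: \code{bin_width_s}, \code{n_features},
#'   \code{accuracy}, plus one column per odorant.
#' @export
temporalResolutionSweep <- function(ds,
                                    protocol = classifierProtocol(
                                      nTrainPerStimulus = 10000L),
                                    binWidths = c(3, 1, 0.5, 0.25, 0.1),
                                    responseDur = 3) {
  rows <- lapply(binWidths, function(bw) {
    p <- protocol
    p$window <- c(0, responseDur)
    p$binWidthS <- if (bw >= responseDur) NULL else bw
    nFeat <- length(ds@unitIds) *
      max(1L, ceiling(responseDur / bw - 1e-9))
    if (nFeat > p$nTrainPerStimulus * length(stimulusSet(ds@nOdorants)))
      warning("feature count (", nFeat, ") exceeds training rows")
    res <- crossValidate(ds, p)
    cbind(data.frame(bin_width_s = bw, n_features = nFeat,
                     accuracy = res$accuracy),
          as.data.frame(as.list(stats::setNames(
            res$perOdorant, paste0("odorant", seq_along(res$perOdorant))))))
  })
  do.call(rbind, rows)
}
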