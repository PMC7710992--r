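#' Area under the ROC curve for two score samples
#'
#' Empirical auROC with firing rate as the score: the probability that a
#' randomly chosen positive-class trial has a higher score than a
#' negative-class one, with ties counting 1/2 (the Mann-Whitney
#' convention); equal to U / (n1 n2).
#'
#' @param pos scores of the positive class (target present).
#' @param neg scores of the negative class.
#' @return auROC in \eqn{[0, 1]}.
#' @export
aurocScore <- function(pos, neg) {
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) stop("both classes must be nonempty")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Detectability of a target odorant from one unit's trial rates
#'
#' auROC for discriminating trials whose stimulus contains the target
#' odorant from trials whose stimulus does not, using the firing rate in
#' a window from the alignment anchor as the score.
#'
#' @param rates per-trial firing rates (Hz).
#' @param bitmasks per-trial stimulus bitmasks.
#' @param targetOdorant 1-based odorant index.
#' @return auROC in \eqn{[0, 1]}.
#' @export
rocDetect <- function(rates, bitmasks, targetOdorant) {
  stopifnot(length(rates) == length(bitmasks))
  pos <- bitwAnd(as.integer(bitmasks),
                 bitwShiftL(1L, targetOdorant - 1L)) != 0L
  if (!any(pos) || all(pos))
    stop("both target-present and target-absent trials are required")
  aurocScore(rates[pos], rates[!pos])
}

#' auROC grid over all units and target odorants
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param window rate window \code{[lo, hi)} from the anchor (s).
#' @return data.frame with columns \code{unit_id}, \code{odorant},
#'   \code{auroc}.
#' @export
rocTable <- function(ds, window = c(0, 3)) {
  rates <- trialRates(ds, window)
  masks <- ds@trials$stimulus_bitmask
  grid <- expand.grid(unit = seq_along(ds@unitIds),
                      odorant = seq_len(ds@nOdorants))
  data.frame(unit_id = ds@unitIds[grid$unit], odorant = grid$odorant,
             auroc = mapply(function(u, o)
               rocDetect(rates[, u], masks, o), grid$unit, grid$odorant))
}

#' Best detected odorant per neuron
#'
#' @param roc output of [rocTable()].
#' @return data.frame per unit: the best auROC across odorants and which
#'   odorant achieved it.
#' @export
bestPerNeuron <- function(roc) {
  do.call(rbind, lapply(split(roc, roc$unit_id), function(d) {
    i <- which.max(d$auroc)
    data.frame(unit_id = d$unit_id[1], bestOdorant = d$odorant[i],
               auroc = d$auroc[i])
  }))
}

#' Best detecting neuron per odorant
#'
#' @param roc output of [rocTable()].
#' @return data.frame per odorant: the best auROC across units and which
#'   unit achieved it.
#' @export
bestPerOdorant <- function(roc) {
  do.call(rbind, lapply(split(roc, roc$odorant), function(d) {
    i <- which.max(d$auroc)
    data.frame(odorant = d$odorant[1], bestUnit = d$unit_id[i],
               auroc = d$auroc[i])
  }))
}

#' Shuffled-label control distribution for the auROC grid
#'
#' For each unit x odorant the stimulus labels are permuted once
#' (seeded) and the auROC recomputed, giving a pooled null distribution
#' (e.g. 224 values for 56 units x 4 odorants). A unit/odorant pair is
#' above control iff its observed auROC exceeds every value in the pooled
#' shuffled distribution.
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param window rate window (s from the anchor).
#' @param seed RNG seed for the permutations.
#' @return list: \code{roc} (the [rocTable()] with added columns
#'   \code{shuffled} and \code{above_control}), \code{shuffledValues}
#'   (the pooled distribution).
#' @export
shuffledControl <- function(ds, window = c(0, 3), seed = 1L) {
  rates <- trialRates(ds, window)
  masks <- ds@trials$stimulus_bitmask
  roc <- rocTable(ds, window)
  set.seed(as.integer(seed))
  roc$shuffled <- NA_real_
  for (k in seq_len(nrow(roc))) {
    u <- match(roc$unit_id[k], ds@unitIds)
    roc$shuffled[k] <- rocDetect(rates[, u], sample(masks), roc$odorant[k])
  }
  ceiling_ <- max(roc$shuffled)
  roc$above_control <- roc$auroc > ceiling_
  list(roc = roc, shuffledValues = roc$shuffled)
}

#' auROC as a function of integration-window duration
#'
#' Growing windows from the alignment anchor: rates are integrated over
#' \code{[0, d)} for each duration d and the auROC recomputed. Windows
#' with no spikes in any trial are uninformative and return 0.5 by the
#' tie convention.
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param unitId unit to analyze.
#' @param targetOdorant 1-based odorant index.
#' @param durations window durations (s).
#' @return data.frame with columns \code{duration_s}, \code{auroc}.
#' @export
integrationWindowSweep <- function(ds, unitId, targetOdorant,
                                   durations = c(0.1, 0.2, 0.4, 0.8,
                                                 1.6, 3)) {
  u <- match(unitId, ds@unitIds)
  if (is.na(u)) stop("unknown unit ", unitId)
  masks <- ds@trials$stimulus_bitmask
  auc <- vapply(durations, function(d) {
    r <- trialRates(ds, c(0, d))[, u]
    rocDetect(r, masks, targetOdorant)
  }, numeric(1))
  data.frame(duration_s = durations, auroc = auc)
}

#' auROC time course with a sliding 200 ms integration window
#'
#' The detection window \code{[t, t + width)} slides along the response in
#' \code{step} increments; the auROC is computed per window. Also returns
#' the Pearson correlation between the auROC time course and the unit's
#' PSTH in response to the target odorant alone (averaged over the same
#' windows), which measures how tightly detectability tracks the evoked
#' response.
#'
#' @param ds an aligned [OdorExperiment-class].
#' @param unitId unit to analyze.
#' @param targetOdorant 1-based odorant index.
#' @param width window width (s), default 200 ms.
#' @param step window step (s), default 50 ms.
#' @param range scanned extent \code{[lo, hi)} from the anchor (s).
#' @return list: \code{sweep} (data.frame \code{t_start}, \code{auroc},
#'   \code{psth}), \code{psthCorrelation}.
#' @export
slidingWindowSweep <- function(ds, unitId, targetOdorant, width = 0.2,
                               step = 0.05, range = c(0, 3)) {
  u <- match(unitId, ds@unitIds)
  if (is.na(u)) stop("unknown unit ", unitId)
  masks <- ds@trials$stimulus_bitmask
  starts <- seq(range[1], range[2] - width, by = step)
  auc <- vapply(starts, function(t1) {
    r <- trialRates(ds, c(t1, t1 + width))[, u]
    if (all(r == 0)) return(0.5)
    rocDetect(r, masks, targetOdorant)
  }, numeric(1))
  ## PSTH of the target odorant presented alone, averaged per window
  spk <- splitSpikes(ds)
  tgt <- which(masks == bitwShiftL(1L, targetOdorant - 1L))
  aligned <- lapply(tgt, function(t2) spk[[t2]][[u]] - ds@trials$t0_s[t2])
  p <- buildPsth(aligned, window = range, binS = 0.001)
  psthW <- vapply(starts, function(t1)
    mean(p$rate[p$time >= t1 & p$time < t1 + width]), numeric(1))
  ok <- stats::sd(auc) > 0 && stats::sd(psthW) > 0
  list(sweep = data.frame(t_start = starts, auroc = auc, psth = psthW),
       psthCorrelation = if (ok) stats::cor(auc, psthW) else NA_real_)
}
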