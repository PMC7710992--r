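#' Saturating logistic normalization model
#'
#' The mixture response predicted from the linear sum LP of a unit's
#' single-component responses:
#' \deqn{R = R_{max}\left(\frac{2}{1 + e^{-s \cdot LP}} - 1\right)
#'       = R_{max} \tanh(s \cdot LP / 2),}
#' an odd, monotone, saturating map with initial slope
#' \eqn{R_{max} s / 2} at LP = 0. The tanh form is algebraically identical
#' and immune to exponent overflow.
#'
#' @param rmax saturating response (Hz), >= 0.
#' @param s initial-slope parameter (1/Hz), >= 0.
#' @param lp linear prediction(s) (Hz).
#' @return predicted response(s), same length as \code{lp}.
#' @examples
#' evalNormModel(10, 0.2, 5) # 10 * (2 / (1 + exp(-1)) - 1)
#' @export
evalNormModel <- function(rmax, s, lp) {
  rmax * tanh(s * lp / 2)
}

#' Fit the normalization model to a unit's mixture responses
#'
#' Least-squares fit of (Rmax, s) to observed responses as a function of
#' the linear prediction, by bounded quasi-Newton optimization from
#' multiple starts (best sum of squared errors wins; ties broken toward
#' smaller s). Bounds: \code{Rmax} in \code{[0, 3 max|R|]}, \code{s} in
#' \code{[0, 10 / max|LP|]}; starts at \code{Rmax = max(R)} and
#' \code{s in {0.1, 1, 10} / max|LP|}.
#'
#' @param lp numeric linear predictions (Hz).
#' @param robs numeric observed responses (Hz); same length, >= 3 pairs.
#' The nonlinear least-squares solver is Levenberg-Marquardt
#' (\pkg{minpack.lm}).
#'
#' @return list of class \code{"NormalizationFit"}: \code{rmax}, \code{s},
#'   \code{r2} (coefficient of determination about the mean observed
#'   response; NA when the observations have zero variance),
#'   \code{slopeLinfit} (slope of a straight-line fit of observed vs LP),
#'   \code{nPoints}, \code{converged}, \code{sse}.
#' @export
fitNormModel <- function(lp, robs) {
  stopifnot(length(lp) == length(robs))
  ok <- is.finite(lp) & is.finite(robs)
  lp <- lp[ok]; robs <- robs[ok]
  if (length(lp) < 3L) stop("need at least 3 (LP, R) pairs")
  maxAbsR <- max(abs(robs))
  maxAbsLP <- max(abs(lp))
  slopeLin <- if (stats::sd(lp) > 0)
    unname(stats::coef(stats::lm(robs ~ lp))[2]) else NA_real_
  if (maxAbsR == 0 || maxAbsLP == 0) {
    ## degenerate: flat observations or no drive; any (rmax, s->0) fits
    return(structure(list(rmax = 0, s = 0, r2 = NA_real_,
                          slopeLinfit = slopeLin,
                          nPoints = length(lp), converged = TRUE, sse = 0),
                     class = "NormalizationFit"))
  }
  upper <- c(3 * maxAbsR, 10 / maxAbsLP)
  starts <- lapply(c(0.1, 1, 10) / maxAbsLP, function(s0)
    c(min(max(max(robs), 1e-6), upper[1]), s0))
  best <- NULL
  dat <- data.frame(lp = lp, robs = robs)
  for (st in starts) {
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(
        robs ~ evalNormModel(rmax, s, lp), data = dat,
        start = list(rmax = st[1], s = st[2]),
        lower = c(0, 0), upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-14, ptol = 1e-14))
      list(par = unname(stats::coef(m)), value = stats::deviance(m))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[2] < best$par[2]))
      best <- fit
  }
  if (is.null(best)) {
    return(structure(list(rmax = NA_real_, s = NA_real_, r2 = -Inf,
                          slopeLinfit = slopeLin,
                          nPoints = length(lp), converged = FALSE,
                          sse = NA_real_),
                     class = "NormalizationFit"))
  }
  ssTot <- sum((robs - mean(robs))^2)
  r2 <- if (ssTot > 0) 1 - best$value / ssTot else NA_real_
  structure(list(rmax = best$par[1], s = best$par[2], r2 = r2,
                 slopeLinfit = slopeLin, nPoints = length(lp),
                 converged = TRUE, sse = best$value),
            class = "NormalizationFit")
}

#' @export
print.NormalizationFit <- function(x, ...) {
  cat(sprintf("Normalization fit: Rmax = %.3g Hz, s = %.3g /Hz, R2 = %s (n = %d)\n",
              x$rmax, x$s, format(x$r2, digits = 3), x$nPoints))
  invisible(x)
}

#' Fit the normalization model for every unit of a response table
#'
#' The fit set is the multi-component mixtures only: single-odorant
#' responses define the linear prediction but are not fit targets (they
#' sit on the identity by construction).
#'
#' @param rt a [ResponseTable-class].
#' @return data.frame, one row per fit-eligible unit, with columns
#'   \code{unit_id}, \code{rmax}, \code{s}, \code{r2},
#'   \code{slope_linfit}, \code{n_points}, \code{converged}.
#' @export
fitNormModels <- function(rt) {
  lsc <- linearSumComparison(rt)
  if (is.null(lsc) || nrow(lsc) == 0L) stop("no fit-eligible units")
  out <- lapply(split(lsc, lsc$unit_id), function(d) {
    f <- fitNormModel(d$LP, d$R_observed)
    data.frame(unit_id = d$unit_id[1], rmax = f$rmax, s = f$s, r2 = f$r2,
               slope_linfit = f$slopeLinfit, n_points = f$nPoints,
               converged = f$converged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$unit_id), ]
}

## circular-linear correlation of a linear variable x with an angle phi
circLinCor <- function(x, phi) {
  rxc <- stats::cor(x, cos(phi)); rxs <- stats::cor(x, sin(phi))
  rcs <- stats::cor(cos(phi), sin(phi))
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  r <- sqrt(max(r2, 0))
  p <- stats::pchisq(length(x) * r^2, df = 2, lower.tail = FALSE)
  c(r = r, p = p)
}

#' Relate normalization fit quality to unit properties
#'
#' Pairs each unit's coefficient of determination with its unit-level
#' properties (baseline rate, optional spike width, preferred respiratory
#' phase, and the observed-vs-LP straight-line slope) and reports the
#' corresponding correlations: Pearson for linear properties, a
#' circular-linear correlation for the preferred phase.
#'
#' @param fits output of [fitNormModels()].
#' @param properties data.frame with \code{unit_id} and any of
#'   \code{baseline_hz}, \code{spike_width_ms}, \code{preferred_phase}.
#' @return data.frame with columns \code{property}, \code{r}, \code{p},
#'   \code{n}. Properties missing from the input, or with undefined
#'   correlations (constant vectors), are skipped or reported as NA.
#' @export
fitQualityCorrelates <- function(fits, properties = NULL) {
  d <- fits[is.finite(fits$r2), ]
  if (!is.null(properties)) d <- merge(d, properties, by = "unit_id")
  rows <- list()
  addPearson <- function(name, x) {
    ok <- is.finite(x) & is.finite(d$r2)
    if (sum(ok) < 3L) return()
    if (stats::sd(x[ok]) == 0 || stats::sd(d$r2[ok]) == 0) {
      rows[[length(rows) + 1L]] <<- data.frame(
        property = name, r = NA_real_, p = NA_real_, n = sum(ok))
      return()
    }
    ct <- stats::cor.test(x[ok], d$r2[ok])
    rows[[length(rows) + 1L]] <<- data.frame(
      property = name, r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
  addPearson("slope_linfit", d$slope_linfit)
  if ("baseline_hz" %in% names(d)) addPearson("baseline_hz", d$baseline_hz)
  if ("spike_width_ms" %in% names(d))
    addPearson("spike_width_ms", d$spike_width_ms)
  if ("preferred_phase" %in% names(d)) {
    ok <- is.finite(d$preferred_phase) & is.finite(d$r2)
    if (sum(ok) >= 4L && stats::sd(d$r2[ok]) > 0) {
      cl <- circLinCor(d$r2[ok], d$preferred_phase[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        property = "preferred_phase", r = cl["r"], p = cl["p"], n = sum(ok))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
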