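test_that("ridge logistic regression agrees with glm on a well-posed problem", {
  set.seed(90)
  n <- 400
  X <- cbind(rnorm(n), rnorm(n))
  y <- ifelse(X[, 1] - 0.5 * X[, 2] + rnorm(n) > 0, 1, -1)
  fit <- ridgeLogistic(X, y, lambda = 1e-8)
  ref <- stats::glm.fit(cbind(X, 1), (y + 1) / 2,
                        family = stats::binomial())
  expect_equal(c(fit$w, fit$b), unname(ref$coefficients), tolerance = 1e-4)
  expect_true(fit$converged)
  ## separable data stay bounded thanks to the ridge
  ys <- ifelse(X[, 1] > 0, 1, -1)
  fs <- ridgeLogistic(X, ys, lambda = 0.01)
  expect_true(all(is.finite(fs$w)))
})

test_that("pseudo-trial assembly draws per unit with replacement and excludes held trials", {
  ## pool rows tagged by their index so draws are traceable
  pool <- cbind(1:7, 101:107)   # 7 reps, 2 units, 1 bin each
  set.seed(3)
  X <- assemblePseudotrials(pool, 500, exclude = c(3L, 5L), nBins = 1L)
  expect_equal(dim(X), c(500L, 2L))
  expect_false(any(X[, 1] == 3))       # held-out trial never drawn
  expect_false(any(X[, 2] == 105))
  expect_setequal(unique(X[, 1]), c(1, 2, 4, 5, 6, 7))
  ## units are sampled independently: columns are not locked together
  expect_gt(length(unique(paste(X[, 1], X[, 2]))), 7)
  ## single remaining trial: all pseudo-trials identical
  one <- matrix(c(2, 9), 1, 2)
  Xo <- assemblePseudotrials(one, 10)
  expect_true(all(Xo[, 1] == 2 & Xo[, 2] == 9))
  expect_error(assemblePseudotrials(one, 5, exclude = c(1L, NA)),
               "no remaining trials")
})

test_that("independent trial pools give uncorrelated pseudo-trial features", {
  set.seed(91)
  pool <- cbind(rnorm(30), rnorm(30))
  X <- assemblePseudotrials(pool, 4000)
  expect_lt(abs(stats::cor(X[, 1], X[, 2])), 0.06)
})

test_that("detectors separate noise-free classes and count features correctly", {
  stim <- stimulusSet(4)
  ## deterministic feature: unit u = 1 iff odorant u present
  X <- t(vapply(stim, function(m) {
    v <- numeric(4); v[stimulusComponents(m)] <- 1; v
  }, numeric(4)))
  X <- X[rep(1:15, each = 20), ]
  masks <- rep(stim, each = 20)
  for (o in 1:4) {
    fit <- trainDetector(X, masks, o)
    pred <- as.vector(X %*% fit$w + fit$b) > 0
    truth <- bitwAnd(masks, bitwShiftL(1L, o - 1L)) != 0L
    expect_equal(mean(pred == truth), 1)
  }
  expect_error(trainDetector(X, rep(15L, nrow(X)), 1L), "both classes")
})

test_that("cross-validation is perfect on deterministic features and seed-stable", {
  toy <- alignTrials(makeToyDataset(
    nUnits = 4, nOdorants = 4, reps = 5,
    rateFun = function(u, m) 2 + 8 * (bitwAnd(m, bitwShiftL(1L, u - 1L)) != 0L)))
  pr <- classifierProtocol(nTrainPerStimulus = 60, nIterations = 4, seed = 9)
  res <- crossValidate(toy, pr)
  expect_equal(res$accuracy, 1)
  expect_equal(unname(res$perOdorant), rep(1, 4))
  ## identical protocol => identical result (derived per-iteration seeds)
  res2 <- crossValidate(toy, pr)
  expect_identical(res$iterations, res2$iterations)
})

test_that("uninformative populations sit in the binomial band around 8/15", {
  cfg <- generatorConfig(nUnits = 5, nTrialsPerStimulus = 8,
                         tuningSparsity = 0, seed = 55)
  ds <- alignTrials(simulatePopulation(cfg)$dataset)
  pr <- classifierProtocol(nTrainPerStimulus = 100, nIterations = 15,
                           seed = 2)
  res <- crossValidate(ds, pr)
  nDecisions <- 15 * pr$nIterations * 4
  band <- 4 * sqrt((8 / 15) * (7 / 15) / nDecisions)
  expect_lt(abs(res$accuracy - 8 / 15), band + 0.05)
  ## label permutation on informative data also falls to chance
  toy <- alignTrials(makeToyDataset(
    nUnits = 4, nOdorants = 4, reps = 5,
    rateFun = function(u, m) 2 + 8 * (bitwAnd(m, bitwShiftL(1L, u - 1L)) != 0L)))
  resP <- crossValidate(toy, classifierProtocol(nTrainPerStimulus = 60,
                                                nIterations = 10, seed = 4),
                        permuteLabels = TRUE)
  expect_lt(abs(resP$accuracy - 8 / 15), 0.12)
})

test_that("accuracy decreases for richer mixtures on high-SNR populations", {
  fx <- snrSim()
  res <- cachedFixture("snr_cv", function()
    crossValidate(fx$ds, classifierProtocol(nTrainPerStimulus = 200,
                                            nIterations = 10, seed = 12)))
  expect_gt(res$accuracy, 0.85)
  expect_equal(res$bySize$size, 1:4)
  expect_gte(res$bySize$accuracy[1], res$bySize$accuracy[4] - 0.05)
})

test_that("weight pruning keeps informative units and spans down to one unit", {
  ## unit 1 linearly separates presence of either odorant (rates chosen
  ## so each bit is threshold-separable); remaining units constant
  toy <- alignTrials(makeToyDataset(
    nUnits = 5, nOdorants = 2, reps = 6,
    rateFun = function(u, m) if (u == 1) c(1, 9, 5)[m] else 3,
    poisson = FALSE, seed = 8))
  pr <- classifierProtocol(nTrainPerStimulus = 50, nIterations = 3, seed = 6)
  out <- prunePopulation(toy, pr)
  expect_setequal(unique(out$curve$n_units), 1:5)
  acc1 <- out$curve$accuracy[out$curve$n_units == 1]
  expect_true(all(acc1 == 1))
  expect_true(all(out$nNinetyPercent >= 1))
  ## all-noise population: flat near chance (2 odorants -> 2/3 majority)
  noise <- alignTrials(makeToyDataset(
    nUnits = 3, nOdorants = 2, reps = 6,
    rateFun = function(u, m) 3, baselineHz = 1, poisson = TRUE, seed = 9))
  outN <- prunePopulation(noise, pr)
  expect_lt(max(abs(outN$curve$accuracy - 2 / 3)), 0.34)
})

test_that("integration-time sweep is consistent with the default protocol", {
  fx <- snrSim()
  pr <- classifierProtocol(nTrainPerStimulus = 100, nIterations = 3,
                           seed = 13)
  sw <- integrationTimeSweep(fx$ds, pr, durations = c(0.1, 3))
  full <- crossValidate(fx$ds, {
    p <- pr; p$window <- c(0, 3); p
  })
  expect_equal(sw$accuracy[sw$duration_s == 3], full$accuracy)
  ## windows shorter than every latency carry no information
  expect_lt(sw$accuracy[sw$duration_s == 0.1], 0.75)
  expect_gt(sw$accuracy[sw$duration_s == 3],
            sw$accuracy[sw$duration_s == 0.1])
})

test_that("temporal features multiply out and a single bin reproduces the rate code", {
  fx <- snrSim()
  pr <- classifierProtocol(nTrainPerStimulus = 100, nIterations = 3,
                           seed = 14)
  suppressWarnings(
    sw <- temporalResolutionSweep(fx$ds, pr, binWidths = c(3, 0.5),
                                  responseDur = 3))
  expect_equal(sw$n_features,
               c(nUnits(fx$ds), nUnits(fx$ds) * 6L))
  rate <- crossValidate(fx$ds, {
    p <- pr; p$window <- c(0, 3); p$binWidthS <- NULL; p
  })
  expect_equal(sw$accuracy[sw$bin_width_s == 3], rate$accuracy)
  ## binnedRates bookkeeping: counts split across bins sum to the total
  arr <- binnedRates(fx$ds, seq(0, 3, by = 0.5))
  tot <- trialRates(fx$ds, c(0, 3))
  expect_equal(apply(sweep(arr, 3, 0.5, "*"), c(1, 2), sum) / 3, tot)
})
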