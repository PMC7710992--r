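test_that("pseudo-population assembly pools, normalizes and excludes dead units", {
  fx <- snrSim()
  pt <- cachedFixture("snr_pt", function() buildPseudopopulation(fx$ds))
  d <- dim(pt@rates)
  expect_equal(d[2], 15L)
  expect_equal(d[3], 6000L)
  expect_true(all(pt@unitSd > 0))
  ## pooling the same dataset twice duplicates every unit's row
  pt2 <- buildPseudopopulation(list(fx$ds, fx$ds))
  expect_equal(nUnits(pt2), 2L * nUnits(pt))
  expect_equal(pt2@rates[1, , ], pt2@rates[nUnits(pt) + 1L, , ])
  ## a unit with no rate variation at all has zero SD and is excluded
  toy <- makeToyDataset(nUnits = 2, reps = 3,
                        rateFun = function(u, m) if (u == 1) 0 else 3 * m,
                        baselineHz = 0)
  toy <- alignTrials(toy)
  expect_warning(ptc <- buildPseudopopulation(toy), "zero response SD")
  expect_equal(nUnits(ptc), 1L)
})

test_that("PCA trajectories satisfy the spectral bookkeeping", {
  fx <- snrSim()
  pt <- cachedFixture("snr_pt", function() buildPseudopopulation(fx$ds))
  pc <- pcaTrajectories(pt, nComponents = 2)
  expect_true(all(pc$varExplained >= 0))
  expect_equal(sum(pc$varExplained), 1, tolerance = 1e-9)
  expect_equal(dim(pc$projections)[1], 15L)
  expect_error(pcaTrajectories(pt, nComponents = nUnits(pt) + 1L),
               "components")
  ## permuting unit order leaves projections identical up to sign
  perm <- rev(seq_len(nUnits(pt)))
  ptp <- pt
  ptp@rates <- pt@rates[perm, , , drop = FALSE]
  ptp@unitSd <- pt@unitSd[perm]
  ptp@unitIds <- pt@unitIds[perm]
  pcp <- pcaTrajectories(ptp, nComponents = 2)
  for (ci in 1:2) {
    a <- as.vector(pc$projections[, , ci])
    b <- as.vector(pcp$projections[, , ci])
    expect_equal(min(sum((a - b)^2), sum((a + b)^2)), 0, tolerance = 1e-6)
  }
  ## rank-1 tensor: PC1 explains everything
  r1 <- array(0, c(3, 3, 4))
  w <- c(1, -2, 0.5)
  for (si in 1:3) r1[, si, ] <- outer(w, si * c(1, 2, 3, 4))
  pt1 <- makeTensor(r1 + 1e-9 * array(seq_len(36), c(3, 3, 4)),
                    nOdorants = 2L, odorEpoch = c(-1, 1))
  pc1 <- pcaTrajectories(pt1, nComponents = 2, downsampleS = 0.5)
  expect_gt(pc1$varExplained[1], 0.999)
})

test_that("model predictions implement the four integration rules", {
  ## hand tensor: 2 units, 2 odorants (3 stimuli), constant-in-time rates
  rates <- array(0, c(2, 3, 4))
  rates[1, 1, ] <- 3; rates[1, 2, ] <- 5; rates[1, 3, ] <- 6
  rates[2, 1, ] <- 1; rates[2, 2, ] <- 2; rates[2, 3, ] <- 2.5
  pt <- makeTensor(rates, time = c(-0.5, 0, 0.5, 1), nOdorants = 2L)
  lin <- predictMixturePsths(pt, "linear")
  avg <- predictMixturePsths(pt, "mean")
  mx <- predictMixturePsths(pt, "max")
  expect_equal(lin$mixtures, 3L)
  expect_equal(unique(as.vector(lin$predicted[1, 1, ])), 8)
  expect_equal(unique(as.vector(avg$predicted[1, 1, ])), 4)
  expect_equal(unique(as.vector(mx$predicted[1, 1, ])), 5)
  expect_equal(unique(as.vector(lin$predicted[2, 1, ])), 3)
  expect_error(predictMixturePsths(pt, "ridge"), "arg")
  ## all-zero components predict zero under every model
  z <- rates; z[] <- 0; z[1, 3, ] <- 2   # response only to the mixture
  ptz <- makeTensor(z, time = c(-0.5, 0, 0.5, 1), nOdorants = 2L)
  for (m in c("linear", "mean", "max"))
    expect_true(all(predictMixturePsths(ptz, m)$predicted == 0))
})

test_that("linear >= max >= mean bin-wise for nonnegative components", {
  fx <- snrSim()
  pt <- cachedFixture("snr_pt", function() buildPseudopopulation(fx$ds))
  ptPos <- pt
  ptPos@rates <- pmax(pt@rates, 0)
  lin <- predictMixturePsths(ptPos, "linear")$predicted
  mx <- predictMixturePsths(ptPos, "max")$predicted
  avg <- predictMixturePsths(ptPos, "mean")$predicted
  expect_true(all(lin - mx >= -1e-12))
  expect_true(all(mx - avg >= -1e-12))
})

test_that("normalization prediction is exact on noiseless model data and beats linear", {
  ## single unit whose mixture PSTH is exactly the normalization model
  ## of the summed
  ## component PSTHs
  nb <- 40
  tgrid <- seq(-0.5, by = 0.05, length.out = nb)
  k1 <- pmax(0, sin(seq(0, pi, length.out = nb))) * 10
  k2 <- rev(k1) * 0.6
  rmax <- 12; s <- 0.15
  rates <- array(0, c(1, 3, nb))
  rates[1, 1, ] <- k1
  rates[1, 2, ] <- k2
  rates[1, 3, ] <- evalNormModel(rmax, s, k1 + k2)
  pt <- makeTensor(rates, time = tgrid, nOdorants = 2L,
                   odorEpoch = c(-0.5, 1.5))
  ## makeTensor computes a single-unit SD; ensure it is positive
  norm <- predictMixturePsths(pt, "normalization")
  lin <- predictMixturePsths(pt, "linear")
  errN <- modelErrors(norm, pt)$epochMean$meanError
  errL <- modelErrors(lin, pt)$epochMean$meanError
  expect_lt(errN, 1e-3)
  expect_gt(errL, errN)
  expect_equal(norm$fits$rmax, rmax, tolerance = 1e-3)
  expect_equal(norm$fits$s, s, tolerance = 1e-3)
})

test_that("normalization tends to the linear model in the initial-slope limit", {
  lp <- seq(-5, 5, by = 0.1)
  for (s in c(1e-3, 1e-4)) {
    rmax <- 2 / s  # keeps initial slope rmax*s/2 = 1
    expect_equal(evalNormModel(rmax, s, lp), lp, tolerance = 1e-5)
  }
})

test_that("population error metric is a distance with the expected invariances", {
  fx <- snrSim()
  pt <- cachedFixture("snr_pt", function() buildPseudopopulation(fx$ds))
  lin <- predictMixturePsths(pt, "linear")
  ## prediction == observation gives zero error at every bin
  self <- lin
  self$predicted <- pt@rates[, match(lin$mixtures, pt@stimuli), ,
                             drop = FALSE]
  errSelf <- modelErrors(self, pt)
  expect_true(all(unlist(errSelf$timecourse) < 1e-12))
  ## invariant under unit permutation
  perm <- sample(seq_len(nUnits(pt)))
  ptp <- pt
  ptp@rates <- pt@rates[perm, , , drop = FALSE]
  ptp@unitSd <- pt@unitSd[perm]
  ptp@unitIds <- pt@unitIds[perm]
  linp <- predictMixturePsths(ptp, "linear")
  expect_equal(modelErrors(linp, ptp)$epochMean$meanError,
               modelErrors(lin, pt)$epochMean$meanError, tolerance = 1e-9)
})

test_that("inter-stimulus distances cover all 105 pairs and bound model error", {
  fx <- snrSim()
  pt <- cachedFixture("snr_pt", function() buildPseudopopulation(fx$ds))
  d <- interStimulusDistances(pt)
  expect_equal(nrow(d), choose(15, 2))
  expect_true(all(d$distance >= 0))
  ## identical responses would have distance zero
  ptSame <- pt
  ptSame@rates[, 2, ] <- ptSame@rates[, 1, ]
  dS <- interStimulusDistances(ptSame)
  expect_equal(dS$distance[dS$stimA == ptSame@stimuli[1] &
                             dS$stimB == ptSame@stimuli[2]], 0)
  ## on matched synthetic data the normalization error is below the
  ## typical separation between stimuli
  norm <- predictMixturePsths(pt, "normalization")
  err <- modelErrors(norm, pt)
  cmp <- compareErrorsToDistances(
    err$epochMean[err$epochMean$model == "normalization", ], d)
  expect_lt(cmp$medianError, cmp$medianDistance)
  expect_true(is.finite(cmp$pRankSum) && is.finite(cmp$pPairedMin))
})
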