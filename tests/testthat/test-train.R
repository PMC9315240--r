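test_that("mseLoss is the mean of squared residuals", {
  expect_equal(mseLoss(c(1, 2), c(1, 2)), 0)
  expect_equal(mseLoss(c(0, 0), c(1, 3)), 5)
  set.seed(40)
  for (i in 1:20) {
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(mseLoss(a, b), sum((a - b)^2) / 7)
  }
  expect_error(mseLoss(numeric(0), numeric(0)), "empty")
  expect_error(mseLoss(1:3, 1:2), "mismatch")
})

test_that("communityLoss pulls members toward their centers", {
  Z <- matrix(c(0, 2, 0, 2), 2, 2, byrow = FALSE)  # rows (0,0) and (2,2)
  part <- list(centers = 1L, membership = c(1L, 1L))
  expect_equal(communityLoss(list(Z), list(part)), 4)  # mean((2,2)^2)

  # members equal to centers: zero loss
  Zeq <- matrix(1, 3, 2)
  pall <- list(centers = 2L, membership = rep(1L, 3))
  expect_equal(communityLoss(list(Zeq), list(pall)), 0)

  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    Z <- matrix(rnorm(n * 3), n, 3)
    S <- pairwiseDistance(Z)
    centers <- selectCenters(centerProbability(S), 0.5)
    part <- assignMembers(S, centers)
    expect_equal(communityLoss(list(Z), list(part)),
                 oracleCommunityLoss(Z, part$centers, part$membership),
                 tolerance = 1e-8)
  }
})

test_that("totalLoss combines the weighted components", {
  Z <- matrix(0, 2, 2)
  part <- list(centers = 1L, membership = c(1L, 1L))
  cfg <- trainConfig(eta1 = 0.5, eta2 = 0)
  out <- totalLoss(c(1, 2), c(0, 0), list(Z), list(part), cfg)
  expect_equal(out$total, 0.5 * 2.5)

  # reference weights: 0.5 * 1 + 0.01 * 100 = 1.5
  cfg2 <- trainConfig(eta1 = 0.5, eta2 = 0.01)
  mockComm <- list(centers = 1L, membership = c(1L, 1L))
  Zm <- matrix(c(0, 10, 0, 10), 2, 2)  # member-center diff (10,10), MSE 100
  out2 <- totalLoss(c(1, 3), c(0, 2), list(Zm), list(mockComm), cfg2)
  expect_equal(out2$mse, 1)
  expect_equal(out2$community, 100)
  expect_equal(out2$total, 0.5 * 1 + 0.01 * 100)

  out0 <- totalLoss(c(1), c(1), list(matrix(0, 1, 1)),
                    list(list(centers = 1L, membership = 1L)), cfg2)
  expect_equal(out0$total, 0)
})

test_that("the learning-rate schedule decays polynomially to zero", {
  cfg <- trainConfig(lr0 = 0.001, decayPower = 0.9, maxEpochs = 500L)
  expect_equal(lrAt(0, cfg), 0.001)
  expect_equal(lrAt(500, cfg), 0)
  expect_equal(lrAt(250, cfg), 0.001 * 0.5^0.9, tolerance = 1e-10)
  expect_equal(lrAt(250, cfg), 5.359e-4, tolerance = 1e-3)
  lrs <- vapply(0:500, lrAt, numeric(1), config = cfg)
  expect_true(all(diff(lrs) < 0))
  expect_error(lrAt(501, cfg), "epoch")
  expect_error(lrAt(-1, cfg), "epoch")
})

smallCohort <- function(seed = 50, n = 50L) {
  makeCohort(synthConfig(nSubjects = n, nNodes = 12L, nCommunities = 3L,
                         signalNodes = c(2L, 6L, 10L), featureDim = 4L,
                         seed = seed))
}

smallModelConfig <- function() {
  modelConfig(numPoolingModules = 2L, hiddenDim = 8L, mlpHidden = c(8L),
              seed = 1)
}

test_that("training reduces the training loss on a small synthetic set", {
  cohort <- smallCohort()
  tc <- trainConfig(seed = 0, maxEpochs = 100L, patience = 100L)
  m <- trainModel(cohort[1:40]@samples, cohort[41:50]@samples,
                  smallModelConfig(), tc)
  h <- m$history
  expect_lt(tail(h$train_total, 1), h$train_total[1])
  expect_true(all(is.finite(h$val_total)))
})

test_that("training histories are bit-identical across runs with one seed", {
  cohort <- smallCohort()
  tc <- trainConfig(seed = 7, maxEpochs = 15L)
  m1 <- trainModel(cohort[1:40]@samples, cohort[41:50]@samples,
                   smallModelConfig(), tc)
  m2 <- trainModel(cohort[1:40]@samples, cohort[41:50]@samples,
                   smallModelConfig(), tc)
  expect_identical(m1$history, m2$history)
  expect_identical(connectopool:::flattenParams(m1$params),
                   connectopool:::flattenParams(m2$params))
})

test_that("early stopping halts within patience and keeps the best epoch", {
  cohort <- smallCohort()
  tc <- trainConfig(seed = 3, maxEpochs = 200L, patience = 10L)
  m <- trainModel(cohort[1:40]@samples, cohort[41:50]@samples,
                  smallModelConfig(), tc)
  h <- m$history
  lastEpoch <- max(h$epoch)
  expect_lte(lastEpoch, 200L)
  if (lastEpoch < 200L)  # stopped early: exactly patience epochs past best
    expect_equal(lastEpoch, m$bestEpoch + 10L)
  # best-epoch val loss is the running minimum of the whole history
  expect_equal(m$bestValLoss, min(h$val_total))
  expect_equal(h$val_total[m$bestEpoch], min(h$val_total))
})

test_that("cross-validation folds are disjoint, exhaustive, reproducible", {
  cohort <- smallCohort(seed = 60, n = 30L)
  mc <- smallModelConfig()
  tc <- trainConfig(seed = 11, maxEpochs = 5L, folds = 5L)
  cv1 <- crossValidate(cohort, mc, tc, returnModels = TRUE)
  cv2 <- crossValidate(cohort, mc, tc, returnModels = TRUE)
  expect_identical(cv1$folds, cv2$folds)
  allTest <- sort(unlist(cv1$testIndices))
  expect_identical(allTest, seq_len(30L))      # partition of the cohort
  expect_equal(nrow(cv1$folds), 5L)
  expect_true(all(cv1$folds$test_mae >= 0))
  expect_error(crossValidate(cohort[1:3], mc, tc), "fewer samples")
})

test_that("the loss-weight grid reports one CV row per weight pair", {
  cohort <- smallCohort(seed = 62, n = 24L)
  tc <- trainConfig(seed = 4, maxEpochs = 3L, folds = 3L)
  grid <- lossWeightGrid(cohort, smallModelConfig(), tc,
                         eta1Grid = c(0.1, 0.5), eta2Grid = 0.01)
  expect_equal(nrow(grid), 2L)
  expect_true(all(!is.na(grid$mae_mean)))
  expect_true(!is.unsorted(grid$mae_mean))
})

test_that("a constant-target cohort is fit with zero MAE", {
  cohort <- smallCohort(seed = 61, n = 20L)
  cohort@samples <- lapply(cohort@samples, function(g) {
    g@targets <- c(score = 2.5); g
  })
  # a model whose MLP output is forced to the constant predicts perfectly
  mc <- smallModelConfig()
  params <- initModelParams(mc, 4L, 12L)
  params$mlp$W <- lapply(params$mlp$W, function(w) w * 0)
  params$mlp$b[[length(params$mlp$b)]] <- 2.5
  pred <- predictScores(list(params = params, modelConfig = mc),
                        cohort@samples)
  expect_equal(mean(abs(pred - targetVector(cohort))), 0)
})
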