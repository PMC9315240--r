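#' Training configuration
#'
#' Defaults follow the reference optimization recipe: loss weights 0.5
#' (regression) and 0.01 (community coherence), Adam with batch size 256,
#' initial learning rate 0.001 decayed by (1 - epoch/maxEpochs)^0.9, L2
#' weight decay 1e-5, early stopping after 20 epochs without validation
#' improvement, at most 500 epochs, and 5-fold cross-validation with a 10
#' percent inner validation split.
#'
#' @param eta1 weight on the regression MSE term.
#' @param eta2 weight on the community-coherence term.
#' @param batchSize minibatch size; clamped to the training-set size.
#' @param lr0 initial learning rate.
#' @param decayPower exponent of the polynomial learning-rate decay.
#' @param weightDecay L2 regularization coefficient.
#' @param patience epochs without validation improvement before stopping.
#' @param maxEpochs hard epoch cap.
#' @param folds number of cross-validation folds.
#' @param valFraction fraction of each training fold held out for early
#'   stopping.
#' @param seed RNG seed for fold splits and batch shuffling.
#' @return a \code{TrainConfig} list.
#' @export
trainConfig <- function(eta1 = 0.5, eta2 = 0.01, batchSize = 256L,
                        lr0 = 0.001, decayPower = 0.9, weightDecay = 1e-5,
                        patience = 20L, maxEpochs = 500L, folds = 5L,
                        valFraction = 0.1, seed = 1L) {
  if (eta1 < 0 || eta2 < 0) stop("loss weights must be nonnegative")
  if (patience < 1L) stop("patience must be >= 1")
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(eta1 = eta1, eta2 = eta2, batchSize = as.integer(batchSize),
                 lr0 = lr0, decayPower = decayPower,
                 weightDecay = weightDecay, patience = as.integer(patience),
                 maxEpochs = as.integer(maxEpochs), folds = as.integer(folds),
                 valFraction = valFraction, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Mean squared error
#' @param pred,truth equal-length numeric vectors.
#' @return mean of squared differences.
#' @export
mseLoss <- function(pred, truth) {
  if (!length(pred)) stop("empty input")
  if (length(pred) != length(truth)) stop("length mismatch")
  mean((pred - truth)^2)
}

#' Community-coherence loss
#'
#' For every pooling scale, the sum over communities and their non-center
#' members of the mean squared difference between the member's latent
#' feature vector and its center's; summed across scales. Minimizing it
#' pulls community members toward their centers in latent space.
#'
#' @param latentScales list of per-scale latent feature matrices.
#' @param partitions list of matching \code{CommunityPartition}s.
#' @return nonnegative scalar.
#' @export
communityLoss <- function(latentScales, partitions) {
  if (length(latentScales) != length(partitions))
    stop("one partition per latent scale required")
  total <- 0
  for (t in seq_along(latentScales)) {
    Z <- latentScales[[t]]
    part <- partitions[[t]]
    centerOf <- part$centers[part$membership]
    isCenter <- seq_len(nrow(Z)) %in% part$centers
    if (all(isCenter)) next
    diff <- Z[!isCenter, , drop = FALSE] - Z[centerOf[!isCenter], , drop = FALSE]
    total <- total + sum(rowMeans(diff^2))
  }
  total
}

#' Joint training loss
#'
#' total = eta1 * MSE(pred, truth) + eta2 * community. Both components are
#' returned alongside the total for logging.
#'
#' @param pred,truth prediction and target vectors.
#' @param latentScales,partitions forwarded to \code{\link{communityLoss}};
#'   for a batch, pass lists of per-graph inputs (the community term is then
#'   averaged over graphs, matching the training objective).
#' @param config a \code{TrainConfig} supplying eta1 and eta2.
#' @return list with \code{total}, \code{mse}, \code{community}.
#' @export
totalLoss <- function(pred, truth, latentScales, partitions, config) {
  mse <- mseLoss(pred, truth)
  comm <- if (length(latentScales) && is.list(latentScales[[1]]) &&
              !is.matrix(latentScales[[1]]))
    mean(mapply(communityLoss, latentScales, partitions))
  else communityLoss(latentScales, partitions)
  list(total = config$eta1 * mse + config$eta2 * comm,
       mse = mse, community = comm)
}

#' Learning rate at a given epoch
#'
#' lr(epoch) = lr0 * (1 - epoch/maxEpochs)^decayPower: polynomial decay
#' from lr0 at epoch 0 to exactly 0 at maxEpochs, strictly decreasing.
#'
#' @param epoch integer in [0, maxEpochs].
#' @param config a \code{TrainConfig}.
#' @return learning rate.
#' @export
lrAt <- function(epoch, config) {
  if (epoch < 0 || epoch > config$maxEpochs)
    stop("epoch must be in [0, maxEpochs]")
  config$lr0 * (1 - epoch / config$maxEpochs)^config$decayPower
}

## ---- parameter flattening (internal) ----

flattenParams <- function(params) {
  unlist(lapply(params$scales, function(s)
    c(unlist(s$gcn), s$readout)), use.names = FALSE) |>
    c(unlist(params$mlp$W, use.names = FALSE),
      unlist(params$mlp$b, use.names = FALSE))
}

unflattenParams <- function(vec, skeleton) {
  pos <- 0L
  take <- function(n) {
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  out <- skeleton
  for (t in seq_along(skeleton$scales)) {
    for (l in seq_along(skeleton$scales[[t]]$gcn)) {
      w <- skeleton$scales[[t]]$gcn[[l]]
      out$scales[[t]]$gcn[[l]] <- matrix(take(length(w)), nrow(w), ncol(w))
    }
    out$scales[[t]]$readout <- take(length(skeleton$scales[[t]]$readout))
  }
  for (l in seq_along(skeleton$mlp$W)) {
    w <- skeleton$mlp$W[[l]]
    out$mlp$W[[l]] <- matrix(take(length(w)), nrow(w), ncol(w))
  }
  for (l in seq_along(skeleton$mlp$b))
    out$mlp$b[[l]] <- take(length(skeleton$mlp$b[[l]]))
  out
}

cohortArrays <- function(samples, score) {
  list(A = lapply(samples, adjacency),
       X = lapply(samples, nodeFeatures),
       y = vapply(samples, function(g) unname(g@targets[[score]]), numeric(1)))
}

batchEval <- function(arr, idx, params, config, train, wantGrad) {
  cpp_batch(arr$A[idx], arr$X[idx], arr$y[idx],
            lapply(params$scales, `[[`, "gcn"),
            lapply(params$scales, `[[`, "readout"),
            params$mlp$W, params$mlp$b,
            config$poolingRatio, config$eps,
            if (config$distance == "l1") 0L else 1L,
            match(config$fusion, c("concatenate", "sum", "average")) - 1L,
            train$eta1, train$eta2, wantGrad)
}

gradVector <- function(res) {
  unlist(lapply(seq_along(res$gradGcn), function(t)
    c(unlist(res$gradGcn[[t]]), res$gradReadout[[t]])),
    use.names = FALSE) |>
    c(unlist(res$gradMlpW, use.names = FALSE),
      unlist(res$gradMlpB, use.names = FALSE))
}

#' Train the hierarchical model
#'
#' Adam with the polynomial learning-rate schedule of \code{\link{lrAt}}
#' (applied per epoch), classic L2 weight decay added to the gradient, and
#' early stopping on the validation total loss: training halts when the
#' best validation loss has not improved by at least 1e-6 for
#' \code{patience} consecutive epochs, and the returned parameters are the
#' best-validation ones, not the last.
#'
#' @param trainSet,valSet lists of \code{BrainGraph} (or Cohorts).
#' @param modelConfig a \code{ModelConfig}.
#' @param train a \code{TrainConfig}.
#' @param score target name; defaults to the first target of the first
#'   training sample.
#' @param params optional warm-start \code{ModelParams}.
#' @return a \code{TrainedModel} list: \code{params}, \code{history}
#'   (per-epoch data.frame with loss components and learning rate),
#'   \code{bestEpoch}, \code{bestValLoss}, \code{modelConfig},
#'   \code{trainConfig}, \code{score}.
#' @export
trainModel <- function(trainSet, valSet, modelConfig, train = trainConfig(),
                       score = NULL, params = NULL) {
  if (is(trainSet, "Cohort")) {
    if (is.null(score)) score <- scoreName(trainSet)
    trainSet <- trainSet@samples
  }
  if (is(valSet, "Cohort")) valSet <- valSet@samples
  if (!length(trainSet) || !length(valSet))
    stop("train and validation sets must be nonempty")
  if (is.null(score)) score <- names(trainSet[[1]]@targets)[1]

  N <- nrow(adjacency(trainSet[[1]]))
  d <- ncol(nodeFeatures(trainSet[[1]]))
  if (is.null(params)) params <- initModelParams(modelConfig, d, N)
  skeleton <- params
  theta <- flattenParams(params)

  arrTrain <- cohortArrays(trainSet, score)
  arrVal <- cohortArrays(valSet, score)
  nTrain <- length(trainSet)
  bs <- min(train$batchSize, nTrain)

  m <- v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8
  step <- 0L

  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(train$seed)

  best <- Inf; bestTheta <- theta; bestEpoch <- 0L; wait <- 0L
  hist <- vector("list", train$maxEpochs)

  for (epoch in seq_len(train$maxEpochs)) {
    lr <- lrAt(epoch - 1L, train)
    ord <- sample.int(nTrain)
    starts <- seq(1L, nTrain, by = bs)
    epochTotal <- epochMse <- epochComm <- 0
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1L, nTrain)]
      prm <- unflattenParams(theta, skeleton)
      res <- batchEval(arrTrain, idx, prm, modelConfig, train, TRUE)
      wb <- length(idx) / nTrain
      epochTotal <- epochTotal + res$total * wb
      epochMse <- epochMse + res$mse * wb
      epochComm <- epochComm + res$community * wb
      g <- gradVector(res) + train$weightDecay * theta
      step <- step + 1L
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^step)
      vhat <- v / (1 - beta2^step)
      theta <- theta - lr * mhat / (sqrt(vhat) + adamEps)
    }
    if (!is.finite(epochTotal))
      stop("non-finite training loss at epoch ", epoch)
    prm <- unflattenParams(theta, skeleton)
    valRes <- batchEval(arrVal, seq_along(arrVal$A), prm, modelConfig,
                        train, FALSE)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_total = epochTotal,
                                train_mse = epochMse,
                                train_community = epochComm,
                                val_total = valRes$total)
    if (best - valRes$total >= 1e-6) {
      best <- valRes$total
      bestTheta <- theta
      bestEpoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train$patience) break
    }
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  structure(list(params = unflattenParams(bestTheta, skeleton),
                 history = history, bestEpoch = bestEpoch,
                 bestValLoss = best, modelConfig = modelConfig,
                 trainConfig = train, score = score),
            class = "TrainedModel")
}

#' Predict scores for a set of graphs
#'
#' @param model a \code{TrainedModel} (or a list with \code{params} and
#'   \code{modelConfig}).
#' @param graphs a \code{Cohort} or list of \code{BrainGraph}.
#' @return numeric vector of predictions.
#' @export
predictScores <- function(model, graphs) {
  if (is(graphs, "Cohort")) graphs <- graphs@samples
  arr <- list(A = lapply(graphs, adjacency),
              X = lapply(graphs, nodeFeatures),
              y = numeric(length(graphs)))
  cfg <- model$modelConfig
  res <- cpp_batch(arr$A, arr$X, arr$y,
                   lapply(model$params$scales, `[[`, "gcn"),
                   lapply(model$params$scales, `[[`, "readout"),
                   model$params$mlp$W, model$params$mlp$b,
                   cfg$poolingRatio, cfg$eps,
                   if (cfg$distance == "l1") 0L else 1L,
                   match(cfg$fusion, c("concatenate", "sum", "average")) - 1L,
                   1, 0, FALSE)
  as.vector(res$preds)
}

#' Simple grid search over the two loss weights
#'
#' Cross-validates every combination of the candidate regression and
#' community-coherence weights (defaults mirror the reference search
#' ranges) and reports the CV MAE per pair. No broader hyperparameter
#' search is provided by design.
#'
#' @param cohort a \code{Cohort}.
#' @param modelConfig a \code{ModelConfig}.
#' @param train a \code{TrainConfig} whose eta1/eta2 are overridden.
#' @param eta1Grid,eta2Grid candidate weights.
#' @return data.frame with \code{eta1}, \code{eta2}, \code{mae_mean},
#'   \code{mae_sd}, sorted by \code{mae_mean}.
#' @export
lossWeightGrid <- function(cohort, modelConfig, train = trainConfig(),
                           eta1Grid = c(0.1, 0.5, 1),
                           eta2Grid = c(0.01, 0.05, 0.1)) {
  rows <- list()
  for (e1 in eta1Grid) for (e2 in eta2Grid) {
    tc <- train
    tc$eta1 <- e1
    tc$eta2 <- e2
    cv <- crossValidate(cohort, modelConfig, tc)
    rows[[length(rows) + 1L]] <- data.frame(eta1 = e1, eta2 = e2,
                                            mae_mean = cv$maeMean,
                                            mae_sd = cv$maeSd)
  }
  out <- do.call(rbind, rows)
  out[order(out$mae_mean), ]
}

#' K-fold cross-validated evaluation
#'
#' Disjoint folds drawn with the training seed; within each fold the
#' training portion donates \code{valFraction} of its samples to an inner
#' validation split for early stopping. Reports the held-out MAE per fold,
#' its mean and population standard deviation, and the
#' predict-the-training-mean baseline MAE for reference.
#'
#' @param cohort a \code{Cohort} with an active score.
#' @param modelConfig a \code{ModelConfig}.
#' @param train a \code{TrainConfig}.
#' @param returnModels keep the per-fold \code{TrainedModel}s (and test
#'   indices) in the result.
#' @return a \code{CrossValResult} list: \code{folds} (data.frame with
#'   \code{fold}, \code{test_mae}, \code{baseline_mae}, \code{best_epoch}),
#'   \code{maeMean}, \code{maeSd}, \code{baselineMean}, and optionally
#'   \code{models}, \code{testIndices}.
#' @export
crossValidate <- function(cohort, modelConfig, train = trainConfig(),
                          returnModels = FALSE) {
  n <- length(cohort)
  if (n < train$folds) stop("fewer samples than folds")
  score <- scoreName(cohort)
  y <- targetVector(cohort)

  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(train$seed)
  foldId <- sample(rep(seq_len(train$folds), length.out = n))
  valPick <- lapply(seq_len(train$folds), function(k) {
    pool <- which(foldId != k)
    sample(pool, max(1L, round(train$valFraction * length(pool))))
  })
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)

  rows <- vector("list", train$folds)
  models <- vector("list", train$folds)
  testIdx <- vector("list", train$folds)
  for (k in seq_len(train$folds)) {
    test <- which(foldId == k)
    val <- valPick[[k]]
    tr <- setdiff(which(foldId != k), val)
    model <- trainModel(cohort@samples[tr], cohort@samples[val],
                        modelConfig, train, score = score)
    pred <- predictScores(model, cohort@samples[test])
    mae <- mean(abs(pred - y[test]))
    base <- mean(abs(mean(y[c(tr, val)]) - y[test]))
    rows[[k]] <- data.frame(fold = k, test_mae = mae, baseline_mae = base,
                            best_epoch = model$bestEpoch)
    if (returnModels) {
      models[[k]] <- model
      testIdx[[k]] <- test
    }
  }
  folds <- do.call(rbind, rows)
  out <- list(folds = folds,
              maeMean = mean(folds$test_mae),
              maeSd = sqrt(mean((folds$test_mae - mean(folds$test_mae))^2)),
              baselineMean = mean(folds$baseline_mae))
  if (returnModels) {
    out$models <- models
    out$testIndices <- testIdx
  }
  structure(out, class = "CrossValResult")
}
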