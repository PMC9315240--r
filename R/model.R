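#' Model architecture configuration
#'
#' Defaults follow the reference configuration: 3 pooling modules at ratio
#' 0.5, 2 graph-convolution layers per block, 64 latent dimensions, readouts
#' fused by concatenation, and an MLP head with hidden sizes 64 and 32.
#'
#' @param numPoolingModules number of stacked pooling modules (>= 1).
#' @param poolingRatio fraction of nodes kept per module, in (0, 1].
#' @param hiddenDim latent feature dimension c.
#' @param gcnLayersPerBlock graph-convolution layers per block.
#' @param fusion "concatenate", "sum", or "average".
#' @param mlpHidden integer vector of MLP hidden-layer sizes.
#' @param distance "l1" or "l2" feature distance.
#' @param eps guard added to distances in the aggregation denominator.
#' @param seed RNG seed for weight initialization.
#' @return a \code{ModelConfig} list.
#' @export
modelConfig <- function(numPoolingModules = 3L, poolingRatio = 0.5,
                        hiddenDim = 64L, gcnLayersPerBlock = 2L,
                        fusion = c("concatenate", "sum", "average"),
                        mlpHidden = c(64L, 32L),
                        distance = c("l1", "l2"), eps = 1e-6, seed = 1L) {
  fusion <- match.arg(fusion)
  distance <- match.arg(distance)
  if (numPoolingModules < 1L) stop("numPoolingModules must be >= 1")
  if (poolingRatio <= 0 || poolingRatio > 1)
    stop("poolingRatio must be in (0, 1]")
  if (gcnLayersPerBlock < 1L) stop("gcnLayersPerBlock must be >= 1")
  if (hiddenDim < 1L) stop("hiddenDim must be >= 1")
  structure(list(numPoolingModules = as.integer(numPoolingModules),
                 poolingRatio = poolingRatio,
                 hiddenDim = as.integer(hiddenDim),
                 gcnLayersPerBlock = as.integer(gcnLayersPerBlock),
                 fusion = fusion, mlpHidden = as.integer(mlpHidden),
                 distance = distance, eps = eps, seed = as.integer(seed)),
            class = "ModelConfig")
}

#' Node counts at every pooling scale
#'
#' The ceiling recurrence N_{t} = ceiling(ratio * N_{t-1}) applied
#' \code{numPoolingModules} times; e.g. 246 nodes at ratio 0.5 over three
#' modules gives 123, 62, 31.
#'
#' @param N atlas size.
#' @param config a \code{ModelConfig} (or a ratio plus count, see arguments).
#' @param ratio,times used when \code{config} is missing.
#' @return integer vector of post-pooling sizes, one per module.
#' @export
scaleSizes <- function(N, config = NULL, ratio = 0.5, times = 3L) {
  if (!is.null(config)) {
    ratio <- config$poolingRatio
    times <- config$numPoolingModules
  }
  out <- integer(times)
  n <- N
  for (t in seq_len(times)) {
    n <- as.integer(ceiling(ratio * n))
    out[t] <- n
  }
  out
}

#' Initialize all trainable parameters
#'
#' Glorot-uniform graph-convolution and MLP weights, zero biases, and
#' per-scale readout vectors, drawn under the config seed. Readout length at
#' scale t is the post-pooling node count, which is deterministic given the
#' atlas size, so parameters are shared across a cohort with a common atlas.
#'
#' @param config a \code{ModelConfig}.
#' @param inputDim node feature dimension d.
#' @param atlasSize common node count N.
#' @return a \code{ModelParams} list: \code{scales[[t]]$gcn} (list of weight
#'   matrices), \code{scales[[t]]$readout} (vector), \code{mlp$W},
#'   \code{mlp$b}.
#' @export
initModelParams <- function(config, inputDim, atlasSize) {
  sizes <- scaleSizes(atlasSize, config)
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(config$seed)

  scales <- vector("list", config$numPoolingModules)
  inDim <- inputDim
  for (t in seq_len(config$numPoolingModules)) {
    gcn <- vector("list", config$gcnLayersPerBlock)
    for (l in seq_len(config$gcnLayersPerBlock)) {
      gcn[[l]] <- glorotInit(inDim, config$hiddenDim)
      inDim <- config$hiddenDim
    }
    # Pooled features are entrywise nonnegative, so a sign-symmetric readout
    # weight frequently starts with every ReLU preactivation negative (a dead
    # readout with no regression gradient). Start near mean pooling instead:
    # positive weights around 1/M, with uniform jitter to break symmetry.
    M <- sizes[t]
    scales[[t]] <- list(gcn = gcn,
                        readout = runif(M, 0.5, 1.5) / M)
  }
  fusedDim <- if (config$fusion == "concatenate")
    config$hiddenDim * config$numPoolingModules else config$hiddenDim
  dims <- c(fusedDim, config$mlpHidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    W[[l]] <- t(glorotInit(dims[l], dims[l + 1L]))  # out x in
    b[[l]] <- rep(0, dims[l + 1L])
  }
  structure(list(scales = scales, mlp = list(W = W, b = b)),
            class = "ModelParams")
}

#' Fuse per-scale readouts
#'
#' @param readouts list of equal-length numeric vectors, one per scale.
#' @param mode "concatenate", "sum", or "average".
#' @return fused vector (length c * k for concatenation, c otherwise).
#' @export
fuseReadouts <- function(readouts, mode = c("concatenate", "sum", "average")) {
  mode <- match.arg(mode)
  if (!length(readouts)) stop("no readouts to fuse")
  switch(mode,
         concatenate = unlist(readouts, use.names = FALSE),
         sum = Reduce(`+`, readouts),
         average = Reduce(`+`, readouts) / length(readouts))
}

#' MLP regression head
#'
#' Fully connected layers with ReLU between hidden layers and a linear
#' scalar output.
#'
#' @param fused fused representation vector.
#' @param mlp list with \code{W} (out x in matrices) and \code{b} (vectors).
#' @return scalar prediction.
#' @export
mlpHead <- function(fused, mlp) {
  a <- fused
  L <- length(mlp$W)
  for (l in seq_len(L)) {
    if (ncol(mlp$W[[l]]) != length(a))
      stop("MLP layer ", l, " expects input of length ", ncol(mlp$W[[l]]),
           ", got ", length(a))
    a <- as.vector(mlp$W[[l]] %*% a) + mlp$b[[l]]
    if (l < L) a <- pmax(a, 0)
  }
  a
}

#' Full hierarchical forward pass
#'
#' Alternates a graph-convolution block, a community-pooling module, and a
#' per-scale readout for \code{numPoolingModules} rounds, each round
#' consuming the previous round's coarsened graph (whose adjacency is
#' re-normalized fresh). Readouts are fused and mapped to a scalar
#' prediction by the MLP head. The returned trace retains everything the
#' interpretability pipeline needs.
#'
#' @param graph a \code{BrainGraph}, or a list with \code{adjacency} and
#'   \code{nodeFeatures}.
#' @param config a \code{ModelConfig}.
#' @param params a \code{ModelParams}.
#' @return a \code{ForwardTrace} list: \code{prediction},
#'   \code{perScaleReadouts}, \code{partitions}, \code{fused},
#'   \code{latentFeatures}, \code{pooledFeatures}, \code{atlasRoots}
#'   (per-scale atlas root of each surviving node), \code{scaleSizes}.
#' @export
forwardModel <- function(graph, config, params) {
  if (is(graph, "BrainGraph")) {
    A <- adjacency(graph); X <- nodeFeatures(graph)
  } else {
    A <- graph$adjacency; X <- graph$nodeFeatures
  }
  Tn <- config$numPoolingModules
  readouts <- vector("list", Tn)
  partitions <- vector("list", Tn)
  latents <- vector("list", Tn)
  pooled <- vector("list", Tn)
  atlasRoots <- vector("list", Tn)
  root <- seq_len(nrow(A))
  aset <- as.list(seq_len(nrow(A)))
  for (t in seq_len(Tn)) {
    layers <- lapply(params$scales[[t]]$gcn,
                     function(w) list(weight = w, activation = "relu"))
    Z <- gcnBlock(A, X, layers)
    step <- poolGraph(Z, A, ratio = config$poolingRatio,
                      metric = config$distance, eps = config$eps,
                      atlasRoot = root, atlasSet = aset)
    readouts[[t]] <- readout(step$features, params$scales[[t]]$readout)
    partitions[[t]] <- step$partition
    latents[[t]] <- Z
    pooled[[t]] <- step$features
    atlasRoots[[t]] <- step$atlasRoot
    A <- step$adjacency
    X <- step$features
    root <- step$atlasRoot
    aset <- step$atlasSet
  }
  fused <- fuseReadouts(readouts, config$fusion)
  pred <- mlpHead(fused, params$mlp)
  structure(list(prediction = pred, perScaleReadouts = readouts,
                 partitions = partitions, fused = fused,
                 latentFeatures = latents, pooledFeatures = pooled,
                 atlasRoots = atlasRoots,
                 scaleSizes = vapply(atlasRoots, length, integer(1))),
            class = "ForwardTrace")
}
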