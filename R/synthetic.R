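#' Synthetic cohort configuration
#'
#' Describes a cohort of weighted graphs with planted community structure
#' (a planted-partition model with exponentially weighted edges),
#' community-prototype node features, and continuous targets driven by a
#' planted subset of signal nodes.
#'
#' Signal nodes are generated as feature-space hubs: instead of their
#' community prototype they carry a per-subject activation s_k along a fixed
#' low-magnitude direction, which places them centrally in feature space
#' (small total distance to all other nodes) the way behaviorally salient
#' regions sit between community clusters. The target is a linear
#' combination of the signal nodes' mean feature values plus noise, so
#' ground truth exists both for regression and for effecting-node
#' enrichment. With \code{groupBSignalNodes} set, half the subjects form
#' group "B" whose targets and feature hubs use the alternative node set,
#' giving a planted group difference for the permutation-test pipeline.
#'
#' @param nSubjects number of subjects.
#' @param nNodes atlas size N.
#' @param nCommunities number of planted communities (contiguous blocks).
#' @param pIn,pOut within/between-community edge probabilities.
#' @param weightScale mean of the exponential edge weights; the default
#'   keeps edge weights small relative to the unit self-loop so message
#'   passing mixes neighbor information without drowning each node's own
#'   features.
#' @param featureDim node feature dimension d.
#' @param featureNoiseSd per-coordinate feature noise.
#' @param signalNodes planted signal node indices (default: spread across
#'   communities via \code{\link{defaultSignalNodes}}).
#' @param signalCoefficients target weights, one per signal node.
#' @param targetNoiseSd target noise standard deviation.
#' @param signalDirection per-coordinate magnitude of the fixed hub
#'   direction (signal feature row = anchor + s_k * signalDirection * 1 +
#'   noise, anchored at the community-prototype centroid).
#' @param hubEdgeProb connection probability of a signal node to every
#'   other node (connector-hub topology); \code{NULL} leaves signal nodes
#'   with plain planted-partition connectivity.
#' @param groupBSignalNodes optional alternative signal set for group B.
#' @param seed cohort seed; topology, features and target noise use
#'   independent derived streams.
#' @param protoSeed seed of the community-prototype draw; defaults to
#'   \code{seed}. Pass a common value to make replicate cohorts samples
#'   from one fixed population (same atlas-level feature structure, fresh
#'   subjects), as in replicated significance studies.
#' @return a \code{SynthConfig} list.
#' @export
synthConfig <- function(nSubjects = 200L, nNodes = 30L, nCommunities = 4L,
                        pIn = 0.6, pOut = 0.1, weightScale = 0.1,
                        featureDim = 8L, featureNoiseSd = 0.3,
                        signalNodes = NULL, signalCoefficients = NULL,
                        targetNoiseSd = 0.1, signalDirection = 0.5,
                        hubEdgeProb = 0.8,
                        groupBSignalNodes = NULL, seed = 1L,
                        protoSeed = NULL) {
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1))
    stop("need 0 <= pOut < pIn <= 1")
  if (is.null(signalNodes))
    signalNodes <- defaultSignalNodes(nNodes, nCommunities, 5L)
  if (any(signalNodes < 1L | signalNodes > nNodes))
    stop("signalNodes out of range")
  if (is.null(signalCoefficients))
    signalCoefficients <- rep(1, length(signalNodes))
  if (length(signalCoefficients) != length(signalNodes))
    stop("one coefficient per signal node required")
  if (!is.null(groupBSignalNodes) &&
      any(groupBSignalNodes < 1L | groupBSignalNodes > nNodes))
    stop("groupBSignalNodes out of range")
  structure(list(nSubjects = as.integer(nSubjects),
                 nNodes = as.integer(nNodes),
                 nCommunities = as.integer(nCommunities),
                 pIn = pIn, pOut = pOut, weightScale = weightScale,
                 featureDim = as.integer(featureDim),
                 featureNoiseSd = featureNoiseSd,
                 signalNodes = as.integer(signalNodes),
                 signalCoefficients = signalCoefficients,
                 targetNoiseSd = targetNoiseSd,
                 signalDirection = signalDirection,
                 hubEdgeProb = hubEdgeProb,
                 groupBSignalNodes = if (is.null(groupBSignalNodes)) NULL
                                     else as.integer(groupBSignalNodes),
                 seed = as.integer(seed),
                 protoSeed = if (is.null(protoSeed)) as.integer(seed)
                             else as.integer(protoSeed)),
            class = "SynthConfig")
}

#' Planted community assignment
#'
#' Contiguous blocks, sizes as even as possible.
#'
#' @param nNodes,nCommunities atlas size and community count.
#' @return integer vector of community labels in 1..nCommunities.
#' @export
communityAssignment <- function(nNodes, nCommunities) {
  sizes <- rep(nNodes %/% nCommunities, nCommunities)
  extra <- nNodes %% nCommunities
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(nCommunities), times = sizes)
}

#' Default planted signal nodes
#'
#' Picks \code{nSignal} nodes spread across the communities (the second
#' node of each block, cycling to later block positions when nSignal
#' exceeds the community count).
#'
#' @param nNodes,nCommunities,nSignal sizes.
#' @return integer vector of node indices.
#' @export
defaultSignalNodes <- function(nNodes, nCommunities, nSignal = 5L) {
  comm <- communityAssignment(nNodes, nCommunities)
  starts <- match(seq_len(nCommunities), comm)
  picks <- integer(0)
  offset <- 1L
  while (length(picks) < nSignal) {
    cand <- starts + offset
    cand <- cand[cand <= nNodes & comm[pmin(cand, nNodes)] == seq_len(nCommunities)]
    picks <- c(picks, cand)
    offset <- offset + 1L
  }
  sort(picks[seq_len(nSignal)])
}

#' Draw one planted-partition adjacency matrix
#'
#' Within-community node pairs are connected with probability pIn, between
#' with pOut; present edges get independent Exponential(mean weightScale)
#' weights. Signal nodes are additionally rewired as connector hubs: every
#' pair involving a signal node is connected with probability
#' \code{hubEdgeProb} instead (skipped when \code{hubEdgeProb} is NULL).
#' Symmetric with a zero diagonal; draws from the current RNG state
#' (seeding is managed by \code{\link{makeCohort}}).
#'
#' @param config a \code{SynthConfig}.
#' @param signalNodes hub node set (defaults to the config's).
#' @return N x N numeric matrix.
#' @export
generateAdjacency <- function(config, signalNodes = config$signalNodes) {
  n <- config$nNodes
  comm <- communityAssignment(n, config$nCommunities)
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  p <- ifelse(comm[ut[, 1]] == comm[ut[, 2]], config$pIn, config$pOut)
  if (!is.null(config$hubEdgeProb)) {
    isHub <- ut[, 1] %in% signalNodes | ut[, 2] %in% signalNodes
    p[isHub] <- config$hubEdgeProb
  }
  present <- runif(nrow(ut)) < p
  w <- numeric(nrow(ut))
  w[present] <- rexp(sum(present), rate = 1 / config$weightScale)
  A[ut] <- w
  A + t(A)
}

#' Draw node features for one subject
#'
#' Every community has a standard-normal d-dimensional prototype drawn once
#' per cohort (deterministically from the config seed, mirroring how the
#' broad feature organization of the brain is shared across subjects);
#' non-signal nodes are their prototype plus N(0, featureNoiseSd) noise.
#' Signal nodes (argument \code{signalNodes}, defaulting to the config's)
#' instead carry s_k * signalDirection in every coordinate plus the same
#' noise, with s_k ~ N(0, 1) per subject: feature-space hubs whose
#' activation drives the target.
#'
#' @param adjacency subject adjacency (fixes N; passed for interface
#'   symmetry, features depend only on the planted communities).
#' @param config a \code{SynthConfig}.
#' @param signalNodes node set to treat as signal hubs.
#' @return N x d matrix with attribute \code{"activations"} (named s_k).
#' @export
generateFeatures <- function(adjacency, config,
                             signalNodes = config$signalNodes) {
  n <- config$nNodes
  d <- config$featureDim
  comm <- communityAssignment(n, config$nCommunities)
  proto <- communityPrototypes(config)
  X <- proto[comm, , drop = FALSE] +
    matrix(rnorm(n * d, sd = config$featureNoiseSd), n, d)
  s <- rnorm(length(signalNodes))
  hubAnchor <- colMeans(proto)
  X[signalNodes, ] <- rep(1, length(signalNodes)) %o% hubAnchor +
    s %o% rep(config$signalDirection, d) +
    matrix(rnorm(length(signalNodes) * d, sd = config$featureNoiseSd),
           length(signalNodes), d)
  attr(X, "activations") <- stats::setNames(s, signalNodes)
  X
}

#' Cohort-level community feature prototypes
#'
#' One standard-normal d-dimensional prototype per community, drawn from a
#' stream derived from the config seed (so all subjects of a cohort share
#' the same prototypes and the surrounding RNG state is untouched).
#'
#' @param config a \code{SynthConfig}.
#' @return nCommunities x featureDim matrix.
#' @export
communityPrototypes <- function(config) {
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  ps <- if (is.null(config$protoSeed)) config$seed else config$protoSeed
  set.seed((as.double(ps) * 31 + 17) %% 2147483647)
  matrix(rnorm(config$nCommunities * config$featureDim),
         config$nCommunities, config$featureDim)
}

#' Draw the target score for one subject
#'
#' y = sum_k coefficients[k] * mean(feature row of signal node k) +
#' N(0, targetNoiseSd): the target depends only on the planted nodes.
#'
#' @param graph a \code{BrainGraph} or a list with \code{nodeFeatures}.
#' @param config a \code{SynthConfig}.
#' @param signalNodes signal set (defaults to the config's).
#' @return scalar target.
#' @export
generateTarget <- function(graph, config, signalNodes = config$signalNodes) {
  if (!length(signalNodes)) stop("signalNodes must be nonempty")
  X <- if (is(graph, "BrainGraph")) nodeFeatures(graph) else graph$nodeFeatures
  sum(config$signalCoefficients * rowMeans(X[signalNodes, , drop = FALSE])) +
    rnorm(1, sd = config$targetNoiseSd)
}

#' Generate a full synthetic cohort
#'
#' n independent (adjacency, features, target) triples. Topology, features
#' and target noise use independent seeded streams, so changing e.g. the
#' feature noise does not perturb the drawn topologies. When
#' \code{groupBSignalNodes} is set, subjects alternate between groups "A"
#' and "B" (balanced within one) and group B's features and targets use the
#' alternative signal set.
#'
#' @param config a \code{SynthConfig}.
#' @return a \code{Cohort} with score "score"; the planted truth (signal
#'   sets per group) is attached as attribute \code{"groundTruth"}.
#' @export
makeCohort <- function(config) {
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  base <- as.double(config$seed)
  twoGroup <- !is.null(config$groupBSignalNodes)
  samples <- vector("list", config$nSubjects)
  for (i in seq_len(config$nSubjects)) {
    grp <- if (!twoGroup) NA_character_ else if (i %% 2L == 1L) "A" else "B"
    sig <- if (identical(grp, "B")) config$groupBSignalNodes
           else config$signalNodes
    set.seed((base * 1000003 + i) %% 2147483647)
    A <- generateAdjacency(config, signalNodes = sig)
    set.seed((base * 1000003 + 331 * i + 104729) %% 2147483647)
    X <- generateFeatures(A, config, signalNodes = sig)
    attr(X, "activations") <- NULL
    set.seed((base * 1000003 + 709 * i + 1299709) %% 2147483647)
    y <- generateTarget(list(nodeFeatures = X), config, signalNodes = sig)
    samples[[i]] <- BrainGraph(A, X,
                               subjectId = sprintf("sub%04d", i),
                               group = grp,
                               targets = c(score = y))
  }
  cohort <- Cohort(samples, scoreName = "score")
  attr(cohort, "groundTruth") <- list(
    signalNodes = config$signalNodes,
    groupBSignalNodes = config$groupBSignalNodes,
    communities = communityAssignment(config$nNodes, config$nCommunities))
  cohort
}
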