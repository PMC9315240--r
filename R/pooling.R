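#' Pairwise feature-distance matrix
#'
#' S[i, j] is the L1 (default) or L2 distance between latent feature rows i
#' and j. The L1 form follows the pooling operator's defining formula; L2 is
#' available because the surrounding description of the operator speaks of
#' Euclidean distance, and the choice is exposed rather than resolved.
#'
#' @param Z N x c latent feature matrix.
#' @param metric "l1" or "l2".
#' @return symmetric N x N matrix with zero diagonal.
#' @export
pairwiseDistance <- function(Z, metric = c("l1", "l2")) {
  metric <- match.arg(metric)
  Z <- as.matrix(Z)
  if (nrow(Z) < 1L) stop("Z must have at least one row")
  S <- as.matrix(dist(Z, method = if (metric == "l1") "manhattan" else "euclidean"))
  dimnames(S) <- NULL
  S
}

#' Community-center probability vector
#'
#' Row sums of the distance matrix are min-max normalized to [0, 1]; the
#' probability vector is softmax(1 - normalized row sums), so nodes that sit
#' densely among the others (small total distance) receive high probability.
#' When all row sums are equal (e.g. all features identical) the normalized
#' vector is defined as all zeros and the result is uniform.
#'
#' @param S distance matrix from \code{\link{pairwiseDistance}}.
#' @return probability vector summing to 1.
#' @export
centerProbability <- function(S) {
  r <- rowSums(S)
  rng <- max(r) - min(r)
  normed <- if (rng > 0) (r - min(r)) / rng else rep(0, length(r))
  logits <- 1 - normed
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Select the top-M community centers
#'
#' M = ceiling(ratio * N). Ties in probability are broken toward the smaller
#' node index; the result is ordered by decreasing probability (then index),
#' so position in the returned vector is the center's rank.
#'
#' @param P probability vector.
#' @param ratio pooling ratio in (0, 1].
#' @return integer vector of M node indices (1-based).
#' @export
selectCenters <- function(P, ratio) {
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]")
  n <- length(P)
  M <- as.integer(ceiling(ratio * n))
  order(-P, seq_len(n))[seq_len(M)]
}

#' Assign every node to its nearest community center
#'
#' Non-center nodes go to the center with the smallest feature distance;
#' distance ties resolve to the earlier-listed (higher-probability) center.
#' Every center belongs to its own community.
#'
#' @param S distance matrix.
#' @param centers index vector from \code{\link{selectCenters}}.
#' @return a \code{CommunityPartition}: list with \code{centers},
#'   \code{membership} (length-N community index in 1..M), and
#'   \code{parentMap} (initialized to singleton atlas sets; composed
#'   hierarchies are maintained by \code{\link{poolGraph}}).
#' @export
assignMembers <- function(S, centers) {
  if (!length(centers)) stop("centers must be nonempty")
  if (anyDuplicated(centers)) stop("centers must be distinct")
  D <- S[, centers, drop = FALSE]
  membership <- max.col(-D, ties.method = "first")
  membership[centers] <- seq_along(centers)
  structure(list(centers = as.integer(centers),
                 membership = as.integer(membership),
                 parentMap = as.list(seq_len(nrow(S)))[centers]),
            class = "CommunityPartition")
}

#' Center-anchored community feature aggregation
#'
#' Community i's representation is the center's latent feature plus the sum
#' of each non-center member's feature scaled by the inverse of its distance
#' to the center: Zhat_i = Z[c_i, ] + sum_j Z[v_j, ] / (S[c_i, v_j] + eps).
#' A community containing only its center contributes the center row
#' exactly (the guard eps is never invoked).
#'
#' @param Z N x c latent features.
#' @param S distance matrix over the same nodes.
#' @param partition a \code{CommunityPartition}.
#' @param eps additive guard against zero distances (duplicate features).
#' @return M x c matrix of community representations.
#' @export
communityRepresentation <- function(Z, S, partition, eps = 1e-6) {
  B <- poolingMatrix(S, partition, eps)
  B %*% Z
}

#' Pooling aggregation matrix
#'
#' The M x N matrix B with B[i, c_i] = 1 and B[i, j] = 1 / (S[c_i, j] + eps)
#' for non-center members j of community i, so that the community
#' representation is B \%*\% Z. Exposed for reuse in gradient computations
#' and tests.
#'
#' @inheritParams communityRepresentation
#' @return M x N matrix.
#' @export
poolingMatrix <- function(S, partition, eps = 1e-6) {
  centers <- partition$centers
  membership <- partition$membership
  n <- length(membership)
  M <- length(centers)
  B <- matrix(0, M, n)
  for (i in seq_len(M)) {
    members <- setdiff(which(membership == i), centers[i])
    if (length(members))
      B[i, members] <- 1 / (S[centers[i], members] + eps)
    B[i, centers[i]] <- 1
  }
  B
}

#' Coarsen an adjacency matrix over a community partition
#'
#' Block sums: the edge weight between coarse nodes k and l is the total
#' original weight between their communities; the coarse diagonal keeps only
#' within-community weight between distinct nodes, so total off-diagonal
#' mass is conserved (sum(A') = sum(A) - trace(A)).
#'
#' @param A N x N symmetric nonnegative matrix.
#' @param partition a \code{CommunityPartition} over the same nodes.
#' @return M x M symmetric nonnegative matrix.
#' @export
coarsenAdjacency <- function(A, partition) {
  membership <- partition$membership
  M <- length(partition$centers)
  Ind <- matrix(0, nrow(A), M)
  Ind[cbind(seq_len(nrow(A)), membership)] <- 1
  Ac <- t(Ind) %*% A %*% Ind
  selfMass <- rowsum(diag(A), group = factor(membership, levels = seq_len(M)))
  diag(Ac) <- diag(Ac) - as.vector(selfMass)
  Ac
}

#' Per-scale graph readout
#'
#' A learned linear combination of the pooled community features followed by
#' a ReLU: readout = relu(w \%*\% Zhat), one fixed-length vector per scale.
#'
#' @param Zhat M x c pooled feature matrix.
#' @param w length-M weight vector.
#' @return length-c numeric vector.
#' @export
readout <- function(Zhat, w) {
  if (length(w) != nrow(Zhat))
    stop("readout weight length ", length(w), " != node count ", nrow(Zhat))
  pmax(as.vector(t(w) %*% Zhat), 0)
}

#' One full community-pooling step
#'
#' Composes distance computation, center scoring and selection, membership
#' assignment, feature aggregation, and adjacency coarsening, while
#' maintaining the provenance of every coarse node back to the original
#' atlas: \code{atlasRoot} is the atlas index of each coarse node's
#' center-lineage ancestor, and \code{atlasSet} the full set of atlas nodes
#' absorbed into it.
#'
#' @param Z current-scale latent features.
#' @param A current-scale adjacency.
#' @param ratio pooling ratio.
#' @param metric distance metric, "l1" or "l2".
#' @param eps distance guard.
#' @param atlasRoot integer vector: atlas root of each current node
#'   (default: identity, for the original scale).
#' @param atlasSet list: atlas cover of each current node.
#' @return list with \code{features} (M x c), \code{adjacency} (M x M),
#'   \code{partition}, \code{P}, \code{S}, \code{atlasRoot},
#'   \code{atlasSet}.
#' @export
poolGraph <- function(Z, A, ratio = 0.5, metric = "l1", eps = 1e-6,
                      atlasRoot = seq_len(nrow(Z)),
                      atlasSet = as.list(seq_len(nrow(Z)))) {
  S <- pairwiseDistance(Z, metric)
  P <- centerProbability(S)
  centers <- selectCenters(P, ratio)
  partition <- assignMembers(S, centers)
  Zhat <- communityRepresentation(Z, S, partition, eps)
  Ac <- coarsenAdjacency(A, partition)
  newRoot <- atlasRoot[centers]
  newSet <- lapply(seq_along(centers), function(i)
    sort(unlist(atlasSet[partition$membership == i])))
  partition$parentMap <- newSet
  list(features = Zhat, adjacency = Ac, partition = partition,
       P = P, S = S, atlasRoot = newRoot, atlasSet = newSet)
}
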