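# Brute-force reference implementations and small random-input factories.
# Oracles are deliberately written as plain double loops, independent of the
# package's vectorized/C++ code paths.

randomSymAdj <- function(n, density = 0.5) {
  A <- matrix(0, n, n)
  if (n > 1) {
    ut <- upper.tri(A)
    w <- ifelse(runif(sum(ut)) < density, rexp(sum(ut)), 0)
    A[ut] <- w
    A <- A + t(A)
  }
  A
}

randomGraph <- function(n, d) {
  list(adjacency = randomSymAdj(n), nodeFeatures = matrix(rnorm(n * d), n, d))
}

oraclePairwiseL1 <- function(Z) {
  n <- nrow(Z)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- sum(abs(Z[i, ] - Z[j, ]))
  S
}

oracleSelectCenters <- function(P, ratio) {
  M <- ceiling(ratio * length(P))
  ord <- order(-P, seq_along(P))
  ord[seq_len(M)]
}

oracleAssign <- function(S, centers) {
  n <- nrow(S)
  memb <- integer(n)
  for (j in seq_len(n)) {
    best <- 1
    for (k in seq_along(centers))
      if (S[j, centers[k]] < S[j, centers[best]]) best <- k
    memb[j] <- best
  }
  for (k in seq_along(centers)) memb[centers[k]] <- k
  memb
}

oracleCommunityRep <- function(Z, S, centers, memb, eps) {
  M <- length(centers)
  out <- matrix(0, M, ncol(Z))
  for (i in seq_len(M)) {
    acc <- Z[centers[i], ]
    for (j in seq_len(nrow(Z))) {
      if (memb[j] == i && j != centers[i])
        acc <- acc + Z[j, ] / (S[centers[i], j] + eps)
    }
    out[i, ] <- acc
  }
  out
}

oracleCoarsen <- function(A, memb, M) {
  out <- matrix(0, M, M)
  for (k in seq_len(M)) for (l in seq_len(M)) {
    tot <- 0
    for (i in which(memb == k)) for (j in which(memb == l))
      if (!(k == l && i == j)) tot <- tot + A[i, j]
    out[k, l] <- tot
  }
  out
}

oracleCommunityLoss <- function(Z, centers, memb) {
  tot <- 0
  for (i in seq_along(centers)) for (j in which(memb == i)) {
    if (j == centers[i]) next
    tot <- tot + mean((Z[j, ] - Z[centers[i], ])^2)
  }
  tot
}

# shared fixture for the heavier acceptance checks (built once per run)
.fixtures <- new.env(parent = emptyenv())

referenceCrossVal <- function() {
  if (is.null(.fixtures$cv)) {
    cohort <- makeCohort(synthConfig(seed = 0))
    mc <- modelConfig(numPoolingModules = 2L, poolingRatio = 0.5, seed = 0)
    .fixtures$cohort <- cohort
    .fixtures$cv <- crossValidate(cohort, mc, trainConfig(seed = 0),
                                  returnModels = TRUE)
  }
  list(cohort = .fixtures$cohort, cv = .fixtures$cv)
}
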