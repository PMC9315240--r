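test_that("pairwiseDistance computes L1 distances", {
  Z <- matrix(c(0, 1, 3), 3, 1)
  expect_equal(pairwiseDistance(Z),
               matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3))
  Zc <- matrix(1, 4, 3)
  expect_equal(pairwiseDistance(Zc), matrix(0, 4, 4))
  set.seed(20)
  Z <- matrix(rnorm(24), 8, 3)
  expect_equal(pairwiseDistance(Z), oraclePairwiseL1(Z))
  # l2 option
  expect_equal(pairwiseDistance(Z, "l2")[1, 2],
               sqrt(sum((Z[1, ] - Z[2, ])^2)))
})

test_that("centerProbability favors dense nodes and sums to one", {
  # degenerate: all features identical -> uniform
  expect_equal(centerProbability(matrix(0, 5, 5)), rep(0.2, 5))
  # hand computation: rows 0,1,3 -> row sums (4,3,5), softmax(1-minmax)
  S <- pairwiseDistance(matrix(c(0, 1, 3), 3, 1))
  P <- centerProbability(S)
  expect_equal(P, c(0.30719589, 0.50648039, 0.18632372), tolerance = 1e-7)
  expect_true(P[2] > P[1] && P[1] > P[3])
  set.seed(21)
  for (i in 1:20) {
    S <- pairwiseDistance(matrix(rnorm(30), 10, 3))
    expect_equal(sum(centerProbability(S)), 1, tolerance = 1e-8)
  }
})

test_that("selectCenters keeps ceil(ratio N) nodes with index tie-breaks", {
  P <- c(0.1, 0.4, 0.2, 0.3)
  expect_equal(selectCenters(P, 1.0), c(2L, 4L, 3L, 1L))
  expect_length(selectCenters(runif(5), 0.5), 3L)      # ceil(2.5)
  expect_equal(selectCenters(rep(0.25, 4), 0.5), c(1L, 2L))
  expect_error(selectCenters(P, 0), "ratio")
})

test_that("selectCenters matches a sort-then-slice oracle with duplicates", {
  set.seed(22)
  for (i in 1:1000) {
    n <- sample(1:50, 1)
    P <- if (runif(1) < 0.5) runif(n) else
      sample(c(0.1, 0.2, 0.3), n, replace = TRUE)  # force duplicates
    ratio <- sample(c(0.25, 0.5, 0.75, 1), 1)
    expect_identical(selectCenters(P, ratio),
                     as.integer(oracleSelectCenters(P, ratio)))
  }
})

test_that("assignMembers sends nodes to the nearest center, ties to rank", {
  Z <- matrix(c(0, 10, 5), 3, 1)          # node 3 equidistant from 1 and 2
  S <- pairwiseDistance(Z)
  part <- assignMembers(S, centers = c(1L, 2L))
  expect_equal(part$membership, c(1L, 2L, 1L))
  # single center: one community
  part1 <- assignMembers(S, centers = 2L)
  expect_equal(part1$membership, rep(1L, 3))
  # coincident centers still own themselves
  S0 <- matrix(0, 3, 3)
  p0 <- assignMembers(S0, centers = c(2L, 3L))
  expect_equal(p0$membership[2], 1L)
  expect_equal(p0$membership[3], 2L)
  expect_error(assignMembers(S, integer(0)), "nonempty")
})

test_that("assignMembers matches the exhaustive argmin oracle", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    S <- pairwiseDistance(matrix(rnorm(n * 3), n, 3))
    centers <- sample(n, 4)
    expect_equal(assignMembers(S, centers)$membership,
                 oracleAssign(S, centers))
  }
})

test_that("communityRepresentation anchors on centers", {
  # all singleton communities: representation = center rows exactly
  set.seed(24)
  Z <- matrix(rnorm(12), 4, 3)
  S <- pairwiseDistance(Z)
  part <- assignMembers(S, centers = 1:4)
  expect_identical(communityRepresentation(Z, S, part, eps = 1e-6),
                   Z[part$centers, ])

  # hand computation: center (1,0), member (1,2) at L1 distance 2
  Z2 <- matrix(c(1, 1, 0, 2), 2, 2)
  S2 <- pairwiseDistance(Z2)
  part2 <- assignMembers(S2, centers = 1L)
  expect_equal(communityRepresentation(Z2, S2, part2, eps = 0),
               matrix(c(1.5, 1), 1, 2))

  # duplicate rows stay finite under the eps guard
  Z3 <- matrix(1, 3, 2)
  S3 <- pairwiseDistance(Z3)
  part3 <- assignMembers(S3, centers = 1L)
  expect_true(all(is.finite(communityRepresentation(Z3, S3, part3, 1e-6))))
})

test_that("coarsenAdjacency conserves off-diagonal mass", {
  # ratio-1 identity coarsening zeroes the diagonal
  set.seed(25)
  A <- randomSymAdj(5); diag(A) <- runif(5)
  S <- pairwiseDistance(matrix(rnorm(15), 5, 3))
  idPart <- assignMembers(S, 1:5)
  Aid <- coarsenAdjacency(A, idPart)
  expect_equal(Aid, A - diag(diag(A)))

  # 4-node graph, unit edges everywhere, two 2-node communities
  A4 <- matrix(1, 4, 4); diag(A4) <- 0
  part <- list(centers = c(1L, 3L), membership = c(1L, 1L, 2L, 2L))
  expect_equal(coarsenAdjacency(A4, part), matrix(c(2, 4, 4, 2), 2, 2))

  for (i in 1:20) {
    n <- sample(4:15, 1)
    A <- randomSymAdj(n); diag(A) <- runif(n)
    S <- pairwiseDistance(matrix(rnorm(n * 2), n, 2))
    centers <- selectCenters(centerProbability(S), 0.5)
    part <- assignMembers(S, centers)
    Ac <- coarsenAdjacency(A, part)
    expect_equal(sum(Ac), sum(A) - sum(diag(A)), tolerance = 1e-8)
    expect_lt(max(abs(Ac - t(Ac))), 1e-10)
  }
})

test_that("readout is a weighted ReLU combination of community features", {
  set.seed(26)
  Zhat <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(readout(Zhat, rep(1 / 4, 4)), colMeans(Zhat))
  expect_equal(readout(Zhat, c(0, 0, 1, 0)), Zhat[3, ])
  expect_equal(readout(Zhat, rep(0, 4)), rep(0, 3))
  expect_error(readout(Zhat, rep(1, 5)), "length")
})

test_that("poolGraph keeps exactly ceil(ratio N) nodes at every call", {
  set.seed(27)
  for (ratio in c(0.25, 0.5, 0.75, 1.0)) {
    for (i in 1:10) {
      n <- sample(2:40, 1)
      Z <- matrix(rnorm(n * 3), n, 3)
      step <- poolGraph(Z, randomSymAdj(n), ratio = ratio)
      expect_equal(nrow(step$features), ceiling(ratio * n))
      expect_equal(length(step$partition$centers), ceiling(ratio * n))
      tab <- tabulate(step$partition$membership,
                      length(step$partition$centers))
      expect_equal(sum(tab), n)  # every node in exactly one community
    }
  }
})

test_that("pooling is equivariant: permuted nodes give the same multiset of
           community representations", {
  set.seed(28)
  for (i in 1:10) {
    n <- 12
    Z <- matrix(rnorm(n * 3), n, 3)
    A <- randomSymAdj(n)
    perm <- sample(n)
    a <- poolGraph(Z, A, 0.5)
    b <- poolGraph(Z[perm, , drop = FALSE], A[perm, perm], 0.5)
    sortRows <- function(M) M[do.call(order, as.data.frame(M)), , drop = FALSE]
    expect_lt(max(abs(sortRows(a$features) - sortRows(b$features))), 1e-6)
  }
})

test_that("parent maps across three stacked pools cover the atlas exactly", {
  set.seed(29)
  n <- 24
  Z <- matrix(rnorm(n * 4), n, 4)
  A <- randomSymAdj(n)
  root <- seq_len(n); aset <- as.list(seq_len(n))
  for (t in 1:3) {
    step <- poolGraph(Z, A, 0.5, atlasRoot = root, atlasSet = aset)
    cover <- sort(unlist(step$atlasSet))
    expect_identical(cover, seq_len(n))            # disjoint-union complete
    expect_true(all(lengths(step$atlasSet) >= 1L))
    expect_true(all(step$atlasRoot %in% seq_len(n)))
    # the lineage root of each coarse node lies inside its own cover set
    for (m in seq_along(step$atlasRoot))
      expect_true(step$atlasRoot[m] %in% step$atlasSet[[m]])
    Z <- step$features; A <- step$adjacency
    root <- step$atlasRoot; aset <- step$atlasSet
  }
})

test_that("community representation matches the brute-force oracle", {
  set.seed(30)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    Z <- matrix(rnorm(n * 3), n, 3)
    S <- pairwiseDistance(Z)
    centers <- selectCenters(centerProbability(S), 0.5)
    part <- assignMembers(S, centers)
    expect_equal(communityRepresentation(Z, S, part, 1e-6),
                 oracleCommunityRep(Z, S, part$centers, part$membership, 1e-6),
                 tolerance = 1e-10)
  }
})
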