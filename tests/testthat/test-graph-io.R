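test_that("loadMatrix parses delimited matrices exactly as stored", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1", "1,0"), p)
  expect_equal(loadMatrix(p), matrix(c(0, 1, 1, 0), 2, 2))

  # whitespace autodetection, asymmetric content kept as-is
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 2.5 0", "1 0 0", "0 0 3"), p2)
  M <- loadMatrix(p2)
  expect_equal(M[1, 2], 2.5)
  expect_equal(M[2, 1], 1)  # no silent symmetrization
})

test_that("loadMatrix rejects malformed files with line diagnostics", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "4,5"), p)
  expect_error(loadMatrix(p), "line 2")
  writeLines(c("1,2", "3,oops"), p)
  expect_error(loadMatrix(p), "non-numeric.*line 2")
  expect_error(loadMatrix(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("a 246-node atlas matrix round-trips through write/load", {
  set.seed(5)
  A <- randomSymAdj(246, density = 0.2)
  p <- withr::local_tempfile(fileext = ".csv")
  writeMatrix(A, p)
  B <- loadMatrix(p)
  expect_identical(dim(B), c(246L, 246L))
  expect_identical(B, A)  # %.17g round-trip is bit-exact for doubles
})

test_that("BrainGraph validity enforces symmetry, nonnegativity, shapes", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  g <- BrainGraph(A, targets = c(score = 1.5))
  expect_equal(nodeFeatures(g), matrix(1, 2, 1))
  Abad <- A; Abad[1, 2] <- 2
  expect_error(BrainGraph(Abad), "symmetric")
  expect_equal(adjacency(BrainGraph(Abad, symmetrize = TRUE))[1, 2], 1.5)
  Aneg <- A; Aneg[1, 2] <- Aneg[2, 1] <- -1
  expect_error(BrainGraph(Aneg), "negative")
  expect_equal(adjacency(BrainGraph(Aneg, clipNegative = TRUE))[1, 2], 0)
  expect_error(BrainGraph(A, nodeFeatures = matrix(0, 3, 1)), "rows")
  expect_error(BrainGraph(A, targets = c(score = NaN)), "finite")
})

writeToyCohort <- function(dir, ids = c("s1", "s2", "s3"), withFunc = FALSE) {
  dir.create(dir, showWarnings = FALSE)
  for (id in ids) {
    A <- randomSymAdj(4)
    writeMatrix(A, file.path(dir, paste0(id, ".csv")))
    if (withFunc)
      writeMatrix(matrix(rnorm(16), 4, 4),
                  file.path(dir, paste0(id, "_func.csv")))
  }
  allIds <- c(ids, "ghost")
  man <- data.frame(subject_id = allIds,
                    group = rep(c("A", "B"), length.out = length(allIds)),
                    attn = seq(1.2, by = 2.2, length.out = length(allIds)))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  file.path(dir, "manifest.csv")
}

test_that("buildCohort excludes missing-matrix subjects without crashing", {
  dir <- withr::local_tempdir()
  man <- writeToyCohort(dir)
  expect_message(
    cohort <- buildCohort(man, dir, featureMode = "ones"),
    "1 subject")
  expect_equal(length(cohort), 3L)
  expect_equal(exclusions(cohort), "ghost")
  expect_equal(ncol(nodeFeatures(cohort[[1]])), 1L)
  expect_true(all(nodeFeatures(cohort[[2]]) == 1))
})

test_that("functional feature mode yields d = N node features", {
  dir <- withr::local_tempdir()
  man <- writeToyCohort(dir, ids = c("s1", "s2"), withFunc = TRUE)
  cohort <- buildCohort(man, dir, featureMode = "functional")
  expect_equal(ncol(nodeFeatures(cohort[[1]])), atlasSize(cohort))
  expect_equal(length(cohort), 2L)
})

test_that("an empty cohort after exclusions is an error", {
  dir <- withr::local_tempdir()
  man <- data.frame(subject_id = "nobody", score = 1)
  mp <- file.path(dir, "m.csv")
  write.csv(man, mp, row.names = FALSE)
  expect_error(suppressMessages(buildCohort(mp, dir, featureMode = "ones")),
               "empty cohort")
})

test_that("targets stay aligned to subject ids under manifest shuffling", {
  dir <- withr::local_tempdir()
  ids <- sprintf("s%02d", 1:6)
  for (id in ids) writeMatrix(randomSymAdj(3), file.path(dir, paste0(id, ".csv")))
  scores <- seq(10, 60, by = 10)
  man <- data.frame(subject_id = ids, attn = scores)
  shuffled <- man[sample(nrow(man)), ]
  mp <- file.path(dir, "m.csv")
  write.csv(shuffled, mp, row.names = FALSE)
  cohort <- buildCohort(mp, dir, featureMode = "ones")
  got <- targetVector(cohort)
  expect_equal(got, scores[match(subjectId(cohort), ids)])
})

test_that("full-rank PCA projection is an isometry and k reduces dimension", {
  set.seed(2)
  samples <- lapply(1:4, function(i)
    BrainGraph(randomSymAdj(6), matrix(rnorm(6 * 5), 6, 5),
               subjectId = paste0("s", i), targets = c(y = i)))
  cohort <- Cohort(samples)
  full <- reduceFeatures(cohort, k = 5L)
  d0 <- dist(nodeFeatures(cohort[[2]]))
  d1 <- dist(nodeFeatures(full[[2]]))
  expect_lt(max(abs(d0 - d1)), 1e-6)

  red <- reduceFeatures(cohort, k = 2L)
  expect_equal(ncol(nodeFeatures(red[[1]])), 2L)
  expect_error(reduceFeatures(cohort, k = 6L), "exceeds")
  expect_error(reduceFeatures(cohort, k = 0L), ">= 1")
})

test_that("PCA on 30-dim synthetic features reduces to k = 10", {
  set.seed(3)
  samples <- lapply(1:5, function(i)
    BrainGraph(randomSymAdj(8), matrix(rnorm(8 * 30), 8, 30),
               subjectId = paste0("s", i), targets = c(y = 0)))
  red <- reduceFeatures(Cohort(samples), k = 10L)
  expect_equal(ncol(nodeFeatures(red[[3]])), 10L)
})

test_that("rank-1 features are fully explained by one component", {
  set.seed(4)
  base <- rnorm(7)
  samples <- lapply(1:3, function(i)
    BrainGraph(randomSymAdj(5), outer(rnorm(5), base),
               subjectId = paste0("s", i), targets = c(y = 0)))
  cohort <- Cohort(samples)
  red <- reduceFeatures(cohort, k = 1L)
  totalVar <- sum(apply(do.call(rbind, lapply(cohort@samples, nodeFeatures)),
                        2, var))
  keptVar <- var(as.vector(do.call(rbind, lapply(red@samples, nodeFeatures))))
  expect_gt(keptVar / totalVar, 0.999)
})

test_that("writeCohortDir and buildCohort round-trip a synthetic cohort", {
  cohort <- makeCohort(synthConfig(nSubjects = 4L, nNodes = 10L, seed = 9))
  dir <- withr::local_tempdir()
  writeCohortDir(cohort, dir)
  back <- buildCohort(file.path(dir, "manifest.csv"), dir,
                      featureMode = "functional")
  expect_equal(length(back), 4L)
  expect_equal(adjacency(back[[2]]), adjacency(cohort[[2]]))
  expect_equal(nodeFeatures(back[[3]]), nodeFeatures(cohort[[3]]))
  expect_equal(targetVector(back), targetVector(cohort))
})
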