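#' @import methods
#' @importFrom stats dist prcomp rnorm rexp runif sd
#' @importFrom utils head read.csv write.table
#' @useDynLib connectopool, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.SYM_TOL <- 1e-8

#' BrainGraph: one subject's weighted network
#'
#' Container for a single subject: a square, symmetric, nonnegative
#' adjacency matrix (structural connectivity in arbitrary units), a node
#' feature matrix with one row per node, an optional group label, and a named
#' vector of continuous target scores.
#'
#' @slot subjectId character scalar, unique within a cohort.
#' @slot adjacency N x N numeric matrix; symmetric within 1e-8, nonnegative.
#' @slot nodeFeatures N x d numeric matrix.
#' @slot group character scalar; \code{NA} when no grouping applies.
#' @slot targets named numeric vector of regression targets; all finite.
#'
#' @export
setClass("BrainGraph",
  representation(
    subjectId    = "character",
    adjacency    = "matrix",
    nodeFeatures = "matrix",
    group        = "character",
    targets      = "numeric"
  )
)

setValidity("BrainGraph", function(object) {
  A <- object@adjacency
  msgs <- character(0)
  if (nrow(A) != ncol(A))
    msgs <- c(msgs, "adjacency must be square")
  else {
    if (max(abs(A - t(A))) > .SYM_TOL)
      msgs <- c(msgs, sprintf(
        "adjacency not symmetric within %g (max |A - t(A)| = %g)",
        .SYM_TOL, max(abs(A - t(A)))))
    if (any(A < 0))
      msgs <- c(msgs, "adjacency has negative entries")
  }
  if (!all(is.finite(A)))
    msgs <- c(msgs, "adjacency has non-finite entries")
  if (nrow(object@nodeFeatures) != nrow(A))
    msgs <- c(msgs, sprintf("nodeFeatures has %d rows but adjacency has %d",
                            nrow(object@nodeFeatures), nrow(A)))
  if (!all(is.finite(object@nodeFeatures)))
    msgs <- c(msgs, "nodeFeatures has non-finite entries")
  if (length(object@targets) > 0) {
    if (is.null(names(object@targets)) || any(!nzchar(names(object@targets))))
      msgs <- c(msgs, "targets must be a named vector")
    if (!all(is.finite(object@targets)))
      msgs <- c(msgs, "targets must all be finite")
  }
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msgs <- c(msgs, "subjectId must be a non-empty character scalar")
  if (length(object@group) != 1L)
    msgs <- c(msgs, "group must be a character scalar (possibly NA)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BrainGraph
#'
#' @param adjacency square numeric matrix of nonnegative edge weights.
#' @param nodeFeatures numeric matrix with one row per node; defaults to an
#'   N x 1 all-ones matrix (the featureless initialization).
#' @param subjectId character scalar identifier.
#' @param group optional group label.
#' @param targets named numeric vector of target scores.
#' @param symmetrize average the matrix with its transpose before
#'   validation. Off by default: asymmetric input beyond tolerance is an
#'   error unless explicitly requested.
#' @param clipNegative set negative weights to zero instead of erroring.
#' @return a validated \code{BrainGraph}.
#' @export
BrainGraph <- function(adjacency, nodeFeatures = NULL, subjectId = "subject",
                       group = NA_character_, targets = numeric(0),
                       symmetrize = FALSE, clipNegative = FALSE) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  if (symmetrize) adjacency <- (adjacency + t(adjacency)) / 2
  if (clipNegative) adjacency[adjacency < 0] <- 0
  if (is.null(nodeFeatures))
    nodeFeatures <- matrix(1, nrow = nrow(adjacency), ncol = 1L)
  nodeFeatures <- as.matrix(nodeFeatures)
  storage.mode(nodeFeatures) <- "double"
  new("BrainGraph",
      subjectId = as.character(subjectId),
      adjacency = adjacency,
      nodeFeatures = nodeFeatures,
      group = as.character(group),
      targets = targets)
}

#' Cohort: an ordered collection of BrainGraph samples
#'
#' All samples share a common atlas size N; subject ids are unique. One
#' named score is the active regression target.
#'
#' @slot samples list of \code{BrainGraph}.
#' @slot atlasSize common node count N.
#' @slot scoreName name of the active regression target.
#' @slot exclusions subject ids dropped during assembly (missing files etc.).
#' @export
setClass("Cohort",
  representation(
    samples    = "list",
    atlasSize  = "integer",
    scoreName  = "character",
    exclusions = "character"
  )
)

setValidity("Cohort", function(object) {
  msgs <- character(0)
  if (length(object@samples) == 0L)
    msgs <- c(msgs, "cohort must contain at least one sample")
  if (!all(vapply(object@samples, is, logical(1), "BrainGraph")))
    msgs <- c(msgs, "all samples must be BrainGraph objects")
  else {
    ns <- vapply(object@samples, function(g) nrow(g@adjacency), integer(1))
    if (length(unique(ns)) > 1L)
      msgs <- c(msgs, "all samples must share the same atlas size")
    else if (length(ns) && ns[1] != object@atlasSize)
      msgs <- c(msgs, "atlasSize does not match the samples")
    ids <- vapply(object@samples, function(g) g@subjectId, character(1))
    if (anyDuplicated(ids))
      msgs <- c(msgs, "subject ids must be unique")
  }
  if (length(object@scoreName) != 1L)
    msgs <- c(msgs, "scoreName must be a character scalar")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Cohort from a list of BrainGraph samples
#'
#' @param samples list of \code{BrainGraph}.
#' @param scoreName active regression target; defaults to the first target
#'   name of the first sample (or NA when samples carry no targets).
#' @param exclusions optional character vector of excluded subject ids.
#' @return a validated \code{Cohort}.
#' @export
Cohort <- function(samples, scoreName = NULL, exclusions = character(0)) {
  if (is.null(scoreName)) {
    tn <- names(samples[[1]]@targets)
    scoreName <- if (length(tn)) tn[1] else NA_character_
  }
  new("Cohort",
      samples = samples,
      atlasSize = nrow(samples[[1]]@adjacency),
      scoreName = as.character(scoreName),
      exclusions = exclusions)
}
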