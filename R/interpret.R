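#' Effecting nodes of one subject
#'
#' The centers selected by the last pooling module, mapped back through the
#' hierarchy to the original atlas: each final node's identity is the atlas
#' root of its center lineage (centers persist by index through the parent
#' maps), so the set size always equals the final scale size.
#'
#' @param trace a \code{ForwardTrace} from \code{\link{forwardModel}}.
#' @return integer vector of atlas node indices.
#' @export
effectingNodes <- function(trace) {
  if (is.null(trace$atlasRoots) || !length(trace$atlasRoots))
    stop("trace lacks atlas provenance maps")
  sort(trace$atlasRoots[[length(trace$atlasRoots)]])
}

#' Effecting-node frequency profile of a group
#'
#' For every atlas node, the fraction of the group's subjects whose
#' effecting-node set contains it. Entries are exact multiples of
#' 1/n_subjects.
#'
#' @param model a \code{TrainedModel} (or list with \code{params},
#'   \code{modelConfig}).
#' @param groupSamples nonempty list of \code{BrainGraph}.
#' @param groupLabel label stored in the profile.
#' @param atlasSize atlas node count; defaults to the first sample's.
#' @return an \code{EffectingNodeProfile} list: \code{group},
#'   \code{frequency} (atlas-length vector in [0,1]), \code{nSubjects},
#'   \code{effectingSets} (per-subject index sets, reusable by the
#'   permutation test).
#' @export
nodeFrequency <- function(model, groupSamples, groupLabel = NA_character_,
                          atlasSize = NULL) {
  if (!length(groupSamples)) stop("group must be nonempty")
  if (is.null(atlasSize)) atlasSize <- nrow(adjacency(groupSamples[[1]]))
  sets <- lapply(groupSamples, function(g)
    effectingNodes(forwardModel(g, model$modelConfig, model$params)))
  freqFromSets(sets, atlasSize, groupLabel)
}

freqFromSets <- function(sets, atlasSize, groupLabel = NA_character_) {
  counts <- tabulate(unlist(sets), nbins = atlasSize)
  structure(list(group = groupLabel,
                 frequency = counts / length(sets),
                 nSubjects = length(sets),
                 effectingSets = sets),
            class = "EffectingNodeProfile")
}

#' Normalized mutual information between two frequency profiles
#'
#' Both vectors are discretized into \code{nBins} equal-width bins over
#' [0, 1]; the discrete mutual information of the node-wise joint bin
#' assignment is normalized by the arithmetic mean of the two marginal
#' entropies. Identical vectors give 1; independent ones approach 0. When
#' both marginal entropies are zero the vectors are constant: the result is
#' defined as 1 if the binned vectors are identical and 0 otherwise.
#'
#' @param freqA,freqB equal-length vectors of values in [0, 1].
#' @param nBins number of bins (>= 2).
#' @return NMI in [0, 1].
#' @export
nmiScore <- function(freqA, freqB, nBins = 10L) {
  if (length(freqA) != length(freqB)) stop("length mismatch")
  if (nBins < 2L) stop("nBins must be >= 2")
  if (inherits(freqA, "EffectingNodeProfile")) freqA <- freqA$frequency
  if (inherits(freqB, "EffectingNodeProfile")) freqB <- freqB$frequency
  binOf <- function(x) pmin(pmax(ceiling(x * nBins), 1L), nBins)
  a <- binOf(freqA); b <- binOf(freqB)
  joint <- table(factor(a, levels = seq_len(nBins)),
                 factor(b, levels = seq_len(nBins))) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  Ha <- ent(pa); Hb <- ent(pb)
  if (Ha == 0 && Hb == 0) return(if (all(a == b)) 1 else 0)
  mi <- 0
  for (i in seq_len(nBins)) for (j in seq_len(nBins)) {
    pij <- joint[i, j]
    if (pij > 0) mi <- mi + pij * log(pij / (pa[i] * pb[j]))
  }
  denom <- (Ha + Hb) / 2
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

#' Permutation test for a group difference in effecting-node profiles
#'
#' The observed statistic is the NMI between the two groups' frequency
#' profiles; low NMI means the profiles are dissimilar. Each permutation
#' reshuffles the pooled subjects into pseudo-groups of the original sizes
#' and recomputes the NMI; the one-sided lower-tail p-value uses the
#' add-one estimator p = (1 + #\{null <= observed\}) / (1 + nPerm). Each
#' subject's effecting-node set is computed once and reused across
#' permutations (the forward pass does not depend on group labels).
#'
#' @param model a \code{TrainedModel}.
#' @param samplesA,samplesB the two groups (lists of \code{BrainGraph}).
#' @param nPerm number of permutations.
#' @param nBins NMI binning.
#' @param seed RNG seed for the permutations.
#' @return a \code{PermutationResult} list: \code{observedNmi},
#'   \code{nullNmis}, \code{pValue}, \code{profileA}, \code{profileB}.
#' @export
permutationTest <- function(model, samplesA, samplesB, nPerm = 100L,
                            nBins = 10L, seed = 1L) {
  if (!length(samplesA) || !length(samplesB))
    stop("both groups must be nonempty")
  if (length(samplesA) < 2L || length(samplesB) < 2L)
    warning("group size < 2: permutation test has degenerate power")
  atlasN <- nrow(adjacency(samplesA[[1]]))
  setsA <- lapply(samplesA, function(g)
    effectingNodes(forwardModel(g, model$modelConfig, model$params)))
  setsB <- lapply(samplesB, function(g)
    effectingNodes(forwardModel(g, model$modelConfig, model$params)))
  profA <- freqFromSets(setsA, atlasN, "A")
  profB <- freqFromSets(setsB, atlasN, "B")
  observed <- nmiScore(profA$frequency, profB$frequency, nBins)

  # canonical pooled order and split size, so that the null distribution --
  # and hence the p-value -- does not depend on which group is called "A"
  pooled <- c(setsA, setsB)
  pooled <- pooled[order(vapply(pooled, paste, character(1), collapse = ","))]
  nSmall <- min(length(setsA), length(setsB))
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)
  nulls <- vapply(seq_len(nPerm), function(p) {
    perm <- sample.int(length(pooled))
    fa <- freqFromSets(pooled[perm[seq_len(nSmall)]], atlasN)
    fb <- freqFromSets(pooled[perm[-seq_len(nSmall)]], atlasN)
    nmiScore(fa$frequency, fb$frequency, nBins)
  }, numeric(1))
  structure(list(observedNmi = observed, nullNmis = nulls,
                 pValue = (1 + sum(nulls <= observed)) / (1 + nPerm),
                 profileA = profA, profileB = profB),
            class = "PermutationResult")
}
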