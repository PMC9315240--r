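#' Read a connectivity matrix from delimited text
#'
#' One subject's N x N matrix, no header, comma- or whitespace-delimited
#' (autodetected unless \code{delimiter} is given). The matrix is returned
#' exactly as stored: no symmetrization, clipping, or diagonal edits.
#'
#' @param path file path.
#' @param delimiter field separator; \code{NULL} autodetects ("," if any
#'   comma occurs in the first line, otherwise whitespace).
#' @return numeric matrix.
#' @export
loadMatrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl(",", lines[1], fixed = TRUE)) "," else "[[:space:]]+"
  fields <- strsplit(trimws(lines), delimiter)
  len <- lengths(fields)
  if (length(unique(len)) > 1L) {
    bad <- which(len != len[1])[1]
    stop(sprintf("ragged rows in %s: line %d has %d fields, line 1 has %d",
                 path, bad, len[bad], len[1]))
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  badrow <- which(vapply(vals, anyNA, logical(1)))
  if (length(badrow))
    stop(sprintf("non-numeric field in %s at line %d", path, badrow[1]))
  do.call(rbind, vals)
}

#' Write a matrix as delimited text
#'
#' Values are written with \code{\%.17g} so that a
#' \code{loadMatrix}/\code{writeMatrix} round trip reproduces doubles
#' bit-comparably.
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @param delimiter field separator (default comma).
#' @export
writeMatrix <- function(mat, path, delimiter = ",") {
  rows <- apply(mat, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = delimiter))
  writeLines(rows, path)
  invisible(path)
}

#' Read a phenotype manifest
#'
#' CSV with header; requires a \code{subject_id} column, accepts an optional
#' \code{group} column, and treats every other numeric column as a score.
#'
#' @param path CSV path.
#' @return data.frame with attribute \code{"scoreColumns"}.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(man))
    stop("manifest must contain a 'subject_id' column")
  man$subject_id <- as.character(man$subject_id)
  scores <- setdiff(names(man), c("subject_id", "group"))
  scores <- scores[vapply(man[scores], is.numeric, logical(1))]
  if (!length(scores)) stop("manifest has no numeric score column")
  attr(man, "scoreColumns") <- scores
  man
}

#' Assemble a Cohort from a manifest and matrix directories
#'
#' Structural matrices are expected at \code{matrixDir/<subject_id>.<ext>}.
#' With \code{featureMode = "functional"}, the rows of a per-subject
#' functional matrix (at \code{functionalDir/<subject_id>.<ext>}) become the
#' node features (d = N); with \code{"ones"}, features are a single all-ones
#' column. \code{"pca"} loads functional features and then projects them to
#' \code{k} principal components via \code{\link{reduceFeatures}} (fitted on
#' the whole cohort; refit on training folds yourself when evaluating).
#'
#' Subjects listed in the manifest whose matrix files are missing are
#' excluded, not fatal: their ids are recorded in \code{exclusions()} of the
#' returned cohort and a count is messaged.
#'
#' @param manifest data.frame from \code{\link{readManifest}}, or a path.
#' @param matrixDir directory of structural matrices.
#' @param featureMode "functional", "ones", or "pca".
#' @param functionalDir directory of functional matrices (defaults to
#'   \code{matrixDir}; functional files may then carry a "_func" suffix
#'   before the extension to disambiguate).
#' @param scoreName active score; defaults to the first score column.
#' @param k number of principal components when \code{featureMode = "pca"}.
#' @param symmetrize,clipNegative forwarded to \code{\link{BrainGraph}}.
#' @return a \code{Cohort}.
#' @export
buildCohort <- function(manifest, matrixDir,
                        featureMode = c("functional", "ones", "pca"),
                        functionalDir = NULL, scoreName = NULL, k = NULL,
                        symmetrize = FALSE, clipNegative = FALSE) {
  featureMode <- match.arg(featureMode)
  if (is.character(manifest)) manifest <- readManifest(manifest)
  scores <- attr(manifest, "scoreColumns")
  if (is.null(scores))
    scores <- setdiff(names(manifest), c("subject_id", "group"))
  if (is.null(scoreName)) scoreName <- scores[1]
  if (is.null(functionalDir)) functionalDir <- matrixDir

  findFile <- function(dir, id, suffixes = "") {
    for (sfx in suffixes) for (ext in c("csv", "txt", "tsv", "mat.txt")) {
      p <- file.path(dir, paste0(id, sfx, ".", ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }

  samples <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    structPath <- findFile(matrixDir, id)
    funcPath <- if (featureMode %in% c("functional", "pca"))
      findFile(functionalDir, id,
               suffixes = if (identical(functionalDir, matrixDir))
                 "_func" else c("", "_func"))
    else NA_character_
    if (is.na(structPath) ||
        (featureMode %in% c("functional", "pca") && is.na(funcPath))) {
      excluded <- c(excluded, id)
      next
    }
    A <- loadMatrix(structPath)
    feats <- switch(featureMode,
      ones = matrix(1, nrow = nrow(A), ncol = 1L),
      loadMatrix(funcPath))
    tg <- unlist(manifest[i, scores, drop = FALSE])
    names(tg) <- scores
    grp <- if ("group" %in% names(manifest))
      as.character(manifest$group[i]) else NA_character_
    samples[[length(samples) + 1L]] <-
      BrainGraph(A, feats, subjectId = id, group = grp, targets = tg,
                 symmetrize = symmetrize, clipNegative = clipNegative)
  }
  if (length(excluded))
    message(length(excluded), " subject(s) excluded (missing matrix files): ",
            paste(excluded, collapse = ", "))
  if (!length(samples))
    stop("empty cohort: all ", nrow(manifest), " subjects were excluded")
  cohort <- Cohort(samples, scoreName = scoreName, exclusions = excluded)
  if (featureMode == "pca") {
    if (is.null(k)) stop("featureMode 'pca' requires k")
    cohort <- reduceFeatures(cohort, k)
  }
  cohort
}

#' Project node features onto principal components
#'
#' PCA is fitted on the stacked node-feature rows of the samples indexed by
#' \code{fitOn} (pass the training portion to avoid leakage into held-out
#' folds), then every sample's features are replaced by their k-dimensional
#' projection.
#'
#' @param cohort a \code{Cohort} with d-dimensional node features.
#' @param k number of components, 1 <= k <= d.
#' @param fitOn sample indices used to fit the projection (default: all).
#' @return the cohort with d = k features.
#' @export
reduceFeatures <- function(cohort, k, fitOn = seq_len(length(cohort))) {
  d <- ncol(nodeFeatures(cohort[[1]]))
  if (k < 1) stop("k must be >= 1")
  if (k > d) stop("k = ", k, " exceeds feature dimension d = ", d)
  stacked <- do.call(rbind, lapply(cohort@samples[fitOn], nodeFeatures))
  ctr <- colMeans(stacked)
  pc <- prcomp(stacked, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  cohort@samples <- lapply(cohort@samples, function(g) {
    g@nodeFeatures <- sweep(g@nodeFeatures, 2L, ctr) %*% rot
    g
  })
  validObject(cohort)
  cohort
}

#' Write a cohort to disk in the package's interchange format
#'
#' One structural matrix per subject (\code{<id>.csv}), optionally one
#' functional/feature matrix (\code{<id>_func.csv}) when features are not the
#' all-ones column, plus \code{manifest.csv}.
#'
#' @param cohort a \code{Cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohortDir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort@samples, function(g) {
    writeMatrix(adjacency(g), file.path(dir, paste0(subjectId(g), ".csv")))
    f <- nodeFeatures(g)
    if (!(ncol(f) == 1L && all(f == 1)))
      writeMatrix(f, file.path(dir, paste0(subjectId(g), "_func.csv")))
    c(subject_id = subjectId(g), group = groupLabel(g),
      vapply(targets(g), function(v) sprintf("%.17g", v), character(1)))
  })
  man <- do.call(rbind, rows)
  write.table(as.data.frame(man), file.path(dir, "manifest.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
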