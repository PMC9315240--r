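#' @rdname BrainGraph-class
#' @param x a \code{BrainGraph} or \code{Cohort}.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname BrainGraph-class
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname BrainGraph-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname BrainGraph-class
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname BrainGraph-class
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname Cohort-class
#' @param x a \code{Cohort}.
#' @export
setGeneric("atlasSize", function(x) standardGeneric("atlasSize"))

#' @rdname Cohort-class
#' @export
setGeneric("scoreName", function(x) standardGeneric("scoreName"))

#' @rdname Cohort-class
#' @param value replacement value.
#' @export
setGeneric("scoreName<-", function(x, value) standardGeneric("scoreName<-"))

#' @rdname Cohort-class
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

setMethod("adjacency", "BrainGraph", function(x) x@adjacency)
setMethod("nodeFeatures", "BrainGraph", function(x) x@nodeFeatures)
setMethod("subjectId", "BrainGraph", function(x) x@subjectId)
setMethod("groupLabel", "BrainGraph", function(x) x@group)
setMethod("targets", "BrainGraph", function(x) x@targets)

setMethod("atlasSize", "Cohort", function(x) x@atlasSize)
setMethod("scoreName", "Cohort", function(x) x@scoreName)
setMethod("exclusions", "Cohort", function(x) x@exclusions)
setMethod("scoreName<-", "Cohort", function(x, value) {
  stopifnot(is.character(value), length(value) == 1L)
  x@scoreName <- value
  validObject(x)
  x
})

#' @describeIn Cohort-class number of samples.
#' @export
setMethod("length", "Cohort", function(x) length(x@samples))

#' @describeIn Cohort-class extract one sample.
#' @param i sample index.
#' @export
setMethod("[[", "Cohort", function(x, i) x@samples[[i]])

#' @describeIn Cohort-class subset to a new Cohort.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "Cohort", function(x, i, j, ..., drop = FALSE) {
  new("Cohort", samples = x@samples[i], atlasSize = x@atlasSize,
      scoreName = x@scoreName, exclusions = x@exclusions)
})

#' @describeIn Cohort-class subject ids of all samples.
#' @export
setMethod("subjectId", "Cohort", function(x)
  vapply(x@samples, function(g) g@subjectId, character(1)))

#' @describeIn Cohort-class group labels of all samples.
#' @export
setMethod("groupLabel", "Cohort", function(x)
  vapply(x@samples, function(g) g@group, character(1)))

#' Active-score target vector of a cohort
#'
#' @param cohort a \code{Cohort} with a set \code{scoreName}.
#' @return numeric vector of the active score, in sample order.
#' @export
targetVector <- function(cohort) {
  sc <- scoreName(cohort)
  if (is.na(sc)) stop("cohort has no active score")
  vapply(cohort@samples, function(g) {
    if (!sc %in% names(g@targets))
      stop("subject ", g@subjectId, " lacks target '", sc, "'")
    unname(g@targets[[sc]])
  }, numeric(1))
}

setMethod("show", "BrainGraph", function(object) {
  cat(sprintf("BrainGraph '%s': %d nodes, %d feature dim(s)%s\n",
              object@subjectId, nrow(object@adjacency),
              ncol(object@nodeFeatures),
              if (is.na(object@group)) "" else paste0(", group ", object@group)))
  if (length(object@targets))
    cat("  targets:", paste(names(object@targets),
                            signif(object@targets, 4),
                            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d subjects, atlas size %d, active score '%s'\n",
              length(object@samples), object@atlasSize, object@scoreName))
  gl <- groupLabel(object)
  if (!all(is.na(gl))) {
    tab <- table(gl, useNA = "no")
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (length(object@exclusions))
    cat("  excluded during assembly:", length(object@exclusions), "subject(s)\n")
})
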