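#' @name FeatureTable-accessors
#' @title Accessors for FeatureTable, DMMModel, ClusterAssignment and
#'   TransitionModel objects
#' @param x,object an object of the documented class
#' @param ... unused
#' @return The slot content named by the accessor.
NULL

#' @rdname FeatureTable-accessors
#' @export
setGeneric("counts", function(x, ...) standardGeneric("counts"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("taxonIDs", function(x) standardGeneric("taxonIDs"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("relativeAbundance", function(x) standardGeneric("relativeAbundance"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("dirichletAlphas", function(x) standardGeneric("dirichletAlphas"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("laplaceScore", function(x) standardGeneric("laplaceScore"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("responsibilities", function(x) standardGeneric("responsibilities"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("transitionCounts", function(x, interval) standardGeneric("transitionCounts"))

#' @rdname FeatureTable-accessors
#' @export
setMethod("counts", "FeatureTable", function(x, ...) x@counts)

#' @rdname FeatureTable-accessors
#' @export
setMethod("sampleIDs", "FeatureTable", function(x) rownames(x@counts))

#' @rdname FeatureTable-accessors
#' @export
setMethod("taxonIDs", "FeatureTable", function(x) colnames(x@counts))

#' @rdname FeatureTable-accessors
#' @export
setMethod("taxonomy", "FeatureTable", function(x) x@taxonomy)

#' @rdname FeatureTable-accessors
#' @export
setMethod("relativeAbundance", "FeatureTable", function(x)
  x@counts / rowSums(x@counts))

#' @rdname FeatureTable-accessors
#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@counts))

#' @rdname FeatureTable-accessors
#' @param i,j,drop sample/taxon index for subsetting (drop is ignored)
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  m <- x@counts[i, j, drop = FALSE]
  tx <- x@taxonomy
  if (length(tx)) tx <- tx[names(tx) %in% colnames(m)]
  methods::new("FeatureTable", counts = m, taxonomy = tx)
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d samples x %d taxa\n",
              nrow(object@counts), ncol(object@counts)))
  tot <- rowSums(object@counts)
  cat(sprintf("  sample totals: min %d, median %d, max %d\n",
              as.integer(min(tot)), as.integer(stats::median(tot)),
              as.integer(max(tot))))
  if (length(object@taxonomy))
    cat(sprintf("  taxonomy for %d taxa\n", length(object@taxonomy)))
})

#' @rdname FeatureTable-accessors
#' @export
setMethod("mixtureWeights", "DMMModel", function(x) x@weights)

#' @rdname FeatureTable-accessors
#' @export
setMethod("dirichletAlphas", "DMMModel", function(x) x@alphas)

#' @rdname FeatureTable-accessors
#' @export
setMethod("laplaceScore", "DMMModel", function(x) x@laplace)

setMethod("show", "DMMModel", function(object) {
  cat(sprintf("DMMModel: K = %d over %d taxa\n", object@K, ncol(object@alphas)))
  cat(sprintf("  logLik %.2f, Laplace score %.2f, %s after %d iterations\n",
              object@logLik, object@laplace,
              if (object@converged) "converged" else "NOT converged",
              length(object@logLikTrace)))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "), "\n")
})

#' @rdname FeatureTable-accessors
#' @export
setMethod("responsibilities", "ClusterAssignment", function(x) x@responsibilities)

#' @rdname FeatureTable-accessors
#' @export
setMethod("stateLabels", "ClusterAssignment", function(x) x@labels)

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d samples, %d components\n",
              nrow(object@responsibilities), ncol(object@responsibilities)))
  print(table(object@labels))
})

#' @rdname FeatureTable-accessors
#' @export
setMethod("transitionProbs", "TransitionModel", function(x) x@pooledProbs)

#' @rdname FeatureTable-accessors
#' @export
setMethod("transitionCounts", "TransitionModel", function(x, interval) {
  if (missing(interval)) x@pooledCounts else x@intervalCounts[[interval]]
})

setMethod("show", "TransitionModel", function(object) {
  cat(sprintf("TransitionModel: %d states, %d intervals, %d transitions\n",
              length(object@states), length(object@intervalCounts),
              sum(object@pooledCounts)))
  cat("  pooled transition probabilities:\n")
  print(round(object@pooledProbs, 3))
})
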