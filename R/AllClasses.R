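#' FeatureTable: a samples x taxa count matrix with optional taxonomy
#'
#' The universal input container of the pipeline: non-negative integer
#' counts with samples as rows and taxa (ASVs, genera, species, pathways)
#' as columns, plus an optional taxonomy lineage string per taxon.
#'
#' @slot counts numeric matrix, samples x taxa, non-negative integers,
#'   with unique row (sample) and column (taxon) names.
#' @slot taxonomy named character vector mapping taxon id to a lineage
#'   string; may be empty.
#'
#' @seealso [featureTable()], [readFeatureTable()], [rarefyTable()]
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(counts = "matrix", taxonomy = "character"))

setValidity("FeatureTable", function(object) {
  m <- object@counts
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have sample (row) and taxon (column) names")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate sample id")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate taxon id")
  }
  if (!is.numeric(m)) msg <- c(msg, "counts must be numeric")
  else {
    if (any(m < 0)) msg <- c(msg, "negative counts")
    if (any(abs(m - round(m)) > 1e-8)) msg <- c(msg, "non-integer counts")
    if (nrow(m) == 0L || ncol(m) == 0L) msg <- c(msg, "empty table")
    else if (any(rowSums(m) == 0)) msg <- c(msg, "sample with zero total count")
  }
  if (length(object@taxonomy) &&
      !all(names(object@taxonomy) %in% colnames(m)))
    msg <- c(msg, "taxonomy names must be taxon ids of the table")
  if (length(msg)) msg else TRUE
})

#' DMMModel: a fitted Dirichlet-multinomial mixture
#'
#' @slot K integer number of mixture components.
#' @slot weights numeric mixture weights, length K, summing to 1.
#' @slot alphas numeric K x n_taxa matrix of positive Dirichlet
#'   concentration parameters, one row per component.
#' @slot logLik observed-data log-likelihood at convergence.
#' @slot laplace negative log model evidence under the Laplace
#'   approximation (lower = better-supported K).
#' @slot logLikTrace per-iteration observed-data log-likelihood.
#' @slot converged logical; FALSE when max_iter was reached first.
#'
#' @exportClass DMMModel
setClass("DMMModel",
  representation(K = "integer", weights = "numeric", alphas = "matrix",
                 logLik = "numeric", laplace = "numeric",
                 logLikTrace = "numeric", converged = "logical"))

setValidity("DMMModel", function(object) {
  msg <- character()
  if (length(object@weights) != object@K || nrow(object@alphas) != object@K)
    msg <- c(msg, "weights and alphas must have K entries/rows")
  if (abs(sum(object@weights) - 1) > 1e-10)
    msg <- c(msg, "mixture weights must sum to 1")
  if (any(object@alphas <= 0)) msg <- c(msg, "alpha entries must be > 0")
  if (!is.finite(object@laplace)) msg <- c(msg, "laplace score must be finite")
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: per-sample DMM responsibilities and hard labels
#'
#' @slot responsibilities numeric samples x K matrix; rows sum to 1.
#' @slot labels integer hard component labels (argmax responsibility),
#'   named by sample id.
#'
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(responsibilities = "matrix", labels = "integer"))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@responsibilities) - 1) > 1e-10))
    msg <- c(msg, "responsibility rows must sum to 1")
  if (length(object@labels) != nrow(object@responsibilities))
    msg <- c(msg, "one label per sample required")
  if (length(msg)) msg else TRUE
})

#' TransitionModel: Markov-chain transition counts and probabilities
#'
#' Per-interval transition count matrices between community states at
#' consecutive grid timepoints, the pooled count matrix, and the pooled
#' maximum-likelihood transition probability matrix.
#'
#' @slot states character state labels (matrix row/column order).
#' @slot intervalCounts named list of K x K integer count matrices, one per
#'   consecutive timepoint interval, names like "-21->1".
#' @slot pooledCounts K x K integer matrix, sum over intervals.
#' @slot pooledProbs K x K row-stochastic matrix (rows with observations).
#' @slot intervals data.frame with columns from, to, n_subjects (subjects
#'   contributing an observed transition to that interval).
#' @slot nSkipped integer; subject-intervals skipped because one endpoint
#'   was unobserved.
#'
#' @exportClass TransitionModel
setClass("TransitionModel",
  representation(states = "character", intervalCounts = "list",
                 pooledCounts = "matrix", pooledProbs = "matrix",
                 intervals = "data.frame", nSkipped = "integer"))

setValidity("TransitionModel", function(object) {
  msg <- character()
  rs <- rowSums(object@pooledCounts)
  pr <- rowSums(object@pooledProbs)[rs > 0]
  if (length(pr) && any(abs(pr - 1) > 1e-12))
    msg <- c(msg, "pooled probability rows with observations must sum to 1")
  if (any(object@pooledCounts < 0) ||
      any(abs(object@pooledCounts - round(object@pooledCounts)) > 0))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})
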