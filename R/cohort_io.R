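#' Construct a FeatureTable
#'
#' @param counts numeric matrix of non-negative integer counts, samples as
#'   rows and taxa as columns, with unique dimnames.
#' @param taxonomy optional named character vector of lineage strings,
#'   names drawn from the taxon ids.
#' @return a validated [FeatureTable-class] object.
#' @examples
#' m <- matrix(c(10, 0, 5, 5, 0, 7), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:3), c("t1", "t2")))
#' featureTable(m)
#' @export
featureTable <- function(counts, taxonomy = character()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  methods::new("FeatureTable", counts = counts, taxonomy = taxonomy)
}

#' Read a feature count table from TSV
#'
#' Reads a tab-separated count table with an id header row and an id first
#' column. The common amplicon export orientation (taxa as rows) is the
#' default; the result is always normalized to samples x taxa.
#'
#' @param path file path of the TSV.
#' @param orientation `"taxa-rows"` (default) or `"samples-rows"`.
#' @return a validated [FeatureTable-class].
#' @export
readFeatureTable <- function(path, orientation = c("taxa-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L) stop("empty table")
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  if (!all(vapply(body, is.numeric, logical(1L))))
    stop("non-numeric counts in ", path)
  m <- as.matrix(body)
  # [.data.frame silently repairs duplicate column names; restore the
  # on-disk ids so validation can catch duplicates
  colnames(m) <- names(df)[-1L]
  rownames(m) <- ids
  if (orientation == "taxa-rows") m <- t(m)
  if (anyDuplicated(rownames(m))) stop("duplicate sample id")
  if (anyDuplicated(colnames(m))) stop("duplicate taxon id")
  featureTable(m)
}

#' Read a BIOM-format (JSON) feature table
#'
#' Read-only support for the BIOM interchange format via the biomformat
#' package; the result is normalized to the samples x taxa orientation.
#' TSV remains the primary on-disk format.
#'
#' @param path path to a BIOM 1.0 (JSON) file.
#' @return a validated [FeatureTable-class].
#' @export
readBiomTable <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))   # biom stores taxa x samples
  featureTable(m)
}

#' Write a FeatureTable to TSV
#'
#' @param x a [FeatureTable-class].
#' @param path output path.
#' @param orientation on-disk orientation; default writes taxa as rows.
#' @export
writeFeatureTable <- function(x, path,
                              orientation = c("taxa-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  m <- counts(x)
  if (orientation == "taxa-rows") {
    m <- t(m)
    idcol <- "taxon_id"
  } else idcol <- "sample_id"
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- idcol
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate a cohort design table
#'
#' A cohort design is a data.frame with one row per sample and required
#' columns `sample_id`, `subject_id`, `day` (integer day relative to
#' calving, negative = prepartum) and `habitat`; any further columns are
#' treated as covariates or phenotypes. Each (subject, day, habitat)
#' combination may occur at most once.
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame with class `"CohortDesign"` prepended.
#' @export
cohortDesign <- function(df) {
  req <- c("sample_id", "subject_id", "day", "habitat")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing design columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample id in design")
  if (any(df$day != round(df$day))) stop("day must be integer-valued")
  key <- paste(df$subject_id, df$day, df$habitat, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, day, habitat) combination in design")
  df$day <- as.integer(df$day)
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  class(df) <- c("CohortDesign", class(df))
  df
}

#' Read a cohort design / metadata table from TSV
#'
#' @param path file path of the TSV metadata table.
#' @return a validated cohort design data.frame; see [cohortDesign()].
#' @export
readCohortDesign <- function(path) {
  cohortDesign(utils::read.table(path, header = TRUE, sep = "\t",
                                 check.names = FALSE,
                                 stringsAsFactors = FALSE))
}

#' Rarefy a FeatureTable to even depth
#'
#' Subsamples every sample without replacement (multivariate
#' hypergeometric draw) to a common depth. Samples whose total is below
#' the requested depth are dropped with a warning, never padded.
#'
#' @param x a [FeatureTable-class].
#' @param depth positive integer target depth, or `"min"` (default) for
#'   the minimum sample total, the depth convention for longitudinal
#'   amplicon designs rarefied to the minimum sequence quantity.
#' @param seed integer seed making the subsampling deterministic.
#' @return a rarefied [FeatureTable-class]; every retained sample total
#'   equals `depth`.
#' @export
rarefyTable <- function(x, depth = "min", seed = 1L) {
  m <- counts(x)
  tot <- rowSums(m)
  if (identical(depth, "min")) depth <- min(tot)
  depth <- as.numeric(depth)
  if (length(depth) != 1L || !is.finite(depth) || depth <= 0)
    stop("depth must be a positive integer")
  keep <- tot >= depth
  if (!any(keep)) stop("all samples below rarefaction depth")
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(m)[!keep], collapse = ", "))
  m <- m[keep, , drop = FALSE]
  set.seed(seed)
  # multivariate hypergeometric draw per sample via sequential
  # univariate hypergeometric sampling over taxa
  out <- m
  for (i in seq_len(nrow(m))) {
    if (sum(m[i, ]) == depth) next
    remaining <- sum(m[i, ])
    to_draw <- depth
    for (j in seq_len(ncol(m))) {
      xj <- m[i, j]
      remaining <- remaining - xj
      k <- stats::rhyper(1L, xj, remaining, to_draw)
      out[i, j] <- k
      to_draw <- to_draw - k
      if (to_draw == 0L) {
        if (j < ncol(m)) out[i, (j + 1L):ncol(m)] <- 0
        break
      }
    }
  }
  featureTable(out, taxonomy(x))
}

#' Align a feature table with a design table and optional phylogeny
#'
#' Restricts samples to the table/design intersection and, when a tree is
#' supplied, records which taxa are absent from the tree tips (those taxa
#' are excluded from phylogenetic assembly analysis only).
#'
#' @param x a [FeatureTable-class].
#' @param design a cohort design data.frame ([cohortDesign()]).
#' @param tree optional rooted `ape::phylo` with tip labels matching taxon
#'   ids.
#' @return list with elements `table` (samples restricted),
#'   `design` (rows restricted, ordered as the table), `tree`,
#'   `dropped` (list of dropped sample ids on each side and taxa missing
#'   from the tree).
#' @export
alignTables <- function(x, design, tree = NULL) {
  shared <- intersect(sampleIDs(x), design$sample_id)
  if (!length(shared)) stop("empty sample intersection between table and design")
  dropped <- list(
    table_only = setdiff(sampleIDs(x), shared),
    design_only = setdiff(design$sample_id, shared),
    taxa_not_in_tree = character())
  tab <- x[match(shared, sampleIDs(x)), ]
  des <- design[match(shared, design$sample_id), , drop = FALSE]
  if (!is.null(tree)) {
    missing_taxa <- setdiff(taxonIDs(tab), tree$tip.label)
    dropped$taxa_not_in_tree <- missing_taxa
    if (length(missing_taxa))
      message(length(missing_taxa),
              " taxa absent from tree tips; excluded from assembly analysis")
  }
  list(table = tab, design = des, tree = tree, dropped = dropped)
}
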