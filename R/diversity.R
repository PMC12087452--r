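#' Bias-corrected Chao1 richness
#'
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)), with F1 and F2 the singleton and
#' doubleton counts. The bias-corrected form avoids division by zero when
#' no doubletons are present.
#'
#' @param x one sample's non-negative integer count vector.
#' @return Chao1 estimate (>= observed richness).
#' @export
chao1 <- function(x) {
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("all-zero count vector")
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' -sum p_i log p_i over taxa with positive abundance; natural log by
#' default (the convention of vegan's `diversity`).
#'
#' @param x one sample's non-negative count (or abundance) vector.
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon index in `[0, log S]`.
#' @export
shannonDiversity <- function(x, base = exp(1)) {
  if (sum(x) <= 0) stop("zero total abundance")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

#' Alpha diversity for every sample of a FeatureTable
#'
#' @param x a [FeatureTable-class].
#' @return data.frame with sample_id, chao1, shannon and observed
#'   richness.
#' @export
alphaDiversity <- function(x) {
  m <- counts(x)
  data.frame(sample_id = rownames(m),
             richness = rowSums(m > 0),
             chao1 = apply(m, 1L, chao1),
             shannon = apply(m, 1L, shannonDiversity),
             row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed on counts by
#' default (intended for rarefied tables) or on relative abundances.
#'
#' @param x a [FeatureTable-class] with at least 2 samples.
#' @param relative compute on per-sample relative abundances instead of
#'   raw counts (default FALSE; rarefy first for the count convention).
#' @return a `dist` object labelled by sample id, symmetric with zero
#'   diagonal.
#' @export
brayCurtis <- function(x, relative = FALSE) {
  m <- counts(x)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  if (any(rowSums(m) == 0)) stop("sample with zero total")
  if (relative) m <- m / rowSums(m)
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared distances (Gower centering) and
#' eigendecomposes; axes are ordered by eigenvalue, negative eigenvalues
#' are dropped from the coordinates and reported.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @param k maximum number of axes to retain (default: all positive).
#' @return list of class `"OrdinationResult"`: `points` (samples x axes),
#'   `eig` (all eigenvalues), `prop_explained` (per retained axis,
#'   relative to the sum of positive eigenvalues), `negative_eig` (number
#'   dropped).
#' @export
pcoaOrdination <- function(d, k = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3L) stop("need at least 3 samples for ordination")
  # cmdscale warns when fewer than k eigenvalues are positive; negative
  # eigenvalues are expected for non-Euclidean dissimilarities and are
  # counted and reported below
  sc <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (!length(pos)) {            # all-zero distances: degenerate but valid
    pts <- matrix(0, n, 1L, dimnames = list(attr(d, "Labels"), "Axis1"))
    out <- list(points = pts, eig = eig, prop_explained = 0,
                negative_eig = sum(eig < 0))
    class(out) <- "OrdinationResult"
    return(out)
  }
  if (!is.null(k)) pos <- pos[seq_len(min(k, length(pos)))]
  pts <- sc$points[, pos, drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_along(pos))
  rownames(pts) <- attr(d, "Labels")
  out <- list(points = pts, eig = eig,
              prop_explained = eig[pos] / sum(eig[eig > 0]),
              negative_eig = sum(eig < 0))
  class(out) <- "OrdinationResult"
  out
}

# sum over groups of within-group sums of squared distances / group size
.ssWithin <- function(d2, labels) {
  s <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' PERMANOVA (one-way, distance-based)
#'
#' Pseudo-F from the among/within decomposition of squared
#' dissimilarities, with a permutation p-value
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm) under free permutation of
#' labels, or the exact p over all distinct label arrangements when
#' `exhaustive = TRUE`.
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param labels group labels, one per sample; at least 2 groups.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all distinct permutations instead (exact
#'   test; feasible for small n). The exact p is the fraction of all
#'   arrangements, including the observed one, with F >= F_obs.
#' @param strata optional blocking factor (e.g. subject) restricting
#'   permutations to within-stratum shuffles, for repeated-measures
#'   designs.
#' @return list with `F`, `R2`, `p`, `n_perm_used`.
#' @export
permanovaTest <- function(d, labels, n_perm = 999L, seed = 1L,
                          exhaustive = FALSE, strata = NULL) {
  d <- as.matrix(stats::as.dist(d))
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per sample required")
  g <- length(unique(labels))
  if (g < 2L) stop("need at least 2 groups")
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  ss_within <- .ssWithin(d2, labels)
  ss_among <- ss_total - ss_within
  f_stat <- function(lab) {
    sw <- .ssWithin(d2, lab)
    ((ss_total - sw) / (g - 1)) / (sw / (n - g))
  }
  f_obs <- ((ss_among) / (g - 1)) / (ss_within / (n - g))
  if (exhaustive) {
    perms <- .allPermutations(n)
    f_perm <- apply(perms, 1L, function(ix) f_stat(labels[ix]))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    set.seed(seed)
    f_perm <- replicate(n_perm, {
      ix <- if (is.null(strata)) sample.int(n) else .strataPermute(strata)
      f_stat(labels[ix])
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(F = f_obs, R2 = ss_among / ss_total, p = p, n_perm_used = n_used)
}

.allPermutations <- function(n) {
  if (n > 9L) stop("exhaustive enumeration limited to n <= 9")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

.strataPermute <- function(strata) {
  ix <- seq_along(strata)
  for (s in unique(strata)) {
    w <- which(strata == s)
    ix[w] <- w[sample.int(length(w))]
  }
  ix
}

#' Intra- and inter-individual compositional variability
#'
#' Per subject: the intra-individual variability is the median
#' dissimilarity over all within-subject sample pairs (all C(n, 2) of
#' them -- 15 for a complete six-timepoint series); the inter-individual
#' variability is the median dissimilarity of that subject's samples
#' against all samples of other subjects.
#'
#' @param d `dist` or matrix of dissimilarities over samples.
#' @param design cohort design data.frame with `sample_id` and
#'   `subject_id` covering the samples of `d`.
#' @return data.frame with subject_id, n_samples, intra, inter; subjects
#'   with a single sample get `NA` intra (with a message).
#' @export
individualVariability <- function(d, design) {
  d <- as.matrix(stats::as.dist(d))
  ids <- rownames(d)
  subj <- design$subject_id[match(ids, design$sample_id)]
  if (anyNA(subj)) stop("design does not cover all samples of d")
  res <- lapply(unique(subj), function(s) {
    w <- which(subj == s)
    intra <- if (length(w) >= 2L) {
      dd <- d[w, w]
      stats::median(dd[upper.tri(dd)])
    } else NA_real_
    inter <- stats::median(d[w, which(subj != s)])
    data.frame(subject_id = s, n_samples = length(w), intra = intra,
               inter = inter)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$intra))
    message(sum(is.na(out$intra)),
            " subject(s) with <2 samples excluded from intra-variability")
  out
}
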