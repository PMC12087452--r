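#' Procrustes comparison of two ordinations
#'
#' Symmetric Procrustes superposition (both configurations centred and
#' scaled to unit trace before the optimal rotation), reporting the sum
#' of squared residuals M-squared in [0, 1], a permutation p-value
#' (rows of one configuration permuted) and per-sample residual
#' distances after superposition.
#'
#' @param ord_a,ord_b [pcoaOrdination()] results (or any objects with a
#'   `points` matrix) over shared samples; axes truncated to the common
#'   count.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `"ProcrustesResult"`: `m2`, `p`, `residuals`
#'   (named per sample), `correlation` (Procrustes correlation
#'   sqrt(1 - M2)).
#' @export
procrustesCompare <- function(ord_a, ord_b, n_perm = 999L, seed = 1L) {
  A <- ord_a$points
  B <- ord_b$points
  shared <- intersect(rownames(A), rownames(B))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  k <- min(ncol(A), ncol(B))
  A <- A[shared, seq_len(k), drop = FALSE]
  B <- B[shared, seq_len(k), drop = FALSE]
  set.seed(seed)
  pro <- vegan::protest(A, B, permutations = n_perm, symmetric = TRUE)
  res <- stats::residuals(pro)
  names(res) <- shared
  out <- list(m2 = unname(pro$ss), p = unname(pro$signif),
              residuals = res, correlation = unname(pro$t0))
  class(out) <- "ProcrustesResult"
  out
}

#' Paired comparison of Procrustes residuals
#'
#' Wilcoxon signed-rank test on matched per-sample residual vectors from
#' two Procrustes analyses (e.g. rumen-vs-phenotype and
#' feces-vs-phenotype), asking whether one compartment tracks the other
#' configuration more closely.
#'
#' @param res_a,res_b named numeric residual vectors over the same
#'   samples.
#' @return list with `p`, `statistic`, `median_difference`, `n`.
#' @export
compareResiduals <- function(res_a, res_b) {
  shared <- intersect(names(res_a), names(res_b))
  if (!length(shared)) stop("unmatched residual vectors")
  a <- res_a[shared]
  b <- res_b[shared]
  if (length(shared) < 5L)
    warning("fewer than 5 matched residuals; test underpowered")
  if (all(a == b))
    return(list(p = 1, statistic = NA_real_, median_difference = 0,
                n = length(shared)))
  wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
  list(p = wt$p.value, statistic = unname(wt$statistic),
       median_difference = stats::median(a - b), n = length(shared))
}

#' Gibbs-sampler microbial source tracking
#'
#' Estimates, for each sink sample, the mixing proportions over a set of
#' declared source communities plus an "unknown" source, by collapsed
#' Gibbs sampling over per-read source assignments. Known sources get a
#' Dirichlet prior `alpha1` on their taxon distributions; the unknown
#' source is learned from the sink reads themselves under prior `alpha2`;
#' the mixing proportions carry a flat prior of `beta` counts per source.
#' Proportions are posterior means over the post-burn-in draws, averaged
#' across independent restarts.
#'
#' @param sinks a [FeatureTable-class] of sink samples.
#' @param sources a [FeatureTable-class] of source samples (one row per
#'   declared source), taxa aligned with the sinks by taxon id (union
#'   used; missing taxa count as zero).
#' @param alpha1 Dirichlet prior on known-source taxon distributions
#'   (default 0.001).
#' @param alpha2 Dirichlet prior on the unknown source (default 10).
#'   Because the unknown source's taxon distribution is learned from the
#'   sink reads themselves, it can imitate any sink under a
#'   near-uninformative prior; a strong smoothing prior keeps it diffuse
#'   so that declared sources are preferred whenever they actually
#'   explain the sink.
#' @param beta prior counts on the mixing proportions (default 10).
#' @param burn_in Gibbs sweeps discarded per restart (default 100).
#' @param n_draws retained sweeps per restart (default 25).
#' @param restarts independent chains (default 10).
#' @param seed integer seed.
#' @return matrix sinks x (sources + "unknown") of mixing proportions,
#'   rows summing to 1.
#' @export
sourceTrack <- function(sinks, sources, alpha1 = 0.001, alpha2 = 10,
                        beta = 10, burn_in = 100L, n_draws = 25L,
                        restarts = 10L, seed = 1L) {
  taxa <- union(taxonIDs(sinks), taxonIDs(sources))
  S <- matrix(0, nrow(counts(sinks)), length(taxa),
              dimnames = list(sampleIDs(sinks), taxa))
  S[, taxonIDs(sinks)] <- counts(sinks)
  V <- matrix(0, nrow(counts(sources)), length(taxa),
              dimnames = list(sampleIDs(sources), taxa))
  V[, taxonIDs(sources)] <- counts(sources)
  n_src <- nrow(V)
  m_tax <- length(taxa)
  # known-source taxon distributions are fixed at their posterior mean
  phi <- (V + alpha1) / (rowSums(V) + alpha1 * m_tax)
  seeds <- .childSeeds(seed, paste0("restart", seq_len(restarts)))
  out <- matrix(0, nrow(S), n_src + 1L,
                dimnames = list(rownames(S),
                                c(rownames(V), "unknown")))
  for (si in seq_len(nrow(S))) {
    x <- S[si, ]
    if (sum(x) == 0) stop("zero-depth sink: ", rownames(S)[si])
    reads <- rep.int(seq_len(m_tax), x)
    n_reads <- length(reads)
    acc <- numeric(n_src + 1L)
    for (ri in seq_len(restarts)) {
      set.seed(seeds[ri] + si)
      z <- sample.int(n_src + 1L, n_reads, replace = TRUE)
      n_v <- tabulate(z, n_src + 1L)
      u <- tabulate(reads[z == n_src + 1L], m_tax)
      drawn <- numeric(n_src + 1L)
      for (sweep_i in seq_len(burn_in + n_draws)) {
        ord <- sample.int(n_reads)
        for (r in ord) {
          v_old <- z[r]
          tx <- reads[r]
          n_v[v_old] <- n_v[v_old] - 1L
          if (v_old == n_src + 1L) u[tx] <- u[tx] - 1L
          u_tot <- sum(u)
          p_known <- (n_v[seq_len(n_src)] + beta) * phi[, tx]
          p_unk <- (n_v[n_src + 1L] + beta) *
            (u[tx] + alpha2) / (u_tot + alpha2 * m_tax)
          p <- c(p_known, p_unk)
          v_new <- sample.int(n_src + 1L, 1L, prob = p)
          z[r] <- v_new
          n_v[v_new] <- n_v[v_new] + 1L
          if (v_new == n_src + 1L) u[tx] <- u[tx] + 1L
        }
        if (sweep_i > burn_in) drawn <- drawn + n_v / n_reads
      }
      acc <- acc + drawn / n_draws
    }
    out[si, ] <- acc / restarts
  }
  out
}

#' Fit covariates onto an ordination (EnvFit)
#'
#' Continuous covariates are fitted as least-squares vectors in
#' ordination space (r-squared of the projection); categorical covariates
#' as centroids (r-squared from centroid separation). Permutation
#' p-values by shuffling covariate rows. Constant covariates are
#' reported with r-squared 0 and a flag instead of an error.
#'
#' @param ordination a [pcoaOrdination()] result.
#' @param covariates data.frame of covariates, rows matching (named by)
#'   the ordination samples.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return data.frame with covariate, type (vector/factor/constant), r2,
#'   p.
#' @export
envfitCovariates <- function(ordination, covariates, n_perm = 999L,
                             seed = 1L) {
  pts <- ordination$points
  if (nrow(covariates) != nrow(pts))
    stop("covariate rows must match ordination samples")
  if (!is.null(rownames(covariates)) &&
      all(rownames(pts) %in% rownames(covariates)))
    covariates <- covariates[rownames(pts), , drop = FALSE]
  res <- lapply(names(covariates), function(v) {
    val <- covariates[[v]]
    if (length(unique(val[!is.na(val)])) < 2L)
      return(data.frame(covariate = v, type = "constant", r2 = 0,
                        p = NA_real_))
    set.seed(seed)
    ef <- vegan::envfit(pts, covariates[, v, drop = FALSE],
                        permutations = n_perm, na.rm = TRUE)
    if (!is.null(ef$vectors) && length(ef$vectors$r))
      data.frame(covariate = v, type = "vector",
                 r2 = unname(ef$vectors$r), p = unname(ef$vectors$pvals))
    else
      data.frame(covariate = v, type = "factor",
                 r2 = unname(ef$factors$r), p = unname(ef$factors$pvals))
  })
  do.call(rbind, res)
}

#' Revised insulin-sensitivity check index with beta-hydroxybutyrate
#'
#' RBHB = 1 / [log10 glucose (mg/dl) + log10 insulin (uU/ml) +
#' log10 NEFA (mmol/l) + log10 BHB (mmol/l)]. Any non-positive component
#' makes the index undefined for that sample (returned as NA).
#'
#' @param glucose,insulin,nefa,bhb numeric vectors in the units above.
#' @param base logarithm base (default 10, the original QUICKI
#'   convention).
#' @return numeric vector of RBHB values, NA where undefined.
#' @export
rbhb <- function(glucose, insulin, nefa, bhb, base = 10) {
  ok <- !is.na(glucose) & !is.na(insulin) & !is.na(nefa) & !is.na(bhb) &
    glucose > 0 & insulin > 0 & nefa > 0 & bhb > 0
  out <- rep(NA_real_, length(glucose))
  s <- log(glucose[ok], base) + log(insulin[ok], base) +
    log(nefa[ok], base) + log(bhb[ok], base)
  out[ok] <- 1 / s
  if (any(!ok))
    attr(out, "undefined") <- which(!ok)
  out
}

#' Succession-type effects on phenotype changes
#'
#' Each subject-interval carries a transition type ("stage_t->stage_t+1")
#' and a phenotype change (value at t+1 minus value at t). Types with at
#' least `min_group` subjects are compared per phenotype by
#' Kruskal-Wallis with Dunn post hoc tests (Benjamini-Hochberg adjusted).
#'
#' @param types character transition-type label per subject-interval.
#' @param deltas data.frame of phenotype changes, one column per
#'   phenotype, rows matching `types`.
#' @param min_group minimum subjects per type (default 3; smaller types
#'   are excluded with a message).
#' @return list per phenotype: `kw` ([kruskalDunn()] output) plus
#'   `significant_pairs` (Dunn pairs with adjusted p < 0.05); attribute
#'   `"excluded_types"` lists dropped types.
#' @export
successionTypeEffects <- function(types, deltas, min_group = 3L) {
  types <- as.character(types)
  tab <- table(types)
  keep <- names(tab)[tab >= min_group]
  dropped <- setdiff(names(tab), keep)
  if (length(dropped))
    message("excluded ", length(dropped), " type(s) below min_group: ",
            paste(dropped, collapse = ", "))
  if (length(keep) < 2L) stop("fewer than 2 types meet min_group")
  sel <- types %in% keep
  out <- lapply(names(deltas), function(v) {
    kw <- kruskalDunn(deltas[[v]][sel], types[sel])
    sig <- kw$posthoc[!is.na(kw$posthoc$p_adj) & kw$posthoc$p_adj < 0.05, ,
                      drop = FALSE]
    list(kw = kw, significant_pairs = sig)
  })
  names(out) <- names(deltas)
  attr(out, "excluded_types") <- dropped
  out
}
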