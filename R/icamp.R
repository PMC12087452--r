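# Phylogenetic-bin null-model partitioning of community assembly.
#
# Taxa are grouped into phylogenetic bins of at least `ds` members
# (default 24); within each bin and sample pair, the abundance-weighted
# beta mean-nearest-taxon distance (bMNTD) is standardized against a
# within-bin taxon-shuffling null (bNTI) and Bray-Curtis is standardized
# as the modified Raup-Crick metric (RC). Threshold rules then assign one
# of five assembly processes per (pair, bin): heterogeneous selection
# (HeS, bNTI > +1.96), homogeneous selection (HOS, bNTI < -1.96),
# dispersal limitation (DL, RC > +0.95), homogenizing dispersal (HD,
# RC < -0.95) and drift (the interior region).

.PROCESSES <- c("HeS", "HOS", "HD", "DL", "drift")

#' Group taxa into phylogenetic bins
#'
#' Cuts the UPGMA hierarchy of cophenetic distances into
#' `floor(n / ds)` clusters, then merges every cluster smaller than `ds`
#' into the phylogenetically nearest bin (minimum mean inter-bin
#' cophenetic distance) until all bins have at least `ds` taxa.
#' Deterministic and invariant to taxon input order.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param taxa taxa to bin (subset of the tip labels); defaults to all
#'   tips.
#' @param ds minimum number of taxa per bin (default 24, the customary
#'   bin-size limit of phylogenetic-bin null-model analysis).
#' @return list of class `"PhyloBins"`: `bins` (named list of taxon
#'   character vectors), `ds`, `diameter` (max within-bin cophenetic
#'   distance per bin).
#' @export
buildBins <- function(tree, taxa = NULL, ds = 24L) {
  if (is.null(taxa)) taxa <- tree$tip.label
  taxa <- sort(taxa)
  if (!all(taxa %in% tree$tip.label)) stop("taxa must be tree tips")
  if (ds < 2L) stop("ds must be >= 2")
  n <- length(taxa)
  if (n < ds) stop("fewer taxa than the minimum bin size")
  D <- stats::cophenetic(ape::keep.tip(tree, taxa))[taxa, taxa]
  g0 <- max(1L, n %/% as.integer(ds))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- stats::cutree(hc, k = g0)
  repeat {
    sizes <- table(cl)
    small <- names(sizes)[sizes < ds]
    if (!length(small)) break
    # merge the smallest cluster into its phylogenetically nearest bin
    s <- small[which.min(sizes[small])]
    members <- which(cl == as.integer(s))
    others <- setdiff(unique(cl), as.integer(s))
    mean_d <- vapply(others, function(o)
      mean(D[members, cl == o, drop = FALSE]), numeric(1L))
    cl[members] <- others[which.min(mean_d)]
  }
  ids <- sort(unique(cl))
  bins <- lapply(ids, function(i) taxa[cl == i])
  names(bins) <- sprintf("bin%02d", seq_along(bins))
  diameter <- vapply(bins, function(b)
    max(D[b, b]), numeric(1L))
  out <- list(bins = bins, ds = as.integer(ds), diameter = diameter)
  class(out) <- "PhyloBins"
  out
}

# abundance-weighted beta mean-nearest-taxon distance for all sample
# pairs at once; P: samples x taxa within-bin relative abundances,
# pres: list of present-taxon index vectors, D: taxon distance matrix
.bmntdAllPairs <- function(P, pres, D) {
  n <- nrow(P)
  m <- ncol(P)
  MinD <- matrix(NA_real_, n, m)
  for (s in seq_len(n)) {
    idx <- pres[[s]]
    if (length(idx))
      MinD[s, ] <- do.call(pmin, as.data.frame(D[, idx, drop = FALSE]))
  }
  T1 <- P %*% t(MinD)   # (a,b): sum_i p_ai * min-dist of taxon i into b
  0.5 * (T1 + t(T1))
}

#' Within-bin beta nearest-taxon index (bNTI)
#'
#' For every sample pair and bin: the observed abundance-weighted bMNTD
#' restricted to the bin's taxa, standardized as a z-score against
#' `n_null` within-bin taxon-label shuffles on the tree. Pairs in which a
#' sample has no bin taxa, or whose null distribution is degenerate, are
#' marked non-evaluable and carry no weight downstream.
#'
#' @param x a [FeatureTable-class].
#' @param tree rooted `ape::phylo` covering the binned taxa.
#' @param bins a [buildBins()] result.
#' @param n_null number of null shuffles (>= 100; default 1000).
#' @param seed integer seed.
#' @return long data.frame with sample_a, sample_b, bin, obs_bmntd,
#'   null_mean, null_sd, bnti, weight (mean of the pair's two relative
#'   bin abundances), evaluable.
#' @export
betaNTI <- function(x, tree, bins, n_null = 1000L, seed = 1L) {
  if (n_null < 100L) stop("n_null must be >= 100")
  m <- counts(x)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  tot <- rowSums(m)
  set.seed(seed)
  pair_idx <- which(upper.tri(diag(nrow(m))), arr.ind = TRUE)
  out <- vector("list", length(bins$bins))
  for (b in seq_along(bins$bins)) {
    taxa_b <- intersect(bins$bins[[b]], colnames(m))
    D <- stats::cophenetic(ape::keep.tip(tree, taxa_b))[taxa_b, taxa_b]
    cb <- m[, taxa_b, drop = FALSE]
    bin_tot <- rowSums(cb)
    P <- cb / ifelse(bin_tot == 0, 1, bin_tot)
    pres <- apply(cb > 0, 1L, which, simplify = FALSE)
    obs <- .bmntdAllPairs(P, pres, D)
    s1 <- matrix(0, nrow(m), nrow(m))
    s2 <- matrix(0, nrow(m), nrow(m))
    k <- ncol(D)
    for (r in seq_len(n_null)) {
      perm <- sample.int(k)
      nb <- .bmntdAllPairs(P, pres, D[perm, perm])
      s1 <- s1 + nb
      s2 <- s2 + nb^2
    }
    mu <- s1 / n_null
    sdv <- sqrt(pmax(s2 / n_null - mu^2, 0) * n_null / (n_null - 1))
    z <- (obs - mu) / sdv
    w <- outer(bin_tot / tot, bin_tot / tot, `+`) / 2
    ok <- outer(bin_tot > 0, bin_tot > 0, `&`) & is.finite(z) & sdv > 1e-12
    out[[b]] <- data.frame(
      sample_a = rownames(m)[pair_idx[, 1L]],
      sample_b = rownames(m)[pair_idx[, 2L]],
      bin = names(bins$bins)[b],
      obs_bmntd = obs[pair_idx], null_mean = mu[pair_idx],
      null_sd = sdv[pair_idx], bnti = ifelse(ok[pair_idx], z[pair_idx], NA),
      weight = w[pair_idx], evaluable = ok[pair_idx])
  }
  do.call(rbind, out)
}

#' Within-bin modified Raup-Crick metric (RC)
#'
#' For every sample pair and bin: observed within-bin Bray-Curtis
#' compared against `n_null` null assemblages that preserve each sample's
#' bin total while redistributing it over the bin's taxa with regional
#' relative-abundance probabilities. RC = 2 (fraction of null values
#' below the observed + half the ties) - 1, in [-1, 1].
#'
#' @inheritParams betaNTI
#' @return long data.frame with sample_a, sample_b, bin, obs_bray, rc,
#'   evaluable.
#' @export
raupCrick <- function(x, bins, n_null = 1000L, seed = 1L) {
  if (n_null < 100L) stop("n_null must be >= 100")
  m <- counts(x)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  set.seed(seed)
  n <- nrow(m)
  pair_idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  out <- vector("list", length(bins$bins))
  for (b in seq_along(bins$bins)) {
    taxa_b <- intersect(bins$bins[[b]], colnames(m))
    cb <- m[, taxa_b, drop = FALSE]
    bin_tot <- rowSums(cb)
    regional <- colSums(cb)
    if (sum(regional) == 0) {
      out[[b]] <- data.frame(sample_a = rownames(m)[pair_idx[, 1L]],
                             sample_b = rownames(m)[pair_idx[, 2L]],
                             bin = names(bins$bins)[b], obs_bray = NA,
                             rc = NA, evaluable = FALSE)
      next
    }
    regional <- regional / sum(regional)
    obs <- as.matrix(vegan::vegdist(cb + 1e-12, method = "bray"))
    less <- matrix(0, n, n)
    ties <- matrix(0, n, n)
    for (r in seq_len(n_null)) {
      nullcb <- t(vapply(seq_len(n), function(s) {
        if (bin_tot[s] == 0) numeric(length(taxa_b))
        else as.numeric(stats::rmultinom(1L, bin_tot[s], regional))
      }, numeric(length(taxa_b))))
      nb <- as.matrix(vegan::vegdist(nullcb + 1e-12, method = "bray"))
      less <- less + (nb < obs - 1e-12)
      ties <- ties + (abs(nb - obs) <= 1e-12)
    }
    rc <- 2 * ((less + 0.5 * ties) / n_null) - 1
    ok <- outer(bin_tot > 0, bin_tot > 0, `&`)
    out[[b]] <- data.frame(
      sample_a = rownames(m)[pair_idx[, 1L]],
      sample_b = rownames(m)[pair_idx[, 2L]],
      bin = names(bins$bins)[b],
      obs_bray = ifelse(ok[pair_idx], obs[pair_idx], NA),
      rc = ifelse(ok[pair_idx], rc[pair_idx], NA),
      evaluable = ok[pair_idx])
  }
  do.call(rbind, out)
}

#' Classify assembly processes from bNTI and RC
#'
#' Pure threshold rule per evaluable (pair, bin): bNTI < -`z_sel` gives
#' homogeneous selection, bNTI > +`z_sel` heterogeneous selection;
#' otherwise RC < -`rc_disp` homogenizing dispersal, RC > +`rc_disp`
#' dispersal limitation, and the interior is drift. Aggregate fractions
#' are weighted by the mean relative bin abundance of each pair.
#'
#' @param bnti output of [betaNTI()].
#' @param rc output of [raupCrick()].
#' @param z_sel selection threshold on |bNTI| (default 1.96).
#' @param rc_disp dispersal threshold on |RC| (default 0.95).
#' @return list of class `"AssemblyResult"`: `pair_bin` (merged long
#'   table with the per-(pair, bin) `process`), `fractions`
#'   (abundance-weighted fractions of the five processes; sums to 1),
#'   `per_bin` (per-bin process fractions, dominant process, mean
#'   weight), `pair_fractions` (per-pair weighted process fractions).
#' @export
classifyProcesses <- function(bnti, rc, z_sel = 1.96, rc_disp = 0.95) {
  key <- c("sample_a", "sample_b", "bin")
  df <- merge(bnti, rc[, c(key, "obs_bray", "rc", "evaluable")],
              by = key, suffixes = c("_bnti", "_rc"))
  df$evaluable <- df$evaluable_bnti & df$evaluable_rc
  if (any(df$evaluable & (is.na(df$bnti) | is.na(df$rc))))
    stop("missing metric for an evaluable pair")
  df$process <- NA_character_
  ev <- df$evaluable
  df$process[ev & df$bnti < -z_sel] <- "HOS"
  df$process[ev & df$bnti > z_sel] <- "HeS"
  mid <- ev & abs(df$bnti) <= z_sel
  df$process[mid & df$rc < -rc_disp] <- "HD"
  df$process[mid & df$rc > rc_disp] <- "DL"
  df$process[mid & abs(df$rc) <= rc_disp] <- "drift"
  use <- df[ev, , drop = FALSE]
  if (!nrow(use)) stop("no evaluable (pair, bin) combinations")
  wsum <- tapply(use$weight, factor(use$process, levels = .PROCESSES), sum,
                 default = 0)
  fractions <- as.numeric(wsum) / sum(use$weight)
  names(fractions) <- .PROCESSES

  per_bin <- do.call(rbind, lapply(split(use, use$bin), function(dd) {
    fr <- tapply(dd$weight, factor(dd$process, levels = .PROCESSES), sum,
                 default = 0) / sum(dd$weight)
    data.frame(bin = dd$bin[1L], t(as.numeric(fr)),
               dominant = .PROCESSES[which.max(fr)],
               mean_weight = mean(dd$weight))
  }))
  names(per_bin)[2:6] <- .PROCESSES
  rownames(per_bin) <- NULL

  pair_key <- paste(use$sample_a, use$sample_b, sep = "\r")
  pair_fractions <- do.call(rbind, lapply(split(use, pair_key), function(dd) {
    fr <- tapply(dd$weight, factor(dd$process, levels = .PROCESSES), sum,
                 default = 0) / sum(dd$weight)
    data.frame(sample_a = dd$sample_a[1L], sample_b = dd$sample_b[1L],
               t(as.numeric(fr)), weight = sum(dd$weight))
  }))
  names(pair_fractions)[3:7] <- .PROCESSES
  rownames(pair_fractions) <- NULL

  out <- list(pair_bin = df, fractions = fractions, per_bin = per_bin,
              pair_fractions = pair_fractions,
              thresholds = c(z_sel = z_sel, rc_disp = rc_disp))
  class(out) <- "AssemblyResult"
  out
}

#' Compare assembly-process fractions across succession stages
#'
#' Groups sample pairs whose two members share a stage, reports the
#' weighted process fractions within each stage, and tests per-process
#' differences across stages by Kruskal-Wallis with Dunn post hoc tests
#' (Benjamini-Hochberg adjusted) on the per-pair process fractions.
#'
#' @param result an [classifyProcesses()] `"AssemblyResult"`.
#' @param sample_stages per-sample group labels named by sample id --
#'   typically succession stages (a `SuccessionStaging` mapped over
#'   per-sample states), but any grouping works, e.g. timepoints.
#' @return list with `stage_fractions` (stage x process), `tests` (named
#'   list per process: Kruskal-Wallis and Dunn results), `n_pairs` per
#'   stage.
#' @export
compareStages <- function(result, sample_stages) {
  pf <- result$pair_fractions
  st_a <- sample_stages[pf$sample_a]
  st_b <- sample_stages[pf$sample_b]
  within <- !is.na(st_a) & !is.na(st_b) & st_a == st_b
  pf <- pf[within, , drop = FALSE]
  pf$stage <- st_a[within]
  counts_by_stage <- table(pf$stage)
  keep <- names(counts_by_stage)[counts_by_stage >= 2L]
  if (length(keep) < 2L) stop("need >= 2 stages with >= 2 within-stage pairs")
  pf <- pf[pf$stage %in% keep, , drop = FALSE]
  stage_fractions <- do.call(rbind, lapply(split(pf, pf$stage), function(dd) {
    w <- dd$weight / sum(dd$weight)
    colSums(as.matrix(dd[, .PROCESSES]) * w)
  }))
  tests <- lapply(.PROCESSES, function(pr)
    kruskalDunn(pf[[pr]], pf$stage))
  names(tests) <- .PROCESSES
  list(stage_fractions = stage_fractions, tests = tests,
       n_pairs = counts_by_stage[keep])
}
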