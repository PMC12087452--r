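#' Prevalence/abundance differential filter with Kruskal-Wallis tests
#'
#' Keeps features present in more than `prevalence_min` of samples AND
#' with mean relative abundance above `abundance_min` (the species filter
#' convention is >50% prevalence and >0.1% abundance; pathways use
#' >0.01%). Surviving features are tested across groups by
#' Kruskal-Wallis with Benjamini-Hochberg adjustment, and Dunn post hoc
#' z-tests are run on the BH-significant features.
#'
#' @param x a [FeatureTable-class] or numeric samples x features matrix
#'   (e.g. TPM pathway abundances).
#' @param groups group labels per sample (>= 2 groups), or NULL to skip
#'   the tests and filter on prevalence/abundance only.
#' @param prevalence_min prevalence threshold, strict (default 0.5).
#' @param abundance_min mean relative-abundance threshold, strict
#'   (default 0.001).
#' @param alpha BH-adjusted significance level gating the Dunn tests
#'   (default 0.05).
#' @return list of class `"DifferentialFilter"`: `surviving` (feature
#'   names passing both thresholds), `stats` (per surviving feature:
#'   prevalence, mean relative abundance, H, p, p_adj), `dunn` (named
#'   list of Dunn tables for BH-significant features), `significant`
#'   (names with p_adj < alpha).
#' @export
differentialFilter <- function(x, groups = NULL, prevalence_min = 0.5,
                               abundance_min = 0.001, alpha = 0.05) {
  m <- if (methods::is(x, "FeatureTable")) counts(x) else as.matrix(x)
  rel <- m / rowSums(m)
  prevalence <- colMeans(m > 0)
  mean_ab <- colMeans(rel)
  # strict thresholds, but a threshold of 1 keeps ubiquitous features
  surviving <- colnames(m)[prevalence > min(prevalence_min, 1 - 1e-9) &
                             mean_ab > abundance_min]
  if (!length(surviving)) {
    warning("no features pass the prevalence/abundance filter")
    out <- list(surviving = character(), stats = NULL, dunn = list(),
                significant = character())
    class(out) <- "DifferentialFilter"
    return(out)
  }
  stats_df <- data.frame(feature = surviving,
                         prevalence = prevalence[surviving],
                         mean_abundance = mean_ab[surviving],
                         H = NA_real_, p = NA_real_, p_adj = NA_real_,
                         row.names = NULL)
  dunn <- list()
  significant <- character()
  if (!is.null(groups)) {
    groups <- factor(groups)
    if (nlevels(groups) < 2L) stop("need at least 2 groups")
    kw <- lapply(surviving, function(f)
      kruskalDunn(rel[, f], groups, always_posthoc = FALSE))
    stats_df$H <- vapply(kw, `[[`, numeric(1L), "h")
    stats_df$p <- vapply(kw, `[[`, numeric(1L), "p")
    stats_df$p_adj <- stats::p.adjust(stats_df$p, "BH")
    significant <- surviving[stats_df$p_adj < alpha]
    dunn <- lapply(significant, function(f)
      kruskalDunn(rel[, f], groups)$posthoc)
    names(dunn) <- significant
  }
  out <- list(surviving = surviving, stats = stats_df, dunn = dunn,
              significant = significant)
  class(out) <- "DifferentialFilter"
  out
}

# closed-form OLS pieces of the two mediation equations from (co)variances
.mediationCoefs <- function(vs, vm, vy, csm, csy, cmy) {
  a <- csm / vs
  det <- vs * vm - csm^2
  c_prime <- (vm * csy - csm * cmy) / det
  b <- (vs * cmy - csm * csy) / det
  # total = c' + a*b equals the simple-regression slope csy/vs
  # algebraically; composing it keeps the decomposition exact in
  # floating point as well
  c(a = a, b = b, c_prime = c_prime, acme = a * b, ade = c_prime,
    total = c_prime + a * b)
}

#' Product-of-coefficients mediation analysis with bootstrap inference
#'
#' Two-equation linear mediation: mediator model
#' `pathway = a * species + e1` and outcome model
#' `phenotype = c' * species + b * pathway + e2` (both with intercepts).
#' ACME = a*b (mediated effect), ADE = c' (direct effect), and the total
#' effect c' + a*b, which for OLS equals the simple-regression slope of
#' phenotype on species exactly. Inference by nonparametric bootstrap
#' with percentile confidence intervals and two-sided percentile
#' p-values.
#'
#' @param species,pathway,phenotype numeric vectors of equal length
#'   (>= 10), no missing values.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list of class `"MediationResult"`: `estimates` (a, b, c_prime,
#'   acme, ade, total, prop_mediated), `ci` (percentile bounds for acme,
#'   ade, total), `p` (bootstrap p-values), `collinear` flag.
#' @export
mediate <- function(species, pathway, phenotype, n_boot = 1000L, seed = 1L,
                    conf = 0.95) {
  n <- length(species)
  if (length(pathway) != n || length(phenotype) != n)
    stop("inputs must have equal length")
  if (n < 10L) stop("need at least 10 observations")
  if (anyNA(species) || anyNA(pathway) || anyNA(phenotype))
    stop("missing values not allowed; complete cases required")
  vs <- stats::var(species); vm <- stats::var(pathway)
  vy <- stats::var(phenotype)
  if (vs == 0 || vm == 0 || vy == 0) stop("zero variance in an input")
  collinear <- abs(stats::cor(species, pathway)) > 0.999
  if (collinear)
    warning("species and mediator are (near-)collinear; estimates unstable")
  est <- .mediationCoefs(vs, vm, vy, stats::cov(species, pathway),
                         stats::cov(species, phenotype),
                         stats::cov(pathway, phenotype))

  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  bs <- matrix(species[idx], nrow = n)
  bm <- matrix(pathway[idx], nrow = n)
  by <- matrix(phenotype[idx], nrow = n)
  cm <- function(u, v) (colSums(u * v) - n * colMeans(u) * colMeans(v)) / (n - 1)
  vs_b <- cm(bs, bs); vm_b <- cm(bm, bm)
  csm <- cm(bs, bm); csy <- cm(bs, by); cmy <- cm(bm, by)
  a_b <- csm / vs_b
  det_b <- vs_b * vm_b - csm^2
  cp_b <- (vm_b * csy - csm * cmy) / det_b
  b_b <- (vs_b * cmy - csm * csy) / det_b
  boot <- cbind(acme = a_b * b_b, ade = cp_b, total = cp_b + a_b * b_b)

  lo <- (1 - conf) / 2
  ci <- apply(boot, 2L, stats::quantile, probs = c(lo, 1 - lo), na.rm = TRUE)
  pval <- apply(boot, 2L, function(v) {
    v <- v[is.finite(v)]
    max(2 * min(mean(v <= 0), mean(v >= 0)), 2 / (length(v) + 1))
  })
  out <- list(estimates = c(est,
                            prop_mediated = unname(est["acme"] / est["total"])),
              ci = ci, p = pval, collinear = collinear, n = n,
              n_boot = n_boot)
  class(out) <- "MediationResult"
  out
}

#' Screen all species x pathway x phenotype triples for mediation
#'
#' Applies the differential filters to the species and pathway tables,
#' standardizes surviving species (z of log10 relative abundance), and
#' tests every surviving triple with the closed-form two-equation model.
#' ACME significance is assessed by the Sobel large-sample test with
#' Benjamini-Hochberg adjustment across the screen; "mediating" triples
#' have adjusted ACME p below `alpha`, and "full" triples additionally
#' have significant direct and total effects. Results are ranked by
#' |proportion mediated| within the mediating set.
#'
#' @param species_table [FeatureTable-class] of species counts.
#' @param pathway_table numeric samples x pathways matrix (TPM-like).
#' @param phenotypes data.frame of phenotype values, rows aligned with
#'   the tables' samples.
#' @param groups optional group labels gating the differential filters.
#' @param species_prevalence_min,species_abundance_min species filter
#'   thresholds (defaults 0.5 and 0.001).
#' @param pathway_prevalence_min,pathway_abundance_min pathway filter
#'   thresholds (defaults 0.5 and 0.0001).
#' @param alpha significance level (default 0.05).
#' @return list of class `"MediationScreen"`: `results` (one row per
#'   tested triple with estimates, p-values and the mediating/full
#'   flags), `mediating`, `full` (subsets), `filters` (the two
#'   DifferentialFilter objects).
#' @export
mediationScreen <- function(species_table, pathway_table, phenotypes,
                            groups = NULL,
                            species_prevalence_min = 0.5,
                            species_abundance_min = 0.001,
                            pathway_prevalence_min = 0.5,
                            pathway_abundance_min = 0.0001,
                            alpha = 0.05) {
  samp <- intersect(sampleIDs(species_table), rownames(pathway_table))
  samp <- intersect(samp, rownames(phenotypes))
  if (!length(samp)) stop("no aligned samples across the three inputs")
  sp <- species_table[match(samp, sampleIDs(species_table)), ]
  pw <- as.matrix(pathway_table)[samp, , drop = FALSE]
  ph <- phenotypes[samp, , drop = FALSE]
  g <- if (is.null(groups)) NULL else groups[match(samp, names(groups))]

  f_sp <- differentialFilter(sp, g, species_prevalence_min,
                             species_abundance_min, alpha)
  f_pw <- differentialFilter(pw, g, pathway_prevalence_min,
                             pathway_abundance_min, alpha)
  sp_keep <- if (is.null(groups)) f_sp$surviving else f_sp$significant
  pw_keep <- if (is.null(groups)) f_pw$surviving else f_pw$significant
  if (!length(sp_keep) || !length(pw_keep)) {
    warning("empty surviving species or pathway set; nothing to screen")
    out <- list(results = NULL, mediating = NULL, full = NULL,
                filters = list(species = f_sp, pathways = f_pw))
    class(out) <- "MediationScreen"
    return(out)
  }
  Z <- speciesZScores(sp)[, sp_keep, drop = FALSE]
  usable <- colnames(Z)[apply(Z, 2L, stats::sd) > 0]
  Z <- Z[, usable, drop = FALSE]
  M <- pw[, pw_keep, drop = FALSE]
  n <- nrow(Z)

  rows <- list()
  for (s_i in colnames(Z)) for (m_i in colnames(M)) {
    s <- Z[, s_i]; m <- M[, m_i]
    vs <- stats::var(s); vm <- stats::var(m)
    if (vm == 0) next
    csm <- stats::cov(s, m)
    det <- vs * vm - csm^2
    if (det <= 0) next
    a <- csm / vs
    var_e1 <- max((vm - a^2 * vs) * (n - 1) / (n - 2), 0)
    se_a <- sqrt(var_e1 / ((n - 1) * vs))
    for (y_i in names(ph)) {
      y <- ph[[y_i]]
      vy <- stats::var(y)
      if (!is.finite(vy) || vy == 0) next
      csy <- stats::cov(s, y); cmy <- stats::cov(m, y)
      cf <- .mediationCoefs(vs, vm, vy, csm, csy, cmy)
      var_e2 <- max((vy - cf["c_prime"] * csy - cf["b"] * cmy) *
                      (n - 1) / (n - 3), 0)
      se_b <- sqrt(var_e2 * vs / det / (n - 1))
      se_cp <- sqrt(var_e2 * vm / det / (n - 1))
      se_acme <- sqrt(cf["a"]^2 * se_b^2 + cf["b"]^2 * se_a^2)
      var_et <- max((vy - cf["total"] * csy) * (n - 1) / (n - 2), 0)
      se_tot <- sqrt(var_et / ((n - 1) * vs))
      p2 <- function(stat, se) if (se == 0) NA_real_ else
        2 * stats::pnorm(-abs(stat / se))
      rows[[length(rows) + 1L]] <- data.frame(
        species = s_i, pathway = m_i, phenotype = y_i,
        acme = unname(cf["acme"]), ade = unname(cf["ade"]),
        total = unname(cf["total"]),
        prop_mediated = unname(cf["acme"] / cf["total"]),
        p_acme = p2(cf["acme"], se_acme), p_ade = p2(cf["ade"], se_cp),
        p_total = p2(cf["total"], se_tot))
    }
  }
  res <- do.call(rbind, rows)
  res$p_acme_adj <- stats::p.adjust(res$p_acme, "BH")
  res$mediating <- !is.na(res$p_acme_adj) & res$p_acme_adj < alpha
  res$full <- res$mediating & res$p_ade < alpha & res$p_total < alpha
  res <- res[order(res$mediating, abs(res$prop_mediated),
                   decreasing = TRUE), ]
  rownames(res) <- NULL
  out <- list(results = res,
              mediating = res[res$mediating, , drop = FALSE],
              full = res[res$full, , drop = FALSE],
              filters = list(species = f_sp, pathways = f_pw))
  class(out) <- "MediationScreen"
  out
}
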