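# Dirichlet-multinomial mixture machinery.
#
# Per-component density (multinomial coefficient omitted; it is constant
# across components and across K, so likelihood comparisons are unaffected):
#   log DM(x | a) = lgamma(A) - lgamma(N + A)
#                 + sum_j [lgamma(x_j + a_j) - lgamma(a_j)],  A = sum a_j

.dmLogDensity <- function(m, N, a) {
  A <- sum(a)
  lgamma(A) - lgamma(N + A) +
    rowSums(lgamma(sweep(m, 2L, a, "+"))) - sum(lgamma(a))
}

# Minka-style fixed-point update of one component's concentrations under
# responsibilities r (bound-based, so the weighted likelihood never
# drops); a few inner iterations per EM step speed up the linear tail
.dmAlphaUpdate <- function(m, N, a, r, inner = 2L,
                           lower = 1e-8, upper = 1e6) {
  for (it in seq_len(inner)) {
    A <- sum(a)
    num <- colSums(r * (digamma(sweep(m, 2L, a, "+")) -
                          rep(digamma(a), each = nrow(m))))
    den <- sum(r * (digamma(N + A) - digamma(A)))
    if (den <= 0) return(a)
    a <- pmin(pmax(a * num / den, lower), upper)
  }
  a
}

# diagonal Hessian (direct alpha parameterization) of one component's
# negative weighted log-likelihood, for the Laplace evidence
.dmHessDiag <- function(m, N, a, r) {
  A <- sum(a)
  cross <- sum(r * (trigamma(A) - trigamma(N + A)))
  h <- -(colSums(r * (trigamma(sweep(m, 2L, a, "+")) -
                        rep(trigamma(a), each = nrow(m)))) + cross)
  pmax(h, 1e-10)
}

#' Fit a Dirichlet-multinomial mixture by EM
#'
#' EM over component responsibilities with a Dirichlet-multinomial
#' likelihood per component. Concentration parameters are updated by a
#' bound-based fixed-point step (monotone in the weighted likelihood), so
#' the observed-data log-likelihood is non-decreasing across iterations.
#' Initialization is seeded k-means on relative-abundance proportions.
#'
#' @param x a [FeatureTable-class]; clustering is at whatever taxonomic
#'   level the table holds (genus for community-state typing).
#' @param K number of mixture components (1 <= K <= n_samples).
#' @param seed integer seed for the initialization.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations; reaching it raises a warning,
#'   not an error.
#' @param init optional warm start: list with `weights` (length K) and
#'   `alphas` (K x n_taxa), e.g. from a previous short run.
#' @return list with `model` ([DMMModel-class]) and `assignment`
#'   ([ClusterAssignment-class]).
#' @export
fitDMM <- function(x, K, seed = 1L, tol = 1e-8, max_iter = 300L,
                   init = NULL) {
  m <- counts(x)
  n <- nrow(m)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of samples")
  N <- rowSums(m)
  p <- m / N

  set.seed(seed)
  if (!is.null(init)) {
    alphas <- init$alphas
    w <- init$weights
    stopifnot(nrow(alphas) == K, length(w) == K)
  } else {
    if (K == 1L) {
      hard <- rep(1L, n)
    } else {
      km <- stats::kmeans(p, centers = K, nstart = 3L, iter.max = 50L)
      hard <- km$cluster
    }
    s0 <- 50   # initial concentration scale; EM re-estimates it
    alphas <- t(vapply(seq_len(K), function(k) {
      pk <- colMeans(p[hard == k, , drop = FALSE])
      pmax(pk * s0, 1e-3)
    }, numeric(ncol(m))))
    w <- tabulate(hard, K) / n
    w <- pmax(w, 1e-6); w <- w / sum(w)
  }

  trace <- numeric(0)
  r <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logp <- vapply(seq_len(K), function(k) .dmLogDensity(m, N, alphas[k, ]),
                   numeric(n))
    logp <- matrix(logp, nrow = n)
    lw <- sweep(logp, 2L, log(w), "+")
    lse <- .logRowSumExp(lw)
    ll <- sum(lse)
    trace <- c(trace, ll)
    r <- exp(lw - lse)
    if (it > 1L &&
        abs(ll - trace[it - 1L]) < tol * (abs(trace[it - 1L]) + 1)) {
      converged <- TRUE
      break
    }
    w <- pmax(colMeans(r), 1e-10)
    w <- w / sum(w)
    for (k in seq_len(K))
      alphas[k, ] <- .dmAlphaUpdate(m, N, alphas[k, ], r[, k])
  }
  if (!converged) {
    warning("EM did not converge within ", max_iter, " iterations")
    # the stored parameters were updated after the last recorded
    # likelihood: re-evaluate so logLik matches the returned parameters
    logp <- vapply(seq_len(K), function(k) .dmLogDensity(m, N, alphas[k, ]),
                   numeric(n))
    lw <- sweep(matrix(logp, nrow = n), 2L, log(w), "+")
    lse <- .logRowSumExp(lw)
    trace <- c(trace, sum(lse))
    r <- exp(lw - lse)
  }

  # Laplace approximation of the negative log model evidence:
  # -[ logL + (d/2) log 2pi - 1/2 log |H| ], H block-diagonal with the
  # per-component concentration curvature and the mixture-weight Fisher
  # information (multinomial, K-1 free parameters)
  d_free <- K * ncol(m) + (K - 1L)
  log_det_h <- 0
  for (k in seq_len(K))
    log_det_h <- log_det_h + sum(log(.dmHessDiag(m, N, alphas[k, ], r[, k])))
  if (K > 1L)
    log_det_h <- log_det_h + (K - 1) * log(n) - sum(log(w))
  ll <- trace[length(trace)]
  laplace <- -(ll + d_free / 2 * log(2 * pi) - 0.5 * log_det_h)

  rownames(alphas) <- paste0("state", seq_len(K))
  colnames(alphas) <- colnames(m)
  labels <- max.col(r, ties.method = "first")
  names(labels) <- rownames(m)
  dimnames(r) <- list(rownames(m), rownames(alphas))
  model <- methods::new("DMMModel", K = K, weights = unname(w),
                        alphas = alphas, logLik = ll, laplace = laplace,
                        logLikTrace = trace, converged = converged)
  assignment <- methods::new("ClusterAssignment", responsibilities = r,
                             labels = as.integer(labels))
  names(assignment@labels) <- rownames(m)
  list(model = model, assignment = assignment)
}

#' Select the number of DMM components by lowest Laplace score
#'
#' Fits every K on the grid with `n_init` seeded restarts and returns
#' the K minimizing the Laplace approximation score (negative log model
#' evidence; lowest is best). Restarts follow the em-EM strategy: each
#' initialization runs a short EM burst, and only the best-likelihood
#' burst is polished to convergence.
#'
#' @param x a [FeatureTable-class].
#' @param k_grid integer vector of candidate K values.
#' @param seed integer seed (expanded per K and restart).
#' @param n_init restarts per K (default 3).
#' @param burst_iter EM iterations of each exploratory restart
#'   (default 15).
#' @param ... passed to [fitDMM()] (`tol`, `max_iter`).
#' @return list with `best_k`, `scores` (data.frame K, logLik, laplace,
#'   converged) and `fits` (the best fit per K, named by K).
#' @export
selectK <- function(x, k_grid, seed = 1L, n_init = 3L, burst_iter = 15L,
                    ...) {
  if (!length(k_grid)) stop("empty K grid")
  seeds <- .childSeeds(seed, paste0("k", seq_len(length(k_grid) * n_init)))
  fits <- vector("list", length(k_grid))
  names(fits) <- as.character(k_grid)
  scores <- data.frame(K = as.integer(k_grid), logLik = NA_real_,
                       laplace = NA_real_, converged = NA)
  idx <- 0L
  for (i in seq_along(k_grid)) {
    best <- NULL
    if (n_init == 1L || k_grid[i] == 1L) {   # K = 1 has no local optima
      idx <- idx + 1L
      best <- suppressWarnings(fitDMM(x, k_grid[i], seed = seeds[idx], ...))
    } else {
      bursts <- vector("list", n_init)
      for (j in seq_len(n_init)) {
        idx <- idx + 1L
        bursts[[j]] <- suppressWarnings(
          fitDMM(x, k_grid[i], seed = seeds[idx], max_iter = burst_iter))
      }
      ll <- vapply(bursts, function(f) f$model@logLik, numeric(1L))
      top <- bursts[[which.max(ll)]]$model
      best <- suppressWarnings(
        fitDMM(x, k_grid[i], seed = seeds[idx],
               init = list(weights = top@weights, alphas = top@alphas),
               ...))
    }
    fits[[i]] <- best
    scores$logLik[i] <- best$model@logLik
    scores$laplace[i] <- best$model@laplace
    scores$converged[i] <- best$model@converged
  }
  list(best_k = k_grid[which.min(scores$laplace)], scores = scores,
       fits = fits)
}

#' Rank cluster-driver taxa of a fitted DMM
#'
#' Scores each taxon for each cluster as the Kruskal-Wallis H statistic of
#' its relative abundance across the hard clusters, multiplied by the
#' cluster's mean-abundance excess over the grand mean (signed driver
#' score); ties are broken by the cluster mean abundance. A taxon with an
#' identical distribution across clusters scores ~0 everywhere.
#'
#' @param model a [DMMModel-class].
#' @param assignment the matching [ClusterAssignment-class].
#' @param x the [FeatureTable-class] the model was fitted to.
#' @param top_n how many taxa to report per cluster (default 5).
#' @return named list, one data.frame per cluster (taxon, score, H,
#'   mean_excess, mean_abundance), ranked by score.
#' @export
driverTaxa <- function(model, assignment, x, top_n = 5L) {
  if (top_n < 1L) stop("top_n must be >= 1")
  p <- relativeAbundance(x)
  labels <- factor(stateLabels(assignment), levels = seq_len(model@K))
  H <- apply(p, 2L, function(v) {
    if (nlevels(droplevels(labels)) < 2L) return(0)
    if (stats::sd(v) == 0) return(0)
    unname(stats::kruskal.test(v, labels)$statistic)
  })
  grand <- colMeans(p)
  out <- lapply(seq_len(model@K), function(k) {
    in_k <- labels == k
    if (!any(in_k))                       # component with no hard members
      return(data.frame(taxon = character(), score = numeric(),
                        H = numeric(), mean_excess = numeric(),
                        mean_abundance = numeric()))
    mk <- colMeans(p[in_k, , drop = FALSE])
    excess <- mk - grand
    score <- H * excess
    ord <- order(-score, -mk)
    utils::head(data.frame(taxon = colnames(p)[ord], score = score[ord],
                           H = H[ord], mean_excess = excess[ord],
                           mean_abundance = mk[ord], row.names = NULL),
                top_n)
  })
  names(out) <- rownames(model@alphas)
  out
}
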