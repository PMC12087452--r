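#' Estimate Markov-chain transitions between community states
#'
#' Counts, for every pair of consecutive grid timepoints, the subjects
#' observed in state i at the earlier and state j at the later timepoint
#' (one series per subject and habitat). Subject-series missing either
#' endpoint of an interval contribute no transition to it. The pooled
#' count matrix sums all intervals and the pooled probability matrix is
#' its row-wise maximum-likelihood normalization.
#'
#' @param labels per-sample state labels: a [ClusterAssignment-class] or a
#'   vector named by sample id.
#' @param design cohort design data.frame with `sample_id`, `subject_id`,
#'   `day` and `habitat`.
#' @return a [TransitionModel-class].
#' @export
estimateTransitions <- function(labels, design) {
  if (methods::is(labels, "ClusterAssignment")) labels <- stateLabels(labels)
  if (is.null(names(labels))) stop("labels must be named by sample id")
  idx <- match(design$sample_id, names(labels))
  des <- design[!is.na(idx), , drop = FALSE]
  lab <- as.character(labels[stats::na.omit(idx)])
  states <- sort(unique(as.character(labels)))
  K <- length(states)
  grid <- sort(unique(des$day))
  if (length(grid) < 2L) stop("no observable consecutive timepoint pairs")
  series <- paste(des$subject_id, des$habitat, sep = "\r")
  key <- paste(series, des$day, sep = "\r")
  state_at <- function(s, d) {
    w <- match(paste(s, d, sep = "\r"), key)
    ifelse(is.na(w), NA_character_, lab[w])
  }
  all_series <- unique(series)
  intervalCounts <- list()
  intervals <- data.frame(from = integer(), to = integer(),
                          n_subjects = integer())
  skipped <- 0L
  for (t in seq_len(length(grid) - 1L)) {
    from_s <- state_at(all_series, grid[t])
    to_s <- state_at(all_series, grid[t + 1L])
    ok <- !is.na(from_s) & !is.na(to_s)
    skipped <- skipped + sum(!ok)
    C <- table(factor(from_s[ok], levels = states),
               factor(to_s[ok], levels = states))
    C <- matrix(as.integer(C), K, K, dimnames = list(states, states))
    nm <- paste0(grid[t], "->", grid[t + 1L])
    intervalCounts[[nm]] <- C
    intervals <- rbind(intervals,
                       data.frame(from = grid[t], to = grid[t + 1L],
                                  n_subjects = sum(ok)))
  }
  pooled <- Reduce(`+`, intervalCounts)
  if (sum(pooled) == 0L) stop("no observable consecutive transitions")
  rs <- rowSums(pooled)
  P <- pooled / ifelse(rs == 0, 1, rs)
  methods::new("TransitionModel", states = states,
               intervalCounts = intervalCounts, pooledCounts = pooled,
               pooledProbs = P, intervals = intervals,
               nSkipped = as.integer(skipped))
}

#' Classify community states into succession stages
#'
#' Applies the self/mutual transition-rate rule to the pooled transition
#' probabilities, in order: (1) a state with self-transition rate below
#' `self_rapid` is a rapid-transition state; (2) a state with self-rate
#' at or above `self_stable` is stable -- either it exchanges with a
#' partner stable state at a reciprocal rate of at least `mutual_stable`
#' (reported in `mutual_partner`), or it stands alone, the absorbing
#' limit; (3) everything else is a transition state. Defaults
#' (0.20 / 0.50 / 0.30) follow the descriptive cutoffs of peripartum
#' succession staging (self-rates below 20% marking rapidly disappearing
#' states; stable states with self-rates near 60% and mutual rates above
#' 30%).
#'
#' @param model a [TransitionModel-class].
#' @param self_rapid upper self-rate bound of rapid-transition states.
#' @param self_stable lower self-rate bound of stable-eligible states.
#' @param mutual_stable reciprocal-rate bound between stable states.
#' @return list of class `"SuccessionStaging"`: `stages` (named character
#'   vector over states with values rapid_transition / transition /
#'   stable), `mutual_partner` (whether each state has a reciprocal
#'   partner among the high-self-rate states) and `thresholds`.
#' @export
classifyStages <- function(model, self_rapid = 0.20, self_stable = 0.50,
                           mutual_stable = 0.30) {
  P <- transitionProbs(model)
  if (any(abs(rowSums(P)[rowSums(model@pooledCounts) > 0] - 1) > 1e-8))
    stop("unnormalized transition probability matrix")
  states <- model@states
  self <- diag(P)
  eligible <- self >= self_stable
  mutual_partner <- vapply(seq_along(states), function(i) {
    others <- setdiff(which(eligible), i)
    eligible[i] && length(others) > 0L &&
      any(P[i, others] >= mutual_stable & P[others, i] >= mutual_stable)
  }, logical(1L))
  stages <- vapply(seq_along(states), function(i) {
    if (self[i] < self_rapid) return("rapid_transition")
    # a high-self-rate state is stable whether it exchanges with a
    # partner stable state (mutual rate corroborates) or stands alone
    # (the absorbing limit)
    if (eligible[i]) return("stable")
    "transition"
  }, character(1L))
  names(stages) <- names(mutual_partner) <- states
  out <- list(stages = stages, mutual_partner = mutual_partner,
              thresholds = c(self_rapid = self_rapid,
                             self_stable = self_stable,
                             mutual_stable = mutual_stable))
  class(out) <- "SuccessionStaging"
  out
}

#' Rank dominant transitions within an interval
#'
#' Shares of each observed i -> j transition among all transitions of the
#' interval (or of the pooled chain), descending; ties broken
#' lexicographically by (from, to).
#'
#' @param model a [TransitionModel-class].
#' @param interval interval name as in `model@intervalCounts` (e.g.
#'   `"-21->1"`); omit for the pooled counts.
#' @return data.frame with from, to, count, share.
#' @export
dominantTransitions <- function(model, interval) {
  C <- transitionCounts(model, interval)
  if (sum(C) == 0L) stop("no observed transitions in interval")
  df <- data.frame(from = rep(rownames(C), ncol(C)),
                   to = rep(colnames(C), each = nrow(C)),
                   count = as.vector(C))
  df <- df[df$count > 0, , drop = FALSE]
  df$share <- df$count / sum(df$count)
  df[order(-df$share, df$from, df$to), , drop = FALSE]
}

.macroAUC <- function(truth, prob) {
  truth <- factor(truth)
  aucs <- vapply(levels(truth), function(cl) {
    y <- truth == cl
    if (length(unique(y)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(FALSE, TRUE))))
  }, numeric(1L))
  mean(aucs, na.rm = TRUE)
}

.stratifiedSplit <- function(y, frac) {
  train <- integer(0)
  for (cl in levels(y)) {
    w <- which(y == cl)
    n_tr <- max(1L, round(frac * length(w)))
    train <- c(train, sample(w, n_tr))
  }
  sort(train)
}

#' Train and evaluate a succession-stage classifier
#'
#' Candidate features are taxa with mean relative abundance above
#' `abundance_min` (default 0.1%). Evaluation: `n_repeats` stratified
#' 70/30 splits; within each training set features are ranked by random
#' forest impurity importance and, when several `top_n_grid` sizes are
#' offered, the feature count is tuned by internal k-fold
#' cross-validation on the training samples; the tuned model's macro
#' one-vs-rest AUC is then measured on the held-out 30%.
#'
#' @param x a [FeatureTable-class].
#' @param stages per-sample stage labels, named by sample id (>= 2 stages,
#'   each with >= 2 samples; fewer than 10 per stage raises a warning).
#' @param abundance_min mean relative-abundance filter (default 0.001).
#' @param top_n_grid candidate numbers of top-ranked features.
#' @param n_repeats number of stratified train/test repeats (default 5).
#' @param train_frac training fraction per repeat (default 0.7).
#' @param inner_folds folds of the internal tuning CV (default 10).
#' @param n_tree random forest size (default 500).
#' @param seed integer seed.
#' @return list of class `"StageClassifierReport"`: `auc` (per repeat),
#'   `mean_auc`, `selected_top_n` (per repeat), `features` (candidate
#'   pool), `importance` (mean impurity importance of the final models,
#'   ranked).
#' @export
trainStageClassifier <- function(x, stages, abundance_min = 0.001,
                                 top_n_grid = c(10L, 25L, 50L, 100L),
                                 n_repeats = 5L, train_frac = 0.7,
                                 inner_folds = 10L, n_tree = 500L,
                                 seed = 1L) {
  p <- relativeAbundance(x)
  stages <- stages[match(rownames(p), names(stages))]
  if (anyNA(stages)) stop("stages must cover all samples, named by sample id")
  y <- factor(as.character(stages))
  if (nlevels(y) < 2L) stop("need at least 2 stages")
  tab <- table(y)
  if (any(tab < 2L)) stop("a stage has fewer than 2 samples")
  if (any(tab < 10L))
    warning("a stage has fewer than 10 samples; AUC estimates unstable")
  pool <- colnames(p)[colMeans(p) > abundance_min]
  if (length(pool) < 2L) stop("fewer than 2 features pass the abundance filter")
  X <- p[, pool, drop = FALSE]
  top_n_grid <- pmin(as.integer(top_n_grid), length(pool))
  top_n_grid <- sort(unique(top_n_grid))

  set.seed(seed)
  aucs <- numeric(n_repeats)
  chosen <- integer(n_repeats)
  imp_sum <- numeric(length(pool))
  names(imp_sum) <- pool
  for (rep_i in seq_len(n_repeats)) {
    tr <- .stratifiedSplit(y, train_frac)
    te <- setdiff(seq_along(y), tr)
    rf_rank <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                          ntree = n_tree)
    ranked <- names(sort(rf_rank$importance[, "MeanDecreaseGini"],
                         decreasing = TRUE))
    best_n <- top_n_grid[1L]
    if (length(top_n_grid) > 1L) {
      folds <- sample(rep_len(seq_len(inner_folds), length(tr)))
      cv_auc <- vapply(top_n_grid, function(nn) {
        feats <- ranked[seq_len(nn)]
        fold_auc <- vapply(seq_len(inner_folds), function(f) {
          trn <- tr[folds != f]; val <- tr[folds == f]
          if (length(val) < 2L || nlevels(droplevels(y[trn])) < 2L)
            return(NA_real_)
          fit <- randomForest::randomForest(X[trn, feats, drop = FALSE],
                                            y[trn], ntree = n_tree)
          pr <- stats::predict(fit, X[val, feats, drop = FALSE],
                               type = "prob")
          .macroAUC(y[val], pr)
        }, numeric(1L))
        mean(fold_auc, na.rm = TRUE)
      }, numeric(1L))
      best_n <- top_n_grid[which.max(cv_auc)]
    }
    feats <- ranked[seq_len(best_n)]
    fit <- randomForest::randomForest(X[tr, feats, drop = FALSE], y[tr],
                                      ntree = n_tree)
    pr <- stats::predict(fit, X[te, feats, drop = FALSE], type = "prob")
    aucs[rep_i] <- .macroAUC(y[te], pr)
    chosen[rep_i] <- best_n
    imp_sum[feats] <- imp_sum[feats] + fit$importance[, "MeanDecreaseGini"]
  }
  importance <- sort(imp_sum / n_repeats, decreasing = TRUE)
  out <- list(auc = aucs, mean_auc = mean(aucs), selected_top_n = chosen,
              features = pool,
              importance = importance[importance > 0 | seq_along(importance) <= 10])
  class(out) <- "StageClassifierReport"
  out
}
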