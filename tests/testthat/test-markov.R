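mkDesign <- function(subjects, days, habitat = "rumen") {
  grid <- expand.grid(subject_id = subjects, day = days,
                      stringsAsFactors = FALSE)
  grid$habitat <- habitat
  grid$sample_id <- paste(grid$subject_id, grid$day, sep = "_")
  cohortDesign(grid[, c("sample_id", "subject_id", "day", "habitat")])
}

test_that("transition counting matches direct path reading", {
  des <- mkDesign("c1", c(1L, 2L, 3L, 4L))
  lab <- c("A", "B", "A", "B")
  names(lab) <- des$sample_id
  tm <- estimateTransitions(lab, des)
  P <- transitionProbs(tm)
  expect_equal(P["A", "B"], 1)
  expect_equal(P["B", "A"], 1)
  expect_equal(sum(transitionCounts(tm)), 3)
})

test_that("transition counts equal the brute-force oracle on a cohort", {
  set.seed(41)
  des <- mkDesign(paste0("c", 1:5), c(-21L, 1L, 3L, 7L, 14L, 21L))
  lab <- sample(c("A", "B", "C"), nrow(des), replace = TRUE)
  names(lab) <- des$sample_id
  # knock out a few observations to exercise the skip rule
  lab <- lab[-c(3, 11, 20)]
  tm <- estimateTransitions(lab, des)
  oracle <- oracleTransitionCounts(lab, des, tm@states)
  expect_identical(transitionCounts(tm), oracle + 0L)
  expect_equal(tm@nSkipped, 25L - sum(oracle))
  rs <- rowSums(transitionCounts(tm))
  expect_true(all(abs(rowSums(transitionProbs(tm))[rs > 0] - 1) < 1e-12))
})

test_that("counts normalize to maximum-likelihood probabilities", {
  des <- mkDesign(paste0("c", 1:4), c(1L, 2L))
  lab <- c(A1 = "A", A2 = "A", A3 = "A", A4 = "A",
           B1 = "A", B2 = "B", B3 = "A", B4 = "B")
  names(lab) <- des$sample_id
  tm <- estimateTransitions(lab, des)
  expect_equal(transitionProbs(tm)["A", "A"], 0.5)
})

test_that("stage rule reproduces the self/mutual-rate thresholds", {
  mk <- function(P) {
    methods::new("TransitionModel", states = as.character(seq_len(nrow(P))),
                 intervalCounts = list(),
                 pooledCounts = matrix(10L, nrow(P), ncol(P)),
                 pooledProbs = P, intervals = data.frame(), nSkipped = 0L)
  }
  # self-rates 0.1 / 0.4 / 0.6 / 0.65, mutual 0.35 between the last two
  P <- rbind(c(0.10, 0.30, 0.30, 0.30),
             c(0.20, 0.40, 0.20, 0.20),
             c(0.02, 0.03, 0.60, 0.35),
             c(0.00, 0.00, 0.35, 0.65))
  st <- classifyStages(mk(P))
  expect_equal(unname(st$stages),
               c("rapid_transition", "transition", "stable", "stable"))
  # self-rate 0.15 -> rapid regardless of the rest
  P2 <- rbind(c(0.15, 0.85), c(0.5, 0.5))
  expect_equal(unname(classifyStages(mk(P2))$stages[1]), "rapid_transition")
  # absorbing limit: identity matrix -> all stable
  expect_true(all(classifyStages(mk(diag(3)))$stages == "stable"))
  # high self-rate states are stable with or without reciprocity, and
  # the reciprocal-partner report distinguishes the two situations
  P3 <- rbind(c(0.6, 0.4, 0), c(0.02, 0.55, 0.43), c(0.3, 0.3, 0.4))
  st3 <- classifyStages(mk(P3))
  expect_equal(unname(st3$stages), c("stable", "stable", "transition"))
  expect_false(any(st3$mutual_partner))
  st4 <- classifyStages(mk(P))
  expect_true(st4$mutual_partner[["3"]] && st4$mutual_partner[["4"]])
})

test_that("raising a self-rate never demotes a state", {
  rank <- c(rapid_transition = 1, transition = 2, stable = 3)
  mk <- function(self) {
    P <- matrix((1 - self) / 2, 3, 3)
    diag(P) <- self
    methods::new("TransitionModel", states = as.character(1:3),
                 intervalCounts = list(), pooledCounts = matrix(10L, 3, 3),
                 pooledProbs = P, intervals = data.frame(), nSkipped = 0L)
  }
  stages <- vapply(seq(0.05, 0.95, by = 0.05), function(s)
    unname(classifyStages(mk(s))$stages[1]), character(1))
  expect_true(all(diff(rank[stages]) >= 0))
})

test_that("dominant transitions rank by share with stable ties", {
  des <- mkDesign(paste0("c", 1:4), c(1L, 2L))
  lab <- c("A", "A", "A", "B", "B", "B", "B", "B")
  names(lab) <- des$sample_id                      # A->B x3, B->B x1
  lab[des$sample_id[des$day == 1]] <- c("A", "A", "A", "B")
  lab[des$sample_id[des$day == 2]] <- c("B", "B", "B", "B")
  tm <- estimateTransitions(lab, des)
  dom <- dominantTransitions(tm, "1->2")
  expect_equal(dom$share, c(0.75, 0.25))
  expect_equal(dom$from[1], "A")
  one <- dominantTransitions(tm)
  expect_equal(sum(one$share), 1)
})

test_that("stage classifier separates labelled communities and nulls", {
  set.seed(47)
  n <- 120
  # background taxa: noisy Dirichlet proportions identical in law across
  # classes, so the driver taxon carries (almost) all the class signal
  p_driver <- rep(c(0.5, 0.1), each = n / 2)
  m <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(10, 2)
    p <- c((1 - p_driver[i]) * g / sum(g), p_driver[i])
    rmultinom(1, 1000, p)[, 1]
  }, numeric(11)))
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("t", 1:11))
  tab <- featureTable(m)
  stages <- setNames(rep(c("early", "late"), each = n / 2), rownames(m))
  rep1 <- trainStageClassifier(tab, stages, top_n_grid = 5, n_repeats = 2,
                               n_tree = 200, seed = 1)
  expect_gte(rep1$mean_auc, 0.99)
  # compositional closure spreads signal over all taxa, but the driver
  # must rank among the top features
  expect_true("t11" %in% names(rep1$importance)[1:3])
  # shuffled labels give chance-level AUC
  set.seed(48)
  rep0 <- trainStageClassifier(tab, setNames(sample(stages), names(stages)),
                               top_n_grid = 5, n_repeats = 3, n_tree = 200,
                               seed = 2)
  expect_lt(abs(rep0$mean_auc - 0.5), 0.15)
  expect_error(trainStageClassifier(tab, setNames(rep("x", n), rownames(m))),
               "at least 2 stages")
  few <- stages; few[2:n] <- "late"
  expect_error(trainStageClassifier(tab, few), "fewer than 2 samples")
})
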