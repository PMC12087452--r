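test_that("procrustes M2 is 0 for congruent shapes and rigid-motion stable", {
  set.seed(83)
  A <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
  th <- pi / 7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  B <- 3 * A %*% R + 5
  pr <- procrustesCompare(list(points = A), list(points = B), n_perm = 99)
  expect_lt(pr$m2, 1e-10)
  # joint rigid motion of both configurations leaves M2 unchanged
  C <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
  base <- procrustesCompare(list(points = A), list(points = C), n_perm = 99)
  moved <- procrustesCompare(list(points = 0.5 * A %*% R + 2),
                             list(points = 0.5 * C %*% R + 2), n_perm = 99)
  expect_equal(base$m2, moved$m2, tolerance = 1e-10)
  # independent configurations: high M2, typically non-significant
  set.seed(89)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(paste0("q", 1:100), NULL))
  Y <- matrix(rnorm(200), 100, 2, dimnames = list(paste0("q", 1:100), NULL))
  ind <- procrustesCompare(list(points = X), list(points = Y), n_perm = 199)
  expect_gt(ind$m2, 0.7)
  expect_gt(ind$p, 0.05)
  expect_error(procrustesCompare(list(points = A[1:2, ]),
                                 list(points = B[1:2, ])), "at least 3")
})

test_that("residual comparison detects planted shifts only", {
  r <- abs(rnorm(50, 0.3, 0.05))
  names(r) <- paste0("s", 1:50)
  same <- compareResiduals(r, r)
  expect_equal(same$p, 1)
  shifted <- compareResiduals(r, r + 0.2)
  expect_lt(shifted$p, 0.01)
  expect_equal(shifted$median_difference, -0.2)
  expect_warning(compareResiduals(r[1:2], r[1:2] + c(0.1, 0.2)),
                 "underpowered")
  expect_error(compareResiduals(setNames(1, "a"), setNames(1, "b")),
               "unmatched")
})

test_that("source tracking recovers pure sinks and flags foreign taxa", {
  set.seed(97)
  src <- rbind(
    feces_prev = stats::rmultinom(1, 40000, prop.table(rlnorm(40, 0, 1.5)))[, 1],
    rumen_same = stats::rmultinom(1, 40000, prop.table(rlnorm(40, 0, 1.5)))[, 1])
  colnames(src) <- paste0("t", 1:40)
  p1 <- src[1, ] / sum(src[1, ])
  sink <- matrix(stats::rmultinom(1, 3000, p1)[, 1], 1,
                 dimnames = list("sink1", colnames(src)))
  st <- sourceTrack(featureTable(sink), featureTable(src), restarts = 2,
                    burn_in = 40, n_draws = 15, seed = 101)
  expect_equal(sum(st), 1, tolerance = 1e-8)
  expect_gt(st[1, "feces_prev"], 0.85)
  # reproducible given the seed
  st2 <- sourceTrack(featureTable(sink), featureTable(src), restarts = 2,
                     burn_in = 40, n_draws = 15, seed = 101)
  expect_identical(st, st2)
  # sink on taxa absent from all sources goes to unknown
  alien <- matrix(stats::rmultinom(1, 2000, rep(0.1, 10))[, 1], 1,
                  dimnames = list("alien", paste0("x", 1:10)))
  st3 <- sourceTrack(featureTable(alien), featureTable(src), restarts = 2,
                     burn_in = 40, n_draws = 15, seed = 7)
  expect_gt(st3[1, "unknown"], 0.9)
})

test_that("envfit r2 tracks ordination structure and ignores rescaling", {
  set.seed(103)
  pts <- matrix(rnorm(120), 60, 2,
                dimnames = list(paste0("s", 1:60), c("Axis1", "Axis2")))
  ord <- list(points = pts)
  cov <- data.frame(axis_clone = pts[, 1], noise = rnorm(60),
                    flat = rep(1, 60), row.names = rownames(pts))
  ef <- envfitCovariates(ord, cov, n_perm = 199, seed = 1)
  expect_gt(ef$r2[ef$covariate == "axis_clone"], 0.99)
  expect_equal(ef$p[ef$covariate == "axis_clone"], 1 / 200)
  expect_lt(ef$r2[ef$covariate == "noise"], 0.15)
  expect_equal(ef$r2[ef$covariate == "flat"], 0)
  expect_equal(ef$type[ef$covariate == "flat"], "constant")
  # affine rescaling of a continuous covariate leaves r2 unchanged
  cov2 <- data.frame(v = 100 + 42 * pts[, 1] + 0 * pts[, 2],
                     row.names = rownames(pts))
  cov3 <- data.frame(v = pts[, 1], row.names = rownames(pts))
  e2 <- envfitCovariates(ord, cov2, n_perm = 99, seed = 2)
  e3 <- envfitCovariates(ord, cov3, n_perm = 99, seed = 2)
  expect_equal(e2$r2, e3$r2, tolerance = 1e-10)
  # a factor perfectly separating samples along axis 1
  covf <- data.frame(grp = factor(pts[, 1] > 0), row.names = rownames(pts))
  ef2 <- envfitCovariates(ord, covf, n_perm = 99, seed = 3)
  expect_equal(ef2$type, "factor")
  expect_gt(ef2$r2, 0.2)
})

test_that("the insulin-sensitivity index follows the printed formula", {
  expect_equal(rbhb(100, 10, 1, 10), 0.25)
  expect_equal(rbhb(100, 10, 1, 1), 1 / 3)
  out <- rbhb(c(100, 100), c(10, 10), c(1, 0), c(10, 10))
  expect_equal(out[1], 0.25)
  expect_true(is.na(out[2]))
  expect_equal(attr(out, "undefined"), 2L)
  # natural-log option
  expect_equal(rbhb(exp(1), exp(1), exp(1), exp(1), base = exp(1)), 0.25)
})

test_that("succession-type effects flag planted shifts and filter groups", {
  set.seed(107)
  types <- rep(c("S1-S1", "S1-S2", "S2-S2"), each = 30)
  deltas <- data.frame(GLU = rnorm(90), NEFA = rnorm(90))
  deltas$NEFA[types == "S1-S2"] <- deltas$NEFA[types == "S1-S2"] + 2
  res <- successionTypeEffects(types, deltas)
  expect_gt(res$GLU$kw$p, 0.05)
  expect_lt(res$NEFA$kw$p, 0.001)
  expect_true(nrow(res$NEFA$significant_pairs) >= 1)
  # a singleton type is excluded with a message
  types2 <- c(types, "S2-S1")
  deltas2 <- rbind(deltas, data.frame(GLU = 0, NEFA = 0))
  expect_message(res2 <- successionTypeEffects(types2, deltas2),
                 "excluded 1")
  expect_equal(attr(res2, "excluded_types"), "S2-S1")
  expect_error(successionTypeEffects(rep("S1-S1", 10), deltas[1:10, ]),
               "fewer than 2 types")
})
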