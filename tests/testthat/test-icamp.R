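test_that("bins respect the minimum size and recover deep clades", {
  b1 <- buildBins(starTree(48), ds = 24)
  expect_lte(length(b1$bins), 2L)
  expect_true(all(lengths(b1$bins) >= 24L))
  expect_setequal(unlist(b1$bins), paste0("t", 1:48))

  tree2 <- twoCladeTree(30, 30)
  b2 <- buildBins(tree2, ds = 24)
  expect_equal(length(b2$bins), 2L)
  expect_setequal(b2$bins[[1]], paste0("a", 1:30))
  expect_setequal(b2$bins[[2]], paste0("b", 1:30))
  # deterministic and invariant to taxon input order
  b3 <- buildBins(tree2, taxa = sample(tree2$tip.label), ds = 24)
  expect_identical(b2$bins, b3$bins)
  expect_error(buildBins(starTree(10), ds = 24), "fewer taxa")
  expect_error(buildBins(starTree(48), ds = 1), "ds must be")
})

test_that("observed beta-MNTD agrees with picante and degenerates to 0", {
  skip_if_not_installed("picante")
  set.seed(53)
  tree <- ape::rtree(14)
  m <- matrix(rpois(6 * 14, 2), 6, 14,
              dimnames = list(paste0("s", 1:6), tree$tip.label))
  m[1, ] <- m[2, ] <- c(rep(4, 7), rep(0, 7))      # identical pair
  m[rowSums(m) == 0, 1] <- 1
  D <- stats::cophenetic(tree)
  P <- m / rowSums(m)
  pres <- apply(m > 0, 1, which, simplify = FALSE)
  mine <- MicrobiomeSuccession:::.bmntdAllPairs(P, pres, D)
  ref <- as.matrix(picante::comdistnt(m, D, abundance.weighted = TRUE))
  expect_equal(mine, ref, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(mine[1, 2]), 0)                      # identical communities
})

test_that("beta-NTI z-scores are standardized under neutral assembly", {
  sc <- simulateAssemblyScenario("drift", n_taxa = 120, n_samples = 15,
                                 seed = 59)
  bins <- buildBins(sc$tree, ds = 24)
  bn <- betaNTI(sc$table, sc$tree, bins, n_null = 200, seed = 61)
  z <- bn$bnti[bn$evaluable]
  expect_gt(length(z), 30)
  expect_lt(abs(mean(z)), 0.35)
  expect_lt(abs(stats::sd(z) - 1), 0.35)
  # identical seed reproduces identical metrics
  bn2 <- betaNTI(sc$table, sc$tree, bins, n_null = 200, seed = 61)
  expect_identical(bn, bn2)
})

test_that("Raup-Crick stays in [-1, 1] and centres under neutrality", {
  sc <- simulateAssemblyScenario("drift", n_taxa = 60, n_samples = 12,
                                 seed = 67)
  bins <- buildBins(sc$tree, ds = 24)
  rc <- raupCrick(sc$table, bins, n_null = 200, seed = 71)
  v <- rc$rc[rc$evaluable]
  expect_true(all(v >= -1 & v <= 1))
  expect_lt(abs(mean(v)), 0.25)
  expect_error(raupCrick(sc$table, bins, n_null = 10), ">= 100")
})

test_that("process classification is a pure threshold rule", {
  mk <- function(bnti, rc) {
    key <- data.frame(sample_a = "x", sample_b = "y", bin = "bin01")
    list(bnti = cbind(key, obs_bmntd = 1, null_mean = 1, null_sd = 1,
                      bnti = bnti, weight = 0.5, evaluable = TRUE),
         rc = cbind(key, obs_bray = 0.5, rc = rc, evaluable = TRUE))
  }
  call1 <- function(bnti, rc) {
    x <- mk(bnti, rc)
    classifyProcesses(x$bnti, x$rc)$pair_bin$process
  }
  expect_equal(call1(-2.5, 0.99), "HOS")           # selection beats RC
  expect_equal(call1(2.5, 0), "HeS")
  expect_equal(call1(0.5, 0.97), "DL")
  expect_equal(call1(0.5, -0.97), "HD")
  expect_equal(call1(0, 0), "drift")
  # boundary values stay inside the interior region
  expect_equal(call1(1.96, 0.95), "drift")
})

test_that("process fractions sum to one at every aggregation level", {
  sc <- simulateAssemblyScenario("dispersal_limitation", n_taxa = 60,
                                 n_samples = 10, seed = 73)
  bins <- buildBins(sc$tree, ds = 24)
  bn <- betaNTI(sc$table, sc$tree, bins, n_null = 150, seed = 3)
  rc <- raupCrick(sc$table, bins, n_null = 150, seed = 4)
  res <- classifyProcesses(bn, rc)
  expect_equal(sum(res$fractions), 1, tolerance = 1e-10)
  procs <- c("HeS", "HOS", "HD", "DL", "drift")
  expect_true(all(abs(rowSums(res$per_bin[, procs]) - 1) < 1e-10))
  expect_true(all(abs(rowSums(res$pair_fractions[, procs]) - 1) < 1e-10))
  # dispersal limitation dominates its own scenario
  expect_gt(res$fractions["DL"], 0.5)
})

test_that("stage comparison separates selection- from drift-dominated pairs", {
  sel <- simulateAssemblyScenario("selection", n_taxa = 80, n_samples = 10,
                                  seed = 79)
  dri <- simulateAssemblyScenario("drift", n_taxa = 80, n_samples = 10,
                                  seed = 79)
  m <- rbind(counts(sel$table), counts(dri$table))
  rownames(m) <- c(paste0("sel", 1:10), paste0("dri", 1:10))
  tab <- featureTable(m)
  bins <- buildBins(sel$tree, ds = 24)
  bn <- betaNTI(tab, sel$tree, bins, n_null = 150, seed = 5)
  rc <- raupCrick(tab, bins, n_null = 150, seed = 6)
  res <- classifyProcesses(bn, rc)
  stages <- setNames(rep(c("S1", "S2"), each = 10), rownames(m))
  cmp <- compareStages(res, stages)
  expect_gt(cmp$stage_fractions["S1", "HOS"] +
              cmp$stage_fractions["S1", "HeS"],
            cmp$stage_fractions["S2", "HOS"] +
              cmp$stage_fractions["S2", "HeS"])
  expect_lt(cmp$tests$HOS$p, 0.05)
  expect_error(compareStages(res, setNames(rep("S1", 20), rownames(m))),
               ">= 2 stages")
})
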