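test_that("differential filter matches a hand-enumerated toy table", {
  # 6 samples x 5 taxa; taxa t1 and t2 pass >50% prevalence and >0.1%
  # mean relative abundance, t3 fails prevalence (3/6), t4 fails
  # abundance, t5 fails both
  m <- rbind(c(500, 400, 9, 1, 0),
             c(450, 420, 8, 1, 0),
             c(480, 390, 7, 0, 0),
             c(520, 410, 0, 1, 0),
             c(300, 380, 0, 0, 1),
             c(310, 405, 0, 0, 0))
  dimnames(m) <- list(paste0("s", 1:6), paste0("t", 1:5))
  f <- differentialFilter(featureTable(m), groups = rep(c("a", "b"), 3),
                          prevalence_min = 0.5, abundance_min = 0.001)
  expect_setequal(f$surviving, c("t1", "t2"))
  expect_true(all(f$stats$p_adj >= f$stats$p))
  # prevalence threshold of 1 keeps exactly the ubiquitous features
  f2 <- differentialFilter(featureTable(m), prevalence_min = 1,
                           abundance_min = 0)
  expect_setequal(f2$surviving, c("t1", "t2"))
  expect_warning(differentialFilter(featureTable(m), prevalence_min = 1,
                                    abundance_min = 0.9), "no features")
  # order-invariant and idempotent on the surviving set
  perm <- c(4, 2, 5, 1, 3)
  f3 <- differentialFilter(featureTable(m[, perm]), prevalence_min = 0.5,
                           abundance_min = 0.001)
  expect_setequal(f3$surviving, f$surviving)
})

test_that("mediation point estimates follow the product of coefficients", {
  set.seed(109)
  n <- 500
  s <- rnorm(n)
  m <- 0.5 * s + rnorm(n, 0, 0.1)
  y <- 0.2 * s + 0.4 * m + rnorm(n, 0, 0.1)
  med <- mediate(s, m, y, n_boot = 500, seed = 1)
  est <- med$estimates
  expect_lt(abs(est["acme"] - 0.2), 0.05)
  expect_lt(abs(est["ade"] - 0.2), 0.05)
  expect_lt(abs(est["total"] - 0.4), 0.05)
  # the decomposition is an exact algebraic identity
  expect_equal(unname(est["acme"] + est["ade"]), unname(est["total"]))
  expect_lt(med$p["acme"], 0.05)
  # oracle: the same coefficients from lm fits
  fit_m <- stats::lm(m ~ s)
  fit_y <- stats::lm(y ~ s + m)
  expect_equal(unname(est["a"]), unname(coef(fit_m)["s"]))
  expect_equal(unname(est["b"]), unname(coef(fit_y)["m"]))
  expect_equal(unname(est["c_prime"]), unname(coef(fit_y)["s"]))
})

test_that("a broken mediation path gives an ACME interval covering 0", {
  set.seed(113)
  n <- 300
  s <- rnorm(n)
  m <- 0.5 * s + rnorm(n, 0, 0.2)
  y <- 0.3 * s + rnorm(n)                          # b = 0
  med <- mediate(s, m, y, n_boot = 500, seed = 2)
  expect_lt(med$ci["2.5%", "acme"], 0)
  expect_gt(med$ci["97.5%", "acme"], 0)
  # degenerate inputs
  expect_warning(mediate(s, s, y, n_boot = 100, seed = 1), "collinear")
  expect_error(mediate(s, rep(1, n), y), "zero variance")
  expect_error(mediate(s[1:5], m[1:5], y[1:5]), "at least 10")
  expect_error(mediate(s, m[1:10], y), "equal length")
})

test_that("bootstrap replication is deterministic given the seed", {
  set.seed(127)
  s <- rnorm(50); m <- 0.4 * s + rnorm(50); y <- 0.3 * m + rnorm(50)
  m1 <- mediate(s, m, y, n_boot = 200, seed = 9)
  m2 <- mediate(s, m, y, n_boot = 200, seed = 9)
  expect_identical(m1$ci, m2$ci)
  expect_identical(m1$p, m2$p)
})

screenFixture <- function(seed, shuffle_phenos = FALSE) {
  # a single-state cohort with concentrated Dirichlet parameters keeps
  # species near-independent, so the only real mediation paths are the
  # planted ones
  cfg <- syntheticCohortConfig(n_subjects = 50, n_taxa = 50,
                               habitats = "rumen", n_pathways = 20,
                               K_states = 1,
                               initial_state_probs = 1,
                               transition_matrix = matrix(1, 1, 1),
                               state_dirichlet_alphas =
                                 matrix(10, 1, 50),
                               seed = seed)
  sim <- simulateCohort(cfg)
  ph <- as.data.frame(sim$design[, c("NEFA", "INS", "TG")])
  rownames(ph) <- sim$design$sample_id
  if (shuffle_phenos) {
    set.seed(seed + 1)
    ph[] <- ph[sample.int(nrow(ph)), ]
  }
  list(sim = sim, ph = ph)
}

test_that("the screen recovers planted triples with few false positives", {
  fx <- screenFixture(131)
  scr <- mediationScreen(fx$sim$table, fx$sim$pathways, fx$ph,
                         species_prevalence_min = 0.2)
  truth <- fx$sim$truth$triples
  for (i in seq_len(nrow(truth))) {
    hit <- scr$full$species == truth$species[i] &
      scr$full$pathway == truth$pathway[i] &
      scr$full$phenotype == truth$phenotype[i]
    expect_true(any(hit))
  }
  expect_lte(nrow(scr$full) - nrow(truth), 1)
  # permuted phenotypes leave the full set empty
  fx0 <- screenFixture(131, shuffle_phenos = TRUE)
  scr0 <- mediationScreen(fx0$sim$table, fx0$sim$pathways, fx0$ph,
                          species_prevalence_min = 0.2)
  expect_equal(nrow(scr0$full), 0L)
})

test_that("an empty surviving set returns an empty screen with a warning", {
  fx <- screenFixture(137)
  expect_warning(
    expect_warning(
      scr <- mediationScreen(fx$sim$table, fx$sim$pathways, fx$ph,
                             species_abundance_min = 0.999),
      "empty surviving"),
    "no features pass")
  expect_null(scr$results)
})
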