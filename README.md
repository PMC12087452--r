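# MicrobiomeSuccession

Longitudinal community-state succession and assembly analysis for
host-associated microbiomes.

Cohorts sampled repeatedly around a physiological transition — the
motivating design is peripartum dairy cows, with rumen and fecal
communities profiled at six days around calving — pose a chain of
questions that this package answers as one tested pipeline:

1. **Which community states exist?** Dirichlet-multinomial mixture (DMM)
   clustering with the number of states chosen by the lowest
   Laplace-approximation score (negative log model evidence):
   samples are typed by components with concentrations `α_k` and weights
   `π_k`, fitted by EM with monotone likelihood.
2. **How do individuals move between states?** Per-interval and pooled
   Markov transition matrices `P_ij = C_ij / Σ_j C_ij`, a succession
   staging rule on self/mutual transition rates (rapid transition
   < 20% self-rate; stable ≥ 50%, with reciprocal rates ≥ 30% reported),
   dominant-transition shares, and a random-forest stage classifier
   evaluated by repeated stratified splits (macro one-vs-rest AUC).
3. **Which ecological processes drive turnover?** Phylogenetic-bin
   null-model partitioning: taxa are binned on the tree
   (`bin.size.limit = 24`), within-bin βNTI (z-score of abundance-
   weighted βMNTD against taxon-shuffling nulls) and modified Raup–Crick
   (RC) classify every (sample pair, bin) into homogeneous/heterogeneous
   selection (|βNTI| > 1.96), homogenizing dispersal / dispersal
   limitation (|RC| > 0.95), or drift, with abundance-weighted process
   fractions overall, per bin, and per succession stage.
4. **How coupled are compartments?** Symmetric Procrustes (M² ∈ [0, 1]
   with permutation p and per-sample residuals) and Gibbs-sampler
   microbial source tracking (declared sources + a learned "unknown").
5. **Does succession mark the host?** EnvFit covariate r² on
   ordinations, Kruskal–Wallis + Dunn tests of phenotype changes across
   stage-transition types, the insulin-sensitivity index
   `RBHB = 1/[log₁₀ GLU + log₁₀ INS + log₁₀ NEFA + log₁₀ BHB]`, and
   species → pathway → phenotype mediation (ACME = a·b, ADE = c′,
   total = c′ + a·b, bootstrap intervals, BH-screened over all triples).

A synthetic-cohort generator (`simulateCohort()`,
`simulateAssemblyScenario()`) reproduces the study's statistical
skeleton — latent Markov state paths, Dirichlet-multinomial count
emission, a phylogeny with conserved habitat preference, planted
mediation paths, and single-process assembly scenarios — so every stage
is validated against known ground truth.

## Worked example

```r
library(MicrobiomeSuccession)

cfg <- syntheticCohortConfig(n_subjects = 40, habitats = "rumen", seed = 7)
sim <- simulateCohort(cfg)
sim$table
#> FeatureTable: 240 samples x 60 taxa
#>   sample totals: min 10548, median 19678, max 40328

sel <- selectK(sim$table, 1:5, seed = 1, n_init = 3)
sel$best_k
#> [1] 3
fit <- sel$fits[[as.character(sel$best_k)]]
mclust::adjustedRandIndex(stateLabels(fit$assignment), sim$truth$states)
#> [1] 1

tm <- estimateTransitions(fit$assignment, sim$design)
round(transitionProbs(tm), 2)
#>      1    2    3
#> 1 0.98 0.01 0.02
#> 2 0.56 0.11 0.33
#> 3 0.50 0.03 0.47
classifyStages(tm)$stages
#>                  1                  2                  3
#>           "stable" "rapid_transition"       "transition"
```

The selected `K = 3` matches the generator's three latent states
(adjusted Rand index 1 against the true labels; mixture-component
numbering is arbitrary), and the staging rule reads the estimated chain
as one rapidly vanishing early state, one bridging state, and one stable
late state that the others drain into — the succession structure the
generator planted.

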