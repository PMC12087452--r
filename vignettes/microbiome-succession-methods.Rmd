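---
title: "Methods: community-state succession and assembly analysis"
author: "MicrobiomeSuccession"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community-state succession and assembly analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicrobiomeSuccession)
```

# The problem

Longitudinal gut-microbiome cohorts around a physiological transition --
here, dairy cows sampled in two habitats (rumen fluid and feces) at six
days around calving (-21, 1, 3, 7, 14, 21) -- raise a chain of linked
questions: which discrete community states exist, how do individuals move
between them over time, which ecological processes drive the turnover,
how tightly are the two gut compartments coupled, and do the succession
dynamics leave a measurable mark on host metabolism. This package
implements that chain as a tested pipeline, and pairs it with a
synthetic-cohort generator so every stage can be validated against known
ground truth.

# Community-state typing (Dirichlet-multinomial mixtures)

Counts for sample $i$ under component $k$ follow a Dirichlet-multinomial
with concentrations $\alpha_k$; mixture weights $\pi_k$ complete the
model. `fitDMM()` runs EM over component responsibilities; the M-step
updates $\alpha_k$ with a bound-based fixed-point iteration (a few inner
steps per EM step), so the observed-data log-likelihood is non-decreasing
-- a property the tests assert on every fixture. Initialization is
seeded k-means on relative abundances; because EM is a local optimizer,
`selectK()` uses an em-EM strategy (several short seeded bursts per
candidate $K$, only the best-likelihood burst polished to convergence).

The number of states is chosen by the lowest Laplace-approximation score:
the negative log model evidence
$-[\log \hat L + \tfrac{d}{2}\log 2\pi - \tfrac12 \log |H|]$ with
$d = K\,T + (K-1)$ free parameters ($T$ taxa). $H$ is approximated
block-diagonally: per-component diagonal curvature of the
Dirichlet-multinomial likelihood in the direct $\alpha$ parameterization
(small concentrations then carry large curvature and are penalized), plus
the multinomial Fisher information of the mixture weights. This behaves
like a BIC-strength penalty and recovers the generating $K$ on
well-separated synthetic cohorts. Concentrations are bounded in
$[10^{-8}, 10^{6}]$ during optimization; zero-count taxa need no special
handling under the Dirichlet-multinomial.

Cluster "driver" taxa are ranked by a defined score -- the
Kruskal-Wallis $H$ of a taxon's relative abundance across hard clusters,
signed by the cluster's mean-abundance excess, ties broken by mean
abundance. This is a documented stand-in for LDA-effect-size style
ranking, not a claim of equivalence.

# Succession staging (Markov chains)

`estimateTransitions()` counts, per consecutive grid-timepoint interval,
the subject series (one per subject and habitat) observed in state $i$
then state $j$; series missing either endpoint contribute nothing (no
imputation across gaps). The pooled matrix is the time-homogeneous
maximum-likelihood chain; per-interval matrices are always retained
because both views are informative.

Stages follow the self/mutual-transition-rate rule with defaults 0.20 /
0.50 / 0.30: self-rate below 0.20 marks a rapid-transition state;
self-rate at or above 0.50 marks a stable state; everything else is a
transition state. We read the mutual-rate threshold as corroborative
rather than gating: an absorbing state with no exchange partner is the
limiting case of stability, so it stays stable, and
`classifyStages()` reports separately which stable states form a
reciprocal pair (rate $\ge 0.30$ both ways). This is the only reading
under which the rule's own limiting cases (identity chain; a lone
high-self-rate state) are all consistent. The thresholds are descriptive
conventions, exposed as arguments.

The stage classifier (`trainStageClassifier()`) filters taxa at mean
relative abundance > 0.1%, then runs repeated stratified 70/30 splits; on
each training split a random forest ranks features, an internal 10-fold
CV tunes the feature count over a grid, and the tuned model's macro
one-vs-rest AUC is measured on the held-out 30%. The published
description of this protocol mixes a 10-fold and a 70/30 scheme; we
resolved it as "repeats of a 70/30 split with inner 10-fold tuning", and
both knobs (`n_repeats`, `inner_folds`, `top_n_grid`) are arguments.

# Assembly partitioning (phylogenetic-bin null models)

`buildBins()` cuts the UPGMA hierarchy of cophenetic distances into
$\lfloor n/\mathrm{ds} \rfloor$ clusters and merges clusters below the
minimum bin size (ds = 24 by default) into their phylogenetically nearest
bin -- deterministic and order-invariant.

Within each bin and sample pair, `betaNTI()` computes abundance-weighted
beta mean-nearest-taxon distance (bMNTD) and standardizes it against a
null that shuffles the bin's taxon labels on the tree (both samples
remapped under the same permutation, so shared taxa keep their
conspecific zeros); `raupCrick()` standardizes within-bin Bray-Curtis
against null assemblages that preserve each sample's bin total while
redistributing it by regional relative abundance, giving
$RC \in [-1, 1]$. `classifyProcesses()` applies the standard thresholds:
bNTI $< -1.96$ homogeneous selection, $> +1.96$ heterogeneous selection,
then RC $< -0.95$ homogenizing dispersal, $> +0.95$ dispersal
limitation, interior drift. Aggregation weights each (pair, bin) by the
mean of the pair's two relative bin abundances; fractions sum to one at
every level by construction. Pairs where a bin is empty in a sample, or
whose null is degenerate (e.g. complete membership overlap), are
non-evaluable and carry no weight. Null draw counts default to 1000 and
are arguments; the validation harness uses 200.

A caveat worth making explicit: nearest-taxon nulls are uninformative
when every taxon occurs in every sample -- the nearest taxon is then
always the conspecific at distance zero, observed and null alike. Real
amplicon tables are sparse; synthetic scenarios must be too (see below).

# Compartment coupling and host links

Procrustes comparison wraps vegan's symmetric `protest` (both
configurations scaled to unit trace, so $M^2 \in [0,1]$ and congruent
shapes give exactly 0), returning per-sample residuals for paired
Wilcoxon comparison between compartments. EnvFit covariate fitting wraps
`vegan::envfit` (vectors for continuous covariates, centroids for
factors), reporting $r^2$ and permutation p; constant covariates are
flagged with $r^2 = 0$ rather than erroring.

Source tracking is a collapsed Gibbs sampler over per-read source
assignments: declared sources have their taxon distributions fixed at the
posterior mean under a Dirichlet(0.001) prior, an "unknown" source is
learned from the sink's own reads, and mixing proportions carry 10 prior
counts per source. Because the unknown can imitate any sink perfectly,
its taxon prior must be strongly smoothing to keep the model
identifiable; we default it to 10 per taxon, under which a sink resampled
from one source is attributed to it at $\ge 0.9$ while a sink on taxa
foreign to all sources still goes entirely to unknown. Proportions are
posterior means over post-burn-in sweeps averaged across restarts
(defaults: burn-in 100, 25 draws, 10 restarts).

The insulin-sensitivity index RBHB is
$1/[\log_{10}\mathrm{GLU} + \log_{10}\mathrm{INS} +
\log_{10}\mathrm{NEFA} + \log_{10}\mathrm{BHB}]$ in the units mg/dl,
uU/ml, mmol/l, mmol/l; any non-positive component makes it undefined
(NA with a reason attribute). Succession-type phenotype tests pair each
subject-interval's stage-transition label with the within-subject
phenotype change over the same interval (the "change level" definition
is ours; per-timepoint values were the alternative) and compare types by
Kruskal-Wallis with Dunn post hoc z-tests, BH-adjusted.

# Mediation

Species are standardized as z-scores of $\log_{10}$ relative abundance
with half-minimum replacement of zeros (comparable scale across taxa; the
transform is a package choice). The two-equation linear model
$m = a s + e_1$, $y = c' s + b m + e_2$ gives ACME $= ab$, ADE $= c'$,
and total $= c' + ab$, which equals the simple-regression slope exactly
-- an identity the tests assert. `mediate()` uses a nonparametric
bootstrap (percentile intervals, default 1000 resamples);
`mediationScreen()` tests all surviving species x pathway x phenotype
triples with closed-form coefficients and large-sample (Sobel) ACME
p-values, BH-adjusted across the screen -- "mediating" means adjusted
ACME p < 0.05, "full" additionally requires significant direct and total
effects. The differential filters keep features with prevalence strictly
above 50% (a threshold of 1 keeps ubiquitous features) and mean relative
abundance above 0.1% (species) or 0.01% (pathways, on their own scale).

# The synthetic cohort: what it emulates and what it does not

`simulateCohort()` reproduces the statistical skeleton of the study
design: 91 subjects (by default) x 6 timepoints x 2 habitats; per-series
latent state paths from a configurable Markov chain (default: three
states with self-rates 0.15/0.48/0.80 arranged so early states drain
into a stable late state); Dirichlet-multinomial emission where each
state shares a sparse baseline (total mass 5) plus its own enrichment
block (mass 20, ~80% of expected abundance), so states share taxa but
differ in drivers; a persistent per-subject multiplicative signature on
the concentrations (log-normal, sd 0.3) giving each individual a stable
compositional identity; log-normal sequencing depth truncated below; a
birth-death phylogeny whose Brownian trait sets multiplicative habitat
preference (phylogenetically conserved, as selection detection assumes);
and mediation triples planted into the pathway table and serum panel.
Planted phenotypes are generated on the analyte's natural scale as
$\mu_v + \sigma_v \eta$ with standardized effects inside $\eta$, and the
truth table records $\sigma_v$ and the pathway offset so recovery tests
work on the standardized scale. One global seed expands into
per-component child seeds.

`simulateAssemblyScenario()` provides three single-process communities
at 30 samples x 120 taxa, depth 1000 with a lognormal(0, 1.5)
metacommunity -- deliberately sparse, for the reason above:

* **drift** -- neutral multinomial resampling of one metacommunity whose
  abundances are assigned to tips at random; bNTI z-scores are then
  genuinely standardized (mean ~0, sd ~1).
* **dispersal_limitation** -- each sample assembles from its own random
  species pool (20% of taxa), giving high compositional turnover without
  phylogenetic structure: RC pins at +1 while bNTI stays interior.
* **selection** -- niche-lottery filtering: a strong Gaussian filter on
  an Ornstein-Uhlenbeck trait leaves a sparse set of occupied
  "niches" (small clades of near-redundant relatives), and each sample
  fills each niche with one lottery-drawn member. Turnover is therefore
  confined to close relatives while richness stays far below the pool,
  which is exactly the regime where observed bMNTD falls far below the
  within-bin null. The OU trait (rather than Brownian) stops the favored
  niches from piling into a single deep clade, where within-bin nulls
  lose power. Naive alternatives -- one fixed fitness vector, or
  jittered optima without redundancy -- provably fail to move |bNTI|
  past 1.96 at this scale because membership overlap degenerates the
  null; the lottery mechanism is the point, not a tuning artifact.

The individuality signature is deliberately mild (a distance-based
PERMANOVA attributes roughly a fifth to a quarter of compositional
variance to subject at the default, as `scripts/acceptance.R`
recomputes), because a stronger one would blur the community-state
separation the typing stages assume. One consequence: the *median*
intra- vs inter-individual dissimilarities are dominated by the state
mix of each pair set and their ordering can go either way between
realizations, while the subject PERMANOVA R-squared reflects
individuality robustly -- on real data, where the individual signature
is strong, the median comparison is the customary summary.

What the generator does **not** emulate: real taxonomies, co-occurrence
network structure, overdispersion beyond the Dirichlet-multinomial,
habitat-coupled state dynamics (rumen and fecal chains are independent),
measurement error in the serum panel, or confounded covariates (parity,
diet, sire are independent noise). Passing tests therefore demonstrate
correctness of the machinery under the stated model, not performance on
real data; in particular the mediation screen's false-positive behavior
is assessed on a single-state cohort, because a multi-state cohort
induces real correlated mediation paths through the block structure --
those are true positives of the model, not errors of the screen.

# Numerical choices and problem sizes

EM tolerance is a relative log-likelihood change of $10^{-8}$ (cap 300
iterations, warning on non-convergence); concentrations are clamped to
$[10^{-8}, 10^6]$; degenerate inputs (all-zero samples, zero-variance
covariates or mediators, single groups) error or flag early with
explicit messages. Rarefaction subsamples without replacement via a
sequential hypergeometric chain and drops (never pads) samples below
depth. PERMANOVA offers exhaustive enumeration up to n = 9 for exact
p-values, free permutation otherwise, and an optional within-subject
restriction for repeated measures. The validation suite runs the DMM
selection study at 120 subjects x 6 timepoints x 60 taxa over 20 seeds,
the assembly discrimination at 30 samples x 120 taxa x 200 nulls over 10
seeds per scenario, Markov recovery at 500 subjects x 2 habitats, and
mediation coverage over 100 replicates at n = 300 -- sizes chosen so the
whole suite completes comfortably on a single CPU while leaving the
statistical margins wide.

# Known limitations

The Laplace evidence uses a diagonal Hessian approximation; it is a
model-selection score, not a calibrated marginal likelihood. The Markov
chain is first-order and time-homogeneous when pooled (per-interval
matrices are exported for the inhomogeneous view). Within-bin
taxon-label shuffling is the only null scheme implemented for bNTI.
Mediation rests on the usual sequential-ignorability assumptions;
nothing here identifies causality in observational data. Source-tracking
uncertainty is summarized by posterior means only.
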