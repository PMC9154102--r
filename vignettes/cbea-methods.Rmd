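---
title: "Competitive balances for taxon-set enrichment: model and methods"
author: "cbea package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive balances for taxon-set enrichment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbea)
```

## The problem

Microbiome taxonomic tables are high-dimensional, sparse and compositional:
sequencing depth is arbitrary, so only relative abundances carry
information. A common way to tame the dimensionality is to aggregate taxa
into pre-defined sets (taxonomic clades, tropism classes, ecosystem roles)
and to ask, per sample, whether a set is enriched. The prevailing practice —
summing counts within a set — is not scale-invariant across set sizes, does
not preserve inter-sample geometry, and amplifies taxon-specific protocol
bias. This package scores sets multiplicatively instead, with a log-ratio
balance, and attaches sample-level significance via an empirical null.

## The enrichment statistic

For a closed composition $x \in \mathbb{S}^p$ (row sums 1) and a set $K$ of
size $K$ with complement $\bar K$, the score is the scaled log-ratio of
geometric means

$$
M \;=\; \sqrt{\frac{K\,(p-K)}{p}}\;
\ln\!\frac{g(x_j : j \in K)}{g(x_j : j \notin K)},
\qquad g(z) = \exp\!\Big(\tfrac1n\sum \ln z_i\Big).
$$

This is the isometric-log-ratio balance
$\sqrt{rs/(r+s)}\,\ln\left(g(x_R)/g(x_S)\right)$ specialised to $R = K$,
$S = \bar K$ (note $\sqrt{K(p-K)/p} = \sqrt{rs/(r+s)}$ with $r = K$,
$s = p - K$). It formalises the *competitive* null hypothesis: taxa in the
set are, as a group, no more abundant than the background taxa of the same
sample. Because it is a ratio of geometric means it is invariant to row
scaling (counts and proportions give identical scores, so `cbea()` accepts
both and always applies the closure internally) and antisymmetric in set
versus complement. Since the geometric mean is an exponential of a mean of
logs, the score is also, up to the coefficient, a difference of mean
log-abundances — the form `scoreMatrix()` actually computes, in log space,
so long sets of small proportions cannot underflow.

Zeros invalidate log-ratios. When any zero is present, a pseudocount
(default $10^{-5}$) is added to *every* entry before closure, with a
message; the pseudocount precedes the closure because adding it afterwards
would break the sum-to-one invariant. Users who prefer model-based zero
replacement can pre-process and pass a dense table, in which case the
package leaves it untouched. Sets must be non-empty proper subsets of the
taxon universe — a set equal to the universe has no complement to compare
against and is rejected; singleton sets are legitimate balances and are
allowed.

## The empirical null

Under the competitive null, a set of randomly drawn taxa should not be
enriched. The null distribution of $M$ is therefore estimated from the data
by *taxa permutation*: shuffle the columns of the table (one shared uniform
permutation per replicate, applied identically to every sample, so each
sample's composition is intact while the taxon-to-set assignment is
destroyed), re-score, and pool. `buildNull()` pools $n \times
n_\mathrm{perm}$ scores per set; the default $n_\mathrm{perm} = 100$ gives
tens of thousands of null draws for stable tail estimates. Pooling across
permutation replicates (rather than fitting per replicate) and sharing one
permutation across all sets per replicate are implementation choices the
procedure's description leaves open; both are documented here and fixed.

Two parametric families are available for the pooled scores:

* **normal** — maximum-likelihood $(\mu, \sigma)$ (the $1/N$ variance
  estimator);
* **mixture2** — a two-component Gaussian mixture fitted by EM, the more
  flexible family for skewed or platykurtic nulls (sparsity skews the null
  because the pseudocount pushes zero-replaced entries far below the rest;
  within-set correlation flattens it). A caveat the test suite makes
  explicit: with this package's homogeneous independent-taxa generator the
  global-null scores are already close to normal — each score averages tens
  of log-abundances, and at 50% masking the in-set zero count is a
  symmetric binomial — so at moderate set sizes the mixture's
  goodness-of-fit advantage is real but small (it wins the KS comparison
  in most, not all, seeded repetitions; decisive dominance appears for
  small sets or correlated sets). The mixture fit is never meaningfully
  worse than the normal, which is why it is the default.

Finalised scores are the null CDF evaluated at the raw score (`"cdf"`), the
upper-tail p-value `1 - cdf` (`"pval"`), or a z-score (`"zscore"`). For the
normal family the z-score is $(x-\mu)/\sigma$; for the mixture there is no
single standardisation, so the package uses the probit of the mixture CDF,
which preserves the CDF's ranking exactly and reduces to $(x-\mu)/\sigma$
when the mixture collapses to one component. All four output types are
strictly monotone in the raw score, so they rank samples identically.

### EM details

EM for overlapping univariate components converges slowly, so the fit is
engineered conservatively:

* initialisation by a quantile split at the median, plus two random-split
  restarts (seeded); each start runs a 25-iteration burn-in and only the
  best-likelihood start continues to convergence — the usual short-run
  ("emEM") strategy;
* convergence when the log-likelihood changes by less than `tol` (default
  `1e-6`) with a cap of `maxIter = 1000` iterations; hitting the cap is
  flagged in the per-set diagnostics, not fatal;
* a degenerate outcome (component weight below 0.01 or standard deviation
  below 1e-8) falls back to the normal fit for that set, again flagged.

The inner loop is compiled (Rcpp) with a log-sum-exp E-step; fits on the
default pooled null (tens of thousands of points) take seconds.

### Correlation adjustment

Taxa permutation destroys inter-taxa correlation, and the variance of a
mean of correlated summands carries a correlation-dependent inflation term.
A set whose members are strongly correlated therefore has raw scores more
dispersed than its permutation null, and would be flagged even when its
mean abundance is unremarkable. With `adjust = TRUE` the package keeps the
*location* (and, for the mixture, the weights) of the permuted-null fit but
replaces its *spread* with that of a fit to the set's unpermuted scores —
mixture components are matched by ascending mean before the swap, a pairing
the procedure's description leaves open. The adjusted variant assumes the
statistic's variance is the same under null and alternative. It trades
power for protection: enrichment in mean still shifts location, but merely
correlated sets are no longer rejected. Adjustment is off by default
because set-level screening is exploratory and correlated sets can be
biologically interesting; the unadjusted mixture-normal variant is the one
with reliably controlled sample-level type-I error on independent-taxa
nulls.

## The synthetic-data generator

`simulateCounts()` / `simulateTwoGroups()` emulate the calibration study's
generative design: negative-binomial marginals, optional structural zeros,
block-exchangeable correlation, and mean-inflated enrichment.

* Taxa are partitioned into `nSets` disjoint blocks of `setSize`.
* A latent Gaussian vector has exchangeable correlation `rho` inside
  *designated* blocks (`enrichedSets`) and independence elsewhere, sampled
  in closed form as $\sqrt{\rho}\,u + \sqrt{1-\rho}\,\varepsilon$; margins
  are mapped through the NB quantile function (a Gaussian copula). `rho`
  is the latent-scale correlation; the induced count-scale rank correlation
  is attenuated, so tests assert ordering, not equality.
* All taxa share `nbMean` and `nbDispersion`; `nbDispersion` is the NB
  `size` parameter (variance $\mu + \mu^2/\mathrm{size}$). Designated taxa
  get mean `nbMean * foldChange` with the *same* dispersion — in all
  samples for the single-group design, in case samples only for the
  two-group design. `foldChange = 1` is the global null.
* Zero inflation is independent Bernoulli(`zeroProb`) masking applied after
  the counts are drawn — structural zeros; the generator does not
  distinguish them from sampling zeros downstream.

Defaults (`nbMean = 100`, `nbDispersion = 1`, i.e. variance
$\mu + \mu^2$) give strongly overdispersed counts typical of 16S gene
tables; they are declared choices, recorded in the simulation metadata, and
not tuned per experiment. Grids mirroring the calibration study's axes are
`zeroProb` in {0, 0.2, 0.4, 0.6}, `rho` in {0, 0.2, 0.5}, set sizes in
{20, 50, 100, 150, 200}.

What the generator deliberately does **not** emulate: taxon-specific
measurement bias, heterogeneous baseline means across non-enriched taxa,
partially-associated sets (all members of an enriched set share the same
fold change), and non-NB data-generating processes (Dirichlet-multinomial,
logistic-normal). Calibration results on these simulations therefore
demonstrate internal consistency of the method, not robustness to those
real-data features.

## The calibration harness

* `type1SampleLevel()` — draws random taxon sets on a fixed table and
  records the fraction of samples rejected at `alpha`; random sets realise
  the competitive null, so this estimates sample-level type-I error. The
  Wilcoxon rank-sum baseline (`method = "wilcoxon"`, in-set versus
  remainder abundances within one sample) is the standard calibrated
  comparator.
* `type1Population()` — computes scores once, then repeatedly assigns
  random binary labels and applies per-set Welch's t-tests; sets with
  constant scores are excluded with a diagnostic count rather than counted
  as accepts or rejects.
* `powerAndAuroc()` — on a simulated dataset with known truth: power is the
  rejection fraction among truly enriched set/sample pairs; AUROC ranks a
  set's scores against case/control labels, with DeLong intervals (pROC).
  Scoring never sees the truth labels; they enter only in the final tally.
* Proportion uncertainty is reported two ways: the empirical standard error
  of the rejection fraction across replicates (matching how the calibration
  experiments draw their error bars) and an Agresti–Coull interval.

Problem sizes are chosen so the full suite runs on a laptop: the
sample-level calibration uses a 500 x 400 global-null table with 100 random
sets of size 50 (the reference experiments use 500 replicates; 100 keeps
two-standard-error comparisons meaningful), the population-level check a
300 x 400 table with 20 disjoint sets of 20 and 100 label draws, and the
distributional-fit and adjustment checks use 500-sample simulations. The
`scripts/acceptance.R` entry point re-runs the two calibration quantities
from scratch at exactly these sizes.

## Numerical and design choices, in brief

* Geometric means via `exp(mean(log(x)))`; scoring via a single
  matrix product on the log-table.
* Permutation granularity: one column permutation per replicate shared by
  all samples and sets (per-sample shuffling would destroy the
  compositions themselves).
* Identifier matching between tables and set collections is exact-string;
  no lineage-aware normalisation.
* Missing values are rejected, never imputed.
* p-values are upper-tail (`1 - cdf`) per the procedure's convention; a
  per-sample Benjamini–Hochberg correction across sets is available
  post-hoc via `stats::p.adjust` but is not applied by default (screening
  convention is raw p at $\alpha = 0.05$).
* Every stochastic step (permutation, EM restarts, simulation, harness
  replicates) accepts a seed and restores the caller's RNG state
  (`withr::with_seed`), so end-to-end runs are bit-reproducible.

## Limitations

Sample-level inference is sensitive to inter-taxa correlation unless the
conservative adjustment is enabled; the mixture null's EM can be slow or
degenerate when components overlap heavily (handled by flagging and
fallback); and the simulation design's homogeneity means calibration
figures here should not be read as guarantees for real tables with
taxon-specific bias or partially-associated sets. Phylogeny-driven
partitions and weighted set members are out of scope.

## A minimal session

```{r example, eval = FALSE}
sim <- simulateTwoGroups(
    simConfig(nSamples = 100, nTaxa = 200, setSize = 20, nSets = 5,
              foldChange = 3, enrichedSets = 2L),
    nCases = 50, nControls = 50, seed = 1)

res <- cbea(simCounts(sim), simSets(sim), family = "mixture2",
            outputType = "pval", seed = 1)
head(scores(res))

powerAndAuroc(sim, seed = 1)
```
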