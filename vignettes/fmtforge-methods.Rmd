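---
title: "Predicting and designing FMT outcomes from donor microbiomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and designing FMT outcomes from donor microbiomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In fecal microbiota transplantation (FMT), stool from a donor is transferred
into a recipient's gut. Clinicians would like to choose donors by the outcome
they induce — the recipient's post-transplant diversity, the engraftment of
particular taxa, or clinical improvement — but outcomes are usually only known
after the fact. `fmtforge` implements a donor-only modelling pipeline: every
predictor sees the donor's microbial composition (plus simple donor covariates
and the number of days post-FMT at which the outcome is read) and never the
recipient's. If such models work, donor selection and even the design of
synthetic donor communities can be done before any transplant.

## The taxonomy-image predictor

The core model embeds a donor's composition into a levels-by-leaves matrix
built from the taxonomy: leaves (the preprocessed taxa) form the columns,
ordered by a depth-first traversal of the taxonomy tree with children sorted
by descending abundance; row $r$ of column $c$ holds the value of leaf $c$'s
ancestor at rank $r$, where each internal node's value is the mean of its
children's values, computed recursively from the leaves. Closely related taxa
are therefore adjacent, and coarse taxonomic structure appears as
low-frequency horizontal structure — which is what makes a small convolutional
network an appropriate reader of the matrix.

Two definitions of an internal node's value are defensible: the recursive mean
of child values, and the flat mean over all descendant leaves. They coincide
on balanced trees but not in general. We use the recursive child mean, which
treats each child lineage as one unit regardless of how many leaves it
carries; the package's tests verify the builder against an independent
bottom-up recomputation rather than against flat leaf means.

Because every image cell is a fixed convex combination of leaf values, the
embedding is precompiled at training time into one sparse matrix
(`taxonomy_image_map()`), so imaging a batch of donors — including the
thousands of candidates evaluated inside the genetic algorithm — is a single
matrix product.

The network itself (implemented in the package, trained with Adam) is small
by design: two convolution layers (8 then 16 channels, 2x3 kernels), max
pooling over the leaf axis, one 32-unit dense layer with dropout 0.2, and a
linear or sigmoid head. Covariates are concatenated to the flattened
convolutional features. Defaults: learning rate 1e-3, minibatch 32, at most
150 epochs with early stopping (patience 20) on an internal validation split
that keeps all samples of a recipient on one side. All of these are exposed
through `hyperparams`. The backward pass is verified against finite
differences in the test suite.

A bank of classical baselines (ridge, k-nearest neighbours, SVR, random
forest, gradient boosting, a dense network) consumes the identical design
matrix (flat preprocessed donor vector plus the same covariates), so model
comparisons are confounder-free.

## Preprocessing

Feature tables are merged to a chosen rank (default species, `"mean"`
aggregation), closed to relative abundance, and log-transformed as
$x \mapsto \log_{10}(x + \varepsilon)$ with $\varepsilon = 10^{-4}$ — small
enough to sit below any observed abundance, large enough to keep zeros
finite. Lineages that are unresolved at the target rank are completed with
`"<parent>__unclassified"` placeholders so every leaf has a full
root-to-leaf path, which the image builder requires. Optional per-taxon
z-scoring, covariate standardization and covariate imputation statistics are
always learned on training data only and frozen into the fitted model.

Shannon diversity is computed in nats (`base` is configurable); vectors are
closed before the entropy is taken, so the statistic is scale-invariant.

## Evaluation protocol

All accuracy numbers come from recipient-grouped 10-fold cross-validation:
recipients (not samples) are partitioned, so repeated timepoints of one
recipient can never appear on both sides of a split. Metrics are the held-out
coefficient of determination (which may be negative), Spearman correlation,
and AUC for binary tasks, reported as mean with the standard error over
folds. Leave-one-dataset-out evaluation holds out an entire cohort. Model
comparison uses a one-way ANOVA on per-fold metrics followed, when
significant at 0.05, by one-sided t-tests of the best model against each
other model. Per-taxon presence tasks whose evaluation split carries fewer
than five positives or negatives are skipped and reported, since AUC is
unstable there.

## Donor versus recipient background: the distance hierarchy

Where one donor feeds several recipients, three groups of between-sample
distances separate the donor's influence from the recipient's background:
within-recipient over time (SDSR), between recipients of the same donor at
matched timepoints (SDDR), and between recipients of different donors at
matched timepoints (DDDR). Distances are Euclidean on order-level relative
abundances (no log, so the vectors remain compositions) or absolute Shannon
differences. If the donor drives the outcome, SDSR <= SDDR < DDDR; one-sided
Welch t-tests score each step of the hierarchy. Timepoint matching is exact
by default with an optional tolerance in days for ragged sampling schedules.

## Donor ranking and clinical contrasts

`rank_donors()` orders candidate donors by predicted outcome
(deterministically, ties broken by donor id); `split_donor_groups()` forms
predicted-high and predicted-low arms (the validation-experiment design used
8 optimal and 16 sub-optimal donors), optionally adding a covariate-matched
low arm drawn from the high arm's dominant stratum. With outcome labels,
`success_fraction_per_donor()` summarizes per-donor success rates, and
`success_vs_failure_richness()` compares the predicted post-FMT diversity of
clinical successes and failures with a two-sided t-test.

## The generative genetic algorithm

To design a transplant community rather than merely pick a donor, a GA
searches donor-profile space against the trained predictor. Each candidate is
a relative-abundance vector $a_i$ with support mask $b_i = \mathbb{1}[a_i > 0]$
(re-derived after every operator), and

$$\mathrm{fitness}(s_i, b_i) = s_i - \gamma \sum_j b_{ij},$$

where $s_i$ is the predicted recipient outcome at day 7 and $\gamma \ge 0$
prices each non-zero taxon; minimization tasks negate $s_i$ inside the same
form. Per generation: predict, select the 30 fittest of 100 (ties to the
sparser candidate), keep the elites unchanged, and refill with offspring bred
from elite pairs by uniform crossover (probability 0.3) then mutation
(probability 0.3; Poisson(3)+1 taxa toggled, a switched-on taxon drawing its
abundance from the pool's empirical non-zero distribution for that taxon).
Keeping elites unmutated makes the best fitness non-decreasing, which gives
convergence a clean definition; the alternative reading — mutating the
selected parents themselves — would forfeit that property. The run length
defaults to 25 generations, with an optional plateau rule.

The candidate pool is grown from real donors by `expand_donor_pool()`. A
plain convex mixture of two parents would have the union of their supports,
inflating per-taxon prevalence from $p$ to $2p - p^2$; we therefore mix
shared taxa convexly and inherit parent-exclusive taxa with probability equal
to that parent's weight, which preserves expected prevalence exactly while
still interpolating abundances, followed by lognormal jitter and closure.

Two diagnostics accompany every run: the dominant-order table of the final
elites, and a "triviality" Spearman correlation between each elite donor's
own value of the target property and its predicted recipient outcome — high
values warn that the optimizer is merely maximizing the donor property
itself.

## The synthetic cohort generator

Real paired FMT cohorts are external data, so the package ships a generator
whose ground truth is known. Donors are sparse lognormal compositions; the
recipient composition $t$ days post-FMT is

$$\mathrm{close}\big(\delta\, e^{-\tau t} (e \odot d) + \rho\, h_i + (1 - \delta - \rho)\, \eta\big),$$

with donor composition $d$, per-taxon engraftability $e$, recipient
background $h_i$, fresh noise $\eta$, and multiplicative lognormal jitter
(sd 0.3) before closure. This linear-in-composition transfer model is the
simplest mechanism that produces the three phenomena the package must
exhibit: a donor effect exceeding the background (SDDR < DDDR), a
non-trivial donor-to-recipient property map, and time decay. By default
engraftability is `Bernoulli(0.6) * Unif(0.05, 1)`: a substantial minority of
taxa never engraft. That choice is what makes the donor's own Shannon
diversity an imperfect univariate predictor, so multivariate models have
signal to recover beyond the raw donor-recipient correlation — mirroring the
motivating observation that trained predictors beat univariate baselines.
Clinical outcomes are Bernoulli with success probability
$\sigma(3 H - 10.5)$ on the realized recipient Shannon $H$, linking success
to engrafted diversity (at the realized diversities this yields a minority of
successes, as in inflammatory-bowel-disease FMT trials).

Four presets emulate increasing recipient-background strength: germ-free mice
($\rho = 0$), antibiotic-treated mice ($\rho = 0.1$), antibiotic-treated
humans ($\rho = 0.25$), untreated humans ($\rho = 0.45$), with
$\delta = 0.9 - \rho$ so the residual noise weight stays fixed and the
donor/background trade-off is the only thing that varies across regimes.

What the generator does *not* emulate: ecological dynamics (no interactions
between taxa, no generalized Lotka-Volterra), strain-level competition,
measurement depth effects, or batch effects between cohorts. Passing tests on
this generator therefore demonstrate that the pipeline recovers a planted,
compositional, taxon-weighted transfer signal — not that any particular
clinical accuracy will be reached on real cohorts.

## Study conditions used by the tests

The test suite and the acceptance script run at desk scale, with sizes chosen
so each phenomenon is well-powered: the main cohort uses 100 taxa over 8
orders, 100 donors with 4 recipients each (400 pairs) sampled at day 7,
$\delta = 0.7$, $\rho = 0.1$; regime comparisons use 75 donors per preset
with 4-fold recipient-grouped cross-validation; distance-hierarchy
replicates use 15-20 donors with 3 recipients each; the GA runs on a pool of
2000 profiles expanded from the cohort's 100 donors. Under these conditions
the image CNN reaches a held-out Shannon Spearman correlation of about 0.8
(10-fold grouped CV), against a raw univariate donor-recipient correlation of
about 0.5.

## Numerical choices and edge cases

* Relative-abundance detection on file read uses a 1e-6 tolerance on row
  sums; anything else is treated as counts and closed on demand.
* Re-normalizing an already log-normalized table is an error (no silent
  double transforms); all-zero sample rows are an error naming the sample.
* Fold assignment, model fits, the generator and the GA are deterministic
  given their seeds; the CNN trains single-threaded with a fixed minibatch
  stream per seed.
* GA tie-breaks: equal fitness resolves toward fewer non-zero taxa, then
  stable position; ranking ties resolve by donor id.
* Degenerate GA draws (all-zero offspring) fall back to a parent or the
  uniform composition; both keep the simplex invariant intact.
* Predictions for donors carrying taxa absent from the training axis are
  refused (rather than silently dropped) when those taxa are non-zero.

## Known limitations

* The CNN is intentionally small and CPU-bound; it is not tuned per task, and
  its hyperparameters are package defaults rather than a search result.
* `knn`'s probability output for presence tasks is a vote fraction, which can
  be coarse at small k.
* The generator's clinical outcome depends on recipient diversity alone;
  cohort-specific outcome definitions (e.g., severity indices) are inputs,
  not modelled.
* Pre-FMT samples are only generated when requested (`pre_fmt = TRUE`) and
  carry `days_post_fmt = 0`; analyses treat day 0 as "before transplant".
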