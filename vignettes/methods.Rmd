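---
title: "Methods: phylogenetic signal and trait-abundance models along an urbanization gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic signal and trait-abundance models along an urbanization gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanphylo)
```

## The question and the data

Urban remnant forests retain a filtered subset of the regional woody flora.
Because related species resemble each other, a correlation between a
functional trait and a species' success along the urbanization gradient can
be a real ecological filter or an artefact of shared ancestry. `urbanphylo`
operationalizes the analysis that separates the two. Its inputs are a
rooted species-level phylogeny with branch lengths (newick), a trait table
(`species`, `habit` ∈ {tree, shrub}, nine continuous traits), a patch table
(`patch_id`, impervious-surface percentage in the landscape buffer) and an
occupancy/abundance table (`species`, `patch_id`, `count` of individuals).

## Patch strata and species groups

Impervious cover classifies patches as low (< 20%), moderate (20–50%) or
high (> 50%) urbanization. The printed ranges leave the endpoints 20 and 50
ambiguous between bands; we read them literally, so both endpoints fall in
the moderate band (low = [0, 20), moderate = [20, 50], high = (50, 100]).
This matters only for patches sitting exactly on a threshold.

With H, M and L the sets of species present in at least one patch of each
stratum, species are partitioned as urban = H \\ L, rural = L \\ H,
general = H ∩ L, and middle = species found only under moderate
urbanization. These four sets cover every recorded species exactly once
(urban absorbs H ∩ M species, rural absorbs L ∩ M species), a property the
test suite asserts over randomized occupancy matrices. Groups are assigned
from the pooled species list; all downstream statistics are then run
separately per growth habit, since trees and shrubs respond differently to
urbanization while occupancy alone defines the grouping.

## Phylogenetic covariance

Under Brownian-motion evolution, tip values are multivariate normal with
covariance σ²V, where V(i, j) is the branch length shared by tips i and j —
the root-to-MRCA path length, with root-to-tip depths on the diagonal. V is
computed by a single pass over the tree in postorder and is valid for
non-ultrametric trees (a maximum-likelihood molecular tree is not
clocklike) and for polytomies. All statistics use V through its Cholesky
factor; V is never inverted explicitly.

Zero-length terminal branches (routine in ML trees) make V singular. They
are clamped to 10⁻⁸ × tree depth with a warning: a documented jitter is
preferable to a silent singular solve, and at that magnitude the
perturbation is far below the precision of any reported statistic. Missing
branch lengths are an error by default, with an opt-in substitution of 1.0.
Species names are matched between tree and tables exactly, case-sensitively,
after trimming whitespace and converting internal spaces to underscores;
mismatches abort with the complete offender list (a `drop` mode analyses
the intersection instead).

## Blomberg's K and its permutation null

For trait vector x on n species, the GLS root estimate is
â = (1ᵀV⁻¹1)⁻¹1ᵀV⁻¹x. K is the ratio of the unweighted to the
phylogenetically weighted mean squared error,

- MSE₀ = (x − â1)ᵀ(x − â1)/(n − 1),
- MSE = (x − â1)ᵀV⁻¹(x − â1)/(n − 1),

standardized by the Brownian expectation
E[MSE₀/MSE] = [tr(V) − n/(1ᵀV⁻¹1)]/(n − 1), so that K = 1 under Brownian
motion, K < 1 with weaker signal, K > 1 with stronger. K is invariant to
affine trait transforms and to rescaling all branch lengths; on an
equal-branch star phylogeny the algebra collapses and K ≡ 1 for any
non-constant trait — both are exact tests in the suite, and the Monte-Carlo
calibration (1000 Brownian traits on a 50-tip pure-birth tree) checks that
mean K sits near 1.

Significance comes from shuffling trait values across tips (default
`n_perm = 999`). The permutation statistic is the weighted MSE, with â
re-estimated for each shuffled vector; small MSE means trait variation
tracks the tree. One-tailed, with the add-one rule
p = (1 + #{null MSE ≤ observed})/(n_perm + 1), so p ∈ [1/(n_perm+1), 1].
A `statistic = "k"` option permutes on K itself (counting null K ≥
observed); the two differ only through the re-estimated MSE₀ and agree on
clear signals. The classical alternative of permuting the variance of
phylogenetically independent contrasts is deliberately not implemented —
the MSE route follows this package's definition of K directly, and
maintaining two inequivalent nulls under one flag invites
misinterpretation.

A group × trait cell needs at least 4 species (`min_n`); K on 3 species is
numerically meaningful but statistically vacuous, so smaller cells are
reported as `insufficient_n` with K and p absent rather than as an error or
a number. Constant traits are a `degenerate_trait` status, not K = 0.

## GLS and PGLS trait–abundance models

Each trait–abundance relationship is fitted twice with
β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y, X = [1, x]: once with V = I (ordinary least
squares) and once with V from the tree pruned to the cell's species
(PGLS — Brownian residuals). σ̂² = RSS_V/(n − 2), t = β̂₁/se(β̂₁), two-sided
p on n − 2 df. With V = I the code path reproduces closed-form OLS to
machine precision; the PGLS t is invariant to rescaling branch lengths; a
perfect fit reports t = ±∞ with p = 0 and a `degenerate fit` warning
instead of dividing by zero.

Three choices here were genuinely open and are exposed as configuration
rather than hard-coded:

- **Direction.** Abundance is the response and the trait the predictor by
  default (`response = "abundance"`). The slope t is direction-symmetric
  under OLS but not under PGLS, so the choice is visible, documented and
  switchable.
- **Abundance aggregation.** Total individual count per species summed over
  all patches. Per-patch means are a config alternative.
- **Transformation.** None by default; a log10 option for abundance exists
  but is off, since count scales are left untransformed in the reporting
  conventions this package mirrors.

Flags use p < .05 (strict) for signal tables and p < .01 (strict) for model
tables, with no multiple-testing correction — these are reporting
conventions of the table layout, not recommendations; all raw p-values are
emitted. Regression cells need at least 5 species (df ≥ 3).

## The synthetic-data generator

The generator emulates the study design end to end so the pipeline is
testable without survey data: a pure-birth (Yule) tree simulated forward
with exponential waiting times (birth rate 1 per lineage per unit time;
~100 species, matching a city-scale woody flora); nine traits as
independent latent Brownian variables mapped onto realistic positive scales
(germination rate through a logistic to (0, 100)); nine patches drawn three
per stratum; per-patch Bernoulli presence (default probability 0.2 per
patch, which yields all four occupancy groups at workable sizes on 100
species); and counts of 1 + negative binomial (dispersion 5 — woody-plant
counts are overdispersed; Poisson is the large-dispersion limit), whose
log-mean combines an intercept of log 5, a slope of 0.5 on the standardized
focal trait, and a Brownian random effect (log-scale SD 0.5 at mean tip
depth) so phylogenetic residual correlation is present by construction.

The trait signal weight w blends a Brownian realization with white noise of
matched marginal variance: w = 1 (the default) gives tip covariance σ²V
exactly — this is the regime under which PGLS's assumptions hold and
parameter-recovery tests are fair — and w = 0 destroys the signal, driving
K toward 0. For regression calibration specifically,
`simulate_pgls_data()` draws y = β₀ + β₁x + e with exactly multivariate
normal Brownian residuals, because the negative-binomial community counts
only approximate the PGLS model and would conflate model error with
estimation error in recovery tests.

What the generator does *not* emulate: spatial patch geometry and
edge/interior structure, environmental covariates, trait–trait correlation
(off by default; the analysis treats traits marginally), measurement error
in traits, and the taxonomic idiosyncrasies of a real flora. Passing tests
therefore demonstrate the statistical machinery is correct under its stated
model, not that any particular field dataset satisfies that model.

## Determinism and seeds

Every generator and the permutation test take explicit seeds and restore
the caller's RNG state. Pipeline cells derive their seed deterministically
from the root seed and the (habit, group, trait) labels, so any single cell
can be recomputed in isolation and results do not depend on execution
order. Identical config and seed give byte-identical report files.

## Problem sizes

The test suite calibrates with 1000 Brownian replicates on 50 tips (mean
K), 500 replicates × 199 permutations for test size, and 500 replicates at
n = 100 for PGLS recovery; pipeline round-trips use 40–60 species with 99
permutations. These sizes put Monte-Carlo error comfortably inside the
asserted bands (binomial 99% intervals for rejection rates) while keeping
the suite quick to run; the acceptance script uses the full sizes above.

## Known limitations

- PGLS assumes strict Brownian residuals; Pagel's-λ-optimized PGLS and OU
  correlation structures are out of scope.
- The permutation null is exchangeable-tips; no PIC-variance permutation.
- No multiple-testing correction is applied anywhere, by design of the
  table conventions.
- The pipeline consumes a finished phylogeny; alignment, tree inference,
  dating and ultrametricization are upstream problems.
- Occupancy grouping uses presence/absence only; abundance enters solely
  through the regressions.
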