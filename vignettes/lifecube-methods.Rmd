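---
title: "Methods: dimensionless life-history metrics and their macroevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimensionless life-history metrics and their macroevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecube)
```

## The scientific problem

Life-history traits carry units of mass and time, which makes a shrew and a
whale hard to compare directly. Charnov's three dimensionless metrics remove
those magnitudes so that strategies can be compared on a common scale:

* **LRE** (lifetime reproductive effort): litter size × litters per year ×
  mass at independence / adult body mass × adult lifespan. The lifetime
  allocation to offspring expressed in units of the mother's own mass.
* **RRL** (relative reproductive lifespan): adult lifespan / age at female
  maturity. Time available for reproduction relative to time spent reaching
  it.
* **ROS** (relative offspring size): mass at independence / adult body mass.

Together with (log) adult body mass these span a four-dimensional
"life-history cube". `lifecube` computes the metrics from compiled trait
tables, asks how they evolve along dated phylogenies (phylogenetic signal,
trait-evolution models, phylogenetic regression, evolutionary correlations),
and quantifies how much of the cube each clade occupies (kernel-density
hypervolumes and their overlaps).

"Mass at independence" is clade-specific by convention: fledging mass in
birds, weaning mass in mammals, hatchling mass in reptiles, offspring or egg
mass in amphibians. Adult lifespan is taken as maximum longevity minus age at
female maturity: the definition is the time from maturity to death, and
maximum longevity is the endpoint that compiled databases actually provide.
`adult_lifespan_mode = "raw_longevity"` is available for sensitivity runs.
Records in which maturity meets or exceeds longevity are excluded and flagged,
never silently passed through. Missing fields leave a metric *undefined* —
metrics are never imputed or zero-filled, and a species enters the metric
table only when all three metrics are computable.

Amphibian databases often report a snout–vent length (SVL) range rather than
a mean adult mass. `amphibian_mass_mode = "mean_mass_from_svl"` converts the
minimum and maximum SVL to mass through a user-supplied power-law allometry
(`a * svl^b`, group-specific for frogs and salamanders) and averages the two.
The coefficients are deliberately configuration, not constants: published
allometries differ by group and study, so `allometry_params()` makes the
choice explicit and auditable. When both offspring and egg mass exist for an
amphibian, the offspring value is preferred (configurable), since it is the
closer analogue of mass at independence.

## Data merging

Compiled trait data come from a primary database plus supplements.
`merge_trait_sources()` implements a strict precedence rule: values present
in the primary table always win; only fields missing in the primary are
filled from the supplement; species absent from the primary are appended
whole. Every filled cell is tagged with per-field provenance
(`primary` / `supplement`), duplicate species within a table are an error,
and species names are normalized (whitespace trimmed, spaces to underscores)
so they match Newick tip labels exactly. No synonym resolution is attempted —
matching is by exact name.

## Trait-evolution models and the likelihood engine

For a continuous trait $x$ on a rooted tree, Brownian motion (BM) makes tip
values multivariate normal with mean $z_0$ and covariance $\sigma^2 C$, where
$C_{ij}$ is the shared root-to-MRCA path length. Three transformations of $C$
give the other models:

* **Pagel's λ** multiplies off-diagonal entries by $\lambda \in [0, 1]$:
  $\lambda = 1$ is BM, $\lambda = 0$ a star phylogeny with no signal.
* **κ** raises each branch length to the power $\kappa \ge 0$ (with
  $0^0 := 0$); $\kappa = 0$ approximates speciational change.
* **Ornstein–Uhlenbeck (OU)**, mean reversion with pull $\alpha$, in its
  stationary form on an ultrametric tree of height $T$:
  $C_{ij} = \frac{1}{2\alpha} e^{-2\alpha (T - s_{ij})}(1 - e^{-2\alpha s_{ij}})$,
  which converges to the BM covariance $s_{ij}$ as $\alpha \to 0$.

Likelihoods are computed by a linear-time post-order pruning pass that
accumulates $\log|C|$, $\mathbf{1}'C^{-1}\mathbf{1}$, $\mathbf{1}'C^{-1}x$
and $x'C^{-1}x$ without ever forming $C$; each shape parameter is realized as
an edge-length substitution on the fixed topology (λ scales edges and
re-extends terminal branches; κ exponentiates; OU remaps node heights through
the monotone function $g(h) = e^{-2\alpha(T-h)}(1 - e^{-2\alpha h})/2\alpha$,
written in `expm1` form to avoid cancellation at small $\alpha$). Polytomies
and zero-length internal branches are handled naturally; a zero-length
terminal branch is an error because the tip density is then degenerate.

Given a shape parameter, $z_0$ (GLS mean) and $\sigma^2$ (mean squared GLS
residual) are profiled in closed form; the shape parameter itself is
optimized by Brent search with tolerance $10^{-8}$ on $\lambda \in [0,1]$,
$\kappa \in [0,3]$ and $\ln\alpha \in [\ln(10^{-8}/T), \ln(100/T)]$, with the
interval endpoints also evaluated explicitly because boundary optima
($\lambda = 1$, $\alpha \to 0$) are common. Everything is ML, not REML, so
that AIC values are comparable across models; `n_params` is 2 for BM and 3
otherwise, and model selection takes the minimum AIC with exact ties broken
toward fewer parameters and then a fixed model order, making the choice
invariant to the order in which fits are supplied.

A statistical caveat worth stating: on data truly generated by BM, the
three-parameter alternatives each overfit with the usual chi-square tail
probability (2Δlogℓ exceeds the 2-unit AIC penalty in roughly 8–16% of
datasets), so min-AIC selection returns κ or OU in roughly a quarter of
BM-generated replicates. This is a property of AIC itself, not of the
likelihood computation, which is validated against dense matrix evaluation
to $10^{-8}$.

## Phylogenetic signal

`phylo_signal_lambda()` estimates λ by ML and attaches a permutation
p-value: tip values are shuffled across the fixed tree, the likelihood-ratio
statistic $2(\log\ell(\hat\lambda) - \log\ell(\lambda = 0))$ is recomputed
for each permutation, and $p = (1 + \#\{LR_{perm} \ge LR_{obs}\})/(B + 1)$.
With $B = 999$ the smallest attainable p is 0.001, the floor a strongly
signalled trait will sit on. The permutation approach is distribution-free
and reproducible under a seed; a chi-square LRT would be an alternative but
behaves poorly at the $\lambda = 0$ and $\lambda = 1$ boundaries. Constant
traits return a degenerate-flag result rather than a spurious estimate.

## Phylogenetic regression

`pgls()` regresses one log metric on log mass with error covariance
proportional to the tip covariance of a chosen evolutionary model — in the
pipeline, the best-AIC model of log body-mass evolution for that clade, so
the regression's correlation structure is informed by how mass itself
evolved. The covariance scale is profiled out; standard errors use
$RSS_V/(n-2)$ and two-sided t tests. With a λ = 0 transform on an
ultrametric tree PGLS is exactly OLS, and under BM the slope equals the
independent-contrasts regression through the origin — both are used as test
oracles.

`mv_pgls()` fits the three log metrics jointly on log mass under a *shared*
Pagel's λ: response $k$ has tip covariance $R_{kk} C_\lambda (+ e_k I)$ and
responses $k, l$ share $R_{kl} C_\lambda$. The evolutionary covariance $R$
of the residuals, standardized to correlations
$r_{kl} = R_{kl}/\sqrt{R_{kk} R_{ll}}$, measures correlated evolution among
the metrics *after* controlling for body mass — the quantity of interest,
since shared mass allometries would otherwise induce spurious correlations.
With measurement error off, B and R have closed matrix-normal forms given λ
and only λ is profiled. With `estimate_error = TRUE`, per-response error
variances $e_k$ are estimated as nuisance parameters: rotating by the
eigenvectors of $C_\lambda$ makes tips independent with per-tip covariance
$d_i R + \mathrm{diag}(e)$, so each likelihood evaluation is
$O(n\,m^3)$; the optimizer works on $(\lambda, e, \mathrm{chol}(R))$ with B
profiled by GLS, started from the closed-form no-error fit. A shared λ
across responses is the convention of the multivariate phylogenetic GLS
literature; per-response λ is out of scope. Multivariate fits are
complete-case only — no imputation.

## Ancestral states, ANOVA, supertree

`asr_bm()` returns, for every internal node, the GLS/ML conditional
expectation of the node state given the tips under BM, with the root at the
GLS phylogenetic mean — on a star tree the root is the arithmetic tip mean,
and on a two-tip tree the precision-weighted mean. `class_anova()` treats
clades as independent groups (their stems diverged deep in the Paleozoic, so
cross-clade phylogenetic covariance is negligible relative to within-clade
structure) and runs a standard one-way ANOVA with Tukey HSD pairwise
comparisons on the natural-log metrics.

`stitch_trees()` builds the tetrapod supertree from dated clade trees and a
table of divergence ages: clades attach along a ladder backbone in a stated
nesting order — the shipped default is (Amphibia,(Mammalia,(Reptilia,Aves)))
— with each stem branch equal to attachment age minus crown age. Within-clade
distances are preserved exactly and the result is ultrametric by
construction; a crown age at or above its attachment age is an error naming
the clade. This calibration arithmetic is a deliberate, simpler replacement
for congruification-style dating pipelines, which are out of scope.

## Hypervolumes

Each clade's cloud of species in (log mass, log LRE, log RRL, log ROS) is
summarized by a Gaussian kernel density estimate with per-dimension
(diagonal) Silverman bandwidths
$b_j = (4/((d+2)n))^{1/(d+4)} \, s_j$. The hypervolume is the region where
the density exceeds the threshold $t$ enclosing fraction $q$ (default 0.95)
of the probability mass. $N$ points (default $10^5$) are drawn from the KDE
itself; $t$ is the empirical $(1-q)$ quantile of their densities; and the
volume is the importance-sampling estimate
$\hat V = \frac{1}{N}\sum_i \mathbf{1}\{f(x_i) \ge t\}/f(x_i)$, which is
unbiased for the Lebesgue volume of the super-threshold region. Pairwise
intersections are estimated the same way from the balanced mixture
$(f_1 + f_2)/2$, with each point counted when it clears both thresholds;
Sorensen similarity is $2V_\cap/(V_1 + V_2)$ and the unique fraction
$(V_i - V_\cap)/V_i$. Seeding each component's half-sample identically makes
the overlap exactly symmetric in its arguments, and widely separated clouds
give a Sorensen of exactly zero (no pooled point clears both thresholds).
This estimator is a reproducible, unbiased *approximation of* — not a clone
of — the point-process heuristics used by the established hypervolume
package; volumes are reported in log-unit$^d$ and are meant for relative
comparison. The computational kernel (KDE evaluation at $N$ points) is in
C++; the data are sorted on the first axis so only the kernel support window
is scanned, which is exactly equivalent to the analytic cutoff of
negligible terms (squared standardized distance > 120).

Choices that matter: `q` trades interpretability against noise (0.95 is the
field convention); bandwidths are diagonal, so strongly correlated clades
are smoothed isotropically; with very small bandwidths in $d \ge 2$ the KDE
mass region becomes granular and volumes are underestimated, so volume
checks against analytic Gaussian regions use either 1-D (where small
bandwidths are safe) or the Silverman default.

## The synthetic-data generator

`generate_trait_database()` produces the study system the tests and the
acceptance script exercise: four clades at the compiled per-clade species
counts (113 amphibians, 491 reptiles, 842 mammals, 171 birds by default),
Yule trees rescaled to crown ages in the range of the published timetrees
(310, 190, 170, 110 Myr), log body mass evolving under OU in the ectotherm
clades and Pagel's λ (0.99) in the endotherm clades, and log metrics built
as intercept + slope × log mass + correlated Brownian residuals (shared
λ = 0.9, LRE–RRL correlation 0.6, LRE–ROS 0.5, RRL–ROS 0) — slopes and
correlations default to the magnitudes reported for the real compilation,
e.g. a ROS-on-mass slope of −0.38.

The metric formulas are then inverted to raw database fields. Four raw
fields map to three metrics, so the inverse is underdetermined; the
generator fixes litters per year at 1 and draws maturity from a lognormal
(meanlog log 2, sdlog 0.5 — a typical few-year maturation), after which
longevity, litter size and independence mass are determined exactly:
longevity = maturity(1 + RRL), independence mass = ROS × mass,
litter = LRE/(ROS × lifespan). This convention keeps the round trip exact
to floating-point precision, which the tests assert at 10⁻¹². Fields are
then masked at configurable rates and split between a primary and a
supplement table (a configurable share of masked values reappears in the
supplement, and some species exist only there), emulating the multi-source
compilation workflow. OU traits are simulated exactly through their
covariance matrix, never by Euler stepping.

What the generator does *not* emulate: real taxon-sampling biases, the
source databases' exact column vocabularies (a configurable column map
covers renaming), measurement error in the raw fields, and non-Gaussian
trait distributions. Passing recovery tests therefore demonstrate that the
estimators are consistent and unbiased under their own model assumptions at
realistic sizes — not that the assumptions hold for any particular empirical
compilation.

## Validation sizes and reproducibility

The test suite and the acceptance script size their simulations to what the
statistics require rather than the full compilation: likelihood oracles use
100 trees of 4–12 tips against dense matrix algebra; λ recovery uses 200-tip
trees (50–100 replicates); multivariate correlation recovery uses 300-tip
trees; the end-to-end pipeline recovery uses four clades of 300 species over
20 replicate seeds; hypervolume geometry uses 10⁴-point Gaussian samples
with 10⁵ Monte-Carlo points. Every random draw descends from a single seed
through a fixed fan-out scheme, so any stage can be reproduced in
isolation; reruns with the same configuration are bit-identical, and the
pipeline writes a manifest (config hash, seeds, per-stage wall time, record
counts at every filter) alongside its tables.

## Known limitations

* Single fixed tree per run: no phylogenetic uncertainty propagation.
* OU is single-optimum and defined on ultrametric trees only; no
  early-burst or trend models.
* λ is restricted to [0, 1] (the PSD-safe range that the reported estimates
  occupy); the extended upper bound some implementations allow is not used.
* Hypervolume kernels are axis-aligned; full-covariance kernels and
  hole-detection analyses are out of scope.
* Exact-name species matching only; taxonomic reconciliation belongs
  upstream.
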