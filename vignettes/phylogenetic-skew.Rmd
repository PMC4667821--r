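---
title: "Phylogenetic skew: model, estimation, and mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic skew: model, estimation, and mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloskew)
```

## The question the indices answer

Two communities with identical species richness can differ radically in
how their species are spread over the tree of life: one may sample clades
evenly, the other may be crowded into a single radiation. `phyloskew`
quantifies that difference with a generative model rather than a
resemblance statistic. The species pool (*meta-community*) is assumed to
have diversified under a constant-rate birth–death process; a local
community is viewed as a *sample* of the pool, and we ask what sampling
fraction would best explain the ages of the community subtree's internal
nodes. Clade-crowded communities have systematically *young* pairwise
divergences — exactly the signature of a densely sampled clade — so their
best-fitting ("effective") sampling proportion $\hat\rho_E$ exceeds the
actual proportion $\rho_0 = \mathrm{SR}/S_{meta}$. Phylogenetic skew is
$PS = \hat\rho_E/\rho_0$ and phylogenetic-clade evenness its reciprocal,
$PE = 1/PS$.

## The likelihood

For a community of $s$ species with ordered subtree node ages
$t_1 > \dots > t_{s-1}$ (all in the tree's relative time units, tips at
age 0), conditional on the root age $t_1$ the remaining $s-2$ ages are
i.i.d. with density $\lambda p_1(t)/v_{t_1}$ on $(0, t_1)$:

$$P(0,t) = \frac{\rho(\lambda-\mu)}
  {\rho\lambda + (\lambda(1-\rho)-\mu)e^{(\mu-\lambda)t}}, \qquad
  p_1(t) = \frac{1}{\rho}P(0,t)^2 e^{(\mu-\lambda)t}, \qquad
  v_t = 1 - \frac{1}{\rho}P(0,t)e^{(\mu-\lambda)t},$$

$$\log L = \log (s-2)! \;+\; \sum_{j=2}^{s-1}
  \log\frac{\lambda\, p_1(t_j)}{v_{t_1}}.$$

Two consequences the test suite exploits: $v_t' = \lambda p_1(t)$, so
$v_t/v_{t_1}$ is the CDF of a single age and the density integrates to 1;
and at $\mu = 0, \rho = 1$ the factors collapse to the Yule forms
$p_1 = e^{-\lambda t}$, $v = 1-e^{-\lambda t}$. The factorial term is
included in reported values so likelihoods are comparable across
software; it never affects an argmax. The model conditions on the
*community's own* $t_1$, not the meta-tree root age.

## Two-step estimation

**Step 1** (`fit_speciation_extinction`): with $\rho$ fixed (1 for a
completely sampled pool), maximize over $(\lambda, \mu)$. The search runs
on $(\log\lambda,\ \mathrm{logit}(\mu/\lambda))$, which enforces
$\lambda > \mu \ge 0$ without a constrained solver, with Nelder–Mead from
10 Latin-hypercube starts drawn under a fixed internal seed (the caller's
RNG is untouched); `n_starts_agreeing` reports how many starts land
within $10^{-4}$ of the best log-likelihood, a cheap ridge diagnostic.
Standard errors are square roots of the diagonal of the inverse numerical
observed-information matrix (`stats::optimHess`) on the natural
$(\lambda,\mu)$ scale; they are suppressed when $\hat\mu$ sits on its 0
boundary, where the quadratic approximation fails. At least $s \ge 4$
species (3 node ages) are required so that two free ages inform two
rates. Note the single-tree estimates are noisy: $\lambda$ and $\mu$ are
strongly positively correlated along a likelihood ridge (their difference
is much better determined than each alone), which is why calibration
statements in the tests are about means over replicates.

**Step 2** (`fit_sampling_proportion`): holding $(\hat\lambda,\hat\mu)$
fixed, maximize over $\rho \in [\rho_{min}, 1]$ alone,
$\rho_{min} = 10^{-6}$. The 1-D profile is evaluated on a deterministic
41-point logit-spaced grid and refined by `stats::optimize` on the
bracketing interval; the grid guards against flat or multimodal profiles
that a single golden-section search could mishandle. Estimates within
$10^{-5}$ of either end are flagged as boundary hits and get no standard
error.

## The other indices, and their conventions

* **Faith's PD** is the total branch length of the minimum spanning path
  connecting the members — implemented as the induced subtree
  (unary nodes suppressed) and summed. This is the *unrooted* convention:
  the stem below the members' MRCA is not counted. The rooted variant
  would differ for nested subsets; the unrooted one makes "PD of the full
  tip set = total branch length" exact.
* **AvTD** is the mean patristic distance over member *pairs* on the same
  time tree (twice the mean MRCA age on an ultrametric tree), not a
  Linnaean-taxonomy statistic despite the name. Dividing by species
  instead of pairs would rescale each community by $(s-1)/s$ — a
  monotone, rank-preserving change — so the pairs denominator is used and
  documented rather than offered as an option.
* **$S_{meta}$ is a parameter**, defaulting to the tree's tip count, so
  synthetic pools of any size work.
* PS/PE are computed only for communities with at least 11 species
  (`min_sr_ps`, "more than 10"): below that, $\hat\rho_E$ has a strong
  small-sample bias (few ages, heavy boundary attraction). PD and AvTD
  only need 2.

## Gridding, ranking, priorities

Occurrence records rasterize by `floor()` to integer 1×1-degree cells
(cell $(i,j)$ covers $[i,i+1)\times[j,j+1)$; no wraparound merging at
±180°), presences deduplicate, and cells with fewer than 11 species are
dropped before index mapping. Percentile ranks use the mid-rank tie
convention, $100\,(r-0.5)/n$ with average ranks, which is invariant under
strictly increasing transforms. "Top 5%" priority selection flags the
cells at or above the $k$-th largest value with
$k = \lceil (1-q)\,n \rceil$ (ties included, so a flag set can exceed
$k$); with 100 distinct cells at $q = 0.95$ exactly 5 are flagged. The
ceiling is computed with a $10^{-9}$ guard because $(1-0.95)\times 100$
exceeds 5 in double precision. The phylogenetic priority set is the union
of the PD, AvTD and PE flags; the full set adds SR. Latitudinal trends
use 10-degree bands plus LOWESS (span 2/3, tricube weights) against
absolute and signed latitude.

## The synthetic-data generator

The generator exists so every stage is testable without the proprietary
occurrence database, and it is built to be *mutually validating* with the
likelihood: trees are simulated ages-first — draw $t_1$, then draw the
remaining node ages i.i.d. by closed-form inverse of the CDF
$v_t/v_{t_1}$, then build the topology backward by merging uniformly
chosen lineage pairs at each successive age. For the constant-rate
reconstructed process, ranked labeled topologies are uniform given the
ages, so this backward pairing reproduces the model exactly; it is what
makes "simulate under $(\lambda,\mu,\rho)$, estimate, recover" a fair
test. The default root age is drawn by rejection from the forward
process (Gillespie from 2 lineages until $n/\rho$ survive, extinct runs
rejected); `root_age = 1` fixes it for unit-scale tests.

Grid scenarios plant the latitudinal signal of interest: tropical cells
($|$lat$| < 23.5°$) draw their species clade-biased with probability
`skew_strength`, temperate cells uniformly. Defaults mirror the study
conditions at desk scale: a 236-species pool at $(\lambda, \mu) =
(17, 6)$ — the meta-community estimates — 100 cells split evenly between
the bands, and `base_rho0 = 0.2` (about 47 species per cell, safely above
the richness filter; communities are resampled until they hold at least
11 species). The favored clade defaults to the one closest to a quarter
of the tips; inside/outside inclusion odds are about 20:1, rescaled so
the expected community size still matches `base_rho0`. All randomness
flows from the mandatory scenario seed; written CSVs embed it in a `#`
comment header.

What the generator does **not** emulate: range-polygon rasterization
(records are points), spatial autocorrelation between neighboring cells
(cells are independent draws), detection failure, taxonomic error, or any
ecological mechanism producing clade skew — the biased-inclusion model is
a test harness, not a biogeographic claim. Passing the planted-signal
tests therefore shows the *estimator chain* works, not that real
communities assemble this way.

## Numerical choices and degenerate inputs

* Ultrametricity is checked with relative tolerance $10^{-6}$; within it,
  tip ages snap to exactly 0. Polytomies are rejected by default (the
  likelihood assumes a strictly ranked history) and can be resolved
  randomly with zero-length branches on request.
* Tied node ages — common in files rounded to few digits — are broken
  deterministically by subtracting $k\varepsilon$
  ($\varepsilon = 10^{-9}\times$ root age, $k$ the 0-based occurrence
  index), so ordered-times vectors are strictly descending as the density
  requires, at a perturbation far below any biological signal.
* $s = 2$ communities have an empty likelihood product
  ($\log L = 0$); non-root ages at or above $t_1$ are an error, not a
  silent clamp.
* Likelihood evaluations that overflow or leave the domain return a large
  finite penalty inside the optimizers, so multi-start search recovers
  rather than aborts.

## Problem sizes in the shipped tests

The suite simulates at sizes chosen to keep the full run around two
minutes on one core while leaving calibration bands comfortably
resolvable: 50 replicate fits of 200-age datasets for rate recovery
(means within 15% of truth), 100 uniform and 100 clade-restricted
subsamples of a 236-tip tree for PS calibration (mean in $[0.8, 1.2]$;
median $> 1.5$), a 100-cell end-to-end grid, and exhaustive
subset-vs-oracle comparisons on 8-tip trees (all 247 subsets of 20
trees). `scripts/acceptance.R` re-runs the same pipeline from a
command-line seed.

## Known limitations

* Constant rates: no time-varying, diversity-dependent, or
  lineage-specific $(\lambda, \mu)$; a single tree is consumed as-is
  (no averaging over a posterior sample of trees).
* $\hat\rho_E$ inherits the noise of the step-1 estimates; errors in
  $(\hat\lambda,\hat\mu)$ propagate into every cell's PS with the same
  sign, so *between-cell contrasts* are more trustworthy than absolute
  PS values.
* Time units are relative (a molecular-rate-scaled tree is fine); rates
  are per unit of that same scale and are never silently rescaled.
* PS is undefined below 11 species, so species-poor cells are invisible
  to the skew map no matter how distinctive they are.
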