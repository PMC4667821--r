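# phyloskew

Community phylogenetics for conservation mapping: given a time-scaled
ultrametric phylogeny of a species pool (the *meta-community*) and
geo-referenced occurrence records, `phyloskew` computes, for every
1×1-degree grid cell, species richness (SR), Faith's phylogenetic
diversity (PD), average taxonomic distinctness (AvTD), and a pair of
model-based composition indices — **phylogenetic skew (PS)** and its
reciprocal, **phylogenetic-clade evenness (PE)** — then ranks cells by
percentile and selects top-percentile priority cells. It is aimed at
macroecologists and conservation planners who want to locate communities
whose species are crowded into few clades (high PS) or spread evenly
across the tree (high PE).

## The model

The internal node ages of a community's induced subtree,
`t_1 > t_2 > … > t_{s−1}` (`t_1` the subtree root age), are modelled by
the generalized birth–death process with speciation rate λ, extinction
rate μ and sampling proportion ρ. Conditional on `t_1`, the non-root ages
are i.i.d. with density `λ p1(t) / v(t_1)` on `(0, t_1)`, where

    P(0,t) = ρ(λ−μ) / (ρλ + (λ(1−ρ)−μ) e^{(μ−λ)t})
    p1(t)  = (1/ρ) P(0,t)² e^{(μ−λ)t}
    v(t)   = 1 − (1/ρ) P(0,t) e^{(μ−λ)t}

so the log-likelihood of the ordered times is
`log(s−2)! + Σ_{j≥2} log[λ p1(t_j) / v(t_1)]`.

Estimation is two-step. **Step 1:** with ρ fixed at 1, maximize the
likelihood of the full meta-community tree's divergence times over
(λ, μ). **Step 2:** holding (λ̂, μ̂) fixed, maximize over ρ alone for each
grid cell's induced subtree, giving the *effective sampling proportion*
ρ̂_E — the sampling fraction that best explains how young or old the
cell's divergences are. With ρ₀ = SR / S_meta the *actual* sampling
proportion,

    PS = ρ̂_E / ρ₀        PE = ρ₀ / ρ̂_E = 1 / PS.

A random draw from the pool gives PS ≈ 1; members concentrated in few
clades have young divergences, which mimic denser sampling and push
ρ̂_E — hence PS — above 1.

## Worked example

Everything below is synthetic and reproducible — no downloads needed.

```r
library(phyloskew)

# a 236-species meta-community tree evolving at lambda = 17, mu = 6
tree <- simulate_timetree(236, bd_params(17, 6, 1), seed = 7)

# step 1: rates from the meta-tree's 235 ordered node ages
fit <- fit_speciation_extinction(divergence_times(tree))
fit
#> birth-death ML fit
#>   lambda = 19.2285  mu = 10.8612  rho = 1.000000
#>   SE: lam = 2.423, mu = 5.060
#>   logL = 1462.0353  converged = TRUE  starts agreeing = 6

# step 2: a uniform 20% community is unskewed ...
m <- sample_community_random(tree, 0.2, seed = 42, min_size = 11)
community_indices(tree, m, fit$params)
#>   sr   pd avtd  rho0  rhoE   ps    pe flags
#> 1 48 5.68  0.5 0.203 0.278 1.37 0.731

# ... while a clade-concentrated community of the same size is skewed
nd <- pick_skew_clade(tree, 0.25)
mc <- sample_community_clade_biased(tree, nd, p_in = 0.8, p_out = 0.02,
                                    seed = 42, min_size = 11)
community_indices(tree, mc, fit$params)
#>   sr pd  avtd  rho0  rhoE   ps   pe flags
#> 1 46  4 0.319 0.195 0.629 3.23 0.31
```

Reading the output: both communities hold ~47 of 236 species
(ρ₀ ≈ 0.2). The uniform draw's divergence times look like a 28% sample
(PS 1.37, within the calibration band), while the clade-biased draw's
young divergences look like a 63% sample — PS 3.2, a strongly skewed
community with correspondingly lower PD and AvTD.

The full spatial pipeline goes through an occurrence table:

```r
sc  <- grid_scenario(skew_strength = 1, n_cells = 100, seed = 5)
g   <- generate_grid(sc)                      # tree + occurrences + truth
grid <- filter_cells(build_grid(g$occurrences, tree = g$tree))  # >10 spp
tab <- cell_index_table(grid, g$tree, fit$params)
pri <- select_priority(tab, quantile = 0.95)  # top-5% flags and unions
correlate_indices(tab)                        # SR/PD/AvTD/PE Pearson matrix
latitude_profile(tab, "pe")                   # banded means + LOWESS trend
```

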