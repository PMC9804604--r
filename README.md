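# pollinet

Persistence of plant–pollinator networks under habitat restoration.

`pollinet` asks a restoration-ecology question with a dynamical model: when
invasive plants are removed from a site, what happens to the long-term
persistence of the remaining plants and pollinators? It is aimed at network
ecologists who have bipartite visitation networks (plants × pollinators,
entries = visit counts) collected under contrasting management treatments,
and who want to go beyond static network description to simulated population
persistence.

## The model

Each network is given population dynamics following the mutualistic
Lotka–Volterra model with a type-II (saturating) functional response. For
plant *i* with abundance density `S_i^P`:

```
dS_i^P/dt = α_i S_i^P − Σ_{j∈P} β_ij S_i^P S_j^P
            + S_i^P · (Σ_{k∈A} γ_ik S_k^A) / (1 + h Σ_{l∈A} γ_il S_l^A)
```

and the pollinator equations are the mirror image with the guilds exchanged.
Here `α_i` is the intrinsic growth rate, `β_ij` within-guild competition
(intraspecific `β_ii` stronger than interspecific `β_ij`), `γ_ik` the
per-link mutualistic strength (positive exactly where the observed network
has a link), and `h` the handling time that saturates the benefit when
partners are abundant.

Every replicate run redraws all parameters uniformly from fixed intervals
(`α ∈ [0.85, 1.1]`, `β_ii ∈ [0.99, 1.01]`, `β_ij ∈ [0.22, 0.24]`,
`γ ∈ [0.19, 0.21]`, `h = 0.1`, initial abundances `∈ [0, 1]`) and integrates
the system to its asymptotic state; a species is extinct in a run when its
final abundance density falls below `10⁻¹⁰`. **Persistence** is the fraction
of runs in which a species survives; network-level persistence is the mean
over species, overall and per guild.

Around the simulator the package provides:

* data preparation as used for monthly visitation networks: invertebrate-only
  guild filtering, largest-component restriction, early/late-season pooling
  (`filter_guild()`, `largest_component()`, `pool_season()`);
* the persistence predictors: NODF nestedness, spin-glass modularity,
  weighted closeness centrality and Blüthgen specialisation *d′*
  (`nodf()`, `find_modules()`, `weighted_closeness()`,
  `specialisation_dprime()`);
* a synthetic generator emulating the restored/unrestored × early/late-season
  study design, including a dominant invasive generalist plant present only
  in unrestored sites (`synthetic_design()`, `generate_dataset()`);
* a tidy pipeline joining everything into analysis-ready tables for
  downstream beta-error mixed models (`run_study()`, `summarize_contrast()`,
  `export_model_table()`, `autoplot()`).

## A worked example

```r
library(pollinet)

design  <- synthetic_design(seed = 1)            # 8 sites x 8 months
dataset <- generate_dataset(design)              # 64 monthly networks
season  <- pool_dataset(dataset)                 # 16 seasonal networks

cfg   <- dynamics_config(n_runs = 100, seed = 1)
study <- run_study(season, cfg)

summarize_contrast(study)[, 1:5]
#> # A tibble: 4 × 5
#>   treatment  period     n persistence_plants_mean persistence_plants_sd
#>   <chr>      <chr>  <int>                   <dbl>                 <dbl>
#> 1 restored   early      4                   0.487                0.0497
#> 2 restored   late       4                   0.816                0.0838
#> 3 unrestored early      4                   0.486                0.0583
#> 4 unrestored late       4                   0.561                0.0782
```

Late-season plant persistence is markedly higher in restored sites (0.816
vs 0.561 above): where the invasive generalist still flowers, pollinators
abandon their minor native resources for it and the invasive's own large
population competes with the natives, excluding the weakly connected ones.
The corresponding pollinator columns show the opposite late-season ordering
(0.430 restored vs 0.562 unrestored) — the invasive plant is a major
late-season resource, so pollinator persistence is *higher* in unrestored
sites — and essentially no early-season difference (0.309 vs 0.311). `autoplot(study)` draws the treatment-by-season box plots,
`tidy(study)` returns the species-level table (persistence joined with
closeness and *d′*), and `export_model_table()` writes the CSVs a
`glmmTMB`-style beta-error mixed model would consume.

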