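# nichedyn

Range shifts and climatic niche shifts of species between two survey
periods, from gridded presence data.

## What it is for

Resurveyed occurrence grids — two breeding-bird atlases a few decades
apart, repeated survey routes — record how species' geographic ranges moved
while the climate changed. Whether a species *tracked* its climate during
that move is informative about transient dynamics: **niche unfilling**
(historically occupied climate left unoccupied) points to dispersal
limitation and delayed colonization, while **niche expansion** (occupancy
of climates not used historically) points to extinction debt, competitive
release or adaptation. `nichedyn` computes these diagnostics for whole
cohorts of species and relates them to species traits, and ships a
virtual-species simulator so every step can be validated against planted
mechanisms.

## The method in brief

For each species, occurrences of both periods and the available background
(all cells within a 500 km buffer of any presence) are placed in a common
two-dimensional space — geographic (km, equal-area) or climatic (the first
two axes of a PCA over the 19 bioclimatic variables, fitted on the pooled
background of both periods). In each space, the occurrence density is
estimated by Gaussian-kernel density on a 100 × 100 lattice and corrected
for availability:

    z(x) ∝ occurrence density(x) / background density(x),  Σ z = 1

Between the historical surface z₁ and current surface z₂ the package
computes:

* **Schoener's D** = 1 − ½ Σ |z₁ − z₂|  (0 = disjoint, 1 = identical);
* the standardized partition **U** (unfilling), **S** (stability),
  **E** (expansion) with U + S + E = 1, restricted in climate space to
  analogue climate, with the non-analogue masses reported as niche
  abandonment (A_n) and pioneering (P_n);
* the **centroid shift** distance (km) and compass bearing;
* translation null-model **similarity tests** (the current surface is
  randomly shifted; rank p-values with the plus-one rule) yielding range
  lagging / niche tracking / switching labels;
* **niche coverage** (share of the regional niche inside the global niche
  footprint) and Shannon **niche breadth**, used with occurrence-count and
  prevalence rules to filter species before analysis;
* phylogenetic regressions of logit-transformed metrics on standardized
  traits under a Pagel's-λ covariance, with exhaustive AIC subset selection
  and permutation variable importance.

The methods vignette (`vignettes/niche-range-dynamics.Rmd`) documents every
model, default and numerical choice.

## Worked example

The `analysis/` scripts run the whole study on a simulated cohort — 30
virtual species on a 40 × 40 grid of 50 km cells whose climate warms by
1 °C and dries by 50 mm between periods, with each species' dispersal limit
tied to its hand wing index:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_run_pipeline.R
Rscript analysis/03_summarise_dynamics.R
Rscript analysis/04_summarise_traits.R
```

Step 2 prints, for seed 1:

```
  30 / 30 species pass the filters
  mean range shift 166 km (range 84-268 km)
  mean range overlap D = 0.71, mean niche overlap D = 0.77
```

and step 3 summarises the dynamics (medians over species: geographic
S = 0.76, climate S = 0.79) and the similarity tests — every species shows
significantly low niche unfilling, as expected for a cohort whose median
dispersal limit is large relative to the ~200 km climate displacement.
Step 4 recovers the planted mechanism:

```
Hand wing index -> niche unfilling: -0.91 [-1.07, -0.75]
```

efficient flyers track the shifting climate and leave less of their
historical niche unfilled.

The same functions work on real inputs: climate grids
(`cell_id,x_km,y_km,bio1..bio19`), occurrence tables
(`species,period,cell_id,x_km,y_km`), a Newick phylogeny and a trait CSV,
via `run_pipeline()` or the individual exported functions
(`compute_bioclim()`, `fit_pca()`, `estimate_density()`, `schoener_d()`,
`dynamics_partition()`, `similarity_test()`, `pgls_fit()`, ...).

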