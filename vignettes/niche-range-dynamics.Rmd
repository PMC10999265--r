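---
title: "Quantifying range shifts and climatic niche shifts between two survey periods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying range shifts and climatic niche shifts between two survey periods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When climate shifts, species redistribute — but not instantaneously.
Dispersal limitation delays colonization of newly suitable areas, and slow
local extinction (extinction debt) delays retreat from areas that have
become unsuitable. Comparing how a species' *geographic range* and its
*realized climatic niche* change between two survey periods is a screening
tool for these transient dynamics: a species that tracks climate perfectly
keeps its climatic niche even while its range moves; a dispersal-limited
species leaves part of its historical niche unoccupied (niche unfilling);
a species persisting in now-unsuitable places occupies novel climate
(niche expansion).

`nichedyn` implements this comparison for gridded two-period occurrence
data (breeding-bird atlases and similar resurveys are the motivating case),
together with a virtual-species simulator so that every inference step can
be validated against mechanisms that are known because they were planted.

## The estimation pipeline

### Climate space

The 19 bioclimatic variables (BIO1–BIO19) are derived from monthly
temperature and precipitation with the conventional definitions: quarters
are any three consecutive months with December–January wraparound, ties
between candidate quarters are broken by the earliest starting month (a
fixed tie rule is needed for determinism), BIO4 is the (n−1)-denominator
standard deviation of monthly mean temperature × 100, and BIO15 is the
coefficient of variation of monthly precipitation with the denominator
guarded to 1 only when the mean is exactly zero. Yearly values are averaged
over each period's years.

Climate space is the first two axes of a PCA. The variables are centred
**and scaled to unit variance** before the eigendecomposition: the variables
mix degrees Celsius and millimetres, and unscaled PCA would let
precipitation totals dominate. This is stated as a modelling choice because
analyses of this kind do not always document it. For shift analyses the PCA
is fitted on the species' background (both periods pooled), so the two
periods share one climate space per species; for coverage analyses it is
fitted on the global grid.

### Availability-corrected density surfaces

Occurrences and availability are both turned into Gaussian-kernel densities
on a regular lattice (default 100 × 100), in geographic space and in PCA
space with the *same* routine — nothing in the code branches on which space
is in use. The corrected density is occurrence density divided by
background (availability) density, then renormalized to unit mass, so a
species that uses climates in proportion to their availability gets a flat
surface.

Numerical choices, all logged in the output metadata:

* **Bandwidth** — per-axis Silverman normal-reference rule (`bw.nrd0`),
  computed separately for the occurrence and background sets.
* **Background truncation** — background density below its own 1st
  percentile (of positive values) is treated as unavailable; the ratio is
  not evaluated there. This prevents explosive ratios at the fringe of the
  background.
* **Occurrence truncation** — a Gaussian kernel is positive everywhere, so
  without a second truncation every surface would "occupy" the entire
  footprint and the unfilling/stability/expansion partition would be
  degenerate. Lattice nodes whose occurrence density falls below the 1st
  percentile of the density evaluated *at the occurrence points themselves*
  are treated as unoccupied. The occupancy mask is `z > 0` after both
  truncations.
* **Background buffer** — all study-area cells within 500 km of any
  presence of either period, approximating what the species could have
  reached by dispersal.

The test suite verifies that the headline metrics are stable across lattice
resolutions 50, 100 and 200.

### Overlap, partition, analogue climate

Schoener's D, `1 − ½ Σ|z₁ − z₂|`, measures overlap of the two normalized
surfaces. The dynamics partition splits density mass by the occupancy
masks: unfilling **U** (historical-only mass), stability **S** (shared),
expansion **E** (current-only), standardized so U + S + E = 1.

The raw stability is defined symmetrically, as the *average* of the two
periods' shared-region masses. The framework this generalizes reports
stability on the current-period surface (and unfilling on the historical
one), which makes "stability" depend on the direction of comparison; a
single standardized triplet needs one S, and the symmetric average is the
choice that makes swapping the two periods exactly swap U and E while
fixing S and D. Both single-period variants reduce to the same values in
the identity and disjoint cases.

In climate space the partition is restricted to *analogue* climate — the
lattice region available (above truncation) in both periods. Historical
mass outside that region is niche abandonment (A_n), current mass outside
it is niche pioneering (P_n); both are reported alongside but excluded from
the U/S/E standardization, since they reflect availability change rather
than occupancy change.

Centroid shifts are Euclidean distances between unweighted means of
occupied cell centers (a density-weighted option exists); bearings are
measured clockwise from grid north, undefined at zero displacement.

### Similarity tests

Whether observed overlap/stability/expansion/unfilling differ from chance
is judged by a translation null: the historical surface is held fixed, the
current surface is translated by a uniform random lattice offset, mass
leaving the availability footprint is dropped and the surface renormalized,
and the metrics are recomputed. Draws retaining less than 5% of the mass
are rejected and redrawn (a guard against degenerate slivers; more than
1000 consecutive rejections aborts with an error naming the cause).
One-sided p-values use the plus-one rank rule `p = (count + 1)/(n_reps +
1)` — never zero — and the observed value is not part of the null sample.
Significantly high stability or significantly low unfilling/expansion are
labelled range lagging (geographic) or niche tracking (climate); a
significantly low overlap is labelled switching. The full setting is 1000
replicates; the examples and tests use 199, which is enough for the 0.05
level used in the labels.

No multiple-testing correction is applied across species or metrics; the
per-metric labels are descriptive screening output, and both one-sided
p-values are always reported so users can apply their own thresholds.

### Coverage, breadth, filtering

Niche coverage — how much of a species' global climatic niche the study
region samples — is the proportion of the regional occurrence-density mass
falling inside the global niche footprint, on a lattice fitted to the
global PCA. A mass-based proportion was chosen over a Schoener's-D-style
comparison because coverage asks "how much of the regional niche is
globally familiar", not "how similar are the shapes"; D would penalize
shape differences twice. Niche breadth is the Shannon entropy of the
normalized surface.

The filtering gate excludes pelagic specialists and non-native species
(input flags, with a per-region override for natives introduced locally),
species with fewer than 20 occurrences in either period, species occupying
more than 90% of cells in either period, and species with coverage below
50%; species whose global range does not overlap the study region at all
are flagged separately. All failing reasons are listed, and the filter is
idempotent and order-independent.

### Trait regressions

Each metric (in [0, 1], boundary values occur) is squeezed toward 0.5 by
the number of species, `y' = (y(n−1) + 0.5)/n`, then logit-transformed.
Predictors are centred and unit-scaled; ordinal traits (trophic level,
migration, habitat openness, coded 1–3) enter as numeric.

The regression is generalized least squares under a Pagel's-lambda
covariance: `V(λ) = λC + (1−λ) diag(C)` with `C` the shared-path-length
matrix of the phylogeny. For fixed λ the GLS coefficients and ML σ² are
closed-form; λ is profiled over the closed interval [0, 1] (bounded 1-D
optimization, tolerance 1e−8, endpoints checked). For ultrametric trees
(constant diag C) all V(λ) share C's eigenbasis, so one eigendecomposition
serves the whole search and every subset fit. The implementation is
cross-checked in the test suite against an independent GLS (`nlme::gls`
with `ape::corPagel`) to 1e−6 on coefficients and likelihood.

Model selection is an exhaustive search over predictor subsets (at most 12
candidates, so at most 4096 fits; the intercept is always included),
minimizing AIC with `k` counting coefficients + σ² + λ; ties are broken
toward fewer predictors, then lexicographically. Exhaustive search was
preferred to stepwise selection to remove path-dependence.

R² is reported in the V(λ̂)-whitened coordinates (1 − RSS/TSS against the
intercept-only GLS at the same λ̂), with the observation-space R² reported
alongside. Permutation importance permutes one predictor at a time and
recomputes the whitened R² with the *frozen* fitted coefficients — no refit
— over 99 permutations; the refit variant was considered and rejected as
the default because freezing is the cheaper, deterministic-given-seed
reading and measures the information content of the column in the fitted
model rather than the model class's adaptability.

Species missing from the phylogeny are dropped with a logged list.

## The synthetic world

The simulator is first-class, tested code: it is what makes the inferential
claims of the pipeline checkable.

* **Landscape** — an `nx × ny` equal-area grid (default 40 × 40 cells of
  50 km) with linear spatial gradients per climate variable, an additive
  between-period delta, and i.i.d. Gaussian cell noise. Defaults: a
  temperature-like variable falling 0.5 °C per 100 km northward and a
  precipitation-like variable rising 20 mm per 100 km eastward — magnitudes
  typical of continental-scale gradients — warmed by +1 °C and dried by
  −50 mm between periods (roughly three decades of recent change). The
  remaining 17 bioclim variables are held constant so the PCA is driven by
  the two informative axes; the PCA drops them with a logged warning.
  Noise is spatially uncorrelated by design; autocorrelated noise is a
  noted extension.
* **Species** — Gaussian suitability around a climatic optimum
  (`exp(−½ Σ ((x−opt)/tol)²)`), occupancy where suitability ≥ 0.5.
  Period-2 occupancy adds two mechanisms: colonization only within a
  dispersal limit (Euclidean distance between cell centers, inclusive) of
  period-1 occupied cells, and retention of now-unsuitable cells with a
  persistence probability (the extinction-debt knob). Observed occupancy
  thins truth by a detection probability. RNG consumption is per-cell and
  fixed-order, so outputs are reproducible given the seed regardless of
  the occupancy pattern.
* **Traits** — a constant-rate pure-birth tree rescaled to root depth 1
  (any ultrametric tree suffices for the regression machinery), Brownian
  traits standardized per column with three coerced to ordinal by terciles,
  and a response with Pagel's-lambda residual covariance.
* **Cohort** — 30 species by default, optima spread over the inner climate
  range, dispersal limit tied to hand wing index as
  `150 · exp(z_HWI)` km so flight efficiency is a *planted* cause of
  niche unfilling that the trait regressions must rediscover.

What the simulator does **not** emulate: spatial autocorrelation of noise,
survey-effort heterogeneity beyond one detection probability, demography,
abundance and species interactions. Passing tests therefore show the
estimators recover known mechanisms under clean conditions — not that real
atlas data are free of the observation-process artefacts these omissions
idealize away.

## Validation and problem sizes

The package's claims are checked at three levels, with problem sizes chosen
to exercise the statistics without waste:

* **Exact oracles** — bioclim derivation, kernel density values, Schoener's
  D, the partition and presence aggregation are compared to independent
  definition-level brute-force implementations (loops, per-node double
  sums) to 1e−9 or better, on 10 × 10 lattices and 100 random monthly
  series.
* **Mechanism recovery** — over 20 landscape seeds, full-tracking species
  (unlimited dispersal, no persistence, perfect detection) show median
  niche stability ≥ 0.9 with unfilling and expansion ≤ 0.05; median
  unfilling rises monotonically as the dispersal limit falls through
  ∞, 200, 100, 50 km; median expansion rises monotonically as persistence
  rises through 0, 0.5, 1.
* **Statistical calibration** — for independent historical/current niches
  (random patches on a static landscape, so the observed configuration is
  itself a random placement), the stability similarity test at α = 0.05
  with 199 replicates rejects at a rate inside the exact binomial 95%
  interval over 200 simulated species. Pagel's λ = 0.8 is recovered within
  0.1 (median over 50 replicates, 200 tips); exhaustive AIC selection
  recovers a planted two-predictor model in at least 45 of 50 replicates;
  a zero-coefficient predictor's permutation importance is below 0.01.

## Known limitations

* Leading- and trailing-edge dynamics are not distinguished; the metrics
  are whole-range masses.
* The two-axis climate space discards PCA variance beyond axis 2; species
  whose niche structure lives in higher axes are summarized coarsely.
* The translation null preserves the current surface's shape; nulls that
  also rotate or reflect would be stricter.
* Centroid bearings assume the grid's +y axis is north; inputs must be on
  an equal-area projection in km, and no reprojection is performed.
* With fewer than about 20 species, exhaustive subset selection under PGLS
  is honest but weak — most larger subsets cannot be fitted (`n > k + 2`
  is enforced when λ is estimated) and are skipped with a warning.
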