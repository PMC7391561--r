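---
title: "Methods: colonization-history inference and variation partitioning in refugeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colonization-history inference and variation partitioning in refugeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refugeo)
```

## The scientific problem

Sexual and apomictic (asexually seed-producing) cytotypes of a plant
species often occupy interdigitated ranges. Three classes of explanation
compete: ecological preferences, postglacial colonization history (slow
colonizers may simply not have arrived everywhere), and direct
interactions with the other reproductive mode (competition and
reproductive interference). `refugeo` implements a complete analysis
chain that (a) reconstructs the colonization source of the sexual
cytotype from population-genetic data, (b) converts that source into a
per-population migration-cost predictor, and (c) partitions the deviance
of a binomial occurrence model among the three factor blocks.

## Stage 1: per-population genetic indices

Four indices summarize within-population variation:

* **Haplotype diversity** $h = \frac{n}{n-1}\left(1 - \sum_i x_i^2\right)$,
  the unbiased probability that two chloroplast sequences drawn without
  replacement differ ($x_i$ = haplotype frequencies, $n$ = sample size).
* **Nucleotide diversity** $\pi = \binom{n}{2}^{-1} \sum_{i<j} d_{ij}$,
  the mean pairwise per-site difference. Alignment gaps are first recoded
  by *simple indel coding*: each distinct maximal gap run (same start and
  end) becomes one binary character appended to the alignment; gap events
  shared by every sequence are monomorphic and dropped. Within the
  nucleotide part of a pairwise comparison, sites where either sequence
  carries a gap or `N` are not counted as differences (indel variation
  enters only through the coded characters); the denominator is the full
  alignment length plus the number of indel characters.
* **Gene diversity for dominant markers** (AFLP): per locus
  $H_\ell = \frac{n}{n-1} \, 2 p_\ell (1 - p_\ell)$ with $p_\ell$ the band
  (phenotype) frequency, averaged over loci. Band frequencies are used
  directly, matching the convention of the classical AFLP toolchain; a
  `sqrt` flag switches to the Hardy–Weinberg allele-frequency estimator
  $q = 1 - \sqrt{1 - p}$ for sensitivity analysis.
* **Rarity (frequency-down-weighted marker values)**
  $DW_j = \frac{1}{n_j}\sum_\ell \frac{occ_{j\ell}}{occ_\ell}$ — bands are
  down-weighted by their dataset-wide occurrence, so populations that
  accumulate rare bands (long-isolated, refugium-like populations) score
  high. The values satisfy $\sum_j n_j \, DW_j = L$ (number of retained
  loci), which the tests assert.

Population structure is summarized by **Jost's $D_{est}$**, computed per
locus from $H_S$ (unweighted mean across populations of $2p(1-p)$) and
$H_T$ ($2\bar p(1-\bar p)$), locus-averaged and combined as
$D = \frac{\bar H_T - \bar H_S}{1 - \bar H_S}\cdot\frac{k}{k-1}$. We use
the plain band-frequency heterozygosities without a small-sample
correction (an $n/(n-1)$-corrected $H_S$ would make the duplicate-
population case negative or undefined). The consequence is an $O(1/n)$
positive bias under panmixia — about $+0.05$ at 10 individuals per
population — so absolute $D_{est}$ values from few-individual samples
should be read as upper bounds; the panmixia property test therefore
checks the null at 100 individuals per population. Isolation by distance
is tested with a one-sided (greater) **Mantel test** — Pearson
correlation of the lower distance-matrix triangles, permutation p value
$(\#\{r^\ast \ge r\} + 1)/(B + 1)$ — against great-circle (haversine,
R = 6371 km) distances; the reported $R^2$ is $r^2$.

All indices requiring $n \ge 2$ return `NA` for single-individual
populations, which downstream stages exclude pairwise.

## Stage 2: grid-correlation source inference

Under a single-source expansion, serial founder events erode diversity
and rarity along the colonization pathway. The study extent is divided
into a regular lon/lat grid (default 0.1°; the default bounds
9.4–13.9°E × 44.7–48.1°N give 45 × 34 = 1530 cells). For every cell,
Spearman's rank correlation is computed between the haversine distance
from the cell centroid to each population and the populations' values of
one genetic index: source-like cells show strongly *negative*
coefficients. Cells are ranked ascending (rank 1 = most negative = most
refugium-like), the four per-index rankings are averaged into a combined
ranking, and the combined ranks are correlated with latitude
(Spearman). Because low ranks mark the source, a **positive** rho places
the source at the **southern** ice margin and a negative rho at the
northern one. Every cell correlates against *all* populations — cells
need not contain populations.

Design points: the rank/latitude correlation can be computed against
cell-centroid latitudes (default) or against population latitudes via
each population's containing cell (`variant = "population"`); both are
reported by the pipeline because the published description is ambiguous
about the unit. The p value uses the asymptotic t approximation — with
~1530 cells exactness is immaterial — with a permutation option for
small grids. A planar-degrees distance mode exists for unit tests; at
the default extent it is a near-monotone transform of the haversine
distance and leaves the (rank-based) inference unchanged. Cells with
undefined correlations (possible only for degenerate index vectors) stay
`NA` and are excluded from ranking. Because every step is rank-based,
the whole stage is invariant under strictly increasing transforms of any
index, which the tests assert end-to-end.

## Stage 3: least accumulative cost distance

The inferred margin line is rasterized onto the elevation grid (cells
whose center lies within half a cell of the line, plus all cells the
line traverses, so the source is a connected chain). Accumulated cost is
an exact Dijkstra shortest path over the 8-connected lattice with the
classical GIS move cost
$w_{ab} = \frac{c_a + c_b}{2}\cdot d_{ab}$, where $c$ is the per-cell
impedance (elevation in metres, used directly as cost) and $d_{ab}$ the
planimetric cell distance ($\sqrt 2$ times larger on diagonals). In
geographic mode the N–S cell dimension is 111.195 km/degree and the E–W
dimension is scaled by cos(latitude) of the cell row (diagonals use the
mean of the two row widths), so accumulated costs are cost-units × km.
Elevations at or below 0 m are floored at 1 m: Dijkstra requires
positive edge weights and zero-cost plateaus would create ambiguous
ties. `NA` cells are impassable; unreachable cells stay `NA`. The
shortest-path accumulation is delegated to an exact graph library; the
test suite checks it cell-for-cell (1e-9) against an independent
Bellman–Ford relaxation oracle on random rasters up to 20 × 20 over 50
seeds, including nodata walls, and asserts linear scaling in the cost
raster, lattice symmetries, and monotonicity in the source set.
Population cost distances are read from the containing cell; populations
on nodata cells are flagged and later dropped from the history predictor
by listwise deletion.

Only ESRI ASCII grids are read and written; the package does not parse
GeoTIFF georeferencing, so projected rasters should be exported to ASCII
grid first (a declared-units field distinguishes degree from metre
rasters).

## Stage 4: GLM screens and variation partitioning

Predictors are prepared once: annual precipitation (bio12) is cube-root
transformed (its raw distribution is right-skewed), all continuous
covariates — elevation, inclination, aspect (divergence from north,
0–180°), NDVI, bio04, bio12, bio15, cost distance — are z-scored with
the sample SD (n−1), and the binary land-use indicator
(0 = oligohemerobic/(semi)natural, 1 = mesohemerobic) stays unscaled.
Populations with any missing covariate are dropped with a warning, not
imputed.

Binomial (logit) GLMs are fitted by IRLS with a relative deviance
tolerance of 1e-12 (tighter than the conventional 1e-8: at 1e-8 the Wald
z of a binary predictor was not direction-symmetric to the 1e-6 the
cross-occurrence screen asserts) and at most 100 iterations.
(Quasi-)separation is flagged when fitted probabilities reach 0/1
numerically or a slope exceeds 15 on standardized predictors; deviances
are still reported at the convergence cutoff. Explained deviance is
$D^2 = (\text{null} - \text{residual})/\text{null}$ and
$\text{adj } D^2 = 1 - \frac{n-1}{n-p}(1 - D^2)$ with $p$ counting all
fitted coefficients including the intercept. Single-predictor screens
report Wald z tests with Bonferroni-adjusted p values
($p_{adj} = \min(1, p \cdot m)$; family sizes default to 12 for the main
screen and 3 for the cytotype cross-occurrence screen, both
configurable).

Three-matrix variation partitioning fits the 7 models on the unions of
the ecology (A), history (B) and apomict-occurrence (C) blocks and
decomposes $R(\cdot) = \text{adj } D^2$ into unique, pairwise-joint and
three-way fractions by inclusion–exclusion; the additivity identity
$a + \dots + g = R(ABC)$ holds algebraically and is asserted to 1e-10.
Fractions may be negative and are never truncated. Inside these
constituent fits, perfectly collinear columns are dropped (and excluded
from the coefficient count) rather than raising an error — unions of
overlapping predictor blocks are collinear by construction.

## The synthetic-data generators

**Serial founder simulator.** A lattice of demes (default 10 × 13 over
the default extent) is colonized wavefront-style from one edge, in order
of increasing cost distance computed by the package's own cost-distance
stage on a synthetic DEM (flat by default). Each new deme is founded by
K binomially sampled diploid founders (and K chloroplast lineages
multinomially) from its cheapest already-colonized neighbour, then
drifts for a fixed number of Wright–Fisher generations at deme size N.
AFLP loci are dominant biallelic markers (band probability
$1 - (1-q)^2$); cpDNA haplotypes are distinct sequences differing by a
few substitutions, one carrying a 4-bp deletion so the indel-coding path
is exercised. Defaults emulate the study conditions: 68 sampled
populations of 4 individuals, 370 loci, 8 ancestral haplotypes. The
drift intensity (K = 10, N = 50, 5 generations per step) is not
something the study reports; the values were fixed once to produce a
clear, qualitatively realistic diversity decline away from the source
and are otherwise arbitrary. They produce more absolute differentiation
(synthetic $D_{est}$ ≈ 0.2) than the weakly structured real system
(≈ 0.05); the inference consumes only rank information, so this affects
no direction conclusion. Setting K = N with 0 generations per step
switches founding to deterministic transplantation — a no-drift control
under which every gradient is flat and the direction test is
uninformative by design. All randomness flows from one integer seed
through named substreams.

**Occurrence simulator.** 235 populations; 7 continuous covariates plus
cost distance drawn from an exchangeable correlated Gaussian
(ρ = 0.2) and mapped to raw covariate scales by strictly increasing
transforms (so analysis-side standardization recovers the latent
values); binary land use (prevalence 0.5); apomict presences Bernoulli
with prevalences (0.35, 0.25, 0.12), chosen so that ≈57% of populations
contain an apomict; sexual presence Bernoulli with
logit = β₀ + β_eco·x + β_hist·cd + β_apo·z. Default coefficients are the
published single-predictor effect sizes used as generator truth (history
effect 0), and β₀ = 3.64 was moment-matched numerically, once at design
time, to a sexual prevalence of ≈0.583. Because the generator is a joint
model, *marginal* single-predictor estimates on simulated data are
attenuated relative to these conditional coefficients (logistic
non-collapsibility) — the synthetic pentaploid screen coefficient is
≈ −1.7, not −3.65; this is a property of the emulation, not a fitting
error.

**What passing the synthetic tests does and does not show.** The
generators reproduce the *statistical structure* the analysis assumes —
a monotone diversity gradient from one source edge, and a logistic
occurrence process on correlated covariates. They do not emulate spatial
autocorrelation of covariates, admixture from secondary contact,
landscape-driven anisotropic migration, or observation error in ploidy
screening; green tests certify the machinery, not those aspects of real
data.

## Validation design and problem sizes

The validation suite runs (1) closed-form and oracle checks (indices
against exhaustive pair enumeration; Dijkstra against Bellman–Ford; GLM
slopes/SEs against 2×2 log-odds-ratio formulas; partition additivity)
and calibration checks (Mantel and Bonferroni type-I error at or below
nominal plus Monte-Carlo tolerance); and (2) recovery studies: 100
serial-founder replicates at default parameters must recover the
southern source at least 95 times, and 500 occurrence replicates must
give pooled 95% Wald coverage of the apomict coefficients within
0.95 ± 0.03. The coverage study fits the generating 5-parameter model
(one ecological covariate, three apomict flags, n = 235). Fitting a
13-parameter joint model at n = 235 instead gives ≈0.91 pooled coverage
— not a defect but the familiar away-from-zero bias of the logistic MLE
with strong, sparse binary effects (at n = 2000 the same fits are
unbiased with ≈0.95 coverage); users comparing many covariates at this
sample size should prefer profile-likelihood or penalized intervals.

Reproduction checks against the externally deposited study tables (the
per-population index table, the deposited AFLP/cpDNA data, and the
ecological/cytotype table) are included in the suite but require the
user to place those deposits under `inst/extdata/deposited/`; without
them they report as failures pointing to the required files.

## Known limitations

* GeoTIFF input is not parsed; convert rasters to ESRI ASCII grid.
* $D_{est}$ from band frequencies carries finite-sample positive bias
  (see above) and, per the dominant-marker convention, no
  Lynch–Milligan null-allele correction.
* Cost-distance semantics are isotropic; no slope-direction (anisotropic)
  models, corridors or back-links.
* The pipeline runner always executes the full chain; numbered stage
  outputs plus a manifest make reruns cheap and verifiable, and at these
  runtimes (seconds to ~2 minutes) resume-from-stage machinery would add
  state-invalidation complexity without benefit.
* No spatial autocorrelation correction in the GLMs, no AMOVA, no
  coalescent-based or approximate-Bayesian alternatives to the grid
  correlation method.
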