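---
title: "Trait-based scoring and hotspot delineation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based scoring and hotspot delineation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katydiv)
```

katydiv turns occurrence records and an expert trait table for an insect
fauna into conservation-priority maps, and tests whether the resulting
priority cells coincide with independently delineated biodiversity
hotspot polygons. This vignette is the package's account of the models it
implements, the parameters that matter, and the design decisions taken
where the methodology left genuine latitude.

## The composite species score

Each assessed species receives four elemental scores:

* **T** (threat, 0–3): LC = 0, VU = 1, EN = 2, CR = 3, in ascending order
  of Red List threat. Data Deficient and Not Evaluated species are
  excluded before any scoring; every exported entry point enforces this.
* **D** (distribution, 0–3): the narrower the range, the higher the
  score, from national and regional coverage fractions, province counts
  and endemism/marginality flags.
* **M** (mobility, 0–2): fully flighted = 0, one sex or partially
  flighted = 1, flightless = 2.
* **Tr** (trophic level, 0–3): omnivore = 0, predator = 1, polyphagous
  herbivore = 2, monophagous herbivore = 3.
* **LH** (life history, 0–3): the chart image of M + Tr
  (0 → 0, 1–2 → 1, 3 → 2, 4–5 → 3).

Six composite sums (T+D, T+LH, D+LH, T+D+M, T+D+Tr, T+D+LH) serve as
species-level diversity measures; the full composite T+D+LH ranges from 0
to 9, and `scripts/acceptance.R` re-derives that maximum by exhaustive
enumeration.

The distribution column is the one place where the published chart mixes
qualitative phrases ("very common", "localized") with overlapping
percentage clauses, so it is encoded here as an explicit decision list
over `(frac_SA, frac_sA, n_provinces, endemic_to_SA, marginal_in_SA)`
with two interpretive choices:

1. **Rule order by specificity (3, 2, 0, 1).** The score-0 clause
   (> 75% of both national and regional range) is numerically a subset of
   the score-1 clause (> 66% of both); a naive 3→0 scan would therefore
   never assign 0. The qualitative labels make clear that the
   very-common rule is the more specific one, so it is evaluated before
   the score-1 rule. All printed thresholds are strict inequalities;
   boundary values fall through to the next rule, and inputs matching no
   rule are rejected with a per-rule diagnostic rather than silently
   defaulted.
2. **The `marginal_in_SA` flag.** The score-1 clause "very common in 1–3
   provinces, 0–33% nationally" and the score-2 clause "widespread
   regionally but marginal and very rare nationally, < 33%" overlap
   numerically; the chart does not name the disambiguating variable. The
   package resolves the overlap with an explicit marginality flag in the
   trait table, documented as an interpretation.

Score elements are compared across threat categories with tie-corrected
Kruskal–Wallis tests followed by Nemenyi all-pairs post-hoc comparisons
(chi-square approximation with tie correction, suitable for unequal group
sizes) and a compact letter display at α = 0.05. When every value is
identical the comparison reports H = 0 and p = 1 rather than the
undefined tie-corrected statistic.

## Range metrics

**EOO** is the area of the minimum convex polygon around a species'
localities, measured on a Lambert azimuthal equal-area projection
centered on the points' centroid. A centroid-centered projection keeps
areas comparable across species without committing to any national CRS
(the original GIS workflow did not name one). Degenerate configurations
— single records, coincident or collinear points (projected hull area
below 1 mm² in km² units) — fall back to the AOO value, so a singleton
has EOO = AOO = 4 km². The IUCN convention that EOO should not be
smaller than AOO is *not* otherwise enforced; the per-species summary
flags `eoo_lt_aoo` instead. Because the projection recenters as points
are added, EOO monotonicity under record addition holds only to
projection tolerance (well under 0.5%).

**AOO** counts occupied 2 km × 2 km cells on the same equal-area
projection, anchored at a fixed projection origin (lon 0, lat 0 by
default) rather than at the data: a fixed anchor makes the measure
monotone when records accrue. Origin optimization permitted by IUCN
guidance is deliberately not implemented.

**Screening** applies the range-threshold part of Red List Criterion B
only (CR below 100/10 km², EN below 5000/500, VU below 20000/2000, on
EOO/AOO respectively): subcriteria on fragmentation and decline, and
population-based Criterion D, need data this pipeline does not see, so
published statuses remain a user input wherever available. The
**endemism** rule is strict: EOO < 5000 km², the EN cut-off and the
natural break in the range-size distribution; `eoo_gap_profile()`
reproduces the successive-gap inspection that motivates it.

## Gridding

The fishnet is a 1° × 1° graticule aligned to integer degrees (origin
configurable). The published cells carry map-sheet labels, consistent
with graticule alignment, but no origin is stated; integer alignment is
recorded here as an assumption. Cells are clipped to the region
polygon by Sutherland–Hodgman rectangle clipping and carry their
spherical land area, since cropped coastal cells must not be compared on
equal footing. Record membership is half-open (`[min, max)` in both
axes), so a record on an interior edge belongs to the east/north cell.

Per-cell metrics are species-level, never record-level: duplicated
records change `n_records` but not richness or mean scores. Cells with
no records are "no data", distinct from zero, and are excluded from all
percentile computations, association denominators and comparisons — the
inclusion-rule percentages only reproduce with the data-bearing-cell
denominator, which fixes that convention.

## Hotspot delineation and association

* **Count-based hotspots**: the union of the top 10% of cells for total,
  threatened (CR/EN/VU), endemic (EOO < 5000 km²) and sensitive (LH = 3)
  species richness.
* **Score-based hotspots**: the top 10% of mean T+D+LH.

The percentile threshold is the empirical quantile over cells with data,
with all ties at the threshold included — the 10% cut was chosen for
natural breaks in the cell-value histograms, which implies inclusive
treatment of the break. A degenerate all-equal metric returns every cell
with a warning.

Cells are classified against biodiversity hotspot polygons by the
fraction of their land area falling inside the polygons; rules 0.25,
0.50 and 0.75 are strict (> rule), rule 1.00 means complete inclusion
within a 10⁻⁶ relative area tolerance. The default working rule is 0.50:
conservative while keeping enough hotspot cells for stable tests, and
`inclusion_rule_sensitivity()` verifies the choice is immaterial
(Kruskal–Wallis across the four rules on hotspot-minus-non-hotspot
median differences). Hotspot polygons are assumed to lie on land within
the study region and to be mutually disjoint; holes in polygons are not
supported.

Pairwise hotspot association uses the Pearson chi-squared test on the
2 × 2 cross-tabulation over data-bearing cells with Yates continuity
correction on by default — the stock behaviour of a 2 × 2 chi-squared
test in R, hence almost surely what produced the published statistics —
with the uncorrected statistic available behind a flag, since the
original choice is not stated. Diversity measures inside vs outside
hotspot polygons are compared per measure with Mann–Whitney rank-sum
tests (normal approximation with tie correction).

## Spatial statistics

**Moran's I** is the global statistic
I = (n/ΣΣw)·(ΣΣ w_ij z_i z_j)/(Σ z_i²) with centred values, zero
diagonal and inverse great-circle-distance weights between cell
centroids, without row standardization. The original analysis used a
spatial-correlogram package but reports single global values; reducing
the correlogram to one global statistic with inverse-distance weights is
documented as this package's interpretation. Significance comes from a
seeded two-sided permutation test (default 999 permutations) around the
null expectation −1/(n−1).

**Spatially correlated regression** follows the penalized
quasi-likelihood scheme: initialize at the ordinary Poisson fit, iterate
the working response z = η + (y − μ)/μ with weights W = diag(μ), and
solve generalized least squares under
Σ(ρ) = W^(−1/2) C(ρ) W^(−1/2), C_ij = exp(−d_ij/ρ), until the largest
coefficient change falls below 10⁻⁶ (at most 50 iterations;
non-convergence is flagged, never silently accepted). The range ρ is
profiled on 20 log-spaced values spanning [0.1 × median d, 2 × max d]
and refined once by golden-section search: with on the order of a
hundred cells a free range parameter is weakly identified, and a
grid-plus-refine profile is robust and reproducible where a joint
optimizer is fragile. Because Σ factorizes through W, one Cholesky of
C(ρ) per candidate ρ serves every PQL iteration. Count responses use
the Poisson family; the mean-score response (a bounded real) uses the
identity working response in the same GLS loop, as the original
analysis fit all responses with one routine without stating a family
for the score measure. No nugget is used; the original settings are
unstated, which is why the published coefficient table is validated by
property-based parameter recovery rather than value matching.

Model fit is summarized by the marginal r²,
var(η_fixed) / (var(η_fixed) + σ²_d), with the lognormal approximation
σ²_d = ln(1 + 1/exp(β₀)) for the Poisson family and the residual
variance for the Gaussian working model — appropriate for models with no
random effects. Fixed-effect predictors are the paired diversity measure
and the cell land area.

## Phylogenetic comparative analysis

The comparative tree is derived from taxonomy alone: subfamilies, genera
and subgenera assumed monophyletic, nested as polytomies with unit
internal branch lengths — a deliberately conservative topology.
Single-member levels are collapsed, so every internal node is a real
split. Two further interpretations are recorded:

* The source describes its tree as unrooted, but a trait covariance
  matrix needs root-to-tip depths; the tree is rooted at the basal
  subfamily polytomy.
* With subgenera present in only part of the taxonomy, raw tip depths
  differ. Terminal branches are padded to a common depth (ultrametric).
  Padding changes no shared path length — relative relatedness is
  untouched — and makes the λ = 0 model coincide exactly with ordinary
  least squares, which the test suite asserts to 10⁻⁸.

Pagel's λ multiplies the off-diagonal of the Brownian covariance;
λ ∈ [0, 1] is estimated by maximum likelihood with a bounded
one-dimensional search (tolerance 10⁻⁶) plus explicit endpoint checks,
since boundary estimates (λ̂ = 0 in particular) are common in practice.
All fits are ML, not REML, so AIC is comparable across fixed-effect
structures; the AIC parameter count is the coefficients plus the
residual variance plus one when λ is estimated, and ties rank the
simpler model first. Ordinal scores are regressed as continuous
responses — a documented limitation inherited from the original design.
The standard model set relates T to D, LH, M, Tr and the D-interactions,
plus D to LH, each as OLS and PGLS (16 models). Where morphological
evidence resolves relationships below the subgenus (two species pairs in
the original fauna), the taxonomy columns can simply encode the
resolved groups as additional subgenera; no guessing is built in.

## Species accumulation curves

Sample-based curves use the exact combinatorial expectation of richness
in t samples drawn without replacement with unconditional-variance 95%
normal intervals; individual-based rarefaction uses the hypergeometric
expectation E[S_n] = Σᵢ(1 − C(N−Nᵢ, n)/C(N, n)) with its analytic
variance. The computational engine is vegan (`specaccum(method =
"exact", conditioned = FALSE)`, `rarefy`); the test suite checks both
curves against exhaustive subset enumeration on small fixtures to 10⁻⁹.
Which confidence-interval variant the original EstimateS workflow used
is not stated; the analytic (non-resampling) variance is this package's
documented choice, for determinism. Curves for cells inside vs outside
biodiversity hotspots are compared by per-effort confidence-interval
overlap, reporting the minimal effort at which the intervals separate.

## The synthetic data generator

`simulate_dataset()` produces a complete study system with known ground
truth. Its defaults are the study conditions the rest of the package is
tested under: 130 species, 1100 records, a 10° × 8° region with a
coastline notch (so clipped cells and land-area weighting are always
exercised), hotspot polygons covering 30% of the region, and enrichment
odds of 4 for specialist ranges to sit inside them.

The generative model, in order:

1. A random nested taxonomy (8 subfamilies → genera → subgenera) gives
   the tree; latent Gaussian fields with Pagel's λ = 0.8 on that tree
   drive range narrowness, mobility and trophic specialization. The
   mobility and trophic latents are strongly coupled to narrowness
   (correlations 0.85 and 0.80): narrow-range species tend to be
   flightless diet specialists, mirroring the tight
   distribution–life-history relationship that motivates the composite
   score in the first place.
2. Statuses are assigned by narrowness rank at marginal proportions
   mirroring the published fauna (≈ 65% LC, 15% VU, 8% EN, 12% CR of
   assessed, with 12% DD drawn independently); each species receives a
   true range area log-uniform within its status band, so screening the
   true areas reproduces the pre-noise statuses exactly, and the
   recorded status is then perturbed to a neighbouring category with
   probability 0.05 — status stays a distinct input rather than a
   deterministic function of range.
3. Range kernels are Gaussian with sd = √(EOO/π)/2. Narrow-range
   specialists (D = 3, LH ≥ 2) cluster in radiation cores — about one
   core per two specialists, each core sited inside the hotspot polygons
   with odds multiplied by the enrichment factor, snapped to the centre
   of a distinct grid cell so the planted unit matches the analysis
   resolution. Ordinary species centres are drawn uniformly, inset 0.8°
   from the region boundary so edge cells are covered by kernel tails
   rather than orphan range centres.
4. Records are allocated with a mild museum-collection bias toward
   widespread species (expected share ∝ EOO^0.45, floor of 3 records per
   species) and sampled from the kernels truncated to the region.

The planted hotspot truth is the top decile of the *expected observable*
score surface: for each cell, species are weighted by their detection
probability 1 − (1 − m)^E[records], where m is the kernel mass in the
cell rectangle scaled by the cell's land fraction, and the cell's true
score is the detection-weighted mean composite. This is the surface a
faithful sampler estimates, which is exactly what a recovery test should
target; defining truth from raw kernel masses instead would punish the
estimator for not seeing species that the sampling design itself cannot
detect.

What the generator does **not** emulate: real biogeography and
environmental gradients, spatially biased collecting effort (roadside or
coastal access bias), taxonomic misidentification, or temporal turnover.
Passing recovery tests therefore demonstrates that the pipeline
recovers planted structure under honest sampling noise — not that any
real fauna meets these assumptions.

All draws flow from one integer seed through three derived stage seeds
(traits, geography, records), so any intermediate can be regenerated
exactly.

## Problem sizes and numerical conventions in the test suite

The suite validates every statistical engine against independent
oracles: rarefaction against exhaustive subset enumeration (≤ 12
individuals), Moran's I against the literal double sum, the 2 × 2
chi-squared against its closed form, PGLS against an independent GLS
implementation at fixed λ. Parameter recovery uses 200 replicates of a
15 × 15 lattice for the spatial Poisson slope (planted 0.5, tolerance
0.05 on the mean), 200 Brownian simulations on a 114-tip taxonomy tree
for λ, and 100 end-to-end replicates at the generator defaults for
hotspot recovery (Jaccard ≥ 0.5 against the planted cells in ≥ 80% of
replicates, and a non-significant score–polygon association in ≥ 90%
under enrichment 1). A hand-computed six-species worked example
(`worked_fixture()`, with expected outputs under `inst/extdata/worked/`)
pins every cell metric, flag and Venn count bit-exactly.

Conventions enforced centrally: WGS84 decimal degrees everywhere, areas
in km², half-open cell membership, strict inequalities at every
published threshold, and `NA` (never 0) for cells without data.

## Known limitations

* Polygon handling supports outer rings only (no holes) and assumes
  hotspot polygons are disjoint and lie within the study region.
* EOO for very large ranges inherits the distortion of a single
  azimuthal projection; for continental-scale ranges a geodesic hull
  would be preferable.
* The PQL working-response approximation is known to bias variance
  components for small counts; slopes (the quantity interpreted here)
  recover well in simulation, but absolute r² values should be read
  qualitatively.
* Scores are ordinal; treating them as continuous in regressions is a
  pragmatic inheritance, and rank-based alternatives are used wherever
  the design allows.
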