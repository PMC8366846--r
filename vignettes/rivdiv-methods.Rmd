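---
title: "Multi-facet river-fish diversity: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-facet river-fish diversity: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivdiv)
```

`rivdiv` analyses a fish metacommunity sampled at sites along a
dendritic river network in three facets — taxonomic (TD), functional
(FD) and phylogenetic (PD) diversity — and asks how dams and network
position structure those facets and how vulnerable each facet is to
species loss. This vignette explains the models behind each stage, the
parameters that matter, the design choices made where more than one
reasonable convention exists, and what the bundled synthetic data do
and do not establish.

## Inputs and their invariants

The community matrix holds non-negative integer counts, sites × species,
with no empty site and no globally absent species — the species pool is
an *observed* pool. Abundances drive TD and FD alpha indices;
presence/absence drives PD and all beta diversity, matching common
practice for survey data where detection of presence is more reliable
than counts. The trait table carries seven strictly positive continuous
morphometric ratios (head length/standard length, eye diameter/head
depth, snout length/head length, head depth/body depth, pectoral-fin
length/standard length, caudal peduncle depth/caudal fin depth, body
depth/standard length) and three categorical traits: rheophily
(rheophilic/limnophilic/eurytopic), water-column position
(benthic/benthopelagic/pelagic), and life span binned in years (≤10,
10–20, >20). Life span is the only *ordered* categorical trait — the
bins are a discretised number. The phylogeny is a rooted, branch-length
Newick tree whose tips cover the community species; maximum-likelihood
trees are typically non-ultrametric and the code never assumes
ultrametricity. Basal polytomies are accepted: the basal node of the
parsed file is taken as the root.

## Functional trait space

Mixed trait types require a mixed-type dissimilarity; we use Gower's
coefficient with equal weights (no weighting scheme is imposed by the
data, and equal weights are the neutral default; a weight vector is
exposed). Continuous traits contribute range-normalised absolute
differences, nominal traits 0/1 mismatches, and life span a
range-normalised rank difference. A continuous trait with zero range is
uninformative and contributes zero with a warning rather than an error.

Gower matrices are usually non-Euclidean, so classical PCoA produces
negative eigenvalues. The default is the Lingoes correction (adds a
constant to squared off-diagonal dissimilarities — the gentlest fix that
preserves the ordering of distances); Cailliez and "none" (fractions of
positive-eigenvalue variance only) are available. Axis signs from an
eigendecomposition are arbitrary; we fix each axis so its
largest-magnitude coordinate is positive, making results reproducible
across BLAS implementations.

All downstream functional computation — Rao's Q distances, FEve, convex
hulls — happens in the *retained* axis space (default 5 axes), not on
the raw Gower matrix. This makes the functional-space dimension an
explicit, inspectable choice and keeps hull geometry well-posed.

## Alpha indices and their conventions

* Shannon entropy uses natural logarithms; evenness is `H / ln S`,
  undefined (NA) at S = 1.
* Rao's Q uses distances scaled by the global maximum pairwise
  functional distance (flag `scale_distances`), so values are
  comparable across runs and bounded by 1 on like-scaled inputs.
* FEve follows the minimum-spanning-tree formulation; it needs S ≥ 3
  and non-coincident points, else NA.
* Faith's PD includes the path to the root by default (`include_root`),
  the convention under which a single-species community has positive PD
  equal to its root path; the flag exposes the other convention.
* PSE standardises the phylogenetic covariance by each species'
  root-to-tip depth — exact correlation for non-ultrametric ML trees;
  on an ultrametric tree this reduces to the usual 1/(total depth)
  scaling. PSE is NA at S = 1; it equals PSV under equal abundances and
  1 on a star phylogeny, both of which are tested.

## Beta diversity and the turnover/nestedness partition

All three facets use the same Sorensen family: total dissimilarity
`(b+c)/(2a+b+c)`, turnover `min(b,c)/(a+min(b,c))`, nestedness the
difference. The partition is additive by construction and the suite
checks `β_sor = β_sim + β_nes` to 1e-12 on 10,000 random triples. For
TD, `a/b/c` are presence/absence species counts. For PD they are branch
lengths of the two communities' spanning subtrees (same rooting flag as
Faith's PD); on a star tree with unit branches this provably collapses
to the TD counts, which the suite verifies exhaustively. For FD they are
convex-hull volumes in the first `n_axes_fd` (default 4) trait axes.

Hull geometry is the one place where exact computation has a hard
combinatorial wall. In 2-3 dimensions we compute facet half-spaces by
subset enumeration, intersection vertices from the combined system, and
volumes by recursive cone decomposition — exact to floating point. In 4+
dimensions vertex enumeration over the combined system explodes, so the
three volumes (two hulls and their intersection) are estimated from one
shared, seeded Monte Carlo sample (default 200,000 points) in the
bounding box of the union; sharing the sample guarantees
`a ≤ min(v1, v2)` so the Sorensen components stay in range. The exact
and Monte Carlo routes are cross-checked against each other within three
binomial standard errors in the test suite.

Site pairs where the poorer community has fewer than `n_axes_fd + 1`
species cannot span a hull; the pair is recomputed with the axis count
reduced to (min richness − 1) and flagged in the `reduced` matrix.
Below 3 species (or a degenerate hull after reduction) the entry is NA
and logged. This makes the dimensionality handling explicit instead of
silently failing on species-poor sites.

## River network and spatial statistics

The network is a directed tree of segments draining to one outlet.
Strahler order increments only when two (or more) tributaries *tie* at
the maximal order. The downstream link of a site is the magnitude
(number of order-1 source segments upstream) of the link below the next
confluence downstream; sites on the outlet link take the outlet link's
own magnitude, logged. log2 magnitudes are binned 1–2 / 2–3 / 3–4. Dam
categories classify a site by dams on any upstream path (Up), on the
path to the outlet (Down), both, or — unlike a field survey where every
site had a dam somewhere — "None", which synthetic networks can produce;
the ANOVA simply runs on whatever levels exist and drops levels with
fewer than two sites with a warning.

No weighting scheme for spatial tests is dictated by the data, so the
package defaults to inverse-distance, row-standardised weights and
records the scheme in the report metadata; k-nearest and
binary-threshold schemes are available. Moran's I uses the closed-form
expectation −1/(n−1) and the normality-assumption variance (the
randomization variance differs in the third decimal on typical layouts);
a permutation mode switches automatically to *exhaustive* enumeration
when n! fits in the permutation budget, making small-n p-values exact.
Lee's L significance comes from joint permutation of site labels, which
preserves the aspatial correlation of the two variables while breaking
their spatial arrangement.

The per-index connectivity tests are one-way F tests (one F per index
per factor), with an optional joint Pillai-trace test behind a flag;
pairwise level letters use pooled-variance t tests at the 0.99 level.
The suite calibrates the F test's type-I error at α = 0.01 over 1,000
null simulations.

## Congruence curves

For each quantile fraction q ∈ {0.1, …, 1.0}, the curve reports the
overlap of the facets' top-q item sets divided by `ceil(q·n)`; items
are sites (alpha mode) or unordered site pairs (beta mode). `ceil`
guarantees a non-empty set at q = 0.1 for 24 sites (k = 3). Boundary
ties are broken by identifier order, making curves bit-reproducible.
Overlap is not monotone in q and the only guaranteed value is 1 at
q = 1, which is asserted.

## Leave-one-out vulnerability

"Removal with replacement" is read as a jackknife: each species is
removed once from the *intact* community, never cumulatively. The delta
is defined only where the species occurs; species contributions average
over occupied sites only, because zero-filling absent sites would
swamp narrow-range species — exactly the species such analyses
highlight. An emptied site has index 0 for all facets; a single
remaining species keeps its root-path PD under the default rooting.
Site vulnerability is the mean delta over the site's species; whether
one facet's deltas disperse more than another's is tested with a
Fligner-Killeen rank dispersion test (robust to the heavy-tailed,
non-normal deltas the jackknife produces), with a Levene-type
absolute-deviation ANOVA behind a flag.

Distinctive species are those with any continuous (or ordered) trait at
or beyond the 10%/90% quantiles of the pool, or prevalence at or above
the 90% quantile; nominal traits are excluded because extremeness is
undefined without an order. Where a reported table could average
within-facet then union across facets, or rank a cross-facet mean, the
union reading is implemented; occupancy summaries are computed for the
full distinctive set (both are derivable from the returned objects).

## The synthetic world

The generator emulates the structure the analysis assumes: 24 sites on
a dendritic network (13 sources, 25 segments, 5 dams), 82 species, a
pure-birth phylogeny with exponential branch lengths (rate 1), traits
evolving by Brownian motion (σ² = 0.1 per unit branch) exponentiated
for positivity, with categorical guilds thresholded from hidden
Brownian traits so related species share guilds. Occupancy combines a
Gaussian niche on the upstream-downstream gradient (breadth τ = 0.12,
optima spread over the realized gradient range so every species has a
reachable site), a right-skewed rarity term with a floor (an observed
pool cannot contain species with vanishing detectability), and a
downstream-increasing site capacity; abundances are lognormal(1, 1)
rounded up. Rheophilic or benthic species at sites with an upstream dam
have occupancy multiplied by 0.3 — dams act on occupancy, not
abundance, the simplest mechanism consistent with habitat filtering.

Two deliberate constructions deserve note. First, in the nestedness
regime the Bernoulli draws share a single uniform deviate per species
across sites, so poorer sites hold subsets of richer ones while the
*marginal* occupancy probabilities stay exactly `r_i · h_s`; turnover
regimes use independent draws. Second, species or sites still empty
after bounded resampling are placed deterministically at their
highest-probability site/species — the limiting conditional draw given
at least one occurrence — which keeps every bundle valid without
distorting the niche structure.

Calibration (set once, before any acceptance run, and not revisited):
richness per site lands mostly in the 5–10 range with maxima in the
teens and low-prevalence-dominated occupancy, the qualitative shape of
a subtropical river survey. The generator does *not* emulate detection
error, temporal turnover, abundance covariance between species, or
hydrological realism; a green regime-recovery test establishes that the
pipeline distinguishes turnover-driven from nestedness-driven worlds at
this scale, not that it would estimate either from noisy field data.

## Numerical choices

Geometry tolerances: 1e-9 (relative) for facet side-tests, 1e-7 for
point-in-hull checks, 7-digit rounding for vertex/facet deduplication.
Monte Carlo seeds are derived deterministically per site pair from the
master seed. All random routines snapshot and restore the caller's RNG
state, so library calls never perturb user scripts. Permutation
p-values use the (count + 1)/(n_perm + 1) convention except in the
exhaustive branch, where the proportion is exact. Write/read
round-trips preserve doubles to better than 1e-12 (17 significant
digits).

## Known limitations

* Exact hull intersections above 3 dimensions are Monte Carlo only; the
  estimator's standard error is reported internally and the default
  200,000 points give ~3-digit volumes on unit-scale hulls.
* The ANOVA letters use pooled-variance t tests, not Tukey HSD;
  at these sample sizes (24 sites over ≤4 levels) the difference is
  minor but the letters are not family-wise-error controlled.
* Lee's L has no analytic null here; its expectation is reported as the
  permutation mean.
* The Cailliez correction computes an eigenvalue of a 2n × 2n matrix
  and is O(n³) in the species count; Lingoes is the default partly for
  this reason.
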