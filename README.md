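# rivdiv

Multi-facet diversity analysis for stream-fish metacommunities on
dam-fragmented dendritic river networks.

Freshwater fish assemblages sampled along a river differ in three
complementary ways: in *which species* are present (taxonomic diversity,
TD), in *what those species do* (functional diversity, FD, from
morphological and ecological traits), and in *how much evolutionary
history* they represent (phylogenetic diversity, PD). Conservation
planning in fragmented basins needs all three, plus a way to ask which
species and sites the system would miss most if species were lost.
`rivdiv` implements that full workflow for site-by-species survey data,
and ships a seeded synthetic-data generator so every stage can be
exercised and tested without any field data.

## What it computes

**Alpha diversity** (per site): Shannon entropy `H = -Σ p_i ln p_i` and
Shannon evenness `H / ln S`; Rao's quadratic entropy
`Q = Σ_ij d_ij p_i p_j` on functional distances; functional evenness
(FEve, regularity of abundance along the trait-space minimum spanning
tree); Faith's PD (total branch length of the minimal subtree spanning
the community); and phylogenetic species evenness
`PSE = (M Σ m_i C_ii − mᵀCm) / (M² − Σ m_i²)` from the phylogenetic
correlation matrix C.

**Functional trait space**: Gower dissimilarity over mixed
continuous/categorical traits (life span treated as ordered), principal
coordinates analysis with Lingoes/Cailliez corrections, retained-axis
coordinates and distances.

**Beta diversity** (per site pair, three facets): the Sorensen partition

    β_sor = (b + c) / (2a + b + c),   β_sim = min(b,c) / (a + min(b,c)),
    β_nes = β_sor − β_sim

where `a, b, c` are shared/unique species counts (TD), shared/unique
convex-hull volumes in trait space (FD; exact half-space geometry in 2-3
dimensions, seeded Monte Carlo beyond), or shared/unique branch lengths
of the spanning subtrees (PD). Plus summary statistics, histograms and
quadratic component regressions.

**River-network connectivity**: Strahler stream order, downstream-link
magnitude with log2 binning, dam categories (Up / Down / Up&Down /
None), spatial weights, Moran's I (analytic and permutation), Lee's L
bivariate spatial association, and per-index one-way ANOVAs of each
diversity index against each connectivity factor with 0.99-level
pairwise letters.

**Congruence and vulnerability**: quantile-concordance curves (overlap
of top-q site or site-pair sets between facets, q = 0.1 … 1.0);
leave-one-out species-removal vulnerability (`Δ = D(site) −
D(site∖{species})` for Shannon/RaoQ/PD), species contributions, site
vulnerability summaries with a cross-facet dispersion test, and
distinctive-species identification (extreme-trait and top-prevalence
deciles).

## Worked example

```r
library(rivdiv)

bundle <- simulate_scenario(scenario_config(seed = 42))
bundle$community
#> community_matrix: 24 sites x 82 species, 990 individuals
#>   richness range: 2 - 18

space <- build_trait_space(bundle$traits, n_axes = 5)
space
#> trait_space: 82 species, 5 retained axes (27.9% cumulative variance)
#>   lingoes correction, constant 0.2089

alpha <- alpha_table(bundle$community, space, bundle$tree)
round(head(alpha, 4), 3)
#>        richness individuals_per_species Shannon  SEve  RaoQ  FEve PDfaith PSEve
#> site01       13                   4.846   2.225 0.867 0.485 0.664  65.900 0.831
#> site02        3                   3.333   0.898 0.817 0.224 0.892  18.900 0.967
#> site03        3                   3.333   1.055 0.960 0.380 0.464  20.214 0.794
#> site04       11                   4.545   2.178 0.908 0.433 0.781  50.533 0.753

td <- taxonomic_beta(bundle$community)
s <- beta_summary(td)
sprintf("TD beta_sor: mean %.2f +/- %.2f, range %.2f-%.2f; turnover share %.2f",
        s$sor$mean, s$sor$sd, s$sor$min, s$sor$max, s$sim$mean / s$sor$mean)
#> "TD beta_sor: mean 0.90 +/- 0.13, range 0.40-1.00; turnover share 0.96"

mi <- morans_i(alpha$Shannon, build_weights(bundle$site_attributes))
mi
#> morans_i_normal: statistic 0.1006, expected -0.0435, p = 0.02123
```

Reading this: sites hold 2-18 of the 82 species, compositional
dissimilarity between sites is high (mean β_sor = 0.90) and almost
entirely species *replacement* rather than richness loss (turnover share
0.96 — the mixed scenario sorts species along the upstream-downstream
gradient), and site-level Shannon diversity shows no spatial
autocorrelation at the 0.99 confidence level (p = 0.021 > 0.01; the
expected value under no autocorrelation at 24 sites is −1/23 ≈ −0.04).

The one-call orchestrator runs everything and can write all tables as
delimited text:

```r
report <- run_pipeline(bundle$community, bundle$traits, bundle$tree,
                       bundle$site_attributes, out_dir = "report")
```

There is also a CLI (`exec/rivdiv` or `rivdiv_cli()`) with subcommands
`validate`, `alpha`, `beta`, `congruence`, `spatial`, `vulnerability`,
`report` (all driven by a `key = value` config file) and
`simulate --scenario {turnover,nestedness,mixed} --seed N --out DIR`.

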