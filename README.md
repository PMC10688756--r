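# ddcomm

Abiotic and biotic drivers of direct-developing species in communities.

Direct development — eggs hatching as miniature adults, with no
free-living tadpole — is a derived amphibian reproductive mode that is
strongly concentrated in a few clades and tied to humid, climatically
stable, often montane environments. `ddcomm` is an R package for asking,
across hundreds of local communities at once, how climate, topography,
phylogenetic composition and functional diversity relate to the
proportion of direct-developing species (%DD). It is aimed at community
ecologists and evolutionary biologists working with a sites × species
incidence table, a species trait table, a dated phylogeny and site-level
environmental predictors.

## What it computes

* **Composition-controlled %DD** — the observed per-community proportion
  of direct developers standardized against a null model that permutes
  the species → development-mode map (the D matrix) over the whole
  regional pool: `SES = (obs − mean_null) / sd_null`, 999 permutations.
* **PCPS** — principal coordinates of phylogenetic structure: incidences
  smoothed by phylogenetic similarity `S = 1 − D/max(D)` into a
  row-normalized P matrix, ordinated by PCoA of square-root Bray–Curtis
  dissimilarities. Axis 1 captures the deepest phylogenetic gradients.
  Taxa missing from the reference tree are grafted at their most derived
  consensus clade (`add_taxon_at_mdcc()`).
* **SES.FD** — Petchey–Gaston functional diversity (root-inclusive
  branch-length sum on a UPGMA dendrogram of phylogeny-controlled
  traits, with missing morphometrics imputed by maximum likelihood under
  multivariate Brownian motion), standardized against 999 tip-label
  permutations.
* **Spatial GLS** — site-level regressions with exponential spatial
  correlation `corr(d) = exp(−d/ρ)` fit by maximum likelihood, plus
  Moran's I permutation tests and AIC model-selection tables.
* **Piecewise SEM** — a directed acyclic path model fit equation by
  equation with the spatial GLS; the d-separation basis set of missing
  edges is tested by regression and combined into Fisher's
  `C = −2 Σ ln pᵢ` with `df = 2k`; the model is consistent with the data
  when the upper-tail χ² probability exceeds 0.05.
* **A synthetic-data generator** — birth–death phylogenies, a
  clade-concentrated development trait, Brownian traits with
  missingness, spatially autocorrelated environments, and communities
  assembled by a logistic Gaussian-niche model whose latent %DD
  propensity follows configurable standardized path coefficients, so
  every stage of the chain can be verified against known ground truth.

## Worked example

```r
library(ddcomm)

sc <- simulate_scenario(scenario_config(n_species = 80, n_sites = 120,
                                        dd_fraction = 0.12,
                                        dd_clade_count = 2, seed = 1))
sc$cm
#> Community matrix: 120 sites x 80 species
#>   richness: 2-25 (mean 13.37)
#>   occupancy fill: 16.71%

ses <- ses_dd_proportion(sc$cm, sc$dev, n_null = 999, seed = 2)
ses
#> Standardized effect sizes (prop_dd), 120 sites, 999 null replicates
#>   SES: mean -0.76, sd 0.918

fit <- fit_piecewise_sem(dd_path_model(), sc$site_table, sc$coords)
fit
#> Piecewise SEM (exponential errors), n = 120
#>
#> Paths (standardized coefficients):
#>    from      to coefficient    se  p_value
#>    ...
#>    BIO4 prop_dd      -0.259 0.085 2.72e-03
#>     ET0 prop_dd      -0.403 0.075 4.16e-07
#>  SES.FD prop_dd       0.228 0.065 6.36e-04
#>
#> R-squared:
#>   PCPS1  SES.FD prop_dd
#>   0.146   0.090   0.474
#>
#> Independence claims:
#>      x      y         conditioning p_value
#>  PCPS1 SES.FD BIO4,BIO12,ET0,slope   0.161
#>
#> Fisher's C = 3.653, df = 2, p = 0.161  (model consistent with data)
```

The mean SES below zero says communities hold fewer direct developers
than random draws from the pool would (the trait is clustered in rare,
localized lineages). The SEM recovers the generating structure: at 120
sites the fitted standardized paths into %DD (ET0 −0.40, BIO4 −0.26,
SES.FD +0.23) surround the configured truth (−0.45, −0.30, +0.23), the
single d-separation claim (the deliberately absent PCPS1–SES.FD edge) is
not rejected, and Fisher's C accepts the DAG.

File-based workflows go through `run_pipeline()`, which reads the four
input tables (CSV or XLSX, Newick for the tree), aligns them, runs every
stage and writes SES tables, ordination scores, the SEM report and a
JSON log; `write_scenario()` emits a simulated scenario in exactly those
input formats.

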