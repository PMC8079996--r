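# lifecube

Comparative macroevolution of Charnov's dimensionless life-history metrics
across tetrapods, as an R package.

Life-history parameters carry units of mass and time, so the strategies of
small, short-lived species cannot be compared directly with those of large,
long-lived ones. Three dimensionless metrics remove the magnitudes and leave
the trade-offs:

* **LRE**, lifetime reproductive effort:

  LRE = litter size (n) x litters per year (n/yr) x mass at independence (g)
  / adult body mass (g) x adult lifespan (yr)

* **RRL**, relative reproductive lifespan: adult lifespan (yr) / time to
  female maturity (yr)

* **ROS**, relative offspring size: mass at independence (g) / adult body
  mass (g)

with adult lifespan = maximum longevity − age at female maturity, and "mass
at independence" the clade-specific convention (fledging for birds, weaning
for mammals, hatching for reptiles, offspring or egg for amphibians).
Together with natural-log body mass they span a 4-D "life-history cube" in
which clades occupy characteristic subspaces.

The package provides, for anyone analysing trait compilations on dated
phylogenies:

* trait-table ingestion and multi-source merging with strict primary-first
  precedence and per-field provenance (`read_trait_table`,
  `merge_trait_sources`, `build_metric_table`);
* an original linear-time pruning likelihood engine for Brownian motion,
  Ornstein–Uhlenbeck, Pagel's lambda and kappa trait models, with ML
  fitting, AIC selection and permutation tests of phylogenetic signal
  (`bm_loglik`, `fit_model`, `select_model`, `phylo_signal_lambda`);
* univariate and multivariate phylogenetic generalized least squares, the
  latter with a shared Pagel's lambda, optional per-response measurement
  error, and evolutionary correlations among responses after controlling for
  body mass (`pgls`, `mv_pgls`);
* Brownian ancestral-state reconstruction, clade-level ANOVA with Tukey HSD,
  and supertree stitching from divergence-age calibrations (`asr_bm`,
  `class_anova`, `stitch_trees`);
* Gaussian-KDE hypervolumes with Silverman bandwidths, importance-sampled
  volumes, Sorensen overlap and unique fractions (`build_hypervolume`,
  `overlap_stats`, `clade_hypervolume_report`);
* a seeded synthetic-data generator with known ground truth
  (`simulate_yule`, `simulate_mvbm`, `generate_trait_database`) and an
  end-to-end pipeline driver (`run_pipeline`), plus a thin CLI at
  `inst/cli/lifecube`.

Tree I/O and manipulation are delegated to `ape`; the statistics above are
implemented in the package and validated against independent oracles (dense
matrix likelihoods, closed forms, independent contrasts, simulation
recovery) in the test suite.

## Worked example

Generate a synthetic four-clade trait database with known ground truth,
compute the metric table, fit body-mass evolution models for mammals, run
PGLS and the multivariate fit, and compare clade hypervolumes:

```r
library(lifecube)

cfg <- sim_config(
  n_tips = c(Amphibia = 60, Reptilia = 80, Mammalia = 100, Aves = 60),
  crown_ages = c(Amphibia = 310, Reptilia = 190, Mammalia = 170, Aves = 110),
  mass_model = list(
    Amphibia = list(model = "OU",     sigma2 = 0.05, z0 = 3.5, param = 0.01),
    Reptilia = list(model = "OU",     sigma2 = 0.08, z0 = 4.0, param = 0.01),
    Mammalia = list(model = "lambda", sigma2 = 0.05, z0 = 6.0, param = 0.99),
    Aves     = list(model = "lambda", sigma2 = 0.04, z0 = 4.5, param = 0.99)
  ),
  seed = 2026
)
bundle <- generate_trait_database(cfg)
mt <- build_metric_table(merge_trait_sources(bundle$primary, bundle$supplement))
head(mt$metrics[, c("species", "clade", "mass_g", "lre", "rrl", "ros")], 3)
#>    species    clade mass_g   lre rrl    ros
#> 1  Amp_sp1 Amphibia   61.3 5.350 2.5 0.9659
#> 2 Amp_sp10 Amphibia   11.8 0.354 3.3 0.0402
#> 3 Amp_sp11 Amphibia   26.9 0.459 3.5 0.0403
```

Of the 300 simulated species, 228 have all three metrics computable under
the default ~10% per-field missingness; `mt$report` itemizes the 72 drops by
clade and missing field. Per-clade inference:

```r
pc <- species_tree_intersect(mt$metrics[mt$metrics$clade == "Mammalia", ],
                             bundle$trees$Mammalia)
x <- setNames(pc$table$log_mass, pc$table$species)
best <- select_model(lapply(c("BM", "lambda", "kappa", "OU"),
                            function(m) fit_model(pc$tree, x, m)))
pgls(pc$tree, setNames(pc$table$log_ros, pc$table$species), x, best)
#> PGLS fit (correlation: BM, n = 79)
#>         term estimate      se       t         p
#>  (Intercept)  -0.7160 1.26261 -0.5671 5.723e-01
#>        slope  -0.6384 0.08944 -7.1369 4.571e-10

Y <- as.matrix(pc$table[, c("log_lre", "log_rrl", "log_ros")])
dimnames(Y) <- list(pc$table$species, c("lre", "rrl", "ros"))
mv_pgls(pc$tree, Y, x, estimate_error = FALSE)
#> Multivariate PGLS (shared Pagel's lambda = 0.9052, n = 79)
#> Coefficients:
#>                 lre    rrl     ros
#> (Intercept)  1.9712 1.4758 -1.0292
#> slope       -0.3371 0.0230 -0.5982
#> Evolutionary correlations:
#>       lre    rrl    ros
#> lre 1.000  0.593  0.442
#> rrl 0.593  1.000 -0.049
#> ros 0.442 -0.049  1.000
```

The log-ROS slope is negative (larger species produce relatively smaller
offspring) and the LRE–RRL evolutionary correlation of 0.59 sits close to
the generating value of 0.6; the multivariate lambda of 0.91 recovers the
generating residual signal of 0.9. Hypervolumes on the four log axes:

```r
rep <- clade_hypervolume_report(mt$metrics, hv_config(n_samples = 2e4, seed = 1))
rep$volumes
#>      group  n volume
#> 1 Amphibia 42   4012
#> 2     Aves 43   1071
#> 3 Mammalia 79   2033
#> 4 Reptilia 64   1474
```

Volumes are in log-unit^4 and meant for relative comparison: the amphibian
cloud here is about four times the size of the avian one.
`rep$sorensen` holds the pairwise overlap matrix.

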