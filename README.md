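# microguilds

Co-abundance guild detection and aging-trajectory signature analysis for
three-generation gut-microbiome cohorts.

## The problem

Cohort studies of human longevity compare the gut microbiome of
centenarians (G1), their elderly children (G2) and young grandchildren
(G3), sampled within families. The interesting structure is not taxon
lists but *relationships*: which taxa covary as ecological guilds, how the
co-occurrence network degrades or rewires with age, which taxa follow a
rejuvenation trajectory (young ≈ centenarian, distinct from elderly) or a
centenarian-specific one, and which species are stably carried within
families across generations. All of this must be computed on relative
abundances, i.e. compositional data, where naive correlations are spurious
by construction.

microguilds implements this analysis stack as a tested, deterministic,
tidyverse-native R package:

* **SparCC basis correlations** from compositional counts: log-ratio
  variances `t_ij = var log(x_i/x_j)`, the basis system
  `Λ w = T·1`, `Λ = (D−2)I + 11ᵀ`, correlations
  `ρ_ij = (w_i + w_j − t_ij) / (2√(w_i w_j))`, with iterative exclusion of
  strongly correlated pairs;
* **guild detection**: prevalence filter → Ward clustering of the `1 − ρ`
  distance → top-down tree division, each split tested by PERMANOVA on the
  node's distance submatrix (auditable `division_log`);
* **per-group Spearman co-occurrence networks** (`|ρ| ≥ 0.7`, BH
  `q < 0.05`) with shared / specific / discordant edge accounting and
  Wasserman–Faust closeness + eigenvector centralities;
* **trajectory signatures**: pairwise Wilcoxon + BH per group pair,
  bootstrap confirmation (1000 resamples of 10 per group, 90% percentile
  interval), and classification into rejuvenation / centenarian /
  monotone / stable / other;
* **family-stable species**: present in ≥ half of the multi-generation
  families and no group difference (Kruskal–Wallis `p ≥ .05`);
* **taxa–host associations** (cytokines, amyloid-β, BDNF analogues) via
  Spearman with BH control;
* self-implemented **Shannon, richness, Bray–Curtis, PCoA, ANOSIM,
  PERMANOVA** (add-one permutation p-values, exhaustive enumeration for
  tiny designs);
* a **synthetic cohort generator** with planted guilds, trajectories,
  family effects and host covariates, so every stage is testable against a
  known truth without any external data.

## Worked example

```r
library(microguilds)

sim <- simulate_cohort(cohort_config(seed = 1))
sim
#> simulated cohort: 150 taxa x 73 samples (G3=11, G2=30, G1=32), 8 guild(s)

filt   <- prevalence_filter(sim$counts, min_prevalence = 0.2)
fit    <- sparcc(filt)
guilds <- divide_tree(ward_tree(fit$rho), fit$rho,
                      n_perm = 999, alpha = 0.001, seed = 1)
glance(guilds)
#> # A tibble: 1 × 7
#>   n_taxa n_guilds largest_guild smallest_guild n_singletons alpha n_perm
#>    <int>    <int>         <int>          <int>        <int> <dbl>  <int>
#> 1    150       16            13              5            0 0.001    999

truth   <- sim$truth$guild_of[guilds$assignment$taxon_id]
planted <- !is.na(truth)
adjusted_rand_index(guilds$assignment$guild[planted], truth[planted])
#> [1] 0.8524594
```

The 8 planted guilds are recovered at ARI 0.85 (free taxa, which have no
planted guild, cluster into additional noise guilds — hence 16 detected).
Trajectory classification recovers every planted rejuvenation and
centenarian taxon:

```r
cls <- classify_signatures(differential_abundance(sim$counts, sim$metadata))
table(planted = sim$truth$signature_of[cls$taxon_id], detected = cls$class)
#>                detected
#> planted         rejuvenation centenarian stable
#>   centenarian              0          10      0
#>   monotone_up              0           8      0   # strong trajectories can
#>   rejuvenation            10           0      0   # blur into neighbours
#>   stable                   0           0    109

d <- bray_curtis(to_relative(sim$counts))
anosim_test(d, sim$metadata$group, n_perm = 999, seed = 1)
#> ANOSIM: statistic = 0.402, p = 0.001 (Monte Carlo, 999 permutations)
```

`run_cohort_pipeline(counts, metadata, out_dir = "out", seed = 1)` chains
every stage and writes fixed-name TSV/GraphML outputs plus a manifest of
per-stage content hashes; the same seed reproduces the run byte-for-byte.
A thin CLI wrapper lives at `inst/scripts/microguilds-cli.R`
(`simulate` and `run-all` subcommands).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates the default synthetic cohort at the given seed, runs the full
pipeline end-to-end (all stages, 999 permutations) and writes the JSON
report to `--out`.

## Vignette

`vignettes/microguilds-methods.Rmd` documents the estimators, every
tunable parameter with its default and rationale, the synthetic world and
what green tests do and do not establish, numerical conventions, and known
limitations (including the selection bias inherent in testing
clustering-proposed splits).
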