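---
title: "Methods: guild detection and aging-trajectory signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guild detection and aging-trajectory signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microguilds)
```

## Setting

microguilds analyses gut-microbiome count tables from three-generation
longevity cohorts: centenarians (G1), their elderly children (G2) and young
grandchildren (G3), sampled within families. Its inputs are a taxa-by-sample
integer count table (with optional `k__;p__;...` lineage strings) and a
metadata table (`sample_id`, `group`, `family_id`, `generation`, plus
numeric host variables such as serum cytokines, amyloid-beta or BDNF). All
analyses operate on relative abundances, i.e. compositions — which is why
the package centres on correlation estimators designed for compositional
data rather than naive Pearson/Spearman on proportions where closure alone
induces spurious negative correlation.

## SparCC basis correlations

For taxa $i, j$ with per-sample fractions $x_i$, the variance of the
log-ratio across samples,
$t_{ij} = \mathrm{var}\,\log(x_i / x_j)$,
is invariant to closure and relates to the latent ("basis") log absolute
abundances through
$t_{ij} = \omega_i + \omega_j - 2 \rho_{ij}\sqrt{\omega_i \omega_j}$,
with $\omega_i$ the basis variance and $\rho_{ij}$ the basis correlation.
Under the sparsity assumption $\sum_{j \ne i} \rho_{ij} \approx 0$, summing
over $j$ gives the linear system
$\Lambda\, \omega = T\,\mathbf{1}$ with
$\Lambda = (D - 2) I + \mathbf{1}\mathbf{1}^\top$ for $D$ taxa, after which
$\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i \omega_j})$.

Strongly correlated pairs violate the sparsity assumption, so the pair with
the largest $|\rho|$ above the exclusion threshold is removed from the
system (its $t_{ij}$ dropped, the affected diagonal and off-diagonal
entries decremented) and the basis re-solved, iterating up to
`max_exclusion_rounds`. Choices and defaults:

* **pseudocount 0.5** added to counts before closure — zeros are pervasive
  in 16S tables and the estimator needs strictly positive fractions;
* **exclusion threshold 0.8, at most 10 rounds** — customary for this
  estimator family; exclusion stops early (flagged `converged = FALSE`)
  if a taxon would retain fewer than three partners;
* **deterministic by default** (`n_restarts = 1`); Dirichlet-resampled
  averaging is available but off so a pipeline run is reproducible without
  qualification;
* estimates outside $[-1, 1]$ (a known finite-sample behaviour) are clipped
  with a warning and counted in the fit object.

The primary correctness oracle is the closed-form three-component solution
$\omega_1 = (t_{12} + t_{13} - t_{23})/2$ (and cyclic), which the solver
must reproduce to $10^{-10}$; recovery of planted correlations is checked on
simulated compositions.

## Guild detection

Guilds (co-abundance groups) are sets of taxa that rise and fall together.
The pipeline: (1) prevalence filter — taxa present in at least 20% of
samples (or at a configurable relative-abundance floor); (2) SparCC
$\rho$; (3) correlation distance $d = 1 - \rho \in [0, 2]$ and Ward
minimum-variance agglomeration (taxa are sorted lexicographically first so
the tree is invariant to input order); (4) top-down tree division: at each
internal node a PERMANOVA compares the two child memberships on the node's
$1-\rho$ submatrix; the split is kept when $p \le \alpha$ and both children
hold at least two taxa, and recursion continues into the children;
otherwise the node's taxa form one guild. Every tested node is recorded in
`division_log` so the division is auditable.

Two deliberate choices deserve emphasis:

* **Acceptance is $p \le \alpha$, not $p < \alpha$.** Monte Carlo p-values
  use the add-one estimator $(1 + b)/(1 + B)$, whose floor with $B = 999$
  permutations is exactly $10^{-3}$ — the default $\alpha$. A strict
  inequality could then never split at all; the $\le$ convention makes the
  test's resolution explicit rather than silently disabling division. At
  the cohort default of $B = 9999$ the distinction is immaterial.
* **The division tests the split the clustering itself proposed**, so the
  per-node p-value is selection-biased ("double dipping"): on diffuse,
  purely noisy correlation structure the Ward split is near-optimal among
  all label arrangements and the division will keep cutting until nodes
  become small. This mirrors how the procedure behaves on real cohorts
  (many small guilds) and is why recovery is assessed with the adjusted
  Rand index on *planted* guild members, where the criterion is sharp:
  exact planted blocks must be recovered perfectly, and the full synthetic
  pipeline must reach median ARI >= 0.8 over seeds. Free (independent)
  taxa have no planted guild to recover and are excluded from the metric.

Guild abundance is the **sum** of member relative abundances per sample
(computed on the unfiltered table); group differences per guild use
Kruskal-Wallis plus pairwise Wilcoxon with BH adjustment across guilds.
The displayed guild network keeps edges with $|\rho|$ above 0.70.

## Permutation statistics

All permutation machinery is self-contained and shared:

* PERMANOVA pseudo-F from squared distances
  ($SS_\text{total} = \sum_{i<j} d_{ij}^2 / n$, within-group analogue per
  group size), unrestricted label permutation, vectorised over
  permutations; an exhaustive mode enumerates every distinct label
  arrangement (used for the $n = 6$ exactness checks, where the null has
  exactly 20 splits).
* ANOSIM on mid-ranked distances, $R = (\bar r_B - \bar r_W)/(M/2)$.
* Spearman correlations use mid-ranks throughout; p-values come from the
  exact permutation null when $n \le 9$ without ties (the null of the sum
  of squared rank differences is enumerated once per $n$ and cached) and
  the t-approximation otherwise — relevant because the young group has
  only 11 samples.
* Benjamini-Hochberg is the step-up rule applied to exactly the family of
  tests actually performed; untestable pairs (constant vectors) are
  excluded from the family rather than diluted into it.
* Monte Carlo p-values are never zero (add-one estimator) and every test
  records its seed and permutation count.

PCoA is classical scaling of the Gower double-centred matrix; negative
eigenvalues are reported but never returned as coordinates, and requesting
more axes than the positive spectrum supports yields fewer axes with a
warning and a `truncated` flag.

## Trajectory signatures and bootstrap confirmation

Per taxon, three pairwise Wilcoxon tests (G3vG2, G2vG1, G3vG1) on relative
abundances with BH adjustment within each pair family define a significance
pattern; "similar" is operationalised as *not significant at the same BH
threshold used for "distinct"* — no equivalence test is implied by the
underlying protocol, and the classification is a pure function of the
pattern:

| pattern | class |
|---|---|
| G3vG1 ns, G2vG1 sig, G3vG2 sig | rejuvenation |
| G3vG2 ns, G2vG1 sig, G3vG1 sig | centenarian |
| adjacent steps both sig, same direction (or only G3vG1 sig) | monotone |
| nothing sig | stable |
| anything else | other |

Bootstrap confirmation follows the cohort protocol literally: per taxon and
pair, 1000 replicates each draw 10 samples *with replacement* from each
group, the difference of mean relative abundance (older minus younger) is
recorded, and the empirical central 90% percentile interval must exclude 0.
When the subsample (10) is smaller than the group, the interval is slightly
conservative — under the null the confirmed fraction sits near, but a
little below, the nominal 10%; the calibration test asserts the
[0.05, 0.15] band. Interval width must shrink as the subsample grows,
which is also asserted.

Stable (heritable) species: eligible families are those sampled in at least
two distinct age groups; a taxon is "present" in a family when any member
carries it; retention requires presence in at least half the eligible
families *and* Kruskal-Wallis $p \ge 0.05$ across groups — unadjusted by
default, because the rule is an absence-of-evidence screen (a BH-adjusted
variant is available by flag, which can only admit more taxa).

## Co-occurrence networks and discrepancy

Per group: taxa filtered within the group (default: relative abundance
>= 0.1% in >= 20% of the group's samples; the presence-only variant is the
`min_rel_abundance = 0` setting), all-vs-all Spearman, and edges kept at
$|\rho| \ge 0.7$ AND BH $q < 0.05$. Edge identity across groups is the
unordered node pair, sign-blind; sign flips are reported as discordant.
Shared edges appear in every group, specific edges in exactly one, and
edges in some-but-not-all groups are counted separately as partial — so
shared + specific never double-count. Closeness centrality uses the
Wasserman-Faust component-scaled form (the networks are visibly
disconnected, so a convention must be fixed); eigenvector centrality is
power iteration on the unsigned adjacency from a deterministic uniform
start, tolerance $10^{-10}$, max-normalised. Centralities are reported only
for nodes present in every compared network, with within-group ranks.

## The synthetic cohort

Per sample $k$ and taxon $i$:

$$y_{ik} = \mu_i + \lambda_i f_{g(i),k} + \beta_i(\text{group}_k)\,\delta
  + \gamma_{i,\text{fam}(k)} + \varepsilon_{ik}$$

with guild factors $f \sim N(0, \tau^2)$, loadings $\lambda_i$ uniform on
[0.8, 1.2] (zero for free taxa), trajectory patterns over (G3, G2, G1):
monotone-up $(0, \tfrac12, 1)$, monotone-down reversed, rejuvenation
$(0, 1, 0)$, centenarian $(0, 0, 1)$, stable $(0,0,0)$, family effects
$\gamma \sim N(0, 1)$ drawn once per (taxon, family) for stable-class taxa,
and $\varepsilon \sim N(0, \sigma^2)$. The composition is the softmax of
$y$ over taxa; counts are multinomial at depth
$\sim \text{LogNormal}(\ln 20000, 0.3)$ (an optional Dirichlet
overdispersion layer exists and is off by default — multinomial sampling is
the simplest model that preserves compositionality). Host variables are the
configured coefficient times the mean *latent* log-abundance of their
linked taxa plus standard-normal noise, so association-recovery tests have
a noise-free planted truth at the source.

Defaults state the cohort world: group sizes G3/G2/G1 = 11/30/32 (73
samples), 32 families assigned round-robin so no family repeats a group
(families 1-11 then span all three generations, matching a cohort in which
about two dozen families have two or more generations sampled), 150 taxa
with 8 guilds of sizes 5-15, $\delta = 1.5$, $\tau = 1$, $\sigma = 0.5$,
base abundances $\mu_i \sim N(0, 1.5)$ (a realistic several-orders-of-
magnitude abundance spread), ten planted taxa per non-stable trajectory
class, drawn from the free taxa so trajectory and guild structure do not
confound each other. The effect size has no empirical anchor in published
cohorts, so $\delta$ is chosen for testability, not realism.

What the generator does **not** emulate: sequencing error and taxonomy
misassignment, zero-inflation beyond what multinomial sampling at finite
depth produces, phylogenetically structured lineages, uneven group
dispersion, and longitudinal sampling. A green recovery test therefore
establishes that the estimators recover the stated generative structure at
the stated sizes — not that real cohort results are reproduced. Two
further notes: with $\delta = 0$ and family effects on, samples within a
family are weakly dependent, so the exchangeability (uniform Kruskal-Wallis
p) property is asserted at `family_effect_sd = 0`; and because the
composition closes to 1, planted shifts in some taxa induce small
compensatory shifts in all others — at the default sizes these stay well
below detection thresholds, which the null-labelling tests verify rather
than assume.

## Determinism

One global seed drives everything: each stage derives a fixed sub-seed
(stage offset), permutation tests and bootstraps record their seeds, and
the simulator is bit-reproducible from its config. The pipeline manifest
stores a content hash per stage; re-running with identical inputs and seed
reproduces identical hashes and byte-identical output files (timings
aside). RNG state of the calling session is saved and restored around
every seeded operation.

## Known limitations

* The tree-division p-values are selection-biased (above); guild counts on
  noisy data should be read as a resolution-dependent summary, not as the
  number of "real" modules.
* SparCC assumes sparse basis correlations; dense correlation structure
  biases all estimates, only partially mitigated by pair exclusion.
* The Wilcoxon/Kruskal-Wallis layer treats samples as independent; family
  structure is used for the stable-species screen but not modelled as a
  random effect.
* Observed richness is reported as-is; no extrapolated richness estimator
  is implemented.
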