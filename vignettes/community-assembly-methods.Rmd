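---
title: "Models and methods behind halocline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind halocline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halocline)
```

halocline implements the downstream community-ecology workflow used to ask
how a salinity gradient shifts a host-associated bacterial community between
stochastic assembly (drift and dispersal) and deterministic assembly
(environmental filtering): diversity profiling, core-taxon detection, Sloan
neutral-model fitting, null-model stochasticity ratios, Levins niche breadth
and ensemble co-occurrence networks. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices that were
genuinely open.

## Data model

Every stage consumes a *count table*: a tibble whose first column
(`taxon_id`) identifies OTUs/taxa and whose remaining numeric columns are
samples. Tables stay tidy end to end; distance matrices are the one
exception, carried as base `dist` objects because that is the currency of
the vegan/ape ecosystem the beta-diversity stage delegates to.

## Rarefaction and diversity

`rarefy()` subsamples each sample's reads **without replacement**
(multivariate hypergeometric), the direct reading of "subsampling to a
common depth": once a read is drawn it cannot be drawn again. Samples below
the target depth are dropped with a message rather than silently scaled.
The alpha estimators are the classical closed forms: Shannon (natural log
by default; the base is an argument because upstream tools disagree),
Simpson as the dominance form $\sum_i p_i^2$ (so the value *rises* as
diversity falls — this matches tables in which the most diverse group shows
the smallest Simpson value), bias-corrected Chao1
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (defined even when no doubletons exist),
classical ACE with rare cutoff 10, and Good's coverage $1 - F_1/N$. When
every rare-class read is a singleton ACE's sample coverage is zero; the
function falls back to Chao1 with a warning rather than returning infinity.

## Beta diversity

Bray-Curtis dissimilarity, principal coordinates via eigendecomposition of
the double-centred Gower matrix (`stats::cmdscale`), PERMANOVA via
`vegan::adonis2` with raw label permutation and the add-one p-value rule,
and UPGMA (average-linkage) clustering. Negative PCoA eigenvalues are
reported raw but excluded from the variance-explained denominator, since no
convention is universal. Samples are sorted lexicographically before UPGMA
so agglomeration ties resolve deterministically. The clustering method is a
choice: the emulated workflow says only "hierarchical cluster tree", and
average linkage is the standard reading for community distance trees.

## Core microbiome

A taxon is core within a sample set when it occurs in at least 80% of the
samples **and** its unweighted mean per-sample relative abundance is at
least 0.1%; both thresholds are inclusive and exposed as arguments. The
mean relative abundance is the mean of per-sample proportions, not the
proportion of pooled counts — pooling would let one deep sample carry a
taxon over the threshold. Occurrence is evaluated within each metadata
group by default (`core_sets()`), with the study-wide alternative available
by calling `find_core()` on the whole table.

## Sloan neutral community model

Under neutral drift with immigration, the stationary distribution of a
taxon's local relative abundance is Beta$(Nm\,p,\; Nm(1-p))$, where $p$ is
its metacommunity relative abundance and $Nm$ the product of local
community size and immigration rate. The probability of *detecting* the
taxon is then the upper tail of that Beta beyond a detection limit $d$,
giving the predicted occurrence frequency that `fit_ncm()` fits to the
observed (mean relative abundance, occurrence frequency) cloud by least
squares over $\log Nm$ (three bracketed golden-section searches across
$[10^{-2}N, 10^{3}N]$, so a poor local optimum in one bracket cannot win).

The detection limit deserves care. The popular convention is $d = 1/N$
(one read at mean depth $N$). But detection under read sampling is not a
sharp threshold: a taxon at relative abundance $x$ is detected with
probability $1-(1-x)^N$. Fitting a sharp-threshold model to data generated
with smooth detection biases $Nm$ upward by roughly a quarter at study
scale. halocline therefore centres the threshold at the *half-detection*
abundance $d = \ln 2 / N$, the solution of $1-(1-x)^N = 1/2$ — an analytic
constant, not a fitted one — which makes parameter recovery on
neutral-by-construction data essentially unbiased (median recovered $m$
within ~1% of truth in the acceptance checks). Pass `d = 1/N` explicitly to
reproduce the conventional behaviour.

$R^2 = 1 - SSE/SST$ with SST centred on the mean observed frequency, the
coefficient-of-determination convention of the widely used fitting scripts;
values near 1 mean the frequency-abundance cloud is explained by drift plus
immigration alone. The 95% band is a Wilson binomial interval around each
predicted frequency with the number of samples as trial count; taxa above
the band occur more often than neutrality predicts (e.g. host selection),
taxa below occur less often (e.g. dispersal limitation).

## Normalized stochasticity ratio

`nst()` asks how far observed pairwise dissimilarity sits from its
expectation under a null that keeps each sample's richness and read total
fixed while drawing taxon identities by regional occurrence frequency and
abundances proportional to regional mean relative abundance (the
proportional-abundance, fixed-richness null). Each drawn taxon is seeded
with one read before largest-remainder rounding so the richness constraint
cannot be violated by rounding a small quota to zero. For a sample pair
with observed dissimilarity $D$, similarity $C = 1-D$ and null means
$\bar D$, $\bar C$, the selection strength is $(C-\bar C)/(1-\bar C)$ when
the pair is *more similar* than the null and $(D-\bar D)/(1-\bar D)$ when
*more dissimilar*; the pairwise stochasticity ratio is one minus that
strength, capped to $[0,1]$, and the group NST is the mean over
within-group pairs. NST $> 0.5$ is read as stochasticity-dominated
assembly. When observed and null dissimilarities coincide at a boundary
(both 0 or both 1) the strength is defined as zero — the observation is
indistinguishable from the null there.

1000 null draws per group is the default; 100 is a practical floor below
which the null mean is noisy. With a seed, per-group streams are derived
deterministically so adding a group never changes another group's result.

## Levins niche breadth

$B_j = 1/\sum_i P_{ij}^2$ with $P_{ij}$ the share of taxon $j$'s total
abundance found in community $i$: 1 for a single-site specialist, $N$ (the
number of communities) for perfectly even occupancy.
`community_niche_breadth()` summarises per sample, by default as the
unweighted mean over taxa present in the sample. Note a confound of the
unweighted form: presence of *rare* taxa is depth- and
composition-dependent, and sporadically detected rare taxa have low $B$ by
construction, so groups that detect fewer rare taxa (e.g. strongly filtered
communities concentrating reads on few members) can show *higher*
unweighted Bcom for reasons unrelated to niche structure. The
`weighted = TRUE` form (abundance-weighted mean) reflects where the reads
actually sit and is the form used for the gradient-trend checks in this
package's tests.

## Ensemble co-occurrence networks

`build_network()` follows the CoNet recipe on the most abundant taxa
(default 100, genus level when a taxonomy is supplied):

1. **Scores.** Pearson and Spearman correlation across samples, Bray-Curtis
   similarity between taxon profiles, and symmetric Kullback-Leibler
   divergence on row-normalised profiles (pseudocount: half the smallest
   nonzero relative abundance of the taxon, so zeros never produce infinite
   divergence).
2. **Permutation null with renormalization.** Taxon rows are shuffled
   across samples and the table's columns are re-closed to sum one before
   rescoring. Re-closure keeps the compositional structure in the null, so
   the spurious negative correlation that closure induces does not surface
   as signal. Two-sided p-values are centred on the null mean with the
   add-one rule. The bulk path shuffles every row of the table once per
   replicate and scores all pairs simultaneously; the per-pair
   `permutation_null()` shuffles only the pair in question. The two nulls
   differ only through third-party rows entering the re-closure, a
   negligible perturbation at 100 taxa.
3. **Bootstrap restoration.** Samples are resampled with replacement and an
   edge's score interval (95% percentile) is compared with its null
   expectation; edges whose interval covers the null mean are unstable and
   dropped. An edge must survive in at least two measures to proceed.
4. **Brown merge.** The surviving measures' p-values are combined by
   Fisher's statistic referred to a scaled chi-square whose scale and
   degrees of freedom come from the empirical covariance of $-2\ln p$
   across the shared permutation replicates — Fisher's method corrected for
   the strong dependence between measures computed on the same pair.
5. **BH control and signs.** Benjamini-Hochberg at $q = 0.05$ over the
   merged p-values; the edge sign is the sign of the mean of Pearson and
   Spearman, and pairs whose two correlations disagree in sign are
   discarded as unreliable.

Topology metrics follow the NetworkAnalyzer conventions: average number of
neighbours $2E/N$, density $E/(N(N-1))$ (the directed-denominator form NetworkAnalyzer reports), mean local
clustering with degree-<2 nodes contributing zero, and the diameter of the
largest connected component.

Defaults — 1000 permutations, 100 bootstraps, $q = 0.05$, top 100 taxa —
are package choices; all are arguments.

## Synthetic communities

The generators produce data whose *statistical structure* matches what each
analysis assumes, so round-trip tests mean something:

- `simulate_neutral()` draws metacommunity proportions once from a
  log-normal (shape 2 by default: a few dominant taxa, a long rare tail),
  then per sample a Dirichlet with concentration $N m p$ — whose marginals
  are exactly the Beta distributions of the Sloan model — and multinomial
  counts. Parameter recovery by `fit_ncm()` is therefore a genuine
  estimator test, not a smoke test.
- `simulate_filtered()` gives each taxon a salinity optimum (uniform over
  the gradient span) and damps its weight by a Gaussian kernel of width
  `filter_sigma` around the sample's salinity. Width 3 psu against a
  31-55 psu gradient makes filtering strong but not degenerate.
- `simulate_correlated()` plants pairwise correlations in a latent Gaussian
  copula pushed through log-normal abundances and multinomial closure —
  compositional attenuation included, which is exactly what the network
  stage must overcome.
- `simulate_gradient_dataset()` mixes neutral and filtered weights per
  sample with the mixing fraction rising 0 → 0.9 across the four groups;
  with `diversity_decline = TRUE` (default) the filter width also shrinks
  along the gradient so alpha diversity falls too, mirroring the designed
  study's direction.

Defaults (500 taxa, 6 samples/group, 30,000 reads/sample, salinities
31/39/47/55 psu) echo the emulated design at desk-scale cost. What the
generators do **not** emulate: sequencing error, chimeras, taxonomy
mis-assignment, overdispersion beyond the Dirichlet, or phylogenetic
structure among taxa — so green tests here certify the estimators and the
pipeline's logic, not robustness to those artefacts.

The test-suite problem sizes (e.g. 20 neutral replicates for recovery, 10
replicates per NST condition, 20 calibration runs for the network at 500
permutations) were chosen as the package's own compromise between
Monte-Carlo stability and a test suite that stays pleasant to run.

## Numerical choices and degenerate inputs

- Abundance quotas are integerised by largest remainder (exact totals; ties
  broken by index order).
- Weighted sampling without replacement uses the exponential-race scheme
  (`order(rexp(S)/w)`), distributionally identical to sequential weighted
  draws and much faster.
- The NCM optimiser works on $\log Nm$ with three bracketed restarts;
  degenerate all-zero or constant inputs error early with the offending
  taxon or sample named.
- Constant taxa make Pearson/Spearman undefined: the pair is flagged and
  excluded rather than silently zeroed.
- `stochasticity_ratio` defines 0/0 boundary cases as zero selection
  strength.
- One global pipeline seed expands into per-stage seeds by a deterministic
  integer hash, so any stage can be re-run in isolation with an identical
  stream.

## Known limitations

- NST is implemented for the proportional-abundance fixed-richness null
  only; phylogenetic variants (pNST, betaNTI) are out of scope.
- PERMANOVA permutes raw labels without strata.
- The network stage tests pairwise association only; no conditional
  independence or mutual-information scoring.
- Niche-breadth inference shares the detection confound discussed above;
  treat unweighted Bcom comparisons across groups with different effective
  diversities with caution.
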