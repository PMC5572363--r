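---
title: "Co-segregating markers and genetic map inflation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-segregating markers and genetic map inflation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosegmap)
```

## The problem

High-density SNP assays place far more markers on a genetic map than a
biparental population of a few hundred individuals can resolve. A
doubled haploid (DH) population of *n* lines cannot distinguish loci
closer than roughly 100/*n* cM, so a large fraction of markers — often
well over half — show zero observed recombination with at least one
other marker and collapse onto shared map positions. These
*co-segregating markers* form clusters (bins), and a *skeleton map*
keeps a single delegate marker per cluster.

Co-segregating markers would be harmless if genotype calls were
perfect: a marker identical to its delegate adds zero distance
anywhere it is placed. Under a per-call miscall rate $\varepsilon$,
however, two markers at the same locus disagree in a line with
probability $2\varepsilon(1-\varepsilon)$, so their estimated
recombination fraction is positive and every extra cluster member
stretches the map. With $\varepsilon = 0.01$ the expected discordance
is $0.0198$, which the Haldane mapping function turns into
$-50\ln(1 - 2 \times 0.0198) \approx 2$ cM of spurious length per
added marker — the familiar rule that every 1% of scoring error
inflates a dense map by about 2 cM. cosegmap exists to quantify this
mechanism end to end: it simulates DH genotypes with known truth,
builds full, skeleton and *sequential* maps (skeleton plus a subset of
co-segregating markers added back), and measures the inflation factor

$$\mathrm{IF} = \frac{L_\mathrm{seq} - L_\mathrm{sket}}{L_\mathrm{sket}} \times 100,$$

together with the Spearman collinearity of marker order between each
sequential map and the skeleton.

## The simulator

`simulate_dh_population()` draws, for every line and linkage group,
one gamete under the no-interference model: the crossover count is
Poisson with mean $L/100$ for a chromosome of $L$ cM and crossover
positions are uniform, so recombination fractions between loci follow
the Haldane map function by construction. The starting parental allele
of each chromosome is a fair coin flip, giving the 1:1 segregation
expected of DH lines at every marker. Interference is deliberately
omitted: the downstream machinery works through mapping functions, and
a Kosambi-style interference model would only rescale the distances
without changing the inflation mechanism.

Markers are placed by drawing `n_unique_loci` distinct positions per
linkage group and adding extra marker copies at randomly chosen loci
until the configured co-segregation proportion is reached
(`round(n_unique_loci / (1 - coseg_proportion))` markers per group).
After inheritance, two independent noise processes act per call:
symmetric A↔B miscalls with probability `miscall_rate`, then masking
to missing (U) with probability `missing_rate`, capped at 10% to match
the usual curation rule for dense SNP data. The generator returns the
genotype matrix plus a truth table (true position and cluster of every
marker) and the exact error/missing masks, so parameter-recovery tests
can compare estimates against known values.

Defaults emulate a durum-wheat-like study: 177 lines, 14 linkage
groups, 85% co-segregating markers. Chromosome length (150 cM) and
distinct-locus count (40 per group) are round values typical of dense
wheat consensus maps; they matter only through the ratio of locus
spacing to population resolution.

What the simulator does *not* emulate: segregation distortion,
heterozygous residual calls, allele-intensity artefacts, non-random
missingness, and position-dependent error rates. Passing tests
therefore demonstrate the co-segregation inflation mechanism and the
correctness of the mapping machinery, not the full error structure of
any particular genotyping platform.

## The mapping core

**Recombination fractions.** For DH data the natural estimator is the
discordant-call fraction among lines non-missing at both markers.
`pairwise_linkage()` computes all pairs at once via two cross-products
of the ±1/0-coded call matrix. Independence is tested with the exact
two-sided binomial test of the discordant count against
$\mathrm{Bin}(n, 1/2)$ — deterministic and exact for this sampling
model, rather than an approximate LOD threshold. Pairs sharing fewer
than `min_informative = 20` lines are flagged uninformative and
treated as unlinked; below that the estimate's variance makes grouping
and ordering unstable. The raw estimate can exceed 0.5 under noise; it
is retained as-is in records and clamped at 0.4999 only when converted
to distance, where the mapping functions diverge.

**Grouping.** Linkage groups are connected components of the graph
joining pairs with independence *p* < 1e-10 and estimated distance ≤
15 cM — the stringent cutoffs customary for high-density DH maps. Both
thresholds are exposed. Singleton components are reported as unplaced
rather than dropped silently.

**Ordering.** Marker ordering minimizes the sum of adjacent
recombination fractions (SARF) — a path version of the travelling
salesman problem. The implementation builds the complete r̂-weighted
graph, extracts a minimum spanning tree with a deterministic Prim
scan (ties by marker identifier), and takes the MST itself (when it
is a path) or a depth-first traversal from one endpoint of the tree
diameter as the initial order. The order is then refined by
deterministic local search — 2-opt segment reversals plus or-opt
relocations of segments of length 1–3 — run from multiple
deterministic starts (the MST path and nearest-neighbour
constructions from up to eight spread-out seed markers), keeping the
lowest-SARF result. Single-start 2-opt alone was measurably
insufficient: on noisy instances with 4–7 markers it missed the
exhaustive-enumeration optimum in roughly 0.6% of cases, and the
multi-start or-opt scheme closed that gap (0 misses in 5,000 random
instances) while staying fully reproducible. All ties everywhere
break by marker-identifier or index order, and every returned order
is canonically oriented with the lexicographically smaller terminal
marker first, so reruns are bit-identical.

**Distances.** Haldane ($d = -50\ln(1-2r)$) and Kosambi
($d = 25\ln\frac{1+2r}{1-2r}$) functions are provided with exact
inverses. Kosambi is the package default, matching the default of the
mapping software family this workflow emulates; the simulator's
meiosis model is Haldane-consistent, so parameter-recovery checks
against simulated truth use Haldane (Kosambi compresses those
distances by design, about 5% at 5 cM spacing). Map positions are
cumulative sums of adjacent-pair distances along the order.

**Double-recombinant correction.** At high density, a single call that
disagrees with both flanking calls implies two crossovers within a few
cM and is almost always a scoring error. `correct_double_recombinants()`
replaces such calls with the flanking genotype when both nearest
non-missing flanks lie within 10 cM and agree with each other.
Decisions are made against a snapshot of the original calls and
applied in one pass — iterating the pass is deliberately avoided
because repeated flanking imputation can erase genuine tight double
crossovers; terminal markers are never modified and missing calls are
never imputed.

## Clusters, skeletons and the resampling experiments

Co-segregation clusters are connected components of the
zero-recombination graph: pairs with no discordant call among at
least 20 pairwise-complete lines. Defining clusters through estimated
recombination (rather than byte-identical columns) lets markers that
differ only at missing positions share a cluster. The delegate of each
cluster is its most informative member: highest polymorphism
information content ($\mathrm{PIC} = 1 - p^2 - q^2$), then lowest
missing fraction, then a seeded uniform draw.

The bookkeeping identity `n_coseg = total markers − number of
clusters` counts, per cluster, every member beyond the delegate; those
markers form the pool that the experiments add back:

* **Sequential maps, one marker at a time** (`phase1_sequential()`):
  a seeded permutation of the pool; for each prefix length the map is
  fully rebuilt (reordered from scratch, not inserted into a frozen
  order) on delegates plus prefix. One record per added marker.
* **Proportion levels** (`phase2_sampled()`): for levels 10–80% (step
  10) with 50 replicates each — or the 10–60% / 20-replicate fallback
  on groups whose own co-segregation proportion is below the top
  level — a round-half-up sample of the pool is drawn without
  replacement and the map rebuilt on delegates plus sample. Every
  record's RNG seed derives deterministically from (master seed,
  group, level, replicate), so any single map can be regenerated in
  isolation.

Rebuilding with full reordering at every step keeps all maps
methodologically identical, so differences between sequential and
skeleton maps reflect the added markers, not a change of algorithm.
Sequential maps contain the delegates plus the sampled co-segregating
markers only; the alternative reading (all unique markers plus
sample) is equivalent here because every non-delegate marker is by
construction a cluster member.

One practical point discovered in simulation and worth stating
plainly: with miscalls present, *detected* zero-recombination clusters
fragment, because a single discordant call anywhere breaks exact
co-segregation — at $\varepsilon = 0.01$ and $n = 200$, a truly
co-located pair survives with probability
$(1 - 2\varepsilon(1-\varepsilon))^{200} \approx 0.02$. One pass of
double-recombinant correction repairs most errors and restores much
of the clustering (about 58% detected versus 85% true in a typical
run), but not all of it. The resampling experiments on noisy
simulations therefore use the generator's known cluster membership
(`clusters_from_truth()`), which realizes the full 8-level design and
isolates the inflation mechanism from cluster-detection loss;
detection-based clustering (`find_clusters()`) is used whenever the
calls are clean and remains the default in `run_study()`. Both routes
produce identical structures and are interchangeable everywhere.

## Predicting inflation from the co-segregation proportion

`fit_if_models()` regresses IF (percent) on the proportion level
(percent) — the response is IF rather than raw length because IF is
the scale-free quantity the experiments summarize. Eight model tags
run on shared seeded partitions: LR (ordinary least squares), GLM
(Gaussian identity link, numerically identical to LR and asserted so
in tests), POLY2/POLY3 (raw polynomial OLS), KNN (k = 5 on the
standardized predictor), SVM (radial-basis support-vector regression
with package defaults), CART (regression tree pruned at the
cross-validation-minimal complexity), and RF (500-tree random
forest). Two partition designs are scored side by side, since either
could reasonably stand behind a single reported table: an 80/20
holdout, and 10-fold cross-validation with 5 replicates where RMSE
and the Pearson correlation of predicted versus observed are computed
per held-out fold and averaged over the 50 fold-evaluations.
Hyperparameters stay at their documented defaults throughout — the
point of the panel is that on data with a linear trend plus noise all
the learners near-tie, which is exactly what the package's tests
assert (every RMSE within 15% of the LR RMSE on such data).

## Numerical and degenerate-input choices

* Recombination fractions are clamped at 0.4999 before distance
  conversion; raw values are retained.
* Uninformative pairs contribute a fixed SARF penalty of 0.75 —
  worse than any genuine estimate — so ordering pushes them apart
  instead of failing; an *adjacent* uninformative pair in a final map
  is an error naming the pair.
* A linkage group with fewer than two clusters yields a flagged
  zero-length skeleton; resampling on such a group aborts with a
  warning and an empty record set rather than dividing by zero.
* A zero-variance response (as in zero-noise studies where all IF are
  exactly 0) is predicted as the constant training mean for SVM and
  RF, and flags Pearson accuracy as undefined rather than NaN.
* All randomness flows from explicit seeds through a single
  multiplicative-congruential mixer (`derive_seed()`); identical
  configurations are bit-reproducible, and no function disturbs the
  caller's RNG state.

## Resolution limits and test scales

A population of *n* lines resolves order only for loci separated by
clearly more than 100/*n* cM. At *n* = 200 and 1 cM spacing, a pair of
adjacent distinct loci shows zero recombinants with probability
$\approx 0.13$ — the data then genuinely cannot order them, and
near-tied estimates can make a slightly scrambled order the true SARF
optimum. Order-recovery checks therefore use 5–8 cM spacing, where
recovery up to full reversal is deterministic in practice (no failures
in 200 instances at *n* = 200); at tighter spacing occasional local
swaps are a property of the data, not the algorithm.

The checks shipped with the package run at desk scale: the zero-noise
exactness suite uses a 14-group genome of 177 lines with 24 markers
per group; the monotonicity experiment uses one 150 cM group of 200
lines at 85% co-segregation with eight levels of 20 replicates; the
ordering oracle enumerates all orders for 1,000 random 4–7-marker
instances; skeleton-length recovery averages 100 replicates of a
20-marker 100 cM chromosome; and the learner panel fits 400 records
under both partition designs. These sizes were chosen so each property
is measured well inside its Monte-Carlo error, and they are stated
here so readers can scale them up.

## Known limitations

* The simulator's miscalls are symmetric and independent; clustered
  or allele-biased errors would inflate maps differently.
* Cluster detection requires exactly zero discordance; a
  near-cluster rule (tolerating one conflicting call) would trade
  false merges for robustness and is deliberately not implemented.
* Sequential-map experiments scale quadratically in markers per group
  through the pairwise matrix; genome-scale runs should use the
  precomputed-pairwise entry points as `run_study()` does.
* The prediction panel uses a single predictor by design; covariates
  such as group length or marker count are easy to add to the dataset
  but are off by default to keep the modelled relationship the one
  the experiments actually vary.
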