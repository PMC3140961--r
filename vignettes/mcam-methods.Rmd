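---
title: "Ensemble clustering with biological-information feedback: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble clustering with biological-information feedback: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcam)
```

## The problem and the model

Unsupervised clustering of quantitative phosphoproteomic trajectories is
sensitive to every preprocessing and algorithmic choice, and no internal
validity index tells you which choice surfaces biology. `mcam` treats the
whole space of choices as the object of analysis: it builds the ensemble of
all partitions reachable from a parameter vocabulary, scores each partition
by how much *annotated biological information* it concentrates into
clusters, discards parameter values that demonstrably dilute that
information, and then reads hypotheses out of what the surviving ensemble
agrees on.

The statistical core is deliberately elementary. For a cluster of size $n$
inside a dataset of $N$ peptides of which $K$ carry some label, the evidence
of overrepresentation is the hypergeometric upper tail
$P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, K, n)$, computed by
`stats::phyper`. All tests of one category within one clustering set form a
single family controlled by Benjamini–Hochberg FDR at $\alpha = 0.05$
(`stats::p.adjust`; Bonferroni is available as a stricter alternative).
Two choices here are worth making explicit:

* the background is always the **full dataset**, including peptides with no
  annotation in the category — enrichment answers "is this label denser in
  the cluster than in the data as a whole";
* only labels actually observed in a cluster ($k \ge 1$) generate tests,
  and the BH family size is the number of tests actually performed in the
  (set, category) family. Labels with $k = 0$ carry no evidence of
  overrepresentation and testing them would only pad the family.

## The parameter grid

The vocabulary is 12 row-wise transforms, 5 distances, 5 algorithms, and an
even K grid. Transforms are per-peptide because the clustered vectors are
single-peptide trajectories; their definitions are in `?transforms`. Two
composites (`normMax_log10`, `zscore_log10`) chain left to right. A
transform whose output is non-finite for any row of a given dataset (log of
a non-positive value, a zero-variance row under `zscore`) marks every
configuration using it **degenerate**: those configurations are skipped at
run time, with the skip recorded in the run manifest, but still counted in
the grid expansion so that the combinatorial size of a design is a property
of the vocabulary, not of the data. `zscore_log10` in particular is almost
always degenerate on real relative-phosphorylation data; we implement it
literally (zscore, then log10) rather than inventing an offset, and let the
degeneracy rule handle it.

Constraints mirror what each algorithm can accept: affinity propagation
takes no K (its cluster number is emergent), the self-organizing map is
euclidean-only, and k-means uses the squared euclidean criterion and cannot
use chebychev. The K grid runs over even values up to the largest K that
would leave roughly `per_cluster = 5` peptides per cluster under an equal
split; for 77 peptides that is $K_{max} = 14$, and the full vocabulary
expands to 1,320 configurations.

Algorithm implementations: hierarchical clustering is
`stats::hclust(method = "average")` cut at K; the SOM is a 1×K line trained
with `class::batchSOM` (a line makes the unit count equal K; the map shape
is otherwise immaterial to the partition); k-means is a Lloyd iteration
written here because the standard implementations are euclidean-only —
centroid updates follow the metric (component median for cityblock,
normalized mean for cosine/correlation), and an emptied cluster is refilled
with the point farthest from its centroid, which keeps the requested K and
stays deterministic given the stored seed; normalized cut forms the
similarity $s_{ij} = \exp(-d_{ij}^2/\sigma^2)$ with $\sigma$ the median
pairwise distance (a scale-free, self-tuning bandwidth), takes the top K
eigenvectors of the normalized affinity, row-normalizes, and partitions the
embedding with a deterministic farthest-first Lloyd iteration; affinity
propagation follows the standard responsibility/availability updates with
damping 0.9, preference at the median similarity, and up to 1,000
iterations with a 100-iteration stability window. Every non-deterministic
configuration (k-means, SOM) carries its own seed, drawn from the base
seed and recorded in the manifest, so a run is exactly reproducible while
different configurations are not forced into a shared local minimum.

## Dynamic metrics

Besides annotation categories, each peptide contributes four trajectory
statistics — minimum, maximum, maximum consecutive rise and maximum
consecutive fall — binned into dataset-wide quartiles and used as enrichable
labels (`MaxValue:Q4` etc.). These act as markers linking a clustering
outcome to the feature of the dynamics that drove it. Quartile binning is a
parameter-free discretization; it is isolated behind `dynamic_labels()` so a
different binning can be swapped in. Bins are computed on the
*untransformed* data: the metrics describe the measured dynamics, not any
one transform's view of them.

## Parameter refinement

For every parameter value we remove all sets carrying it and measure the
relative change of the per-set mean number of significant labels, overall
and per category. A parameter is pruned when removal improves the overall
score by at least 2% and no category loses more than 10%. Both thresholds
are arguments (`improve_threshold`, `degrade_threshold`) since stricter
improvement requirements are appropriate when comparing ensembles of
different sizes. The score is normalized **per set** because removing sets
always shrinks a raw total; the per-set mean is the natural invariant
quantity. Evaluation is single-pass against the full ensemble, with all
qualifying parameters removed jointly; an iterative mode (re-enrich, re-test
until fixed point) is available behind `iterative = TRUE`. If the joint
removal would empty the ensemble the pruning aborts with its report and no
change.

## Ensemble mining

*Mutual information* between partitions uses the joint co-membership
distribution, in nats — the base is immaterial because MI is only used
comparatively, and the self-MI diagonal equals each partition's entropy.
Subset mean MI (`subset_mean_mi`) averages the off-diagonal MI within a
parameter-matched subset, the device for asking which parameter type drives
similarity between solutions.

*Quartile analysis* ranks sets by significant-label counts within one
metric (ties broken by set id for determinism), takes the top and bottom
$\lceil M/4 \rceil$ sets, and tests each parameter value for
overrepresentation in each quartile with the same hypergeometric tail, BH
corrected per metric. The overlap of two metrics' quartiles is compared to
a null of two random same-size subsets: 1,000 draws give a normal
approximation (mean $\to q^2/M$); an exact hypergeometric mode exists for
small ensembles.

The *co-occurrence matrix* counts, per peptide pair, the sets in which the
pair shares a cluster. For display on a log scale, zero frequencies are
replaced by the half-count pseudo-frequency $0.5/M$ before taking log10.
Derived views: summary statistics (pairs never co-clustering, pairs
co-clustering in a majority of sets — percentages reported to one decimal),
*robust clusters* (peptides inside a label-enriched cluster in at least
half of the sets where that label is enriched anywhere; the denominator is
the label-enriched sets, not all sets, so the question is "when the signal
is visible, who carries it"), peptide-centric clusters, and cross-dataset
comparison (Pearson correlation of upper-triangle frequencies over shared
peptides, plus the ≥ 75% → < 25% extreme-difference screen in both
directions).

## The synthetic generator and the controls

`synthetic_spec()` emulates the shape of a saturating-ligand
phosphotyrosine time course: 77 peptides × 4 timepoints by default, with
four archetypal positive trajectories (early-transient, sustained,
late-rising, down-regulated) as group templates and multiplicative
log-normal noise (`noise_sd = 0.2` on the log scale — a realistic relative
precision for label-free relative quantification) since such measurements
are positive and ratio-scaled. Annotations plant one label per (group,
category) with `within_prob = 0.8` and sprinkle background labels at
`background_prob = 0.05`. What the generator does **not** emulate: missing
values, peptide-level correlation structure beyond group membership,
acquisition noise models, and realistic annotation ontologies with nested
terms. Passing tests on this generator therefore demonstrates the machinery
(combinatorics, calibration, recovery of planted structure), not
performance on any particular real dataset.

Two randomization controls are provided. The matrix shuffle permutes all
$n \times T$ values **globally** — the stronger null, destroying temporal
and peptide structure at once (a within-column mode preserves per-condition
distributions). The label shuffle permutes the peptide-to-trajectory
mapping by one uniform bijection, preserving each peptide's annotation
multiset. `control_runs()` re-clusters and re-enriches each randomization
and `empirical_fpr()` pools per-category rejection rates; on null data every
category's rate should sit at or below $\alpha$ up to binomial error, which
the test suite checks with an $\alpha + 3\,\mathrm{SE}$ band.

## Numerical choices and problem sizes

Distances derived from similarities (correlation, cosine) are clipped at
zero against round-off; MI terms use $0 \log 0 = 0$; eigenvector sign
ambiguity in the spectral embedding is harmless because only pairwise
distances of embedded points matter. Affinity propagation adds a
deterministic jitter of order machine epsilon to break similarity ties, as
reference implementations do with random noise; determinism is preserved.

The packaged tests and the acceptance script run on deliberately modest
problem sizes — ensembles of tens to 150 configurations on 16–77 peptides,
10 control repetitions — which exercise every code path in about a minute
while matching the 77 × 4 geometry of the motivating experiment. The
combinatorial checks (grid size 1,320, pair count 2,926, $K_{max} = 14$)
are exact and size-independent.

## Known limitations

Pruning evaluates parameters marginally; interactions between parameter
values (a transform that is only useful with one distance) are visible in
the quartile analysis but not acted on by the pruning rule. The enrichment
model treats labels within a category as exchangeable and ignores ontology
structure. Affinity propagation's emergent K is not forced into the even K
grid, so AP sets can have any effective cluster count. Cross-dataset
comparison assumes the shared-peptide co-occurrence frequencies are
comparable, which requires both ensembles to be built from comparable
parameter vocabularies.
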