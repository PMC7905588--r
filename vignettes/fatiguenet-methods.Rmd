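---
title: "Methods: co-occurrence networks, contraction importance, and tongue-pulse CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, contraction importance, and tongue-pulse CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguenet)
```

This vignette documents the statistical model behind every number the
package produces, the numerical conventions it commits to (including the
ones where more than one defensible choice exists), and the limits of the
synthetic-cohort generator. It is written for a reader who wants to audit
or extend the methods, not merely run them.

## 1. From raw records to a binary feature matrix

A cohort table carries, per subject, TCM symptom scores, Western medicine
indexes, an H20 health-status score, a clinician fatigue flag, and a
clinician disease flag. `binarize()` maps each record to 0/1:

* **TCM scores** (`kind = "score"`): 0 means absent, 1 (mild) and 2
  (severe) both map to 1. Severity is deliberately discarded — an edge
  weight counts *subjects*, not severity mass, so the network stays a pure
  co-occurrence count.
* **Qualitative indexes** (`kind = "qualitative"`): `-` maps to 0; `+`,
  `++`, `+++` map to 1.
* **Quantitative indexes** (`kind = "quantitative"`): abnormal (1) when the
  value falls strictly outside the closed normal range `[low, high]`.
* **Missing values** map to 0 with a warning. A missing record cannot
  contribute a co-occurrence, and imputing presence would manufacture
  edges; the warning exists because silent zero-filling distorts
  prevalences if missingness is heavy.

`assign_group()` then partitions subjects: a disease flag together with a
fatigue flag gives `disease_fatigue`; otherwise subjects with no positive
index are `subhealthy` when H20 is in [60, 79] and `healthy` when H20 is in
[80, 100]; everything else is `unclassified`. The `positive_index` argument
is the clinician diagnosis flag, not the raw index columns: a synthetic
healthy subject can carry sporadic borderline index positives that no
clinician would call disease.

## 2. The weighted co-occurrence network

For a binary subject-by-feature matrix $M$, `build_network()` computes
$W = M^\top M$ and stores the upper triangle as triples $[V_i, V_j, W_{ij}]$:
$W_{ij}$ is the number of subjects in whom features $i$ and $j$ are abnormal
simultaneously. Zero-weight pairs are not stored; features that co-occur
with nothing remain as isolated nodes, because "present in the cohort but
never jointly abnormal" is itself a finding. A useful invariant (tested
exhaustively and used as a conservation check in the acceptance script):

$$\sum_{i<j} W_{ij} \;=\; \sum_{\text{subjects } s} \binom{k_s}{2},$$

where $k_s$ is the number of abnormal features of subject $s$.

`normalize_weights()` divides every weight by the network-wide maximum, so
association strengths lie in $(0, 1]$ and the strongest pair scores exactly
1. Normalization is always global over the network handed in: when both
within-block (symptom–symptom, index–index) and cross-block (symptom–index)
associations are reported for the same group, they are normalized **once**
over the combined core network and then split by block, so values are
comparable across the three tables. Tables are sorted by normalized weight
descending with a lexicographic `(pair_a, pair_b)` tie-break, which makes
output order a pure function of the data.

On thresholds: with count weights normalized by the maximum, a cutoff such
as `> 0.5` can interact awkwardly with ties and with pairs sitting exactly
at the boundary; published association lists built this way sometimes
include entries at or below the nominal cutoff. `filter_associations()`
therefore applies its threshold strictly (`normalized_weight > value`) and
offers `top_k` as the alternative when a fixed-size list is wanted.

## 3. Cohesion and contraction importance (IMC)

The cohesion of a weighted graph $WG$ is

$$\partial(WG) = \frac{1}{s \times l},$$

and the importance of node $V_i$ is the relative gain in cohesion when
$V_i$ is contracted with its entire closed neighbourhood into a single
super-node:

$$\mathrm{IMC}(V_i) = 1 - \frac{\partial(WG)}{\partial(WG * V_i)}.$$

Two readings of $s$ are defensible, and the package implements both:

* `strength_aggregation = "strength_over_degree"` (default): each node
  contributes its strength (sum of incident weights) divided by its number
  of neighbours, summed over nodes that have neighbours. This is the
  "average tie strength per neighbour, summed" reading.
* `"degree_weighted"`: each node contributes degree × strength. This is the
  literal product-form reading.

Both produce the same *ranking logic*; they differ in scale and in how much
hubs dominate. The default was chosen because it keeps $s$ on the scale of
edge weights and makes the unit-weight special case collapse to
$\partial = 1/(n \bar{l})$ (tested).

Remaining conventions, all of which matter numerically:

* **Hop distances, not weighted distances.** $l$ is the mean shortest
  *hop* distance on the unweighted skeleton of edges whose weight exceeds
  `edge_threshold` (default 0, i.e. every stored edge counts). Large
  co-occurrence counts indicate *strong* ties; treating them as lengths
  would invert their meaning.
* **Disconnected graphs.** `disconnected_policy = "finite_pairs_only"`
  (default) averages over reachable pairs only — equivalent to a
  pair-count-weighted average of per-component means.
  `"component_restricted"` instead takes the unweighted mean of per-component
  mean distances, so small components are not drowned out.
* **Degenerate cases.** A single node has infinite cohesion (nothing to
  hold together, $l$ has no pairs), so contracting a node together with the
  whole graph yields $\mathrm{IMC} = 1$. A graph with nodes but no edges
  has no defined cohesion and raises an error — except inside `imc()`,
  where a contraction that consumes every edge also returns 1, and
  contracting an isolated node (which changes nothing) returns exactly 0.
* **Contraction bookkeeping.** The super-node inherits the contracted
  node's code; edges from the merged set to the outside are summed, which
  preserves total outside weight.

`rank_core()` ranks all nodes by IMC with ties broken by strength
(descending) and then code (lexicographic), and returns the top `k = 10`
as the core set; `extract_core_subnetwork()` induces the subnetwork on one
core (or tags within/cross edges for two cores). IMC frequently saturates
at 1.000 for many nodes of a dense clinical network — contracting any hub
of a near-clique collapses the giant component — which is why the strength
tie-break, not IMC alone, determines the printed order.

Distances are computed with `igraph`; the test suite re-derives cohesion,
contraction, and IMC with an independent matrix-BFS oracle on every labeled
connected graph with up to 5 nodes (771 graphs, every node contracted) and
on 500 random weighted graphs with up to 8 nodes, at a tolerance of 1e-12.

## 4. Canonical correlation of tongue and pulse blocks

`fit_cca()` z-scores both blocks, whitens via the symmetric inverse square
roots of the within-block correlation matrices (eigendecomposition, with a
rank check at 1e-10 relative tolerance), and takes the singular value
decomposition of the whitened cross-correlation. Canonical variates have
unit variance; signs follow the convention that the largest-magnitude
x-loading of each dimension is positive, with the paired y-side flipped in
lockstep — so results are reproducible to the sign. Significance is the
Bartlett chi-square approximation on Wilks' $\Lambda_k$,

$$\chi^2_k = -\left(n - 1 - \tfrac{p + q + 1}{2}\right)\ln\Lambda_k,
\qquad \Lambda_k = \prod_{i \ge k}(1 - r_i^2),$$

with $(p - k + 1)(q - k + 1)$ degrees of freedom, or a permutation test
(`cca_significance(method = "permutation")`) that shuffles the rows of one
block. `structure_loadings()` reports per-variable correlations with the
own-block canonical variate, which is the interpretable quantity when
raw coefficients are unstable under collinearity.

Before CCA, `exclude_outlier_subjects()` drops subjects with any variable
beyond the Tukey hinge fences (hinges from `stats::fivenum`, inner fence at
1.5 × hinge spread by default, outer at 3×), logging each exclusion. Note a
side effect visible in every run: trimming multivariate tails removes
disproportionately informative subjects, so recovered canonical
correlations sit a few hundredths *below* the generator's planted value.
That is a property of the procedure, not an estimation error.

## 5. The synthetic cohort generator

The generator exists so the pipeline is fully testable without clinical
data. What it emulates:

* **Group sizes** default to 742 healthy, 361 sub-healthy, 1529
  disease-fatigue (total 2632), with disease subgroups drawn in proportions
  311/157/518/442 (hypertension, diabetes, hyperlipemia, fatty liver).
* **Binary features** arise from a latent-factor noisy-OR model: subject
  $s$ activates a sparse set of latent factors (coating, neuro, somatic,
  metabolic, hematologic — with group-specific activation probabilities),
  and feature $j$ fires with
  $p_{sj} = 1 - (1 - \pi_j)\prod_{f \text{ active}}(1 - \lambda_{fj})$,
  where $\pi_j$ is a baseline prevalence. Shared factors are what create
  the block structure that the network methods are supposed to find.
* **H20 scores** are truncated normal per group: healthy 88 ± 5 on
  [80, 100], sub-healthy 70 ± 4 on [60, 79], disease 62 ± 10 (drawn by
  inverse-CDF, so they are exact and seed-reproducible).
* **Tongue-pulse tables** plant a first canonical correlation: a latent
  bivariate normal pair $(u, v)$ with correlation $\rho$ drives both blocks
  through fixed loading vectors plus independent noise,
  $x_j = \mu_j + \sigma_j(a_j u + \tau \varepsilon_j)$. With per-variable
  noise $\tau$ (`noise_sd`), the population first canonical correlation is
  attenuated to approximately $\rho / (1 + \tau^2)$; the default
  $\tau = 0.12$ was chosen analytically so the attenuation is below 0.02 at
  $\rho = 0.42$ — small enough that the planted value is the effective
  truth, large enough that no variable is a deterministic copy of the
  latent. Group defaults: $\rho$ = 0.475 (healthy), 0.05 (sub-health),
  0.42 (disease); n = 1160 for a standalone table.

What it deliberately does **not** emulate: severity gradation within
symptoms (scores are generated directly as 0/1 presence), measurement
units or physiologic ranges of the tongue/pulse variables (blocks are
affine families around nominal means — CCA is affine-invariant, so this
costs nothing), missingness, age/sex structure, and any causal link
between the binary features and the tongue-pulse blocks (the two are
generated independently given the group). Sample CCA on a near-null block
pair overfits — the expected first sample correlation at $p = q = 14$,
$n \approx 320$ is around 0.35 even when $\rho = 0.05$ — which is exactly
why the sub-health group shows a sizeable but non-significant estimate;
the package reports the Bartlett p-value alongside every correlation for
this reason.

## 6. Determinism and run manifests

`run_study()` derives every random stream from the single config seed
(per-stage offsets, all below $2^{31}$), and writes `manifest.yaml` with
the seed, package version, parameters, and an md5 checksum per artifact —
and **no timestamps**, so two runs with the same seed produce byte-identical
manifests. Reproducibility is checkable with `md5sum`, not eyeballs.

## 7. Problem sizes and limitations

The methods are exercised at the study scale (2632 subjects, 20 symptoms,
15 indexes, 28 tongue-pulse variables) and at the property-testing scale
(graphs to 8 nodes against oracles). Practical limits:

* IMC requires one cohesion evaluation per ranked node; with all-pairs BFS
  at $O(nm)$ per evaluation this is comfortable to a few thousand nodes but
  not beyond.
* The Bartlett test is asymptotic; for small $n$ relative to $p + q$, use
  the permutation test.
* Count weights make normalized associations cohort-size dependent;
  compare normalized values across groups, never raw counts.
* IMC saturation in dense networks means the core *membership* is robust
  but the ordering within the saturated set rests on the strength
  tie-break.
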