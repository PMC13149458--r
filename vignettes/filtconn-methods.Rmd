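---
title: "Methods: group analysis of structural connectomes under tractogram filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group analysis of structural connectomes under tractogram filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filtconn)
```

# Overview

`filtconn` analyzes cohorts of structural brain connectomes — symmetric,
nonnegative weight matrices over a fixed parcellation (by default the 90
cortical and subcortical AAL regions) — for differences between a patient
group (PD) and healthy controls (HC), at three levels:

1. **Edges.** Mass-univariate Welch t statistics per region pair,
   aggregated by threshold-free network-based statistics (TFNBS) with
   permutation family-wise error (FWE) control, for both directed
   hypotheses (t1: PD > HC, t2: HC > PD).
2. **Nodes and whole brain.** Weighted graph measures per subject
   (strength, betweenness centrality, clustering coefficient;
   whole-brain node averages and strength assortativity), compared
   between groups with Welch t tests, Benjamini–Yekutieli (BY)
   correction, and Cohen's d effect sizes including the change in d under
   filtering (Δd).
3. **Whole connectome.** PD-vs-HC classification with linear SVMs on the
   4005 upper-triangle edge weights (optionally PCA-reduced to 64
   components) and with message-passing graph neural networks that use
   each node's connection profile as its input features.

Each connectome exists in two filtering states — *unfiltered* and
*filtered* — linked by SIFT2-style per-edge weight multipliers in
\[0, 1\]. The package's central question is how this filtering step
changes the three analyses; the *filtering-impact taxonomy* classifies
every node-level comparison cell as a **null effect** (significant in
both states), **removal** (only unfiltered), or **emergence** (only
filtered), judged at the pre-correction α = 0.05 as in the reporting
convention the tables follow.

Because real diffusion-MRI cohorts are not required (or desk-scale
reproducible), the package ships a synthetic cohort generator that
emulates the statistical structure of such data, so every stage is
testable and calibratable end to end.

# Edge-level inference: TFNBS

For one metric and filtering state, each subject contributes the
n(n−1)/2 upper-triangle edge weights. Per edge we compute a Welch
(unequal-variance) two-sample t statistic, positive when the PD mean
exceeds the HC mean. Welch's form was chosen because the design is
unbalanced (67 vs 166 by default) and edge-weight variances differ
between groups; the test behind the printed tables is not otherwise
pinned down.

TFNBS replaces the single cluster-forming threshold of the classical
network-based statistic with a ladder of thresholds. For threshold h,
edges with t > h form a suprathreshold graph; every suprathreshold edge
accumulates

  extent(component)^E · h^H · Δh,

where *extent* is the number of **edges** in its connected component
(matching the "number of connections" reading of extent) and Δh the
ladder spacing. Defaults are E = 0.5, H = 3, 100 ladder levels — values
inside the ranges recommended by the TFNBS literature; the source tables
print none, so all three are configuration parameters.

**Threshold ladder.** By default the ladder is data-driven: 100 levels
evenly spaced over (0, max t]. Crucially, this makes the score a fixed
*function of the t-map*: in the permutation test every permuted map is
scored with its own (0, max t] ladder. Scoring permuted maps on the
observed map's ladder would truncate permutations whose maximum exceeds
the observed one and anticonservatively shrink the null distribution —
we verified a family-wise rejection rate of ≈ 0.09 instead of 0.05 under
that variant, and ≈ 0.035–0.05 under the per-map ladder (the acceptance
suite re-checks this calibration on every run).

**Numerical knife edge.** The top ladder level sits exactly at max t, so
the test `t > tmax·k/n` at k = n is floating-point fragile. The scorer
therefore uses the cross-multiplied comparison `t·n > tmax·k`, which is
exact when t equals tmax: the maximal edge never survives its own top
level, in exact agreement with the limit of the continuous definition.

**FWE control.** For B random group-label permutations (default 5000,
seeded, shared between the two hypotheses so their nulls are comparable),
the maximum score over edges forms the null distribution and
p_FWE(edge) = (1 + #{perm max ≥ score}) / (1 + B), never below
1/(B + 1). When the number of distinct group assignments is at most B
the test switches to exhaustive enumeration and the p-values are exact;
the observed labeling is then counted exactly once. The observed map's t
statistics are recomputed through the same batched routine as the
permutations so that the observed labeling's presence in the null set
survives floating-point arithmetic.

Edges with zero variance in both groups get t = 0 (equal means) and are
flagged; covariates (age, sex) are carried in the manifest but not
adjusted for, since the reference analysis describes none.

# Graph measures

All measures treat the connectome as a dense weighted undirected graph —
no thresholding anywhere, consistent with how the connectomes are built.

* **Strength**: s_i = Σ_j w_ij.
* **Betweenness centrality**: fraction of all-pairs shortest paths
  through each node, with fractional credit for ties, on edge lengths
  l = 1/w (the standard "strong edge = short path" convention for
  connectivity weights; computed via igraph's weighted Brandes
  algorithm), normalized by (N−1)(N−2)/2 into \[0, 1\].
* **Clustering coefficient**: the Onnela weighted form with weights
  rescaled by the graph maximum — the dominant convention in the
  brain-connectivity literature when only the concept, not the formula,
  is specified. It is invariant to global rescaling of the weights.
* **Assortativity**: Pearson correlation of endpoint *strengths* over
  the edge list (each undirected edge contributing both orientations) —
  the measure is defined on strengths, deliberately not on degrees,
  which in a dense graph are uninformative. Degenerate graphs (constant
  endpoint strengths) yield `NA`, reported as missing and excluded
  pairwise from group tests.

All four are validated against brute-force oracles (row sums, exhaustive
simple-path enumeration, triple loops, hand-built edge lists) on random
graphs with up to 8 nodes at tolerance 1e-9.

# Group comparisons, BY correction, effect sizes

Node-level and whole-brain comparisons use two-sided Welch t tests. The
BY procedure (valid under arbitrary dependence — graph measures of one
subject are strongly dependent across nodes) is applied across the 90
nodes *within* one (metric, filtering, measure) family, matching the
"corrected across all 90 nodes" convention; pooling families would
change the question being asked. Significance stars in the wide reports
(`P**`, `H*`, `-`) reflect *pre-correction* p-values, as the reporting
convention does, with direction P meaning PD mean higher; BY-corrected
p-values are a separate column so corrected inference stays explicit.

Cohen's d uses the classical pooled standard deviation; its 95% CI uses
the normal approximation se(d) ≈ sqrt((n1+n2)/(n1·n2) + d²/(2(n1+n2))).
Δd = d_filtered − d_unfiltered summarizes how filtering moves effect
sizes.

One dependence effect deserves emphasis: measures with a graph-global
ingredient — Onnela clustering through its max-weight rescaling, and to
a lesser degree betweenness through path competition — share a common
per-subject factor across all nodes, so the 90 node tests of one family
are strongly positively correlated. In a single cohort the
pre-correction rejection count is then nearly all-or-nothing (we observe
per-cohort null rates of 0 or 1 for FA clustering, averaging ≈ 0.05
across cohorts, i.e. each node's test is individually calibrated). This
is exactly the regime BY is designed for — it remains valid under
arbitrary dependence — and is why the pre-correction star counts in the
wide reports must not be read as a calibration statement.

# Classification

Folds are stratified by group (5-fold by default, seeded): with a 67/166
imbalance, unstratified folds can easily produce near-single-class
validation sets. PD is the positive class for precision/recall/F1 — the
disease-detection convention; AUC is computed from SVM decision values
or GNN probabilities by the rank statistic. Standardization and PCA are
fitted on the training folds only, so no information leaks from
validation data into the transforms.

The GNNs are implemented from scratch (dense linear algebra, manual
backpropagation verified against numerical gradients, Adam). Messages
are *node-concat*: message(i, j) = MLP(x_i ‖ x_j) for the GCN, and
MLP(x_i ‖ a_ij·x_j) for the GAT, where a_ij is a single-head attention
coefficient — a LeakyReLU-scored learned function of the endpoint
features, softmax-normalized over each node's neighborhood. With all
a_ij forced to 1 the GAT layer reduces *exactly* to the GCN layer, and
the test suite asserts this identity at full-model level. Node input
features are connection profiles (the node's row of the weight matrix);
messages are mean-aggregated, node features mean-pooled, and a linear
head produces the PD logit, trained with inverse-frequency
class-weighted cross-entropy. Defaults (2 layers, hidden width 8, 30
epochs, Adam lr 0.01, batch 16) are minimal and fully configurable.

GNN inputs are centered per entry and scaled by the *average* training
entry standard deviation rather than z-scored entrywise: entrywise
scaling equalizes informative and pure-noise entries and measurably hurt
recovery of planted effects, while a global scale preserves the relative
variance structure.

# The synthetic cohort generator

The generator emulates what the imaging pipeline hands to the analysis —
nothing upstream of it (no streamlines, no images):

* **Cohort**: 67 HC and 166 PD by default, sex ratios 24F/43M and
  61F/105M, ages normal per group and sex (58.8 ± 8.6, 61.8 ± 12.0,
  60.1 ± 9.0, 61.7 ± 9.7 years).
* **SC** (streamline count): log-normal per edge with a latent
  distance-decay mean structure over random 3-D region positions
  (log-mean 4 − 3·distance, per-edge spread τ = 1.0, per-subject noise
  σ = 0.6), so hubs and weak edges coexist and every edge is present —
  the dense regime of unthresholded probabilistic tractography. One
  global multiplicative factor per subject (sd 10%) emulates
  between-subject streamline-count variability.
* **FA**: logit-normal around 0.45 (bounded in (0, 1));
  **AD/RD**: log-normal around 1.7 and 0.5 (units of 10⁻³ mm²/s);
  **MD** = (AD + 2·RD)/3 up to 1% multiplicative noise, mimicking the
  tensor coupling. Real SC scales are not published for the reference
  cohort, so these baselines are conventions — flagged as such, chosen
  once, at magnitudes typical for AAL-90 connectomes.
* **Filtering**: per-edge multipliers m ~ Beta with mean decreasing in a
  latent edge implausibility score (longer edges are less plausible;
  logistic mean 1.2 − 2·z, concentration 30), identical in law for both
  groups — filtering unbiased by disease status, which the
  multiplier-histogram comparison (Kolmogorov–Smirnov over 10 + 10
  random subjects) verifies. Filtered SC = m × unfiltered SC exactly;
  mean-metric weights are shrunk toward the edge population mean in
  proportion to γ(1 − m), γ = 0.5, never leaving the metric's range.

**Planted effects.** An effect specifies target edges (or all edges
incident to target nodes), a metric, a Cohen's d on the analyzed
raw-weight scale, and a filtering-interaction stage. Location shifts are
applied on the log (SC, diffusivities) or logit (FA) scale, but a naive
shift of d·σ does *not* produce raw-scale Cohen's d = d for skewed
weight laws (planting 1.5 that way yields ≈ 1.17). The generator
therefore solves numerically (quadrature + root finding) for the
transformed-scale shift whose population raw-scale pooled-sd d equals
the request, and refuses infeasible requests up front — for a log-normal
family the raw-scale d of a location shift is bounded (≈ 2.1 at σ = 0.6),
so e.g. d = 5 on SC is a configuration error, while d = 5 on the nearly
symmetric FA family is fine.

The two filtering-interaction stages model streamline-count mechanics
(and therefore require SC):

* `unfiltered_only` (removal): the effect is planted *additively* and
  the targeted edges get small, highly variable multipliers
  (Beta mean 0.05, concentration 2). Multiplicative filtering would
  preserve a multiplicative effect exactly, which is why the removal
  channel must be additive; the high-variance multipliers then both
  shrink the mean difference and inflate the variance after filtering.
* `masked_until_filtered` (emergence): the planted (multiplicative)
  effect is multiplied by heavy spurious-streamline noise
  n ≥ 1 (1 + log-normal(1, 1.5)), and the multiplier for those edges is
  m = m_base/n — filtering removes exactly the spurious mass, as a
  signal-explainability filter is designed to, revealing the effect.

**Determinism.** One master seed; per-subject sub-seeds are drawn from
it up front, so cohorts are byte-identical across runs.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: spatial autocorrelation of edge
weights beyond distance decay, site/scanner effects, head-motion
artifacts, age/sex dependence of connectivity (covariates are generated
but independent of the weights), disease heterogeneity (a single planted
effect, not subtypes), and any real relationship between SIFT2 weights
and streamline geometry. Calibration results (FWE, BY) transfer to real
data only insofar as subject exchangeability under the null holds there
too.

# Problem sizes used by the tests and the acceptance analysis

All simulation-based checks run at desk scale, chosen once as the
smallest sizes at which each property is statistically identifiable:
graph-measure oracles on ≥ 200 random graphs of 4–8 nodes; TFNBS oracle
on 50 random 10-node maps; exhaustive permutation on a 4-vs-4 toy (70
assignments); FWE calibration on 200 null cohorts of 20 nodes, 15 + 15
subjects, 500 permutations; effect recovery at 100 subjects per group;
scenario enrichment on 20-node, 40 + 40 cohorts pooled over three
replicates; classification checks on 10-node cohorts of 100 per group
(SVM and GNN) and the full 67/166 grid only for structural checks of the
report. The headline acceptance script reruns the study-sized (90-node,
67 + 166) null analysis end to end.

Two classification behaviors deserve honesty. First, with 4005 features
and ~200 subjects (p ≫ n), a maximum-margin SVM dilutes a single
informative feature across noise dimensions — even a d = 5 edge is *not*
reliably found at 90 nodes, which is itself a faithful property of this
model class at these sizes. Second, the generator's noise laws are
unbounded, so a location shift of any finite d can never *guarantee* a
linearly separable draw. The separability sanity checks therefore use an
explicitly constructed cohort — bounded uniform edge noise with one edge
shifted by exactly d = 5, leaving a literal gap between the groups — in
the classical n > p regime (6 nodes, 100 per group), where the SVM
attains fold AUC 1.0 and the GNNs exceed 0.9 robustly across seeds. The
GNN's reported results use short training schedules (8–30 epochs) sized
for the cohorts above.

# Known limitations

* TFNBS exponents (E, H) and ladder depth are conventions; conclusions
  about specific components can be sensitive to them.
* The BY family choice (per metric/filtering/measure) is a reporting
  decision; pooling across metrics would be stricter.
* Betweenness and clustering conventions (1/w lengths, Onnela with
  graph-max rescaling) are the field's defaults but not the only ones;
  both are isolated behind single functions and easy to swap.
* The normal-approximation CI for d is first-order only; at the default
  group sizes the approximation error is well below the reported
  precision.
* GNN determinism holds for a fixed seed and BLAS; across BLAS builds,
  last-ulp differences can change individual fold metrics (never the
  reduction identity, which is arithmetic).
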