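---
title: "Methods: integrative mRNA/miRNA network analysis in ildnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative mRNA/miRNA network analysis in ildnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ildnet)
```

`ildnet` chains the stages of an integrative case/control expression study
of interstitial lung disease: normalize and filter paired mRNA/miRNA
matrices, call differential features, cluster samples, rank two-feature
biomarkers, integrate predicted miRNA targets by inverse correlation,
assemble a signed TF/miRNA/gene network, enumerate feed-forward loops, and
test gene sets and marker-stratified modules. This vignette records the
statistical model behind each stage, the tunable parameters and their
defaults, the numerical conventions, and the design choices that were
genuinely open — together with what the synthetic benchmark does and does
not establish about real data.

## The synthetic cohort: what is emulated

`simulate_cohort()` draws a two-arm cohort shaped like the motivating
study: 23 cases (round-robin across three FVC strata, with rotating
diagnosis labels) versus 6 controls, ~2000 gene probes and ~300 miRNA
probes. The generative model is additive on the log2 scale:

* per-feature baselines are Gaussian, `baseline_mean = 8`,
  `baseline_sd = 1`, matching the typical spread of log2 array
  intensities; a `frac_absent = 0.2` subset of genes is drawn from a low
  component at `absent_mean = 2` (≈6 baseline sds below the expressed
  component, the regime where present/absent calling is meaningful);
* planted differential features shift case samples by
  ±`effect_log2fc = 1.5` (≈2.8-fold, comfortably above the 1.5-fold call
  threshold);
* independent Gaussian noise with `noise_sd = 0.7` per feature and sample
  — the original study reports no within-group variance estimate, so this
  is a free parameter chosen to put per-feature t statistics in a
  realistic moderate-power regime, not an estimate from the deposited
  arrays;
* planted miRNA targets are repressed additively:
  `gene −= repression_strength × (miRNA − mean(miRNA))`. Additive log2
  coupling is the simplest mechanism that simultaneously (a) induces
  differential expression in the target opposite in direction to its
  miRNA and (b) makes the pair negatively correlated across pooled
  samples — the two facts the integration stage relies on. The default
  `repression_strength = 1` was chosen analytically: with a miRNA group
  shift of 1.5 and noise sd 0.7 under the 23v6 design, the pooled
  target–miRNA correlation is ≈ −0.8;
* TF regulons couple targets to the TF's centered profile with
  `tf_coupling = 0.8`, signs chosen to reinforce each target's planted
  direction so that the planted sign is also the recoverable sign;
* planted feed-forward loops are realized through the regulon and target
  tables, so a planted triad is exactly recoverable whenever its three
  edges survive the statistical filters.

Deliberately **not** emulated: probe-level artifacts, batch effects,
sex-linked expression, correlated noise between features, and the
heavy-tailed variance heterogeneity of real arrays. Passing recovery tests
therefore demonstrates that the pipeline's inference is correct under its
own assumptions — not that those assumptions hold on any particular GEO
series.

## Preprocessing

**Quantile normalization** replaces each value by the cross-sample mean of
its rank's order statistic. Ties receive the mean of the reference values
over their rank range, which keeps the transform deterministic and
idempotent; on tie-free input every column ends with the identical
multiset of values.

**Present/absent calls** fit a one-dimensional two-component
*equal-variance* Gaussian mixture by EM to per-feature mean log2
intensity. Equal variances guarantee a single monotone decision boundary
(a feature is present iff its mean exceeds a threshold), which makes the
call testable and interpretable. EM is initialized deterministically by a
median split, with tolerance `1e-8` on the log-likelihood and 500
iterations; there are no random restarts. Two degenerate regimes fall back
to a median threshold with a warning: non-convergence, and fits whose
components sit closer than two within-component sds — on effectively
unimodal data the equal-variance EM converges to spurious splits of 0.6–
1.5 sd, well separated from the ≥6 sd gaps of genuinely bimodal intensity
data, so 2 sd is a safe boundary between the regimes. The filter is an
mRNA-only policy: miRNA matrices pass through unchanged.

The mixture is fit on per-feature summaries rather than per-array values;
with per-feature means over ~29 arrays the absent/present separation is
essentially the baseline-level separation, and calls are stable.

## Differential expression and the pFDR

Per feature, a two-sample *t* on log2 values. The default is the
**pooled-variance Student t**, not Welch: the cohort design is strongly
unbalanced (23 vs 6), and in that regime the Welch–Satterthwaite
approximation is anti-conservative in the far tail — simulation under the
package's own equal-variance noise model shows null tail inflation of
≈1.8× at p = 3×10⁻³ and ≈2.5× at 10⁻³, which is exactly the region where
FDR thresholds operate, and the realized false discovery proportion rises
accordingly. Under the generator's equal-variance model the pooled t is
exactly calibrated. Welch remains available (`var_equal = FALSE`) for data
with genuine group-variance differences; a variance floor of 1e-9 keeps
degenerate zero-variance features finite.

q-values follow the positive-FDR construction: π₀ is estimated as
min(1, #{p > λ}/(m(1−λ))) with λ = 0.5 (floored at 1/m so q stays in
(0, 1]), and q for the i-th ordered p is the running minimum of
π₀·m·p₍ⱼ₎/j over j ≥ i. With π₀ forced to 1 this *is* Benjamini–Hochberg
step-up, which is the reduction the tests pin. Differential calls require
|fold| ≥ 1.5 **and** q strictly < 0.1, the thresholds of the motivating
analysis; calls pool cases across FVC strata.

## Clustering and top-scoring pairs

Samples are clustered with average linkage on 1 − Pearson correlation
between expression profiles over the differential features. Neither the
distance nor the linkage is dictated by the source analysis; this pairing
is the conventional expression-heatmap dialect, is invariant to per-sample
affine rescaling, and is fully testable against a brute-force linkage
oracle. Samples are processed in lexicographic id order so tied merges are
deterministic.

The TSP score for an ordered pair (i, j), i < j lexicographically, is
Δ = |P̂(Xᵢ < Xⱼ | class 1) − P̂(Xᵢ < Xⱼ | class 2)| with the *strict*
event and ties counted as event-false — deterministic on discretized
data. A secondary score Γ (between-class difference in mean within-pair
rank gap) orders Δ-ties, and remaining ties resolve lexicographically, so
the ranking is total. Classification uses the pair's orientation; an exact
tie in a test sample goes to the class with the higher training prevalence
of the false event. Leave-one-out cross-validation re-selects the top pair
inside every training fold and contains no randomness.

## miRNA–target integration

Candidates are the predicted (miRNA, gene) pairs whose miRNA and gene are
both differential. Each candidate is scored by the Pearson correlation of
its profiles across all samples pooled — pooling reflects the group-level
contrast the analysis targets and maximizes n at the cohort's scale — with
a one-sided p-value for negative correlation (t transform, n − 2 df),
Benjamini–Hochberg adjustment *globally across candidates* (a per-miRNA
adjustment would change the denominator per family; the global choice is
the deterministic default), and retention iff r < 0 and q < 0.1. The pFDR
estimator is available by flag for symmetry with the differential stage.

One property of this filter deserves emphasis: across a pooled
case/control cohort, *any* two differential features shifted in opposite
directions are genuinely anticorrelated through the shared group effect.
The filter cannot — and should not — distinguish that from repression;
this is inherent to pooled-correlation integration, and it is why the
recovery benchmark evaluates specificity on decoy pairs drawn among
features with no planted structure (truly uncorrelated profiles), while
retention of direction-discordant decoy predictions is reported as an
unasserted diagnostic.

## The signed network, modules and hubs

Binding-predicted TF→target pairs are signed by expression: Pearson r
across shared samples, two-sided p, BH across pairs, kept at q < 0.1;
r > 0 becomes `tf_activate` (+1), r < 0 `tf_repress` (−1). Retained
miRNA pairs enter as `mirna_repress` (−1). PPI and pathway edges are
unsigned context (sign 0) and never participate in sign logic. Assembly
restricts all edges to the differential node universe (DEG / DETF /
DEmiRNA, where a DETF is a DEG present in a user-supplied TF catalog),
drops self-loops, and collapses duplicate (source, target, type) triples
with provenance concatenated. A scope flag reproduces the TF-centered
network variant in which miRNA edges onto non-TF genes are excluded.

Module detection is greedy agglomerative modularity maximization on the
undirected unsigned projection. The reference analysis names only
"connectivity-based" grouping, so the algorithm was chosen for exact
reproducibility: communities are labeled by their smallest member id,
candidate merges are scanned in lexicographic label order, modularity-gain
ties resolve to the first pair, merging stops when no merge strictly
increases Q, and isolated nodes stay singletons. The module *count* of any
particular published figure is not a target — it depends on annotation
snapshots — but partitions are total, deterministic, and never worse than
the trivial one-module partition. Hub ranking is plain unweighted degree
(in + out, each typed edge once), ties lexicographic.

Marker stratification splits case samples at the marker's median
expression (the median sample goes to "low"), tests each module gene
between strata (Welch here, since stratum variances have no reason to be
equal), and adjusts within the module.

## Feed-forward loops

A triad (TF, miRNA, gene) is an FFL when the network carries signed edges
TF→miRNA and TF→gene and a repression edge miRNA→gene, with the gene
distinct from both regulators. The miRNA→target branch is fixed at −1 —
miRNA regulation is modeled as repression throughout, and no positive
miRNA edge type exists. The indirect branch sign is s_TF→miRNA × (−1);
the loop is *coherent* iff that equals s_direct, so exactly two of the
four sign configurations are coherent: a TF that represses its target
while activating the target's repressor acts synergistically (coherent),
while a TF that activates both its target and the target's repressor
opposes itself (incoherent). Both TF edges pass through the same q < 0.1
filter — there is no reason to hold the direct branch to a different
standard than the indirect one.

## Enrichment

Over-representation only (the motivating analysis reports enrichment, not
depletion): exact hypergeometric upper tail via log-gamma combinatorics,
universe = features present after the mRNA filter (the actual analysis
population), BH across sets within each query column.

## Benchmark scales and what the tests show

The recovery experiments run at the scales the package documents as its
study conditions: 2000 genes, 60 planted DEGs at |log2FC| 1.5 and noise
sd 0.7 under the 23v6 design (20 replicates) for differential recovery;
2000 null features at 12v12 (50 replicates) for false-positive control;
the default cohort (20 replicates) for integration retention; 25 random
50-node signed networks for FFL oracle equivalence; exhaustive universes
up to N = 12 for the hypergeometric oracle. These sizes give Monte-Carlo
standard errors comfortably below the margins being asserted while keeping
the full suite fast. Every expected value in the tests is either computed
by an independent oracle (brute force, enumeration, permutation, or closed
form) or derived by hand from the definitions.

Known limitations: no empirical-Bayes variance moderation (deliberately
out of scope; at n = 29 the pooled t is adequate and simpler to reason
about); no covariate adjustment (sex, smoking); pooled-correlation
integration inherits the group-effect confounding described above;
quantile normalization with strongly asymmetric differential expression
slightly redistributes signal into null features (visible as mildly
elevated miRNA false-discovery on 300-feature panels); and the synthetic
benchmark's independence assumptions are favorable to every method tested.
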