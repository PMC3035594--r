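# ildnet

Integrative mRNA/miRNA regulatory-network analysis for interstitial lung
disease (ILD) case/control expression studies.

Interstitial lung diseases — idiopathic pulmonary fibrosis (IPF),
non-specific interstitial pneumonia (NSIP) and related disorders — perturb
thousands of transcripts at once, and much of that perturbation is organized
by a small layer of regulators: transcription factors (TFs) and microRNAs.
`ildnet` implements, as tested and reusable R functions, the analysis chain
that takes paired mRNA and miRNA expression matrices from an ILD-style
cohort (cases stratified by forced vital capacity vs controls) to an
integrated, signed regulatory network:

1. **Preprocessing** — quantile normalization; present/absent calls from a
   two-component equal-variance Gaussian mixture fit by EM on per-feature
   mean log2 intensity (only *present* mRNA probes are analyzed; all miRNA
   probes are kept).
2. **Differential expression** — per-feature two-sample *t* statistics,
   positive-false-discovery-rate q-values with Storey's
   π₀(λ) = min(1, #{p > λ} / (m(1−λ))) estimate, and calls at
   |fold change| ≥ 1.5 with q < 0.1.
3. **Sample structure** — average-linkage hierarchical clustering on
   1 − Pearson correlation; top-scoring-pair (TSP) biomarkers scored by
   Δ = |P(Xᵢ < Xⱼ | case) − P(Xᵢ < Xⱼ | control)| with leave-one-out
   cross-validation.
4. **miRNA–target integration** — predicted target pairs restricted to
   differential features, then filtered to inversely correlated pairs
   (one-sided test on pooled Pearson r, FDR < 0.1).
5. **Network assembly** — correlation-signed TF→target edges
   (activation/repression), miRNA-repression edges, and unsigned PPI /
   pathway context edges over DEG/DETF/DEmiRNA nodes; greedy-modularity
   connectivity modules; degree-ranked hubs; marker-gene (e.g. MYOCD- or
   ZEB1-style) patient stratification.
6. **Feed-forward loops** — enumeration of (TF, miRNA, gene) triads where
   the TF regulates the gene directly and through the miRNA; a loop is
   *coherent* when s_direct = s_TF→miRNA × (−1), i.e. both branches push
   the target the same way.
7. **Enrichment** — exact hypergeometric over-representation of query
   lists against GMT gene-set collections within the present-feature
   universe.

Because the original cohort and the version-locked annotation snapshots
(target predictions, TF binding sites, PPI, pathways) are not
redistributable, the package ships a **synthetic-cohort generator**
(`simulate_cohort()`, `simulate_knowledge()`) that plants known
differential features, miRNA→target repression, signed TF regulons,
feed-forward loops and decoy annotations, so every stage can be
benchmarked against ground truth.

## Worked example

```r
library(ildnet)

cfg <- pipeline_config(sim = sim_config(seed = 42))
res <- run_pipeline(cfg)
print(res)
#> Integrative mRNA/miRNA pipeline result
#>   present genes: 1597 / 2000; DEGs: 98 (53 up, 45 down); DEmiRNAs: 40
#>   interactions: 42 candidates -> 38 retained (29 miRNAs, 38 genes)
#>   network: 138 nodes, 253 edges, 28 modules (Q = 0.448); FFLs: 5 (5 coherent)
#>   TSP: top delta = 1.000, LOOCV accuracy = 1.000
#>   recovery: DE gene sens 0.93 / FDR 0.07; true-pair retention 1.00; decoy 0.20
```

Reading the output: of 2000 simulated gene probes, 1597 pass the
present/absent mixture filter; 98 genes and 40 miRNAs are called
differential at the 1.5-fold, q < 0.1 thresholds. Intersecting predicted
miRNA targets with the differential lists gives 42 candidate pairs, 38 of
which survive the inverse-correlation filter. The assembled signed network
has 138 nodes and 253 typed edges; five planted feed-forward loops survive
the statistical filters and all five are recovered (all coherent, as
planted). The top-scoring gene pair separates cases from controls
perfectly (Δ = 1, LOOCV accuracy 1.0), and the recovery block compares
every call against the planted ground truth. Setting
`pipeline_config(out_dir = ...)` writes each stage artifact (TSV / GraphML
/ JSON) to disk; `summary(res)` returns the same counts as a list.

A thin command-line wrapper is included at
`inst/scripts/ildnet-cli.R` (`simulate` and `run-all` subcommands).

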