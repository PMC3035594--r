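#' Simulation configuration for a synthetic ILD-style cohort
#'
#' Bundles every tunable of the synthetic-cohort generator: cohort geometry
#' (cases in three FVC strata vs controls), feature universe sizes, planted
#' differential-expression structure, the miRNA-repression and TF-regulon
#' couplings, present/absent mixture geometry, and knowledge-table decoy
#' counts. The defaults emulate the study design the package targets: 23 ILD
#' cases against 6 controls, ~2000 gene probes, planted differential features
#' at |log2 fold change| 1.5 over per-sample Gaussian noise with sd 0.7.
#'
#' @param n_case,n_control Number of case and control samples.
#' @param n_genes,n_mirnas Number of gene (mRNA) and miRNA features.
#' @param n_tfs Number of genes flagged as transcription factors (the TF
#'   catalog); the first `n_tfs` gene ids.
#' @param n_de_genes,n_de_mirnas Number of planted differentially expressed
#'   genes / miRNAs (gene count includes the regulon TFs, which are planted
#'   DE so that signed TF edges are recoverable).
#' @param effect_log2fc Planted absolute log2 fold change (case minus
#'   control) of directly perturbed features.
#' @param noise_sd Per-feature, per-sample Gaussian noise sd on the log2
#'   scale.
#' @param baseline_mean,baseline_sd Mean and sd of per-feature baseline log2
#'   intensity for expressed ("present") features.
#' @param absent_mean Mean baseline of the low ("absent") mixture component.
#' @param frac_absent Fraction of gene features drawn from the absent
#'   component (miRNA features are always expressed; the presence filter is
#'   an mRNA-only policy).
#' @param n_target_pairs_true Number of planted miRNA->gene repression pairs.
#' @param n_target_pairs_decoy Number of decoy target-prediction pairs added
#'   by [simulate_knowledge()].
#' @param repression_strength Coupling in \[0, 1\]: a repressed gene's log2
#'   value is lowered by `repression_strength` times the (sample-centered)
#'   log2 level of its miRNA. At the default noise and effect sizes this
#'   yields planted pair correlations near -0.8.
#' @param n_regulons Number of TF regulons (each owned by one planted-DE TF).
#' @param regulon_size Number of targets (genes and miRNAs) per regulon.
#' @param tf_coupling Additive coupling of regulon targets to the centered TF
#'   profile; the edge sign times this coupling is applied, and edge signs
#'   are chosen to reinforce each target's planted direction.
#' @param n_ffls_planted Number of planted TF/miRNA/gene feed-forward loops
#'   (realized through the regulon and target tables, so they are consistent
#'   with the emitted knowledge base).
#' @param seed Integer seed; identical configurations reproduce
#'   byte-identical cohorts.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [simulate_knowledge()]
#' @export
sim_config <- function(n_case = 23, n_control = 6,
                       n_genes = 2000, n_mirnas = 300, n_tfs = 80,
                       n_de_genes = 60, n_de_mirnas = 30,
                       effect_log2fc = 1.5, noise_sd = 0.7,
                       baseline_mean = 8, baseline_sd = 1,
                       absent_mean = 2, frac_absent = 0.2,
                       n_target_pairs_true = 40, n_target_pairs_decoy = 500,
                       repression_strength = 1,
                       n_regulons = 6, regulon_size = 8, tf_coupling = 0.8,
                       n_ffls_planted = 6, seed = 1L) {
  cfg <- list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    n_tfs = as.integer(n_tfs),
    n_de_genes = as.integer(n_de_genes), n_de_mirnas = as.integer(n_de_mirnas),
    effect_log2fc = as.numeric(effect_log2fc), noise_sd = as.numeric(noise_sd),
    baseline_mean = as.numeric(baseline_mean), baseline_sd = as.numeric(baseline_sd),
    absent_mean = as.numeric(absent_mean), frac_absent = as.numeric(frac_absent),
    n_target_pairs_true = as.integer(n_target_pairs_true),
    n_target_pairs_decoy = as.integer(n_target_pairs_decoy),
    repression_strength = as.numeric(repression_strength),
    n_regulons = as.integer(n_regulons), regulon_size = as.integer(regulon_size),
    tf_coupling = as.numeric(tf_coupling),
    n_ffls_planted = as.integer(n_ffls_planted),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_case", "n_control", "n_genes", "n_mirnas", "n_tfs",
              "n_de_genes", "n_de_mirnas", "n_target_pairs_true",
              "n_target_pairs_decoy", "n_regulons", "regulon_size",
              "n_ffls_planted")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop(sprintf("'%s' must be a non-negative count", f))
  }
  if (cfg$n_case < 1L || cfg$n_control < 1L)
    stop("sample counts must be positive")
  if (cfg$n_tfs > cfg$n_genes) stop("'n_tfs' cannot exceed 'n_genes'")
  if (cfg$n_de_genes > cfg$n_genes) stop("'n_de_genes' cannot exceed 'n_genes'")
  if (cfg$n_de_mirnas > cfg$n_mirnas) stop("'n_de_mirnas' cannot exceed 'n_mirnas'")
  if (cfg$effect_log2fc < 0) stop("'effect_log2fc' must be >= 0")
  if (cfg$noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (cfg$frac_absent < 0 || cfg$frac_absent > 1)
    stop("'frac_absent' must lie in [0, 1]")
  if (cfg$repression_strength < 0 || cfg$repression_strength > 1)
    stop("'repression_strength' must lie in [0, 1]")
  if (cfg$n_regulons > cfg$n_tfs) stop("'n_regulons' cannot exceed 'n_tfs'")
  if (cfg$n_regulons > cfg$n_de_genes)
    stop("'n_regulons' cannot exceed 'n_de_genes' (regulon TFs are planted DE)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  samples: %d cases vs %d controls\n", x$n_case, x$n_control))
  cat(sprintf("  features: %d genes (%d TFs), %d miRNAs\n",
              x$n_genes, x$n_tfs, x$n_mirnas))
  cat(sprintf("  planted DE: %d genes, %d miRNAs at |log2FC| = %.2g, noise sd %.2g\n",
              x$n_de_genes, x$n_de_mirnas, x$effect_log2fc, x$noise_sd))
  cat(sprintf("  miRNA targets: %d true + %d decoy, repression %.2g\n",
              x$n_target_pairs_true, x$n_target_pairs_decoy,
              x$repression_strength))
  cat(sprintf("  regulons: %d x %d targets (coupling %.2g); %d planted FFLs\n",
              x$n_regulons, x$regulon_size, x$tf_coupling, x$n_ffls_planted))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
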