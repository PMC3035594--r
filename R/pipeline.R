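#' Configuration for the end-to-end analysis pipeline
#'
#' Either a synthetic run (`sim` is a [sim_config()]; the knowledge tables
#' are generated alongside the cohort) or a file-based run (`inputs` is a
#' named list of paths: `mrna`, `mirna`, `metadata`, `targets`,
#' `tf_binding`, `ppi`, `pathway_edges`, `gene_sets`, `tf_catalog`).
#'
#' @param sim A [sim_config()] for synthetic mode, or `NULL`.
#' @param inputs Named list of input file paths for file mode, or `NULL`.
#' @param fc_min Fold-change cutoff for differential calls.
#' @param q_max_de,q_max_int,q_max_tf q-value cutoffs for the differential,
#'   miRNA-integration and TF-edge stages.
#' @param lambda pi0 tuning parameter for the pFDR estimator.
#' @param var_equal Per-feature test variant (see [two_sample_stats()]).
#' @param cluster_k Flat groups to cut from the sample dendrogram.
#' @param tsp_max_features Cap on DE features fed to the TSP stage (kept by
#'   largest |t|).
#' @param include_mirna_gene Network scope flag (see [assemble_network()]).
#' @param marker_genes Marker gene ids for stratified module tests; default
#'   `NULL` picks the best-connected DETF.
#' @param out_dir Directory for stage artifacts, or `NULL` to skip writing.
#' @param seed Seed governing all stochastic stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL,
                            fc_min = 1.5, q_max_de = 0.1, q_max_int = 0.1,
                            q_max_tf = 0.1, lambda = 0.5, var_equal = TRUE,
                            cluster_k = 2L, tsp_max_features = 30L,
                            include_mirna_gene = TRUE, marker_genes = NULL,
                            out_dir = NULL, seed = NULL) {
  if (is.null(sim) && is.null(inputs))
    stop("either 'sim' or 'inputs' must be provided")
  stopifnot(fc_min >= 1, q_max_de > 0, q_max_de <= 1, q_max_int > 0,
            q_max_int <= 1, q_max_tf > 0, q_max_tf <= 1,
            lambda >= 0, lambda < 1, cluster_k >= 1)
  if (is.null(seed)) seed <- if (!is.null(sim)) sim$seed else 1L
  structure(list(sim = sim, inputs = inputs, fc_min = fc_min,
                 q_max_de = q_max_de, q_max_int = q_max_int,
                 q_max_tf = q_max_tf, lambda = lambda,
                 var_equal = var_equal, cluster_k = as.integer(cluster_k),
                 tsp_max_features = as.integer(tsp_max_features),
                 include_mirna_gene = include_mirna_gene,
                 marker_genes = marker_genes, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

check_inputs <- function(inputs) {
  required <- c("mrna", "mirna", "metadata", "targets", "tf_binding",
                "tf_catalog")
  for (f in required) {
    if (is.null(inputs[[f]]))
      stop(sprintf("pipeline input '%s' is missing from the configuration", f))
    if (!file.exists(inputs[[f]]))
      stop(sprintf("pipeline input '%s' does not exist: %s", f, inputs[[f]]))
  }
  for (f in c("ppi", "pathway_edges", "gene_sets")) {
    if (!is.null(inputs[[f]]) && !file.exists(inputs[[f]]))
      stop(sprintf("pipeline input '%s' does not exist: %s", f, inputs[[f]]))
  }
  invisible(inputs)
}

#' Run the full integrative analysis pipeline
#'
#' Executes, in order: quantile normalization; mixture-model presence calls
#' and the present-mRNA filter; differential expression of genes and miRNAs
#' (fold change + pFDR); hierarchical clustering of samples on the DEGs;
#' top-scoring-pair ranking with LOOCV; miRNA-target candidate intersection
#' and anticorrelation filtering; signed TF edge inference; network
#' assembly, module detection and hub ranking; FFL enumeration and
#' coherence classification; gene-set enrichment of the up- and
#' down-regulated DEGs; and a marker-gene stratified module test. When
#' ground truth is available (synthetic mode) a recovery block compares
#' every stage against the planted structure.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `ild_pipeline`: all stage results plus a
#'   `summary` list of counts and recovery metrics. If `config$out_dir` is
#'   set, stage TSVs, a GraphML network, and `summary.json` are written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL; kb <- NULL
  if (is.null(config$sim)) {
    check_inputs(config$inputs)
    mrna <- read_expression_tsv(config$inputs$mrna)
    mirna <- read_expression_tsv(config$inputs$mirna)
    metadata <- read_tsv(config$inputs$metadata)
    tf_catalog <- readLines(config$inputs$tf_catalog)
    kb <- list(
      target_predictions = read_tsv(config$inputs$targets),
      tf_binding = read_tsv(config$inputs$tf_binding),
      ppi_edges = if (!is.null(config$inputs$ppi))
        read_tsv(config$inputs$ppi) else NULL,
      pathway_edges = if (!is.null(config$inputs$pathway_edges))
        read_tsv(config$inputs$pathway_edges) else NULL,
      gene_sets = if (!is.null(config$inputs$gene_sets))
        read_gmt(config$inputs$gene_sets) else list())
  } else {
    cohort <- simulate_cohort(config$sim)
    kb <- simulate_knowledge(cohort$truth, config$sim)
    mrna <- cohort$mrna; mirna <- cohort$mirna
    metadata <- cohort$metadata
    truth <- cohort$truth
    tf_catalog <- truth$tf_ids
  }
  set.seed(config$seed)
  labels <- metadata$group[match(colnames(mrna), metadata$sample_id)]

  ## preprocess
  mrna_qn <- quantile_normalize(mrna)
  mirna_qn <- quantile_normalize(mirna)
  presence <- call_presence(mrna_qn)
  mrna_f <- apply_presence_filter(mrna_qn, presence, kind = "mRNA")

  ## differential expression
  de_g <- differential_expression(mrna_f, labels, var_equal = config$var_equal,
                                  fc_min = config$fc_min,
                                  q_max = config$q_max_de,
                                  lambda = config$lambda)
  de_m <- differential_expression(mirna_qn, labels,
                                  var_equal = config$var_equal,
                                  fc_min = config$fc_min,
                                  q_max = config$q_max_de,
                                  lambda = config$lambda)
  deg_ids <- c(de_g$up, de_g$down)
  demir_ids <- c(de_m$up, de_m$down)

  ## sample clustering on DEGs
  clust <- if (length(deg_ids) >= 2L)
    hierarchical_cluster(mrna_f, feature_subset = deg_ids,
                         k = config$cluster_k) else NULL

  ## TSP on the strongest DE genes
  tsp <- NULL
  if (length(deg_ids) >= 2L) {
    recs <- de_g$records[de_g$records$is_de, ]
    keep <- recs$feature[order(-abs(recs$t))][
      seq_len(min(config$tsp_max_features, nrow(recs)))]
    tsp_m <- mrna_f[keep, , drop = FALSE]
    tsp <- list(scores = tsp_scores(tsp_m, labels),
                cv = tsp_cv(tsp_m, labels))
  }

  ## miRNA-target integration
  candidates <- candidate_interactions(kb$target_predictions, demir_ids,
                                       deg_ids)
  interactions <- filter_anticorrelated(candidates, mrna_f, mirna_qn,
                                        q_max = config$q_max_int)
  retained <- interactions[interactions$retained, , drop = FALSE]

  ## network assembly
  de_gene_rec <- de_g$records[de_g$records$is_de, ]
  de_mir_rec <- de_m$records[de_m$records$is_de, ]
  nodes <- network_nodes(de_gene_rec, de_mir_rec, tf_catalog)
  binding <- kb$tf_binding[
    kb$tf_binding$tf %in% nodes$id[nodes$role == "DETF"] &
      kb$tf_binding$target %in% nodes$id, , drop = FALSE]
  tf_edges <- sign_tf_edges(binding, mrna_f, mirna_qn,
                            q_max = config$q_max_tf)
  net <- assemble_network(nodes, tf_edges, retained,
                          ppi = kb$ppi_edges, pathway = kb$pathway_edges,
                          include_mirna_gene = config$include_mirna_gene)
  modules <- detect_modules(net)
  ranking <- connectivity_ranking(net)
  ffls <- enumerate_ffls(net)

  ## enrichment of up/down DEGs within the present-gene universe
  universe <- rownames(mrna_f)
  enrich <- list(
    up = if (length(kb$gene_sets)) enrich_sets(de_g$up, kb$gene_sets, universe),
    down = if (length(kb$gene_sets)) enrich_sets(de_g$down, kb$gene_sets,
                                                 universe))

  ## marker-gene stratification on the marker's own module
  markers <- config$marker_genes
  if (is.null(markers)) {
    detf_rank <- ranking[ranking$role == "DETF", ]
    if (nrow(detf_rank)) markers <- detf_rank$id[1L]
  }
  marker_tests <- list()
  case_ids <- metadata$sample_id[metadata$group != "control"]
  for (mk in markers) {
    if (!(mk %in% rownames(mrna_f)) || !(mk %in% names(modules))) next
    mod_genes <- names(modules)[modules == modules[[mk]]]
    mod_genes <- setdiff(intersect(mod_genes, rownames(mrna_f)), mk)
    if (length(mod_genes) < 2L) next
    marker_tests[[mk]] <- marker_stratified_module_test(
      mrna_f, mk, mod_genes, case_ids, q_max = config$q_max_de)
  }

  recovery <- if (!is.null(truth))
    recovery_metrics(truth, de_g, de_m, interactions, net, ffls, clust,
                     metadata) else NULL

  summary <- list(
    n_genes_input = nrow(mrna), n_genes_present = nrow(mrna_f),
    n_mirnas = nrow(mirna),
    n_deg = length(deg_ids), n_deg_up = length(de_g$up),
    n_deg_down = length(de_g$down),
    n_demirna = length(demir_ids), n_demirna_up = length(de_m$up),
    n_demirna_down = length(de_m$down),
    n_candidate_pairs = nrow(candidates),
    n_retained_pairs = nrow(retained),
    n_retained_mirnas = length(unique(retained$mirna)),
    n_retained_genes = length(unique(retained$gene)),
    nodes_by_role = as.list(table(net$nodes$role)),
    edges_by_type = as.list(table(net$edges$type)),
    n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
    n_modules = max(modules),
    modularity = attr(modules, "modularity"),
    n_ffls = nrow(ffls),
    n_ffls_coherent = sum(ffls$coherence == "coherent"),
    n_ffls_incoherent = sum(ffls$coherence == "incoherent"),
    tsp_top_delta = if (!is.null(tsp)) tsp$scores$delta[1L] else NA_real_,
    tsp_loocv_accuracy = if (!is.null(tsp)) tsp$cv$accuracy else NA_real_,
    recovery = recovery)

  res <- structure(list(
    mrna = mrna_qn, mrna_present = mrna_f, mirna = mirna_qn,
    metadata = metadata, presence = presence, de_genes = de_g,
    de_mirnas = de_m, cluster = clust, tsp = tsp,
    interactions = interactions, network = net, modules = modules,
    ranking = ranking, ffls = ffls, enrichment = enrich,
    marker_tests = marker_tests, truth = truth, kb = kb,
    config = config, summary = summary), class = "ild_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

recovery_metrics <- function(truth, de_g, de_m, interactions, net, ffls,
                             clust, metadata) {
  called_g <- de_g$records$feature[de_g$records$is_de]
  called_m <- de_m$records$feature[de_m$records$is_de]
  planted_g <- intersect(unique(truth$de_genes$id), de_g$records$feature)
  planted_m <- unique(truth$de_mirnas$id)
  sens_g <- if (length(planted_g)) mean(planted_g %in% called_g) else NA_real_
  fdr_g <- if (length(called_g))
    mean(!(called_g %in% truth$de_genes$id)) else 0
  sens_m <- if (length(planted_m)) mean(planted_m %in% called_m) else NA_real_
  fdr_m <- if (length(called_m))
    mean(!(called_m %in% truth$de_mirnas$id)) else 0

  key_true <- paste(truth$true_targets$mirna, truth$true_targets$gene)
  key_cand <- paste(interactions$mirna, interactions$gene)
  is_true <- key_cand %in% key_true
  ret <- interactions$retained
  true_retention <- if (any(is_true)) mean(ret[is_true]) else NA_real_
  decoy_retention <- if (any(!is_true)) mean(ret[!is_true]) else NA_real_

  ## planted FFLs whose three edges survived -> must all be enumerated
  ffl_cond <- NA_real_
  pf <- truth$planted_ffls
  if (nrow(pf)) {
    has_edge <- function(s, t) any(net$edges$source == s &
                                     net$edges$target == t &
                                     net$edges$sign != 0L)
    surviving <- vapply(seq_len(nrow(pf)), function(i)
      has_edge(pf$tf[i], pf$mirna[i]) && has_edge(pf$tf[i], pf$gene[i]) &&
        has_edge(pf$mirna[i], pf$gene[i]), logical(1L))
    if (any(surviving)) {
      fkey <- paste(ffls$tf, ffls$mirna, ffls$gene)
      pkey <- paste(pf$tf, pf$mirna, pf$gene)[surviving]
      ffl_cond <- mean(pkey %in% fkey)
    }
    n_surviving <- sum(surviving)
  } else n_surviving <- 0L

  rand <- NA_real_
  if (!is.null(clust)) {
    lab <- metadata$group[match(names(clust$groups), metadata$sample_id)]
    rand <- rand_index(clust$groups, lab)
  }
  list(de_gene_sensitivity = sens_g, de_gene_fdr = fdr_g,
       de_mirna_sensitivity = sens_m, de_mirna_fdr = fdr_m,
       interaction_true_retention = true_retention,
       interaction_decoy_retention = decoy_retention,
       n_planted_ffls_surviving = n_surviving,
       ffl_conditional_recovery = ffl_cond,
       cluster_rand_index = rand)
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$presence, file.path(dir, "presence_calls.tsv"))
  write_tsv(res$de_genes$records, file.path(dir, "de_genes.tsv"))
  write_tsv(res$de_mirnas$records, file.path(dir, "de_mirnas.tsv"))
  if (!is.null(res$cluster))
    write_tsv(data.frame(sample = names(res$cluster$groups),
                         group = res$cluster$groups),
              file.path(dir, "cluster_groups.tsv"))
  if (!is.null(res$tsp)) {
    write_tsv(utils::head(res$tsp$scores, 100L),
              file.path(dir, "tsp_pairs.tsv"))
    jsonlite::write_json(list(accuracy = res$tsp$cv$accuracy,
                              folds = res$tsp$cv$folds),
                         file.path(dir, "tsp_cv.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  write_tsv(res$interactions, file.path(dir, "interactions.tsv"))
  export_network(res$network, file.path(dir, "network_edges.tsv"),
                 file.path(dir, "network.graphml"))
  write_tsv(data.frame(node = names(res$modules),
                       module = as.integer(res$modules)),
            file.path(dir, "modules.tsv"))
  write_tsv(res$ranking, file.path(dir, "connectivity_ranking.tsv"))
  write_tsv(as.data.frame(res$ffls), file.path(dir, "ffls.tsv"))
  if (!is.null(res$enrichment$up))
    write_tsv(res$enrichment$up, file.path(dir, "enrichment_up.tsv"))
  if (!is.null(res$enrichment$down))
    write_tsv(res$enrichment$down, file.path(dir, "enrichment_down.tsv"))
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.ild_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Integrative mRNA/miRNA pipeline result\n")
  cat(sprintf("  present genes: %d / %d; DEGs: %d (%d up, %d down); DEmiRNAs: %d\n",
              s$n_genes_present, s$n_genes_input, s$n_deg, s$n_deg_up,
              s$n_deg_down, s$n_demirna))
  cat(sprintf("  interactions: %d candidates -> %d retained (%d miRNAs, %d genes)\n",
              s$n_candidate_pairs, s$n_retained_pairs, s$n_retained_mirnas,
              s$n_retained_genes))
  cat(sprintf("  network: %d nodes, %d edges, %d modules (Q = %.3f); FFLs: %d (%d coherent)\n",
              s$n_nodes, s$n_edges, s$n_modules, s$modularity, s$n_ffls,
              s$n_ffls_coherent))
  if (!is.na(s$tsp_top_delta))
    cat(sprintf("  TSP: top delta = %.3f, LOOCV accuracy = %.3f\n",
                s$tsp_top_delta, s$tsp_loocv_accuracy))
  if (!is.null(s$recovery)) {
    r <- s$recovery
    cat(sprintf("  recovery: DE gene sens %.2f / FDR %.2f; true-pair retention %.2f; decoy %.2f\n",
                r$de_gene_sensitivity, r$de_gene_fdr,
                r$interaction_true_retention, r$interaction_decoy_retention))
  }
  invisible(x)
}

#' @export
summary.ild_pipeline <- function(object, ...) object$summary
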