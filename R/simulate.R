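#' Simulate a paired mRNA/miRNA case-control cohort with planted structure
#'
#' Generates log2 expression matrices for genes and miRNAs over a two-arm
#' cohort (ILD-style cases in three FVC strata vs controls), together with
#' the ground truth needed to benchmark every downstream stage. The
#' generative model is additive on the log2 scale:
#'
#' * each feature has a Gaussian baseline (`baseline_mean`, `baseline_sd`),
#'   or a low "absent" baseline (`absent_mean`) for a `frac_absent` subset of
#'   genes;
#' * planted differential features shift case samples by `+-effect_log2fc`;
#' * regulon targets are coupled additively to their TF's centered profile
#'   (`tf_coupling`), with edge signs chosen to reinforce each target's
#'   planted direction;
#' * planted miRNA targets are repressed additively: the gene's log2 value is
#'   lowered by `repression_strength` times the centered miRNA profile,
#'   which both induces differential expression in the target (opposite in
#'   direction to the miRNA) and makes the pair negatively correlated across
#'   pooled samples;
#' * independent Gaussian noise (`noise_sd`) is added per feature and
#'   sample.
#'
#' Planted feed-forward loops are realized through the regulon and target
#' tables, so every planted triad is recoverable from the emitted knowledge
#' base when its edges survive the statistical filters.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `ild_cohort`: a list with `mrna` and `mirna`
#'   (features x samples log2 matrices), `metadata` (one row per sample:
#'   `sample_id`, `group`, `fvc_class`, `diagnosis`, `sex`), `truth` (class
#'   `ground_truth`; see Details), and `config`.
#'
#' @details The `truth` element carries: `de_genes` (id, direction, mode =
#'   direct/induced), `de_mirnas`, `true_targets` (mirna, gene),
#'   `tf_regulons` (tf, target, sign), `planted_ffls` (tf, mirna, gene,
#'   s_direct, s_tm), `absent_genes`, `pathway_truth` (named list of member
#'   gene ids), `tf_ids`, and the full feature universes.
#' @seealso [simulate_knowledge()], [export_simulation()]
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  mirna_ids <- sprintf("mir%04d", seq_len(cfg$n_mirnas))
  tf_ids <- gene_ids[seq_len(cfg$n_tfs)]

  n <- cfg$n_case + cfg$n_control
  sample_ids <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
                  sprintf("ctrl_%02d", seq_len(cfg$n_control)))
  is_case <- c(rep(TRUE, cfg$n_case), rep(FALSE, cfg$n_control))
  metadata <- data.frame(
    sample_id = sample_ids,
    group = ifelse(is_case, "ILD", "control"),
    fvc_class = c(rep(c("<50%", "50-80%", ">80%"), length.out = cfg$n_case),
                  rep("-", cfg$n_control)),
    diagnosis = c(rep(c("UIP/IPF", "NSIP", "other ILD"), length.out = cfg$n_case),
                  rep("normal", cfg$n_control)),
    sex = rep(c("M", "F"), length.out = n),
    stringsAsFactors = FALSE)

  ## --- planted structure -------------------------------------------------
  regulon_tfs <- tf_ids[seq_len(cfg$n_regulons)]
  non_tf_genes <- setdiff(gene_ids, tf_ids)
  n_direct_other <- cfg$n_de_genes - cfg$n_regulons
  de_other <- sort(sample(non_tf_genes, n_direct_other))
  direct_de <- c(regulon_tfs, de_other)
  direct_dir <- rep(c(1L, -1L), length.out = length(direct_de))
  names(direct_dir) <- direct_de

  de_mirnas <- sort(sample(mirna_ids, cfg$n_de_mirnas))
  mirna_dir <- rep(c(1L, -1L), length.out = length(de_mirnas))
  names(mirna_dir) <- de_mirnas

  target_pool <- setdiff(non_tf_genes, direct_de)
  if (cfg$n_target_pairs_true > length(target_pool))
    stop("not enough free genes to plant the requested miRNA target pairs")
  if (cfg$n_target_pairs_true > 0L && cfg$n_de_mirnas == 0L)
    stop("cannot plant miRNA target pairs without planted DE miRNAs")
  target_genes <- if (cfg$n_target_pairs_true > 0L)
    sort(sample(target_pool, cfg$n_target_pairs_true)) else character()
  true_targets <- data.frame(
    mirna = rep(de_mirnas, length.out = cfg$n_target_pairs_true),
    gene = target_genes, stringsAsFactors = FALSE)

  reserved <- c(tf_ids, direct_de, target_genes)
  n_absent <- floor(cfg$frac_absent * cfg$n_genes)
  free_genes <- setdiff(gene_ids, reserved)
  if (n_absent > length(free_genes))
    stop("'frac_absent' too large: absent genes would overlap planted structure")
  absent_genes <- sort(sample(free_genes, n_absent))

  ## regulons: each regulon TF regulates a mix of DE miRNAs and DE genes,
  ## signs reinforcing each target's planted direction
  regulons <- list()
  if (cfg$n_regulons > 0L && cfg$regulon_size > 0L) {
    for (i in seq_len(cfg$n_regulons)) {
      tf <- regulon_tfs[i]
      n_m <- min(ceiling(cfg$regulon_size / 2), length(de_mirnas))
      n_g <- min(cfg$regulon_size - n_m, length(setdiff(de_other, tf)))
      tgt_m <- if (n_m > 0) sample(de_mirnas, n_m) else character()
      tgt_g <- if (n_g > 0) sample(setdiff(de_other, tf), n_g) else character()
      tgt <- c(tgt_m, tgt_g)
      tgt_dir <- c(mirna_dir[tgt_m], direct_dir[tgt_g])
      regulons[[i]] <- data.frame(
        tf = tf, target = tgt,
        sign = as.integer(tgt_dir) * direct_dir[[tf]],
        stringsAsFactors = FALSE)
    }
  }
  tf_regulons <- if (length(regulons)) do.call(rbind, regulons) else
    data.frame(tf = character(), target = character(), sign = integer())
  rownames(tf_regulons) <- NULL

  ## planted FFLs: walk the true-target list, attach each (miRNA, gene) pair
  ## to a regulon already containing that miRNA, and add the direct TF->gene
  ## edge; guarantees consistency with the emitted tables
  ffls <- list()
  if (cfg$n_ffls_planted > 0L && nrow(true_targets) > 0L && nrow(tf_regulons) > 0L) {
    for (j in seq_len(nrow(true_targets))) {
      if (length(ffls) >= cfg$n_ffls_planted) break
      m <- true_targets$mirna[j]; g <- true_targets$gene[j]
      owners <- unique(tf_regulons$tf[tf_regulons$target == m])
      if (!length(owners)) next
      tf <- owners[1L]
      dir_g <- -mirna_dir[[m]]   # repression-induced direction of the target
      s_direct <- as.integer(dir_g * direct_dir[[tf]])
      s_tm <- tf_regulons$sign[tf_regulons$tf == tf & tf_regulons$target == m][1L]
      if (!any(tf_regulons$tf == tf & tf_regulons$target == g)) {
        tf_regulons <- rbind(tf_regulons, data.frame(
          tf = tf, target = g, sign = s_direct, stringsAsFactors = FALSE))
      }
      ffls[[length(ffls) + 1L]] <- data.frame(
        tf = tf, mirna = m, gene = g,
        s_direct = s_direct, s_tm = as.integer(s_tm),
        stringsAsFactors = FALSE)
    }
    if (length(ffls) < cfg$n_ffls_planted)
      warning(sprintf("only %d of %d requested FFLs could be planted",
                      length(ffls), cfg$n_ffls_planted))
  }
  planted_ffls <- if (length(ffls)) do.call(rbind, ffls) else
    data.frame(tf = character(), mirna = character(), gene = character(),
               s_direct = integer(), s_tm = integer())
  rownames(planted_ffls) <- NULL

  ## --- expression matrices ----------------------------------------------
  base_g <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(base_g) <- gene_ids
  base_g[absent_genes] <- stats::rnorm(length(absent_genes), cfg$absent_mean,
                                       cfg$baseline_sd)
  base_m <- stats::rnorm(cfg$n_mirnas, cfg$baseline_mean, cfg$baseline_sd)
  names(base_m) <- mirna_ids

  mrna <- base_g + matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
                          cfg$n_genes, n,
                          dimnames = list(gene_ids, sample_ids))
  mirna <- base_m + matrix(stats::rnorm(cfg$n_mirnas * n, 0, cfg$noise_sd),
                           cfg$n_mirnas, n,
                           dimnames = list(mirna_ids, sample_ids))
  mrna[direct_de, is_case] <- mrna[direct_de, is_case] +
    direct_dir * cfg$effect_log2fc
  mirna[de_mirnas, is_case] <- mirna[de_mirnas, is_case] +
    mirna_dir * cfg$effect_log2fc

  ## TF -> target coupling (TF rows are never regulon targets, so they are
  ## final before coupling is applied)
  if (nrow(tf_regulons) > 0L && cfg$tf_coupling != 0) {
    for (r in seq_len(nrow(tf_regulons))) {
      tf <- tf_regulons$tf[r]; tgt <- tf_regulons$target[r]
      drive <- tf_regulons$sign[r] * cfg$tf_coupling *
        (mrna[tf, ] - mean(mrna[tf, ]))
      if (tgt %in% gene_ids) mrna[tgt, ] <- mrna[tgt, ] + drive
      else mirna[tgt, ] <- mirna[tgt, ] + drive
    }
  }

  ## miRNA repression of planted targets (after TF coupling, so the realized
  ## miRNA profile drives the target)
  if (nrow(true_targets) > 0L && cfg$repression_strength > 0) {
    for (r in seq_len(nrow(true_targets))) {
      m <- true_targets$mirna[r]; g <- true_targets$gene[r]
      mrna[g, ] <- mrna[g, ] - cfg$repression_strength *
        (mirna[m, ] - mean(mirna[m, ]))
    }
  }

  induced <- if (nrow(true_targets) > 0L && cfg$repression_strength > 0)
    data.frame(id = true_targets$gene,
               direction = -mirna_dir[true_targets$mirna],
               mode = "induced", stringsAsFactors = FALSE)
  else data.frame(id = character(), direction = integer(), mode = character())
  de_genes <- rbind(
    data.frame(id = direct_de, direction = as.integer(direct_dir),
               mode = rep("direct", length(direct_de)),
               stringsAsFactors = FALSE),
    induced)
  rownames(de_genes) <- NULL

  up_direct <- direct_de[direct_dir > 0]
  down_direct <- direct_de[direct_dir < 0]
  decoy_pool <- setdiff(gene_ids, c(direct_de, target_genes, absent_genes))
  pathway_truth <- list(
    pathway_up = sort(c(up_direct, sample(decoy_pool, min(10, length(decoy_pool))))),
    pathway_down = sort(c(down_direct, sample(decoy_pool, min(10, length(decoy_pool))))))

  truth <- structure(list(
    de_genes = de_genes,
    de_mirnas = data.frame(id = de_mirnas, direction = as.integer(mirna_dir),
                           stringsAsFactors = FALSE),
    true_targets = true_targets,
    tf_regulons = tf_regulons,
    planted_ffls = planted_ffls,
    absent_genes = absent_genes,
    pathway_truth = pathway_truth,
    tf_ids = tf_ids,
    gene_ids = gene_ids,
    mirna_ids = mirna_ids), class = "ground_truth")

  structure(list(mrna = mrna, mirna = mirna, metadata = metadata,
                 truth = truth, config = cfg),
            class = "ild_cohort")
}

#' @export
print.ild_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ILD cohort: %d genes x %d samples (mRNA), %d miRNAs\n",
              nrow(x$mrna), ncol(x$mrna), nrow(x$mirna)))
  cat(sprintf("  %d cases / %d controls; %d planted DE genes, %d DE miRNAs\n",
              sum(x$metadata$group == "ILD"), sum(x$metadata$group == "control"),
              nrow(x$truth$de_genes), nrow(x$truth$de_mirnas)))
  invisible(x)
}

#' Emit knowledge tables (target predictions, TF binding, PPI, pathways)
#'
#' Builds the annotation side of a synthetic benchmark: target-prediction and
#' TF-binding tables that contain every planted interaction plus uniformly
#' drawn decoys, context edge lists (undirected PPI, directed pathway), and
#' gene-set collections containing the planted pathway sets plus decoy sets.
#'
#' @param truth `ground_truth` object from [simulate_cohort()].
#' @param config The same [sim_config()] used to generate the cohort.
#' @param n_ppi,n_pathway_edges,n_decoy_sets,decoy_set_size Sizes of the
#'   context tables (defaults give a Fig-4-scale annotation layer).
#' @return An object of class `knowledge_base`: list with
#'   `target_predictions` (mirna, gene), `tf_binding` (tf, target; unsigned),
#'   `ppi_edges`, `pathway_edges`, and `gene_sets` (named list).
#' @export
simulate_knowledge <- function(truth, config,
                               n_ppi = 100L, n_pathway_edges = 100L,
                               n_decoy_sets = 8L, decoy_set_size = 30L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  gene_ids <- truth$gene_ids; mirna_ids <- truth$mirna_ids
  n_g <- length(gene_ids); n_m <- length(mirna_ids)

  true_key <- paste(truth$true_targets$mirna, truth$true_targets$gene)
  universe <- n_m * n_g - length(true_key)
  if (config$n_target_pairs_decoy > universe)
    stop("decoy target-pair count exceeds the available pair universe")
  decoys <- sample_pairs(mirna_ids, gene_ids, config$n_target_pairs_decoy,
                         exclude = true_key)
  target_predictions <- rbind(
    truth$true_targets,
    stats::setNames(decoys, c("mirna", "gene")))
  target_predictions <- unique(target_predictions)
  rownames(target_predictions) <- NULL

  reg_key <- paste(truth$tf_regulons$tf, truth$tf_regulons$target)
  all_feats <- c(gene_ids, mirna_ids)
  n_bind_decoy <- nrow(truth$tf_regulons)
  bind_decoys <- sample_pairs(truth$tf_ids, all_feats, n_bind_decoy,
                              exclude = reg_key, no_self = TRUE)
  tf_binding <- unique(rbind(
    data.frame(tf = truth$tf_regulons$tf, target = truth$tf_regulons$target,
               stringsAsFactors = FALSE),
    stats::setNames(bind_decoys, c("tf", "target"))))
  rownames(tf_binding) <- NULL

  ## context edges drawn among the planted DE genes so they survive the
  ## restriction to differential nodes in network assembly
  de_pool <- unique(truth$de_genes$id)
  ppi_edges <- sample_undirected_pairs(de_pool, n_ppi)
  pathway_edges <- sample_pairs(de_pool, de_pool, n_pathway_edges,
                                no_self = TRUE)
  names(pathway_edges) <- c("source", "target")

  decoy_sets <- lapply(seq_len(n_decoy_sets), function(i)
    sort(sample(gene_ids, min(decoy_set_size, n_g))))
  names(decoy_sets) <- sprintf("decoy_set%02d", seq_len(n_decoy_sets))
  gene_sets <- c(truth$pathway_truth, decoy_sets)

  structure(list(target_predictions = target_predictions,
                 tf_binding = tf_binding,
                 ppi_edges = ppi_edges,
                 pathway_edges = pathway_edges,
                 gene_sets = gene_sets),
            class = "knowledge_base")
}

## uniform pairs (a, b) from A x B without replacement, excluding an id-key
## set and (optionally) self pairs
sample_pairs <- function(a_ids, b_ids, n, exclude = character(),
                         no_self = FALSE) {
  out <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  n_a <- length(a_ids); n_b <- length(b_ids)
  seen <- exclude
  guard <- 0L
  while (nrow(out) < n && guard < 100L) {
    guard <- guard + 1L
    need <- n - nrow(out)
    idx <- sample.int(n_a * n_b, min(n_a * n_b, need * 2L + 10L))
    a <- a_ids[((idx - 1L) %% n_a) + 1L]
    b <- b_ids[((idx - 1L) %/% n_a) + 1L]
    keep <- !(paste(a, b) %in% seen)
    if (no_self) keep <- keep & a != b
    a <- a[keep]; b <- b[keep]
    dup <- duplicated(paste(a, b))
    a <- a[!dup]; b <- b[!dup]
    take <- seq_len(min(length(a), need))
    out <- rbind(out, data.frame(a = a[take], b = b[take],
                                 stringsAsFactors = FALSE))
    seen <- c(seen, paste(a[take], b[take]))
  }
  if (nrow(out) < n) stop("could not draw the requested number of decoy pairs")
  rownames(out) <- NULL
  out
}

sample_undirected_pairs <- function(ids, n) {
  if (length(ids) < 2L || n == 0L)
    return(data.frame(a = character(), b = character()))
  got <- character(0)
  res <- list()
  guard <- 0L
  while (length(got) < n && guard < 200L) {
    guard <- guard + 1L
    pick <- replicate(2L * (n - length(got)) + 2L,
                      sort(sample(ids, 2L)), simplify = FALSE)
    for (p in pick) {
      key <- paste(p, collapse = " ")
      if (!(key %in% got)) {
        got <- c(got, key)
        res[[length(res) + 1L]] <- p
        if (length(got) >= n) break
      }
    }
    if (length(got) >= choose(length(ids), 2)) break
  }
  df <- as.data.frame(do.call(rbind, res), stringsAsFactors = FALSE)
  names(df) <- c("a", "b")
  rownames(df) <- NULL
  df
}
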