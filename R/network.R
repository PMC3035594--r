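#' Sign predicted TF edges by expression correlation
#'
#' For each binding-predicted (TF, target) pair with both profiles measured,
#' computes the Pearson correlation across shared samples and a two-sided
#' p-value (t transform, n - 2 df), adjusts across all pairs
#' (Benjamini-Hochberg), and keeps pairs with `q < q_max`. Kept edges are
#' typed `tf_activate` (sign +1) when r > 0 and `tf_repress` (sign -1)
#' otherwise.
#'
#' @param tf_binding Data frame with columns `tf`, `target` (targets may be
#'   genes or miRNAs). Pairs whose endpoints are not measured are dropped.
#' @param mrna,mirna Expression matrices (TF profiles come from `mrna`;
#'   targets are looked up in `mrna` first, then `mirna`).
#' @param q_max FDR cutoff for edge retention.
#' @return Edge data frame: `source`, `target`, `type`, `sign`, `r`, `p`,
#'   `q`, `directed = TRUE`, `provenance = "tf_binding"`.
#' @export
sign_tf_edges <- function(tf_binding, mrna, mirna = NULL, q_max = 0.1) {
  stopifnot(all(c("tf", "target") %in% names(tf_binding)))
  shared <- colnames(mrna)
  if (!is.null(mirna)) shared <- intersect(shared, colnames(mirna))
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  tb <- tf_binding[tf_binding$tf != tf_binding$target, , drop = FALSE]
  measured_t <- tb$target %in% rownames(mrna) |
    (!is.null(mirna) & tb$target %in% rownames(mirna))
  tb <- tb[tb$tf %in% rownames(mrna) & measured_t, , drop = FALSE]
  n <- length(shared)
  if (!nrow(tb))
    return(data.frame(source = character(), target = character(),
                      type = character(), sign = integer(), r = numeric(),
                      p = numeric(), q = numeric(), directed = logical(),
                      provenance = character()))
  tfp <- mrna[tb$tf, shared, drop = FALSE]
  in_mrna <- tb$target %in% rownames(mrna)
  tgt <- matrix(NA_real_, nrow(tb), n)
  if (any(in_mrna)) tgt[in_mrna, ] <- mrna[tb$target[in_mrna], shared]
  if (any(!in_mrna)) tgt[!in_mrna, ] <- mirna[tb$target[!in_mrna], shared]
  sd_a <- apply(tfp, 1L, stats::sd); sd_b <- apply(tgt, 1L, stats::sd)
  ok <- sd_a > 0 & sd_b > 0
  if (any(!ok))
    warning(sprintf("%d binding pair(s) skipped: zero-variance profile",
                    sum(!ok)))
  tb <- tb[ok, , drop = FALSE]; tfp <- tfp[ok, , drop = FALSE]
  tgt <- tgt[ok, , drop = FALSE]
  ac <- tfp - rowMeans(tfp); bc <- tgt - rowMeans(tgt)
  r <- rowSums(ac * bc) / sqrt(rowSums(ac^2) * rowSums(bc^2))
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  q <- stats::p.adjust(p, "BH")
  keep <- q < q_max
  data.frame(source = tb$tf[keep], target = tb$target[keep],
             type = ifelse(r[keep] > 0, "tf_activate", "tf_repress"),
             sign = ifelse(r[keep] > 0, 1L, -1L),
             r = r[keep], p = p[keep], q = q[keep],
             directed = TRUE, provenance = "tf_binding",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the node table of a regulatory network
#'
#' Differential genes become `DEG` nodes, or `DETF` when they appear in the
#' TF catalog; differential miRNAs become `DEmiRNA` nodes.
#'
#' @param de_gene_records,de_mirna_records Data frames with `feature` and
#'   `log2fc` columns restricted to differential features (e.g. the `is_de`
#'   rows of [differential_expression()] records).
#' @param tf_catalog Character vector of TF gene ids.
#' @return Data frame: `id`, `role`, `log2fc`.
#' @export
network_nodes <- function(de_gene_records, de_mirna_records,
                          tf_catalog = character()) {
  g <- data.frame(id = de_gene_records$feature,
                  role = ifelse(de_gene_records$feature %in% tf_catalog,
                                "DETF", "DEG"),
                  log2fc = de_gene_records$log2fc, stringsAsFactors = FALSE)
  m <- data.frame(id = de_mirna_records$feature, role = "DEmiRNA",
                  log2fc = de_mirna_records$log2fc, stringsAsFactors = FALSE)
  out <- rbind(g, m)
  if (anyDuplicated(out$id)) stop("duplicate node ids")
  rownames(out) <- NULL
  out
}

#' Assemble the signed TF/miRNA/gene regulatory network
#'
#' Combines signed transcriptional edges, retained miRNA-repression pairs,
#' and unsigned PPI/pathway context edges into one typed network over the
#' differential (DEG/DETF/DEmiRNA) node universe. Edges with an endpoint
#' outside the node table are dropped (the restriction to differential
#' entities); self-loops are removed; duplicate (source, target, type)
#' triples are collapsed with their provenances concatenated.
#'
#' @param nodes Node table from [network_nodes()].
#' @param tf_edges Signed edges from [sign_tf_edges()] (or `NULL`).
#' @param mirna_pairs Retained rows of [filter_anticorrelated()] (or
#'   `NULL`); they become `mirna_repress` edges with sign -1.
#' @param ppi Data frame of undirected gene pairs (first two columns), or
#'   `NULL`.
#' @param pathway Data frame of directed gene pairs (first two columns), or
#'   `NULL`.
#' @param include_mirna_gene Scope flag: when `FALSE`, miRNA->gene edges are
#'   restricted to DETF targets (the miRNA/TF-centered network variant);
#'   when `TRUE` all retained miRNA targets are kept.
#' @return Object of class `ild_network`: list with `nodes` and `edges`
#'   (`source`, `target`, `type`, `sign`, `directed`, `provenance`).
#' @export
assemble_network <- function(nodes, tf_edges = NULL, mirna_pairs = NULL,
                             ppi = NULL, pathway = NULL,
                             include_mirna_gene = TRUE) {
  stopifnot(all(c("id", "role") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  edges <- list()
  if (!is.null(tf_edges) && nrow(tf_edges))
    edges$tf <- data.frame(source = tf_edges$source, target = tf_edges$target,
                           type = tf_edges$type, sign = tf_edges$sign,
                           directed = TRUE, provenance = "tf_binding",
                           stringsAsFactors = FALSE)
  if (!is.null(mirna_pairs) && nrow(mirna_pairs))
    edges$mir <- data.frame(source = mirna_pairs$mirna,
                            target = mirna_pairs$gene,
                            type = "mirna_repress", sign = -1L,
                            directed = TRUE, provenance = "target_prediction",
                            stringsAsFactors = FALSE)
  if (!is.null(ppi) && nrow(ppi)) {
    a <- pmin(ppi[[1L]], ppi[[2L]]); b <- pmax(ppi[[1L]], ppi[[2L]])
    edges$ppi <- data.frame(source = a, target = b, type = "ppi", sign = 0L,
                            directed = FALSE, provenance = "ppi",
                            stringsAsFactors = FALSE)
  }
  if (!is.null(pathway) && nrow(pathway))
    edges$path <- data.frame(source = pathway[[1L]], target = pathway[[2L]],
                             type = "pathway", sign = 0L, directed = TRUE,
                             provenance = "pathway", stringsAsFactors = FALSE)
  e <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(), type = character(),
               sign = integer(), directed = logical(),
               provenance = character())
  e <- e[e$source %in% nodes$id & e$target %in% nodes$id, , drop = FALSE]
  e <- e[e$source != e$target, , drop = FALSE]
  if (!include_mirna_gene && nrow(e)) {
    role <- stats::setNames(nodes$role, nodes$id)
    drop <- e$type == "mirna_repress" & role[e$target] != "DETF"
    e <- e[!drop, , drop = FALSE]
  }
  if (nrow(e)) {
    key <- paste(e$source, e$target, e$type)
    prov <- tapply(e$provenance, key, function(x)
      paste(sort(unique(x)), collapse = ","))
    e <- e[!duplicated(key), , drop = FALSE]
    e$provenance <- as.character(prov[paste(e$source, e$target, e$type)])
    e <- e[order(e$source, e$target, e$type), , drop = FALSE]
  }
  rownames(e) <- NULL
  structure(list(nodes = nodes, edges = e), class = "ild_network")
}

#' @export
print.ild_network <- function(x, ...) {
  cat(sprintf("Regulatory network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat("  nodes by role: ",
      paste(sprintf("%s=%d", names(table(x$nodes$role)),
                    table(x$nodes$role)), collapse = ", "), "\n", sep = "")
  if (nrow(x$edges))
    cat("  edges by type: ",
        paste(sprintf("%s=%d", names(table(x$edges$type)),
                      table(x$edges$type)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Connectivity-based module detection
#'
#' Greedy agglomerative modularity maximization (Clauset-Newman-Moore style)
#' on the undirected, unsigned projection of the network. The procedure is
#' fully deterministic: communities are labeled by their smallest member id,
#' candidate merges are scanned in lexicographic label order, and ties in
#' modularity gain resolve to the lexicographically first pair. Merging
#' stops when no merge strictly increases modularity; isolated nodes remain
#' singleton modules. Module numbers are canonicalized to 1..K by the
#' smallest member id of each module.
#'
#' @param net An `ild_network`.
#' @return Named integer vector (module id per node) with attribute
#'   `modularity` (the Q of the returned partition).
#' @export
detect_modules <- function(net) {
  ids <- sort(net$nodes$id)
  n <- length(ids)
  if (n == 0L) stop("network has no nodes")
  ## unsigned undirected projection, deduplicated
  prj <- unique(data.frame(
    a = pmin(net$edges$source, net$edges$target),
    b = pmax(net$edges$source, net$edges$target),
    stringsAsFactors = FALSE))
  prj <- prj[prj$a != prj$b, , drop = FALSE]
  part <- stats::setNames(rep(NA_integer_, n), ids)
  if (!nrow(prj)) {
    part[] <- seq_len(n)
    attr(part, "modularity") <- 0
    return(part)
  }
  m <- nrow(prj)
  idx <- stats::setNames(seq_len(n), ids)
  ## E[i, j]: fraction of edges between current communities i and j
  E <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(m)) {
    i <- idx[[prj$a[r]]]; j <- idx[[prj$b[r]]]
    E[i, j] <- E[i, j] + 1 / (2 * m)
    E[j, i] <- E[j, i] + 1 / (2 * m)
  }
  a <- rowSums(E)                 # a_i = deg_i / 2m
  label <- ids                    # community label = smallest member id
  alive <- rep(TRUE, n)
  members <- as.list(ids)
  repeat {
    best_dq <- 0; best <- NULL
    live <- which(alive)
    ord <- live[order(label[live])]          # lexicographic label scan
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      if (ii == length(ord)) break
      for (jj in (ii + 1L):length(ord)) {
        j <- ord[jj]
        if (E[i, j] <= 0) next               # only connected communities
        dq <- 2 * (E[i, j] - a[i] * a[j])
        if (dq > best_dq + 1e-12) { best_dq <- dq; best <- c(i, j) }
      }
    }
    if (is.null(best)) break
    i <- best[1L]; j <- best[2L]
    E[i, ] <- E[i, ] + E[j, ]; E[, i] <- E[, i] + E[, j]
    a[i] <- a[i] + a[j]
    members[[i]] <- c(members[[i]], members[[j]])
    label[i] <- min(label[i], label[j])
    alive[j] <- FALSE
    E[j, ] <- 0; E[, j] <- 0; a[j] <- 0
  }
  comms <- members[alive]
  firsts <- vapply(comms, min, character(1L))
  comms <- comms[order(firsts)]
  for (k in seq_along(comms)) part[comms[[k]]] <- k
  attr(part, "modularity") <- network_modularity(net, part)
  part
}

#' Modularity of a node partition
#'
#' Newman modularity `Q = sum_c (e_cc - a_c^2)` on the undirected, unsigned,
#' deduplicated projection of the network.
#'
#' @param net An `ild_network`.
#' @param part Named module vector over the network's nodes.
#' @return The modularity Q (0 for an edgeless network).
#' @export
network_modularity <- function(net, part) {
  prj <- unique(data.frame(
    a = pmin(net$edges$source, net$edges$target),
    b = pmax(net$edges$source, net$edges$target),
    stringsAsFactors = FALSE))
  prj <- prj[prj$a != prj$b, , drop = FALSE]
  m <- nrow(prj)
  if (!m) return(0)
  same <- part[prj$a] == part[prj$b]
  deg <- table(c(prj$a, prj$b))
  a_c <- tapply(as.numeric(deg), part[names(deg)], sum) / (2 * m)
  e_cc <- rep(0, length(a_c)); names(e_cc) <- names(a_c)
  if (any(same)) {
    tab <- table(part[prj$a][same])
    e_cc[names(tab)] <- as.numeric(tab) / m
  }
  sum(e_cc - a_c^2)
}

#' Rank nodes by connectivity
#'
#' Total unweighted degree (in + out over all edge types, each typed edge
#' counted once), sorted degree-descending with lexicographic ids breaking
#' ties.
#'
#' @param net An `ild_network`.
#' @return Data frame: `id`, `role`, `degree`.
#' @export
connectivity_ranking <- function(net) {
  deg <- stats::setNames(rep(0L, nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$source, net$edges$target))
    deg[names(tab)] <- as.integer(tab)
  }
  out <- data.frame(id = net$nodes$id, role = net$nodes$role,
                    degree = as.integer(deg[net$nodes$id]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$id), ]
  rownames(out) <- NULL
  out
}

#' Marker-gene stratification test of a module
#'
#' Splits the case samples at the median expression of a marker gene (the
#' median sample goes to the "low" stratum), then tests each module gene
#' between the high and low strata with a Welch t-test and adjusts within
#' the module (Benjamini-Hochberg).
#'
#' @param m Log2 expression matrix.
#' @param marker Marker gene id (must be measured in >= 4 case samples).
#' @param module_genes Gene ids of the module under test.
#' @param case_samples Sample ids of the case arm.
#' @param q_max Per-gene significance cutoff for the module summary.
#' @return List: `records` (per-gene stats with `q`) and `summary`
#'   (`n_genes`, `n_flagged`, `mean_abs_log2fc`, stratum sizes).
#' @export
marker_stratified_module_test <- function(m, marker, module_genes,
                                          case_samples, q_max = 0.1) {
  case_samples <- intersect(case_samples, colnames(m))
  if (!(marker %in% rownames(m))) stop("marker gene not in matrix: ", marker)
  missing <- setdiff(module_genes, rownames(m))
  if (length(missing))
    stop("module gene(s) absent from matrix: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  if (length(case_samples) < 4L)
    stop("marker stratification needs >= 4 case samples")
  mv <- m[marker, case_samples]
  strata <- ifelse(mv > stats::median(mv), "high", "low")
  if (min(table(strata)) < 2L) stop("a marker stratum has < 2 samples")
  rec <- two_sample_stats(m[module_genes, case_samples, drop = FALSE],
                          strata, case = "high", control = "low",
                          var_equal = FALSE)
  rec$q <- stats::p.adjust(rec$p, "BH")
  list(records = rec,
       summary = list(marker = marker,
                      n_genes = nrow(rec),
                      n_flagged = sum(rec$q < q_max),
                      mean_abs_log2fc = mean(abs(rec$log2fc)),
                      n_high = sum(strata == "high"),
                      n_low = sum(strata == "low")))
}
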