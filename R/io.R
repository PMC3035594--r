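#' Read / write tab-delimited expression matrices
#'
#' Expression TSVs have one row per feature; the first column (`feature`)
#' holds the feature id and the remaining columns are samples.
#'
#' @param path File path.
#' @return `read_expression_tsv`: numeric matrix with feature rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' @rdname read_expression_tsv
#' @param m Numeric matrix, features x samples.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Export a regulatory network
#'
#' Writes the edge list as TSV (`source`, `target`, `type`, `sign`,
#' `directed`, `provenance`) and, optionally, a GraphML rendering with node
#' `role`/`log2fc` and edge `type`/`sign` attributes.
#'
#' @param net An `ild_network`.
#' @param edges_path Path for the edge-list TSV.
#' @param graphml_path Optional path for GraphML output.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, edges_path, graphml_path = NULL) {
  write_tsv(net$edges, edges_path)
  if (!is.null(graphml_path)) write_graphml(net, graphml_path)
  invisible(c(edges_path, graphml_path))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a network as GraphML
#'
#' @param net An `ild_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="role" for="node" attr.name="role" attr.type="string"/>')
  w('  <key id="log2fc" for="node" attr.name="log2fc" attr.type="double"/>')
  w('  <key id="type" for="edge" attr.name="type" attr.type="string"/>')
  w('  <key id="sign" for="edge" attr.name="sign" attr.type="int"/>')
  w('  <graph id="G" edgedefault="directed">')
  for (i in seq_len(nrow(net$nodes))) {
    w('    <node id="%s"><data key="role">%s</data><data key="log2fc">%g</data></node>',
      xml_escape(net$nodes$id[i]), xml_escape(net$nodes$role[i]),
      if (is.null(net$nodes$log2fc)) 0 else net$nodes$log2fc[i])
  }
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    w('    <edge source="%s" target="%s"><data key="type">%s</data><data key="sign">%d</data></edge>',
      xml_escape(e$source[i]), xml_escape(e$target[i]),
      xml_escape(e$type[i]), as.integer(e$sign[i]))
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}

#' Export a simulated cohort and knowledge base to plain-text files
#'
#' Writes the expression matrices, sample metadata, knowledge tables, gene
#' sets (GMT), TF catalog, and ground truth (JSON) under `dir`.
#'
#' @param cohort An `ild_cohort` from [simulate_cohort()].
#' @param kb A `knowledge_base` from [simulate_knowledge()], or `NULL`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
export_simulation <- function(cohort, kb = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(cohort$mrna, file.path(dir, "mrna.tsv"))
  write_expression_tsv(cohort$mirna, file.path(dir, "mirna.tsv"))
  write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  writeLines(cohort$truth$tf_ids, file.path(dir, "tf_catalog.txt"))
  truth <- cohort$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  if (!is.null(kb)) {
    write_tsv(kb$target_predictions, file.path(dir, "targets.tsv"))
    write_tsv(kb$tf_binding, file.path(dir, "tf_binding.tsv"))
    write_tsv(kb$ppi_edges, file.path(dir, "ppi.tsv"))
    write_tsv(kb$pathway_edges, file.path(dir, "pathway_edges.tsv"))
    write_gmt(kb$gene_sets, file.path(dir, "gene_sets.gmt"))
  }
  invisible(dir)
}
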