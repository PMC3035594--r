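#' Classify feed-forward-loop coherence
#'
#' A TF regulates a target directly (sign `s_direct`) and indirectly through
#' a miRNA: the TF->miRNA branch carries `s_tm` and the miRNA->target branch
#' is always repressive (-1), so the indirect branch sign is `s_tm * (-1)`.
#' The loop is coherent when both branches push the target the same way
#' (`s_direct == -s_tm`), incoherent otherwise. Exactly two of the four sign
#' configurations are coherent.
#'
#' @param s_direct,s_tm Edge signs, each +1 or -1 (vectorized).
#' @return Character vector: `"coherent"` or `"incoherent"`.
#' @export
classify_coherence <- function(s_direct, s_tm) {
  if (!all(s_direct %in% c(-1L, 1L)) || !all(s_tm %in% c(-1L, 1L)))
    stop("signs must be +1 or -1 (unsigned edges cannot form FFL branches)")
  ifelse(s_direct == s_tm * -1L, "coherent", "incoherent")
}

#' Enumerate TF-miRNA-gene feed-forward loops
#'
#' Finds every triad (TF, miRNA, gene) such that the network contains a
#' signed transcriptional edge TF->miRNA, a signed transcriptional edge
#' TF->gene, and a miRNA-repression edge miRNA->gene, with gene distinct
#' from both the TF and the miRNA. PPI and pathway context edges are
#' unsigned and never participate. Each triad is reported once with its
#' branch signs and coherence class.
#'
#' @param net An `ild_network` with signed `tf_activate`/`tf_repress` edges
#'   and `mirna_repress` edges.
#' @return Data frame of class `ffl_table`: `tf`, `mirna`, `gene`,
#'   `s_direct`, `s_tm`, `s_mt` (always -1), `coherence`; attribute
#'   `summary` holds distinct TF/miRNA/gene counts and per-class totals.
#' @export
enumerate_ffls <- function(net) {
  e <- net$edges
  role <- stats::setNames(net$nodes$role, net$nodes$id)
  tfe <- e[e$type %in% c("tf_activate", "tf_repress"), , drop = FALSE]
  tf_mir <- tfe[role[tfe$target] == "DEmiRNA", , drop = FALSE]
  tf_gene <- tfe[role[tfe$target] != "DEmiRNA", , drop = FALSE]
  mir_gene <- e[e$type == "mirna_repress", , drop = FALSE]
  empty <- data.frame(tf = character(), mirna = character(),
                      gene = character(), s_direct = integer(),
                      s_tm = integer(), s_mt = integer(),
                      coherence = character())
  if (!nrow(tf_mir) || !nrow(tf_gene) || !nrow(mir_gene)) {
    out <- empty
  } else {
    ## join: (tf, m) x (m, g) on the miRNA, then require (tf, g)
    j1 <- merge(
      data.frame(tf = tf_mir$source, mirna = tf_mir$target,
                 s_tm = tf_mir$sign, stringsAsFactors = FALSE),
      data.frame(mirna = mir_gene$source, gene = mir_gene$target,
                 stringsAsFactors = FALSE),
      by = "mirna")
    direct <- data.frame(tf = tf_gene$source, gene = tf_gene$target,
                         s_direct = tf_gene$sign, stringsAsFactors = FALSE)
    out <- merge(j1, direct, by = c("tf", "gene"))
    out <- out[out$gene != out$tf & out$gene != out$mirna, , drop = FALSE]
    if (nrow(out)) {
      out <- data.frame(tf = out$tf, mirna = out$mirna, gene = out$gene,
                        s_direct = as.integer(out$s_direct),
                        s_tm = as.integer(out$s_tm), s_mt = -1L,
                        stringsAsFactors = FALSE)
      out <- unique(out)
      out$coherence <- classify_coherence(out$s_direct, out$s_tm)
      out <- out[order(out$tf, out$mirna, out$gene), , drop = FALSE]
    } else out <- empty
  }
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_ffls = nrow(out),
    n_tfs = length(unique(out$tf)),
    n_mirnas = length(unique(out$mirna)),
    n_genes = length(unique(out$gene)),
    n_coherent = sum(out$coherence == "coherent"),
    n_incoherent = sum(out$coherence == "incoherent"))
  class(out) <- c("ffl_table", "data.frame")
  out
}
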