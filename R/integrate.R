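#' Candidate DEmiRNA-DEG interaction pairs
#'
#' Intersects a miRNA->gene target-prediction table with the differential
#' lists: a predicted pair is a candidate when its miRNA is differentially
#' expressed and its target gene is a differentially expressed gene.
#'
#' @param target_predictions Data frame with columns `mirna`, `gene`.
#' @param de_mirnas,de_genes Character vectors of differential feature ids.
#' @return Deduplicated data frame (`mirna`, `gene`) of candidate pairs.
#' @export
candidate_interactions <- function(target_predictions, de_mirnas, de_genes) {
  stopifnot(all(c("mirna", "gene") %in% names(target_predictions)))
  keep <- target_predictions$mirna %in% de_mirnas &
    target_predictions$gene %in% de_genes
  out <- unique(target_predictions[keep, c("mirna", "gene")])
  rownames(out) <- NULL
  out
}

#' Retain inversely correlated miRNA-target pairs at an FDR
#'
#' For each candidate pair, computes the Pearson correlation of the miRNA
#' and gene profiles across the shared samples (cases and controls pooled),
#' a one-sided p-value for negative correlation via the t transform with
#' n - 2 degrees of freedom, and a multiplicity adjustment across all
#' candidates. A pair is retained when `r < 0` and `q < q_max`. Pairs with a
#' zero-variance profile are skipped with a warning (returned with `NA`
#' statistics, never retained).
#'
#' @param pairs Candidate pairs from [candidate_interactions()].
#' @param mrna,mirna Log2 expression matrices holding the gene and miRNA
#'   profiles (features x samples; >= 3 shared samples required).
#' @param q_max FDR cutoff.
#' @param method `"BH"` (default) or `"pfdr"` (Storey pi0 via
#'   [qvalues_pfdr()]).
#' @return The pairs with `r`, `p`, `q`, `retained` columns, plus attribute
#'   `summary`: pair/distinct-miRNA/distinct-gene counts for candidates and
#'   retained pairs.
#' @export
filter_anticorrelated <- function(pairs, mrna, mirna, q_max = 0.1,
                                  method = c("BH", "pfdr")) {
  method <- match.arg(method)
  shared <- intersect(colnames(mrna), colnames(mirna))
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  missing_g <- setdiff(pairs$gene, rownames(mrna))
  missing_m <- setdiff(pairs$mirna, rownames(mirna))
  if (length(missing_g) || length(missing_m))
    stop("pair ids absent from the expression matrices: ",
         paste(utils::head(c(missing_g, missing_m), 3L), collapse = ", "))
  n <- length(shared)
  pairs$r <- NA_real_; pairs$p <- NA_real_
  if (nrow(pairs)) {
    g <- mrna[pairs$gene, shared, drop = FALSE]
    mm <- mirna[pairs$mirna, shared, drop = FALSE]
    sd_g <- apply(g, 1L, stats::sd); sd_m <- apply(mm, 1L, stats::sd)
    ok <- sd_g > 0 & sd_m > 0
    if (any(!ok))
      warning(sprintf("%d pair(s) skipped: zero-variance profile", sum(!ok)))
    if (any(ok)) {
      gc <- g[ok, , drop = FALSE] - rowMeans(g[ok, , drop = FALSE])
      mc <- mm[ok, , drop = FALSE] - rowMeans(mm[ok, , drop = FALSE])
      r <- rowSums(gc * mc) / sqrt(rowSums(gc^2) * rowSums(mc^2))
      r <- pmin(1, pmax(-1, r))
      tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
      pairs$r[ok] <- r
      pairs$p[ok] <- stats::pt(tt, df = n - 2)   # one-sided, r < 0
    }
  }
  ok <- !is.na(pairs$p)
  pairs$q <- NA_real_
  if (any(ok)) {
    pairs$q[ok] <- if (method == "BH") stats::p.adjust(pairs$p[ok], "BH")
    else as.numeric(qvalues_pfdr(pairs$p[ok]))
  }
  pairs$retained <- !is.na(pairs$r) & pairs$r < 0 & pairs$q < q_max
  ret <- pairs[pairs$retained, , drop = FALSE]
  attr(pairs, "summary") <- list(
    n_candidates = nrow(pairs),
    n_retained = nrow(ret),
    n_mirnas_retained = length(unique(ret$mirna)),
    n_genes_retained = length(unique(ret$gene)))
  pairs
}
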