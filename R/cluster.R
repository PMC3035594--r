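#' Hierarchical clustering of samples on a feature subset
#'
#' Clusters the sample columns with average linkage on the correlation
#' distance (1 - Pearson correlation between sample expression profiles),
#' the conventional pairing for expression heatmaps, and cuts the tree into
#' `k` flat groups. Samples are processed in lexicographic id order so tied
#' merges resolve deterministically.
#'
#' @param m Numeric matrix, features x samples.
#' @param feature_subset Optional feature ids to cluster on (e.g. the DE
#'   genes); default all rows.
#' @param k Number of flat groups to cut (>= 1).
#' @return List of class `ild_dendro`: `tree` (an [stats::hclust] object),
#'   `groups` (named integer vector, cluster per sample), `k`,
#'   `distance = "1 - Pearson"`, `linkage = "average"`.
#' @export
hierarchical_cluster <- function(m, feature_subset = NULL, k = 2L) {
  if (k < 1L) stop("'k' must be >= 1")
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, rownames(m))
    if (length(missing))
      stop("feature_subset contains unknown features: ",
           paste(utils::head(missing, 3L), collapse = ", "))
    m <- m[feature_subset, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need >= 2 features to define sample profiles")
  m <- m[, order(colnames(m)), drop = FALSE]
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant sample profile (undefined correlation): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(m))
  tree <- stats::hclust(d, method = "average")
  groups <- stats::cutree(tree, k = min(k, ncol(m)))
  structure(list(tree = tree, groups = groups, k = k,
                 distance = "1 - Pearson", linkage = "average"),
            class = "ild_dendro")
}

#' @export
print.ild_dendro <- function(x, ...) {
  cat(sprintf("Sample dendrogram (%s distance, %s linkage): %d samples, k = %d\n",
              x$distance, x$linkage, length(x$groups), x$k))
  print(table(x$groups))
  invisible(x)
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on which two partitions agree (both together or
#' both apart).
#'
#' @param a,b Cluster label vectors of equal length.
#' @return The Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
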