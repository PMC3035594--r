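#' Hypergeometric upper-tail p-value for set overlap
#'
#' Probability of observing at least `k` members of a size-`K` set in a
#' size-`n` draw from a universe of `N` items:
#' `p = sum_{i = k..min(n, K)} C(K, i) C(N - K, n - i) / C(N, n)`,
#' computed exactly through log-gamma combinatorics
#' ([stats::phyper]), stable for universes up to at least 1e5.
#'
#' @param k Overlap count (0 <= k <= min(n, K)).
#' @param K Set size in the universe.
#' @param n Query size in the universe.
#' @param N Universe size.
#' @return The upper-tail probability (1 when `k = 0`).
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  args <- c(k = k, K = K, n = n, N = N)
  if (any(args != round(args)) || any(args < 0))
    stop("arguments must be non-negative integers")
  if (K > N || n > N) stop("set and query sizes cannot exceed the universe")
  if (k > min(n, K)) stop("overlap k cannot exceed min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a query list against gene sets
#'
#' One-sided hypergeometric enrichment of a query id list against each set
#' in a collection, within a stated universe. Query ids outside the
#' universe are discarded (the count is reported as an attribute); sets
#' with no universe member are skipped. P-values are adjusted across sets
#' (Benjamini-Hochberg) and results are sorted by p.
#'
#' @param query Character vector of query ids.
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector: the analysis population (e.g. all
#'   present features).
#' @return Data frame: `set_id`, `k`, `n`, `K`, `N`, `p`, `q`; attribute
#'   `n_query_discarded`.
#' @export
enrich_sets <- function(query, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  q_in <- unique(intersect(query, universe))
  discarded <- length(unique(query)) - length(q_in)
  rows <- lapply(names(gene_sets), function(s) {
    K_set <- intersect(unique(gene_sets[[s]]), universe)
    if (!length(K_set)) return(NULL)
    k <- length(intersect(q_in, K_set))
    data.frame(set_id = s, k = k, n = length(q_in), K = length(K_set),
               N = length(universe),
               p = hypergeom_pvalue(k, length(K_set), length(q_in),
                                    length(universe)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric())
  out$q <- if (nrow(out)) stats::p.adjust(out$p, "BH") else numeric(0)
  out <- out[order(out$p, out$set_id), ]
  rownames(out) <- NULL
  attr(out, "n_query_discarded") <- discarded
  out
}

#' Read a GMT gene-set collection
#'
#' Tab-delimited, one set per line: set name, description, then member ids.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output file path.
#' @param description Description field written for every set.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(names(gene_sets), function(s)
    paste(c(s, description, gene_sets[[s]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}
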