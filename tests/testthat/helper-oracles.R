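# Independent brute-force oracles used to validate the package
# implementations on small inputs. These deliberately share no code with
# the functions they check.

# All-pairs TSP scoring by explicit loops over samples.
oracle_tsp <- function(m, labels) {
  classes <- sort(unique(as.character(labels)))
  ids <- sort(rownames(m))
  m <- m[ids, , drop = FALSE]
  R <- apply(m, 2, rank)
  rows <- list()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      probs <- gaps <- numeric(2)
      for (c in 1:2) {
        cols <- which(labels == classes[c])
        ev <- 0; gap <- 0
        for (s in cols) {
          ev <- ev + as.numeric(m[i, s] < m[j, s])
          gap <- gap + (R[i, s] - R[j, s])
        }
        probs[c] <- ev / length(cols)
        gaps[c] <- gap / length(cols)
      }
      rows[[length(rows) + 1]] <- data.frame(
        feature_i = ids[i], feature_j = ids[j],
        delta = abs(probs[1] - probs[2]), gamma = abs(gaps[1] - gaps[2]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$delta, -out$gamma, out$feature_i, out$feature_j), ]
}

# Naive average-linkage agglomeration on a distance matrix; returns merge
# heights and the flat k-cut as a membership vector.
oracle_average_linkage <- function(D, k) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  membership <- NULL
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d_ab <- mean(D[clusters[[a]], clusters[[b]]])
        if (d_ab < best_d) { best_d <- d_ab; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    if (length(clusters) == k) {
      membership <- integer(n)
      for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
    }
  }
  list(heights = heights, membership = membership)
}

# Triple-loop FFL enumeration over a signed edge table.
oracle_ffls <- function(nodes, edges) {
  role <- setNames(nodes$role, nodes$id)
  tfs <- nodes$id[nodes$role == "DETF"]
  mirs <- nodes$id[nodes$role == "DEmiRNA"]
  genes <- nodes$id[nodes$role != "DEmiRNA"]
  sig <- edges[edges$type %in% c("tf_activate", "tf_repress"), ]
  rep_e <- edges[edges$type == "mirna_repress", ]
  find_sign <- function(tab, s, t) {
    hit <- tab$sign[tab$source == s & tab$target == t]
    if (length(hit)) hit[1] else NA_integer_
  }
  rows <- list()
  for (tf in tfs) for (m in mirs) for (g in genes) {
    if (g == tf || g == m) next
    s_tm <- find_sign(sig, tf, m)
    s_tg <- find_sign(sig, tf, g)
    if (is.na(s_tm) || is.na(s_tg)) next
    if (!any(rep_e$source == m & rep_e$target == g)) next
    rows[[length(rows) + 1]] <- data.frame(
      tf = tf, mirna = m, gene = g, s_direct = s_tg, s_tm = s_tm,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), s_direct = integer(),
                      s_tm = integer()))
  out <- do.call(rbind, rows)
  out[order(out$tf, out$mirna, out$gene), ]
}

# Random signed regulatory network over typed nodes.
random_signed_network <- function(n_tf = 10, n_mir = 15, n_gene = 25,
                                  density = 0.1) {
  tfs <- sprintf("tf%02d", seq_len(n_tf))
  mirs <- sprintf("mi%02d", seq_len(n_mir))
  genes <- sprintf("gn%02d", seq_len(n_gene))
  nodes <- data.frame(
    id = c(tfs, mirs, genes),
    role = c(rep("DETF", n_tf), rep("DEmiRNA", n_mir), rep("DEG", n_gene)),
    log2fc = 0, stringsAsFactors = FALSE)
  edge_rows <- list()
  add <- function(s, t, type, sign) {
    edge_rows[[length(edge_rows) + 1]] <<- data.frame(
      source = s, target = t, type = type, sign = sign, directed = TRUE,
      provenance = "sim", stringsAsFactors = FALSE)
  }
  for (tf in tfs) {
    for (t in c(mirs, genes, setdiff(tfs, tf))) {
      if (runif(1) < density) {
        sg <- sample(c(-1L, 1L), 1)
        add(tf, t, if (sg > 0) "tf_activate" else "tf_repress", sg)
      }
    }
    }
  for (m in mirs) for (g in c(genes, tfs)) {
    if (runif(1) < density) add(m, g, "mirna_repress", -1L)
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(source = character(), target = character(), type = character(),
               sign = integer(), directed = logical(), provenance = character())
  structure(list(nodes = nodes, edges = edges), class = "ild_network")
}

# Hypergeometric upper tail by enumerating every size-n draw from 1..N.
oracle_hypergeom_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# Tiny balanced null cohort matrix for calibration tests.
null_matrix <- function(n_feat, n1, n2, sd = 0.7) {
  m <- matrix(rnorm(n_feat * (n1 + n2), 8, sd), n_feat,
              dimnames = list(sprintf("f%04d", seq_len(n_feat)),
                              c(sprintf("a%02d", seq_len(n1)),
                                sprintf("b%02d", seq_len(n2)))))
  attr(m, "labels") <- c(rep("ILD", n1), rep("control", n2))
  m
}
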