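toy_net <- function() {
  nodes <- data.frame(
    id = c("tf1", "tf2", "mi1", "mi2", "g1", "g2", "g3"),
    role = c("DETF", "DETF", "DEmiRNA", "DEmiRNA", "DEG", "DEG", "DEG"),
    log2fc = c(1, -1, 2, -2, 1, -1, 0.8), stringsAsFactors = FALSE)
  tf_edges <- data.frame(
    source = c("tf1", "tf1", "tf2"), target = c("mi1", "g1", "g2"),
    type = c("tf_activate", "tf_repress", "tf_activate"),
    sign = c(1L, -1L, 1L), stringsAsFactors = FALSE)
  mirna_pairs <- data.frame(mirna = c("mi1", "mi2"), gene = c("g1", "g3"))
  ppi <- data.frame(a = c("g1", "g2"), b = c("g2", "g3"))
  pathway <- data.frame(source = "g3", target = "g1")
  assemble_network(nodes, tf_edges, mirna_pairs, ppi, pathway)
}

test_that("expression correlation signs TF edges", {
  set.seed(111)
  n <- 20
  tfp <- rnorm(n)
  mrna <- rbind(tf1 = tfp, gSame = tfp, gAnti = -tfp + mean(tfp) * 2,
                gNull = rnorm(n))
  colnames(mrna) <- sprintf("s%02d", 1:n)
  binding <- data.frame(tf = "tf1", target = c("gSame", "gAnti", "gNull"))
  e <- sign_tf_edges(binding, mrna, q_max = 0.1)
  expect_setequal(e$target, c("gSame", "gAnti"))  # null edge filtered out
  expect_equal(e$type[e$target == "gSame"], "tf_activate")
  expect_equal(e$sign[e$target == "gSame"], 1)
  expect_equal(e$type[e$target == "gAnti"], "tf_repress")
  expect_equal(e$sign[e$target == "gAnti"], -1)
})

test_that("planted regulon signs are recovered from expression", {
  cfg <- sim_config(n_genes = 600, n_mirnas = 60, n_tfs = 20,
                    n_de_genes = 30, n_de_mirnas = 15,
                    n_target_pairs_true = 0, n_regulons = 5,
                    n_ffls_planted = 0)
  hits <- c()
  for (r in 1:20) {
    cfg$seed <- 700 + r
    co <- simulate_cohort(cfg)
    reg <- co$truth$tf_regulons
    e <- sign_tf_edges(reg[, c("tf", "target")], co$mrna, co$mirna,
                       q_max = 0.1)
    m <- merge(e, reg, by.x = c("source", "target"),
               by.y = c("tf", "target"))
    hits <- c(hits, m$sign.x == m$sign.y)
  }
  expect_gte(mean(hits), 0.9)
})

test_that("network assembly restricts, deduplicates and counts edges", {
  net <- toy_net()
  expect_equal(nrow(net$nodes), 7)
  counts <- table(net$edges$type)
  expect_equal(as.integer(counts[c("tf_activate", "tf_repress",
                                   "mirna_repress", "ppi", "pathway")]),
               c(2L, 1L, 2L, 2L, 1L))
  expect_equal(nrow(net$edges), 8)

  # nodes-only network
  empty <- assemble_network(net$nodes)
  expect_equal(nrow(empty$edges), 0)

  # dangling endpoints are dropped by the DE restriction
  extra <- data.frame(source = "tfX", target = "g1", type = "tf_activate",
                      sign = 1L, stringsAsFactors = FALSE)
  net2 <- assemble_network(net$nodes, extra)
  expect_equal(nrow(net2$edges), 0)

  # same edge from two sources collapses with provenance preserved
  nodes <- net$nodes
  tf_e <- data.frame(source = "tf1", target = "g1", type = "pathway",
                     sign = 0L)
  net3 <- assemble_network(nodes,
                           pathway = data.frame(source = c("tf1", "tf1"),
                                                target = c("g1", "g1")))
  expect_equal(nrow(net3$edges), 1)

  # scope flag drops miRNA edges onto non-TF genes
  net4 <- assemble_network(net$nodes,
                           mirna_pairs = data.frame(mirna = c("mi1", "mi1"),
                                                    gene = c("g1", "tf2")),
                           include_mirna_gene = FALSE)
  expect_equal(net4$edges$target, "tf2")
})

test_that("module detection splits cliques at the bridge (exhaustive check)", {
  ids <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  clique <- function(v) t(combn(v, 2))
  ed <- rbind(clique(ids[1:5]), clique(ids[6:10]), c("a1", "b1"))
  edges <- data.frame(source = ed[, 1], target = ed[, 2], type = "ppi",
                      sign = 0L, directed = FALSE, provenance = "ppi",
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, role = "DEG", log2fc = 0,
                      stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "ild_network")
  part <- detect_modules(net)
  expect_equal(max(part), 2)
  expect_equal(length(unique(part[ids[1:5]])), 1)
  expect_equal(length(unique(part[ids[6:10]])), 1)

  # exhaustive check: no 2-partition has higher modularity
  best_q <- -Inf
  for (mask in 0:(2^9 - 1)) {
    assign <- c(1L, as.integer(intToBits(mask))[1:9] + 1L)
    names(assign) <- ids
    q <- network_modularity(net, assign)
    best_q <- max(best_q, q)
  }
  expect_equal(attr(part, "modularity"), best_q, tolerance = 1e-12)
})

test_that("module partitions are total, deterministic and beat the trivial partition", {
  set.seed(117)
  net <- random_signed_network(density = 0.08)
  p1 <- detect_modules(net)
  p2 <- detect_modules(net)
  expect_identical(p1, p2)
  expect_setequal(names(p1), net$nodes$id)
  expect_false(anyNA(p1))
  trivial <- setNames(rep(1L, nrow(net$nodes)), net$nodes$id)
  expect_gte(attr(p1, "modularity"), network_modularity(net, trivial))

  # edgeless network: all singletons; single clique: one module
  iso <- structure(list(nodes = net$nodes,
                        edges = net$edges[0, ]), class = "ild_network")
  expect_equal(max(detect_modules(iso)), nrow(net$nodes))
  ids <- sprintf("n%d", 1:6)
  cl <- t(combn(ids, 2))
  cl_net <- structure(list(
    nodes = data.frame(id = ids, role = "DEG", log2fc = 0),
    edges = data.frame(source = cl[, 1], target = cl[, 2], type = "ppi",
                       sign = 0L, directed = FALSE, provenance = "ppi")),
    class = "ild_network")
  expect_equal(max(detect_modules(cl_net)), 1)
})

test_that("modularity agrees with igraph on the undirected projection", {
  set.seed(119)
  net <- random_signed_network(density = 0.1)
  part <- detect_modules(net)
  prj <- unique(data.frame(a = pmin(net$edges$source, net$edges$target),
                           b = pmax(net$edges$source, net$edges$target)))
  g <- igraph::graph_from_data_frame(prj, directed = FALSE,
                                     vertices = net$nodes$id)
  q_ig <- igraph::modularity(g, part[igraph::V(g)$name])
  expect_equal(attr(part, "modularity"), q_ig, tolerance = 1e-12)
})

test_that("connectivity ranking counts typed degree with lexicographic ties", {
  # star graph: center first
  edges <- data.frame(source = "hub", target = sprintf("x%d", 1:4),
                      type = "tf_activate", sign = 1L, directed = TRUE,
                      provenance = "tf_binding", stringsAsFactors = FALSE)
  nodes <- data.frame(id = c("hub", sprintf("x%d", 1:4)),
                      role = c("DETF", rep("DEG", 4)), log2fc = 0)
  net <- structure(list(nodes = nodes, edges = edges), class = "ild_network")
  rk <- connectivity_ranking(net)
  expect_equal(rk$id[1], "hub")
  expect_equal(rk$degree[1], 4)
  # equal-degree nodes come in lexicographic order
  expect_equal(rk$id[-1], sprintf("x%d", 1:4))

  # hand count on the toy network (in + out, all edge types once)
  net2 <- toy_net()
  rk2 <- connectivity_ranking(net2)
  deg <- setNames(rk2$degree, rk2$id)
  expect_equal(deg[["g1"]], 4)  # tf1->g1, mi1->g1, ppi g1-g2, pathway g3->g1
  expect_equal(deg[["tf1"]], 2)
  expect_equal(deg[["mi2"]], 1)
})

test_that("marker stratification flags a planted module shift and stays null otherwise", {
  set.seed(127)
  n_case <- 20
  samples <- sprintf("case_%02d", 1:n_case)
  marker <- rnorm(n_case, 8, 1)
  high <- marker > median(marker)
  mod_genes <- sprintf("mg%02d", 1:10)
  m <- matrix(rnorm(11 * n_case, 8, 0.5), 11, n_case,
              dimnames = list(c("MARKER", mod_genes), samples))
  m["MARKER", ] <- marker
  m[mod_genes, high] <- m[mod_genes, high] + 1   # planted 1 log2-unit shift
  res <- marker_stratified_module_test(m, "MARKER", mod_genes, samples)
  expect_gt(res$summary$n_flagged, 5)
  expect_gt(res$summary$mean_abs_log2fc, 0.5)

  # identical strata: expected flagged fraction below the q threshold
  m0 <- matrix(rnorm(11 * n_case, 8, 0.5), 11, n_case,
               dimnames = list(c("MARKER", mod_genes), samples))
  m0["MARKER", ] <- marker
  res0 <- marker_stratified_module_test(m0, "MARKER", mod_genes, samples)
  expect_lte(res0$summary$n_flagged / res0$summary$n_genes, 0.1)

  # odd case count: the median sample lands in "low"
  res_odd <- marker_stratified_module_test(m[, 1:19], "MARKER", mod_genes,
                                           samples[1:19])
  expect_equal(res_odd$summary$n_low, 10)
  expect_equal(res_odd$summary$n_high, 9)
  expect_error(marker_stratified_module_test(m, "MARKER", c("nope"), samples),
               "absent")
})

test_that("role and edge-type counts survive a serialization round-trip", {
  net <- toy_net()
  d <- withr::local_tempdir()
  export_network(net, file.path(d, "edges.tsv"), file.path(d, "net.graphml"))
  back <- read.delim(file.path(d, "edges.tsv"), stringsAsFactors = FALSE)
  expect_equal(table(back$type), table(net$edges$type))
  expect_equal(nrow(back), nrow(net$edges))
  g <- igraph::read_graph(file.path(d, "net.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_equal(sort(table(igraph::V(g)$role)), sort(table(net$nodes$role)),
               ignore_attr = TRUE)
})
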