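identity_matching <- function(net, netB = net) {
  X <- diag(net$n)
  dimnames(X) <- list(net$nodes, netB$nodes)
  m <- greedy_match(X)
  complete_matching(m, X)
}

test_that("alignment graph keeps exactly the edges conserved in both networks", {
  tri <- net_from_edges("x", "y", "y", "z", "z", "x", name = "tri")
  m <- identity_matching(tri)
  ag <- build_alignment_graph(m, tri, tri)
  expect_equal(conserved_edge_count(ag), 3L)
  expect_equal(length(alignment_components(ag)), 1L)

  # single pair: no edges
  one <- greedy_match(matrix(c(1, 0, 0, 0), 2, 2,
                             dimnames = list(tri$nodes[1:2], tri$nodes[1:2])))
  expect_equal(conserved_edge_count(build_alignment_graph(one, tri, tri)), 0L)

  # triangle vs path a-b-c: only the path's two edges survive
  path <- net_from_edges("x", "y", "y", "z", name = "path")
  agp <- build_alignment_graph(identity_matching(tri, path), tri, path)
  expect_equal(conserved_edge_count(agp), 2L)

  # K4 self-alignment conserves all C(4,2) edges
  k4 <- net_from_edges("a", "b", "a", "c", "a", "d", "b", "c", "b", "d",
                       "c", "d")
  expect_equal(conserved_edge_count(
    build_alignment_graph(identity_matching(k4), k4, k4)), 6L)

  expect_error(build_alignment_graph(m, net_from_edges("x", "y"), tri),
               "out of range")
})

test_that("conserved edges match the brute-force pair check on random instances", {
  set.seed(99)
  for (rep in 1:40) {
    netA <- random_net(sample(4:9, 1), p = 0.45, prefix = "a")
    netB <- random_net(sample(4:9, 1), p = 0.45, prefix = "b")
    k <- min(netA$n, netB$n)
    ij <- cbind(sample(netA$n, k), sample(netB$n, k))
    X <- matrix(runif(netA$n * netB$n),
                dimnames = list(netA$nodes, netB$nodes),
                nrow = netA$n)
    m <- netalignr:::new_matching(ij, X, "fuzz")
    ag <- build_alignment_graph(m, netA, netB)
    expect_equal(conserved_edge_count(ag),
                 conserved_edges_brute(m, netA, netB))
    expect_lte(conserved_edge_count(ag),
               min(network_edge_count(netA), network_edge_count(netB)))
  }
})

test_that("identity self-alignment conserves every edge and each component", {
  set.seed(123)
  net <- random_net(8, p = 0.3)
  ag <- build_alignment_graph(identity_matching(net), net, net)
  expect_equal(conserved_edge_count(ag), network_edge_count(net))
  expect_equal(length(alignment_components(ag)),
               igraph::components(as_igraph(net))$no)
})

test_that("components are sorted by size then lexicographic representative", {
  netA <- net_from_edges("a", "b", "b", "c", "d", "e",
                         isolated = c("a", "b", "c", "d", "e", "f"))
  ag <- build_alignment_graph(identity_matching(netA), netA, netA)
  comps <- alignment_components(ag)
  expect_equal(lengths(comps), c(3L, 2L, 1L))
  expect_equal(comps[[1]], c("a|a", "b|b", "c|c"))
  expect_equal(comps[[3]], "f|f")

  # edgeless graph: all singletons
  iso <- as_ppi_net(data.frame(a = character(), b = character()),
                    isolated = c("p", "q", "r"))
  agi <- build_alignment_graph(identity_matching(iso), iso, iso)
  expect_equal(lengths(alignment_components(agi)), rep(1L, 3))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # planted 3-of-3 module in a background of 10: p = 1/C(10,3) = 1/120
  comp <- list(c("g1|h1", "g2|h2", "g3|h3"))
  ann <- annotation_set(setNames(rep(list("T"), 3), c("g1", "g2", "g3")),
                        background = c(paste0("g", 1:3), paste0("f", 1:7)))
  er <- enrich_components(comp, ann, NULL)
  expect_equal(er$terms$p_value, 1 / 120, tolerance = 1e-12)
  expect_true(er$terms$enriched)
  expect_equal(er$summary$tnr, 100)
  expect_equal(er$summary$tpr, 1L)

  # exact agreement with enumeration for all k on backgrounds <= 12
  set.seed(77)
  for (rep in 1:25) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    for (k in 0:min(K, n)) {
      expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   hyper_tail_enum(k, K, N, n), tolerance = 1e-12)
    }
  }
})

test_that("enrichment summaries use union TPR and count unenriched components", {
  background <- paste0("g", 1:30)
  ann <- annotation_set(
    setNames(rep(list("T"), 6), paste0("g", 1:6)), background = background)
  # two components enriched for the same term: union TPR = 1
  comps <- list(paste0("g", 1:3, "|x"), paste0("g", 4:6, "|x"))
  er <- enrich_components(comps, ann, NULL)
  expect_equal(er$summary$tpr, 1L)
  expect_equal(er$summary$tnr, 100)

  # a component sharing no annotated node contributes no terms
  comps2 <- c(comps, list(paste0("g", 25:27, "|x")))
  er2 <- enrich_components(comps2, ann, NULL)
  expect_equal(er2$summary$n_enriched, 2L)
  expect_equal(er2$summary$tnr, 100 * 2 / 3, tolerance = 1e-12)

  # empty component list: TNR undefined, TPR zero
  er3 <- enrich_components(list(), ann, NULL)
  expect_true(is.na(er3$summary$tnr))
  expect_equal(er3$summary$tpr, 0L)
})

test_that("raising the enrichment threshold never lowers TPR or TNR", {
  set.seed(88)
  background <- paste0("g", 1:20)
  mapping <- lapply(setNames(nm = paste0("g", 1:12)), function(g) {
    sample(paste0("T", 1:4), sample(1:2, 1))
  })
  ann <- annotation_set(mapping, background = background)
  comps <- list(paste0("g", c(1, 3, 5), "|x"), paste0("g", c(2, 8), "|x"),
                paste0("g", c(9, 11, 12, 15), "|x"))
  prev_tpr <- -1
  prev_tnr <- -1
  for (th in c(0.001, 0.01, 0.05, 0.2, 0.5, 1)) {
    er <- enrich_components(comps, ann, NULL, threshold = th)
    expect_gte(er$summary$tpr, prev_tpr)
    expect_gte(er$summary$tnr, prev_tnr)
    prev_tpr <- er$summary$tpr
    prev_tnr <- er$summary$tnr
  }
})

test_that("bonferroni option only makes calls more conservative", {
  set.seed(66)
  background <- paste0("g", 1:15)
  mapping <- lapply(setNames(nm = paste0("g", 1:10)), function(g) {
    sample(paste0("T", 1:3), 2)
  })
  ann <- annotation_set(mapping, background = background)
  comps <- list(paste0("g", 1:4, "|x"))
  raw <- enrich_components(comps, ann, NULL)
  adj <- enrich_components(comps, ann, NULL, bonferroni = TRUE)
  expect_true(all(adj$terms$p_value >= raw$terms$p_value))
  expect_lte(adj$summary$tpr, raw$summary$tpr)
})

test_that("assessment report bundles topology and optional enrichment", {
  tri <- net_from_edges("x", "y", "y", "z", "z", "x")
  m <- identity_matching(tri)
  rep_topo <- assessment_report(m, tri, tri)
  expect_null(rep_topo$enrichment)
  expect_equal(rep_topo$topology$conserved_edges, 3)
  expect_equal(rep_topo$topology$n_pairs, 3L)

  ann <- annotation_set(setNames(rep(list("T"), 3), tri$nodes),
                        background = c(tri$nodes, paste0("o", 1:7)))
  rep_full <- assessment_report(m, tri, tri, ann, ann)
  expect_s3_class(rep_full$enrichment, "enrichment_report")
  expect_equal(nrow(glance(rep_full)), 2L)
  expect_equal(unique(glance(rep_full)$conserved_edges), 3)
  td <- tidy(rep_full)
  expect_true(all(c("component", "size", "n_enriched") %in% names(td)))
})
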