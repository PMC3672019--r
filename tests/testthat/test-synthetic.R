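test_that("planted pairs are reproducible and isomorphic at zero rewiring", {
  i1 <- generate_pair(20, edge_prob = 0.2, seed = 7)
  i2 <- generate_pair(20, edge_prob = 0.2, seed = 7)
  expect_identical(i1$truth, i2$truth)
  expect_identical(as.matrix(i1$netB$adj), as.matrix(i2$netB$adj))
  expect_false(identical(i1$truth$node_b,
                         generate_pair(20, edge_prob = 0.2, seed = 8)$truth$node_b))

  # rewire 0: netB restricted to mapped nodes is netA relabeled, so the
  # truth matching conserves every edge of netA
  inst <- generate_pair(25, edge_prob = 0.15, rewire_frac = 0,
                        extra_nodes = 4, seed = 11)
  expect_equal(inst$netB$n, 29L)
  X <- matrix(1, inst$netA$n, inst$netB$n,
              dimnames = list(inst$netA$nodes, inst$netB$nodes))
  tm <- truth_matching(inst, X)
  ag <- build_alignment_graph(tm, inst$netA, inst$netB)
  expect_equal(conserved_edge_count(ag), network_edge_count(inst$netA))
})

test_that("rewiring removes and reinserts the requested number of edges", {
  inst0 <- generate_pair(30, edge_prob = 0.2, rewire_frac = 0,
                         extra_nodes = 0, seed = 5)
  mA <- network_edge_count(inst0$netA)
  for (rw in c(0.1, 0.5, 1)) {
    inst <- generate_pair(30, edge_prob = 0.2, rewire_frac = rw,
                          extra_nodes = 0, seed = 5)
    # same netA under the same seed; |E_B| stays near |E_A| (insertions can
    # be capped only when non-edges run out)
    expect_equal(network_edge_count(inst$netA), mA)
    X <- matrix(1, inst$netA$n, inst$netB$n,
                dimnames = list(inst$netA$nodes, inst$netB$nodes))
    conserved <- conserved_edge_count(build_alignment_graph(
      truth_matching(inst, X), inst$netA, inst$netB))
    # kept mapped edges stay conserved; reinsertions can at most refill
    # deleted slots
    expect_gte(conserved, mA - ceiling(rw * mA))
    expect_lte(conserved, mA)
    if (rw == 1) {
      # all original edges deleted: conservation is down to chance reinsertion
      expect_lt(conserved, mA)
    }
  }
})

test_that("full rewiring leaves only chance-level conservation on average", {
  set.seed(42)
  n <- 14
  p <- 0.3
  obs <- sapply(1:60, function(s) {
    inst <- generate_pair(n, edge_prob = p, rewire_frac = 1,
                          extra_nodes = 0, seed = s)
    X <- matrix(1, n, n, dimnames = list(inst$netA$nodes, inst$netB$nodes))
    c(cons = conserved_edge_count(build_alignment_graph(
        truth_matching(inst, X), inst$netA, inst$netB)),
      m = network_edge_count(inst$netA))
  })
  # after deleting all mapped edges every pair is a non-edge, so the m
  # reinsertions sample uniformly among C(n,2) slots and a conserved edge
  # arises only where one hits an original edge: expectation m^2 / C(n,2)
  expected <- mean(obs["m", ]^2 / choose(n, 2))
  expect_lt(abs(mean(obs["cons", ]) - expected), 2)
})

test_that("elemental scores are supported on the truth unless noise is added", {
  inst <- generate_pair(15, edge_prob = 0.25, seed = 3)
  H <- generate_elemental(inst, true_score = 2, seed = 3)
  ti <- cbind(match(inst$truth$node_a, rownames(H)),
              match(inst$truth$node_b, colnames(H)))
  expect_true(all(H[ti] == 2))
  expect_equal(sum(H > 0), nrow(ti))

  # zero-range noise is equivalent to no noise
  H0 <- generate_elemental(inst, noise_pairs = 10, noise_score_max = 0,
                           seed = 4)
  expect_equal(sum(H0 > 0), nrow(ti))

  Hn <- generate_elemental(inst, noise_pairs = 25, noise_score_max = 0.5,
                           seed = 5)
  expect_equal(sum(Hn > 0), nrow(ti) + 25L)
  expect_true(all(Hn[ti] == 1))

  expect_error(generate_elemental(inst, noise_pairs = 1e6), "exceeds")
})

test_that("planted annotation modules are connected and mirrored across species", {
  inst <- generate_pair(30, edge_prob = 0.2, seed = 13)
  ann <- generate_annotations(inst, n_terms = 4, module_size = 4, seed = 13)
  expect_setequal(ann$annA$background, inst$netA$nodes)
  expect_setequal(ann$annB$background, inst$netB$nodes)
  map_b <- setNames(inst$truth$node_b, inst$truth$node_a)
  gA <- as_igraph(inst$netA)
  for (term in paste0("T", sprintf("%03d", 1:4))) {
    nodesA <- names(Filter(function(t) term %in% t, ann$annA$mapping))
    nodesB <- names(Filter(function(t) term %in% t, ann$annB$mapping))
    expect_setequal(unname(map_b[nodesA]), nodesB)
    sub <- igraph::induced_subgraph(gA, nodesA)
    expect_equal(igraph::components(sub)$no, 1L)
  }
  # no terms requested: empty annotation sets
  ann0 <- generate_annotations(inst, n_terms = 0, seed = 1)
  expect_equal(length(ann0$annA$mapping), 0L)
})

test_that("an intact aligned module is called enriched at the default threshold", {
  # subcritical density keeps alignment-graph components near module size,
  # so the planted term is a large fraction of its component's projection
  inst <- generate_pair(40, edge_prob = 0.02, seed = 21)
  ann <- generate_annotations(inst, n_terms = 1, module_size = 4, seed = 21)
  H <- generate_elemental(inst, seed = 22)
  X <- isorank_iterate(inst$netA, inst$netB, H)
  m <- greedy_match(X)
  rep <- assessment_report(m, inst$netA, inst$netB, ann$annA, ann$annB)
  terms <- rep$enrichment$terms
  expect_true(any(terms$enriched[terms$term == "T001"]))
})

test_that("recovery degrades monotonically with rewiring under a noisy prior", {
  rates <- sapply(c(0, 0.3, 0.6), function(rw) {
    mean(sapply(1:8, function(s) {
      inst <- generate_pair(40, rewire_frac = rw, seed = s)
      H <- generate_elemental(inst, noise_pairs = 400, noise_score_max = 1,
                              seed = s + 1000)
      X <- isorank_iterate(inst$netA, inst$netB, H)
      recovery_rate(greedy_match(X), inst)
    }))
  })
  expect_true(all(diff(rates) <= 0.02))
  expect_gt(rates[1], rates[3])
})
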