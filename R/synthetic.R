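#' Generate a pair of networks with a planted node correspondence
#'
#' Draws `netA` as an Erdős–Rényi graph G(n, edge_prob), relabels a shuffled
#' copy as `netB`, rewires a requested fraction of its edges (delete
#' `ceiling(rewire_frac * |E_A|)` edges uniformly, insert the same number
#' uniformly among non-edges of the mapped nodes), and appends
#' `extra_nodes` additional nodes that are isolated or attached to one
#' random mapped node with equal probability. The relabeling is returned as
#' the ground-truth correspondence, so recovery of the planted alignment
#' can be scored at any rewiring level.
#'
#' @param n number of nodes in `netA` (>= 2).
#' @param edge_prob edge probability of the Erdős–Rényi draw (default 0.1,
#'   giving sparse graphs of PPI-like mean degree at the default sizes).
#' @param rewire_frac fraction of `netA`'s edges rewired in `netB`
#'   (default 0: `netB` restricted to mapped nodes is isomorphic to
#'   `netA`).
#' @param extra_nodes unmatched nodes added to `netB` (default 5,
#'   mimicking proteins without an ortholog).
#' @param seed integer seed; the instance is fully reproducible from it.
#' @return a `planted_instance`: list with `netA`, `netB` (`ppi_net`),
#'   `truth` (tibble `node_a`, `node_b`), `params` and `seed`.
#' @export
generate_pair <- function(n, edge_prob = 0.1, rewire_frac = 0,
                          extra_nodes = 5, seed = 1L) {
  stopifnot(n >= 2, rewire_frac >= 0, rewire_frac <= 1, extra_nodes >= 0)
  set.seed(seed)
  labels_a <- sprintf("a%03d", seq_len(n))
  edges_a <- NULL
  for (try in 1:25) {
    g <- igraph::sample_gnp(n, edge_prob)
    if (igraph::gsize(g) > 0) {
      edges_a <- igraph::as_edgelist(g)
      break
    }
  }
  if (is.null(edges_a)) {
    stop("edge_prob too small: could not draw a non-empty graph")
  }
  netA <- as_ppi_net(data.frame(from = labels_a[edges_a[, 1]],
                                to = labels_a[edges_a[, 2]]),
                     name = "synthA", isolated = labels_a)
  nb <- n + extra_nodes
  labels_b <- sprintf("b%03d", seq_len(nb))
  perm <- sample.int(n)
  truth <- tibble::tibble(node_a = labels_a, node_b = labels_b[perm])
  map_b <- stats::setNames(truth$node_b, truth$node_a)

  eb <- cbind(unname(map_b[labels_a[edges_a[, 1]]]),
              unname(map_b[labels_a[edges_a[, 2]]]))
  m <- nrow(eb)
  n_rw <- ceiling(rewire_frac * m)
  if (n_rw > 0) {
    keep <- sort(sample.int(m, m - n_rw))
    eb <- eb[keep, , drop = FALSE]
    # insert among non-edges of the mapped nodes
    present <- paste(pmin(eb[, 1], eb[, 2]), pmax(eb[, 1], eb[, 2]))
    mapped <- sort(unname(map_b))
    all_pairs <- utils::combn(mapped, 2)
    key <- paste(pmin(all_pairs[1, ], all_pairs[2, ]),
                 pmax(all_pairs[1, ], all_pairs[2, ]))
    free <- which(!(key %in% present))
    add <- sample(free, min(n_rw, length(free)))
    eb <- rbind(eb, t(all_pairs[, add, drop = FALSE]))
  }
  if (extra_nodes > 0) {
    ex <- labels_b[(n + 1):nb]
    attach_to <- stats::runif(extra_nodes) < 0.5
    if (any(attach_to)) {
      eb <- rbind(eb, cbind(ex[attach_to],
                            sample(truth$node_b, sum(attach_to),
                                   replace = TRUE)))
    }
  }
  netB <- as_ppi_net(data.frame(from = eb[, 1], to = eb[, 2]),
                     name = "synthB", isolated = labels_b)
  structure(list(netA = netA, netB = netB, truth = truth,
                 params = list(n = n, edge_prob = edge_prob,
                               rewire_frac = rewire_frac,
                               extra_nodes = extra_nodes),
                 seed = seed),
            class = "planted_instance")
}

#' @export
print.planted_instance <- function(x, ...) {
  cat(sprintf(
    "<planted_instance>  n=%d (+%d extra), p=%g, rewire=%g, seed=%d\n",
    x$params$n, x$params$extra_nodes, x$params$edge_prob,
    x$params$rewire_frac, x$seed))
  invisible(x)
}

#' Generate elemental similarities consistent with a planted truth
#'
#' Every true pair scores `true_score`; `noise_pairs` random off-truth
#' pairs get Uniform(0, `noise_score_max`) scores; everything else is 0.
#' Emulates a sequence-similarity prior that favours the planted
#' orthologs.
#'
#' @param instance a [generate_pair()] result.
#' @param true_score score of planted pairs (> 0, default 1).
#' @param noise_pairs number of spurious scored pairs (default 0).
#' @param noise_score_max upper bound of the spurious scores (default 0).
#' @param seed integer seed for the noise placement.
#' @return a dense elemental similarity matrix with dimnames.
#' @export
generate_elemental <- function(instance, true_score = 1, noise_pairs = 0,
                               noise_score_max = 0, seed = 1L) {
  stopifnot(inherits(instance, "planted_instance"), true_score > 0,
            noise_pairs >= 0)
  set.seed(seed)
  netA <- instance$netA
  netB <- instance$netB
  H <- matrix(0, netA$n, netB$n, dimnames = list(netA$nodes, netB$nodes))
  ti <- cbind(match(instance$truth$node_a, netA$nodes),
              match(instance$truth$node_b, netB$nodes))
  if (noise_pairs > netA$n * netB$n - nrow(ti)) {
    stop("noise_pairs exceeds the number of off-truth pairs")
  }
  H[ti] <- true_score
  if (noise_pairs > 0 && noise_score_max > 0) {
    off <- setdiff(seq_len(netA$n * netB$n), (ti[, 2] - 1) * netA$n + ti[, 1])
    cells <- sample(off, noise_pairs)
    H[cells] <- stats::runif(noise_pairs, 0, noise_score_max)
  }
  H
}

#' Plant term annotations on connected modules
#'
#' Each of `n_terms` terms annotates one connected module of `netA` (grown
#' by random neighbour expansion to `module_size` nodes, or to the whole
#' component if smaller) and the truth-image of that module in `netB`. All
#' nodes of each network form the annotation background.
#'
#' @param instance a [generate_pair()] result.
#' @param n_terms number of planted terms (default 3).
#' @param module_size nodes per module (default 4; must be <= n).
#' @param seed integer seed.
#' @return list with `annA` and `annB` ([annotation_set()]s).
#' @export
generate_annotations <- function(instance, n_terms = 3, module_size = 4,
                                 seed = 1L) {
  stopifnot(inherits(instance, "planted_instance"),
            module_size <= instance$params$n)
  set.seed(seed)
  netA <- instance$netA
  map_b <- stats::setNames(instance$truth$node_b, instance$truth$node_a)
  mapA <- list()
  mapB <- list()
  for (t in seq_len(max(0, n_terms))) {
    term <- sprintf("T%03d", t)
    module <- grow_module(netA, module_size)
    for (nd in module) mapA[[nd]] <- c(mapA[[nd]], term)
    for (nd in unname(map_b[module])) mapB[[nd]] <- c(mapB[[nd]], term)
  }
  list(annA = annotation_set(lapply(mapA, unique), background = netA$nodes),
       annB = annotation_set(lapply(mapB, unique),
                             background = instance$netB$nodes))
}

# grow a connected node set by random neighbour expansion
grow_module <- function(net, size) {
  start <- sample(net$nodes, 1)
  module <- start
  while (length(module) < size) {
    idx <- match(module, net$nodes)
    nbr <- unique(net$nodes[Matrix::which(
      Matrix::rowSums(net$adj[, idx, drop = FALSE]) > 0)])
    frontier <- setdiff(nbr, module)
    if (length(frontier) == 0) break
    module <- c(module, sample(frontier, 1))
  }
  module
}

#' Truth matching of a planted instance on a score matrix
#'
#' Builds the matching induced by the planted correspondence, scored on
#' `X`, so its weight can be compared with a matcher's output.
#' @param instance a [generate_pair()] result.
#' @param X a score matrix whose dimnames are the two node sets.
#' @return a `net_matching` with `method = "truth"`.
#' @export
truth_matching <- function(instance, X) {
  stopifnot(inherits(instance, "planted_instance"))
  ij <- cbind(match(instance$truth$node_a, rownames(X)),
              match(instance$truth$node_b, colnames(X)))
  new_matching(ij, as_score_matrix(X, allow_negative = TRUE),
               "truth")
}

#' Fraction of planted pairs recovered by a matching
#' @param matching a `net_matching` with `node_a`/`node_b` labels.
#' @param instance the [generate_pair()] instance that defines the truth.
#' @return recovery rate in `[0, 1]`.
#' @export
recovery_rate <- function(matching, instance) {
  stopifnot(inherits(instance, "planted_instance"))
  got <- paste(matching$node_a, matching$node_b)
  want <- paste(instance$truth$node_a, instance$truth$node_b)
  mean(want %in% got)
}
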