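# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# random undirected network on n labelled nodes, each pair an edge with
# probability p (isolated nodes kept)
random_net <- function(n, p = 0.4, prefix = "v") {
  labels <- paste0(prefix, seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- if (any(keep)) {
    data.frame(from = labels[pairs[1, keep]], to = labels[pairs[2, keep]])
  } else {
    data.frame(from = character(), to = character())
  }
  as_ppi_net(edges, name = paste0(prefix, "net"), isolated = labels)
}

# network from an explicit edge list given as a two-column matrix of labels
net_from_edges <- function(..., name = "net", isolated = character()) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  as_ppi_net(data.frame(from = e[, 1], to = e[, 2]), name = name,
             isolated = isolated)
}

# independent conserved-edge oracle: brute-force double loop over all pairs
# of matched pairs, checking adjacency in both networks
conserved_edges_brute <- function(matching, netA, netB) {
  k <- nrow(matching)
  if (k < 2) return(0L)
  count <- 0L
  for (u in seq_len(k - 1)) {
    for (v in (u + 1):k) {
      if (netA$adj[matching$i[u], matching$i[v]] != 0 &&
          netB$adj[matching$j[u], matching$j[v]] != 0) {
        count <- count + 1L
      }
    }
  }
  count
}

# independent hypergeometric upper tail by exhaustive enumeration of all
# draws of size n from a background of size N with K successes
hyper_tail_enum <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= k)
}

# write a small text fixture and return its path
tmp_file <- function(lines) {
  path <- withr::local_tempfile(lines = lines,
                                .local_envir = parent.frame())
  path
}
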