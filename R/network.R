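#' Undirected interaction network
#'
#' A `ppi_net` stores an undirected, unweighted network: a character vector
#' of unique node labels (in first-appearance order) and a symmetric binary
#' sparse adjacency matrix with zero diagonal. It is the container used for
#' both input networks of an alignment.
#'
#' @param edges a data frame whose first two columns give the endpoints of
#'   each edge (character); both orientations of a pair map to the same
#'   undirected edge, duplicates are collapsed and self-loops are dropped
#'   with a warning.
#' @param name short identifier for the network (used in reports).
#' @param isolated optional character vector of extra node labels to include
#'   even if they touch no edge.
#'
#' @return an object of class `ppi_net` with elements `name`, `nodes`
#'   (character), `adj` (symmetric sparse 0/1 `Matrix` with zero diagonal)
#'   and `n` (node count).
#' @export
#' @examples
#' net <- as_ppi_net(data.frame(a = c("p1", "p2"), b = c("p2", "p3")), "toy")
#' net$n
#' network_edge_count(net)
as_ppi_net <- function(edges, name = "net", isolated = character()) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop(s) in network '%s'",
                    sum(loops), name), call. = FALSE)
    a <- a[!loops]
    b <- b[!loops]
  }
  nodes <- unique(c(rbind(as.character(edges[[1]]), as.character(edges[[2]]))))
  nodes <- unique(c(nodes, as.character(isolated)))
  if (length(nodes) < 1L) stop("network must contain at least one node")
  i <- match(a, nodes)
  j <- match(b, nodes)
  n <- length(nodes)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n), dimnames = list(nodes, nodes),
                              use.last.ij = TRUE)
  adj@x[] <- 1  # collapse duplicate edges to weight 1
  adj <- Matrix::drop0(adj)
  structure(list(name = name, nodes = nodes, adj = adj, n = n),
            class = "ppi_net")
}

#' @export
print.ppi_net <- function(x, ...) {
  cat(sprintf("<ppi_net '%s'>  %d nodes, %d edges\n",
              x$name, x$n, network_edge_count(x)))
  invisible(x)
}

#' Number of undirected edges in a network
#'
#' Each unordered node pair is counted once.
#' @param net a [as_ppi_net()] object.
#' @return integer edge count.
#' @export
network_edge_count <- function(net) {
  stopifnot(inherits(net, "ppi_net"))
  as.integer(Matrix::nnzero(net$adj) / 2)
}

#' Node degrees of a network
#' @param net a `ppi_net`.
#' @return named integer vector of degrees in node order.
#' @export
network_degrees <- function(net) {
  d <- Matrix::rowSums(net$adj)
  stats::setNames(as.integer(d), net$nodes)
}

#' Edge table of a network
#'
#' @param net a `ppi_net`.
#' @return tibble with columns `from`, `to`, each unordered edge once, with
#'   `from` preceding `to` in node order.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "ppi_net"))
  tr <- Matrix::which(Matrix::triu(net$adj, 1) != 0, arr.ind = TRUE)
  tibble::tibble(from = net$nodes[tr[, 1]], to = net$nodes[tr[, 2]])
}

#' Convert a network to an igraph graph
#' @param net a `ppi_net`.
#' @return an undirected `igraph` object with vertex names.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_net"))
  igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected")
}
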