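#' Build the alignment graph of a matching
#'
#' The alignment graph has one node per matched pair m = (i, j) and an edge
#' between pairs m1 = (i1, j1) and m2 = (i2, j2) exactly when i1–i2 is an
#' edge of `netA` and j1–j2 is an edge of `netB`. Its edges are the
#' *conserved edges* of the alignment: interactions preserved under the
#' node mapping in both networks.
#'
#' @param matching a `net_matching` whose indices refer to `netA` (rows)
#'   and `netB` (columns).
#' @param netA,netB the two aligned networks (`ppi_net`).
#' @return an `alignment_graph`: list with `pairs` (tibble of matched
#'   pairs), `graph` (an `igraph` on the pairs, vertex names
#'   `"<nodeA>|<nodeB>"`), and `provenance`.
#' @export
build_alignment_graph <- function(matching, netA, netB) {
  stopifnot(inherits(matching, "net_matching"),
            inherits(netA, "ppi_net"), inherits(netB, "ppi_net"))
  if (nrow(matching) > 0 &&
      (max(matching$i) > netA$n || max(matching$j) > netB$n)) {
    stop("matching indices out of range for the given networks")
  }
  if (any(grepl("|", c(netA$nodes, netB$nodes), fixed = TRUE))) {
    stop("node labels must not contain '|' (used to name matched pairs)")
  }
  pairs <- tibble::as_tibble(matching)
  vnames <- paste(netA$nodes[pairs$i], netB$nodes[pairs$j], sep = "|")
  edges <- integer(0)
  if (nrow(pairs) > 1) {
    # conserved edge iff both endpoints' originals are adjacent in A and B
    subA <- netA$adj[pairs$i, pairs$i, drop = FALSE]
    subB <- netB$adj[pairs$j, pairs$j, drop = FALSE]
    both <- Matrix::which(Matrix::triu(subA * subB, 1) != 0, arr.ind = TRUE)
    edges <- t(both)
  }
  g <- igraph::make_empty_graph(n = nrow(pairs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vnames)
  if (length(edges)) g <- igraph::add_edges(g, as.vector(edges))
  structure(list(pairs = pairs, graph = g,
                 provenance = list(method = attr(matching, "method"),
                                   params = attr(matching, "params"),
                                   net_a = netA$name, net_b = netB$name)),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(sprintf("<alignment_graph>  %d matched pairs, %d conserved edges (%s)\n",
              nrow(x$pairs), conserved_edge_count(x),
              x$provenance$method %||% "?"))
  invisible(x)
}

#' Number of conserved edges in an alignment graph
#'
#' Each unordered pair of matched pairs is counted once. More conserved
#' edges mean more of the two networks' link structure is preserved under
#' the alignment.
#' @param ag an [build_alignment_graph()] result.
#' @return integer edge count.
#' @export
conserved_edge_count <- function(ag) {
  stopifnot(inherits(ag, "alignment_graph"))
  igraph::gsize(ag$graph)
}

#' Connected components of an alignment graph
#'
#' The components are the common connected subgraphs of the alignment:
#' clusters of matched pairs that also conserve their link pattern.
#' Singletons are included.
#'
#' @param ag an `alignment_graph`.
#' @return a list of character vectors of alignment-graph vertex names
#'   (`"<nodeA>|<nodeB>"`), sorted by decreasing size, then by their
#'   lexicographically smallest member; members sorted within each
#'   component.
#' @export
alignment_components <- function(ag) {
  stopifnot(inherits(ag, "alignment_graph"))
  comp <- igraph::components(ag$graph)
  if (comp$no == 0) return(list())
  groups <- split(igraph::V(ag$graph)$name, comp$membership)
  groups <- lapply(groups, sort)
  reps <- vapply(groups, `[[`, "", 1L)
  unname(groups[order(-lengths(groups), reps)])
}

#' Term enrichment of alignment-graph components
#'
#' Each connected component is treated as a predicted functionally related
#' group and cross-validated against the annotations of each species
#' separately: the component is projected onto that species' nodes and,
#' for every term annotating at least one projected node, the exact
#' hypergeometric upper-tail probability of drawing at least that many
#' term-annotated nodes in a sample of the projection's size from the
#' annotation background is computed. A term is enriched when its p-value
#' is at or below `threshold`; a component is enriched when at least one
#' of its terms is.
#'
#' Two summary criteria are reported per species: TNR (specificity), the
#' percentage of components with at least one enriched term, and TPR
#' (sensitivity), the number of distinct enriched terms covered over all
#' components.
#'
#' @param components list of components from [alignment_components()].
#' @param annA,annB [annotation_set()]s for the two species (`NULL` to
#'   skip a species).
#' @param threshold p-value threshold (default 0.05).
#' @param bonferroni if `TRUE`, apply a Bonferroni correction per component
#'   (multiply each p-value by the number of terms tested in that
#'   component). Default `FALSE`: the raw threshold is applied.
#' @return an `enrichment_report`: list with `terms` (tibble: component,
#'   species, term, overlap k, term size K, draw size, background size,
#'   p-value, enriched flag) and `summary` (tibble: species, number of
#'   components, enriched components, TNR percent, TPR count).
#' @export
enrich_components <- function(components, annA, annB, threshold = 0.05,
                              bonferroni = FALSE) {
  species <- list()
  if (!is.null(annA)) species$A <- annA
  if (!is.null(annB)) species$B <- annB
  stopifnot(length(species) > 0)
  rows <- list()
  summ <- list()
  for (sp in names(species)) {
    ann <- species[[sp]]
    stopifnot(inherits(ann, "annotation_set"))
    if (length(ann$background) == 0) {
      stop("annotation background for species ", sp, " is empty")
    }
    term_nodes <- invert_mapping(ann$mapping)
    side <- if (sp == "A") 1L else 2L
    n_enriched_comp <- 0L
    enriched_terms <- character()
    for (ci in seq_along(components)) {
      proj <- unique(vapply(strsplit(components[[ci]], "|", fixed = TRUE),
                            `[[`, "", side))
      proj <- intersect(proj, ann$background)
      if (length(proj) == 0) next
      terms <- unique(unlist(ann$mapping[proj], use.names = FALSE))
      if (length(terms) == 0) next
      N <- length(ann$background)
      comp_enriched <- FALSE
      for (tm in terms) {
        K <- length(term_nodes[[tm]])
        k <- length(intersect(proj, term_nodes[[tm]]))
        p <- stats::phyper(k - 1, K, N - K, length(proj), lower.tail = FALSE)
        if (bonferroni) p <- min(1, p * length(terms))
        enr <- p <= threshold
        if (enr) {
          comp_enriched <- TRUE
          enriched_terms <- c(enriched_terms, tm)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          component = ci, species = sp, term = tm, k = k, K = K,
          draw = length(proj), background = N, p_value = p, enriched = enr)
      }
      if (comp_enriched) n_enriched_comp <- n_enriched_comp + 1L
    }
    summ[[sp]] <- tibble::tibble(
      species = sp,
      n_components = length(components),
      n_enriched = n_enriched_comp,
      tnr = if (length(components) > 0) {
        100 * n_enriched_comp / length(components)
      } else NA_real_,
      tpr = length(unique(enriched_terms)))
  }
  structure(list(
    terms = if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
      component = integer(), species = character(), term = character(),
      k = integer(), K = integer(), draw = integer(), background = integer(),
      p_value = numeric(), enriched = logical()),
    summary = dplyr::bind_rows(summ),
    threshold = threshold),
    class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report>  threshold", x$threshold, "\n")
  print(x$summary)
  invisible(x)
}

invert_mapping <- function(mapping) {
  node <- rep(names(mapping), lengths(mapping))
  term <- unlist(mapping, use.names = FALSE)
  lapply(split(node, term), unique)
}

#' Full topological and biological assessment of a matching
#'
#' Bundles the alignment-graph construction with its topological summary
#' (conserved edges, component sizes) and, when annotations are supplied,
#' the per-species enrichment summary of [enrich_components()].
#'
#' @param matching a `net_matching` on `netA` x `netB`.
#' @param netA,netB the aligned networks.
#' @param annA,annB optional [annotation_set()]s; when both are `NULL` only
#'   the topological section is produced.
#' @param threshold enrichment p-value threshold (default 0.05).
#' @return an `alignment_assessment`: list with `alignment_graph`,
#'   `topology` (one-row tibble: pairs, conserved edges, components,
#'   largest component, singletons), `component_sizes` (tibble), and
#'   `enrichment` (an `enrichment_report` or `NULL`).
#' @export
assessment_report <- function(matching, netA, netB, annA = NULL,
                              annB = NULL, threshold = 0.05) {
  ag <- build_alignment_graph(matching, netA, netB)
  comps <- alignment_components(ag)
  sizes <- lengths(comps)
  topology <- tibble::tibble(
    n_pairs = nrow(ag$pairs),
    conserved_edges = conserved_edge_count(ag),
    n_components = length(comps),
    largest_component = if (length(sizes)) max(sizes) else 0L,
    n_singletons = sum(sizes == 1L))
  enr <- NULL
  if (!is.null(annA) || !is.null(annB)) {
    enr <- enrich_components(comps, annA, annB, threshold = threshold)
  }
  structure(list(alignment_graph = ag,
                 topology = topology,
                 component_sizes = tibble::tibble(
                   component = seq_along(sizes), size = as.integer(sizes)),
                 enrichment = enr),
            class = "alignment_assessment")
}

#' @export
print.alignment_assessment <- function(x, ...) {
  cat("<alignment_assessment>\n")
  print(x$topology)
  if (!is.null(x$enrichment)) print(x$enrichment$summary)
  invisible(x)
}
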