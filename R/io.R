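#' Read an undirected network from a tab-delimited edge list
#'
#' Each non-comment line holds at least two tab-separated fields naming the
#' two endpoints of an edge. Lines starting with `#` and blank lines are
#' ignored. The file encodes an undirected network: both orientations of a
#' pair collapse to one edge, duplicate edges are merged, and self-loops are
#' dropped with a warning. Nodes are kept in first-appearance order.
#'
#' @param path path to the edge-list file.
#' @param name identifier for the returned network.
#' @return a [as_ppi_net()] object.
#' @export
read_edge_list <- function(path, name = basename(path)) {
  lines <- read_data_lines(path)
  iso <- sub("^\\s*#\\s*node\\s+", "", grep("^\\s*#\\s*node\\s+\\S",
                                            lines$comments, value = TRUE))
  if (length(lines$text) == 0L && length(iso) == 0L) {
    stop("empty edge list: ", path)
  }
  parts <- strsplit(lines$text, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge-list line %d in %s: need >= 2 tab-separated fields",
                 lines$lineno[bad[1]], path))
  }
  edges <- tibble::tibble(from = vapply(parts, `[[`, "", 1L),
                          to   = vapply(parts, `[[`, "", 2L))
  as_ppi_net(edges, name = name, isolated = iso)
}

#' Read elemental node-pair similarity scores
#'
#' Reads tab-separated triples `nodeA<TAB>nodeB<TAB>score` (e.g.
#' BLAST-derived sequence similarities) into the elemental similarity
#' matrix H, with rows indexed by `netA`'s nodes and columns by `netB`'s.
#' Pairs not listed score 0; a pair listed more than once keeps its maximum
#' score (conservative for multi-HSP BLAST inputs).
#'
#' @param path path to the triples file.
#' @param netA,netB the two networks the scores refer to.
#' @param missing_policy what to do with a line naming a node absent from
#'   the networks: `"error"` (default) or `"skip"` with a warning.
#' @return a dense numeric matrix of non-negative scores, `netA$n` rows by
#'   `netB$n` columns, with dimnames set to the node labels.
#' @export
read_similarity_triples <- function(path, netA, netB,
                                    missing_policy = c("error", "skip")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(netA, "ppi_net"), inherits(netB, "ppi_net"))
  lines <- read_data_lines(path)
  H <- matrix(0, netA$n, netB$n, dimnames = list(netA$nodes, netB$nodes))
  if (length(lines$text) > 0L) {
    parts <- strsplit(lines$text, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) < 3L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed similarity line %d in %s: need nodeA<TAB>nodeB<TAB>score",
                   lines$lineno[bad[1]], path))
    }
    a <- vapply(parts, `[[`, "", 1L)
    b <- vapply(parts, `[[`, "", 2L)
    s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(s)) {
      stop(sprintf("non-numeric score on line %d in %s",
                   lines$lineno[which(is.na(s))[1]], path))
    }
    if (any(s < 0)) {
      stop(sprintf("negative score on line %d in %s",
                   lines$lineno[which(s < 0)[1]], path))
    }
    i <- match(a, netA$nodes)
    j <- match(b, netB$nodes)
    miss <- is.na(i) | is.na(j)
    if (any(miss)) {
      if (missing_policy == "error") {
        stop(sprintf("line %d in %s names a node absent from the networks",
                     lines$lineno[which(miss)[1]], path))
      }
      warning(sprintf("skipping %d similarity line(s) naming unknown nodes",
                      sum(miss)), call. = FALSE)
      i <- i[!miss]; j <- j[!miss]; s <- s[!miss]
    }
    for (k in seq_along(i)) {
      H[i[k], j[k]] <- max(H[i[k], j[k]], s[k])
    }
  }
  if (all(H == 0)) {
    stop("all-zero elemental similarity: at least one positive score is required")
  }
  H
}

#' Read a node-to-term annotation map
#'
#' Two tab-separated columns, one `node<TAB>term` pair per line. Terms are
#' aggregated per node; the background is the set of all nodes appearing in
#' the file.
#'
#' @param path path to the annotation file.
#' @return an `annotation_set`: a list with `mapping` (named list of unique
#'   character term vectors) and `background` (character vector).
#' @export
read_annotations <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    warning("empty annotation file: ", path, call. = FALSE)
    return(annotation_set(list()))
  }
  parts <- strsplit(lines$text, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed annotation line %d in %s: need node<TAB>term",
                 lines$lineno[bad[1]], path))
  }
  node <- vapply(parts, `[[`, "", 1L)
  term <- vapply(parts, `[[`, "", 2L)
  mapping <- lapply(split(term, node), unique)
  annotation_set(mapping)
}

#' Construct an annotation set from a mapping
#'
#' @param mapping named list: node label -> character vector of term ids.
#' @param background optional background of annotated node labels; defaults
#'   to (and must contain) the mapping's names.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(mapping, background = names(mapping)) {
  mapping <- mapping[lengths(mapping) > 0L]
  background <- unique(as.character(background))
  if (!all(names(mapping) %in% background)) {
    stop("background must contain every annotated node")
  }
  structure(list(mapping = mapping, background = background),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set>  %d annotated nodes, %d terms, background %d\n",
              length(x$mapping), length(unique(unlist(x$mapping))),
              length(x$background)))
  invisible(x)
}

#' Write a matching to a tab-separated file
#'
#' Writes `nodeA<TAB>nodeB<TAB>score` lines, sorted by descending score and
#' then lexicographically by labels, preceded by one `#` header comment
#' recording the matcher and its parameters. Byte output is deterministic
#' for a fixed matching.
#'
#' @param matching a matching tibble from one of the matchers (see
#'   [greedy_match()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matching <- function(matching, path) {
  stopifnot(inherits(matching, "net_matching"))
  prov <- attr(matching, "params")
  header <- sprintf("# netalignr matching\tmethod=%s%s\tweight=%.10g",
                    attr(matching, "method"),
                    if (length(prov)) paste0("\t", paste(names(prov), unlist(prov),
                                                         sep = "=", collapse = "\t"))
                    else "",
                    attr(matching, "weight"))
  m <- dplyr::arrange(tibble::as_tibble(matching),
                      dplyr::desc(.data$score), .data$node_a, .data$node_b)
  body <- sprintf("%s\t%s\t%.10g", m$node_a, m$node_b, m$score)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a matching written by [write_matching()]
#'
#' @param path file path.
#' @return a tibble with columns `node_a`, `node_b`, `score`.
#' @export
read_matching <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(tibble::tibble(node_a = character(), node_b = character(),
                          score = numeric()))
  }
  parts <- strsplit(lines$text, "\t", fixed = TRUE)
  tibble::tibble(node_a = vapply(parts, `[[`, "", 1L),
                 node_b = vapply(parts, `[[`, "", 2L),
                 score  = as.numeric(vapply(parts, `[[`, "", 3L)))
}

#' Write a network as a tab-delimited edge list
#'
#' Inverse of [read_edge_list()]; isolated nodes are recorded as
#' `# node <label>` comments so a round trip preserves the node set.
#' @param net a `ppi_net`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  e <- network_edges(net)
  iso <- setdiff(net$nodes, unique(c(e$from, e$to)))
  writeLines(c(sprintf("# network %s", net$name),
               sprintf("# node %s", iso),
               sprintf("%s\t%s", e$from, e$to)), path)
  invisible(path)
}

# Shared line reader: drops blank and "# ..." comment lines, keeps original
# line numbers for error messages. "# node <label>" comments are honoured by
# read_edge_list callers through read_isolated_comments().
read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(text = raw[keep], lineno = which(keep),
       comments = raw[grepl("^\\s*#", raw)])
}
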