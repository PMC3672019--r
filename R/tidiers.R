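#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a matching into a plain tibble of pairs
#'
#' @param x a `net_matching`.
#' @param ... unused.
#' @return tibble with columns `node_a`, `node_b`, `score`.
#' @export
tidy.net_matching <- function(x, ...) {
  tibble::tibble(node_a = x$node_a, node_b = x$node_b, score = x$score)
}

#' One-row summary of a matching
#'
#' @param x a `net_matching`.
#' @param ... unused.
#' @return tibble with `method`, `n_pairs`, `weight`.
#' @export
glance.net_matching <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), n_pairs = nrow(x),
                 weight = attr(x, "weight"))
}

#' Tidy a similarity matrix into long node-pair form
#'
#' @param x an `isorank_sim` matrix.
#' @param ... unused.
#' @return tibble with `node_a`, `node_b`, `score`, one row per pair.
#' @export
tidy.isorank_sim <- function(x, ...) {
  m <- as_score_matrix(x)
  tibble::tibble(node_a = rep(rownames(m), ncol(m)),
                 node_b = rep(colnames(m), each = nrow(m)),
                 score = as.vector(m))
}

#' One-row summary of a similarity computation
#' @param x an `isorank_sim`.
#' @param ... unused.
#' @return tibble with dimensions, `alpha`, `iterations`, total mass.
#' @export
glance.isorank_sim <- function(x, ...) {
  tibble::tibble(n_a = nrow(x), n_b = ncol(x), alpha = attr(x, "alpha"),
                 iterations = attr(x, "iterations"),
                 total = sum(as_score_matrix(x)))
}

#' Tidy an assessment into its per-component table
#'
#' @param x an `alignment_assessment`.
#' @param ... unused.
#' @return tibble of component sizes, joined with per-species enrichment
#'   term counts when enrichment was computed.
#' @export
tidy.alignment_assessment <- function(x, ...) {
  out <- x$component_sizes
  if (!is.null(x$enrichment) && nrow(x$enrichment$terms) > 0) {
    hits <- dplyr::summarise(
      dplyr::group_by(x$enrichment$terms, .data$component, .data$species),
      n_terms = dplyr::n(), n_enriched = sum(.data$enriched),
      min_p = min(.data$p_value), .groups = "drop")
    out <- dplyr::left_join(out, hits, by = "component")
  }
  out
}

#' One-row-per-species summary of an assessment
#'
#' @param x an `alignment_assessment`.
#' @param ... unused.
#' @return the topology summary, crossed with per-species TPR/TNR when
#'   enrichment was computed.
#' @export
glance.alignment_assessment <- function(x, ...) {
  if (is.null(x$enrichment)) return(x$topology)
  dplyr::bind_cols(
    x$topology[rep(1, nrow(x$enrichment$summary)), ],
    dplyr::select(x$enrichment$summary, -"n_components"))
}

#' @export
tidy.net_alignment <- function(x, ...) tidy(x$matching, ...)

#' @export
glance.net_alignment <- function(x, ...) {
  dplyr::bind_cols(glance(x$matching),
                   dplyr::select(x$assessment$topology, -"n_pairs"))
}
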