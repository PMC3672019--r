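#' Align two networks end to end
#'
#' Chains the full pipeline: diffusion similarity ([isorank_iterate()]),
#' matching extraction ([greedy_match()], [auction_match()] or
#' [adaptive_auction_match()]), and assessment ([assessment_report()]).
#'
#' @param netA,netB the networks to align (`ppi_net`).
#' @param H elemental similarity matrix (`netA$n` by `netB$n`).
#' @param alpha diffusion blending weight (default 0.8).
#' @param iterations diffusion iterations (default 20).
#' @param matcher one of `"adaptive-auction"` (default), `"greedy"`,
#'   `"auction"`.
#' @param annA,annB optional [annotation_set()]s for enrichment assessment.
#' @param threshold enrichment p-value threshold (default 0.05).
#' @param epsilon,epsilon0,growth,delta,scale matcher parameters, passed to
#'   the selected matcher; `NULL` uses its documented default.
#' @return a `net_alignment`: list with `similarity` (`isorank_sim`),
#'   `matching` (`net_matching`) and `assessment`
#'   (`alignment_assessment`).
#' @export
align_networks <- function(netA, netB, H, alpha = 0.8, iterations = 20,
                           matcher = c("adaptive-auction", "greedy",
                                       "auction"),
                           annA = NULL, annB = NULL, threshold = 0.05,
                           epsilon = NULL, epsilon0 = NULL, growth = 4,
                           delta = NULL, scale = 1e6) {
  matcher <- match.arg(matcher)
  X <- isorank_iterate(netA, netB, H, alpha = alpha, iterations = iterations)
  matching <- switch(matcher,
    "greedy" = greedy_match(X),
    "auction" = auction_match(X, epsilon = epsilon, scale = scale),
    "adaptive-auction" = adaptive_auction_match(
      X, epsilon0 = epsilon0, growth = growth, delta = delta, scale = scale))
  assessment <- assessment_report(matching, netA, netB, annA, annB,
                                  threshold = threshold)
  structure(list(similarity = X, matching = matching,
                 assessment = assessment,
                 config = list(alpha = alpha, iterations = iterations,
                               matcher = matcher, threshold = threshold)),
            class = "net_alignment")
}

#' @export
print.net_alignment <- function(x, ...) {
  cat(sprintf("<net_alignment>  matcher=%s, alpha=%g, %d iterations\n",
              x$config$matcher, x$config$alpha, x$config$iterations))
  cat(sprintf("  %d matched pairs, weight %.6g\n", nrow(x$matching),
              matching_weight(x$matching)))
  print(x$assessment$topology)
  invisible(x)
}

#' Run an alignment from input files and write its outputs
#'
#' File-level front end: reads the edge lists, similarity triples and
#' optional annotations, runs [align_networks()], and writes the matching,
#' the alignment-graph edge list, the assessment tables and a JSON run
#' manifest into `out_dir`. For fixed inputs and configuration the
#' matching file is byte-identical across runs.
#'
#' @param net_a,net_b paths to the two edge-list files.
#' @param similarity path to the elemental similarity triples file.
#' @param ann_a,ann_b optional paths to annotation files.
#' @param out_dir output directory (created if missing).
#' @param missing_policy passed to [read_similarity_triples()].
#' @param ... further arguments for [align_networks()].
#' @return invisibly, a named list of written file paths plus the
#'   `net_alignment` object (`$result`).
#' @export
run_alignment <- function(net_a, net_b, similarity, ann_a = NULL,
                          ann_b = NULL, out_dir = ".",
                          missing_policy = "skip", ...) {
  netA <- read_edge_list(net_a, name = "netA")
  netB <- read_edge_list(net_b, name = "netB")
  H <- read_similarity_triples(similarity, netA, netB,
                               missing_policy = missing_policy)
  annA <- if (!is.null(ann_a)) read_annotations(ann_a)
  annB <- if (!is.null(ann_b)) read_annotations(ann_b)
  res <- align_networks(netA, netB, H, annA = annA, annB = annB, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    matching = file.path(out_dir, "matching.tsv"),
    alignment_graph = file.path(out_dir, "alignment_graph.tsv"),
    topology = file.path(out_dir, "topology.tsv"),
    components = file.path(out_dir, "components.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_matching(res$matching, paths$matching)
  ag <- res$assessment$alignment_graph
  el <- igraph::as_edgelist(ag$graph)
  writeLines(c("# alignment-graph conserved edges: pair1<TAB>pair2",
               sprintf("%s\t%s", el[, 1], el[, 2])),
             paths$alignment_graph)
  utils::write.table(res$assessment$topology, paths$topology, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$assessment$component_sizes, paths$components,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$assessment$enrichment)) {
    paths$enrichment_terms <- file.path(out_dir, "enrichment_terms.tsv")
    paths$enrichment_summary <- file.path(out_dir, "enrichment_summary.tsv")
    utils::write.table(res$assessment$enrichment$terms,
                       paths$enrichment_terms, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(res$assessment$enrichment$summary,
                       paths$enrichment_summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  manifest <- c(res$config,
                list(inputs = list(net_a = net_a, net_b = net_b,
                                   similarity = similarity),
                     package_version = as.character(
                       utils::packageVersion("netalignr")),
                     timestamp = format(Sys.time(), tz = "UTC")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, list(result = res)))
}

#' Write a synthetic planted instance to disk
#'
#' Generates a [generate_pair()] instance (plus elemental similarities and
#' planted annotations) and writes it in the package's input formats, so
#' synthetic instances are indistinguishable from real inputs to
#' [run_alignment()]. A `truth.tsv` file records the planted
#' correspondence.
#'
#' @param out_dir output directory.
#' @param n,edge_prob,rewire_frac,extra_nodes see [generate_pair()].
#' @param true_score,noise_pairs,noise_score_max see [generate_elemental()].
#' @param n_terms,module_size see [generate_annotations()].
#' @param seed integer seed controlling the whole instance.
#' @return invisibly, a named list of written file paths plus the
#'   `planted_instance` (`$instance`).
#' @export
simulate_instance <- function(out_dir, n = 50, edge_prob = 0.1,
                              rewire_frac = 0, extra_nodes = 5,
                              true_score = 1, noise_pairs = 0,
                              noise_score_max = 0, n_terms = 3,
                              module_size = 4, seed = 1L) {
  inst <- generate_pair(n, edge_prob, rewire_frac, extra_nodes, seed = seed)
  H <- generate_elemental(inst, true_score, noise_pairs, noise_score_max,
                          seed = seed + 1L)
  ann <- generate_annotations(inst, n_terms, module_size, seed = seed + 2L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(net_a = file.path(out_dir, "netA.tsv"),
                net_b = file.path(out_dir, "netB.tsv"),
                similarity = file.path(out_dir, "similarity.tsv"),
                ann_a = file.path(out_dir, "annA.tsv"),
                ann_b = file.path(out_dir, "annB.tsv"),
                truth = file.path(out_dir, "truth.tsv"))
  write_edge_list(inst$netA, paths$net_a)
  write_edge_list(inst$netB, paths$net_b)
  nz <- which(H > 0, arr.ind = TRUE, useNames = FALSE)
  writeLines(c("# elemental similarity triples",
               sprintf("%s\t%s\t%.10g", rownames(H)[nz[, 1]],
                       colnames(H)[nz[, 2]], H[nz])),
             paths$similarity)
  write_annotation_file <- function(ann_set, path) {
    node <- rep(names(ann_set$mapping), lengths(ann_set$mapping))
    term <- unlist(ann_set$mapping, use.names = FALSE)
    writeLines(c("# node<TAB>term annotations",
                 sprintf("%s\t%s", node, term)), path)
  }
  write_annotation_file(ann$annA, paths$ann_a)
  write_annotation_file(ann$annB, paths$ann_b)
  writeLines(c("# planted correspondence",
               sprintf("%s\t%s", inst$truth$node_a, inst$truth$node_b)),
             paths$truth)
  invisible(c(paths, list(instance = inst)))
}
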