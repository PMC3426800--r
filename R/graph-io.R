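#' Write and read concept graphs
#'
#' Two formats are supported. `"tsv"` writes a diff-friendly edge list with
#' columns `cui_u`, `cui_v`, `weight`, `relation_label`, `source` (weights
#' in full-precision decimal so round trips are bit-exact), plus a
#' `<path>.nodes.tsv` sidecar listing every node with its BFS depth and the
#' seed flag — isolated nodes would otherwise be lost. `"graphml"` writes a
#' single self-contained GraphML document carrying the same node and edge
#' attributes. Writing then reading either format reproduces the graph
#' exactly.
#'
#' @param graph A `concept_graph`.
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_concept_graph <- function(graph, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- graph$edges
    out <- tibble(
      cui_u = edges$u, cui_v = edges$v,
      weight = format_weight(edges$weight),
      relation_label = ifelse(is.na(edges$relation), "", edges$relation),
      source = ifelse(is.na(edges$source), "", edges$source)
    )
    write_atomically(path, function(tmp) readr::write_tsv(out, tmp))
    nodes <- tibble(
      cui = graph$nodes$cui, depth = graph$nodes$depth,
      is_seed = as.integer(graph$nodes$cui == graph$seed)
    )
    write_atomically(paste0(path, ".nodes.tsv"), function(tmp) readr::write_tsv(nodes, tmp))
  } else {
    ig <- as_igraph(graph)
    igraph::E(ig)$relation <- ifelse(is.na(igraph::E(ig)$relation), "", igraph::E(ig)$relation)
    igraph::E(ig)$source <- ifelse(is.na(igraph::E(ig)$source), "", igraph::E(ig)$source)
    ig <- igraph::set_graph_attr(ig, "seed", graph$seed)
    write_atomically(path, function(tmp) igraph::write_graph(ig, tmp, format = "graphml"))
  }
  invisible(path)
}

#' @rdname write_concept_graph
#' @return `read_concept_graph()` returns a `concept_graph`.
#' @export
read_concept_graph <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- read_tsv_strict(path, c("cui_u", "cui_v", "weight", "relation_label", "source"))
    nodes_path <- paste0(path, ".nodes.tsv")
    if (!file.exists(nodes_path)) {
      abort(sprintf("Node sidecar '%s' not found.", nodes_path))
    }
    nodes <- read_tsv_strict(nodes_path, c("cui", "depth", "is_seed"))
    seed <- nodes$cui[nodes$is_seed == "1"]
    if (length(seed) != 1) abort("Node sidecar must flag exactly one seed.")
    concept_graph(
      seed,
      nodes = tibble(cui = nodes$cui, depth = as.integer(nodes$depth)),
      edges = tibble(
        u = edges$cui_u, v = edges$cui_v, weight = as.numeric(edges$weight),
        relation = ifelse(edges$relation_label == "", NA_character_, edges$relation_label),
        source = ifelse(edges$source == "", NA_character_, edges$source)
      )
    )
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    seed <- igraph::graph_attr(ig, "seed")
    nodes <- tibble(
      cui = igraph::V(ig)$name,
      depth = as.integer(igraph::V(ig)$depth)
    )
    ed <- igraph::as_data_frame(ig, what = "edges")
    edges <- tibble(
      u = ed$from, v = ed$to, weight = as.numeric(ed$weight),
      relation = if (nrow(ed) > 0) ifelse(ed$relation == "", NA_character_, ed$relation) else character(),
      source = if (nrow(ed) > 0) ifelse(ed$source == "", NA_character_, ed$source) else character()
    )
    concept_graph(seed, nodes = nodes, edges = edges)
  }
}
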