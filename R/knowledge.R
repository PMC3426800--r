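#' Knowledge-base curation of nearest-neighbor graphs
#'
#' Distributional similarity is noisy: a high cosine says two concepts share
#' contexts, not that they are clinically related. The knowledge filter
#' keeps a graph edge only if *some* relation between its endpoints exists
#' in a curated thesaurus (UMLS Metathesaurus shape) or in
#' literature-mined predications (SemRep shape), regardless of the
#' relation's direction or type, and labels the survivor with the relation
#' name. Thesaurus labels are rendered with the prefix `UMLS:`; literature
#' labels are bare.
#'
#' @name knowledge-filter
NULL

#' Index a triple table for symmetric pair lookup
#'
#' @param triples Tibble of relation triples (see [knowledge_triples()]).
#'   Self-relations (subject equal to object) are ignored by lookups.
#' @return A `knowledge_base` object with a pair index.
#' @export
knowledge_base <- function(triples) {
  triples <- knowledge_triples(triples)
  usable <- triples[triples$subject != triples$object, , drop = FALSE]
  index <- tibble(
    key = pair_key(usable$subject, usable$object),
    predicate = usable$predicate,
    source = usable$source
  )
  structure(list(triples = triples, index = index), class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(
    "<knowledge_base> %d triples (%d THESAURUS, %d LITERATURE)\n",
    nrow(x$triples),
    sum(x$triples$source == "THESAURUS"),
    sum(x$triples$source == "LITERATURE")
  ))
  invisible(x)
}

#' Look up a supporting relation for a concept pair
#'
#' The lookup is symmetric in `(u, v)`. When both sources support the pair,
#' the thesaurus relation takes precedence; within a source, the
#' lexicographically smallest predicate is chosen so output is
#' deterministic.
#'
#' @param kb A [knowledge_base()].
#' @param u,v Distinct CUIs.
#' @return One-row tibble (`relation`, `source`) — with the `UMLS:` prefix
#'   applied to thesaurus labels — or `NULL` if the pair is unsupported.
#' @export
validate_edge <- function(kb, u, v) {
  assert_scalar_string(u, "u")
  assert_scalar_string(v, "v")
  if (u == v) abort("`u` and `v` must be distinct concepts.")
  hits <- kb$index[kb$index$key == pair_key(u, v), , drop = FALSE]
  if (nrow(hits) == 0) return(NULL)
  pick_support(hits$predicate, hits$source)
}

pick_support <- function(predicate, source) {
  thesaurus <- source == "THESAURUS"
  if (any(thesaurus)) {
    label <- paste0("UMLS:", min(predicate[thesaurus]))
    src <- "THESAURUS"
  } else {
    label <- min(predicate)
    src <- "LITERATURE"
  }
  tibble(relation = label, source = src)
}

#' Remove graph edges unsupported by the knowledge base
#'
#' Every edge whose endpoint pair has no relation in either database is
#' deleted; surviving edges keep their cosine weight and gain the relation
#' label and source. All nodes are retained, even if the filter isolates
#' them — isolated concepts are excluded from inference only via
#' [active_subgraph()].
#'
#' @param graph A `concept_graph`.
#' @param kb A [knowledge_base()].
#' @param verbose If `TRUE`, print a kept/removed audit line per edge.
#' @return The filtered `concept_graph`.
#' @export
filter_graph <- function(graph, kb, verbose = FALSE) {
  edges <- graph$edges
  if (nrow(edges) == 0) return(graph)
  if (nrow(kb$index) == 0) {
    if (verbose) {
      for (i in seq_len(nrow(edges))) {
        message(sprintf("removed %s -- %s (no supporting relation)", edges$u[i], edges$v[i]))
      }
    }
    return(concept_graph(graph$seed, graph$nodes, empty_edges()))
  }
  keys <- pair_key(edges$u, edges$v)
  support <- kb$index |>
    group_by(.data$key) |>
    summarise(support = list(pick_support(.data$predicate, .data$source))) |>
    tidyr::unnest("support")
  hit <- match(keys, support$key)
  keep <- !is.na(hit)
  if (verbose) {
    for (i in seq_along(keep)) {
      if (keep[i]) {
        message(sprintf(
          "kept    %s -- %s (%s, %s)",
          edges$u[i], edges$v[i], support$relation[hit[i]], support$source[hit[i]]
        ))
      } else {
        message(sprintf("removed %s -- %s (no supporting relation)", edges$u[i], edges$v[i]))
      }
    }
  }
  out <- edges[keep, , drop = FALSE]
  out$relation <- support$relation[hit[keep]]
  out$source <- support$source[hit[keep]]
  concept_graph(graph$seed, graph$nodes, out)
}

#' Restrict a graph to the connected component containing the seed
#'
#' Concepts disconnected from the seed cannot exchange activation with it
#' and are dropped along with their edges.
#'
#' @param graph A `concept_graph`.
#' @return The seed-component `concept_graph`.
#' @export
active_subgraph <- function(graph) {
  ig <- as_igraph(graph)
  comp <- igraph::components(ig)
  members <- names(comp$membership)[comp$membership == comp$membership[graph$seed]]
  nodes <- graph$nodes[graph$nodes$cui %in% members, , drop = FALSE]
  edges <- graph$edges[graph$edges$u %in% members & graph$edges$v %in% members, , drop = FALSE]
  concept_graph(graph$seed, nodes, edges)
}
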