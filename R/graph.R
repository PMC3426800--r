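#' Weighted concept graphs around a seed phenotype concept
#'
#' A `concept_graph` holds the neighborhood of a seed CUI discovered by
#' breadth-first expansion over a semantic vector store: a node table
#' (`cui`, `depth` = BFS level, seed at depth 0) and an undirected edge
#' table (`u`, `v`, `weight` = cosine at build time, plus `relation` and
#' `source` labels filled in by the knowledge filter). There is at most one
#' edge per unordered pair and no self-loops.
#'
#' @name concept-graph
NULL

new_concept_graph <- function(seed, nodes, edges) {
  structure(
    list(seed = seed, nodes = nodes, edges = edges),
    class = "concept_graph"
  )
}

#' Construct a concept graph from node and edge tables
#'
#' @param seed Seed CUI; must appear in `nodes` at depth 0.
#' @param nodes Data frame with columns `cui` and `depth`.
#' @param edges Data frame with columns `u`, `v`, `weight` and optionally
#'   `relation`, `source`.
#' @return A validated `concept_graph`.
#' @export
concept_graph <- function(seed, nodes, edges) {
  assert_scalar_string(seed, "seed")
  nodes <- as_tibble(nodes)
  if (!all(c("cui", "depth") %in% names(nodes))) {
    abort("`nodes` needs columns `cui` and `depth`.")
  }
  nodes$cui <- as.character(nodes$cui)
  nodes$depth <- as.integer(nodes$depth)
  if (anyDuplicated(nodes$cui)) abort("Duplicate node CUIs.")
  if (!seed %in% nodes$cui || nodes$depth[match(seed, nodes$cui)] != 0L) {
    abort("The seed must be a node at depth 0.")
  }
  edges <- as_tibble(edges)
  if (nrow(edges) == 0 && !all(c("u", "v", "weight") %in% names(edges))) {
    edges <- empty_edges()
  }
  if (!all(c("u", "v", "weight") %in% names(edges))) {
    abort("`edges` needs columns `u`, `v`, `weight`.")
  }
  if (!"relation" %in% names(edges)) edges$relation <- NA_character_
  if (!"source" %in% names(edges)) edges$source <- NA_character_
  edges <- edges[c("u", "v", "weight", "relation", "source")]
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  edges$weight <- as.numeric(edges$weight)
  if (nrow(edges) > 0) {
    if (any(edges$u == edges$v)) abort("Self-loop edges are not allowed.")
    if (!all(c(edges$u, edges$v) %in% nodes$cui)) {
      abort("Every edge endpoint must be a node.")
    }
    key <- pair_key(edges$u, edges$v)
    if (anyDuplicated(key)) abort("At most one edge per unordered pair.")
  }
  new_concept_graph(seed, nodes, edges)
}

empty_edges <- function() {
  tibble(
    u = character(), v = character(), weight = numeric(),
    relation = character(), source = character()
  )
}

pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\x1f")
}

#' Grow a nearest-neighbor concept graph by capped breadth-first search
#'
#' Starting from the seed at level 0, each frontier concept (in insertion
#' order) queries its `branching` nearest neighbors by semantic-vector
#' cosine. Neighbors below `min_cosine` are dropped; a neighbor already in
#' the graph is not added again (and, by default, contributes no extra
#' edge); new neighbors join the next level with an edge weighted by the
#' cosine. Expansion stops after `max_depth` levels, so the node count is
#' bounded by `bfs_node_bound(branching, max_depth)` — with the defaults
#' (6 neighbors, 3 levels) at most 1 + 6 + 36 + 216 = 259 concepts.
#'
#' @param store A `semantic_vectors` object.
#' @param seed Seed CUI, present in the store.
#' @param branching Maximum neighbors added per expanded concept (default 6).
#' @param max_depth Maximum number of expansion levels (default 3).
#' @param min_cosine Minimum cosine for a neighbor to be considered
#'   (default 0, excluding anti-correlated concepts).
#' @param cross_edges If `TRUE`, a queried neighbor that is already in the
#'   graph still gains an edge to the expanding concept (the node is never
#'   duplicated). Default `FALSE`, keeping the near-tree structure.
#' @return A `concept_graph`.
#' @export
build_bfs_graph <- function(store, seed, branching = 6, max_depth = 3,
                            min_cosine = 0, cross_edges = FALSE) {
  assert_scalar_string(seed, "seed")
  branching <- assert_count(branching, "branching", min = 1L)
  max_depth <- assert_count(max_depth, "max_depth", min = 0L)
  if (!seed %in% rownames(store$vectors)) {
    abort(sprintf("Seed CUI '%s' is not in the vector store.", seed))
  }

  nodes <- character()
  depth <- integer()
  add_node <- function(cui, d) {
    nodes[[length(nodes) + 1L]] <<- cui
    depth[[length(depth) + 1L]] <<- d
  }
  add_node(seed, 0L)
  edges_u <- character(); edges_v <- character(); edges_w <- numeric()
  frontier <- seed

  for (level in seq_len(max_depth)) {
    next_frontier <- character()
    for (u in frontier) {
      nn <- nearest_neighbors(store, u, k = branching)
      nn <- nn[nn$cosine >= min_cosine, , drop = FALSE]
      for (i in seq_len(nrow(nn))) {
        v <- nn$cui[i]
        if (v %in% nodes) {
          if (cross_edges && !pair_key(u, v) %in% pair_key(edges_u, edges_v)) {
            edges_u <- c(edges_u, u); edges_v <- c(edges_v, v)
            edges_w <- c(edges_w, nn$cosine[i])
          }
          next
        }
        add_node(v, level)
        edges_u <- c(edges_u, u); edges_v <- c(edges_v, v)
        edges_w <- c(edges_w, nn$cosine[i])
        next_frontier <- c(next_frontier, v)
      }
    }
    frontier <- next_frontier
    if (length(frontier) == 0) break
  }

  concept_graph(
    seed,
    nodes = tibble(cui = nodes, depth = depth),
    edges = tibble(
      u = edges_u, v = edges_v, weight = edges_w,
      relation = NA_character_, source = NA_character_
    )
  )
}

#' BFS level capacity and total node bound
#'
#' With branching factor `b`, level `l` of the expansion can add at most
#' `b^l` concepts, and a graph expanded for `d` levels holds at most
#' `1 + b + b^2 + ... + b^d` nodes.
#'
#' @param branching Branching factor.
#' @param level,max_depth Level index / number of levels.
#' @return A count.
#' @examples
#' bfs_level_capacity(6, 2) # 36
#' bfs_node_bound(6, 3)     # 259
#' @export
bfs_level_capacity <- function(branching, level) {
  branching <- assert_count(branching, "branching", min = 1L)
  level <- assert_count(level, "level", min = 0L)
  branching^level
}

#' @rdname bfs_level_capacity
#' @export
bfs_node_bound <- function(branching, max_depth) {
  max_depth <- assert_count(max_depth, "max_depth", min = 0L)
  sum(vapply(0:max_depth, function(l) bfs_level_capacity(branching, l), numeric(1)))
}

#' Convert a concept graph to an igraph object
#'
#' @param graph A `concept_graph`.
#' @return An undirected [igraph::graph] with node attribute `depth` and
#'   edge attributes `weight`, `relation`, `source`.
#' @export
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    d = graph$edges,
    directed = FALSE,
    vertices = graph$nodes
  )
  g
}

#' Node, edge and seed-component counts of a concept graph
#'
#' Components are computed on the undirected edge set; the seed component is
#' the connected component containing the seed concept.
#'
#' @param graph A `concept_graph`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `seed_component_nodes`,
#'   `seed_component_edges`.
#' @export
graph_stats <- function(graph) {
  ig <- as_igraph(graph)
  comp <- igraph::components(ig)
  seed_comp <- comp$membership[graph$seed]
  members <- names(comp$membership)[comp$membership == seed_comp]
  sub <- igraph::induced_subgraph(ig, members)
  tibble(
    n_nodes = nrow(graph$nodes),
    n_edges = nrow(graph$edges),
    seed_component_nodes = length(members),
    seed_component_edges = igraph::ecount(sub)
  )
}

#' @export
print.concept_graph <- function(x, ...) {
  st <- graph_stats(x)
  cat(sprintf(
    "<concept_graph> seed %s: %d nodes, %d edges (seed component: %d nodes, %d edges)\n",
    x$seed, st$n_nodes, st$n_edges, st$seed_component_nodes, st$seed_component_edges
  ))
  invisible(x)
}

#' @method tidy concept_graph
#' @export
tidy.concept_graph <- function(x, ...) {
  left <- x$edges
  depth_of <- setNames(x$nodes$depth, x$nodes$cui)
  left$depth_u <- depth_of[left$u]
  left$depth_v <- depth_of[left$v]
  as_tibble(left)
}

#' @method glance concept_graph
#' @export
glance.concept_graph <- function(x, ...) {
  graph_stats(x)
}
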