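# Independent oracles and fixture builders. Everything here is written as a
# separate route from the package implementation: plain loops, dense matrix
# algebra, and hand arithmetic.

# --- cosine / k-NN ----------------------------------------------------------

brute_cosine <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  s <- 0
  for (i in seq_along(a)) s <- s + a[i] * b[i]
  s / (na * nb)
}

brute_knn <- function(store, cui, k, exclude = character()) {
  mat <- store$vectors
  q <- mat[cui, ]
  others <- setdiff(rownames(mat), c(cui, exclude))
  sims <- vapply(others, function(o) brute_cosine(q, mat[o, ]), numeric(1))
  ord <- order(-sims, others)
  data.frame(cui = others[ord], cosine = sims[ord])[seq_len(min(k, length(others))), ]
}

# --- BFS graph --------------------------------------------------------------

# Queue-based reimplementation using only brute_knn; returns node/edge tables.
brute_bfs <- function(store, seed, branching = 6, max_depth = 3, min_cosine = 0) {
  depth <- stats::setNames(0L, seed)
  edges <- data.frame(u = character(), v = character(), weight = numeric())
  queue <- seed
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    if (depth[[u]] >= max_depth) next
    nn <- brute_knn(store, u, branching)
    for (i in seq_len(nrow(nn))) {
      if (nn$cosine[i] < min_cosine) next
      v <- nn$cui[i]
      if (!v %in% names(depth)) {
        depth[[v]] <- depth[[u]] + 1L
        edges <- rbind(edges, data.frame(u = u, v = v, weight = nn$cosine[i]))
        queue <- c(queue, v)
      }
    }
  }
  list(
    nodes = data.frame(cui = names(depth), depth = as.integer(depth)),
    edges = edges
  )
}

# --- spreading activation ---------------------------------------------------

# Dense synchronous-update transition matrix; states are row vectors.
transition_matrix <- function(graph, retain = 0) {
  nodes <- graph$nodes$cui
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(graph$edges))) {
    u <- graph$edges$u[i]; v <- graph$edges$v[i]; w <- graph$edges$weight[i]
    W[u, v] <- W[u, v] + w
    W[v, u] <- W[v, u] + w
  }
  s <- rowSums(W)
  P <- diag(n)
  dimnames(P) <- dimnames(W)
  for (u in seq_len(n)) {
    if (s[u] > 0) {
      P[u, ] <- (1 - retain) * W[u, ] / s[u]
      P[u, u] <- retain
    }
  }
  P
}

oracle_spread <- function(graph, state, steps, retain = 0) {
  P <- transition_matrix(graph, retain)
  a <- stats::setNames(state$activation, state$cui)[rownames(P)]
  a <- matrix(a, nrow = 1)
  for (i in seq_len(steps)) a <- a %*% P
  tibble::tibble(cui = rownames(P), activation = as.numeric(a))
}

# --- connected components (union-find) --------------------------------------

uf_components <- function(nodes, edges_u, edges_v) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(edges_u)) {
    ru <- find(edges_u[i]); rv <- find(edges_v[i])
    if (ru != rv) parent[[ru]] <- rv
  }
  vapply(nodes, find, character(1))
}

# --- random fixtures --------------------------------------------------------

random_concept_graph <- function(n_nodes, edge_prob = 0.15, seed = 1) {
  withr::with_seed(seed, {
    cuis <- sprintf("C%07d", sample.int(9999999, n_nodes))
    pairs <- utils::combn(n_nodes, 2)
    keep <- stats::runif(ncol(pairs)) < edge_prob
    edges <- tibble::tibble(
      u = cuis[pairs[1, keep]],
      v = cuis[pairs[2, keep]],
      weight = stats::runif(sum(keep), 0.05, 1)
    )
    concept_graph(
      cuis[1],
      nodes = tibble::tibble(cui = cuis, depth = c(0L, rep(1L, n_nodes - 1))),
      edges = edges
    )
  })
}

random_state <- function(graph, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    cui = graph$nodes$cui,
    activation = stats::runif(nrow(graph$nodes), 0, 2)
  ))
}

# Small synthetic vector store: unit vectors over `dim` dimensions.
random_store <- function(n_concepts, dim = 16, seed = 1) {
  withr::with_seed(seed, {
    cuis <- sort(sprintf("C%07d", sample.int(9999999, n_concepts)))
    mat <- matrix(stats::rnorm(n_concepts * dim), n_concepts, dim)
    mat <- mat / sqrt(rowSums(mat^2))
    rownames(mat) <- cuis
    structure(list(vectors = mat, dim = dim), class = "semantic_vectors")
  })
}

# Hand-sized corpus used across I/O and embedding tests.
tiny_corpus <- function() {
  concept_corpus(tibble::tibble(
    patient_id = c("p1", "p1", "p1", "p2", "p2", "p2", "p2"),
    doc_id     = c("d1", "d1", "d2", "d1", "d1", "d2", "d3"),
    cui        = c("C0000001", "C0000002", "C0000001", "C0000002",
                   "C0000003", "C0000003", "C0000004"),
    confidence = c(1000L, 800L, 600L, 900L, 700L, 500L, 1000L)
  ))
}

# Topology fixture: a 14-node/14-edge seed component plus a separate 6-node,
# 4-edge piece -> 20 nodes, 18 edges overall.
topology_fixture <- function() {
  seed <- "C0006142"
  comp <- sprintf("C10000%02d", 1:13)     # 13 nodes + seed = 14
  far <- sprintf("C20000%02d", 1:6)       # disconnected piece
  nodes <- tibble::tibble(
    cui = c(seed, comp, far),
    depth = c(0L, rep(1L, 6), rep(2L, 7), rep(3L, 6))
  )
  edges <- tibble::tibble(
    u = c(rep(seed, 6), comp[1:7], far[1:4]),
    v = c(comp[1:6], comp[7:13], far[2:5]),
    weight = seq(0.95, by = -0.02, length.out = 17)
  )
  # one extra edge inside the seed component closes a cycle: 14 edges there
  edges <- rbind(edges, tibble::tibble(u = comp[2], v = comp[3], weight = 0.5))
  concept_graph(seed, nodes, edges)
}

# KB that supports exactly the 14 seed-component edges of topology_fixture().
topology_kb <- function() {
  g <- topology_fixture()
  comp_nodes <- c("C0006142", sprintf("C10000%02d", 1:13))
  keep <- g$edges$u %in% comp_nodes & g$edges$v %in% comp_nodes
  knowledge_triples(tibble::tibble(
    subject = g$edges$u[keep],
    predicate = "ASSOCIATED_WITH",
    object = g$edges$v[keep],
    source = rep(c("THESAURUS", "LITERATURE"), length.out = sum(keep))
  ))
}
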