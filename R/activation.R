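#' Spreading-activation phenotyping
#'
#' A patient's record is projected onto the curated concept graph: every
#' graph node starts at the sum of the normalized extraction confidences
#' (score / 1000) of that concept's mentions across all of the patient's
#' documents, 0 if never mentioned. Activation then spreads synchronously
#' along the weighted edges: at each step every connected node distributes
#' its activation to its neighbors in proportion to incident-edge weights
#' (optionally retaining a fraction), so total activation is conserved.
#' After a fixed number of steps (default 3) the activation of the seed
#' concept is read out; the patient is called positive when it exceeds the
#' decision threshold. The threshold is the method's key tuning knob: the
#' default 0 treats any activation reaching the seed as evidence.
#'
#' Inference runs on the seed's connected component plus isolated nodes;
#' concepts in other components cannot influence the seed and are ignored.
#'
#' @name activation
NULL

#' Map extraction confidence scores to \[0, 1\]
#'
#' @param score Integer score(s) in \[0, 1000\], as produced by an automated
#'   coder such as MetaMap.
#' @return `score / 1000`.
#' @export
normalize_confidence <- function(score) {
  if (any(is.na(score) | score < 0 | score > 1000)) {
    abort("Confidence scores must lie in [0, 1000].")
  }
  score / 1000
}

#' Initial activation of a graph from one patient's mentions
#'
#' @param graph A `concept_graph`.
#' @param patient Mention rows (`patient_id`, `doc_id`, `cui`, `confidence`)
#'   belonging to a single patient; a zero-row table gives the all-zero
#'   state.
#' @return Tibble (`cui`, `activation`) over all graph nodes, in node order:
#'   each node's activation is the sum of normalized confidences over every
#'   mention instance of that CUI in the patient's documents. Mentions of
#'   concepts outside the graph are ignored.
#' @export
initial_activation <- function(graph, patient) {
  patient <- as_tibble(patient)
  if (nrow(patient) > 0 && length(unique(patient$patient_id)) > 1) {
    abort("`patient` must contain mentions of a single patient.")
  }
  act <- setNames(numeric(nrow(graph$nodes)), graph$nodes$cui)
  if (nrow(patient) > 0) {
    hits <- patient[patient$cui %in% names(act), , drop = FALSE]
    if (nrow(hits) > 0) {
      sums <- tapply(normalize_confidence(hits$confidence), hits$cui, sum)
      act[names(sums)] <- as.numeric(sums)
    }
  }
  tibble(cui = names(act), activation = unname(act))
}

# State matrix spreading: rows are independent activation states (patients),
# columns are graph nodes. Edge-wise message passing, one synchronous step.
spread_matrix_step <- function(graph, A, retain = 0) {
  edges <- graph$edges
  if (nrow(edges) > 0 && any(edges$weight < 0)) {
    abort("Spreading requires nonnegative edge weights (set min_cosine >= 0).")
  }
  nodes <- graph$nodes$cui
  strength <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    strength[edges$u[i]] <- strength[edges$u[i]] + edges$weight[i]
    strength[edges$v[i]] <- strength[edges$v[i]] + edges$weight[i]
  }
  connected <- strength > 0
  keep_frac <- ifelse(connected, retain, 1)
  new_A <- sweep(A, 2, keep_frac, `*`)
  for (i in seq_len(nrow(edges))) {
    u <- edges$u[i]; v <- edges$v[i]; w <- edges$weight[i]
    new_A[, v] <- new_A[, v] + (1 - retain) * A[, u] * (w / strength[u])
    new_A[, u] <- new_A[, u] + (1 - retain) * A[, v] * (w / strength[v])
  }
  new_A
}

state_to_matrix <- function(graph, state) {
  state <- as_tibble(state)
  if (!all(c("cui", "activation") %in% names(state))) {
    abort("`state` needs columns `cui` and `activation`.")
  }
  if (!setequal(state$cui, graph$nodes$cui)) {
    abort("State domain must equal the graph's node set.")
  }
  if (any(state$activation < 0)) abort("Activation values must be nonnegative.")
  a <- setNames(state$activation, state$cui)[graph$nodes$cui]
  matrix(a, nrow = 1, dimnames = list(NULL, graph$nodes$cui))
}

#' One synchronous spreading-activation step
#'
#' Every node with at least one incident edge sends its activation (times
#' `1 - retain`) to its neighbors, split in proportion to edge weights;
#' its new activation is the sum of its inflows plus the retained fraction.
#' Isolated nodes keep their activation unchanged. Total activation is
#' conserved exactly.
#'
#' @param graph A `concept_graph` with nonnegative edge weights.
#' @param state Tibble (`cui`, `activation`) over the graph nodes.
#' @param retain Fraction of activation each connected node keeps per step
#'   (default 0: full redistribution).
#' @return The new activation state, same shape as `state`.
#' @export
spread_step <- function(graph, state, retain = 0) {
  A <- spread_matrix_step(graph, state_to_matrix(graph, state), retain)
  tibble(cui = colnames(A), activation = as.numeric(A[1, ]))
}

#' @rdname spread_step
#' @param steps Number of steps (default 3); `steps = 0` returns the input
#'   state.
#' @export
spread <- function(graph, state, steps = 3, retain = 0) {
  steps <- assert_count(steps, "steps", min = 0L)
  A <- state_to_matrix(graph, state)
  for (s in seq_len(steps)) A <- spread_matrix_step(graph, A, retain)
  tibble(cui = colnames(A), activation = as.numeric(A[1, ]))
}

# Seed component plus isolated nodes: the sub-structure on which patient
# inference runs.
inference_graph <- function(graph) {
  act <- active_subgraph(graph)
  deg <- table(c(graph$edges$u, graph$edges$v))
  isolated <- setdiff(graph$nodes$cui[!graph$nodes$cui %in% names(deg)], act$nodes$cui)
  nodes <- bind_rows(act$nodes, graph$nodes[graph$nodes$cui %in% isolated, , drop = FALSE])
  concept_graph(graph$seed, nodes, act$edges)
}

#' Phenotype one patient by spreading activation to the seed
#'
#' @param graph The curated `concept_graph` (output of [filter_graph()]).
#' @param patient Mention rows of a single patient.
#' @param steps Spreading steps (default 3).
#' @param threshold Decision threshold on the seed's final activation
#'   (default 0; the patient is positive when `seed_activation > threshold`).
#' @param retain Per-step retained fraction (default 0).
#' @return One-row tibble: `patient_id`, `seed_activation`, `label`,
#'   `method = "GRAPH"`.
#' @export
classify_patient <- function(graph, patient, steps = 3, threshold = 0, retain = 0) {
  patient <- as_tibble(patient)
  pid <- if (nrow(patient) > 0) unique(patient$patient_id) else NA_character_
  if (length(pid) > 1) abort("`patient` must contain mentions of a single patient.")
  ig <- inference_graph(graph)
  state <- initial_activation(ig, patient)
  final <- spread(ig, state, steps = steps, retain = retain)
  seed_act <- final$activation[final$cui == ig$seed]
  tibble(
    patient_id = pid,
    seed_activation = seed_act,
    label = seed_act > threshold,
    method = "GRAPH"
  )
}

#' Phenotype every patient of a corpus
#'
#' Equivalent to calling [classify_patient()] per patient, but all patients'
#' activation states are propagated together.
#'
#' @param graph The curated `concept_graph`.
#' @param corpus A [concept_corpus()].
#' @inheritParams classify_patient
#' @return Tibble with one row per patient (sorted by `patient_id`):
#'   `patient_id`, `seed_activation`, `label`, `method = "GRAPH"`.
#' @export
classify_patients <- function(graph, corpus, steps = 3, threshold = 0, retain = 0) {
  corpus <- concept_corpus(corpus)
  steps <- assert_count(steps, "steps", min = 0L)
  ig <- inference_graph(graph)
  patients <- sort(unique(corpus$patient_id))
  nodes <- ig$nodes$cui
  hits <- corpus[corpus$cui %in% nodes, , drop = FALSE]
  A <- matrix(0, nrow = length(patients), ncol = length(nodes),
              dimnames = list(patients, nodes))
  if (nrow(hits) > 0) {
    sums <- hits |>
      group_by(.data$patient_id, .data$cui) |>
      summarise(activation = sum(normalize_confidence(.data$confidence)), .groups = "drop")
    A[cbind(sums$patient_id, sums$cui)] <- sums$activation
  }
  for (s in seq_len(steps)) A <- spread_matrix_step(ig, A, retain)
  tibble(
    patient_id = patients,
    seed_activation = as.numeric(A[, ig$seed]),
    label = as.numeric(A[, ig$seed]) > threshold,
    method = "GRAPH"
  )
}

#' Unsupervised decision threshold from the activation distribution
#'
#' When a cohort's seed activations are bimodal — a low mode of patients
#' whose records merely brush the graph and a high mode of patients whose
#' records load it — a natural operating point is the split minimizing the
#' weighted within-class variance of the two groups (Otsu's criterion,
#' computed exactly on the sorted values). The rule uses no labels and is
#' deterministic; the threshold returned is the midpoint between the two
#' classes' adjacent values.
#'
#' @param activations Numeric vector of seed activations (e.g. the
#'   `seed_activation` column of [classify_patients()] output).
#' @return A single threshold value. If all activations are equal it is
#'   returned unchanged (so `activation > threshold` is all-negative).
#' @export
choose_threshold <- function(activations) {
  x <- sort(as.numeric(activations))
  n <- length(x)
  if (n == 0) abort("`activations` must be non-empty.")
  if (n == 1 || x[1] == x[n]) return(x[1])
  csum <- cumsum(x)
  csum2 <- cumsum(x^2)
  k <- seq_len(n - 1)
  # within-group sums of squares for split after position k
  left <- csum2[k] - csum[k]^2 / k
  right <- (csum2[n] - csum2[k]) - (csum[n] - csum[k])^2 / (n - k)
  wss <- left + right
  best <- which.min(wss)
  (x[best] + x[best + 1]) / 2
}

#' Direct-mention baseline classifier
#'
#' Calls a patient positive when any document of theirs mentions the seed
#' concept at all — the behavior of an automated coder used as-is. Presence,
#' not confidence, decides the label; `seed_activation` reports the summed
#' normalized confidence for reference.
#'
#' @param corpus A [concept_corpus()].
#' @param seed Seed CUI.
#' @return Tibble with one row per patient (sorted by `patient_id`):
#'   `patient_id`, `seed_activation`, `label`, `method = "BASELINE"`.
#' @export
baseline_classify <- function(corpus, seed) {
  corpus <- concept_corpus(corpus)
  assert_scalar_string(seed, "seed")
  per_patient <- corpus |>
    group_by(.data$patient_id) |>
    summarise(
      seed_activation = sum(normalize_confidence(.data$confidence[.data$cui == seed])),
      label = any(.data$cui == seed),
      .groups = "drop"
    ) |>
    arrange(.data$patient_id)
  per_patient$method <- "BASELINE"
  per_patient
}
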