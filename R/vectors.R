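#' Reflective random indexing of clinical concepts
#'
#' Reflective random indexing (RRI) embeds every concept (CUI) of a corpus in
#' a low-dimensional space in two passes. First each CUI gets a random
#' *elemental* vector: a sparse ternary vector (entries in \{-1, 0, +1\})
#' whose high dimension makes distinct vectors close to orthogonal. Each
#' document is then represented as the log-entropy-weighted superposition of
#' the elemental vectors of the CUIs it mentions, normalized to unit length.
#' Finally each CUI's *semantic* vector is the normalized sum of the vectors
#' of the documents that mention it. Because the document pass mixes
#' co-occurring concepts, cosines between semantic vectors capture
#' second-order association: two CUIs that never co-occur directly but share
#' contexts end up with correlated vectors.
#'
#' Elemental vectors are generated deterministically from
#' (`master_seed`, `cui`), so a vector store can be rebuilt bit-identically
#' from its metadata without persisting the elemental pass.
#'
#' @name rri
NULL

#' Deterministic sparse ternary elemental vector for one CUI
#'
#' @param cui Concept identifier string.
#' @param dim Vector dimension (default 1000).
#' @param nonzeros Even number of nonzero entries (default 10); half are +1
#'   and half -1, at positions drawn without replacement by a generator
#'   keyed on (`master_seed`, `cui`).
#' @param master_seed Integer seed shared by all elemental vectors of a run.
#' @return Numeric vector of length `dim` with entries in \{-1, 0, 1\}.
#' @examples
#' v <- make_elemental_vector("C0006142", dim = 100, nonzeros = 4, master_seed = 7)
#' sum(v != 0)
#' @export
make_elemental_vector <- function(cui, dim = 1000, nonzeros = 10, master_seed = 1) {
  assert_scalar_string(cui, "cui")
  dim <- assert_count(dim, "dim", min = 1L)
  nonzeros <- assert_count(nonzeros, "nonzeros", min = 2L)
  if (nonzeros %% 2 != 0) abort("`nonzeros` must be even (balanced +1/-1 entries).")
  if (nonzeros > dim) abort("`nonzeros` must not exceed `dim`.")
  v <- numeric(dim)
  pos <- with_local_seed(
    derive_seed(master_seed, cui),
    sample.int(dim, nonzeros)
  )
  half <- nonzeros %/% 2
  v[pos[seq_len(half)]] <- 1
  v[pos[half + seq_len(half)]] <- -1
  v
}

#' Elemental vector store for a vocabulary
#'
#' @param cuis Character vector of CUIs.
#' @inheritParams make_elemental_vector
#' @return An `elemental_vectors` object: a CUI-by-dimension matrix with the
#'   generation parameters attached.
#' @export
elemental_vectors <- function(cuis, dim = 1000, nonzeros = 10, master_seed = 1) {
  cuis <- unique(as.character(cuis))
  mat <- t(vapply(
    cuis,
    function(cui) make_elemental_vector(cui, dim, nonzeros, master_seed),
    numeric(dim)
  ))
  rownames(mat) <- cuis
  structure(
    list(vectors = mat, dim = as.integer(dim), nonzeros = as.integer(nonzeros),
         master_seed = as.integer(master_seed)),
    class = "elemental_vectors"
  )
}

#' Log-entropy global weights for every CUI of a corpus
#'
#' For CUI \eqn{i} with per-document term frequencies \eqn{tf_{ij}} and
#' global frequency \eqn{gf_i = \sum_j tf_{ij}}, the entropy weight over an
#' n-document corpus is
#' \deqn{g_i = 1 + \sum_j \frac{p_{ij} \log p_{ij}}{\log n}, \quad
#'       p_{ij} = tf_{ij} / gf_i.}
#' A CUI confined to a single document gets weight 1; a CUI spread uniformly
#' over all documents gets weight 0, so the weight emphasizes focal concepts.
#' For a single-document corpus every weight is 1 by convention.
#'
#' @param corpus A [concept_corpus()].
#' @return Tibble with columns `cui` and `weight` (in \[0, 1\]), one row per
#'   vocabulary entry.
#' @export
log_entropy_weights <- function(corpus) {
  corpus <- concept_corpus(corpus)
  n_docs <- nrow(distinct(corpus, .data$patient_id, .data$doc_id))
  tf <- count(corpus, .data$cui, .data$patient_id, .data$doc_id, name = "tf")
  if (n_docs == 1) {
    return(tibble(cui = sort(unique(tf$cui)), weight = 1))
  }
  w <- tf |>
    group_by(.data$cui) |>
    summarise(weight = {
      p <- .data$tf / sum(.data$tf)
      1 + sum(p * log(p)) / log(n_docs)
    }) |>
    arrange(.data$cui)
  # clamp tiny negative values from floating-point cancellation
  w$weight <- pmin(1, pmax(0, w$weight))
  w
}

doc_key <- function(patient_id, doc_id) paste(patient_id, doc_id, sep = "\x1f")

#' Document vectors by weighted superposition of elemental vectors
#'
#' Each document's raw vector is
#' \eqn{\sum_i \log(1 + tf_{ij}) \, g_i \, e_i} over the distinct CUIs
#' \eqn{i} it mentions (elemental vectors \eqn{e_i}, global weights
#' \eqn{g_i}), scaled to unit Euclidean norm. A document whose every CUI has
#' weight 0 yields the zero vector and a warning.
#'
#' @param corpus A [concept_corpus()].
#' @param elemental An [elemental_vectors()] store covering the vocabulary.
#' @param weights Global weight table from [log_entropy_weights()].
#' @return A `document_vectors` object: a documents-by-dimension matrix plus
#'   a tibble mapping rows to (`patient_id`, `doc_id`).
#' @export
build_document_vectors <- function(corpus, elemental, weights) {
  corpus <- concept_corpus(corpus)
  vocab <- corpus_vocabulary(corpus)
  missing_elem <- setdiff(vocab, rownames(elemental$vectors))
  if (length(missing_elem) > 0) {
    abort(sprintf("Elemental store lacks CUI(s): %s", paste(head(missing_elem, 5), collapse = ", ")))
  }
  g <- setNames(weights$weight, weights$cui)
  missing_w <- setdiff(vocab, names(g))
  if (length(missing_w) > 0) {
    abort(sprintf("Weight table lacks CUI(s): %s", paste(head(missing_w, 5), collapse = ", ")))
  }

  docs <- distinct(corpus, .data$patient_id, .data$doc_id)
  keys <- doc_key(docs$patient_id, docs$doc_id)
  tf <- count(corpus, .data$patient_id, .data$doc_id, .data$cui, name = "tf")
  local_w <- log(1 + tf$tf) * g[tf$cui]
  L <- Matrix::sparseMatrix(
    i = match(doc_key(tf$patient_id, tf$doc_id), keys),
    j = match(tf$cui, vocab),
    x = local_w,
    dims = c(length(keys), length(vocab))
  )
  raw <- as.matrix(L %*% elemental$vectors[vocab, , drop = FALSE])
  mat <- normalize_rows(raw)
  n_zero <- sum(attr(mat, "zero_rows"))
  if (n_zero > 0) {
    warn(sprintf("%d document vector(s) are zero (all mentioned CUIs have weight 0).", n_zero))
  }
  structure(
    list(vectors = strip_zero_attr(mat), docs = docs, dim = ncol(mat)),
    class = "document_vectors"
  )
}

#' Semantic concept vectors from document vectors
#'
#' The semantic vector of a CUI is the sum of the vectors of every document
#' in which it occurs (each containing document counted once, regardless of
#' how many times the CUI is mentioned in it), normalized to unit length.
#'
#' @param corpus A [concept_corpus()].
#' @param docs A `document_vectors` store from [build_document_vectors()].
#' @return A `semantic_vectors` object: CUI-by-dimension matrix of unit
#'   vectors over the corpus vocabulary.
#' @export
build_concept_vectors <- function(corpus, docs) {
  corpus <- concept_corpus(corpus)
  vocab <- corpus_vocabulary(corpus)
  keys <- doc_key(docs$docs$patient_id, docs$docs$doc_id)
  occ <- distinct(corpus, .data$patient_id, .data$doc_id, .data$cui)
  row_idx <- match(doc_key(occ$patient_id, occ$doc_id), keys)
  if (anyNA(row_idx)) abort("Document store does not cover the corpus documents.")
  B <- Matrix::sparseMatrix(
    i = match(occ$cui, vocab),
    j = row_idx,
    x = 1,
    dims = c(length(vocab), length(keys))
  )
  raw <- as.matrix(B %*% docs$vectors)
  rownames(raw) <- vocab
  mat <- normalize_rows(raw)
  n_zero <- sum(attr(mat, "zero_rows"))
  if (n_zero > 0) {
    warn(sprintf("%d concept vector(s) are zero (every containing document has a zero vector).", n_zero))
  }
  structure(
    list(vectors = strip_zero_attr(mat), dim = ncol(mat)),
    class = "semantic_vectors"
  )
}

#' One-call RRI build: elemental, document, and concept vectors
#'
#' @inheritParams build_document_vectors
#' @inheritParams make_elemental_vector
#' @return A `semantic_vectors` object (see [build_concept_vectors()]) with
#'   the generation parameters attached.
#' @export
build_semantic_vectors <- function(corpus, dim = 1000, nonzeros = 10, master_seed = 1) {
  corpus <- concept_corpus(corpus)
  elem <- elemental_vectors(corpus_vocabulary(corpus), dim, nonzeros, master_seed)
  w <- log_entropy_weights(corpus)
  docs <- build_document_vectors(corpus, elem, w)
  store <- build_concept_vectors(corpus, docs)
  store$nonzeros <- elem$nonzeros
  store$master_seed <- elem$master_seed
  store
}

normalize_rows <- function(mat, tol = 1e-12) {
  norms <- sqrt(rowSums(mat^2))
  zero <- norms < tol
  scale <- ifelse(zero, 0, 1 / pmax(norms, tol))
  out <- mat * scale
  attr(out, "zero_rows") <- zero
  out
}

strip_zero_attr <- function(mat) {
  attr(mat, "zero_rows") <- NULL
  mat
}

#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length. If either is the zero vector
#'   the cosine is defined as 0.
#' @return The cosine of the angle between `a` and `b`, in \[-1, 1\].
#' @examples
#' cosine(c(1, 1, 0), c(1, 0, 1)) # 0.5
#' @export
cosine <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Exact k-nearest-neighbor query on a semantic vector store
#'
#' Scans the full store, ranking concepts by cosine to the query concept in
#' descending order; ties are broken by CUI in ascending lexicographic order.
#' The query concept itself is never returned.
#'
#' @param store A `semantic_vectors` object.
#' @param cui Query concept, present in the store.
#' @param k Number of neighbors to return (`k = 0` gives an empty result).
#' @param exclude Character vector of CUIs to omit from the ranking.
#' @return Tibble with columns `cui` and `cosine`, at most `k` rows.
#' @export
nearest_neighbors <- function(store, cui, k, exclude = character()) {
  assert_scalar_string(cui, "cui")
  k <- assert_count(k, "k", min = 0L)
  mat <- store$vectors
  if (!cui %in% rownames(mat)) abort(sprintf("CUI '%s' is not in the vector store.", cui))
  if (k == 0) return(tibble(cui = character(), cosine = numeric()))
  q <- mat[cui, ]
  qn <- sqrt(sum(q^2))
  norms <- sqrt(rowSums(mat^2))
  sims <- as.numeric(mat %*% q)
  denom <- norms * qn
  sims <- unname(ifelse(denom == 0, 0, sims / pmax(denom, .Machine$double.xmin)))
  keep <- !(rownames(mat) %in% c(cui, exclude))
  cand <- tibble(cui = rownames(mat)[keep], cosine = sims[keep])
  cand <- cand[order(-cand$cosine, cand$cui), ]
  head(cand, k)
}

#' @export
print.semantic_vectors <- function(x, ...) {
  cat(sprintf(
    "<semantic_vectors> %d concepts x %d dimensions\n",
    nrow(x$vectors), x$dim
  ))
  invisible(x)
}

#' @export
print.elemental_vectors <- function(x, ...) {
  cat(sprintf(
    "<elemental_vectors> %d concepts x %d dimensions (%d nonzeros, seed %d)\n",
    nrow(x$vectors), x$dim, x$nonzeros, x$master_seed
  ))
  invisible(x)
}
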