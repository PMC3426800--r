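test_that("elemental vectors are deterministic, balanced and parameter-checked", {
  v1 <- make_elemental_vector("C0006142", dim = 1000, nonzeros = 10, master_seed = 3)
  v2 <- make_elemental_vector("C0006142", dim = 1000, nonzeros = 10, master_seed = 3)
  expect_identical(v1, v2)
  expect_equal(sum(v1 == 1), 5)
  expect_equal(sum(v1 == -1), 5)
  expect_equal(sum(v1 == 0), 990)

  # different seed or cui changes the vector
  expect_false(identical(v1, make_elemental_vector("C0006142", 1000, 10, 4)))
  expect_false(identical(v1, make_elemental_vector("C0006143", 1000, 10, 3)))

  # forced structure: dim = nonzeros = 4 gives a signed arrangement
  w <- make_elemental_vector("C0000001", dim = 4, nonzeros = 4, master_seed = 1)
  expect_equal(sort(w), c(-1, -1, 1, 1))

  expect_error(make_elemental_vector("C1", dim = 10, nonzeros = 3), "even")
  expect_error(make_elemental_vector("C1", dim = 4, nonzeros = 6), "exceed")
})

test_that("elemental vectors of distinct CUIs are near-orthogonal", {
  cuis <- sprintf("C%07d", 1:100)
  elem <- elemental_vectors(cuis, dim = 1000, nonzeros = 10, master_seed = 11)
  mat <- elem$vectors
  total <- 0; n_pairs <- 0
  for (i in 1:99) {
    for (j in (i + 1):100) {
      total <- total + abs(brute_cosine(mat[i, ], mat[j, ]))
      n_pairs <- n_pairs + 1
    }
  }
  expect_equal(n_pairs, 4950)
  expect_lt(total / n_pairs, 0.05)
})

test_that("log-entropy weights match closed-form endpoints and the hand value", {
  # one mention in 1 of 10 documents: zero entropy, weight 1
  focal <- concept_corpus(tibble::tibble(
    patient_id = "p1", doc_id = sprintf("d%02d", 1:10),
    cui = c("C0000009", rep("C0000001", 9)), confidence = 500L
  ))
  w <- log_entropy_weights(focal)
  expect_equal(w$weight[w$cui == "C0000009"], 1)

  # once in each of 10 documents: maximal entropy, weight 0
  uniform <- concept_corpus(tibble::tibble(
    patient_id = "p1", doc_id = sprintf("d%02d", 1:10),
    cui = "C0000001", confidence = 500L
  ))
  expect_equal(log_entropy_weights(uniform)$weight, 0)

  # tf = (2, 1, 0) over 3 documents:
  # g = 1 + (2/3 log(2/3) + 1/3 log(1/3)) / log 3 = 0.4206198357 (hand)
  corpus <- concept_corpus(tibble::tibble(
    patient_id = "p1", doc_id = c("d1", "d1", "d2", "d3"),
    cui = c("C0000001", "C0000001", "C0000001", "C0000002"),
    confidence = 500L
  ))
  w <- log_entropy_weights(corpus)
  expect_equal(w$weight[w$cui == "C0000001"], 0.4206198357, tolerance = 1e-9)

  # single-document corpus: weight 1 by convention
  single <- concept_corpus(tibble::tibble(
    patient_id = "p1", doc_id = "d1", cui = c("C0000001", "C0000002"),
    confidence = 500L
  ))
  expect_equal(log_entropy_weights(single)$weight, c(1, 1))
})

test_that("document vectors equal the normalized weighted superposition", {
  # single-CUI document: unit-normalized elemental vector
  corpus <- concept_corpus(tibble::tibble(
    patient_id = c("p1", "p2"), doc_id = "d1",
    cui = c("C0000001", "C0000002"), confidence = 800L
  ))
  elem <- elemental_vectors(corpus_vocabulary(corpus), dim = 64, nonzeros = 4, master_seed = 5)
  w <- log_entropy_weights(corpus)
  docs <- build_document_vectors(corpus, elem, w)
  e1 <- elem$vectors["C0000001", ]
  expect_equal(
    docs$vectors[1, ], e1 / sqrt(sum(e1^2)),
    tolerance = 1e-12, ignore_attr = TRUE
  )

  # 2-CUI document at dim 8: brute-force weighted sum
  corpus2 <- concept_corpus(tibble::tibble(
    patient_id = "p1",
    doc_id = c("d1", "d1", "d1", "d2", "d3"),
    cui = c("C0000001", "C0000001", "C0000002", "C0000001", "C0000003"),
    confidence = 700L
  ))
  elem2 <- elemental_vectors(corpus_vocabulary(corpus2), dim = 8, nonzeros = 2, master_seed = 9)
  w2 <- log_entropy_weights(corpus2)
  docs2 <- build_document_vectors(corpus2, elem2, w2)
  g <- stats::setNames(w2$weight, w2$cui)
  raw <- log(1 + 2) * g["C0000001"] * elem2$vectors["C0000001", ] +
    log(1 + 1) * g["C0000002"] * elem2$vectors["C0000002", ]
  expect_equal(docs2$vectors[1, ], raw / sqrt(sum(raw^2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("documents whose CUIs all have zero weight get the zero vector", {
  # C0000001 uniform over both docs -> weight 0; d1 contains nothing else
  corpus <- concept_corpus(tibble::tibble(
    patient_id = "p1", doc_id = c("d1", "d2", "d2"),
    cui = c("C0000001", "C0000001", "C0000002"), confidence = 500L
  ))
  elem <- elemental_vectors(corpus_vocabulary(corpus), dim = 32, nonzeros = 2, master_seed = 1)
  w <- log_entropy_weights(corpus)
  expect_warning(
    docs <- build_document_vectors(corpus, elem, w),
    "zero"
  )
  expect_equal(unname(docs$vectors[1, ]), rep(0, 32))
  expect_gt(sqrt(sum(docs$vectors[2, ]^2)), 0.999999999)
})

test_that("concept vectors are unit norm and match brute-force recomputation", {
  corpus <- tiny_corpus()
  elem <- elemental_vectors(corpus_vocabulary(corpus), dim = 32, nonzeros = 4, master_seed = 2)
  w <- log_entropy_weights(corpus)
  docs <- build_document_vectors(corpus, elem, w)
  store <- build_concept_vectors(corpus, docs)

  norms <- sqrt(rowSums(store$vectors^2))
  expect_true(all(abs(norms - 1) < 1e-9))

  # brute force: per CUI, sum vectors of containing documents (binary), normalize
  key <- paste(docs$docs$patient_id, docs$docs$doc_id)
  for (cui in corpus_vocabulary(corpus)) {
    containing <- unique(paste(corpus$patient_id, corpus$doc_id)[corpus$cui == cui])
    raw <- rep(0, 32)
    for (dk in containing) raw <- raw + docs$vectors[match(dk, key), ]
    expect_equal(store$vectors[cui, ], raw / sqrt(sum(raw^2)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # a CUI occurring in exactly one document equals that document's vector
  expect_equal(store$vectors["C0000004", ],
               docs$vectors[match("p2 d3", key), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the full RRI build is deterministic", {
  corpus <- tiny_corpus()
  s1 <- build_semantic_vectors(corpus, dim = 128, nonzeros = 4, master_seed = 13)
  s2 <- build_semantic_vectors(corpus, dim = 128, nonzeros = 4, master_seed = 13)
  expect_identical(s1$vectors, s2$vectors)
})

test_that("cosine follows hand arithmetic and handles degenerate input", {
  expect_equal(cosine(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine(c(1, 0, 0, 1), c(0, 1, 1, 0)), 0)
  expect_equal(cosine(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine(c(0, 0), c(1, 1)), 0)
  expect_error(cosine(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("nearest_neighbors agrees with an exhaustive scan and obeys exclusions", {
  store <- random_store(30, dim = 16, seed = 21)
  cui <- rownames(store$vectors)[1]

  expect_equal(nrow(nearest_neighbors(store, cui, k = 0)), 0)

  nn <- nearest_neighbors(store, cui, k = 6)
  oracle <- brute_knn(store, cui, 6)
  expect_equal(nn$cui, oracle$cui)
  expect_equal(nn$cosine, oracle$cosine, tolerance = 1e-12)
  expect_false(cui %in% nn$cui)

  excl <- oracle$cui[1:2]
  nn2 <- nearest_neighbors(store, cui, k = 6, exclude = excl)
  expect_false(any(excl %in% nn2$cui))
  expect_equal(nn2$cui, brute_knn(store, cui, 6, exclude = excl)$cui)

  # full-store query matches the brute scan for every concept
  for (q in rownames(store$vectors)[1:5]) {
    expect_equal(
      nearest_neighbors(store, q, k = 29)$cui,
      brute_knn(store, q, 29)$cui
    )
  }
  expect_error(nearest_neighbors(store, "C0000000", k = 3), "not in the vector store")
})

test_that("ties in the neighbor ranking break lexicographically", {
  mat <- rbind(
    A = c(1, 0), B = c(0, 1), C = c(0, 1), D = c(-1, 0)
  )
  rownames(mat) <- c("C0000009", "C0000003", "C0000001", "C0000005")
  store <- structure(list(vectors = mat, dim = 2), class = "semantic_vectors")
  nn <- nearest_neighbors(store, "C0000003", k = 3)
  # C0000001 is identical (cosine 1); the other two tie at cosine 0
  expect_equal(nn$cui, c("C0000001", "C0000005", "C0000009"))
})

test_that("RRI captures second-order association between non-co-occurring CUIs", {
  # A and B never share a document but both co-occur with C;
  # unrelated background CUIs occur in separate documents.
  withr::with_seed(31, {
    rows <- list()
    for (d in 1:20) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = "p1", doc_id = sprintf("ab%02d", d),
        cui = c(if (d %% 2 == 0) "C0000001" else "C0000002", "C0000003"),
        confidence = 900L
      )
    }
    for (d in 1:20) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = "p1", doc_id = sprintf("bg%02d", d),
        cui = sample(sprintf("C1%06d", 1:10), 3),
        confidence = 900L
      )
    }
  })
  corpus <- concept_corpus(dplyr::bind_rows(rows))
  store <- build_semantic_vectors(corpus, dim = 500, nonzeros = 10, master_seed = 17)
  ab <- cosine(store$vectors["C0000001", ], store$vectors["C0000002", ])
  background <- sprintf("C1%06d", 1:10)
  ref <- vapply(background, function(b) {
    cosine(store$vectors["C0000001", ], store$vectors[b, ])
  }, numeric(1))
  expect_gt(ab, stats::median(ref))
})

test_that("vector stores persist with metadata and reload close to exactly", {
  corpus <- tiny_corpus()
  store <- build_semantic_vectors(corpus, dim = 64, nonzeros = 4, master_seed = 23)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vector_store(store, path, corpus_checksum = "abc123")
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_vector_store(path)
  expect_equal(rownames(back$vectors), rownames(store$vectors))
  expect_equal(back$vectors, store$vectors, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back$master_seed, 23)
  expect_equal(back$nonzeros, 4)
})
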