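two_node_graph <- function(w = 1) {
  concept_graph("C0000001",
    nodes = tibble::tibble(cui = c("C0000001", "C0000002"), depth = c(0L, 1L)),
    edges = tibble::tibble(u = "C0000001", v = "C0000002", weight = w)
  )
}

path_graph <- function(weights) {
  n <- length(weights) + 1
  cuis <- sprintf("C%07d", seq_len(n))
  concept_graph(cuis[1],
    nodes = tibble::tibble(cui = cuis, depth = seq_len(n) - 1L),
    edges = tibble::tibble(u = cuis[-n], v = cuis[-1], weight = weights)
  )
}

mention <- function(patient_id, cui, confidence, doc_id = "d1") {
  tibble::tibble(patient_id = patient_id, doc_id = doc_id,
                 cui = cui, confidence = as.integer(confidence))
}

test_that("confidence normalization is linear on [0, 1000]", {
  expect_equal(normalize_confidence(1000L), 1)
  expect_equal(normalize_confidence(0L), 0)
  expect_equal(normalize_confidence(500L), 0.5)
  expect_equal(normalize_confidence(c(250L, 750L)), c(0.25, 0.75))
  expect_error(normalize_confidence(1001L), "\\[0, 1000\\]")
  expect_error(normalize_confidence(-1L), "\\[0, 1000\\]")
})

test_that("initial activation sums normalized confidences per graph node", {
  g <- two_node_graph()
  none <- initial_activation(g, mention("p1", "C9999999", 800))
  expect_equal(none$activation, c(0, 0))

  two <- initial_activation(g, dplyr::bind_rows(
    mention("p1", "C0000002", 600, doc_id = "d1"),
    mention("p1", "C0000002", 400, doc_id = "d2")
  ))
  expect_equal(two$activation[two$cui == "C0000002"], 1.0)

  expect_error(
    initial_activation(g, dplyr::bind_rows(
      mention("p1", "C0000001", 100), mention("p2", "C0000001", 100)
    )),
    "single patient"
  )

  # three-document fixture against a naive per-CUI sum
  docs <- dplyr::bind_rows(
    mention("p1", "C0000001", 300, "d1"),
    mention("p1", "C0000001", 200, "d1"),
    mention("p1", "C0000002", 1000, "d2"),
    mention("p1", "C9999999", 999, "d3")
  )
  st <- initial_activation(g, docs)
  naive <- c(C0000001 = (300 + 200) / 1000, C0000002 = 1000 / 1000)
  expect_equal(stats::setNames(st$activation, st$cui), naive[st$cui], ignore_attr = TRUE)
})

test_that("a single step transfers activation along edges and fixes isolated nodes", {
  g <- two_node_graph()
  s0 <- tibble::tibble(cui = c("C0000001", "C0000002"), activation = c(1, 0))
  s1 <- spread_step(g, s0)
  expect_equal(s1$activation, c(0, 1))

  iso <- concept_graph("C0000001",
    nodes = tibble::tibble(cui = c("C0000001", "C0000002", "C0000003"),
                           depth = c(0L, 1L, 1L)),
    edges = tibble::tibble(u = "C0000001", v = "C0000002", weight = 0.8)
  )
  s <- tibble::tibble(cui = iso$nodes$cui, activation = c(0.2, 0.1, 0.7))
  for (i in 1:5) s <- spread_step(iso, s)
  expect_equal(s$activation[s$cui == "C0000003"], 0.7)

  neg <- concept_graph("C0000001",
    nodes = tibble::tibble(cui = c("C0000001", "C0000002"), depth = c(0L, 1L)),
    edges = tibble::tibble(u = "C0000001", v = "C0000002", weight = -0.1)
  )
  expect_error(spread_step(neg, s0), "nonnegative")
})

test_that("spreading equals dense transition-matrix powers on a weighted path", {
  g <- path_graph(c(0.9, 0.4, 0.7))
  s0 <- tibble::tibble(cui = g$nodes$cui, activation = c(1, 0.5, 0, 2))
  expect_equal(spread_step(g, s0), oracle_spread(g, s0, 1), tolerance = 1e-12)
  expect_equal(spread(g, s0, steps = 3), oracle_spread(g, s0, 3), tolerance = 1e-12)
  # retained fraction generalization
  expect_equal(spread(g, s0, steps = 2, retain = 0.3),
               oracle_spread(g, s0, 2, retain = 0.3), tolerance = 1e-12)
})

test_that("zero steps is the identity and total activation is conserved", {
  g <- random_concept_graph(12, edge_prob = 0.25, seed = 2)
  s0 <- random_state(g, seed = 3)
  expect_equal(spread(g, s0, steps = 0), s0)
  s3 <- spread(g, s0, steps = 3)
  expect_equal(sum(s3$activation), sum(s0$activation), tolerance = 1e-9)
})

test_that("patient classification reads the seed node after spreading", {
  g <- filter_graph(topology_fixture(), knowledge_base(topology_kb()))

  nothing <- classify_patient(g, mention("p1", "C9999999", 1000))
  expect_equal(nothing$seed_activation, 0)
  expect_false(nothing$label)

  # seed-only mention: compare against the matrix oracle on the active part
  act <- active_subgraph(g)
  seed_only <- mention("p1", g$seed, 1000)
  res <- classify_patient(g, seed_only)
  s0 <- initial_activation(act, seed_only)
  oracle <- oracle_spread(act, s0, 3)
  expect_equal(res$seed_activation,
               oracle$activation[oracle$cui == g$seed], tolerance = 1e-12)
  expect_true(res$label)

  # two depth-1 neighbors and no seed mention: activation reaches the seed
  d1 <- g$nodes$cui[g$nodes$depth == 1][1:2]
  neighbors_only <- dplyr::bind_rows(
    mention("p1", d1[1], 900), mention("p1", d1[2], 800)
  )
  res2 <- classify_patient(g, neighbors_only)
  expect_gt(res2$seed_activation, 0)
  expect_true(res2$label)
  s0b <- initial_activation(act, neighbors_only)
  oracle2 <- oracle_spread(act, s0b, 3)
  expect_equal(res2$seed_activation,
               oracle2$activation[oracle2$cui == g$seed], tolerance = 1e-12)
})

test_that("mentions on disconnected graph pieces never reach the seed", {
  g <- filter_graph(topology_fixture(), knowledge_base(topology_kb()))
  far_nodes <- setdiff(g$nodes$cui, active_subgraph(g)$nodes$cui)
  far_only <- dplyr::bind_rows(lapply(far_nodes, function(cc) mention("p1", cc, 1000)))
  res <- classify_patient(g, far_only)
  expect_equal(res$seed_activation, 0)
  expect_false(res$label)
})

test_that("classify_patients matches per-patient classification", {
  g <- filter_graph(topology_fixture(), knowledge_base(topology_kb()))
  withr::with_seed(11, {
    corpus <- concept_corpus(tibble::tibble(
      patient_id = rep(sprintf("p%02d", 1:8), each = 6),
      doc_id = rep(c("d1", "d1", "d2", "d2", "d3", "d3"), 8),
      cui = sample(c(g$nodes$cui, "C9999999"), 48, replace = TRUE),
      confidence = sample(100:1000, 48, replace = TRUE)
    ))
  })
  bulk <- classify_patients(g, corpus, threshold = 0.2)
  for (p in unique(corpus$patient_id)) {
    single <- classify_patient(g, corpus[corpus$patient_id == p, ], threshold = 0.2)
    expect_equal(bulk$seed_activation[bulk$patient_id == p],
                 single$seed_activation, tolerance = 1e-12)
    expect_equal(bulk$label[bulk$patient_id == p], single$label)
  }
})

test_that("spreading is linear and monotone in the evidence", {
  g <- random_concept_graph(15, edge_prob = 0.2, seed = 5)
  s1 <- random_state(g, seed = 6)
  s2 <- random_state(g, seed = 7)
  alpha <- 0.4; beta <- 1.7
  combo <- tibble::tibble(cui = s1$cui, activation = alpha * s1$activation + beta * s2$activation)
  lhs <- spread(g, combo, steps = 3)
  r1 <- spread(g, s1, steps = 3)
  r2 <- spread(g, s2, steps = 3)
  expect_equal(lhs$activation, alpha * r1$activation + beta * r2$activation,
               tolerance = 1e-9)

  # adding a mention of any seed-component node never decreases seed activation
  g2 <- filter_graph(topology_fixture(), knowledge_base(topology_kb()))
  base_rec <- mention("p1", g2$nodes$cui[2], 500)
  base_act <- classify_patient(g2, base_rec)$seed_activation
  for (cc in active_subgraph(g2)$nodes$cui) {
    more <- dplyr::bind_rows(base_rec, mention("p1", cc, 400, doc_id = "d9"))
    expect_gte(classify_patient(g2, more)$seed_activation, base_act - 1e-12)
  }
})

test_that("the direct-mention baseline keys on presence, not confidence", {
  empty_rec <- concept_corpus(mention("p1", "C0000002", 500))
  base <- baseline_classify(empty_rec, "C0006142")
  expect_false(base$label)

  faint <- concept_corpus(mention("p1", "C0006142", 1))
  expect_true(baseline_classify(faint, "C0006142")$label)

  # neighbor-only record: baseline negative while the graph method is positive
  g <- filter_graph(topology_fixture(), knowledge_base(topology_kb()))
  d1 <- g$nodes$cui[g$nodes$depth == 1][1]
  rec <- concept_corpus(mention("p1", d1, 900))
  expect_false(baseline_classify(rec, g$seed)$label)
  expect_true(classify_patient(g, rec)$label)
})

test_that("the unsupervised threshold splits well-separated activation modes", {
  expect_equal(choose_threshold(c(1, 1, 1)), 1)
  expect_equal(choose_threshold(5), 5)
  th <- choose_threshold(c(0.1, 0.2, 0.15, 6, 7, 6.5))
  expect_gt(th, 0.2)
  expect_lt(th, 6)
  # scale invariance of the split point's position
  th2 <- choose_threshold(10 * c(0.1, 0.2, 0.15, 6, 7, 6.5))
  expect_equal(th2, 10 * th)
})
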