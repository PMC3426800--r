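#' Synthetic phenotyping study generator
#'
#' @description
#' Generates a fully synthetic study — concept corpus, relation knowledge
#' base, and gold labels — with a planted seed-associated concept cluster,
#' so the whole pipeline can be exercised and scored without any clinical
#' data. Each patient is a case with probability `prevalence`. Per document,
#' cases mention the seed CUI with probability `p_mention_seed_given_case`
#' and each associated concept with `p_mention_assoc_given_case`; controls
#' mention associated concepts with `p_mention_assoc_given_control` and
#' never the seed. Background concepts are mentioned uniformly by everyone,
#' providing unrelated vocabulary. Confidence scores are drawn uniformly
#' from `confidence_range`. The knowledge base supports a
#' `kb_support_fraction` share of the (seed, associated) and
#' (associated, associated) pairs, split between thesaurus and literature
#' sources; background concepts get no triples, so knowledge filtering is
#' observable as noise-edge removal.
#'
#' Generation is a pure function of the configuration: the same `rng_seed`
#' reproduces the same study byte-for-byte.
#'
#' @name synthetic-data
NULL

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the evaluation scale of the method's original study: 428
#' patients with a 19.2% phenotype prevalence.
#'
#' @param n_patients Number of patients (default 428).
#' @param docs_per_patient Integer range (length-2 vector) of documents per
#'   patient, inclusive (default `c(3, 8)`).
#' @param prevalence Probability a patient is a case, in (0, 1)
#'   (default 0.192).
#' @param seed_cui Seed phenotype concept (default `"C0006142"`).
#' @param n_associated Size of the planted seed-associated cluster
#'   (default 12).
#' @param n_background Unrelated vocabulary size (default 60).
#' @param p_mention_seed_given_case Per-document probability a case mentions
#'   the seed (default 0.6).
#' @param p_mention_assoc_given_case Per-document probability a case
#'   mentions each associated concept (default 0.8).
#' @param p_mention_assoc_given_control Same for controls (default 0.05);
#'   must not exceed the case probability (the planted signal is
#'   nonnegative).
#' @param p_mention_background Per-document probability any patient mentions
#'   each background concept (default 0.1).
#' @param confidence_range Inclusive integer range of confidence scores
#'   within \[0, 1000\] (default `c(500, 1000)`).
#' @param kb_support_fraction Share of plausible cluster pairs supported by
#'   a knowledge-base triple (default 1).
#' @param rng_seed Integer seed controlling all randomness (default 1).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 428,
                              docs_per_patient = c(3, 8),
                              prevalence = 0.192,
                              seed_cui = "C0006142",
                              n_associated = 12,
                              n_background = 60,
                              p_mention_seed_given_case = 0.6,
                              p_mention_assoc_given_case = 0.8,
                              p_mention_assoc_given_control = 0.05,
                              p_mention_background = 0.1,
                              confidence_range = c(500, 1000),
                              kb_support_fraction = 1,
                              rng_seed = 1) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients", min = 1L),
    docs_per_patient = docs_per_patient,
    prevalence = prevalence,
    seed_cui = seed_cui,
    n_associated = assert_count(n_associated, "n_associated", min = 1L),
    n_background = assert_count(n_background, "n_background", min = 0L),
    p_mention_seed_given_case = p_mention_seed_given_case,
    p_mention_assoc_given_case = p_mention_assoc_given_case,
    p_mention_assoc_given_control = p_mention_assoc_given_control,
    p_mention_background = p_mention_background,
    confidence_range = confidence_range,
    kb_support_fraction = kb_support_fraction,
    rng_seed = assert_count(rng_seed, "rng_seed", min = 0L)
  )
  assert_scalar_string(cfg$seed_cui, "seed_cui")
  probs <- c(
    prevalence = cfg$prevalence,
    p_mention_seed_given_case = cfg$p_mention_seed_given_case,
    p_mention_assoc_given_case = cfg$p_mention_assoc_given_case,
    p_mention_assoc_given_control = cfg$p_mention_assoc_given_control,
    p_mention_background = cfg$p_mention_background,
    kb_support_fraction = cfg$kb_support_fraction
  )
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad) > 0) {
    abort(sprintf("Probabilities outside [0, 1]: %s", paste(bad, collapse = ", ")))
  }
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1) {
    abort("`prevalence` must lie strictly between 0 and 1.")
  }
  if (cfg$p_mention_assoc_given_control > cfg$p_mention_assoc_given_case) {
    abort("Control mention probability must not exceed the case probability.")
  }
  if (length(cfg$docs_per_patient) != 2 || any(cfg$docs_per_patient < 1) ||
      cfg$docs_per_patient[1] > cfg$docs_per_patient[2]) {
    abort("`docs_per_patient` must be an increasing range of positive counts.")
  }
  if (length(cfg$confidence_range) != 2 || any(cfg$confidence_range < 0) ||
      any(cfg$confidence_range > 1000) ||
      cfg$confidence_range[1] > cfg$confidence_range[2]) {
    abort("`confidence_range` must be an increasing range within [0, 1000].")
  }
  structure(cfg, class = "simulation_config")
}

sim_assoc_cuis <- function(cfg) sprintf("C1%06d", seq_len(cfg$n_associated))
sim_background_cuis <- function(cfg) {
  if (cfg$n_background == 0) character() else sprintf("C2%06d", seq_len(cfg$n_background))
}

#' Generate a synthetic study
#'
#' @param config A [simulation_config()].
#' @return A list with elements `corpus` (a [concept_corpus()]), `kb`
#'   (triple tibble), `labels` (gold labels tibble), and `associated`
#'   (the planted cluster CUIs).
#' @export
simulate_phenotype_data <- function(config = simulation_config()) {
  cfg <- config
  if (!inherits(cfg, "simulation_config")) cfg <- do.call(simulation_config, config)
  assoc <- sim_assoc_cuis(cfg)
  background <- sim_background_cuis(cfg)
  if (length(assoc) + length(background) == 0) abort("Empty simulated vocabulary.")

  with_local_seed(cfg$rng_seed, {
    patient_ids <- sprintf("P%05d", seq_len(cfg$n_patients))
    is_case <- stats::runif(cfg$n_patients) < cfg$prevalence

    rows <- vector("list", cfg$n_patients)
    for (p in seq_len(cfg$n_patients)) {
      n_docs <- sample(seq(cfg$docs_per_patient[1], cfg$docs_per_patient[2]), 1)
      p_assoc <- if (is_case[p]) cfg$p_mention_assoc_given_case else cfg$p_mention_assoc_given_control
      doc_rows <- vector("list", n_docs)
      for (d in seq_len(n_docs)) {
        cuis <- character()
        if (is_case[p] && stats::runif(1) < cfg$p_mention_seed_given_case) {
          cuis <- c(cuis, cfg$seed_cui)
        }
        cuis <- c(cuis, assoc[stats::runif(length(assoc)) < p_assoc])
        cuis <- c(cuis, background[stats::runif(length(background)) < cfg$p_mention_background])
        # every document carries at least one concept so no patient vanishes
        # from the corpus
        if (length(cuis) == 0) {
          pool <- c(background, assoc)
          cuis <- pool[sample.int(length(pool), 1)]
        }
        doc_rows[[d]] <- tibble(
          patient_id = patient_ids[p],
          doc_id = sprintf("%s-D%03d", patient_ids[p], d),
          cui = cuis,
          confidence = sample(
            seq(cfg$confidence_range[1], cfg$confidence_range[2]),
            length(cuis), replace = TRUE
          )
        )
      }
      rows[[p]] <- bind_rows(doc_rows)
    }
    corpus <- concept_corpus(bind_rows(rows))

    kb <- simulate_kb(cfg, assoc)
    labels <- tibble(patient_id = patient_ids, label = is_case)
    list(corpus = corpus, kb = kb, labels = labels, associated = assoc)
  })
}

# KB triples over the planted cluster: all (seed, assoc) pairs plus all
# (assoc, assoc) pairs, thinned to kb_support_fraction, sources alternating.
simulate_kb <- function(cfg, assoc) {
  pairs_a <- tibble(subject = cfg$seed_cui, object = assoc)
  pairs_b <- if (length(assoc) > 1) {
    idx <- utils::combn(length(assoc), 2)
    tibble(subject = assoc[idx[1, ]], object = assoc[idx[2, ]])
  } else {
    tibble(subject = character(), object = character())
  }
  pairs <- bind_rows(pairs_a, pairs_b)
  keep <- stats::runif(nrow(pairs)) < cfg$kb_support_fraction
  pairs <- pairs[keep, , drop = FALSE]
  predicates <- c("ASSOCIATED_WITH", "TREATS", "DIAGNOSES", "PROCESS_OF", "isa")
  if (nrow(pairs) == 0) {
    return(knowledge_triples(tibble(
      subject = character(), predicate = character(),
      object = character(), source = character()
    )))
  }
  knowledge_triples(tibble(
    subject = pairs$subject,
    predicate = predicates[1 + (seq_len(nrow(pairs)) - 1) %% length(predicates)],
    object = pairs$object,
    source = ifelse(seq_len(nrow(pairs)) %% 2 == 1, "THESAURUS", "LITERATURE")
  ))
}

#' Hide direct seed mentions for a share of case patients
#'
#' Emulates records in which the phenotype is never stated explicitly: for a
#' `fraction` share of case patients (chosen deterministically as the first
#' cases in sorted patient-id order) every mention of the seed CUI is
#' deleted, while associated-concept mentions remain. A direct-mention
#' baseline must miss exactly these patients; the graph method can still
#' recover them through their associated concepts.
#'
#' @param corpus A [concept_corpus()].
#' @param gold Gold labels tibble.
#' @param fraction Share of case patients to occult, in \[0, 1\].
#' @param seed_cui The seed concept whose mentions are removed.
#' @return The modified corpus, with attribute `occulted` listing the
#'   affected patient ids.
#' @export
occult_seed_mentions <- function(corpus, gold, fraction, seed_cui = "C0006142") {
  corpus <- concept_corpus(corpus)
  gold <- gold_labels(gold)
  if (fraction < 0 || fraction > 1) abort("`fraction` must lie in [0, 1].")
  cases <- sort(gold$patient_id[gold$label])
  n_occult <- ceiling(fraction * length(cases))
  occulted <- cases[seq_len(n_occult)]
  out <- corpus[!(corpus$patient_id %in% occulted & corpus$cui == seed_cui), , drop = FALSE]
  out <- concept_corpus(out)
  attr(out, "occulted") <- occulted
  out
}
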