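#' Concept corpora, relation knowledge bases, labels and predictions
#'
#' All on-disk artifacts are UTF-8, LF-terminated, tab-separated files with a
#' mandatory header. A concept corpus holds one row per concept mention
#' instance, the output shape of an automated coder such as MetaMap: a patient
#' identifier, a document identifier, a UMLS Concept Unique Identifier (CUI,
#' `C` followed by digits), and an integer extraction confidence in
#' \[0, 1000\]. Duplicate mentions of a CUI within a document are meaningful
#' (they feed term frequencies and activation sums) and are preserved.
#'
#' @name corpus-io
NULL

new_concept_corpus <- function(df) {
  structure(df, class = c("concept_corpus", class(tibble())))
}

#' Build a concept corpus from a data frame of mention instances
#'
#' @param df A data frame with columns `patient_id`, `doc_id`, `cui`,
#'   `confidence` (one row per mention instance).
#' @return A `concept_corpus` tibble (one row per mention), with the same
#'   columns, validated.
#' @examples
#' concept_corpus(data.frame(
#'   patient_id = "p1", doc_id = "d1", cui = "C0006142", confidence = 900L
#' ))
#' @export
concept_corpus <- function(df) {
  req <- c("patient_id", "doc_id", "cui", "confidence")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Corpus is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)[req]
  if (nrow(df) == 0) abort("empty corpus")
  df$patient_id <- as.character(df$patient_id)
  df$doc_id <- as.character(df$doc_id)
  df$cui <- as.character(df$cui)
  bad_cui <- which(is.na(df$cui) | !grepl("^C[0-9]+$", df$cui))
  if (length(bad_cui) > 0) {
    abort(sprintf(
      "Invalid CUI at data row(s) %s (expected 'C' followed by digits).",
      paste(head(bad_cui, 5), collapse = ", ")
    ))
  }
  conf <- suppressWarnings(as.numeric(df$confidence))
  bad_conf <- which(is.na(conf) | conf < 0 | conf > 1000 | conf != floor(conf))
  if (length(bad_conf) > 0) {
    abort(sprintf(
      "Confidence outside [0, 1000] or non-integer at data row(s) %s.",
      paste(head(bad_conf, 5), collapse = ", ")
    ))
  }
  df$confidence <- as.integer(conf)
  new_concept_corpus(df)
}

#' @rdname corpus-io
#' @param path Path to a corpus TSV with header
#'   `patient_id  doc_id  cui  confidence`.
#' @return `read_concept_corpus()` returns a `concept_corpus` tibble.
#' @export
read_concept_corpus <- function(path) {
  df <- read_tsv_strict(path, c("patient_id", "doc_id", "cui", "confidence"))
  if (nrow(df) == 0) abort("empty corpus")
  concept_corpus(df)
}

#' @rdname corpus-io
#' @param corpus A `concept_corpus`.
#' @export
write_concept_corpus <- function(corpus, path) {
  corpus <- concept_corpus(corpus)
  write_atomically(path, function(tmp) {
    readr::write_tsv(as_tibble(corpus), tmp)
  })
}

#' Distinct CUIs present in a corpus
#'
#' @param corpus A `concept_corpus`.
#' @return Character vector of the corpus vocabulary, sorted.
#' @export
corpus_vocabulary <- function(corpus) {
  sort(unique(corpus$cui))
}

#' @rdname corpus-io
#' @details A relation knowledge base is a de-duplicated set of triples
#'   (subject CUI, predicate label, object CUI) tagged with their provenance:
#'   `THESAURUS` for curated thesaurus relations (UMLS Metathesaurus shape) or
#'   `LITERATURE` for predications mined from articles (SemRep shape).
#' @return `read_knowledge_base()` returns a tibble with columns
#'   `subject`, `predicate`, `object`, `source`, de-duplicated.
#' @export
read_knowledge_base <- function(path) {
  df <- read_tsv_strict(path, c("subject", "predicate", "object", "source"))
  knowledge_triples(df)
}

#' Validate a data frame of relation triples
#'
#' @param df Data frame with columns `subject`, `predicate`, `object`,
#'   `source` (`THESAURUS` or `LITERATURE`).
#' @return A de-duplicated tibble of triples.
#' @export
knowledge_triples <- function(df) {
  req <- c("subject", "predicate", "object", "source")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Knowledge base is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)[req]
  for (col in req) df[[col]] <- as.character(df[[col]])
  if (nrow(df) > 0) {
    bad_src <- which(!df$source %in% c("THESAURUS", "LITERATURE"))
    if (length(bad_src) > 0) {
      abort(sprintf(
        "Unknown relation source %s at data row(s) %s (expected THESAURUS or LITERATURE).",
        dQuote(df$source[bad_src[1]]), paste(head(bad_src, 5), collapse = ", ")
      ))
    }
    if (any(!nzchar(df$predicate))) abort("Empty predicate label in knowledge base.")
  }
  distinct(df)
}

#' @rdname corpus-io
#' @param triples Tibble of relation triples (see [knowledge_triples()]).
#' @export
write_knowledge_base <- function(triples, path) {
  triples <- knowledge_triples(triples)
  write_atomically(path, function(tmp) readr::write_tsv(triples, tmp))
}

#' Gold phenotype labels
#'
#' Labels are a two-column TSV `patient_id  label` with `label` in `{0, 1}`
#' (1 = condition present). Duplicate patient ids are an error.
#'
#' @param path Path to the labels TSV.
#' @return A tibble with columns `patient_id` (character) and `label`
#'   (logical).
#' @export
read_gold_labels <- function(path) {
  df <- read_tsv_strict(path, c("patient_id", "label"))
  gold_labels(df)
}

#' @rdname read_gold_labels
#' @param df Data frame with columns `patient_id` and `label` (0/1 or
#'   logical).
#' @export
gold_labels <- function(df) {
  req <- c("patient_id", "label")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Labels are missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)[req]
  df$patient_id <- as.character(df$patient_id)
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate patient_id in labels: %s", paste(unique(dup), collapse = ", ")))
  }
  if (is.logical(df$label)) {
    lab <- df$label
  } else {
    val <- suppressWarnings(as.numeric(df$label))
    if (any(is.na(val) | !val %in% c(0, 1))) {
      abort("Labels must be 0 or 1.")
    }
    lab <- val == 1
  }
  tibble(patient_id = df$patient_id, label = lab)
}

#' @rdname read_gold_labels
#' @param labels Tibble of gold labels.
#' @export
write_gold_labels <- function(labels, path) {
  labels <- gold_labels(labels)
  out <- tibble(patient_id = labels$patient_id, label = as.integer(labels$label))
  write_atomically(path, function(tmp) readr::write_tsv(out, tmp))
}

#' Read and write phenotype predictions
#'
#' Predictions are a TSV `patient_id  seed_activation  label  method`, one
#' row per patient, written sorted by `patient_id` so repeated runs are
#' byte-identical.
#'
#' @param predictions Tibble as returned by [classify_patients()] or
#'   [baseline_classify()].
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  req <- c("patient_id", "seed_activation", "label")
  missing_cols <- setdiff(req, names(predictions))
  if (length(missing_cols) > 0) {
    abort(paste0("Predictions are missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(predictions)
  if (!"method" %in% names(out)) out$method <- "GRAPH"
  out <- arrange(out[c("patient_id", "seed_activation", "label", "method")], .data$patient_id)
  out$label <- as.integer(out$label)
  out$seed_activation <- format_weight(out$seed_activation)
  write_atomically(path, function(tmp) readr::write_tsv(out, tmp))
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- read_tsv_strict(path, c("patient_id", "seed_activation", "label", "method"))
  tibble(
    patient_id = as.character(df$patient_id),
    seed_activation = as.numeric(df$seed_activation),
    label = as.numeric(df$label) == 1,
    method = as.character(df$method)
  )
}

# Strict TSV reader: exact header, everything as character, no dropped rows.
read_tsv_strict <- function(path, columns) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, lazy = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "Malformed row(s) in '%s' at line(s) %s.",
      path, paste(head(unique(probs$row + 1L), 5), collapse = ", ")
    ))
  }
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "'%s' is missing column(s): %s", path, paste(missing_cols, collapse = ", ")
    ))
  }
  df
}

# Decimal representation with enough digits for exact double round-trips.
format_weight <- function(x) {
  formatC(x, digits = 17, format = "g")
}
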