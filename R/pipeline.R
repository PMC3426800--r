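#' End-to-end phenotyping pipeline
#'
#' Runs the four phases in order — build semantic vectors from the corpus,
#' grow the BFS nearest-neighbor graph around the seed, curate it against
#' the knowledge base, classify every patient by spreading activation — and,
#' when gold labels are supplied, scores both the graph method and the
#' direct-mention baseline. Every stage's artifact is persisted under
#' `out_dir` together with a JSON run manifest (tool version, resolved
#' parameters, input checksums, timestamp). Writes are atomic
#' (temp-then-rename), so a failed run leaves no partial final outputs.
#'
#' @param corpus_path Path to the corpus TSV.
#' @param kb_path Path to the knowledge-base TSV.
#' @param out_dir Output directory (created if needed).
#' @param labels_path Optional path to gold labels; enables evaluation.
#' @param seed_cui Seed phenotype concept (default `"C0006142"`).
#' @param dim,nonzeros,master_seed Elemental-vector parameters (defaults
#'   1000, 10, 1).
#' @param branching,max_depth,min_cosine Graph-growth parameters (defaults
#'   6, 3, 0).
#' @param steps,threshold,retain Spreading-activation parameters (defaults
#'   3, 0, 0).
#' @param verbose Print per-stage progress to stderr.
#' @return Invisibly, a list with the vector store, graphs, predictions and
#'   (if labels were given) the two `phenotype_eval` objects.
#' @export
run_pipeline <- function(corpus_path, kb_path, out_dir,
                         labels_path = NULL,
                         seed_cui = "C0006142",
                         dim = 1000, nonzeros = 10, master_seed = 1,
                         branching = 6, max_depth = 3, min_cosine = 0,
                         steps = 3, threshold = 0, retain = 0,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(corpus_path)) abort("`corpus_path` is required.")
  if (is.null(kb_path)) abort("`kb_path` is required.")
  if (is.null(out_dir)) abort("`out_dir` is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("reading corpus '%s'", corpus_path)
  corpus <- read_concept_corpus(corpus_path)
  say("reading knowledge base '%s'", kb_path)
  kb <- knowledge_base(read_knowledge_base(kb_path))

  say("building semantic vectors (dim %d, %d nonzeros, seed %d)", dim, nonzeros, master_seed)
  store <- build_semantic_vectors(corpus, dim = dim, nonzeros = nonzeros,
                                  master_seed = master_seed)
  write_vector_store(store, file.path(out_dir, "vectors.tsv"),
                     corpus_checksum = unname(tools::md5sum(corpus_path)))

  say("growing BFS graph around %s (branching %d, depth %d)", seed_cui, branching, max_depth)
  graph <- build_bfs_graph(store, seed_cui, branching = branching,
                           max_depth = max_depth, min_cosine = min_cosine)
  write_concept_graph(graph, file.path(out_dir, "graph.tsv"))

  say("filtering graph against the knowledge base")
  filtered <- filter_graph(graph, kb, verbose = verbose)
  write_concept_graph(filtered, file.path(out_dir, "graph.filtered.tsv"))

  say("classifying %d patients (steps %d, threshold %g)",
      length(unique(corpus$patient_id)), steps, threshold)
  predictions <- classify_patients(filtered, corpus, steps = steps,
                                   threshold = threshold, retain = retain)
  write_predictions(predictions, file.path(out_dir, "predictions.tsv"))
  baseline <- baseline_classify(corpus, seed_cui)
  write_predictions(baseline, file.path(out_dir, "baseline_predictions.tsv"))

  result <- list(
    store = store, graph = graph, filtered = filtered,
    predictions = predictions, baseline = baseline
  )

  if (!is.null(labels_path)) {
    say("evaluating against '%s'", labels_path)
    gold <- read_gold_labels(labels_path)
    result$graph_eval <- evaluate_predictions(predictions, gold)
    result$baseline_eval <- evaluate_predictions(baseline, gold)
    report <- bind_rows(
      dplyr::bind_cols(tibble(method = "GRAPH"), glance(result$graph_eval)),
      dplyr::bind_cols(tibble(method = "BASELINE"), glance(result$baseline_eval))
    )
    write_atomically(file.path(out_dir, "report.tsv"),
                     function(tmp) readr::write_tsv(report, tmp))
    result$report <- report
  }

  params <- list(
    seed_cui = seed_cui, dim = dim, nonzeros = nonzeros, master_seed = master_seed,
    branching = branching, max_depth = max_depth, min_cosine = min_cosine,
    steps = steps, threshold = threshold, retain = retain
  )
  write_manifest(out_dir, params, c(
    corpus = corpus_path, kb = kb_path,
    if (!is.null(labels_path)) c(labels = labels_path)
  ))
  invisible(result)
}

write_manifest <- function(out_dir, params, input_paths) {
  manifest <- list(
    tool = "phenospread",
    version = as.character(packageVersion("phenospread")),
    parameters = params,
    inputs = lapply(as.list(input_paths), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored. Values are parsed as numbers where possible, otherwise kept as
#' strings. Keys mirror the arguments of [run_pipeline()] and
#' [simulation_config()].
#'
#' @param path Path to the config file.
#' @return Named list of parameters.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: '%s'", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("Malformed config line (expected key=value): '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
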