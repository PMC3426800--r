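#' Persist and reload a semantic vector store
#'
#' Vectors are written as TSV: one row per CUI, a `cui` column followed by
#' `dim` float columns with 9 significant digits. A JSON sidecar
#' (`<path>.meta.json`) records the dimension, elemental nonzero count,
#' master seed and an optional corpus checksum, so the elemental pass can be
#' regenerated exactly.
#'
#' @param store A `semantic_vectors` object.
#' @param path Output TSV path.
#' @param corpus_checksum Optional checksum string of the source corpus file.
#' @export
write_vector_store <- function(store, path, corpus_checksum = NULL) {
  mat <- store$vectors
  write_atomically(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(paste(c("cui", paste0("v", seq_len(ncol(mat)))), collapse = "\t"), con, sep = "\n")
    body <- vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], formatC(mat[i, ], digits = 9, format = "g")), collapse = "\t")
    }, character(1))
    writeLines(body, con, sep = "\n")
  })
  meta <- list(
    dim = ncol(mat),
    nonzeros = store$nonzeros %||% NA_integer_,
    master_seed = store$master_seed %||% NA_integer_,
    corpus_checksum = corpus_checksum %||% NA_character_
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_vector_store
#' @return `read_vector_store()` returns a `semantic_vectors` object.
#' @export
read_vector_store <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    cui = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, lazy = FALSE)
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$cui
  colnames(mat) <- NULL
  store <- structure(list(vectors = mat, dim = ncol(mat)), class = "semantic_vectors")
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    store$nonzeros <- meta$nonzeros
    store$master_seed <- meta$master_seed
  }
  store
}
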