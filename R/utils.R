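# Internal helpers shared across modules.

# Polynomial rolling hash of a string, exact in double arithmetic.
# 31*h + byte stays far below 2^53 because h < 2^31, so no precision loss.
str_hash31 <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  h
}

# Derive a 32-bit-safe integer seed from a master seed and a string key.
derive_seed <- function(master_seed, key) {
  h <- str_hash31(key)
  as.integer((master_seed %% 2147483647 * 48271 + h) %% 2147483647)
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

assert_scalar_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("`%s` must be a single non-empty string.", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Percent with one decimal, rounding half away from zero (report convention).
percent_1dp <- function(x) {
  p <- x * 100
  sign(p) * floor(abs(p) * 10 + 0.5) / 10
}

# Atomic write: write to a temp file in the same directory, then rename.
write_atomically <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(sprintf("Could not write '%s'.", path))
  }
  invisible(path)
}
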