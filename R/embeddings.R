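#' Static word-embedding table
#'
#' A named matrix-like container: one fixed-dimension vector per word.
#' Lookups of unknown words return the zero vector with attribute
#' `oov = TRUE` so callers can drop them from means.
#'
#' @param words character vector.
#' @param vectors numeric matrix, one row per word.
#' @return Object of class `embedding_table`.
#' @export
embedding_table <- function(words, vectors) {
  stopifnot(length(words) == nrow(vectors))
  rownames(vectors) <- words
  structure(list(vectors = vectors, dim = ncol(vectors)), class = "embedding_table")
}

#' Deterministic random embedding table for a word list
#'
#' Hash-seeded standard-normal vectors scaled to roughly unit norm; the same
#' (word, dim, seed) always yields the same vector, independent of R's RNG.
#'
#' @param words character vector.
#' @param dim embedding dimension (default 50).
#' @param seed integer seed.
#' @return An [embedding_table].
#' @export
random_embedding_table <- function(words, dim = 50, seed = 1) {
  words <- unique(words)
  V <- t(vapply(words, hash_embed, numeric(dim), dim = dim, seed = seed))
  embedding_table(words, V)
}

#' Look up one word vector
#'
#' @param emb an [embedding_table].
#' @param word a single token.
#' @return Numeric vector; the zero vector (with attribute `oov = TRUE`) for
#'   unknown words.
#' @export
embed_lookup <- function(emb, word) {
  if (word %in% rownames(emb$vectors)) {
    emb$vectors[word, ]
  } else {
    structure(numeric(emb$dim), oov = TRUE)
  }
}

#' Write / read an embedding table in the standard text format
#'
#' Header line `n_words dim`, then one `word v1 ... v_dim` per line.
#'
#' @param emb an [embedding_table].
#' @param path file path.
#' @return `write_embeddings` returns `path` invisibly; `read_embeddings`
#'   an [embedding_table].
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb$vectors), emb$dim), con)
  for (i in seq_len(nrow(emb$vectors))) {
    writeLines(
      paste(
        rownames(emb$vectors)[i],
        paste(formatC(emb$vectors[i, ], format = "g", digits = 17), collapse = " ")
      ),
      con
    )
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop_arg("empty embedding file: %s", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || any(is.na(hdr))) {
    stop_arg("malformed embedding header at line 1 of %s", path)
  }
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) < n + 1L) stop_arg("embedding file truncated: %s", path)
  words <- character(n)
  V <- matrix(0, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != d + 1L) {
      stop_arg("malformed embedding at line %d of %s", i + 1L, path)
    }
    words[i] <- parts[1]
    V[i, ] <- as.numeric(parts[-1])
  }
  embedding_table(words, V)
}
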