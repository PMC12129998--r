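#' Toy contextual text encoder
#'
#' The text-encoder contract maps a token sequence to a matrix of per-token
#' vectors of fixed model dimension `d`. The toy instance (used throughout
#' the test profile) combines a deterministic hash-seeded token embedding
#' with a single residual local mixing layer:
#' \deqn{C_t = 0.5 E_t + 0.25 E_{t-1} + 0.25 E_{t+1}, \quad H = E + \tanh(C W)}
#' so encodings are mildly contextual while remaining fully reproducible
#' (same tokens, dim and seed give byte-identical output in any session).
#' Any encoder satisfying the contract (e.g. a pretrained bidirectional
#' transformer) can be substituted; the rest of the package only consumes
#' the per-token matrix.
#'
#' @param dim model dimension (production default 768; test profile 32).
#' @param seed integer seed for the frozen embedding and mixing weights.
#' @return Object of class `text_encoder` with elements `dim`, `seed` and
#'   `encode(tokens)`.
#' @export
toy_text_encoder <- function(dim = 32, seed = 1) {
  W <- hash_orth(dim, dim, "toy_encoder_mixing", seed)
  # lightweight per-encoder memoisation: token embeddings are pure functions
  cache <- new.env(parent = emptyenv())
  tok_embed <- function(tok) {
    if (is.null(cache[[tok]])) cache[[tok]] <- hash_embed(tok, dim, seed)
    cache[[tok]]
  }
  encode <- function(tokens) {
    if (length(tokens) == 0L) return(matrix(0, 0, dim))
    E <- t(vapply(tokens, tok_embed, numeric(dim)))
    n <- nrow(E)
    C <- 0.5 * E
    if (n > 1) {
      C[2:n, ] <- C[2:n, ] + 0.25 * E[1:(n - 1), , drop = FALSE]
      C[1:(n - 1), ] <- C[1:(n - 1), ] + 0.25 * E[2:n, , drop = FALSE]
      C[1, ] <- C[1, ] + 0.25 * E[1, ]
      C[n, ] <- C[n, ] + 0.25 * E[n, ]
    } else {
      C <- E
    }
    H <- E + tanh(C %*% W)
    rownames(H) <- NULL
    H
  }
  structure(list(dim = dim, seed = seed, encode = encode), class = "text_encoder")
}

# Frozen token embedding (pre-mixing) used by the decoder input; shares the
# encoder's hash space so generation and encoding see consistent tokens.
token_embedding <- function(token, dim, seed) hash_embed(token, dim, seed)

# Embed a relation label deterministically (the relation-label embedding is
# frozen after initialization; only the maps applied to it are trainable).
relation_embedder <- function(dim, seed = 1) {
  function(rtype) hash_embed(paste0("rel:", rtype), dim, seed)
}
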