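#' Embedding-average similarity between two texts
#'
#' Cosine similarity of the mean word vectors of a generated and a reference
#' text; out-of-vocabulary tokens are excluded from the means. A fully
#' out-of-vocabulary text raises an error (callers skip the record and log).
#'
#' @param generated,reference character token vectors.
#' @param emb an [embedding_table].
#' @return Similarity in `[-1, 1]`.
#' @export
embedding_average <- function(generated, reference, emb) {
  cosine_similarity(mean_embedding(generated, emb), mean_embedding(reference, emb))
}

#' DISTINCT-n diversity
#'
#' Pooled corpus-level ratio of distinct to total n-grams across all texts
#' (the dominant convention for generation diversity).
#'
#' @param texts list of character token vectors (a single vector is accepted).
#' @param n n-gram order (>= 1).
#' @return Ratio in `(0, 1]`.
#' @export
distinct_n <- function(texts, n = 1) {
  if (n < 1) stop_arg("n must be >= 1")
  if (is.character(texts)) texts <- list(texts)
  grams <- unlist(lapply(texts, function(toks) {
    L <- length(toks)
    if (L < n) return(character(0))
    vapply(seq_len(L - n + 1L), function(i) {
      paste(toks[i:(i + n - 1L)], collapse = "\u0001")
    }, character(1))
  }))
  if (length(grams) == 0L) stop_arg("no %d-gram in the given texts", n)
  length(unique(grams)) / length(grams)
}

#' Medical named-entity density of a text
#'
#' Fraction of token positions covered by a knowledge-graph surface-form
#' match, using longest-match non-overlapping scanning so multi-token
#' entities contribute their full token span and the ratio stays <= 1.
#'
#' @param text character token vector (non-empty).
#' @param kg a [med_kg] (its surface-form lexicon is the entity authority).
#' @return Ratio in `[0, 1]`.
#' @export
entity_density <- function(text, kg) {
  if (length(text) == 0L) stop_arg("empty text")
  m <- kg_match_forms(text, kg)
  covered <- logical(length(text))
  if (nrow(m)) {
    m <- m[order(-m$len, m$start), , drop = FALSE]
    for (r in seq_len(nrow(m))) {
      span <- m$start[r]:(m$start[r] + m$len[r] - 1L)
      if (!any(covered[span])) covered[span] <- TRUE
    }
  }
  sum(covered) / length(text)
}

#' Mean reciprocal rank
#'
#' Mean over queries of 1 / (rank of the first relevant item). Accepts
#' either a vector of 1-based gold ranks or a list of per-query relevance
#' vectors (logical / 0-1, ordered by the ranking).
#'
#' @param results integer vector of gold ranks, or list of relevance vectors.
#' @return MRR in `(0, 1]`.
#' @export
mean_reciprocal_rank <- function(results) {
  ranks <- if (is.list(results)) {
    vapply(results, function(rel) {
      w <- which(as.logical(rel))
      if (length(w) == 0L) stop_arg("a query has no relevant item")
      w[1]
    }, numeric(1))
  } else {
    as.numeric(results)
  }
  if (length(ranks) == 0L || any(ranks < 1)) stop_arg("invalid ranks")
  mean(1 / ranks)
}
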