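#' Cosine similarity of two vectors
#'
#' Symmetric and scale-invariant. The undefined 0/0 case (a zero vector on
#' either side) is returned as 0 with a warning rather than NaN.
#'
#' @param u,v numeric vectors of equal length.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop_arg("cosine: vectors of unequal dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("cosine similarity of a zero vector is undefined; returning 0")
    return(0)
  }
  sum(u * v) / (nu * nv)
}

#' Mean word embedding of a token sequence
#'
#' Out-of-vocabulary tokens are excluded from both numerator and denominator
#' (mapping them to zero vectors would bias means toward the origin).
#'
#' @param tokens character vector with at least one in-vocabulary token.
#' @param emb an [embedding_table].
#' @return Numeric vector of dimension `emb$dim`.
#' @export
mean_embedding <- function(tokens, emb) {
  known <- tokens[tokens %in% rownames(emb$vectors)]
  if (length(known) == 0L) stop_arg("no in-vocabulary token in sequence")
  colMeans(emb$vectors[known, , drop = FALSE])
}

#' Classify a question by surface-form pattern matching
#'
#' Scans the question for knowledge-graph entity surface forms and returns
#' the matched entity's disease category. When forms of several categories
#' match, the longest surface form wins (specificity), ties broken by
#' earliest match position, then lexicographic entity id. Returns `NA` when
#' no form occurs, signalling the caller to fall through to semantic soft
#' matching.
#'
#' @param question character vector of tokens (non-empty).
#' @param kg a [med_kg].
#' @return A category label, or `NA_character_` if nothing matches.
#' @export
classify_by_pattern <- function(question, kg) {
  if (length(question) == 0L) stop_arg("empty question")
  m <- kg_match_forms(question, kg)
  if (nrow(m) == 0L) return(NA_character_)
  m <- m[order(-m$len, m$start, m$entity_id), , drop = FALSE]
  m$category[1]
}

#' Classify a question by embedding soft match
#'
#' Returns the category of the entity maximizing the word-level cosine
#' similarity `max_i max_j cos(e_i^q, e_j^v)` between question-word vectors
#' and entity-name vectors. Entities with multi-token names are represented
#' by their mean word vector. Ties break by lexicographic entity id.
#'
#' @param question character vector of tokens.
#' @param kg a [med_kg].
#' @param emb an [embedding_table] covering question words and entity names.
#' @return A category label.
#' @export
soft_match_category <- function(question, kg, emb) {
  qtoks <- question[question %in% rownames(emb$vectors)]
  if (length(qtoks) == 0L) stop_arg("uncategorizable: no in-vocabulary question word")
  ents <- kg$entities[order(kg$entities$entity_id), , drop = FALSE]
  best_sim <- -Inf; best_cat <- NA_character_
  for (i in seq_len(nrow(ents))) {
    name_toks <- strsplit(ents$surface_forms[[i]][1], " ", fixed = TRUE)[[1]]
    ev <- tryCatch(mean_embedding(name_toks, emb), error = function(e) NULL)
    if (is.null(ev)) next
    for (qt in qtoks) {
      s <- cosine_similarity(emb$vectors[qt, ], ev)
      if (s > best_sim + 1e-12) { # strict improvement; earlier (lexicographic) id wins ties
        best_sim <- s
        best_cat <- ents$category[i]
      }
    }
  }
  if (is.na(best_cat)) stop_arg("uncategorizable: no comparable entity")
  best_cat
}

#' Build a Q&A retrieval database
#'
#' Precomputes a mean question vector per entry; entries whose questions are
#' fully out-of-vocabulary are dropped with a warning.
#'
#' @param questions list of token vectors.
#' @param answers list of token vectors.
#' @param doctor_ids character vector.
#' @param categories character vector of disease categories.
#' @param emb an [embedding_table].
#' @return Object of class `qa_database`.
#' @export
build_qa_database <- function(questions, answers, doctor_ids, categories, emb) {
  n <- length(questions)
  stopifnot(length(answers) == n, length(doctor_ids) == n, length(categories) == n)
  vecs <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    v <- tryCatch(mean_embedding(questions[[i]], emb), error = function(e) NULL)
    keep[i] <- !is.null(v)
    vecs[[i]] <- v
  }
  if (!all(keep)) warning(sum(!keep), " database entr(y/ies) fully out-of-vocabulary; dropped")
  structure(
    list(
      questions = questions[keep], answers = answers[keep],
      doctor_ids = doctor_ids[keep], categories = categories[keep],
      qvec = do.call(rbind, vecs[keep]), emb_dim = emb$dim
    ),
    class = "qa_database"
  )
}

#' Retrieve the top-K most similar same-category questions' answers
#'
#' Stage-two retrieval: within the database slice of `category`, rank entries
#' by cosine similarity of mean question vectors, descending; ties keep
#' stable database order. Returns `min(k, available)` results (a shortfall is
#' reported as a warning, not an error).
#'
#' @param question character vector of tokens.
#' @param db a `qa_database` from [build_qa_database()].
#' @param category disease category restricting the slice.
#' @param k number of candidates (>= 1).
#' @param emb an [embedding_table].
#' @return data.frame with columns `answer` (list), `doctor_id`, `similarity`,
#'   in non-increasing similarity order.
#' @export
retrieve_candidates <- function(question, db, category, k, emb) {
  if (k < 1) stop_arg("k must be >= 1")
  slice <- which(db$categories == category)
  if (length(slice) == 0L) stop_arg("no database entry for category '%s'", category)
  qv <- mean_embedding(question, emb)
  sims <- vapply(slice, function(i) cosine_similarity(qv, db$qvec[i, ]), numeric(1))
  ord <- order(-sims) # stable in R: ties keep database order
  take <- utils::head(ord, k)
  if (length(take) < k) {
    warning(sprintf(
      "retrieval shortfall: %d requested, %d available in category '%s'",
      k, length(take), category
    ))
  }
  out <- data.frame(
    doctor_id = db$doctor_ids[slice[take]],
    similarity = sims[take],
    stringsAsFactors = FALSE
  )
  out$answer <- db$answers[slice[take]]
  out[, c("answer", "doctor_id", "similarity")]
}
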