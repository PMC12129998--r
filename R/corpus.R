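#' One question-answering instance
#'
#' A `qa_record` bundles a tokenized user question, K candidate answers with
#' their answering doctors, the gold best-answer and recommended-doctor
#' indices, and a tokenized reference answer. Token sequences are
#' space-delimited word vectors (a segmenter for unsegmented text is a
#' preprocessing hook upstream of this type).
#'
#' @param question character vector of question tokens.
#' @param candidates list of K character vectors (candidate answers).
#' @param candidate_doctors character vector of K doctor ids.
#' @param gold_answer_index 1-based index of the best answer.
#' @param gold_doctor_index 1-based index of the recommended doctor; by
#'   convention the doctor who authored the best answer.
#' @param reference_answer character vector of reference-answer tokens.
#' @param category optional disease-category label.
#' @param extra named list of unknown fields preserved on file round-trips.
#' @return An object of class `qa_record`.
#' @export
qa_record <- function(question, candidates, candidate_doctors,
                      gold_answer_index, gold_doctor_index,
                      reference_answer, category = NA_character_,
                      extra = list()) {
  k <- length(candidates)
  if (k == 0L || length(candidate_doctors) != k) {
    stop_arg("candidates and candidate_doctors must have equal positive length")
  }
  if (gold_answer_index < 1 || gold_answer_index > k ||
    gold_doctor_index < 1 || gold_doctor_index > k) {
    stop_arg("gold indices must lie in [1, K]")
  }
  if (length(question) == 0L || length(reference_answer) == 0L ||
    any(vapply(candidates, length, integer(1)) == 0L)) {
    stop_arg("token sequences must be non-empty")
  }
  structure(
    list(
      question = question, candidates = candidates,
      candidate_doctors = candidate_doctors,
      gold_answer_index = as.integer(gold_answer_index),
      gold_doctor_index = as.integer(gold_doctor_index),
      reference_answer = reference_answer, category = category,
      extra = extra
    ),
    class = "qa_record"
  )
}

#' Doctor profile
#'
#' The profile word list is the empirical top-100 high-frequency words of the
#' doctor's historical answers, ordered by descending frequency (ties
#' lexicographic). Downstream the profile is encoded as one token sequence.
#'
#' @param doctor_id opaque identifier.
#' @param profile_words ordered character vector, length <= 100.
#' @param home_category disease category of the doctor's expertise
#'   (synthetic corpora only; `NA` for real data).
#' @return An object of class `doctor_profile`.
#' @export
doctor_profile <- function(doctor_id, profile_words, home_category = NA_character_) {
  if (length(profile_words) > 100L) stop_arg("profile_words longer than 100")
  if (any(!nzchar(profile_words))) stop_arg("profile words must be non-empty")
  structure(
    list(
      doctor_id = doctor_id, profile_words = profile_words,
      home_category = home_category
    ),
    class = "doctor_profile"
  )
}

question_word_pool <- function() {
  c(
    "hello", "doctor", "my", "father", "mother", "has", "had", "pain",
    "for", "days", "weeks", "what", "should", "we", "do", "please", "help",
    "advice", "worried", "about", "feel", "recently", "hospital", "need",
    "is", "it", "serious", "can", "recover"
  )
}

answer_word_pool <- function() {
  c(
    "recommend", "rest", "take", "medicine", "check", "hospital", "recovery",
    "care", "diet", "exercise", "follow", "doctor", "advice", "important",
    "treatment", "regular", "avoid", "observe", "timely", "attention",
    "improve", "condition", "patient", "consult", "department", "review"
  )
}

category_terms <- function(cat, n = 4) sprintf("%s_term%02d", cat, seq_len(n))

# compose a token sequence: given parts are shuffled together with filler
compose_text <- function(specific, generic_pool, n_generic) {
  generic <- sample(generic_pool, n_generic, replace = TRUE)
  toks <- unname(c(specific, generic))
  toks[sample(length(toks))]
}

#' Generate a synthetic QA corpus over a knowledge graph
#'
#' Emulates the statistical structure a hybrid retrieve-rank-generate QA
#' architecture assumes: each question mentions entities of one disease
#' category; the gold candidate answer is written by that category's expert
#' doctor and is entity-dense (>= 2 category surface forms); the K-1
#' distractor answers come from experts of other categories and mention at
#' most one off-category entity (retrieval pulls them by superficial
#' similarity only); the reference answer shares at least one entity surface
#' form with the gold candidate so that copy-mode decoding is rewarded.
#' Doctor profiles are the empirical top-100 frequency words of each
#' doctor's generated answers. Deterministic per seed.
#'
#' @param kg a [med_kg] with at least `k` categories.
#' @param n_records number of QA records (>= 1).
#' @param k candidates (and candidate doctors) per record; default 4.
#' @param seed integer seed.
#' @return list with elements `records` (list of [qa_record]) and
#'   `profiles` (list of [doctor_profile]).
#' @export
generate_corpus <- function(kg, n_records, k = 4, seed = 1) {
  if (n_records < 1) stop_arg("n_records must be >= 1")
  if (k > length(kg$categories)) {
    stop_arg("k = %d exceeds the %d categories in the graph", k, length(kg$categories))
  }
  with_seed(derive_seed(seed, "corpus"), {
    cats <- kg$categories
    forms_of <- lapply(cats, function(cat) {
      f <- unlist(kg$entities$surface_forms[kg$entities$category == cat])
      f[!grepl(" ", f, fixed = TRUE)] # single-token forms for in-text use
    })
    names(forms_of) <- cats
    doctor_of <- stats::setNames(paste0("doc_", cats), cats)
    answers_by_doctor <- stats::setNames(
      replicate(length(cats), list(), simplify = FALSE), doctor_of
    )

    # single-token surface form of an entity, and one-hop neighbourhoods:
    # expert answers discuss the concepts *linked* to the asked condition
    # (treatments, examinations, symptoms), which is what makes the
    # knowledge subgraph informative for generation
    form1_of <- function(eid) {
      f <- kg$entities$surface_forms[[match(eid, kg$entities$entity_id)]]
      f <- f[!grepl(" ", f, fixed = TRUE)]
      if (length(f)) f[1] else NA_character_
    }
    neighbors_of <- function(eids) {
      rel <- kg$relations
      unique(c(rel$tail[rel$head %in% eids], rel$head[rel$tail %in% eids]))
    }
    entity_of_form <- kg_token_entity(kg)

    # Expert answers are topically dense (about half the tokens are category
    # entities or terms), mirroring how specialists answer inside their
    # domain; off-category distractors read mostly generic.
    make_gold_answer <- function(cat, q_entities) {
      neigh <- setdiff(neighbors_of(q_entities), q_entities)
      neigh_forms <- stats::na.omit(vapply(neigh, form1_of, character(1)))
      n_need <- sample(3:4, 1)
      ents <- sample(neigh_forms, min(n_need - 1, length(neigh_forms)))
      pool <- setdiff(forms_of[[cat]], ents)
      if (length(ents) < n_need && length(pool)) {
        ents <- c(ents, sample(pool, min(n_need - length(ents), length(pool))))
      }
      terms <- sample(category_terms(cat), sample(3:4, 1), replace = TRUE)
      compose_text(c(ents, terms), answer_word_pool(), sample(4:6, 1))
    }
    make_distractor_answer <- function(cat) {
      ents <- sample(forms_of[[cat]], 1)
      terms <- sample(category_terms(cat), 2, replace = TRUE)
      compose_text(c(ents, terms), answer_word_pool(), sample(8:10, 1))
    }

    records <- vector("list", n_records)
    for (r in seq_len(n_records)) {
      # patients name their condition repeatedly: 2 distinct entity mentions
      # plus 2 repeated mentions among ~6 generic tokens
      cat <- sample(cats, 1)
      q_ents <- sample(forms_of[[cat]], min(2, length(forms_of[[cat]])))
      q_ents <- c(q_ents, sample(q_ents, 2, replace = TRUE))
      question <- compose_text(q_ents, question_word_pool(), sample(5:7, 1))

      q_entity_ids <- unname(entity_of_form[unique(q_ents)])
      gold <- make_gold_answer(cat, q_entity_ids)
      other_cats <- sample(setdiff(cats, cat), k - 1)
      distractors <- lapply(other_cats, make_distractor_answer)
      answer_cats <- c(cat, other_cats)
      answers <- c(list(gold), distractors)
      doctors <- unname(doctor_of[answer_cats])

      perm <- sample(k)
      answers <- answers[perm]
      doctors <- doctors[perm]
      gold_idx <- which(perm == 1L)

      for (i in seq_len(k)) {
        d <- doctors[i]
        answers_by_doctor[[d]][[length(answers_by_doctor[[d]]) + 1L]] <- answers[[i]]
      }

      # the reference discusses the concepts linked to the asked condition:
      # some shared with the gold candidate (>= 1 surface form, rewarding
      # copy-mode decoding) and some only reachable through the knowledge
      # graph neighbourhood (rewarding graph-context generation)
      gold_ents <- intersect(gold, forms_of[[cat]])
      neigh_forms <- stats::na.omit(vapply(
        setdiff(neighbors_of(q_entity_ids), q_entity_ids), form1_of, character(1)
      ))
      unshared <- setdiff(neigh_forms, gold_ents)
      ref_ents <- unique(c(
        sample(gold_ents, min(2, length(gold_ents))),
        if (length(unshared)) sample(unshared, min(2, length(unshared)))
      ))
      terms <- sample(category_terms(cat), sample(2:4, 1), replace = TRUE)
      reference <- compose_text(c(ref_ents, terms), answer_word_pool(), sample(4:6, 1))

      records[[r]] <- qa_record(
        question = question, candidates = answers,
        candidate_doctors = doctors,
        gold_answer_index = gold_idx, gold_doctor_index = gold_idx,
        reference_answer = reference, category = cat
      )
    }

    profiles <- lapply(cats, function(cat) {
      d <- doctor_of[[cat]]
      words <- unlist(answers_by_doctor[[d]])
      if (is.null(words)) words <- category_terms(cat) # doctor never sampled
      tab <- table(words)
      ord <- order(-as.integer(tab), names(tab))
      doctor_profile(d, utils::head(names(tab)[ord], 100L), home_category = cat)
    })
    list(records = records, profiles = profiles)
  })
}

#' Split a corpus into train/dev/test
#'
#' Default proportions 60/20/20 in corpus order (the generator already
#' randomizes record order), exact within rounding of one record.
#'
#' @param records list of [qa_record].
#' @param proportions numeric length-3 vector summing to 1.
#' @return Named list of three lists: `train`, `dev`, `test`.
#' @export
split_corpus <- function(records, proportions = c(0.6, 0.2, 0.2)) {
  stopifnot(length(proportions) == 3, abs(sum(proportions) - 1) < 1e-8)
  n <- length(records)
  n_train <- round(proportions[1] * n)
  n_dev <- round(proportions[2] * n)
  idx <- seq_len(n)
  list(
    train = records[idx <= n_train],
    dev = records[idx > n_train & idx <= n_train + n_dev],
    test = records[idx > n_train + n_dev]
  )
}

# ---- Vocabulary ------------------------------------------------------------

#' Build a token vocabulary from a corpus
#'
#' Indices are 1-based: positions 1-4 are the reserved symbols `<pad>`,
#' `<unk>`, `<bos>`, `<eos>`; observed tokens follow in descending frequency
#' (ties lexicographic), making the mapping deterministic.
#'
#' @param records list of [qa_record].
#' @param profiles optional list of [doctor_profile] whose words join the pool.
#' @return A `qa_vocab`: list with `tokens` (index -> token) and `index`
#'   (token -> index, named integer vector).
#' @export
build_vocab <- function(records, profiles = NULL) {
  if (length(records) == 0L) stop_arg("cannot build a vocabulary from an empty corpus")
  toks <- unlist(lapply(records, function(r) {
    c(r$question, unlist(r$candidates), r$reference_answer)
  }))
  if (!is.null(profiles)) {
    toks <- c(toks, unlist(lapply(profiles, `[[`, "profile_words")))
  }
  tab <- table(toks)
  ord <- order(-as.integer(tab), names(tab))
  tokens <- c("<pad>", "<unk>", "<bos>", "<eos>", names(tab)[ord])
  structure(
    list(tokens = tokens, index = stats::setNames(seq_along(tokens), tokens)),
    class = "qa_vocab"
  )
}

#' Encode tokens as vocabulary indices
#'
#' Tokens absent from the vocabulary map to the `<unk>` index (2).
#'
#' @param tokens character vector.
#' @param vocab a `qa_vocab` from [build_vocab()].
#' @return Integer vector of indices.
#' @export
encode_tokens <- function(tokens, vocab) {
  idx <- vocab$index[tokens]
  idx[is.na(idx)] <- 2L
  unname(idx)
}

# ---- Line-delimited record I/O --------------------------------------------

record_to_json <- function(r) {
  x <- c(
    list(
      question = r$question,
      candidates = lapply(r$candidates, identity),
      doctors = r$candidate_doctors,
      gold_answer = r$gold_answer_index,
      gold_doctor = r$gold_doctor_index,
      reference = r$reference_answer,
      category = r$category
    ),
    r$extra
  )
  jsonlite::toJSON(x, auto_unbox = FALSE, null = "null", na = "null")
}

#' Write / read a QA corpus in line-delimited JSON
#'
#' One record per line with keys `question`, `candidates`, `doctors`,
#' `gold_answer`, `gold_doctor`, `reference`, `category`. Unknown keys are
#' preserved on round-trip. Indices are stored 1-based.
#'
#' @param records list of [qa_record].
#' @param path file path.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` a record list.
#' @export
write_corpus <- function(records, path) {
  lines <- vapply(records, function(r) as.character(record_to_json(r)), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty corpus file: ", path)
    return(list())
  }
  known <- c(
    "question", "candidates", "doctors", "gold_answer", "gold_doctor",
    "reference", "category"
  )
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(
      jsonlite::fromJSON(lines[i],
        simplifyVector = TRUE, simplifyDataFrame = FALSE, simplifyMatrix = FALSE
      ),
      error = function(e) stop_arg("parse error at line %d of %s: %s", i, path, conditionMessage(e))
    )
    miss <- setdiff(setdiff(known, "category"), names(x))
    if (length(miss)) {
      stop_arg("parse error at line %d of %s: missing key(s) %s", i, path, paste(miss, collapse = ", "))
    }
    cand <- lapply(x$candidates, function(a) as.character(unlist(a)))
    out[[i]] <- qa_record(
      question = as.character(unlist(x$question)),
      candidates = cand,
      candidate_doctors = as.character(unlist(x$doctors)),
      gold_answer_index = as.integer(x$gold_answer),
      gold_doctor_index = as.integer(x$gold_doctor),
      reference_answer = as.character(unlist(x$reference)),
      category = if (is.null(x$category) || is.null(unlist(x$category))) NA_character_ else as.character(unlist(x$category)),
      extra = x[setdiff(names(x), known)]
    )
  }
  out
}

#' Write / read doctor profiles as line-delimited JSON
#'
#' @param profiles list of [doctor_profile].
#' @param path file path.
#' @return `write_profiles` returns `path` invisibly; `read_profiles` a list.
#' @export
write_profiles <- function(profiles, path) {
  lines <- vapply(profiles, function(p) {
    as.character(jsonlite::toJSON(
      list(
        doctor_id = p$doctor_id, profile_words = p$profile_words,
        home_category = p$home_category
      ),
      auto_unbox = FALSE, na = "null"
    ))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i]),
      error = function(e) stop_arg("parse error at line %d of %s", i, path)
    )
    hc <- unlist(x$home_category)
    doctor_profile(
      as.character(unlist(x$doctor_id)), as.character(unlist(x$profile_words)),
      if (is.null(hc)) NA_character_ else as.character(hc)
    )
  })
}
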