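test_that("knowledge graph generation is deterministic and well-shaped", {
  kg1 <- generate_knowledge_graph(2, 3, seed = 7)
  kg2 <- generate_knowledge_graph(2, 3, seed = 7)
  expect_identical(kg1, kg2)
  expect_equal(nrow(kg1$entities), 6)
  expect_gte(nrow(kg1$relations), 4)
  expect_equal(length(kg1$categories), 2)
  expect_false(identical(kg1, generate_knowledge_graph(2, 3, seed = 8)))
})

test_that("degenerate single-entity graph has no edges", {
  kg <- generate_knowledge_graph(1, 1, seed = 3)
  expect_equal(nrow(kg$entities), 1)
  expect_equal(nrow(kg$relations), 0)
})

test_that("every entity is reachable from its category hub within one hop", {
  kg <- generate_knowledge_graph(3, 4, seed = 11)
  for (cat in kg$categories) {
    hub <- cat
    members <- setdiff(kg$entities$entity_id[kg$entities$category == cat], hub)
    one_hop <- unique(c(
      kg$relations$tail[kg$relations$head == hub],
      kg$relations$head[kg$relations$tail == hub]
    ))
    expect_true(all(members %in% one_hop))
  }
})

test_that("graph construction rejects invalid inputs", {
  expect_error(generate_knowledge_graph(0, 3), "must be >= 1")
  expect_error(generate_knowledge_graph(2, 3, relation_vocab = character(0)), "empty")
  expect_error(
    med_kg(
      data.frame(entity_id = "a", category = "c", surface_forms = I(list("a"))),
      data.frame(head = "a", rtype = "treatment", tail = "missing"),
      "c", default_relation_vocab()
    ),
    "dangling"
  )
})

test_that("generated corpus has the declared candidate structure", {
  kg <- generate_knowledge_graph(4, 5, seed = 7)
  corpus <- generate_corpus(kg, 40, 4, seed = 1)
  expect_length(corpus$records, 40)
  gold_idx <- integer(0)
  for (r in corpus$records) {
    expect_length(r$candidates, 4)
    expect_length(unique(r$candidate_doctors), 4)
    expect_equal(r$gold_doctor_index, r$gold_answer_index)
    gold_idx <- c(gold_idx, r$gold_answer_index)
  }
  # gold positions shuffled across the full range
  expect_setequal(unique(gold_idx), 1:4)
  expect_identical(corpus, generate_corpus(kg, 40, 4, seed = 1))
})

test_that("gold candidates are category-entity dense and distractors are not", {
  kg <- generate_knowledge_graph(4, 5, seed = 7)
  corpus <- generate_corpus(kg, 30, 4, seed = 2)
  forms_by_cat <- split(
    unlist(kg$entities$surface_forms)[!grepl(" ", unlist(kg$entities$surface_forms))],
    rep(kg$entities$category, lengths(kg$entities$surface_forms))[
      !grepl(" ", unlist(kg$entities$surface_forms))
    ]
  )
  for (r in corpus$records) {
    cat_forms <- forms_by_cat[[r$category]]
    expect_gte(sum(r$question %in% cat_forms), 1)
    gold_overlap <- sum(r$candidates[[r$gold_answer_index]] %in% cat_forms)
    expect_gte(gold_overlap, 2)
    for (k in setdiff(seq_along(r$candidates), r$gold_answer_index)) {
      # learnability: strictly more in-category overlap for the gold answer
      expect_lt(sum(r$candidates[[k]] %in% cat_forms), gold_overlap)
    }
    expect_gte(length(intersect(r$reference_answer, r$candidates[[r$gold_answer_index]])), 1)
  }
})

test_that("doctor profiles are the top-frequency words of their answers", {
  kg <- generate_knowledge_graph(4, 5, seed = 7)
  corpus <- generate_corpus(kg, 60, 4, seed = 3)
  authored <- list()
  for (r in corpus$records) {
    for (k in seq_along(r$candidates)) {
      d <- r$candidate_doctors[k]
      authored[[d]] <- c(authored[[d]], r$candidates[[k]])
    }
  }
  for (p in corpus$profiles) {
    words <- authored[[p$doctor_id]]
    expect_equal(length(p$profile_words), min(100L, length(unique(words))))
    # profile order matches empirical frequency, ties lexicographic
    tab <- table(words)
    ord <- order(-as.integer(tab), names(tab))
    expect_identical(p$profile_words, utils::head(names(tab)[ord], 100L))
  }
})

test_that("corpus generation rejects k beyond the category count", {
  kg <- generate_knowledge_graph(3, 4, seed = 7)
  expect_error(generate_corpus(kg, 10, 4, seed = 1), "exceeds")
})

test_that("splits follow 60/20/20 within one record", {
  recs <- generate_corpus(generate_knowledge_graph(4, 5, seed = 7), 201, 4, seed = 1)$records
  sp <- split_corpus(recs)
  expect_equal(length(sp$train), round(0.6 * 201))
  expect_equal(length(sp$dev), round(0.2 * 201))
  expect_equal(length(sp$train) + length(sp$dev) + length(sp$test), 201)
})

test_that("vocabulary is deterministic with reserved symbols and UNK fallback", {
  cc <- tiny_corpus()
  v1 <- build_vocab(cc$records, cc$profiles)
  v2 <- build_vocab(cc$records, cc$profiles)
  expect_identical(v1, v2)
  expect_identical(v1$tokens[1:4], c("<pad>", "<unk>", "<bos>", "<eos>"))
  n_distinct <- length(unique(c(
    unlist(lapply(cc$records, function(r) c(r$question, unlist(r$candidates), r$reference_answer))),
    unlist(lapply(cc$profiles, `[[`, "profile_words"))
  )))
  expect_length(v1$tokens, n_distinct + 4L)
  expect_equal(unname(encode_tokens("never_seen_token_xyz", v1)), 2L)
  # frequency-descending ordering over observed tokens
  counts <- table(c(
    unlist(lapply(cc$records, function(r) c(r$question, unlist(r$candidates), r$reference_answer))),
    unlist(lapply(cc$profiles, `[[`, "profile_words"))
  ))
  expect_true(all(diff(as.integer(counts[v1$tokens[-(1:4)]])) <= 0))
})
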