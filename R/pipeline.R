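#' Run the full pipeline: synthesize, retrieve, train, generate, evaluate
#'
#' Stages, each seeded by a documented split of the global seed so it is
#' independently reproducible:
#' \enumerate{
#'   \item synthesize a knowledge graph and QA corpus, split 60/20/20;
#'   \item build the word-embedding table and a retrieval database from the
#'     training split, and measure retrieval-stage category classification
#'     on the dev split;
#'   \item train the multi-task model on the training split;
#'   \item generate answers and rank candidates/doctors on the test split;
#'   \item compute the automatic metrics (embedding average, DISTINCT-1/2,
#'     entity density, answer and doctor MRR).
#' }
#' All artifacts (corpus, graph tables, embeddings, generations, metric
#' report and a deterministic manifest) are written under `out_dir`.
#'
#' @param config a configuration list, see [validate_config()].
#' @param out_dir output directory (created if missing).
#' @param verbose print stage progress.
#' @return List with `metrics`, `history`, `generations` and file `paths`
#'   (invisibly writes everything under `out_dir`).
#' @export
run_pipeline <- function(config = toy_profile(), out_dir = tempfile("qa_run_"),
                         verbose = FALSE) {
  config <- validate_config(config, base = toy_profile())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))

  # -- stage 1: synthesize ---------------------------------------------------
  say("stage synth")
  kg <- generate_knowledge_graph(
    config$corpus$n_categories, config$corpus$entities_per_category,
    seed = derive_seed(seed, "stage_kg")
  )
  corpus <- generate_corpus(
    kg, config$corpus$n_records, config$corpus$k,
    seed = derive_seed(seed, "stage_corpus")
  )
  splits <- split_corpus(corpus$records)
  write_kg(kg, file.path(out_dir, "kg"))
  write_corpus(corpus$records, file.path(out_dir, "corpus.jsonl"))
  write_profiles(corpus$profiles, file.path(out_dir, "profiles.jsonl"))

  # -- stage 2: retrieval ----------------------------------------------------
  say("stage retrieve")
  vocab <- build_vocab(corpus$records, corpus$profiles)
  emb <- random_embedding_table(
    vocab$tokens, config$embeddings$dim,
    seed = derive_seed(seed, "stage_emb")
  )
  write_embeddings(emb, file.path(out_dir, "embeddings.txt"))
  db <- build_qa_database(
    questions = lapply(splits$train, `[[`, "question"),
    answers = lapply(splits$train, function(r) r$candidates[[r$gold_answer_index]]),
    doctor_ids = vapply(splits$train, function(r) r$candidate_doctors[r$gold_answer_index], character(1)),
    categories = vapply(splits$train, `[[`, character(1), "category"),
    emb = emb
  )
  cls <- vapply(splits$dev, function(r) {
    hit <- classify_by_pattern(r$question, kg)
    if (is.na(hit)) hit <- soft_match_category(r$question, kg, emb)
    identical(hit, r$category)
  }, logical(1))
  retrieval_accuracy <- mean(cls)

  # -- stage 3: train --------------------------------------------------------
  say("stage train")
  model <- init_model(vocab, config, seed = derive_seed(seed, "stage_model"))
  fit <- train_model(
    model, splits$train, splits$dev, kg, corpus$profiles,
    epochs = config$train$epochs, batch_size = config$train$batch_size,
    lr = config$train$lr, warmup = config$train$warmup,
    seed = derive_seed(seed, "stage_train"),
    loss_scale = config$train$loss_scale,
    weight_decay = config$train$weight_decay,
    graph_dropout = config$train$graph_dropout, verbose = verbose
  )
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"), row.names = FALSE)

  # -- stage 4: generate + rank on test --------------------------------------
  say("stage generate")
  test_encs <- lapply(splits$test, encode_record,
    model = fit$model, kg = kg, profiles = corpus$profiles
  )
  gens <- vector("list", length(splits$test))
  for (i in seq_along(splits$test)) {
    gens[[i]] <- decode_answer(
      fit$model, splits$test[[i]], kg, corpus$profiles,
      beam = config$decode$beam, topk = config$decode$topk,
      max_len = config$decode$max_len, min_len = config$decode$min_len,
      rep_penalty = config$decode$rep_penalty,
      seed = derive_seed(seed, paste0("decode_", i)),
      sample = config$decode$sample, enc = test_encs[[i]]
    )
  }
  writeLines(
    vapply(gens, function(g) paste(g$tokens, collapse = " "), character(1)),
    file.path(out_dir, "generations.txt")
  )

  # -- stage 5: evaluate -----------------------------------------------------
  say("stage evaluate")
  test_ranks <- evaluate_ranking(test_encs, fit$model$theta)
  gen_texts <- lapply(gens, `[[`, "tokens")
  usable <- vapply(gen_texts, function(g) {
    length(g) > 0 && any(g %in% rownames(emb$vectors))
  }, logical(1))
  ea <- mean(vapply(which(usable), function(i) {
    embedding_average(gen_texts[[i]], splits$test[[i]]$reference_answer, emb)
  }, numeric(1)))
  dens <- mean(vapply(gen_texts[lengths(gen_texts) > 0], entity_density, numeric(1), kg = kg))
  distractors <- unlist(lapply(splits$test, function(r) {
    lapply(r$candidates[-r$gold_answer_index], identity)
  }), recursive = FALSE)
  metrics <- list(
    embedding_average = ea,
    distinct_1 = distinct_n(gen_texts[lengths(gen_texts) > 0], 1),
    distinct_2 = distinct_n(gen_texts[lengths(gen_texts) > 1], 2),
    entity_density = dens,
    distractor_entity_density = mean(vapply(distractors, entity_density, numeric(1), kg = kg)),
    answer_mrr = mean_reciprocal_rank(test_ranks$answer_rank),
    doctor_mrr = mean_reciprocal_rank(test_ranks$doctor_rank),
    retrieval_accuracy = retrieval_accuracy,
    n_test = length(splits$test)
  )
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("medkgqa")),
    seed = seed,
    config = config,
    stage_seeds = list(
      kg = derive_seed(seed, "stage_kg"),
      corpus = derive_seed(seed, "stage_corpus"),
      emb = derive_seed(seed, "stage_emb"),
      model = derive_seed(seed, "stage_model"),
      train = derive_seed(seed, "stage_train")
    ),
    metrics = metrics
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    metrics = metrics, history = fit$history, generations = gens,
    model = fit$model, kg = kg, corpus = corpus, splits = splits,
    paths = list(out_dir = out_dir)
  ))
}
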