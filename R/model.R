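#' Initialize a question-answering model
#'
#' Builds the frozen encoder stack (toy text encoder, KRGAT parameters,
#' knowledge-aware attention and gate parameters) and the trainable output
#' layer (decoder MLP, copy scorer, generation gate, two ranking heads and
#' the three uncertainty weights). Ablation switches: `use_kg = FALSE`
#' replaces every association matrix by zeros and every subgraph by the
#' empty subgraph; `use_doctor = FALSE` removes doctor encodings from the
#' answer interaction and from the recommendation head.
#'
#' @param vocab a `qa_vocab` from [build_vocab()].
#' @param config configuration list, see [default_config()]; the relevant
#'   keys are `encoder$dim`, `krgat$layers`, `attention$score_form`,
#'   `gate$per_channel`, `model$use_kg`, `model$use_doctor`.
#' @param seed integer seed for the frozen initializations.
#' @return Object of class `qa_model`.
#' @export
init_model <- function(vocab, config = default_config(), seed = 1) {
  d <- config$encoder$dim
  sf <- config$attention$score_form
  V <- length(vocab$tokens)
  tok_emb <- t(vapply(vocab$tokens, token_embedding, numeric(d), dim = d, seed = seed))
  h_dim <- d
  x_dim <- 3 * d # decoder input: [prev-token emb; question ctx; graph ctx]
  init <- function(nr, nc, tag) hash_matrix(nr, nc, tag, seed, sd = 0.1)
  theta <- list(
    dec_W1 = init(h_dim, x_dim, "dec_W1"),
    dec_b1 = numeric(h_dim),
    dec_W2 = init(V, h_dim, "dec_W2"),
    dec_b2 = numeric(V),
    W_c = init(h_dim, d, "W_c"),
    w_gate = numeric(2 * d),
    b_gate = 0,
    w_rank = numeric(3 * d),
    W_bil_rank = matrix(0, d, d),
    b_rank = 0,
    w_doc = numeric(if (isFALSE(config$model$use_doctor)) 3 * d else 5 * d),
    W_bil_doc_a = matrix(0, d, d),
    W_bil_doc_d = matrix(0, d, d),
    b_doc = 0,
    log_sigma = c(gen = 0, rank = 0, doc = 0)
  )
  structure(
    list(
      dim = d, vocab = vocab, tok_emb = tok_emb, seed = seed,
      config = config,
      use_kg = !isFALSE(config$model$use_kg),
      use_doctor = !isFALSE(config$model$use_doctor),
      encoder = toy_text_encoder(d, seed),
      rel_embedder = relation_embedder(d, seed),
      krgat = krgat_params(d, layers = config$krgat$layers, seed = seed,
        leaky_slope = config$krgat$leaky_slope %||% 0.2),
      attn = list(
        self_q = attn_params(d, "self_q", seed, sf),
        self_a = attn_params(d, "self_a", seed, sf),
        self_d = attn_params(d, "self_d", seed, sf),
        inter_qa = attn_params(d, "inter_qa", seed, sf),
        inter_aq = attn_params(d, "inter_aq", seed, sf),
        inter_ad = attn_params(d, "inter_ad", seed, sf),
        inter_dq = attn_params(d, "inter_dq", seed, sf),
        global_qa = attn_params(d, "global_qa", seed, sf)
      ),
      proj = list(
        W = hash_orth(d, 2 * d, "answer_proj_W", seed, gain = 1 / sqrt(2)),
        b = numeric(d)
      ),
      gate = gate_params(d, hidden = d, seed = seed,
        per_channel = isTRUE(config$gate$per_channel)),
      theta = theta,
      doctor_cache = new.env(parent = emptyenv())
    ),
    class = "qa_model"
  )
}

#' Knock the knowledge graph out of a trained model
#'
#' Returns the same model (same trained parameters) with the knowledge
#' graph disabled: every association matrix is zeroed and every subgraph is
#' empty, so the graph context the decoder consumes is the zero vector.
#' Used to measure the trained model's causal reliance on the graph;
#' contrast with retraining from scratch under `config$model$use_kg =
#' FALSE`, where the optimizer can re-route around the missing component.
#'
#' @param model a `qa_model`.
#' @return The modified `qa_model`.
#' @export
knockout_kg <- function(model) {
  model$use_kg <- FALSE
  model$doctor_cache <- new.env(parent = emptyenv())
  model
}

#' @export
print.qa_model <- function(x, ...) {
  cat(sprintf(
    "<qa_model> dim %d, |V| %d, krgat layers %d, use_kg %s, use_doctor %s\n",
    x$dim, length(x$vocab$tokens), length(x$krgat$layers), x$use_kg, x$use_doctor
  ))
  invisible(x)
}

# Self-attended doctor encoding, cached per doctor id (profiles are static).
doctor_self_encoding <- function(model, doctor_id, profiles, kg) {
  key <- paste0(doctor_id, if (model$use_kg) ":kg" else ":nokg")
  if (!is.null(model$doctor_cache[[key]])) return(model$doctor_cache[[key]])
  prof <- NULL
  for (p in profiles) if (p$doctor_id == doctor_id) prof <- p
  if (is.null(prof)) stop_arg("unknown doctor id '%s'", doctor_id)
  toks <- prof$profile_words
  H <- model$encoder$encode(toks)
  M <- if (model$use_kg) {
    build_assoc_matrix(toks, toks, kg, model$rel_embedder, model$dim)
  } else {
    zero_assoc(length(toks), length(toks), model$dim)
  }
  out <- list(
    tokens = toks, H_enc = H,
    H_self = H + knowledge_self_attention(H, M, model$attn$self_d)$H
  )
  model$doctor_cache[[key]] <- out
  out
}

#' Encode one QA record through the full attention stack
#'
#' Runs the text encoder, subgraph extraction + KRGAT, knowledge-aware
#' self-attention, global + word-level interaction attention and gated
#' fusion for the question, every candidate answer and every candidate
#' doctor, returning the fused encodings and their pooled contexts.
#'
#' @param record a [qa_record].
#' @param model a `qa_model` from [init_model()].
#' @param kg the [med_kg].
#' @param profiles list of [doctor_profile] covering the record's doctors.
#' @return List of class `record_encoding` with fused matrices (`H_q`,
#'   `H_a` list, `H_d` list), pooled contexts (`pq`, `pa`, `pd`, `pg`),
#'   subgraph node encodings and the record itself.
#' @export
encode_record <- function(record, model, kg, profiles) {
  d <- model$dim
  K <- length(record$candidates)
  qtoks <- record$question
  assoc <- function(ta, tb) {
    if (model$use_kg) {
      build_assoc_matrix(ta, tb, kg, model$rel_embedder, d)
    } else {
      zero_assoc(length(ta), length(tb), d)
    }
  }

  # attention outputs are composed residually (H + attn) so token-level
  # content survives the frozen stack; the attention operations themselves
  # are the plain weighted sums
  H_q_enc <- model$encoder$encode(qtoks)
  H_q_self <- H_q_enc +
    knowledge_self_attention(H_q_enc, assoc(qtoks, qtoks), model$attn$self_q)$H

  # knowledge subgraph
  G <- if (model$use_kg) {
    encode_subgraph(extract_subgraph(qtoks, kg), kg, model$krgat, model$encoder)
  } else {
    matrix(0, 0, d)
  }

  H_a_enc <- vector("list", K); H_a_self <- vector("list", K)
  doctors <- vector("list", K)
  for (k in seq_len(K)) {
    atoks <- record$candidates[[k]]
    H_a_enc[[k]] <- model$encoder$encode(atoks)
    H_a_self[[k]] <- H_a_enc[[k]] + knowledge_self_attention(
      H_a_enc[[k]], assoc(atoks, atoks), model$attn$self_a
    )$H
    doctors[[k]] <- doctor_self_encoding(model, record$candidate_doctors[k], profiles, kg)
  }

  # interaction attention
  alpha_g <- global_interaction(
    pool_mean(H_q_enc, d), lapply(H_a_enc, pool_mean, dim = d), model$attn$global_qa
  )
  H_q_inter_k <- vector("list", K)
  H_a_inter <- vector("list", K)
  H_d_inter <- vector("list", K)
  for (k in seq_len(K)) {
    atoks <- record$candidates[[k]]
    M_qa <- assoc(qtoks, atoks)
    H_q_inter_k[[k]] <- H_q_enc + word_level_interaction(
      H_q_enc, H_a_enc[[k]], M_qa, model$attn$inter_qa
    )$H
    M_aq <- aperm(M_qa, c(2, 1, 3))
    if (model$use_doctor) {
      dtoks <- doctors[[k]]$tokens
      H_a_inter[[k]] <- H_a_enc[[k]] + answer_interaction_encoding(
        H_a_enc[[k]], H_q_enc, doctors[[k]]$H_enc,
        M_aq, assoc(atoks, dtoks),
        model$attn$inter_aq, model$attn$inter_ad, model$proj
      )
      H_d_inter[[k]] <- doctors[[k]]$H_enc + doctor_interaction_encoding(
        doctors[[k]]$H_enc, H_q_enc, assoc(dtoks, qtoks), model$attn$inter_dq
      )
    } else {
      H_a_inter[[k]] <- H_a_enc[[k]] + knowledge_attention(
        H_a_enc[[k]], H_q_enc, M_aq, model$attn$inter_aq
      )$H
    }
  }
  H_q_inter <- question_interaction_encoding(H_q_inter_k, alpha_g)

  # gated fusion
  H_q_fus <- gated_fusion(H_q_self, H_q_inter, model$gate)$H
  H_a_fus <- lapply(seq_len(K), function(k) {
    gated_fusion(H_a_self[[k]], H_a_inter[[k]], model$gate)$H
  })
  H_d_fus <- if (model$use_doctor) {
    lapply(seq_len(K), function(k) {
      gated_fusion(doctors[[k]]$H_self, H_d_inter[[k]], model$gate)$H
    })
  } else {
    NULL
  }

  structure(
    list(
      record = record,
      H_q = H_q_fus, H_a = H_a_fus, H_d = H_d_fus, graph = G,
      alpha_global = alpha_g,
      pq = pool_mean(H_q_fus, d),
      pa = lapply(H_a_fus, pool_mean, dim = d),
      pd = if (is.null(H_d_fus)) NULL else lapply(H_d_fus, pool_mean, dim = d),
      pg = pool_mean(G, d),
      cand_idx = lapply(record$candidates, encode_tokens, vocab = model$vocab),
      ref_idx = encode_tokens(record$reference_answer, model$vocab)
    ),
    class = "record_encoding"
  )
}
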