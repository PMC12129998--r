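#' Generation distribution of the decoder
#'
#' The toy autoregressive decoder conditions on the previous token's frozen
#' embedding and on two pooled contexts (fused question encoding and
#' knowledge-subgraph encoding; the best candidate influences decoding
#' through the copy distribution and the gate, not the generation mode)
#' through a two-layer MLP: `h = tanh(W1 x + b1)`, `logits = W2 h + b2`, `p_gen = softmax(logits)`.
#' Any conditional language model satisfying the contract can be substituted.
#'
#' @param state decoder state: list with `x` (input feature vector) or `h`
#'   (precomputed hidden); see [decoder_state()].
#' @param theta trainable head parameters (`dec_W1`, `dec_b1`, `dec_W2`,
#'   `dec_b2`).
#' @return List with `p` (probability vector over the vocabulary), `h`
#'   (hidden state) and `logits`.
#' @export
generation_distribution <- function(state, theta) {
  h <- state$h
  if (is.null(h)) h <- tanh(as.numeric(theta$dec_W1 %*% state$x) + theta$dec_b1)
  logits <- as.numeric(theta$dec_W2 %*% h) + theta$dec_b2
  list(p = softmax(logits), h = h, logits = logits)
}

#' Decoder state at one generation step
#'
#' @param prev_emb embedding of the previously generated token.
#' @param ctx_question pooled fused question encoding.
#' @param ctx_graph pooled knowledge-subgraph encoding (zero vector for an
#'   empty subgraph).
#' @return List of class `decoder_state` with the concatenated input `x`.
#' @export
decoder_state <- function(prev_emb, ctx_question, ctx_graph) {
  structure(
    list(x = c(prev_emb, ctx_question, ctx_graph)),
    class = "decoder_state"
  )
}

#' Copy distribution over the best candidate answer
#'
#' Position scores are bilinear in the decoder hidden state and the
#' candidate's fused per-token encodings, softmaxed over positions; the
#' probability of a word is the sum of the position probabilities where that
#' word occurs. Words absent from the candidate get exactly zero.
#'
#' @param h decoder hidden state.
#' @param H_cand fused per-token encoding of the candidate answer.
#' @param cand_idx integer vocabulary indices of the candidate tokens.
#' @param vocab_size size of the generation vocabulary.
#' @param theta trainable parameters (`W_c`).
#' @return List with `p` (vocabulary distribution) and `pi` (position
#'   probabilities).
#' @export
copy_distribution <- function(h, H_cand, cand_idx, vocab_size, theta) {
  if (length(cand_idx) == 0L) stop_arg("copy: empty candidate")
  if (nrow(H_cand) != length(cand_idx)) {
    stop_arg("copy: candidate token count != encoding rows")
  }
  scores <- as.numeric(H_cand %*% as.numeric(t(theta$W_c) %*% h))
  pi <- softmax(scores)
  p <- numeric(vocab_size)
  agg <- rowsum(pi, group = cand_idx)
  p[as.integer(rownames(agg))] <- agg[, 1]
  list(p = p, pi = pi, scores = scores)
}

#' Generation/copy trade-off gate
#'
#' `g = sigmoid(w . [pool(H_q); pool(H_a)] + b)`, strictly inside (0, 1) for
#' finite inputs; zero weights give exactly 0.5.
#'
#' @param ctx_question,ctx_answer pooled fused encodings.
#' @param theta trainable parameters (`w_gate`, `b_gate`).
#' @return Scalar gate in (0, 1).
#' @export
generation_gate <- function(ctx_question, ctx_answer, theta) {
  sigmoid(sum(theta$w_gate * c(ctx_question, ctx_answer)) + theta$b_gate)
}

#' Mix generation and copy distributions
#'
#' `p_final = g * p_gen + (1 - g) * p_copy`; a convex mixture of two valid
#' distributions, so for words outside the candidate `p_final = g * p_gen`
#' exactly.
#'
#' @param g_gen gate in `[0, 1]`.
#' @param p_gen,p_copy valid probability vectors over the same vocabulary.
#' @return Probability vector.
#' @export
mix_distributions <- function(g_gen, p_gen, p_copy) {
  if (length(p_gen) != length(p_copy)) stop_arg("mix: vocabulary size mismatch")
  check_prob(p_gen, what = "p_gen")
  check_prob(p_copy, what = "p_copy")
  g_gen * p_gen + (1 - g_gen) * p_copy
}

# Ranking features: concatenation of the pooled encodings augmented with
# elementwise products; the score additionally carries bilinear terms
# (pq^T W pa), which let a head that is linear in its parameters express
# question-candidate matching across the differently-projected frozen
# encoder features.
rank_features <- function(pq, pa) c(pq, pa, pq * pa)
doctor_features <- function(pq, pa, pd, use_doctor = TRUE) {
  if (use_doctor && !is.null(pd)) c(pq, pa, pd, pq * pa, pq * pd) else rank_features(pq, pa)
}

#' Candidate answer ranking head
#'
#' Score per candidate from the pooled question/answer encodings: an affine
#' term over the concatenated features plus a bilinear question-answer
#' matching term, softmaxed over the K candidates. Permuting candidates
#' permutes the probabilities identically.
#'
#' @param ctx_question pooled fused question encoding.
#' @param ctx_answers list of K pooled fused candidate encodings.
#' @param theta trainable parameters (`w_rank`, `W_bil_rank`, `b_rank`).
#' @return Probability vector over the K candidates.
#' @export
rank_answers <- function(ctx_question, ctx_answers, theta) {
  if (length(ctx_answers) == 0L) stop_arg("ranking needs at least one candidate")
  qW <- as.numeric(ctx_question %*% theta$W_bil_rank)
  f <- vapply(ctx_answers, function(pa) {
    sum(theta$w_rank * rank_features(ctx_question, pa)) + sum(qW * pa) + theta$b_rank
  }, numeric(1))
  softmax(f)
}

#' Doctor recommendation head
#'
#' As [rank_answers()] with the triple concatenation of question, candidate
#' answer and doctor encodings and bilinear question-answer and
#' question-doctor matching terms. When the model is ablated without doctor
#' encodings (`ctx_doctors = NULL`) the head falls back to question/answer
#' features only.
#'
#' @param ctx_question pooled fused question encoding.
#' @param ctx_answers list of K pooled candidate encodings.
#' @param ctx_doctors list of K pooled doctor encodings, or `NULL`.
#' @param theta trainable parameters (`w_doc`, `W_bil_doc_a`, `W_bil_doc_d`,
#'   `b_doc`).
#' @return Probability vector over the K doctors.
#' @export
rank_doctors <- function(ctx_question, ctx_answers, ctx_doctors, theta) {
  K <- length(ctx_answers)
  if (K == 0L) stop_arg("ranking needs at least one candidate")
  use_d <- !is.null(ctx_doctors)
  qWa <- as.numeric(ctx_question %*% theta$W_bil_doc_a)
  qWd <- if (use_d) as.numeric(ctx_question %*% theta$W_bil_doc_d) else NULL
  f <- vapply(seq_len(K), function(k) {
    phi <- doctor_features(
      ctx_question, ctx_answers[[k]],
      if (use_d) ctx_doctors[[k]] else NULL, use_d
    )
    s <- sum(theta$w_doc * phi) + sum(qWa * ctx_answers[[k]]) + theta$b_doc
    if (use_d) s <- s + sum(qWd * ctx_doctors[[k]])
    s
  }, numeric(1))
  softmax(f)
}

#' Uncertainty-weighted multi-task loss
#'
#' \deqn{L = \frac{L_{gen}}{2\alpha^2} + \frac{L_{rank}}{2\beta^2} +
#'   \frac{L_{doc}}{2\gamma^2} + \log\alpha + \log\beta + \log\gamma}
#' The log regularizers (from the homoscedastic-uncertainty weighting the
#' weighted combination is based on) keep the trainable weights finite: a
#' task with persistently large loss grows its weight, down-scaling that
#' task's gradient contribution.
#'
#' @param gen_nll,rank_nll,doc_nll mean per-task negative log-likelihoods.
#' @param weights numeric vector `c(alpha, beta, gamma)`, strictly positive.
#' @return Scalar total loss.
#' @export
multitask_loss <- function(gen_nll, rank_nll, doc_nll, weights) {
  if (any(weights <= 0)) stop_arg("task weights must be strictly positive")
  a <- weights[1]; b <- weights[2]; g <- weights[3]
  gen_nll / (2 * a^2) + rank_nll / (2 * b^2) + doc_nll / (2 * g^2) +
    log(a) + log(b) + log(g)
}
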