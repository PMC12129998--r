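#' Knowledge association matrix between two token sequences
#'
#' A token-pair tensor: cell (i, j) holds the relation embedding of the
#' knowledge-graph edge joining the entities matched by tokens i and j
#' (either direction, first stored edge when several), and the zero vector
#' when either token matches no entity or no edge joins them. The
#' self-association matrix is obtained with `tokens_b = tokens_a`. Only
#' single-token surface forms participate (cells are defined per token pair).
#'
#' @param tokens_a,tokens_b character vectors.
#' @param kg a [med_kg].
#' @param rel_embedder function mapping a relation label to a numeric vector.
#' @param dim embedding dimension of the relation cells.
#' @return 3-d array `[length(a), length(b), dim]` of class `assoc_matrix`.
#' @export
build_assoc_matrix <- function(tokens_a, tokens_b, kg, rel_embedder, dim) {
  tok2ent <- kg_token_entity(kg)
  Ta <- length(tokens_a); Tb <- length(tokens_b)
  M <- array(0, dim = c(Ta, Tb, dim))
  ea <- tok2ent[tokens_a]; eb <- tok2ent[tokens_b]
  for (i in seq_len(Ta)) {
    if (is.na(ea[i])) next
    for (j in seq_len(Tb)) {
      if (is.na(eb[j])) next
      rt <- kg_edge_between(kg, ea[i], eb[j])
      if (!is.na(rt)) M[i, j, ] <- rel_embedder(rt)
    }
  }
  structure(M, class = c("assoc_matrix", "array"))
}

zero_assoc <- function(Ta, Tb, dim) {
  structure(array(0, dim = c(Ta, Tb, dim)), class = c("assoc_matrix", "array"))
}

#' Attention parameters for one attended pair
#'
#' Projection maps `W_q`, `W_k`, `W_v`, a relation map `W_r` applied to
#' association-matrix cells, and a scoring vector `v`. The additive score
#' form is \eqn{s_{ij} = v^\top \tanh(q_i + k_j + W_r m_{ij})}; the
#' `concat_dot` alternative scores the tanh of the concatenation with a
#' 3d-long vector.
#'
#' @param dim model dimension.
#' @param tag unique name of the attended pair (keys the frozen init).
#' @param seed integer seed.
#' @param score_form `"additive"` (default) or `"concat_dot"`.
#' @return Object of class `attn_params`.
#' @export
attn_params <- function(dim, tag, seed = 1, score_form = "additive") {
  score_form <- match.arg(score_form, c("additive", "concat_dot"))
  sd <- 1 / sqrt(dim)
  structure(
    list(
      dim = dim, score_form = score_form,
      W_q = hash_orth(dim, dim, paste0(tag, "_Wq"), seed),
      W_k = hash_orth(dim, dim, paste0(tag, "_Wk"), seed),
      W_v = hash_orth(dim, dim, paste0(tag, "_Wv"), seed),
      W_r = hash_orth(dim, dim, paste0(tag, "_Wr"), seed),
      v = hash_matrix(dim, 1, paste0(tag, "_v"), seed, sd = sd)[, 1],
      v3 = hash_matrix(3 * dim, 1, paste0(tag, "_v3"), seed, sd = sd)[, 1]
    ),
    class = "attn_params"
  )
}

# Shared scoring + softmax + value aggregation for all knowledge-aware
# attention variants. H_a attends over H_b.
knowledge_attention <- function(H_a, H_b, M, params) {
  d <- params$dim
  if (ncol(H_a) != d || ncol(H_b) != d) stop_arg("attention: dimension mismatch")
  Ta <- nrow(H_a); Tb <- nrow(H_b)
  if (!all(dim(M)[1:2] == c(Ta, Tb))) {
    stop_arg("attention: association matrix is %dx%d but sequences are %dx%d",
      dim(M)[1], dim(M)[2], Ta, Tb)
  }
  Q <- H_a %*% params$W_q
  K <- H_b %*% params$W_k
  V <- H_b %*% params$W_v
  S <- matrix(0, Ta, Tb)
  for (j in seq_len(Tb)) {
    # rows: q_i + k_j + W_r m_ij for all i at once
    Mj <- matrix(M[, j, ], nrow = Ta)
    Z <- tanh(sweep(Q + Mj %*% params$W_r, 2, K[j, ], `+`))
    if (params$score_form == "additive") {
      S[, j] <- Z %*% params$v
    } else {
      Zc <- cbind(
        tanh(Q), matrix(tanh(K[j, ]), Ta, d, byrow = TRUE),
        tanh(Mj %*% params$W_r)
      )
      S[, j] <- Zc %*% params$v3
    }
  }
  A <- t(apply(S, 1, softmax))
  if (Tb == 1L) A <- matrix(A, ncol = 1) # apply() drops dims
  list(H = A %*% V, alpha = A, scores = S, V = V)
}

#' Knowledge-aware self-attention
#'
#' Standard projected self-attention whose scores carry an additive
#' relation term from the knowledge association matrix; each attention row
#' is a softmax and sums to one.
#'
#' @param H per-token encoding matrix.
#' @param M self-association matrix from [build_assoc_matrix()].
#' @param params an [attn_params()].
#' @return List with `H` (re-encoded tokens) and `alpha` (attention rows).
#' @export
knowledge_self_attention <- function(H, M, params) {
  out <- knowledge_attention(H, H, M, params)
  out[c("H", "alpha")]
}

#' Word-level interaction attention
#'
#' Tokens of sequence A (e.g. the question) attend over tokens of sequence B
#' (e.g. a candidate answer) with the same knowledge-aware additive scoring
#' as self-attention; output rows follow sequence A.
#'
#' @param H_a,H_b per-token encodings of the attending / attended sequence.
#' @param M cross association matrix (`nrow(H_a)` by `nrow(H_b)`).
#' @param params an [attn_params()].
#' @return List with `H` and `alpha`.
#' @export
word_level_interaction <- function(H_a, H_b, M, params) {
  out <- knowledge_attention(H_a, H_b, M, params)
  out[c("H", "alpha")]
}

#' Global interaction weights over candidate answers
#'
#' Scaled dot-product attention between the mean question encoding and each
#' candidate answer's mean encoding: \eqn{\alpha = softmax_k(q_g \cdot
#' k_g^{(k)} / \sqrt d)}. The weights sum to one over candidates.
#'
#' @param mean_q mean question encoding (length-d vector).
#' @param mean_a_list list of K mean candidate-answer encodings.
#' @param params an [attn_params()] (its `W_q`, `W_k` are used).
#' @return Numeric vector of K weights.
#' @export
global_interaction <- function(mean_q, mean_a_list, params) {
  K <- length(mean_a_list)
  if (K == 0L) stop_arg("global interaction needs at least one candidate")
  d <- params$dim
  qg <- as.numeric(mean_q %*% params$W_q)
  scores <- vapply(mean_a_list, function(ma) {
    kg_ <- as.numeric(ma %*% params$W_k)
    sum(qg * kg_) / sqrt(d)
  }, numeric(1))
  softmax(scores)
}

#' Combine per-candidate question encodings with global weights
#'
#' Convex combination over candidates of the word-level question encodings.
#'
#' @param H_inter_list list of K matrices (same shape).
#' @param alpha_global K weights summing to one.
#' @return Single matrix of the question encoding.
#' @export
question_interaction_encoding <- function(H_inter_list, alpha_global) {
  if (length(H_inter_list) != length(alpha_global)) {
    stop_arg("weight/candidate count mismatch")
  }
  if (abs(sum(alpha_global) - 1) > 1e-6) stop_arg("global weights must sum to 1")
  Reduce(`+`, Map(function(H, a) a * H, H_inter_list, alpha_global))
}

#' Interaction encoding of a candidate answer
#'
#' Answer tokens attend over the question and over the answering doctor's
#' profile; the two outputs are concatenated per token and projected back to
#' model dimension by a linear layer.
#'
#' @param H_a,H_q,H_d per-token encodings of answer, question, doctor.
#' @param M_aq,M_ad association matrices answer-question / answer-doctor.
#' @param params_aq,params_ad [attn_params()] for the two attended pairs.
#' @param proj list with `W` (d x 2d) and `b` (length d) combination layer.
#' @return Matrix with `nrow(H_a)` rows.
#' @export
answer_interaction_encoding <- function(H_a, H_q, H_d, M_aq, M_ad,
                                        params_aq, params_ad, proj) {
  o_q <- knowledge_attention(H_a, H_q, M_aq, params_aq)$H
  o_d <- knowledge_attention(H_a, H_d, M_ad, params_ad)$H
  sweep(cbind(o_q, o_d) %*% t(proj$W), 2, proj$b, `+`)
}

#' Interaction encoding of a doctor profile
#'
#' Doctor-profile tokens attend over the question only (doctors answer
#' within their expertise, so the question is the relevant context).
#'
#' @param H_d,H_q per-token encodings.
#' @param M_dq association matrix doctor-question.
#' @param params an [attn_params()].
#' @return Matrix with `nrow(H_d)` rows.
#' @export
doctor_interaction_encoding <- function(H_d, H_q, M_dq, params) {
  knowledge_attention(H_d, H_q, M_dq, params)$H
}

#' Gate parameters of the fusion network
#'
#' Two-layer MLP producing one gating coefficient per token position.
#'
#' @param dim model dimension.
#' @param hidden hidden width of the gate MLP.
#' @param seed integer seed.
#' @param per_channel if `TRUE` the gate has one output per channel instead
#'   of a scalar per position.
#' @return Object of class `gate_params`.
#' @export
gate_params <- function(dim, hidden = dim, seed = 1, per_channel = FALSE) {
  n_out <- if (per_channel) dim else 1L
  structure(
    list(
      dim = dim, per_channel = per_channel,
      W1 = hash_matrix(hidden, 2 * dim, "gate_W1", seed, sd = 1 / sqrt(2 * dim)),
      b1 = numeric(hidden),
      W2 = hash_matrix(n_out, hidden, "gate_W2", seed, sd = 1 / sqrt(hidden)),
      b2 = numeric(n_out)
    ),
    class = "gate_params"
  )
}

#' Gated fusion of self- and interaction-attention encodings
#'
#' Per token position: `z = [h_self ; h_inter]`,
#' `g = sigmoid(W2 ReLU(W1 z + b1) + b2)` and
#' `h_fusion = g * h_self + (1 - g) * h_inter`. With all-zero gate weights
#' `g = 0.5` exactly and the fusion is the elementwise mean. The output is a
#' per-position convex combination of the two encodings.
#'
#' @param H_self,H_inter matrices of equal shape.
#' @param gate a [gate_params()].
#' @return List with `H` (fused encoding) and `g` (gate values).
#' @export
gated_fusion <- function(H_self, H_inter, gate) {
  if (!all(dim(H_self) == dim(H_inter))) stop_arg("fusion: shape mismatch")
  Z <- cbind(H_self, H_inter)
  Hh <- relu(sweep(Z %*% t(gate$W1), 2, gate$b1, `+`))
  G <- sigmoid(sweep(Hh %*% t(gate$W2), 2, gate$b2, `+`))
  if (!gate$per_channel) {
    g <- as.numeric(G)
    H <- H_self * g + H_inter * (1 - g)
  } else {
    H <- H_self * G + H_inter * (1 - G)
    g <- G
  }
  list(H = H, g = g)
}
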