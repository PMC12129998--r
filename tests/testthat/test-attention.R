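rel_emb8 <- medkgqa:::relation_embedder(8, seed = 1)

test_that("association matrices hold relation embeddings exactly where edges exist", {
  kg <- toy_kg()
  M0 <- build_assoc_matrix(c("foo", "bar"), c("baz", "qux"), kg, rel_emb8, 8)
  expect_true(all(M0 == 0))
  toks <- c("headache", "and", "brain_tumor")
  M <- build_assoc_matrix(toks, toks, kg, rel_emb8, 8)
  e_sym <- rel_emb8("clinical_symptom")
  expect_equal(M[1, 3, ], e_sym) # headache -- brain_tumor edge, either direction
  expect_equal(M[3, 1, ], e_sym)
  expect_true(all(M[1, 1, ] == 0)) # no self-referential edge -> diagonal zero
  expect_true(all(M[2, , ] == 0)) # non-entity token row is zero
})

test_that("knowledge self-attention matches loop oracle and its ablation", {
  d <- 8
  params <- attn_params(d, "t_self", seed = 5)
  # single token: output equals its own value vector
  H1 <- rand_mat(1, d, 1)
  out1 <- knowledge_self_attention(H1, array(0, c(1, 1, d)), params)
  expect_equal(out1$H, H1 %*% params$W_v, tolerance = 1e-12)
  expect_equal(out1$alpha[1, 1], 1.0)
  # zero association matrix reduces to relation-free attention
  H <- rand_mat(5, d, 2)
  Mz <- array(0, c(5, 5, d))
  got <- knowledge_self_attention(H, Mz, params)
  ref <- oracle_attention(H, H, Mz, params, use_rel = FALSE)
  expect_equal(got$H, ref$H, tolerance = 1e-6)
  # nonzero association matrix against the full loop oracle
  M <- array(rnorm(5 * 5 * d, sd = 0.5), c(5, 5, d))
  got2 <- knowledge_self_attention(H, M, params)
  ref2 <- oracle_attention(H, H, M, params, use_rel = TRUE)
  expect_equal(got2$H, ref2$H, tolerance = 1e-6)
  expect_equal(got2$alpha, ref2$alpha, tolerance = 1e-6)
  expect_equal(rowSums(got2$alpha), rep(1, 5), tolerance = 1e-9)
})

test_that("attention scores react to the association matrix when W_r is nonzero", {
  d <- 8
  params <- attn_params(d, "t_sens", seed = 6)
  H <- rand_mat(4, d, 3)
  M <- array(rnorm(4 * 4 * d), c(4, 4, d))
  with_m <- knowledge_self_attention(H, M, params)
  without_m <- knowledge_self_attention(H, array(0, c(4, 4, d)), params)
  expect_false(isTRUE(all.equal(with_m$alpha, without_m$alpha)))
})

test_that("word-level interaction matches the loop oracle", {
  d <- 8
  params <- attn_params(d, "t_wl", seed = 7)
  H_q <- rand_mat(4, d, 4)
  # one-token answer: every question token receives that value vector
  H_a1 <- rand_mat(1, d, 5)
  out <- word_level_interaction(H_q, H_a1, array(0, c(4, 1, d)), params)
  v <- as.numeric(H_a1 %*% params$W_v)
  for (i in 1:4) expect_equal(out$H[i, ], v, tolerance = 1e-12)
  # random pair against the loop oracle
  H_a <- rand_mat(6, d, 6)
  M <- array(rnorm(4 * 6 * d, sd = 0.5), c(4, 6, d))
  got <- word_level_interaction(H_q, H_a, M, params)
  ref <- oracle_attention(H_q, H_a, M, params)
  expect_equal(got$H, ref$H, tolerance = 1e-6)
  expect_equal(rowSums(got$alpha), rep(1, 4), tolerance = 1e-9)
})

test_that("global interaction weights follow the scaled-dot softmax", {
  params <- attn_params(1, "t_glob_d1", seed = 8)
  params$W_q <- matrix(1); params$W_k <- matrix(1)
  # K = 1 -> singleton
  expect_equal(global_interaction(c(0.3), list(c(2)), params), 1.0)
  # identical candidates -> uniform 1/K
  p4 <- attn_params(8, "t_glob", seed = 8)
  mq <- rnorm(8)
  ma <- rnorm(8)
  expect_equal(
    global_interaction(mq, list(ma, ma, ma, ma), p4),
    rep(0.25, 4),
    tolerance = 1e-12
  )
  # d = 1, scores (2, 0, 0, 0): closed-form softmax
  a <- global_interaction(c(1), list(c(2), c(0), c(0), c(0)), params)
  expect_equal(a, exp(c(2, 0, 0, 0)) / sum(exp(c(2, 0, 0, 0))), tolerance = 1e-8)
  expect_equal(a, c(0.71123, 0.09626, 0.09626, 0.09626), tolerance = 1e-4)
  expect_error(global_interaction(mq, list(), p4), "at least one")
})

test_that("question interaction encoding is the stated convex combination", {
  Hs <- lapply(1:4, function(i) rand_mat(3, 8, i))
  expect_equal(question_interaction_encoding(Hs, c(1, 0, 0, 0)), Hs[[1]])
  expect_equal(
    question_interaction_encoding(list(Hs[[1]], Hs[[1]]), c(0.4, 0.6)),
    Hs[[1]],
    tolerance = 1e-12
  )
  w <- c(0.1, 0.2, 0.3, 0.4)
  got <- question_interaction_encoding(Hs, w)
  ref <- w[1] * Hs[[1]] + w[2] * Hs[[2]] + w[3] * Hs[[3]] + w[4] * Hs[[4]]
  expect_equal(got, ref, tolerance = 1e-12)
  expect_error(question_interaction_encoding(Hs, c(0.5, 0.5)), "mismatch")
})

test_that("answer interaction concatenates two attentions and projects", {
  d <- 8
  p_aq <- attn_params(d, "t_aq", seed = 9)
  p_ad <- attn_params(d, "t_ad", seed = 9) # same seed/tag-style params
  proj <- list(W = rand_mat(d, 2 * d, 11), b = rnorm(d))
  H_a <- rand_mat(5, d, 12); H_q <- rand_mat(4, d, 13)
  M_aq <- array(rnorm(5 * 4 * d, sd = 0.3), c(5, 4, d))
  M_ad <- array(rnorm(5 * 4 * d, sd = 0.3), c(5, 4, d))
  # doctor text = question text with shared parameters and matrices:
  # both attention outputs coincide and the result is the projection of the
  # duplicated output
  same <- answer_interaction_encoding(H_a, H_q, H_q, M_aq, M_aq, p_aq, p_aq, proj)
  o <- oracle_attention(H_a, H_q, M_aq, p_aq)$H
  expect_equal(same, sweep(cbind(o, o) %*% t(proj$W), 2, proj$b, `+`), tolerance = 1e-6)
  # general case against the loop oracle
  H_d <- rand_mat(4, d, 14)
  got <- answer_interaction_encoding(H_a, H_q, H_d, M_aq, M_ad, p_aq, p_ad, proj)
  o_q <- oracle_attention(H_a, H_q, M_aq, p_aq)$H
  o_d <- oracle_attention(H_a, H_d, M_ad, p_ad)$H
  expect_equal(got, sweep(cbind(o_q, o_d) %*% t(proj$W), 2, proj$b, `+`), tolerance = 1e-6)
})

test_that("doctor interaction attends over the question only", {
  d <- 8
  params <- attn_params(d, "t_dq", seed = 15)
  H_d <- rand_mat(6, d, 16)
  # single-token question: all doctor positions receive its value vector
  H_q1 <- rand_mat(1, d, 17)
  out <- doctor_interaction_encoding(H_d, H_q1, array(0, c(6, 1, d)), params)
  v <- as.numeric(H_q1 %*% params$W_v)
  for (i in 1:6) expect_equal(out[i, ], v, tolerance = 1e-12)
  # random instance vs oracle
  H_q <- rand_mat(5, d, 18)
  M <- array(rnorm(6 * 5 * d, sd = 0.4), c(6, 5, d))
  expect_equal(
    doctor_interaction_encoding(H_d, H_q, M, params),
    oracle_attention(H_d, H_q, M, params)$H,
    tolerance = 1e-6
  )
})

test_that("gated fusion is a per-position convex combination", {
  d <- 8
  gate <- gate_params(d, seed = 19)
  H_self <- rand_mat(5, d, 20)
  H_inter <- rand_mat(5, d, 21)
  # zero gate network -> g = 0.5 exactly, elementwise mean
  gate0 <- gate
  gate0$W1 <- gate0$W1 * 0; gate0$W2 <- gate0$W2 * 0
  f0 <- gated_fusion(H_self, H_inter, gate0)
  expect_equal(f0$g, rep(0.5, 5))
  expect_equal(f0$H, (H_self + H_inter) / 2, tolerance = 1e-12)
  # large positive bias saturates toward the self encoding
  gate_b <- gate0
  gate_b$b2 <- 50
  expect_equal(gated_fusion(H_self, H_inter, gate_b)$H, H_self, tolerance = 1e-12)
  # identical inputs are a fixed point for any gate
  expect_equal(gated_fusion(H_self, H_self, gate)$H, H_self, tolerance = 1e-12)
  # convexity: fusion lies between the two encodings elementwise
  f <- gated_fusion(H_self, H_inter, gate)
  expect_true(all(f$H >= pmin(H_self, H_inter) - 1e-12))
  expect_true(all(f$H <= pmax(H_self, H_inter) + 1e-12))
  expect_true(all(f$g > 0 & f$g < 1))
  expect_error(gated_fusion(H_self, H_inter[1:3, ], gate), "shape")
})

test_that("concat_dot score form is available and differs from additive", {
  d <- 8
  pa <- attn_params(d, "t_form", seed = 22, score_form = "additive")
  pc <- attn_params(d, "t_form", seed = 22, score_form = "concat_dot")
  H <- rand_mat(4, d, 23)
  M <- array(0, c(4, 4, d))
  out_a <- knowledge_self_attention(H, M, pa)
  out_c <- knowledge_self_attention(H, M, pc)
  expect_equal(rowSums(out_c$alpha), rep(1, 4), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(out_a$alpha, out_c$alpha)))
})
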