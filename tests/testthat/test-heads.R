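# minimal trainable-parameter set for head tests
tiny_theta <- function(V = 10, d = 6, h = 6) {
  list(
    dec_W1 = rand_mat(h, 3 * d, 31), dec_b1 = rnorm(h),
    dec_W2 = rand_mat(V, h, 32), dec_b2 = rnorm(V),
    W_c = rand_mat(h, d, 33),
    w_gate = rnorm(2 * d), b_gate = 0.3,
    w_rank = rnorm(3 * d), W_bil_rank = rand_mat(d, d, 34), b_rank = 0.1,
    w_doc = rnorm(5 * d), W_bil_doc_a = rand_mat(d, d, 35),
    W_bil_doc_d = rand_mat(d, d, 36), b_doc = -0.2,
    log_sigma = c(gen = 0, rank = 0, doc = 0)
  )
}

test_that("generation distribution is a valid softmax of the decoder MLP", {
  th <- tiny_theta()
  x <- rnorm(18)
  out <- generation_distribution(list(x = x), th)
  expect_equal(sum(out$p), 1, tolerance = 1e-12)
  expect_true(all(out$p > 0))
  # independent recomputation
  h <- tanh(as.numeric(th$dec_W1 %*% x) + th$dec_b1)
  logits <- as.numeric(th$dec_W2 %*% h) + th$dec_b2
  expect_equal(out$p, exp(logits - max(logits)) / sum(exp(logits - max(logits))), tolerance = 1e-12)
  # uniform logits -> uniform distribution
  th0 <- th; th0$dec_W2 <- th0$dec_W2 * 0; th0$dec_b2 <- th0$dec_b2 * 0
  expect_equal(generation_distribution(list(x = x), th0)$p, rep(0.1, 10))
  # a dominant logit saturates to (nearly) one-hot
  th1 <- th0; th1$dec_b2[4] <- 1e4
  expect_equal(generation_distribution(list(x = x), th1)$p[4], 1, tolerance = 1e-12)
})

test_that("copy distribution aggregates position probabilities per word", {
  th <- tiny_theta()
  # single-token candidate: that token gets probability 1
  out1 <- copy_distribution(rnorm(6), rand_mat(1, 6, 41), 7L, 10, th)
  expect_equal(out1$p[7], 1.0)
  expect_equal(sum(out1$p), 1, tolerance = 1e-12)
  # candidate "a b a" with equal position scores -> p(a) = 2/3, p(b) = 1/3
  H_same <- rand_mat(1, 6, 42)[rep(1, 3), ]
  out2 <- copy_distribution(rnorm(6), H_same, c(2L, 5L, 2L), 10, th)
  expect_equal(out2$p[2], 2 / 3, tolerance = 1e-12)
  expect_equal(out2$p[5], 1 / 3, tolerance = 1e-12)
  # words outside the candidate get exactly zero
  expect_true(all(out2$p[-c(2, 5)] == 0))
  expect_error(copy_distribution(rnorm(6), rand_mat(0, 6, 43), integer(0), 10, th), "empty")
})

test_that("the generation gate is a sigmoid with the documented limits", {
  th <- tiny_theta()
  th0 <- th; th0$w_gate <- th0$w_gate * 0; th0$b_gate <- 0
  expect_equal(generation_gate(rnorm(6), rnorm(6), th0), 0.5)
  th1 <- th0; th1$b_gate <- 100
  expect_equal(generation_gate(rnorm(6), rnorm(6), th1), 1, tolerance = 1e-12)
  g <- generation_gate(rnorm(6), rnorm(6), th)
  expect_true(g > 0 && g < 1)
})

test_that("mixing recovers the pure modes at the gate limits", {
  p_gen <- softmax_vec <- exp(rnorm(10)); p_gen <- p_gen / sum(p_gen)
  p_copy <- numeric(10); p_copy[c(2, 5)] <- c(0.75, 0.25)
  expect_equal(mix_distributions(1, p_gen, p_copy), p_gen)
  expect_equal(mix_distributions(0, p_gen, p_copy), p_copy)
  expect_equal(mix_distributions(0.5, p_gen, p_gen), p_gen, tolerance = 1e-15)
  pf <- mix_distributions(0.3, p_gen, p_copy)
  expect_equal(sum(pf), 1, tolerance = 1e-12)
  expect_error(mix_distributions(0.5, p_gen * 2, p_copy), "sum to 1")
})

test_that("off-candidate probability mass equals the gate times generation mass", {
  set.seed(77)
  for (i in 1:100) {
    V <- sample(8:40, 1)
    cand <- sample(V, sample(2:6, 1), replace = TRUE)
    p_gen <- exp(rnorm(V)); p_gen <- p_gen / sum(p_gen)
    pi <- exp(rnorm(length(cand))); pi <- pi / sum(pi)
    p_copy <- numeric(V)
    agg <- rowsum(pi, cand)
    p_copy[as.integer(rownames(agg))] <- agg[, 1]
    g <- runif(1)
    pf <- mix_distributions(g, p_gen, p_copy)
    off <- setdiff(seq_len(V), cand)
    expect_equal(sum(pf[off]), g * sum(p_gen[off]), tolerance = 1e-12)
  }
})

test_that("answer ranking head reproduces closed-form softmax scores", {
  d <- 6
  th <- tiny_theta(d = d)
  # identical candidates -> uniform over K = 4
  pq <- rnorm(d); pa <- rnorm(d)
  expect_equal(rank_answers(pq, list(pa, pa, pa, pa), th), rep(0.25, 4), tolerance = 1e-12)
  # K = 1 -> probability one
  expect_equal(rank_answers(pq, list(pa), th), 1.0)
  # craft scores (2, 0, 0, 0): zero all weights except a single read-out
  th0 <- th
  th0$w_rank <- c(numeric(d), 1, numeric(d - 1), numeric(d)) # reads pa[1]
  th0$W_bil_rank <- th0$W_bil_rank * 0; th0$b_rank <- 0
  cands <- list(c(2, numeric(d - 1)), numeric(d), numeric(d), numeric(d))
  p <- rank_answers(numeric(d), cands, th0)
  expect_equal(p, exp(c(2, 0, 0, 0)) / sum(exp(c(2, 0, 0, 0))), tolerance = 1e-12)
})

test_that("ranking heads are permutation-equivariant", {
  d <- 6
  th <- tiny_theta(d = d)
  pq <- rnorm(d)
  pas <- lapply(1:4, function(i) rnorm(d))
  pds <- lapply(1:4, function(i) rnorm(d))
  perm <- c(3, 1, 4, 2)
  expect_equal(rank_answers(pq, pas[perm], th), rank_answers(pq, pas, th)[perm], tolerance = 1e-12)
  expect_equal(
    rank_doctors(pq, pas[perm], pds[perm], th),
    rank_doctors(pq, pas, pds, th)[perm],
    tolerance = 1e-12
  )
})

test_that("doctor head handles the ablated (no-doctor) feature set", {
  d <- 6
  th <- tiny_theta(d = d)
  th$w_doc <- rnorm(3 * d) # ablated head size
  pq <- rnorm(d)
  pas <- lapply(1:4, function(i) rnorm(d))
  p <- rank_doctors(pq, pas, NULL, th)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  pa <- pas[[1]]
  expect_equal(rank_doctors(pq, list(pa, pa, pa, pa), NULL, th), rep(0.25, 4), tolerance = 1e-12)
})

test_that("uncertainty-weighted loss matches closed forms and monotonicity", {
  expect_equal(multitask_loss(2, 2, 2, c(1, 1, 1)), 3.0)
  expect_equal(multitask_loss(0, 0, 0, c(1, 1, 1)), 0.0)
  base <- multitask_loss(4, 1, 1, c(1, 1, 1))
  doubled <- multitask_loss(4, 1, 1, c(2, 1, 1))
  # doubling alpha shrinks the generation term and adds log(2)
  expect_equal(doubled - base, 4 / (2 * 4) - 4 / 2 + log(2), tolerance = 1e-12)
  expect_error(multitask_loss(1, 1, 1, c(0, 1, 1)), "positive")
})
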