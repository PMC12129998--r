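# ---- Per-record losses and exact analytic gradients ------------------------
#
# The encoder stack is frozen; the trainable surface is the output layer
# (decoder MLP, copy scorer, generation gate, ranking heads) plus the three
# uncertainty weights, so every gradient below is exact, not approximated.

zeros_like <- function(theta) lapply(theta, function(p) p * 0)

rank_forward_backward <- function(enc, theta, grad = TRUE) {
  K <- length(enc$pa)
  gold <- enc$record$gold_answer_index
  p <- rank_answers(enc$pq, enc$pa, theta)
  out <- list(nll = -log(p[gold]), p = p)
  if (grad) {
    y <- replace(numeric(K), gold, 1)
    dk <- p - y
    phi <- lapply(enc$pa, function(pa) rank_features(enc$pq, pa))
    out$grads <- list(
      w_rank = Reduce(`+`, Map(`*`, phi, dk)),
      W_bil_rank = Reduce(`+`, Map(function(pa, d_) d_ * outer(enc$pq, pa), enc$pa, dk)),
      b_rank = sum(dk)
    )
  }
  out
}

doctor_forward_backward <- function(enc, theta, grad = TRUE) {
  K <- length(enc$pa)
  gold <- enc$record$gold_doctor_index
  use_d <- !is.null(enc$pd)
  p <- rank_doctors(enc$pq, enc$pa, enc$pd, theta)
  out <- list(nll = -log(p[gold]), p = p)
  if (grad) {
    y <- replace(numeric(K), gold, 1)
    dk <- p - y
    phi <- lapply(seq_len(K), function(k) {
      doctor_features(enc$pq, enc$pa[[k]], if (use_d) enc$pd[[k]] else NULL, use_d)
    })
    out$grads <- list(
      w_doc = Reduce(`+`, Map(`*`, phi, dk)),
      W_bil_doc_a = Reduce(`+`, Map(function(pa, d_) d_ * outer(enc$pq, pa), enc$pa, dk)),
      b_doc = sum(dk)
    )
    if (use_d) {
      out$grads$W_bil_doc_d <-
        Reduce(`+`, Map(function(pd, d_) d_ * outer(enc$pq, pd), enc$pd, dk))
    }
  }
  out
}

# Teacher-forced generation loss over the reference answer. a_kmax is the
# gold candidate during training (the model argmax is a moving target early
# on); inference uses the ranking head's argmax.
gen_forward_backward <- function(enc, model, theta, grad = TRUE, kmax = NULL,
                                 drop_graph = FALSE) {
  d <- model$dim
  kmax <- kmax %||% enc$record$gold_answer_index
  ca <- enc$pa[[kmax]]
  H_cand <- enc$H_a[[kmax]]
  cand_idx <- enc$cand_idx[[kmax]]
  Vn <- length(model$vocab$tokens)
  seqs <- c(3L, enc$ref_idx, 4L) # <bos> ... <eos>
  Tn <- length(seqs) - 1L

  gate_in <- c(enc$pq, ca)
  g <- sigmoid(sum(theta$w_gate * gate_in) + theta$b_gate)

  nll <- 0
  if (grad) {
    gr <- list(
      dec_W1 = theta$dec_W1 * 0, dec_b1 = theta$dec_b1 * 0,
      dec_W2 = theta$dec_W2 * 0, dec_b2 = theta$dec_b2 * 0,
      W_c = theta$W_c * 0, w_gate = theta$w_gate * 0, b_gate = 0
    )
  }
  Wc_Ha <- H_cand %*% t(theta$W_c) # rows: W_c^T? (j, h-dim): h . row_j = score_j

  for (t in seq_len(Tn)) {
    prev <- seqs[t]; target <- seqs[t + 1L]
    x <- c(model$tok_emb[prev, ], enc$pq, if (drop_graph) numeric(d) else enc$pg)
    h <- tanh(as.numeric(theta$dec_W1 %*% x) + theta$dec_b1)
    logits <- as.numeric(theta$dec_W2 %*% h) + theta$dec_b2
    p_gen <- softmax(logits)
    sc <- as.numeric(Wc_Ha %*% h)
    pi <- softmax(sc)
    p_copy_t <- sum(pi[cand_idx == target])
    p_f <- g * p_gen[target] + (1 - g) * p_copy_t
    nll <- nll - log(p_f)
    if (grad) {
      # generation path
      cg <- g * p_gen[target] / p_f
      dz <- cg * p_gen
      dz[target] <- dz[target] - cg
      gr$dec_W2 <- gr$dec_W2 + outer(dz, h)
      gr$dec_b2 <- gr$dec_b2 + dz
      dh <- as.numeric(t(theta$dec_W2) %*% dz)
      # copy path: score_j = a_j^T W_c^T h, so dW_c = sum_j ds_j h a_j^T
      cc <- (1 - g) / p_f
      ds <- -cc * pi * ((cand_idx == target) - p_copy_t)
      gr$W_c <- gr$W_c + outer(h, as.numeric(t(H_cand) %*% ds))
      dh <- dh + as.numeric(t(Wc_Ha) %*% ds)
      # hidden -> first layer
      dpre <- dh * (1 - h^2)
      gr$dec_W1 <- gr$dec_W1 + outer(dpre, x)
      gr$dec_b1 <- gr$dec_b1 + dpre
      # gate
      dgate <- -(p_gen[target] - p_copy_t) / p_f * g * (1 - g)
      gr$w_gate <- gr$w_gate + dgate * gate_in
      gr$b_gate <- gr$b_gate + dgate
    }
  }
  out <- list(nll = nll / Tn)
  if (grad) out$grads <- lapply(gr, function(x) x / Tn)
  out
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(theta) {
  list(m = zeros_like(theta), v = zeros_like(theta), t = 0)
}

adam_step <- function(state, theta, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, theta = theta)
}

# Linear warmup then linear decay to zero over the training horizon.
lr_schedule <- function(step, base_lr, warmup, total) {
  if (step <= warmup) {
    base_lr * step / max(warmup, 1)
  } else {
    base_lr * max(0, (total - step) / max(total - warmup, 1))
  }
}

# ---- Ranking evaluation ----------------------------------------------------

#' Rank candidates and doctors for encoded records
#'
#' @param encs list of `record_encoding`s.
#' @param theta trainable parameters of a `qa_model`.
#' @return data.frame with per-record gold ranks and probabilities.
#' @export
evaluate_ranking <- function(encs, theta) {
  rows <- lapply(encs, function(enc) {
    pr <- rank_forward_backward(enc, theta, grad = FALSE)$p
    pd <- doctor_forward_backward(enc, theta, grad = FALSE)$p
    data.frame(
      answer_rank = rank_of(pr, enc$record$gold_answer_index),
      doctor_rank = rank_of(pd, enc$record$gold_doctor_index)
    )
  })
  do.call(rbind, rows)
}

# 1-based rank of index `gold` when probabilities are sorted descending;
# ties resolved pessimistically (gold ranked after equal scores) so a
# constant head does not score well by accident.
rank_of <- function(p, gold) {
  sum(p > p[gold]) + sum(p == p[gold]) # pessimistic: equals count fully
}

# ---- Training loop ---------------------------------------------------------

#' Train the multi-task output layer
#'
#' Encodes every record once through the frozen attention stack, then runs
#' mini-batch Adam on the decoder, copy scorer, gate, ranking heads and
#' uncertainty weights under the uncertainty-weighted multi-task loss.
#' Deterministic given the seed (single-threaded).
#'
#' @param model a `qa_model` from [init_model()].
#' @param train_records,dev_records lists of [qa_record].
#' @param kg the [med_kg].
#' @param profiles list of [doctor_profile].
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr peak learning rate (after warmup).
#' @param warmup warmup steps.
#' @param seed integer seed (batch shuffling).
#' @param loss_scale length-3 multipliers of the per-task losses
#'   (`c(gen, rank, doc)`); used by calibration experiments, default 1.
#' @param weight_decay decoupled L2 decay applied to the ranking-head
#'   weights (their bilinear terms are the most overfit-prone parameters).
#' @param graph_dropout probability of zeroing the decoder's graph context
#'   for a record within a batch. Keeps the empty-graph condition
#'   in-distribution (questions without entity mentions, graph knockouts)
#'   and forces the decoder to tie entity specifics to the subgraph rather
#'   than memorize them.
#' @param max_steps optional hard cap on optimizer steps.
#' @param encodings,dev_encodings optional precomputed [encode_record()]
#'   lists for the train/dev records (skips re-encoding).
#' @param verbose print per-epoch progress.
#' @return List with the trained `model` (updated `theta`), `history`
#'   (per-epoch data.frame: losses, weights, dev MRRs) and the cached
#'   encodings.
#' @export
train_model <- function(model, train_records, dev_records, kg, profiles,
                        epochs = 30, batch_size = 20, lr = 0.02, warmup = 30,
                        seed = 1, loss_scale = c(1, 1, 1), weight_decay = 1e-3,
                        graph_dropout = 0.25, max_steps = Inf,
                        encodings = NULL, dev_encodings = NULL,
                        verbose = FALSE) {
  encs <- encodings %||%
    lapply(train_records, encode_record, model = model, kg = kg, profiles = profiles)
  dev_encs <- dev_encodings %||%
    lapply(dev_records, encode_record, model = model, kg = kg, profiles = profiles)
  theta <- model$theta
  opt <- adam_init(theta)
  n <- length(encs)
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- min(epochs * steps_per_epoch, max_steps)
  hist <- list()
  step <- 0
  best_score <- -Inf
  best_theta <- theta
  best_epoch <- 0L
  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      if (step >= total_steps) break
      ord <- sample(n)
      ep_loss <- c(gen = 0, rank = 0, doc = 0)
      for (b in seq_len(steps_per_epoch)) {
        if (step >= total_steps) break
        idx <- ord[((b - 1) * batch_size + 1):min(b * batch_size, n)]
        B <- length(idx)
        acc <- zeros_like(theta)
        L <- c(gen = 0, rank = 0, doc = 0)
        for (i in idx) {
          gfb <- gen_forward_backward(encs[[i]], model, theta,
            drop_graph = stats::runif(1) < graph_dropout)
          rfb <- rank_forward_backward(encs[[i]], theta)
          dfb <- doctor_forward_backward(encs[[i]], theta)
          L <- L + c(gfb$nll, rfb$nll, dfb$nll) / B
          for (nm in names(gfb$grads)) acc[[nm]] <- acc[[nm]] + gfb$grads[[nm]] / B
          for (nm in names(rfb$grads)) acc[[nm]] <- acc[[nm]] + rfb$grads[[nm]] / B
          for (nm in names(dfb$grads)) acc[[nm]] <- acc[[nm]] + dfb$grads[[nm]] / B
        }
        L <- L * loss_scale
        if (!all(is.finite(L))) stop_arg("divergent loss (non-finite) at step %d", step + 1)
        sig <- exp(theta$log_sigma) # (alpha, beta, gamma)
        w_task <- 1 / (2 * sig^2) * loss_scale
        grads <- zeros_like(theta)
        for (nm in c("dec_W1", "dec_b1", "dec_W2", "dec_b2", "W_c", "w_gate", "b_gate")) {
          grads[[nm]] <- acc[[nm]] * w_task[1]
        }
        for (nm in c("w_rank", "W_bil_rank", "b_rank")) {
          grads[[nm]] <- acc[[nm]] * w_task[2]
        }
        for (nm in c("w_doc", "W_bil_doc_a", "W_bil_doc_d", "b_doc")) {
          grads[[nm]] <- acc[[nm]] * w_task[3]
        }
        # d/d log sigma of L_i/(2 sigma^2) + log sigma = -L_i/sigma^2 + 1
        grads$log_sigma <- 1 - L / sig^2
        step <- step + 1
        lr_t <- lr_schedule(step, lr, warmup, total_steps)
        upd <- adam_step(opt, theta, grads, lr_t)
        opt <- upd$state; theta <- upd$theta
        if (weight_decay > 0) {
          for (nm in c("w_rank", "W_bil_rank", "w_doc", "W_bil_doc_a", "W_bil_doc_d")) {
            theta[[nm]] <- theta[[nm]] * (1 - lr_t * weight_decay)
          }
        }
        ep_loss <- ep_loss + L / steps_per_epoch
      }
      dev_ranks <- evaluate_ranking(dev_encs, theta)
      dev_score <- mean(1 / dev_ranks$answer_rank) + mean(1 / dev_ranks$doctor_rank)
      if (dev_score >= best_score) {
        best_score <- dev_score
        best_theta <- theta
        best_epoch <- ep
      }
      hist[[ep]] <- data.frame(
        epoch = ep, step = step,
        loss_gen = ep_loss["gen"], loss_rank = ep_loss["rank"], loss_doc = ep_loss["doc"],
        total = multitask_loss(ep_loss["gen"], ep_loss["rank"], ep_loss["doc"], exp(theta$log_sigma)),
        alpha = exp(theta$log_sigma[["gen"]]),
        beta = exp(theta$log_sigma[["rank"]]),
        gamma = exp(theta$log_sigma[["doc"]]),
        dev_answer_mrr = mean(1 / dev_ranks$answer_rank),
        dev_doctor_mrr = mean(1 / dev_ranks$doctor_rank),
        row.names = NULL
      )
      if (verbose) {
        message(sprintf(
          "epoch %d: L=(%.3f,%.3f,%.3f) dev MRR a=%.3f d=%.3f",
          ep, ep_loss["gen"], ep_loss["rank"], ep_loss["doc"],
          hist[[ep]]$dev_answer_mrr, hist[[ep]]$dev_doctor_mrr
        ))
      }
    }
  })
  # keep the best-dev checkpoint (standard early stopping; the final epoch
  # can sit past the generalization peak on a corpus this small)
  model$theta <- best_theta
  list(
    model = model, history = do.call(rbind, hist), best_epoch = best_epoch,
    final_theta = theta, encodings = encs, dev_encodings = dev_encs
  )
}
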