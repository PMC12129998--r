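#' Generate an answer for a record by beam sampling
#'
#' The top-ranked candidate (ranking-head argmax) supplies the copy source;
#' each decoding step mixes the decoder's generation distribution with the
#' copy distribution through the learned gate, truncates to the `topk` most
#' probable tokens, renormalizes, and either samples (`sample = TRUE`,
#' default, the beam-sampling regime) or expands deterministically by the
#' top tokens. `beam` hypotheses are kept by cumulative log-probability;
#' decoding stops at `<eos>` or `max_len`. Seeded and deterministic given
#' the seed.
#'
#' @param model a trained `qa_model`.
#' @param record a [qa_record] (or a precomputed `record_encoding` via `enc`).
#' @param kg the [med_kg].
#' @param profiles list of [doctor_profile].
#' @param beam beam size (default 5).
#' @param topk per-step truncation (default 64).
#' @param max_len maximum generated length (default 30 tokens).
#' @param min_len `<eos>` is suppressed before this many tokens (default 8).
#' @param rep_penalty probability discount factor for tokens already present
#'   in the hypothesis (default 3; 1 disables). The toy decoder has no
#'   coverage state, so this standard penalty stands in for it.
#' @param seed integer seed for sampling.
#' @param sample draw stochastic expansions (default) or deterministic top
#'   tokens.
#' @param enc optional precomputed [encode_record()] output.
#' @return List with `tokens` (generated token vector), `kmax` (index of the
#'   copy-source candidate) and `logp` (cumulative log-probability).
#' @export
decode_answer <- function(model, record, kg, profiles, beam = 5, topk = 64,
                          max_len = 30, min_len = 8, rep_penalty = 3,
                          seed = 1, sample = TRUE, enc = NULL) {
  if (beam < 1 || topk < 1) stop_arg("beam and topk must be >= 1")
  if (is.null(enc)) enc <- encode_record(record, model, kg, profiles)
  theta <- model$theta
  p_rank <- rank_forward_backward(enc, theta, grad = FALSE)$p
  kmax <- which.max(p_rank)
  ca <- enc$pa[[kmax]]
  H_cand <- enc$H_a[[kmax]]
  cand_idx <- enc$cand_idx[[kmax]]
  g <- generation_gate(enc$pq, ca, theta)
  Vn <- length(model$vocab$tokens)
  Wc_Ha <- H_cand %*% t(theta$W_c)

  # p_final depends on the previous token only; memoise per token id
  cache <- new.env(parent = emptyenv())
  p_final_of <- function(prev) {
    key <- as.character(prev)
    if (!is.null(cache[[key]])) return(cache[[key]])
    x <- c(model$tok_emb[prev, ], enc$pq, enc$pg)
    gd <- generation_distribution(list(x = x), theta)
    pi <- softmax(as.numeric(Wc_Ha %*% gd$h))
    p_copy <- numeric(Vn)
    agg <- rowsum(pi, group = cand_idx)
    p_copy[as.integer(rownames(agg))] <- agg[, 1]
    p <- g * gd$p + (1 - g) * p_copy
    p[1] <- 0 # never emit <pad>
    p <- p / sum(p)
    cache[[key]] <- p
    p
  }

  beams <- list(list(seq = 3L, logp = 0, done = FALSE)) # <bos>
  with_seed(derive_seed(seed, "decode"), {
    for (step in seq_len(max_len)) {
      if (all(vapply(beams, `[[`, logical(1), "done"))) break
      cand <- list()
      for (bm in beams) {
        if (bm$done) {
          cand[[length(cand) + 1L]] <- bm
          next
        }
        p <- p_final_of(bm$seq[length(bm$seq)])
        if (length(bm$seq) - 1L < min_len && sum(p[-4L]) > 0) {
          p[4L] <- 0 # suppress early <eos>
        }
        if (rep_penalty > 1) {
          seen <- unique(bm$seq[-1L])
          p[seen] <- p[seen] / rep_penalty
        }
        p <- p / sum(p)
        ord <- order(-p)
        keep <- utils::head(ord[p[ord] > 0], topk)
        pk <- p[keep] / sum(p[keep])
        picks <- if (sample) {
          keep[sample.int(length(keep), size = min(beam, length(keep)), prob = pk)]
        } else {
          utils::head(keep, beam)
        }
        for (tok in picks) {
          cand[[length(cand) + 1L]] <- list(
            seq = c(bm$seq, tok),
            logp = bm$logp + log(p[tok]),
            done = tok == 4L # <eos>
          )
        }
      }
      scores <- vapply(cand, `[[`, numeric(1), "logp")
      beams <- cand[utils::head(order(-scores), beam)]
    }
  })
  scores <- vapply(beams, `[[`, numeric(1), "logp")
  best <- beams[[which.max(scores)]]
  ids <- best$seq[best$seq != 3L & best$seq != 4L]
  list(tokens = model$vocab$tokens[ids], kmax = kmax, logp = best$logp)
}
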