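# Pure-loop reference implementations, kept deliberately scalar-wise and
# independent of the package's vectorized code paths.

naive_softmax <- function(x) exp(x) / sum(exp(x))

oracle_leaky <- function(x, slope) if (x >= 0) x else slope * x

# Knowledge-aware attention of sequence A over sequence B (additive scores).
oracle_attention <- function(H_a, H_b, M, params, use_rel = TRUE) {
  Ta <- nrow(H_a); Tb <- nrow(H_b); d <- ncol(H_a)
  out <- matrix(0, Ta, d)
  alpha <- matrix(0, Ta, Tb)
  for (i in seq_len(Ta)) {
    s <- numeric(Tb)
    for (j in seq_len(Tb)) {
      q_i <- as.numeric(H_a[i, ] %*% params$W_q)
      k_j <- as.numeric(H_b[j, ] %*% params$W_k)
      rel <- if (use_rel) as.numeric(M[i, j, ] %*% params$W_r) else numeric(d)
      s[j] <- sum(params$v * tanh(q_i + k_j + rel))
    }
    alpha[i, ] <- naive_softmax(s)
    for (j in seq_len(Tb)) {
      out[i, ] <- out[i, ] + alpha[i, j] * as.numeric(H_b[j, ] %*% params$W_v)
    }
  }
  list(H = out, alpha = alpha)
}

# Directed neighbour list of a node: targets of out-edges and sources of
# in-edges, each with its stored edge index.
oracle_neighbours <- function(i, edges) {
  out <- list()
  for (e in seq_len(nrow(edges))) {
    if (edges$head[e] == i) out[[length(out) + 1L]] <- c(j = edges$tail[e], eid = e)
    if (edges$tail[e] == i && edges$head[e] != i) {
      out[[length(out) + 1L]] <- c(j = edges$head[e], eid = e)
    }
  }
  out
}

oracle_krgat_attention <- function(V, edges, E, layer, slope = 0.2) {
  res <- data.frame(src = integer(0), dst = integer(0), eid = integer(0), alpha = numeric(0))
  for (i in seq_len(nrow(V))) {
    nb <- oracle_neighbours(i, edges)
    if (!length(nb)) next
    beta <- vapply(nb, function(p) {
      vi <- as.numeric(V[i, ] %*% layer$W_k)
      vj <- as.numeric(V[p["j"], ] %*% layer$W_k)
      er <- as.numeric(E[p["eid"], ] %*% layer$W_r)
      oracle_leaky(sum(layer$a * c(vi, vj, er)), slope)
    }, numeric(1))
    a <- naive_softmax(beta)
    for (k in seq_along(nb)) {
      res <- rbind(res, data.frame(
        src = i, dst = nb[[k]]["j"], eid = nb[[k]]["eid"], alpha = a[k]
      ))
    }
  }
  res
}

oracle_krgat_layer <- function(V, edges, E, layer, slope = 0.2) {
  att <- oracle_krgat_attention(V, edges, E, layer, slope)
  out <- V
  for (i in seq_len(nrow(V))) {
    rows <- att[att$src == i, , drop = FALSE]
    if (!nrow(rows)) next
    acc <- numeric(ncol(V))
    for (r in seq_len(nrow(rows))) {
      er <- as.numeric(E[rows$eid[r], ] %*% layer$W_r)
      acc <- acc + rows$alpha[r] * (V[rows$dst[r], ] + er)
    }
    out[i, ] <- ifelse(acc >= 0, acc, exp(acc) - 1)
  }
  out
}

# Relation-free graph-attention score (the traditional form): the attention
# vector sees only the two transformed endpoints.
oracle_eq5_scores <- function(V, edges, W_k, a2, slope = 0.2) {
  res <- data.frame(src = integer(0), dst = integer(0), beta = numeric(0))
  for (i in seq_len(nrow(V))) {
    for (p in oracle_neighbours(i, edges)) {
      vi <- as.numeric(V[i, ] %*% W_k)
      vj <- as.numeric(V[p["j"], ] %*% W_k)
      res <- rbind(res, data.frame(
        src = i, dst = p["j"],
        beta = oracle_leaky(sum(a2 * c(vi, vj)), slope)
      ))
    }
  }
  res
}
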