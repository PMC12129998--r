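#' Extract the one-hop knowledge subgraph of a question
#'
#' Entities whose surface forms occur in the question (exact token-sequence
#' match, longest forms included) become central nodes; their one-hop
#' neighbours join them. Edges are all graph edges between included nodes
#' that are incident to a central node. No match yields an empty subgraph,
#' which encodes downstream to a zero context vector.
#'
#' @param question character vector of tokens.
#' @param kg a [med_kg].
#' @return Object of class `kg_subgraph`: `nodes` (entity ids) and `edges`
#'   (data.frame `head`, `rtype`, `tail`).
#' @export
extract_subgraph <- function(question, kg) {
  m <- kg_match_forms(question, kg)
  central <- unique(m$entity_id)
  if (length(central) == 0L) {
    return(structure(
      list(nodes = character(0), edges = kg$relations[0, , drop = FALSE]),
      class = "kg_subgraph"
    ))
  }
  rel <- kg$relations
  inc <- rel$head %in% central | rel$tail %in% central
  edges <- rel[inc, , drop = FALSE]
  nodes <- unique(c(central, edges$head, edges$tail))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "kg_subgraph")
}

#' Parameters of a relation-aware graph attention (KRGAT) stack
#'
#' Per layer: a shared node transform `W_k`, a relation transform `W_r` and
#' an attention vector `a` of length `3 d` scoring the concatenation of the
#' transformed endpoints and the transformed relation embedding. The leaky
#' ReLU slope (0.2) and the single attention head follow standard graph
#' attention conventions.
#'
#' @param dim node/relation embedding dimension.
#' @param layers number of layers (default 2).
#' @param seed integer seed for the frozen random initialization.
#' @param leaky_slope negative slope of the scoring nonlinearity.
#' @return Object of class `krgat_params`.
#' @export
krgat_params <- function(dim, layers = 2, seed = 1, leaky_slope = 0.2) {
  if (layers < 1) stop_arg("layers must be >= 1")
  lay <- lapply(seq_len(layers), function(l) {
    list(
      W_k = hash_orth(dim, dim, sprintf("krgat_Wk_l%d", l), seed),
      W_r = hash_orth(dim, dim, sprintf("krgat_Wr_l%d", l), seed),
      a = hash_matrix(3 * dim, 1, sprintf("krgat_a_l%d", l), seed, sd = 1 / sqrt(dim))[, 1]
    )
  })
  structure(
    list(dim = dim, layers = lay, leaky_slope = leaky_slope),
    class = "krgat_params"
  )
}

# Directed pair list for attention: each stored edge (h, t) yields t in N(h)
# and h in N(t) with the same (frozen) edge embedding; self-edges once.
krgat_pairs <- function(n_nodes, edges_idx) {
  if (nrow(edges_idx) == 0L) {
    return(data.frame(src = integer(0), dst = integer(0), eid = integer(0)))
  }
  fwd <- data.frame(src = edges_idx$head, dst = edges_idx$tail, eid = seq_len(nrow(edges_idx)))
  bwd <- data.frame(src = edges_idx$tail, dst = edges_idx$head, eid = seq_len(nrow(edges_idx)))
  rbind(fwd, bwd[bwd$src != bwd$dst, , drop = FALSE])
}

#' Relation-aware attention weights over a subgraph
#'
#' For each directed neighbour pair the unnormalized score is
#' \deqn{\beta_{ij} = \mathrm{LeakyReLU}(a^\top [W_k v_i \| W_k v_j \| W_r e^r_{ij}])}
#' and attention weights are the softmax of \eqn{\beta_{ij}} over the
#' neighbour set of each source node, so rows sum to one for every node with
#' at least one neighbour. Setting `W_r = 0` reduces the score exactly to the
#' relation-free graph-attention form (the third block contributes nothing).
#'
#' @param node_embs numeric matrix, one row per node.
#' @param edges data.frame with integer columns `head`, `tail` (row indices
#'   into `node_embs`) and column `eid` or implicit edge order.
#' @param edge_embs numeric matrix, one row per edge of `edges`.
#' @param layer a single layer of [krgat_params()] (`W_k`, `W_r`, `a`).
#' @param leaky_slope negative slope (default 0.2).
#' @return data.frame `src`, `dst`, `eid`, `beta`, `alpha`.
#' @export
krgat_attention <- function(node_embs, edges, edge_embs, layer, leaky_slope = 0.2) {
  d <- ncol(node_embs)
  if (ncol(layer$W_k) != d || length(layer$a) != 3 * d) {
    stop_arg("krgat: dimension mismatch between embeddings and parameters")
  }
  pairs <- krgat_pairs(nrow(node_embs), edges)
  if (nrow(pairs) == 0L) {
    return(data.frame(
      src = integer(0), dst = integer(0), eid = integer(0),
      beta = numeric(0), alpha = numeric(0)
    ))
  }
  WkV <- node_embs %*% layer$W_k
  WrE <- edge_embs %*% layer$W_r
  z <- cbind(
    WkV[pairs$src, , drop = FALSE],
    WkV[pairs$dst, , drop = FALSE],
    WrE[pairs$eid, , drop = FALSE]
  )
  beta <- leaky_relu(as.numeric(z %*% layer$a), leaky_slope)
  alpha <- numeric(length(beta))
  for (i in unique(pairs$src)) {
    sel <- pairs$src == i
    alpha[sel] <- softmax(beta[sel])
  }
  data.frame(src = pairs$src, dst = pairs$dst, eid = pairs$eid, beta = beta, alpha = alpha)
}

#' One KRGAT propagation layer
#'
#' Updates every node by the attention-weighted sum of its neighbours'
#' embeddings shifted by the transformed relation embedding,
#' \deqn{v_i^{(l)} = \sigma\big(\sum_{j \in N(i)} \alpha_{ij} (v_j^{(l-1)} + W_r e^r_{ij})\big)}
#' with \eqn{\sigma} = ELU. Nodes without neighbours pass through unchanged
#' (the subgraph encoder injects reserved self-edges beforehand so this only
#' occurs when called directly on an edgeless graph).
#'
#' @inheritParams krgat_attention
#' @return Numeric matrix of updated node embeddings.
#' @export
krgat_layer <- function(node_embs, edges, edge_embs, layer, leaky_slope = 0.2) {
  att <- krgat_attention(node_embs, edges, edge_embs, layer, leaky_slope)
  out <- node_embs
  if (nrow(att)) {
    WrE <- edge_embs %*% layer$W_r
    msg <- (node_embs[att$dst, , drop = FALSE] + WrE[att$eid, , drop = FALSE]) * att$alpha
    agg <- rowsum(msg, group = att$src)
    touched <- as.integer(rownames(agg))
    out[touched, ] <- elu(agg)
  }
  out
}

#' Encode a knowledge subgraph with a KRGAT stack
#'
#' Node embeddings are initialized by encoding each entity's canonical
#' surface form with the text encoder (mean-pooled over its tokens); edge
#' embeddings encode the relation label and are frozen. Isolated nodes get a
#' reserved `self` relation edge so the neighbour sum is never empty. The
#' subgraph encoding is the matrix of final-layer node vectors in node order
#' (their concatenation); an empty subgraph encodes to a zero-row matrix
#' whose pooled context is the zero vector.
#'
#' @param sub a `kg_subgraph` from [extract_subgraph()].
#' @param kg the [med_kg] the subgraph came from (for surface forms).
#' @param params a [krgat_params()].
#' @param encoder a `text_encoder` used for node/edge initialization.
#' @return Numeric matrix with one row per subgraph node (zero rows when the
#'   subgraph is empty), rownames = entity ids.
#' @export
encode_subgraph <- function(sub, kg, params, encoder) {
  d <- params$dim
  if (length(sub$nodes) == 0L) return(matrix(0, 0, d))
  name_of <- function(eid) {
    kg$entities$surface_forms[[match(eid, kg$entities$entity_id)]][1]
  }
  V <- t(vapply(sub$nodes, function(eid) {
    pool_mean(encoder$encode(strsplit(name_of(eid), " ", fixed = TRUE)[[1]]), d)
  }, numeric(d)))
  idx <- stats::setNames(seq_along(sub$nodes), sub$nodes)
  edges <- data.frame(
    head = unname(idx[sub$edges$head]),
    tail = unname(idx[sub$edges$tail]),
    rtype = sub$edges$rtype,
    stringsAsFactors = FALSE
  )
  # reserved self relation for isolated nodes
  incident <- unique(c(edges$head, edges$tail))
  isolated <- setdiff(seq_along(sub$nodes), incident)
  if (length(isolated)) {
    edges <- rbind(edges, data.frame(head = isolated, tail = isolated, rtype = "self"))
  }
  rel_emb <- relation_embedder(d, encoder$seed)
  E <- t(vapply(edges$rtype, rel_emb, numeric(d)))
  if (nrow(edges) == 1L) E <- matrix(E, 1, d)
  for (layer in params$layers) {
    V <- krgat_layer(V, edges[, c("head", "tail")], E, layer, params$leaky_slope)
  }
  rownames(V) <- sub$nodes
  V
}
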