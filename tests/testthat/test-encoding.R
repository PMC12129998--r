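test_that("subgraph extraction collects central entities and one-hop neighbours", {
  kg <- toy_kg()
  # "brain_tumor" has 3 neighbours -> 4 nodes, 3 edges
  sub <- extract_subgraph(c("about", "brain_tumor", "please"), kg)
  expect_setequal(sub$nodes, c("brain_tumor", "headache", "ct_scan", "craniotomy"))
  expect_equal(nrow(sub$edges), 3)
  # no entity mention -> empty subgraph
  empty <- extract_subgraph(c("nothing", "matches"), kg)
  expect_length(empty$nodes, 0)
  expect_equal(nrow(empty$edges), 0)
  # two central entities sharing a neighbour appear once
  sub2 <- extract_subgraph(c("headache", "ct_scan"), kg)
  expect_equal(anyDuplicated(sub2$nodes), 0)
  expect_true("brain_tumor" %in% sub2$nodes)
  # multi-token surface form also anchors the subgraph
  sub3 <- extract_subgraph(c("persistent", "headache", "tumor"), kg)
  expect_true("brain_tumor" %in% sub3$nodes)
})

test_that("attention weights are singleton-1, symmetric under tied scores, normalized", {
  d <- 6
  layer <- krgat_params(d, layers = 1, seed = 3)$layers[[1]]
  # node with exactly one neighbour -> alpha = 1 regardless of parameters
  V <- rand_mat(2, d, 1)
  E <- rand_mat(1, d, 2)
  att <- krgat_attention(V, data.frame(head = 1L, tail = 2L), E, layer)
  expect_equal(att$alpha[att$src == 1], 1.0)
  expect_equal(att$alpha[att$src == 2], 1.0)
  # two neighbours with identical (node, edge) content -> 0.5 each
  V2 <- rbind(V[1, ], V[2, ], V[2, ])
  E2 <- rbind(E[1, ], E[1, ])
  att2 <- krgat_attention(V2, data.frame(head = c(1L, 1L), tail = c(2L, 3L)), E2, layer)
  expect_equal(att2$alpha[att2$src == 1], c(0.5, 0.5))
  # normalization on a random graph
  V3 <- rand_mat(7, d, 5)
  edges3 <- data.frame(head = c(1L, 1L, 2L, 3L, 5L), tail = c(2L, 3L, 4L, 4L, 6L))
  E3 <- rand_mat(5, d, 6)
  att3 <- krgat_attention(V3, edges3, E3, layer)
  sums <- tapply(att3$alpha, att3$src, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("krgat attention and layer match the nested-loop reference", {
  d <- 5
  for (s in 1:50) {
    n <- withr::with_seed(s, sample(3:8, 1))
    n_e <- withr::with_seed(s + 100, sample(2:10, 1))
    V <- rand_mat(n, d, s)
    edges <- withr::with_seed(s + 200, data.frame(
      head = sample(n, n_e, replace = TRUE),
      tail = sample(n, n_e, replace = TRUE)
    ))
    E <- rand_mat(n_e, d, s + 300)
    layer <- krgat_params(d, layers = 1, seed = s)$layers[[1]]
    got <- krgat_attention(V, edges, E, layer)
    ref <- oracle_krgat_attention(V, edges, E, layer)
    got_key <- got[order(got$src, got$dst, got$eid), ]
    ref_key <- ref[order(ref$src, ref$dst, ref$eid), ]
    expect_equal(got_key$alpha, ref_key$alpha, tolerance = 1e-6)
    expect_equal(
      krgat_layer(V, edges, E, layer),
      oracle_krgat_layer(V, edges, E, layer),
      tolerance = 1e-6
    )
  }
})

test_that("two-layer subgraph stack matches step-by-step loop computation", {
  kg <- toy_kg()
  params <- krgat_params(8, layers = 2, seed = 4)
  enc <- toy_text_encoder(8, seed = 4)
  sub <- extract_subgraph(c("brain_tumor", "please"), kg)
  got <- encode_subgraph(sub, kg, params, enc)
  # rebuild inputs exactly as the encoder does, then loop the layers
  name_of <- function(eid) kg$entities$surface_forms[[match(eid, kg$entities$entity_id)]][1]
  V <- t(vapply(sub$nodes, function(eid) {
    colMeans(enc$encode(strsplit(name_of(eid), " ")[[1]]))
  }, numeric(8)))
  idx <- stats::setNames(seq_along(sub$nodes), sub$nodes)
  edges <- data.frame(head = unname(idx[sub$edges$head]), tail = unname(idx[sub$edges$tail]))
  rel_emb <- medkgqa:::relation_embedder(8, enc$seed)
  E <- t(vapply(sub$edges$rtype, rel_emb, numeric(8)))
  for (layer in params$layers) V <- oracle_krgat_layer(V, edges, E, layer)
  expect_equal(unname(got), unname(V), tolerance = 1e-6)
})

test_that("relation transform zero reduces scoring to the relation-free form", {
  d <- 6
  layer <- krgat_params(d, layers = 1, seed = 8)$layers[[1]]
  layer$W_r <- layer$W_r * 0
  V <- rand_mat(5, d, 2)
  edges <- data.frame(head = c(1L, 2L, 3L), tail = c(2L, 3L, 4L))
  E <- rand_mat(3, d, 3)
  got <- krgat_attention(V, edges, E, layer)
  ref <- oracle_eq5_scores(V, edges, layer$W_k, layer$a[1:(2 * d)])
  got_key <- got[order(got$src, got$dst), ]
  ref_key <- ref[order(ref$src, ref$dst), ]
  expect_equal(got_key$beta, ref_key$beta, tolerance = 1e-12)
})

test_that("attention is sensitive to relation types", {
  d <- 6
  layer <- krgat_params(d, layers = 1, seed = 8)$layers[[1]]
  V <- rand_mat(4, d, 2)
  edges <- data.frame(head = c(1L, 1L), tail = c(2L, 3L))
  E <- rand_mat(2, d, 3)
  base <- krgat_attention(V, edges, E, layer)
  swapped <- krgat_attention(V, edges, E[2:1, ], layer)
  expect_false(isTRUE(all.equal(base$beta, swapped$beta)))
})

test_that("isolated nodes receive a reserved self relation and empty graphs pool to zero", {
  kg <- toy_kg()
  params <- krgat_params(8, layers = 2, seed = 4)
  enc <- toy_text_encoder(8, seed = 4)
  # a subgraph with a single node and no edges
  sub <- structure(
    list(nodes = "stroke", edges = kg$relations[0, ]),
    class = "kg_subgraph"
  )
  out <- encode_subgraph(sub, kg, params, enc)
  expect_equal(nrow(out), 1)
  expect_true(all(is.finite(out)))
  # singleton softmax: the self-edge output is elu(v + W_r e_self) layered
  empty <- encode_subgraph(
    structure(list(nodes = character(0), edges = kg$relations[0, ]), class = "kg_subgraph"),
    kg, params, enc
  )
  expect_equal(nrow(empty), 0)
  expect_equal(medkgqa:::pool_mean(empty, 8), numeric(8))
})

test_that("subgraph encoding is equivariant to node order", {
  kg <- toy_kg()
  params <- krgat_params(8, layers = 2, seed = 4)
  enc <- toy_text_encoder(8, seed = 4)
  sub <- extract_subgraph(c("brain_tumor"), kg)
  perm <- c(3, 1, 4, 2)
  sub_p <- structure(
    list(nodes = sub$nodes[perm], edges = sub$edges),
    class = "kg_subgraph"
  )
  a <- encode_subgraph(sub, kg, params, enc)
  b <- encode_subgraph(sub_p, kg, params, enc)
  expect_equal(a[sub$nodes[perm], ], b[sub$nodes[perm], ], tolerance = 1e-10)
})

test_that("toy encoder obeys the text-encoder contract deterministically", {
  enc <- toy_text_encoder(16, seed = 2)
  H <- enc$encode(c("one", "two", "three"))
  expect_equal(dim(H), c(3, 16))
  expect_identical(H, toy_text_encoder(16, seed = 2)$encode(c("one", "two", "three")))
  expect_false(isTRUE(all.equal(H, toy_text_encoder(16, seed = 3)$encode(c("one", "two", "three")))))
  expect_equal(nrow(enc$encode(character(0))), 0)
})
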