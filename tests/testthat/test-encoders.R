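# Encoder contracts: GINE update correctness, pooling invariances, shape
# contracts, and the freeze behaviour.

test_that("gine_layer matches the hand-evaluated two-node example", {
  x <- rbind(c(1, -2), c(0.5, 3))
  ei <- cbind(c(1L, 2L), c(2L, 1L))   # one bond, both directions
  e <- rbind(c(0.2, 0.1), c(0.2, 0.1))
  out <- gine_layer(x, ei, e, eps = 0)
  expect_equal(out[1, ], x[1, ] + pmax(x[2, ] + e[2, ], 0))
  expect_equal(out[2, ], x[2, ] + pmax(x[1, ] + e[1, ], 0))
  # isolated node: empty neighbour sum
  iso <- gine_layer(matrix(c(1, 2), 1), matrix(integer(0), 2, 0),
                    matrix(0, 0, 2), eps = 0.5)
  expect_equal(iso, matrix(c(1.5, 3), 1))
})

test_that("gine_layer agrees with a dense brute-force oracle on random graphs", {
  set.seed(21)
  mlp <- function(z) pmax(z %*% matrix(rnorm(16, sd = 0.5), 4, 4), 0)
  for (i in 1:40) {
    g <- random_graph(sample(1:6, 1), 4L)
    eps <- rnorm(1)
    got <- gine_layer(g$x, g$edge_index, g$eproj, eps, identity)
    ref <- gine_dense_oracle(g$x, g$edge_index, g$eproj, eps, identity)
    expect_lt(max(abs(got - ref)), 1e-10)
  }
})

test_that("encode_graph is invariant to node relabeling and sums over components", {
  enc <- new_encoder(small_graph_cfg(), seed = 1)
  g <- featurize_graph(parse_and_validate("CC(=O)c1ccc(Cl)cc1"))
  e0 <- encode_graph(enc, g)
  set.seed(22)
  for (i in 1:10) {
    p <- sample(nrow(g$node_features))
    inv <- match(seq_along(p), p)
    gp <- list(node_features = g$node_features[p, , drop = FALSE],
               edge_index = matrix(inv[g$edge_index], 2L),
               edge_attr = g$edge_attr)
    expect_lt(max(abs(encode_graph(enc, gp) - e0)), 1e-9)
  }
  # disjoint duplicated copy doubles the pooled pre-projection vector:
  # per-node states replicate, so the global sum pool scales by two
  n <- nrow(g$node_features)
  gdup <- list(node_features = rbind(g$node_features, g$node_features),
               edge_index = cbind(g$edge_index, g$edge_index + n),
               edge_attr = rbind(g$edge_attr, g$edge_attr))
  b1 <- moltitox:::batch_graphs(list(g))
  b2 <- moltitox:::batch_graphs(list(gdup))
  tpa <- moltitox:::ad_tape(enc$params, training = FALSE)
  tpb <- moltitox:::ad_tape(enc$params, training = FALSE)
  pa <- colSums(moltitox:::forward_graph_nodes(enc, b1, tpa)$val)
  pb <- colSums(moltitox:::forward_graph_nodes(enc, b2, tpb)$val)
  expect_equal(pb, 2 * pa, tolerance = 1e-9)
  expect_true(all(is.finite(encode_graph(enc, gdup))))
  expect_identical(dim(e0), c(1L, 16L))     # shape contract d_g
})

test_that("encode_smiles pools only real tokens and honors shape contracts", {
  vocab <- build_vocab(c("CCO", "CC(=O)c1ccc(Cl)cc1", "c1ccncc1"))
  enc <- new_encoder(small_smiles_cfg(), seed = 2, vocab = vocab)
  tk <- tokenize_smiles("CC(=O)c1ccc(Cl)cc1", vocab)
  e0 <- encode_smiles(enc, tk)
  expect_identical(dim(e0), c(1L, 16L))
  # pad length must not matter
  v50 <- vocab; v50$max_len <- 50L
  expect_lt(max(abs(encode_smiles(enc, tokenize_smiles("CC(=O)c1ccc(Cl)cc1", v50)) - e0)),
            1e-9)
  # a single-token sequence mean-pools to that token's contextual state
  t1 <- tokenize_smiles("C", vocab)
  expect_identical(sum(t1$mask), 1L)
  expect_true(all(is.finite(encode_smiles(enc, t1))))
  # an all-pad sequence is rejected
  bad <- list(ids = rep(vocab$pad_id, 202L), mask = rep(0L, 202L))
  expect_error(encode_smiles(enc, bad), "all-pad")
})

test_that("image encoder honors the backbone contract and rejects bad shapes", {
  enc <- new_encoder(small_image_cfg(), seed = 3)
  img <- normalize_image(render_image(parse_and_validate("CCO")))
  e <- encode_image(enc, img)
  expect_identical(dim(e), c(1L, 16L))
  bb <- encode_image(enc, img, backbone = TRUE)
  expect_identical(ncol(bb), 32L)             # last stage width
  # default configuration: 512-dimensional backbone feature vector
  expect_identical(encoder_config("image")$widths[4], 512L)
  # all-zero input still yields finite output through bias paths
  z <- array(0, c(3L, 224L, 224L))
  expect_true(all(is.finite(encode_image(enc, z))))
  expect_error(encode_image(enc, array(0, c(3L, 100L, 100L))), "expected")
})

test_that("spectrum encoder honors the 768-dim default contract and distinguishes shifts", {
  expect_identical(encoder_config("spectrum")$backbone_dim, 768L)
  enc <- new_encoder(small_spectrum_cfg(), seed = 4)
  b1 <- bin_spectrum(c(25, 128))
  b2 <- bin_spectrum(c(25, 128) + 100)        # shifted by +100 bins
  e1 <- encode_spectrum(enc, b1)
  e2 <- encode_spectrum(enc, b2)
  expect_identical(dim(e1), c(1L, 16L))
  expect_gt(max(abs(e1 - e2)), 0)
  expect_error(encode_spectrum(enc, b1[1:100]), "bins")
})

test_that("frozen spectrum backbone stays bit-identical while the head trains", {
  cfg <- small_spectrum_cfg(backbone_frozen = TRUE)
  enc <- new_encoder(cfg, seed = 5)
  backbone_names <- grep("^(c[0-9]|bn[0-9]|bb\\.)", ls(enc$params), value = TRUE)
  head_names <- grep("^(head|probe)", ls(enc$params), value = TRUE)
  before <- lapply(ls(enc$params), function(n) enc$params[[n]])
  names(before) <- ls(enc$params)
  set.seed(51)
  bits <- matrix(rbinom(4 * 260, 1, 0.05), 4, 260)
  labels <- matrix(rbinom(48, 1, 0.5), 4, 12)
  tp <- moltitox:::ad_tape(enc$params, training = TRUE)
  emb <- moltitox:::forward_spectrum(enc, bits, tp)$emb
  logits <- moltitox:::nn_linear(tp, emb, "probe")
  loss <- moltitox:::ad_bce_masked(logits, labels, matrix(1, 4, 12))
  grads <- moltitox:::ad_backward(tp, loss)
  # frozen parameters receive exactly zero gradient
  for (nm in backbone_names) {
    expect_true(all(moltitox:::grad_of(grads, enc$params, nm) == 0))
  }
  opt <- moltitox:::opt_adam(lr = 1e-2)
  moltitox:::opt_step(opt, enc$params, grads)
  for (nm in backbone_names) {
    expect_identical(enc$params[[nm]], before[[nm]])
  }
  changed <- vapply(head_names, function(nm) {
    !identical(enc$params[[nm]], before[[nm]])
  }, TRUE)
  expect_true(any(changed))
})

test_that("all encoders are deterministic in evaluation mode", {
  vocab <- build_vocab("CC(=O)c1ccc(Cl)cc1")
  encs <- list(
    graph = new_encoder(small_graph_cfg(), seed = 6),
    smiles = new_encoder(small_smiles_cfg(), seed = 6, vocab = vocab),
    image = new_encoder(small_image_cfg(), seed = 6),
    spectrum = new_encoder(small_spectrum_cfg(), seed = 6)
  )
  mol <- parse_and_validate("CC(=O)c1ccc(Cl)cc1")
  g <- featurize_graph(mol)
  tk <- tokenize_smiles("CC(=O)c1ccc(Cl)cc1", vocab)
  img <- normalize_image(render_image(mol))
  bits <- bin_spectrum(c(25, 128, 180))
  expect_identical(encode_graph(encs$graph, g), encode_graph(encs$graph, g))
  expect_identical(encode_smiles(encs$smiles, tk), encode_smiles(encs$smiles, tk))
  expect_identical(encode_image(encs$image, img), encode_image(encs$image, img))
  expect_identical(encode_spectrum(encs$spectrum, bits),
                   encode_spectrum(encs$spectrum, bits))
})

test_that("load_backbone_weights validates names and shapes", {
  enc <- new_encoder(small_spectrum_cfg(), seed = 7)
  w <- enc$params[["c1.W"]] * 0 + 1
  load_backbone_weights(enc, list(`c1.W` = w))
  expect_identical(enc$params[["c1.W"]], w)
  expect_error(load_backbone_weights(enc, list(nope = w)), "unknown")
  expect_error(load_backbone_weights(enc, list(`c1.W` = w[, 1:2])), "shape")
})
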