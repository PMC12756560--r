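# Fusion contracts: projection with missing-token substitution, attention
# normalization, prediction head, and attention summaries.

make_fusion <- function(d_e = 16L, n_heads = 2L, mods = moltitox:::MODALITY_ORDER,
                        seed = 9L, dm = 8L) {
  new_fusion(fusion_config(d_e = d_e, n_heads = n_heads,
                           active_modalities = mods),
             stats::setNames(as.list(rep(dm, length(mods))), mods),
             seed = seed)
}

test_that("project_modalities substitutes the missing token and ignores absent inputs", {
  fus <- make_fusion()
  set.seed(31)
  embs <- list(graph = rnorm(8), smiles = rnorm(8), image = rnorm(8),
               spectrum = rnorm(8))
  X <- project_modalities(fus, embs)
  expect_identical(dim(X), c(4L, 16L))
  expect_identical(rownames(X), c("graph", "smiles", "image", "spectrum"))
  # absent spectrum: projected row is independent of the supplied vector
  pres <- c(graph = TRUE, smiles = TRUE, image = TRUE, spectrum = FALSE)
  X1 <- project_modalities(fus, embs, pres)
  embs2 <- embs; embs2$spectrum <- embs2$spectrum + 1000
  X2 <- project_modalities(fus, embs2, pres)
  expect_identical(X1, X2)
  # zero-initialized token propagates to ReLU(bias) before training
  b <- as.numeric(fus$params[["proj.spectrum.b"]])
  expect_equal(unname(X1["spectrum", ]), pmax(b, 0), tolerance = 1e-12)
  # ... and to exactly zero if the map carries no bias
  fus0 <- fus
  fus0$params[["proj.spectrum.b"]] <- fus0$params[["proj.spectrum.b"]] * 0
  X0 <- project_modalities(fus0, embs, pres)
  expect_true(all(X0["spectrum", ] == 0))
  expect_gt(sum(abs(X1["graph", ])), 0)
})

test_that("attention rows are stochastic, uniform for identical tokens, and trivial at M=1", {
  fus <- make_fusion()
  set.seed(32)
  tok <- matrix(rnorm(64), 4, 16)
  af <- attention_fuse(fus, tok)
  for (hh in 1:2) {
    expect_equal(rowSums(af$attention[hh, , ]), rep(1, 4), tolerance = 1e-5)
  }
  same <- matrix(rep(rnorm(16), each = 4), 4, 16)
  af2 <- attention_fuse(fus, same)
  expect_equal(as.vector(af2$attention), rep(0.25, 2 * 16), tolerance = 1e-9)
  af1 <- attention_fuse(fus, tok[1, , drop = FALSE])
  expect_equal(as.vector(af1$attention), c(1, 1))
  expect_equal(af1$fused, as.numeric(af1$attended[1, ]))
  # fused is the mean of the attended rows
  expect_equal(af$fused, colMeans(af$attended))
})

test_that("the prediction head emits 12 deterministic logits and reduces to bias when weights vanish", {
  fus <- make_fusion()
  set.seed(33)
  fused <- rnorm(16)
  l1 <- predict_endpoints(fus, fused)
  expect_identical(dim(l1), c(1L, 12L))
  expect_identical(l1, predict_endpoints(fus, fused))
  # zero weights, bias b -> logits = b
  for (nm in c("head.1.W", "head.2.W", "head.3.W")) {
    fus$params[[nm]] <- fus$params[[nm]] * 0
  }
  b <- rnorm(12)
  fus$params[["head.3.b"]] <- matrix(b, 1L)
  expect_equal(as.numeric(predict_endpoints(fus, fused)), b)
})

test_that("missing-token gradient is exactly zero on full batches and nonzero on mixed ones", {
  mods <- c("graph", "spectrum")
  fus <- make_fusion(mods = mods)
  # generic parameters: perturb the projection bias off its zero init
  set.seed(34)
  fus$params[["proj.spectrum.b"]] <- matrix(rnorm(16, sd = 0.5), 1L)
  fus$params[["missing.spectrum"]] <- matrix(rnorm(8, sd = 0.1), 1L)
  embs <- list(graph = matrix(rnorm(48), 6, 8),
               spectrum = matrix(rnorm(48), 6, 8))
  labels <- matrix(rbinom(72, 1, 0.5), 6, 12)
  grad_token <- function(pres_spec) {
    tp <- moltitox:::ad_tape(fus$params, training = FALSE)
    fwd <- moltitox:::forward_fusion(fus, embs,
                                     list(graph = rep(TRUE, 6),
                                          spectrum = pres_spec), tp)
    loss <- moltitox:::ad_bce_masked(fwd$logits, labels, matrix(1, 6, 12))
    grads <- moltitox:::ad_backward(tp, loss)
    moltitox:::grad_of(grads, fus$params, "missing.spectrum")
  }
  expect_true(all(grad_token(rep(TRUE, 6)) == 0))
  expect_gt(sum(abs(grad_token(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)))), 0)
})

test_that("logits are bit-identical under perturbation of an ignored spectrum input", {
  mods <- c("graph", "smiles", "spectrum")
  fus <- make_fusion(mods = mods)
  set.seed(35)
  embs <- list(graph = matrix(rnorm(24), 3, 8), smiles = matrix(rnorm(24), 3, 8),
               spectrum = matrix(rnorm(24), 3, 8))
  pres <- list(graph = rep(TRUE, 3), smiles = rep(TRUE, 3),
               spectrum = c(TRUE, FALSE, FALSE))
  tp1 <- moltitox:::ad_tape(fus$params, training = FALSE)
  l1 <- moltitox:::forward_fusion(fus, embs, pres, tp1)$logits$val
  embs2 <- embs
  embs2$spectrum[2:3, ] <- embs2$spectrum[2:3, ] * -57 + 3
  tp2 <- moltitox:::ad_tape(fus$params, training = FALSE)
  l2 <- moltitox:::forward_fusion(fus, embs2, pres, tp2)$logits$val
  expect_identical(l1, l2)
})

test_that("deactivating a modality removes its parameters from the gradient graph", {
  fus <- make_fusion(mods = c("graph", "smiles"))
  set.seed(36)
  embs <- list(graph = matrix(rnorm(16), 2, 8), smiles = matrix(rnorm(16), 2, 8))
  labels <- matrix(1, 2, 12)
  tp <- moltitox:::ad_tape(fus$params, training = FALSE)
  fwd <- moltitox:::forward_fusion(fus, embs, list(), tp)
  grads <- moltitox:::ad_backward(
    tp, moltitox:::ad_bce_masked(fwd$logits, labels, labels))
  expect_false(any(grepl("^(proj|missing)\\.(image|spectrum)", ls(grads))))
  expect_true("proj.graph.W" %in% ls(grads))
  # attention over the active pair still normalizes
  for (b in 1:2) {
    amap <- attention_fuse(fus, project_modalities(
      fus, list(graph = embs$graph[b, ], smiles = embs$smiles[b, ])))$attention
    expect_equal(rowSums(amap[1, , ]), rep(1, 2), tolerance = 1e-5)
  }
})

test_that("attention summaries average correctly and stay row-stochastic", {
  mods <- moltitox:::MODALITY_ORDER
  one <- array(runif(1 * 16), c(1, 4, 4))
  for (i in 1:4) one[1, i, ] <- one[1, i, ] / sum(one[1, i, ])
  s1 <- extract_attention_summary(list(one), mods)
  expect_equal(s1$mean_map, one[1, , ], ignore_attr = TRUE)   # mean of one
  expect_equal(sum(s1$received), 1, tolerance = 1e-9)         # conservation
  # pooling two disjoint halves of equal size equals the global mean
  set.seed(37)
  maps <- lapply(1:6, function(i) {
    a <- array(runif(2 * 16), c(2, 4, 4))
    for (hh in 1:2) for (r in 1:4) a[hh, r, ] <- a[hh, r, ] / sum(a[hh, r, ])
    a
  })
  g <- extract_attention_summary(maps, mods)$mean_map
  h1 <- extract_attention_summary(maps[1:3], mods)$mean_map
  h2 <- extract_attention_summary(maps[4:6], mods)$mean_map
  expect_equal((h1 + h2) / 2, g, tolerance = 1e-12)
  expect_equal(unname(rowSums(g)), rep(1, 4), tolerance = 1e-9)
})
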