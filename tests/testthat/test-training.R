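# Masked multi-task objective, the two-phase training protocol, and the
# seeded random search.

test_that("masked loss matches closed forms and ignores masked slots exactly", {
  # single observed entry, logit 0, target 1 -> -log sigmoid(0) = log 2
  logits <- matrix(0, 1, 12)
  targets <- matrix(0, 1, 12); targets[1, 3] <- 1
  observed <- matrix(0, 1, 12); observed[1, 3] <- 1
  expect_equal(masked_multitask_loss(logits, targets, observed), log(2),
               tolerance = 1e-12)
  # all entries missing -> 0
  expect_identical(masked_multitask_loss(logits, targets, observed * 0), 0)
  # flipping a masked value changes nothing, bit-exactly
  set.seed(41)
  z <- matrix(rnorm(24), 2, 12)
  t1 <- matrix(rbinom(24, 1, 0.5), 2, 12)
  obs <- matrix(rbinom(24, 1, 0.6), 2, 12)
  t2 <- t1; t2[obs == 0] <- 1 - t2[obs == 0]
  expect_identical(masked_multitask_loss(z, t1, obs),
                   masked_multitask_loss(z, t2, obs))
  # NA in masked slots is tolerated
  t3 <- t1; t3[obs == 0] <- NA
  expect_identical(masked_multitask_loss(z, t1, obs),
                   masked_multitask_loss(z, t3, obs))
})

test_that("an all-missing batch yields zero loss and zero parameter gradients", {
  params <- new.env(parent = emptyenv())
  moltitox:::init_linear(params, "l", 4, 12)
  set.seed(42)
  x <- matrix(rnorm(8), 2, 4)
  tp <- moltitox:::ad_tape(params, training = FALSE)
  z <- moltitox:::nn_linear(tp, moltitox:::ad_const(tp, x), "l")
  loss <- moltitox:::ad_bce_masked(z, matrix(1, 2, 12), matrix(0, 2, 12))
  expect_identical(as.numeric(loss$val), 0)
  grads <- moltitox:::ad_backward(tp, loss)
  expect_true(all(moltitox:::grad_of(grads, params, "l.W") == 0))
  expect_true(all(moltitox:::grad_of(grads, params, "l.b") == 0))
})

test_that("per-task loss weighting averages tasks before entries", {
  labels <- rbind(c(1, rep(NA, 11)), c(1, 0, rep(NA, 10)))
  lm_flat <- moltitox:::loss_mask(labels, per_task = FALSE)
  lm_task <- moltitox:::loss_mask(labels, per_task = TRUE)
  z <- matrix(0, 2, 12)
  # flat: mean over 3 observed entries of log 2
  expect_equal(sum(lm_flat$weights * (log(2))) / sum(lm_flat$weights), log(2))
  # per-task weights sum to 1
  expect_equal(sum(lm_task$weights), 1, tolerance = 1e-12)
  # task 1 (2 entries) and task 2 (1 entry) carry equal total weight
  expect_equal(sum(lm_task$weights[, 1]), sum(lm_task$weights[, 2]),
               tolerance = 1e-12)
})

make_training_fixture <- function(n = 48L, seed = 3L) {
  fix <- tiny_benchmark(n = n, seed = seed)
  data <- prepare_modalities(fix$ds, c("graph", "spectrum"))
  split <- scaffold_split(fix$ds, seed = 1L)
  list(data = data, split = split, ds = fix$ds)
}

test_that("encoder training logs are reproducible and best-metric bookkeeping is monotone", {
  fx <- make_training_fixture()
  tc <- train_config("encoder", max_epochs = 4L, patience = 3L, seed = 11L)
  r1 <- train_encoder("graph", fx$data, fx$split, tc, small_graph_cfg())
  r2 <- train_encoder("graph", fx$data, fx$split, tc, small_graph_cfg())
  expect_identical(r1$log, r2$log)                     # seed determinism
  expect_true(all(diff(r1$log$best_auc) >= -1e-12))    # monotone bookkeeping
  expect_true(r1$best_epoch <= nrow(r1$log))
  expect_identical(r1$log$valid_auc[r1$best_epoch], max(r1$log$valid_auc))
  # restored weights reproduce the best epoch's validation metric
  idx <- moltitox:::split_indices(fx$split, fx$data$ids)
  emb <- moltitox:::encode_indices(r1$model, fx$data, idx$valid)
  auc <- moltitox:::macro_auc(moltitox:::probe_logits(r1$model, emb),
                              fx$data$labels[idx$valid, , drop = FALSE])$macro
  expect_equal(auc, max(r1$log$valid_auc), tolerance = 1e-9)
})

test_that("spectrum encoder training is restricted to spectrum-present records", {
  fx <- make_training_fixture()
  pres <- fx$data$spectrum$presence
  expect_true(any(pres) && any(!pres))   # mixed availability in the fixture
  tc <- train_config("encoder", max_epochs = 2L, patience = 1L, seed = 12L)
  r <- train_encoder("spectrum", fx$data, fx$split, tc, small_spectrum_cfg())
  expect_s3_class(r$model, "moltitox_encoder")
})

test_that("fusion training freezes encoders, moves the missing token, and supports M=1", {
  fx <- make_training_fixture()
  tc <- train_config("encoder", max_epochs = 2L, patience = 1L, seed = 13L)
  encs <- list(
    graph = train_encoder("graph", fx$data, fx$split, tc, small_graph_cfg())$model,
    spectrum = train_encoder("spectrum", fx$data, fx$split, tc,
                             small_spectrum_cfg())$model
  )
  snap <- lapply(encs, function(e) as.list(e$params, all.names = TRUE))
  ftc <- train_config("fusion", max_epochs = 3L, patience = 2L, seed = 13L)
  run <- train_fusion(encs, fx$data, fx$split, ftc,
                      fusion_config(d_e = 16L, n_heads = 2L,
                                    active_modalities = c("graph", "spectrum")))
  # every encoder parameter bit-identical after fusion training
  for (m in names(encs)) {
    now <- as.list(encs[[m]]$params, all.names = TRUE)
    expect_identical(now, snap[[m]])
  }
  # the missing token left its zero initialization on mixed batches
  expect_gt(sqrt(sum(run$fusion$params[["missing.spectrum"]]^2)), 0)
  # single-modality fusion degenerates to M=1 attention and still trains
  run1 <- train_fusion(encs["graph"], fx$data, fx$split, ftc,
                       fusion_config(d_e = 16L, n_heads = 2L,
                                     active_modalities = "graph"))
  expect_true(is.finite(run1$log$train_loss[1]))
  expect_error(train_fusion(list(), fx$data, fx$split, ftc), "empty")
})

test_that("a sample with all labels missing contributes nothing to loss or gradients", {
  fx <- make_training_fixture()
  enc <- new_encoder(small_spectrum_cfg(), seed = 14L)
  bits <- fx$data$spectrum$bits[1:4, , drop = FALSE]
  labels <- fx$data$labels[1:4, , drop = FALSE]
  labels[2, ] <- NA                       # sample 2 fully missing
  lm <- moltitox:::loss_mask(labels)
  run <- function(b) {
    tp <- moltitox:::ad_tape(enc$params, training = FALSE)
    emb <- moltitox:::forward_spectrum(enc, b, tp)$emb
    logits <- moltitox:::nn_linear(tp, emb, "probe")
    loss <- moltitox:::ad_bce_masked(logits, lm$targets, lm$weights)
    grads <- moltitox:::ad_backward(tp, loss)
    gl <- lapply(sort(ls(grads)), function(n) grads[[n]])
    list(loss = as.numeric(loss$val), grads = gl,
         logit_grad = local({
           # gradient arriving at the logits of the masked sample is zero
           zv <- logits$val
           m <- lm$weights
           (m * (stats::plogis(zv) - lm$targets) / sum(m))[2, ]
         }))
  }
  r1 <- run(bits)
  expect_gt(r1$loss, 0)
  expect_true(all(r1$logit_grad == 0))
  # perturbing the masked sample's input features changes nothing:
  # loss and every parameter gradient are bit-identical (evaluation-mode
  # normalization; batch statistics would couple samples during training)
  bits2 <- bits
  bits2[2, ] <- 1L - bits2[2, ]
  r2 <- run(bits2)
  expect_identical(r1$loss, r2$loss)
  expect_identical(r1$grads, r2$grads)
  # flipping the stored value of a masked entry leaves the loss bit-exact
  t2 <- lm$targets; t2[2, ] <- 1 - t2[2, ]
  tp <- moltitox:::ad_tape(enc$params, training = FALSE)
  emb <- moltitox:::forward_spectrum(enc, bits, tp)$emb
  logits <- moltitox:::nn_linear(tp, emb, "probe")
  l2 <- moltitox:::ad_bce_masked(logits, t2, lm$weights)
  expect_identical(r1$loss, as.numeric(l2$val))
})

test_that("hyperparameter search is seeded, exhaustive in degenerate spaces, and validates budget", {
  space <- list(lr = c(1e-3, 1e-2), hidden = c(8L, 16L, 32L))
  evals <- function(cfg) as.numeric(cfg$hidden) / 32 - as.numeric(cfg$lr)
  r1 <- hyperparameter_search(space, budget = 5L, evals, seed = 1L)
  r2 <- hyperparameter_search(space, budget = 5L, evals, seed = 1L)
  expect_identical(r1$trials, r2$trials)
  expect_identical(nrow(r1$trials), 5L)
  expect_gte(r1$best_metric, max(r1$trials$metric) - 1e-12)
  # budget 1 returns the single sampled configuration
  rb <- hyperparameter_search(space, budget = 1L, evals, seed = 2L)
  expect_identical(nrow(rb$trials), 1L)
  # degenerate one-point space returns that point
  rd <- hyperparameter_search(list(lr = 0.5), budget = 3L,
                              function(cfg) cfg$lr, seed = 3L)
  expect_identical(rd$best_config$lr, 0.5)
  # different seeds may disagree but both are fully logged
  r3 <- hyperparameter_search(space, budget = 4L, evals, seed = 9L)
  expect_identical(nrow(r3$trials), 4L)
  expect_error(hyperparameter_search(space, budget = 0L, evals), "budget")
})
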