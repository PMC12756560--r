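# Two-phase optimization: per-modality encoders with a 12-task linear probe,
# then fusion over frozen encoders. Objective: masked binary cross-entropy
# over observed endpoint labels only.

#' Training configuration
#'
#' @param phase `"encoder"` or `"fusion"`; sets the phase defaults
#'   (encoder: 50 epochs, patience 10; fusion: 30 epochs, patience 5).
#' @param max_epochs,batch_size,patience,lr,weight_decay,seed usual knobs.
#' @param augment_images apply image augmentation during encoder training.
#' @param per_task_loss if `TRUE`, average the loss per task first
#'   (mean-of-means) instead of over all observed entries.
#' @param stop_target optional early exit once the validation metric
#'   reaches this value (used by capacity/overfit checks).
#' @param select_best if `FALSE`, train for the full epoch budget and keep
#'   the final weights instead of restoring the best-validation epoch —
#'   appropriate when the validation subset is too small for its metric to
#'   rank epochs reliably (e.g. the spectrum-present validation records).
#' @param swa_start optional epoch index from which parameters are averaged
#'   (stochastic weight averaging over the training tail); implies training
#'   the full budget and returning the averaged weights. Reduces the
#'   epoch-to-epoch variance that makes noisy validation selection
#'   unreliable on small folds.
#' @return a `train_config`.
#' @export
train_config <- function(phase = c("encoder", "fusion"), max_epochs = NULL,
                         batch_size = 32L, patience = NULL, lr = 1e-3,
                         weight_decay = 0, seed = 0L, augment_images = TRUE,
                         per_task_loss = FALSE, stop_target = NULL,
                         select_best = TRUE, swa_start = NULL) {
  phase <- match.arg(phase)
  max_epochs <- max_epochs %||% if (phase == "encoder") 50L else 30L
  patience <- patience %||% if (phase == "encoder") 10L else 5L
  stopifnot(batch_size >= 1L, patience < max_epochs)
  structure(list(phase = phase, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), lr = lr,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 augment_images = isTRUE(augment_images),
                 per_task_loss = isTRUE(per_task_loss),
                 stop_target = stop_target,
                 select_best = isTRUE(select_best),
                 swa_start = if (!is.null(swa_start)) as.integer(swa_start)),
            class = "train_config")
}

#' Masked multi-task binary cross-entropy
#'
#' Mean of the per-entry binary cross-entropy with logits over observed
#' entries only; 0 when nothing is observed. Values stored in masked slots
#' never influence the loss (or, in training, any gradient).
#'
#' @param logits batch x n_tasks matrix of pre-sigmoid scores.
#' @param targets batch x n_tasks matrix in \{0, 1\} (masked entries may
#'   hold anything, including `NA`).
#' @param observed batch x n_tasks logical/0-1 matrix; `FALSE` = missing.
#' @return scalar loss.
#' @export
masked_multitask_loss <- function(logits, targets, observed) {
  observed <- (observed == 1) & !is.na(targets)
  if (!any(observed)) return(0)
  z <- logits[observed]
  t0 <- targets[observed]
  sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  mean(sp - t0 * z)
}

# targets/mask pair with NA-safe coding; optionally per-task weighting
loss_mask <- function(labels, per_task = FALSE) {
  obs <- !is.na(labels)
  tgt <- labels
  tgt[!obs] <- 0
  if (!per_task) return(list(targets = tgt, weights = 1 * obs, normalize = TRUE))
  w <- matrix(0, nrow(labels), ncol(labels))
  counts <- colSums(obs)
  live <- counts > 0
  for (j in which(live)) w[obs[, j], j] <- 1 / (counts[j] * sum(live))
  list(targets = tgt, weights = w, normalize = FALSE)
}

ad_loss <- function(tp, logits, lm) {
  if (lm$normalize) {
    ad_bce_masked(logits, lm$targets, lm$weights)
  } else {
    zv <- logits$val
    sp <- ifelse(zv > 0, zv + log1p(exp(-zv)), log1p(exp(zv)))
    val <- sum(lm$weights * (sp - lm$targets * zv))
    w <- lm$weights; tgt <- lm$targets
    ad_node(logits$tp, matrix(val, 1L, 1L), logits$id, function(g) {
      list(as.numeric(g) * w * (stats::plogis(zv) - tgt))
    })
  }
}

# ---- modality data preparation ---------------------------------------------

#' Precompute modality representations for a dataset
#'
#' Featurizes every record once: graph features, token sequences, binned
#' spectra (with presence flags) and rendered images (cached as PNG files
#' and loaded per batch to bound memory).
#'
#' @param ds a `moltitox_dataset`.
#' @param modalities which modalities to prepare.
#' @param vocab SMILES vocabulary; built from all records if `NULL` (pass a
#'   training-split vocabulary to avoid leakage when that matters).
#' @param grid spectrum bin grid.
#' @param image_dir cache directory for rendered images; the default is
#'   keyed by the dataset content so different datasets sharing record ids
#'   never collide in the cache.
#' @param image_size depiction size in pixels.
#' @return a `modal_data` list with per-record features, labels and ids.
#' @export
prepare_modalities <- function(ds, modalities = MODALITY_ORDER, vocab = NULL,
                               grid = spectrum_grid(),
                               image_dir = NULL,
                               image_size = 224L) {
  records <- ds$records
  ids <- dataset_ids(ds)
  out <- list(ids = ids, labels = dataset_labels(ds), endpoints = ds$endpoints,
              grid = grid, image_size = as.integer(image_size))
  if ("graph" %in% modalities) {
    out$graph <- lapply(records, function(r) featurize_graph(r$mol))
  }
  if ("smiles" %in% modalities) {
    if (is.null(vocab)) vocab <- build_vocab(vapply(records, `[[`, "", "smiles"))
    out$vocab <- vocab
    out$smiles <- lapply(records, function(r) tokenize_smiles(r$smiles, vocab))
  }
  if ("spectrum" %in% modalities) {
    presence <- vapply(records, function(r) !is.null(r$peaks) &&
                         length(r$peaks) > 0L, TRUE)
    bits <- matrix(0L, length(records), grid$n_bins)
    for (i in which(presence)) bits[i, ] <- bin_spectrum(records[[i]]$peaks, grid)
    out$spectrum <- list(bits = bits, presence = presence)
  }
  if ("image" %in% modalities) {
    if (is.null(image_dir)) {
      key <- hash_string(paste(ids, vapply(records, `[[`, "", "smiles"),
                               collapse = "|"))
      image_dir <- file.path(tempdir(), sprintf("moltitox_img_%d", key))
    }
    dir.create(image_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(length(records))
    for (i in seq_along(records)) {
      r <- records[[i]]
      if (!is.null(r$image_path)) {
        paths[i] <- r$image_path
      } else {
        render_image(r$mol, size = image_size, cache_dir = image_dir,
                     cache_key = r$id)
        paths[i] <- file.path(image_dir, paste0(r$id, ".png"))
      }
    }
    out$image <- list(paths = paths,
                      pool_cache = new.env(parent = emptyenv()))
  }
  class(out) <- "modal_data"
  out
}

# assemble the encoder batch input for record indices `idx`
modality_batch <- function(data, modality, idx, augment = FALSE,
                           image_pool = 1L) {
  switch(modality,
    graph = batch_graphs(data$graph[idx]),
    smiles = list(ids = do.call(rbind, lapply(data$smiles[idx], `[[`, "ids")),
                  mask = do.call(rbind, lapply(data$smiles[idx], `[[`, "mask"))),
    spectrum = list(bits = data$spectrum$bits[idx, , drop = FALSE]),
    image = {
      if (!augment && image_pool > 1L) {
        # augmentation off: the fixed stem pooling of each raster is
        # deterministic, so pooled columns are computed once and cached
        cache <- data$image$pool_cache
        xmat <- do.call(rbind, lapply(idx, function(i) {
          key <- paste0(i, "_", image_pool)
          if (is.null(cache[[key]])) {
            cols <- raster_to_columns(png::readPNG(data$image$paths[i])[, , 1:3])
            cache[[key]] <- pool_columns(cols, data$image_size, image_pool)
          }
          cache[[key]]
        }))
        attr(xmat, "prepooled") <- image_pool
      } else {
        xmat <- do.call(rbind, lapply(data$image$paths[idx], function(p) {
          raster_to_columns(png::readPNG(p)[, , 1:3], augment = augment)
        }))
      }
      list(xmat = xmat, B = length(idx))
    }
  )
}

# embeddings for `idx` in evaluation mode, batched
encode_indices <- function(model, data, idx, batch_size = 64L) {
  if (length(idx) == 0L) return(matrix(0, 0L, model$cfg$output_dim))
  pool <- if (model$modality == "image") model$cfg$stem_pool %||% 1L else 1L
  out <- NULL
  for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
    tp <- ad_tape(model$params, training = FALSE)
    b <- modality_batch(data, model$modality, chunk, augment = FALSE,
                        image_pool = pool)
    out <- rbind(out, forward_encoder(model, b, tp)$val)
  }
  out
}

probe_logits <- function(model, emb) {
  sweep(emb %*% model$params[["probe.W"]], 2L,
        as.numeric(model$params[["probe.b"]]), `+`)
}

# ---- encoder phase ---------------------------------------------------------

#' Train a modality encoder with its 12-task linear probe
#'
#' Optimizes the encoder and a linear probe head jointly on the training
#' partition under the masked multi-task loss, early-stopping on validation
#' macro ROC-AUC (endpoints with a single observed class are skipped, with
#' a log entry); the best-epoch weights are restored. The spectrum encoder
#' is automatically restricted to spectrum-present records.
#'
#' @param modality one of the four modality names.
#' @param data a `modal_data` from [prepare_modalities()].
#' @param split a `scaffold_split` (or list with `train`/`valid` id vectors).
#' @param cfg a [train_config()] (phase `"encoder"`).
#' @param enc_cfg an [encoder_config()]; defaults per modality.
#' @return list with the trained `model`, the per-epoch `log` data frame
#'   (train_loss, valid_auc, best_auc) and `best_epoch`.
#' @export
train_encoder <- function(modality, data, split, cfg = train_config("encoder"),
                          enc_cfg = NULL) {
  enc_cfg <- enc_cfg %||% encoder_config(modality)
  idx <- split_indices(split, data$ids)
  tr <- idx$train; va <- idx$valid
  if (modality == "spectrum") {
    tr <- tr[data$spectrum$presence[tr]]
    va <- va[data$spectrum$presence[va]]
    if (length(tr) == 0L) stopf("no spectrum-present training records")
  }
  model <- new_encoder(enc_cfg, seed = cfg$seed, vocab = data$vocab)
  run_training_loop(
    cfg = cfg,
    params = model$params, state = model$state,
    forward_loss = function(batch_idx, tp) {
      aug <- cfg$augment_images && modality == "image"
      b <- modality_batch(data, modality, batch_idx, augment = aug,
                          image_pool = if (modality == "image" && !aug)
                            enc_cfg$stem_pool %||% 1L else 1L)
      emb <- forward_encoder(model, b, tp)
      logits <- nn_linear(tp, emb, "probe")
      lm <- loss_mask(data$labels[batch_idx, , drop = FALSE], cfg$per_task_loss)
      ad_loss(tp, logits, lm)
    },
    valid_metric = function() {
      emb <- encode_indices(model, data, va)
      macro_auc(probe_logits(model, emb),
                data$labels[va, , drop = FALSE])$macro
    },
    train_idx = tr
  ) -> res
  list(model = model, log = res$log, best_epoch = res$best_epoch)
}

# shared seeded loop with early stopping and best-weight restoration
run_training_loop <- function(cfg, params, state, forward_loss, valid_metric,
                              train_idx) {
  opt <- opt_adam(lr = cfg$lr, weight_decay = cfg$weight_decay,
                  wd_exclude = cfg$wd_exclude)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    valid_auc = numeric(0), best_auc = numeric(0))
  best <- -Inf; best_epoch <- 0L; wait <- 0L
  best_params <- copy_env(params); best_state <- copy_env(state)
  swa_sum <- NULL; swa_n <- 0L
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      total <- 0
      for (bidx in batches) {
        tp <- ad_tape(params, training = TRUE)
        loss <- forward_loss(bidx, tp)
        grads <- ad_backward(tp, loss)
        opt_step(opt, params, grads)
        total <- total + as.numeric(loss$val) * length(bidx)
      }
      vm <- valid_metric()
      if (!is.null(cfg$swa_start) && epoch >= cfg$swa_start) {
        if (is.null(swa_sum)) {
          swa_sum <- as.list(copy_env(params), all.names = TRUE)
          swa_n <- 1L
        } else {
          for (nm in names(swa_sum)) swa_sum[[nm]] <- swa_sum[[nm]] + params[[nm]]
          swa_n <- swa_n + 1L
        }
      }
      if (!is.null(cfg$swa_start)) {
        best_epoch <- epoch
        if (!is.na(vm) && vm > best) best <- vm
        log[nrow(log) + 1L, ] <- list(epoch, total / length(train_idx), vm,
                                      max(best, vm, na.rm = TRUE))
        next
      }
      if (!isTRUE(cfg$select_best)) {
        # fixed-budget training: keep the latest weights, no epoch selection
        best_epoch <- epoch
        if (!is.na(vm) && vm > best) best <- vm
        best_params <- copy_env(params); best_state <- copy_env(state)
      } else if (is.na(vm)) {
        # no usable validation signal: keep training and keep the latest
        # weights (logged; typical of very small spectrum-present subsets)
        mt_log(sprintf("epoch %d: validation metric undefined", epoch))
        best_epoch <- epoch
        best_params <- copy_env(params); best_state <- copy_env(state)
      } else if (vm > best) {               # ties keep the earlier epoch
        best <- vm; best_epoch <- epoch; wait <- 0L
        best_params <- copy_env(params); best_state <- copy_env(state)
      } else {
        wait <- wait + 1L
      }
      log[nrow(log) + 1L, ] <- list(epoch, total / length(train_idx), vm,
                                    max(best, vm, na.rm = TRUE))
      if (!is.null(cfg$stop_target) && !is.na(vm) && vm >= cfg$stop_target) break
      if (wait >= cfg$patience) break
    }
  })
  if (!is.null(cfg$swa_start)) {
    if (!is.null(swa_sum)) {
      for (nm in names(swa_sum)) params[[nm]] <- swa_sum[[nm]] / swa_n
    }
    # else: the budget never reached swa_start; keep the final weights
  } else {
    restore_env(params, best_params)
    restore_env(state, best_state)
  }
  list(log = log, best_epoch = best_epoch, best_metric = best)
}

# ---- fusion phase ----------------------------------------------------------

#' Cache frozen-encoder embeddings for fusion training
#'
#' Encodes every record with each trained encoder in evaluation mode (no
#' augmentation). Spectrum-absent records get a zero placeholder row; the
#' fusion forward substitutes the learnable missing token for them.
#'
#' @param encoders named list of trained encoders (from [train_encoder()],
#'   `$model`), one per active modality.
#' @param data a `modal_data`.
#' @param idx record indices (default: all).
#' @return list with `embs` (named list of matrices) and `presence`.
#' @export
cache_embeddings <- function(encoders, data, idx = seq_along(data$ids)) {
  embs <- list(); presence <- list()
  for (m in names(encoders)) {
    model <- encoders[[m]]
    if (m == "spectrum") {
      pres <- data$spectrum$presence[idx]
      E <- matrix(0, length(idx), model$cfg$output_dim)
      if (any(pres)) E[pres, ] <- encode_indices(model, data, idx[pres])
      embs[[m]] <- E
      presence[[m]] <- pres
    } else {
      embs[[m]] <- encode_indices(model, data, idx)
      presence[[m]] <- rep(TRUE, length(idx))
    }
  }
  list(embs = embs, presence = presence, idx = idx)
}

#' Train the fusion network over frozen encoders
#'
#' Only the fusion parameters and the missing-modality token receive
#' gradients; encoder weights never enter the computation graph (their
#' embeddings are precomputed constants), so they are bit-identical after
#' training. Supports any non-empty modality subset for ablations.
#'
#' @param encoders named list of trained encoders for the active modalities.
#' @param data a `modal_data`.
#' @param split a `scaffold_split`.
#' @param cfg a [train_config()] (phase `"fusion"`).
#' @param fus_cfg a [fusion_config()]; its `active` set defaults to the
#'   names of `encoders`.
#' @param cache optional precomputed [cache_embeddings()] result.
#' @return list with `fusion`, `encoders`, `log`, `best_epoch`, `cache`.
#' @export
train_fusion <- function(encoders, data, split, cfg = train_config("fusion"),
                         fus_cfg = NULL, cache = NULL) {
  if (length(encoders) == 0L) stopf("train_fusion: empty encoder set")
  mods <- MODALITY_ORDER[MODALITY_ORDER %in% names(encoders)]
  fus_cfg <- fus_cfg %||% fusion_config(active_modalities = mods)
  stopifnot(setequal(fus_cfg$active, mods))
  dims <- lapply(encoders, function(e) e$cfg$output_dim)
  fusion <- new_fusion(fus_cfg, dims, seed = cfg$seed)
  cache <- cache %||% cache_embeddings(encoders, data)
  idx <- split_indices(split, data$ids)
  sub_embs <- function(rows) lapply(cache$embs, function(E) E[rows, , drop = FALSE])
  sub_pres <- function(rows) lapply(cache$presence, function(p) p[rows])
  dummy_state <- new.env(parent = emptyenv())
  res <- run_training_loop(
    cfg = cfg,
    params = fusion$params, state = dummy_state,
    forward_loss = function(batch_idx, tp) {
      fwd <- forward_fusion(fusion, sub_embs(batch_idx), sub_pres(batch_idx), tp)
      lm <- loss_mask(data$labels[batch_idx, , drop = FALSE], cfg$per_task_loss)
      ad_loss(tp, fwd$logits, lm)
    },
    valid_metric = function() {
      ev <- evaluate_fusion(fusion, cache, data, idx$valid)
      ev$macro
    },
    train_idx = idx$train
  )
  list(fusion = fusion, encoders = encoders, log = res$log,
       best_epoch = res$best_epoch, cache = cache)
}

#' Evaluate a fusion model on a record subset
#'
#' @param fusion a trained `moltitox_fusion`.
#' @param cache a [cache_embeddings()] result covering the records.
#' @param data the `modal_data`.
#' @param rows record indices to evaluate.
#' @param collect_attention also return per-sample attention maps.
#' @return list: `scores` (probabilities), `logits`, `per_task` AUCs,
#'   `macro`, and optionally `attention`.
#' @export
evaluate_fusion <- function(fusion, cache, data, rows,
                            collect_attention = FALSE) {
  tp <- ad_tape(fusion$params, training = FALSE)
  embs <- lapply(cache$embs, function(E) E[rows, , drop = FALSE])
  pres <- lapply(cache$presence, function(p) p[rows])
  fwd <- forward_fusion(fusion, embs, pres, tp,
                        collect_attention = collect_attention)
  logits <- fwd$logits$val
  ma <- macro_auc(logits, data$labels[rows, , drop = FALSE])
  out <- list(scores = stats::plogis(logits), logits = logits,
              per_task = ma$per_task, macro = ma$macro)
  if (collect_attention) out$attention <- fwd$attention
  out
}

# ---- hyperparameter search -------------------------------------------------

#' Seeded random hyperparameter search
#'
#' Samples `budget` configurations uniformly from a discrete space (a named
#' list of candidate value vectors), evaluates each with `eval_fn`
#' (returning a validation metric to maximize, conventionally macro
#' ROC-AUC) and returns the best. Deterministic given the seed.
#'
#' @param space named list; each element a vector/list of candidate values.
#' @param budget number of configurations to try (>= 1).
#' @param eval_fn function(config list) -> numeric metric.
#' @param seed RNG seed.
#' @return list with `best_config`, `best_metric` and a `trials` data frame.
#' @export
hyperparameter_search <- function(space, budget, eval_fn, seed = 0L) {
  stopifnot(length(space) >= 1L)
  if (budget < 1L) stopf("hyperparameter_search: budget must be >= 1")
  configs <- with_seed(seed, {
    lapply(seq_len(budget), function(i) {
      lapply(space, function(vals) {
        vals[[sample.int(length(vals), 1L)]]
      })
    })
  })
  metrics <- vapply(configs, eval_fn, 0)
  best <- which.max(metrics)
  trials <- data.frame(trial = seq_len(budget), metric = metrics)
  trials$config <- vapply(configs, function(cc) {
    paste(names(cc), vapply(cc, function(v) paste(v, collapse = "/"), ""),
          sep = "=", collapse = ";")
  }, "")
  list(best_config = configs[[best]], best_metric = metrics[best],
       trials = trials)
}
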