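# Modality-ablation benchmark: train/evaluate every (seed, modality-subset)
# cell, aggregate mean +/- sd across scaffold splits, and compare each model
# against the full four-modality reference with paired t-tests.

modality_subsets <- function(which = c("full", "singles", "quad")) {
  which <- match.arg(which)
  singles <- as.list(MODALITY_ORDER)
  if (which == "singles") return(singles)
  if (which == "quad") return(list(MODALITY_ORDER))
  pairs <- utils::combn(MODALITY_ORDER, 2L, simplify = FALSE)
  triple <- list(c("graph", "smiles", "image"))
  c(singles, pairs, triple, list(MODALITY_ORDER))
}

subset_label <- function(mods) paste(mods, collapse = "+")

#' Format a mean and standard deviation as `0.831±0.023`
#'
#' @param m,s mean and sd.
#' @param digits decimal places.
#' @export
format_mean_sd <- function(m, s, digits = 3L) {
  sprintf(paste0("%.", digits, "f±%.", digits, "f"), m, s)
}

#' Training/model profile for benchmark runs
#'
#' Bundles encoder configurations and phase training configurations. The
#' `"small"` profile uses compact encoders (documented in the methods
#' vignette) suited to synthetic benchmarks of a few hundred molecules on a
#' single CPU; `"default"` uses the package default encoder sizes and the
#' standard 50/30-epoch schedules.
#'
#' @param scale `"small"` or `"default"`.
#' @param seed base seed (per-seed runs derive from the split seed).
#' @return list with `enc_cfgs`, `enc_train`, `fus_train`, `d_e`, `n_heads`.
#' @export
benchmark_profile <- function(scale = c("small", "default"), seed = 0L) {
  scale <- match.arg(scale)
  if (scale == "default") {
    list(
      enc_cfgs = stats::setNames(lapply(MODALITY_ORDER, encoder_config),
                                 MODALITY_ORDER),
      enc_train = train_config("encoder", seed = seed),
      fus_train = train_config("fusion", seed = seed),
      d_e = 256L, n_heads = 4L
    )
  } else {
    list(
      enc_cfgs = list(
        graph = encoder_config("graph", n_layers = 3L, hidden_dim = 64L,
                               output_dim = 64L),
        smiles = encoder_config("smiles", n_layers = 2L, n_heads = 4L,
                                hidden_dim = 64L, output_dim = 64L),
        image = encoder_config("image", stem_pool = 8L, stem_kernel = 3L,
                               stem_stride = 2L,
                               widths = c(16L, 32L, 32L, 64L),
                               output_dim = 64L),
        spectrum = encoder_config("spectrum", conv_widths = c(8L, 16L),
                                  backbone_dim = 64L, output_dim = 32L,
                                  dropout = 0.3)
      ),
      # small validation folds rank epochs too noisily for best-epoch
      # selection at this scale; every phase trains a fixed regularized
      # budget and averages the parameter tail (SWA) instead
      enc_train = train_config("encoder", max_epochs = 25L, patience = 6L,
                               weight_decay = 1e-4, seed = seed,
                               augment_images = FALSE),
      enc_epochs = c(graph = 20L, smiles = 15L, image = 8L, spectrum = 15L),
      enc_overrides = list(graph = list(swa_start = 8L),
                           smiles = list(swa_start = 6L),
                           image = list(swa_start = 4L),
                           spectrum = list(swa_start = 6L)),
      fus_train = train_config("fusion", max_epochs = 60L, patience = 59L,
                               weight_decay = 1e-3, seed = seed,
                               swa_start = 20L),
      fus_dropout = 0.3,
      d_e = 64L, n_heads = 4L
    )
  }
}

#' Run the modality-ablation benchmark matrix
#'
#' For every seed: scaffold-split the dataset, train each required modality
#' encoder on the training partition (the spectrum encoder on its
#' spectrum-present subset), cache frozen-encoder embeddings, then train one
#' fusion model per multi-modality subset and evaluate on the test
#' partition. Singleton subsets are reported as the encoder + probe
#' baseline evaluated directly on test (the spectrum baseline on
#' spectrum-present test records only); single-modality *fusion* models can
#' still be trained explicitly with [train_fusion()].
#' Reports per-endpoint and macro ROC-AUC per cell, cross-seed mean and sd,
#' threshold metrics, paired t-tests of every subset against the full
#' four-modality model, and split-level attention summaries for the full
#' model.
#'
#' @param ds a `moltitox_dataset`.
#' @param seeds integer vector of split seeds (>= 1).
#' @param subsets `"full"` (4 singles + 6 pairs + the graph/smiles/image
#'   triple + the quad), `"singles"`, `"quad"`, or a list of modality
#'   character vectors.
#' @param profile a [benchmark_profile()].
#' @param image_epochs optional cap on image-encoder epochs (the image
#'   branch dominates compute).
#' @param data optional precomputed [prepare_modalities()] result.
#' @return a `moltitox_report`.
#' @export
benchmark_matrix <- function(ds, seeds = 0:4, subsets = "full",
                             profile = benchmark_profile("small"),
                             image_epochs = NULL, data = NULL) {
  stopifnot(length(seeds) >= 1L)
  if (is.character(subsets)) subsets <- modality_subsets(subsets)
  stopifnot(length(subsets) >= 1L)
  needed <- unique(unlist(subsets))
  data <- data %||% prepare_modalities(ds, needed)
  ref_label <- subset_label(MODALITY_ORDER[MODALITY_ORDER %in% needed])

  per_run <- NULL; thr_rows <- NULL; attn_summaries <- list()
  splits <- list()
  scafs <- vapply(ds$records, function(r) bemis_murcko_scaffold(r$mol), "")
  for (seed in seeds) {
    split <- scaffold_split(ds, seed = seed, scaffolds = scafs)
    splits[[as.character(seed)]] <- split
    encoders <- list()
    for (m in needed) {
      etc <- profile$enc_train
      etc$seed <- as.integer(seed)
      cap <- if (m == "image" && !is.null(image_epochs)) {
        as.integer(image_epochs)
      } else if (!is.null(profile$enc_epochs) && m %in% names(profile$enc_epochs)) {
        as.integer(profile$enc_epochs[[m]])
      } else NULL
      if (!is.null(cap)) {
        etc$max_epochs <- cap
        etc$patience <- min(etc$patience, cap - 1L)
      }
      ov <- profile$enc_overrides[[m]]
      if (!is.null(ov)) etc[names(ov)] <- ov
      encoders[[m]] <- train_encoder(m, data, split, etc,
                                     profile$enc_cfgs[[m]])$model
    }
    cache <- cache_embeddings(encoders, data)
    idx <- split_indices(split, data$ids)
    for (mods in subsets) {
      mods <- MODALITY_ORDER[MODALITY_ORDER %in% mods]
      label <- subset_label(mods)
      if (length(mods) == 1L) {
        # single-modality baseline: the trained encoder with its own probe
        # head, evaluated directly (the spectrum encoder only on records
        # that have a spectrum — it has no missing-modality path of its own)
        m <- mods
        rows <- idx$test
        if (m == "spectrum") {
          rows <- rows[data$spectrum$presence[rows]]
          mt_log("spectrum baseline evaluated on spectrum-present test records")
        }
        logits <- probe_logits(encoders[[m]],
                               cache$embs[[m]][rows, , drop = FALSE])
        ma <- macro_auc(logits, data$labels[rows, , drop = FALSE])
        ev <- list(scores = stats::plogis(logits), per_task = ma$per_task,
                   macro = ma$macro, attention = NULL)
      } else {
        ftc <- profile$fus_train
        ftc$seed <- as.integer(seed)
        fcfg <- fusion_config(d_e = profile$d_e, n_heads = profile$n_heads,
                              dropout = profile$fus_dropout %||% 0.1,
                              active_modalities = mods)
        sub_cache <- list(embs = cache$embs[mods],
                          presence = cache$presence[mods], idx = cache$idx)
        run <- train_fusion(encoders[mods], data, split, ftc, fcfg,
                            cache = sub_cache)
        ev <- evaluate_fusion(run$fusion, sub_cache, data, idx$test,
                              collect_attention = identical(label, ref_label))
        rows <- idx$test
      }
      per_run <- rbind(per_run, data.frame(
        seed = seed, model = label,
        endpoint = c(data$endpoints, ".macro"),
        auc = c(ev$per_task, ev$macro)))
      tm <- lapply(seq_len(ncol(data$labels)), function(j) {
        threshold_metrics(ev$scores[, j], data$labels[rows, j])
      })
      thr_rows <- rbind(thr_rows, data.frame(
        seed = seed, model = label,
        accuracy = mean(vapply(tm, `[[`, 0, "accuracy"), na.rm = TRUE),
        balanced_accuracy = mean(vapply(tm, `[[`, 0, "balanced_accuracy"),
                                 na.rm = TRUE),
        kappa = mean(vapply(tm, `[[`, 0, "kappa"), na.rm = TRUE),
        mcc = mean(vapply(tm, `[[`, 0, "mcc"), na.rm = TRUE),
        sensitivity = mean(vapply(tm, `[[`, 0, "sensitivity"), na.rm = TRUE),
        specificity = mean(vapply(tm, `[[`, 0, "specificity"), na.rm = TRUE)))
      if (identical(label, ref_label) && !is.null(ev$attention)) {
        summ <- extract_attention_summary(ev$attention, mods)
        summ$table$split_seed <- seed
        attn_summaries[[as.character(seed)]] <- summ
      }
    }
  }

  macro <- per_run[per_run$endpoint == ".macro", ]
  models <- unique(macro$model)
  summary <- do.call(rbind, lapply(models, function(mm) {
    v <- macro$auc[macro$model == mm][order(macro$seed[macro$model == mm])]
    ref <- macro$auc[macro$model == ref_label][order(macro$seed[macro$model == ref_label])]
    p <- if (mm == ref_label || length(v) < 2L) NA_real_ else {
      suppressWarnings(paired_t_test(v, ref)$p_value)
    }
    data.frame(model = mm, mean_macro = mean(v), sd_macro = stats::sd(v),
               display = format_mean_sd(mean(v),
                                        ifelse(is.na(stats::sd(v)), 0,
                                               stats::sd(v))),
               p_value = p)
  }))
  structure(list(per_run = per_run, summary = summary,
                 threshold = thr_rows, attention = attn_summaries,
                 splits = splits, reference = ref_label, seeds = seeds),
            class = "moltitox_report")
}

#' @export
print.moltitox_report <- function(x, ...) {
  cat("<moltitox_report> test macro ROC-AUC over seeds",
      paste(x$seeds, collapse = ","), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-32s %s%s\n", s$model[i], s$display[i],
                ifelse(is.na(s$p_value[i]), " (reference)",
                       sprintf(" (p=%.3f)", s$p_value[i]))))
  }
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' Emits `metrics.json`, per-endpoint and summary CSVs, attention-summary
#' CSV (query_modality, key_modality, mean_weight, split_seed) and one
#' `splits/seed<k>.csv` (id, scaffold, partition) per seed.
#'
#' @param report a `moltitox_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_run, file.path(dir, "per_endpoint_auc.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$threshold, file.path(dir, "threshold_metrics.csv"),
                   row.names = FALSE)
  if (length(report$attention) > 0L) {
    at <- do.call(rbind, lapply(report$attention, `[[`, "table"))
    utils::write.csv(at, file.path(dir, "attention_summary.csv"),
                     row.names = FALSE)
  }
  sdir <- file.path(dir, "splits")
  dir.create(sdir, showWarnings = FALSE)
  for (k in names(report$splits)) {
    sp <- report$splits[[k]]
    utils::write.csv(data.frame(id = names(sp$partition_of),
                                scaffold = unname(sp$scaffold_of),
                                partition = unname(sp$partition_of)),
                     file.path(sdir, sprintf("seed%s.csv", k)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(reference = report$reference, seeds = report$seeds,
         summary = report$summary,
         per_run = report$per_run,
         threshold = report$threshold),
    file.path(dir, "metrics.json"),
    dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
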