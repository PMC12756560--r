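# Scaffold-based partitioning and evaluation metrics.

#' Scaffold split of a dataset
#'
#' Groups molecules by Bemis-Murcko scaffold (acyclic molecules share the
#' empty-scaffold group by default), shuffles the groups with the given seed
#' and assigns whole groups greedily: train fills until it first reaches 80%
#' of molecules, then validation until 10%, the remainder is test. Whole
#' groups only, so no scaffold ever spans two partitions.
#'
#' @param ds a `moltitox_dataset` (or a list of records).
#' @param seed split seed.
#' @param ratios length-3 numeric, normalized internally (default 8:1:1).
#' @param pool_acyclic if `FALSE`, each acyclic molecule forms its own
#'   group rather than sharing one.
#' @param size_sorted if `TRUE`, use the deterministic largest-first group
#'   order instead of a seeded shuffle.
#' @param scaffolds optional precomputed scaffold strings (one per record,
#'   in order) to avoid recomputation across seeds.
#' @return a `scaffold_split` with `seed`, `scaffold_of` (named by id),
#'   `partition_of` (named by id) and id vectors `train`, `valid`, `test`.
#' @export
scaffold_split <- function(ds, seed = 0L, ratios = c(8, 1, 1),
                           pool_acyclic = TRUE, size_sorted = FALSE,
                           scaffolds = NULL) {
  records <- if (inherits(ds, "moltitox_dataset")) ds$records else ds
  ids <- vapply(records, `[[`, "", "id")
  scaf <- scaffolds %||%
    vapply(records, function(r) bemis_murcko_scaffold(r$mol), "")
  stopifnot(length(scaf) == length(records))
  key <- scaf
  if (!pool_acyclic) {
    acy <- !nzchar(scaf)
    key[acy] <- paste0(".acyclic.", ids[acy])
  }
  # locale-independent group order (factor levels via radix sort)
  groups <- split(seq_along(records),
                  factor(key, levels = sort(unique(key), method = "radix")))
  if (length(groups) < 3L) {
    stopf("scaffold_split: only %d distinct scaffold group(s); need >= 3",
          length(groups))
  }
  ord <- if (size_sorted) {
    order(-lengths(groups), xtfrm(names(groups)), method = "radix")
  } else {
    with_seed(seed, sample(length(groups)))
  }
  # a group larger than a whole validation/test fold can only sit in train;
  # assigning such groups first keeps the greedy fill from overshooting the
  # 80% boundary by a giant group and collapsing the small partitions
  n_total <- length(records)
  ratios_n <- ratios / sum(ratios)
  fold_cap <- ceiling(min(ratios_n[2], ratios_n[3]) * n_total)
  sizes <- lengths(groups)[ord]
  ord <- c(ord[sizes > fold_cap], ord[sizes <= fold_cap])
  groups <- groups[ord]
  n <- length(records)
  ratios <- ratios / sum(ratios)
  part <- character(n)
  filled <- 0L
  gi <- 1L
  for (target in list(c("train", ratios[1]), c("valid", ratios[1] + ratios[2]))) {
    while (gi <= length(groups) && filled < ceiling(as.numeric(target[2]) * n)) {
      part[groups[[gi]]] <- target[1]
      filled <- filled + length(groups[[gi]])
      gi <- gi + 1L
    }
  }
  while (gi <= length(groups)) {
    part[groups[[gi]]] <- "test"
    gi <- gi + 1L
  }
  # guarantee non-empty partitions by stealing singleton-most groups
  for (p in c("valid", "test")) {
    if (!any(part == p)) {
      from <- if (sum(part == "train") > 1L) "train" else "valid"
      cand <- split(which(part == from), key[part == from])
      smallest <- cand[[which.min(lengths(cand))]]
      part[smallest] <- p
    }
  }
  structure(list(
    seed = as.integer(seed),
    scaffold_of = stats::setNames(scaf, ids),
    partition_of = stats::setNames(part, ids),
    train = ids[part == "train"], valid = ids[part == "valid"],
    test = ids[part == "test"]
  ), class = "scaffold_split")
}

#' @export
print.scaffold_split <- function(x, ...) {
  cat(sprintf("<scaffold_split> seed %d: %d train / %d valid / %d test (%d scaffolds)\n",
              x$seed, length(x$train), length(x$valid), length(x$test),
              length(unique(x$scaffold_of))))
  invisible(x)
}

split_indices <- function(split, ids) {
  list(train = which(ids %in% split$train),
       valid = which(ids %in% split$valid),
       test = which(ids %in% split$test))
}

#' Area under the ROC curve
#'
#' Rank-based computation equal to P(score_pos > score_neg) + 0.5 P(tie)
#' over all positive/negative pairs. Returns `NA` when only one class is
#' present (degenerate endpoints are excluded from macro averages, with a
#' log entry).
#'
#' @param scores numeric predictions (any monotone scale).
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\], or `NA` if undefined.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(labels) & !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

macro_auc <- function(score_mat, label_mat) {
  aucs <- vapply(seq_len(ncol(label_mat)), function(j) {
    roc_auc(score_mat[, j], label_mat[, j])
  }, 0)
  und <- sum(is.na(aucs))
  if (und > 0L) mt_log(sprintf("%d endpoint(s) with one class: excluded from macro AUC", und))
  if (all(is.na(aucs))) return(list(per_task = aucs, macro = NA_real_))
  list(per_task = aucs, macro = mean(aucs, na.rm = TRUE))
}

#' Threshold classification metrics
#'
#' Confusion-matrix metrics at `sigmoid(score) >= threshold` (scores are
#' probabilities if already in \[0, 1\]; pass `is_logit = TRUE` for logits).
#'
#' @param scores predictions.
#' @param labels 0/1 labels.
#' @param threshold decision threshold on the probability scale.
#' @param is_logit if `TRUE`, apply the sigmoid first.
#' @return named list: accuracy, balanced_accuracy, kappa, mcc,
#'   sensitivity, specificity.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5,
                              is_logit = FALSE) {
  keep <- !is.na(labels) & !is.na(scores)
  if (!any(keep)) {
    return(list(accuracy = NA_real_, balanced_accuracy = NA_real_,
                kappa = NA_real_, mcc = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_))
  }
  scores <- scores[keep]; labels <- labels[keep]
  p <- if (is_logit) stats::plogis(scores) else scores
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  n <- tp + fp + tn + fn
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bacc <- mean(c(sens, spec))
  p_yes <- ((tp + fp) / n) * ((tp + fn) / n)
  p_no <- ((tn + fn) / n) * ((tn + fp) / n)
  pe <- p_yes + p_no
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  list(accuracy = acc, balanced_accuracy = bacc, kappa = kappa, mcc = mcc,
       sensitivity = sens, specificity = spec)
}

#' Paired two-tailed t-test across split seeds
#'
#' Classical paired t with df = n - 1. Degenerate cases follow fixed
#' conventions: identical vectors give p = 1 (logged); a nonzero constant
#' difference (zero variance) gives p = 0 with a warning.
#'
#' @param metric_a,metric_b equal-length numeric vectors (>= 2 values).
#' @return list with `p_value`, `t`, `df`, `mean_diff`.
#' @export
paired_t_test <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2L,
            all(is.finite(metric_a)), all(is.finite(metric_b)))
  d <- metric_a - metric_b
  n <- length(d)
  if (all(d == 0)) {
    mt_log("paired_t_test: identical vectors; p = 1 by convention")
    return(list(p_value = 1, t = 0, df = n - 1L, mean_diff = 0))
  }
  if (stats::sd(d) == 0) {
    warning("paired_t_test: zero-variance nonzero difference; p -> 0",
            call. = FALSE)
    return(list(p_value = 0, t = sign(mean(d)) * Inf, df = n - 1L,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(p_value = unname(tt$p.value), t = unname(tt$statistic),
       df = unname(tt$parameter), mean_diff = mean(d))
}

#' Circular (Morgan-style) fingerprint export hook
#'
#' 2048-bit hashed circular fingerprints with radius 2: atom environments
#' are iteratively hashed from (symbol, degree, H count, charge,
#' aromaticity) seeds over bond-type-labeled neighborhoods, and every
#' environment up to the radius sets one bit. Provided as an export hook
#' for downstream chemical-space visualization.
#'
#' @param mols list of `moltitox_mol` handles.
#' @param nbits fingerprint width (default 2048).
#' @param radius neighborhood radius (default 2).
#' @return 0/1 integer matrix with one row per molecule.
#' @export
export_fingerprints <- function(mols, nbits = 2048L, radius = 2L) {
  hash_str <- function(s) {
    # polynomial rolling hash, exact in double precision
    h <- 7
    for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
    h
  }
  t(vapply(mols, function(m) {
    inv <- vapply(seq_len(m$n_atoms), function(i) {
      hash_str(paste(m$symbol[i], m$degree[i], m$n_h[i], m$charge[i],
                     as.integer(m$aromatic[i]), sep = ":"))
    }, 0)
    bits <- integer(nbits)
    bits[(inv %% nbits) + 1L] <- 1L
    if (nrow(m$bonds) > 0L) {
      nbr <- vector("list", m$n_atoms)
      for (j in seq_len(nrow(m$bonds))) {
        bt <- if (m$bond_aromatic[j]) 4L else m$bonds$order[j]
        a <- m$bonds$a1[j]; b <- m$bonds$a2[j]
        nbr[[a]] <- rbind(nbr[[a]], c(b, bt))
        nbr[[b]] <- rbind(nbr[[b]], c(a, bt))
      }
      for (r in seq_len(radius)) {
        inv <- vapply(seq_len(m$n_atoms), function(i) {
          if (is.null(nbr[[i]])) return(inv[i])
          env <- sort(paste0(nbr[[i]][, 2], "|", inv[nbr[[i]][, 1]]),
                      method = "radix")
          hash_str(paste(inv[i], paste(env, collapse = ","), sep = ";"))
        }, 0)
        bits[(inv %% nbits) + 1L] <- 1L
      }
    }
    bits
  }, integer(nbits)))
}
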