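# Attention-based modality fusion with a learnable missing-modality token.
#
# The four modality embeddings are linearly projected (with bias, ReLU) to
# a common dimension, stacked in the fixed order (graph, smiles, image,
# spectrum), unit-normalized, passed through one shared multi-head
# self-attention module Z = MultiHead(X, X, X), mean-pooled over tokens, and
# fed to the endpoint head. For a sample without a spectrum the learnable missing token replaces
# the *pre-projection* spectrum embedding, so the projection matrix W_sp is
# shared between the real and the missing path.

MODALITY_ORDER <- c("graph", "smiles", "image", "spectrum")

#' Fusion network configuration
#'
#' @param d_e common embedding dimension (must be divisible by `n_heads`).
#' @param n_heads number of attention heads.
#' @param dropout dropout rate in the prediction head.
#' @param active_modalities subset of
#'   `c("graph", "smiles", "image", "spectrum")`, kept in this fixed order
#'   so attention maps are comparable across runs.
#' @param n_tasks number of endpoints (12).
#' @param residual if `TRUE`, wrap the attention in a pre-norm residual
#'   block; the default is the plain `Z = MultiHead(X, X, X)` form.
#' @return a `fusion_config`.
#' @export
fusion_config <- function(d_e = 256L, n_heads = 4L, dropout = 0.1,
                          active_modalities = MODALITY_ORDER,
                          n_tasks = N_TASKS, residual = FALSE) {
  active_modalities <- MODALITY_ORDER[MODALITY_ORDER %in% active_modalities]
  if (length(active_modalities) == 0L) stopf("active_modalities must be non-empty")
  stopifnot(d_e %% n_heads == 0L, n_tasks >= 1L, dropout >= 0, dropout < 1)
  structure(list(d_e = as.integer(d_e), n_heads = as.integer(n_heads),
                 dropout = dropout, active = active_modalities,
                 n_tasks = as.integer(n_tasks), residual = isTRUE(residual)),
            class = "fusion_config")
}

#' Create a fusion network
#'
#' @param cfg a [fusion_config()].
#' @param encoder_dims named integer vector/list: embedding dimension of
#'   each active modality encoder.
#' @param seed seed for parameter initialization.
#' @return a `moltitox_fusion` model. The missing-modality tokens are
#'   zero-initialized, one per active modality (only the spectrum token is
#'   exercised by the default pipeline).
#' @export
new_fusion <- function(cfg, encoder_dims, seed = 0L) {
  stopifnot(inherits(cfg, "fusion_config"))
  params <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (m in cfg$active) {
      dm <- as.integer(encoder_dims[[m]])
      # biased projection with a uniform nonzero bias: a zero-initialized
      # missing token only sees gradient through ReLU units whose
      # pre-activation ReLU(W . 0 + b) is positive, so some b entries must
      # start positive for the token to be trainable at all
      init_linear(params, paste0("proj.", m), dm, cfg$d_e, bias = TRUE)
      bound <- 1 / sqrt(dm)
      params[[paste0("proj.", m, ".b")]] <-
        matrix(stats::runif(cfg$d_e, -bound, bound), 1L)
      params[[paste0("missing.", m)]] <- matrix(0, 1L, dm)
    }
    d <- cfg$d_e
    for (nm in c("attn.q", "attn.k", "attn.v", "attn.o")) {
      init_linear(params, nm, d, d)
    }
    if (cfg$residual) init_norm(params, "attn.ln", d)
    init_linear(params, "head.1", d, d)
    init_linear(params, "head.2", d, max(1L, d %/% 2L))
    init_linear(params, "head.3", max(1L, d %/% 2L), cfg$n_tasks)
  })
  structure(list(cfg = cfg, params = params,
                 encoder_dims = lapply(encoder_dims, as.integer)),
            class = "moltitox_fusion")
}

# ---- batched forward -------------------------------------------------------

# embs: named list modality -> B x d_m matrix (plain values; encoders are
# frozen during fusion). presence: named list modality -> logical vector of
# length B (TRUE = modality observed for that sample).
forward_fusion <- function(fus, embs, presence, tp, trainable = TRUE,
                           collect_attention = FALSE) {
  cfg <- fus$cfg
  mods <- cfg$active
  B <- nrow(embs[[mods[1]]])
  proj <- vector("list", length(mods))
  for (k in seq_along(mods)) {
    m <- mods[k]
    pres <- presence[[m]] %||% rep(TRUE, B)
    E <- embs[[m]]
    if (any(!pres)) {
      E <- E * pres                       # absent rows contribute nothing
      ind <- matrix(as.numeric(!pres), B, 1L)
      X <- ad_add(ad_const(tp, E),
                  ad_matmul(ad_const(tp, ind),
                            ad_param(tp, paste0("missing.", m), trainable)))
    } else {
      X <- ad_const(tp, E)
    }
    proj[[k]] <- ad_relu(nn_linear(tp, X, paste0("proj.", m), trainable))
  }
  M <- length(mods)
  # unit-normalized tokens enter the shared attention: raw modality
  # embeddings differ in scale by orders of magnitude, which saturates the
  # score softmax and starves the fusion of gradient
  tokens_m <- ad_l2norm_rows(ad_rbind(proj))  # rows (modality, sample)
  # reorder to sample-major so each sample's M tokens are contiguous
  perm <- as.vector(t(matrix(seq_len(B * M), B, M)))
  tokens <- ad_gather(tokens_m, perm)
  att_in <- if (cfg$residual) nn_layernorm(tp, tokens, "attn.ln", trainable)
            else tokens
  d <- cfg$d_e
  dh <- d %/% cfg$n_heads
  head_cols <- split(seq_len(d), rep(seq_len(cfg$n_heads), each = dh))
  q <- nn_linear(tp, att_in, "attn.q", trainable)
  k <- nn_linear(tp, att_in, "attn.k", trainable)
  v <- nn_linear(tp, att_in, "attn.v", trainable)
  # block-diagonal batched attention over chunks of samples
  per_chunk <- max(1L, 256L %/% M)
  chunk_ids <- split(seq_len(B), ceiling(seq_len(B) / per_chunk))
  block_mask <- function(ns) {
    madd <- matrix(-1e9, ns * M, ns * M)
    for (s in seq_len(ns)) {
      blk <- (s - 1L) * M
      madd[blk + seq_len(M), blk + seq_len(M)] <- 0
    }
    madd
  }
  masks <- list()
  outs <- vector("list", length(chunk_ids))
  attn_maps <- if (collect_attention) vector("list", B) else NULL
  for (ch in seq_along(chunk_ids)) {
    cb <- chunk_ids[[ch]]
    ns <- length(cb)
    key <- as.character(ns)
    if (is.null(masks[[key]])) masks[[key]] <- block_mask(ns)
    rows <- (cb[1] - 1L) * M + seq_len(ns * M)
    hs <- vector("list", cfg$n_heads)
    for (hh in seq_len(cfg$n_heads)) {
      jc <- head_cols[[hh]]
      qh <- ad_cols(ad_gather(q, rows), jc)
      kh <- ad_cols(ad_gather(k, rows), jc)
      vh <- ad_cols(ad_gather(v, rows), jc)
      A <- ad_softmax_rows(ad_scale(ad_matmul(qh, ad_transpose(kh)),
                                    1 / sqrt(dh)), masks[[key]])
      if (collect_attention) {
        for (s in seq_len(ns)) {
          b <- cb[s]
          if (is.null(attn_maps[[b]])) {
            attn_maps[[b]] <- array(0, c(cfg$n_heads, M, M))
          }
          blk <- (s - 1L) * M
          attn_maps[[b]][hh, , ] <- A$val[blk + seq_len(M), blk + seq_len(M)]
        }
      }
      hs[[hh]] <- ad_matmul(A, vh)
    }
    outs[[ch]] <- ad_cbind(hs)
  }
  z <- nn_linear(tp, ad_rbind(outs), "attn.o", trainable)
  if (cfg$residual) z <- ad_add(tokens, z)
  # fused = per-sample mean over the M attended tokens
  fused <- ad_scale(ad_scatter_sum(z, rep(seq_len(B), each = M), B), 1 / M)
  h1 <- ad_relu(nn_linear(tp, fused, "head.1", trainable))
  h1 <- ad_dropout(h1, cfg$dropout)
  h2 <- ad_relu(nn_linear(tp, h1, "head.2", trainable))
  logits <- nn_linear(tp, h2, "head.3", trainable)
  list(logits = logits, fused = fused, attention = attn_maps)
}

# ---- public single-sample operations --------------------------------------

#' Project modality embeddings to the common fusion dimension
#'
#' Applies the per-modality linear projection + ReLU, substituting the
#' learnable missing token for any modality whose presence flag is `FALSE`
#' (a supplied embedding for an absent modality is ignored). Rows are stacked
#' in the fixed order graph, smiles, image, spectrum restricted to the active
#' set.
#'
#' @param fus a `moltitox_fusion` model.
#' @param embeddings named list of numeric vectors (one per active modality;
#'   entries for absent modalities may be `NULL`).
#' @param presence named logical vector; defaults to all present.
#' @return M x d_e matrix of projected modality tokens.
#' @export
project_modalities <- function(fus, embeddings, presence = NULL) {
  cfg <- fus$cfg
  for (m in setdiff(names(embeddings), cfg$active)) {
    mt_log(sprintf("ignoring embedding for inactive modality '%s'", m))
  }
  out <- matrix(0, length(cfg$active), cfg$d_e,
                dimnames = list(cfg$active, NULL))
  for (m in cfg$active) {
    pres <- if (is.null(presence)) TRUE else isTRUE(presence[[m]])
    e <- if (pres) {
      matrix(as.numeric(embeddings[[m]]), 1L)
    } else {
      fus$params[[paste0("missing.", m)]]
    }
    y <- e %*% fus$params[[paste0("proj.", m, ".W")]]
    bb <- fus$params[[paste0("proj.", m, ".b")]]
    if (!is.null(bb)) y <- y + as.numeric(bb)
    out[m, ] <- pmax(y, 0)
  }
  out
}

#' Fuse modality tokens by shared multi-head self-attention
#'
#' Row-normalizes the M modality tokens to unit length, computes
#' `Z = MultiHead(X, X, X)` over them and the fused representation
#' `fused = mean_m Z_m`; attention maps are returned for reporting.
#'
#' @param fus a `moltitox_fusion` model.
#' @param tokens M x d_e matrix from [project_modalities()].
#' @return list with `fused` (length-d_e vector), `attended` (M x d_e) and
#'   `attention` (n_heads x M x M array of row-stochastic maps).
#' @export
attention_fuse <- function(fus, tokens) {
  cfg <- fus$cfg
  M <- nrow(tokens)
  p <- fus$params
  tokens <- tokens / sqrt(rowSums(tokens^2) + 1e-8)  # unit-normalized tokens
  att_in <- tokens
  if (cfg$residual) {
    mu <- rowMeans(tokens); v <- rowMeans((tokens - mu)^2)
    att_in <- sweep(sweep((tokens - mu) / sqrt(v + 1e-5), 2L,
                          as.numeric(p[["attn.ln.gamma"]]), `*`),
                    2L, as.numeric(p[["attn.ln.beta"]]), `+`)
  }
  lin <- function(x, nm) sweep(x %*% p[[paste0(nm, ".W")]], 2L,
                               as.numeric(p[[paste0(nm, ".b")]]), `+`)
  q <- lin(att_in, "attn.q"); k <- lin(att_in, "attn.k")
  v <- lin(att_in, "attn.v")
  dh <- cfg$d_e %/% cfg$n_heads
  attention <- array(0, c(cfg$n_heads, M, M))
  z <- matrix(0, M, cfg$d_e)
  for (hh in seq_len(cfg$n_heads)) {
    jc <- (hh - 1L) * dh + seq_len(dh)
    sc <- q[, jc, drop = FALSE] %*% t(k[, jc, drop = FALSE]) / sqrt(dh)
    e <- exp(sc - apply(sc, 1L, max))
    A <- e / rowSums(e)
    attention[hh, , ] <- A
    z[, jc] <- A %*% v[, jc, drop = FALSE]
  }
  attended <- lin(z, "attn.o")
  if (cfg$residual) attended <- tokens + attended
  list(fused = colMeans(attended), attended = attended,
       attention = attention)
}

#' Predict endpoint logits from fused representations
#'
#' Applies the prediction head (Linear -> ReLU -> Dropout, then the final
#' MLP) in evaluation mode. Logits are pre-sigmoid; the sigmoid is applied
#' only when metrics are computed.
#'
#' @param fus a `moltitox_fusion` model.
#' @param fused numeric vector of length d_e or a B x d_e matrix.
#' @return B x n_tasks matrix of logits.
#' @export
predict_endpoints <- function(fus, fused) {
  if (!is.matrix(fused)) fused <- matrix(fused, nrow = 1L)
  p <- fus$params
  lin <- function(x, nm) {
    y <- x %*% p[[paste0(nm, ".W")]]
    sweep(y, 2L, as.numeric(p[[paste0(nm, ".b")]]), `+`)
  }
  h1 <- pmax(lin(fused, "head.1"), 0)
  h2 <- pmax(lin(h1, "head.2"), 0)
  lin(h2, "head.3")
}

#' Summarize attention maps over samples and heads
#'
#' Averages per-sample `n_heads x M x M` attention arrays over samples and
#' heads; rows are labeled by query modality and columns by key modality.
#' Also reports the mean attention each modality receives (column means of
#' the averaged map).
#'
#' @param attn_maps list of `n_heads x M x M` arrays (one per sample), e.g.
#'   collected by [evaluate_fusion()].
#' @param modalities character vector of modality names (length M).
#' @return list with `mean_map` (M x M), `received` (named numeric), and a
#'   long-format `table` data frame (query_modality, key_modality,
#'   mean_weight).
#' @export
extract_attention_summary <- function(attn_maps, modalities) {
  stopifnot(length(attn_maps) >= 1L)
  M <- length(modalities)
  acc <- matrix(0, M, M, dimnames = list(modalities, modalities))
  for (a in attn_maps) {
    for (hh in seq_len(dim(a)[1])) acc <- acc + a[hh, , ]
  }
  mean_map <- acc / (length(attn_maps) * dim(attn_maps[[1]])[1])
  tab <- data.frame(
    query_modality = rep(modalities, times = M),
    key_modality = rep(modalities, each = M),
    mean_weight = as.vector(mean_map)
  )
  list(mean_map = mean_map,
       received = colMeans(mean_map),
       table = tab)
}
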