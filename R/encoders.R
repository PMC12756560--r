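# Modality encoders: edge-aware GIN for graphs, a small transformer for
# SMILES token sequences, a residual 2D CNN for structure images, and a 1D
# CNN for binned carbon-13 spectra. Each encoder ends in an MLP projection
# head producing a fixed-length modality embedding.

#' Encoder configuration
#'
#' Returns the configuration for one modality encoder with the package
#' defaults; every field can be overridden. Sizes are deliberately modest:
#' encoders are trained from scratch at desk scale (no pretrained backbones).
#'
#' @param modality one of `"graph"`, `"smiles"`, `"image"`, `"spectrum"`.
#' @param ... overrides for the defaults listed below.
#' @return an `encoder_config` list.
#' @details Defaults per modality:
#' * graph: `n_layers = 5`, `hidden_dim = 128`, `output_dim = 128`,
#'   `dropout = 0.1`.
#' * smiles: `n_layers = 4`, `n_heads = 4`, `hidden_dim = 128`,
#'   `ffn_mult = 2`, `max_len = 202`, `output_dim = 128`, `dropout = 0.1`.
#' * image: `stem_pool = 4` (fixed average-pool downsampling of the 224 px
#'   raster before the first convolution), `stem_kernel = 5`,
#'   `stem_stride = 2`, `widths = c(32, 64, 128, 512)` (four residual
#'   stages; the last width is the 512-dim backbone vector), `size = 224`,
#'   `output_dim = 128`, `dropout = 0.1`.
#' * spectrum: `conv_widths = c(32, 64, 128)`, `kernel = 5`, `pool = 2`,
#'   `backbone_dim = 768`, `n_bins = 260`, `backbone_frozen = FALSE`,
#'   `output_dim = 128`, `dropout = 0.1`.
#' @export
encoder_config <- function(modality = c("graph", "smiles", "image", "spectrum"),
                           ...) {
  modality <- match.arg(modality)
  cfg <- switch(modality,
    graph = list(n_layers = 5L, hidden_dim = 128L, output_dim = 128L,
                 dropout = 0.1),
    smiles = list(n_layers = 4L, n_heads = 4L, hidden_dim = 128L,
                  ffn_mult = 2L, max_len = 202L, output_dim = 128L,
                  dropout = 0.1),
    image = list(stem_pool = 4L, stem_kernel = 5L, stem_stride = 2L,
                 widths = c(32L, 64L, 128L, 512L), size = 224L,
                 output_dim = 128L, dropout = 0.1),
    spectrum = list(conv_widths = c(32L, 64L, 128L), kernel = 5L, pool = 2L,
                    backbone_dim = 768L, n_bins = 260L,
                    backbone_frozen = FALSE, output_dim = 128L,
                    dropout = 0.1)
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg$modality <- modality
  stopifnot(cfg$output_dim >= 1L, cfg$dropout >= 0, cfg$dropout < 1)
  structure(cfg, class = "encoder_config")
}

#' Create a modality encoder
#'
#' Initializes encoder parameters (Glorot-uniform, seeded) together with the
#' 12-task linear probe head used during the encoder training phase.
#'
#' @param cfg an [encoder_config()].
#' @param seed integer seed for parameter initialization.
#' @param vocab SMILES vocabulary (required for the smiles modality).
#' @return a `moltitox_encoder` model object.
#' @export
new_encoder <- function(cfg, seed = 0L, vocab = NULL) {
  stopifnot(inherits(cfg, "encoder_config"))
  params <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  consts <- list()
  with_seed(seed, {
    switch(cfg$modality,
      graph = {
        h <- cfg$hidden_dim
        init_linear(params, "in", N_NODE_FEATURES, h)
        init_linear(params, "eproj", 4L, h, bias = FALSE)
        for (k in seq_len(cfg$n_layers)) {
          params[[sprintf("eps.%d", k)]] <- matrix(0, 1L, 1L)
          init_linear(params, sprintf("mlp%d.1", k), h, h)
          init_linear(params, sprintf("mlp%d.2", k), h, h)
          init_norm(params, sprintf("bn.%d", k), h)
        }
        init_linear(params, "head.1", h, h)
        init_linear(params, "head.2", h, cfg$output_dim)
      },
      smiles = {
        stopifnot(!is.null(vocab))
        h <- cfg$hidden_dim
        init_matrix(params, "tok.emb", vocab$size, h, scale = 0.1)
        for (l in seq_len(cfg$n_layers)) {
          init_norm(params, sprintf("ln1.%d", l), h)
          init_norm(params, sprintf("ln2.%d", l), h)
          init_linear(params, sprintf("attn%d.q", l), h, h)
          init_linear(params, sprintf("attn%d.k", l), h, h)
          init_linear(params, sprintf("attn%d.v", l), h, h)
          init_linear(params, sprintf("attn%d.o", l), h, h)
          init_linear(params, sprintf("ffn%d.1", l), h, h * cfg$ffn_mult)
          init_linear(params, sprintf("ffn%d.2", l), h * cfg$ffn_mult, h)
        }
        init_norm(params, "final_ln", h)
        init_linear(params, "head.1", h, h)
        init_linear(params, "head.2", h, cfg$output_dim)
        # sinusoidal position encoding, fixed
        pos <- seq_len(cfg$max_len) - 1L
        i2 <- floor((seq_len(h) - 1L) / 2L)
        ang <- outer(pos, 1 / 10000^(2 * i2 / h))
        pe <- ang
        even <- seq(1L, h, by = 2L)
        pe[, even] <- sin(ang[, even])
        if (h > 1L) {
          odd <- seq(2L, h, by = 2L)
          pe[, odd] <- cos(ang[, odd])
        }
        consts$pe <- pe
      },
      image = {
        w <- cfg$widths
        init_conv2d(params, "stem", cfg$stem_kernel^2 * 3L, w[1])
        init_norm(params, "stem.bn", w[1])
        cin <- w[1]
        for (s in seq_along(w)) {
          init_conv2d(params, sprintf("s%d.c1", s), 9L * cin, w[s])
          init_norm(params, sprintf("s%d.bn1", s), w[s])
          init_conv2d(params, sprintf("s%d.c2", s), 9L * w[s], w[s])
          init_norm(params, sprintf("s%d.bn2", s), w[s])
          if (s > 1L || cin != w[s]) {
            init_conv2d(params, sprintf("s%d.sk", s), cin, w[s], bias = FALSE)
            init_norm(params, sprintf("s%d.skbn", s), w[s])
          }
          cin <- w[s]
        }
        bd <- w[length(w)]
        init_linear(params, "head.1", bd, bd)
        init_linear(params, "head.2", bd, cfg$output_dim)
      },
      spectrum = {
        w <- cfg$conv_widths
        cin <- 2L    # peak-bit channel + normalized bin-position channel
        for (s in seq_along(w)) {
          init_conv2d(params, sprintf("c%d", s), cfg$kernel * cin, w[s])
          init_norm(params, sprintf("bn%d", s), w[s])
          cin <- w[s]
        }
        init_linear(params, "bb.out", cin, cfg$backbone_dim)
        init_linear(params, "head.1", cfg$backbone_dim, cfg$backbone_dim)
        init_linear(params, "head.2", cfg$backbone_dim, cfg$output_dim)
      }
    )
    init_linear(params, "probe", cfg$output_dim, N_TASKS)
  })
  structure(list(modality = cfg$modality, cfg = cfg, params = params,
                 state = state, consts = consts, vocab = vocab,
                 conv_cache = new.env(parent = emptyenv())),
            class = "moltitox_encoder")
}

#' Load externally trained backbone weights into an encoder
#'
#' Hook for swapping in pretrained backbone parameters. `weights` is a named
#' list of matrices whose names and shapes must match the encoder's
#' parameters. Provided as an integration point; it is not exercised against
#' any original pretrained checkpoints.
#'
#' @param model a `moltitox_encoder`.
#' @param weights named list of matrices.
#' @return the model, invisibly.
#' @export
load_backbone_weights <- function(model, weights) {
  for (nm in names(weights)) {
    cur <- model$params[[nm]]
    if (is.null(cur)) stopf("unknown parameter '%s'", nm)
    w <- as.matrix(weights[[nm]])
    if (!identical(dim(cur), dim(w))) stopf("shape mismatch for '%s'", nm)
    model$params[[nm]] <- w
  }
  invisible(model)
}

# ---- graph -----------------------------------------------------------------

#' One edge-aware GIN message-passing layer (functional form)
#'
#' Computes, for each node v,
#' `out_v = MLP((1 + eps) * x_v + sum_{u in N(v)} ReLU(x_u + e_{u,v}))`,
#' where the sum runs over incoming directed edges. This is the plain-matrix
#' form used for verification; the encoder applies the same update on the
#' autodiff tape, followed by batch normalization, ReLU and dropout.
#'
#' @param node_states N x h matrix.
#' @param edge_index 2 x E integer matrix (row 1 = source, row 2 =
#'   destination), 1-based.
#' @param edge_attr_projected E x h matrix of edge features already
#'   projected to the node dimension.
#' @param eps scalar.
#' @param mlp a function mapping an N x h matrix to an N x h' matrix
#'   (defaults to the identity).
#' @return N x h' matrix of updated node states.
#' @export
gine_layer <- function(node_states, edge_index, edge_attr_projected,
                       eps = 0, mlp = identity) {
  n <- nrow(node_states)
  agg <- matrix(0, n, ncol(node_states))
  if (ncol(edge_index) > 0L) {
    msg <- pmax(node_states[edge_index[1L, ], , drop = FALSE] +
                  edge_attr_projected, 0)
    rs <- rowsum(msg, edge_index[2L, ])
    agg[as.integer(rownames(rs)), ] <- rs
  }
  mlp((1 + eps) * node_states + agg)
}

# stack a list of GraphFeatures into one disjoint-union batch
batch_graphs <- function(gfeats) {
  ns <- vapply(gfeats, function(g) nrow(g$node_features), 1L)
  offs <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(gfeats, `[[`, "node_features"))
  ei <- do.call(cbind, lapply(seq_along(gfeats), function(i) {
    gfeats[[i]]$edge_index + offs[i]
  }))
  ea <- do.call(rbind, lapply(gfeats, `[[`, "edge_attr"))
  list(X = X, edge_index = ei, edge_attr = ea,
       graph_id = rep(seq_along(gfeats), ns), n_graphs = length(gfeats))
}

forward_graph_nodes <- function(model, gb, tp, trainable = TRUE) {
  cfg <- model$cfg
  x <- nn_linear(tp, ad_const(tp, gb$X), "in", trainable)
  eproj <- nn_linear(tp, ad_const(tp, gb$edge_attr), "eproj", trainable)
  src <- gb$edge_index[1L, ]
  dst <- gb$edge_index[2L, ]
  n <- nrow(gb$X)
  for (k in seq_len(cfg$n_layers)) {
    if (length(src) > 0L) {
      msg <- ad_relu(ad_add(ad_gather(x, src), eproj))
      agg <- ad_scatter_sum(msg, dst, n)
    } else {
      agg <- ad_scale(x, 0)
    }
    eps <- ad_param(tp, sprintf("eps.%d", k), trainable)
    z <- ad_add(ad_add(x, ad_mul(x, eps)), agg)
    z <- nn_linear(tp, z, sprintf("mlp%d.1", k), trainable)
    z <- ad_relu(z)
    z <- nn_linear(tp, z, sprintf("mlp%d.2", k), trainable)
    z <- nn_batchnorm(tp, z, sprintf("bn.%d", k), model$state, trainable)
    z <- ad_relu(z)
    x <- ad_dropout(z, cfg$dropout)
  }
  x
}

forward_graph <- function(model, gb, tp, trainable = TRUE) {
  cfg <- model$cfg
  x <- forward_graph_nodes(model, gb, tp, trainable)
  pooled <- ad_scatter_sum(x, gb$graph_id, gb$n_graphs)  # global sum pooling
  hemb <- ad_relu(nn_linear(tp, pooled, "head.1", trainable))
  hemb <- ad_dropout(hemb, cfg$dropout)
  nn_linear(tp, hemb, "head.2", trainable)
}

#' Encode molecular graphs (evaluation mode)
#'
#' @param model a graph `moltitox_encoder`.
#' @param gfeats a single [featurize_graph()] result or a list of them.
#' @return matrix of embeddings, one row per molecule.
#' @export
encode_graph <- function(model, gfeats) {
  stopifnot(model$modality == "graph")
  if (!is.null(gfeats$node_features)) gfeats <- list(gfeats)
  tp <- ad_tape(model$params, training = FALSE)
  forward_graph(model, batch_graphs(gfeats), tp)$val
}

# ---- smiles ----------------------------------------------------------------

forward_smiles <- function(model, ids, mask, tp, trainable = TRUE) {
  cfg <- model$cfg
  B <- nrow(ids)
  lens <- rowSums(mask)
  if (any(lens == 0L)) stopf("encode_smiles: all-pad sequence")
  lmax <- max(lens)
  ids <- ids[, seq_len(lmax), drop = FALSE]
  mask <- mask[, seq_len(lmax), drop = FALSE]
  h <- cfg$hidden_dim
  flat_ids <- as.integer(t(ids))                    # (b, pos), pos fastest
  x <- ad_gather(ad_param(tp, "tok.emb", trainable), flat_ids)
  pe <- model$consts$pe[rep(seq_len(lmax), B), , drop = FALSE]
  x <- ad_add(x, ad_const(tp, pe))
  dh <- h / cfg$n_heads
  head_cols <- split(seq_len(h), rep(seq_len(cfg$n_heads), each = dh))
  # block-diagonal batched attention: samples are processed in contiguous
  # chunks whose joint score matrix stays small; cross-sample and pad-key
  # scores are pushed to -1e9 before the softmax
  per_chunk <- max(1L, 192L %/% lmax)
  chunk_ids <- split(seq_len(B), ceiling(seq_len(B) / per_chunk))
  chunk_masks <- lapply(chunk_ids, function(cb) {
    nc <- length(cb) * lmax
    madd <- matrix(-1e9, nc, nc)
    for (s in seq_along(cb)) {
      blk <- (s - 1L) * lmax
      allowed <- which(mask[cb[s], ] == 1L)
      madd[blk + seq_len(lmax), blk + allowed] <- 0
    }
    madd
  })
  for (l in seq_len(cfg$n_layers)) {
    xn <- nn_layernorm(tp, x, sprintf("ln1.%d", l), trainable)
    q <- nn_linear(tp, xn, sprintf("attn%d.q", l), trainable)
    k <- nn_linear(tp, xn, sprintf("attn%d.k", l), trainable)
    v <- nn_linear(tp, xn, sprintf("attn%d.v", l), trainable)
    outs <- vector("list", length(chunk_ids))
    for (ch in seq_along(chunk_ids)) {
      cb <- chunk_ids[[ch]]
      rows <- (cb[1] - 1L) * lmax + seq_len(length(cb) * lmax)
      hs <- lapply(head_cols, function(jc) {
        qh <- ad_cols(ad_gather(q, rows), jc)
        kh <- ad_cols(ad_gather(k, rows), jc)
        vh <- ad_cols(ad_gather(v, rows), jc)
        sc <- ad_scale(ad_matmul(qh, ad_transpose(kh)), 1 / sqrt(dh))
        ad_matmul(ad_softmax_rows(sc, chunk_masks[[ch]]), vh)
      })
      outs[[ch]] <- ad_cbind(hs)
    }
    att <- nn_linear(tp, ad_rbind(outs), sprintf("attn%d.o", l), trainable)
    x <- ad_add(x, ad_dropout(att, cfg$dropout))
    xn <- nn_layernorm(tp, x, sprintf("ln2.%d", l), trainable)
    ff <- ad_gelu(nn_linear(tp, xn, sprintf("ffn%d.1", l), trainable))
    ff <- nn_linear(tp, ff, sprintf("ffn%d.2", l), trainable)
    x <- ad_add(x, ad_dropout(ff, cfg$dropout))
  }
  x <- nn_layernorm(tp, x, "final_ln", trainable)
  # masked mean pooling over real tokens
  real <- which(as.logical(t(mask)))
  sample_of <- rep(seq_len(B), each = lmax)[real]
  s <- ad_scatter_sum(ad_gather(x, real), sample_of, B)
  pooled <- ad_mul(s, ad_const(tp, matrix(1 / lens, B, h)))
  hemb <- nn_linear(tp, pooled, "head.1", trainable)
  hemb <- ad_gelu(ad_dropout(hemb, cfg$dropout))
  hemb <- nn_linear(tp, hemb, "head.2", trainable)
  ad_gelu(ad_dropout(hemb, cfg$dropout))
}

#' Encode tokenized SMILES sequences (evaluation mode)
#'
#' @param model a smiles `moltitox_encoder`.
#' @param tokens a single [tokenize_smiles()] result or a list of them.
#' @return matrix of embeddings, one row per sequence.
#' @export
encode_smiles <- function(model, tokens) {
  stopifnot(model$modality == "smiles")
  if (!is.null(tokens$ids)) tokens <- list(tokens)
  ids <- do.call(rbind, lapply(tokens, `[[`, "ids"))
  mask <- do.call(rbind, lapply(tokens, `[[`, "mask"))
  tp <- ad_tape(model$params, training = FALSE)
  forward_smiles(model, ids, mask, tp)$val
}

# ---- image -----------------------------------------------------------------

# channels-first tensors -> (B*H*W) x 3 matrix; rows enumerate (b, x, y)
# with y fastest (column-major order of each channel slice; equivalent to
# the x-fastest convention for square images since convolution geometry is
# symmetric in the two axes)
image_batch_matrix <- function(tensors) {
  do.call(rbind, lapply(tensors, function(tt) {
    cbind(as.vector(tt[1, , ]), as.vector(tt[2, , ]), as.vector(tt[3, , ]))
  }))
}

forward_image <- function(model, xmat, B, tp, trainable = TRUE) {
  cfg <- model$cfg
  w <- cfg$widths
  sz <- cfg$size
  cache <- model$conv_cache
  x <- ad_const(tp, xmat)
  if ((cfg$stem_pool %||% 1L) > 1L) {
    pre <- attr(xmat, "prepooled")
    if (!is.null(pre)) {
      stopifnot(pre == cfg$stem_pool)     # loader already pooled the input
      sz <- sz %/% cfg$stem_pool
    } else {
      x <- ad_pool2d(x, B, sz, sz, cfg$stem_pool)
      sz <- sz %/% cfg$stem_pool
    }
  }
  ci <- conv_index_cached(cache, B, sz, sz, cfg$stem_kernel, cfg$stem_stride,
                          cfg$stem_kernel %/% 2L)
  x <- nn_conv2d(tp, x, "stem", ci, trainable)
  x <- ad_relu(nn_batchnorm(tp, x, "stem.bn", model$state, trainable))
  hcur <- ci$ho
  strides <- c(1L, rep(2L, length(w) - 1L))
  cin <- w[1]
  for (s in seq_along(w)) {
    ci1 <- conv_index_cached(cache, B, hcur, hcur, 3L, strides[s], 1L)
    y <- nn_conv2d(tp, x, sprintf("s%d.c1", s), ci1, trainable)
    y <- ad_relu(nn_batchnorm(tp, y, sprintf("s%d.bn1", s), model$state,
                              trainable))
    hout <- ci1$ho
    ci2 <- conv_index_cached(cache, B, hout, hout, 3L, 1L, 1L)
    y <- nn_conv2d(tp, y, sprintf("s%d.c2", s), ci2, trainable)
    y <- nn_batchnorm(tp, y, sprintf("s%d.bn2", s), model$state, trainable)
    if (!is.null(model$params[[sprintf("s%d.sk.W", s)]])) {
      cisk <- conv_index_cached(cache, B, hcur, hcur, 1L, strides[s], 0L)
      sk <- nn_conv2d(tp, x, sprintf("s%d.sk", s), cisk, trainable)
      sk <- nn_batchnorm(tp, sk, sprintf("s%d.skbn", s), model$state,
                         trainable)
    } else {
      sk <- x
    }
    x <- ad_relu(ad_add(y, sk))
    hcur <- hout
    cin <- w[s]
  }
  npos <- hcur * hcur
  feat <- nn_gap(x, rep(seq_len(B), each = npos), B, npos)  # B x 512
  hemb <- ad_relu(nn_linear(tp, feat, "head.1", trainable))
  hemb <- ad_dropout(hemb, cfg$dropout)
  list(emb = nn_linear(tp, hemb, "head.2", trainable), backbone = feat)
}

#' Encode normalized structure images (evaluation mode)
#'
#' @param model an image `moltitox_encoder`.
#' @param tensors a single `3 x H x W` tensor from [normalize_image()] or a
#'   list of them.
#' @param backbone if `TRUE`, return the pre-head global-average-pooled
#'   backbone features instead of the projected embedding.
#' @return matrix with one row per image.
#' @export
encode_image <- function(model, tensors, backbone = FALSE) {
  stopifnot(model$modality == "image")
  if (is.array(tensors) && length(dim(tensors)) == 3L) tensors <- list(tensors)
  sz <- model$cfg$size
  for (tt in tensors) {
    if (!identical(dim(tt), c(3L, sz, sz))) {
      stopf("encode_image: expected 3 x %d x %d tensor", sz, sz)
    }
  }
  tp <- ad_tape(model$params, training = FALSE)
  out <- forward_image(model, image_batch_matrix(tensors), length(tensors), tp)
  if (backbone) out$backbone$val else out$emb$val
}

# ---- spectrum --------------------------------------------------------------

# 1D analogue of conv_index: rows enumerate (b, pos)
conv1d_index <- function(batch, len, k, stride, pad) {
  lo <- (len + 2L * pad - k) %/% stride + 1L
  n_out <- batch * lo
  R <- batch * len
  b <- rep(seq_len(batch) - 1L, each = lo)
  op <- rep(seq_len(lo) - 1L, times = batch)
  idx <- integer(n_out * k)
  pos <- 1L
  for (kk in seq_len(k) - 1L) {
    ip <- op * stride - pad + kk
    inside <- ip >= 0L & ip < len
    rows <- b * len + ip + 1L
    rows[!inside] <- R + 1L
    idx[pos:(pos + n_out - 1L)] <- rows
    pos <- pos + n_out
  }
  list(idx = idx, n_out = n_out, ho = lo, k2 = k)
}

pool1d_groups <- function(batch, len, p) {
  lo <- len %/% p
  b <- rep(seq_len(batch) - 1L, each = len)
  pos <- rep(seq_len(len) - 1L, times = batch)
  keep <- pos < lo * p
  g <- b * lo + pos %/% p + 1L
  list(groups = g, keep = keep, n = batch * lo, ho = lo, p2 = p)
}

forward_spectrum <- function(model, bits, tp, trainable = TRUE) {
  cfg <- model$cfg
  B <- nrow(bits)
  if (ncol(bits) != cfg$n_bins) {
    stopf("encode_spectrum: expected %d bins, got %d", cfg$n_bins, ncol(bits))
  }
  bb_trainable <- trainable && !isTRUE(cfg$backbone_frozen)
  # frozen backbone also runs its batch norms on running statistics
  saved_training <- tp$training
  if (!bb_trainable) tp$training <- FALSE
  # a normalized bin-position channel accompanies the peak bits: stacked
  # convolutions with pooling are otherwise translation-invariant, and the
  # absolute chemical-shift position is chemically meaningful
  pos <- rep(seq_len(cfg$n_bins) / cfg$n_bins, B)
  x <- ad_const(tp, cbind(as.numeric(t(bits)), pos))
  len <- cfg$n_bins
  cache <- model$conv_cache
  for (s in seq_along(cfg$conv_widths)) {
    key <- paste("c1d", B, len, s, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- conv1d_index(B, len, cfg$kernel, 1L, cfg$kernel %/% 2L)
    }
    ci <- cache[[key]]
    x <- ad_im2col(x, ci$idx, ci$n_out, ci$k2) |>
      (\(p) ad_matmul(p, ad_param(tp, sprintf("c%d.W", s), bb_trainable)))() |>
      (\(p) ad_add(p, ad_param(tp, sprintf("c%d.b", s), bb_trainable)))()
    x <- ad_relu(nn_batchnorm(tp, x, sprintf("bn%d", s), model$state,
                              bb_trainable))
    pkey <- paste("p1d", B, len, s, sep = "_")
    if (is.null(cache[[pkey]])) cache[[pkey]] <- pool1d_groups(B, len, cfg$pool)
    pg <- cache[[pkey]]
    xs <- if (all(pg$keep)) x else ad_gather(x, which(pg$keep))
    x <- ad_scale(ad_scatter_sum(xs, pg$groups[pg$keep], pg$n), 1 / pg$p2)
    len <- pg$ho
  }
  feat <- ad_scale(ad_scatter_sum(x, rep(seq_len(B), each = len), B), 1 / len)
  feat <- nn_linear(tp, feat, "bb.out", bb_trainable)   # 768-dim backbone out
  tp$training <- saved_training
  hemb <- ad_relu(nn_linear(tp, feat, "head.1", trainable))
  hemb <- ad_dropout(hemb, cfg$dropout)
  list(emb = nn_linear(tp, hemb, "head.2", trainable), backbone = feat)
}

#' Encode binned spectra (evaluation mode)
#'
#' @param model a spectrum `moltitox_encoder`.
#' @param bits a single 0/1 bin vector from [bin_spectrum()] or a matrix
#'   with one spectrum per row. Missing spectra are not encoded here: the
#'   fusion stage substitutes the learnable missing token instead.
#' @param backbone if `TRUE`, return the backbone feature vector(s).
#' @return matrix with one row per spectrum.
#' @export
encode_spectrum <- function(model, bits, backbone = FALSE) {
  stopifnot(model$modality == "spectrum")
  if (!is.matrix(bits)) bits <- matrix(bits, nrow = 1L)
  tp <- ad_tape(model$params, training = FALSE)
  out <- forward_spectrum(model, bits, tp)
  if (backbone) out$backbone$val else out$emb$val
}

# unified internal entry: returns the embedding node on an existing tape
forward_encoder <- function(model, batch, tp, trainable = TRUE) {
  switch(model$modality,
    graph = forward_graph(model, batch, tp, trainable),
    smiles = forward_smiles(model, batch$ids, batch$mask, tp, trainable),
    image = forward_image(model, batch$xmat, batch$B, tp, trainable)$emb,
    spectrum = forward_spectrum(model, batch$bits, tp, trainable)$emb
  )
}
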