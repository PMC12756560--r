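# Parameter initialisation, layer helpers and the Adam optimizer.

init_matrix <- function(params, name, nr, nc, scale = NULL) {
  scale <- scale %||% sqrt(6 / (nr + nc))   # Glorot uniform
  params[[name]] <- matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
  invisible(name)
}

init_linear <- function(params, prefix, fan_in, fan_out, bias = TRUE) {
  init_matrix(params, paste0(prefix, ".W"), fan_in, fan_out)
  if (bias) params[[paste0(prefix, ".b")]] <- matrix(0, 1L, fan_out)
  invisible(prefix)
}

init_norm <- function(params, prefix, dim) {
  params[[paste0(prefix, ".gamma")]] <- matrix(1, 1L, dim)
  params[[paste0(prefix, ".beta")]] <- matrix(0, 1L, dim)
  invisible(prefix)
}

nn_linear <- function(tp, x, prefix, trainable = TRUE) {
  W <- ad_param(tp, paste0(prefix, ".W"), trainable)
  y <- ad_matmul(x, W)
  bname <- paste0(prefix, ".b")
  if (!is.null(tp$params[[bname]])) {
    y <- ad_add(y, ad_param(tp, bname, trainable))
  }
  y
}

nn_layernorm <- function(tp, x, prefix, trainable = TRUE) {
  ad_layernorm(x, ad_param(tp, paste0(prefix, ".gamma"), trainable),
               ad_param(tp, paste0(prefix, ".beta"), trainable))
}

nn_batchnorm <- function(tp, x, prefix, state, trainable = TRUE) {
  ad_batchnorm(x, ad_param(tp, paste0(prefix, ".gamma"), trainable),
               ad_param(tp, paste0(prefix, ".beta"), trainable),
               state, prefix)
}

# ---- convolution index maps ------------------------------------------------

# Rows of a spatial activation matrix enumerate (batch, y, x) with x fastest.
# conv_index builds the im2col row-index vector for a given geometry; index
# R+1 denotes the zero padding row. Cached per geometry in an environment.
conv_index <- function(batch, h, w, k, stride, pad) {
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  n_out <- batch * ho * wo
  R <- batch * h * w
  # output position grids
  b <- rep(seq_len(batch) - 1L, each = ho * wo)
  oy <- rep(rep(seq_len(ho) - 1L, each = wo), times = batch)
  ox <- rep(seq_len(wo) - 1L, times = batch * ho)
  idx <- integer(n_out * k * k)
  pos <- 1L
  for (ky in seq_len(k) - 1L) {
    for (kx in seq_len(k) - 1L) {
      iy <- oy * stride - pad + ky
      ix <- ox * stride - pad + kx
      inside <- iy >= 0L & iy < h & ix >= 0L & ix < w
      rows <- b * (h * w) + iy * w + ix + 1L
      rows[!inside] <- R + 1L
      idx[pos:(pos + n_out - 1L)] <- rows
      pos <- pos + n_out
    }
  }
  list(idx = idx, n_out = n_out, ho = ho, wo = wo, k2 = k * k)
}

conv_index_cached <- function(cache, batch, h, w, k, stride, pad) {
  key <- paste(batch, h, w, k, stride, pad, sep = "_")
  if (is.null(cache[[key]])) cache[[key]] <- conv_index(batch, h, w, k, stride, pad)
  cache[[key]]
}

# 2D convolution: x is (batch*h*w) x c_in, weight (k2*c_in) x c_out with rows
# ordered channel-major, kernel position fastest (matches ad_im2col columns).
nn_conv2d <- function(tp, x, prefix, ci, trainable = TRUE) {
  ci_im <- ad_im2col(x, ci$idx, ci$n_out, ci$k2)
  y <- ad_matmul(ci_im, ad_param(tp, paste0(prefix, ".W"), trainable))
  bname <- paste0(prefix, ".b")
  if (!is.null(tp$params[[bname]])) y <- ad_add(y, ad_param(tp, bname, trainable))
  y
}

init_conv2d <- function(params, prefix, k2cin, cout, bias = TRUE) {
  init_matrix(params, paste0(prefix, ".W"), k2cin, cout,
              scale = sqrt(6 / (k2cin + cout)))
  if (bias) params[[paste0(prefix, ".b")]] <- matrix(0, 1L, cout)
  invisible(prefix)
}

# non-overlapping average pooling over p x p blocks (spatial rows layout)
avgpool_groups <- function(batch, h, w, p) {
  ho <- h %/% p; wo <- w %/% p
  b <- rep(seq_len(batch) - 1L, each = h * w)
  y <- rep(rep(seq_len(h) - 1L, each = w), times = batch)
  x <- rep(seq_len(w) - 1L, times = batch * h)
  keep <- y < ho * p & x < wo * p
  g <- b * (ho * wo) + (y %/% p) * wo + (x %/% p) + 1L
  list(groups = g, keep = keep, n = batch * ho * wo, ho = ho, wo = wo, p2 = p * p)
}

nn_avgpool <- function(x, ap) {
  xs <- if (all(ap$keep)) x else ad_gather(x, which(ap$keep))
  s <- ad_scatter_sum(xs, ap$groups[ap$keep], ap$n)
  ad_scale(s, 1 / ap$p2)
}

# global average pool: rows grouped by image id
nn_gap <- function(x, image_id, n_images, npos) {
  ad_scale(ad_scatter_sum(x, image_id, n_images), 1 / npos)
}

# ---- Adam ------------------------------------------------------------------

opt_adam <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0, wd_exclude = NULL) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2
  e$eps <- eps; e$wd <- weight_decay
  e$wd_exclude <- wd_exclude   # regex of parameter names exempt from decay
  e$m <- new.env(parent = emptyenv())
  e$v <- new.env(parent = emptyenv())
  e$t <- new.env(parent = emptyenv())
  e
}

opt_step <- function(opt, params, grads) {
  for (name in ls(grads)) {
    g <- grads[[name]]
    p <- params[[name]]
    decay <- opt$wd > 0 &&
      (is.null(opt$wd_exclude) || !grepl(opt$wd_exclude, name))
    if (decay) g <- g + opt$wd * p
    if (is.null(opt$m[[name]])) {
      opt$m[[name]] <- g * 0
      opt$v[[name]] <- g * 0
      opt$t[[name]] <- 0L
    }
    opt$t[[name]] <- opt$t[[name]] + 1L
    opt$m[[name]] <- opt$beta1 * opt$m[[name]] + (1 - opt$beta1) * g
    opt$v[[name]] <- opt$beta2 * opt$v[[name]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[name]] / (1 - opt$beta1^opt$t[[name]])
    vhat <- opt$v[[name]] / (1 - opt$beta2^opt$t[[name]])
    params[[name]] <- p - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(NULL)
}

# ---- parameter bookkeeping -------------------------------------------------

copy_env <- function(e) list2env(as.list(e, all.names = TRUE), parent = emptyenv())

restore_env <- function(target, snapshot) {
  rm(list = ls(target, all.names = TRUE), envir = target)
  for (n in ls(snapshot, all.names = TRUE)) target[[n]] <- snapshot[[n]]
  invisible(target)
}

param_fingerprint <- function(params) {
  ns <- sort(ls(params, all.names = TRUE))
  sum(vapply(ns, function(n) sum(params[[n]]^2), 0))
}
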