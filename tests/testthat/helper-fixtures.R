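# Shared fixtures: tiny synthetic datasets, compact model configs, and a
# finite-difference gradient checker. Everything is generated in code at
# test time; nothing is read from stored binaries.

tiny_benchmark <- local({
  memo <- new.env(parent = emptyenv())
  function(n = 60L, seed = 7L, signal = "default", key = NULL) {
    key <- key %||% paste(n, seed, signal, sep = "_")
    if (is.null(memo[[key]])) {
      dir <- file.path(tempdir(), paste0("mtx_fix_", key))
      cfg <- synth_config(n_molecules = n, seed = seed, signal = signal)
      bm <- build_benchmark(cfg, dir)
      ds <- load_dataset(bm$compound_csv, bm$peaks_json)
      memo[[key]] <- list(cfg = cfg, bm = bm, ds = ds)
    }
    memo[[key]]
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

small_graph_cfg <- function(...) {
  encoder_config("graph", n_layers = 2L, hidden_dim = 24L, output_dim = 16L,
                 ...)
}
small_smiles_cfg <- function(...) {
  encoder_config("smiles", n_layers = 2L, n_heads = 2L, hidden_dim = 16L,
                 output_dim = 16L, ...)
}
small_image_cfg <- function(...) {
  encoder_config("image", stem_pool = 8L, stem_kernel = 3L, stem_stride = 1L,
                 widths = c(8L, 16L, 16L, 32L), output_dim = 16L, ...)
}
small_spectrum_cfg <- function(...) {
  encoder_config("spectrum", conv_widths = c(8L, 16L), backbone_dim = 32L,
                 output_dim = 16L, ...)
}

# max |analytic - finite difference| over a few entries of each parameter
num_grad_check <- function(params, fwd, names = NULL, n_per = 4L,
                           eps = 1e-6) {
  r <- fwd()
  grads <- moltitox:::ad_backward(r$tp, r$loss)
  names <- names %||% ls(params)
  maxerr <- 0
  for (nm in names) {
    p <- params[[nm]]
    take <- seq_len(min(length(p), n_per))
    for (i in take) {
      p0 <- p[i]
      params[[nm]][i] <- p0 + eps
      lp <- as.numeric(fwd()$loss$val)
      params[[nm]][i] <- p0 - eps
      lm <- as.numeric(fwd()$loss$val)
      params[[nm]][i] <- p0
      ana <- moltitox:::grad_of(grads, params, nm)[i]
      maxerr <- max(maxerr, abs((lp - lm) / (2 * eps) - ana))
    }
  }
  maxerr
}

# dense brute-force GINE oracle: adjacency loop, no sparsity tricks
gine_dense_oracle <- function(x, edge_index, eproj, eps, mlp = identity) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (v in seq_len(n)) {
    acc <- (1 + eps) * x[v, ]
    if (ncol(edge_index) > 0L) {
      for (e in seq_len(ncol(edge_index))) {
        if (edge_index[2L, e] == v) {
          u <- edge_index[1L, e]
          acc <- acc + pmax(x[u, ] + eproj[e, ], 0)
        }
      }
    }
    out[v, ] <- acc
  }
  mlp(out)
}

random_graph <- function(n_nodes, h, p_edge = 0.5) {
  x <- matrix(stats::rnorm(n_nodes * h), n_nodes, h)
  pairs <- if (n_nodes >= 2L) utils::combn(n_nodes, 2L) else
    matrix(integer(0), 2L, 0L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  pairs <- pairs[, keep, drop = FALSE]
  ei <- cbind(pairs, pairs[2:1, , drop = FALSE])
  if (ncol(ei) == 0L) ei <- matrix(integer(0), 2L, 0L)
  eproj <- matrix(stats::rnorm(ncol(ei) * h), ncol(ei), h)
  list(x = x, edge_index = ei, eproj = eproj)
}
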