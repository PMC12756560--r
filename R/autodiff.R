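# Reverse-mode automatic differentiation over base-R matrices.
#
# A tape records each primitive op with its value and a backward closure.
# Values are always plain numeric matrices (scalars are 1x1). Parameters live
# in an environment (name -> matrix) owned by a model; registering a parameter
# on a tape with trainable = FALSE detaches it, so frozen components
# contribute no gradient at all (their entries are simply absent from the
# gradient environment).

ad_tape <- function(params = NULL, training = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp$params <- params
  tp$pids <- new.env(parent = emptyenv())
  tp$training <- isTRUE(training)
  class(tp) <- "ad_tape"
  tp
}

ad_node <- function(tp, val, parents = integer(0), backfn = NULL, pname = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[n]] <- list(parents = parents, backfn = backfn, pname = pname)
  tp$n <- n
  list(id = n, val = val, tp = tp)
}

ad_const <- function(tp, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  ad_node(tp, x)
}

ad_param <- function(tp, name, trainable = TRUE) {
  key <- if (trainable) name else paste0(".frozen.", name)
  if (!is.null(tp$pids[[key]])) return(tp$pids[[key]])
  val <- tp$params[[name]]
  if (is.null(val)) stopf("unknown parameter '%s'", name)
  h <- ad_node(tp, val, pname = if (trainable) name else NULL)
  tp$pids[[key]] <- h
  h
}

ad_backward <- function(tp, loss) {
  stopifnot(length(loss$val) == 1L)
  gr <- vector("list", tp$n)
  gr[[loss$id]] <- matrix(1, 1L, 1L)
  grads <- new.env(parent = emptyenv())
  for (id in seq.int(loss$id, 1L)) {
    g <- gr[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    if (!is.null(node$pname)) {
      old <- grads[[node$pname]]
      grads[[node$pname]] <- if (is.null(old)) g else old + g
    }
    if (!is.null(node$backfn)) {
      pg <- node$backfn(g)
      for (k in seq_along(node$parents)) {
        p <- node$parents[k]
        if (is.null(pg[[k]])) next
        gr[[p]] <- if (is.null(gr[[p]])) pg[[k]] else gr[[p]] + pg[[k]]
      }
    }
    gr[id] <- list(NULL)
  }
  grads
}

grad_of <- function(grads, params, name) {
  g <- grads[[name]]
  if (is.null(g)) {
    v <- params[[name]]
    g <- matrix(0, nrow(v), ncol(v))
  }
  g
}

# ---- primitive ops ---------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- a$val; bv <- b$val
  ad_node(a$tp, av %*% bv, c(a$id, b$id), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# b may match a, be a 1 x ncol(a) row vector (bias broadcast), or be 1 x 1.
ad_add <- function(a, b) {
  av <- a$val; bv <- b$val
  if (identical(dim(av), dim(bv))) {
    val <- av + bv
    back <- function(g) list(g, g)
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    val <- av + rep(as.numeric(bv), each = nrow(av))
    back <- function(g) list(g, matrix(colSums(g), 1L))
  } else if (length(bv) == 1L) {
    val <- av + as.numeric(bv)
    back <- function(g) list(g, matrix(sum(g), 1L, 1L))
  } else stopf("ad_add: incompatible shapes")
  ad_node(a$tp, val, c(a$id, b$id), back)
}

ad_scale <- function(a, s) {
  ad_node(a$tp, a$val * s, a$id, function(g) list(g * s))
}

# elementwise product; b same shape as a, or 1 x 1 scalar node
ad_mul <- function(a, b) {
  av <- a$val; bv <- b$val
  if (length(bv) == 1L) {
    val <- av * as.numeric(bv)
    back <- function(g) list(g * as.numeric(bv), matrix(sum(g * av), 1L, 1L))
  } else {
    stopifnot(identical(dim(av), dim(bv)))
    val <- av * bv
    back <- function(g) list(g * bv, g * av)
  }
  ad_node(a$tp, val, c(a$id, b$id), back)
}

ad_relu <- function(a) {
  av <- a$val
  ad_node(a$tp, pmax(av, 0), a$id, function(g) list(g * (av > 0)))
}

# tanh-approximation GELU (the form standard transformer implementations
# use; far cheaper than the exact Gaussian CDF)
ad_gelu <- function(a) {
  av <- a$val
  c0 <- sqrt(2 / pi)
  u <- c0 * (av + 0.044715 * av^3)
  th <- tanh(u)
  ad_node(a$tp, 0.5 * av * (1 + th), a$id, function(g) {
    du <- c0 * (1 + 3 * 0.044715 * av^2)
    list(g * (0.5 * (1 + th) + 0.5 * av * (1 - th^2) * du))
  })
}

ad_sum <- function(a) {
  av <- a$val
  ad_node(a$tp, matrix(sum(av), 1L, 1L), a$id, function(g) {
    matrix(as.numeric(g), nrow(av), ncol(av)) |> list()
  })
}

ad_transpose <- function(a) {
  ad_node(a$tp, t(a$val), a$id, function(g) list(t(g)))
}

ad_gather <- function(a, rows) {
  av <- a$val
  rows <- as.integer(rows)
  ad_node(a$tp, av[rows, , drop = FALSE], a$id, function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    rs <- rowsum(g, rows)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

# sum rows of a into ngroups buckets (groups: integer in 1..ngroups per row)
ad_scatter_sum <- function(a, groups, ngroups) {
  av <- a$val
  groups <- as.integer(groups)
  val <- matrix(0, ngroups, ncol(av))
  if (nrow(av) > 0L) {
    rs <- rowsum(av, groups)
    val[as.integer(rownames(rs)), ] <- rs
  }
  ad_node(a$tp, val, a$id, function(g) list(g[groups, , drop = FALSE]))
}

ad_cols <- function(a, j) {
  av <- a$val
  j <- as.integer(j)
  ad_node(a$tp, av[, j, drop = FALSE], a$id, function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    out[, j] <- g
    list(out)
  })
}

ad_cbind <- function(hs) {
  tp <- hs[[1]]$tp
  vals <- lapply(hs, `[[`, "val")
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tp, do.call(cbind, vals), vapply(hs, `[[`, 1L, "id"), function(g) {
    lapply(seq_along(hs), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ad_rbind <- function(hs) {
  tp <- hs[[1]]$tp
  vals <- lapply(hs, `[[`, "val")
  hh <- vapply(vals, nrow, 1L)
  ends <- cumsum(hh)
  starts <- ends - hh + 1L
  ad_node(tp, do.call(rbind, vals), vapply(hs, `[[`, 1L, "id"), function(g) {
    lapply(seq_along(hs), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

# row-wise softmax; mask_add is an optional constant matrix added to the
# scores before the softmax (use large negatives to mask keys out)
ad_softmax_rows <- function(a, mask_add = NULL) {
  av <- a$val
  if (!is.null(mask_add)) av <- av + mask_add
  m <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  e <- exp(av - m)
  y <- e / rowSums(e)
  ad_node(a$tp, y, a$id, function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

ad_dropout <- function(a, p) {
  if (!a$tp$training || p <= 0) return(a)
  av <- a$val
  keep <- matrix((stats::runif(length(av)) >= p) / (1 - p), nrow(av), ncol(av))
  ad_node(a$tp, av * keep, a$id, function(g) list(g * keep))
}

ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- a$val
  mu <- rowMeans(av)
  xc <- av - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$val); bv <- as.numeric(beta$val)
  n <- nrow(av)
  val <- xhat * rep(gv, each = n) + rep(bv, each = n)
  ad_node(a$tp, val, c(a$id, gamma$id, beta$id), function(g) {
    dxhat <- g * rep(gv, each = n)
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

# column-wise batch normalization with running statistics kept in `state`
# (an environment): keys <key>.mean / <key>.var.
ad_batchnorm <- function(a, gamma, beta, state, key, momentum = 0.1, eps = 1e-5) {
  av <- a$val
  gv <- as.numeric(gamma$val); bv <- as.numeric(beta$val)
  mk <- paste0(key, ".mean"); vk <- paste0(key, ".var")
  if (is.null(state[[mk]])) {
    state[[mk]] <- rep(0, ncol(av))
    state[[vk]] <- rep(1, ncol(av))
  }
  nb <- nrow(av)
  if (a$tp$training) {
    mu <- colMeans(av)
    xc <- av - rep(mu, each = nb)
    v <- colMeans(xc^2)
    state[[mk]] <- (1 - momentum) * state[[mk]] + momentum * mu
    nb <- nrow(av)
    vu <- if (nb > 1L) v * nb / (nb - 1L) else v
    state[[vk]] <- (1 - momentum) * state[[vk]] + momentum * vu
  } else {
    mu <- state[[mk]]
    v <- state[[vk]]
    xc <- av - rep(mu, each = nb)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = nb)
  val <- xhat * rep(gv, each = nb) + rep(bv, each = nb)
  training <- a$tp$training
  ad_node(a$tp, val, c(a$id, gamma$id, beta$id), function(g) {
    dxhat <- g * rep(gv, each = nb)
    if (training) {
      mdx <- colMeans(dxhat)
      mdxx <- colMeans(dxhat * xhat)
      dx <- (dxhat - rep(mdx, each = nb) - xhat * rep(mdxx, each = nb)) *
        rep(inv, each = nb)
    } else {
      dx <- dxhat * rep(inv, each = nb)
    }
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

# im2col patch extraction: `idx` indexes rows of a (with nrow(a)+1 meaning a
# zero padding row), arranged as k2 consecutive blocks of n_out entries.
# Output is n_out x (k2 * ncol(a)), columns ordered channel-major with kernel
# position fastest (consistent with conv weight layout built by conv_weight_rows).
ad_im2col <- function(a, idx, n_out, k2) {
  av <- a$val
  R <- nrow(av); C <- ncol(av)
  xx <- rbind(av, matrix(0, 1L, C))
  G <- xx[idx, , drop = FALSE]
  dim(G) <- c(n_out, k2 * C)
  ad_node(a$tp, G, a$id, function(g) {
    # scatter-add per kernel-position block: within one block every
    # non-padding index is distinct, so a vectorized indexed add suffices
    # (rowsum over millions of rows would pay for character rownames)
    dim(g) <- c(n_out * k2, C)
    out <- matrix(0, R, C)
    for (kp in seq_len(k2)) {
      rows <- idx[(kp - 1L) * n_out + seq_len(n_out)]
      sel <- rows <= R
      gi <- (kp - 1L) * n_out + which(sel)
      ri <- rows[sel]
      out[ri, ] <- out[ri, , drop = FALSE] + g[gi, , drop = FALSE]
    }
    list(out)
  })
}

# row-wise L2 normalization: y = x / sqrt(sum(x^2) + eps)
ad_l2norm_rows <- function(a, eps = 1e-8) {
  av <- a$val
  n <- sqrt(rowSums(av^2) + eps)
  y <- av / n
  ad_node(a$tp, y, a$id, function(g) {
    list(g / n - y * (rowSums(g * av) / n^2))
  })
}

# plain-value single-image pooling (shared by the tape op and loaders that
# pre-pool constant inputs)
pool_columns <- function(xcols, H, p) {
  h1o <- H %/% p
  out <- vapply(seq_len(ncol(xcols)), function(c) {
    v <- xcols[, c]
    m1 <- colMeans(matrix(v, p, length(v) %/% p))
    ap <- aperm(array(m1, c(h1o, H, 1L)), c(2L, 1L, 3L))
    m2 <- colMeans(matrix(as.vector(ap), p, length(m1) %/% p))
    as.vector(aperm(array(m2, c(h1o, h1o, 1L)), c(2L, 1L, 3L)))
  }, numeric(h1o * h1o))
  if (!is.matrix(out)) out <- matrix(out, ncol = ncol(xcols))
  out
}

# non-overlapping p x p average pooling over spatial rows (b, h2, h1) with
# h1 fastest, via reshapes and colMeans — no grouping tables. Requires
# H1 %% p == 0 and H2 %% p == 0.
ad_pool2d <- function(a, B, H1, H2, p) {
  av <- a$val
  stopifnot(H1 %% p == 0L, H2 %% p == 0L, nrow(av) == B * H1 * H2)
  h1o <- H1 %/% p; h2o <- H2 %/% p
  C <- ncol(av)
  pool_col <- function(v) {
    m1 <- colMeans(matrix(v, p, length(v) %/% p))          # (h1o, h2, b)
    ap <- aperm(array(m1, c(h1o, H2, B)), c(2L, 1L, 3L))   # (h2, h1o, b)
    m2 <- colMeans(matrix(as.vector(ap), p, length(m1) %/% p)) # (h2o, h1o, b)
    as.vector(aperm(array(m2, c(h2o, h1o, B)), c(2L, 1L, 3L)))
  }
  val <- vapply(seq_len(C), function(c) pool_col(av[, c]), numeric(B * h1o * h2o))
  if (!is.matrix(val)) val <- matrix(val, ncol = C)
  ad_node(a$tp, val, a$id, function(g) {
    unpool_col <- function(gv) {
      gp <- aperm(array(gv, c(h1o, h2o, B)), c(2L, 1L, 3L)) # (h2o, h1o, b)
      g2 <- rep(as.vector(gp) / p, each = p)                # (h2, h1o, b)
      gb <- aperm(array(g2, c(H2, h1o, B)), c(2L, 1L, 3L))  # (h1o, h2, b)
      rep(as.vector(gb) / p, each = p)                      # (h1, h2, b)
    }
    gout <- vapply(seq_len(C), function(c) unpool_col(g[, c]),
                   numeric(B * H1 * H2))
    if (!is.matrix(gout)) gout <- matrix(gout, ncol = C)
    list(gout)
  })
}

# masked binary cross-entropy with logits; targets/mask constant matrices.
# Mean over observed entries; 0 (with zero gradient) when nothing observed.
ad_bce_masked <- function(z, targets, mask) {
  zv <- z$val
  nobs <- sum(mask)
  if (nobs == 0) return(ad_scale(ad_sum(ad_mul(z, ad_const(z$tp, mask * 0))), 0))
  sp <- ifelse(zv > 0, zv + log1p(exp(-zv)), log1p(exp(zv)))
  loss <- sum(mask * (sp - targets * zv)) / nobs
  ad_node(z$tp, matrix(loss, 1L, 1L), z$id, function(g) {
    list(as.numeric(g) * mask * (stats::plogis(zv) - targets) / nobs)
  })
}
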