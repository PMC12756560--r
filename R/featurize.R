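# Deterministic modality featurizers: molecular graph, token sequence,
# binned spectrum, and rendered/normalized structure image.

# 43-symbol vocabulary; anything else maps to the trailing "other" slot
ATOM_SYMBOLS <- c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na",
                  "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl", "Yb",
                  "Sb", "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn", "H", "Li",
                  "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn", "Zr", "Cr", "Pt",
                  "Hg", "Pb")
HYBRID_STATES <- c("s", "sp", "sp2", "sp3", "sp3d", "sp3d2", "other")
BOND_TYPES <- c("single", "double", "triple", "aromatic")
N_NODE_FEATURES <- 78L

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_STD <- c(0.229, 0.224, 0.225)

one_hot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Featurize a molecule as an attributed graph
#'
#' Builds the node feature matrix (N x 78), the directed edge index and the
#' bond-type one-hot edge attributes consumed by the graph encoder. The 78
#' node feature slots are: atomic symbol one-hot over a fixed 43-symbol
#' vocabulary plus "other" (44), degree one-hot 0-10 (11), total hydrogen
#' count one-hot 0-10 (11), hybridization one-hot over 7 states (7), formal
#' charge (1), radical electron count (1), aromatic flag (1), in-ring flag
#' (1) and chiral-center flag (1). Every undirected bond contributes two
#' adjacent directed edges. Indices are 1-based, as is idiomatic in R.
#'
#' @param mol a `moltitox_mol` handle.
#' @return a list with `node_features` (N x 78), `edge_index` (2 x 2B) and
#'   `edge_attr` (2B x 4, rows summing to 1).
#' @export
featurize_graph <- function(mol) {
  stopifnot(inherits(mol, "moltitox_mol"))
  n <- mol$n_atoms
  if (n < 1L) stopf("featurize_graph: molecule has no heavy atoms")
  sym_idx <- match(mol$symbol, ATOM_SYMBOLS)
  n_other <- sum(is.na(sym_idx))
  if (n_other > 0L) {
    mt_log(sprintf("%d atom(s) outside the symbol vocabulary -> 'other'", n_other))
  }
  sym_idx[is.na(sym_idx)] <- length(ATOM_SYMBOLS) + 1L
  hyb_idx <- match(mol$hybrid, HYBRID_STATES)
  hyb_idx[is.na(hyb_idx)] <- length(HYBRID_STATES)
  X <- cbind(
    one_hot(sym_idx, length(ATOM_SYMBOLS) + 1L),
    one_hot(pmin(mol$degree, 10L) + 1L, 11L),
    one_hot(pmin(mol$n_h, 10L) + 1L, 11L),
    one_hot(hyb_idx, length(HYBRID_STATES)),
    mol$charge,
    mol$radical,
    as.numeric(mol$aromatic),
    as.numeric(mol$in_ring),
    as.numeric(mol$chiral)
  )
  stopifnot(ncol(X) == N_NODE_FEATURES)

  bonds <- mol$bonds
  nb <- nrow(bonds)
  if (nb == 0L) {
    return(list(node_features = X,
                edge_index = matrix(integer(0), 2L, 0L),
                edge_attr = matrix(0, 0L, 4L)))
  }
  btype <- integer(nb)
  for (j in seq_len(nb)) {
    if (mol$bond_aromatic[j]) {
      btype[j] <- 4L
    } else if (bonds$order[j] %in% 1:3) {
      btype[j] <- bonds$order[j]
    } else {
      stopf("featurize_graph: unknown bond order %d (corrupt input)",
            bonds$order[j])
    }
  }
  # both directions of each bond, adjacent in the edge list
  ei <- matrix(0L, 2L, 2L * nb)
  ei[1L, ] <- as.integer(rbind(bonds$a1, bonds$a2))
  ei[2L, ] <- as.integer(rbind(bonds$a2, bonds$a1))
  ea <- one_hot(rep(btype, each = 2L), 4L)
  list(node_features = X, edge_index = ei, edge_attr = ea)
}

# ---- SMILES tokenization ---------------------------------------------------

SMILES_TOKEN_RE <- "\\[[^\\]]*\\]|Br|Cl|%\\d{2}|."

smiles_tokens <- function(smiles) {
  regmatches(smiles, gregexpr(SMILES_TOKEN_RE, smiles, perl = TRUE))[[1]]
}

#' Build a SMILES token vocabulary from a corpus
#'
#' Tokenizes with a regex in which bracket atoms, two-character element
#' symbols and two-digit ring-closure labels are single tokens. The pad token
#' gets id 1 and the unknown token id 2.
#'
#' @param smiles_vec character vector of SMILES strings (typically the
#'   training split only, to avoid leakage).
#' @param max_len maximum sequence length (default 202).
#' @return a vocabulary object for [tokenize_smiles()].
#' @export
build_vocab <- function(smiles_vec, max_len = 202L) {
  toks <- sort(unique(unlist(lapply(smiles_vec, smiles_tokens))),
               method = "radix")   # locale-independent token order
  ids <- stats::setNames(seq_along(toks) + 2L, toks)
  structure(list(ids = ids, pad_id = 1L, unk_id = 2L,
                 size = length(toks) + 2L, max_len = as.integer(max_len)),
            class = "moltitox_vocab")
}

#' Tokenize a SMILES string to a fixed-length id sequence
#'
#' Sequences longer than `vocab$max_len` are truncated; shorter ones are
#' padded. The mask is a prefix of ones marking real tokens. Unknown tokens
#' map to the unknown id and are counted, never raised as errors.
#'
#' @param smiles a SMILES string.
#' @param vocab a vocabulary from [build_vocab()].
#' @return a list with integer `ids` and `mask` of length `vocab$max_len`,
#'   plus `n_real` and `n_unknown`.
#' @export
tokenize_smiles <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "moltitox_vocab"))
  toks <- smiles_tokens(smiles)
  if (length(toks) == 0L) stopf("tokenize_smiles: empty SMILES")
  if (length(toks) > vocab$max_len) toks <- toks[seq_len(vocab$max_len)]
  ids <- unname(vocab$ids[toks])
  n_unk <- sum(is.na(ids))
  if (n_unk > 0L) mt_log(sprintf("%d unknown token(s) in '%s'", n_unk, smiles))
  ids[is.na(ids)] <- vocab$unk_id
  n <- length(ids)
  out_ids <- rep(vocab$pad_id, vocab$max_len)
  out_ids[seq_len(n)] <- ids
  mask <- rep(0L, vocab$max_len)
  mask[seq_len(n)] <- 1L
  list(ids = as.integer(out_ids), mask = mask, n_real = n, n_unknown = n_unk)
}

# ---- spectrum binning ------------------------------------------------------

#' Default chemical-shift bin grid
#'
#' 1 ppm bins over the half-open interval \[-20, 240) ppm: 260 bins covering
#' the usual carbon-13 shift range (aromatic carbons around 110-150 ppm,
#' carbonyls around 160-220 ppm).
#'
#' @param lo,hi grid limits in ppm.
#' @param width bin width in ppm.
#' @export
spectrum_grid <- function(lo = -20, hi = 240, width = 1) {
  nb <- as.integer(floor((hi - lo) / width))
  stopifnot(nb >= 1L)
  list(lo = lo, hi = hi, width = width, n_bins = nb)
}

#' Discretize a carbon-13 peak list to a binary bin vector
#'
#' Bit b (0-based) is set iff some peak falls in `[lo + b*width,
#' lo + (b+1)*width)`. Out-of-range peaks clamp to the boundary bins and are
#' logged; peak multiplicity within a bin is ignored.
#'
#' @param peaks numeric vector of chemical shifts (ppm); must be non-empty
#'   and finite (an empty list is an error: absent spectra take the
#'   missing-modality path instead).
#' @param grid a grid from [spectrum_grid()].
#' @return integer 0/1 vector of length `grid$n_bins`.
#' @export
bin_spectrum <- function(peaks, grid = spectrum_grid()) {
  if (length(peaks) == 0L) {
    stopf("bin_spectrum: empty peak list (use the missing-modality path)")
  }
  if (!all(is.finite(peaks))) stopf("bin_spectrum: non-finite peak")
  idx <- floor((peaks - grid$lo) / grid$width)
  n_clamp <- sum(idx < 0 | idx >= grid$n_bins)
  if (n_clamp > 0L) mt_log(sprintf("%d peak(s) clamped to boundary bins", n_clamp))
  idx <- pmax(0, pmin(grid$n_bins - 1L, idx))
  bits <- integer(grid$n_bins)
  bits[unique(as.integer(idx)) + 1L] <- 1L
  bits
}

# ---- image rendering -------------------------------------------------------

ELEMENT_COLORS <- list(
  N = c(0.10, 0.10, 0.90), O = c(0.90, 0.10, 0.10), S = c(0.80, 0.70, 0.05),
  F = c(0.10, 0.75, 0.25), Cl = c(0.10, 0.60, 0.10), Br = c(0.60, 0.25, 0.05),
  I = c(0.45, 0.05, 0.65), P = c(0.95, 0.55, 0.05)
)

# pixel accumulators: drawing collects (y, x, r, g, b) rows; the raster is
# painted in one vectorized assignment at the end (later rows win)
line_pixels <- function(x0, y0, x1, y1, col, size) {
  len <- max(abs(x1 - x0), abs(y1 - y0), 1)
  ts <- seq(0, 1, length.out = max(2L, ceiling(2 * len)))
  xs <- round(x0 + ts * (x1 - x0))
  ys <- round(y0 + ts * (y1 - y0))
  keep <- xs >= 1 & xs <= size & ys >= 1 & ys <= size
  if (!any(keep)) return(NULL)
  cbind(ys[keep], xs[keep], col[1], col[2], col[3])
}

disk_pixels <- function(x, y, r, col, size) {
  xs <- max(1L, floor(x - r)):min(size, ceiling(x + r))
  ys <- max(1L, floor(y - r)):min(size, ceiling(y + r))
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  keep <- (gx - x)^2 + (gy - y)^2 <= r^2
  if (!any(keep)) return(NULL)
  cbind(gy[keep], gx[keep], col[1], col[2], col[3])
}

paint_pixels <- function(img, px) {
  if (is.null(px) || nrow(px) == 0L) return(img)
  for (c in 1:3) img[cbind(px[, 1], px[, 2], c)] <- px[, 2 + c]
  img
}

#' Render a 2D structure depiction
#'
#' Rasterizes the molecule's 2D coordinates into a white-background RGB
#' image: bonds as black line segments (double/triple bonds as parallel
#' lines, using the kekulized bond orders), heteroatoms as element-colored
#' disks. The rendering is deterministic. When `cache_dir` and `cache_key`
#' are supplied the raster is cached to `<cache_dir>/<cache_key>.png` and
#' re-read on subsequent calls.
#'
#' @param mol a `moltitox_mol` handle.
#' @param size image side in pixels (default 224).
#' @param cache_dir optional PNG cache directory.
#' @param cache_key optional file stem used for caching (e.g. a record id).
#' @return numeric array `size x size x 3` with values in \[0, 1\].
#' @export
render_image <- function(mol, size = 224L, cache_dir = NULL, cache_key = NULL) {
  stopifnot(inherits(mol, "moltitox_mol"))
  cache_file <- NULL
  if (!is.null(cache_dir) && !is.null(cache_key)) {
    cache_file <- file.path(cache_dir, paste0(cache_key, ".png"))
    if (file.exists(cache_file)) return(png::readPNG(cache_file)[, , 1:3])
  }
  img <- array(1, c(size, size, 3L))
  xy <- mol$coords
  pad <- round(size * 0.09)
  rngx <- range(xy[, 1]); rngy <- range(xy[, 2])
  span <- max(rngx[2] - rngx[1], rngy[2] - rngy[1], 1e-9)
  sc <- (size - 2 * pad) / span
  px <- pad + (xy[, 1] - mean(rngx)) * sc + (size - 2 * pad) / 2
  py <- pad + (mean(rngy) - xy[, 2]) * sc + (size - 2 * pad) / 2
  black <- c(0, 0, 0)
  pixels <- list()
  if (nrow(mol$bonds) > 0L) {
    for (j in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[j]; b <- mol$bonds$a2[j]
      dx <- px[b] - px[a]; dy <- py[b] - py[a]
      nrm <- sqrt(dx^2 + dy^2) + 1e-9
      ox <- -dy / nrm * 2.2; oy <- dx / nrm * 2.2
      offs <- switch(mol$bonds$order[j], `1` = 0, `2` = c(-1, 1),
                     `3` = c(-1, 0, 1), 0)
      for (o in offs) {
        pixels[[length(pixels) + 1L]] <-
          line_pixels(px[a] + o * ox, py[a] + o * oy,
                      px[b] + o * ox, py[b] + o * oy, black, size)
      }
    }
  }
  for (i in seq_len(mol$n_atoms)) {
    col <- ELEMENT_COLORS[[mol$symbol[i]]]
    if (is.null(col) && mol$symbol[i] != "C") col <- c(0.45, 0.45, 0.45)
    if (!is.null(col)) {
      pixels[[length(pixels) + 1L]] <- disk_pixels(px[i], py[i], 4.2, col, size)
    }
  }
  if (mol$n_atoms == 1L) {
    pixels[[length(pixels) + 1L]] <- disk_pixels(px[1], py[1], 4.2, black, size)
  }
  img <- paint_pixels(img, do.call(rbind, pixels))
  if (!is.null(cache_file)) {
    dir.create(dirname(cache_file), showWarnings = FALSE, recursive = TRUE)
    png::writePNG(img, cache_file)
    img <- png::readPNG(cache_file)[, , 1:3]   # quantized, as later reads see it
  }
  img
}

.rotation_grid_cache <- new.env(parent = emptyenv())

rotate_raster <- function(img, theta) {
  size <- dim(img)[1]
  key <- as.character(size)
  gr <- .rotation_grid_cache[[key]]
  if (is.null(gr)) {
    gr <- list(y = rep(seq_len(size), times = size),
               x = rep(seq_len(size), each = size))
    .rotation_grid_cache[[key]] <- gr
  }
  ct <- (size + 1) / 2
  cosz <- cos(-theta); sinz <- sin(-theta)
  sx <- round(ct + cosz * (gr$x - ct) - sinz * (gr$y - ct))
  sy <- round(ct + sinz * (gr$x - ct) + cosz * (gr$y - ct))
  ok <- sx >= 1 & sx <= size & sy >= 1 & sy <= size
  lin <- (sx - 1L) * size + sy           # column-major index into a channel
  out <- array(1, dim(img))
  n2 <- size * size
  for (c in 1:3) {
    ch <- img[, , c]
    dst <- rep(1, n2)
    dst[ok] <- ch[lin[ok]]
    out[, , c] <- dst
  }
  out
}

#' Normalize (and optionally augment) a structure image
#'
#' With `augment = TRUE`, applies a random horizontal flip (p = 0.5), a
#' rotation uniform in +/-15 degrees (nearest-neighbour, white fill) and
#' random grayscaling (p = 0.2), drawing randomness from the current RNG
#' stream; with `augment = FALSE` the input passes through unchanged. Pixels
#' are then standardized per channel with the ImageNet mean
#' (0.485, 0.456, 0.406) and standard deviation (0.229, 0.224, 0.225).
#'
#' @param raster `H x W x 3` array with values in \[0, 1\].
#' @param augment logical; augmentation is for training only.
#' @return channels-first numeric array `3 x H x W`.
#' @export
normalize_image <- function(raster, augment = FALSE) {
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3] == 3L)
  if (isTRUE(augment)) raster <- augment_raster(raster)
  out <- array(0, c(3L, dim(raster)[1], dim(raster)[2]))
  for (c in 1:3) out[c, , ] <- (raster[, , c] - IMAGENET_MEAN[c]) / IMAGENET_STD[c]
  out
}

augment_raster <- function(raster) {
  if (stats::runif(1) < 0.5) raster <- raster[, rev(seq_len(dim(raster)[2])), ]
  theta <- stats::runif(1, -15, 15) * pi / 180
  raster <- rotate_raster(raster, theta)
  if (stats::runif(1) < 0.2) {
    g <- 0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
    raster <- array(rep(g, 3L), dim(raster))
  }
  raster
}

# batch-assembly fast path: raster -> normalized channel columns in
# column-major (y-fastest) order, skipping the channels-first intermediate
raster_to_columns <- function(raster, augment = FALSE) {
  if (isTRUE(augment)) raster <- augment_raster(raster)
  cbind((as.vector(raster[, , 1]) - IMAGENET_MEAN[1]) / IMAGENET_STD[1],
        (as.vector(raster[, , 2]) - IMAGENET_MEAN[2]) / IMAGENET_STD[2],
        (as.vector(raster[, , 3]) - IMAGENET_MEAN[3]) / IMAGENET_STD[3])
}

#' Invert the per-channel image normalization
#'
#' @param tensor channels-first `3 x H x W` array from [normalize_image()].
#' @return `H x W x 3` raster with pixels on the original \[0, 1\] scale.
#' @export
denormalize_image <- function(tensor) {
  stopifnot(length(dim(tensor)) == 3L, dim(tensor)[1] == 3L)
  out <- array(0, c(dim(tensor)[2], dim(tensor)[3], 3L))
  for (c in 1:3) out[, , c] <- tensor[c, , ] * IMAGENET_STD[c] + IMAGENET_MEAN[c]
  out
}
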