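# Parsing, validation and the four deterministic featurizers.

test_that("parse_and_validate accepts valid structures and rejects broken SMILES", {
  m <- parse_and_validate("CCO")
  expect_s3_class(m, "moltitox_mol")
  expect_identical(m$n_atoms, 3L)
  fig <- parse_and_validate("Oc1c(I)cc(Cl)c2cccnc12")  # halogenated quinolinol
  expect_s3_class(fig, "moltitox_mol")
  expect_identical(fig$n_atoms, 13L)
  expect_true(any(fig$aromatic))
  expect_null(parse_and_validate("C1CC"))   # unclosed ring
  expect_null(parse_and_validate(""))
  expect_null(parse_and_validate("not a molecule"))
  # single heavy atom is valid
  methane <- parse_and_validate("C")
  expect_identical(methane$n_atoms, 1L)
  expect_identical(methane$n_h, 4L)
})

test_that("graph featurization follows the 78-slot layout and edge conventions", {
  g1 <- featurize_graph(parse_and_validate("C"))
  expect_identical(dim(g1$node_features), c(1L, 78L))
  expect_identical(dim(g1$edge_index), c(2L, 0L))

  g <- featurize_graph(parse_and_validate("CCO"))
  expect_identical(dim(g$node_features), c(3L, 78L))
  expect_identical(dim(g$edge_index), c(2L, 4L))        # 2 bonds -> 4 directed
  expect_identical(dim(g$edge_attr), c(4L, 4L))
  expect_true(all(g$edge_attr[, 1] == 1))               # all single bonds
  expect_true(all(rowSums(g$edge_attr) == 1))
  # the two directions of each bond are adjacent and mutually reversed
  for (j in seq(1L, ncol(g$edge_index), by = 2L)) {
    expect_identical(g$edge_index[, j], rev(g$edge_index[, j + 1L]))
  }

  b <- featurize_graph(parse_and_validate("c1ccccc1"))
  expect_identical(ncol(b$edge_index), 12L)             # 6 aromatic bonds
  expect_true(all(b$edge_attr[, 4] == 1))               # all aromatic one-hot
  arom_col <- 44L + 11L + 11L + 7L + 2L + 1L            # aromatic flag slot
  expect_true(all(b$node_features[, arom_col] == 1))
})

test_that("SMILES tokenization pads, truncates and masks consistently", {
  vocab <- build_vocab(c("CCO", "c1ccccc1", "CC(=O)N", "[nH]1cccc1"))
  t1 <- tokenize_smiles("CCO", vocab)
  expect_identical(sum(t1$mask), 3L)
  expect_true(all(t1$ids[4:202] == vocab$pad_id))
  expect_length(t1$ids, 202L)
  # bracket atoms are single tokens
  expect_identical(moltitox:::smiles_tokens("[nH]"), "[nH]")
  expect_identical(moltitox:::smiles_tokens("CCl"), c("C", "Cl"))
  expect_identical(sum(tokenize_smiles("[nH]", vocab)$mask), 1L)
  # truncation bound
  long <- paste(rep("C", 300L), collapse = "")
  expect_identical(sum(tokenize_smiles(long, vocab)$mask), 202L)
  # unknown tokens counted, not fatal
  t2 <- tokenize_smiles("CSi", vocab)
  expect_gt(t2$n_unknown, 0L)
})

test_that("token mask equals a ones-prefix and pads fill the tail on random strings", {
  pool <- c("C", "N", "O", "c1ccccc1", "Cl", "(", ")", "=O", "CC")
  vocab <- build_vocab(pool)
  set.seed(4)
  for (i in 1:200) {
    smi <- paste(sample(c("C", "N", "O", "Cl", "CC"), sample(1:40, 1),
                        replace = TRUE), collapse = "")
    tk <- tokenize_smiles(smi, vocab)
    n <- tk$n_real
    expect_identical(tk$mask, c(rep(1L, n), rep(0L, 202L - n)))
    expect_true(all(tk$ids[tk$mask == 0L] == vocab$pad_id))
    expect_true(all(tk$ids[tk$mask == 1L] != vocab$pad_id))
  }
})

test_that("spectrum binning sets the documented bins, collapses and clamps", {
  bits <- bin_spectrum(c(128.5, 170.2))
  expect_identical(which(bits == 1L) - 1L, c(148L, 190L))  # offset +20
  expect_identical(sum(bits), 2L)
  expect_identical(sum(bin_spectrum(c(10.0, 10.4))), 1L)   # same-bin collapse
  expect_identical(which(bin_spectrum(-100) == 1L), 1L)    # clamp to bin 0
  expect_identical(which(bin_spectrum(1000) == 1L), 260L)
  expect_error(bin_spectrum(numeric(0)), "missing-modality")
  # popcount never exceeds the peak count
  set.seed(5)
  for (i in 1:50) {
    pk <- runif(sample(1:20, 1), -30, 250)
    expect_lte(sum(bin_spectrum(pk)), length(pk))
  }
  # equality when peaks land in distinct in-range bins
  pk <- c(10.5, 50.5, 100.5, 199.5)
  expect_identical(sum(bin_spectrum(pk)), 4L)
})

test_that("image normalization matches the stated channel statistics and inverts", {
  const <- array(0, c(8L, 8L, 3L))
  const[, , 1] <- 0.485; const[, , 2] <- 0.456; const[, , 3] <- 0.406
  expect_equal(max(abs(normalize_image(const))), 0, tolerance = 1e-12)
  white <- array(1, c(8L, 8L, 3L))
  wt <- normalize_image(white)
  expect_equal(wt[1, 1, 1], (1 - 0.485) / 0.229, tolerance = 1e-6)
  expect_identical(normalize_image(white), normalize_image(white))
  set.seed(6)
  img <- array(runif(8 * 8 * 3), c(8L, 8L, 3L))
  expect_equal(denormalize_image(normalize_image(img)), img,
               tolerance = 1e-6)
})

test_that("augmentation draws from the RNG stream and keeps shape", {
  set.seed(7)
  img <- array(runif(16 * 16 * 3), c(16L, 16L, 3L))
  a1 <- with_seed(1L, normalize_image(img, augment = TRUE))
  a2 <- with_seed(1L, normalize_image(img, augment = TRUE))
  a3 <- with_seed(2L, normalize_image(img, augment = TRUE))
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  expect_identical(dim(a1), c(3L, 16L, 16L))
})

test_that("rendering is deterministic, mostly white, and structure-sensitive", {
  ccO <- parse_and_validate("CCO")
  r1 <- render_image(ccO)
  expect_identical(dim(r1), c(224L, 224L, 3L))
  white <- r1[, , 1] == 1 & r1[, , 2] == 1 & r1[, , 3] == 1
  expect_gt(mean(white), 0.99)
  expect_identical(r1, render_image(parse_and_validate("CCO")))
  benzene <- render_image(parse_and_validate("c1ccccc1"))
  expect_false(identical(r1, benzene))
})

test_that("load_dataset drops invalid rows, joins spectra first-match-wins, and decodes -1", {
  dir <- withr::local_tempdir()
  df <- data.frame(id = paste0("m", 1:5),
                   smiles = c("CCO", "C1CC", "c1ccccc1", "CCN", "CC(=O)O"))
  for (ep in moltitox:::TOX21_ENDPOINTS) df[[ep]] <- c(1, 0, -1, "", 1)
  csv <- file.path(dir, "compounds.csv")
  write.csv(df, csv, row.names = FALSE)
  pk1 <- file.path(dir, "p1.json")
  pk2 <- file.path(dir, "p2.json")
  jsonlite::write_json(list(m1 = c(15, 60), m4 = c(40)), pk1)
  jsonlite::write_json(list(m1 = c(999), m3 = c(128)), pk2)
  ds <- load_dataset(csv, peaks_files = c(pk1, pk2))
  expect_identical(ds$summary$n_valid, 4L)       # C1CC dropped
  expect_identical(ds$summary$n_dropped, 1L)
  rec <- ds$records[[which(vapply(ds$records, `[[`, "", "id") == "m1")]]
  expect_identical(rec$peaks, c(15, 60))          # first source wins
  expect_true(all(is.na(ds$records[[2]]$labels))) # -1 -> missing
  expect_true(is.na(ds$records[[3]]$labels[1]))   # empty cell -> missing
  # duplicate ids and out-of-range labels are hard errors
  df2 <- df; df2$id <- rep("dup", 5)
  csv2 <- file.path(dir, "dup.csv"); write.csv(df2, csv2, row.names = FALSE)
  expect_error(load_dataset(csv2), "duplicate")
  df3 <- df; df3[["NR-AR"]] <- c(2, 0, 1, 0, 1)
  csv3 <- file.path(dir, "bad.csv"); write.csv(df3, csv3, row.names = FALSE)
  expect_error(load_dataset(csv3), "label")
})

test_that("featurizers are deterministic across repeated calls", {
  for (smi in c("CCO", "c1ccc(Cl)cc1", "CC(=O)N")) {
    m <- parse_and_validate(smi)
    expect_identical(featurize_graph(m), featurize_graph(m))
    v <- build_vocab(smi)
    expect_identical(tokenize_smiles(smi, v), tokenize_smiles(smi, v))
  }
  expect_identical(bin_spectrum(c(12, 100.7)), bin_spectrum(c(12, 100.7)))
})
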