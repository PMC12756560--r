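# Scaffold splitting, ROC-AUC, threshold metrics, paired tests and the
# ablation bookkeeping.

test_that("Bemis-Murcko scaffolds strip side chains and pool acyclic molecules", {
  expect_identical(bemis_murcko_scaffold(parse_and_validate("c1ccccc1CCN")),
                   "c1ccccc1")
  expect_identical(bemis_murcko_scaffold(parse_and_validate("CCO")), "")
  s1 <- bemis_murcko_scaffold(parse_and_validate("c1ccccc1"))
  s2 <- bemis_murcko_scaffold(parse_and_validate("Cc1ccccc1C"))
  expect_identical(s1, s2)   # same scaffold group
  s3 <- bemis_murcko_scaffold(parse_and_validate("CCc1ccncc1"))
  expect_false(identical(s1, s3))
})

fake_records <- function(smiles) {
  lapply(seq_along(smiles), function(i) {
    list(id = sprintf("f%03d", i), smiles = smiles[i],
         mol = parse_and_validate(smiles[i]),
         labels = rep(NA_integer_, 12), peaks = NULL, image_path = NULL)
  })
}

test_that("ten singleton scaffolds split exactly 8:1:1 and groups never split", {
  smis <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "c1ccc2ccccc2c1",
            "C1CCOC1", "C1CCNC1", "c1ccsc1", "c1cc[nH]c1", "C1CCCC1",
            "C1CCOCC1")
  recs <- fake_records(smis)
  recs <- recs[!vapply(recs, function(r) is.null(r$mol), TRUE)]
  skip_if(length(recs) < 10L, "not all ring systems parsed")
  for (seed in 0:3) {
    sp <- scaffold_split(recs, seed = seed)
    expect_identical(lengths(list(sp$train, sp$valid, sp$test)),
                     c(8L, 1L, 1L), ignore_attr = TRUE)
  }
  # co-partitioning: two molecules sharing a scaffold stay together
  recs2 <- fake_records(c(smis, "Cc1ccccc1", "CCc1ccccc1"))
  for (seed in 0:5) {
    sp <- scaffold_split(recs2, seed = seed)
    benz <- sp$partition_of[c("f001", "f011", "f012")]
    expect_identical(length(unique(benz)), 1L)
  }
  expect_error(scaffold_split(fake_records(c("c1ccccc1", "Cc1ccccc1")),
                              seed = 0), ">= 3")
})

test_that("scaffold sets of train/valid/test are pairwise disjoint", {
  fix <- tiny_benchmark(n = 80L, seed = 19L)
  for (seed in 0:2) {
    sp <- scaffold_split(fix$ds, seed = seed)
    sc <- function(ids) unique(sp$scaffold_of[ids])
    expect_length(intersect(sc(sp$train), sc(sp$valid)), 0L)
    expect_length(intersect(sc(sp$train), sc(sp$test)), 0L)
    expect_length(intersect(sc(sp$valid), sc(sp$test)), 0L)
    expect_identical(sort(c(sp$train, sp$valid, sp$test)),
                     sort(names(sp$partition_of)))
  }
  # the size-sorted deterministic variant also satisfies the invariant
  sp <- scaffold_split(fix$ds, seed = 0, size_sorted = TRUE)
  expect_length(intersect(unique(sp$scaffold_of[sp$train]),
                          unique(sp$scaffold_of[sp$test])), 0L)
})

test_that("roc_auc equals the O(n^2) pairwise oracle exactly", {
  pair_oracle <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  expect_identical(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_identical(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_true(is.na(roc_auc(c(0.5, 0.7), c(1, 1))))
  set.seed(61)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    l <- rbinom(n, 1, 0.4)
    expect_identical(roc_auc(s, l), pair_oracle(s, l))
  }
})

test_that("threshold metrics reproduce confusion-matrix arithmetic", {
  # TP=2, FP=1, TN=6, FN=1
  scores <- c(0.9, 0.8, 0.6, 0.4, rep(0.2, 6))
  labels <- c(1, 1, 0, 1, rep(0, 6))
  m <- threshold_metrics(scores, labels)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_equal(m$accuracy, 0.8)
  # perfect predictions
  mp <- threshold_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(mp$kappa, 1)
  expect_equal(mp$mcc, 1)
  # constant majority-class predictions give kappa 0
  mc <- threshold_metrics(rep(0.1, 10), c(rep(0, 8), 1, 1))
  expect_equal(mc$kappa, 0)
})

test_that("paired t-test matches the closed form and handles degeneracies", {
  a <- c(0.5, -0.3, 0.8, 0.2, -0.1)
  b <- rep(0, 5)
  r <- paired_t_test(a, b)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(r$t, tstat, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(tstat), df = 4), tolerance = 1e-12)
  expect_identical(paired_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_warning(rz <- paired_t_test(c(2, 2, 2), c(1, 1, 1)), "zero-variance")
  expect_identical(rz$p_value, 0)
})

test_that("macro AUC is invariant to endpoint ordering and skips one-class endpoints", {
  set.seed(62)
  scores <- matrix(rnorm(60), 10, 6)
  labels <- matrix(rbinom(60, 1, 0.5), 10, 6)
  labels[, 6] <- 1   # degenerate endpoint
  m1 <- moltitox:::macro_auc(scores, labels)
  perm <- c(3, 1, 6, 2, 5, 4)
  m2 <- moltitox:::macro_auc(scores[, perm], labels[, perm])
  expect_equal(m1$macro, m2$macro, tolerance = 1e-12)
  expect_true(is.na(m1$per_task[6]))
})

test_that("the full ablation grid enumerates 12 model rows", {
  subsets <- moltitox:::modality_subsets("full")
  expect_length(subsets, 12L)   # C(4,1) + C(4,2) + triple + quad
  labels <- vapply(subsets, moltitox:::subset_label, "")
  expect_identical(sum(lengths(subsets) == 1L), 4L)
  expect_identical(sum(lengths(subsets) == 2L), 6L)
  expect_true("graph+smiles+image" %in% labels)
  expect_true("graph+smiles+image+spectrum" %in% labels)
  expect_identical(format_mean_sd(0.831, 0.023), "0.831±0.023")
})

test_that("benchmark_matrix bookkeeping: 12 endpoint AUCs plus macro per cell", {
  fix <- tiny_benchmark(n = 48L, seed = 3L)
  profile <- benchmark_profile("small", seed = 0L)
  profile$enc_cfgs$graph <- small_graph_cfg()
  profile$enc_train <- train_config("encoder", max_epochs = 2L, patience = 1L)
  profile$fus_train <- train_config("fusion", max_epochs = 2L, patience = 1L)
  profile$d_e <- 16L; profile$n_heads <- 2L
  rep1 <- benchmark_matrix(fix$ds, seeds = 0L, subsets = list("graph"),
                           profile = profile)
  cell <- rep1$per_run[rep1$per_run$model == "graph", ]
  expect_identical(nrow(cell), 13L)   # 12 endpoints + .macro
  macro_row <- cell$auc[cell$endpoint == ".macro"]
  expect_equal(macro_row, mean(cell$auc[cell$endpoint != ".macro"],
                               na.rm = TRUE), tolerance = 1e-12)
  expect_identical(nrow(rep1$summary), 1L)
})

test_that("circular fingerprints are deterministic and structure-sensitive", {
  mols <- lapply(c("c1ccccc1", "c1ccncc1", "CCO"), parse_and_validate)
  fp <- export_fingerprints(mols)
  expect_identical(dim(fp), c(3L, 2048L))
  expect_identical(fp, export_fingerprints(mols))
  expect_false(identical(fp[1, ], fp[2, ]))
  expect_true(all(fp %in% c(0L, 1L)))
})
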