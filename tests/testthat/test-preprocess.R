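make_qc_matrix <- function() {
  # 500 genes incl. 10 mitochondrial; four hand-crafted cells:
  #   ok:       300 detected genes, low mito
  #   sparse:   150 detected genes
  #   mito20:   300 detected genes, 20% mito counts
  #   boundary: exactly 200 detected genes
  n_genes <- 500L
  ids <- c(sprintf("MT-%02d", 1:10), sprintf("g%03d", 1:490))
  m <- matrix(0L, n_genes, 4,
              dimnames = list(ids, c("ok", "sparse", "mito20", "boundary")))
  m[11:310, "ok"] <- 2L
  m[1, "ok"] <- 6L # mito ~1%
  m[11:160, "sparse"] <- 3L
  m[11:309, "mito20"] <- 2L
  m[1, "mito20"] <- 150L # 150 / 750 = 20% mito, 300 detected
  m[11:210, "boundary"] <- 1L
  expression_matrix(m, "counts")
}

test_that("qc_filter applies the detected-gene and mito rules", {
  em <- make_qc_matrix()
  kept <- qc_filter(em)
  report <- attr(kept, "qc_report")
  expect_setequal(samples(kept), c("ok", "boundary"))
  expect_equal(report$reason[report$cell == "sparse"], "too_few_genes")
  expect_equal(report$reason[report$cell == "mito20"], "high_mito")
  # bounds inclusive on detected genes, strict on mito fraction
  expect_true("boundary" %in% samples(kept))
  mito15 <- em
  mito15$values[1, "mito20"] <- 106L # 106/706 > 15%? => 0.1501...
  expect_false("mito20" %in% samples(qc_filter(mito15)))

  expect_error(qc_filter(em[, character(0)]), "empty")
})

test_that("qc_filter is idempotent and errors when nothing survives", {
  sc <- generate_single_cell(tiny_sc_config(seed = 3))
  once <- qc_filter(sc$matrix)
  twice <- qc_filter(once)
  expect_identical(once$values, twice$values)

  em <- make_qc_matrix()
  strict <- qc_thresholds(min_genes_per_cell = 450, max_genes_per_cell = 460)
  expect_error(qc_filter(em, strict), "binding threshold: too_few_genes")
})

test_that("lognormalize matches the hand-computed formula", {
  m <- matrix(c(5L, 0L), 2, 1, dimnames = list(c("a", "b"), "c1"))
  norm <- lognormalize(expression_matrix(m, "counts"))
  expect_equal(norm$values["a", "c1"], log(1 + 1e4))
  expect_equal(norm$values["b", "c1"], 0)
  expect_equal(norm$layer, "lognorm")

  # per-cell expm1 totals return the scale factor exactly
  sc <- counts_em(with_seed(8, matrix(stats::rpois(600, 3L), 30, 20)))
  norm2 <- lognormalize(sc)
  totals <- colSums(expm1(norm2$values))
  expect_equal(unname(totals), rep(1e4, 20), tolerance = 1e-6)

  # values follow their columns under sample reordering
  perm <- sample(20)
  norm_perm <- lognormalize(sc[, perm])
  expect_equal(norm_perm$values, norm2$values[, perm])

  zero <- counts_em(matrix(c(1L, 0L), 1, 2))
  expect_error(lognormalize(zero), "zero-sum")
})

test_that("tpm_log2 reproduces hand computations and normalizes to 1e6", {
  m <- matrix(c(10L, 20L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  out <- tpm_log2(expression_matrix(m, "counts"), gene_lengths_kb = c(1, 2))
  tpm <- attr(out, "tpm")
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))
  expect_equal(out$values["a", "s1"], log2(5e5 + 1))

  m2 <- with_seed(2, matrix(stats::rpois(50, 8L), 10, 5))
  out2 <- tpm_log2(counts_em(m2), gene_lengths_kb = runif(10, 0.5, 3))
  expect_equal(unname(colSums(attr(out2, "tpm"))), rep(1e6, 5))

  single <- counts_em(matrix(7L, 1, 2))
  expect_message(out3 <- tpm_log2(single), "1 kb")
  expect_equal(unname(attr(out3, "tpm")[1, ]), c(1e6, 1e6))

  expect_error(tpm_log2(counts_em(m2), gene_lengths_kb = c(-1, runif(9))),
               "positive")
})

test_that("select_hvg returns the requested count of variable genes", {
  em <- random_em(2500, 25, seed = 5)
  hv <- select_hvg(em, n_top = 2000)
  expect_length(hv$genes, 2000L)

  # constant gene never selected while positive-variance genes remain
  m <- em$values[1:100, ]
  m[1, ] <- 7
  em2 <- expression_matrix(m, "lognorm")
  hv2 <- select_hvg(em2, n_top = 99)
  expect_false(rownames(m)[1] %in% hv2$genes)
  # n_top beyond the gene count returns every positive-variance gene
  hv3 <- select_hvg(em2, n_top = 500)
  expect_length(hv3$genes, 99L)

  expect_error(select_hvg(random_em(10, 1)), "2 samples")
})

test_that("scale_and_pca is deterministic and matches eigendecomposition", {
  # rank-1 structure: first component dominates
  f <- with_seed(3, stats::rnorm(40))
  m <- outer(stats::rnorm(20, sd = 2), f) +
    matrix(stats::rnorm(800, sd = 1e-4), 20, 40)
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:40))
  em <- expression_matrix(m, "lognorm")
  p <- scale_and_pca(em, n_pcs = 3)
  expect_gt(p$sdev[1]^2 / sum(apply(p$scores, 2, var)), 0.999)

  p2 <- scale_and_pca(em, n_pcs = 3)
  expect_identical(p$scores, p2$scores)

  # score variances equal the eigenvalues of the gene-gene covariance
  em5 <- random_em(5, 30, seed = 9)
  p5 <- scale_and_pca(em5, n_pcs = 5, clip = Inf)
  z <- t(scale(t(em5$values)))
  ev <- eigen(stats::cov(t(z)), symmetric = TRUE)$values
  expect_equal(unname(apply(p5$scores, 2, var)), ev[1:5], tolerance = 1e-8)

  expect_error(scale_and_pca(em5, n_pcs = 10), "n_pcs")
})

test_that("module_score is centred on zero for exchangeable sets", {
  em <- random_em(400, 100, seed = 13, mean = 5)
  set <- sample(genes(em), 30)
  sc <- module_score(em, set, n_bins = 10, n_ctrl_per_gene = 50, seed = 7)
  se <- stats::sd(sc) / sqrt(length(sc))
  expect_lt(abs(mean(sc)), 3 * se + 0.02)

  # constant matrix scores exactly zero
  cm <- expression_matrix(matrix(2, 50, 10,
                                 dimnames = list(sprintf("g%02d", 1:50),
                                                 sprintf("c%02d", 1:10))),
                          "lognorm")
  expect_equal(as.numeric(module_score(cm, sprintf("g%02d", 1:5), n_bins = 5,
                                       seed = 1)),
               rep(0, 10))
})

test_that("module_score recovers a planted shift on single-bin data", {
  delta <- 0.8
  m <- with_seed(21, matrix(stats::rnorm(500 * 60, 5), 500, 60))
  dimnames(m) <- list(sprintf("g%03d", 1:500), sprintf("c%02d", 1:60))
  set <- sprintf("g%03d", 1:40)
  m[set, ] <- m[set, ] + delta
  em <- expression_matrix(m, "lognorm")
  sc <- module_score(em, set, n_bins = 1, n_ctrl_per_gene = 100, seed = 3)
  expect_equal(mean(sc), delta, tolerance = 0.15)

  # scores follow their samples under reordering (same seed, same controls)
  perm <- sample(60)
  em_perm <- expression_matrix(m[, perm], "lognorm")
  sc_perm <- module_score(em_perm, set, n_bins = 1, n_ctrl_per_gene = 100,
                          seed = 3)
  expect_equal(as.numeric(sc_perm), as.numeric(sc[perm]))
})

test_that("module_score handles absent set genes", {
  em <- random_em(100, 10, seed = 2)
  expect_error(module_score(em, c("nope1", "nope2")), "no set genes")
  expect_warning(sc <- module_score(em, c(genes(em)[1:5], "nope")),
                 "absent")
  expect_length(sc, 10L)
})

test_that("cell-cycle phases follow the maximal-score rule", {
  s <- c(0.5, -0.1, 0.2, -0.3)
  g2m <- c(0.1, -0.2, 0.4, -0.1)
  expect_equal(assign_cell_cycle_phase(s, g2m), c("S", "G1", "G2M", "G1"))
})
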