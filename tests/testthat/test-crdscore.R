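test_that("a constant matrix scores zero everywhere", {
  m <- matrix(3, 60, 8, dimnames = list(sprintf("g%02d", 1:60),
                                        sprintf("s%d", 1:8)))
  res <- compute_crdscore(expression_matrix(m, "lognorm"),
                          sprintf("g%02d", 1:10), n_bins = 5,
                          n_random_features = 100, seed = 2)
  expect_equal(res$scores$crdscore, rep(0, 8))
  expect_equal(res$scores$crdscore,
               res$scores$s_random - res$scores$s_crg)
})

test_that("CRDscore is exactly anti-symmetric with module_score", {
  em <- random_em(300, 25, seed = 17, mean = 4)
  set <- sample(genes(em), 20)
  n_ctrl <- 25L
  ms <- module_score(em, set, n_bins = 10, n_ctrl_per_gene = n_ctrl,
                     seed = 99)
  crd <- compute_crdscore(em, set, n_bins = 10,
                          n_random_features = n_ctrl * length(set),
                          seed = 99)
  expect_identical(crd$scores$crdscore, as.numeric(-ms))
  expect_identical(sort(crd$params$control_pool),
                   sort(attr(ms, "control_pool")))
})

test_that("null CRG sets score near zero across 100 seeds", {
  em <- random_em(400, 40, seed = 23, mean = 5)
  crg <- with_seed(31, sample(genes(em), 25))
  means <- vapply(1:100, function(s) {
    mean(compute_crdscore(em, crg, n_bins = 10, n_random_features = 400,
                          seed = s)$scores$crdscore)
  }, numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  # the fixed CRG draw contributes a seed-independent offset of order
  # sd/sqrt(n_crg); allow for it alongside the control-resampling SE
  expect_lt(abs(mean(means)), 3 * se + 1 / sqrt(25))
})

test_that("a planted suppression delta is recovered on single-bin data", {
  delta <- 1.0
  m <- with_seed(41, matrix(stats::rnorm(400 * 30, 5), 400, 30))
  dimnames(m) <- list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:30))
  crg <- sprintf("g%03d", 1:30)
  m[crg, ] <- m[crg, ] - delta
  res <- compute_crdscore(expression_matrix(m, "lognorm"), crg, n_bins = 1,
                          n_random_features = 1000, seed = 5)
  expect_equal(mean(res$scores$crdscore), delta, tolerance = 0.2)
})

test_that("mean CRDscore responds monotonically to the suppression grid", {
  gaps <- vapply(c(0, 0.5, 1.0), function(delta) {
    reps <- vapply(1:5, function(r) {
      cfg <- sim_config(n_samples_per_subtype = c(20L, 20L, 20L, 20L),
                        n_genes = 600L, crg_suppression_delta = delta,
                        seed = 100 * r + delta * 10)
      bulk <- generate_bulk_cohort(cfg)
      res <- compute_crdscore(bulk$matrix, bulk$truth$crg_genes,
                              n_random_features = 400, seed = r)
      labels <- bulk$truth$cell_or_sample_labels
      mean(res$scores$crdscore[labels == "Type2"]) -
        mean(res$scores$crdscore[labels %in% c("Type1", "Type4")])
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_equal(gaps[3] - gaps[1], 1.0, tolerance = 0.25)
})

test_that("per-sample scores are stable across control-draw seeds", {
  bulk <- generate_bulk_cohort(small_bulk_config(seed = 3))
  scores <- vapply(1:50, function(s) {
    compute_crdscore(bulk$matrix, bulk$truth$crg_genes,
                     n_random_features = 1000,
                     seed = s)$scores$crdscore[1]
  }, numeric(1))
  labels <- bulk$truth$cell_or_sample_labels
  one <- compute_crdscore(bulk$matrix, bulk$truth$crg_genes, seed = 1)
  gap <- stats::median(one$scores$crdscore[labels == "Type2"]) -
    stats::median(one$scores$crdscore[labels == "Type1"])
  expect_lt(stats::sd(scores), 0.1 * gap)
})

test_that("missing CADCR genes trigger the tolerance rules", {
  em <- random_em(100, 10, seed = 3)
  mostly_absent <- c(genes(em)[1:2], paste0("zz", 1:10))
  expect_error(compute_crdscore(em, mostly_absent), "50%")
  some_absent <- c(genes(em)[1:10], "zz1")
  expect_warning(res <- compute_crdscore(em, some_absent, n_bins = 5,
                                         n_random_features = 50),
                 "absent")
  expect_length(res$genes_used, 10L)
  expect_error(compute_crdscore(em, genes(em)[1:10], n_bins = 500), "n_bins")
  counts <- counts_em(matrix(1L, 10, 4))
  expect_error(compute_crdscore(counts, rownames(counts$values)[1:5]),
               "lognorm")
})

test_that("CRD levels follow the quartile and median rules", {
  scores <- data.frame(sample = sprintf("s%04d", 1:1000),
                       s_random = 0, s_crg = 0,
                       crdscore = with_seed(5, sample(seq_len(1000))))
  res <- structure(list(scores = scores, params = list(), genes_used = NULL),
                   class = "CRDScoreResult")
  sc <- classify_crd_level(res, "single_cell")
  expect_equal(sum(sc$scores$crd_level == "high"), 250L)
  bulk100 <- classify_crd_level(seq_len(100), "bulk")
  expect_equal(sum(bulk100 == "high"), 50L)
  expect_true(all(classify_crd_level(rep(1, 20), "bulk") == "low"))
  expect_true(all(classify_crd_level(rep(1, 20), "single_cell") == "low"))
  expect_error(classify_crd_level(1, "bulk"), "2 samples")
})

test_that("group comparison keeps its type-I error under the null", {
  scores <- with_seed(61, stats::rnorm(40))
  groups <- rep(c("a", "b"), each = 20)
  rejections <- vapply(1:100, function(r) {
    perm <- with_seed(r, sample(groups))
    compare_crd_between_groups(scores, perm)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.94 - 0.05)
})

test_that("the suppressed subtype has the highest median CRDscore", {
  bulk <- generate_bulk_cohort(small_bulk_config(seed = 44))
  res <- compute_crdscore(bulk$matrix, bulk$truth$crg_genes, seed = 2)
  labels <- bulk$truth$cell_or_sample_labels
  cmp <- compare_crd_between_groups(res, labels)
  expect_equal(cmp$method, "Kruskal-Wallis")
  expect_lt(cmp$p_value, 0.001)
  expect_true(!is.null(cmp$pairwise))
  meds <- vapply(cmp$group_summaries, function(g) g$median, numeric(1))
  expect_equal(names(which.max(meds)), "Type2")

  expect_error(compare_crd_between_groups(res, rep("one", nrow(res$scores))),
               "2 groups")
})
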