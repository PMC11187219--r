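planted_block_em <- function(n_blocks = 2, block_size = 50, n_bg = 20,
                             n_samples = 100, load = 2, seed = 2) {
  with_seed(seed, {
    rows <- list()
    for (b in seq_len(n_blocks)) {
      f <- stats::rnorm(n_samples)
      rows[[b]] <- t(replicate(block_size, load * f + stats::rnorm(n_samples)))
    }
    m <- rbind(do.call(rbind, rows),
               matrix(stats::rnorm(n_bg * n_samples), n_bg))
    dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                        sprintf("s%03d", seq_len(n_samples)))
    list(em = expression_matrix(m, "lognorm"),
         truth = c(rep(seq_len(n_blocks), each = block_size),
                   rep(0L, n_bg)))
  })
}

test_that("mean connectivity shrinks as the soft power grows", {
  em <- random_em(40, 60, seed = 1)
  res <- pick_soft_threshold(em, powers = 1:8, r2_target = 0.8)
  expect_true(all(diff(res$fit_table$mean_k) < 0))
})

test_that("a heavy-tailed hub structure reaches the scale-free target", {
  # latent hub model: cor(i, j) = w_i w_j with power-law-ish loadings
  sim <- with_seed(4, {
    n <- 300
    g <- 200
    w <- (stats::runif(g)^1.6) * 0.95
    f <- stats::rnorm(n)
    m <- t(sapply(w, function(wi) wi * f + sqrt(1 - wi^2) * stats::rnorm(n)))
    dimnames(m) <- list(sprintf("g%03d", 1:g), sprintf("s%03d", 1:n))
    expression_matrix(m, "lognorm")
  })
  res <- pick_soft_threshold(sim, powers = 1:10)
  row <- res$fit_table[res$fit_table$power == res$power, ]
  expect_gte(row$signed_r2, 0.8)
  # independent log-log regression on the chosen power's connectivity
  a <- abs(stats::cor(t(sim$values)))^res$power
  diag(a) <- 1
  k <- rowSums(a) - 1
  br <- cut(k, 10)
  km <- tapply(k, br, mean)
  fr <- tapply(k, br, length)
  ok <- !is.na(km) & km > 0
  fit <- stats::lm(log10(fr[ok]) ~ log10(km[ok]))
  expect_gte(summary(fit)$r.squared, 0.8)
  expect_lt(stats::coef(fit)[2], 0)
})

test_that("r2_target zero returns the smallest candidate power", {
  em <- random_em(40, 40, seed = 6)
  res <- pick_soft_threshold(em, powers = 3:9, r2_target = 0)
  expect_equal(res$power, 3L)
})

test_that("constant-gene input is rejected", {
  m <- matrix(5, 40, 20, dimnames = list(sprintf("g%02d", 1:40),
                                         sprintf("s%02d", 1:20)))
  expect_error(pick_soft_threshold(expression_matrix(m, "lognorm")),
               "constant")
  expect_error(build_tom(expression_matrix(m, "lognorm"), 2), "constant")
})

test_that("TOM equals 1 for perfectly correlated genes at power 1", {
  base <- with_seed(3, stats::rnorm(30))
  m <- rbind(base, 2 * base, 0.5 * base + 1)
  dimnames(m) <- list(c("a", "b", "c"), sprintf("s%02d", 1:30))
  net <- build_tom(expression_matrix(m, "lognorm"), 1)
  expect_equal(unname(net$adjacency), matrix(1, 3, 3), tolerance = 1e-10)
  expect_equal(unname(net$tom), matrix(1, 3, 3), tolerance = 1e-10)
})

test_that("TOM is symmetric, unit-diagonal and bounded on random data", {
  em <- random_em(60, 50, seed = 8)
  net <- build_tom(em, 6)
  expect_equal(net$tom, t(net$tom), tolerance = 1e-12)
  expect_equal(unname(diag(net$tom)), rep(1, 60))
  expect_true(all(net$tom >= 0 & net$tom <= 1))
  # TOM dominates adjacency / (max connectivity + 1)
  k_max <- max(rowSums(net$adjacency) - 1)
  off <- upper.tri(net$tom)
  expect_true(all(net$tom[off] >= net$adjacency[off] / (k_max + 1) - 1e-12))
  expect_error(build_tom(em, 0), "power")
})

test_that("planted blocks are recovered as modules matching the truth", {
  sim <- planted_block_em(n_blocks = 2, seed = 2)
  net <- build_tom(sim$em, 6)
  labels <- detect_modules(net, min_module_size = 30)
  expect_equal(length(unique(labels[labels > 0])), 2L)
  idx <- sim$truth > 0
  expect_equal(adjusted_rand_index(labels[idx], sim$truth[idx]), 1)
  # agreement with an independent partition-similarity implementation
  expect_equal(mclust::adjustedRandIndex(labels[idx], sim$truth[idx]), 1)
})

test_that("independent genes go grey when no module can reach minimum size", {
  em <- random_em(40, 60, seed = 10)
  net <- build_tom(em, 6)
  labels <- detect_modules(net, min_module_size = 50)
  expect_true(all(labels == 0))
})

test_that("module detection is invariant to gene input order", {
  sim <- planted_block_em(n_blocks = 3, block_size = 40, seed = 5)
  net <- build_tom(sim$em, 6)
  l1 <- detect_modules(net)
  perm <- with_seed(1, sample(nrow(sim$em$values)))
  net2 <- build_tom(sim$em[perm, ], 6)
  l2 <- detect_modules(net2)
  expect_equal(adjusted_rand_index(l1[names(l2)], l2), 1)
})

test_that("eigengenes summarize their module and orient consistently", {
  base <- with_seed(7, stats::rnorm(40))
  m <- rbind(base, base * 1.5 + 2, base * 0.7 - 1,
             with_seed(8, matrix(stats::rnorm(80), 2, 40)))
  dimnames(m) <- list(sprintf("g%02d", 1:5), sprintf("s%02d", 1:40))
  em <- expression_matrix(m, "lognorm")
  labels <- c(1L, 1L, 1L, 0L, 0L)
  names(labels) <- genes(em)
  eg <- module_eigengene(em, labels)
  expect_equal(nrow(eg), 1L)
  expect_equal(stats::sd(eg[1, ]), 1)
  for (g in 1:3) expect_equal(abs(stats::cor(m[g, ], eg[1, ])), 1,
                              tolerance = 1e-10)
  expect_gt(stats::cor(m[1, ], eg[1, ]), 0)

  flipped <- em
  flipped$values[1:3, ] <- -flipped$values[1:3, ]
  eg_flip <- module_eigengene(flipped, labels)
  expect_equal(unname(eg_flip[1, ]), unname(-eg[1, ]), tolerance = 1e-10)

  one_gene <- c(1L, 0L, 0L, 0L, 0L)
  names(one_gene) <- genes(em)
  expect_error(module_eigengene(em, one_gene), "fewer than 2")
})

test_that("eigengene variance share matches a direct eigendecomposition", {
  em <- random_em(5, 60, seed = 12)
  labels <- rep(1L, 5)
  names(labels) <- genes(em)
  eg <- module_eigengene(em, labels)
  z <- t(scale(t(em$values)))
  ev <- eigen(tcrossprod(z) / (ncol(z) - 1), symmetric = TRUE)$values
  # variance explained by the eigengene = leading eigenvalue share
  r2 <- sapply(1:5, function(g) stats::cor(z[g, ], eg[1, ])^2)
  expect_equal(sum(r2 * apply(z, 1, var)) / sum(apply(z, 1, var)),
               ev[1] / sum(ev), tolerance = 1e-8)
})

test_that("kME ranks members of planted modules above outsiders", {
  sim <- planted_block_em(n_blocks = 3, block_size = 40, seed = 9)
  net <- build_tom(sim$em, 6)
  labels <- detect_modules(net)
  eg <- module_eigengene(sim$em, labels)
  kme <- compute_kme(sim$em, eg)
  mods <- sort(unique(labels[labels > 0]))
  own_beats_other <- unlist(lapply(mods, function(m) {
    members <- names(labels)[labels == m]
    own <- kme[members, paste0("ME", m)]
    other <- apply(kme[members, paste0("ME", setdiff(mods, m)),
                       drop = FALSE], 1, max)
    own > other
  }))
  expect_gte(mean(own_beats_other), 0.95)

  # a gene identical to the eigengene has kME 1
  m2 <- rbind(sim$em$values, ME = eg["ME1", ])
  em2 <- expression_matrix(m2, "lognorm")
  kme2 <- compute_kme(em2, eg)
  expect_equal(unname(kme2["ME", "ME1"]), 1, tolerance = 1e-10)
})

test_that("hub selection respects kME order, ties and bounds", {
  labels <- c(a = 1L, b = 1L, c = 1L, d = 0L)
  kme <- matrix(c(0.9, 0.5, 0.9, 0.1), 4, 1,
                dimnames = list(c("a", "b", "c", "d"), "ME1"))
  hubs <- hub_genes(kme, labels, 1, n_hubs = 2)
  expect_equal(hubs$genes, c("a", "c")) # tie broken by identifier
  expect_equal(hub_genes(kme, labels, 1, n_hubs = 10)$genes,
               c("a", "c", "b"))
  expect_error(hub_genes(kme, labels, 1, n_hubs = 0), "n_hubs")
})
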