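# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the caller's
#' RNG state afterwards, so seeded operations do not perturb the session
#' stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Equal-occupancy bins by rank of `x`; ties broken by order of appearance so
# the binning is deterministic.
equal_size_bins <- function(x, n_bins) {
  stopifnot(n_bins >= 1L, n_bins <= length(x))
  r <- rank(x, ties.method = "first")
  ceiling(r * n_bins / length(x))
}

# Row variances without matrixStats.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) {
    return(rep(NA_real_, nrow(x)))
  }
  m <- rowMeans(x)
  (rowSums(x * x) - n * m * m) / (n - 1)
}

# Z-score matrix rows; rows with zero variance become all-zero rather than
# NaN. Optionally clip to +/- clip.
zscore_rows <- function(x, clip = Inf) {
  m <- rowMeans(x)
  s <- sqrt(row_vars(x))
  s[!is.finite(s) | s == 0] <- Inf # zero rows out
  z <- (x - m) / s
  if (is.finite(clip)) {
    z[z > clip] <- clip
    z[z < -clip] <- -clip
  }
  z
}

#' Adjusted Rand index between two label vectors (Hubert & Arabie)
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions, ~0 =
#'   chance agreement).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) {
    return(NA_real_)
  }
  tab <- table(a, b)
  choose2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n_pairs <- choose2(length(a))
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

# k-means++ seeding: returns a k x p matrix of initial centers drawn from the
# rows of x. Guarded against duplicate picks on degenerate data.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  stopifnot(k >= 1L, k <= n)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[idx[1L], ], "-")^2)
    for (j in 2L:k) {
      if (all(d2 <= 0)) {
        # all remaining points coincide with a chosen center
        pool <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
        idx[j] <- pool[sample.int(length(pool), 1L)]
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ], "-")^2))
    }
  }
  x[idx, , drop = FALSE]
}

# Best-of-nstart K-means with k-means++ seeding (Euclidean, Lloyd via
# stats::kmeans). Deterministic given the RNG state.
kmeanspp <- function(x, k, nstart = 10L, iter_max = 30L) {
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- kmeanspp_centers(x, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = iter_max)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) { # duplicated seeds on pathological data; plain restart
    best <- suppressWarnings(stats::kmeans(x, centers = k, nstart = nstart,
                                           iter.max = iter_max))
  }
  best
}

# Largest-remainder apportionment of `total` into parts proportional to w.
apportion <- function(w, total) {
  stopifnot(all(w >= 0), sum(w) > 0, total >= 0)
  quota <- total * w / sum(w)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clustering accuracy under optimal label matching
#'
#' Cluster numberings are arbitrary; this reports the highest achievable
#' agreement between two label vectors over one-to-one relabelings of the
#' predicted classes (exact search; intended for small numbers of classes).
#'
#' @param pred,truth Label vectors of equal length.
#' @return Proportion of agreeing labels after the best matching.
#' @export
matched_accuracy <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  tab <- unclass(table(pred, truth))
  k <- max(dim(tab))
  if (k > 8L) stop("too many classes for exact matching")
  # pad to square so unmatched classes score zero
  m <- matrix(0, k, k)
  m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- 0
  permute <- function(fixed, remaining) {
    if (length(remaining) == 0L) {
      score <- sum(m[cbind(seq_len(k), fixed)])
      if (score > best) best <<- score
      return(invisible())
    }
    for (r in remaining) permute(c(fixed, r), setdiff(remaining, r))
  }
  permute(integer(0), seq_len(k))
  best / length(pred)
}
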