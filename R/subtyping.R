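# Consensus clustering for subtype discovery: resampled K-means over a
# range of k, consensus matrices, CDF curves and the delta-area rule for
# choosing k.

#' Consensus K-means clustering
#'
#' For each k, `reps` resampling repetitions each draw
#' `ceiling(subsample_fraction * n)` samples without replacement and run
#' Euclidean K-means (k-means++ seeding, 10 restarts) on per-gene z-scored
#' signature features. The consensus between two samples is the fraction of
#' co-sampled repetitions in which they co-cluster. Final assignments at
#' each k come from average-linkage hierarchical clustering of
#' `1 - consensus` cut into k groups.
#'
#' @param expr `ExpressionMatrix` of the cohort.
#' @param signature Genes to cluster on (`GeneSet` or character), e.g. the
#'   circadian module hub genes; `NULL` uses all genes.
#' @param k_range Candidate cluster numbers (default 2:6).
#' @param reps Resampling repetitions (default 1000).
#' @param subsample_fraction Fraction of samples per repetition (default
#'   0.8).
#' @param seed RNG seed.
#' @param nstart K-means++ restarts per fit.
#' @return A `ConsensusResult`: per-k consensus matrices and assignments,
#'   plus the CDF/delta-area table (see [cdf_and_delta_area()]) and
#'   `chosen_k` from [select_optimal_k()].
#' @export
consensus_cluster <- function(expr, signature = NULL, k_range = 2:6,
                              reps = 1000L, subsample_fraction = 0.8,
                              seed = 1L, nstart = 10L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  v <- expr$values
  if (!is.null(signature)) {
    sig <- as_gene_vector(signature)
    missing <- setdiff(sig, rownames(v))
    if (length(missing) > 0L) {
      stop("signature genes absent: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    v <- v[sig, , drop = FALSE]
  }
  n <- ncol(v)
  k_range <- sort(unique(as.integer(k_range)))
  if (n < 2L * max(k_range)) {
    stop("need at least 2 x max(k_range) samples")
  }
  n_sub <- ceiling(subsample_fraction * n)
  if (max(k_range) > n_sub) stop("k exceeds the subsample size")
  x <- t(zscore_rows(v)) # samples x features
  ids <- colnames(v)

  per_k <- with_seed(seed, {
    lapply(k_range, function(k) {
      co <- matrix(0, n, n)
      tog <- matrix(0, n, n)
      for (r in seq_len(reps)) {
        idx <- sample.int(n, n_sub)
        fit <- kmeanspp(x[idx, , drop = FALSE], k, nstart = nstart)
        ind <- outer(fit$cluster, fit$cluster, "==")
        co[idx, idx] <- co[idx, idx] + ind
        tog[idx, idx] <- tog[idx, idx] + 1
      }
      never <- sum(tog[upper.tri(tog)] == 0)
      if (never > 0L) {
        warning(sprintf("%d sample pair(s) never co-sampled; consensus 0",
                        never))
      }
      cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
      diag(cons) <- 1
      dimnames(cons) <- list(ids, ids)
      tree <- stats::hclust(stats::as.dist(1 - cons), method = "average")
      assign <- stats::cutree(tree, k = k)
      list(k = k, consensus = cons, assignments = assign,
           never_cosampled = never)
    })
  })
  names(per_k) <- paste0("k", k_range)
  res <- structure(list(k_range = k_range, per_k = per_k,
                        params = list(reps = reps,
                                      subsample_fraction = subsample_fraction,
                                      seed = seed, nstart = nstart)),
                   class = "ConsensusResult")
  res$cdf <- cdf_and_delta_area(res)
  res$chosen_k <- select_optimal_k(res)
  res
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: k in {%s}, %d reps, chosen k = %s\n",
              paste(x$k_range, collapse = ","), x$params$reps,
              x$chosen_k %||% "?"))
  invisible(x)
}

#' Consensus CDF curves and delta area
#'
#' The empirical CDF of the upper-triangle consensus values is evaluated on
#' a 100-point grid over [0, 1] and its area computed by the trapezoid
#' rule. The delta area at the smallest k is the area itself; for larger k
#' it is the relative gain `(A(k) - A(k-1)) / A(k-1)`.
#'
#' @param result A `ConsensusResult`.
#' @return Data frame with columns `k`, `area`, `delta_area`; the CDF
#'   matrix (k x grid) is attached as attribute `"cdf_matrix"` with the
#'   grid in `"grid"`.
#' @export
cdf_and_delta_area <- function(result) {
  stopifnot(inherits(result, "ConsensusResult"))
  grid <- seq(0, 1, length.out = 100L)
  cdfm <- t(vapply(result$per_k, function(pk) {
    vals <- pk$consensus[upper.tri(pk$consensus)]
    stats::ecdf(vals)(grid)
  }, numeric(length(grid))))
  area <- apply(cdfm, 1L, function(f) {
    sum(diff(grid) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
  })
  delta <- numeric(length(area))
  delta[1L] <- area[1L]
  if (length(area) > 1L) {
    delta[-1L] <- diff(area) / utils::head(area, -1)
  }
  out <- data.frame(k = result$k_range, area = area, delta_area = delta,
                    row.names = NULL)
  attr(out, "cdf_matrix") <- cdfm
  attr(out, "grid") <- grid
  out
}

#' Choose the number of clusters from the delta-area elbow
#'
#' The chosen k is the largest k (>= 3, since the smallest k's "delta" is
#' its whole area) whose relative CDF-area gain is at least
#' `elbow_threshold`; when none qualifies the smallest candidate k is
#' returned.
#'
#' @param result A `ConsensusResult`.
#' @param elbow_threshold Relative-gain threshold (default 0.1).
#' @return The chosen k; the rationale string is attached as attribute
#'   `"rationale"`.
#' @export
select_optimal_k <- function(result, elbow_threshold = 0.1) {
  stopifnot(inherits(result, "ConsensusResult"))
  tab <- result$cdf %||% cdf_and_delta_area(result)
  if (length(result$k_range) == 1L) {
    k <- result$k_range
    attr(k, "rationale") <- "single candidate k"
    return(k)
  }
  pass <- tab$k[tab$k >= 3L & tab$delta_area >= elbow_threshold]
  if (length(pass) > 0L) {
    k <- max(pass)
    attr(k, "rationale") <- sprintf(
      "largest k with relative CDF-area gain >= %.2f", elbow_threshold)
  } else {
    k <- min(result$k_range)
    attr(k, "rationale") <- sprintf(
      "no k >= 3 gained >= %.2f relative CDF area; defaulting to min(k)",
      elbow_threshold)
  }
  k
}
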