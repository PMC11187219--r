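# Shared fixtures and independent oracles used across the suite. All data
# is built in code; oracles are deliberately naive (enumeration, direct
# life tables) and never reuse package internals.

tiny_sc_config <- function(seed = 1, ...) {
  sim_config(n_cells = 400L, n_genes = 800L, n_modules = 4L,
             module_size = 40L, n_samples_per_subtype = c(30L, 25L, 25L, 30L),
             seed = seed, ...)
}

small_bulk_config <- function(seed = 1, ...) {
  sim_config(n_samples_per_subtype = c(40L, 30L, 30L, 40L), n_genes = 800L,
             seed = seed, ...)
}

random_em <- function(n_genes, n_samples, seed = 1, layer = "lognorm",
                      mean = 0, sd = 1) {
  m <- with_seed(seed, matrix(stats::rnorm(n_genes * n_samples, mean, sd),
                              n_genes, n_samples))
  dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%04d", seq_len(n_samples)))
  expression_matrix(m, layer)
}

counts_em <- function(m) {
  if (is.null(rownames(m))) {
    dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                        sprintf("c%03d", seq_len(ncol(m))))
  }
  expression_matrix(m, "counts")
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all rank splits.
wilcox_enum_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  splits <- utils::combn(n, length(x))
  w_all <- apply(splits, 2, function(idx) {
    sum(seq_len(n)[idx]) - length(x) * (length(x) + 1) / 2
  })
  center <- length(x) * length(y) / 2
  mean(abs(w_all - center) >= abs(w_obs - center))
}

# Fisher two-sided p for a 2x2 table by the point-probability rule,
# enumerating every table with the observed margins.
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Log-rank statistic for two groups from an explicit life table.
logrank_hand <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_all <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_all <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d_all * n1 / n_all
    if (n_all > 1) {
      v <- v + d_all * (n1 / n_all) * (1 - n1 / n_all) *
        (n_all - d_all) / (n_all - 1)
    }
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Rank-based AUC of `scores` separating cases from controls.
rank_auc <- function(scores, is_case) {
  r <- rank(scores)
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
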