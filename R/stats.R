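# The inferential toolbox used downstream of scoring and subtyping: rank
# tests, contingency tests, BH adjustment, Kaplan-Meier / log-rank, and
# stage-by-subtype composition tables. All tests are two-sided. The actual
# test engines are the standard base-R and survival implementations; this
# layer enforces the routing rules (exact vs approximate, chi-square vs
# Fisher) and returns uniform summaries.

new_test_summary <- function(statistic, p_value, method, group_summaries,
                             extra = list()) {
  structure(c(list(statistic = unname(statistic), p_value = unname(p_value),
                   method = method, group_summaries = group_summaries),
              extra),
            class = "TestSummary")
}

#' @export
print.TestSummary <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}

#' Rank test for continuous values across groups
#'
#' Two groups: Wilcoxon rank-sum, exact when both groups have <= 10
#' observations and there are no ties, otherwise the tie-corrected normal
#' approximation (no continuity correction). More than two groups:
#' Kruskal-Wallis with tie correction. Two-sided throughout.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each >= 3 observations).
#' @return A `TestSummary` with per-group n and medians.
#' @export
rank_test <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 3L)) stop("every group needs >= 3 observations")
  gs <- lapply(split(values, groups), function(v) {
    list(n = length(v), median = stats::median(v))
  })
  if (nlevels(groups) == 2L) {
    x <- values[groups == levels(groups)[1L]]
    y <- values[groups == levels(groups)[2L]]
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- length(x) <= 10L && length(y) <= 10L && !ties
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = FALSE))
    new_test_summary(ht$statistic, ht$p.value,
                     if (exact) "Wilcoxon rank-sum (exact)" else
                       "Wilcoxon rank-sum (normal approximation)",
                     gs)
  } else {
    ht <- stats::kruskal.test(values, groups)
    new_test_summary(ht$statistic, ht$p.value, "Kruskal-Wallis", gs,
                     extra = list(df = unname(ht$parameter)))
  }
}

#' Contingency test with expected-count routing
#'
#' Chi-square without continuity correction when every expected count
#' exceeds 5; otherwise Fisher's exact test (two-sided by the
#' point-probability rule) for 2x2 tables, or chi-square with a warning for
#' larger tables.
#' The sample odds ratio is reported for 2x2 tables.
#'
#' @param tab Non-negative integer matrix, at least 2x2, positive margins.
#' @return A `TestSummary`; for 2x2 tables `odds_ratio` is included.
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8)) {
    stop("table must contain non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero margin")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  gs <- list(row_totals = rowSums(tab), col_totals = colSums(tab))
  is2x2 <- nrow(tab) == 2L && ncol(tab) == 2L
  extra <- list(expected = expected)
  if (is2x2) {
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    extra$odds_ratio <- or
  }
  if (all(expected > 5)) {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    new_test_summary(ht$statistic, ht$p.value, "chi-square", gs, extra)
  } else if (is2x2) {
    ht <- stats::fisher.test(tab)
    new_test_summary(NA_real_, ht$p.value, "Fisher exact", gs, extra)
  } else {
    warning("expected counts < 5 in an r x c table; chi-square may be ",
            "unreliable")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    new_test_summary(ht$statistic, ht$p.value,
                     "chi-square (small expected counts)", gs, extra)
  }
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival curves per group and the log-rank chi-square test
#' across groups (hypergeometric variance over event times, g - 1 degrees
#' of freedom).
#'
#' @param surv Data frame with columns `time` (> 0), `event` (0/1) and
#'   `group`.
#' @return List with `test` (a `TestSummary`) and `curves`, a data frame of
#'   per-group step curves (group, time, n_risk, surv).
#' @export
km_logrank <- function(surv) {
  stopifnot(is.data.frame(surv),
            all(c("time", "event", "group") %in% names(surv)))
  if (any(surv$time <= 0)) stop("survival times must be positive")
  surv$group <- factor(surv$group)
  surv$group <- droplevels(surv$group)
  if (nlevels(surv$group) < 2L) stop("need at least 2 groups")
  if (sum(surv$event) < 1L) stop("need at least one event")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = surv)
  df <- nlevels(surv$group) - 1L
  p <- stats::pchisq(sd_fit$chisq, df = df, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = surv)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^group=", "", strata), time = sf$time,
                       n_risk = sf$n.risk, surv = sf$surv, row.names = NULL)
  gs <- lapply(split(surv, surv$group), function(d) {
    list(n = nrow(d), events = sum(d$event))
  })
  test <- new_test_summary(sd_fit$chisq, p, "log-rank", gs,
                           extra = list(df = df, observed = sd_fit$obs,
                                        expected = sd_fit$exp))
  list(test = test, curves = curves)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, order preserving.
#'
#' @param p_values Numeric p-values in (0, 1].
#' @return Adjusted values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Stage-by-subtype composition table
#'
#' Cross-tabulates ordinal stage against subtype, reports within-subtype
#' proportions (each subtype's proportions sum to 1) and the association
#' test from [contingency_test()].
#'
#' @param stage Ordinal stage labels.
#' @param subtype Subtype labels, same length.
#' @return List with `counts` (subtype x stage), `proportions`, `test`.
#' @export
composition_table <- function(stage, subtype) {
  if (length(stage) != length(subtype)) stop("stage/subtype length mismatch")
  counts <- table(subtype = factor(subtype), stage = factor(stage))
  proportions <- sweep(counts, 1L, rowSums(counts), "/")
  list(counts = unclass(counts), proportions = unclass(proportions),
       test = contingency_test(counts))
}
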