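# The circadian-rhythm-disruption score. Per sample,
#   CRDscore = Srandom - SCADCRgenes,
# where SCADCRgenes is the mean expression of the circadian (CADCR) gene
# set and Srandom the mean expression of an expression-bin-matched random
# control pool. Positive scores mean circadian genes sit below their
# matched background, i.e. more disruption.

#' Compute the CRDscore
#'
#' Genes are binned into `n_bins` equal-occupancy bins by mean expression;
#' a control pool of `n_random_features` genes is sampled with replacement
#' from the bins occupied by the CADCR set (allocated proportionally to the
#' set's bin occupancy, excluding the set's own genes); then per sample
#' `Srandom` is the mean expression of the control pool, `SCADCRgenes` the
#' mean expression of the present CADCR genes, and
#' `CRDscore = Srandom - SCADCRgenes`.
#'
#' @param expr `ExpressionMatrix`, layer `lognorm` or `log2tpm`.
#' @param crg CADCR gene set (`GeneSet` or character). At least half must
#'   be present in the matrix.
#' @param n_bins Expression bins (default 25).
#' @param n_random_features Size of the random control pool (default 1000).
#' @param seed Seed for the control draw.
#' @return A `CRDScoreResult`: data frame `scores` (sample, s_random,
#'   s_crg, crdscore) plus the run parameters and the genes used.
#' @export
compute_crdscore <- function(expr, crg, n_bins = 25L,
                             n_random_features = 1000L, seed = 1L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!expr$layer %in% c("lognorm", "log2tpm")) {
    stop("CRDscore expects lognorm or log2tpm expression")
  }
  if (n_bins > nrow(expr$values)) stop("n_bins exceeds the number of genes")
  crg_genes <- as_gene_vector(crg)
  present <- intersect(crg_genes, genes(expr))
  missing <- setdiff(crg_genes, present)
  if (length(present) < length(crg_genes) / 2) {
    stop("fewer than 50% of CADCR genes present; missing: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  if (length(missing) > 0L) {
    warning(sprintf("%d CADCR gene(s) absent from matrix; dropped",
                    length(missing)))
  }
  pool <- bin_matched_controls(
    expr$values, present, n_bins,
    allocation_fn = function(occupancy) {
      apportion(as.numeric(occupancy), n_random_features)
    },
    seed = seed)
  s_random <- colMeans(expr$values[pool, , drop = FALSE])
  s_crg <- colMeans(expr$values[present, , drop = FALSE])
  scores <- data.frame(sample = samples(expr), s_random = unname(s_random),
                       s_crg = unname(s_crg),
                       crdscore = unname(s_random - s_crg),
                       row.names = NULL)
  structure(list(scores = scores,
                 params = list(n_bins = n_bins,
                               n_random_features = n_random_features,
                               seed = seed, control_pool = pool),
                 genes_used = present),
            class = "CRDScoreResult")
}

#' @export
print.CRDScoreResult <- function(x, ...) {
  cat(sprintf("CRDScoreResult: %d samples, %d CADCR genes, %d controls\n",
              nrow(x$scores), length(x$genes_used),
              x$params$n_random_features))
  print(utils::head(x$scores))
  invisible(x)
}

#' Call high/low CRD levels
#'
#' Single-cell mode calls a cell high when its CRDscore exceeds the 75th
#' percentile (linear-interpolation quantile) of the score vector; bulk
#' mode uses the median. Scores tied with the threshold are low.
#'
#' @param result A `CRDScoreResult` (or numeric score vector).
#' @param mode `"single_cell"` or `"bulk"`.
#' @return For a `CRDScoreResult`: the result with a `crd_level` column
#'   added (threshold in attribute `"threshold"`); for a numeric vector: a
#'   character vector of levels.
#' @export
classify_crd_level <- function(result, mode = c("single_cell", "bulk")) {
  mode <- match.arg(mode)
  scores <- if (inherits(result, "CRDScoreResult")) {
    result$scores$crdscore
  } else {
    as.numeric(result)
  }
  if (length(scores) < 2L) stop("need at least 2 samples to set a threshold")
  thr <- if (mode == "single_cell") {
    stats::quantile(scores, 0.75, type = 7, names = FALSE)
  } else {
    stats::median(scores)
  }
  level <- ifelse(scores > thr, "high", "low")
  if (inherits(result, "CRDScoreResult")) {
    result$scores$crd_level <- level
    attr(result, "threshold") <- thr
    result
  } else {
    level
  }
}

#' Compare CRDscore between groups
#'
#' Two groups: Wilcoxon rank-sum. More: Kruskal-Wallis plus pairwise
#' Wilcoxon with Benjamini-Hochberg adjustment. Delegates to [rank_test()].
#'
#' @param result `CRDScoreResult` or numeric score vector.
#' @param groups Group labels, one per sample, each group with >= 3
#'   samples.
#' @return A `TestSummary` from [rank_test()]; for > 2 groups a
#'   `pairwise` data frame (group1, group2, p, fdr) is attached.
#' @export
compare_crd_between_groups <- function(result, groups) {
  scores <- if (inherits(result, "CRDScoreResult")) {
    result$scores$crdscore
  } else {
    as.numeric(result)
  }
  groups <- factor(groups)
  if (length(scores) != length(groups)) {
    stop("groups must align with the scored samples")
  }
  out <- rank_test(scores, groups)
  if (nlevels(groups) > 2L) {
    combos <- utils::combn(levels(groups), 2L)
    p <- apply(combos, 2L, function(pair) {
      sel <- groups %in% pair
      rank_test(scores[sel], droplevels(groups[sel]))$p_value
    })
    out$pairwise <- data.frame(group1 = combos[1L, ], group2 = combos[2L, ],
                               p = p, fdr = bh_adjust(p))
  }
  out
}
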