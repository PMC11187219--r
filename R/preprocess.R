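# Single-cell / bulk preprocessing: QC filtering, library-size
# log-normalization, TPM transform, highly-variable-gene selection, scaled
# PCA, and expression-bin-matched module scoring.

#' QC thresholds for cell filtering
#'
#' Cells are kept when their detected-gene count lies in
#' `[min_genes_per_cell, max_genes_per_cell]` (inclusive) and their
#' mitochondrial UMI fraction is strictly below `max_mito_fraction`.
#'
#' @param min_genes_per_cell Lower bound on detected genes (default 200).
#' @param max_genes_per_cell Upper bound on detected genes (default 4000).
#' @param max_mito_fraction Strict upper bound on the mitochondrial count
#'   fraction (default 0.15).
#' @return A `QCThresholds` list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 200L,
                          max_genes_per_cell = 4000L,
                          max_mito_fraction = 0.15) {
  if (min_genes_per_cell >= max_genes_per_cell) {
    stop("min_genes_per_cell must be < max_genes_per_cell")
  }
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    stop("max_mito_fraction must lie in [0, 1]")
  }
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 max_genes_per_cell = as.integer(max_genes_per_cell),
                 max_mito_fraction = max_mito_fraction),
            class = "QCThresholds")
}

#' Filter cells by detected genes and mitochondrial fraction
#'
#' @param counts Counts `ExpressionMatrix`.
#' @param thresholds A [qc_thresholds()].
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return The filtered counts matrix; the per-cell QC report (detected
#'   genes, mito fraction, kept flag and failure reason) is attached as
#'   attribute `"qc_report"`.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(),
                      mito_prefix = "MT-") {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$layer != "counts") stop("qc_filter expects the counts layer")
  if (ncol(counts$values) == 0L || nrow(counts$values) == 0L) {
    stop("empty expression matrix")
  }
  v <- counts$values
  detected <- colSums(v > 0)
  total <- colSums(v)
  mito_rows <- startsWith(rownames(v), mito_prefix)
  mito_frac <- if (any(mito_rows)) {
    ifelse(total > 0, colSums(v[mito_rows, , drop = FALSE]) / total, 0)
  } else {
    rep(0, ncol(v))
  }
  too_few <- detected < thresholds$min_genes_per_cell
  too_many <- detected > thresholds$max_genes_per_cell
  high_mito <- mito_frac >= thresholds$max_mito_fraction
  keep <- !(too_few | too_many | high_mito)
  reason <- rep("pass", ncol(v))
  reason[high_mito] <- "high_mito"
  reason[too_many] <- "too_many_genes"
  reason[too_few] <- "too_few_genes"
  report <- data.frame(cell = colnames(v), detected_genes = detected,
                       mito_fraction = mito_frac, kept = keep,
                       reason = reason, row.names = NULL)
  if (!any(keep)) {
    fails <- table(reason[reason != "pass"])
    binding <- names(fails)[which.max(fails)]
    stop(sprintf("no cells survive QC; binding threshold: %s", binding))
  }
  out <- counts[, keep]
  attr(out, "qc_report") <- report
  out
}

#' Library-size log-normalization
#'
#' `value = ln(1 + scale_factor * count / column_sum)`, the standard
#' single-cell normalization.
#'
#' @param counts Counts `ExpressionMatrix`.
#' @param scale_factor Target library size (default 1e4).
#' @return An `ExpressionMatrix` with layer `"lognorm"`.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$layer != "counts") stop("lognormalize expects the counts layer")
  cs <- colSums(counts$values)
  if (any(cs == 0)) {
    stop("zero-sum column(s): ",
         paste(colnames(counts$values)[cs == 0][1:min(5, sum(cs == 0))],
               collapse = ", "))
  }
  v <- log1p(sweep(counts$values, 2L, scale_factor / cs, "*"))
  expression_matrix(v, "lognorm")
}

#' Transcripts-per-million transform with log2
#'
#' Counts are converted to length-normalized rates (`count / length_kb`),
#' rescaled to sum to 1e6 per sample, and returned as `log2(TPM + 1)`.
#' UMI-based single-cell counts carry no length bias; when `gene_lengths_kb`
#' is omitted every gene uses 1 kb and a message notes it.
#'
#' @param counts Counts `ExpressionMatrix`.
#' @param gene_lengths_kb Positive gene lengths in kilobases (one per gene),
#'   or `NULL`.
#' @return An `ExpressionMatrix` with layer `"log2tpm"`. The pre-log TPM
#'   matrix is attached as attribute `"tpm"`.
#' @export
tpm_log2 <- function(counts, gene_lengths_kb = NULL) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$layer != "counts") stop("tpm_log2 expects the counts layer")
  if (is.null(gene_lengths_kb)) {
    message("no gene lengths supplied; using 1 kb for every gene")
    gene_lengths_kb <- rep(1, nrow(counts$values))
  }
  if (length(gene_lengths_kb) != nrow(counts$values)) {
    stop("need one gene length per gene")
  }
  if (any(gene_lengths_kb <= 0)) stop("gene lengths must be positive")
  rate <- counts$values / gene_lengths_kb
  totals <- colSums(rate)
  if (any(totals == 0)) stop("zero-count sample(s) cannot be TPM-normalized")
  tpm <- sweep(rate, 2L, 1e6 / totals, "*")
  out <- expression_matrix(log2(tpm + 1), "log2tpm")
  attr(out, "tpm") <- tpm
  out
}

#' Select highly variable genes by bin-standardized dispersion
#'
#' Genes are ranked by dispersion (variance / mean) z-scored within 20
#' mean-expression bins, and the top `n_top` positive-variance genes are
#' returned.
#'
#' @param norm `ExpressionMatrix` (lognorm layer) with >= 2 samples.
#' @param n_top Number of genes to select (default 2000).
#' @param n_bins Mean-expression bins used to standardize dispersion.
#' @return A `GeneSet` named `"hvg"` with exactly
#'   `min(n_top, #positive-variance genes)` genes.
#' @export
select_hvg <- function(norm, n_top = 2000L, n_bins = 20L) {
  stopifnot(inherits(norm, "ExpressionMatrix"))
  if (ncol(norm$values) < 2L) stop("need at least 2 samples to rank variance")
  m <- rowMeans(norm$values)
  v <- row_vars(norm$values)
  eligible <- which(v > 0)
  if (length(eligible) == 0L) stop("no gene has positive variance")
  disp <- v[eligible] / pmax(m[eligible], .Machine$double.eps)
  bins <- equal_size_bins(m[eligible], min(n_bins, length(eligible)))
  z <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    mu <- mean(disp[idx])
    sd_b <- stats::sd(disp[idx])
    z[idx] <- if (is.na(sd_b) || sd_b == 0) 0 else (disp[idx] - mu) / sd_b
  }
  ord <- order(z, decreasing = TRUE)
  take <- ord[seq_len(min(n_top, length(eligible)))]
  gene_set("hvg", rownames(norm$values)[eligible][take])
}

#' Per-gene scaling and exact PCA
#'
#' Genes are z-scored across samples, clipped at +/-10, and decomposed by
#' exact PCA (samples as observations). Components are ordered by
#' decreasing variance and signed so that the largest-magnitude gene
#' loading of each component is positive, making repeated runs identical.
#'
#' @param norm `ExpressionMatrix` (lognorm layer).
#' @param gene_subset Genes to use (`GeneSet` or character); default all.
#' @param n_pcs Number of components.
#' @param clip Z-score clipping bound before PCA.
#' @return List with `scores` (samples x components), `rotation`
#'   (genes x components) and `sdev`.
#' @export
scale_and_pca <- function(norm, gene_subset = NULL, n_pcs = 10L, clip = 10) {
  stopifnot(inherits(norm, "ExpressionMatrix"))
  g <- if (is.null(gene_subset)) genes(norm) else as_gene_vector(gene_subset)
  missing <- setdiff(g, genes(norm))
  if (length(missing) > 0L) {
    stop("genes not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  x <- zscore_rows(norm$values[g, , drop = FALSE], clip = clip)
  if (n_pcs > min(dim(x))) stop("n_pcs exceeds matrix rank bound")
  pr <- stats::prcomp(t(x), center = FALSE, scale. = FALSE, rank. = n_pcs)
  rot <- pr$rotation
  sco <- pr$x
  for (c in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, c]))
    if (rot[j, c] < 0) {
      rot[, c] <- -rot[, c]
      sco[, c] <- -sco[, c]
    }
  }
  list(scores = sco, rotation = rot, sdev = pr$sdev[seq_len(n_pcs)])
}

# Shared machinery for expression-bin-matched control pools. Bins all genes
# by mean expression, then samples control genes (with replacement) from the
# bins occupied by the query set, excluding the set itself, according to a
# per-bin allocation. Both module_score() and compute_crdscore() build their
# controls here, which is what makes the two scores exactly anti-symmetric
# under shared parameters and seed.
bin_matched_controls <- function(values, set_present, n_bins, allocation_fn,
                                 seed) {
  means <- rowMeans(values)
  n_bins <- min(n_bins, nrow(values))
  bins <- equal_size_bins(means, n_bins)
  names(bins) <- rownames(values)
  occupancy <- table(factor(bins[set_present], levels = sort(unique(bins))))
  occupancy <- occupancy[occupancy > 0]
  alloc <- allocation_fn(occupancy)
  all_genes <- rownames(values)
  non_set <- setdiff(all_genes, set_present)
  with_seed(seed, {
    pool <- character(0)
    for (i in seq_along(occupancy)) {
      b <- as.integer(names(occupancy)[i])
      eligible <- setdiff(all_genes[bins == b], set_present)
      if (length(eligible) == 0L) eligible <- non_set # degenerate bin
      pool <- c(pool, eligible[sample.int(length(eligible), alloc[i],
                                          replace = TRUE)])
    }
    pool
  })
}

#' Expression-bin-matched module score
#'
#' The cell-cycle style signature score: genes are binned by average
#' expression, each set gene draws `n_ctrl_per_gene` control genes (with
#' replacement) from its bin, and the per-sample score is
#' `mean(set genes) - mean(control genes)`. Controls exclude the set's own
#' genes.
#'
#' @param norm `ExpressionMatrix` (lognorm or log2tpm layer).
#' @param set `GeneSet` or character vector.
#' @param n_bins Expression bins (default 25).
#' @param n_ctrl_per_gene Controls per set gene (default 100).
#' @param seed Seed for the control draw.
#' @return Named numeric vector of per-sample scores; the control pool is
#'   attached as attribute `"control_pool"`.
#' @export
module_score <- function(norm, set, n_bins = 25L, n_ctrl_per_gene = 100L,
                         seed = 1L) {
  stopifnot(inherits(norm, "ExpressionMatrix"))
  set_genes <- as_gene_vector(set)
  present <- intersect(set_genes, genes(norm))
  if (length(present) == 0L) stop("no set genes present in the matrix")
  if (length(present) < length(set_genes)) {
    warning(sprintf("%d set gene(s) absent from matrix; dropped",
                    length(set_genes) - length(present)))
  }
  pool <- bin_matched_controls(
    norm$values, present, n_bins,
    allocation_fn = function(occupancy) as.integer(occupancy) * n_ctrl_per_gene,
    seed = seed)
  s_set <- colMeans(norm$values[present, , drop = FALSE])
  s_ctrl <- colMeans(norm$values[pool, , drop = FALSE])
  out <- s_set - s_ctrl
  attr(out, "control_pool") <- pool
  out
}

#' Assign cell-cycle phase from S and G2M scores
#'
#' A cell takes the phase with the larger score; when both scores are <= 0
#' it is called G1.
#'
#' @param s_score,g2m_score Per-cell [module_score()] vectors.
#' @return Character vector of `"G1"`, `"S"`, `"G2M"`.
#' @export
assign_cell_cycle_phase <- function(s_score, g2m_score) {
  stopifnot(length(s_score) == length(g2m_score))
  phase <- ifelse(s_score <= 0 & g2m_score <= 0, "G1",
                  ifelse(s_score >= g2m_score, "S", "G2M"))
  unname(phase)
}
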