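# Synthetic cohorts with planted structure: co-expression modules and
# circadian-gene suppression in single-cell data, and subtype blocks with
# stage/survival signal in bulk cohorts. Every downstream stage of the
# package can be checked against the ground truth these generators record.

crg_gene_names <- function(n) sprintf("CRG%03d", seq_len(n))

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the study conditions the package emulates: a two-sample
#' single-cell experiment (stable vs vulnerable plaque, ~2,400 cells before
#' QC) with eight planted co-expression modules of 50 genes, one of them a
#' circadian module suppressed in vulnerable cells; and a bulk discovery
#' cohort of 436 samples split into four subtypes of sizes 124/93/87/132
#' with circadian suppression strongest in subtype 2, stage labels and
#' exponential survival.
#'
#' @param n_cells Cells in the single-cell matrix (pre-QC).
#' @param n_genes Genes in each generated matrix.
#' @param n_samples_per_subtype Bulk cohort subtype sizes; its length defines
#'   the number of subtypes.
#' @param n_modules Planted co-expression modules (module 1 is circadian).
#' @param module_size Genes per module; the circadian module's genes are the
#'   CADCR gene set (`CRG...` identifiers shared between single-cell and
#'   bulk).
#' @param crg_suppression_delta Log-scale downward shift of circadian genes
#'   in vulnerable cells / subtype 2 (subtype 3 gets half of it). Must be
#'   >= 0.
#' @param mito_gene_fraction Fraction of genes given an `MT-` prefix.
#' @param qc_violator_fraction Fraction of cells planted to violate at least
#'   one QC rule.
#' @param nb_dispersion Negative-binomial size parameter for single-cell
#'   counts (smaller = more overdispersed).
#' @param hazard_ratio_by_subtype Per-subtype hazard ratios for the
#'   exponential survival times.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(n_cells = 2400L,
                       n_genes = 3000L,
                       n_samples_per_subtype = c(124L, 93L, 87L, 132L),
                       n_modules = 8L,
                       module_size = 50L,
                       crg_suppression_delta = 1.0,
                       mito_gene_fraction = 0.02,
                       qc_violator_fraction = 0.05,
                       nb_dispersion = 3,
                       hazard_ratio_by_subtype = c(1, 3, 1.5, 1),
                       seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_samples_per_subtype = as.integer(n_samples_per_subtype),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              crg_suppression_delta = crg_suppression_delta,
              mito_gene_fraction = mito_gene_fraction,
              qc_violator_fraction = qc_violator_fraction,
              nb_dispersion = nb_dispersion,
              hazard_ratio_by_subtype = as.numeric(hazard_ratio_by_subtype),
              seed = as.integer(seed))
  counts <- c(cfg$n_cells, cfg$n_genes, cfg$n_modules, cfg$module_size,
              cfg$n_samples_per_subtype)
  if (any(counts <= 0L)) stop("all counts in SimConfig must be positive")
  props <- c(cfg$mito_gene_fraction, cfg$qc_violator_fraction)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$crg_suppression_delta < 0) stop("crg_suppression_delta must be >= 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (length(cfg$hazard_ratio_by_subtype) !=
        length(cfg$n_samples_per_subtype)) {
    stop("hazard_ratio_by_subtype must have one entry per subtype")
  }
  if (any(cfg$hazard_ratio_by_subtype <= 0)) {
    stop("hazard ratios must be positive")
  }
  structure(cfg, class = "SimConfig")
}

#' Generate a synthetic two-sample single-cell count matrix
#'
#' Negative-binomial counts with gene means drawn log-normal. Genes are
#' partitioned into `n_modules` correlated blocks (shared latent factor per
#' block, loading 0.8) plus mitochondrial (`MT-` prefixed) and background
#' genes. Module 1 is the circadian module: its genes carry `CRG`
#' identifiers and their mean log-expression is lowered by
#' `crg_suppression_delta` in vulnerable cells. A planted fraction of cells
#' violates at least one QC rule (too few detected genes, or mitochondrial
#' fraction above threshold); the violators are recorded in the truth.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (counts `ExpressionMatrix`) and `truth`
#'   (labels, module membership, CRG genes, planted QC violators).
#' @export
generate_single_cell <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n_mod_genes <- config$n_modules * config$module_size
  if (n_mod_genes > config$n_genes) {
    stop("module_size x n_modules exceeds n_genes")
  }
  n_mito <- round(config$mito_gene_fraction *
                    (config$n_genes - n_mod_genes))
  n_bg <- config$n_genes - n_mod_genes - n_mito
  gene_ids <- c(
    crg_gene_names(config$module_size),
    unlist(lapply(seq_len(config$n_modules - 1L) + 1L, function(m) {
      sprintf("M%dG%03d", m, seq_len(config$module_size))
    })),
    if (n_mito > 0L) sprintf("MT-G%03d", seq_len(n_mito)),
    sprintf("BG%05d", seq_len(n_bg))
  )
  module <- c(rep(seq_len(config$n_modules), each = config$module_size),
              rep(0L, n_mito + n_bg))
  names(module) <- gene_ids

  n_stable <- config$n_cells %/% 2L
  labels <- c(rep("stable", n_stable),
              rep("vulnerable", config$n_cells - n_stable))
  cell_ids <- sprintf("cell%05d", seq_len(config$n_cells))
  names(labels) <- cell_ids

  out <- with_seed(config$seed, {
    log_mu <- numeric(config$n_genes)
    log_mu[module > 0L] <- stats::rnorm(n_mod_genes, 1.2, 0.3)
    is_mito <- startsWith(gene_ids, "MT-")
    log_mu[is_mito] <- stats::rnorm(n_mito, 1.0, 0.3)
    is_bg <- !is_mito & module == 0L
    log_mu[is_bg] <- stats::rnorm(n_bg, -0.8, 1.0)

    lmu <- matrix(log_mu, config$n_genes, config$n_cells)
    latent <- matrix(stats::rnorm(config$n_modules * config$n_cells),
                     config$n_modules, config$n_cells)
    for (m in seq_len(config$n_modules)) {
      lmu[module == m, ] <- sweep(lmu[module == m, , drop = FALSE], 2L,
                                  0.8 * latent[m, ], "+")
    }
    vuln <- labels == "vulnerable"
    lmu[module == 1L, vuln] <- lmu[module == 1L, vuln] -
      config$crg_suppression_delta

    counts <- matrix(
      stats::rnbinom(length(lmu), mu = exp(lmu), size = config$nb_dispersion),
      config$n_genes, config$n_cells, dimnames = list(gene_ids, cell_ids))

    n_viol <- round(config$qc_violator_fraction * config$n_cells)
    violators <- character(0)
    viol_type <- character(0)
    if (n_viol > 0L) {
      vidx <- sample.int(config$n_cells, n_viol)
      violators <- cell_ids[vidx]
      # alternate between the two planted failure modes
      low <- vidx[seq_along(vidx) %% 2L == 1L]
      high <- setdiff(vidx, low)
      if (n_mito == 0L) {
        low <- vidx
        high <- integer(0)
      }
      for (ci in low) {
        keep <- sample.int(config$n_genes, min(80L, config$n_genes))
        drop <- setdiff(seq_len(config$n_genes), keep)
        counts[drop, ci] <- 0
      }
      if (length(high) > 0L) {
        mito_rows <- which(is_mito)
        for (ci in high) {
          other <- sum(counts[-mito_rows, ci])
          counts[mito_rows, ci] <- counts[mito_rows, ci] +
            ceiling(max(other, 1) / n_mito)
        }
      }
      viol_type <- ifelse(cell_ids[vidx] %in% cell_ids[low],
                          "low_genes", "high_mito")
      names(viol_type) <- cell_ids[vidx]
    }
    list(counts = counts, violators = violators, viol_type = viol_type)
  })

  truth <- structure(list(
    cell_or_sample_labels = labels,
    module_membership = module,
    crg_genes = crg_gene_names(config$module_size),
    qc_violators = out$violators,
    violation_type = out$viol_type,
    survival_time = NULL, event = NULL
  ), class = "SyntheticTruth")
  list(matrix = expression_matrix(out$counts, "counts"), truth = truth)
}

# Per-sample mean-shift matrix encoding the planted bulk subtype structure.
# Split out so effect sizes can be zeroed for null calibration experiments.
bulk_effect_matrix <- function(gene_ids, subtype, crg, marker_block,
                               marker_effect, crg_pattern_effect,
                               crg_global_shift) {
  n_sub <- length(unique(subtype))
  eff <- matrix(0, length(gene_ids), length(subtype),
                dimnames = list(gene_ids, NULL))
  for (s in seq_len(n_sub)) {
    eff[marker_block == s, subtype == s] <-
      eff[marker_block == s, subtype == s] + marker_effect
  }
  # balanced sub-block pattern on the CRG genes: separates all subtypes in
  # CRG space while leaving each subtype's mean CRG expression unchanged
  n_crg <- length(crg)
  per <- n_crg %/% n_sub
  if (per > 0L && n_sub > 1L) {
    for (s in seq_len(n_sub)) {
      sub_genes <- crg[((s - 1L) * per + 1L):(s * per)]
      eff[sub_genes, ] <- eff[sub_genes, ] - crg_pattern_effect / (n_sub - 1L)
      eff[sub_genes, subtype == s] <- eff[sub_genes, subtype == s] +
        crg_pattern_effect + crg_pattern_effect / (n_sub - 1L)
    }
  }
  # global suppression: subtype 2 strongest, subtype 3 half, others none
  shift <- numeric(n_sub)
  if (n_sub >= 2L) shift[2L] <- -crg_global_shift
  if (n_sub >= 3L) shift[3L] <- -crg_global_shift / 2
  for (s in seq_len(n_sub)) {
    eff[crg, subtype == s] <- eff[crg, subtype == s] + shift[s]
  }
  eff
}

#' Generate a synthetic bulk discovery cohort with planted subtypes
#'
#' Gaussian log2-scale expression. Each subtype has a disjoint 50-gene
#' up-regulated marker block; the CADCR (`CRG`) genes carry a balanced
#' subtype-specific sub-block pattern (so the subtypes are separable on the
#' CRG signature alone) plus a global downward shift that is strongest in
#' subtype 2 and half as strong in subtype 3, making subtype 2 the planted
#' high-CRDscore group. Ordinal stage labels (5 groups) are drawn from a
#' proportional-odds model skewed toward severe stages in subtype 2, and
#' survival times are exponential with per-subtype hazard ratios under
#' uniform censoring.
#'
#' @param config A [sim_config()].
#' @param marker_effect Up-shift of each subtype's marker block
#'   (log2 units).
#' @param crg_pattern_effect Magnitude of the balanced CRG sub-block
#'   pattern.
#' @param noise_sd Residual standard deviation.
#' @return List with `matrix` (`log2tpm` layer) and `truth` (subtype labels,
#'   marker blocks, CRG genes, stage, survival).
#' @export
generate_bulk_cohort <- function(config, marker_effect = 1.8,
                                 crg_pattern_effect = 0.8, noise_sd = 1.0) {
  stopifnot(inherits(config, "SimConfig"))
  sizes <- config$n_samples_per_subtype
  if (any(sizes < 3L)) stop("every subtype needs at least 3 samples")
  n_sub <- length(sizes)
  n <- sum(sizes)
  marker_block_size <- 50L
  n_crg <- config$module_size
  need <- n_crg + n_sub * marker_block_size
  if (config$n_genes < need) {
    stop(sprintf("n_genes too small for planted structure (need >= %d)", need))
  }
  crg <- crg_gene_names(n_crg)
  markers <- lapply(seq_len(n_sub), function(s) {
    sprintf("S%dMK%03d", s, seq_len(marker_block_size))
  })
  gene_ids <- c(crg, unlist(markers),
                sprintf("BG%05d", seq_len(config$n_genes - need)))
  marker_block <- integer(config$n_genes)
  names(marker_block) <- gene_ids
  for (s in seq_len(n_sub)) marker_block[markers[[s]]] <- s

  subtype <- rep(seq_len(n_sub), times = sizes)
  sample_ids <- sprintf("s%04d", seq_len(n))
  labels <- factor(paste0("Type", subtype),
                   levels = paste0("Type", seq_len(n_sub)))
  names(labels) <- sample_ids

  out <- with_seed(config$seed, {
    base <- stats::rnorm(config$n_genes, 6, 1.5)
    eff <- bulk_effect_matrix(gene_ids, subtype, crg, marker_block,
                              marker_effect, crg_pattern_effect,
                              config$crg_suppression_delta)
    vals <- matrix(base, config$n_genes, n) + eff +
      matrix(stats::rnorm(config$n_genes * n, 0, noise_sd),
             config$n_genes, n)
    vals[vals < 0] <- 0 # log2(TPM + 1) scale is non-negative
    dimnames(vals) <- list(gene_ids, sample_ids)

    # ordinal stage via proportional-odds draw conditioned on subtype
    a <- numeric(n_sub)
    if (n_sub >= 2L) a[2L] <- 2
    if (n_sub >= 3L) a[3L] <- 0.8
    latent <- a[subtype] + stats::rlogis(n)
    stage <- cut(latent, c(-Inf, -2, -0.5, 1, 2.5, Inf),
                 labels = paste0("stage", 1:5), ordered_result = TRUE)
    names(stage) <- sample_ids

    h0 <- 1 / 1000 # baseline hazard per day
    t_event <- stats::rexp(n, rate = h0 * config$hazard_ratio_by_subtype[subtype])
    censor <- stats::runif(n, 0, 2000)
    time <- pmax(pmin(t_event, censor), 0.5)
    event <- as.integer(t_event <= censor)
    names(time) <- names(event) <- sample_ids
    list(vals = vals, stage = stage, time = time, event = event)
  })

  membership <- c(rep("crg", n_crg),
                  paste0("markers_Type", rep(seq_len(n_sub),
                                             each = marker_block_size)),
                  rep("background", config$n_genes - need))
  names(membership) <- gene_ids
  truth <- structure(list(
    cell_or_sample_labels = labels,
    module_membership = membership,
    crg_genes = crg,
    marker_blocks = stats::setNames(markers, paste0("Type", seq_len(n_sub))),
    signature_genes = crg,
    qc_violators = character(0),
    stage = out$stage,
    survival_time = out$time,
    event = out$event
  ), class = "SyntheticTruth")
  list(matrix = expression_matrix(out$vals, "log2tpm"), truth = truth)
}

#' Generate independent validation cohorts
#'
#' Independent draws from the bulk generative model with distinct seeds,
#' plus cohort-specific global location/scale shifts that mimic platform
#' differences between expression arrays.
#'
#' @param config A [sim_config()]; each cohort uses `config$seed + 1000 * i`.
#' @param n_cohorts Number of cohorts (>= 1).
#' @param location_sd SD of the cohort-level additive shift.
#' @param scale_sd SD (log scale) of the cohort-level multiplicative shift.
#' @param ... Passed to [generate_bulk_cohort()].
#' @return List of `list(matrix, truth)` pairs.
#' @export
generate_validation_cohorts <- function(config, n_cohorts,
                                        location_sd = 0.3, scale_sd = 0.1,
                                        ...) {
  stopifnot(inherits(config, "SimConfig"))
  if (n_cohorts < 1L) stop("n_cohorts must be >= 1")
  lapply(seq_len(n_cohorts), function(i) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * i
    cohort <- generate_bulk_cohort(cfg, ...)
    shift <- with_seed(cfg$seed + 1L, {
      list(location = stats::rnorm(1, 0, location_sd),
           scale = exp(stats::rnorm(1, 0, scale_sd)))
    })
    v <- cohort$matrix$values * shift$scale + shift$location
    v[v < 0] <- 0
    cohort$matrix <- expression_matrix(v, "log2tpm")
    cohort$truth$cohort_shift <- shift
    cohort$truth$seed <- cfg$seed
    cohort
  })
}
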