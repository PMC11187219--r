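# End-to-end orchestration: synthetic single-cell discovery of the
# circadian module and its hubs, CRD scoring of single-cell and bulk data,
# consensus subtyping of the bulk cohort, NTP validation, and the
# downstream statistics, all gathered into a machine-readable run report.

#' Pipeline run configuration
#'
#' Collects every stage parameter and per-stage seed. Defaults mirror the
#' generators' study conditions with consensus/NTP resampling reduced to
#' 200 repetitions; set `reps` and `n_perm` to 1000 for full-scale runs.
#'
#' @param sim A [sim_config()] for the synthetic cohorts.
#' @param qc A [qc_thresholds()].
#' @param n_hvg Highly variable genes kept for network construction.
#' @param power Soft threshold for the TOM; the scale-free selector's fit
#'   table is always reported, but block-structured synthetic data is not
#'   scale-free, so a fixed moderate default is used for module detection.
#' @param min_module_size,cut_height Module detection parameters.
#' @param n_hubs Hub genes taken from the circadian module.
#' @param n_bins,n_random_features CRDscore parameters.
#' @param k_range,reps,subsample_fraction Consensus clustering parameters.
#' @param n_markers,n_perm NTP parameters.
#' @param seeds Named list of per-stage seeds (`score`, `consensus`,
#'   `ntp`); generator seeds live in `sim$seed`.
#' @param out_dir Optional directory for artifacts (TSV/GMT/JSON with
#'   checksums).
#' @return A `RunConfig` list.
#' @export
run_config <- function(sim = sim_config(), qc = qc_thresholds(),
                       n_hvg = 1200L, power = 4L, min_module_size = 30L,
                       cut_height = 0.99, n_hubs = 25L, n_bins = 25L,
                       n_random_features = 1000L, k_range = 2:6,
                       reps = 200L, subsample_fraction = 0.8,
                       n_markers = 50L, n_perm = 200L,
                       seeds = list(score = 11L, consensus = 12L,
                                    ntp = 13L),
                       out_dir = NULL) {
  stopifnot(inherits(sim, "SimConfig"), inherits(qc, "QCThresholds"))
  for (nm in c("score", "consensus", "ntp")) {
    if (is.null(seeds[[nm]])) stop("missing seed: ", nm)
  }
  structure(list(sim = sim, qc = qc, n_hvg = as.integer(n_hvg),
                 power = as.integer(power),
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, n_hubs = as.integer(n_hubs),
                 n_bins = as.integer(n_bins),
                 n_random_features = as.integer(n_random_features),
                 k_range = as.integer(k_range), reps = as.integer(reps),
                 subsample_fraction = subsample_fraction,
                 n_markers = as.integer(n_markers),
                 n_perm = as.integer(n_perm), seeds = seeds,
                 out_dir = out_dir),
            class = "RunConfig")
}

run_stage <- function(stage, expr) {
  tryCatch(force(expr), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the discovery analysis end-to-end
#'
#' Generates the synthetic single-cell and bulk cohorts, runs QC,
#' normalization and HVG selection, builds the co-expression network and
#' detects modules, designates as M1 the module whose eigengene best
#' separates vulnerable from stable cells (largest rank-based AUC
#' deviation), takes its kME hub genes as the CADCR set, computes CRDscore
#' on both cohorts with the matching level rules, derives consensus
#' subtypes of the bulk cohort on the hub signature, and summarizes
#' per-subtype score differences, stage composition and survival.
#'
#' @param config A [run_config()].
#' @return A `run_report` list (seeds, per-stage summaries, chosen k,
#'   subtype sizes, test summaries), with heavyweight objects (templates,
#'   consensus result, truth) attached in its `objects` element.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  sc <- run_stage("simulate_single_cell", generate_single_cell(config$sim))
  bulk <- run_stage("simulate_bulk", generate_bulk_cohort(config$sim))

  filtered <- run_stage("qc", qc_filter(sc$matrix, config$qc))
  qc_report <- attr(filtered, "qc_report")
  norm <- run_stage("normalize", lognormalize(filtered))
  hvg <- run_stage("hvg", select_hvg(norm, n_top = config$n_hvg))
  net_expr <- norm[hvg$genes, ]

  sft <- run_stage("soft_threshold", pick_soft_threshold(net_expr))
  net <- run_stage("tom", build_tom(net_expr, power = config$power))
  modules <- run_stage("modules",
                       detect_modules(net,
                                      min_module_size = config$min_module_size,
                                      cut_height = config$cut_height))
  if (!any(modules > 0)) stop("pipeline stage 'modules' failed: no modules")
  eg <- run_stage("eigengenes", module_eigengene(net_expr, modules))
  kme <- run_stage("kme", compute_kme(net_expr, eg))

  # M1 designation: eigengene most associated with the vulnerable group
  cell_groups <- sc$truth$cell_or_sample_labels[samples(net_expr)]
  mod_ids <- sort(unique(modules[modules > 0]))
  assoc <- vapply(mod_ids, function(m) {
    e <- eg[paste0("ME", m), ]
    r <- rank(e)
    n1 <- sum(cell_groups == "vulnerable")
    n0 <- sum(cell_groups == "stable")
    auc <- (sum(r[cell_groups == "vulnerable"]) - n1 * (n1 + 1) / 2) /
      (n1 * n0)
    abs(auc - 0.5)
  }, numeric(1L))
  m1 <- mod_ids[which.max(assoc)]
  hubs <- run_stage("hubs", hub_genes(kme, modules, m1,
                                      n_hubs = config$n_hubs))

  sc_score <- run_stage("crdscore_sc", classify_crd_level(
    compute_crdscore(norm, hubs, n_bins = config$n_bins,
                     n_random_features = config$n_random_features,
                     seed = config$seeds$score),
    mode = "single_cell"))
  sc_groups <- sc$truth$cell_or_sample_labels[sc_score$scores$sample]
  sc_compare <- run_stage("crd_group_test",
                          compare_crd_between_groups(sc_score, sc_groups))

  bulk_score <- run_stage("crdscore_bulk", classify_crd_level(
    compute_crdscore(bulk$matrix, hubs, n_bins = config$n_bins,
                     n_random_features = config$n_random_features,
                     seed = config$seeds$score),
    mode = "bulk"))

  cons <- run_stage("consensus", consensus_cluster(
    bulk$matrix, signature = hubs, k_range = config$k_range,
    reps = config$reps, subsample_fraction = config$subsample_fraction,
    seed = config$seeds$consensus))
  chosen_k <- as.integer(cons$chosen_k)
  assign <- cons$per_k[[paste0("k", chosen_k)]]$assignments
  subtype <- paste0("Type", assign)

  subtype_compare <- run_stage("subtype_score_test",
                               compare_crd_between_groups(bulk_score, subtype))
  medians <- tapply(bulk_score$scores$crdscore, subtype, stats::median)
  comp <- run_stage("composition",
                    composition_table(bulk$truth$stage, subtype))
  surv_df <- data.frame(time = bulk$truth$survival_time,
                        event = bulk$truth$event, group = subtype)
  surv <- run_stage("survival", km_logrank(surv_df))

  templates <- run_stage("templates",
                         build_templates(bulk$matrix, subtype,
                                         n_markers = config$n_markers))

  report <- list(
    schema_version = "1.0",
    seeds = c(list(sim = config$sim$seed), config$seeds),
    qc = list(cells_in = nrow(qc_report), cells_kept = sum(qc_report$kept)),
    n_hvg = length(hvg$genes),
    soft_threshold = list(picked = sft$power, used = config$power,
                          max_signed_r2 = max(sft$fit_table$signed_r2,
                                              na.rm = TRUE)),
    modules = list(n_modules = length(mod_ids),
                   sizes = as.list(table(modules[modules > 0])),
                   m1 = m1, m1_auc_deviation = unname(max(assoc))),
    hubs = hubs$genes,
    crd_single_cell = list(
      n_high = sum(sc_score$scores$crd_level == "high"),
      test = list(method = sc_compare$method, p = sc_compare$p_value),
      median_by_group = lapply(split(sc_score$scores$crdscore, sc_groups),
                               stats::median)),
    consensus = list(chosen_k = chosen_k,
                     rationale = attr(cons$chosen_k, "rationale"),
                     delta_area = cons$cdf$delta_area,
                     subtype_sizes = as.list(table(subtype))),
    crd_bulk = list(median_by_subtype = as.list(medians),
                    highest_subtype = names(which.max(medians)),
                    test = list(method = subtype_compare$method,
                                p = subtype_compare$p_value)),
    composition = list(p = comp$test$p_value,
                       severe_share = as.list(
                         comp$proportions[, ncol(comp$proportions)])),
    survival = list(chisq = surv$test$statistic, p = surv$test$p_value)
  )
  out <- structure(list(report = report,
                        objects = list(templates = templates,
                                       consensus = cons,
                                       subtype = subtype,
                                       hubs = hubs,
                                       sc_truth = sc$truth,
                                       bulk_truth = bulk$truth,
                                       bulk_matrix = bulk$matrix,
                                       bulk_score = bulk_score)),
                   class = "run_report")
  if (!is.null(config$out_dir)) {
    out$report$artifacts <- write_run_artifacts(out, config$out_dir)
  }
  out
}

#' Run NTP validation on independent cohorts
#'
#' @param config A [run_config()].
#' @param templates A [build_templates()] result from the discovery run.
#' @param cohorts List of `list(matrix, truth)` validation cohorts, e.g.
#'   from [generate_validation_cohorts()].
#' @return A `run_report` with per-cohort NTP accuracy (when truth labels
#'   are attached) and per-subtype CRDscore comparisons.
#' @export
run_validation <- function(config, templates, cohorts) {
  stopifnot(inherits(config, "RunConfig"),
            inherits(templates, "SubtypeTemplates"))
  if (length(cohorts) == 0L) stop("empty cohort list")
  per_cohort <- lapply(seq_along(cohorts), function(i) {
    co <- cohorts[[i]]
    pred <- run_stage(paste0("ntp_cohort", i),
                      ntp_predict(co$matrix, templates,
                                  n_perm = config$n_perm,
                                  seed = config$seeds$ntp + i))
    score <- run_stage(paste0("crdscore_cohort", i), classify_crd_level(
      compute_crdscore(co$matrix, co$truth$crg_genes,
                       n_bins = config$n_bins,
                       n_random_features = config$n_random_features,
                       seed = config$seeds$score),
      mode = "bulk"))
    cmp <- run_stage(paste0("score_test_cohort", i),
                     compare_crd_between_groups(score,
                                                pred$predicted_subtype))
    medians <- tapply(score$scores$crdscore, pred$predicted_subtype,
                      stats::median)
    # consensus-derived template labels are arbitrary numberings, so
    # accuracy is reported under the best one-to-one label matching
    acc <- if (!is.null(co$truth$cell_or_sample_labels)) {
      matched_accuracy(pred$predicted_subtype,
                       as.character(co$truth$cell_or_sample_labels))
    } else {
      NA_real_
    }
    list(n = nrow(pred), accuracy = acc,
         confident = mean(pred$fdr < 0.05),
         highest_subtype = names(which.max(medians)),
         median_by_subtype = as.list(medians),
         test = list(method = cmp$method, p = cmp$p_value))
  })
  structure(list(report = list(schema_version = "1.0",
                               seeds = config$seeds,
                               n_cohorts = length(cohorts),
                               cohorts = per_cohort)),
            class = "run_report")
}

write_run_artifacts <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  obj <- run$objects
  f <- file.path(out_dir, "subtype_assignments.tsv")
  utils::write.table(
    data.frame(sample = samples(obj$bulk_matrix), subtype = obj$subtype),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(out_dir, "m1_hubs.gmt")
  write_gmt(obj$hubs, f)
  paths <- c(paths, f)
  f <- file.path(out_dir, "bulk_crdscore.tsv")
  utils::write.table(obj$bulk_score$scores, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, f)
  sums <- tools::md5sum(paths)
  lapply(seq_along(paths), function(i) {
    list(path = basename(paths[i]), md5 = unname(sums[i]))
  })
}

#' Write a run report as canonical JSON
#'
#' The serialization is deterministic: identical configurations and seeds
#' produce byte-identical files.
#'
#' @param run A `run_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  stopifnot(inherits(run, "run_report"))
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
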