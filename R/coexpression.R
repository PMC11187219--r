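# WGCNA-style single-cell co-expression analysis: soft-threshold selection
# by scale-free fit, unsigned topological overlap, static-cut module
# detection, module eigengenes, kME and hub genes.

#' Choose a soft-threshold power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed,
#' per-gene connectivity computed, and the scale-free fit measured as the
#' signed R^2 of `log10(frequency)` against `log10(connectivity)` over 10
#' connectivity bins (sign flipped so that the expected negative slope gives
#' a positive fit index). Returns the smallest power reaching `r2_target`,
#' or the power maximizing the fit when none does.
#'
#' @param expr `ExpressionMatrix` with >= 30 genes and >= 10 samples.
#' @param powers Candidate integer powers (default 1..20).
#' @param r2_target Fit threshold (default 0.8).
#' @return List with `power` (chosen) and `fit_table` (power, signed R^2,
#'   slope, mean/median/max connectivity).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.8) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  v <- expr$values
  keep <- row_vars(v) > 0
  if (!any(keep)) stop("all genes are constant")
  if (sum(!keep) > 0) {
    warning(sprintf("removed %d constant gene(s)", sum(!keep)))
    v <- v[keep, , drop = FALSE]
  }
  if (nrow(v) < 30L || ncol(v) < 10L) {
    stop("need >= 30 genes and >= 10 samples for scale-free fitting")
  }
  cors <- abs(stats::cor(t(v)))
  rows <- lapply(powers, function(p) {
    a <- cors^p
    diag(a) <- 1
    k <- rowSums(a) - 1
    br <- cut(k, breaks = 10)
    k_mean <- tapply(k, br, mean)
    freq <- tapply(k, br, length)
    ok <- !is.na(k_mean) & k_mean > 0 & !is.na(freq)
    if (sum(ok) < 3L) {
      return(data.frame(power = p, signed_r2 = NA_real_, slope = NA_real_,
                        mean_k = mean(k), median_k = stats::median(k),
                        max_k = max(k)))
    }
    fit <- stats::lm(log10(freq[ok]) ~ log10(k_mean[ok]))
    slope <- unname(stats::coef(fit)[2L])
    r2 <- summary(fit)$r.squared
    data.frame(power = p, signed_r2 = -sign(slope) * r2, slope = slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$signed_r2) & tab$signed_r2 >= r2_target)
  power <- if (length(hit) > 0L) {
    tab$power[hit[1L]]
  } else {
    tab$power[which.max(tab$signed_r2)]
  }
  list(power = power, fit_table = tab)
}

#' Build the unsigned topological overlap matrix
#'
#' Adjacency `a_ij = |cor(i,j)|^beta` with unit diagonal;
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 - a_ij)` with the
#' sum over u distinct from i and j and `k` the node connectivity;
#' `TOM_ii = 1`.
#'
#' @param expr `ExpressionMatrix` with no constant genes.
#' @param power Positive integer soft threshold.
#' @return A `CoexpressionNetwork` list: `power`, `adjacency`, `tom`.
#' @export
build_tom <- function(expr, power) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (power < 1) stop("power must be >= 1")
  v <- expr$values
  if (any(row_vars(v) == 0)) stop("constant genes must be removed first")
  a <- abs(stats::cor(t(v)))^power
  diag(a) <- 1
  k <- rowSums(a) - 1
  numer <- a %*% a - a # = sum_{u != i,j} a_iu a_uj + a_ij  (unit diagonal)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- numer / denom
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  structure(list(power = power, adjacency = a, tom = tom,
                 module_labels = NULL, eigengenes = NULL, kme = NULL),
            class = "CoexpressionNetwork")
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a fixed
#' height; clusters below `min_module_size` become grey (label 0) and the
#' rest are renumbered 1..M by decreasing size.
#'
#' @param network A [build_tom()] result.
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height Static cut height on `1 - TOM` (default 0.99).
#' @return Named integer vector of module labels (0 = grey).
#' @export
detect_modules <- function(network, min_module_size = 30L,
                           cut_height = 0.99) {
  stopifnot(inherits(network, "CoexpressionNetwork"))
  tom <- network$tom
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  big <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- integer(length(raw))
  names(labels) <- rownames(tom)
  if (length(big) > 0L) {
    ord <- big[order(-sizes[as.character(big)], big)]
    for (m in seq_along(ord)) labels[raw == ord[m]] <- m
  }
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' z-scored expression submatrix, oriented so its mean correlation with the
#' member genes is positive, and scaled to unit variance.
#'
#' @param expr `ExpressionMatrix`.
#' @param module_labels Output of [detect_modules()].
#' @return Matrix of eigengenes (module x sample), rows named `ME1`, `ME2`,
#'   ...
#' @export
module_eigengene <- function(expr, module_labels) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  mods <- sort(unique(module_labels[module_labels > 0]))
  if (length(mods) == 0L) stop("no non-grey modules")
  eg <- matrix(0, length(mods), ncol(expr$values),
               dimnames = list(paste0("ME", mods), samples(expr)))
  for (i in seq_along(mods)) {
    member <- names(module_labels)[module_labels == mods[i]]
    if (length(member) < 2L) stop("module with fewer than 2 genes")
    x <- zscore_rows(expr$values[member, , drop = FALSE])
    sv <- svd(x, nu = 0, nv = 1)
    e <- sv$v[, 1L]
    if (mean(stats::cor(t(x), e)) < 0) e <- -e
    eg[i, ] <- e / stats::sd(e)
  }
  eg
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's profile with each module eigengene.
#'
#' @param expr `ExpressionMatrix`.
#' @param eigengenes Output of [module_eigengene()].
#' @return Genes x modules correlation matrix.
#' @export
compute_kme <- function(expr, eigengenes) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  stats::cor(t(expr$values), t(eigengenes))
}

#' Hub genes of a module by kME
#'
#' A module's hub genes are its members with the largest kME to their own
#' eigengene, ties broken by gene identifier order.
#'
#' @param kme [compute_kme()] matrix.
#' @param module_labels [detect_modules()] labels.
#' @param module Module id (> 0).
#' @param n_hubs Number of hubs (default 25); capped at the module size.
#' @return A `GeneSet` named `M<module>_hubs`.
#' @export
hub_genes <- function(kme, module_labels, module, n_hubs = 25L) {
  if (n_hubs < 1L) stop("n_hubs must be >= 1")
  member <- names(module_labels)[module_labels == module]
  if (length(member) == 0L) stop("module has no members")
  col <- paste0("ME", module)
  k <- kme[member, col]
  ord <- order(-k, member)
  take <- member[ord][seq_len(min(n_hubs, length(member)))]
  gene_set(sprintf("M%d_hubs", module), take)
}
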