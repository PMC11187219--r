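#' Gene-by-sample expression matrix with a layer tag
#'
#' Light container used throughout the package: a numeric genes x samples
#' matrix plus a `layer` tag recording what the values are. `counts` must be
#' non-negative integers; `lognorm` is natural-log library-size-normalized
#' expression; `log2tpm` is log2(TPM + 1); `scaled` is per-gene z-scored.
#'
#' @param values Numeric matrix, genes in rows, samples/cells in columns,
#'   with unique non-empty dimnames.
#' @param layer One of `"counts"`, `"lognorm"`, `"log2tpm"`, `"scaled"`.
#' @return An `ExpressionMatrix` object (list with elements `values`,
#'   `layer`).
#' @examples
#' m <- matrix(rpois(20, 5), 4, 5,
#'   dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' em <- expression_matrix(m, "counts")
#' dim(em)
#' @export
expression_matrix <- function(values,
                              layer = c("counts", "lognorm", "log2tpm",
                                        "scaled")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (anyNA(values)) stop("expression values must not contain NA")
  if (layer == "counts") {
    if (any(values < 0)) stop("counts must be non-negative")
    if (any(abs(values - round(values)) > 1e-8)) {
      stop("counts layer must contain integer values")
    }
  }
  structure(list(values = values, layer = layer), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param x An `ExpressionMatrix`.
#' @param i Gene index (names, logical or integer).
#' @param j Sample index.
#' @param ... Ignored.
#' @return An `ExpressionMatrix` on the selected genes/samples.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  out <- x
  out$values <- v
  out
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' Gene identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of gene ids.
#' @export
genes <- function(x) rownames(x$values)

#' Sample identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of sample ids.
#' @export
samples <- function(x) colnames(x$values)

#' Named gene set
#'
#' @param name Set name.
#' @param genes Character vector of unique gene identifiers.
#' @return A `GeneSet` object.
#' @export
gene_set <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene set must be non-empty")
  if (anyDuplicated(genes)) stop("gene set contains duplicate identifiers")
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

# Accept a GeneSet or a plain character vector anywhere a set is expected.
as_gene_vector <- function(set) {
  if (inherits(set, "GeneSet")) set$genes else as.character(set)
}
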