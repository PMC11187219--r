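# Readers and writers for the plain-text formats the package exchanges:
# dense expression TSV (genes in rows), MTX triplets with gene/barcode TSVs,
# and GMT gene-set files. All TSVs are tab-delimited UTF-8 with a header row.

#' Read a dense expression TSV
#'
#' Expects a header row; the first column holds gene identifiers, remaining
#' columns one sample each.
#'
#' @param path File path.
#' @param layer Layer tag for the resulting matrix.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, layer = "lognorm") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus samples")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  expression_matrix(m, layer)
}

#' Write a dense expression TSV
#'
#' @param em An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  df <- data.frame(gene = genes(em), em$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MTX triplet (matrix.mtx + genes.tsv + barcodes.tsv)
#'
#' `genes_path` and `barcodes_path` are one-column TSVs with a header row.
#'
#' @param mtx_path MatrixMarket file with genes in rows.
#' @param genes_path TSV of gene identifiers.
#' @param barcodes_path TSV of cell barcodes.
#' @param layer Layer tag, default `"counts"`.
#' @return An [expression_matrix()] (dense).
#' @export
read_expression_mtx <- function(mtx_path, genes_path, barcodes_path,
                                layer = "counts") {
  m <- as.matrix(Matrix::readMM(mtx_path))
  g <- utils::read.delim(genes_path, stringsAsFactors = FALSE)[[1L]]
  b <- utils::read.delim(barcodes_path, stringsAsFactors = FALSE)[[1L]]
  if (length(g) != nrow(m) || length(b) != ncol(m)) {
    stop("gene/barcode lists do not match matrix dimensions")
  }
  dimnames(m) <- list(as.character(g), as.character(b))
  expression_matrix(m, layer)
}

#' Write an MTX triplet
#'
#' @param em An `ExpressionMatrix` (counts recommended).
#' @param dir Output directory; creates `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @return The directory, invisibly.
#' @export
write_expression_mtx <- function(em, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(em$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene = genes(em)),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(barcode = samples(em)),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (name, description, then genes, tab-separated).
#' @return Named list of `GeneSet` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    gene_set(parts[1L], unique(parts[-c(1L, 2L)]))
  })
  names(sets) <- vapply(sets, function(s) s$name, character(1L))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A `GeneSet`, character vector, or (named) list of either.
#' @param path Output path.
#' @param description Description field (second GMT column).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "crdsubtype") {
  if (inherits(sets, "GeneSet") || is.character(sets)) sets <- list(sets)
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    nm <- if (inherits(s, "GeneSet")) s$name else names(sets)[i] %||%
      paste0("set", i)
    paste(c(nm, description, as_gene_vector(s)), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
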