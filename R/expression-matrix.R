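#' Expression matrix container
#'
#' The package-wide container for expression values. Cells are ROWS and
#' genes are COLUMNS everywhere internally; readers transpose files that
#' are declared gene x cell. The `unit` tag makes the transformation state
#' explicit so downstream operations can enforce their preconditions.
#'
#' @param values numeric matrix, cells x genes.
#' @param unit one of `"raw_tpm"`, `"log2_tpm1"`, `"counts"`,
#'   `"normalized_log"`.
#' @param cell_ids,gene_ids optional id vectors; default to the dimnames
#'   of `values`.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` (dimnamed matrix) and `unit`.
#' @export
expression_matrix <- function(values, unit, cell_ids = rownames(values),
                              gene_ids = colnames(values)) {
  unit <- match.arg(unit, c("raw_tpm", "log2_tpm1", "counts", "normalized_log"))
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("number of cell_ids (", length(cell_ids), ") != rows (", nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("number of gene_ids (", length(gene_ids), ") != columns (", ncol(values), ")")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell id: ", cell_ids[duplicated(cell_ids)][1])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1])
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (unit %in% c("raw_tpm", "counts") && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative value under unit '", unit, "' at cell '",
         cell_ids[bad[1]], "', gene '", gene_ids[bad[2]], "'")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, unit = unit), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "cells x", ncol(x$values),
      "genes, unit =", x$unit, "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Cell and gene identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of ids.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' Subset an ExpressionMatrix by cells and/or genes
#' @param x an `ExpressionMatrix`.
#' @param cells,genes index, logical or id vectors; NULL keeps all.
#' @return an `ExpressionMatrix` with the same unit.
#' @export
em_subset <- function(x, cells = NULL, genes = NULL) {
  v <- x$values
  if (!is.null(cells)) v <- v[cells, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  expression_matrix(v, x$unit)
}

#' Log-transform raw TPM values
#'
#' @param x an `ExpressionMatrix` with unit `raw_tpm` or `counts`.
#' @return `ExpressionMatrix` of log2(value + 1), unit `log2_tpm1`.
#' @export
em_log2 <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!x$unit %in% c("raw_tpm", "counts"))
    stop("em_log2 expects raw_tpm or counts, got ", x$unit)
  expression_matrix(log2(x$values + 1), "log2_tpm1")
}

#' Read an expression matrix from disk
#'
#' Two dialects are supported. `tsv_dense`: a tab-separated table whose
#' first column holds row ids and whose header holds column ids.
#' `matrix_market_triplet`: a MatrixMarket `.mtx` file accompanied by two
#' plain-text id files (one id per line) for its rows and columns, by
#' default `<path>.rows` and `<path>.cols`.
#'
#' @param path file path.
#' @param format `"tsv_dense"` or `"matrix_market_triplet"`.
#' @param unit declared unit of the stored values (see
#'   [expression_matrix()]).
#' @param orientation how the FILE is laid out: `"cells_x_genes"`
#'   (default) or `"genes_x_cells"`; the returned object is always
#'   cells x genes.
#' @param row_ids_path,col_ids_path id files for the MatrixMarket dialect.
#' @return an `ExpressionMatrix`.
#' @export
read_expression <- function(path,
                            format = c("tsv_dense", "matrix_market_triplet"),
                            unit = "raw_tpm",
                            orientation = c("cells_x_genes", "genes_x_cells"),
                            row_ids_path = paste0(path, ".rows"),
                            col_ids_path = paste0(path, ".cols")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "tsv_dense") {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    row_ids <- as.character(df[[1]])
    header_ids <- colnames(df)[-1]
    if (anyDuplicated(header_ids))
      stop("duplicate column id in ", path, ": ",
           header_ids[duplicated(header_ids)][1])
    if (anyDuplicated(row_ids))
      stop("duplicate row id in ", path, ": ", row_ids[duplicated(row_ids)][1])
    m <- as.matrix(df[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- row_ids
  } else {
    sm <- Matrix::readMM(path)
    m <- as.matrix(sm)
    if (!file.exists(row_ids_path)) stop("row id file not found: ", row_ids_path)
    if (!file.exists(col_ids_path)) stop("column id file not found: ", col_ids_path)
    rn <- readLines(row_ids_path)
    cn <- readLines(col_ids_path)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("id file lengths do not match matrix dimensions in ", path)
    dimnames(m) <- list(rn, cn)
  }
  if (orientation == "genes_x_cells") m <- t(m)
  expression_matrix(m, unit)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]; `write_expression` followed by
#' `read_expression` with the same dialect round-trips values and ids.
#'
#' @param x an `ExpressionMatrix`.
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path,
                             format = c("tsv_dense", "matrix_market_triplet"),
                             orientation = c("cells_x_genes", "genes_x_cells"),
                             row_ids_path = paste0(path, ".rows"),
                             col_ids_path = paste0(path, ".cols")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  m <- x$values
  if (orientation == "genes_x_cells") m <- t(m)
  if (format == "tsv_dense") {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), row_ids_path)
    writeLines(colnames(m), col_ids_path)
  }
  invisible(path)
}
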