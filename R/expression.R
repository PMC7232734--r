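#' Construct a per-tissue expression matrix
#'
#' The basic data container of the pipeline: one tissue's expression values as
#' a numeric genes x samples matrix with gene identifiers as row names and
#' sample identifiers as column names.
#'
#' @param values Numeric matrix, rows = genes, columns = samples. Must carry
#'   unique row and column names and contain no missing values.
#' @param tissue Single character string identifying the tissue.
#' @return An object of class `expression_matrix`: a list with elements
#'   `tissue` and `values`.
#' @export
expression_matrix <- function(values, tissue) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (length(tissue) != 1L || !is.character(tissue) || is.na(tissue) ||
      !nzchar(tissue))
    stop("'tissue' must be a single non-empty string")
  if (is.null(rownames(values)))
    stop("'values' must have gene identifiers as row names")
  if (is.null(colnames(values)))
    stop("'values' must have sample identifiers as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (anyNA(values))
    stop("missing values are not allowed")
  structure(list(tissue = tissue, values = values),
            class = "expression_matrix")
}

#' Gene identifiers of an expression matrix or network
#' @param x An `expression_matrix` or `coexpression_network`.
#' @return Character vector of gene identifiers.
#' @export
gene_ids <- function(x) UseMethod("gene_ids")

#' @export
gene_ids.expression_matrix <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x An `expression_matrix`.
#' @return Character vector of sample identifiers.
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  colnames(x$values)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: tissue '%s', %d genes x %d samples\n",
              x$tissue, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write an expression matrix as tab-separated text
#'
#' Format: header row of sample identifiers, first column `gene_id`, one row
#' per gene.
#'
#' @param x An `expression_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from tab-separated text
#'
#' @param path File written by [write_expression()] (first column gene
#'   identifiers, header row of sample identifiers).
#' @param tissue Tissue identifier to attach; defaults to the file name
#'   without extension.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, tissue = NULL) {
  if (is.null(tissue))
    tissue <- sub("\\.[^.]*$", "", basename(path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression file must have a gene-id column and >= 1 sample column")
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values))
    stop("non-numeric expression values in ", path)
  rownames(values) <- as.character(df[[1]])
  expression_matrix(values, tissue)
}
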