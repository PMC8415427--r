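# Expression-matrix plumbing: validation plus TSV / MatrixMarket I/O.
# The rank substrate for enrichment is a plain numeric matrix, genes in rows
# (uppercase symbols as rownames), samples in columns.

as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    # first column = gene symbol, remaining columns = samples
    genes <- as.character(expr[[1L]])
    m <- as.matrix(expr[, -1L, drop = FALSE])
    rownames(m) <- genes
    expr <- m
  }
  if (inherits(expr, "Matrix")) {
    expr <- as.matrix(expr)
  }
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric gene x sample matrix")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("`expr` needs gene symbols as rownames and sample ids as colnames")
  }
  rownames(expr) <- toupper(rownames(expr))
  if (anyDuplicated(rownames(expr))) {
    abort("duplicate gene symbols in `expr` rownames")
  }
  expr
}

check_annotations <- function(annotations, sample_ids,
                              required = c("sample_id", "tissue")) {
  ann <- as_tibble(annotations)
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "annotations lack column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(ann$sample_id)) {
    abort("duplicate sample_id in annotations")
  }
  uncovered <- setdiff(sample_ids, ann$sample_id)
  if (length(uncovered) > 0L) {
    abort(paste0(
      length(uncovered), " matrix sample(s) missing from annotations, e.g. ",
      uncovered[1]
    ))
  }
  if ("tissue" %in% required &&
      anyNA(ann$tissue[ann$sample_id %in% sample_ids])) {
    abort("unlabelled sample: `tissue` is NA for a matrix sample")
  }
  ann[match(sample_ids, ann$sample_id), , drop = FALSE]
}

#' Read a gene x sample expression matrix
#'
#' Supports a dense TSV (first column gene symbol, remaining columns samples)
#' and MatrixMarket sparse triplets with row/column name sidecar files.
#'
#' @param path TSV or `.mtx` file.
#' @param format `"auto"` (from extension), `"tsv"` or `"mtx"`.
#' @param row_names,col_names For MatrixMarket input: one-name-per-line
#'   sidecar files; default `<path>.rownames` / `<path>.colnames`.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx"),
                            row_names = NULL, col_names = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) {
    abort(paste0("expression file not found: ", path))
  }
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    return(as_expression_matrix(df))
  }
  row_names <- row_names %||% paste0(path, ".rownames")
  col_names <- col_names %||% paste0(path, ".colnames")
  for (f in c(row_names, col_names)) {
    if (!file.exists(f)) abort(paste0("sidecar file not found: ", f))
  }
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readr::read_lines(row_names)
  colnames(m) <- readr::read_lines(col_names)
  as_expression_matrix(m)
}

#' Write a gene x sample expression matrix
#'
#' @param expr Numeric matrix, genes in rows.
#' @param path Output TSV (`gene` first column) or `.mtx` triplet file with
#'   `.rownames`/`.colnames` sidecars.
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("auto", "tsv", "mtx")) {
  expr <- as_expression_matrix(expr)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    df <- as_tibble(expr, rownames = "gene")
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), path)
    readr::write_lines(rownames(expr), paste0(path, ".rownames"))
    readr::write_lines(colnames(expr), paste0(path, ".colnames"))
  }
  invisible(path)
}
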