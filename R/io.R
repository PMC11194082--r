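#' Read an expression matrix
#'
#' Supported formats: Matrix Market triplet (`.mtx`) with companion barcode
#' and feature lists (one id per line; defaults are `<stem>.barcodes.tsv` and
#' `<stem>.features.tsv` next to the matrix), and dense CSV/TSV with a header
#' row and ids in the first column. On disk the MTX convention is the usual
#' genes-in-rows, cells-in-columns layout (`cells_as = "cols"`); CSV defaults
#' to cells in rows. The returned matrix is always oriented cells x genes.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mtx"`, `"csv"` or `"tsv"`.
#' @param cells_as Whether cells are `"rows"` or `"cols"` on disk. Default:
#'   `"cols"` for MTX, `"rows"` for CSV/TSV.
#' @param barcodes,features Sidecar paths for MTX; defaults derived from
#'   `path`.
#' @param sparse Return a sparse `Matrix` (MTX only). Default `TRUE` for MTX.
#' @return Cells x genes matrix with ids as dimnames.
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                            cells_as = NULL, barcodes = NULL, features = NULL,
                            sparse = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot infer format from extension '", ext,
                          "'; pass `format`", call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    if (is.null(cells_as)) cells_as <- "cols"
    stem <- sub("\\.mtx$", "", path)
    if (is.null(barcodes)) barcodes <- paste0(stem, ".barcodes.tsv")
    if (is.null(features)) features <- paste0(stem, ".features.tsv")
    m <- Matrix::readMM(path)
    cells <- readLines(barcodes)
    genes <- readLines(features)
    if (cells_as == "cols") {
      m <- Matrix::t(m)
    }
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop("MTX dimensions (", nrow(m), " x ", ncol(m), " after orientation) do not match ",
           length(cells), " barcodes and ", length(genes), " features", call. = FALSE)
    }
    dimnames(m) <- list(cells, genes)
    m <- methods::as(m, "CsparseMatrix")
    if (isFALSE(sparse)) m <- as.matrix(m)
  } else {
    if (is.null(cells_as)) cells_as <- "rows"
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric values in ", path, call. = FALSE)
    if (cells_as == "cols") m <- t(m)
  }
  as_expression_matrix(m)
}

#' Write an expression matrix
#'
#' Mirrors [read_expression()]: MTX writes the matrix plus barcode/feature
#' sidecars (cells in columns on disk by default, the common convention);
#' CSV/TSV writes a dense table with ids in the first column (cells in rows
#' by default). `read_expression(write_expression(m, p))` restores values,
#' ids and orientation exactly.
#'
#' @param m Cells x genes matrix.
#' @param path Output path (extension decides the format unless given).
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("auto", "mtx", "csv", "tsv"),
                             cells_as = NULL, barcodes = NULL, features = NULL) {
  m <- as_expression_matrix(m)
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot infer format for '", path, "'", call. = FALSE))
  }
  if (format == "mtx") {
    if (is.null(cells_as)) cells_as <- "cols"
    stem <- sub("\\.mtx$", "", path)
    if (is.null(barcodes)) barcodes <- paste0(stem, ".barcodes.tsv")
    if (is.null(features)) features <- paste0(stem, ".features.tsv")
    sp <- methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
    out <- if (cells_as == "cols") Matrix::t(sp) else sp
    Matrix::writeMM(out, path)
    writeLines(rownames(m), barcodes)
    writeLines(colnames(m), features)
  } else {
    if (is.null(cells_as)) cells_as <- "rows"
    sep <- if (format == "csv") "," else "\t"
    out <- if (cells_as == "cols") t(as.matrix(m)) else as.matrix(m)
    df <- data.frame(id = rownames(out), out, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read cell stage labels
#'
#' Two-column table (`cell_id`, `stage`), CSV by default.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Tibble with columns `cell_id`, `stage`.
#' @export
read_labels <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file needs columns cell_id, stage", call. = FALSE)
  names(df)[1:2] <- c("cell_id", "stage")
  tibble::as_tibble(df[, 1:2])
}
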