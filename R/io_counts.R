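#' @keywords internal
"_PACKAGE"

# Validate a genes x samples count matrix: non-negative finite values,
# unique gene and sample identifiers.  Errors name the offending cell.
validate_counts <- function(values, gene_ids = rownames(values),
                            sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("empty matrix: no genes")
  if (ncol(values) < 1L) stop("empty matrix: no samples")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match number of rows")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match number of columns")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ", sample_ids[duplicated(sample_ids)][1L])
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop(sprintf("invalid count (negative or non-finite) at gene '%s', sample '%s'",
                 gene_ids[i], sample_ids[j]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Read a genes x samples count table
#'
#' Reads a count matrix from a delimited text file (first column gene
#' identifiers, header row sample identifiers) or from a MatrixMarket
#' `.mtx` file with sidecar identifier files `<stem>.genes.txt` and
#' `<stem>.samples.txt` (one ID per line).
#'
#' Counts are accepted as non-negative reals, not only integers, so that
#' normalized intermediates round-trip through the same format.
#'
#' @param path Path to the count file.
#' @param fmt File format, one of `"tsv"`, `"csv"`, `"mtx"`.
#' @return A numeric matrix, genes in rows and samples in columns, with
#'   gene and sample identifiers as dimnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t4\t0", "g2\t10\t10"), f)
#' read_counts(f)
#' @export
read_counts <- function(path, fmt = c("tsv", "csv", "mtx")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (fmt == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    gf <- paste0(stem, ".genes.txt")
    sf <- paste0(stem, ".samples.txt")
    if (!file.exists(gf) || !file.exists(sf))
      stop("sidecar ID files not found: expected ", gf, " and ", sf)
    vals <- as.matrix(Matrix::readMM(path))
    return(validate_counts(vals, readLines(gf), readLines(sf)))
  }
  sep <- if (fmt == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("count table must have a gene ID column and at least one sample column")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !is.na(raw))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(raw)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(raw)) + 1L
    stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                 raw[bad[1L]], gene_ids[i], sample_ids[j]))
  }
  validate_counts(vals, gene_ids, sample_ids)
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(m))` recovers
#' `m` up to floating-point formatting (1e-9).  The `"mtx"` format
#' writes a sparse MatrixMarket file plus `<stem>.genes.txt` and
#' `<stem>.samples.txt` sidecars.
#'
#' @param m Numeric genes x samples matrix with dimnames.
#' @param path Output file path.
#' @param fmt One of `"tsv"`, `"csv"`, `"mtx"`.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(m, path, fmt = c("tsv", "csv", "mtx")) {
  fmt <- match.arg(fmt)
  m <- validate_counts(m)
  if (fmt == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    sm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                      "CsparseMatrix")
    Matrix::writeMM(sm, path)
    writeLines(rownames(m), paste0(stem, ".genes.txt"))
    writeLines(colnames(m), paste0(stem, ".samples.txt"))
    return(invisible(path))
  }
  sep <- if (fmt == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
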