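#' Read a UMI count matrix
#'
#' Reads a genes x cells UMI count matrix either from Matrix Market
#' coordinate format plus one-per-line gene and barcode lists, or from a
#' dense tab-separated file with gene symbols as row names and barcodes as
#' column names. Counts must be non-negative integers; gene and barcode
#' identifiers must be unique and match the matrix dimensions.
#'
#' @param matrix_path path to a `.mtx` file or a dense TSV.
#' @param genes_path,barcodes_path plain-text identifier lists, one entry per
#'   line; required for `.mtx` input, ignored for dense TSV.
#' @return a `dgCMatrix` with genes as rows and cell barcodes as columns.
#' @export
read_counts <- function(matrix_path, genes_path = NULL, barcodes_path = NULL) {
  if (!file.exists(matrix_path)) stop2("matrix file not found: ", matrix_path)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(barcodes_path))
      stop2("gene and barcode lists are required for Matrix Market input")
    m <- Matrix::readMM(matrix_path)
    genes <- readLines(genes_path)
    barcodes <- readLines(barcodes_path)
    if (nrow(m) != length(genes))
      stop2("dimension mismatch: matrix has ", nrow(m), " rows but ",
            length(genes), " gene identifiers")
    if (ncol(m) != length(barcodes))
      stop2("dimension mismatch: matrix has ", ncol(m), " columns but ",
            length(barcodes), " barcodes")
    dimnames(m) <- list(genes, barcodes)
    m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  } else {
    df <- utils::read.delim(matrix_path, check.names = FALSE, row.names = 1)
    m <- Matrix::Matrix(as.matrix(df), sparse = TRUE)
  }
  validate_counts(m)
  m
}

#' Validate a count matrix
#'
#' Checks the count-matrix contract: non-negative integral entries and
#' unique gene/barcode identifiers matching the matrix dimensions.
#'
#' @param counts a genes x cells matrix.
#' @return `counts`, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("count matrix must carry gene row names and barcode column names")
  if (anyDuplicated(rownames(counts)))
    stop2("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts)))
    stop2("duplicate cell barcodes")
  x <- if (inherits(counts, "sparseMatrix")) counts@x else as.vector(counts)
  if (length(x) && min(x) < 0) stop2("negative counts present")
  if (length(x) && any(abs(x - round(x)) > 1e-8))
    stop2("non-integer counts present")
  invisible(counts)
}

#' Write a UMI count matrix
#'
#' Writes Matrix Market coordinate format plus gene and barcode lists, the
#' inverse of [read_counts()]; the round trip is exact.
#'
#' @param counts genes x cells count matrix with dimnames.
#' @param matrix_path,genes_path,barcodes_path output paths.
#' @return the three paths, invisibly.
#' @export
write_counts <- function(counts, matrix_path, genes_path, barcodes_path) {
  validate_counts(counts)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, matrix_path)
  writeLines(rownames(counts), genes_path)
  writeLines(colnames(counts), barcodes_path)
  invisible(c(matrix_path, genes_path, barcodes_path))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. The description is discarded; duplicate symbols within
#' a line are collapsed with a warning.
#'
#' @param gmt_path path to a GMT file.
#' @return a named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop2("empty GMT file: ", gmt_path)
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop2("GMT line with fewer than 3 fields: ", substr(ln, 1, 40))
    name <- fields[1]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate symbols in gene set '", name, "' collapsed",
              call. = FALSE)
      genes <- unique(genes)
    }
    sets[[name]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param gmt_path output path.
#' @param description description field written for every set.
#' @return `gmt_path`, invisibly.
#' @export
write_gene_sets <- function(sets, gmt_path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  invisible(gmt_path)
}

#' Derive per-cell metadata from a count matrix
#'
#' Builds the per-cell metadata table (total UMIs and number of detected
#' genes per barcode), joined to per-sample labels when supplied.
#'
#' @param counts genes x cells count matrix.
#' @param sample_info optional data frame with columns `barcode`,
#'   `sample_id`, `patient_id`, `site`, `grade` (extra columns carried
#'   through).
#' @return a data frame with one row per cell barcode.
#' @export
cell_metadata <- function(counts, sample_info = NULL) {
  validate_counts(counts)
  meta <- data.frame(
    barcode = colnames(counts),
    total_umis = as.integer(col_totals(counts)),
    n_genes_detected = as.integer(col_detect(counts)),
    stringsAsFactors = FALSE
  )
  if (!is.null(sample_info)) {
    if (!"barcode" %in% names(sample_info))
      stop2("sample_info must have a 'barcode' column")
    missing <- setdiff(meta$barcode, sample_info$barcode)
    if (length(missing))
      stop2(length(missing), " barcodes absent from sample_info")
    meta <- merge(meta, sample_info, by = "barcode", sort = FALSE)
    meta <- meta[match(colnames(counts), meta$barcode), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}
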