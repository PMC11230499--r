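#' @importFrom Matrix readMM writeMM t rowSums colSums Diagonal sparseMatrix
#' @importFrom rlang .data
NULL

GENOTYPE_LEVELS <- c("C57", "NZB")
STATE_LEVELS <- c("NL", "LacD21")
CELLTYPE_LEVELS <- c("AV", "HS", "ME")
CELLTYPE_LEVELS_FULL <- c("AV", "HS", "ME", "unassigned")

# open plain or gzipped text transparently
open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
}

#' Read a 10x Genomics triplet (MTX + features + barcodes) count matrix
#'
#' Reads the MatrixMarket coordinate matrix together with its features and
#' barcodes TSV files and returns a validated sparse UMI count matrix oriented
#' cells x genes (rows = barcodes, columns = gene symbols), whatever the
#' on-disk orientation. Gzipped files are accepted.
#'
#' On-disk 10x matrices are conventionally genes x cells; set
#' `genes_in_rows = FALSE` if the matrix was written cells x genes. Duplicate
#' gene symbols in the features file are collapsed by summing their counts,
#' since all downstream scoring is keyed by symbol.
#'
#' @param matrix_path Path to `matrix.mtx[.gz]` (MatrixMarket coordinate,
#'   integer, non-negative).
#' @param features_path Path to `features.tsv[.gz]`; the gene symbol is taken
#'   from the second column if present, else the first.
#' @param barcodes_path Path to `barcodes.tsv[.gz]`, one barcode per line.
#' @param genes_in_rows Logical; `TRUE` (default, the 10x convention) means
#'   the on-disk matrix is genes x cells.
#'
#' @return A `dgCMatrix` of non-negative integer counts, cells x genes, with
#'   unique rownames (barcodes) and unique colnames (gene symbols).
#' @export
read_10x_triplet <- function(matrix_path, features_path, barcodes_path,
                             genes_in_rows = TRUE) {
  con <- open_maybe_gz(matrix_path)
  on.exit(close(con), add = TRUE)
  m <- Matrix::readMM(con)

  feat_con <- open_maybe_gz(features_path)
  on.exit(close(feat_con), add = TRUE)
  features <- utils::read.delim(feat_con, header = FALSE,
                                colClasses = "character", quote = "")
  bc_con <- open_maybe_gz(barcodes_path)
  on.exit(close(bc_con), add = TRUE)
  barcodes <- readLines(bc_con)

  n_genes_disk <- if (genes_in_rows) nrow(m) else ncol(m)
  n_cells_disk <- if (genes_in_rows) ncol(m) else nrow(m)
  if (nrow(features) != n_genes_disk) {
    stop("format error: features file has ", nrow(features),
         " records but MTX header declares ", n_genes_disk, " genes", call. = FALSE)
  }
  if (length(barcodes) != n_cells_disk) {
    stop("format error: barcodes file has ", length(barcodes),
         " records but MTX header declares ", n_cells_disk, " cells", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("format error: duplicate barcodes in ", barcodes_path, call. = FALSE)
  }

  vals <- m@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
    stop("format error: counts must be non-negative integers", call. = FALSE)
  }

  if (genes_in_rows) m <- Matrix::t(m)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")

  symbols <- if (ncol(features) >= 2L) features[[2L]] else features[[1L]]
  rownames(m) <- barcodes
  if (anyDuplicated(symbols)) {
    m <- collapse_duplicate_genes(m, symbols)
  } else {
    colnames(m) <- symbols
  }
  validate_counts(m)
  m
}

# sum columns sharing a gene symbol; keeps first-occurrence order
collapse_duplicate_genes <- function(m, symbols) {
  lev <- unique(symbols)
  ind <- Matrix::sparseMatrix(i = seq_along(symbols),
                              j = match(symbols, lev),
                              x = 1, dims = c(length(symbols), length(lev)))
  out <- m %*% ind
  out <- methods::as(out, "CsparseMatrix")
  colnames(out) <- lev
  rownames(out) <- rownames(m)
  out
}

#' Validate a cells x genes count matrix
#'
#' Checks the container invariants every pipeline stage relies on: sparse or
#' dense numeric matrix, non-negative integer-valued entries, unique barcode
#' rownames and unique gene-symbol colnames matching the matrix dimensions.
#'
#' @param counts Matrix-like cells x genes object.
#' @return `counts`, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have barcode rownames and gene colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate barcodes in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate gene symbols in count matrix", call. = FALSE)
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
    stop("count matrix entries must be non-negative integers", call. = FALSE)
  }
  invisible(counts)
}

#' Write a count matrix as a 10x triplet
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` under `dir` in the
#' standard on-disk orientation (genes x cells), so that
#' [read_10x_triplet()] round-trips the matrix exactly.
#'
#' @param counts Cells x genes count matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_10x_triplet <- function(counts, dir) {
  validate_counts(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::t(counts), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  feats <- data.frame(id = colnames(counts), symbol = colnames(counts),
                      type = "Gene Expression")
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read per-barcode sample metadata
#'
#' Reads a CSV with columns `barcode`, `sample_id`, `genotype`, `state`,
#' `mouse` and validates the closed vocabularies: genotype must be `C57` or
#' `NZB`, state must be `NL` (non-lactating) or `LacD21` (day 21 of
#' lactation).
#'
#' @param path CSV path.
#' @return A tibble with the five required columns.
#' @export
read_metadata <- function(path) {
  md <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  validate_metadata(md)
}

#' @rdname read_metadata
#' @param metadata A data frame to validate in place.
#' @export
validate_metadata <- function(metadata) {
  required <- c("barcode", "sample_id", "genotype", "state", "mouse")
  missing <- setdiff(required, names(metadata))
  if (length(missing)) {
    stop("format error: metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(metadata$barcode)) {
    stop("format error: duplicate barcode rows in metadata", call. = FALSE)
  }
  bad_gt <- setdiff(unique(metadata$genotype), GENOTYPE_LEVELS)
  if (length(bad_gt)) {
    stop("format error: genotype value(s) outside {C57, NZB}: ",
         paste(bad_gt, collapse = ", "), call. = FALSE)
  }
  bad_st <- setdiff(unique(metadata$state), STATE_LEVELS)
  if (length(bad_st)) {
    stop("format error: state value(s) outside {NL, LacD21}: ",
         paste(bad_st, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(metadata)
}

#' Check that metadata covers exactly the barcodes of a matrix
#'
#' @param counts Cells x genes count matrix.
#' @param metadata Metadata tibble (see [read_metadata()]).
#' @return Invisibly `TRUE`; errors listing offending barcodes otherwise.
#' @export
check_barcodes <- function(counts, metadata) {
  extra <- setdiff(metadata$barcode, rownames(counts))
  absent <- setdiff(rownames(counts), metadata$barcode)
  if (length(extra) || length(absent)) {
    stop("join error: barcodes without a matrix row: [",
         paste(utils::head(extra, 5L), collapse = ", "),
         if (length(extra) > 5L) ", ..." else "",
         "]; matrix barcodes without metadata: [",
         paste(utils::head(absent, 5L), collapse = ", "),
         if (length(absent) > 5L) ", ..." else "", "]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Differential-expression tables
#'
#' A DE table has one row per gene with columns `gene`, `log2fc`, `pvalue`
#' and `padj` (Benjamini-Hochberg adjusted). `read_de_table()` validates
#' ranges on read; if the `padj` column is absent it is computed from
#' `pvalue` by BH and the returned tibble carries attribute
#' `padj_computed = TRUE`. A foreign table with `padj < pvalue` (impossible
#' under BH) triggers a warning, not an error. `write_de_table()` writes full
#' double precision so the round trip is exact to at least 12 significant
#' digits.
#'
#' @param de A DE table (data frame).
#' @param path CSV path.
#' @return `read_de_table()` returns a validated tibble; `write_de_table()`
#'   returns `path` invisibly.
#' @export
write_de_table <- function(de, path) {
  de <- validate_de_table(de)
  readr::write_csv(de, path)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  de <- readr::read_csv(path, show_col_types = FALSE)
  has_padj <- "padj" %in% names(de)
  if (!has_padj && "pvalue" %in% names(de)) {
    de$padj <- bh_adjust(de$pvalue)
  }
  de <- validate_de_table(de)
  attr(de, "padj_computed") <- !has_padj
  de
}

#' @rdname write_de_table
#' @export
validate_de_table <- function(de) {
  required <- c("gene", "log2fc", "pvalue", "padj")
  missing <- setdiff(required, names(de))
  if (length(missing)) {
    stop("format error: DE table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(de$gene)) {
    stop("format error: DE table has more than one row for some gene", call. = FALSE)
  }
  for (col in c("pvalue", "padj")) {
    v <- de[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop("format error: ", col, " values must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(de$padj < de$pvalue - 1e-12)) {
    warning("DE table has padj < pvalue for some genes; ",
            "not a Benjamini-Hochberg adjustment", call. = FALSE)
  }
  tibble::as_tibble(de[, c(required, setdiff(names(de), required))])
}
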