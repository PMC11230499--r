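#' Median-depth normalization
#'
#' Scales each cell's counts so that its total equals the median per-cell
#' total of the dataset, expressed in units of the smallest positive entry
#' of the matrix. On raw UMI counts the smallest positive entry is 1, so
#' this is exactly "rescale every cell to the median total"; measuring the
#' target in entry units additionally makes the output *identical* under any
#' global rescaling of the matrix, so depth normalization, scoring and every
#' downstream call are exactly scale-invariant. Cells with zero total are
#' left all-zero and recorded in the `zero_cells` attribute.
#'
#' @param counts Cells x genes count matrix with dimnames.
#' @return A `dgCMatrix` of the same shape, with attributes `median_total`
#'   (the target total) and `zero_cells` (barcodes with zero counts).
#' @export
depth_normalize <- function(counts) {
  totals <- Matrix::rowSums(counts)
  if (all(totals == 0)) stop("cannot depth-normalize an all-zero matrix", call. = FALSE)
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  unit <- min(vals[vals > 0])
  med <- stats::median(totals[totals > 0]) / unit
  factors <- ifelse(totals > 0, med / totals, 0)
  out <- Matrix::Diagonal(x = factors) %*% counts
  out <- methods::as(out, "CsparseMatrix")
  dimnames(out) <- dimnames(counts)
  attr(out, "median_total") <- med
  attr(out, "zero_cells") <- rownames(counts)[totals == 0]
  out
}

#' Per-cell signature score: log2 feature sum
#'
#' The score of a cell for a signature is the log2-transformed combined
#' feature sum: `log2(pseudocount + sum of expression over the signature's
#' genes)`, where expression is the raw count or, by default, the
#' median-depth-normalized count. Signature genes absent from the matrix
#' contribute zero and are reported (message + `missing_genes` attribute),
#' never silently dropped; if no signature gene is present the call errors.
#'
#' @param counts Cells x genes count matrix.
#' @param signature A [gene_signature] (or character vector of symbols).
#' @param normalization `"median_depth"` (default) or `"none"`.
#' @param pseudocount Added inside the log; default 1 so that an all-zero
#'   cell scores exactly 0.
#' @return A tibble with columns `barcode`, `signature`, `score`, carrying
#'   attributes `normalization`, `pseudocount` and `missing_genes`.
#' @export
#' @examples
#' m <- Matrix::Matrix(c(1, 0, 2, 0, 0, 1), nrow = 1, sparse = TRUE,
#'                     dimnames = list("c1", c("Cenpe", "Ccna2", "Ccnb2",
#'                                             "Mcm6", "Ccnf", "Bud1")))
#' score_signature(m, ppbc_signatures()$proliferation,
#'                 normalization = "none")$score  # log2(1 + 4)
score_signature <- function(counts, signature,
                            normalization = c("median_depth", "none"),
                            pseudocount = 1) {
  normalization <- match.arg(normalization)
  if (!inherits(signature, "gene_signature")) {
    signature <- gene_signature("signature", signature)
  }
  expr <- if (normalization == "median_depth") depth_normalize(counts) else counts
  sc <- feature_sum_score(expr, signature, pseudocount)
  out <- tibble::tibble(barcode = rownames(counts),
                        signature = signature$name,
                        score = as.vector(sc))
  attr(out, "normalization") <- normalization
  attr(out, "pseudocount") <- pseudocount
  attr(out, "missing_genes") <- attr(sc, "missing_genes")
  out
}

# core feature-sum on an already-normalized matrix; returns bare numeric
feature_sum_score <- function(expr, signature, pseudocount = 1) {
  present <- intersect(signature$genes, colnames(expr))
  missing <- setdiff(signature$genes, colnames(expr))
  if (length(present) == 0L) {
    stop("no gene of signature '", signature$name, "' is present in the matrix",
         call. = FALSE)
  }
  if (length(missing)) {
    message("signature '", signature$name, "': ", length(missing),
            " gene(s) absent from matrix (contribute 0): ",
            paste(missing, collapse = ", "))
  }
  s <- Matrix::rowSums(expr[, present, drop = FALSE])
  out <- log2(pseudocount + as.numeric(s))
  names(out) <- rownames(expr)
  attr(out, "missing_genes") <- missing
  out
}

#' Half-of-maximum threshold
#'
#' The classification cutoff for a signature is half of the maximum log2
#' feature sum, the maximum taken over all barcodes pooled across samples
#' (one cutoff per signature for the whole experiment).
#'
#' @param scores A numeric score vector or a tibble from [score_signature()].
#' @return A single threshold value.
#' @export
#' @examples
#' half_max_threshold(c(0, 2, 4, 8))  # 4
half_max_threshold <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) == 0L) stop("cannot threshold an empty score vector", call. = FALSE)
  0.5 * max(scores)
}

#' Classify PPBC-like cells by proliferation/regulon co-expression
#'
#' A cell is positive for a gene list when its log2 feature sum is at least
#' the list's half-of-maximum threshold *and* strictly positive (so an
#' all-zero score vector yields no positives rather than all positives). A
#' cell is PPBC-like when it is positive for both the proliferation list and
#' the regulon.
#'
#' @param proliferation_scores,regulon_scores Tibbles from
#'   [score_signature()] (or named numeric vectors) over identical barcodes.
#' @return A tibble of class `ppbc_classification` with columns `barcode`,
#'   `score_proliferation`, `score_regulon`, `positive_proliferation`,
#'   `positive_regulon`, `is_ppbc_like`; the thresholds used are stored in
#'   the `thresholds` attribute (named numeric of length 2).
#' @export
classify_ppbc_like <- function(proliferation_scores, regulon_scores) {
  sp <- extract_scores(proliferation_scores)
  sr <- extract_scores(regulon_scores)
  if (length(sp) != length(sr) || !identical(names(sp), names(sr))) {
    stop("proliferation and regulon scores must cover identical barcodes ",
         "in identical order", call. = FALSE)
  }
  thr <- c(proliferation = half_max_threshold(sp),
           regulon = half_max_threshold(sr))
  pos_p <- sp >= thr[["proliferation"]] & sp > 0
  pos_r <- sr >= thr[["regulon"]] & sr > 0
  out <- tibble::tibble(
    barcode = names(sp),
    score_proliferation = unname(sp),
    score_regulon = unname(sr),
    positive_proliferation = unname(pos_p),
    positive_regulon = unname(pos_r),
    is_ppbc_like = unname(pos_p & pos_r)
  )
  attr(out, "thresholds") <- thr
  class(out) <- c("ppbc_classification", class(out))
  out
}

extract_scores <- function(x) {
  if (is.data.frame(x)) {
    s <- x$score
    names(s) <- x$barcode
    s
  } else {
    if (is.null(names(x))) stop("score vectors must be named by barcode", call. = FALSE)
    x
  }
}

#' Count cells detecting a gene
#'
#' Positivity for a single gene (e.g. Trp53, the mouse p53 gene) is a
#' detection call: raw UMI count strictly greater than zero. Used to count
#' p53-expressing luminal HS cells per sample.
#'
#' @param counts Cells x genes count matrix.
#' @param gene Gene symbol; an error names it if absent.
#' @param cells Optional character vector of barcodes restricting the count
#'   (may be empty, giving 0); default all cells.
#' @return Integer count of positive cells.
#' @export
gene_positive_count <- function(counts, gene, cells = NULL) {
  stopifnot(is.character(gene), length(gene) == 1L)
  if (!gene %in% colnames(counts)) {
    stop("gene '", gene, "' is absent from the matrix", call. = FALSE)
  }
  if (is.null(cells)) cells <- rownames(counts)
  if (length(cells) == 0L) return(0L)
  bad <- setdiff(cells, rownames(counts))
  if (length(bad)) {
    stop("unknown barcode(s) in cell subset: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  sum(counts[cells, gene] > 0)
}
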