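#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarize a PPBC-like classification
#'
#' `tidy()` returns the per-cell table as a plain tibble; `glance()` returns
#' a one-row summary with the cell count, the number of PPBC-like calls and
#' the two half-max thresholds used.
#'
#' @param x A [classify_ppbc_like()] result.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ppbc_classification <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ppbc_classification")
  attr(out, "thresholds") <- NULL
  out
}

#' @rdname tidy.ppbc_classification
#' @exportS3Method generics::glance
glance.ppbc_classification <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble::tibble(n_cells = nrow(x),
                 n_ppbc_like = sum(x$is_ppbc_like),
                 threshold_proliferation = thr[["proliferation"]],
                 threshold_regulon = thr[["regulon"]])
}

#' Tidy and summarize a Venn partition
#'
#' `tidy()` returns one row per region with its label and size; `glance()`
#' returns the number of input sets, the union size and a check that the
#' disjoint regions add back up to the union.
#'
#' @param x A [venn_partition()] result.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.venn_partition <- function(x, ...) {
  tibble::tibble(region = x$region, n = x$n)
}

#' @rdname tidy.venn_partition
#' @exportS3Method generics::glance
glance.venn_partition <- function(x, ...) {
  tibble::tibble(n_sets = length(attr(x, "set_names")),
                 n_regions = nrow(x),
                 union_size = sum(x$n))
}

#' Tidy and summarize a pipeline report
#'
#' `tidy()` returns the replicate-level Welch t-test table; `glance()`
#' returns a one-row overview of the run.
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ppbc_report <- function(x, ...) {
  x$tests
}

#' @rdname tidy.ppbc_report
#' @exportS3Method generics::glance
glance.ppbc_report <- function(x, ...) {
  tibble::tibble(
    n_cells = x$manifest$n_cells,
    n_samples = length(x$manifest$samples),
    n_ppbc_like = sum(x$classification$is_ppbc_like),
    threshold_proliferation = x$manifest$thresholds$proliferation,
    threshold_regulon = x$manifest$thresholds$regulon,
    precision = if (is.null(x$recovery)) NA_real_ else x$recovery$precision,
    recall = if (is.null(x$recovery)) NA_real_ else x$recovery$recall,
    celltype_accuracy = if (is.null(x$recovery)) NA_real_ else x$recovery$celltype_accuracy)
}
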