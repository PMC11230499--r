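#' Filter a DE table to significantly regulated genes
#'
#' Returns the genes with BH-adjusted p-value strictly below `alpha` and a
#' fold change in the requested direction. A gene with log2 fold change
#' exactly zero belongs to neither direction.
#'
#' @param de A validated DE table (see [validate_de_table()]).
#' @param alpha Adjusted-p cutoff; the boundary itself (padj == alpha) is
#'   excluded.
#' @param direction `"up"` (log2fc > 0) or `"down"` (log2fc < 0).
#' @return Character vector of gene symbols.
#' @export
de_filter <- function(de, alpha = 0.05, direction = c("up", "down")) {
  direction <- match.arg(direction)
  de <- validate_de_table(de)
  keep <- de$padj < alpha &
    if (direction == "up") de$log2fc > 0 else de$log2fc < 0
  de$gene[keep]
}

#' Venn partition of 2-3 named gene sets
#'
#' Partitions the union of the input sets into the `2^k - 1` disjoint Venn
#' regions by exact per-gene membership. Region labels join the member set
#' names with `&` (a singleton label such as `"day8"` is the region
#' *exclusive* to that set).
#'
#' @param sets Named list of 2 or 3 character vectors (duplicate elements
#'   within a set are ignored; duplicate or empty set names are an error).
#' @return A tibble of class `venn_partition` with one row per possible
#'   region: `region` (label), `sets` (list of member set names), `genes`
#'   (list column), `n` (region size). The input set names are kept in the
#'   `set_names` attribute.
#' @export
#' @examples
#' venn_partition(list(day8 = c("a", "b", "c"), day14 = c("b", "c"),
#'                     day21 = "c"))
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    stop("venn_partition takes a named list of 2 or 3 gene sets", call. = FALSE)
  }
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    stop("set names must be unique and non-empty", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  # per-gene membership bitmask over the k inputs
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0L) {
    member <- matrix(logical(0), ncol = length(sets), dimnames = list(NULL, nms))
  }
  k <- length(sets)
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-2L^k, , drop = FALSE]
  names(combos) <- nms
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    mask <- as.logical(combos[i, ])
    in_region <- if (length(universe)) {
      apply(member, 1L, function(r) all(r == mask))
    } else logical(0)
    tibble::tibble(region = paste(nms[mask], collapse = "&"),
                   sets = list(nms[mask]),
                   genes = list(universe[in_region]),
                   n = sum(in_region))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "set_names") <- nms
  class(out) <- c("venn_partition", class(out))
  out
}

#' Extract named regions from a Venn partition
#'
#' `venn_exclusive()` returns the genes found only in the named set;
#' `venn_common()` returns the genes shared by all input sets.
#'
#' @param partition A [venn_partition()] result.
#' @param set_name Name of one input set.
#' @return Character vector of gene symbols.
#' @export
venn_exclusive <- function(partition, set_name) {
  nms <- attr(partition, "set_names")
  if (!set_name %in% nms) stop("unknown set name: ", set_name, call. = FALSE)
  partition$genes[[match(set_name, partition$region)]]
}

#' @rdname venn_exclusive
#' @export
venn_common <- function(partition) {
  nms <- attr(partition, "set_names")
  all_label <- paste(nms, collapse = "&")
  partition$genes[[match(all_label, partition$region)]]
}

#' Split two genotypes' gene sets into shared and genotype-unique genes
#'
#' Given the set of genes regulated across lactation in each genotype,
#' returns the three disjoint pieces of their pairwise Venn diagram: genes
#' common to both genotypes, and genes unique to each.
#'
#' @param set_a,set_b Character vectors of gene symbols.
#' @param names Length-2 character vector naming the two sets (defaults to
#'   the two genotypes).
#' @return Named list with elements `shared`, `unique_<name1>`,
#'   `unique_<name2>`, plus a `counts` attribute (named integer vector).
#' @export
cross_genotype_unique <- function(set_a, set_b, names = c("C57", "NZB")) {
  stopifnot(length(names) == 2L, !anyDuplicated(names))
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  out <- list(shared = intersect(set_a, set_b),
              setdiff(set_a, set_b),
              setdiff(set_b, set_a))
  base::names(out) <- c("shared", paste0("unique_", names))
  attr(out, "counts") <- vapply(out, length, integer(1))
  out
}

#' Convenience bulk differential expression for synthetic data
#'
#' A minimal per-gene Welch t-test on log2 counts-per-million between two
#' groups of bulk samples, BH-adjusted. This is a convenience for generating
#' DE tables from simulated bulk counts so the Venn logic can be exercised
#' end-to-end; it is not the vendor pipeline that produced the original
#' tables, which are accepted as inputs.
#'
#' @param counts Genes x samples matrix of bulk counts with dimnames.
#' @param samples_a,samples_b Disjoint column-name vectors (>= 2 each).
#' @return A DE tibble: `gene`, `log2fc` (A minus B), `pvalue`, `padj`.
#' @export
bulk_de_welch <- function(counts, samples_a, samples_b) {
  counts <- as.matrix(counts)
  if (length(intersect(samples_a, samples_b))) stop("sample groups overlap", call. = FALSE)
  if (length(samples_a) < 2L || length(samples_b) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  bad <- setdiff(c(samples_a, samples_b), colnames(counts))
  if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cpm <- log2(1 + t(t(counts) / colSums(counts)) * 1e6)
  res <- apply(cpm, 1L, function(v) {
    r <- welch_t_two_tailed(v[samples_a], v[samples_b])
    c(r$estimate, r$p.value)
  })
  tibble::tibble(gene = rownames(counts), log2fc = res[1, ],
                 pvalue = res[2, ], padj = bh_adjust(res[2, ]))
}
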