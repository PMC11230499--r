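#' Two-tailed Welch t-test on replicate-level summaries
#'
#' Compares two groups of per-mouse summary values (PPBC-like cell counts,
#' p53-positive counts, type proportions) by an unequal-variance t-test with
#' Welch-Satterthwaite degrees of freedom. With n = 3 mice per group,
#' replicate summaries are occasionally degenerate (zero variance); each
#' group variance is floored at a machine-epsilon-scaled value so that fully
#' separated groups return a finite, astronomically significant statistic
#' instead of an error.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `estimate` (mean of `x` minus mean of `y`),
#'   `statistic` (t), `parameter` (Welch df), `p.value` (two-tailed).
#' @export
welch_t_two_tailed <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  floor_v <- .Machine$double.eps * (max(abs(c(x, y)), 1))^2
  vx <- max(stats::var(x), floor_v)
  vy <- max(stats::var(y), floor_v)
  se2x <- vx / nx; se2y <- vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  tibble::tibble(estimate = mean(x) - mean(y), statistic = t,
                 parameter = df, p.value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values; a thin
#' validating wrapper around [stats::p.adjust()] so callers get a range
#' check and a single documented method.
#'
#' @param p Numeric vector of p-values in [0, 1] (no NA).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must be numeric in [0, 1] with no NA", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential expression between two cell groups
#'
#' For each gene, compares log2(pseudocount + median-depth-normalized
#' counts) between two disjoint cell groups with a two-sided Wilcoxon
#' rank-sum test (normal approximation with tie correction, no continuity
#' correction; a gene with identical values in both groups gets p = 1), and
#' reports the difference of group mean log2 expression as `log2fc`
#' (positive = higher in group A). P-values are BH-adjusted.
#'
#' @param counts Cells x genes count matrix; normalization is computed over
#'   all its cells.
#' @param cells_a,cells_b Disjoint, non-empty barcode vectors.
#' @param normalization,pseudocount As in [score_signature()].
#' @return A DE tibble: `gene`, `log2fc`, `pvalue`, `padj`.
#' @export
per_gene_de <- function(counts, cells_a, cells_b,
                        normalization = c("median_depth", "none"),
                        pseudocount = 1) {
  normalization <- match.arg(normalization)
  if (length(cells_a) == 0L || length(cells_b) == 0L) {
    stop("both cell groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(cells_a, cells_b))) {
    stop("cell groups overlap", call. = FALSE)
  }
  bad <- setdiff(c(cells_a, cells_b), rownames(counts))
  if (length(bad)) stop("unknown barcode(s): ",
                        paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  expr <- if (normalization == "median_depth") depth_normalize(counts) else counts
  sub <- log2(pseudocount + as.matrix(expr[c(cells_a, cells_b), , drop = FALSE]))
  n1 <- length(cells_a); n2 <- length(cells_b); N <- n1 + n2
  in_a <- seq_len(n1)

  pvals <- apply(sub, 2L, function(v) rank_sum_p(v, in_a, n1, n2, N))
  lfc <- colMeans(sub[in_a, , drop = FALSE]) -
    colMeans(sub[-in_a, , drop = FALSE])
  tibble::tibble(gene = colnames(counts), log2fc = unname(lfc),
                 pvalue = unname(pvals), padj = bh_adjust(unname(pvals)))
}

# two-sided rank-sum p, normal approximation with tie correction
rank_sum_p <- function(v, in_a, n1, n2, N) {
  r <- rank(v)
  W <- sum(r[in_a])
  mu <- n1 * (N + 1) / 2
  ties <- table(v)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  2 * stats::pnorm(-abs((W - mu) / sqrt(sigma2)))
}

#' Select the top differentially expressed genes
#'
#' Keeps genes with raw p-value strictly below `p_cutoff`, orders them by
#' ascending p-value, then descending |log2fc|, then gene symbol (so ties
#' resolve identically across runs), and truncates to `n`.
#'
#' @param de A DE table.
#' @param n Maximum number of genes returned.
#' @param p_cutoff Raw p-value cutoff (default 2e-4, i.e. p < 0.0002).
#' @return The qualifying rows of `de`, ordered, at most `n` of them.
#' @export
top_n_genes <- function(de, n = 40, p_cutoff = 2e-4) {
  de <- validate_de_table(de)
  de |>
    dplyr::filter(.data$pvalue < p_cutoff) |>
    dplyr::arrange(.data$pvalue, dplyr::desc(abs(.data$log2fc)), .data$gene) |>
    dplyr::slice_head(n = n)
}

#' Hierarchical ordering for heatmaps
#'
#' Orders the rows and columns of an expression submatrix by average-linkage
#' agglomerative clustering on the correlation distance 1 - Pearson r. A
#' zero-variance row or column has undefined correlation; its correlation is
#' taken as 0 (distance 1). The returned leaf orders are deterministic
#' (hclust's merge rule: earlier-formed clusters first).
#'
#' @param x Numeric matrix (e.g. genes x samples) with >= 2 rows and >= 2
#'   columns.
#' @return List with `row_order`, `col_order` (integer permutations) and the
#'   two `hclust` objects `row_hclust`, `col_hclust`.
#' @export
hierarchical_order <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 rows and 2 columns to cluster", call. = FALSE)
  }
  hc_rows <- hclust_correlation(x)
  hc_cols <- hclust_correlation(t(x))
  list(row_order = hc_rows$order, col_order = hc_cols$order,
       row_hclust = hc_rows, col_hclust = hc_cols)
}

hclust_correlation <- function(x) {
  cm <- suppressWarnings(stats::cor(t(x)))
  cm[!is.finite(cm)] <- 0  # zero-variance convention
  d <- stats::as.dist(1 - cm)
  stats::hclust(d, method = "average")
}

#' Tumor volume by the modified ellipsoidal formula
#'
#' `volume = 1/2 * length * width^2`, with length the greatest longitudinal
#' and width the greatest transverse caliper diameter. A width exceeding its
#' length (caliper noise) triggers a warning but is computed anyway.
#'
#' @param length,width Non-negative numeric vectors (recycled).
#' @return Numeric vector of volumes.
#' @export
#' @examples
#' tumor_volume(10, 6)  # 180
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0)) {
    stop("caliper measurements must be non-negative", call. = FALSE)
  }
  if (any(width > length)) {
    warning("width exceeds length for some measurements; computing anyway",
            call. = FALSE)
  }
  0.5 * length * width^2
}
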