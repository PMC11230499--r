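#' Assign mammary epithelial cell types from marker signatures
#'
#' Scores each cell for the luminal alveolar (AV), luminal hormone-sensing
#' (HS) and myoepithelial (ME) marker panels via [score_signature()],
#' z-standardizes each panel's scores across cells (so panels of different
#' length and baseline compete fairly), and labels each cell with the argmax
#' panel if its z-score is positive, otherwise `unassigned`. Ties are broken
#' by the fixed order AV < HS < ME. A panel whose scores have zero variance
#' contributes z = 0 everywhere.
#'
#' @param counts Cells x genes count matrix.
#' @param markers Named list of three [gene_signature]s with names `AV`,
#'   `HS`, `ME`; defaults to the built-in registry.
#' @param normalization,pseudocount Passed to the scoring step (the matrix is
#'   depth-normalized once and shared across panels).
#' @return A tibble of class `cell_annotation` with columns `barcode`,
#'   `celltype` (factor over AV, HS, ME, unassigned) and one `z_<panel>`
#'   column per marker panel.
#' @export
assign_cell_types <- function(counts,
                              markers = ppbc_signatures()[c("AV", "HS", "ME")],
                              normalization = c("median_depth", "none"),
                              pseudocount = 1) {
  normalization <- match.arg(normalization)
  stopifnot(is.list(markers), setequal(names(markers), CELLTYPE_LEVELS))
  markers <- markers[CELLTYPE_LEVELS]
  expr <- if (normalization == "median_depth") depth_normalize(counts) else counts
  z <- vapply(markers, function(sig) {
    sc <- feature_sum_score(expr, sig, pseudocount)
    sdev <- stats::sd(sc)
    if (is.na(sdev) || sdev == 0) rep(0, length(sc)) else (sc - mean(sc)) / sdev
  }, numeric(nrow(counts)))
  # max.col with ties.method = "first" realizes the AV < HS < ME tie order
  best <- max.col(z, ties.method = "first")
  zmax <- z[cbind(seq_len(nrow(z)), best)]
  label <- ifelse(zmax > 0, CELLTYPE_LEVELS[best], "unassigned")
  out <- tibble::tibble(
    barcode = rownames(counts),
    celltype = factor(label, levels = CELLTYPE_LEVELS_FULL)
  )
  zt <- tibble::as_tibble(z, .name_repair = "minimal")
  names(zt) <- paste0("z_", CELLTYPE_LEVELS)
  out <- dplyr::bind_cols(out, zt)
  class(out) <- c("cell_annotation", class(out))
  out
}

#' Per-sample cell-type proportions
#'
#' Fraction of each sample's cells annotated AV, HS, ME or unassigned; the
#' four fractions sum to one per sample. Used to compare the epithelial
#' composition of non-lactating and lactating glands across genotypes
#' (lactation expands the alveolar compartment).
#'
#' @param annotation A [assign_cell_types()] result (or any data frame with
#'   `barcode` and `celltype`).
#' @param metadata Sample metadata covering exactly the annotated barcodes.
#' @return A tibble with one row per sample x cell type: `sample_id`,
#'   `genotype`, `state`, `mouse`, `celltype`, `n`, `fraction`.
#' @export
type_proportions <- function(annotation, metadata) {
  metadata <- validate_metadata(metadata)
  if (!setequal(annotation$barcode, metadata$barcode)) {
    stop("annotation and metadata must cover identical barcodes", call. = FALSE)
  }
  joined <- dplyr::inner_join(tibble::as_tibble(annotation)[, c("barcode", "celltype")],
                              metadata, by = "barcode")
  empty <- setdiff(unique(metadata$sample_id), unique(joined$sample_id))
  if (length(empty)) {
    stop("sample(s) with no cells: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  joined$celltype <- factor(joined$celltype, levels = CELLTYPE_LEVELS_FULL)
  out <- joined |>
    dplyr::count(.data$sample_id, .data$genotype, .data$state, .data$mouse,
                 .data$celltype, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    # .drop = FALSE crosses all factor combinations; keep real samples only
    dplyr::semi_join(metadata, by = c("sample_id", "genotype", "state", "mouse"))
  out
}
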