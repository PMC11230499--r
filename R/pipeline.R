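#' Run the end-to-end PPBC-like identification pipeline
#'
#' Composes the full analysis on either a simulated dataset (pass a
#' [simulation_config()]) or real data (pass a list with `counts` and
#' `metadata`): cell-type annotation, proliferation and regulon scoring,
#' half-max co-expression classification of PPBC-like cells, per-sample
#' PPBC-like and HS p53-positive counts, cell-type proportions,
#' replicate-level Welch t-tests contrasting the genotypes within each
#' state, per-gene DE between lactating C57 and NZB luminal HS cells with
#' top-gene selection and a hierarchical heatmap ordering, and (when bulk DE
#' tables are supplied) Venn partitions of the up- and down-regulated gene
#' sets. Every parameter and threshold is recorded in the report's
#' `manifest`, and the run is deterministic given the seed.
#'
#' @param x A `sim_config` or a list with elements `counts` (cells x genes
#'   matrix), `metadata`, and optionally `truth` (as from
#'   [simulate_cells()]).
#' @param bulk_tables Optional named list of 2-3 DE tables to Venn-partition
#'   (e.g. one per lactation day, or one per genotype).
#' @param alpha Adjusted-p cutoff for [de_filter()].
#' @param p_cutoff,top_n Raw-p cutoff and size for [top_n_genes()].
#' @param normalization,pseudocount Scoring parameters, shared by every
#'   scoring step.
#' @param p53_gene Symbol used for the positivity count (default `Trp53`).
#' @param run_de Logical; set `FALSE` to skip the per-gene DE stage.
#' @param seed Seed overriding `x$seed` for simulated input.
#' @return A list of class `ppbc_report`; see Details.
#'
#' @details The report bundle contains: `classification`, `annotation`,
#' `proportions`, `ppbc_counts` (per sample), `p53_counts` (luminal HS cells
#' detecting `p53_gene`, per sample), `tests` (Welch t-table of
#' genotype contrasts within each state for both count summaries), `de` and
#' `top_genes` (lactating C57 vs NZB luminal HS contrast), `heatmap_order`,
#' `venn_up`/`venn_down` (when bulk tables are supplied), `recovery`
#' (precision/recall/accuracy against ground truth, simulated input only)
#' and `manifest`.
#' @export
run_pipeline <- function(x = simulation_config(), bulk_tables = NULL,
                         alpha = 0.05, p_cutoff = 2e-4, top_n = 40,
                         normalization = "median_depth", pseudocount = 1,
                         p53_gene = "Trp53", run_de = TRUE, seed = NULL) {
  if (inherits(x, "sim_config")) {
    if (!is.null(seed)) x$seed <- as.integer(seed)
    sim <- simulate_cells(x)
  } else {
    if (!is.list(x) || is.null(x$counts) || is.null(x$metadata)) {
      stop("x must be a simulation_config() or a list with counts and metadata",
           call. = FALSE)
    }
    sim <- x
  }
  counts <- sim$counts
  metadata <- validate_metadata(sim$metadata)
  validate_counts(counts)
  check_barcodes(counts, metadata)

  registry <- ppbc_signatures()
  expr <- if (normalization == "median_depth") depth_normalize(counts) else counts

  # annotation and scoring share the once-normalized matrix
  annotation <- assign_cell_types_prenorm(expr, registry, pseudocount)

  sp <- feature_sum_score(expr, registry$proliferation, pseudocount)
  sr <- feature_sum_score(expr, registry$regulon, pseudocount)
  classification <- classify_ppbc_like(sp, sr)

  proportions <- type_proportions(annotation, metadata)

  per_cell <- dplyr::inner_join(
    dplyr::inner_join(tibble::as_tibble(classification)[, c("barcode", "is_ppbc_like")],
                      tibble::as_tibble(annotation)[, c("barcode", "celltype")],
                      by = "barcode"),
    metadata, by = "barcode")

  ppbc_counts <- per_cell |>
    dplyr::group_by(.data$sample_id, .data$genotype, .data$state, .data$mouse) |>
    dplyr::summarise(n_ppbc_like = sum(.data$is_ppbc_like), .groups = "drop")

  hs_cells <- per_cell$barcode[per_cell$celltype == "HS"]
  p53_counts <- metadata |>
    dplyr::distinct(.data$sample_id, .data$genotype, .data$state, .data$mouse) |>
    dplyr::rowwise() |>
    dplyr::mutate(n_p53_positive = gene_positive_count(
      counts, p53_gene,
      intersect(hs_cells, metadata$barcode[metadata$sample_id == .data$sample_id]))) |>
    dplyr::ungroup()

  tests <- dplyr::bind_rows(
    genotype_contrasts(ppbc_counts, "n_ppbc_like"),
    genotype_contrasts(p53_counts, "n_p53_positive"))

  de <- NULL; top <- NULL; heat <- NULL
  if (isTRUE(run_de)) {
    lac <- metadata$state == "LacD21"
    a <- intersect(hs_cells, metadata$barcode[lac & metadata$genotype == "C57"])
    b <- intersect(hs_cells, metadata$barcode[lac & metadata$genotype == "NZB"])
    if (length(a) && length(b)) {
      de <- per_gene_de(counts, a, b, normalization = normalization,
                        pseudocount = pseudocount)
      top <- top_n_genes(de, n = top_n, p_cutoff = p_cutoff)
      if (nrow(top) >= 2L) {
        # per-sample mean log2 expression of the top genes, for heatmap ordering
        lac_samples <- unique(metadata$sample_id[lac])
        sm <- vapply(lac_samples, function(s) {
          bc <- intersect(hs_cells, metadata$barcode[metadata$sample_id == s])
          if (length(bc) == 0L) return(rep(0, nrow(top)))
          colMeans(log2(pseudocount +
            as.matrix(expr[bc, top$gene, drop = FALSE])))
        }, numeric(nrow(top)))
        rownames(sm) <- top$gene
        if (nrow(sm) >= 2L && ncol(sm) >= 2L) heat <- hierarchical_order(sm)
      }
    }
  }

  venn_up <- NULL; venn_down <- NULL
  if (!is.null(bulk_tables)) {
    venn_up <- venn_partition(lapply(bulk_tables, de_filter,
                                     alpha = alpha, direction = "up"))
    venn_down <- venn_partition(lapply(bulk_tables, de_filter,
                                       alpha = alpha, direction = "down"))
  }

  recovery <- NULL
  if (!is.null(sim$truth)) {
    recovery <- recovery_metrics(classification, annotation, sim$truth)
  }

  manifest <- list(
    n_cells = nrow(counts), n_genes = ncol(counts),
    samples = sort(unique(metadata$sample_id)),
    normalization = normalization, pseudocount = pseudocount,
    half_max_factor = 0.5,
    thresholds = as.list(attr(classification, "thresholds")),
    alpha = alpha, p_cutoff = p_cutoff, top_n = top_n,
    p53_gene = p53_gene,
    seed = if (!is.null(sim$config)) sim$config$seed else NA_integer_,
    simulated = !is.null(sim$truth),
    package_version = as.character(utils::packageVersion("ppbclike")))

  out <- list(classification = classification, annotation = annotation,
              proportions = proportions, ppbc_counts = ppbc_counts,
              p53_counts = p53_counts, tests = tests,
              de = de, top_genes = top, heatmap_order = heat,
              venn_up = venn_up, venn_down = venn_down,
              recovery = recovery, manifest = manifest,
              truth = sim$truth)
  class(out) <- "ppbc_report"
  out
}

# annotation reusing an already depth-normalized matrix
assign_cell_types_prenorm <- function(expr, registry, pseudocount) {
  assign_cell_types(expr, registry[CELLTYPE_LEVELS],
                    normalization = "none", pseudocount = pseudocount)
}

genotype_contrasts <- function(tbl, value_col) {
  purrr::map_dfr(STATE_LEVELS, function(st) {
    a <- tbl[[value_col]][tbl$state == st & tbl$genotype == "C57"]
    b <- tbl[[value_col]][tbl$state == st & tbl$genotype == "NZB"]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    res <- welch_t_two_tailed(a, b)
    dplyr::mutate(res, quantity = value_col, state = st,
                  contrast = "C57 - NZB", .before = 1L)
  })
}

# precision/recall of the PPBC-like call and cell-type accuracy vs truth
recovery_metrics <- function(classification, annotation, truth) {
  cl <- dplyr::inner_join(
    tibble::as_tibble(classification)[, c("barcode", "is_ppbc_like")],
    truth, by = "barcode", suffix = c("_called", "_true"))
  tp <- sum(cl$is_ppbc_like_called & cl$is_ppbc_like_true)
  fp <- sum(cl$is_ppbc_like_called & !cl$is_ppbc_like_true)
  fn <- sum(!cl$is_ppbc_like_called & cl$is_ppbc_like_true)
  ann <- dplyr::inner_join(tibble::as_tibble(annotation)[, c("barcode", "celltype")],
                           truth, by = "barcode", suffix = c("_called", "_true"))
  tibble::tibble(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    celltype_accuracy = mean(as.character(ann$celltype_called) == ann$celltype_true),
    n_called = tp + fp, n_planted = tp + fn)
}

#' @export
print.ppbc_report <- function(x, ...) {
  cat("<ppbc_report> ", x$manifest$n_cells, " cells, ",
      length(x$manifest$samples), " samples\n", sep = "")
  cat("  PPBC-like cells called: ", sum(x$classification$is_ppbc_like),
      " (thresholds: proliferation ",
      signif(x$manifest$thresholds$proliferation, 4), ", regulon ",
      signif(x$manifest$thresholds$regulon, 4), ")\n", sep = "")
  if (!is.null(x$recovery)) {
    cat("  recovery vs ground truth: precision ",
        signif(x$recovery$precision, 3), ", recall ",
        signif(x$recovery$recall, 3), ", celltype accuracy ",
        signif(x$recovery$celltype_accuracy, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes each tabular component as CSV plus the manifest (and thresholds)
#' as JSON under `dir`. Output is deterministic: rerunning an identical
#' pipeline writes byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ppbc_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    if (!is.null(tbl)) readr::write_csv(tibble::as_tibble(tbl),
                                        file.path(dir, paste0(name, ".csv")))
  }
  w(report$classification, "ppbc_classification")
  w(report$annotation, "cell_annotation")
  w(report$proportions, "type_proportions")
  w(report$ppbc_counts, "ppbc_counts")
  w(report$p53_counts, "p53_counts")
  w(report$tests, "tests")
  w(report$de, "hs_de_table")
  w(report$top_genes, "hs_top_genes")
  w(report$recovery, "recovery")
  for (nm in c("venn_up", "venn_down")) {
    vp <- report[[nm]]
    if (!is.null(vp)) {
      w(dplyr::mutate(tibble::as_tibble(vp)[, c("region", "n")]), nm)
      for (i in seq_len(nrow(vp))) {
        writeLines(vp$genes[[i]],
                   file.path(dir, paste0(nm, "_", gsub("&", "_and_", vp$region[i]), ".txt")))
      }
    }
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
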