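#' Simulation configuration for the mammary single-cell study design
#'
#' Builds a validated configuration for [simulate_cells()]. The defaults
#' encode the study design the pipeline targets: two genotypes (C57, NZB) x
#' two states (non-lactating NL, lactation day 21 LacD21) x 3 replicate mice,
#' 2000 cells per sample; three epithelial cell types with marker genes
#' elevated in their own type; a rare PPBC-like subpopulation co-activating
#' the proliferation and regulon gene lists, planted at an elevated fraction
#' only in NZB-LacD21; and Trp53 structurally silenced (counts forced to 0)
#' in a fraction of NZB-LacD21 luminal HS cells.
#'
#' Counts are negative binomial with variance `mu + mu^2/dispersion`
#' (`dispersion` is the NB size parameter); per-gene baseline means are drawn
#' log-normal around `baseline_mean`, and per-cell depth factors are
#' log-normal with log-sd `depth_factor_sd` applied to the mean (not by
#' post-hoc thinning), so fold-changes act on the mean and the NB family is
#' preserved.
#'
#' @param n_genes Number of genes in the simulated universe; must be at least
#'   the number of distinct signature genes plus Trp53 (filler genes named
#'   `Gene0001`, ... make up the rest).
#' @param n_cells_per_sample Cells per mouse sample.
#' @param conditions Data frame with columns `genotype`, `state`, `n_mice`.
#' @param baseline_mean Median of the log-normal per-gene NB baseline mean.
#' @param baseline_sdlog Log-sd of the per-gene baseline mean.
#' @param dispersion NB size parameter (larger = closer to Poisson).
#' @param depth_factor_sd Log-sd of the per-cell depth factor.
#' @param celltype_fractions Named simplex over AV/HS/ME for non-lactating
#'   samples (must sum to 1 within 1e-9).
#' @param celltype_fractions_lactating Same, for lactating samples; the
#'   default raises the alveolar fraction, emulating alveolar expansion
#'   during lactation.
#' @param marker_fold Fold elevation (>= 1) of a type's marker genes in cells
#'   of that type.
#' @param ppbc_fraction Named vector mapping condition (`"genotype.state"`)
#'   to the fraction of planted PPBC-like cells, each in [0, 1).
#' @param ppbc_fold Fold activation (>= 1) of every proliferation-list and
#'   regulon-list gene in planted PPBC-like cells.
#' @param ppbc_hs_enrichment Probability that a planted PPBC-like cell is of
#'   luminal HS type (remainder split between AV and ME proportionally).
#' @param trp53_silencing Named vector mapping condition to the probability
#'   that a luminal HS cell has Trp53 forced to zero (structural silencing).
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 1000,
                              n_cells_per_sample = 2000,
                              conditions = default_conditions(),
                              baseline_mean = 0.1,
                              baseline_sdlog = 0.5,
                              dispersion = 10,
                              depth_factor_sd = 0.2,
                              celltype_fractions = c(AV = 0.40, HS = 0.35, ME = 0.25),
                              celltype_fractions_lactating = c(AV = 0.60, HS = 0.25, ME = 0.15),
                              marker_fold = 16,
                              ppbc_fraction = c(C57.NL = 0.005, C57.LacD21 = 0.005,
                                                NZB.NL = 0.005, NZB.LacD21 = 0.03),
                              ppbc_fold = 16,
                              ppbc_hs_enrichment = 0.61,
                              trp53_silencing = c(C57.NL = 0, C57.LacD21 = 0,
                                                  NZB.NL = 0, NZB.LacD21 = 0.8),
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_sample = as.integer(n_cells_per_sample),
              conditions = tibble::as_tibble(conditions),
              baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
              dispersion = dispersion, depth_factor_sd = depth_factor_sd,
              celltype_fractions = celltype_fractions,
              celltype_fractions_lactating = celltype_fractions_lactating,
              marker_fold = marker_fold, ppbc_fraction = ppbc_fraction,
              ppbc_fold = ppbc_fold, ppbc_hs_enrichment = ppbc_hs_enrichment,
              trp53_silencing = trp53_silencing, seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' @rdname simulation_config
#' @export
default_conditions <- function() {
  tibble::tibble(genotype = rep(GENOTYPE_LEVELS, each = 2L),
                 state = rep(STATE_LEVELS, times = 2L),
                 n_mice = 3L)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (baseline_mean <= 0 || dispersion <= 0 || depth_factor_sd < 0) {
      stop("baseline_mean and dispersion must be positive; depth_factor_sd >= 0",
           call. = FALSE)
    }
    if (marker_fold < 1 || ppbc_fold < 1) stop("folds must be >= 1", call. = FALSE)
    for (fr in list(celltype_fractions, celltype_fractions_lactating)) {
      if (!setequal(names(fr), CELLTYPE_LEVELS)) {
        stop("celltype fractions must be named AV, HS, ME", call. = FALSE)
      }
      if (abs(sum(fr) - 1) > 1e-9) {
        stop("celltype fractions must sum to 1 (within 1e-9)", call. = FALSE)
      }
    }
    keys <- paste(conditions$genotype, conditions$state, sep = ".")
    for (nm in c("ppbc_fraction", "trp53_silencing")) {
      v <- cfg[[nm]]
      miss <- setdiff(keys, names(v))
      if (length(miss)) stop(nm, " missing condition(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
      if (any(v < 0) || any(v >= 1)) stop(nm, " values must lie in [0, 1)", call. = FALSE)
    }
    if (ppbc_hs_enrichment < 0 || ppbc_hs_enrichment > 1) {
      stop("ppbc_hs_enrichment must lie in [0, 1]", call. = FALSE)
    }
  })
  simulated_gene_universe(cfg$n_genes)  # errors if n_genes cannot hold the signatures
  structure(cfg, class = "sim_config")
}

# gene universe: all signature genes, Trp53, then numbered filler
simulated_gene_universe <- function(n_genes, registry = ppbc_signatures()) {
  sig_genes <- unique(unlist(lapply(registry, `[[`, "genes"), use.names = FALSE))
  core <- unique(c(sig_genes, "Trp53"))
  if (n_genes < length(core)) {
    stop("configuration error: n_genes = ", n_genes, " is smaller than the ",
         length(core), " signature genes (plus Trp53) that must exist",
         call. = FALSE)
  }
  c(core, sprintf("Gene%04d", seq_len(n_genes - length(core))))
}

#' Simulate a single-cell experiment with planted subpopulations
#'
#' Draws UMI counts gene-wise from a negative binomial with per-cell depth
#' factors, assigns each cell an epithelial type (elevating that type's
#' marker genes by `marker_fold`), plants PPBC-like cells per condition
#' (multiplying the mean of every proliferation- and regulon-list gene by
#' `ppbc_fold`), and structurally silences Trp53 in a configurable fraction
#' of luminal HS cells per condition. All randomness flows from
#' `config$seed`: identical seeds give identical output.
#'
#' @param config A [simulation_config()].
#' @return A list of class `ppbc_simulation` with elements `counts` (sparse
#'   cells x genes), `metadata` (per-barcode sample table) and `truth`
#'   (tibble `barcode`, `celltype`, `is_ppbc_like`, `trp53_silenced`).
#' @export
simulate_cells <- function(config = simulation_config()) {
  config <- validate_sim_config(unclass(config))
  registry <- ppbc_signatures()
  genes <- simulated_gene_universe(config$n_genes, registry)
  marker_sets <- lapply(registry[CELLTYPE_LEVELS], `[[`, "genes")
  ppbc_genes <- unique(c(registry$proliferation$genes, registry$regulon$genes))

  withr::with_seed(config$seed, {
    mu_g <- config$baseline_mean *
      exp(stats::rnorm(config$n_genes, 0, config$baseline_sdlog))
    names(mu_g) <- genes

    blocks <- list(); md <- list(); truth <- list()
    for (i in seq_len(nrow(config$conditions))) {
      cond <- config$conditions[i, ]
      key <- paste(cond$genotype, cond$state, sep = ".")
      fr <- if (cond$state == "LacD21") config$celltype_fractions_lactating
            else config$celltype_fractions
      for (mouse in seq_len(cond$n_mice)) {
        sample_id <- sprintf("%s_%s_m%d", cond$genotype, cond$state, mouse)
        n <- config$n_cells_per_sample
        barcodes <- sprintf("%s_c%04d", sample_id, seq_len(n))

        is_ppbc <- stats::runif(n) < config$ppbc_fraction[[key]]
        celltype <- sample(CELLTYPE_LEVELS, n, replace = TRUE, prob = fr[CELLTYPE_LEVELS])
        if (any(is_ppbc)) {
          # planted cells enriched for HS; remainder AV/ME by their fractions
          other <- fr[c("AV", "ME")] / sum(fr[c("AV", "ME")])
          repl <- ifelse(stats::runif(sum(is_ppbc)) < config$ppbc_hs_enrichment, "HS",
                         sample(c("AV", "ME"), sum(is_ppbc), replace = TRUE, prob = other))
          celltype[is_ppbc] <- repl
        }

        depth <- exp(stats::rnorm(n, 0, config$depth_factor_sd))
        mu <- outer(depth, mu_g)
        for (ct in CELLTYPE_LEVELS) {
          rows <- celltype == ct
          if (any(rows)) {
            mu[rows, marker_sets[[ct]]] <- mu[rows, marker_sets[[ct]]] * config$marker_fold
          }
        }
        if (any(is_ppbc)) {
          mu[is_ppbc, ppbc_genes] <- mu[is_ppbc, ppbc_genes] * config$ppbc_fold
        }

        cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$dispersion),
                      nrow = n, dimnames = list(barcodes, genes))

        silenced <- rep(FALSE, n)
        p_sil <- config$trp53_silencing[[key]]
        if (p_sil > 0) {
          hs <- celltype == "HS"
          silenced[hs] <- stats::runif(sum(hs)) < p_sil
          cnt[silenced, "Trp53"] <- 0L
        }

        blocks[[sample_id]] <- methods::as(cnt, "CsparseMatrix")
        md[[sample_id]] <- tibble::tibble(
          barcode = barcodes, sample_id = sample_id,
          genotype = cond$genotype, state = cond$state,
          mouse = paste0("m", mouse))
        truth[[sample_id]] <- tibble::tibble(
          barcode = barcodes, celltype = celltype,
          is_ppbc_like = is_ppbc, trp53_silenced = silenced)
      }
    }

    counts <- do.call(rbind, blocks)
    out <- list(counts = counts,
                metadata = dplyr::bind_rows(md),
                truth = dplyr::bind_rows(truth),
                config = config)
    class(out) <- "ppbc_simulation"
    out
  })
}

#' @export
print.ppbc_simulation <- function(x, ...) {
  cat("<ppbc_simulation> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes across ", length(unique(x$metadata$sample_id)), " samples\n", sep = "")
  cat("  planted PPBC-like cells: ", sum(x$truth$is_ppbc_like),
      "; Trp53-silenced HS cells: ", sum(x$truth$trp53_silenced), "\n", sep = "")
  invisible(x)
}

#' Simulate per-day bulk differential-expression tables
#'
#' Builds one DE table per lactation day with exactly known Venn structure:
#' genes are permuted once (from the seed) and assigned deterministically to
#' a common core (significant on every day) and to day-exclusive blocks, for
#' the up- and down-regulated directions separately, so expected Venn region
#' sizes are exact counts, not expectations. Significant genes receive tiny
#' p-values (below 1e-8) and signed log2 fold changes of magnitude around
#' `effect_size`; the `padj` column is an honest Benjamini-Hochberg
#' adjustment of `pvalue`, which by construction leaves the planted
#' membership below 0.05 and everything else above it.
#'
#' @param n_genes Total genes per table.
#' @param days Integer vector of lactation days (subset of 8, 14, 21).
#' @param core_up,core_down Fraction of genes significant in the given
#'   direction on *all* days.
#' @param exclusive_up,exclusive_down Named fraction per day (names matching
#'   `days`) of genes significant in that direction on that day only.
#' @param effect_size Typical |log2 fold change| of significant genes.
#' @param seed Integer seed.
#' @return Named list (`day8`, ...) of DE tibbles, with attribute `truth`
#'   giving the planted gene sets per day and direction.
#' @export
simulate_bulk_de <- function(n_genes = 1000, days = c(8, 14, 21),
                             core_up = 0.20,
                             exclusive_up = c(`8` = 0.10, `14` = 0.05, `21` = 0.05),
                             core_down = 0.05,
                             exclusive_down = c(`8` = 0.02, `14` = 0.02, `21` = 0.02),
                             effect_size = 2, seed = 1L) {
  if (!all(days %in% c(8, 14, 21))) stop("days must be a subset of {8, 14, 21}", call. = FALSE)
  days <- as.character(days)
  exclusive_up <- exclusive_up[days]; exclusive_down <- exclusive_down[days]
  fr <- c(core_up, core_down, exclusive_up, exclusive_down)
  if (any(is.na(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("configuration error: fractions must lie in [0, 1] and name every day",
         call. = FALSE)
  }
  per_day_load <- core_up + core_down + exclusive_up + exclusive_down
  if (any(per_day_load > 1)) {
    stop("configuration error: fractions for day(s) ",
         paste(days[per_day_load > 1], collapse = ", "), " sum to more than 1",
         call. = FALSE)
  }
  total <- ceiling(n_genes * (core_up + core_down + sum(exclusive_up) + sum(exclusive_down)))
  if (total > n_genes) {
    stop("configuration error: planted blocks exceed the gene universe", call. = FALSE)
  }

  genes <- sprintf("bulkGene%05d", seq_len(n_genes))
  withr::with_seed(seed, {
    ord <- sample(genes)  # deterministic permutation; blocks sliced from it
    take <- function(k) {
      out <- utils::head(ord, k)
      ord <<- utils::tail(ord, length(ord) - k)
      out
    }
    up_core <- take(round(n_genes * core_up))
    down_core <- take(round(n_genes * core_down))
    up_excl <- lapply(exclusive_up, function(f) take(round(n_genes * f)))
    down_excl <- lapply(exclusive_down, function(f) take(round(n_genes * f)))

    tables <- lapply(days, function(d) {
      up <- c(up_core, up_excl[[d]])
      down <- c(down_core, down_excl[[d]])
      sig <- c(up, down)
      pvalue <- stats::runif(n_genes, 0.5, 1)
      names(pvalue) <- genes
      pvalue[sig] <- stats::runif(length(sig), 0, 1e-8)
      log2fc <- stats::rnorm(n_genes, 0, 0.2)
      names(log2fc) <- genes
      log2fc[up] <- effect_size + abs(stats::rnorm(length(up), 0, 0.5))
      log2fc[down] <- -effect_size - abs(stats::rnorm(length(down), 0, 0.5))
      tibble::tibble(gene = genes, log2fc = unname(log2fc),
                     pvalue = unname(pvalue),
                     padj = bh_adjust(unname(pvalue)))
    })
    names(tables) <- paste0("day", days)
    attr(tables, "truth") <- list(up_core = up_core, down_core = down_core,
                                  up_exclusive = up_excl, down_exclusive = down_excl)
    tables
  })
}
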