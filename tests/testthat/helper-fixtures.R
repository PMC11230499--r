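# shared fixture builders; everything is generated in code at test time

# dense-logical cells x genes matrix with dimnames, as sparse
toy_matrix <- function(counts, barcodes = NULL, genes = NULL) {
  m <- as.matrix(counts)
  if (is.null(barcodes)) barcodes <- sprintf("cell%02d", seq_len(nrow(m)))
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(ncol(m)))
  dimnames(m) <- list(barcodes, genes)
  methods::as(m, "CsparseMatrix")
}

# write a 10x triplet by hand (MatrixMarket coordinate, genes x cells on disk)
write_raw_10x <- function(dir, n_genes, n_cells, entries, symbols = NULL,
                          barcodes = NULL, header_genes = n_genes,
                          header_cells = n_cells) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(symbols)) symbols <- sprintf("g%02d", seq_len(n_genes))
  if (is.null(barcodes)) barcodes <- sprintf("bc%02d", seq_len(n_cells))
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(header_genes, header_cells, nrow(entries)))
  if (nrow(entries)) {
    lines <- c(lines, apply(entries, 1L, paste, collapse = " "))
  }
  writeLines(lines, file.path(dir, "matrix.mtx"))
  writeLines(paste(paste0("ENSFAKE", seq_len(n_genes)), symbols, "Gene Expression",
                   sep = "\t"),
             file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}

# small random DE table with valid BH structure
random_de_table <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    p <- stats::runif(n)
    tibble::tibble(gene = sprintf("gene%03d", seq_len(n)),
                   log2fc = stats::rnorm(n),
                   pvalue = p,
                   padj = ppbclike::bh_adjust(p))
  })
}

# reduced simulation config for fast tests; study structure kept intact
small_config <- function(seed = 1, ...) {
  ppbclike::simulation_config(n_genes = 300, n_cells_per_sample = 400,
                              seed = seed, ...)
}

# brute-force BH step-up: min over the rank tail of p * m / rank, clipped at 1
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)  # rank of p[i]
    tail_ranks <- rank_i:m
    adj[i] <- min(1, min(p[ord[tail_ranks]] * m / tail_ranks))
  }
  adj
}

# naive average-linkage agglomeration on a distance matrix; returns merge heights
average_linkage_heights <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  dist_between <- function(a, b) mean(D[a, b])
  while (length(active) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i < j) {
          d <- dist_between(active[[i]], active[[j]])
          if (d < bestd) { bestd <- d; best <- c(i, j) }
        }
      }
    }
    heights <- c(heights, bestd)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1L]] <- merged
  }
  heights
}
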