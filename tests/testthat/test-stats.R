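test_that("Welch t handles identical, separated and degenerate groups", {
  same <- welch_t_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # fully separated zero-variance groups: variance floor gives p ~ 0
  sep <- welch_t_two_tailed(c(0, 0, 0), c(10, 10, 10))
  expect_lt(sep$p.value, 1e-10)

  expect_error(welch_t_two_tailed(1, c(1, 2)), "at least 2")
})

test_that("Welch t matches stats::t.test and is antisymmetric in its groups", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
      y <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
      mine <- welch_t_two_tailed(x, y)
      ref <- stats::t.test(x, y)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$parameter, unname(ref$parameter), tolerance = 1e-12)
      expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
      flipped <- welch_t_two_tailed(y, x)
      expect_equal(flipped$statistic, -mine$statistic)
      expect_equal(flipped$p.value, mine$p.value)
    }
  })
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.5)), "\\[0, 1\\]")

  withr::with_seed(12, {
    for (rep in 1:20) {
      p <- runif(sample(5:60, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, bh_brute_force(p), tolerance = 1e-12)
      # monotone in rank and never below raw
      ord <- order(p)
      expect_true(all(diff(adj[ord]) >= -1e-12))
      expect_true(all(adj >= p - 1e-12))
    }
  })
})

test_that("rank-sum DE matches wilcox.test and respects sign contracts", {
  withr::with_seed(8, {
    m <- matrix(rpois(40 * 30, 2), 40, 30)
    m[1:20, 5] <- m[1:20, 5] + 8          # elevated in group A
    m[, 7] <- 3                            # identical everywhere
    m[21:40, 9] <- 0                       # expressed only in A
    mat <- toy_matrix(m)
    a <- rownames(mat)[1:20]; b <- rownames(mat)[21:40]
    de <- per_gene_de(mat, a, b, normalization = "none")

    expect_equal(de$log2fc[7], 0)
    expect_equal(de$pvalue[7], 1)          # full ties
    expect_gt(de$log2fc[9], 0)             # only A expresses it
    expect_lt(de$pvalue[5], 0.001)

    # per-gene oracle: wilcox.test normal approximation without correction
    expr <- log2(1 + as.matrix(mat[c(a, b), ]))
    for (j in c(1, 5, 9, 12)) {
      ref <- suppressWarnings(stats::wilcox.test(expr[1:20, j], expr[21:40, j],
                                                 exact = FALSE, correct = FALSE))
      expect_equal(de$pvalue[j], ref$p.value, tolerance = 1e-9)
    }
    expect_error(per_gene_de(mat, a, c(b, a[1])), "overlap")
    expect_error(per_gene_de(mat, character(0), b), "non-empty")
  })
})

test_that("planted 4-fold genes dominate the top-40 adjusted p-values", {
  withr::with_seed(21, {
    n_a <- 60; n_b <- 60; n_genes <- 1030
    mu <- rep(2, n_genes)
    planted <- 1:30
    m_a <- sapply(seq_len(n_genes), function(j)
      rnbinom(n_a, mu = if (j %in% planted) mu[j] * 4 else mu[j], size = 10))
    m_b <- sapply(seq_len(n_genes), function(j) rnbinom(n_b, mu = mu[j], size = 10))
    mat <- toy_matrix(rbind(m_a, m_b),
                      genes = sprintf("g%04d", seq_len(n_genes)))
    a <- rownames(mat)[seq_len(n_a)]; b <- rownames(mat)[n_a + seq_len(n_b)]
    de <- per_gene_de(mat, a, b, normalization = "none")
    top40 <- de$gene[order(de$padj, de$pvalue)][1:40]
    expect_gte(sum(sprintf("g%04d", planted) %in% top40), 25)
  })
})

test_that("null DE between exchangeable groups stays calibrated", {
  withr::with_seed(31, {
    n <- 40; n_genes <- 2000
    mat <- toy_matrix(matrix(rnbinom(2 * n * n_genes, mu = 2, size = 5), 2 * n),
                      genes = sprintf("g%04d", seq_len(n_genes)))
    a <- rownames(mat)[seq_len(n)]; b <- rownames(mat)[n + seq_len(n)]
    de <- per_gene_de(mat, a, b, normalization = "none")
    expect_lte(mean(de$padj < 0.05), 0.07)
  })
})

test_that("top-gene selection orders by p, then |log2fc|, then symbol", {
  de <- tibble::tibble(gene = c("b", "a", "c", "d", "e"),
                       log2fc = c(1, -2, 1, 3, 0.5),
                       pvalue = c(1e-5, 1e-5, 1e-5, 1e-6, 0.1),
                       padj = c(1e-4, 1e-4, 1e-4, 1e-5, 0.2))
  top <- top_n_genes(de, n = 40, p_cutoff = 2e-4)
  expect_equal(top$gene, c("d", "a", "b", "c"))  # e fails the cutoff
  expect_equal(top_n_genes(de, n = 2, p_cutoff = 2e-4)$gene, c("d", "a"))
  # no qualifying genes: empty result
  expect_equal(nrow(top_n_genes(de, p_cutoff = 1e-9)), 0L)
  # deterministic under repetition
  expect_identical(top_n_genes(de), top_n_genes(de))
})

test_that("hierarchical ordering reproduces brute-force average linkage", {
  # identical rows merge first at height 0
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1),
             d = c(2, 1, 4, 3))
  hc <- hierarchical_order(x)
  expect_equal(hc$row_hclust$height[1], 0)
  expect_setequal(abs(hc$row_hclust$merge[1, ]), c(1, 2))

  # block-diagonal structure keeps blocks contiguous in the leaf order
  withr::with_seed(2, {
    blk <- rbind(matrix(rnorm(5 * 6, mean = rep(c(5, 0), each = 3)), 5, 6, byrow = TRUE),
                 matrix(rnorm(5 * 6, mean = rep(c(0, 5), each = 3)), 5, 6, byrow = TRUE))
    ho <- hierarchical_order(blk)
    grp <- rep(1:2, each = 5)[ho$row_order]
    expect_equal(length(rle(grp)$lengths), 2L)

    # merge heights equal naive recomputation on a 20 x 6 random matrix
    y <- matrix(rnorm(120), 20, 6)
    ho2 <- hierarchical_order(y)
    D <- as.matrix(1 - suppressWarnings(stats::cor(t(y))))
    expect_equal(ho2$row_hclust$height,
                 average_linkage_heights(D), tolerance = 1e-10)
  })

  # zero-variance rows use the correlation-zero convention instead of failing
  z <- rbind(c(1, 1, 1), c(1, 2, 3), c(3, 2, 1))
  expect_silent(hz <- hierarchical_order(z))
  expect_length(hz$row_order, 3L)
  expect_error(hierarchical_order(matrix(1, 1, 3)), "at least 2")
})

test_that("tumor volume follows the modified ellipsoidal formula exactly", {
  expect_equal(tumor_volume(10, 6), 180)
  expect_equal(tumor_volume(7, 0), 0)
  d <- c(1, 2.5, 4)
  expect_equal(tumor_volume(d, d), d^3 / 2)  # spherical degenerate case
  # homogeneous of degree 3 under uniform caliper rescaling
  expect_equal(tumor_volume(3 * 10, 3 * 6), 27 * tumor_volume(10, 6))
  expect_warning(v <- tumor_volume(5, 6), "width exceeds length")
  expect_equal(v, 90)
  expect_error(tumor_volume(-1, 1), "non-negative")
})
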