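test_that("DE filtering applies strict cutoffs and excludes zero fold change", {
  de <- tibble::tibble(gene = c("gA", "gB", "gC", "gD"),
                       log2fc = c(1.2, -2.0, 0.5, 0),
                       pvalue = c(0.001, 0.004, 0.1, 0.0005),
                       padj = c(0.01, 0.04, 0.2, 0.001))
  expect_equal(de_filter(de, 0.05, "up"), "gA")
  expect_equal(de_filter(de, 0.05, "down"), "gB")
  # log2fc exactly 0 is in neither set even when highly significant
  expect_false("gD" %in% c(de_filter(de, 0.05, "up"), de_filter(de, 0.05, "down")))
  # alpha 0: nothing passes a strict inequality
  expect_length(de_filter(de, 0, "up"), 0L)
  # boundary padj == alpha is excluded
  expect_false("gB" %in% de_filter(de, 0.04, "down"))
})

test_that("three-set Venn partition matches hand enumeration", {
  vp <- venn_partition(list(day8 = c("a", "b", "c"), day14 = c("b", "c"),
                            day21 = "c"))
  expect_s3_class(vp, "venn_partition")
  expect_equal(nrow(vp), 7L)  # 2^3 - 1 regions
  g <- function(r) vp$genes[[match(r, vp$region)]]
  expect_equal(g("day8"), "a")
  expect_length(g("day14"), 0L)
  expect_length(g("day21"), 0L)
  expect_equal(g("day8&day14"), "b")
  expect_equal(g("day8&day14&day21"), "c")
  expect_equal(venn_exclusive(vp, "day8"), "a")
  expect_equal(venn_common(vp), "c")

  # identical inputs: everything in the common region
  vp2 <- venn_partition(list(x = c("p", "q"), y = c("p", "q")))
  expect_equal(sort(venn_common(vp2)), c("p", "q"))
  expect_equal(sum(vp2$n), 2L)
  expect_equal(vp2$n[vp2$region != "x&y"], c(0L, 0L))

  expect_error(venn_partition(list(a = "x")), "2 or 3")
  expect_error(venn_partition(stats::setNames(list("x", "y"), c("a", "a"))),
               "unique")
})

test_that("random partitions agree with a per-gene bitmask oracle and conserve the union", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      pool <- sprintf("g%03d", seq_len(sample(20:200, 1)))
      k <- sample(2:3, 1)
      sets <- stats::setNames(
        lapply(seq_len(k), function(i) sample(pool, sample(0:length(pool), 1))),
        paste0("s", seq_len(k)))
      vp <- venn_partition(sets)

      # oracle: tally membership patterns gene by gene
      universe <- unique(unlist(sets))
      pattern <- vapply(universe, function(g) {
        paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
              collapse = "&")
      }, character(1))
      oracle <- table(pattern)
      for (i in seq_len(nrow(vp))) {
        expected <- if (vp$region[i] %in% names(oracle)) oracle[[vp$region[i]]] else 0L
        expect_equal(vp$n[i], expected)
      }
      # conservation: disjoint regions add back to the union
      expect_equal(sum(vp$n), length(universe))
      expect_setequal(unlist(vp$genes), universe)
      # disjointness
      expect_false(anyDuplicated(unlist(vp$genes)) > 0)
    }
  })
})

test_that("permuting input order permutes labels but preserves region sizes", {
  sets <- list(A = c("a", "b", "c", "d"), B = c("b", "d"), C = c("d", "e"))
  vp1 <- venn_partition(sets)
  vp2 <- venn_partition(sets[c(3, 1, 2)])
  norm_label <- function(x) vapply(x$sets, function(s) paste(sort(s), collapse = "&"),
                                   character(1))
  m <- match(norm_label(vp1), norm_label(vp2))
  expect_equal(vp1$n, vp2$n[m])
  expect_equal(lapply(vp1$genes, sort), lapply(vp2$genes[m], sort))
})

test_that("a partition's reconstructed inputs reproduce the partition", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "e"))
  vp <- venn_partition(sets)
  rebuilt <- lapply(names(sets), function(nm) {
    unlist(vp$genes[vapply(vp$sets, function(s) nm %in% s, logical(1))])
  })
  names(rebuilt) <- names(sets)
  expect_equal(lapply(rebuilt, sort), lapply(sets, sort))
  vp2 <- venn_partition(rebuilt)
  expect_equal(vp2$n[match(vp$region, vp2$region)], vp$n)
})

test_that("cross-genotype sets split into shared and unique pieces", {
  res <- cross_genotype_unique(c("x", "y"), c("y", "z"))
  expect_equal(res$shared, "y")
  expect_equal(res$unique_C57, "x")
  expect_equal(res$unique_NZB, "z")
  expect_equal(attr(res, "counts"),
               c(shared = 1L, unique_C57 = 1L, unique_NZB = 1L))
  # disjoint inputs share nothing
  expect_length(cross_genotype_unique("a", "b")$shared, 0L)
})

test_that("bulk simulation feeds the cross-genotype split with exact counts", {
  c57 <- simulate_bulk_de(n_genes = 500, core_up = 0.2,
                          exclusive_up = c(`8` = 0.1, `14` = 0, `21` = 0),
                          core_down = 0, exclusive_down = c(`8` = 0, `14` = 0, `21` = 0),
                          days = 8, seed = 1)
  nzb <- simulate_bulk_de(n_genes = 500, core_up = 0.2,
                          exclusive_up = c(`8` = 0.1, `14` = 0, `21` = 0),
                          core_down = 0, exclusive_down = c(`8` = 0, `14` = 0, `21` = 0),
                          days = 8, seed = 2)
  a <- de_filter(c57$day8, direction = "up")
  b <- de_filter(nzb$day8, direction = "up")
  expect_length(a, 150L)  # 20% core + 10% exclusive of 500
  expect_length(b, 150L)
  res <- cross_genotype_unique(a, b)
  counts <- attr(res, "counts")
  expect_equal(sum(counts), length(union(a, b)))
  expect_equal(counts[["shared"]] + counts[["unique_C57"]], 150L)
})

test_that("the convenience bulk DE recovers a planted fold change", {
  withr::with_seed(13, {
    counts <- matrix(rnbinom(200 * 6, mu = 50, size = 20), 200, 6,
                     dimnames = list(sprintf("g%03d", 1:200),
                                     c(paste0("a", 1:3), paste0("b", 1:3))))
    counts[1:5, 1:3] <- counts[1:5, 1:3] * 8
    de <- bulk_de_welch(counts, paste0("a", 1:3), paste0("b", 1:3))
    expect_true(all(de$log2fc[1:5] > 1))
    expect_true(all(sprintf("g%03d", 1:5) %in% de$gene[order(de$pvalue)][1:10]))
    expect_true(all(de$padj >= de$pvalue - 1e-12))
    expect_error(bulk_de_welch(counts, "a1", paste0("b", 1:3)), "at least 2")
    expect_error(bulk_de_welch(counts, paste0("a", 1:3), c("a1", "b1")), "overlap")
  })
})
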