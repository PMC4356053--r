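test_that("Fisher exact agrees with closed forms and the enumeration oracle", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5, "two"), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10, "one-greater"),
               1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 7, 2, 8, "two"),
               fisher_oracle(3, 7, 2, 8, "two"), tolerance = 1e-9)
  # random spot checks in both tails
  withr::with_seed(3, {
    for (i in 1:25) {
      t4 <- as.integer(rmultinom(1, sample(8:30, 1), runif(4, 0.05, 1)))
      expect_equal(fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4], "two"),
                   fisher_oracle(t4[1], t4[2], t4[3], t4[4], "two"),
                   tolerance = 1e-9, info = paste(t4, collapse = ","))
      expect_equal(fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4], "one-greater"),
                   fisher_oracle(t4[1], t4[2], t4[3], t4[4], "one"),
                   tolerance = 1e-9)
    }
  })
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "zero")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.05, 0.01)), c(0.05, 0.02))
  withr::with_seed(8, {
    p <- runif(50)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  })
  expect_error(bh_adjust(c(0.5, 0)), "lie in")
  expect_error(bh_adjust(c(0.5, 1.2)), "lie in")
})

test_that("projection test uses the binomial null on query midpoints", {
  g <- genome_spec("c", 1000)
  q <- region_set("c", seq(0, 900, 100), seq(10, 910, 100), g)
  full <- region_set("c", 0, 1000, g)
  res <- projection_test(q, full)
  expect_equal(res$p0, 1)
  expect_equal(res$k, res$n)
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "none")

  # n = 10, p0 = 0.5, k = 10
  half <- region_set("c", 0, 500, g)
  q2 <- region_set("c", seq(0, 450, 50), seq(10, 460, 50), g)
  res2 <- projection_test(q2, half)
  expect_equal(res2$k, 10)
  expect_equal(res2$p_value, 2 / 1024, tolerance = 1e-12)
  expect_equal(res2$direction, "enriched")

  # n = 6, k = 4, p0 = 0.25 against the explicit binomial summation
  quarter <- region_set("c", 0, 250, g)
  pos <- c(10, 60, 110, 160, 300, 600)
  q3 <- region_set("c", pos, pos + 4, g)
  res3 <- projection_test(q3, quarter)
  expect_equal(res3$k, 4)
  expect_equal(res3$p_value, projection_oracle(4, 6, 0.25), tolerance = 1e-12)
  expect_error(projection_test(q3[0], quarter), "empty")
})

test_that("DE gene selection applies FDR and fold-change cutoffs jointly", {
  genes <- data.frame(id = letters[1:4], log2fc = c(2.5, 1.5, -3, -3),
                      fdr = c(0.005, 0.005, 0.02, 0.001))
  de <- select_de_genes(genes)
  expect_equal(de$up$id, "a")
  expect_equal(de$down$id, "d")
  expect_error(select_de_genes(genes[, 1, drop = FALSE]), "lacks")
})

test_that("gene-set enrichment and list overlap follow the hypergeometric", {
  uni <- sprintf("g%02d", 1:20)
  hits <- uni[1:5]
  sets <- list(hit_set = uni[1:10], null_set = uni[c(1, 6:14)])
  res <- gene_set_enrichment(hits, uni, sets)
  expect_equal(res$p_value[res$set == "hit_set"], 252 / 15504,
               tolerance = 1e-12)
  expect_gte(res$p_value[res$set == "null_set"], 0.5)
  expect_error(gene_set_enrichment(c("zz"), uni, sets), "subset")

  expect_equal(list_overlap_test(letters[1:3], letters[4:6], 6), 1)
  a <- sprintf("m%02d", 1:51); b <- sprintf("m%02d", 30:93)
  ov <- length(intersect(a, b))
  expect_equal(ov, 22)
  p <- list_overlap_test(a, b, 300)
  # hypergeometric enumeration: P(overlap >= 22 | 51, 64 of 300)
  p_oracle <- sum(stats::dhyper(22:51, 64, 300 - 64, 51))
  expect_equal(p, p_oracle, tolerance = 1e-9)
})

test_that("region-domain enrichment detects forced structure and symmetry", {
  g <- genome_spec("c", 1e5)
  dom <- region_set("c", 0, 2e4, g)
  inside_regions <- region_set("c", seq(100, 19000, length.out = 40),
                               seq(100, 19000, length.out = 40) + 200, g)
  res <- region_vs_domains_enrichment(inside_regions, dom, n_random = 50,
                                      seed = 4)
  expect_equal(res$observed_fraction, 1)
  expect_equal(res$direction, "enriched")
  expect_lt(res$p_value, 1e-6)

  comp <- region_set("c", 2e4, 1e5, g)
  res2 <- region_vs_domains_enrichment(inside_regions, comp, n_random = 50,
                                       seed = 4)
  expect_equal(res2$direction, "depleted")
  expect_equal(res$table["inside", "observed"], res2$table["outside", "observed"])
})

test_that("gene-LAD association respects boundary conventions and degeneracy", {
  g <- genome_spec("c", 1e5)
  lads <- region_set("c", 2e4, 4e4, g)
  genes <- data.frame(id = c("a", "b", "c"), chrom = "c",
                      tss = c(2e4, 4e4, 3e4), strand = "+",
                      expr = c(1, 2, 3), log2fc = c(3, -3, 0),
                      fdr = c(0.001, 0.001, 0.9))
  de <- select_de_genes(genes)
  res <- gene_lad_association(genes, lads, g, de)
  # TSS at LAD start is inside (positive distance), at LAD end outside
  # (distance 0 but counted in the outside column)
  expect_gte(res$distances[1], 0)
  expect_lte(res$distances[2], 0)
  expect_equal(res$table["up", "inside"], 1)
  expect_equal(res$table["down", "outside"], 1)

  all_in <- data.frame(id = c("a", "b"), chrom = "c", tss = c(2.5e4, 3e4),
                       strand = "+", expr = 1:2, log2fc = c(3, -3),
                       fdr = c(0.001, 0.001))
  res2 <- gene_lad_association(all_in, lads, g, select_de_genes(all_in))
  expect_true(is.na(res2$p_value))
  expect_equal(sum(res2$table[, "outside"]), 0)
})
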