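test_that("region standardization recenters, clips and is idempotent", {
  g <- genome_spec("chr1", 1000)
  r <- region_set("chr1", c(100, 10, 0), c(200, 50, 6), g)
  std <- standardize_region_length(r, 40)
  expect_equal(GenomicRanges::start(std) - 1, c(130, 10, 0))
  expect_equal(GenomicRanges::end(std), c(170, 50, 40))
  expect_identical(standardize_region_length(std, 40), std)
  g2 <- genome_spec("s", 30)
  expect_error(standardize_region_length(region_set("s", 0, 10, g2), 40),
               "shorter than target")
})

test_that("promoter regions follow the upstream-of-TSS strand convention", {
  g <- genome_spec("chr1", 10000)
  genes <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                      tss = c(5000, 5000, 500), strand = c("+", "-", "+"))
  pr <- promoter_regions(genes, g, width = 1000)
  expect_equal(GenomicRanges::start(pr) - 1, c(4000, 5000, 0))
  expect_equal(GenomicRanges::end(pr), c(5000, 6000, 500))
  genes$strand <- "x"
  expect_error(promoter_regions(genes, g), "strand")
})

test_that("midpoint overlap fraction follows the half-open convention", {
  g <- genome_spec("chr1", 1000)
  a <- region_set("chr1", c(100, 600), c(200, 700), g)   # midpoints 150, 650
  b <- region_set("chr1", 0, 500, g)
  res <- interval_overlap_fraction(a, b)
  expect_equal(res$midpoint_fraction, 0.5)
  expect_equal(res$overlap_bp, c(100, 0))
  expect_equal(interval_overlap_fraction(region_set("chr1", 100, 200, g),
                                         region_set("chr1", 0, 1000, g))$midpoint_fraction, 1)
  expect_equal(interval_overlap_fraction(a, region_set("chr1", 900, 950, g))$midpoint_fraction, 0)
  # midpoint exactly at a domain end lies outside
  edge <- region_set("chr1", 499, 501, g)   # midpoint 500
  expect_equal(interval_overlap_fraction(edge, b)$midpoint_fraction, 0)
  b2 <- region_set(c("chrX"), 0, 10, genome_spec("chrX", 100))
  expect_error(interval_overlap_fraction(a, b2), "different genomes")
})

test_that("BED, bedGraph and chrom-sizes files round-trip exactly", {
  g <- genome_spec(c("chr1", "chr2"), c(2000, 1500))
  r <- region_set(c("chr1", "chr2"), c(0, 10), c(100, 1500), g,
                  strand = c("+", "-"), score = c(1.5, -2), name = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(r, f)
  r2 <- read_bed(f, g)
  expect_equal(GenomicRanges::start(r2), GenomicRanges::start(r))
  expect_equal(GenomicRanges::end(r2), GenomicRanges::end(r))
  expect_equal(r2$name, r$name)
  expect_equal(r2$score, r$score)
  expect_equal(as.character(GenomicRanges::strand(r2)),
               as.character(GenomicRanges::strand(r)))

  tr <- coverage_track(g, 500, list(chr1 = c(1, 0, 2.5, 4), chr2 = c(0, 7, 1)),
                       units = "RPKM")
  f2 <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f2)
  tr2 <- read_bedgraph(f2, g)
  expect_equal(tr2$values, tr$values)
  expect_equal(tr2$bin, tr$bin)

  f3 <- withr::local_tempfile()
  write_chrom_sizes(g, f3)
  expect_equal(unclass(read_chrom_sizes(f3)), unclass(g),
               ignore_attr = TRUE)
})

test_that("random regions are reproducible, length-weighted and uniform", {
  g1 <- genome_spec("c", 1000)
  s1 <- sample_random_regions(rep(40, 10), g1, n_sets = 1, seed = 7)[[1]]
  s2 <- sample_random_regions(rep(40, 10), g1, n_sets = 1, seed = 7)[[1]]
  expect_identical(GenomicRanges::start(s1), GenomicRanges::start(s2))
  expect_true(all(GenomicRanges::width(s1) == 40))

  forced <- sample_random_regions(40, genome_spec("c", 40), seed = 1)[[1]]
  expect_equal(GenomicRanges::start(forced) - 1, 0)
  expect_equal(GenomicRanges::end(forced), 40)

  # placement-count weighting: length-1 draws land on the 100-bp chromosome
  # with probability 100/1000
  g2 <- genome_spec(c("big", "small"), c(900, 100))
  draws <- sample_random_regions(rep(1, 10000), g2, seed = 3)[[1]]
  frac_small <- mean(as.character(GenomicRanges::seqnames(draws)) == "small")
  expect_lt(abs(frac_small - 0.100), 0.01)

  # per-chromosome start positions are uniform (chi-square GoF, 10 bins)
  starts <- GenomicRanges::start(draws[GenomicRanges::seqnames(draws) == "big"]) - 1
  cs <- suppressWarnings(stats::chisq.test(table(cut(starts, seq(0, 900, length.out = 11),
                                                     include.lowest = TRUE))))
  expect_gt(cs$p.value, 0.01)

  expect_error(sample_random_regions(2000, g2, seed = 1), "exceeds")
})
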