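test_that("RPKM normalization follows the closed form", {
  g <- genome_spec("chr1", 3000)
  # 10 fragments fully inside bin 1 of a 1,000-bp binning, total padded to 1e6
  # is impractical; check the formula directly at two scales instead
  fr <- region_set("chr1", rep(100, 10), rep(200, 10), g)
  tr <- rpkm_normalize(fr, 1000)
  # value = 10 / ((1000/1000) * (10/1e6)) = 1e6
  expect_equal(tr$values$chr1, c(1e6, 0, 0))
  fr2 <- region_set("chr1", c(0, 100, 200, 300, 400), c(50, 150, 250, 350, 450), g)
  tr2 <- rpkm_normalize(fr2, 500)
  expect_equal(tr2$values$chr1[1], 5 / ((500 / 1000) * (5 / 1e6)))
  expect_equal(tr2$values$chr1[2:6], rep(0, 5))
  expect_error(rpkm_normalize(fr[0], 100), "empty")
})

test_that("fragments increment every bin they overlap", {
  g <- genome_spec("chr1", 1000)
  fr <- region_set("chr1", 90, 210, g)     # spans bins 1-3 at bin = 100
  counts <- senesceq:::bin_fragment_counts(fr, 100)
  expect_equal(counts$values$chr1, c(1, 1, 1, rep(0, 7)))
})

test_that("metaprofile equals direct track lookups", {
  g <- genome_spec("chr1", 10000)
  vals <- rep(2.5, 100)
  tr <- coverage_track(g, 100, list(chr1 = vals))
  anchors <- region_set("chr1", c(2000, 5000), c(2100, 5100), g)
  mp <- metaprofile(tr, anchors, half_window = 500, step = 100)
  expect_true(all(mp$mean == 2.5))
  expect_true(all(mp$n == 2))

  # planted bump read off the track directly for a single anchor
  vals2 <- numeric(100); vals2[40:60] <- seq(1, 21)
  tr2 <- coverage_track(g, 100, list(chr1 = vals2))
  a1 <- region_set("chr1", 4950, 4951, g)   # midpoint 4950, bin 50
  mp2 <- metaprofile(tr2, a1, half_window = 1000, step = 100)
  direct <- vals2[floor((4950 + mp2$offset) / 100) + 1]
  expect_equal(mp2$mean, direct)

  # mean of two anchors at every offset
  a2 <- region_set("chr1", c(4950, 5950), c(4951, 5951), g)
  mp3 <- metaprofile(tr2, a2, half_window = 500, step = 100)
  v1 <- vals2[floor((4950 + mp3$offset) / 100) + 1]
  v2 <- vals2[floor((5950 + mp3$offset) / 100) + 1]
  expect_equal(mp3$mean, (v1 + v2) / 2)

  # anchors whose window leaves the chromosome are excluded
  edge <- region_set("chr1", c(100, 5000), c(101, 5001), g)
  mp4 <- metaprofile(tr, edge, half_window = 500, step = 100)
  expect_equal(attr(mp4, "n_excluded"), 1)
  expect_error(metaprofile(tr, edge[1], half_window = 500, step = 100),
               "excluded")
})

test_that("differential signal at probe sites is late minus early", {
  g <- genome_spec("chr1", 10000)
  e <- coverage_track(g, 100, list(chr1 = rep(1, 100)))
  l <- coverage_track(g, 100, list(chr1 = rep(3, 100)))
  sites <- data.frame(id = c("p1", "p2"), chrom = "chr1", pos = c(2000, 7000))
  expect_equal(differential_signal_at_sites(e, e, sites)$diff, c(0, 0))
  expect_equal(differential_signal_at_sites(e, l, sites)$diff, c(2, 2))
  bad <- data.frame(id = "px", chrom = "chr1", pos = 20000)
  expect_error(differential_signal_at_sites(e, l, bad), "px")
})

test_that("neighborhood beta profile matches a quadratic brute-force oracle", {
  # single anchor with one neighbor at +120 lands in the [+100, +150) bin
  probes1 <- data.frame(id = c("a", "n"), chrom = "c", pos = c(1000, 1120),
                        beta_early = c(0.5, 0.6), beta_late = c(0.5, 0.8))
  prof1 <- neighborhood_beta_profile(probes1, probes1[1, ], window = 500, bin = 50)
  row <- prof1[prof1$offset == 100, ]
  expect_equal(row$beta_late, 0.8)
  expect_equal(row$beta_early, 0.6)
  expect_true(is.na(prof1$beta_late[prof1$offset == 300]))

  withr::with_seed(14, {
    probes <- data.frame(
      id = sprintf("p%03d", 1:200),
      chrom = sample(c("c1", "c2"), 200, TRUE),
      pos = sample.int(20000, 200),
      beta_early = runif(200), beta_late = runif(200))
  })
  anchors <- probes[seq(1, 200, by = 7), ]
  prof <- neighborhood_beta_profile(probes, anchors, window = 500, bin = 50)
  breaks <- seq(-500, 500, by = 50)
  # nested loop over (anchor, probe) pairs
  for (bi in seq_len(length(breaks) - 1)) {
    vals_e <- c(); vals_l <- c()
    for (i in seq_len(nrow(anchors))) for (j in seq_len(nrow(probes))) {
      if (anchors$chrom[i] != probes$chrom[j]) next
      d <- probes$pos[j] - anchors$pos[i]
      if (d >= breaks[bi] && d < breaks[bi + 1]) {
        vals_e <- c(vals_e, probes$beta_early[j])
        vals_l <- c(vals_l, probes$beta_late[j])
      }
    }
    if (length(vals_e)) {
      expect_equal(prof$beta_early[bi], mean(vals_e), tolerance = 1e-12)
      expect_equal(prof$beta_late[bi], mean(vals_l), tolerance = 1e-12)
    } else {
      expect_true(is.na(prof$beta_early[bi]))
    }
  }
})

test_that("inside/outside comparison is exact on small groups and symmetric", {
  g <- genome_spec("c", 2000)
  dom <- region_set("c", 0, 1000, g)
  const <- coverage_track(g, 100, list(c = rep(4, 20)))
  res <- inside_outside_test(const, dom)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_inside, res$mean_outside)

  # inside bins exactly one less than outside bins: exact rank enumeration
  vals <- c(seq(2, 20, by = 2) - 1, seq(2, 20, by = 2))  # inside then outside
  tr <- coverage_track(g, 100, list(c = vals))
  res2 <- inside_outside_test(tr, dom)
  expect_lt(res2$mean_inside, res2$mean_outside)
  # brute-force enumeration over all C(20,10) group assignments
  allv <- vals; r <- rank(allv)
  u_obs <- sum(r[1:10]) - 10 * 11 / 2
  combs <- utils::combn(20, 10)
  u_all <- colSums(matrix(r[combs], nrow = 10)) - 10 * 11 / 2
  p_exact <- mean(abs(u_all - 50) >= abs(u_obs - 50) - 1e-9)
  expect_equal(res2$p_value, p_exact, tolerance = 1e-9)

  comp <- region_set("c", 1000, 2000, g)
  res3 <- inside_outside_test(tr, comp)
  expect_equal(res3$mean_inside, res2$mean_outside)
  expect_equal(res3$mean_outside, res2$mean_inside)
})

test_that("LAD border profile reproduces a constructed step track", {
  g <- genome_spec("c", 1e5)
  lads <- region_set("c", c(3e4, 7e4), c(5e4, 9e4), g)
  # value 1 outside LADs, 0 inside
  vals <- rep(1, 100)
  for (i in seq_along(lads)) {
    s <- GenomicRanges::start(lads[i]) - 1; e <- GenomicRanges::end(lads[i])
    vals[(s / 1000 + 1):(e / 1000)] <- 0
  }
  tr <- coverage_track(g, 1000, list(c = vals))
  prof <- lad_border_profile(tr, lads, flank = 8000, step = 1000)
  inside <- prof$mean[prof$offset > 0]
  outside <- prof$mean[prof$offset < -1000]
  expect_true(all(inside == 0))
  expect_true(all(outside == 1))

  const <- coverage_track(g, 1000, list(c = rep(3, 100)))
  prof2 <- lad_border_profile(const, lads, flank = 5000, step = 1000)
  expect_true(all(prof2$mean[prof2$n > 0] == 3))
})

test_that("significant CpG selection applies both thresholds", {
  probes <- data.frame(id = c("a", "b", "c", "d"),
                       beta_early = c(0.3, 0.3, 0.8, 0.5),
                       beta_late = c(0.55, 0.45, 0.3, 0.4),
                       adj_p = c(0.04, 0.04, 0.06, 0.01))
  sel <- select_significant_cpgs(probes)
  expect_equal(sel$hyper$id, "a")        # 0.04, +0.25
  expect_equal(nrow(sel$hypo), 0)        # -0.5 but p 0.06; -0.1 too small
  expect_error(select_significant_cpgs(probes[, 1:3]), "lacks")
})
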