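# geometric phantoms built in code
make_disc <- function(sz, cx, cy, a, b = a, level = 0.5) {
  xs <- matrix(rep(seq_len(sz), sz), sz)
  ys <- matrix(rep(seq_len(sz), each = sz), sz)
  img <- matrix(0, sz, sz)
  img[((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1] <- level
  img
}

add_spot <- function(img, x, y, amp, sigma = 1.5) {
  xs <- matrix(rep(seq_len(nrow(img)), ncol(img)), nrow(img))
  ys <- matrix(rep(seq_len(ncol(img)), each = nrow(img)), nrow(img))
  img + amp * exp(-((xs - x)^2 + (ys - y)^2) / (2 * sigma^2))
}

test_that("segmentation recovers area and elongation of planted shapes", {
  circ <- make_disc(100, 50, 50, 30)
  nuc <- segment_nuclei(circ)
  expect_length(nuc, 1)
  expect_lt(abs(nuc[[1]]$elongation - 1), 0.05)
  expect_lt(abs(nuc[[1]]$area - pi * 900) / (pi * 900), 0.05)

  ell <- make_disc(100, 50, 50, 30, 15)
  nuc2 <- segment_nuclei(ell)
  expect_lt(abs(nuc2[[1]]$area - pi * 450) / (pi * 450), 0.05)
  expect_lt(abs(nuc2[[1]]$elongation - 2), 0.1)

  expect_error(segment_nuclei(matrix(0, 50, 50)), "no nucleus")
})

test_that("zone partition splits the mask into thirds of boundary depth", {
  circ <- make_disc(100, 50, 50, 30) > 0
  zones <- partition_zones(circ)
  expect_true(all((zones > 0) == circ))             # exact partition
  area <- sum(circ)
  expect_lt(abs(sum(zones == 3) / area - (1 / 3)^2), 0.02)
  expect_lt(abs(sum(zones == 1) / area - (1 - (2 / 3)^2)), 0.03)

  thin <- matrix(FALSE, 20, 20); thin[10, 3:18] <- TRUE
  zthin <- partition_zones(thin)
  expect_true(all(zthin[thin] == 1L))               # degenerate: all border
  expect_error(partition_zones(matrix(FALSE, 5, 5)), "empty")
})

test_that("spot detection recovers planted Gaussians and merges close pairs", {
  withr::with_seed(2, {
    img <- make_disc(120, 60, 60, 45, level = 0)
    mask <- make_disc(120, 60, 60, 45) > 0
    noise_sd <- 0.002
    centers <- cbind(c(40, 60, 80, 50, 75), c(40, 80, 45, 65, 70))
    for (i in 1:5) img <- add_spot(img, centers[i, 1], centers[i, 2],
                                   amp = 10 * noise_sd)
    img <- img + matrix(rnorm(120^2, 0, noise_sd), 120)
  })
  spots <- detect_spots(img, mask)
  expect_equal(nrow(spots), 5)
  d <- vapply(1:5, function(i)
    min(sqrt((spots$x - centers[i, 1])^2 + (spots$y - centers[i, 2])^2)),
    numeric(1))
  expect_true(all(d <= 1.5))

  flat <- matrix(0, 60, 60); fm <- make_disc(60, 30, 30, 20) > 0
  expect_equal(nrow(detect_spots(flat, fm)), 0)

  two <- add_spot(add_spot(make_disc(60, 30, 30, 25, level = 0), 30, 30, 0.1),
                  32, 30, 0.1)
  m2 <- make_disc(60, 30, 30, 25) > 0
  expect_equal(nrow(detect_spots(two, m2)), 1)     # 2 px apart: merged
})

test_that("length proxy is linear in amplitude and few-spot nuclei excluded", {
  base <- image_config()
  cfgA <- list(early = utils::modifyList(base$early, list(amplitude = 0.04)),
               amplitude_cv = 0, n_spots = c(6, 12))
  cfgB <- list(early = utils::modifyList(base$early, list(amplitude = 0.08)),
               amplitude_cv = 0, n_spots = c(6, 12))
  gA <- generate_nucleus_images(8, "early", config = cfgA, seed = 6)
  gB <- generate_nucleus_images(8, "early", config = cfgB, seed = 6)
  mA <- telomere_summary(analyze_image_set(gA$images))
  mB <- telomere_summary(analyze_image_set(gB$images))
  expect_lt(abs(mB$mean_length_proxy / mA$mean_length_proxy - 2), 0.1)

  # a nucleus with two spots is measured but excluded from summaries
  cfg2 <- list(n_spots = c(2, 2))
  g2 <- generate_nucleus_images(2, "early", config = cfg2, seed = 9)
  meas <- analyze_image_set(g2$images)
  expect_true(all(!meas$included[meas$n_spots < 3]))
  cfg3 <- list(n_spots = c(5, 8))
  g3 <- generate_nucleus_images(2, "early", config = cfg3, seed = 9)
  both <- rbind(analyze_image_set(g3$images), meas[meas$n_spots < 3, ])
  summ <- telomere_summary(both)
  expect_equal(summ$included_n, sum(both$n_spots >= 3))
  only_small <- meas[meas$n_spots < 3, , drop = FALSE]
  if (nrow(only_small)) expect_error(telomere_summary(only_small), "no nucleus")
})
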