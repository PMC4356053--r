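# Q-FISH image quantification: nucleus segmentation, three-zone partition by
# normalized boundary distance, telomere spot detection and the
# intensity-based telomere length proxy.

#' Segment nuclei in a DAPI image
#'
#' Global Otsu threshold, hole filling and connected-component labeling;
#' components smaller than `min_area` are discarded. Elongation is the square
#' root of the eigenvalue ratio of the pixel-coordinate covariance (major /
#' minor second-moment axis).
#'
#' @param dapi 2D numeric matrix in [0, 1].
#' @param min_area minimal component area in px^2 (default 200).
#' @return list of per-nucleus lists: `id`, `mask` (logical matrix), `area`,
#'   `elongation`, `centroid`.
#' @export
segment_nuclei <- function(dapi, min_area = 200) {
  if (length(dim(dapi)) != 2) stop("dapi must be a single-channel 2D image")
  th <- EBImage::otsu(EBImage::Image(dapi))
  mask <- EBImage::fillHull(dapi > th)
  labels <- EBImage::bwlabel(mask)
  n <- max(labels)
  out <- list()
  for (k in seq_len(n)) {
    m <- labels == k
    area <- sum(m)
    if (area < min_area) next
    idx <- which(m, arr.ind = TRUE)
    ctr <- colMeans(idx)
    cv <- stats::cov(idx)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    elong <- sqrt(max(ev) / max(min(ev), 1e-12))
    out[[length(out) + 1]] <- list(id = length(out) + 1, mask = m,
                                   area = area, elongation = elong,
                                   centroid = ctr)
  }
  if (!length(out)) stop("no nucleus found (no component above min_area)")
  out
}

#' Partition a nucleus mask into border, middle and center zones
#'
#' Normalized boundary depth `d(p) = dist_to_boundary(p) / max_dist`; zones:
#' border `d < 1/3`, middle `1/3 <= d < 2/3`, center `d >= 2/3`. Degenerate
#' masks whose maximal boundary distance is at the pixel floor are entirely
#' border.
#'
#' @param mask logical matrix (the nucleus).
#' @return integer matrix, 0 outside, 1 border, 2 middle, 3 center.
#' @export
partition_zones <- function(mask) {
  if (!any(mask)) stop("empty mask")
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  dm <- as.matrix(EBImage::imageData(dm))
  mx <- max(dm)
  zones <- matrix(0L, nrow(mask), ncol(mask))
  if (mx <= 1) {           # thin mask: everything touches the boundary
    zones[mask] <- 1L
    return(zones)
  }
  d <- dm / mx
  zones[mask & d < 1 / 3] <- 1L
  zones[mask & d >= 1 / 3 & d < 2 / 3] <- 2L
  zones[mask & d >= 2 / 3] <- 3L
  zones
}

#' Detect telomere spots in a Cy3 channel
#'
#' Spots are local maxima (8-neighborhood) of a matched-filtered image
#' (Gaussian smoothing at the expected spot scale) inside the mask whose
#' filtered response is at least `k` raw-background standard deviations
#' above the filtered background; the background is estimated from masked
#' pixels and refined after excluding 3-sigma discs around candidate spots.
#' Filtering suppresses single-pixel noise, so the `k`-sd rule on the
#' filtered response keeps spurious maxima out while a spot of amplitude
#' `10 x` noise retains a filtered response of about five raw sds. Maxima
#' closer than `min_sep` px are merged (brightest kept). Reported peak
#' intensities and the background attributes are on the raw image, as the
#' length proxy subtracts the raw nucleus background.
#'
#' @param cy3 2D numeric matrix (same shape as `mask`).
#' @param mask logical nucleus mask.
#' @param k detection threshold in background sds (default 3).
#' @param min_sep minimal spot separation in px (default 3).
#' @param spot_sigma expected spot sigma in px: matched-filter scale and
#'   exclusion-disc radius (default 1.5; 0 disables smoothing).
#' @return data.frame `x`, `y`, `peak` (raw intensity), plus attributes
#'   `bg_mean`, `bg_sd` (raw background of this nucleus).
#' @export
detect_spots <- function(cy3, mask, k = 3, min_sep = 3, spot_sigma = 1.5) {
  if (!all(dim(cy3) == dim(mask))) stop("cy3 and mask shapes differ")
  sm <- if (spot_sigma > 0)
    as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(cy3),
                                                sigma = spot_sigma)))
  else cy3
  r <- max(1, ceiling(3 * max(spot_sigma, 1)))
  # background mean/sd of the raw image, refined by excluding candidate discs;
  # the detection threshold is k raw-background sds above the filtered
  # background (the filter suppresses single-pixel noise, so filtered noise
  # essentially never reaches k raw sds)
  # upper-quantile spread: insensitive both to the bright spots themselves
  # and to the zero-clamped lower tail a camera offset of 0 produces
  robust_sd <- function(x) {
    q <- stats::quantile(x, c(0.5, 0.84), names = FALSE, type = 7)
    s <- (q[2] - q[1]) / 0.9945
    if (!is.finite(s) || s == 0) s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- 1e-12
    s
  }
  # seed the background estimate by excluding discs around the brightest
  # filtered maxima (capped so exclusions cover at most half the mask), then
  # refine once with the calibrated threshold
  bg_mean <- mean(cy3[mask]); bg_sd <- robust_sd(cy3[mask])
  bg_sm <- stats::median(sm[mask])
  cand <- local_maxima(sm, mask, -Inf)
  n_keep <- min(60, max(5, floor(sum(mask) / (2 * (2 * r + 1)^2))))
  cand <- utils::head(cand[order(-cand$peak), ], n_keep)
  for (iter in 1:2) {
    excl <- spot_disc_mask(dim(sm), cand, r)
    bgpx <- cy3[mask & !excl]
    if (length(bgpx) > 20) {
      bg_mean <- mean(bgpx); bg_sd <- robust_sd(bgpx)
      bg_sm <- mean(sm[mask & !excl])
    }
    cand <- local_maxima(sm, mask, bg_sm + k * bg_sd)
  }
  peaks <- local_maxima(sm, mask, bg_sm + k * bg_sd)
  # brightest first: merge maxima closer than min_sep, and suppress skirt
  # artifacts - secondary maxima riding on the flank of a much brighter
  # spot within its 3-sigma footprint
  if (nrow(peaks) > 1) {
    peaks <- peaks[order(-peaks$peak), ]
    prom_r <- 3 * max(spot_sigma, 1)
    keep <- rep(TRUE, nrow(peaks))
    for (j in 2:nrow(peaks)) {
      prev <- which(keep[seq_len(j - 1)])
      d <- sqrt((peaks$x[prev] - peaks$x[j])^2 +
                  (peaks$y[prev] - peaks$y[j])^2)
      too_close <- any(d < min_sep)
      skirt <- any(d < prom_r &
                     (peaks$peak[j] - bg_sm) <
                       0.5 * (peaks$peak[prev] - bg_sm))
      if (too_close || skirt) keep[j] <- FALSE
    }
    peaks <- peaks[keep, ]
  }
  rownames(peaks) <- NULL
  # raw peak = maximum raw intensity within 1 px of the filtered maximum
  if (nrow(peaks)) {
    peaks$peak <- vapply(seq_len(nrow(peaks)), function(j) {
      xs <- max(1, peaks$x[j] - 1):min(nrow(cy3), peaks$x[j] + 1)
      ys <- max(1, peaks$y[j] - 1):min(ncol(cy3), peaks$y[j] + 1)
      max(cy3[xs, ys])
    }, numeric(1))
  }
  excl <- spot_disc_mask(dim(cy3), peaks, r)
  bgpx_raw <- cy3[mask & !excl]
  if (length(bgpx_raw) < 20) bgpx_raw <- cy3[mask]
  attr(peaks, "bg_mean") <- mean(bgpx_raw)
  attr(peaks, "bg_sd") <- max(stats::sd(bgpx_raw), 1e-12)
  peaks
}

spot_disc_mask <- function(dims, peaks, r) {
  excl <- matrix(FALSE, dims[1], dims[2])
  for (j in seq_len(nrow(peaks))) {
    xs <- max(1, peaks$x[j] - r):min(dims[1], peaks$x[j] + r)
    ys <- max(1, peaks$y[j] - r):min(dims[2], peaks$y[j] + r)
    excl[xs, ys] <- TRUE
  }
  excl
}

local_maxima <- function(img, mask, threshold) {
  n <- nrow(img); m <- ncol(img)
  pad <- matrix(-Inf, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- img
  ctr <- pad[2:(n + 1), 2:(m + 1)]
  is_max <- matrix(TRUE, n, m)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2 + dx):(n + 1 + dx), (2 + dy):(m + 1 + dy)]
    is_max <- is_max & (ctr >= nb)
  }
  sel <- which(is_max & mask & img >= threshold, arr.ind = TRUE)
  if (!nrow(sel))
    return(data.frame(x = integer(0), y = integer(0), peak = numeric(0)))
  data.frame(x = sel[, 1], y = sel[, 2], peak = img[sel])
}

#' Quantify one two-channel nucleus image
#'
#' Runs segmentation on channel 1, zone partition, spot detection on channel
#' 2, and assembles the per-nucleus measurement. With several nuclei in the
#' field, each is measured separately.
#'
#' @param img `h x w x 2` array (DAPI, Cy3) on the unit scale.
#' @param min_area,k,min_sep passed to the component operations.
#' @return data.frame with one row per nucleus: `area`, `elongation`,
#'   `n_spots`, `length_proxy` (mean spot peak minus nucleus background),
#'   `frac_border`, `frac_middle`, `frac_center`, `included` (>= 3 spots).
#' @export
analyze_nucleus_image <- function(img, min_area = 200, k = 3, min_sep = 3) {
  nuclei <- segment_nuclei(img[, , 1], min_area = min_area)
  rows <- lapply(nuclei, function(nc) {
    zones <- partition_zones(nc$mask)
    spots <- detect_spots(img[, , 2], nc$mask, k = k, min_sep = min_sep)
    ns <- nrow(spots)
    zcounts <- c(border = 0, middle = 0, center = 0)
    lp <- NA_real_
    if (ns > 0) {
      zi <- zones[cbind(spots$x, spots$y)]
      zcounts <- c(border = sum(zi == 1), middle = sum(zi == 2),
                   center = sum(zi == 3))
      lp <- mean(spots$peak) - attr(spots, "bg_mean")
    }
    data.frame(area = nc$area, elongation = nc$elongation, n_spots = ns,
               length_proxy = lp,
               frac_border = if (ns) zcounts[1] / ns else NA_real_,
               frac_middle = if (ns) zcounts[2] / ns else NA_real_,
               frac_center = if (ns) zcounts[3] / ns else NA_real_,
               included = ns >= 3)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize telomere measurements per group
#'
#' Nuclei with fewer than 3 detected spots are excluded from group summaries.
#'
#' @param measurements data.frame from [analyze_nucleus_image()] rows
#'   (possibly several images concatenated).
#' @return list `per_nucleus` (the input), `included_n`, `mean_area`,
#'   `mean_elongation`, `mean_length_proxy`, `zone_distribution`
#'   (pooled spot fractions border/middle/center).
#' @export
telomere_summary <- function(measurements) {
  inc <- measurements[measurements$included, , drop = FALSE]
  if (!nrow(inc)) stop("no nucleus with >= 3 spots in this group")
  tot_sp <- sum(inc$n_spots)
  zones <- c(
    border = sum(inc$frac_border * inc$n_spots) / tot_sp,
    middle = sum(inc$frac_middle * inc$n_spots) / tot_sp,
    center = sum(inc$frac_center * inc$n_spots) / tot_sp)
  list(per_nucleus = measurements,
       included_n = nrow(inc),
       mean_area = mean(inc$area),
       mean_elongation = mean(inc$elongation),
       mean_length_proxy = mean(inc$length_proxy),
       zone_distribution = zones)
}

#' Quantify a list of nucleus images
#'
#' @param images list of `h x w x 2` arrays (from
#'   [generate_nucleus_images()] or read from paired TIFFs).
#' @param ... passed to [analyze_nucleus_image()].
#' @return data.frame, one row per nucleus, with `image` index column.
#' @export
analyze_image_set <- function(images, ...) {
  rows <- lapply(seq_along(images), function(i) {
    df <- analyze_nucleus_image(images[[i]], ...)
    df$image <- i
    df
  })
  do.call(rbind, rows)
}
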