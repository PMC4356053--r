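# Synthetic two-channel nucleus images with planted truth: an elliptical
# DAPI-stained nucleus and Gaussian telomere spots whose amplitude and radial
# position depend on the passage group.

#' Default parameters for synthetic nucleus images
#'
#' Intensities are on the unit scale of a 16-bit image (1.0 = 65535).
#' Late-passage nuclei are larger and more elongated; their spots are dimmer
#' (shorter telomeres) and sit closer to the nuclear center. `radial` ranges
#' are normalized radial positions (0 = center, 1 = rim) from which planted
#' spot positions are drawn uniformly.
#'
#' @return named list of parameters per passage group.
#' @export
image_config <- function() {
  list(
    size = 192,
    nucleus_level = 0.25,
    noise_sd = 100 / 65535,
    spot_sigma = 1.5,
    n_spots = c(3, 20),
    min_spot_sep = 5,
    early = list(minor_axis = c(28, 36), elongation = c(1.0, 1.3),
                 amplitude = 3000 / 65535, radial = c(0.5, 0.95)),
    late = list(minor_axis = c(36, 46), elongation = c(1.4, 2.0),
                amplitude = 1500 / 65535, radial = c(0.05, 0.6)),
    amplitude_cv = 0.2)
}

#' Generate synthetic nucleus images with planted spot truth
#'
#' Each image holds one nucleus: channel 1 (DAPI) is a filled ellipse,
#' channel 2 (Cy3) contains Gaussian telomere spots. Spot radial positions
#' are drawn from the group's `radial` range and mapped onto the ellipse so a
#' normalized radial position r corresponds to normalized boundary depth
#' 1 - r. Deterministic for a fixed seed.
#'
#' @param n_nuclei number of nuclei (>= 1).
#' @param passage `"early"` or `"late"`.
#' @param config parameter list; missing entries default to [image_config()].
#' @param seed integer seed.
#' @param dir when not `NULL`, images are written as paired single-channel
#'   16-bit TIFFs (`<passage>_<i>_dapi.tif`, `_cy3.tif`) via EBImage.
#' @return list with `images` (list of `size x size x 2` arrays, unit scale)
#'   and `truth` (data.frame: nucleus, spot, x, y, amplitude, radial - the
#'   planted normalized radial position).
#' @export
generate_nucleus_images <- function(n_nuclei, passage = c("early", "late"),
                                    config = list(), seed, dir = NULL) {
  passage <- match.arg(passage)
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  cfg <- utils::modifyList(image_config(), config)
  grp <- cfg[[passage]]
  withr::with_seed(seed, {
    images <- vector("list", n_nuclei)
    truth <- list()
    sz <- cfg$size
    for (i in seq_len(n_nuclei)) {
      b <- stats::runif(1, grp$minor_axis[1], grp$minor_axis[2])
      elong <- stats::runif(1, grp$elongation[1], grp$elongation[2])
      a <- b * elong
      theta <- stats::runif(1, 0, pi)
      cx <- sz / 2 + stats::runif(1, -5, 5)
      cy <- sz / 2 + stats::runif(1, -5, 5)
      xs <- matrix(rep(seq_len(sz), sz), sz)       # row coordinate
      ys <- matrix(rep(seq_len(sz), each = sz), sz)
      xr <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
      yr <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
      inside <- (xr / a)^2 + (yr / b)^2 <= 1
      dapi <- matrix(0, sz, sz)
      dapi[inside] <- cfg$nucleus_level
      cy3 <- matrix(0, sz, sz)
      spot_range <- cfg$n_spots[1]:cfg$n_spots[2]
      n_spots <- spot_range[sample.int(length(spot_range), 1)]
      placed <- matrix(numeric(0), ncol = 2)
      for (s in seq_len(n_spots)) {
        for (try in 1:200) {
          r <- stats::runif(1, grp$radial[1], grp$radial[2])
          phi <- stats::runif(1, 0, 2 * pi)
          # scaled-ellipse placement: radial position r => scale factor r
          px <- cx + r * a * cos(phi) * cos(theta) - r * b * sin(phi) * sin(theta)
          py <- cy + r * a * cos(phi) * sin(theta) + r * b * sin(phi) * cos(theta)
          px <- round(px); py <- round(py)
          if (px < 3 || px > sz - 2 || py < 3 || py > sz - 2) next
          if (nrow(placed) &&
              min(sqrt((placed[, 1] - px)^2 + (placed[, 2] - py)^2)) <
                cfg$min_spot_sep) next
          amp <- grp$amplitude *
            max(0.2, 1 + stats::rnorm(1, 0, cfg$amplitude_cv))
          cy3 <- cy3 + amp *
            exp(-((xs - px)^2 + (ys - py)^2) / (2 * cfg$spot_sigma^2))
          placed <- rbind(placed, c(px, py))
          truth[[length(truth) + 1]] <- data.frame(
            nucleus = i, spot = s, x = px, y = py,
            amplitude = amp, radial = r, passage = passage)
          break
        }
      }
      img <- array(0, dim = c(sz, sz, 2))
      img[, , 1] <- clamp01(dapi + stats::rnorm(sz * sz, 0, cfg$noise_sd))
      img[, , 2] <- clamp01(cy3 + stats::rnorm(sz * sz, 0, cfg$noise_sd))
      images[[i]] <- img
    }
    truth <- do.call(rbind, truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(n_nuclei)) {
        EBImage::writeImage(images[[i]][, , 1],
                            file.path(dir, sprintf("%s_%03d_dapi.tif", passage, i)),
                            type = "tiff", bits.per.sample = 16)
        EBImage::writeImage(images[[i]][, , 2],
                            file.path(dir, sprintf("%s_%03d_cy3.tif", passage, i)),
                            type = "tiff", bits.per.sample = 16)
      }
      utils::write.table(truth, file.path(dir, paste0(passage, "_truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(images = images, truth = truth)
  })
}

clamp01 <- function(x) pmin(1, pmax(0, x))
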