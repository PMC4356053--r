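# Windowed signal summaries: metaprofiles around anchors, differential
# capture signal at array CpGs, neighborhood beta profiles, LAD
# inside/outside comparison and LAD border profiles.

#' Average signal metaprofile around anchor midpoints
#'
#' For every anchor (interval midpoint) the track is read at signed offsets
#' `-half_window, ..., +half_window` in steps of `step`; the profile is the
#' mean across anchors at each offset. Anchors whose window exceeds the
#' chromosome bounds are excluded (and counted in `n_excluded`).
#'
#' @param track a [coverage_track()].
#' @param anchors GRanges of anchor intervals.
#' @param half_window window half-width in bp (multiple of `step`).
#' @param step offset step in bp.
#' @return data.frame with `offset`, `mean`, `n` plus attribute `n_excluded`.
#' @export
metaprofile <- function(track, anchors, half_window, step) {
  if (length(anchors) == 0) stop("anchor set is empty")
  if (half_window %% step != 0) stop("half_window must be a multiple of step")
  offsets <- seq(-half_window, half_window, by = step)
  chrom <- as.character(GenomicRanges::seqnames(anchors))
  mid <- midpoints(anchors)
  clen <- unclass(track$genome)[chrom]
  ok <- (mid - half_window) >= 0 & (mid + half_window) < clen
  if (!any(ok)) stop("all anchors excluded: windows exceed chromosome bounds")
  chrom <- chrom[ok]; mid <- mid[ok]
  vals <- vapply(offsets, function(o) {
    v <- track_value_at(track, chrom, mid + o)
    c(mean(v), sum(!is.na(v)))
  }, numeric(2))
  out <- data.frame(offset = offsets, mean = vals[1, ], n = as.integer(vals[2, ]))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Differential capture signal in windows around probe sites
#'
#' Late-minus-early mean track signal in a window centered on each probe
#' position, the comparison used to check array-defined methylation changes
#' against capture coverage.
#'
#' @param early,late [coverage_track()]s on the same genome and binning.
#' @param sites probe data.frame (see [read_probe_table()]).
#' @param window window size in bp (default 600), centered on the probe.
#' @return data.frame `id, chrom, pos, diff` (late - early window mean).
#' @export
differential_signal_at_sites <- function(early, late, sites, window = 600) {
  if (!identical(early$bin, late$bin) ||
      !identical(unclass(early$genome), unclass(late$genome)))
    stop("tracks must share genome and bin size")
  half <- floor(window / 2)
  clen <- unclass(early$genome)[sites$chrom]
  if (any(is.na(clen)) || any(sites$pos < 0) || any(sites$pos >= clen)) {
    bad <- which(is.na(clen) | sites$pos < 0 | sites$pos >= clen)
    stop("probe(s) off genome: ", paste(sites$id[bad], collapse = ", "))
  }
  diff <- vapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]; p <- sites$pos[i]
    lo <- max(0, p - half); hi <- min(clen[i] - 1, p + half - 1)
    idx <- (floor(lo / early$bin):floor(hi / early$bin)) + 1
    mean(late$values[[ch]][idx]) - mean(early$values[[ch]][idx])
  }, numeric(1))
  data.frame(id = sites$id, chrom = sites$chrom, pos = sites$pos, diff = diff)
}

#' Mean beta profile in the neighborhood of anchor CpGs
#'
#' For each anchor probe, neighboring probes within `window` bp are binned by
#' signed distance (anchor at 0); per-bin mean beta (early and late
#' separately) is averaged over all anchor-neighbor pairs. Bins without any
#' pair are reported as `NA`, never zero.
#'
#' @param probes probe map data.frame (all probes).
#' @param anchor_probes data.frame of anchor probes (subset or same map).
#' @param window neighborhood half-width in bp (default 500).
#' @param bin distance bin width in bp (default 50).
#' @return data.frame `offset` (bin left edge), `beta_early`, `beta_late`, `n`.
#' @export
neighborhood_beta_profile <- function(probes, anchor_probes,
                                      window = 500, bin = 50) {
  breaks <- seq(-window, window, by = bin)
  nb <- length(breaks) - 1
  sum_e <- numeric(nb); sum_l <- numeric(nb); n <- integer(nb)
  for (ch in unique(anchor_probes$chrom)) {
    ap <- anchor_probes$pos[anchor_probes$chrom == ch]
    pr <- probes[probes$chrom == ch, , drop = FALSE]
    if (!nrow(pr) || !length(ap)) next
    ord <- order(pr$pos)
    pos <- pr$pos[ord]; be <- pr$beta_early[ord]; bl <- pr$beta_late[ord]
    for (a in ap) {
      lo <- findInterval(a - window, pos) + 1
      hi <- findInterval(a + window - 1e-9, pos)
      if (hi < lo) next
      d <- pos[lo:hi] - a
      k <- findInterval(d, breaks, rightmost.closed = FALSE)
      keep <- k >= 1 & k <= nb
      k <- k[keep]
      sum_e <- sum_e + as.numeric(tabulate_sum(k, be[lo:hi][keep], nb))
      sum_l <- sum_l + as.numeric(tabulate_sum(k, bl[lo:hi][keep], nb))
      n <- n + tabulate(k, nb)
    }
  }
  if (!sum(n)) stop("no neighboring probes found for any anchor")
  data.frame(offset = breaks[-length(breaks)],
             beta_early = ifelse(n > 0, sum_e / n, NA_real_),
             beta_late = ifelse(n > 0, sum_l / n, NA_real_),
             n = n)
}

tabulate_sum <- function(bin_idx, values, nbins) {
  out <- numeric(nbins)
  agg <- tapply(values, factor(bin_idx, levels = seq_len(nbins)), sum)
  out[!is.na(agg)] <- agg[!is.na(agg)]
  out
}

#' Compare track signal inside versus outside a domain set
#'
#' The sampling unit is the track bin (membership by bin midpoint, half-open
#' convention); the comparison is a Mann-Whitney/Wilcoxon rank-sum test of
#' equal distributions with tie correction (exact enumeration when both
#' groups have <= 50 untied bins, normal approximation otherwise).
#'
#' @param track a [coverage_track()].
#' @param domains GRanges (e.g. LADs).
#' @return list `mean_inside`, `mean_outside`, `U`, `p_value`, `n_inside`,
#'   `n_outside`.
#' @export
inside_outside_test <- function(track, domains) {
  if (length(domains) == 0) stop("domain set is empty")
  dom <- GenomicRanges::reduce(domains, ignore.strand = TRUE)
  genome <- track$genome
  inside <- numeric(0); outside <- numeric(0)
  for (ch in names(genome)) {
    v <- track$values[[ch]]
    mids <- (seq_along(v) - 1) * track$bin + floor(track$bin / 2)
    mids <- pmin(mids, unclass(genome)[[ch]] - 1)
    mp <- GenomicRanges::GRanges(ch, IRanges::IRanges(mids + 1, width = 1))
    inb <- IRanges::overlapsAny(mp, dom, ignore.strand = TRUE)
    inside <- c(inside, v[inb]); outside <- c(outside, v[!inb])
  }
  if (!length(inside) || !length(outside))
    stop("one of the groups (inside/outside) is empty")
  n1 <- length(inside); n2 <- length(outside)
  if (stats::sd(c(inside, outside)) == 0) {
    return(list(mean_inside = mean(inside), mean_outside = mean(outside),
                U = n1 * n2 / 2, p_value = 1,
                n_inside = n1, n_outside = n2))
  }
  exact <- n1 <= 50 && n2 <= 50 && !any(duplicated(c(inside, outside)))
  wt <- suppressWarnings(stats::wilcox.test(inside, outside, exact = exact,
                                            correct = !exact))
  list(mean_inside = mean(inside), mean_outside = mean(outside),
       U = unname(wt$statistic), p_value = wt$p.value,
       n_inside = n1, n_outside = n2)
}

#' Average signal profile across domain borders
#'
#' Both borders of every domain contribute; right borders are mirrored so
#' positive offsets always point into the domain and negative offsets
#' outside. Offsets reaching past the domain midpoint, or outside the
#' chromosome, are excluded from that border's contribution.
#'
#' @param track a [coverage_track()].
#' @param lads GRanges of domains (e.g. LADs).
#' @param flank maximal distance from the border in bp (default 1e5).
#' @param step offset step in bp (default 1000).
#' @return data.frame `offset` (negative outside, positive inside), `mean`, `n`.
#' @export
lad_border_profile <- function(track, lads, flank = 1e5, step = 1000) {
  if (length(lads) == 0) stop("no domains supplied")
  offsets <- seq(-flank, flank, by = step)
  sums <- numeric(length(offsets)); n <- integer(length(offsets))
  chrom <- as.character(GenomicRanges::seqnames(lads))
  s0 <- GenomicRanges::start(lads) - 1
  e0 <- GenomicRanges::end(lads)
  clen <- unclass(track$genome)[chrom]
  half_len <- (e0 - s0) / 2
  any_border <- FALSE
  for (i in seq_along(lads)) {
    for (side in c("left", "right")) {
      # position at signed offset o (o > 0 inside the domain)
      pos <- if (side == "left") s0[i] + offsets else e0[i] - 1 - offsets
      ok <- offsets < half_len[i] & pos >= 0 & pos < clen[i]
      if (!any(ok)) next
      any_border <- TRUE
      v <- track_value_at(track, rep(chrom[i], sum(ok)), pos[ok])
      sums[ok] <- sums[ok] + v
      n[ok] <- n[ok] + 1L
    }
  }
  if (!any_border) stop("no usable domain borders")
  data.frame(offset = offsets,
             mean = ifelse(n > 0, sums / n, NA_real_), n = n)
}

#' Select significant CpG probes by adjusted p and effect size
#'
#' Hypermethylated: `adj_p < alpha` and `delta > min_delta`; hypomethylated:
#' `adj_p < alpha` and `delta < -min_delta` (delta = beta_late - beta_early).
#'
#' @param probes probe data.frame (see [read_probe_table()]).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_delta minimal absolute beta change (default 0.20).
#' @return list with `hyper` and `hypo` data.frames (disjoint).
#' @export
select_significant_cpgs <- function(probes, alpha = 0.05, min_delta = 0.20) {
  needed <- c("adj_p", "beta_early", "beta_late")
  if (!all(needed %in% names(probes)))
    stop("probe table lacks column(s): ",
         paste(setdiff(needed, names(probes)), collapse = ", "))
  delta <- probes$beta_late - probes$beta_early
  list(hyper = probes[probes$adj_p < alpha & delta > min_delta, , drop = FALSE],
       hypo = probes[probes$adj_p < alpha & delta < -min_delta, , drop = FALSE])
}
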