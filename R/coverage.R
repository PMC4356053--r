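# Fixed-bin coverage tracks and RPKM normalization.

#' Fixed-bin coverage track
#'
#' Per-chromosome signal in fixed-size bins. Bin `i` (1-based) covers
#' positions `[(i-1)*bin, i*bin)`; the last bin of a chromosome may be
#' truncated.
#'
#' @param genome a [genome_spec()].
#' @param bin bin size in bp.
#' @param values named list (one numeric vector per chromosome) of per-bin
#'   values; lengths must equal `ceiling(chrom_length / bin)`.
#' @param units `"counts"`, `"RPKM"` or `"unknown"`.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(genome, bin, values, units = "counts") {
  stopifnot(bin > 0)
  if (!identical(sort(names(values)), sort(names(genome))))
    stop("values must be a named list covering every chromosome")
  for (ch in names(genome)) {
    n_expected <- ceiling(unclass(genome)[[ch]] / bin)
    if (length(values[[ch]]) != n_expected)
      stop("wrong number of bins for ", ch, ": expected ", n_expected)
  }
  structure(list(genome = genome, bin = bin,
                 values = values[names(genome)], units = units),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track: bin", x$bin, "bp,", x$units, "over",
      length(x$genome), "chromosomes\n")
  invisible(x)
}

# per-bin fragment-overlap counts; a fragment increments every bin it overlaps
bin_fragment_counts <- function(fragments, bin) {
  genome <- genome_of(fragments)
  values <- lapply(names(genome), function(ch) {
    L <- unclass(genome)[[ch]]
    n <- ceiling(L / bin)
    starts0 <- seq(0, (n - 1) * bin, by = bin)
    bins <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts0 + 1,
                                                        pmin(starts0 + bin, L)))
    fr <- fragments[GenomicRanges::seqnames(fragments) == ch]
    GenomicRanges::countOverlaps(bins, fr, ignore.strand = TRUE)
  })
  names(values) <- names(genome)
  coverage_track(genome, bin, values, units = "counts")
}

#' RPKM-normalize a fragment set into a coverage track
#'
#' `value(bin) = count(bin) / ((bin/1000) * (total/1e6))` where `count(bin)`
#' is the number of fragments overlapping the bin (every overlapped bin is
#' incremented) and `total` the fragment count of the sample.
#'
#' @param fragments GRanges of aligned fragments (with seqlengths).
#' @param bin bin size in bp.
#' @return a [coverage_track()] in RPKM units.
#' @export
rpkm_normalize <- function(fragments, bin) {
  if (length(fragments) == 0) stop("fragment set is empty")
  track <- bin_fragment_counts(fragments, bin)
  denom <- (bin / 1000) * (length(fragments) / 1e6)
  track$values <- lapply(track$values, function(v) v / denom)
  track$units <- "RPKM"
  track
}

# track value at arbitrary 0-based positions (vectorized, one chrom at a time)
track_value_at <- function(track, chrom, pos0) {
  out <- rep(NA_real_, length(pos0))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    v <- track$values[[ch]]
    if (is.null(v)) stop("unknown chromosome: ", ch)
    idx <- floor(pos0[sel] / track$bin) + 1
    ok <- idx >= 1 & idx <= length(v) & pos0[sel] >= 0
    out[sel][ok] <- v[idx[ok]]
  }
  out
}
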