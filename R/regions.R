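# Region standardization, promoter derivation and the size-matched
# random-region null used throughout the package.

#' Standardize regions to a fixed length
#'
#' Re-centers every interval on its midpoint (`floor((start+end)/2)`) and
#' resizes it to `target_len` bp, the convention used before motif scanning.
#' Regions clipped by a chromosome end are shifted inward so the length is
#' preserved.
#'
#' @param gr GRanges with seqlengths.
#' @param target_len target length in bp (default 40).
#' @return GRanges of constant width `target_len`.
#' @export
standardize_region_length <- function(gr, target_len = 40) {
  stopifnot(target_len > 0)
  genome <- genome_of(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  clen <- unclass(genome)[chrom]
  if (any(clen < target_len))
    stop("chromosome(s) shorter than target length: ",
         paste(unique(chrom[clen < target_len]), collapse = ", "))
  mid <- midpoints(gr)
  half <- floor(target_len / 2)
  s0 <- mid - half
  s0 <- pmax(s0, 0)
  s0 <- pmin(s0, clen - target_len)
  out <- gr
  IRanges::ranges(out) <- IRanges::IRanges(start = s0 + 1, width = target_len)
  out
}

#' Sample size-matched random regions
#'
#' The resampling null: for each requested length, draws one interval with the
#' chromosome chosen proportionally to the number of valid placements
#' (`chrom_length - region_length + 1`) and the start uniform over valid
#' positions. Regions may overlap each other; only size is matched.
#'
#' @param lengths integer vector of region lengths (bp).
#' @param genome a [genome_spec()].
#' @param n_sets number of independent region sets to draw.
#' @param seed integer seed; output is reproducible for a fixed seed.
#' @return list of `n_sets` GRanges, each with `length(lengths)` regions in
#'   the requested order.
#' @export
sample_random_regions <- function(lengths, genome, n_sets = 1, seed) {
  lengths <- as.numeric(lengths)
  if (n_sets < 1) stop("n_sets must be >= 1")
  clen <- unclass(genome)
  if (any(lengths > max(clen)))
    stop("requested region length exceeds the longest chromosome")
  if (any(lengths <= 0)) stop("region lengths must be positive")
  nl <- length(lengths)
  withr::with_seed(seed, {
    # vectorized over all draws, grouped by unique length
    chrom_idx <- integer(nl * n_sets)
    start0 <- numeric(nl * n_sets)
    for (len in unique(lengths)) {
      sel <- which(rep(lengths, n_sets) == len)
      w <- pmax(clen - len + 1, 0)
      ci <- sample.int(length(clen), length(sel), replace = TRUE, prob = w)
      chrom_idx[sel] <- ci
      start0[sel] <- pmin(floor(stats::runif(length(sel)) * w[ci]), w[ci] - 1)
    }
    lapply(seq_len(n_sets), function(i) {
      j <- (i - 1) * nl + seq_len(nl)
      region_set(names(clen)[chrom_idx[j]], start0[j], start0[j] + rep(lengths, 1),
                 genome)
    })
  })
}

#' Derive promoter regions upstream of TSSs
#'
#' Promoters are the `width` bp upstream of the transcription start site:
#' `[tss - width, tss)` on the + strand, `[tss, tss + width)` on the - strand,
#' clipped at chromosome bounds (length may shrink at an edge).
#'
#' @param genes data.frame with columns `chrom`, `tss` (0-based), `strand`
#'   (`+`/`-`) and optionally `id`.
#' @param genome a [genome_spec()].
#' @param width promoter width in bp (default 1000).
#' @return GRanges, one promoter per gene, `name` = gene id when present.
#' @export
promoter_regions <- function(genes, genome, width = 1000) {
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand value(s): ",
         paste(setdiff(unique(genes$strand), c("+", "-")), collapse = ", "))
  clen <- unclass(genome)[genes$chrom]
  plus <- genes$strand == "+"
  s0 <- ifelse(plus, genes$tss - width, genes$tss)
  e0 <- ifelse(plus, genes$tss, genes$tss + width)
  s0 <- pmax(s0, 0)
  e0 <- pmin(e0, clen)
  if (any(e0 <= s0)) stop("TSS outside chromosome bounds")
  region_set(genes$chrom, s0, e0, genome, strand = genes$strand,
             name = if (!is.null(genes$id)) genes$id else NULL)
}

#' Overlap of one region set with another
#'
#' Computes, per interval of `a`, the overlap in bp with the union of `b`, and
#' the fraction of `a` midpoints falling inside `b`. Midpoint membership uses
#' the half-open convention: a midpoint equal to an interval end is outside.
#'
#' @param a,b GRanges on the same genome.
#' @return list with `overlap_bp` (per `a` interval) and `midpoint_fraction`.
#' @export
interval_overlap_fraction <- function(a, b) {
  check_same_genome(a, b)
  bu <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(
    IRanges::findOverlapPairs(a, bu, ignore.strand = TRUE))
  hits <- GenomicRanges::findOverlaps(a, bu, ignore.strand = TRUE)
  overlap_bp <- numeric(length(a))
  if (length(hits)) {
    w <- GenomicRanges::width(ov)
    overlap_bp <- as.numeric(tapply(w, factor(S4Vectors::queryHits(hits),
                                              levels = seq_along(a)), sum))
    overlap_bp[is.na(overlap_bp)] <- 0
  }
  list(overlap_bp = overlap_bp,
       midpoint_fraction = mean(midpoints_inside(a, bu)))
}

# logical: is each midpoint of `a` inside the union of `b`? (half-open)
midpoints_inside <- function(a, b) {
  mid <- midpoints(a)
  mp <- GenomicRanges::GRanges(GenomicRanges::seqnames(a),
                               IRanges::IRanges(mid + 1, width = 1))
  IRanges::overlapsAny(mp, b, ignore.strand = TRUE)
}
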