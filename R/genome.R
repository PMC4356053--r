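#' Genome specification
#'
#' A genome specification is a named vector of chromosome lengths (bp). All
#' coordinates in the package are 0-based half-open (BED dialect); intervals
#' are carried as [GenomicRanges::GRanges] whose `seqlengths` come from the
#' genome spec.
#'
#' @param chroms character vector of chromosome names (unique).
#' @param lengths integer vector of chromosome lengths in bp (all > 0).
#' @return A named numeric vector of class `genome_spec`.
#' @examples
#' gs <- genome_spec(c("chr1", "chr2"), c(1e6, 5e5))
#' genome_size(gs)
#' @export
genome_spec <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have equal length")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive")
  structure(stats::setNames(lengths, chroms), class = "genome_spec")
}

#' @rdname genome_spec
#' @param genome a `genome_spec`.
#' @export
genome_size <- function(genome) {
  sum(unclass(genome))
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x), "chromosomes,",
      format(genome_size(x), big.mark = ","), "bp\n")
  print(unclass(x))
  invisible(x)
}

as_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = as.integer(unclass(genome)))
}

#' Read or write a chrom-sizes file
#'
#' Two-column tab-separated text: chromosome name, length.
#'
#' @param path file path.
#' @return `read_chrom_sizes` returns a `genome_spec`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_spec(df$chrom, df$length)
}

#' @rdname read_chrom_sizes
#' @param genome a `genome_spec`.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(chrom = names(genome), length = format(unclass(genome), scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a region set (GRanges) on a genome
#'
#' Builds a [GenomicRanges::GRanges] from 0-based half-open coordinates and
#' attaches the genome's `seqinfo`. Out-of-bounds intervals are an error.
#'
#' @param chrom,start,end vectors of chromosome, 0-based start, exclusive end.
#' @param genome a [genome_spec()].
#' @param strand strand vector (`+`, `-`, `*`); default `*` (BED "." maps to `*`).
#' @param score,name optional numeric scores / labels.
#' @return GRanges with seqlengths set.
#' @export
region_set <- function(chrom, start, end, genome, strand = "*",
                       score = NULL, name = NULL) {
  if (any(start < 0) || any(end <= start))
    stop("invalid interval: require 0 <= start < end")
  unknown <- setdiff(unique(as.character(chrom)), names(genome))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  strand <- gsub("\\.", "*", as.character(strand))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(chrom), levels = names(genome)),
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand,
    seqinfo = as_seqinfo(genome))
  bad <- end > unclass(genome)[as.character(chrom)]
  if (any(bad))
    stop("interval exceeds chromosome length on ",
         paste(unique(as.character(chrom)[bad]), collapse = ", "))
  if (!is.null(score)) gr$score <- as.numeric(score)
  if (!is.null(name)) gr$name <- as.character(name)
  gr
}

genome_of <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl))) stop("GRanges has no seqlengths; build with region_set()")
  genome_spec(names(sl), sl)
}

check_same_genome <- function(a, b) {
  ga <- GenomeInfoDb::seqlengths(a); gb <- GenomeInfoDb::seqlengths(b)
  if (!identical(ga[order(names(ga))], gb[order(names(gb))]))
    stop("region sets are on different genomes")
  invisible(TRUE)
}

#' Interval midpoints
#'
#' Midpoint of a 0-based half-open interval `[start, end)` is
#' `floor((start + end) / 2)`; returned as 0-based positions.
#'
#' @param gr a GRanges.
#' @return numeric vector of 0-based midpoint positions.
#' @export
midpoints <- function(gr) {
  s0 <- GenomicRanges::start(gr) - 1
  e0 <- GenomicRanges::end(gr)
  floor((s0 + e0) / 2)
}
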