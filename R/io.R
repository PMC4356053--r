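# Plain-text readers/writers for the formats the pipeline consumes:
# BED3/BED6, bedGraph, probe TSV, gene TSV, GMT gene sets.

#' Read a BED file as a region set
#'
#' BED3/BED6, tab-separated, no header. Coordinates stay 0-based half-open
#' internally (GRanges stores them 1-based; conversion is handled here).
#'
#' @param path BED file path.
#' @param genome a [genome_spec()].
#' @return GRanges; `name`/`score` columns kept when present.
#' @export
read_bed <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "", quote = "",
                          colClasses = c("character", "numeric", "numeric",
                                         rep(NA, 3))[seq_len(
                                           max(utils::count.fields(path, sep = "\t")))])
  n <- ncol(df)
  region_set(df[[1]], df[[2]], df[[3]], genome,
             strand = if (n >= 6) df[[6]] else "*",
             score  = if (n >= 5) as.numeric(df[[5]]) else NULL,
             name   = if (n >= 4) as.character(df[[4]]) else NULL)
}

#' @rdname read_bed
#' @param gr GRanges to write.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = fmt_num(GenomicRanges::start(gr) - 1),
                   end = fmt_num(GenomicRanges::end(gr)))
  has_name <- !is.null(gr$name); has_score <- !is.null(gr$score)
  st <- as.character(GenomicRanges::strand(gr))
  has_strand <- any(st != "*")
  if (has_name || has_score || has_strand) {
    df$name <- if (has_name) gr$name else "."
    df$score <- if (has_score) gr$score else 0
    df$strand <- gsub("\\*", ".", st)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read or write a bedGraph file
#'
#' Four columns: chrom, start (0-based), end, value. `read_bedgraph` returns a
#' [coverage_track()] when the intervals form a regular binning, otherwise a
#' data.frame.
#'
#' @param path file path.
#' @param genome a [genome_spec()].
#' @export
read_bedgraph <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  widths <- df$end - df$start
  bin <- widths[1]
  regular <- all(df$start %% bin == 0) &&
    all(widths == bin | df$end == unclass(genome)[df$chrom])
  if (!regular) return(df)
  values <- lapply(names(genome), function(ch) {
    n <- ceiling(unclass(genome)[[ch]] / bin)
    v <- numeric(n)
    sub <- df[df$chrom == ch, , drop = FALSE]
    v[sub$start / bin + 1] <- sub$value
    v
  })
  names(values) <- names(genome)
  coverage_track(genome, bin, values, units = "unknown")
}

#' @rdname read_bedgraph
#' @param track a [coverage_track()].
#' @export
write_bedgraph <- function(track, path) {
  genome <- track$genome
  rows <- lapply(names(genome), function(ch) {
    v <- track$values[[ch]]
    start <- (seq_along(v) - 1) * track$bin
    end <- pmin(start + track$bin, unclass(genome)[[ch]])
    data.frame(chrom = ch, start = fmt_num(start), end = fmt_num(end),
               value = v)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write a 450k-style probe table
#'
#' Tab-separated with header: `id, chrom, pos, beta_early, beta_late, adj_p`.
#' Positions are 1-based in the file (array convention) and converted to
#' 0-based on read. The `delta` column (beta_late - beta_early) is recomputed.
#'
#' @param path TSV path.
#' @return data.frame with columns id, chrom, pos (0-based), beta_early,
#'   beta_late, delta, adj_p.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "numeric", "numeric"))
  needed <- c("id", "chrom", "pos", "beta_early", "beta_late", "adj_p")
  if (!all(needed %in% names(df)))
    stop("probe table must have columns: ", paste(needed, collapse = ", "))
  df$pos <- df$pos - 1
  df$delta <- df$beta_late - df$beta_early
  df[c("id", "chrom", "pos", "beta_early", "beta_late", "delta", "adj_p")]
}

#' @rdname read_probe_table
#' @param probes probe data.frame (0-based `pos`; written 1-based).
#' @export
write_probe_table <- function(probes, path) {
  out <- probes[c("id", "chrom", "pos", "beta_early", "beta_late", "adj_p")]
  out$pos <- fmt_num(out$pos + 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a gene table with DE statistics
#'
#' Tab-separated with header: `id, chrom, tss, strand, expr, log2fc, fdr`;
#' `tss` is 0-based.
#'
#' @param path TSV path.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric",
                                         "character", "numeric", "numeric",
                                         "numeric"))
  needed <- c("id", "chrom", "tss", "strand", "expr", "log2fc", "fdr")
  if (!all(needed %in% names(df)))
    stop("gene table must have columns: ", paste(needed, collapse = ", "))
  df
}

#' @rdname read_gene_table
#' @param genes gene data.frame.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes[c("id", "chrom", "tss", "strand", "expr", "log2fc", "fdr")]
  out$tss <- fmt_num(out$tss)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GMT-style gene sets
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}
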