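# PWM motif models: JASPAR-format parsing, log-odds construction, exact
# dynamic-programming calibration of the score threshold at a target
# false-discovery rate, both-strand scanning, and enrichment of motifs in a
# region set against size-matched random region sets.

DNA_BASES <- c("A", "C", "G", "T")

#' Read motifs from JASPAR-style PFM text
#'
#' Accepts the JASPAR 2014 dialect (`>id name` followed by four rows, either
#' `A [ 1 2 3 ]` or bare numbers in A, C, G, T order).
#'
#' @param path PFM text file.
#' @param pseudocount,background passed to [build_motif()].
#' @param fdr when not `NULL`, thresholds are calibrated at this FDR via
#'   [calibrate_threshold()].
#' @return named list of `motif_model` objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.1,
                        background = rep(0.25, 4), fdr = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no motif headers ('>') found in ", path)
  motifs <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    rows <- lines[from:to]
    if (length(rows) != 4) stop("motif block must have 4 rows: ", lines[heads[i]])
    parsed <- lapply(rows, function(r) {
      r <- sub("^[ACGTacgt]\\s*\\[?", "", r)
      r <- sub("\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(lengths(parsed))) != 1)
      stop("ragged motif matrix: ", lines[heads[i]])
    counts <- do.call(rbind, parsed)
    rownames(counts) <- DNA_BASES
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]]
    name <- if (length(id) > 1) paste(id[-1], collapse = " ") else id[1]
    m <- build_motif(counts, pseudocount = pseudocount,
                     background = background, id = id[1], name = name)
    if (!is.null(fdr)) m <- calibrate_threshold(m, fdr = fdr)
    motifs[[id[1]]] <- m
  }
  motifs
}

#' @rdname read_jaspar
#' @param motifs named list of `motif_model`s.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$id, " ", m$name), con)
    for (b in DNA_BASES)
      writeLines(paste0(b, " [ ", paste(fmt_num(m$counts[b, ]), collapse = " "),
                        " ]"), con)
  }
  invisible(path)
}

#' Build a log-odds motif model from a count matrix
#'
#' `log_odds(b, j) = log2( (counts(b,j) + pseudocount * background(b)) /
#' (column_total + pseudocount) / background(b) )`.
#'
#' @param counts 4 x w non-negative matrix, rows A, C, G, T.
#' @param pseudocount added mass per column (default 0.1).
#' @param background base composition, sums to 1 (default uniform).
#' @param id,name identifiers.
#' @param score_step lattice on which log-odds scores live (default 0.01);
#'   matrix entries are rounded to this grid so that scanning scores and the
#'   calibrated threshold share one exact discretization.
#' @return `motif_model`: list with `counts`, `prob`, `log_odds`, `width`,
#'   `background`, `threshold` (NA until calibrated), `consensus`.
#' @export
build_motif <- function(counts, pseudocount = 0.1,
                        background = rep(0.25, 4), id = "motif", name = id,
                        score_step = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  tot <- colSums(counts)
  if (any(tot + pseudocount <= 0)) stop("zero column total with zero pseudocount")
  rownames(counts) <- DNA_BASES
  prob <- sweep(counts + pseudocount * background,
                2, tot + pseudocount, "/")
  lo <- round(log2(prob / background) / score_step) * score_step
  structure(list(id = id, name = name, counts = counts, prob = prob,
                 log_odds = lo, width = ncol(counts),
                 background = stats::setNames(background, DNA_BASES),
                 pseudocount = pseudocount, score_step = score_step,
                 threshold = NA_real_,
                 consensus = paste(DNA_BASES[apply(counts, 2, which.max)],
                                   collapse = "")),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model", x$id, "(", x$name, "): width", x$width,
      "consensus", x$consensus, "threshold",
      if (is.na(x$threshold)) "uncalibrated" else format(x$threshold), "\n")
  invisible(x)
}

# exact discretized score distribution of a random background word:
# convolution of per-column score mass functions on a fixed integer grid
motif_score_distribution <- function(motif, step = NULL) {
  if (is.null(step)) step <- if (is.null(motif$score_step)) 0.01 else motif$score_step
  si <- round(motif$log_odds / step)
  lo_min <- sum(apply(si, 2, min)); lo_max <- sum(apply(si, 2, max))
  n <- lo_max - lo_min + 1
  pmf <- c(1, numeric(n - 1))  # distribution of (sum - running minimum)
  run_min <- 0
  for (j in seq_len(motif$width)) {
    col <- si[, j]; cmin <- min(col)
    new <- numeric(n)
    for (b in 1:4) {
      off <- col[b] - cmin
      idx <- seq_len(n - off)
      new[idx + off] <- new[idx + off] + motif$background[b] * pmf[idx]
    }
    pmf <- new
    run_min <- run_min + cmin
  }
  list(scores = (seq_len(n) - 1 + run_min) * step, pmf = pmf, step = step)
}

#' Calibrate a motif score threshold at a target FDR
#'
#' Computes the exact score distribution of a random background word by
#' dynamic programming over a discretized score grid (step 0.01 score units)
#' and returns the smallest threshold `t` with `P(score >= t) <= fdr`.
#'
#' @param motif a `motif_model`.
#' @param fdr target false-discovery rate per scanned position (default 1e-4).
#' @param step discretization step in score units.
#' @return the motif with `threshold` set (and attribute `fdr_attained`);
#'   when even the maximal score is too likely the threshold is the maximal
#'   score and `threshold_warning = TRUE`.
#' @export
calibrate_threshold <- function(motif, fdr = 1e-4, step = NULL) {
  if (fdr <= 0 || fdr > 1) stop("fdr must lie in (0, 1]")
  dist <- motif_score_distribution(motif, step)
  tail_p <- rev(cumsum(rev(dist$pmf)))
  ok <- which(tail_p <= fdr)
  if (!length(ok)) {
    motif$threshold <- max(dist$scores)
    motif$threshold_warning <- TRUE
    attr(motif$threshold, "fdr_attained") <- tail_p[length(tail_p)]
    return(motif)
  }
  i <- ok[1]
  motif$threshold <- dist$scores[i]
  motif$threshold_warning <- FALSE
  attr(motif$threshold, "fdr_attained") <- tail_p[i]
  motif
}

encode_dna <- function(seqs) {
  # list of integer vectors, A=1 C=2 G=3 T=4, anything else NA
  lapply(strsplit(toupper(seqs), ""), function(ch) {
    match(ch, DNA_BASES)
  })
}

revcomp_motif_matrix <- function(lo) {
  lo[4:1, ncol(lo):1, drop = FALSE]
}

scan_scores <- function(code, lo) {
  # scores of all windows of one integer-coded sequence against matrix lo;
  # windows containing non-ACGT are NA
  w <- ncol(lo); n <- length(code)
  if (n < w) return(numeric(0))
  nw <- n - w + 1
  sc <- numeric(nw)
  for (j in seq_len(w)) {
    v <- lo[, j][code[j:(j + nw - 1)]]
    sc <- sc + v
  }
  sc
}

#' Scan sequences for motif matches on both strands
#'
#' Every offset of every sequence is scored on both strands against the
#' motif's log-odds matrix; positions scoring at or above the calibrated
#' threshold are matches. Windows containing non-ACGT characters are skipped.
#' Sequences shorter than the motif yield no matches.
#'
#' @param sequences character vector (or `Biostrings::DNAStringSet`) of
#'   DNA sequences over A, C, G, T, N.
#' @param motif a calibrated `motif_model`.
#' @return data.frame `seq_index`, `offset` (0-based), `strand`, `score`.
#' @export
scan_sequences <- function(sequences, motif) {
  if (is.na(motif$threshold))
    stop("motif threshold is not calibrated; run calibrate_threshold()")
  seqs <- as.character(sequences)
  codes <- encode_dna(seqs)
  lo_f <- motif$log_odds
  lo_r <- revcomp_motif_matrix(lo_f)
  out <- vector("list", length(codes))
  for (i in seq_along(codes)) {
    sf <- scan_scores(codes[[i]], lo_f)
    sr <- scan_scores(codes[[i]], lo_r)
    hf <- which(!is.na(sf) & sf >= motif$threshold - 1e-9)
    hr <- which(!is.na(sr) & sr >= motif$threshold - 1e-9)
    if (length(hf) || length(hr)) {
      out[[i]] <- data.frame(
        seq_index = i,
        offset = c(hf, hr) - 1,
        strand = rep(c("+", "-"), c(length(hf), length(hr))),
        score = c(sf[hf], sr[hr]))
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(seq_index = integer(0), offset = integer(0),
                      strand = character(0), score = numeric(0)))
  do.call(rbind, out)
}

# number of sequences with >= 1 match (fast path used by the enrichment test)
count_matching_sequences <- function(codes, motif) {
  lo_f <- motif$log_odds
  lo_r <- revcomp_motif_matrix(lo_f)
  hits <- vapply(codes, function(cd) {
    sf <- scan_scores(cd, lo_f)
    if (length(sf) && any(!is.na(sf) & sf >= motif$threshold - 1e-9)) return(TRUE)
    sr <- scan_scores(cd, lo_r)
    length(sr) > 0 && any(!is.na(sr) & sr >= motif$threshold - 1e-9)
  }, logical(1))
  sum(hits)
}

#' Motif enrichment in a region set against a random-region null
#'
#' For every motif, counts target regions with at least one match and
#' compares, by a one-sided-greater Fisher exact test, against the pooled
#' counts over `n_random` size-matched random region sets whose sequence is
#' drawn from the supplied genome sequence; p-values are BH-corrected across
#' motifs.
#'
#' @param target_seqs character vector / DNAStringSet of target region
#'   sequences (1:1 with `source_regions`).
#' @param source_regions GRanges the targets were extracted from (supplies
#'   the lengths for size matching).
#' @param genome_seq `Biostrings::DNAStringSet` of the genome (chromosome
#'   names matching the genome spec).
#' @param motifs named list of calibrated `motif_model`s.
#' @param n_random number of random sets (default 100).
#' @param seed integer seed.
#' @return data.frame `motif`, `name`, `target_with_match`, `target_total`,
#'   `random_with_match`, `random_total`, `p_value`, `adj_p`, `rank`,
#'   ordered by p-value.
#' @export
motif_enrichment_test <- function(target_seqs, source_regions, genome_seq,
                                  motifs, n_random = 100, seed) {
  if (!length(motifs)) stop("no motifs supplied")
  if (length(target_seqs) != length(source_regions))
    stop("target_seqs and source_regions must correspond 1:1")
  genome <- genome_of(source_regions)
  if (!all(names(genome) %in% names(genome_seq)))
    stop("genome sequence lacks chromosome(s)")
  rand_sets <- sample_random_regions(GenomicRanges::width(source_regions),
                                     genome, n_sets = n_random, seed = seed)
  rand_all <- suppressWarnings(do.call(c, rand_sets))
  rand_seqs <- extract_region_sequences(genome_seq, rand_all)
  target_codes <- encode_dna(as.character(target_seqs))
  rand_codes <- encode_dna(as.character(rand_seqs))
  nt <- length(target_codes); nr <- length(rand_codes)
  rows <- lapply(motifs, function(m) {
    a <- count_matching_sequences(target_codes, m)
    c2 <- count_matching_sequences(rand_codes, m)
    data.frame(motif = m$id, name = m$name,
               target_with_match = a, target_total = nt,
               random_with_match = c2, random_total = nr,
               p_value = fisher_exact_2x2(a, nt - a, c2, nr - c2,
                                          sided = "one-greater"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, -out$target_with_match), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Extract region sequences from a genome sequence
#'
#' @param genome_seq `Biostrings::DNAStringSet`.
#' @param regions GRanges (0-based half-open internally).
#' @return `Biostrings::DNAStringSet`, one sequence per region.
#' @export
extract_region_sequences <- function(genome_seq, regions) {
  chrom <- as.character(GenomicRanges::seqnames(regions))
  Biostrings::subseq(genome_seq[chrom],
                     start = GenomicRanges::start(regions),
                     end = GenomicRanges::end(regions))
}
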