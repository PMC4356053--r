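# Synthetic genome bundle with planted truth: LADs, histone-mark domains,
# hyper-/hypomethylated regions, methyl-capture fragments for an early and a
# late sample, array-style probes, genes with DE statistics, promoter
# sequences with a planted motif, and a genome sequence.

#' Default configuration for the synthetic genome bundle
#'
#' @return named list of generator parameters (see Details).
#' @details
#' * `n_chrom`, `chrom_length`: 3 chromosomes of 2 Mb.
#' * `n_lads`, `lad_fraction`: 20 LADs scaled to cover 40% of the genome
#'   (relative lengths drawn uniformly with a 1:5 ratio).
#' * `n_hyper`, `n_hypo`, `dmr_len`: 100 + 100 planted DMRs of 300-1000 bp.
#' * `p_hypo_in_lad`, `p_hyper_out_lad`: midpoint placement probabilities
#'   (both 0.8).
#' * `n_genes`, `frac_up`, `frac_down`: 500 genes, 10% up- and 10%
#'   downregulated.
#' * `n_fragments`, `frag_len`: 2e5 fragments of 200-400 bp per sample.
#' * `fold`: capture-intensity multiplier over planted DMRs (4; hyper in the
#'   late sample, hypo in the early sample).
#' * `lad_background_factor`: baseline methylation-intensity multiplier
#'   inside LADs, both samples (0.7) - the planted LAD methylation deficit,
#'   on the scale of partially methylated lamina-associated heterochromatin.
#' * `n_probes`, `probe_delta`, `beta_noise_sd`: ~5000 CpG probes, planted
#'   beta change > 0.2, noise sd 0.05.
#' * `hyper_near_de_frac`, `de_window`: half of the hyper-DMRs are placed
#'   within 5 kb of a differentially expressed TSS.
#' * `planted_motif`, `plant_frac_dmr`, `plant_frac_promoter`: consensus of
#'   the planted motif is inserted in 50% of hyper-DMRs and 50% of DE-gene
#'   promoters.
#' @export
bundle_config <- function() {
  list(
    n_chrom = 3, chrom_length = 2e6,
    n_lads = 20, lad_fraction = 0.4,
    n_hyper = 100, n_hypo = 100, dmr_len = c(300, 1000),
    p_hypo_in_lad = 0.8, p_hyper_out_lad = 0.8,
    n_genes = 500, frac_up = 0.1, frac_down = 0.1,
    n_fragments = 2e5, frag_len = c(200, 400),
    fold = 4, lad_background_factor = 0.7,
    n_probes = 5000, probe_delta = c(0.25, 0.4), beta_noise_sd = 0.05,
    hyper_near_de_frac = 0.5, de_window = 5000,
    planted_motif = NULL,  # NULL = first motif in the motif file
    plant_frac_dmr = 0.5, plant_frac_promoter = 0.5,
    motif_file = system.file("extdata", "synthetic_motifs.pfm",
                             package = "senesceq"))
}

#' Generate the synthetic genome bundle
#'
#' Builds a toy genome whose statistical structure mirrors the senescence
#' study design: hypomethylated regions concentrated inside LADs and H3K9me3
#' domains, hypermethylated regions outside LADs and near differentially
#' expressed genes, a LAD-wide methylation deficit, array probes with planted
#' beta changes at truth regions, and a planted transcription-factor motif in
#' hyper-DMRs and DE promoters. Deterministic for a fixed seed.
#'
#' @param config parameter list; missing entries default to [bundle_config()].
#' @param seed integer seed.
#' @param dir when not `NULL`, all inputs are also written as files (BED,
#'   bedGraph, TSV, FASTA, chrom sizes, JSON truth manifest) under `dir`.
#' @return list with `genome`, `genome_seq`, `lads`, `histone` (list of four
#'   GRanges), `truth` (hyper/hypo GRanges, planted probe ids, motif id and
#'   insertion table), `fragments_early`, `fragments_late`, `probes`,
#'   `genes`, `promoters`, `promoter_seqs`, `motifs`, and `files` (paths,
#'   when written).
#' @export
generate_genome_bundle <- function(config = list(), seed, dir = NULL) {
  cfg <- utils::modifyList(bundle_config(), config)
  genome <- genome_spec(paste0("chr", seq_len(cfg$n_chrom)),
                        rep(cfg$chrom_length, cfg$n_chrom))
  gsize <- genome_size(genome)
  lad_total <- cfg$lad_fraction * gsize
  if (lad_total >= gsize || cfg$n_lads * 2 > gsize)
    stop("infeasible LAD configuration")
  bundle <- withr::with_seed(seed, {
    ## LADs: non-overlapping, relative lengths 1:5, scaled to lad_fraction
    rel <- stats::runif(cfg$n_lads, 1, 5)
    lad_len <- round(rel / sum(rel) * lad_total)
    lads <- place_nonoverlapping(lad_len, genome, max_tries = 5000)
    lads <- GenomicRanges::sort(lads)

    ## histone domains: H3K9me3 follows LADs (jittered), the active/polycomb
    ## marks are drawn outside LADs
    histone <- list(
      H3K9me3 = jitter_domains(lads, genome, 0.2),
      H3K27me3 = place_relative(30, c(1e4, 5e4), genome, lads, inside = FALSE),
      H3K4me3 = place_relative(60, c(1e3, 3e3), genome, lads, inside = FALSE),
      H3K4me1 = place_relative(60, c(1e3, 5e3), genome, lads, inside = FALSE))

    ## genes: uniform TSS; DE status independent of LADs; expression lower
    ## inside LADs (baseline structure, not senescence-associated)
    n_up <- round(cfg$n_genes * cfg$frac_up)
    n_down <- round(cfg$n_genes * cfg$frac_down)
    gchrom <- sample(names(genome), cfg$n_genes, replace = TRUE,
                     prob = unclass(genome))
    gtss <- floor(stats::runif(cfg$n_genes) * (unclass(genome)[gchrom] - 2000)) + 1000
    gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    status <- rep("ns", cfg$n_genes)
    de_idx <- sample.int(cfg$n_genes, n_up + n_down)
    status[de_idx[seq_len(n_up)]] <- "up"
    status[de_idx[n_up + seq_len(n_down)]] <- "down"
    log2fc <- stats::rnorm(cfg$n_genes, 0, 0.5)
    log2fc[status == "up"] <- stats::runif(n_up, 2.5, 5)
    log2fc[status == "down"] <- -stats::runif(n_down, 2.5, 5)
    fdr <- stats::runif(cfg$n_genes, 0.02, 1)
    fdr[status != "ns"] <- 10^stats::runif(n_up + n_down, -8, -3)
    expr <- exp(stats::rnorm(cfg$n_genes, 4, 1))
    tss_gr <- region_set(gchrom, gtss, gtss + 1, genome)
    in_lad <- midpoints_inside(tss_gr, lads)
    expr[in_lad] <- expr[in_lad] * 0.3
    genes <- data.frame(id = sprintf("GENE%04d", seq_len(cfg$n_genes)),
                        chrom = gchrom, tss = gtss, strand = gstrand,
                        expr = round(expr, 3), log2fc = round(log2fc, 4),
                        fdr = signif(fdr, 4), status = status)

    ## planted DMRs
    hyper <- place_dmrs(cfg$n_hyper, cfg$dmr_len, genome, lads,
                        p_inside = 1 - cfg$p_hyper_out_lad,
                        near = genes[genes$status != "ns", , drop = FALSE],
                        near_frac = cfg$hyper_near_de_frac,
                        near_window = cfg$de_window)
    hypo <- place_dmrs(cfg$n_hypo, cfg$dmr_len, genome, lads,
                       p_inside = cfg$p_hypo_in_lad)
    hyper$name <- sprintf("hyper%03d", seq_along(hyper))
    hypo$name <- sprintf("hypo%03d", seq_along(hypo))

    ## methyl-capture fragments: piecewise-constant intensity
    frag_early <- sample_fragments(cfg$n_fragments, cfg$frag_len, genome,
                                   list(list(regions = lads,
                                             factor = cfg$lad_background_factor),
                                        list(regions = hypo, factor = cfg$fold)))
    frag_late <- sample_fragments(cfg$n_fragments, cfg$frag_len, genome,
                                  list(list(regions = lads,
                                            factor = cfg$lad_background_factor),
                                       list(regions = hyper, factor = cfg$fold)))

    ## probes: two per planted DMR plus a uniform background set
    probes <- make_probes(cfg, genome, hyper, hypo)

    ## genome sequence with planted motif insertions
    motifs <- read_jaspar(cfg$motif_file, fdr = 1e-4)
    planted_id <- if (is.null(cfg$planted_motif)) names(motifs)[1] else cfg$planted_motif
    consensus <- motifs[[planted_id]]$consensus
    seq_chars <- random_genome_chars(genome)
    promoters <- promoter_regions(genes, genome, width = 1000)
    ins <- plant_motif(seq_chars, consensus, hyper, promoters,
                       genes$status != "ns", cfg)
    seqs <- Biostrings::DNAStringSet(ins$seqs)
    promoter_seqs <- extract_region_sequences(seqs, promoters)
    names(promoter_seqs) <- genes$id

    list(genome = genome, genome_seq = seqs, lads = lads, histone = histone,
         genes = genes, promoters = promoters, promoter_seqs = promoter_seqs,
         probes = probes$table,
         fragments_early = frag_early, fragments_late = frag_late,
         motifs = motifs,
         truth = list(hyper = hyper, hypo = hypo,
                      planted_motif = planted_id,
                      motif_insertions = ins$insertions,
                      hyper_probe_ids = probes$hyper_ids,
                      hypo_probe_ids = probes$hypo_ids),
         config = cfg, seed = seed)
  })
  if (!is.null(dir)) bundle$files <- write_bundle(bundle, dir)
  bundle
}

place_nonoverlapping <- function(lengths, genome, max_tries = 5000,
                                 avoid = NULL) {
  placed <- GenomicRanges::GRanges(seqinfo = as_seqinfo(genome))
  for (len in lengths) {
    for (try in seq_len(max_tries)) {
      cand <- sample_random_region_once(len, genome)
      blocked <- length(placed) && IRanges::overlapsAny(cand, placed)
      if (!blocked && !is.null(avoid))
        blocked <- IRanges::overlapsAny(cand, avoid)
      if (!blocked) { placed <- suppressWarnings(c(placed, cand)); break }
      if (try == max_tries) stop("could not place features; genome too crowded")
    }
  }
  placed
}

sample_random_region_once <- function(len, genome) {
  clen <- unclass(genome)
  w <- pmax(clen - len + 1, 0)
  if (all(w == 0)) stop("region length exceeds every chromosome")
  ci <- sample.int(length(clen), 1, prob = w)
  s0 <- min(floor(stats::runif(1) * w[ci]), w[ci] - 1)
  region_set(names(clen)[ci], s0, s0 + len, genome)
}

jitter_domains <- function(domains, genome, rel_jitter) {
  s0 <- GenomicRanges::start(domains) - 1
  e0 <- GenomicRanges::end(domains)
  w <- e0 - s0
  s0 <- pmax(0, round(s0 + stats::runif(length(w), -rel_jitter, rel_jitter) * w))
  e0 <- pmin(unclass(genome)[as.character(GenomicRanges::seqnames(domains))],
             round(e0 + stats::runif(length(w), -rel_jitter, rel_jitter) * w))
  keep <- e0 > s0
  region_set(as.character(GenomicRanges::seqnames(domains))[keep],
             s0[keep], e0[keep], genome)
}

# sorted interval boundaries per chromosome for fast midpoint membership
region_boundaries <- function(regions) {
  r <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  ch <- as.character(GenomicRanges::seqnames(r))
  s0 <- GenomicRanges::start(r) - 1; e0 <- GenomicRanges::end(r)
  lapply(split(data.frame(s0, e0), ch), function(d) sort(c(d$s0, d$e0)))
}

# half-open membership of 0-based points via interleaved boundaries
points_inside_fast <- function(chrom, pos, bnd) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    b <- bnd[[ch]]
    sel <- chrom == ch
    out[sel] <- if (is.null(b)) FALSE else
      findInterval(pos[sel], b) %% 2 == 1
  }
  out
}

place_relative <- function(n, len_range, genome, ref, inside = TRUE,
                           max_tries = 200) {
  bnd <- region_boundaries(ref)
  clen <- unclass(genome)
  lens <- round(stats::runif(n, len_range[1], len_range[2]))
  chrom <- character(n); start0 <- rep(NA_real_, n)
  for (try in seq_len(max_tries)) {
    miss <- which(is.na(start0))
    if (!length(miss)) break
    ci <- sample.int(length(clen), length(miss), replace = TRUE, prob = clen)
    w <- clen[ci] - lens[miss] + 1
    s <- pmin(floor(stats::runif(length(miss)) * w), w - 1)
    mid <- s + floor(lens[miss] / 2)
    ok <- points_inside_fast(names(clen)[ci], mid, bnd) == inside
    chrom[miss[ok]] <- names(clen)[ci[ok]]
    start0[miss[ok]] <- s[ok]
    if (try == max_tries) stop("could not place domain relative to reference")
  }
  region_set(chrom, start0, start0 + lens, genome)
}

place_dmrs <- function(n, len_range, genome, lads, p_inside,
                       near = NULL, near_frac = 0, near_window = 5000,
                       max_tries = 2000) {
  bnd <- region_boundaries(lads)
  clen <- unclass(genome)
  n_near <- if (!is.null(near) && nrow(near) > 0) round(n * near_frac) else 0
  lens <- round(stats::runif(n, len_range[1], len_range[2]))
  want_inside <- stats::runif(n) < p_inside
  chrom <- character(n); start0 <- rep(NA_real_, n)
  for (i in seq_len(n_near)) {
    for (try in seq_len(max_tries)) {
      g <- near[sample.int(nrow(near), 1), , drop = FALSE]
      L <- clen[[g$chrom]]
      center <- g$tss + round(stats::runif(1, -near_window, near_window))
      s0 <- max(0, min(center - floor(lens[i] / 2), L - lens[i]))
      mid <- s0 + floor(lens[i] / 2)
      if (points_inside_fast(g$chrom, mid, bnd) == want_inside[i]) {
        chrom[i] <- g$chrom; start0[i] <- s0; break
      }
      if (try == max_tries) stop("could not place DMR near a DE gene")
    }
  }
  for (try in seq_len(200)) {
    miss <- which(is.na(start0))
    if (!length(miss)) break
    ci <- sample.int(length(clen), length(miss), replace = TRUE, prob = clen)
    w <- clen[ci] - lens[miss] + 1
    s <- pmin(floor(stats::runif(length(miss)) * w), w - 1)
    mid <- s + floor(lens[miss] / 2)
    ok <- points_inside_fast(names(clen)[ci], mid, bnd) == want_inside[miss]
    chrom[miss[ok]] <- names(clen)[ci[ok]]
    start0[miss[ok]] <- s[ok]
    if (try == 200) stop("could not place DMR")
  }
  region_set(chrom, start0, start0 + lens, genome)
}

# fragment midpoints drawn from a piecewise-constant intensity map:
# background 1, multiplied by `factor` over each modifier's regions
sample_fragments <- function(n, len_range, genome, modifiers) {
  segs <- intensity_segments(genome, modifiers)
  mass <- segs$weight * (segs$end - segs$start)
  seg_idx <- sample.int(nrow(segs), n, replace = TRUE, prob = mass)
  u <- stats::runif(n)
  mid <- floor(segs$start[seg_idx] + u * (segs$end[seg_idx] - segs$start[seg_idx]))
  len <- round(stats::runif(n, len_range[1], len_range[2]))
  clen <- unclass(genome)[segs$chrom[seg_idx]]
  s0 <- pmax(0, pmin(mid - floor(len / 2), clen - len))
  region_set(segs$chrom[seg_idx], s0, s0 + len, genome)
}

intensity_segments <- function(genome, modifiers) {
  rows <- lapply(names(genome), function(ch) {
    L <- unclass(genome)[[ch]]
    cuts <- c(0, L)
    for (m in modifiers) {
      r <- m$regions[as.character(GenomicRanges::seqnames(m$regions)) == ch]
      cuts <- c(cuts, GenomicRanges::start(r) - 1, GenomicRanges::end(r))
    }
    cuts <- sort(unique(pmax(0, pmin(cuts, L))))
    s <- cuts[-length(cuts)]; e <- cuts[-1]
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    w <- rep(1, length(s))
    midp <- (s + e) / 2
    for (m in modifiers) {
      r <- m$regions[as.character(GenomicRanges::seqnames(m$regions)) == ch]
      if (!length(r)) next
      s0 <- GenomicRanges::start(r) - 1; e0 <- GenomicRanges::end(r)
      inside <- vapply(midp, function(x) any(x >= s0 & x < e0), logical(1))
      w[inside] <- w[inside] * m$factor
    }
    data.frame(chrom = ch, start = s, end = e, weight = w)
  })
  do.call(rbind, rows)
}

make_probes <- function(cfg, genome, hyper, hypo) {
  plant_two <- function(regions) {
    ch <- rep(as.character(GenomicRanges::seqnames(regions)), each = 2)
    s0 <- rep(GenomicRanges::start(regions) - 1, each = 2)
    w <- rep(GenomicRanges::width(regions), each = 2)
    pos <- s0 + floor(stats::runif(length(ch)) * w)
    data.frame(chrom = ch, pos = pos)
  }
  hyper_df <- plant_two(hyper); hypo_df <- plant_two(hypo)
  n_bg <- max(0, cfg$n_probes - nrow(hyper_df) - nrow(hypo_df))
  bg_ch <- sample(names(genome), n_bg, replace = TRUE, prob = unclass(genome))
  bg_df <- data.frame(chrom = bg_ch,
                      pos = floor(stats::runif(n_bg) * unclass(genome)[bg_ch]))
  all_df <- rbind(hyper_df, hypo_df, bg_df)
  n <- nrow(all_df)
  type <- rep(c("hyper", "hypo", "bg"),
              c(nrow(hyper_df), nrow(hypo_df), n_bg))
  base <- stats::runif(n, 0.2, 0.7)
  delta <- numeric(n)
  delta[type == "hyper"] <- stats::runif(sum(type == "hyper"),
                                         cfg$probe_delta[1], cfg$probe_delta[2])
  delta[type == "hypo"] <- -stats::runif(sum(type == "hypo"),
                                         cfg$probe_delta[1], cfg$probe_delta[2])
  be <- pmin(1, pmax(0, base + stats::rnorm(n, 0, cfg$beta_noise_sd)))
  bl <- pmin(1, pmax(0, base + delta + stats::rnorm(n, 0, cfg$beta_noise_sd)))
  adj_p <- stats::runif(n, 0.05, 1)
  adj_p[type != "bg"] <- 10^stats::runif(sum(type != "bg"), -8, -3)
  tab <- data.frame(id = sprintf("cg%06d", seq_len(n)),
                    chrom = all_df$chrom, pos = all_df$pos,
                    beta_early = round(be, 4), beta_late = round(bl, 4),
                    adj_p = signif(adj_p, 4))
  tab$delta <- tab$beta_late - tab$beta_early
  ord <- order(tab$chrom, tab$pos)
  tab <- tab[ord, ]
  type <- type[ord]
  list(table = tab,
       hyper_ids = tab$id[type == "hyper"],
       hypo_ids = tab$id[type == "hypo"])
}

random_genome_chars <- function(genome) {
  seqs <- vapply(names(genome), function(ch) {
    paste(sample(DNA_BASES, unclass(genome)[[ch]], replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- names(genome)
  seqs
}

plant_motif <- function(seqs, consensus, hyper, promoters, is_de, cfg) {
  w <- nchar(consensus)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
  ins <- list()
  # centers of a fraction of hyper-DMRs
  n_dmr <- round(length(hyper) * cfg$plant_frac_dmr)
  if (n_dmr > 0) {
    idx <- sample.int(length(hyper), n_dmr)
    ins[[1]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(hyper))[idx],
      pos = midpoints(hyper[idx]) - floor(w / 2),
      where = "hyper_dmr")
  }
  # interior of a fraction of DE-gene promoters
  de_prom <- which(is_de)
  n_prom <- round(length(de_prom) * cfg$plant_frac_promoter)
  if (n_prom > 0) {
    idx <- sample(de_prom, n_prom)
    widths <- GenomicRanges::width(promoters[idx])
    offs <- vapply(pmax(1, widths - w), function(m) sample.int(m, 1), 1L) - 1
    ins[[length(ins) + 1]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(promoters))[idx],
      pos = GenomicRanges::start(promoters[idx]) - 1 + offs,
      where = "promoter")
  }
  if (!length(ins)) {
    return(list(seqs = seqs,
                insertions = data.frame(chrom = character(0), pos = numeric(0),
                                        strand = character(0), where = character(0))))
  }
  tab <- do.call(rbind, ins)
  tab$strand <- ifelse(stats::runif(nrow(tab)) < 0.5, "+", "-")
  # apply all insertions per chromosome in one reconstruction pass,
  # skipping (rare) insertions that would overlap an earlier one
  kept <- list()
  for (ch in unique(tab$chrom)) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    ok <- rep(TRUE, nrow(sub)); last_end <- -1
    for (j in seq_len(nrow(sub))) {
      if (sub$pos[j] <= last_end) ok[j] <- FALSE else last_end <- sub$pos[j] + w - 1
    }
    sub <- sub[ok, , drop = FALSE]
    kept[[ch]] <- sub
    s <- seqs[[ch]]
    pieces <- character(2 * nrow(sub) + 1)
    prev <- 0
    for (j in seq_len(nrow(sub))) {
      pieces[2 * j - 1] <- substr(s, prev + 1, sub$pos[j])
      pieces[2 * j] <- if (sub$strand[j] == "+") consensus else rc
      prev <- sub$pos[j] + w
    }
    pieces[2 * nrow(sub) + 1] <- substr(s, prev + 1, nchar(s))
    seqs[[ch]] <- paste(pieces, collapse = "")
  }
  kept <- do.call(rbind, kept)
  rownames(kept) <- NULL
  list(seqs = seqs, insertions = kept[c("chrom", "pos", "strand", "where")])
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- list(
    chrom_sizes = p("genome.chrom.sizes"),
    genome_fasta = p("genome.fa"),
    lads = p("lads.bed"),
    truth_hyper = p("truth_hyper.bed"),
    truth_hypo = p("truth_hypo.bed"),
    fragments_early = p("fragments_early.bed"),
    fragments_late = p("fragments_late.bed"),
    probes = p("probes.tsv"),
    genes = p("genes.tsv"),
    promoters_fasta = p("promoters.fa"),
    truth = p("truth.json"))
  write_chrom_sizes(bundle$genome, files$chrom_sizes)
  Biostrings::writeXStringSet(bundle$genome_seq, files$genome_fasta)
  write_bed(bundle$lads, files$lads)
  for (mark in names(bundle$histone)) {
    files[[paste0("histone_", mark)]] <- p(paste0(mark, ".bed"))
    write_bed(bundle$histone[[mark]], files[[paste0("histone_", mark)]])
  }
  write_bed(bundle$truth$hyper, files$truth_hyper)
  write_bed(bundle$truth$hypo, files$truth_hypo)
  write_bed(bundle$fragments_early, files$fragments_early)
  write_bed(bundle$fragments_late, files$fragments_late)
  write_probe_table(bundle$probes, files$probes)
  write_gene_table(bundle$genes, files$genes)
  Biostrings::writeXStringSet(bundle$promoter_seqs, files$promoters_fasta)
  truth_json <- list(
    seed = bundle$seed,
    planted_motif = bundle$truth$planted_motif,
    n_hyper = length(bundle$truth$hyper),
    n_hypo = length(bundle$truth$hypo),
    hyper_probe_ids = bundle$truth$hyper_probe_ids,
    hypo_probe_ids = bundle$truth$hypo_probe_ids,
    motif_insertions = bundle$truth$motif_insertions)
  jsonlite::write_json(truth_json, files$truth, auto_unbox = TRUE, digits = NA)
  files
}
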