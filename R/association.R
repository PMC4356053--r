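# Association machinery: exact Fisher 2x2, BH correction, the binomial
# projection test for region-gene association, LAD enrichment against
# size-matched random regions, gene-LAD association and flat gene-set
# enrichment.

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional (hypergeometric) test. Two-sided p is the sum of the
#' probabilities of all tables, conditional on the margins, no more probable
#' than the observed one.
#'
#' @param a,b,c,d counts: rows = in-set/not, columns = condition/not.
#' @param sided `"two"` (default) or `"one-greater"` (upper tail on `a`).
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, sided = c("two", "one-greater")) {
  sided <- match.arg(sided)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if (a + b + c + d == 0) stop("table is all zero")
  m <- matrix(c(a, c, b, d), 2)
  alt <- if (sided == "two") "two.sided" else "greater"
  stats::fisher.test(m, alternative = alt)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment; the original order is preserved.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Projection test for region-set association
#'
#' Projects query-region midpoints onto a reference set (merged to disjoint
#' intervals): under the null, the number of midpoints landing inside is
#' binomial with success probability `p0` = reference bp / genome bp. The
#' two-sided p-value is twice the smaller exact tail, capped at 1; the
#' direction label uses p < 0.05.
#'
#' @param query,reference GRanges on the same genome.
#' @return list `n`, `k`, `p0`, `p_value`, `direction`
#'   (`"enriched"`, `"depleted"` or `"none"`).
#' @export
projection_test <- function(query, reference) {
  if (length(query) == 0) stop("query set is empty")
  if (length(reference) == 0) stop("reference set is empty")
  check_same_genome(query, reference)
  genome <- genome_of(query)
  ref <- GenomicRanges::reduce(reference, ignore.strand = TRUE)
  p0 <- sum(GenomicRanges::width(ref)) / genome_size(genome)
  n <- length(query)
  k <- sum(midpoints_inside(query, ref))
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  lower <- stats::pbinom(k, n, p0)
  p <- min(1, 2 * min(upper, lower))
  direction <- "none"
  if (p < 0.05) direction <- if (k / n > p0) "enriched" else "depleted"
  list(n = n, k = k, p0 = p0, p_value = p, direction = direction)
}

#' Enrichment of regions in domains versus size-matched random regions
#'
#' Draws `n_random` region sets size-matched to the query, pools them into a
#' single column of a 2x2 table (rows = midpoint inside/outside domains,
#' columns = observed/random) and applies the two-sided Fisher exact test.
#'
#' @param regions query GRanges (e.g. DMRs).
#' @param domains GRanges (e.g. LADs).
#' @param n_random number of random sets (default 100).
#' @param seed integer seed for the resampling null.
#' @return list `observed_fraction`, `random_fraction`, `table` (2x2 matrix),
#'   `p_value`, `direction`.
#' @export
region_vs_domains_enrichment <- function(regions, domains, n_random = 100, seed) {
  if (length(regions) == 0) stop("region set is empty")
  if (length(domains) == 0) stop("domain set is empty")
  check_same_genome(regions, domains)
  genome <- genome_of(regions)
  dom <- GenomicRanges::reduce(domains, ignore.strand = TRUE)
  obs_in <- sum(midpoints_inside(regions, dom))
  obs_out <- length(regions) - obs_in
  rand_sets <- sample_random_regions(GenomicRanges::width(regions), genome,
                                     n_sets = n_random, seed = seed)
  rand_all <- suppressWarnings(do.call(c, rand_sets))
  rnd_in <- sum(midpoints_inside(rand_all, dom))
  rnd_out <- length(rand_all) - rnd_in
  tab <- matrix(c(obs_in, obs_out, rnd_in, rnd_out), 2,
                dimnames = list(c("inside", "outside"),
                                c("observed", "random")))
  p <- fisher_exact_2x2(obs_in, obs_out, rnd_in, rnd_out, sided = "two")
  obs_f <- obs_in / length(regions)
  rnd_f <- rnd_in / length(rand_all)
  direction <- "none"
  if (p < 0.05) direction <- if (obs_f > rnd_f) "enriched" else "depleted"
  list(observed_fraction = obs_f, random_fraction = rnd_f,
       table = tab, p_value = p, direction = direction)
}

#' Select differentially expressed genes
#'
#' Up: `fdr < fdr_cut` and `log2fc > lfc_cut`; down: `fdr < fdr_cut` and
#' `log2fc < -lfc_cut`.
#'
#' @param genes gene data.frame (see [read_gene_table()]).
#' @param fdr_cut FDR cutoff (default 0.01).
#' @param lfc_cut absolute log2 fold-change cutoff (default 2).
#' @return list with `up` and `down` data.frames.
#' @export
select_de_genes <- function(genes, fdr_cut = 0.01, lfc_cut = 2) {
  if (!all(c("log2fc", "fdr") %in% names(genes)))
    stop("gene table lacks log2fc/fdr columns")
  list(up = genes[genes$fdr < fdr_cut & genes$log2fc > lfc_cut, , drop = FALSE],
       down = genes[genes$fdr < fdr_cut & genes$log2fc < -lfc_cut, , drop = FALSE])
}

#' Gene-LAD association
#'
#' Computes, per gene, the signed distance of the TSS to the nearest LAD
#' border (positive inside a LAD, negative outside; a TSS at a LAD start is
#' inside, at a LAD end outside), a mean-expression profile binned by that
#' distance, and a 2x2 table of up/down-regulated genes by LAD membership
#' with a two-sided Fisher p. When one membership column is empty the table
#' is reported and the test declined (`p_value = NA`).
#'
#' @param genes gene data.frame.
#' @param lads GRanges of LADs.
#' @param genome a [genome_spec()].
#' @param de result of [select_de_genes()] (list with `up`, `down`).
#' @param profile_bin distance bin width for the expression profile (bp).
#' @return list `distances` (per gene), `profile` (data.frame offset, mean_expr,
#'   n), `table`, `p_value`.
#' @export
gene_lad_association <- function(genes, lads, genome, de,
                                 profile_bin = 10000) {
  if (length(lads) == 0) stop("no LADs supplied")
  dom <- GenomicRanges::reduce(lads, ignore.strand = TRUE)
  tss <- region_set(genes$chrom, genes$tss, genes$tss + 1, genome)
  inside <- midpoints_inside(tss, dom)
  s0 <- GenomicRanges::start(dom) - 1
  e0 <- GenomicRanges::end(dom)
  bch <- c(as.character(GenomicRanges::seqnames(dom)),
           as.character(GenomicRanges::seqnames(dom)))
  bpos <- c(s0, e0)
  dist <- vapply(seq_len(nrow(genes)), function(i) {
    sel <- bch == genes$chrom[i]
    if (!any(sel)) return(-Inf)
    min(abs(bpos[sel] - genes$tss[i]))
  }, numeric(1))
  signed <- ifelse(inside, dist, -dist)
  fin <- is.finite(signed)
  br <- pretty(signed[fin], n = 20)
  if (length(br) < 2) br <- c(-profile_bin, 0, profile_bin)
  k <- findInterval(signed[fin], br, rightmost.closed = TRUE)
  prof <- data.frame(
    offset = br[-length(br)],
    mean_expr = as.numeric(tapply(genes$expr[fin],
                                  factor(k, levels = seq_len(length(br) - 1)),
                                  mean)),
    n = tabulate(k, length(br) - 1))
  up_in <- sum(genes$id[inside] %in% de$up$id)
  up_out <- nrow(de$up) - up_in
  dn_in <- sum(genes$id[inside] %in% de$down$id)
  dn_out <- nrow(de$down) - dn_in
  tab <- matrix(c(up_in, dn_in, up_out, dn_out), 2,
                dimnames = list(c("up", "down"), c("inside", "outside")))
  p <- if (sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) NA_real_ else
    fisher_exact_2x2(up_in, dn_in, up_out, dn_out, sided = "two")
  list(distances = signed, profile = prof, table = tab, p_value = p)
}

#' Flat gene-set enrichment by Fisher's exact test
#'
#' Per set: 2x2 of (hits in set, hits not in set, set members not hit, rest of
#' universe), one-sided-greater Fisher, BH correction across sets.
#'
#' @param hits character vector of hit gene ids (subset of `universe`).
#' @param universe character vector of all gene ids.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @return data.frame `set`, `size`, `overlap`, `p_value`, `adj_p`, sorted by p.
#' @export
gene_set_enrichment <- function(hits, universe, sets) {
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  hits <- unique(hits); universe <- unique(universe)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    ov <- length(intersect(hits, s))
    a <- ov
    b <- length(hits) - ov
    c2 <- length(s) - ov
    d <- length(universe) - length(hits) - c2
    data.frame(set = nm, size = length(s), overlap = ov,
               p_value = fisher_exact_2x2(a, b, c2, d, sided = "one-greater"))
  })
  out <- do.call(rbind, res)
  out$adj_p <- bh_adjust(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' One-sided overlap test between two id lists
#'
#' Hypergeometric (one-sided-greater Fisher) test of whether two lists drawn
#' from a common universe overlap more than expected.
#'
#' @param list_a,list_b character vectors of ids.
#' @param universe_size total number of ids in the universe.
#' @return p-value.
#' @export
list_overlap_test <- function(list_a, list_b, universe_size) {
  a <- unique(list_a); b <- unique(list_b)
  ov <- length(intersect(a, b))
  if (length(a) > universe_size || length(b) > universe_size)
    stop("list sizes exceed the universe")
  rest <- universe_size - length(union(a, b))
  fisher_exact_2x2(ov, length(a) - ov, length(b) - ov, rest,
                   sided = "one-greater")
}
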