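# Small configurations keep these structural checks fast; full-scale
# behavior is exercised in the acceptance suite.

small_cfg <- list(n_fragments = 2e4, n_hyper = 20, n_hypo = 20,
                  n_genes = 100, n_probes = 600, n_lads = 8)

test_that("bundle generation is deterministic and emits re-parseable files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- generate_genome_bundle(small_cfg, seed = 11, dir = d1)
  b2 <- generate_genome_bundle(small_cfg, seed = 11, dir = d2)
  for (f in names(b1$files)) {
    expect_identical(readLines(unlist(b1$files[[f]])),
                     readLines(unlist(b2$files[[f]])),
                     info = paste("file:", f))
  }
  g <- read_chrom_sizes(b1$files$chrom_sizes)
  expect_equal(unclass(g), unclass(b1$genome), ignore_attr = TRUE)
  lads <- read_bed(b1$files$lads, g)
  expect_equal(length(lads), length(b1$lads))
  frags <- read_bed(b1$files$fragments_late, g)
  expect_equal(length(frags), small_cfg$n_fragments)
  probes <- read_probe_table(b1$files$probes)
  expect_equal(nrow(probes), small_cfg$n_probes)
  expect_true(all(abs(probes$delta - (probes$beta_late - probes$beta_early)) < 1e-9))
  genes <- read_gene_table(b1$files$genes)
  expect_equal(nrow(genes), small_cfg$n_genes)
  seqs <- Biostrings::readDNAStringSet(b1$files$genome_fasta)
  expect_equal(unname(Biostrings::width(seqs)), unname(unclass(g)),
               ignore_attr = TRUE)
})

test_that("planting probabilities are honored at their extremes", {
  b <- generate_genome_bundle(c(small_cfg, list(p_hypo_in_lad = 1.0)), seed = 5)
  expect_true(all(senesceq:::midpoints_inside(b$truth$hypo, b$lads)))
  b2 <- generate_genome_bundle(c(small_cfg, list(p_hyper_out_lad = 1.0,
                                                 hyper_near_de_frac = 0)),
                               seed = 5)
  expect_false(any(senesceq:::midpoints_inside(b2$truth$hyper, b2$lads)))
})

test_that("with fold 1 coverage over truth regions is equal in both samples", {
  b <- generate_genome_bundle(c(small_cfg, list(fold = 1)), seed = 21)
  truth <- suppressWarnings(c(b$truth$hyper, b$truth$hypo))
  k_late <- sum(GenomicRanges::countOverlaps(truth, b$fragments_late))
  k_early <- sum(GenomicRanges::countOverlaps(truth, b$fragments_early))
  p <- stats::binom.test(k_late, k_late + k_early, 0.5)$p.value
  expect_gt(p, 0.01)
})

test_that("planted motif insertions are present in the genome sequence", {
  b <- generate_genome_bundle(small_cfg, seed = 31)
  cons <- b$motifs[[b$truth$planted_motif]]$consensus
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  ins <- b$truth$motif_insertions
  expect_gt(nrow(ins), 0)
  words <- vapply(seq_len(nrow(ins)), function(i) {
    as.character(Biostrings::subseq(b$genome_seq[[ins$chrom[i]]],
                                    ins$pos[i] + 1, ins$pos[i] + nchar(cons)))
  }, character(1))
  expect_true(all(words == ifelse(ins$strand == "+", cons, rc)))
})

test_that("nucleus image generation is deterministic with planted contrasts", {
  e1 <- generate_nucleus_images(4, "early", seed = 3)
  e2 <- generate_nucleus_images(4, "early", seed = 3)
  expect_identical(e1$images, e2$images)
  expect_identical(e1$truth, e2$truth)
  l <- generate_nucleus_images(30, "late", seed = 4)
  e <- generate_nucleus_images(30, "early", seed = 4)
  expect_lt(mean(l$truth$amplitude), mean(e$truth$amplitude))
  expect_error(generate_nucleus_images(0, "early", seed = 1), "n_nuclei")
})

test_that("spots planted at high radial positions land in the border zone", {
  cfg <- list(early = utils::modifyList(image_config()$early,
                                        list(radial = c(0.85, 0.95))))
  gen <- generate_nucleus_images(3, "early", config = cfg, seed = 8)
  for (i in 1:3) {
    nuc <- segment_nuclei(gen$images[[i]][, , 1])[[1]]
    zones <- partition_zones(nuc$mask)
    tr <- gen$truth[gen$truth$nucleus == i, ]
    expect_true(all(zones[cbind(tr$x, tr$y)] == 1L))
  }
})
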