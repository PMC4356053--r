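# Configuration-driven orchestration: synthetic bundle (or file ingest) ->
# DMR calling in both orientations -> signal profiles -> enrichment and
# projection statistics -> motif enrichment -> imaging -> report, with a
# JSON manifest chaining content hashes for reproducibility.

#' Default pipeline configuration
#'
#' @return nested list: `seed`, `output_dir`, `synthetic` block (bundle
#'   overrides and imaging sizes), per-stage parameter blocks and the stage
#'   list to run.
#' @export
pipeline_config <- function() {
  list(
    seed = 1,
    output_dir = "senesceq_out",
    stages = c("generate", "dmr", "profiles", "enrich", "motifs",
               "imaging", "report"),
    inputs = NULL,          # named file paths for ingest mode (else synthetic)
    synthetic = list(bundle = list(), n_nuclei = 10),
    dmr = list(bin = 100, p_cut = 1e-5, merge_gap = 200, min_len = 200),
    profiles = list(rpkm_bin = 100, site_window = 600,
                    border_flank = 5e4, border_step = 1000),
    enrich = list(n_random = 100),
    motifs = list(n_random = 100, fdr = 1e-4, target_len = 40))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; every stage writes its tabular outputs
#' under `output_dir` plus a manifest entry (parameters, derived seed, md5
#' content hashes, hash of the previous stage's entry). Rerunning with the
#' same configuration reproduces all hashes. A stage failure aborts with the
#' stage named; outputs of completed stages are retained.
#'
#' @param config nested list (see [pipeline_config()]) or path to a YAML file.
#' @return invisible list with stage results, the output directory and the
#'   manifest path.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipeline_config(), config)
  validate_pipeline_config(cfg)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  manifest_path <- file.path(out_dir, "manifest.json")
  state <- new.env(parent = emptyenv())
  prev_hash <- ""
  results <- list()
  for (stage in cfg$stages) {
    res <- tryCatch(
      run_stage(stage, cfg, state, out_dir),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    files <- unlist(res$files)
    hashes <- if (length(files))
      as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
    else list()
    entry <- list(stage = stage, seed = stage_seed(cfg$seed, stage),
                  params = res$params, files = hashes, previous = prev_hash)
    prev_hash <- digest_entry(entry)
    entry$hash <- prev_hash
    manifest$stages[[stage]] <- entry
    results[[stage]] <- res$result
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(list(results = results, output_dir = out_dir,
                 manifest = manifest_path))
}

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    missing <- unlist(cfg$inputs)[!file.exists(unlist(cfg$inputs))]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  invisible(TRUE)
}

# stable per-stage seed derivation: adding a stage never perturbs others
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% (2^31 - 1))
}

digest_entry <- function(entry) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(stage, cfg, state, out_dir) {
  switch(stage,
    generate = stage_generate(cfg, state, out_dir),
    dmr = stage_dmr(cfg, state, out_dir),
    profiles = stage_profiles(cfg, state, out_dir),
    enrich = stage_enrich(cfg, state, out_dir),
    motifs = stage_motifs(cfg, state, out_dir),
    imaging = stage_imaging(cfg, state, out_dir),
    report = stage_report(cfg, state, out_dir),
    stop("unknown stage: ", stage))
}

stage_generate <- function(cfg, state, out_dir) {
  sd <- stage_seed(cfg$seed, "generate")
  if (is.null(cfg$inputs)) {
    bundle <- generate_genome_bundle(cfg$synthetic$bundle, seed = sd,
                                     dir = file.path(out_dir, "inputs"))
    state$bundle <- bundle
    return(list(result = bundle["truth"], files = bundle$files,
                params = list(mode = "synthetic",
                              overrides = cfg$synthetic$bundle)))
  }
  inp <- cfg$inputs
  genome <- read_chrom_sizes(inp$chrom_sizes)
  bundle <- list(
    genome = genome,
    lads = read_bed(inp$lads, genome),
    fragments_early = read_bed(inp$fragments_early, genome),
    fragments_late = read_bed(inp$fragments_late, genome),
    probes = read_probe_table(inp$probes),
    genes = read_gene_table(inp$genes),
    genome_seq = Biostrings::readDNAStringSet(inp$genome_fasta),
    motifs = read_jaspar(inp$motifs, fdr = cfg$motifs$fdr),
    truth = NULL)
  names(bundle$genome_seq) <- sub("\\s.*", "", names(bundle$genome_seq))
  state$bundle <- bundle
  list(result = NULL, files = list(), params = list(mode = "ingest"))
}

stage_dmr <- function(cfg, state, out_dir) {
  b <- state$bundle
  pars <- cfg$dmr
  hyper <- call_dmrs(b$fragments_late, b$fragments_early, "hyper",
                     bin = pars$bin, p_cut = pars$p_cut,
                     merge_gap = pars$merge_gap, min_len = pars$min_len)
  hypo <- call_dmrs(b$fragments_early, b$fragments_late, "hypo",
                    bin = pars$bin, p_cut = pars$p_cut,
                    merge_gap = pars$merge_gap, min_len = pars$min_len)
  f1 <- file.path(out_dir, "dmrs_hyper.bed"); f2 <- file.path(out_dir, "dmrs_hyper.tsv")
  f3 <- file.path(out_dir, "dmrs_hypo.bed"); f4 <- file.path(out_dir, "dmrs_hypo.tsv")
  write_dmrs(hyper, f1, f2)
  write_dmrs(hypo, f3, f4)
  state$dmrs <- list(hyper = hyper, hypo = hypo)
  list(result = list(n_hyper = length(hyper), n_hypo = length(hypo)),
       files = list(f1, f2, f3, f4), params = pars)
}

stage_profiles <- function(cfg, state, out_dir) {
  b <- state$bundle
  pars <- cfg$profiles
  early <- rpkm_normalize(b$fragments_early, pars$rpkm_bin)
  late <- rpkm_normalize(b$fragments_late, pars$rpkm_bin)
  sig <- select_significant_cpgs(b$probes)
  dsig <- differential_signal_at_sites(early, late,
                                       rbind(sig$hyper, sig$hypo),
                                       window = pars$site_window)
  border <- lad_border_profile(late, b$lads, flank = pars$border_flank,
                               step = pars$border_step)
  io <- inside_outside_test(late, b$lads)
  f1 <- file.path(out_dir, "late_rpkm.bedgraph")
  f2 <- file.path(out_dir, "site_differential.tsv")
  f3 <- file.path(out_dir, "lad_border_profile.tsv")
  write_bedgraph(late, f1)
  utils::write.table(dsig, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(border, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  state$tracks <- list(early = early, late = late)
  state$profiles <- list(site_differential = dsig, border = border,
                         inside_outside = io, significant = sig)
  list(result = list(inside_outside = io[c("mean_inside", "mean_outside",
                                           "p_value")]),
       files = list(f1, f2, f3), params = pars)
}

stage_enrich <- function(cfg, state, out_dir) {
  b <- state$bundle
  sd <- stage_seed(cfg$seed, "enrich")
  n_random <- cfg$enrich$n_random
  de <- select_de_genes(b$genes)
  rows <- list()
  tests <- list()
  for (dir_name in c("hyper", "hypo")) {
    dmrs <- state$dmrs[[dir_name]]
    if (!length(dmrs)) next
    enr <- region_vs_domains_enrichment(dmrs, b$lads, n_random = n_random,
                                        seed = sd + match(dir_name, c("hyper", "hypo")))
    tests[[paste0(dir_name, "_lad")]] <- enr
    rows[[length(rows) + 1]] <- data.frame(
      test = paste0(dir_name, "_in_lads"),
      statistic = enr$observed_fraction, null = enr$random_fraction,
      p_value = enr$p_value, direction = enr$direction)
    for (de_name in c("up", "down")) {
      g <- de[[de_name]]
      if (!nrow(g)) next
      vic <- promoter_vicinity(g, b$genome, window = 5000)
      pt <- projection_test(dmrs, vic)
      tests[[paste0(dir_name, "_", de_name)]] <- pt
      rows[[length(rows) + 1]] <- data.frame(
        test = paste0(dir_name, "_vs_", de_name, "regulated"),
        statistic = pt$k / pt$n, null = pt$p0,
        p_value = pt$p_value, direction = pt$direction)
    }
  }
  gla <- gene_lad_association(b$genes, b$lads, b$genome, de)
  rows[[length(rows) + 1]] <- data.frame(
    test = "de_genes_vs_lads", statistic = NA_real_, null = NA_real_,
    p_value = gla$p_value, direction = "none")
  tab <- do.call(rbind, rows)
  f1 <- file.path(out_dir, "enrichment_tests.tsv")
  utils::write.table(tab, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  state$enrich <- tests
  list(result = tests, files = list(f1),
       params = list(n_random = n_random))
}

# +/- window around the TSS of each gene: the "vicinity" reference used for
# the projection test against differentially expressed genes
promoter_vicinity <- function(genes, genome, window = 5000) {
  clen <- unclass(genome)[genes$chrom]
  s0 <- pmax(0, genes$tss - window)
  e0 <- pmin(clen, genes$tss + window)
  region_set(genes$chrom, s0, e0, genome)
}

stage_motifs <- function(cfg, state, out_dir) {
  b <- state$bundle
  sd <- stage_seed(cfg$seed, "motifs")
  pars <- cfg$motifs
  dmrs <- state$dmrs$hyper
  if (!length(dmrs)) stop("no hyper DMRs available for motif analysis")
  std <- standardize_region_length(dmrs, pars$target_len)
  seqs <- extract_region_sequences(b$genome_seq, std)
  res <- motif_enrichment_test(seqs, std, b$genome_seq, b$motifs,
                               n_random = pars$n_random, seed = sd)
  f1 <- file.path(out_dir, "motif_enrichment.tsv")
  utils::write.table(res, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  state$motifs <- res
  list(result = res[1, c("motif", "adj_p")], files = list(f1), params = pars)
}

stage_imaging <- function(cfg, state, out_dir) {
  sd <- stage_seed(cfg$seed, "imaging")
  n <- cfg$synthetic$n_nuclei
  groups <- list()
  rows <- list()
  for (grp in c("early", "late")) {
    gen <- generate_nucleus_images(n, grp, seed = sd + (grp == "late"))
    meas <- analyze_image_set(gen$images)
    summ <- telomere_summary(meas)
    groups[[grp]] <- summ
    rows[[grp]] <- data.frame(
      group = grp, included_n = summ$included_n, mean_area = summ$mean_area,
      mean_elongation = summ$mean_elongation,
      mean_length_proxy = summ$mean_length_proxy,
      frac_border = summ$zone_distribution[["border"]],
      frac_middle = summ$zone_distribution[["middle"]],
      frac_center = summ$zone_distribution[["center"]])
  }
  tab <- do.call(rbind, rows)
  f1 <- file.path(out_dir, "telomere_groups.tsv")
  utils::write.table(tab, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  state$imaging <- groups
  list(result = tab, files = list(f1), params = list(n_nuclei = n))
}

stage_report <- function(cfg, state, out_dir) {
  rep <- list(
    n_hyper_dmrs = length(state$dmrs$hyper),
    n_hypo_dmrs = length(state$dmrs$hypo))
  if (!is.null(state$enrich)) {
    if (!is.null(state$enrich$hypo_lad)) {
      rep$hypo_in_lad_fraction <- state$enrich$hypo_lad$observed_fraction
      rep$hypo_lad_direction <- state$enrich$hypo_lad$direction
      rep$hypo_lad_p <- state$enrich$hypo_lad$p_value
    }
    if (!is.null(state$enrich$hyper_lad)) {
      rep$hyper_in_lad_fraction <- state$enrich$hyper_lad$observed_fraction
      rep$hyper_lad_direction <- state$enrich$hyper_lad$direction
    }
  }
  if (!is.null(state$motifs)) {
    rep$top_motif <- state$motifs$motif[1]
    rep$top_motif_adj_p <- state$motifs$adj_p[1]
  }
  if (!is.null(state$profiles)) {
    rep$rpkm_inside_lads <- state$profiles$inside_outside$mean_inside
    rep$rpkm_outside_lads <- state$profiles$inside_outside$mean_outside
  }
  f1 <- file.path(out_dir, "report.json")
  jsonlite::write_json(rep, f1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(result = rep, files = list(f1), params = list())
}
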