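---
title: "Methods: models, parameters and design choices in senesceq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in senesceq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`senesceq` re-implements, as one tested toolkit, the analyses that link
replicative senescence to DNA-methylation change and nuclear reorganization:
differentially methylated region (DMR) calling from methyl-capture coverage,
signal metaprofiles, enrichment of DMRs in lamina-associated domains (LADs)
and histone-mark territories, a projection test against differentially
expressed (DE) genes, transcription-factor motif enrichment, and telomere
Q-FISH quantification. This vignette documents the statistical models, the
parameters that matter, and the design choices made where more than one
reasonable implementation exists. All empirical claims here are the ones the
package's own test suite and `scripts/acceptance.R` compute.

## Coordinates and containers

All coordinates are 0-based half-open (the BED dialect). Interval sets are
`GRanges` objects carrying the genome's chromosome lengths in their
`seqinfo`; a genome is a named length vector built by `genome_spec()`. The
midpoint of `[start, end)` is `floor((start + end) / 2)`, and midpoint
membership in a half-open interval decides all "inside a domain" questions:
DMRs and probes are small relative to LADs, so point membership keeps every
count unambiguous (a midpoint exactly at a domain end is outside; a TSS at a
domain start is inside). Probe positions arrive 1-based in array-style TSV
files and are converted on read.

## DMR calling

`call_dmrs()` compares two fragment samples with a local-Poisson enrichment
model, run once with the late sample as signal (hypermethylation) and once
swapped (hypomethylation):

1. Per-bin fragment-overlap counts (default bin 100 bp; a fragment
   increments every bin it overlaps, since captured fragments represent
   methylated DNA along their whole length, unlike point-shifted ChIP tags).
2. Control counts are scaled by `total_signal / total_control`. The per-bin
   null rate is `max(genome-wide rate, local rates)`, with local rates taken
   from centered running means of the scaled control over 1, 5 and 10 kb
   windows. The genome-wide floor protects low-coverage regions from
   spurious calls at the price of power inside coverage-poor domains.
3. Bins with upper-tail Poisson p below `p_cut` (default 1e-5) are kept,
   kept bins within `merge_gap` (200 bp) merged, and regions shorter than
   `min_len` (200 bp) dropped.
4. Boundary refinement: full-fragment counting blurs region edges by about
   half a fragment length, so each merged region's edges are re-estimated by
   a two-change-point Poisson fit on signal fragment *midpoints* (an
   unbiased point process over the methylated interval). The background
   midpoint rate comes from a median over 1-kb flanking chunks of the scaled
   control — a median, because a neighboring opposite-direction region would
   inflate a mean — and each edge maximizes the step-process likelihood on a
   5-bp grid, iterated twice. Refinement never invents a region; it only
   sharpens the edges of detected ones, and is switchable (`refine = FALSE`).

Region-level outputs are the Poisson p of the summed counts, fold enrichment
(summed signal over summed null rate), and the summit bin. There is no
q-value step: the per-bin p cutoff is the operative threshold and a plain
config knob. Reference peak callers for capture data are version-ambiguous
about defaults, so the parameterization above is fixed and documented rather
than emulated bit-for-bit.

## Signal profiles

`rpkm_normalize()` uses `count / ((bin/1000) * (total/1e6))` with the same
every-overlapped-bin counting rule (config-visible through the shared
binning helper). Metaprofiles (`metaprofile()`, `lad_border_profile()`)
average track values at signed offsets around anchor midpoints or domain
borders; right-hand borders are mirrored so positive offsets always point
into the domain, offsets beyond a domain's midpoint are excluded so long
flanks never leak across small domains, and empty bins are `NA`, never zero
— zeros would bias means downward exactly where data are sparse.
`differential_signal_at_sites()` reports the *difference* of window-mean
RPKM (late minus early; default 600-bp windows): a log-ratio is undefined at
the zero-coverage bins a capture assay legitimately produces.
`inside_outside_test()` compares per-bin track values inside versus outside
a domain set with a Mann-Whitney test (exact when both groups have at most
50 untied bins, normal approximation with tie correction otherwise); the
sampling unit is the track bin, matching a comparison of average signal
intensity; a per-region alternative can be built by aggregating first.
`select_significant_cpgs()` applies the array convention: adjusted p < 0.05
and an absolute beta change above 0.20.

## Association statistics

Fisher's exact test, Benjamini-Hochberg correction and the Mann-Whitney test
are delegated to R's reference implementations behind the package's
interfaces; the test suite checks them against explicit enumeration oracles
(all 2x2 tables with total at most 40; hand-computed step-up) rather than
trusting either side.

The projection test (`projection_test()`) associates a query region set with
a reference set by projecting query midpoints: under the null the number of
midpoints inside the merged reference is binomial with success probability
equal to the reference's genome fraction. The two-sided p is twice the
smaller exact tail, capped at 1, with an enriched/depleted label at p <
0.05. The cited description of this test gives no formula, so point
projection with a binomial null is the implemented reading; the one-sided
tails are exposed through the reported `k`, `n`, `p0`.

`region_vs_domains_enrichment()` draws `n_random` (default 100) region sets
size-matched to the query — chromosome chosen by available placement count,
start uniform, no exclusion rules beyond size since only size matching is
specified — and pools all random regions into one integer column of a 2x2
table (inside/outside x observed/random), tested two-sided. Pooling keeps
the table integer-valued; the type-I error of the combined procedure is
checked empirically in the acceptance suite (200 effect-free simulations,
nominal 0.05, accepted band 0.02-0.08). `gene_set_enrichment()` is flat
(no ontology DAG): one-sided Fisher per set, BH across sets.

## Motif enrichment

Motifs are position frequency matrices in JASPAR-2014 text form.
`build_motif()` forms log-odds
`log2((count + pc * bg) / (total + pc) / bg)` with pseudocount 0.1 and, by
design, rounds the matrix onto a 0.01 score lattice: the threshold
calibration computes the *exact* null score distribution by dynamic
programming (per-column score mass functions convolved over the lattice),
and keeping scanning scores on the same lattice makes "score >= threshold"
mean precisely the tail probability the DP computed — with exact log-odds a
borderline word can fall on the wrong side of a threshold derived from
rounded scores. `calibrate_threshold()` returns the smallest lattice score
whose null tail is at most the target FDR (default 1e-4 per scanned
position, an analytic calibration); if even the maximal score is too likely
the threshold is the maximum with a warning flag. Scanning covers both
strands at every offset, skips windows containing N, and the enrichment test
counts *regions with at least one match* — per-region counting keeps the
Fisher margins fixed and the units countable; per-site counts are available
from `scan_sequences()`. Random-region sequences are drawn from the supplied
genome FASTA; composition beyond size is not matched. DMRs are standardized
to 40 bp around their midpoints and promoters are the 1 kb upstream of the
TSS before scanning.

## Telomere imaging

Analysis is 2D (the source material quantifies single z-slices and maximum
projections). `segment_nuclei()` applies a global Otsu threshold, hole
filling and connected components, discarding components under 200 px^2;
elongation is the square root of the eigenvalue ratio of the pixel
covariance. `partition_zones()` divides a nucleus by normalized
distance-to-boundary d into border (d < 1/3), middle and center (d >= 2/3):
the published zone geometry is not reproduced in the source, so equal thirds
of normalized depth is the implemented reading, with the cutoffs
configurable; a mask whose maximal depth is at the pixel floor is all
border. `detect_spots()` localizes candidates as local maxima of a
matched-filtered image (Gaussian at the expected spot scale, sigma 1.5 px)
and accepts those whose filtered response exceeds the filtered background
by `k = 3` *raw*-background standard deviations: filtering suppresses
single-pixel noise, so spurious maxima essentially never reach three raw
sds, while a spot of amplitude ten times the noise keeps a filtered
response of about five. The background sd is a quantile spread
(`q84 - q50`), insensitive both to the spots themselves and to the
zero-clamped lower tail of an offset-free camera; it is seeded by excluding
discs around the brightest maxima (capped at half the mask) and refined
once. Maxima closer than 3 px merge into the brighter one, and a secondary
maximum riding within the 3-sigma footprint of a spot more than twice as
bright is discarded as a skirt artifact. The
telomere length proxy is mean raw spot peak minus the nucleus's raw
background, in arbitrary units; nuclei with fewer than three spots are
measured but excluded from group summaries.

## The synthetic-data module

`generate_genome_bundle()` is first-class, tested code that generates the
study conditions: 3 chromosomes of 2 Mb; 20 non-overlapping LADs scaled to
40% of the genome (the scale of lamina-associated heterochromatin in
fibroblasts); 100 hypermethylated and 100 hypomethylated DMRs of 300-1000
bp, hypo-DMR midpoints inside LADs with probability 0.8 and hyper-DMR
midpoints outside with probability 0.8; 500 genes with 10% up- and 10%
downregulated (DE status independent of LADs; expression reduced inside
LADs as a baseline, senescence-independent structure); 2e5 fragments of
200-400 bp per sample drawn from a piecewise-constant intensity map —
background 1, times 4 (the fold) over hyper-DMRs in the late sample and
over hypo-DMRs in the early sample, times 0.7 inside LADs in *both* samples.
That last factor is the planted LAD methylation deficit that gives the
border profile its step and the inside/outside comparison its contrast; 0.7
is on the scale of partially methylated lamina-associated domains and was
chosen once, jointly with the fixed fold-4 / 2e5-fragment conditions, so
that the deficit is clearly visible while planted regions inside LADs
remain recoverable. Probes (two per planted DMR plus a uniform background,
~5000 total) carry beta changes of 0.25-0.4 at truth sites with sd-0.05
noise truncated to [0, 1]; the motif module's consensus word is inserted at
the centers of half the hyper-DMRs and into half the DE-gene promoters, on
a random strand. The shipped matrices in
`inst/extdata/synthetic_motifs.pfm` are synthetic, consensus-dominated
stand-ins in JASPAR text format, not redistributed database entries.

What the generator does *not* emulate: read-level sequence, base-call
quality, bisulfite chemistry, CpG-density bias of capture, inter-replicate
heterogeneity, and correlated probe noise. Passing tests therefore
demonstrate that the implementations recover planted structure under a
clean generative model — not that they are robust to every artifact of real
capture data.

`generate_nucleus_images()` draws one elliptical nucleus per 192x192
two-channel frame (DAPI level 0.25 of the 16-bit range, Gaussian noise sd
100/65535) with 3-20 Gaussian spots (sigma 1.5 px). Late-passage nuclei
have larger minor axes (36-46 vs 28-36 px), higher elongation (1.4-2.0 vs
1.0-1.3), dimmer spots (1500 vs 3000 / 65535) and spot radial positions
drawn nearer the center (0.05-0.6 vs 0.5-0.95 of the normalized radius,
mapped onto the ellipse by uniform scaling — exact for circles, a mild
approximation for elongated nuclei).

## Pipeline and reproducibility

`run_pipeline()` runs generate → dmr → profiles → enrich → motifs → imaging
→ report from a nested-list or YAML configuration, writing each stage's
tabular outputs plus a JSON manifest with parameters, derived seed, md5
content hashes and the previous stage's entry hash (so any tampering breaks
the chain). One global seed fans out to per-stage seeds keyed by stage name,
so adding a stage never perturbs another stage's randomness. Every
stochastic operation takes an explicit seed and is bit-reproducible; the
suite reruns the full pipeline twice and compares manifests verbatim.
A thin command-line wrapper over these functions ships in
`inst/scripts/senesceq.R`; the package functions are the primary interface.

## Problem sizes in the shipped checks

The test and acceptance runs use the default study conditions above for the
planted-truth checks (one 6-Mb bundle, 2e5 fragments per sample), 200
effect-free simulations on a 1-Mb genome for the type-I calibration, 100
random sets for each resampling null, 4^8 exhaustive word enumeration and
1e6 background positions for the motif threshold, and 50 + 50 nuclei for
the imaging contrasts. These sizes were chosen as the smallest at which the
tested properties are statistically unambiguous.

## Known limitations

* The caller's genome-wide rate floor costs power inside coverage-depleted
  domains (visible as slightly lower recovery of planted regions inside
  LADs); a local-only null is a one-line configuration away but loses the
  false-positive protection the floor provides.
* Boundary refinement assumes an approximately piecewise-constant fragment
  midpoint rate; strongly peaked (summit-shaped) enrichments would be
  trimmed conservatively.
* The Mann-Whitney exact path requires tie-free groups; heavily discretized
  tracks fall back to the corrected normal approximation.
* Motif FDR calibration assumes an i.i.d. background at the supplied base
  composition; real promoters violate independence, so empirical match
  rates on biological sequence can exceed the analytic target.
* Zone geometry ("equal thirds of normalized depth") is one reading of a
  three-zone partition; ring definitions with equal areas would shift zone
  fractions but not the direction of group contrasts.
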