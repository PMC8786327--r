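---
title: "Models and methods: break-induced antisense transcription from NET-seq"
author: "dilncseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: break-induced antisense transcription from NET-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilncseq)
```

# Scope

`dilncseq` analyses polymerase-specific NET-seq experiments that ask
whether, and by which RNA polymerase, antisense transcription is induced at
a DNA double-strand break inside an active gene. This vignette explains the
generative model behind the simulator, the analysis statistics, the
numerical conventions, and the design decisions where more than one
reasonable choice existed.

# The generative model

The simulator's latent state is a set of polymerase active-site positions
on a toy genome. One "pool" corresponds to one chromatin (input) library of
one tagged cell line, condition and replicate. Components, with all counts
Poisson around the configured expectations:

* **Sense transcription.** Each gene receives `Poisson(lambda)` polymerases
  with positions from the mixture
  `w_p * Normal(TSS + d_p, sigma_p)` (truncated to the gene span by
  resampling) `+ (1 - w_p) * Uniform(span)`. The normal component models
  promoter-proximal pausing of pol II; defaults `w_p = 0.5`, `d_p = 40` nt,
  `sigma_p = 10` nt give the canonical pause pile-up ~40 nt downstream of
  the TSS. The pol-III locus uses the same law; its pausing component is a
  simplification, not a mechanistic claim.
* **Break-induced antisense transcription.** When a locus is cut, antisense
  polymerases (strand opposite to the gene) are placed uniformly on the
  interval between the TSS and the cut site, with expectation
  `lambda_a0 * f_cut * f_intron` (`f_intron` applies only when the cut gene
  has at least one intron); uncut loci get `lambda_a0`. The uniform law is
  the simplest one consistent with an antisense signal that starts near the
  break and extends to the TSS; real coverage profiles are not flat, so
  positional features of real dilncRNAs (e.g. 5' enrichment at the break)
  are outside what the simulator can validate. The ground-truth polymerase
  of these transcripts is configurable (`dilnc_polymerase`, default pol II).
* **Footprints.** Each polymerase protects the 3'-terminal `L` nt of its
  nascent transcript, `L` drawn from a law on 23–26 nt, so the footprint's
  genomic interval ends at the active site on the transcription strand.
  Benzonase digestion is not modelled mechanistically — only this length
  consequence is.
* **Contamination.** Input libraries additionally carry a fixed 23-nt miRNA
  (planted at its own locus, emulating an abundant cytoplasmic miRNA), rRNA
  fragments from a dedicated interval, and exon-restricted mature-mRNA
  fragments per pol-II gene (default 10% of each gene's sense rate), so the
  chromatin fraction is realistically dominated by processed RNA at exonic
  positions.
* **Immunoprecipitation.** An IP library is a per-read Bernoulli thinning
  of its input pool: a footprint survives with probability `p_t = 0.8` when
  its polymerase matches the tag and `p_b` otherwise; contamination
  survives with `p_b`. Thinning makes every recovery expectation available
  in closed form (the IP/input recovery of a class whose reads all carry
  the tagged polymerase is `p_t * T_input / E[T_ip]`), which the acceptance
  checks exploit. Per-replicate conservation (IP reads are a sub-multiset
  of the input) holds by construction.

Sequencing error, PCR duplicates and quality-score realism are deliberately
not modelled: the exact-match mapping policy would make error modelling a
test of the error model, not of the pipeline.

## Default parameters

Rates are weights normalised so an input library has expected size
`library_depth` (default 1e5 reads). The default gene set plants the
experiment's structure: an intron-containing cleavable gene (`dsbA`, 3
exons, cut 2000 nt downstream of its TSS — beyond both introns), an
intronless cleavable gene (`dsbB`), a never-cut control (`ctrl`), and a
pol-III locus (`trnX`), with a 1 kb rRNA interval and a 23-nt miRNA locus.
`antisense_weight = 10` makes baseline antisense transcription ~3 orders of
magnitude weaker than sense transcription; `f_cut = 5` and `f_intron = 2`
give the ten-fold induction at the intron-containing locus and five-fold at
the intronless one. Inside `dsbA`'s second intron the builder plants a run
of eight A on the sense strand — read as U8 by a polymerase transcribing
antisense, i.e. a pol-III terminator for the dilncRNA — preceded (in the
antisense transcript's 5'->3' direction) by a perfect 6-bp inverted repeat.

`ip_background` defaults to 0.005. The observed structure of this kind of
experiment — pol-III IP recovery of pol-II transcript classes far below 1
and no antisense signal in the pol-III IP — implies that carry-over of
chromatin-engaged footprints of the untagged polymerase is well below the
few-percent level typical of abundant-RNA contamination. A single
background parameter has to serve both roles in this model (a known
simplification), and 0.005 keeps the miRNA visibly present-but-reduced in
IP libraries while keeping the untagged polymerase near the detection
floor. Analyses that need a specific background (e.g. the closed-form
recovery check) set it explicitly.

# Alignment policy

The aligner re-implements a policy rather than wrapping a tool, because the
policy is what matters for the statistics: perfect full-length matches
only; reads with `N` never match; every hit on both strands is enumerated
(k-mer prefix seeding, `k = 12`, followed by full-string verification — `k`
affects speed only); and a read with several perfect hits is reported
exactly once at a uniformly random one of them. The multi-mapper draw is
the only randomness in analysis, and it is seeded per library from the
pipeline root seed. `total_genome_matching` — the number of mapped reads —
is the normaliser for every per-million statistic.

# Locus statistics and tests

A read counts for a locus when its alignment interval overlaps the gene
span (± a configurable flank, default 0) by at least 1 nt; it is sense when
its strand equals the gene's. The overlap rule is deliberately the simplest
auditable one; reads overlapping two annotated genes count for each
independently, which inflates the apparent antisense fraction of convergent
gene pairs and is reported as-is.

Two normalisations are computed per locus and library: the antisense
fraction `antisense / (sense + antisense)` and antisense ppm
`1e6 * antisense / total_genome_matching`. A locus with no reads yields an
explicit `NA`, never a silent zero, so "too few reads at this locus"
propagates visibly instead of being averaged away.

Cut-vs-uncut contrasts use Welch's unequal-variance t-test on the antisense
fraction across replicates, and the paired t-test (pairing cut and uncut
libraries of the same replicate) on antisense ppm. Both are two-sided;
p-values are reported raw because the design tests a handful of named loci,
not a genome-wide screen. Degenerate inputs (zero variance everywhere,
constant differences) return flagged limit results rather than errors. The
implementations are plain formulas over `pt()`; the test suite checks them
against `stats::t.test` and against closed-form noncentral-t power, and
verifies null-uniformity and type-I calibration by simulation.

# The pol-III terminator logic

Pol III terminates on a run of uridines in the nascent transcript; the
default threshold `min_run = 8` reflects a run length that stops most
pol-III complexes (shorter thresholds are one config field away). On the
genome, a `-`-strand transcript reads A-runs of the `+` strand as U-runs,
and a `+`-strand transcript reads T-runs; runs are reported maximally. The
optional hairpin annotation is a maximal inverted-repeat search (stem >=
5 bp, loop 3–10 nt, G·U pairs optional, ties broken by longer stem then
smaller offset) in a window upstream of the run in the transcript's
direction — deliberately not thermodynamic folding, which the question does
not require.

The density comparison splits the region of interest at the run, excludes a
window of 20 nt total centred on it (homopolymers cause library/sequencing
drop-out there), and compares strand-filtered per-nucleotide read counts
with an exact binomial test (conditional on the total count, the upstream
count is binomial with probability proportional to segment length). When
the cut site is known the pipeline restricts the comparison to the
TSS–break interval: the antisense transcript exists only there, and
including sequence beyond the break would dilute the upstream density — an
effect we observed as a spurious ~2-fold density step before making the
restriction. If pol III transcribed the antisense RNA, density should
collapse beyond the run; a ratio near 1 (as the simulator's pol-II ground
truth produces) argues against pol-III involvement.

# Numerical and interface conventions

* Internal coordinates are 1-based closed intervals (the
  GenomicRanges/GFF3 convention); BED I/O converts to 0-based half-open at
  the file boundary. A single internal convention removes a whole class of
  off-by-one errors.
* Gene strand must be `+` or `-`; unstranded gene features are rejected
  because every sense/antisense call depends on strand.
* `N` is allowed in genomes, never emitted in simulated reads, and never
  matches during alignment (the strictest reading of "no mismatches").
* FASTQ reading is a strict 4-line-record parser: truncated records and
  sequence/quality length mismatches are errors with record indices, not
  silently tolerated.
* All randomness flows from explicit seeds: the simulation derives one
  sub-seed per latent pool, alignment one per library. Identical
  (seed, config) reproduce byte-identical outputs, which the manifest of
  md5 digests written next to simulated experiments makes checkable.
* Read ids of simulated libraries encode the latent origin of each read
  (library, component, source locus, polymerase) for test introspection;
  no analysis function parses them.

# Problem sizes used in validation

The test suite validates the aligner against an exhaustive-scan oracle on
fifty random 2-kb genomes with 1000 reads each; multi-mapper uniformity
with 1e4 duplicated-locus reads; test calibration with 1e4 null
replications; and the end-to-end structure with 100 simulated experiments
at the default depth of 1e5 reads per library (pol-II IP detects the
ten-fold induction at the intron-containing locus in >=90% of experiments;
the control locus and the pol-III IP stay at the nominal false-positive
rate). These sizes give stable acceptance bands at desk-scale runtimes.

# Known limitations

* The IP model's single background probability conflates contamination
  carry-over with cross-polymerase capture.
* The uniform antisense position law ignores the 5' positional structure of
  real dilncRNA coverage.
* Convergent/overlapping gene pairs double-count shared reads per locus.
* The simulator emits no sequencing errors, so mapping rates are ~100%;
  real libraries map partially, which affects absolute ppm but not the
  within-experiment contrasts the pipeline tests.
* Abundant structural RNA (rRNA) is modelled only as uniform fragment
  contamination; no inference about such loci should be drawn from the
  pipeline's outputs, and the simulator's rRNA interval exists to exercise
  the contamination path, not to model ribosomal biology.
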