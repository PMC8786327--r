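# dilncseq

Quantifying DNA-break-induced antisense transcription from
polymerase-specific NET-seq libraries.

## The problem

When a chromosome suffers a double-strand break (DSB) inside an active gene,
an RNA polymerase can initiate at the broken end and transcribe *antisense*
relative to the host gene, from the break back toward the transcription
start site. These damage-induced long non-coding RNAs (dilncRNAs) feed the
small-RNA arm of the DNA-damage response, and the magnitude of their
induction depends on whether the broken gene contains introns. Nascent
elongating transcript sequencing (NET-seq) with polymerase-specific
immunoprecipitation can ask *which* polymerase makes them: the
immunopurified polymerase protects a 23–26 nt RNA stump from benzonase
digestion, and sequencing those stumps reports polymerase positions
strand-specifically.

`dilncseq` implements the complete analysis path for such an experiment,
plus a generative simulator so every stage is testable without sequencing
data:

* **Simulator** — chromatin-associated nascent reads with promoter-proximal
  pausing, 23–26 nt polymerase footprints, cytoplasmic miRNA/rRNA/mature
  mRNA contamination, per-read Bernoulli IP enrichment, and DSB-induced
  antisense transcription between the cut site and the TSS whose strength
  depends on intron presence.
* **Aligner** — the exact-match mapping policy: no mismatches tolerated,
  every perfect hit enumerated, and each read reported exactly once, with
  perfect multi-mappers assigned uniformly at random under a recorded seed.
* **Quantification** — strand-resolved locus counts and the two statistics:
  the antisense fraction `antisense / (sense + antisense)` (normalising to
  the locus's own activity) and antisense reads per million genome-matching
  reads (ppm, normalising to library depth); IP/input recovery ratios per
  transcript class as the polymerase-specificity readout.
* **Tests** — Welch's unequal-variance t-test for cut-vs-uncut contrasts
  across replicates, the paired t-test for within-replicate ppm
  comparisons, and an exact binomial test of equal per-nucleotide read
  density.
* **Terminator scan** — RNA polymerase III terminates on ≥8 uridines in the
  nascent transcript; the scanner finds such homopolymer runs for a stated
  transcription orientation (A-runs on the `+` strand terminate a
  `-`-strand transcript), annotates upstream inverted-repeat elements, and
  compares read density upstream vs downstream of the run (with a ~20 nt
  exclusion window where homopolymer chemistry drops out). Similar density
  on both sides argues against pol-III transcribing the antisense RNA.

The experimental design is reciprocally controlled: libraries in which
locus A was cleaved serve as the "uncut" control for locus B and vice
versa.

## Worked example

```r
library(dilncseq)

cfg <- simulation_config(seed = 42, library_depth = 2e4)
sim <- simulate_experiment(cfg)   # 24 libraries: 2 pol x 2 fractions x 2 cuts x 3 reps
res <- run_pipeline(sim, seed = 1)

res$tests[res$tests$fraction == "IP",
          c("locus_id", "polymerase", "mean_fraction_cut",
            "mean_fraction_uncut", "welch_p", "paired_p")]
#>    locus_id polymerase mean_fraction_cut mean_fraction_uncut  welch_p paired_p
#> 1:     dsbA     polIII          0.000000           0.0000000 1.000000   1.0000
#> 2:     dsbB     polIII          0.000000           0.0000000 1.000000   1.0000
#> 3:     ctrl     polIII          0.000000           0.0000000 1.000000   1.0000
#> 4:     trnX     polIII          0.000000           0.0000000 1.000000   1.0000
#> 5:     dsbA      polII          0.004744           0.0005220 0.007278   0.0167
#> 6:     dsbB      polII          0.004023           0.0009675 0.077970   0.0939
#> 7:     ctrl      polII          0.000000           0.0000000 1.000000   1.0000
#> 8:     trnX      polII          0.000000           0.0000000 1.000000   1.0000
```

Cleaving the intron-containing locus `dsbA` raises its pol-II antisense
fraction roughly ten-fold (0.0047 vs 0.0005, Welch p = 0.007); the
intronless locus `dsbB` shows the weaker, here non-significant induction
expected without the intron effect; the uncut control locus and every
pol-III IP contrast are flat. The recovery table shows the IP specificity
(pol-II IP enriches CDS ~1.8x and depletes the pol-III locus to ~0.01;
pol-III IP is the mirror image, tRNA-like recovery ~9.4), and the
terminator report finds the single planted A8 run in the second intron of
`dsbA`:

```r
res$terminator$sites
#>     chrom start   end run_length transcription_strand
#> 1:   chrS  2129  2136          8                    -
res$terminator$density
#> density up 0.01393/nt (n=5) vs down 0.02528/nt (n=41); ratio 0.551, p 0.252
```

Antisense read density is statistically indistinguishable across the run
(at the default full depth of 1e5 reads/library the ratio is ~1.0), i.e. a
pol-III-terminator signature is absent from the antisense transcript.

`simulate_experiment(cfg, outdir = ...)` writes FASTA/GFF3/FASTQ/BED plus a
sample sheet and an md5 manifest; `load_experiment()` reads the same layout
back, so the pipeline runs identically from files.

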