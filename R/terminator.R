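# RNA polymerase III terminator logic: pol III terminates on a run of >= ~8
# uridines in the nascent transcript. On the genome this is a run of T on
# the '+' strand for a '+'-strand transcript and a run of A on the '+'
# strand for a '-'-strand transcript. If pol III transcribed the antisense
# RNA across such a site, read density should drop beyond it; comparing
# strand-filtered read density upstream vs downstream of the site (with a
# small exclusion window around the homopolymer, where library chemistry
# drops out) tests that prediction.

#' Find pol-III terminator candidates for a transcription orientation
#'
#' Scans a region for maximal homopolymer runs that read as poly-U in a
#' transcript of the stated strand: runs of `T` (on the `+` genome strand)
#' for a `+` transcript, runs of `A` for a `-` transcript. Only maximal runs
#' of length `>= min_run` are reported.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param region One-row table (`chrom`, `start`, `end`) to scan.
#' @param transcription_strand Strand of the hypothetical transcript.
#' @param min_run Minimum run length (nt); 8 terminates most pol-III
#'   complexes.
#' @return data.table of `terminator_site`s: `chrom`, `start`, `end`,
#'   `run_length`, `transcription_strand`.
#' @export
find_terminators <- function(genome, region, transcription_strand,
                             min_run = 8L) {
  stopifnot(transcription_strand %in% c("+", "-"))
  s <- substr(genome[[region$chrom]], region$start, region$end)
  if (region$start < 1L || region$end > nchar(genome[[region$chrom]]))
    stop("region outside genome")
  base <- if (transcription_strand == "-") "A" else "T"
  r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
  ends <- cumsum(r$lengths)
  hit <- r$values == base & r$lengths >= min_run
  data.table(chrom = region$chrom,
             start = region$start + ends[hit] - r$lengths[hit],
             end = region$start + ends[hit] - 1L,
             run_length = r$lengths[hit],
             transcription_strand = transcription_strand)
}

# can genome bases b1 (5') and b2 (3') pair in an RNA stem?
pairs_with <- function(b1, b2, allow_gu = FALSE) {
  wc <- (b1 == "A" & b2 == "T") | (b1 == "T" & b2 == "A") |
    (b1 == "G" & b2 == "C") | (b1 == "C" & b2 == "G")
  if (allow_gu)
    wc <- wc | (b1 == "G" & b2 == "T") | (b1 == "T" & b2 == "G")
  wc
}

#' Search for a hairpin element upstream of a terminator site
#'
#' Looks in the `window` nt upstream of the run (in the transcript's 5'->3'
#' direction) for the best inverted repeat: a stem of `>= min_stem`
#' complementary base pairs enclosing a loop of 3..`max_loop` nt. Ties are
#' broken by longest stem, then smallest offset from the run. This is a
#' simple maximal inverted-repeat search, not thermodynamic folding.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param site One row from [find_terminators()].
#' @param window Search window upstream of the run (nt).
#' @param min_stem Minimum stem length (bp).
#' @param max_loop Maximum loop length (nt).
#' @param allow_gu Also accept G-U wobble pairs in the stem?
#' @return One-row data.table (`stem_length`, `loop_length`, `offset`
#'   (nt between the run and the hairpin's run-proximal end), `start`,
#'   `end` genomic span) or `NULL` when no qualifying hairpin exists.
#' @export
find_hairpin <- function(genome, site, window = 60L, min_stem = 5L,
                         max_loop = 10L, allow_gu = FALSE) {
  chrom_seq <- genome[[site$chrom]]
  upstream_right <- site$transcription_strand == "-"
  if (upstream_right) {
    w_start <- site$end + 1L
    w_end <- min(nchar(chrom_seq), site$end + window)
  } else {
    w_start <- max(1L, site$start - window)
    w_end <- site$start - 1L
  }
  if (w_end < w_start) return(NULL)
  b <- strsplit(substr(chrom_seq, w_start, w_end), "", fixed = TRUE)[[1L]]
  n <- length(b)
  best <- NULL
  for (i in seq_len(n)) {   # i: innermost (loop-proximal) base of the 5' arm
    for (loop in 3:max_loop) {
      j <- i + loop + 1L    # innermost base of the 3' arm
      s <- 0L
      while (i - s >= 1L && j + s <= n &&
             pairs_with(b[i - s], b[j + s], allow_gu))
        s <- s + 1L
      if (s >= min_stem) {
        hp_start <- w_start + (i - s + 1L) - 1L
        hp_end <- w_start + (j + s - 1L) - 1L
        offset <- if (upstream_right) hp_start - site$end - 1L
                  else site$start - hp_end - 1L
        cand <- data.table(stem_length = s, loop_length = loop,
                           offset = offset, start = hp_start, end = hp_end)
        if (is.null(best) || cand$stem_length > best$stem_length ||
            (cand$stem_length == best$stem_length &&
               cand$offset < best$offset))
          best <- cand
      }
    }
  }
  best
}

#' Compare read density upstream vs downstream of a terminator
#'
#' Splits the gene span at the terminator site into an upstream and a
#' downstream segment relative to the transcript's direction, excluding a
#' window of `exclusion` nt centred on the homopolymer (where short-read
#' chemistry drops out), counts strand-filtered reads overlapping each
#' segment, and attaches the exact binomial test of equal per-nt density.
#'
#' @param alignments Alignment data.table.
#' @param gene One-row gene table (`chrom`, `start`, `end`).
#' @param site One row from [find_terminators()].
#' @param exclusion Total width (nt) of the excluded window centred on the
#'   run (never narrower than the run itself).
#' @param strand_filter `"both"`, `"+"` or `"-"`: which alignment strands
#'   count.
#' @return A `density_comparison` list: segment coordinates, counts,
#'   per-nt densities, `ratio` (upstream/downstream), and `p` from
#'   [binomial_density_test()]; densities are `NA`-flagged when no reads
#'   survive the exclusion.
#' @export
density_across_terminator <- function(alignments, gene, site,
                                      exclusion = 20L,
                                      strand_filter = "both") {
  stopifnot(site$start >= gene$start, site$end <= gene$end)
  half <- max(0L, ceiling((exclusion - (site$end - site$start + 1L)) / 2))
  ex_start <- max(gene$start, site$start - half)
  ex_end <- min(gene$end, site$end + half)
  seg_left <- c(gene$start, ex_start - 1L)
  seg_right <- c(ex_end + 1L, gene$end)
  if (site$transcription_strand == "-") {
    up <- seg_right; down <- seg_left   # '-' transcripts run right to left
  } else {
    up <- seg_left; down <- seg_right
  }
  if (up[2] < up[1] || down[2] < down[1])
    stop("zero-length segment on one side of the terminator")
  aln <- alignments[alignments$chrom == gene$chrom, , drop = FALSE]
  if (strand_filter != "both")
    aln <- aln[aln$strand == strand_filter, , drop = FALSE]
  cnt <- function(seg) sum(aln$start <= seg[2] & aln$end >= seg[1])
  up_n <- cnt(up); down_n <- cnt(down)
  up_len <- up[2] - up[1] + 1L
  down_len <- down[2] - down[1] + 1L
  bt <- binomial_density_test(up_n, up_len, down_n, down_len)
  structure(list(
    upstream = up, downstream = down,
    excluded = c(ex_start, ex_end),
    upstream_count = up_n, downstream_count = down_n,
    upstream_density = if (up_n + down_n > 0) up_n / up_len else NA_real_,
    downstream_density = if (up_n + down_n > 0) down_n / down_len
                         else NA_real_,
    ratio = if (down_n > 0) (up_n / up_len) / (down_n / down_len)
            else NA_real_,
    p = bt$p), class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat(sprintf(
    "density up %.4g/nt (n=%d) vs down %.4g/nt (n=%d); ratio %.3g, p %.3g\n",
    x$upstream_density, x$upstream_count, x$downstream_density,
    x$downstream_count, x$ratio, x$p))
  invisible(x)
}
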