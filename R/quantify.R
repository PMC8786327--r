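# Locus-level strand-resolved counting and the two per-locus statistics:
# antisense fraction, antisense/(sense+antisense), which normalises to the
# locus's own transcriptional activity; and reads-per-million genome-matching
# (ppm), which normalises to library depth. Undefined values (zero
# denominators) propagate as NA flags, never as zeros.

#' Count sense and antisense reads at a locus
#'
#' A read counts if its alignment interval overlaps the gene span (extended
#' by `flank` on both sides) by at least 1 nt; it is sense when its alignment
#' strand equals the gene strand, antisense otherwise. Each read is counted
#' at most once per locus.
#'
#' @param alignments data.table of alignments (`chrom`, `start`, `end`,
#'   `strand`).
#' @param gene One-row gene table (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param total_genome_matching Library-wide mapped-read count.
#' @param flank Extension of the counting window on each side (nt, >= 0).
#' @param library_id Library identifier carried into the result.
#' @return One-row data.table: `locus_id`, `library_id`, `sense`,
#'   `antisense`, `total_genome_matching`.
#' @export
count_locus <- function(alignments, gene, total_genome_matching = NA_integer_,
                        flank = 0L, library_id = NA_character_) {
  if (flank < 0L) stop("flank must be >= 0")
  lo <- gene$start - flank
  hi <- gene$end + flank
  ov <- alignments$chrom == gene$chrom &
    alignments$start <= hi & alignments$end >= lo
  same <- alignments$strand[ov] == gene$strand
  data.table(locus_id = gene$gene_id, library_id = library_id,
             sense = sum(same), antisense = sum(!same),
             total_genome_matching = total_genome_matching)
}

#' Antisense fraction of a locus
#'
#' `antisense / (sense + antisense)`; `NA` (an explicit undefined flag, not
#' zero) when the locus has no reads at all — the too-few-reads situation
#' must stay visible rather than be averaged away.
#'
#' @param sense,antisense Read counts, or a one-row table from
#'   [count_locus()] as the first argument.
#' @return Numeric in `[0,1]`, or `NA` when undefined.
#' @export
antisense_fraction <- function(sense, antisense = NULL) {
  if (is.null(antisense)) { antisense <- sense$antisense; sense <- sense$sense }
  tot <- sense + antisense
  ifelse(tot > 0, antisense / tot, NA_real_)
}

#' Antisense reads per million genome-matching reads
#'
#' @param antisense Antisense read count, or a one-row table from
#'   [count_locus()].
#' @param total_genome_matching Library-wide mapped-read count (> 0).
#' @return `1e6 * antisense / total_genome_matching`.
#' @export
antisense_ppm <- function(antisense, total_genome_matching = NULL) {
  if (is.null(total_genome_matching)) {
    total_genome_matching <- antisense$total_genome_matching
    antisense <- antisense$antisense
  }
  if (any(is.na(total_genome_matching)) || any(total_genome_matching <= 0))
    stop("total_genome_matching must be > 0")
  1e6 * antisense / total_genome_matching
}

# reads overlapping any interval of a class, each read counted once
class_count <- function(alignments, class_intervals) {
  if (nrow(class_intervals) == 0L) stop("empty transcript class")
  hit <- rep(FALSE, nrow(alignments))
  for (k in seq_len(nrow(class_intervals)))
    hit <- hit | (alignments$chrom == class_intervals$chrom[k] &
                    alignments$start <= class_intervals$end[k] &
                    alignments$end >= class_intervals$start[k])
  sum(hit)
}

#' IP/input recovery ratio for a transcript class
#'
#' Reads-per-million over the class in the IP divided by the same quantity
#' in the input — the polymerase-specificity readout. Zero input signal
#' yields an `NA`-flagged (undefined) recovery.
#'
#' @param class_intervals data.table of class intervals (`chrom`, `start`,
#'   `end`), e.g. one element of a simulated reference's `classes`.
#' @param ip_alignments,input_alignments Alignment tables.
#' @param ip_total,input_total Genome-matching totals of the two libraries.
#' @param class_id Identifier carried into the result.
#' @return One-row data.table: `class_id`, `ip_ppm`, `input_ppm`,
#'   `recovery`.
#' @export
recovery_ratio <- function(class_intervals, ip_alignments, ip_total,
                           input_alignments, input_total,
                           class_id = NA_character_) {
  if (ip_total <= 0 || input_total <= 0)
    stop("genome-matching totals must be > 0")
  ip_ppm <- 1e6 * class_count(ip_alignments, class_intervals) / ip_total
  input_ppm <- 1e6 * class_count(input_alignments, class_intervals) /
    input_total
  data.table(class_id = class_id, ip_ppm = ip_ppm, input_ppm = input_ppm,
             recovery = ifelse(input_ppm > 0, ip_ppm / input_ppm, NA_real_))
}

#' Locus statistics across libraries under the reciprocal-control design
#'
#' Joins per-(locus, library) counts with the sample sheet and labels each
#' row `cut` when the library's cleaved gene is this locus and `uncut`
#' otherwise — so the libraries in which the other locus was cleaved serve
#' as each locus's uncut control.
#'
#' @param counts data.table of [count_locus()] rows across libraries.
#' @param sheet Sample sheet (`library_id`, `fraction`, `polymerase`,
#'   `condition`, `replicate`).
#' @param cut_map Named character vector mapping condition id to the gene
#'   cleaved in that condition.
#' @return Tidy data.table: one row per (locus, library) with `state`
#'   (`cut`/`uncut`), `antisense_fraction` and `antisense_ppm`.
#' @export
cut_vs_uncut_table <- function(counts, sheet, cut_map) {
  sheet <- as.data.table(sheet)
  tab <- merge(as.data.table(counts), sheet, by = "library_id")
  if (nrow(tab) < nrow(counts))
    stop("sample sheet is missing libraries present in the count table")
  # the design requires a same-replicate input for every IP library
  ip <- sheet[fraction == "IP"]
  for (k in seq_len(nrow(ip)))
    if (!any(sheet$fraction == "input" &
               sheet$polymerase == ip$polymerase[k] &
               sheet$condition == ip$condition[k] &
               sheet$replicate == ip$replicate[k]))
      stop("IP library without a same-replicate input pairing: ",
           ip$library_id[k])
  # a cleavable locus is "cut" in its own condition and "uncut" in the
  # other; a never-cut locus is contrasted across the same two library
  # groups, labelled by the first condition (its contrast is a true null)
  ref_cond <- names(cut_map)[1L]
  tab[, state := fifelse(locus_id %in% cut_map,
                         fifelse(cut_map[condition] == locus_id,
                                 "cut", "uncut"),
                         fifelse(condition == ref_cond, "cut", "uncut"))]
  tab[, antisense_fraction := antisense_fraction(sense, antisense)]
  tab[, antisense_ppm := 1e6 * antisense / total_genome_matching]
  tab[, .(locus_id, library_id, fraction, polymerase, condition, replicate,
          state, sense, antisense, total_genome_matching,
          antisense_fraction, antisense_ppm)]
}
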