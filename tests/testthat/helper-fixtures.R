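# Shared fixtures: all built in code at test time.

# a small-depth simulation config for fast end-to-end tests
small_config <- function(seed = 1L, depth = 4000, ...) {
  simulation_config(seed = seed, library_depth = depth, ...)
}

random_genome <- function(n, seed = NULL, chrom = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""), chrom)
}

# independent exhaustive exact-match oracle (Biostrings, overlap-aware)
naive_hits <- function(read, genome) {
  out <- list()
  for (cn in names(genome)) {
    subj <- Biostrings::DNAString(genome[[cn]])
    for (st in c("+", "-")) {
      pat <- if (st == "+") read else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(read)))
      m <- Biostrings::matchPattern(pat, subj)
      if (length(m))
        out[[paste(cn, st)]] <- data.table::data.table(
          chrom = cn, start = Biostrings::start(m),
          end = Biostrings::end(m), strand = st)
    }
  }
  h <- data.table::rbindlist(out)
  if (nrow(h) == 0L)
    h <- data.table::data.table(chrom = character(), start = integer(),
                                end = integer(), strand = character())
  data.table::setorder(h, chrom, start, strand)[]
}

# brute-force strand-resolved locus counter
brute_count <- function(aln, gene, flank = 0L) {
  sense <- 0L; anti <- 0L
  for (i in seq_len(nrow(aln))) {
    if (aln$chrom[i] != gene$chrom) next
    if (aln$end[i] < gene$start - flank || aln$start[i] > gene$end + flank)
      next
    if (aln$strand[i] == gene$strand) sense <- sense + 1L
    else anti <- anti + 1L
  }
  c(sense = sense, antisense = anti)
}

# random alignment table over a genome
random_alignments <- function(n, chrom = "chr1", span = c(1L, 2000L),
                              len = 24L) {
  st <- sample(span[1]:(span[2] - len + 1L), n, replace = TRUE)
  data.table::data.table(
    read_id = sprintf("r%04d", seq_len(n)), chrom = chrom,
    start = st, end = st + len - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE))
}

gff3_text <- function(...) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", ...), f)
  f
}
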