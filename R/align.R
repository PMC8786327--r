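# Exact-match strand-aware read placement, re-implementing the mapping
# policy used for the NET-seq libraries: no mismatches tolerated, every
# perfect hit enumerated, and a read with several perfect hits reported only
# once, at a uniformly random one of them under a recorded seed.

#' Size-select reads
#'
#' Keeps reads whose length lies in the PAGE size-selection window
#' (20-28 nt by default). Retention counts are attached as attribute
#' `retention` (`c(input =, kept =, dropped =)`).
#'
#' @param reads data.frame with a `seq` column.
#' @param min_len,max_len Inclusive length bounds (nt).
#' @return The retained rows.
#' @export
size_select <- function(reads, min_len = 20L, max_len = 28L) {
  stopifnot(min_len <= max_len)
  len <- nchar(reads$seq)
  keep <- len >= min_len & len <= max_len
  out <- reads[keep, , drop = FALSE]
  attr(out, "retention") <- c(input = nrow(reads), kept = sum(keep),
                              dropped = sum(!keep))
  out
}

#' Build an exact-match k-mer index of the forward genome
#'
#' Every genomic k-mer that contains no `N` is recorded once per occurrence.
#' Queries seed at their first k-mer and are verified by full-string
#' comparison, so `k` only affects speed, not results, as long as
#' `k <=` the shortest query length.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param k Seed length (nt).
#' @return An `exact_index`: keyed data.table (`kmer`, `chrom`, `pos`).
#' @export
build_index <- function(genome, k = 12L) {
  if (k < 1L) stop("k must be >= 1")
  tabs <- lapply(names(genome), function(cn) {
    s <- genome[[cn]]
    n <- nchar(s)
    if (n < k) return(NULL)
    p <- seq_len(n - k + 1L)
    data.table(kmer = substring(s, p, p + k - 1L), chrom = cn, pos = p)
  })
  idx <- rbindlist(tabs)
  idx <- idx[!grepl("N", kmer, fixed = TRUE)]
  setkey(idx, kmer)
  structure(list(table = idx, k = k), class = "exact_index")
}

# Vectorised exact-matching engine: for a vector of read sequences, return
# every perfect full-length hit on both strands as a data.table
# (qid = index into `seqs`, chrom, start, end, strand).
exact_hits <- function(seqs, index, genome) {
  k <- index$k
  empty <- data.table(qid = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character())
  if (length(seqs) == 0L) return(empty)
  len <- nchar(seqs)
  ok <- len >= k & !grepl("N", seqs, fixed = TRUE)
  queries <- rbind(
    data.table(qid = which(ok), seq = seqs[ok], strand = "+"),
    data.table(qid = which(ok), seq = revcomp(seqs[ok]), strand = "-"))
  if (nrow(queries) == 0L) return(empty)
  queries[, kmer := substr(seq, 1L, k)]
  cand <- index$table[queries, on = "kmer", allow.cartesian = TRUE,
                      nomatch = NULL]
  if (nrow(cand) == 0L) return(empty)
  cand[, `:=`(start = pos, end = pos + nchar(seq) - 1L)]
  cand <- cand[end <= nchar(genome)[chrom]]
  # full-length verification against the genome (no seed-only hits)
  cand <- cand[, .SD[substring(genome[[.BY$chrom]], start, end) == seq],
               by = chrom]
  cand[, c("qid", "chrom", "start", "end", "strand")]
}

#' Find all perfect hits of one read
#'
#' Exhaustive set of full-length exact matches of the read on `+` and of its
#' reverse complement on `-`, found by k-mer seeding plus full-string
#' verification. Reads containing `N` never match.
#'
#' @param read Read sequence (character scalar).
#' @param index An `exact_index` from [build_index()].
#' @param genome Named character vector of chromosome sequences.
#' @return data.table of hits (`chrom`, `start`, `end`, `strand`).
#' @export
find_all_hits <- function(read, index, genome) {
  h <- exact_hits(read, index, genome)
  setorder(h[, qid := NULL], chrom, start, strand)[]
}

#' Pick a single reported alignment from a hit set
#'
#' Zero hits return `NULL`; one hit is reported as-is; two or more are
#' resolved by a uniformly random draw from the session RNG (seed it at the
#' pipeline level for reproducibility). `n_candidates` records the hit count
#' before assignment.
#'
#' @param read_id Read identifier.
#' @param hits data.table from [find_all_hits()].
#' @return One-row data.table (`read_id`, `chrom`, `start`, `end`, `strand`,
#'   `n_candidates`) or `NULL`.
#' @export
assign_unique <- function(read_id, hits) {
  if (nrow(hits) == 0L) return(NULL)
  pick <- if (nrow(hits) == 1L) 1L else sample.int(nrow(hits), 1L)
  data.table(read_id = read_id, hits[pick],
             n_candidates = nrow(hits))
}

#' Align a read library
#'
#' Applies the full mapping policy to a library: every perfect hit is
#' enumerated for each read and exactly one alignment per mapped read is
#' reported, chosen uniformly at random among perfect multi-mappers under
#' `seed`. `total_genome_matching` (the number of mapped reads) is the
#' normaliser for all per-million statistics.
#'
#' @param reads data.frame with `read_id` and `seq` columns (e.g. from
#'   [read_fastq()] after [size_select()]).
#' @param index An `exact_index`.
#' @param genome Named character vector of chromosome sequences.
#' @param seed Seed for multi-mapper assignment.
#' @return List: `alignments` (data.table `read_id`, `chrom`, `start`,
#'   `end`, `strand`, `n_candidates`), `n_input`, `n_mapped`,
#'   `total_genome_matching` (= `n_mapped`).
#' @export
align_library <- function(reads, index, genome, seed = 1L) {
  hits <- exact_hits(reads$seq, index, genome)
  n_input <- nrow(reads)
  if (nrow(hits) == 0L) {
    aln <- data.table(read_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_candidates = integer())
    return(list(alignments = aln, n_input = n_input, n_mapped = 0L,
                total_genome_matching = 0L))
  }
  setorder(hits, qid, chrom, start, strand) # deterministic candidate order
  set.seed(seed %% .Machine$integer.max)
  grp <- hits[, .(first = .I[1L], n = .N), by = qid]
  pick <- grp$first + floor(stats::runif(nrow(grp)) * grp$n)
  aln <- hits[pick]
  aln[, `:=`(read_id = reads$read_id[qid], n_candidates = grp$n)]
  aln[, qid := NULL]
  setcolorder(aln, c("read_id", "chrom", "start", "end", "strand",
                     "n_candidates"))
  list(alignments = aln[], n_input = n_input, n_mapped = nrow(aln),
       total_genome_matching = nrow(aln))
}

#' Align every library of a simulated or file-based experiment
#'
#' @param libraries Named list of read tables (each `read_id`, `seq`).
#' @param genome Named character vector of chromosome sequences.
#' @param seed Root seed; each library uses a distinct derived sub-seed.
#' @param k Index seed length.
#' @param size_select Apply the 20-28 nt size-selection filter first?
#' @return List per library: `alignments`, `total_genome_matching`,
#'   `n_input`, `n_mapped`; plus attribute `summary` (mapping summary
#'   data.table).
#' @export
align_libraries <- function(libraries, genome, seed = 1L, k = 12L,
                            size_select = TRUE) {
  index <- build_index(genome, k)
  out <- list()
  summ <- list()
  for (i in seq_along(libraries)) {
    lid <- names(libraries)[i]
    reads <- libraries[[i]]
    if (size_select) reads <- size_select(reads)
    sub_seed <- (seed + 7919 * i) %% .Machine$integer.max
    out[[lid]] <- align_library(reads, index, genome, seed = sub_seed)
    summ[[lid]] <- data.table(library_id = lid,
                              input_reads = nrow(libraries[[i]]),
                              size_selected = nrow(reads),
                              mapped = out[[lid]]$n_mapped,
                              total_genome_matching =
                                out[[lid]]$total_genome_matching)
  }
  attr(out, "summary") <- rbindlist(summ)
  out
}
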