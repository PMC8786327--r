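#' @import data.table
NULL

# Internal coordinate convention: 1-based, closed intervals (the
# GenomicRanges convention). GFF3 is already 1-based closed; BED I/O converts
# to/from 0-based half-open at the boundary via rtracklayer.

#' Read a genome FASTA file
#'
#' Parses a (multi-)FASTA file into a named character vector of chromosome
#' sequences, upper-cased. Sequences must be over the alphabet `A,C,G,T,N`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">"))
    stop("malformed FASTA: line 1 is not a header in ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (any(nchar(names(x)) == 0L)) stop("malformed FASTA: empty header name")
  if (any(Biostrings::width(x) == 0L)) {
    bad <- which(Biostrings::width(x) == 0L)[1L]
    stop("malformed FASTA: empty record '", names(x)[bad], "'")
  }
  g <- toupper(as.character(x))
  # keep only the first whitespace-delimited token of each header
  names(g) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(g))) stop("duplicate chromosome names in ", path)
  g
}

#' Write a genome FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line-record FASTQ reader. Every record must have a `@` header, a
#' sequence, a `+` separator and a quality string of the same length as the
#' sequence; violations are reported with the 1-based record index.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return `data.table` with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  ln <- readLines(path)
  if (length(ln) == 0L)
    return(data.table(read_id = character(), seq = character(),
                      qual = character()))
  if (length(ln) %% 4L != 0L)
    stop("truncated FASTQ record ", length(ln) %/% 4L + 1L, " in ", path)
  i <- seq(1L, length(ln), by = 4L)
  if (!all(startsWith(ln[i], "@")))
    stop("malformed FASTQ header at record ",
         which(!startsWith(ln[i], "@"))[1L], " in ", path)
  if (!all(startsWith(ln[i + 2L], "+")))
    stop("malformed FASTQ separator at record ",
         which(!startsWith(ln[i + 2L], "+"))[1L], " in ", path)
  seqs <- ln[i + 1L]; quals <- ln[i + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("sequence/quality length mismatch at record ", bad[1L], " in ", path)
  data.table(read_id = sub("^@", "", sub("\\s.*$", "", ln[i])),
             seq = toupper(seqs), qual = quals)
}

#' Write a FASTQ file
#'
#' @param reads `data.frame` with columns `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) && any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch")
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  out <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+",
                         reads$qual))
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features (exon parentage resolved through the
#' `Parent` attribute) into a set of gene models. Intron intervals are derived
#' as the gaps between consecutive exons. Gene strand must be `+` or `-`;
#' unstranded gene features are rejected because sense/antisense calls depend
#' on them.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` object: list with a `genes` data.table
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`, `n_exons`, `has_intron`)
#'   and named lists `exons` / `introns` of per-gene interval data.tables,
#'   exon rows ordered by genomic start.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  as_models(
    genes = data.table(
      gene_id = as.character(gr$ID[gr$type == "gene"]),
      chrom   = as.character(GenomicRanges::seqnames(gr[gr$type == "gene"])),
      start   = GenomicRanges::start(gr[gr$type == "gene"]),
      end     = GenomicRanges::end(gr[gr$type == "gene"]),
      strand  = as.character(GenomicRanges::strand(gr[gr$type == "gene"]))),
    exons = data.table(
      parent = as.character(unlist(gr$Parent[gr$type == "exon"])),
      start  = GenomicRanges::start(gr[gr$type == "exon"]),
      end    = GenomicRanges::end(gr[gr$type == "exon"])))
}

# Assemble and validate a gene_models object from flat gene and exon tables.
as_models <- function(genes, exons) {
  start <- NULL # NSE
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene feature without '+'/'-' strand: ",
         genes$gene_id[!genes$strand %in% c("+", "-")][1L])
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
  exl <- list(); inl <- list()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k]
    ex <- exons[exons$parent == g$gene_id][order(start)]
    if (nrow(ex) == 0L) ex <- data.table(parent = g$gene_id,
                                         start = g$start, end = g$end)
    if (any(ex$start < g$start | ex$end > g$end))
      stop("exon outside gene span for ", g$gene_id)
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("overlapping exons for ", g$gene_id)
    exl[[g$gene_id]] <- ex[, c("start", "end")]
    inl[[g$gene_id]] <-
      if (nrow(ex) > 1L)
        data.table(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
      else data.table(start = integer(), end = integer())
  }
  genes$n_exons <- vapply(exl[genes$gene_id], nrow, 1L)
  genes$has_intron <- genes$n_exons >= 2L
  structure(list(genes = genes, exons = exl, introns = inl),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes (",
      sum(x$genes$has_intron), "intron-containing )\n")
  print(x$genes)
  invisible(x)
}

#' Write gene models to GFF3
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  rows <- character()
  for (k in seq_len(nrow(g))) {
    gid <- g$gene_id[k]
    rows <- c(rows, sprintf("%s\tdilncseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                            g$chrom[k], g$start[k], g$end[k], g$strand[k], gid))
    ex <- models$exons[[gid]]
    rows <- c(rows, sprintf(
      "%s\tdilncseq\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
      g$chrom[k], ex$start, ex$end, g$strand[k], gid, seq_len(nrow(ex)), gid))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Write intervals or alignments as BED6
#'
#' Converts internal 1-based closed intervals to BED's 0-based half-open
#' convention. The `name` column is taken from `read_id` or `name` if present
#' (else "."); `score` from `n_candidates` or `score` (else 0).
#'
#' @param x `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  if (nrow(x) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  nm <- if ("read_id" %in% names(x)) x$read_id
        else if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  sc <- if ("n_candidates" %in% names(x)) x$n_candidates
        else if ("score" %in% names(x)) x$score else rep(0L, nrow(x))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     x$chrom, x$start - 1L, x$end, nm, sc, x$strand), path)
  invisible(path)
}

#' Read a BED6 (or BED3) file into internal intervals
#'
#' @param path Path to a BED file.
#' @return `data.table` with `chrom`, `start`, `end` (1-based closed),
#'   `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  if (file.size(path) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character()))
  gr <- rtracklayer::import(path, format = "bed")
  data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (is.null(gr$name)) rep(".", length(gr)) else gr$name,
    score = if (is.null(gr$score)) rep(0, length(gr)) else gr$score,
    strand = as.character(GenomicRanges::strand(gr)))
}

#' Write a count (or any rectangular) table as TSV
#'
#' Rows are sorted by `locus_id` then `library_id` when those columns exist,
#' so output is deterministic regardless of computation order.
#'
#' @param table `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(table, path) {
  tab <- as.data.table(table)
  keys <- intersect(c("locus_id", "library_id"), names(tab))
  if (length(keys)) data.table::setorderv(tab, keys)
  fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Read a TSV table written by [write_counts_tsv()]
#'
#' @param path Path to the TSV file.
#' @return `data.table`.
#' @export
read_counts_tsv <- function(path) fread(path, sep = "\t")

# reverse complement of plain character sequences (vectorised)
revcomp <- function(seq) {
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq)))
  names(out) <- NULL
  out
}
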