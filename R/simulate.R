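# Generative model for polymerase-specific NET-seq libraries.
#
# Latent state: polymerase active-site positions on a toy genome. Sense
# transcription places polymerases along each gene with a promoter-proximal
# pausing mixture; a DNA double-strand break adds antisense polymerases
# between the TSS and the cut site. Each polymerase protects a 23-26 nt
# benzonase footprint ending at its active site. Libraries are the footprint
# pool plus cytoplasmic contamination (a fixed miRNA, rRNA fragments, mature
# mRNA fragments); an IP library is a per-read Bernoulli thinning of its
# input pool (capture p_t for the tagged polymerase, background p_b for
# everything else).

#' Simulation configuration
#'
#' Collects every generative parameter of the NET-seq experiment simulator.
#' Component rates are weights normalised so that the expected total input
#' library size equals `library_depth`.
#'
#' Defaults encode the study design being emulated: two reciprocally cut
#' pol-II loci (one intron-containing, one intronless), an uncut control
#' locus, one pol-III locus, promoter-proximal pausing, 23-26 nt footprints,
#' abundant rRNA plus a fixed 23-nt miRNA contaminating the chromatin
#' fraction, and break-induced antisense transcription whose magnitude is
#' boosted when the cut gene contains introns.
#'
#' @param seed Integer root seed; all randomness derives from it.
#' @param genome_length Toy genome length (nt).
#' @param genes data.frame of gene specs: `gene_id`, `length` (nt), `strand`,
#'   `n_exons`, `polymerase` (`"polII"`/`"polIII"`), `weight` (expected sense
#'   polymerases per library, before depth normalisation).
#' @param pause_weight Mixture weight of the promoter-proximal pause
#'   component in `[0,1]`.
#' @param pause_offset Pause centre, nt downstream of the TSS.
#' @param pause_sd Pause position standard deviation (nt).
#' @param footprint_lengths Named probability vector over footprint lengths;
#'   support must lie in 23..26 nt.
#' @param size_range Length window retained by size selection (nt).
#' @param conditions Named character vector mapping condition id to the
#'   gene cleaved in that condition (the reciprocal-control design: each
#'   locus's "uncut" libraries are those in which the other locus was cut).
#' @param cut_offset Named numeric: cut-site distance from the TSS (nt) for
#'   each cleavable gene.
#' @param antisense_weight Expected antisense (break-induced) polymerases at
#'   an uncut locus, same weight scale as `genes$weight`.
#' @param induction_factor Fold induction of antisense transcription when a
#'   locus is cut (>= 1).
#' @param spliceosome_boost Extra antisense fold applied only when the cut
#'   gene contains at least one intron (>= 1).
#' @param dilnc_polymerase Which polymerase transcribes the break-induced
#'   antisense RNA in the simulation ground truth.
#' @param mirna_weight Expected copies of the fixed 23-nt miRNA contaminant.
#' @param rrna_weight Expected rRNA fragment contaminant reads.
#' @param mrna_contamination Mature spliced-mRNA contamination of the input,
#'   as a fraction of each pol-II gene's sense weight (exon-restricted
#'   fragments).
#' @param ip_capture Probability `p_t` that an IP retains a footprint of the
#'   tagged polymerase.
#' @param ip_background Probability `p_b` (< `p_t`) that an IP retains any
#'   other read (contamination or the untagged polymerase's footprints).
#' @param n_replicates Replicates per condition.
#' @param library_depth Expected total reads per input library.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    genome_length = 12000L,
    genes = data.frame(
      gene_id = c("dsbA", "dsbB", "ctrl", "trnX"),
      length = c(2400L, 1200L, 1500L, 300L),
      strand = c("+", "-", "+", "+"),
      n_exons = c(3L, 1L, 2L, 1L),
      polymerase = c("polII", "polII", "polII", "polIII"),
      weight = c(20000, 15000, 15000, 10000)),
    pause_weight = 0.5,
    pause_offset = 40,
    pause_sd = 10,
    footprint_lengths = c("23" = 0.2, "24" = 0.3, "25" = 0.3, "26" = 0.2),
    size_range = c(20L, 28L),
    conditions = c(cutA = "dsbA", cutB = "dsbB"),
    cut_offset = c(dsbA = 2000, dsbB = 900),
    antisense_weight = 10,
    induction_factor = 5,
    spliceosome_boost = 2,
    dilnc_polymerase = "polII",
    mirna_weight = 5000,
    rrna_weight = 30000,
    mrna_contamination = 0.1,
    ip_capture = 0.8,
    ip_background = 0.005,
    n_replicates = 3L,
    library_depth = 1e5) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  cfg$genes <- as.data.table(genes)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  g <- cfg$genes
  chk <- function(ok, field, why)
    if (!ok) stop("invalid config field '", field, "': ", why, call. = FALSE)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed", "one integer")
  chk(all(g$strand %in% c("+", "-")), "genes$strand", "must be '+' or '-'")
  chk(all(g$polymerase %in% c("polII", "polIII")), "genes$polymerase",
      "must be 'polII' or 'polIII'")
  chk(all(g$weight >= 0), "genes$weight", "rates must be >= 0")
  chk(all(g$n_exons >= 1L), "genes$n_exons", "at least one exon")
  chk(cfg$pause_weight >= 0 && cfg$pause_weight <= 1, "pause_weight",
      "must lie in [0,1]")
  fl <- as.integer(names(cfg$footprint_lengths))
  chk(!anyNA(fl) && all(fl >= 23L & fl <= 26L) &&
        abs(sum(cfg$footprint_lengths) - 1) < 1e-8, "footprint_lengths",
      "probabilities over lengths within 23..26 summing to 1")
  chk(cfg$size_range[1] <= cfg$size_range[2], "size_range", "min <= max")
  chk(all(cfg$conditions %in% g$gene_id), "conditions",
      "cut gene not in gene table")
  chk(all(names(cfg$cut_offset) %in% g$gene_id), "cut_offset",
      "gene not in gene table")
  for (gid in names(cfg$cut_offset))
    chk(cfg$cut_offset[[gid]] > 0 &&
          cfg$cut_offset[[gid]] < g$length[g$gene_id == gid],
        "cut_offset", paste0("outside span of ", gid))
  chk(cfg$antisense_weight >= 0, "antisense_weight", "must be >= 0")
  chk(cfg$induction_factor >= 1, "induction_factor", "must be >= 1")
  chk(cfg$spliceosome_boost >= 1, "spliceosome_boost", "must be >= 1")
  chk(cfg$dilnc_polymerase %in% c("polII", "polIII"), "dilnc_polymerase",
      "must be 'polII' or 'polIII'")
  chk(cfg$mirna_weight >= 0 && cfg$rrna_weight >= 0 &&
        cfg$mrna_contamination >= 0, "contamination", "rates must be >= 0")
  chk(cfg$ip_capture > 0 && cfg$ip_capture <= 1, "ip_capture", "in (0,1]")
  chk(cfg$ip_background >= 0 && cfg$ip_background < cfg$ip_capture,
      "ip_background", "must satisfy 0 <= p_b < p_t")
  chk(cfg$n_replicates >= 1L, "n_replicates", "at least 1")
  chk(cfg$library_depth > 0, "library_depth", "must be > 0")
  invisible(cfg)
}

# Absolute expected counts per library for every generative component,
# normalised so the baseline (uncut antisense) expectation sums to
# library_depth.
component_rates <- function(cfg) {
  g <- cfg$genes
  mrna_w <- ifelse(g$polymerase == "polII",
                   cfg$mrna_contamination * g$weight, 0)
  total_w <- sum(g$weight) + sum(mrna_w) + cfg$mirna_weight +
    cfg$rrna_weight + cfg$antisense_weight
  f <- cfg$library_depth / total_w
  list(lambda_sense = stats::setNames(g$weight * f, g$gene_id),
       lambda_mrna = stats::setNames(mrna_w * f, g$gene_id),
       lambda_mirna = cfg$mirna_weight * f,
       lambda_rrna = cfg$rrna_weight * f,
       lambda_antisense0 = cfg$antisense_weight * f)
}

#' Build the toy genome and its annotation
#'
#' Plants the configured genes on a random genome (gap-separated, so the
#' genome is effectively repeat-free at read length), together with an rRNA
#' interval, a 23-nt miRNA locus, and — inside the second intron of the first
#' intron-containing cleavable gene — a homopolymer run of eight A/T on the
#' sense strand (a pol-III terminator for the antisense transcript) preceded,
#' in the antisense transcript's 5'->3' direction, by a perfect 6-bp inverted
#' repeat. Also derives transcript-class interval sets (CDS-like exons,
#' introns, the pol-III locus).
#'
#' @param cfg A `sim_config`.
#' @return A `sim_reference` list: `genome` (named character), `models`
#'   (`gene_models`), `classes` (named list of interval data.tables),
#'   `mirna` (locus + sequence), `rrna` (interval), `cut_sites` (named
#'   genomic positions), `terminator` (planted run coordinates).
#' @export
build_toy_genome <- function(cfg) {
  set.seed(cfg$seed)
  chrom <- "chrS"
  g <- copy(cfg$genes)
  g$chrom <- chrom
  gap <- 500L
  pos <- gap
  g$start <- g$end <- NA_integer_
  for (k in seq_len(nrow(g))) {
    g$start[k] <- pos + 1L
    g$end[k] <- pos + g$length[k]
    pos <- g$end[k] + gap
  }
  rrna <- data.table(chrom = chrom, start = pos + 1L, end = pos + 1000L)
  pos <- rrna$end + gap
  mir <- data.table(chrom = chrom, start = pos + 1L, end = pos + 23L,
                    strand = "+")
  pos <- mir$end + gap
  if (pos > cfg$genome_length)
    stop("invalid config field 'genome_length': too short for the gene set (",
         pos, " nt needed)")
  seq <- paste(sample(c("A", "C", "G", "T"), cfg$genome_length,
                      replace = TRUE), collapse = "")

  # exon/intron structure: fixed 200-nt introns, exons share the remainder
  exons <- list()
  for (k in seq_len(nrow(g))) {
    n <- g$n_exons[k]; L <- g$length[k]
    iw <- if (n > 1L) 200L else 0L
    ew <- (L - (n - 1L) * iw) %/% n
    if (n > 1L && ew < 50L) stop("gene ", g$gene_id[k], " too short for ",
                                 n, " exons")
    st <- g$start[k] + (seq_len(n) - 1L) * (ew + iw)
    en <- st + ew - 1L
    en[n] <- g$end[k]
    exons[[g$gene_id[k]]] <- data.table(parent = g$gene_id[k],
                                        start = st, end = en)
  }
  models <- as_models(
    genes = g[, c("gene_id", "chrom", "start", "end", "strand")],
    exons = rbindlist(exons))

  # plant the terminator motif for the antisense transcript of the cut gene
  term <- NULL
  cut_gene <- cfg$conditions[[1L]]
  gi <- models$genes[models$genes$gene_id == cut_gene]
  introns <- models$introns[[cut_gene]]
  if (nrow(introns) >= 1L) {
    intr <- introns[min(2L, nrow(introns))]
    run_base <- if (gi$strand == "+") "A" else "T" # poly-U in the antisense RNA
    run_start <- intr$start + (intr$end - intr$start + 1L - 8L) %/% 2L
    run <- strrep(run_base, 8L)
    # non-run bases on both sides keep the planted run maximal
    seq <- plant(seq, run_start - 1L, paste0("C", run, "C"))
    # hairpin element upstream of the run in the antisense transcript
    stem <- "GGCCGC"; hp <- paste0(stem, "ATAA", revcomp(stem))
    anti <- flip_strand(gi$strand)
    hp_start <- if (anti == "-") run_start + 8L + 10L
                else run_start - 10L - nchar(hp)
    seq <- plant(seq, hp_start, hp)
    term <- data.table(chrom = chrom, start = run_start,
                       end = run_start + 7L, run_length = 8L,
                       transcription_strand = anti)
  }
  mirna_seq <- substr(seq, mir$start, mir$end)

  pol2 <- models$genes$gene_id[g$polymerase == "polII"]
  pol3 <- models$genes$gene_id[g$polymerase == "polIII"]
  cls <- list(
    cds = rbindlist(lapply(pol2, function(id)
      data.table(chrom = chrom, models$exons[[id]],
                 name = id, strand = g$strand[g$gene_id == id]))),
    intron = rbindlist(lapply(pol2, function(id)
      if (nrow(models$introns[[id]]))
        data.table(chrom = chrom, models$introns[[id]], name = id,
                   strand = g$strand[g$gene_id == id]) else NULL)),
    trna = rbindlist(lapply(pol3, function(id)
      data.table(chrom = chrom,
                 start = g$start[g$gene_id == id],
                 end = g$end[g$gene_id == id], name = id,
                 strand = g$strand[g$gene_id == id]))))

  cut_sites <- vapply(names(cfg$cut_offset), function(gid) {
    gg <- models$genes[models$genes$gene_id == gid]
    if (gg$strand == "+") gg$start + as.integer(cfg$cut_offset[[gid]])
    else gg$end - as.integer(cfg$cut_offset[[gid]])
  }, 1)

  structure(list(genome = stats::setNames(seq, chrom), chrom = chrom,
                 models = models, classes = cls,
                 mirna = cbind(mir, seq = mirna_seq), rrna = rrna,
                 cut_sites = cut_sites, terminator = term),
            class = "sim_reference")
}

# overwrite genome sequence with `motif` starting at 1-based position `at`
plant <- function(seq, at, motif) {
  substr(seq, at, at + nchar(motif) - 1L) <- motif
  seq
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Sample sense-strand polymerase positions for one gene
#'
#' Draws `Poisson(lambda)` active-site positions from the pausing mixture
#' `w_p * N(TSS + d_p, sd_p)` (truncated to the gene span) `+ (1 - w_p) *
#' Uniform(span)`, on the gene's strand.
#'
#' @param gene One-row gene table (`chrom`, `start`, `end`, `strand`,
#'   `polymerase`).
#' @param lambda Expected polymerase count.
#' @param pause_weight,pause_offset,pause_sd Pausing mixture parameters.
#' @return data.table of polymerase positions (`chrom`, `position`, `strand`,
#'   `polymerase`, `origin = "sense"`).
#' @export
sample_sense_positions <- function(gene, lambda, pause_weight = 0,
                                   pause_offset = 40, pause_sd = 10) {
  n <- stats::rpois(1L, lambda)
  if (n == 0L)
    return(data.table(chrom = character(), position = integer(),
                      strand = character(), polymerase = character(),
                      origin = character()))
  paused <- stats::runif(n) < pause_weight
  pos <- integer(n)
  pos[!paused] <- sample.int(gene$end - gene$start + 1L,
                             sum(!paused), replace = TRUE) + gene$start - 1L
  np <- sum(paused)
  if (np > 0L) {
    centre <- if (gene$strand == "+") gene$start + pause_offset
              else gene$end - pause_offset
    draw <- round(stats::rnorm(np, centre, pause_sd))
    bad <- draw < gene$start | draw > gene$end
    while (any(bad)) { # truncate by resampling
      draw[bad] <- round(stats::rnorm(sum(bad), centre, pause_sd))
      bad <- draw < gene$start | draw > gene$end
    }
    pos[paused] <- as.integer(draw)
  }
  data.table(chrom = gene$chrom, position = pos, strand = gene$strand,
             polymerase = gene$polymerase, origin = "sense")
}

#' Sample break-induced antisense polymerase positions
#'
#' Antisense polymerases are placed uniformly between the TSS and the cut
#' site, on the strand opposite the gene, with expected count
#' `lambda0 * induction_factor * spliceosome_boost` when the locus is cut
#' (the intron boost applies only to intron-containing genes) and `lambda0`
#' otherwise.
#'
#' @param gene One-row gene table (needs `has_intron`).
#' @param cut_site Genomic position of the double-strand break.
#' @param lambda0 Baseline expected antisense polymerases (uncut).
#' @param induction_factor,spliceosome_boost Fold factors (>= 1).
#' @param is_cut Is this the cleaved locus in this library?
#' @param polymerase Which polymerase carries the antisense transcript.
#' @return data.table of polymerase positions with `origin = "dilncRNA"`.
#' @export
sample_dilncrna_positions <- function(gene, cut_site, lambda0,
                                      induction_factor = 1,
                                      spliceosome_boost = 1,
                                      is_cut = FALSE,
                                      polymerase = "polII") {
  stopifnot(cut_site >= gene$start, cut_site <= gene$end)
  boost <- if (isTRUE(gene$has_intron)) spliceosome_boost else 1
  lambda <- lambda0 * (if (is_cut) induction_factor * boost else 1)
  n <- stats::rpois(1L, lambda)
  if (n == 0L)
    return(data.table(chrom = character(), position = integer(),
                      strand = character(), polymerase = character(),
                      origin = character()))
  rng <- if (gene$strand == "+") c(gene$start, cut_site)
         else c(cut_site, gene$end)
  pos <- sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) + rng[1] - 1L
  data.table(chrom = gene$chrom, position = as.integer(pos),
             strand = flip_strand(gene$strand), polymerase = polymerase,
             origin = "dilncRNA")
}

#' Convert polymerase positions to benzonase footprints
#'
#' Each footprint is the 3'-terminal `L` nt of the nascent transcript, `L`
#' drawn from the footprint-length law, so the genomic interval ends at the
#' active site on the transcription strand. Read sequences are the genome
#' subsequence, reverse-complemented for `-`-strand transcription. Positions
#' whose footprint would leave the chromosome are discarded; the discard
#' count is attached as attribute `n_discarded`.
#'
#' @param positions data.table from the position samplers.
#' @param genome Named character vector of chromosome sequences.
#' @param footprint_lengths Named probability vector over lengths.
#' @return data.table of reads: `chrom`, `start`, `end`, `strand`, `seq`,
#'   `origin`, `polymerase`.
#' @export
positions_to_footprints <- function(positions, genome, footprint_lengths) {
  if (nrow(positions) == 0L) {
    out <- data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      seq = character(), origin = character(),
                      polymerase = character())
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  lens <- as.integer(names(footprint_lengths))
  L <- lens[sample.int(length(lens), nrow(positions), replace = TRUE,
                       prob = footprint_lengths)]
  plus <- positions$strand == "+"
  start <- fifelse(plus, positions$position - L + 1L, positions$position)
  end <- fifelse(plus, positions$position, positions$position + L - 1L)
  clen <- nchar(genome)[positions$chrom]
  keep <- start >= 1L & end <= clen
  fp <- data.table(chrom = positions$chrom[keep], start = start[keep],
                   end = end[keep], strand = positions$strand[keep],
                   origin = positions$origin[keep],
                   polymerase = positions$polymerase[keep])
  # '-'-strand sequences come from a precomputed reverse-complement genome
  genome_rc <- revcomp(genome)
  n <- nchar(genome)[fp$chrom]
  seq <- character(nrow(fp))
  p <- fp$strand == "+"
  seq[p] <- substring(genome[fp$chrom[p]], fp$start[p], fp$end[p])
  seq[!p] <- substring(genome_rc[match(fp$chrom[!p], names(genome))],
                       n[!p] - fp$end[!p] + 1L, n[!p] - fp$start[!p] + 1L)
  set(fp, j = "seq", value = seq)
  setcolorder(fp, c("chrom", "start", "end", "strand", "seq", "origin",
                    "polymerase"))
  attr(fp, "n_discarded") <- sum(!keep)
  fp
}

# Contamination reads of the chromatin ("input") fraction: the fixed 23-nt
# miRNA, rRNA fragments, and exon-restricted mature-mRNA fragments.
contamination_reads <- function(ref, cfg, rates) {
  out <- list()
  n_mir <- stats::rpois(1L, rates$lambda_mirna)
  if (n_mir > 0L)
    out$mir <- data.table(chrom = ref$mirna$chrom,
                          start = rep(ref$mirna$start, n_mir),
                          end = rep(ref$mirna$end, n_mir), strand = "+",
                          seq = ref$mirna$seq, origin = "contamination",
                          polymerase = NA_character_)
  n_rr <- stats::rpois(1L, rates$lambda_rrna)
  if (n_rr > 0L) {
    L <- sample(cfg$size_range[1]:cfg$size_range[2], n_rr, replace = TRUE)
    st <- ref$rrna$start +
      floor(stats::runif(n_rr) * (ref$rrna$end - ref$rrna$start - L + 2L))
    out$rrna <- data.table(chrom = ref$rrna$chrom, start = as.integer(st),
                           end = as.integer(st + L - 1L), strand = "+",
                           seq = NA_character_, origin = "contamination",
                           polymerase = NA_character_)
  }
  g <- ref$models$genes
  for (gid in g$gene_id) {
    lam <- rates$lambda_mrna[[gid]]
    if (is.null(lam) || lam <= 0) next
    n <- stats::rpois(1L, lam)
    if (n == 0L) next
    ex <- ref$models$exons[[gid]]
    w <- ex$end - ex$start + 1L
    pick <- sample.int(nrow(ex), n, replace = TRUE, prob = w)
    L <- pmin(sample(cfg$size_range[1]:cfg$size_range[2], n, replace = TRUE),
              w[pick])
    st <- ex$start[pick] +
      floor(stats::runif(n) * (w[pick] - L + 1L))
    out[[gid]] <- data.table(chrom = g$chrom[g$gene_id == gid],
                             start = as.integer(st),
                             end = as.integer(st + L - 1L),
                             strand = g$strand[g$gene_id == gid],
                             seq = NA_character_, origin = "contamination",
                             polymerase = NA_character_)
  }
  dt <- rbindlist(out)
  if (nrow(dt)) {
    miss <- is.na(dt$seq)
    dt[miss, seq := substring(ref$genome[chrom], start, end)]
    dt[miss & strand == "-", seq := revcomp(seq)]
  }
  dt
}

# Latent read pool of one input library (one condition x replicate x
# tagged-cell-line): every benzonase footprint plus contamination.
simulate_pool <- function(ref, cfg, condition) {
  rates <- component_rates(cfg)
  g <- merge(ref$models$genes,
             as.data.table(cfg$genes)[, c("gene_id", "polymerase")],
             by = "gene_id", sort = FALSE)
  pos <- list()
  for (k in seq_len(nrow(g))) {
    gene <- g[k]
    pos[[length(pos) + 1L]] <- sample_sense_positions(
      gene, rates$lambda_sense[[gene$gene_id]], cfg$pause_weight,
      cfg$pause_offset, cfg$pause_sd)
    if (gene$gene_id %in% names(ref$cut_sites))
      pos[[length(pos) + 1L]] <- sample_dilncrna_positions(
        gene, ref$cut_sites[[gene$gene_id]], rates$lambda_antisense0,
        cfg$induction_factor, cfg$spliceosome_boost,
        is_cut = identical(cfg$conditions[[condition]], gene$gene_id),
        polymerase = cfg$dilnc_polymerase)
  }
  fp <- positions_to_footprints(rbindlist(pos), ref$genome,
                                cfg$footprint_lengths)
  pool <- rbind(fp, contamination_reads(ref, cfg, rates))
  gene_tag <- rep(".", nrow(pool))
  for (k in seq_len(nrow(g)))
    gene_tag[pool$start <= g$end[k] & pool$end >= g$start[k]] <-
      g$gene_id[k]
  set(pool, j = "gene", value = gene_tag)
  pool
}

#' Assemble one sequencing library from a latent read pool
#'
#' An `input` library contains every pool read. An `IP` library keeps each
#' footprint with probability `ip_capture` when its polymerase matches the
#' entry's tag and `ip_background` otherwise, and keeps each contamination
#' read with probability `ip_background` (per-read Bernoulli thinning, so the
#' IP read multiset is a subset of the input's). Read ids encode the latent
#' origin for test introspection; analysis code never parses them.
#'
#' @param entry One-row sample-sheet data.frame (`library_id`, `fraction`,
#'   `polymerase`).
#' @param pool Latent pool from the simulator.
#' @param cfg A `sim_config`.
#' @return data.table with `read_id`, `seq`, `qual` (plus the pool's latent
#'   columns, retained for tests).
#' @export
assemble_library <- function(entry, pool, cfg) {
  keep <- if (entry$fraction == "input") rep(TRUE, nrow(pool)) else {
    p <- ifelse(!is.na(pool$polymerase) &
                  pool$polymerase == entry$polymerase,
                cfg$ip_capture, cfg$ip_background)
    stats::runif(nrow(pool)) < p
  }
  lib <- pool[keep]
  lib[, read_id := sprintf("%s:%06d|%s|%s|%s", entry$library_id, .I,
                           origin, gene, fifelse(is.na(polymerase), "na",
                                                 polymerase))]
  lib[, qual := strrep("I", nchar(seq))]
  lib[]
}

#' Simulate a full NET-seq experiment
#'
#' Builds the toy reference, then for every (tagged polymerase, condition,
#' replicate) generates a latent chromatin pool and assembles the requested
#' input/IP libraries. Each pool uses a sub-seed derived from the root seed,
#' so replicates are independent and the whole experiment is reproducible.
#'
#' @param cfg A `sim_config`.
#' @param outdir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, per-class BED files, one FASTQ per library,
#'   `sample_sheet.tsv` and an md5 `manifest.tsv`.
#' @param fractions Which fractions to assemble (`"input"`, `"IP"`).
#' @param polymerases Which tagged cell lines to simulate.
#' @return List: `ref`, `cfg`, `sheet` (sample sheet), `libraries` (named
#'   list of read data.tables).
#' @export
simulate_experiment <- function(cfg, outdir = NULL,
                                fractions = c("input", "IP"),
                                polymerases = c("polII", "polIII")) {
  ref <- build_toy_genome(cfg)
  design <- CJ(polymerase = polymerases,
               condition = names(cfg$conditions),
               replicate = seq_len(cfg$n_replicates))
  sheet <- list(); libs <- list()
  for (k in seq_len(nrow(design))) {
    d <- design[k]
    sub_seed <- (cfg$seed + 104729 * k) %% .Machine$integer.max
    set.seed(sub_seed)
    pool <- simulate_pool(ref, cfg, d$condition)
    for (fr in fractions) {
      lid <- sprintf("%s_%s_%s_r%d", d$polymerase, fr, d$condition,
                     d$replicate)
      entry <- data.table(library_id = lid, fraction = fr,
                          polymerase = d$polymerase,
                          condition = d$condition, replicate = d$replicate,
                          fastq_path = paste0(lid, ".fastq"))
      libs[[lid]] <- assemble_library(entry, pool, cfg)
      sheet[[lid]] <- entry
    }
  }
  sheet <- rbindlist(sheet)
  out <- list(ref = ref, cfg = cfg, sheet = sheet, libraries = libs)
  if (!is.null(outdir)) write_experiment(out, outdir)
  out
}

write_experiment <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_genome(sim$ref$genome, file.path(outdir, "genome.fa"))
  write_gene_models(sim$ref$models, file.path(outdir, "annotation.gff3"))
  for (cl in names(sim$ref$classes)) {
    x <- sim$ref$classes[[cl]]
    write_bed6(x, file.path(outdir, paste0("class_", cl, ".bed")))
  }
  for (lid in names(sim$libraries))
    write_fastq(sim$libraries[[lid]],
                file.path(outdir, paste0(lid, ".fastq")))
  # fastq paths are kept relative to the sheet so the directory is portable
  fwrite(sim$sheet, file.path(outdir, "sample_sheet.tsv"), sep = "\t")
  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest", files)]
  man <- data.table(file = basename(files), md5 = tools::md5sum(files),
                    seed = sim$cfg$seed)
  fwrite(man, file.path(outdir, "manifest.tsv"), sep = "\t")
  invisible(outdir)
}
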