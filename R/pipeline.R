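# End-to-end orchestration: simulate (or load) -> size-select -> align ->
# count -> locus statistics -> replicate tests -> recovery ratios ->
# terminator scan, with one root seed driving every random stage through
# named sub-streams.

#' Load a file-based experiment
#'
#' Reads the genome, annotation and every FASTQ listed in a sample sheet
#' (columns `library_id`, `fraction`, `polymerase`, `condition`,
#' `replicate`, `fastq_path`) into the in-memory layout produced by
#' [simulate_experiment()].
#'
#' @param sheet_path Path to the sample-sheet TSV.
#' @param genome_path Path to the genome FASTA.
#' @param annotation_path Path to the GFF3 annotation.
#' @return List with `genome`, `models`, `sheet`, `libraries`.
#' @export
load_experiment <- function(sheet_path, genome_path, annotation_path) {
  sheet <- fread(sheet_path, sep = "\t",
                 colClasses = list(character = "condition"))
  need <- c("library_id", "fraction", "polymerase", "condition",
            "replicate", "fastq_path")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  ip <- sheet[sheet$fraction == "IP"]
  for (k in seq_len(nrow(ip)))
    if (!any(sheet$fraction == "input" &
               sheet$polymerase == ip$polymerase[k] &
               sheet$condition == ip$condition[k] &
               sheet$replicate == ip$replicate[k]))
      stop("IP library without same-replicate input: ", ip$library_id[k])
  paths <- ifelse(file.exists(sheet$fastq_path), sheet$fastq_path,
                  file.path(dirname(sheet_path), sheet$fastq_path))
  libs <- lapply(stats::setNames(paths, sheet$library_id), read_fastq)
  list(genome = read_genome(genome_path),
       models = read_gene_models(annotation_path),
       sheet = sheet, libraries = libs)
}

#' Run the full analysis pipeline
#'
#' Aligns every library under the exact-match policy, counts sense and
#' antisense reads per locus, materialises the reciprocal-control
#' cut-vs-uncut table, runs Welch's test on the antisense fraction and the
#' paired test on antisense ppm for each (locus, polymerase, fraction)
#' contrast, computes IP/input recovery per transcript class, and scans the
#' cleaved gene for antisense-orientation pol-III terminators with a read
#' density comparison.
#'
#' @param experiment List from [simulate_experiment()] or
#'   [load_experiment()]. Needs `genome` (or `ref$genome`), `models` (or
#'   `ref$models`), `sheet`, `libraries`.
#' @param cut_map Named vector condition -> cleaved gene id; defaults to
#'   the simulation config's `conditions` when present.
#' @param classes Optional named list of class interval tables for recovery;
#'   defaults to the simulated reference's classes when present.
#' @param flank Counting-window extension (nt).
#' @param seed Root seed for multi-mapper assignment.
#' @param outdir Optional output directory for TSV/plain-text results.
#' @return A `netseq_results` list: `mapping_summary`, `counts`,
#'   `locus_table`, `tests`, `recovery`, `terminator`.
#' @export
run_pipeline <- function(experiment, cut_map = NULL, classes = NULL,
                         flank = 0L, seed = 1L, outdir = NULL) {
  genome <- experiment$genome %||% experiment$ref$genome
  models <- experiment$models %||% experiment$ref$models
  cut_map <- cut_map %||% experiment$cfg$conditions
  classes <- classes %||% experiment$ref$classes
  sheet <- as.data.table(experiment$sheet)

  aln <- align_libraries(experiment$libraries, genome, seed = seed)
  summary <- attr(aln, "summary")

  counts <- rbindlist(lapply(names(aln), function(lid) {
    rbindlist(lapply(seq_len(nrow(models$genes)), function(k)
      count_locus(aln[[lid]]$alignments, models$genes[k],
                  aln[[lid]]$total_genome_matching, flank = flank,
                  library_id = lid)))
  }))

  locus_table <- cut_vs_uncut_table(counts, sheet, cut_map)
  tests <- contrast_tests(locus_table)
  recovery <- recovery_table(aln, sheet, classes)
  cut_sites <- experiment$ref$cut_sites
  terminator <- terminator_report(
    genome, models, aln, sheet, gene_id = cut_map[[1L]],
    conditions = names(cut_map)[cut_map == cut_map[[1L]]],
    cut_site = if (!is.null(cut_sites)) cut_sites[[cut_map[[1L]]]])

  res <- structure(list(mapping_summary = summary, counts = counts,
                        locus_table = locus_table, tests = tests,
                        recovery = recovery, terminator = terminator),
                   class = "netseq_results")
  if (!is.null(outdir)) write_results(res, outdir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Welch test on antisense fraction and paired test on antisense ppm for
# every (locus, polymerase, fraction) cut-vs-uncut contrast.
contrast_tests <- function(locus_table) {
  tab <- as.data.table(locus_table)
  grid <- unique(tab[, c("locus_id", "polymerase", "fraction")])
  out <- list()
  for (k in seq_len(nrow(grid))) {
    g <- grid[k]
    sub <- tab[locus_id == g$locus_id & polymerase == g$polymerase &
                 fraction == g$fraction]
    if (!all(c("cut", "uncut") %in% sub$state)) next
    setorder(sub, replicate)
    fr_cut <- sub[state == "cut", antisense_fraction]
    fr_unc <- sub[state == "uncut", antisense_fraction]
    ppm_cut <- sub[state == "cut", antisense_ppm]
    ppm_unc <- sub[state == "uncut", antisense_ppm]
    w <- if (sum(!is.na(fr_cut)) >= 2 && sum(!is.na(fr_unc)) >= 2)
      welch_ttest(fr_cut[!is.na(fr_cut)], fr_unc[!is.na(fr_unc)]) else NULL
    p <- if (length(ppm_cut) == length(ppm_unc) && length(ppm_cut) >= 2)
      paired_ttest(ppm_cut, ppm_unc) else NULL
    out[[k]] <- data.table(
      locus_id = g$locus_id, polymerase = g$polymerase,
      fraction = g$fraction,
      mean_fraction_cut = mean(fr_cut, na.rm = TRUE),
      mean_fraction_uncut = mean(fr_unc, na.rm = TRUE),
      welch_t = if (is.null(w)) NA_real_ else w$t,
      welch_df = if (is.null(w)) NA_real_ else w$df,
      welch_p = if (is.null(w)) NA_real_ else w$p,
      mean_ppm_cut = mean(ppm_cut), mean_ppm_uncut = mean(ppm_unc),
      paired_t = if (is.null(p)) NA_real_ else p$t,
      paired_p = if (is.null(p)) NA_real_ else p$p)
  }
  rbindlist(out)
}

# per-(polymerase, condition, replicate) IP/input recovery for every class
recovery_table <- function(aln, sheet, classes) {
  if (is.null(classes) || length(classes) == 0L) return(NULL)
  sheet <- as.data.table(sheet)
  ip <- sheet[fraction == "IP"]
  out <- list()
  for (k in seq_len(nrow(ip))) {
    inp <- sheet[fraction == "input" & polymerase == ip$polymerase[k] &
                   condition == ip$condition[k] &
                   replicate == ip$replicate[k]]
    if (nrow(inp) == 0L) next
    a_ip <- aln[[ip$library_id[k]]]
    a_in <- aln[[inp$library_id[1L]]]
    if (a_ip$total_genome_matching == 0L ||
          a_in$total_genome_matching == 0L) next
    for (cl in names(classes)) {
      r <- recovery_ratio(classes[[cl]], a_ip$alignments,
                          a_ip$total_genome_matching, a_in$alignments,
                          a_in$total_genome_matching, class_id = cl)
      out[[length(out) + 1L]] <- data.table(
        polymerase = ip$polymerase[k], condition = ip$condition[k],
        replicate = ip$replicate[k], r)
    }
  }
  rbindlist(out)
}

#' Terminator report for one gene
#'
#' Scans the gene for pol-III terminator candidates in the antisense
#' orientation, annotates the best site with a hairpin search, and compares
#' antisense-strand read density across it using the pooled cleaved-state
#' pol-II IP alignments (the libraries expected to carry the break-induced
#' antisense transcript).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param models A `gene_models` object.
#' @param aln Alignment list from [align_libraries()].
#' @param sheet Sample sheet.
#' @param gene_id Gene to scan (the cleaved locus).
#' @param conditions Optional condition ids whose libraries carry the
#'   break-induced transcript (default: all).
#' @param cut_site Optional genomic position of the double-strand break.
#'   When given, the scan and the density comparison are restricted to the
#'   interval between the TSS and the break — the region the break-induced
#'   antisense transcript actually covers; segments outside it would only
#'   dilute the density estimates.
#' @param min_run,exclusion See [find_terminators()] and
#'   [density_across_terminator()].
#' @return List: `sites`, `hairpin`, `density` (or `NULL` components when
#'   nothing qualifies).
#' @export
terminator_report <- function(genome, models, aln, sheet, gene_id,
                              conditions = NULL, cut_site = NULL,
                              min_run = 8L, exclusion = 20L) {
  idx <- which(models$genes$gene_id == gene_id) # outside DT[] scoping
  if (length(idx) == 0L) stop("gene_id not in annotation: ", gene_id)
  gene <- models$genes[idx]
  if (!is.null(cut_site)) {
    if (gene$strand == "+") gene$end <- min(gene$end, as.integer(cut_site))
    else gene$start <- max(gene$start, as.integer(cut_site))
  }
  anti <- flip_strand(gene$strand)
  sites <- find_terminators(genome, gene, anti, min_run = min_run)
  if (nrow(sites) == 0L)
    return(list(gene_id = gene_id, sites = sites, hairpin = NULL,
                density = NULL))
  site <- sites[which.max(sites$run_length)]
  hp <- find_hairpin(genome, site)
  sheet <- as.data.table(sheet)
  if (!is.null(conditions)) sheet <- sheet[condition %in% conditions]
  lids <- sheet[fraction == "IP" & polymerase == "polII",
                library_id]
  pooled <- rbindlist(lapply(intersect(lids, names(aln)), function(l)
    aln[[l]]$alignments))
  dens <- if (!is.null(pooled) && nrow(pooled))
    density_across_terminator(pooled, gene, site, exclusion = exclusion,
                              strand_filter = anti) else NULL
  list(gene_id = gene_id, sites = sites, hairpin = hp, density = dens)
}

write_results <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_counts_tsv(res$mapping_summary,
                   file.path(outdir, "mapping_summary.tsv"))
  write_counts_tsv(res$counts, file.path(outdir, "locus_counts.tsv"))
  write_counts_tsv(res$locus_table, file.path(outdir, "locus_table.tsv"))
  write_counts_tsv(res$tests, file.path(outdir, "tests.tsv"))
  if (!is.null(res$recovery))
    write_counts_tsv(res$recovery, file.path(outdir, "recovery.tsv"))
  rep <- c(sprintf("terminator scan: gene %s", res$terminator$gene_id),
           sprintf("  sites found: %d", nrow(res$terminator$sites)))
  if (!is.null(res$terminator$density)) {
    d <- res$terminator$density
    rep <- c(rep, sprintf(
      "  density upstream %.4g/nt (n=%d) vs downstream %.4g/nt (n=%d)",
      d$upstream_density, d$upstream_count, d$downstream_density,
      d$downstream_count),
      sprintf("  ratio %.3g, binomial p %.3g", d$ratio, d$p))
  }
  writeLines(rep, file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' @export
print.netseq_results <- function(x, ...) {
  cat("NET-seq pipeline results\n")
  cat("  libraries:", nrow(x$mapping_summary), "\n")
  cat("  loci:", length(unique(x$counts$locus_id)), "\n")
  cat("  contrasts tested:", nrow(x$tests), "\n")
  invisible(x)
}
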