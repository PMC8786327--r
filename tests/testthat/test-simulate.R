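test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(ip_background = 0.9), "ip_background")
  expect_error(simulation_config(
    footprint_lengths = c("22" = 0.5, "23" = 0.5)), "footprint_lengths")
  expect_error(simulation_config(cut_offset = c(dsbA = 5000, dsbB = 900)),
               "cut_offset")
  expect_error(simulation_config(induction_factor = 0.5),
               "induction_factor")
  expect_error(simulation_config(pause_weight = 1.2), "pause_weight")
})

test_that("the toy genome is deterministic and carries the planted features", {
  cfg <- small_config(seed = 5)
  ref1 <- build_toy_genome(cfg)
  ref2 <- build_toy_genome(cfg)
  expect_identical(ref1$genome, ref2$genome)
  expect_identical(ref1$models$genes, ref2$models$genes)

  # planted A8 in the second intron of the cut gene, sense strand
  term <- ref1$terminator
  run <- substr(ref1$genome[[term$chrom]], term$start, term$end)
  expect_identical(run, strrep("A", 8))
  intr2 <- ref1$models$introns$dsbA[2L]
  expect_true(term$start >= intr2$start && term$end <= intr2$end)
  # the run is maximal: flanking bases break it
  expect_false(substr(ref1$genome, term$start - 1L, term$start - 1L) == "A")
  expect_false(substr(ref1$genome, term$end + 1L, term$end + 1L) == "A")

  # class files cover exons, introns and the pol-III locus
  expect_setequal(names(ref1$classes), c("cds", "intron", "trna"))
  expect_true(nrow(ref1$classes$intron) >= 1L)
})

test_that("gene count in the annotation follows the config", {
  cfg <- small_config(
    seed = 2,
    genes = data.frame(gene_id = c("gA", "gB"),
                       length = c(1000L, 800L), strand = c("+", "-"),
                       n_exons = c(2L, 1L),
                       polymerase = c("polII", "polII"),
                       weight = c(1000, 1000)),
    conditions = c(cutA = "gA", cutB = "gB"),
    cut_offset = c(gA = 800, gB = 600))
  ref <- build_toy_genome(cfg)
  f <- tempfile(fileext = ".gff3")
  write_gene_models(ref$models, f)
  expect_equal(sum(grepl("\tgene\t", readLines(f))), 2L)
})

test_that("sense positions follow the pausing mixture law", {
  cfg <- small_config(seed = 9)
  ref <- build_toy_genome(cfg)
  gene <- cbind(ref$models$genes[1L], polymerase = "polII")

  expect_equal(nrow(sample_sense_positions(gene, 0)), 0L)

  set.seed(42)
  # pure body component: uniform over the span
  u <- sample_sense_positions(gene, 1e4, pause_weight = 0)
  ks <- suppressWarnings(stats::ks.test(
    u$position, "punif", gene$start - 0.5, gene$end + 0.5))
  expect_gt(ks$p.value, 0.001)
  expect_true(all(u$position >= gene$start & u$position <= gene$end))
  expect_true(all(u$strand == gene$strand))

  # pure pause component: concentrated at TSS + offset
  p <- sample_sense_positions(gene, 1e4, pause_weight = 1,
                              pause_offset = 40, pause_sd = 5)
  centre <- gene$start + 40
  expect_gt(mean(abs(p$position - centre) <= 15), 0.95)
})

test_that("antisense induction scales with cutting and intron presence", {
  cfg <- small_config(seed = 13)
  ref <- build_toy_genome(cfg)
  g <- merge(ref$models$genes,
             data.table::as.data.table(cfg$genes)[, c("gene_id", "polymerase")],
             by = "gene_id", sort = FALSE)
  gA <- g[g$gene_id == "dsbA"] # has introns
  gB <- g[g$gene_id == "dsbB"] # intronless

  expect_equal(nrow(sample_dilncrna_positions(
    gA, ref$cut_sites[["dsbA"]], 0, is_cut = FALSE)), 0L)

  set.seed(7)
  nA <- replicate(500, nrow(sample_dilncrna_positions(
    gA, ref$cut_sites[["dsbA"]], lambda0 = 10, induction_factor = 4,
    spliceosome_boost = 2, is_cut = TRUE)))
  nB <- replicate(500, nrow(sample_dilncrna_positions(
    gB, ref$cut_sites[["dsbB"]], lambda0 = 10, induction_factor = 4,
    spliceosome_boost = 2, is_cut = TRUE)))
  # intronless gene is unaffected by the spliceosome boost: means 80 vs 40
  expect_equal(mean(nA) / mean(nB), 2, tolerance = 0.15)
  # and its expected count does not move with the boost at all
  nB2 <- replicate(500, nrow(sample_dilncrna_positions(
    gB, ref$cut_sites[["dsbB"]], lambda0 = 10, induction_factor = 4,
    spliceosome_boost = 50, is_cut = TRUE)))
  expect_equal(mean(nB2) / mean(nB), 1, tolerance = 0.15)

  # positions confined to [TSS, cut site], on the opposite strand
  x <- sample_dilncrna_positions(gA, ref$cut_sites[["dsbA"]], 200,
                                 is_cut = FALSE)
  expect_true(all(x$position >= gA$start &
                    x$position <= ref$cut_sites[["dsbA"]]))
  expect_true(all(x$strand == "-"))
})

test_that("footprints are the 3'-terminal stump ending at the active site", {
  genome <- c(chr1 = strrep("ACGT", 25))
  law <- c("23" = 1)
  plus <- data.table::data.table(chrom = "chr1", position = 50L,
                                 strand = "+", polymerase = "polII",
                                 origin = "sense")
  fp <- positions_to_footprints(plus, genome, law)
  expect_equal(c(fp$start, fp$end), c(28L, 50L))
  expect_identical(fp$seq, unname(substr(genome, 28, 50)))

  minus <- data.table::data.table(chrom = "chr1", position = 50L,
                                  strand = "-", polymerase = "polII",
                                  origin = "sense")
  fm <- positions_to_footprints(minus, genome, law)
  expect_equal(c(fm$start, fm$end), c(50L, 72L))
  expect_identical(
    fm$seq,
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(genome, 50, 72)))))

  # all emitted lengths lie in the protected-footprint window 23-26 nt
  set.seed(1)
  many <- data.table::data.table(chrom = "chr1",
                                 position = sample(30:70, 200, TRUE),
                                 strand = "+", polymerase = "polII",
                                 origin = "sense")
  lens <- with(positions_to_footprints(
    many, genome, c("23" = .25, "24" = .25, "25" = .25, "26" = .25)),
    end - start + 1L)
  expect_true(all(lens >= 23L & lens <= 26L))

  # out-of-bounds footprints are discarded and logged
  edge <- data.table::data.table(chrom = "chr1", position = 5L,
                                 strand = "+", polymerase = "polII",
                                 origin = "sense")
  fe <- positions_to_footprints(edge, genome, law)
  expect_equal(nrow(fe), 0L)
  expect_equal(attr(fe, "n_discarded"), 1L)
})

test_that("IP assembly is Bernoulli thinning of the input pool", {
  cfg <- small_config(seed = 21, depth = 6000)
  ref <- build_toy_genome(cfg)
  set.seed(77)
  pool <- dilncseq:::simulate_pool(ref, cfg, "cutA")

  # p_t = 1, p_b = 0: the IP is exactly the tagged polymerase's footprints
  cfg1 <- small_config(seed = 21, depth = 6000, ip_capture = 1,
                       ip_background = 0)
  entry <- data.table::data.table(library_id = "ip", fraction = "IP",
                                  polymerase = "polII")
  ip <- assemble_library(entry, pool, cfg1)
  expect_equal(nrow(ip),
               sum(!is.na(pool$polymerase) & pool$polymerase == "polII"))

  # conservation: the IP read multiset is a subset of the input's
  inp <- assemble_library(
    data.table::data.table(library_id = "in", fraction = "input",
                           polymerase = "polII"), pool, cfg)
  ip2 <- assemble_library(entry, pool, cfg)
  key <- function(x) paste(x$chrom, x$start, x$end, x$strand, x$seq)
  expect_true(all(table(key(ip2)) <= table(key(inp))[names(table(key(ip2)))]))

  # contamination thinning: IP contamination ~ Binomial(n_input, p_b)
  cfg3 <- small_config(seed = 21, depth = 6000, ip_background = 0.2)
  set.seed(5)
  n_in <- sum(pool$origin == "contamination")
  n_ip <- sum(assemble_library(entry, pool, cfg3)$origin == "contamination")
  ci <- stats::qbinom(c(0.0005, 0.9995), n_in, 0.2)
  expect_gte(n_ip, ci[1]); expect_lte(n_ip, ci[2])
})

test_that("experiment simulation is deterministic and has the full design", {
  cfg <- small_config(seed = 31, depth = 1500)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$libraries, s2$libraries)
  # 2 polymerases x 2 fractions x 2 conditions x 3 replicates
  expect_equal(length(s1$libraries), 24L)
  expect_equal(nrow(s1$sheet), 24L)

  cfg1 <- small_config(seed = 31, depth = 1500, n_replicates = 1L)
  expect_equal(length(simulate_experiment(cfg1)$libraries), 8L)

  # written outputs are byte-identical under the same seed
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_experiment(cfg1, outdir = d1)
  simulate_experiment(cfg1, outdir = d2)
  m1 <- read_counts_tsv(file.path(d1, "manifest.tsv"))
  m2 <- read_counts_tsv(file.path(d2, "manifest.tsv"))
  expect_identical(m1$md5, m2$md5)
})
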