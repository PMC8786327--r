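region_of <- function(genome, chrom = names(genome)[1])
  data.table::data.table(chrom = chrom, start = 1L,
                         end = nchar(genome[[chrom]]))

test_that("terminator runs are detected at the 8-nt threshold, maximally", {
  g <- c(chr1 = paste0(strrep("C", 30), strrep("A", 8), strrep("C", 30)))
  s <- find_terminators(g, region_of(g), "-")
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start, s$end, s$run_length), c(31L, 38L, 8L))

  # 7-mer rejected for the same orientation
  g7 <- c(chr1 = paste0(strrep("C", 30), strrep("A", 7), strrep("C", 30)))
  expect_equal(nrow(find_terminators(g7, region_of(g7), "-")), 0L)

  # an A-run terminates only a '-' transcript; a T-run only a '+' one
  expect_equal(nrow(find_terminators(g, region_of(g), "+")), 0L)
  gt <- c(chr1 = paste0(strrep("C", 10), strrep("T", 9), strrep("G", 10)))
  st <- find_terminators(gt, region_of(gt), "+")
  expect_equal(st$run_length, 9L) # maximal run, no nested sub-runs
  expect_equal(nrow(st), 1L)
})

test_that("run detection matches a regex oracle and is revcomp-symmetric", {
  set.seed(91)
  for (i in 1:50) {
    # A/T-rich alphabet so runs actually occur
    s <- paste(sample(c("A", "T", "A", "T", "C", "G"), 300, TRUE),
               collapse = "")
    g <- c(chr1 = s)
    got <- find_terminators(g, region_of(g), "-", min_run = 5L)
    m <- gregexpr("A{5,}", s)[[1L]]
    if (m[1L] == -1L) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, as.integer(m))
      expect_equal(got$run_length, attr(m, "match.length"))
    }
    # symmetry: '-' sites on s mirror '+' sites on revcomp(s)
    rc <- c(chr1 = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s))))
    flip <- find_terminators(rc, region_of(rc), "+", min_run = 5L)
    n <- nchar(s)
    expect_equal(sort(n - got$end + 1L), sort(flip$start))
    expect_equal(sort(got$run_length), sort(flip$run_length))
  }
})

test_that("a planted inverted repeat upstream of the run is recovered", {
  # '-' transcript: upstream of the run lies at higher genomic coordinates
  arm <- "GCGGCA"
  hp <- paste0(arm, "TTT", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(arm))))
  g <- c(chr1 = paste0(strrep("C", 20), strrep("A", 8), strrep("C", 6),
                       hp, strrep("C", 20)))
  site <- find_terminators(g, region_of(g), "-")
  found <- find_hairpin(g, site, window = 40L, min_stem = 5L, max_loop = 6L)
  expect_equal(found$stem_length, 6L)
  expect_equal(found$loop_length, 3L)
  expect_equal(found$offset, 6L)

  # for a '+' transcript the element must sit left of the run instead
  gt <- c(chr1 = paste0(strrep("C", 20), hp, strrep("C", 6), strrep("T", 8),
                        strrep("C", 20)))
  site_t <- find_terminators(gt, region_of(gt), "+")
  found_t <- find_hairpin(gt, site_t, window = 40L, min_stem = 5L,
                          max_loop = 6L)
  expect_equal(found_t$stem_length, 6L)
  expect_equal(found_t$offset, 6L)

  # random sequence essentially never contains a 12-bp perfect stem
  set.seed(17)
  misses <- sum(vapply(1:20, function(i) {
    gr <- random_genome(120)
    sr <- data.table::data.table(chrom = "chr1", start = 100L, end = 107L,
                                 transcription_strand = "+")
    is.null(find_hairpin(gr, sr, window = 90L, min_stem = 12L))
  }, TRUE))
  expect_gte(misses, 19L)
})

test_that("hairpin detection is invariant under revcomp + strand flip", {
  set.seed(19)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    g <- c(chr1 = s)
    site <- data.table::data.table(chrom = "chr1", start = 120L,
                                   end = 127L, transcription_strand = "-")
    a <- find_hairpin(g, site, window = 80L, min_stem = 4L)
    rc <- c(chr1 = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s))))
    n <- nchar(s)
    site_rc <- data.table::data.table(
      chrom = "chr1", start = n - 127L + 1L, end = n - 120L + 1L,
      transcription_strand = "+")
    b <- find_hairpin(rc, site_rc, window = 80L, min_stem = 4L)
    expect_equal(is.null(a), is.null(b))
    if (!is.null(a)) {
      expect_equal(a$stem_length, b$stem_length)
      expect_equal(a$loop_length, b$loop_length)
      expect_equal(a$offset, b$offset)
    }
  }
})

test_that("density comparison splits the gene at the site with exclusion", {
  gene <- data.table::data.table(gene_id = "g", chrom = "chr1",
                                 start = 1L, end = 2000L, strand = "+")
  site <- data.table::data.table(chrom = "chr1", start = 997L, end = 1004L,
                                 transcription_strand = "-")
  set.seed(29)
  st <- sample(1:1977, 800, replace = TRUE)
  aln <- data.table::data.table(read_id = as.character(1:800),
                                chrom = "chr1", start = st, end = st + 23L,
                                strand = "-")
  d <- density_across_terminator(aln, gene, site, exclusion = 20L,
                                 strand_filter = "-")
  # '-' transcription: upstream is the right (high-coordinate) segment
  expect_equal(d$upstream[1], 1011L)
  expect_equal(d$downstream[2], 990L)
  expect_equal(d$excluded, c(991L, 1010L))
  expect_equal(d$ratio, 1, tolerance = 0.35)
  expect_gt(d$p, 0.001)

  # strand filter removes opposite-strand reads entirely
  plus <- data.table::data.table(read_id = "p", chrom = "chr1",
                                 start = 1500L, end = 1523L, strand = "+")
  d2 <- density_across_terminator(plus, gene, site, strand_filter = "-")
  expect_true(is.na(d2$upstream_density))
  expect_true(is.na(d2$p))

  # reads only inside the exclusion window -> undefined densities
  inside <- data.table::data.table(read_id = "i", chrom = "chr1",
                                   start = 995L, end = 1008L, strand = "-")
  d3 <- density_across_terminator(inside, gene, site, strand_filter = "-")
  expect_true(is.na(d3$upstream_density) && is.na(d3$downstream_density))

  # a site flush against the gene edge has no upstream segment
  edge <- data.table::data.table(chrom = "chr1", start = 1990L, end = 1997L,
                                 transcription_strand = "-")
  expect_error(density_across_terminator(aln, gene, edge), "zero-length")
})
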