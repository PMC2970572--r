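# Format readers/writers, strand-aware midpoint binning and subsampling.

write_lines_tmp <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("BED fragments are read, validated and sorted", {
  path <- write_lines_tmp(c("chr1\t500\t650",
                            "chr1\t100\t250",
                            "chr2\t10\t160"))
  frags <- read_fragments_bed(path)
  expect_length(frags, 3)
  expect_identical(GenomicRanges::start(frags), c(101L, 501L, 11L))

  bad <- write_lines_tmp(c("chr1\t100\t250", "chr1\t300\t300"))
  err <- tryCatch(read_fragments_bed(bad), error = identity)
  expect_s3_class(err, "mirtss_parse_error")
  expect_match(conditionMessage(err), "line\\(s\\) 2")

  oob <- write_lines_tmp(c("chr1\t100\t250", "chr1\t900\t1100"))
  expect_error(read_fragments_bed(oob, genome_layout("chr1", 1000)),
               class = "mirtss_parse_error")
})

test_that("gzip and plain encodings of a BED file load identically", {
  lines <- c("chr1\t500\t650", "chr1\t100\t250", "chr2\t10\t160")
  plain <- write_lines_tmp(lines)
  gzpath <- tempfile(fileext = ".bed.gz")
  con <- gzfile(gzpath, "w"); writeLines(lines, con); close(con)
  expect_identical(read_fragments_bed(plain), read_fragments_bed(gzpath))
})

test_that("fragment round-trip write -> read is identity", {
  frags <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
                                  IRanges::IRanges(c(101, 501, 11),
                                                   c(250, 650, 160)))
  path <- tempfile(fileext = ".bed")
  write_fragments_bed(frags, path)
  expect_identical(read_fragments_bed(path), GenomicRanges::sort(frags))
})

test_that("gene dialects convert coordinates and place the TSS by strand", {
  # refFlat is 0-based half-open; internal representation is 1-based closed
  rf <- write_lines_tmp(c(
    "gplus\tgplus\tchr1\t+\t100\t200\t100\t200\t2\t100,160\t140,200",
    "gminus\tgminus\tchr1\t-\t500\t900\t500\t900\t1\t500\t900"),
    ext = ".refflat")
  genes <- read_genes(rf, "refFlat")
  expect_identical(genes$span_start, c(101, 501))
  expect_identical(genes$span_end, c(200, 900))
  expect_identical(genes$tss, c(101, 900))  # minus-strand TSS = span end
  expect_identical(genes$exon_starts[1], "101,161")

  # GTF is already 1-based closed
  gtf <- write_lines_tmp(paste0(
    "chr1\ttest\tgene\t101\t200\t.\t+\t.\t",
    'gene_id "gA";'), ext = ".gtf")
  gg <- read_genes(gtf, "GTF")
  expect_identical(gg$span_start, 101)
  expect_identical(gg$tss, 101)

  # round-trip through the refFlat writer
  path2 <- tempfile(fileext = ".refflat")
  write_genes_refflat(genes, path2)
  expect_identical(read_genes(path2, "refFlat"), genes)
})

test_that("microRNA GFF3 and BED dialects agree and round-trip", {
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "chr2\tmb\tmiRNA_primary_transcript\t101\t200\t.\t+\t.\tID=mirA;Name=mirA",
    "chr2\tmb\tmiRNA_primary_transcript\t501\t580\t.\t-\t.\tID=mirB;Name=mirB"),
    ext = ".gff3")
  m <- read_mirnas(gff, "GFF3")
  expect_identical(m$mirna_id, c("mirA", "mirB"))
  expect_identical(m$pre_start, c(101, 501))
  # same records as BED (0-based start)
  bed <- write_lines_tmp(c("chr2\t100\t200\tmirA\t0\t+",
                           "chr2\t500\t580\tmirB\t0\t-"))
  mb <- read_mirnas(bed, "BED")
  expect_equal(m, mb)
  path <- tempfile(fileext = ".gff3")
  write_mirnas_gff3(m, path)
  expect_equal(read_mirnas(path, "GFF3"), m)
})

test_that("midpoint binning follows the documented strand and boundary rules", {
  anchor <- 10001L  # 1-based; anchor base a0 = 10000 in 0-based coordinates
  mk <- function(mid0, chrom = "chr1") {
    # fragment of length 150 whose 0-based midpoint is mid0
    GenomicRanges::GRanges(chrom, IRanges::IRanges(mid0 - 75 + 1, mid0 + 75))
  }
  # plus strand: midpoint at anchor+10 -> offset 0
  p <- bin_counts(mk(10010), "chr1", anchor, "+")
  expect_identical(p$counts[p$offsets == 0L], 1L)
  expect_identical(sum(p$counts), 1L)
  # minus strand: midpoint at anchor+300 -> offset -1 (upstream)
  p <- bin_counts(mk(10300), "chr1", anchor, "-")
  expect_identical(p$counts[p$offsets == -1L], 1L)
  # midpoint exactly on a boundary goes to the downstream bin on both strands
  p <- bin_counts(mk(10100), "chr1", anchor, "+")
  expect_identical(p$counts[p$offsets == 1L], 1L)
  p <- bin_counts(mk(10100), "chr1", anchor, "-")
  expect_identical(p$counts[p$offsets == 0L], 1L)
  # unknown chromosome rejected when a layout is given
  expect_error(bin_counts(mk(10010), "chrX", anchor, "+",
                          layout = genome_layout("chr1", 1e6)),
               class = "mirtss_invalid_input")
})

test_that("binning matches a naive per-bin scan and is translation-equivariant", {
  set.seed(33)
  n <- 400
  mid0 <- sort(sample.int(30000, n, replace = TRUE)) + 5000
  frags <- GenomicRanges::GRanges("chr1", IRanges::IRanges(mid0 - 74, mid0 + 75))
  for (strand in c("+", "-")) {
    prof <- bin_counts(frags, "chr1", 20001L, strand, n_up = 10, n_down = 10)
    oracle <- naive_bin_counts(frags, "chr1", 20001L, strand, -10:10)
    expect_identical(as.numeric(prof$counts), oracle)
    expect_lte(sum(prof$counts), length(frags))
  }
  # shifting anchor and fragments together leaves the profile unchanged
  shift <- 1234L
  shifted <- GenomicRanges::shift(frags, shift)
  p0 <- bin_counts(frags, "chr1", 20001L, "+")
  p1 <- bin_counts(shifted, "chr1", 20001L + shift, "+")
  expect_identical(p0$counts, p1$counts)
})

test_that("subsampling is seeded, exact and degenerate-safe", {
  frags <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:100 * 10, width = 50))
  expect_identical(subsample_fragments(frags, 100, seed = 1), GenomicRanges::sort(frags))
  expect_length(subsample_fragments(frags, 0, seed = 1), 0)
  s1 <- subsample_fragments(frags, 40, seed = 9)
  s2 <- subsample_fragments(frags, 40, seed = 9)
  expect_identical(s1, s2)
  expect_length(s1, 40)
  expect_error(subsample_fragments(frags, 101, seed = 1),
               class = "mirtss_invalid_input")
})

test_that("interval and score tracks load and query correctly", {
  cpg <- write_lines_tmp(c("chr1\t100\t200", "chr1\t500\t650"))
  islands <- read_interval_track(cpg)
  expect_length(islands, 2)
  # brute-force overlap for three query regions
  regions <- data.frame(chrom = "chr1",
                        start = c(150, 300, 640),
                        end = c(180, 420, 700))
  expect_equal(cpg_overlap_fraction(regions, islands), 2 / 3)
  expect_equal(cpg_overlap_fraction(regions[2, ], islands), 0)

  # wig and bedGraph encodings of the same step function score identically
  wig <- write_lines_tmp(c("fixedStep chrom=chr1 start=101 step=10 span=10",
                           "1.5", "2.5", "3.5"), ext = ".wig")
  bg <- write_lines_tmp(c("chr1\t100\t110\t1.5",
                          "chr1\t110\t120\t2.5",
                          "chr1\t120\t130\t3.5"), ext = ".bedGraph")
  tw <- read_score_track(wig)
  tb <- read_score_track(bg)
  at <- c(101, 105, 111, 125, 999)
  expect_identical(track_scores(tw, "chr1", at), track_scores(tb, "chr1", at))
  expect_identical(track_scores(tb, "chr1", at), c(1.5, 1.5, 2.5, 3.5, 0))
  expect_equal(track_interval_mean(tb, "chr1", 101, 120), 2.0)
  # empty track -> zero everywhere
  empty <- read_score_track(write_lines_tmp(character(), ext = ".bedGraph"))
  expect_identical(track_scores(empty, "chr1", at), rep(0, 5))
})
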