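# MicroRNA classification, the upstream delta-F scan, empirical FDR calling,
# regulatory-region delineation and cross-condition detection patterns.

test_that("microRNAs are classified by strict intron containment", {
  # toy 3-exon gene: exons [1000,1200], [2000,2200], [3000,3200]
  genes <- data.frame(
    gene_id = "host", chrom = "chr1", strand = "+", tss = 1000,
    span_start = 1000, span_end = 3200,
    exon_starts = "1000,2000,3000", exon_ends = "1200,2200,3200",
    stringsAsFactors = FALSE)
  mirnas <- data.frame(
    mirna_id = c("between_genes", "in_intron2", "straddles_boundary"),
    chrom = "chr1", strand = "+",
    pre_start = c(5000, 2300, 2150),
    pre_end = c(5080, 2380, 2250),
    stringsAsFactors = FALSE)
  cl <- classify_mirnas(mirnas, genes)
  expect_identical(cl$klass, c("intergenic", "intronic", "intergenic"))
  # host strand is ignored by default but can be required
  minus_mirna <- data.frame(mirna_id = "anti", chrom = "chr1", strand = "-",
                            pre_start = 2300, pre_end = 2380,
                            stringsAsFactors = FALSE)
  expect_identical(classify_mirnas(minus_mirna, genes)$klass, "intronic")
  expect_identical(classify_mirnas(minus_mirna, genes,
                                   host_strand = "same")$klass, "intergenic")
})

test_that("span-containment fallback fires with a warning when exons are absent", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      tss = 1000, span_start = 1000, span_end = 3200,
                      stringsAsFactors = FALSE)
  mirnas <- data.frame(mirna_id = "m", chrom = "chr1", strand = "+",
                       pre_start = 2000, pre_end = 2080,
                       stringsAsFactors = FALSE)
  expect_warning(cl <- classify_mirnas(mirnas, genes), "exon")
  expect_identical(cl$klass, "intronic")
})

test_that("empirical FDR matches hand enumeration, caps and is monotone", {
  # clean separation: candidate beats all background
  expect_identical(empirical_fdr(4, c(-5, -1, 3)), 0)
  # hand-computed ratio form
  expect_identical(empirical_fdr(c(2.5, 3.5), c(1, 2, 3, 4)), c(0.5, 0.5))
  # exceedance form on the same input
  expect_identical(empirical_fdr(c(2.5, 3.5), c(1, 2, 3, 4),
                                 method = "exceedance"), c(0.5, 0.25))
  # a candidate below every background score is capped at 1
  expect_identical(empirical_fdr(c(-10, 9), c(1, 2, 3, 4))[1], 1)
  # monotone non-increasing in the score after the step-up pass
  set.seed(5)
  cand <- rnorm(60); bg <- rnorm(80)
  fdr <- empirical_fdr(cand, bg)
  expect_true(all(fdr >= 0 & fdr <= 1))
  expect_true(all(diff(fdr[order(cand)]) <= 0 + 1e-15))
  expect_error(empirical_fdr(numeric(0), bg), class = "mirtss_empty_pool")
  expect_error(empirical_fdr(cand, numeric(0)), class = "mirtss_empty_pool")
})

test_that("regulatory region follows the 90%-decay rule", {
  h <- hidden_params(50, 2, 10, 0.5, 0.25)
  # ln(10)/0.5 = 4.6 -> 4 upstream bins; ln(10)/0.25 = 9.2 -> 9 downstream
  rr <- regulatory_region(h, tss_coord = 100001, strand = "+", chrom = "chr1")
  expect_identical(rr$n_up, 4L)
  expect_identical(rr$n_down, 9L)
  expect_identical(rr$width, (4 + 1 + 9) * 200)
  # instant decay leaves the single TSS bin
  h_fast <- hidden_params(50, 2, 10, 1e6, 1e6)
  rr2 <- regulatory_region(h_fast, 100001, "+", "chr1")
  expect_identical(rr2$width, 200)
  # degenerate s <= b and s <= t -> TSS bin only
  h_flat <- hidden_params(1, 2, 2, 0.5, 0.5)
  expect_identical(regulatory_region(h_flat, 100001, "+", "chr1")$width, 200)
  # doubling kp never widens the upstream extent
  for (kp in c(0.1, 0.3, 0.7, 1.5)) {
    r1 <- regulatory_region(hidden_params(50, 2, 10, kp, 0.4), 1e5, "+")
    r2 <- regulatory_region(hidden_params(50, 2, 10, 2 * kp, 0.4), 1e5, "+")
    expect_lte(r2$n_up, r1$n_up)
  }
  # on the minus strand the upstream side extends to higher coordinates
  rm <- regulatory_region(h, 100001, "-", "chr1")
  expect_identical(rm$end - 100000, 100 + 4 * 200)
  expect_identical(rr$width, rm$width)
})

test_that("per-condition calls assemble into a detection matrix", {
  mk <- function(ids, active) {
    mapply(function(i, a) list(mirna_id = i, active = a),
           ids, active, SIMPLIFY = FALSE)
  }
  calls <- list(
    MCF7 = mk(c("m1", "m2"), c(TRUE, FALSE)),
    MCF7_E2 = mk(c("m1", "m2"), c(TRUE, TRUE)),
    MCF7T = mk(c("m1", "m3"), c(TRUE, FALSE)),   # m2 unscanned here -> 0
    MCF7T_E2 = mk(c("m1", "m2", "m3"), c(TRUE, TRUE, TRUE)))
  dm <- detection_matrix(calls)
  expect_identical(dm$mirna_id, c("m1", "m2", "m3"))
  expect_identical(dm$MCF7, c(1L, 0L, 0L))
  expect_identical(dm$MCF7T, c(1L, 0L, 0L))
  expect_identical(dm$MCF7T_E2, c(1L, 1L, 1L))
  pat <- condition_patterns(dm)
  expect_identical(unname(pat[1]), "constitutive")
})

test_that("condition patterns map onto the six regulatory categories", {
  det <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4", "m5", "m6", "m7"),
    MCF7 = c(1, 0, 0, 1, 0, 0, 1),
    MCF7_E2 = c(1, 1, 0, 1, 1, 1, 0),
    MCF7T = c(1, 0, 1, 0, 0, 1, 1),
    MCF7T_E2 = c(1, 1, 1, 0, 0, 1, 0))
  pat <- condition_patterns(det)
  expect_identical(unname(pat), c(
    "constitutive",
    "E2-inducible, tamoxifen-insensitive",
    "tamoxifen-inducible, E2-independent",
    "tamoxifen-repressed, E2-independent",
    "tamoxifen-repressed, E2-inducible",
    "predisposed induction in MCF7-T",
    "other"))
  expect_identical(names(pat), det$mirna_id)
  expect_error(condition_patterns(data.frame(A = 1, B = 1, C = 1, D = 1)),
               class = "mirtss_invalid_input")
})

test_that("the scan localizes a planted TSS and mirrors under strand flip", {
  phi <- default_sim_phi()
  W <- 200L
  layout <- genome_layout(c("chrP", "chrM"), c(1e6, 1e6))
  anchor_plus <- 500001
  planted <- 17L  # bins upstream of the anchor
  set.seed(314)
  h <- hidden_params(60, 2, 10, 0.8, 0.4)
  offs <- -75:25  # transcriptional offsets relative to the anchor
  lam <- expected_lambda(h, offs + planted)
  cnt <- rpois(length(offs), lam)
  frag_from_counts <- function(anchor, strand, chrom) {
    mids <- integer(0)
    half <- W %/% 2
    a0 <- anchor - 1
    for (j in seq_along(offs)) {
      if (cnt[j] == 0) next
      start0 <- if (strand == "+") a0 - half + offs[j] * W
                else a0 - half - offs[j] * W + 1
      mids <- c(mids, start0 + sample.int(W, cnt[j], replace = TRUE) - 1)
    }
    GenomicRanges::GRanges(chrom, IRanges::IRanges(mids - 74, mids + 75))
  }
  set.seed(99)
  frags_p <- frag_from_counts(anchor_plus, "+", "chrP")
  set.seed(99)
  frags_m <- frag_from_counts(anchor_plus, "-", "chrM")
  mir_p <- list(mirna_id = "mirP", chrom = "chrP", strand = "+",
                pre_start = anchor_plus, pre_end = anchor_plus + 79)
  mir_m <- list(mirna_id = "mirM", chrom = "chrM", strand = "-",
                pre_start = anchor_plus - 79, pre_end = anchor_plus)
  sp <- scan_mirna_upstream(frags_p, mir_p, phi, layout = layout)
  sm <- scan_mirna_upstream(frags_m, mir_m, phi, layout = layout)
  expect_identical(sp$best_offset, -planted)
  # mirrored fixture gives identical scores bin for bin
  expect_equal(sm$delta_f_scores, sp$delta_f_scores, tolerance = 1e-12)
  expect_identical(sm$best_offset, sp$best_offset)
  # called coordinates mirror around the anchor
  expect_identical(sp$best_coord - anchor_plus,
                   -(sm$best_coord - anchor_plus))
})

test_that("an empty fragment track yields flat negative scores", {
  phi <- default_sim_phi()
  layout <- genome_layout("chrZ", 1e6)
  empty <- GenomicRanges::GRanges()
  mir <- list(mirna_id = "m0", chrom = "chrZ", strand = "+",
              pre_start = 500001, pre_end = 500080)
  sc <- scan_mirna_upstream(empty, mir, phi, layout = layout)
  expect_true(all(sc$delta_f_scores < 0))
  expect_lt(max(sc$delta_f_scores) - min(sc$delta_f_scores), 1e-9)
  # tie-break: nearest candidate to the microRNA
  expect_identical(sc$best_offset, -1L)
})

test_that("scan scores are invariant to global coordinate translation", {
  phi <- default_sim_phi()
  set.seed(41)
  mids <- sample.int(20000, 600) + 490000
  frags <- GenomicRanges::GRanges("chrT", IRanges::IRanges(mids - 74, mids + 75))
  mir <- list(mirna_id = "m", chrom = "chrT", strand = "+",
              pre_start = 505001, pre_end = 505080)
  s0 <- scan_mirna_upstream(frags, mir, phi)
  shift <- 40000L
  mir2 <- mir; mir2$pre_start <- mir$pre_start + shift
  mir2$pre_end <- mir$pre_end + shift
  s1 <- scan_mirna_upstream(GenomicRanges::shift(frags, shift), mir2, phi)
  expect_identical(s0$delta_f_scores, s1$delta_f_scores)
  expect_identical(s0$best_offset, s1$best_offset)
})

test_that("call_promoters fills FDR, activity and the regulatory interval", {
  phi <- default_sim_phi()
  cfg <- sim_config(n_expressed = 0, n_unexpressed = 0,
                    n_mirna_active = 6, n_mirna_silent = 4, seed = 21)
  fx <- simulate_genome_fixture(cfg, tempfile("fxcall"))
  frags <- read_fragments_bed(fx$paths$fragments, fx$layout)
  scans <- lapply(seq_len(nrow(fx$mirnas)), function(i)
    scan_mirna_upstream(frags, fx$mirnas[i, ], phi, layout = fx$layout))
  # synthetic null background scores well below the planted signal
  bg <- vapply(scans[7:10], function(s) s$best_score, numeric(1))
  calls <- call_promoters(scans, bg, frags, phi, method = "exceedance",
                          layout = fx$layout)
  active <- vapply(calls, function(s) isTRUE(s$active), logical(1))
  expect_true(all(active[1:6]))
  for (s in calls[active]) {
    expect_identical(s$tss_coord, s$best_coord)
    expect_false(is.null(s$regulatory_interval))
    expect_gte(s$regulatory_interval$width, s$bin_width)
    expect_true(s$regulatory_interval$start <= s$tss_coord &
                  s$regulatory_interval$end >= s$tss_coord)
  }
  # predictions BED has one row per microRNA and 9 columns
  bedp <- tempfile(fileext = ".bed")
  write_predictions_bed(calls, bedp)
  tab <- read.table(bedp, sep = "\t")
  expect_identical(nrow(tab), length(calls))
  expect_identical(ncol(tab), 9L)
})
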