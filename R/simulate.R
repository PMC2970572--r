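## Synthetic-data generator reproducing the model's statistical structure:
## Gamma-distributed per-locus hidden parameters, Poisson bin counts, and a
## toy genome laid out so the whole pipeline (IO, gold standard, fitting,
## scanning, evaluation) can run on generated text files.

#' Default hyperparameters for simulation
#'
#' Synthetic settings (not estimates from any experiment): background around
#' 2 fragments per 200-bp bin, TSS-bin means around 50 (so the mean
#' signal/background ratio is 25), steady transcript level around 10, and
#' upstream decay faster than downstream decay.
#'
#' @param s_mean Mean TSS-bin level (default 50).
#' @param b_mean Mean background level (default 2).
#' @return A [hyper_params()] object.
#' @export
default_sim_phi <- function(s_mean = 50, b_mean = 2) {
  hyper_params(
    gS = gamma_hyper(4, 4 / s_mean),      # CV 0.5
    gB = gamma_hyper(2, 2 / b_mean),      # CV ~0.71
    gT = gamma_hyper(4, 0.4),             # mean 10
    gKp = gamma_hyper(16, 20),            # mean 0.8, CV 0.25
    gKt = gamma_hyper(16, 40)             # mean 0.4
  )
}

#' Simulation configuration
#'
#' @param phi_true True [hyper_params()] generating the hidden parameters.
#' @param n_expressed,n_unexpressed Numbers of expressed/unexpressed genes.
#' @param n_mirna_active,n_mirna_silent Numbers of microRNA loci with and
#'   without a planted upstream TSS.
#' @param bin_width Bin width in bp (default 200).
#' @param window Bins per side for training profiles (default 25).
#' @param fragment_length Emitted fragment length in bp (default 150).
#' @param tss_offset_range Range (bins upstream) for planted microRNA TSSs
#'   (default 5..45, i.e. 1-9 kb).
#' @param locus_spacing Distance between locus anchors in bp (default 40000,
#'   which honours the 10-kb gold-standard isolation rule).
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(phi_true = default_sim_phi(),
                       n_expressed = 300L, n_unexpressed = 150L,
                       n_mirna_active = 40L, n_mirna_silent = 40L,
                       bin_width = 200L, window = 25L,
                       fragment_length = 150L,
                       tss_offset_range = c(5L, 45L),
                       locus_spacing = 40000L, seed) {
  if (missing(seed)) mirtss_stop("a seed is mandatory", "mirtss_invalid_input")
  counts <- c(n_expressed, n_unexpressed, n_mirna_active, n_mirna_silent)
  if (any(counts < 0)) mirtss_stop("counts must be >= 0", "mirtss_invalid_input")
  structure(
    list(phi_true = phi_true, n_expressed = as.integer(n_expressed),
         n_unexpressed = as.integer(n_unexpressed),
         n_mirna_active = as.integer(n_mirna_active),
         n_mirna_silent = as.integer(n_mirna_silent),
         bin_width = as.integer(bin_width), window = as.integer(window),
         fragment_length = as.integer(fragment_length),
         tss_offset_range = as.integer(tss_offset_range),
         locus_spacing = as.integer(locus_spacing),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

## 0-based genomic start of the midpoint support of each transcriptional bin
## offset, matching the binning convention of profile_counts_matrix(): on
## the plus strand bin j covers mids [a0 - half + jW, a0 + half - 1 + jW],
## on the minus strand [a0 - half - jW + 1, a0 + half - jW].
sim_bin_starts0 <- function(anchor_pos, strand, offsets, bin_width) {
  a0 <- anchor_pos - 1L
  half <- bin_width %/% 2L
  if (strand == "+") a0 - half + offsets * bin_width
  else a0 - half - offsets * bin_width + 1L
}

draw_hidden <- function(phi, n) {
  data.frame(
    s = rgamma(n, phi$gS$shape, phi$gS$rate),
    b = rgamma(n, phi$gB$shape, phi$gB$rate),
    t = rgamma(n, phi$gT$shape, phi$gT$rate),
    kp = rgamma(n, phi$gKp$shape, phi$gKp$rate),
    kt = rgamma(n, phi$gKt$shape, phi$gKt$rate)
  )
}

#' Simulate gene profiles from the generative model
#'
#' Draws the five hidden parameters per gene from `phi`'s Gamma laws,
#' computes expected occupancy per offset and draws Poisson counts.
#'
#' @param phi [hyper_params()] generating law.
#' @param n Number of genes.
#' @param seed Integer seed.
#' @param n_up,n_down Bins per side (default 25).
#' @param bin_width Bin width in bp (default 200).
#' @return List with `profiles` (list of [binned_profile()]) and `truth`
#'   (data.frame of the hidden draws, one row per gene).
#' @export
simulate_gene_profiles <- function(phi, n, seed, n_up = 25L, n_down = 25L,
                                   bin_width = 200L) {
  with_seed(seed, {
    truth <- draw_hidden(phi, n)
    truth$gene_id <- sprintf("simgene%04d", seq_len(n))
    offsets <- seq.int(-n_up, n_down)
    profiles <- lapply(seq_len(n), function(i) {
      h <- hidden_params(truth$s[i], truth$b[i], truth$t[i],
                         truth$kp[i], truth$kt[i])
      lam <- expected_lambda(h, offsets)
      binned_profile(rpois(length(lam), lam), offsets,
                     anchor_id = truth$gene_id[i], bin_width = bin_width)
    })
    list(profiles = profiles, truth = truth)
  })
}

## Emit BED fragments for a vector of per-bin counts laid out on a
## chromosome. `bin_start0` gives the 0-based genomic start of each bin.
counts_to_fragments <- function(counts, bin_start0, chrom, bin_width, frag_len) {
  tot <- sum(counts)
  if (tot == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  bin_of <- rep.int(seq_along(counts), counts)
  mids <- bin_start0[bin_of] + sample.int(bin_width, tot, replace = TRUE) - 1
  start <- mids - frag_len %/% 2
  data.frame(chrom = chrom, start = start, end = start + frag_len,
             stringsAsFactors = FALSE)
}

#' Simulate a toy genome fixture on disk
#'
#' Lays out expressed and unexpressed genes on one chromosome and microRNA
#' loci on another, honouring the gold-standard isolation rule; active
#' microRNA loci carry a planted signal-model TSS at a drawn upstream offset,
#' silent loci and unexpressed genes draw counts from the background law
#' only. Fragments are emitted as explicit BED intervals so the whole IO path
#' is exercised; gene annotations are written as refFlat, expression calls as
#' a tab-delimited table, microRNAs as GFF3, the genome layout and the
#' planted truth as tab-delimited files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List with file `paths`, the `layout`, data.frames `genes`,
#'   `expression`, `mirnas`, `truth`, and the per-locus count matrices.
#' @export
simulate_genome_fixture <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  W <- config$bin_width
  spacing <- config$locus_spacing
  frag_len <- config$fragment_length
  margin <- 20000L

  n_genes <- config$n_expressed + config$n_unexpressed
  n_mirna <- config$n_mirna_active + config$n_mirna_silent
  layout <- genome_layout(
    c("chrS1", "chrS2"),
    c(margin * 2 + max(n_genes, 1) * spacing,
      margin * 2 + max(n_mirna, 1) * spacing))

  with_seed(config$seed, {
    ## gene loci: offsets -75..+60 bins around the TSS so that background
    ## scans of unexpressed-gene promoters (50 candidates + context) are
    ## fully covered
    gene_offs <- seq.int(-75L, 60L)
    gene_tss <- margin + spacing * (seq_len(n_genes) - 1L) + 1L
    gene_strand <- rep_len(c("+", "+", "+", "-"), n_genes)
    expressed <- seq_len(config$n_expressed)

    truth_g <- draw_hidden(config$phi_true, n_genes)
    truth_g$locus_id <- sprintf("gene%04d", seq_len(n_genes))
    truth_g$klass <- ifelse(seq_len(n_genes) %in% expressed,
                            "expressed_gene", "unexpressed_gene")

    gene_counts <- matrix(0L, n_genes, length(gene_offs))
    frag_rows <- vector("list", n_genes + n_mirna)
    for (i in seq_len(n_genes)) {
      lam <- if (i %in% expressed) {
        expected_lambda(hidden_params(truth_g$s[i], truth_g$b[i], truth_g$t[i],
                                      truth_g$kp[i], truth_g$kt[i]), gene_offs)
      } else rep(truth_g$b[i], length(gene_offs))
      cnt <- rpois(length(lam), lam)
      gene_counts[i, ] <- cnt
      frag_rows[[i]] <- counts_to_fragments(
        cnt, sim_bin_starts0(gene_tss[i], gene_strand[i], gene_offs, W),
        "chrS1", W, frag_len)
    }

    ## expression intensities correlated with the drawn S so evaluation
    ## tiers are meaningful; unexpressed genes get low Absent intensities
    intensity <- round(truth_g$s * 150 * exp(rnorm(n_genes, 0, 0.3)))
    intensity[-expressed] <- round(runif(config$n_unexpressed, 50, 500))
    call <- ifelse(seq_len(n_genes) %in% expressed, "P", "A")

    genes <- data.frame(
      gene_id = truth_g$locus_id, chrom = rep("chrS1", n_genes),
      strand = gene_strand,
      tss = gene_tss,
      span_start = ifelse(gene_strand == "+", gene_tss, gene_tss - 12000L),
      span_end = ifelse(gene_strand == "+", gene_tss + 12000L, gene_tss),
      stringsAsFactors = FALSE)
    expression <- data.frame(gene_id = genes$gene_id, call = call,
                             intensity = intensity, stringsAsFactors = FALSE)

    ## microRNA loci: anchor = pre-miRNA 5' end; counts over offsets
    ## -75..+25 (15 kb up / 5 kb down retrieval window)
    mir_offs <- seq.int(-75L, 25L)
    mir_anchor <- margin + spacing * (seq_len(n_mirna) - 1L) + 1L
    mir_strand <- rep_len(c("+", "-"), n_mirna)
    active <- seq_len(config$n_mirna_active)
    truth_m <- draw_hidden(config$phi_true, n_mirna)
    truth_m$locus_id <- sprintf("mir%04d", seq_len(n_mirna))
    truth_m$klass <- ifelse(seq_len(n_mirna) %in% active,
                            "active_mirna", "silent_mirna")
    planted <- integer(n_mirna)
    planted[active] <- sample(seq.int(config$tss_offset_range[1],
                                      config$tss_offset_range[2]),
                              length(active), replace = TRUE)

    mir_counts <- matrix(0L, n_mirna, length(mir_offs))
    for (k in seq_len(n_mirna)) {
      i <- n_genes + k
      lam <- if (k %in% active) {
        ## profile centered at the planted TSS, `planted[k]` bins upstream
        expected_lambda(hidden_params(truth_m$s[k], truth_m$b[k], truth_m$t[k],
                                      truth_m$kp[k], truth_m$kt[k]),
                        mir_offs + planted[k])
      } else rep(truth_m$b[k], length(mir_offs))
      cnt <- rpois(length(lam), lam)
      mir_counts[k, ] <- cnt
      frag_rows[[i]] <- counts_to_fragments(
        cnt, sim_bin_starts0(mir_anchor[k], mir_strand[k], mir_offs, W),
        "chrS2", W, frag_len)
    }

    mirnas <- data.frame(
      mirna_id = truth_m$locus_id, chrom = rep("chrS2", n_mirna),
      strand = mir_strand,
      pre_start = ifelse(mir_strand == "+", mir_anchor, mir_anchor - 79L),
      pre_end = ifelse(mir_strand == "+", mir_anchor + 79L, mir_anchor),
      stringsAsFactors = FALSE)

    truth <- rbind(
      cbind(truth_g, anchor = gene_tss, chrom = rep("chrS1", n_genes),
            strand = gene_strand, planted_offset = rep(0L, n_genes),
            planted_tss = ifelse(truth_g$klass == "expressed_gene",
                                 gene_tss, NA_integer_)),
      cbind(truth_m, anchor = mir_anchor, chrom = rep("chrS2", n_mirna),
            strand = mir_strand, planted_offset = planted,
            planted_tss = ifelse(seq_len(n_mirna) %in% active,
                                 ifelse(mir_strand == "+",
                                        mir_anchor - planted * W,
                                        mir_anchor + planted * W),
                                 NA_integer_)))

    frag_df <- do.call(rbind, frag_rows)
    ## clip to chromosome bounds (margins make clipping a no-op in practice)
    frag_df$start <- pmax(frag_df$start, 0)
    frag_df$end <- pmin(frag_df$end, unname(layout[frag_df$chrom]))
    ord <- order(frag_df$chrom, frag_df$start, frag_df$end)
    frag_df <- frag_df[ord, ]

    paths <- list(
      fragments = file.path(dir, "fragments.bed"),
      genes = file.path(dir, "genes.refflat"),
      expression = file.path(dir, "expression.tsv"),
      mirnas = file.path(dir, "mirnas.gff3"),
      layout = file.path(dir, "genome.tsv"),
      truth = file.path(dir, "truth.tsv"))
    write.table(frag_df, paths$fragments, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write_genes_refflat(genes, paths$genes)
    write.table(expression, paths$expression, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_mirnas_gff3(mirnas, paths$mirnas)
    write_genome_layout(layout, paths$layout)
    truth_con <- file(paths$truth, "w")
    writeLines("#mirtss_sim_truth_v1", truth_con)
    write.table(truth, truth_con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(truth_con)

    list(paths = paths, layout = layout, genes = genes,
         expression = expression, mirnas = mirnas, truth = truth,
         gene_counts = gene_counts, gene_offsets = gene_offs,
         mir_counts = mir_counts, mir_offsets = mir_offs,
         config = config)
  })
}

#' Read a simulation truth table
#'
#' @param path `truth.tsv` written by [simulate_genome_fixture()].
#' @return data.frame.
#' @export
read_sim_truth <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, "#mirtss_sim_truth_v1")) {
    mirtss_stop("not a mirtss truth file (missing schema line)",
                "mirtss_parse_error")
  }
  read.table(path, sep = "\t", header = TRUE, skip = 1,
             stringsAsFactors = FALSE)
}
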