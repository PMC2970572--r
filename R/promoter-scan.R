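## Upstream TSS scan for microRNAs: classify intergenic vs intronic, score
## candidate bins with delta_f, call active promoters by empirical FDR
## against unexpressed-gene background loci, and delineate the regulatory
## region from the fitted decay rates.

#' Classify microRNAs as intergenic or intronic
#'
#' A microRNA is intronic when its pre-miRNA span lies entirely within an
#' intron of an annotated gene; otherwise it is intergenic. Host strand is
#' ignored by default. When the gene table carries no exon structure the
#' classification falls back to gene-span containment, with a warning.
#'
#' @param mirnas data.frame with `mirna_id`, `chrom`, `strand`, `pre_start`,
#'   `pre_end` (1-based closed).
#' @param genes data.frame as from [read_genes()]; intron structure is taken
#'   from `exon_starts`/`exon_ends` when present.
#' @param host_strand `"either"` (default) or `"same"`.
#' @return `mirnas` with an added `klass` column (`"intergenic"`/`"intronic"`).
#' @export
classify_mirnas <- function(mirnas, genes, host_strand = c("either", "same")) {
  host_strand <- match.arg(host_strand)
  have_exons <- all(c("exon_starts", "exon_ends") %in% names(genes)) &&
    !all(is.na(genes$exon_starts))
  if (have_exons) {
    introns <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      es <- as.numeric(strsplit(genes$exon_starts[i], ",")[[1]])
      ee <- as.numeric(strsplit(genes$exon_ends[i], ",")[[1]])
      if (length(es) < 2) return(NULL)
      o <- order(es)
      es <- es[o]; ee <- ee[o]
      data.frame(chrom = genes$chrom[i], strand = genes$strand[i],
                 start = ee[-length(ee)] + 1, end = es[-1] - 1,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(introns)) introns <- data.frame(chrom = character(),
                                                strand = character(),
                                                start = numeric(), end = numeric())
    introns <- introns[introns$end >= introns$start, , drop = FALSE]
  } else {
    warning("gene table has no exon structure; falling back to gene-span containment")
    introns <- data.frame(chrom = genes$chrom, strand = genes$strand,
                          start = genes$span_start, end = genes$span_end,
                          stringsAsFactors = FALSE)
  }
  klass <- vapply(seq_len(nrow(mirnas)), function(i) {
    cand <- introns$chrom == mirnas$chrom[i] &
      introns$start <= mirnas$pre_start[i] &
      introns$end >= mirnas$pre_end[i]
    if (host_strand == "same") cand <- cand & introns$strand == mirnas$strand[i]
    if (any(cand)) "intronic" else "intergenic"
  }, character(1))
  mirnas$klass <- klass
  mirnas
}

#' Scan upstream of one microRNA for a TSS-like RPol II pattern
#'
#' Evaluates the [delta_f()] score in each of `n_candidates` bins upstream of
#' the pre-miRNA 5' end (strand-aware), each candidate carrying a
#' 25-bin/25-bin context window. The best bin is the score argmax, ties
#' resolved towards the microRNA.
#'
#' @param frags `GRanges` of fragments.
#' @param mirna One-row data.frame (or list) with `mirna_id`, `chrom`,
#'   `strand`, `pre_start`, `pre_end`.
#' @param phi Fitted [hyper_params()].
#' @param integ [integration_settings()].
#' @param n_candidates Candidate bins upstream (default 50, i.e. 10 kb).
#' @param n_context Context bins on each side of a candidate (default 25).
#' @param bin_width Bin width in bp (default 200).
#' @param layout Optional [genome_layout()] for edge truncation.
#' @param anchor `"pre"` (default; pre-miRNA 5' start locus) or a 1-based
#'   coordinate overriding it.
#' @return An object of class `scan_result` with per-candidate scores,
#'   `best_offset` (bins upstream, negative), `best_score` and the genomic
#'   coordinate `best_coord` of the best bin's center; `fdr`, `active`,
#'   `tss_coord` and `regulatory_interval` are filled in by
#'   [call_promoters()].
#' @export
scan_mirna_upstream <- function(frags, mirna, phi,
                                integ = integration_settings(),
                                n_candidates = 50L, n_context = 25L,
                                bin_width = 200L, layout = NULL,
                                anchor = "pre") {
  mirna <- as.list(mirna)
  anchor_pos <- if (identical(anchor, "pre")) {
    if (mirna$strand == "+") mirna$pre_start else mirna$pre_end
  } else as.integer(anchor)
  sgn <- if (mirna$strand == "+") -1L else 1L
  cand_offsets <- -(seq_len(n_candidates))
  ## bin the whole retrieval window once (n_candidates + n_context bins
  ## upstream, n_context downstream of the anchor); every candidate's
  ## context is a contiguous slice of this anchor-aligned grid
  window <- bin_counts(frags, mirna$chrom, anchor_pos, mirna$strand,
                       n_up = n_candidates + n_context, n_down = n_context,
                       bin_width = bin_width, layout = layout,
                       anchor_id = mirna$mirna_id)
  scores <- vapply(seq_len(n_candidates), function(j) {
    keep <- window$offsets >= -j - n_context & window$offsets <= -j + n_context
    prof <- binned_profile(window$counts[keep], window$offsets[keep] + j,
                           anchor_id = sprintf("%s@-%d", mirna$mirna_id, j),
                           chrom = mirna$chrom,
                           anchor_pos = anchor_pos + sgn * j * bin_width,
                           strand = mirna$strand, bin_width = bin_width)
    delta_f(prof, phi, integ)
  }, numeric(1))
  ## argmax; exact ties go to the candidate nearest the microRNA (smallest j)
  best_j <- which(scores == max(scores))[1]
  structure(
    list(mirna_id = mirna$mirna_id, chrom = mirna$chrom,
         strand = mirna$strand, anchor_pos = anchor_pos,
         bin_width = as.integer(bin_width),
         candidate_offsets = cand_offsets, delta_f_scores = scores,
         best_offset = cand_offsets[best_j], best_score = scores[best_j],
         best_coord = anchor_pos + sgn * best_j * bin_width,
         fdr = NA_real_, active = NA, tss_coord = NA_integer_,
         regulatory_interval = NULL),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s best dF=%.2f at %d bins upstream (fdr=%s)\n",
              x$mirna_id, x$best_score, -x$best_offset,
              ifelse(is.na(x$fdr), "?", format(x$fdr, digits = 3))))
  invisible(x)
}

#' Empirical FDR against background scores
#'
#' For each candidate score `s`, the `"ratio"` form is
#' `min(1, (#bg >= s / N_bg) / (#cand >= s / N_cand))`; the `"exceedance"`
#' form is the background exceedance fraction `#bg >= s / N_bg` alone. Either
#' way a step-up pass enforces monotone non-increase in the score.
#'
#' @param candidate_scores Numeric vector of per-locus best scores.
#' @param background_scores Numeric vector of best scores from background
#'   loci (unexpressed-gene promoters scanned identically).
#' @param method `"ratio"` (default) or `"exceedance"`.
#' @return Numeric FDR in `[0,1]` per candidate.
#' @export
empirical_fdr <- function(candidate_scores, background_scores,
                          method = c("ratio", "exceedance")) {
  method <- match.arg(method)
  if (length(background_scores) == 0) {
    mirtss_stop("background score set is empty", "mirtss_empty_pool")
  }
  if (length(candidate_scores) == 0) {
    mirtss_stop("candidate score set is empty", "mirtss_empty_pool")
  }
  n_bg <- length(background_scores)
  n_cand <- length(candidate_scores)
  raw <- vapply(candidate_scores, function(s) {
    p_bg <- sum(background_scores >= s) / n_bg
    if (method == "exceedance") return(p_bg)
    p_cand <- sum(candidate_scores >= s) / n_cand
    p_bg / p_cand
  }, numeric(1))
  raw <- pmin(raw, 1)
  ## step-up: FDR at score s is the minimum raw FDR over candidates <= s,
  ## which is non-increasing in s
  ord <- order(candidate_scores)
  mono <- raw
  mono[ord] <- cummin(raw[ord])
  mono
}

#' Regulatory region around a called TSS
#'
#' Contiguous bins around the TSS where the fitted RPol II excess over the
#' local asymptote retains at least `1 - decay_threshold` of the TSS-bin
#' excess: `floor(log(1/(1-decay_threshold))/kp)` bins upstream and the
#' analogous count downstream with `kt`. When the TSS level does not exceed
#' an asymptote that side contributes no bins; the degenerate case is the
#' TSS bin alone.
#'
#' @param h [hidden_params()] posterior means at the called TSS.
#' @param tss_coord 1-based genomic coordinate of the called bin center.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome name.
#' @param bin_width Bin width in bp (default 200).
#' @param decay_threshold Decay fraction defining the boundary (default 0.9).
#' @return List with `chrom`, `start`, `end` (1-based closed genomic
#'   interval), `n_up`, `n_down` (qualifying bins per side).
#' @export
regulatory_region <- function(h, tss_coord, strand = "+", chrom = NA_character_,
                              bin_width = 200L, decay_threshold = 0.9) {
  cut <- log(1 / (1 - decay_threshold))
  n_up <- if (h$s > h$b) floor(cut / h$kp) else 0L
  n_down <- if (h$s > h$t) floor(cut / h$kt) else 0L
  half <- bin_width %/% 2
  if (strand == "+") {
    start0 <- (tss_coord - 1) - half - n_up * bin_width
    end0 <- (tss_coord - 1) + half + n_down * bin_width
  } else {
    start0 <- (tss_coord - 1) - half - n_down * bin_width
    end0 <- (tss_coord - 1) + half + n_up * bin_width
  }
  list(chrom = chrom, start = start0 + 1, end = end0,
       n_up = as.integer(n_up), n_down = as.integer(n_down),
       width = end0 - start0)
}

#' Call active promoters from scan results
#'
#' Attaches empirical FDRs to per-microRNA best scores, flags loci at
#' `fdr <= threshold` as active, and for active loci fills in the called TSS
#' coordinate and the regulatory interval from the posterior hidden-parameter
#' means at the called bin.
#'
#' @param scans List of `scan_result` objects.
#' @param background_scores Best scores from background loci.
#' @param frags `GRanges` of fragments (to rebuild the called-bin profile).
#' @param phi Fitted [hyper_params()].
#' @param integ [integration_settings()].
#' @param fdr_threshold Calling threshold (default 0.2).
#' @param method FDR estimator, see [empirical_fdr()].
#' @param layout Optional [genome_layout()].
#' @return The list of `scan_result`s with `fdr`, `active`, `tss_coord` and
#'   `regulatory_interval` filled.
#' @export
call_promoters <- function(scans, background_scores, frags, phi,
                           integ = integration_settings(),
                           fdr_threshold = 0.2,
                           method = c("ratio", "exceedance"),
                           layout = NULL) {
  method <- match.arg(method)
  best <- vapply(scans, function(s) s$best_score, numeric(1))
  fdr <- empirical_fdr(best, background_scores, method = method)
  for (i in seq_along(scans)) {
    scans[[i]]$fdr <- fdr[i]
    scans[[i]]$active <- fdr[i] <= fdr_threshold
    if (scans[[i]]$active) {
      s <- scans[[i]]
      scans[[i]]$tss_coord <- s$best_coord
      prof <- bin_counts(frags, s$chrom, s$best_coord, s$strand,
                         bin_width = s$bin_width, layout = layout,
                         anchor_id = s$mirna_id)
      h <- posterior_hidden_means(prof, phi, integ)
      scans[[i]]$regulatory_interval <-
        regulatory_region(h, s$best_coord, s$strand, s$chrom, s$bin_width)
    }
  }
  scans
}

#' Condition detection-pattern categories
#'
#' Maps each microRNA's active/inactive flags across the four biological
#' conditions (MCF7 vehicle, MCF7 + E2, MCF7-T vehicle, MCF7-T + E2, in that
#' order) onto six named regulatory categories, with `"other"` for patterns
#' outside them.
#'
#' @param detection data.frame or matrix of 0/1 (or logical) flags with
#'   columns named `MCF7`, `MCF7_E2`, `MCF7T`, `MCF7T_E2`; row names or a
#'   `mirna_id` column identify the microRNAs.
#' @return Character vector of categories, named by microRNA.
#' @export
condition_patterns <- function(detection) {
  cond <- c("MCF7", "MCF7_E2", "MCF7T", "MCF7T_E2")
  ids <- NULL
  if (is.data.frame(detection) && "mirna_id" %in% names(detection)) {
    ids <- detection$mirna_id
    detection <- detection[, setdiff(names(detection), "mirna_id"), drop = FALSE]
  }
  if (!all(cond %in% colnames(detection)) ||
      length(setdiff(colnames(detection), cond)) > 0) {
    mirtss_stop(paste("detection columns must be exactly:",
                      paste(cond, collapse = ", ")), "mirtss_invalid_input")
  }
  m <- as.matrix(detection[, cond])
  storage.mode(m) <- "integer"
  if (is.null(ids)) ids <- rownames(m)
  key <- apply(m, 1, paste, collapse = "")
  map <- c("1111" = "constitutive",
           "0101" = "E2-inducible, tamoxifen-insensitive",
           "0011" = "tamoxifen-inducible, E2-independent",
           "1100" = "tamoxifen-repressed, E2-independent",
           "0100" = "tamoxifen-repressed, E2-inducible",
           "0111" = "predisposed induction in MCF7-T")
  out <- unname(map[key])
  out[is.na(out)] <- "other"
  names(out) <- ids
  out
}

#' Assemble a cross-condition detection matrix
#'
#' Combines per-condition promoter calls into the 0/1 matrix consumed by
#' [condition_patterns()] and writable as a tab-delimited table.
#'
#' @param calls_by_condition Named list (condition -> list of called
#'   `scan_result`s, as returned by [call_promoters()]); names must be the
#'   four condition labels `MCF7`, `MCF7_E2`, `MCF7T`, `MCF7T_E2` for the
#'   pattern mapping, but any set of conditions is accepted here.
#' @return data.frame with `mirna_id` plus one 0/1 column per condition.
#' @export
detection_matrix <- function(calls_by_condition) {
  ids <- sort(unique(unlist(lapply(calls_by_condition, function(calls)
    vapply(calls, `[[`, character(1), "mirna_id")))))
  out <- data.frame(mirna_id = ids, stringsAsFactors = FALSE)
  for (cond in names(calls_by_condition)) {
    calls <- calls_by_condition[[cond]]
    act <- vapply(calls, function(s) isTRUE(s$active), logical(1))
    names(act) <- vapply(calls, `[[`, character(1), "mirna_id")
    out[[cond]] <- as.integer(act[ids] %in% TRUE)
  }
  out
}

#' Write promoter predictions as BED6+
#'
#' Columns: chrom, region start/end (regulatory interval when called, best
#' bin otherwise), microRNA id, best delta-F score, strand, then `tss_coord`,
#' `fdr`, `active`.
#'
#' @param scans List of called `scan_result` objects.
#' @param path Output path.
#' @export
write_predictions_bed <- function(scans, path) {
  rows <- lapply(scans, function(s) {
    if (!is.null(s$regulatory_interval)) {
      start0 <- s$regulatory_interval$start - 1
      end <- s$regulatory_interval$end
    } else {
      half <- s$bin_width %/% 2
      start0 <- (s$best_coord - 1) - half
      end <- (s$best_coord - 1) + half
    }
    data.frame(chrom = s$chrom, start = start0, end = end,
               name = s$mirna_id, score = round(s$best_score, 4),
               strand = s$strand,
               tss_coord = ifelse(is.na(s$tss_coord), ".",
                                  as.character(s$tss_coord)),
               fdr = round(s$fdr, 6), active = as.integer(s$active),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
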