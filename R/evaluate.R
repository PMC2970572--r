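## Evaluation suite: tie-aware ROC/AUC (overall and by expression tier),
## sequencing-depth saturation, strand-aware metaprofiles, CpG-island
## overlap and conservation summaries.

#' ROC curve and AUC from two score sets
#'
#' The AUC is computed exactly by pair counting,
#' `P(pos > neg) + 0.5 P(pos = neg)` (equivalently the scaled Wilcoxon rank
#' sum), and is tie-aware; the stored curve enumerates all distinct score
#' thresholds.
#'
#' @param pos_scores,neg_scores Numeric score vectors for the positive and
#'   negative class.
#' @return An object of class `roc_result` with `thresholds`, `tpr`, `fpr`
#'   and `auc`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    mirtss_stop("both score sets must be non-empty", "mirtss_empty_pool")
  }
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), numeric(1))
  structure(list(thresholds = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr),
                 auc = auc, n_pos = np, n_neg = nn),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d pos, %d neg)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Score gold-standard genes with the scan statistic
#'
#' Computes the [delta_f()] score of the profile centered on each gene's
#' annotated TSS -- the per-gene quantity the ROC analyses rank.
#'
#' @param frags `GRanges` of fragments.
#' @param genes data.frame of gene records (`gene_id`, `chrom`, `strand`,
#'   `tss`).
#' @param phi Fitted [hyper_params()].
#' @param integ [integration_settings()].
#' @param n_context Bins per side (default 25).
#' @param bin_width Bin width in bp.
#' @return Named numeric vector of scores (names = gene ids).
#' @export
score_gene_tss <- function(frags, genes, phi, integ = integration_settings(),
                           n_context = 25L, bin_width = 200L) {
  offsets <- seq.int(-n_context, n_context)
  counts <- profile_counts_matrix(
    frags, data.frame(chrom = genes$chrom, pos = genes$tss,
                      strand = genes$strand, stringsAsFactors = FALSE),
    offsets, bin_width)
  st <- grid_stats_matrix(counts, offsets, phi, integ$n_nodes)
  bg <- vapply(seq_len(nrow(counts)), function(i) {
    background_marginal_loglik(
      binned_profile(counts[i, ], offsets, bin_width = bin_width), phi$gB)
  }, numeric(1))
  setNames(st[, "logM"] - bg, genes$gene_id)
}

#' Stratified ROC by expression tier
#'
#' One ROC per intensity tier of the expressed test genes, each against the
#' full unexpressed set -- mirroring evaluation of predictive power as a
#' function of expression level.
#'
#' @param scores Named score vector (from [score_gene_tss()]).
#' @param expression data.frame with `gene_id` and `intensity`.
#' @param pos_ids,neg_ids Gene ids of the expressed test set and the
#'   unexpressed set.
#' @param tiers Intensity cut points (default `c(1000, 5000, 10000)`).
#' @return Named list of `roc_result`, one per tier (empty tiers are skipped
#'   with a warning), plus `overall`.
#' @export
stratified_roc <- function(scores, expression, pos_ids, neg_ids,
                           tiers = c(1000, 5000, 10000)) {
  neg <- scores[intersect(neg_ids, names(scores))]
  pos_int <- expression$intensity[match(pos_ids, expression$gene_id)]
  breaks <- c(-Inf, tiers, Inf)
  labels <- c(paste0("<", tiers[1]),
              if (length(tiers) > 1)
                paste(tiers[-length(tiers)], tiers[-1], sep = "-"),
              paste0(">", tiers[length(tiers)]))
  tier_of <- cut(pos_int, breaks = breaks, labels = labels)
  out <- list(overall = roc_auc(scores[intersect(pos_ids, names(scores))], neg))
  for (lb in labels) {
    ids <- pos_ids[which(tier_of == lb)]
    ids <- intersect(ids, names(scores))
    if (length(ids) == 0) {
      warning(sprintf("expression tier '%s' is empty; skipped", lb))
      next
    }
    out[[lb]] <- roc_auc(scores[ids], neg)
  }
  out
}

#' Sequencing-depth saturation curve
#'
#' For each depth: subsample the fragments, re-fit the hyperparameters on the
#' training genes, score the test and unexpressed genes and compute the AUC.
#' Seeded and reproducible.
#'
#' @param frags `GRanges` of fragments.
#' @param genes Gene table.
#' @param gold A [select_gold_standard()] result.
#' @param depths Integer vector of fragment counts to subsample to.
#' @param settings [fit_settings()] for the per-depth refits.
#' @param integ [integration_settings()].
#' @param seed Integer seed.
#' @return data.frame with columns `depth` and `auc`.
#' @export
saturation_curve <- function(frags, genes, gold, depths,
                             settings = fit_settings(),
                             integ = integration_settings(), seed = 1L) {
  offsets <- seq.int(-25L, 25L)
  train <- genes[genes$gene_id %in% gold$train_expressed, , drop = FALSE]
  evalg <- genes[genes$gene_id %in% c(gold$test_expressed, gold$unexpressed), ,
                 drop = FALSE]
  auc <- vapply(seq_along(depths), function(k) {
    sub <- if (depths[k] >= length(frags)) frags
           else subsample_fragments(frags, depths[k], derive_seed(seed, k))
    counts <- profile_counts_matrix(
      sub, data.frame(chrom = train$chrom, pos = train$tss,
                      strand = train$strand, stringsAsFactors = FALSE),
      offsets, 200L)
    profiles <- lapply(seq_len(nrow(counts)), function(i) {
      binned_profile(counts[i, ], offsets, anchor_id = train$gene_id[i])
    })
    fit <- fit_hyperparams(profiles, settings = settings)
    sc <- score_gene_tss(sub, evalg, fit$phi, integ)
    roc_auc(sc[intersect(gold$test_expressed, names(sc))],
            sc[intersect(gold$unexpressed, names(sc))])$auc
  }, numeric(1))
  data.frame(depth = depths, auc = auc)
}

#' Strand-aware metaprofile around a set of anchors
#'
#' Aggregates a fragment track (mean counts per bin) or a score track (mean
#' per-base score per bin) across anchors after strand flipping, the standard
#' aligned-TSS summary view.
#'
#' @param anchors data.frame with `chrom`, `pos` (1-based) and `strand`.
#' @param track `GRanges` of fragments or a `score_track`.
#' @param flank_bp Flank on each side in bp (default 10000).
#' @param bin_width Bin width in bp (default 200).
#' @return data.frame with `offset` (bins) and `value`; `2*flank/bin_width+1`
#'   rows.
#' @export
metaprofile <- function(anchors, track, flank_bp = 10000L, bin_width = 200L) {
  n_bins <- as.integer(flank_bp %/% bin_width)
  offsets <- seq.int(-n_bins, n_bins)
  if (inherits(track, "score_track")) {
    vals <- matrix(0, nrow(anchors), length(offsets))
    half <- bin_width %/% 2
    for (i in seq_len(nrow(anchors))) {
      sgn <- if (anchors$strand[i] == "+") 1L else -1L
      centers <- anchors$pos[i] + sgn * offsets * bin_width
      vals[i, ] <- vapply(centers, function(cc) {
        track_interval_mean(track, anchors$chrom[i],
                            max(1, cc - half), cc + half - 1)
      }, numeric(1))
    }
    value <- colMeans(vals)
  } else {
    counts <- profile_counts_matrix(track, anchors, offsets, bin_width)
    value <- colMeans(counts)
  }
  data.frame(offset = offsets, value = value)
}

#' Fraction of regions overlapping at least one island
#'
#' @param regions,islands `GRanges` (or data.frames with `chrom`, `start`,
#'   `end`, 1-based closed).
#' @return Fraction in `[0, 1]` of regions with >= 1 bp overlap.
#' @export
cpg_overlap_fraction <- function(regions, islands) {
  as_gr <- function(x) {
    if (inherits(x, "GRanges")) return(x)
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
  }
  regions <- as_gr(regions); islands <- as_gr(islands)
  if (length(regions) == 0) return(NaN)
  mean(GenomicRanges::countOverlaps(regions, islands) > 0)
}

#' Mean conservation score by genomic region class
#'
#' Summarizes a per-base score track over five region classes around called
#' TSSs: the TSS bin itself, the regulatory region, 2 kb upstream of it,
#' 2 kb downstream of it, and length-matched randomly placed intergenic
#' regions (seeded).
#'
#' @param tss_bins data.frame with `chrom`, `start`, `end` (TSS bins,
#'   1-based closed).
#' @param regulatory_regions data.frame with `chrom`, `start`, `end`.
#' @param track A `score_track`.
#' @param layout [genome_layout()] used to place the random regions.
#' @param flank_bp Width of the upstream/downstream flanks (default 2000).
#' @param seed Seed for random intergenic sampling.
#' @return Named numeric vector of five class means.
#' @export
conservation_by_region_class <- function(tss_bins, regulatory_regions, track,
                                         layout, flank_bp = 2000L, seed = 1L) {
  mean_over <- function(df) {
    if (nrow(df) == 0) return(NaN)
    mean(vapply(seq_len(nrow(df)), function(i) {
      track_interval_mean(track, df$chrom[i], df$start[i], df$end[i])
    }, numeric(1)))
  }
  up <- data.frame(chrom = regulatory_regions$chrom,
                   start = pmax(1, regulatory_regions$start - flank_bp),
                   end = regulatory_regions$start - 1)
  down <- data.frame(chrom = regulatory_regions$chrom,
                     start = regulatory_regions$end + 1,
                     end = regulatory_regions$end + flank_bp)
  rand <- with_seed(seed, {
    widths <- regulatory_regions$end - regulatory_regions$start + 1
    chroms <- sample(names(layout), length(widths), replace = TRUE)
    starts <- floor(runif(length(widths), 1, unname(layout[chroms]) - widths))
    data.frame(chrom = chroms, start = starts, end = starts + widths - 1)
  })
  c(tss_bin = mean_over(tss_bins),
    regulatory_region = mean_over(regulatory_regions),
    upstream_2kb = mean_over(up),
    downstream_2kb = mean_over(down),
    random_intergenic = mean_over(rand))
}
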