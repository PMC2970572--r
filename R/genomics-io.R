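## Readers/writers for the genomic text formats touched by the pipeline,
## strand-aware fragment binning, and subsampling. Internal containers are
## Bioconductor-native: fragments are a sorted GRanges, annotations plain
## data.frames with 1-based closed coordinates. BED files (0-based half-open)
## and GFF/GTF (1-based closed) are converted at the boundary.

#' Genome layout (chromosome names and lengths)
#'
#' @param chroms Character vector of chromosome names.
#' @param lengths Positive integer vector of lengths in bp.
#' @return An object of class `genome_layout` (named integer vector).
#' @export
genome_layout <- function(chroms, lengths) {
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths) || any(lengths <= 0) || anyNA(lengths)) {
    mirtss_stop("chromosome lengths must be positive, one per name",
                "mirtss_invalid_input")
  }
  structure(setNames(lengths, chroms), class = "genome_layout")
}

#' @rdname genome_layout
#' @param path Two-column tab-delimited file (chrom, length).
#' @export
read_genome_layout <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  genome_layout(tab$chrom, tab$length)
}

#' @rdname genome_layout
#' @param layout A `genome_layout` object.
#' @export
write_genome_layout <- function(layout, path) {
  writeLines(paste(names(layout), format(unname(layout), scientific = FALSE,
                                         trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Read mapped ChIP-seq fragments from a BED file
#'
#' Accepts BED3+ (plain or gzip). Lines failing the BED contract
#' (non-numeric coordinates, `end <= start`) are reported with their line
#' numbers; when a [genome_layout()] is given, out-of-bounds intervals are
#' rejected. The result is coordinate-sorted.
#'
#' @param path BED3+ file, optionally gzip-compressed.
#' @param layout Optional [genome_layout()] for bounds checking.
#' @return A sorted `GRanges` of fragments (attribute-free; star strand).
#' @export
read_fragments_bed <- function(path, layout = NULL) {
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               quote = "", colClasses = "character"),
    error = function(e) mirtss_stop(paste("cannot read BED:", conditionMessage(e)),
                                    "mirtss_parse_error"))
  if (ncol(tab) < 3) mirtss_stop("BED needs at least 3 columns", "mirtss_parse_error")
  start <- suppressWarnings(as.numeric(tab[[2]]))
  end <- suppressWarnings(as.numeric(tab[[3]]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) {
    mirtss_stop(sprintf("malformed BED interval(s) at line(s) %s (need numeric start < end)",
                        paste(head(bad, 10), collapse = ", ")),
                "mirtss_parse_error")
  }
  if (!is.null(layout)) {
    oob <- which(!(tab[[1]] %in% names(layout)) |
                   start < 0 | end > layout[tab[[1]]])
    if (length(oob)) {
      mirtss_stop(sprintf("interval(s) out of genome bounds at line(s) %s",
                          paste(head(oob, 10), collapse = ", ")),
                  "mirtss_parse_error")
    }
  }
  gr <- GenomicRanges::GRanges(tab[[1]],
                               IRanges::IRanges(start = start + 1, end = end))
  GenomicRanges::sort(gr)
}

#' Write fragments as BED3
#'
#' @param frags `GRanges` of fragments.
#' @param path Output path.
#' @export
write_fragments_bed <- function(frags, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(frags)),
                   start = GenomicRanges::start(frags) - 1L,
                   end = GenomicRanges::end(frags))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read protein-coding gene annotations
#'
#' `refFlat` dialect: the 11-column UCSC table (geneName, name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds), 0-based half-open like all UCSC tables. `GTF` dialect: parsed
#' with `rtracklayer`, gene spans from `gene` features (or the union of a
#' gene's transcripts when absent). The TSS is `span_start` on `+` and
#' `span_end` on `-`.
#'
#' @param path Annotation file.
#' @param dialect `"refFlat"` or `"GTF"`.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `span_start`, `span_end` (1-based closed) and, for refFlat, comma-packed
#'   `exon_starts`/`exon_ends` (1-based closed).
#' @export
read_genes <- function(path, dialect = c("refFlat", "GTF")) {
  dialect <- match.arg(dialect)
  if (dialect == "refFlat") {
    tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                      colClasses = "character")
    if (ncol(tab) < 11) mirtss_stop("refFlat needs 11 columns", "mirtss_parse_error")
    tx_start <- as.numeric(tab[[5]]) + 1  # 0-based half-open -> 1-based closed
    tx_end <- as.numeric(tab[[6]])
    strand <- tab[[4]]
    ex_starts <- vapply(strsplit(tab[[10]], ","), function(v)
      paste(as.numeric(v) + 1, collapse = ","), character(1))
    ex_ends <- vapply(strsplit(tab[[11]], ","), function(v)
      paste(as.numeric(v), collapse = ","), character(1))
    out <- data.frame(gene_id = tab[[1]], chrom = tab[[3]], strand = strand,
                      tss = ifelse(strand == "+", tx_start, tx_end),
                      span_start = tx_start, span_end = tx_end,
                      exon_starts = ex_starts, exon_ends = ex_ends,
                      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    feat <- gr[gr$type == "gene"]
    if (length(feat) == 0) {
      tx <- gr[gr$type %in% c("transcript", "mRNA")]
      feat <- unlist(range(GenomicRanges::split(tx, tx$gene_id)))
      feat$gene_id <- names(feat)
    }
    strand <- as.character(GenomicRanges::strand(feat))
    out <- data.frame(gene_id = feat$gene_id,
                      chrom = as.character(GenomicRanges::seqnames(feat)),
                      strand = strand,
                      tss = as.numeric(ifelse(strand == "+",
                                              GenomicRanges::start(feat),
                                              GenomicRanges::end(feat))),
                      span_start = as.numeric(GenomicRanges::start(feat)),
                      span_end = as.numeric(GenomicRanges::end(feat)),
                      stringsAsFactors = FALSE)
  }
  if (any(!out$strand %in% c("+", "-"))) {
    mirtss_stop("gene records require an explicit +/- strand", "mirtss_parse_error")
  }
  out
}

#' Write genes in refFlat dialect
#'
#' @param genes data.frame as returned by [read_genes()]; genes without exon
#'   columns are written as single-exon models spanning the gene.
#' @param path Output path.
#' @export
write_genes_refflat <- function(genes, path) {
  ex_s <- if ("exon_starts" %in% names(genes)) genes$exon_starts
          else as.character(genes$span_start)
  ex_e <- if ("exon_ends" %in% names(genes)) genes$exon_ends
          else as.character(genes$span_end)
  to0 <- function(s) vapply(strsplit(s, ","), function(v)
    paste(as.numeric(v) - 1, collapse = ","), character(1))
  exon_count <- vapply(strsplit(ex_s, ","), length, integer(1))
  df <- data.frame(genes$gene_id, genes$gene_id, genes$chrom, genes$strand,
                   genes$span_start - 1L, genes$span_end,
                   genes$span_start - 1L, genes$span_end,
                   exon_count, to0(ex_s), ex_e)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read microRNA annotations
#'
#' `GFF3`: miRBase-style, pre-miRNA spans from `miRNA_primary_transcript`
#' features (all features used when that type is absent), `ID` or `Name`
#' attribute as the identifier. `BED`: BED6 with the name column as the
#' identifier.
#'
#' @param path Annotation file.
#' @param dialect `"GFF3"` or `"BED"`.
#' @return data.frame with columns `mirna_id`, `chrom`, `strand`,
#'   `pre_start`, `pre_end` (1-based closed).
#' @export
read_mirnas <- function(path, dialect = c("GFF3", "BED")) {
  dialect <- match.arg(dialect)
  if (dialect == "GFF3") {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "miRNA_primary_transcript")) {
      gr <- gr[gr$type == "miRNA_primary_transcript"]
    }
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    id <- if (!is.null(gr$name)) gr$name else paste0("mir", seq_along(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    mirtss_stop("microRNA records require an explicit +/- strand",
                "mirtss_parse_error")
  }
  data.frame(mirna_id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand,
             pre_start = as.numeric(GenomicRanges::start(gr)),
             pre_end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

#' Write microRNAs as miRBase-style GFF3
#'
#' @param mirnas data.frame as from [read_mirnas()].
#' @param path Output path.
#' @export
write_mirnas_gff3 <- function(mirnas, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmirtss\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     mirnas$chrom, mirnas$pre_start, mirnas$pre_end,
                     mirnas$strand, mirnas$mirna_id, mirnas$mirna_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-delimited with header columns `gene_id`, `call` (P/M/A), `intensity`.
#'
#' @param path Input path.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
  req <- c("gene_id", "call", "intensity")
  if (!all(req %in% names(tab))) {
    mirtss_stop("expression table needs gene_id, call, intensity columns",
                "mirtss_parse_error")
  }
  if (any(!tab$call %in% c("P", "M", "A"))) {
    mirtss_stop("expression calls must be P, M or A", "mirtss_parse_error")
  }
  tab
}

## Fragment midpoints, 0-based: floor((start0 + end0)/2).
fragment_midpoints0 <- function(frags) {
  (GenomicRanges::start(frags) - 1 + GenomicRanges::end(frags)) %/% 2
}

#' Bin fragment counts around an anchor, strand-aware
#'
#' Each fragment is assigned to the bin containing its midpoint (a midpoint
#' exactly on a bin boundary goes to the transcriptionally downstream bin).
#' Offsets are transcriptional: negative is upstream, so minus-strand anchors
#' mirror the genomic axis. The anchor bin (offset 0) is centered on
#' `anchor_pos`.
#'
#' @param frags `GRanges` of fragments.
#' @param chrom Chromosome name.
#' @param anchor_pos 1-based coordinate of the anchor base.
#' @param strand `"+"` or `"-"`.
#' @param n_up,n_down Numbers of upstream/downstream bins (default 25 each).
#' @param bin_width Bin width in bp (default 200).
#' @param layout Optional [genome_layout()]; bins extending past chromosome
#'   ends are dropped from the profile.
#' @param anchor_id Label stored in the profile.
#' @return A [binned_profile()].
#' @export
bin_counts <- function(frags, chrom, anchor_pos, strand = "+",
                       n_up = 25L, n_down = 25L, bin_width = 200L,
                       layout = NULL, anchor_id = NA_character_) {
  if (!is.null(layout) && !chrom %in% names(layout)) {
    mirtss_stop(sprintf("unknown chromosome '%s'", chrom), "mirtss_invalid_input")
  }
  offsets <- seq.int(-n_up, n_down)
  if (!is.null(layout)) {
    half <- bin_width %/% 2
    ## genomic extents of each transcriptional offset
    gstart0 <- if (strand == "+") (anchor_pos - 1) - half + offsets * bin_width
               else (anchor_pos - 1) - half - offsets * bin_width + 1
    keep <- gstart0 >= 0 & (gstart0 + bin_width) <= layout[[chrom]]
    ## truncation must keep a contiguous window including 0
    offsets <- offsets[keep]
    if (length(offsets) == 0 || !any(offsets == 0)) {
      mirtss_stop("anchor bin falls outside the chromosome", "mirtss_invalid_input")
    }
  }
  counts <- profile_counts_matrix(frags, data.frame(
    chrom = chrom, pos = anchor_pos, strand = strand,
    stringsAsFactors = FALSE), offsets, bin_width)[1, ]
  binned_profile(counts, offsets, anchor_id = anchor_id, chrom = chrom,
                 anchor_pos = anchor_pos, strand = strand, bin_width = bin_width)
}

#' Profiles for many anchors at once
#'
#' Vectorized midpoint binning over a table of anchors sharing one offset
#' window; used by the fitting and scanning paths.
#'
#' @param frags `GRanges` of fragments.
#' @param anchors data.frame with columns `chrom`, `pos` (1-based anchor
#'   base) and `strand`.
#' @param offsets Contiguous signed bin offsets including 0.
#' @param bin_width Bin width in bp.
#' @return Integer matrix, one row per anchor, one column per offset.
#' @export
profile_counts_matrix <- function(frags, anchors, offsets, bin_width = 200L) {
  bin_width <- as.integer(bin_width)
  half <- bin_width %/% 2
  mids <- split(fragment_midpoints0(frags),
                as.character(GenomicRanges::seqnames(frags)))
  mids <- lapply(mids, sort)
  n_off <- length(offsets)
  out <- matrix(0L, nrow = nrow(anchors), ncol = n_off)
  for (i in seq_len(nrow(anchors))) {
    mv <- mids[[anchors$chrom[i]]]
    if (is.null(mv) || length(mv) == 0) next
    a0 <- anchors$pos[i] - 1  # 0-based anchor base
    ## transcriptional offset of each midpoint; boundary midpoints fall
    ## downstream on both strands by construction of the two formulas
    off <- if (anchors$strand[i] == "+") (mv - a0 + half) %/% bin_width
           else (a0 - mv + half) %/% bin_width
    off <- off[off >= offsets[1] & off <= offsets[n_off]]
    if (length(off)) {
      tb <- tabulate(off - offsets[1] + 1L, nbins = n_off)
      out[i, ] <- tb
    }
  }
  out
}

#' Subsample fragments without replacement
#'
#' @param frags `GRanges` of fragments.
#' @param n Number of fragments to keep.
#' @param seed Integer seed.
#' @return Sorted `GRanges` with `n` fragments.
#' @export
subsample_fragments <- function(frags, n, seed) {
  n <- as.integer(n)
  if (n < 0 || n > length(frags)) {
    mirtss_stop("subsample size out of range", "mirtss_invalid_input")
  }
  idx <- with_seed(seed, sample.int(length(frags), n))
  GenomicRanges::sort(frags[idx])
}

#' Read an interval track (e.g. CpG islands)
#'
#' @param path BED file of intervals.
#' @return `GRanges`.
#' @export
read_interval_track <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Read a per-base score track
#'
#' Fixed-step wiggle or bedGraph, via `rtracklayer`.
#'
#' @param path Track file.
#' @param dialect `"wig"` or `"bedGraph"` (default: guessed from extension).
#' @return An object of class `score_track`.
#' @export
read_score_track <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(wig)(\\.gz)?$", path)) "wig" else "bedGraph"
  }
  gr <- rtracklayer::import(path, format = dialect)
  structure(list(gr = GenomicRanges::sort(gr)), class = "score_track")
}

#' Per-base scores at positions
#'
#' @param track A `score_track`.
#' @param chrom Chromosome.
#' @param positions 1-based base positions.
#' @return Numeric scores (0 where the track has no coverage).
#' @export
track_scores <- function(track, chrom, positions) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(positions, width = 1))
  hits <- GenomicRanges::findOverlaps(q, track$gr, select = "first")
  sc <- rep(0, length(positions))
  ok <- !is.na(hits)
  sc[ok] <- track$gr$score[hits[ok]]
  sc
}

#' Mean track score over an interval
#'
#' @param track A `score_track`.
#' @param chrom Chromosome.
#' @param start,end 1-based closed interval.
#' @return Mean per-base score (uncovered bases count as 0).
#' @export
track_interval_mean <- function(track, chrom, start, end) {
  mean(track_scores(track, chrom, seq.int(start, end)))
}
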