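# Priority-based peak-to-genome annotation and nearest-TSS assignment.

#' Annotation configuration
#'
#' Window constants for peak annotation. The TSS window is symmetric
#' (+/- `tss_window` bp around the TSS); the two upstream windows are
#' strand-aware (5' of the TSS in transcription direction). "Intergenic"
#' is defined as outside every region between `upstream_far` bp upstream
#' of a TSS and that gene's 3'UTR end.
#'
#' @param tss_window bp around the TSS (default 1000)
#' @param upstream_near outer edge of the near upstream window (default 5000)
#' @param upstream_far outer edge of the far upstream window and of the
#'   gene locus (default 10000)
#' @return an `annotation_config` object
#' @export
annotation_config <- function(tss_window = 1000L, upstream_near = 5000L,
                              upstream_far = 10000L) {
  stopifnot(tss_window > 0, tss_window < upstream_near,
            upstream_near < upstream_far)
  structure(list(tss_window = as.integer(tss_window),
                 upstream_near = as.integer(upstream_near),
                 upstream_far = as.integer(upstream_far)),
            class = "annotation_config")
}

#' Annotation categories in priority order
#' @return character vector of category labels, highest priority first
#' @export
annotation_categories <- function() {
  c("TSS_1KB", "UP_1_5KB", "UP_5_10KB", "EXON", "UTR", "INTRON", "INTERGENIC")
}

#' Annotate peaks to genomic categories with a fixed priority
#'
#' Each peak receives exactly one category: the first, in the priority
#' order `TSS_1KB > UP_1_5KB > UP_5_10KB > EXON > UTR > INTRON >
#' INTERGENIC`, whose region the peak overlaps by at least one base pair
#' for any gene. A peak is `INTERGENIC` iff it overlaps no gene locus
#' (from `upstream_far` bp upstream of a TSS to the 3' end of the
#' transcript). Intronic peaks also carry the index of the overlapped
#' intron, numbered 1..n in transcription direction; when several
#' transcripts' introns overlap the peak, the transcript with the TSS
#' nearest the peak mode decides, then the smallest index.
#'
#' @param peaks peak data frame (`chrom`, `start`, `end`, `mode`, `name`)
#' @param genes gene-model data frame; empty means everything is intergenic
#' @param cfg an [annotation_config()]
#' @return the peak frame with added `category` and `intron_index` columns
#' @export
annotate_peaks <- function(peaks, genes, cfg = annotation_config()) {
  check_cols(peaks, c("chrom", "start", "end", "mode"), "peaks")
  peaks$category <- "INTERGENIC"
  peaks$intron_index <- NA_integer_
  if (!nrow(peaks) || !nrow(genes)) return(peaks)
  reg <- gene_regions(genes, cfg)
  prio <- stats::setNames(seq_along(annotation_categories()),
                          annotation_categories())
  hits <- GenomicRanges::findOverlaps(
    as_granges(peaks),
    as_granges(reg), ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    rank <- prio[reg$category[sh]]
    best <- tapply(rank, qh, min)
    idx <- as.integer(names(best))
    peaks$category[idx] <- annotation_categories()[best]
    # intron index: among overlapped introns of peaks whose category is
    # INTRON, prefer the transcript with the nearest TSS, then the
    # smallest index
    ip <- idx[peaks$category[idx] == "INTRON"]
    if (length(ip)) {
      for (i in ip) {
        s <- sh[qh == i & reg$category[sh] == "INTRON"]
        d <- abs(reg$tss[s] - peaks$mode[i])
        s <- s[d == min(d)]
        peaks$intron_index[i] <- min(reg$intron_index[s])
      }
    }
  }
  peaks
}

#' Assign each peak to the gene with the nearest TSS
#'
#' Distance is |TSS - peak mode| on the same chromosome (cross-chromosome
#' assignment is never made); ties go to the lexicographically smallest
#' `gene_id`. Peaks on chromosomes without genes get `NA`.
#'
#' @param peaks peak data frame with `chrom` and `mode`
#' @param genes gene-model data frame
#' @return data frame: peak `name`, assigned `gene_id`, signed `distance`
#'   (mode - TSS) and `abs_distance`, plus `upstream` (TRUE when the mode
#'   lies 5' of the assigned TSS in transcription direction)
#' @export
nearest_tss <- function(peaks, genes) {
  check_cols(peaks, c("chrom", "mode"), "peaks")
  nm <- if ("name" %in% names(peaks)) peaks$name else as.character(seq_len(nrow(peaks)))
  tss <- gene_tss(genes)
  out <- data.frame(name = nm, gene_id = NA_character_,
                    distance = NA_integer_, abs_distance = NA_integer_,
                    upstream = NA, stringsAsFactors = FALSE)
  for (ch in unique(peaks$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    pi <- which(peaks$chrom == ch)
    if (!nrow(g) || !length(pi)) next
    gt <- tss[g$gene_id]
    ord <- order(g$gene_id)  # lexicographic tie-break: first minimum wins
    g <- g[ord, , drop = FALSE]; gt <- gt[ord]
    for (i in pi) {
      d <- abs(gt - peaks$mode[i])
      j <- which.min(d)
      out$gene_id[i] <- g$gene_id[j]
      out$distance[i] <- as.integer(peaks$mode[i] - gt[j])
      out$abs_distance[i] <- as.integer(d[j])
      out$upstream[i] <- if (g$strand[j] == "+") peaks$mode[i] < gt[j]
                         else peaks$mode[i] > gt[j]
    }
  }
  out
}
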