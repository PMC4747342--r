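# Cistrome-level analyses: annotation fold-enrichment against random
# backgrounds, dual-motif co-occurrence, spatial centering profiles, and
# motif-conditioned peak-set overlap tests.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Wraps the counts, the sample odds ratio `ad/bc` (flagged undefined
#' when `b*c = 0`), and the two-sided exact p-value.
#'
#' @param a,b,c,d nonnegative counts, row-wise: `[[a, b], [c, d]]`
#' @return a `contingency_2x2` object
#' @export
fisher_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  or <- if (b * c == 0) NA_real_ else (a * d) / (b * c)
  p <- stats::fisher.test(m)$p.value
  structure(list(table = m, odds_ratio = or,
                 odds_ratio_undefined = b * c == 0, fisher_p = p),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("2x2 contingency table:\n")
  print(x$table)
  cat(sprintf("odds ratio: %s, Fisher exact p (two-sided): %.4g\n",
              if (x$odds_ratio_undefined) "undefined (zero cell)" else
                sprintf("%.3g", x$odds_ratio), x$fisher_p))
  invisible(x)
}

#' Annotation fold-enrichment of peaks versus random backgrounds
#'
#' Annotates the observed peaks and `n_replicates` random peak sets, each
#' size- and width-matched to the observed set (one random interval per
#' observed peak, same width, start uniform genome-wide), and reports the
#' ratio of observed to mean random count per category, plus the same
#' breakdown by intron index.
#'
#' @param peaks peak data frame
#' @param genes gene-model data frame
#' @param chrom_lengths named chromosome lengths
#' @param cfg an [annotation_config()]
#' @param n_replicates random replicate sets (default 10)
#' @param seed integer seed for the random backgrounds
#' @param fixed_width optional: use this width for all random intervals
#'   instead of width-matching per peak
#' @return a `category_enrichment` object: list with `categories` and
#'   `introns` data frames (`observed`, `random_mean`, `ratio`; ratio is
#'   `NA` when the random mean is 0)
#' @export
annotation_enrichment <- function(peaks, genes, chrom_lengths,
                                  cfg = annotation_config(),
                                  n_replicates = 10L, seed = NULL,
                                  fixed_width = NULL) {
  stopifnot(n_replicates >= 1)
  ann <- annotate_peaks(peaks, genes, cfg)
  cats <- annotation_categories()
  obs <- table(factor(ann$category, levels = cats))
  obs_intron <- table(ann$intron_index[ann$category == "INTRON"])
  widths <- if (is.null(fixed_width)) peaks$end - peaks$start
            else rep(as.integer(fixed_width), nrow(peaks))
  rnd <- matrix(0, n_replicates, length(cats), dimnames = list(NULL, cats))
  rnd_intron <- list()
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      rp <- do.call(rbind, lapply(split(seq_along(widths), widths), function(ii)
        sample_random_intervals(chrom_lengths, length(ii), widths[ii[1]])))
      rp$name <- as.character(seq_len(nrow(rp)))
      ra <- annotate_peaks(rp, genes, cfg)
      rnd[r, ] <- table(factor(ra$category, levels = cats))
      rnd_intron[[r]] <- ra$intron_index[ra$category == "INTRON"]
    }
  })
  rmean <- colMeans(rnd)
  categories <- data.frame(
    category = cats, observed = as.integer(obs),
    random_mean = unname(rmean),
    ratio = ifelse(rmean > 0, as.integer(obs) / rmean, NA_real_),
    stringsAsFactors = FALSE)
  idx <- sort(unique(c(as.integer(names(obs_intron)),
                       unlist(rnd_intron, use.names = FALSE))))
  introns <- data.frame(intron_index = integer(), observed = integer(),
                        random_mean = numeric(), ratio = numeric())
  if (length(idx)) {
    oi <- table(factor(ann$intron_index[ann$category == "INTRON"], levels = idx))
    ri <- sapply(idx, function(k)
      mean(vapply(rnd_intron, function(v) sum(v == k, na.rm = TRUE), numeric(1))))
    introns <- data.frame(intron_index = idx, observed = as.integer(oi),
                          random_mean = ri,
                          ratio = ifelse(ri > 0, as.integer(oi) / ri, NA_real_),
                          stringsAsFactors = FALSE)
  }
  structure(list(categories = categories, introns = introns,
                 n_replicates = n_replicates, n_peaks = nrow(peaks)),
            class = "category_enrichment")
}

#' @export
print.category_enrichment <- function(x, ...) {
  cat(sprintf("Annotation enrichment over %d peaks vs %d random sets:\n",
              x$n_peaks, x$n_replicates))
  print(x$categories, row.names = FALSE)
  invisible(x)
}

#' Co-occurrence of two motifs within a peak set
#'
#' Partitions peaks by presence/absence of each motif (hit multiplicity
#' is irrelevant) and reports the fraction with either motif and the
#' conditional fraction P(motif B | motif A).
#'
#' @param peaks peak data frame
#' @param hits_a,hits_b hit frames from [scan_peaks()] for motifs A and B
#' @return a `cooccurrence_partition` object
#' @export
motif_cooccurrence <- function(peaks, hits_a, hits_b) {
  ha <- peak_has_motif(peaks, hits_a)
  hb <- peak_has_motif(peaks, hits_b)
  n <- nrow(peaks)
  part <- c(n_both = sum(ha & hb), n_a_only = sum(ha & !hb),
            n_b_only = sum(!ha & hb), n_neither = sum(!ha & !hb))
  structure(list(
    counts = part, total = n,
    motif_a = if (nrow(hits_a)) hits_a$motif[1] else "A",
    motif_b = if (nrow(hits_b)) hits_b$motif[1] else "B",
    frac_either = unname((part[1] + part[2] + part[3]) / n),
    frac_b_given_a = if (sum(ha)) unname(part[1] / sum(ha)) else NA_real_),
    class = "cooccurrence_partition")
}

#' @export
print.cooccurrence_partition <- function(x, ...) {
  cat(sprintf("Motif co-occurrence over %d peaks (%s = A, %s = B):\n",
              x$total, x$motif_a, x$motif_b))
  print(x$counts)
  cat(sprintf("either motif: %.1f%%; P(B | A): %.1f%%\n",
              100 * x$frac_either, 100 * x$frac_b_given_a))
  invisible(x)
}

#' Spatial profile of motif hits relative to peak centers
#'
#' Bins observed hit-start offsets over the supplied (pre-filtered) peaks
#' and builds a matched null from random fixed-width regions scanned the
#' same way. Densities are pooled hit counts per bin divided by the
#' number of regions, so observed and null are directly comparable.
#'
#' @param peaks peak data frame, already filtered to the peaks of
#'   interest (e.g. those containing the motif)
#' @param pwm a `pwm` object
#' @param genome a [Biostrings::DNAStringSet]
#' @param null_n number of random null regions (default 2000)
#' @param null_width width of null regions in bp (default 300)
#' @param bins bin edges for offsets relative to center
#'   (default `seq(-150, 150, by = 10)`)
#' @param seed seed for null-region sampling
#' @param p_threshold occurrence threshold (default 1e-4)
#' @return a `spatial_profile` object with a `profile` data frame
#'   (`bin_lo`, `bin_hi`, `observed_density`, `null_density`)
#' @export
spatial_profile <- function(peaks, pwm, genome, null_n = 2000L,
                            null_width = 300L,
                            bins = seq(-150L, 150L, by = 10L),
                            seed = NULL, p_threshold = 1e-4) {
  if (!nrow(peaks)) {
    return(structure(list(profile = data.frame(
      bin_lo = numeric(), bin_hi = numeric(),
      observed_density = numeric(), null_density = numeric()),
      n_peaks = 0L, n_null = 0L), class = "spatial_profile"))
  }
  hits <- scan_peaks(peaks, genome, pwm, p_threshold)
  null_peaks <- sample_random_intervals(genome_lengths(genome), null_n,
                                        null_width, seed = seed)
  null_peaks$name <- paste0("null_", seq_len(nrow(null_peaks)))
  null_hits <- scan_peaks(null_peaks, genome, pwm, p_threshold)
  binify <- function(off, n_regions) {
    h <- graphics::hist(off[off >= min(bins) & off < max(bins)],
                        breaks = bins, plot = FALSE, right = FALSE)
    h$counts / n_regions
  }
  prof <- data.frame(
    bin_lo = bins[-length(bins)], bin_hi = bins[-1],
    observed_density = binify(hits$offset, nrow(peaks)),
    null_density = binify(null_hits$offset, max(1L, nrow(null_peaks))))
  structure(list(profile = prof, n_peaks = nrow(peaks),
                 n_null = nrow(null_peaks)), class = "spatial_profile")
}

#' @export
print.spatial_profile <- function(x, ...) {
  cat(sprintf("Spatial motif profile: %d peaks, %d null regions, %d bins\n",
              x$n_peaks, x$n_null, nrow(x$profile)))
  invisible(x)
}

#' Motif-conditioned peak-set overlap test
#'
#' Given a peak set already filtered for presence of motif 1, cross-
#' classifies those peaks by (overlaps the second peak set by >= 1 bp)
#' x (contains motif 2), and tests association by two-sided Fisher exact.
#'
#' @param peaks_a motif-1-filtered peak set
#' @param peaks_b second peak set (e.g. the fusion-protein cistrome)
#' @param hits2 motif-2 hits on `peaks_a` from [scan_peaks()]
#' @return a `contingency_2x2` with rows = overlap yes/no, columns =
#'   motif-2 yes/no
#' @export
motif_conditioned_overlap_test <- function(peaks_a, peaks_b, hits2) {
  if (!nrow(peaks_a)) stop("peaks_a is empty")
  ov <- GenomicRanges::countOverlaps(as_granges(peaks_a), as_granges(peaks_b)) > 0
  m2 <- peak_has_motif(peaks_a, hits2)
  fisher_2x2(sum(ov & m2), sum(ov & !m2), sum(!ov & m2), sum(!ov & !m2))
}
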