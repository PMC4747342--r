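# Genomic interval arithmetic. All coordinates are 0-based, half-open
# [start, end); BED input is native, 1-based formats are converted on read.

#' Do two genomic intervals overlap?
#'
#' Overlap means at least one shared base pair under half-open coordinates:
#' same chromosome, `start_a < end_b` and `start_b < end_a`. All arguments
#' are vectorized and recycled.
#'
#' @param chrom_a,start_a,end_a first interval(s)
#' @param chrom_b,start_b,end_b second interval(s)
#' @return logical vector
#' @examples
#' interval_overlaps("chr1", 0, 100, "chr1", 99, 200)   # TRUE, 1 bp shared
#' interval_overlaps("chr1", 0, 100, "chr1", 100, 200)  # FALSE, adjacent
#' @export
interval_overlaps <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

#' Redefine peak boundaries around the peak mode
#'
#' ChIP-seq peak boundaries are re-set to a fixed half-width around the
#' position of maximal signal (the mode), the convention used throughout
#' this package: the default of 150 bp yields 300 bp peaks. Intervals are
#' clipped to chromosome bounds; the mode itself is preserved.
#'
#' @param peaks peak data frame with columns `chrom`, `start`, `end`,
#'   `mode` (and any others, which are carried through)
#' @param chrom_lengths named integer vector of chromosome lengths (bp)
#' @param halfwidth bp on each side of the mode (default 150)
#' @return the peak data frame with updated `start`/`end`
#' @export
redefine_boundaries <- function(peaks, chrom_lengths, halfwidth = 150L) {
  check_cols(peaks, c("chrom", "start", "end", "mode"), "peaks")
  stopifnot(is_count(halfwidth), halfwidth > 0)
  bad <- !(peaks$chrom %in% names(chrom_lengths))
  if (any(bad))
    stop("peaks on unknown chromosome(s): ",
         paste(unique(peaks$chrom[bad]), collapse = ", "))
  len <- unname(chrom_lengths[peaks$chrom])
  if (any(peaks$mode < 0 | peaks$mode >= len))
    stop("peak mode outside chromosome bounds")
  peaks$start <- pmax(0L, as.integer(peaks$mode - halfwidth))
  peaks$end <- pmin(as.integer(len), as.integer(peaks$mode + halfwidth))
  peaks
}

#' Sample random genomic intervals of fixed width
#'
#' Null-background intervals for enrichment analyses: `n` intervals of
#' exactly `width` bp, with the start position drawn uniformly over all
#' valid starts genome-wide (so chromosomes are weighted by length).
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp)
#' @param n number of intervals; `n <= 0` returns an empty frame
#' @param width interval width in bp; must not exceed the shortest chromosome
#' @param seed optional integer seed for reproducibility
#' @return data frame with columns `chrom`, `start`, `end`, `mode`
#'   (mode = interval midpoint)
#' @export
sample_random_intervals <- function(chrom_lengths, n, width, seed = NULL) {
  stopifnot(length(chrom_lengths) >= 1L, !is.null(names(chrom_lengths)))
  width <- as.integer(width)
  if (width > min(chrom_lengths))
    stop("width exceeds the shortest chromosome")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), mode = integer(),
                      stringsAsFactors = FALSE)
  if (n <= 0) return(empty)
  with_seed(seed, {
    valid <- pmax(as.numeric(chrom_lengths) - width + 1, 0)
    chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                    prob = valid / sum(valid))
    v <- unname(valid[match(chrom, names(chrom_lengths))])
    start <- pmin(as.integer(floor(stats::runif(n, 0, v))), as.integer(v) - 1L)
    data.frame(chrom = chrom, start = start, end = start + width,
               mode = start + width %/% 2L, stringsAsFactors = FALSE)
  })
}
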