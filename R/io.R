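# Peak BED I/O and small text-format helpers. BED is 0-based half-open
# natively; the peak mode is carried in the thickStart column (column 7)
# and defaults to the interval midpoint when absent.

#' Read peaks from a BED6(+) file
#'
#' Columns: chrom, start, end, name, score, strand, and optionally
#' thickStart holding the peak mode. Missing name/score columns are
#' filled with defaults; a missing mode defaults to the interval
#' midpoint.
#'
#' @param path BED path
#' @return peak data frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `mode`)
#' @export
read_peaks_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns: ", path)
  bad <- which(!(is.numeric(bed[[2]]) & is.numeric(bed[[3]])) |
                 bed[[2]] < 0 | bed[[2]] >= bed[[3]])
  if (length(bad))
    stop(sprintf("malformed BED interval in %s at line %d", path, bad[1]))
  n <- nrow(bed)
  peaks <- data.frame(
    chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]),
    name = if (ncol(bed) >= 4) as.character(bed[[4]]) else
      sprintf("peak%05d", seq_len(n)),
    score = if (ncol(bed) >= 5) suppressWarnings(as.numeric(bed[[5]])) else 0,
    strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else ".",
    stringsAsFactors = FALSE)
  peaks$mode <- if (ncol(bed) >= 7) as.integer(bed[[7]]) else
    peaks$start + (peaks$end - peaks$start) %/% 2L
  peaks
}

#' Write peaks as BED6 + thickStart (mode)
#' @param peaks peak data frame
#' @param path output path
#' @export
write_peaks_bed <- function(peaks, path) {
  check_cols(peaks, c("chrom", "start", "end", "name", "mode"), "peaks")
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    peaks$score %||% 0,
                    if ("strand" %in% names(peaks)) peaks$strand else ".",
                    peaks$mode)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a one-id-per-line gene list
#' @param path text file
#' @return character vector
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a JSON run manifest
#'
#' Records the subcommand or analysis name, input paths, thresholds,
#' seed and package version alongside each output.
#' @param path output JSON path
#' @param analysis analysis name
#' @param inputs named list/vector of input paths
#' @param params named list of thresholds and options
#' @param seed RNG seed used (or `NA`)
#' @export
write_run_manifest <- function(path, analysis, inputs = list(),
                               params = list(), seed = NA) {
  jsonlite::write_json(list(
    analysis = analysis, inputs = inputs, params = params, seed = seed,
    package = "ppfptools",
    version = as.character(utils::packageVersion("ppfptools")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
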