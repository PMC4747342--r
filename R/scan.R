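# FIMO-style motif occurrence calling: both strands of every peak are
# scored against the PWM and windows whose exact null p-value falls below
# the threshold are reported as hits.

#' Read a genome FASTA into a DNAStringSet
#'
#' Contig names are truncated at the first whitespace.
#' @param path FASTA path
#' @return a [Biostrings::DNAStringSet]
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Chromosome lengths of a genome
#' @param genome a [Biostrings::DNAStringSet]
#' @return named integer vector
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Genome-wide mononucleotide frequencies
#'
#' The 0-order background model used by default for motif scanning.
#' @param genome a [Biostrings::DNAStringSet]
#' @return length-4 probability vector (A, C, G, T)
#' @export
base_frequencies <- function(genome) {
  f <- colSums(Biostrings::alphabetFrequency(genome)[, DNA_BASES, drop = FALSE])
  unname(f / sum(f))
}

#' Extract peak sequences from a genome
#' @param peaks peak data frame
#' @param genome a [Biostrings::DNAStringSet]
#' @return character vector of sequences, named by peak name
#' @export
peak_sequences <- function(peaks, genome) {
  bad <- !(peaks$chrom %in% names(genome))
  if (any(bad)) stop("peak(s) on contig absent from FASTA: ",
                     paste(utils::head(peaks$name[bad]), collapse = ", "))
  len <- genome_lengths(genome)[peaks$chrom]
  out <- peaks$end > len | peaks$start < 0
  if (any(out)) stop("peak(s) outside FASTA bounds: ",
                     paste(utils::head(peaks$name[out]), collapse = ", "))
  seqs <- as.character(Biostrings::subseq(genome[peaks$chrom],
                                          start = peaks$start + 1L,
                                          end = peaks$end))
  stats::setNames(seqs, peaks$name)
}

seq_to_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
}

#' Scan peaks for motif occurrences
#'
#' Every window on either strand whose score's exact null exceedance
#' probability is below `p_threshold` is reported. Offsets are the hit
#' start relative to the peak center (negative = left of center); a peak
#' "contains" the motif iff it has at least one hit.
#'
#' @param peaks peak data frame (`chrom`, `start`, `end`, `name`)
#' @param genome a [Biostrings::DNAStringSet] or FASTA path
#' @param pwm a `pwm` object
#' @param p_threshold occurrence threshold on the null p-value
#'   (default 1e-4, the FIMO default)
#' @param background optional length-4 background; default is the
#'   genome-wide mononucleotide frequency of `genome`
#' @return data frame of hits: `peak_name`, `motif`, `offset`, `strand`,
#'   `score` (bits), `pvalue`
#' @export
scan_peaks <- function(peaks, genome, pwm, p_threshold = 1e-4,
                       background = NULL) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  check_cols(peaks, c("chrom", "start", "end"), "peaks")
  if (!"name" %in% names(peaks)) peaks$name <- as.character(seq_len(nrow(peaks)))
  bg <- background %||% base_frequencies(genome)
  pwm <- pwm_from_probs(pwm$probs, name = pwm$name, background = bg)
  tab <- score_pvalue_table(pwm)
  lo_f <- pwm_log_odds_quantized(pwm, tab$granularity)
  lo_r <- pwm_log_odds_quantized(pwm_reverse_complement(pwm), tab$granularity)
  seqs <- peak_sequences(peaks, genome)
  center <- peaks$start + (peaks$end - peaks$start) %/% 2L
  res <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    codes <- seq_to_codes(seqs[[i]])
    sf <- score_windows_int(lo_f, codes)
    sr <- score_windows_int(lo_r, codes)
    hf <- which(pwm_score_pvalue(tab, sf) < p_threshold)
    hr <- which(pwm_score_pvalue(tab, sr) < p_threshold)
    if (!length(hf) && !length(hr)) next
    off <- function(w) as.integer(peaks$start[i] + w - 1L - center[i])
    res[[i]] <- data.frame(
      peak_name = peaks$name[i], motif = pwm$name,
      offset = c(off(hf), off(hr)),
      strand = c(rep("+", length(hf)), rep("-", length(hr))),
      score = c(sf[hf], sr[hr]),
      pvalue = pwm_score_pvalue(tab, c(sf[hf], sr[hr])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(peak_name = character(), motif = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Peaks containing at least one motif hit
#' @param peaks peak data frame
#' @param hits hit frame from [scan_peaks()]
#' @return logical vector along `peaks` rows
#' @export
peak_has_motif <- function(peaks, hits) {
  unknown <- setdiff(unique(hits$peak_name), peaks$name)
  if (length(unknown))
    stop("hits reference unknown peak(s): ",
         paste(utils::head(unknown), collapse = ", "))
  peaks$name %in% hits$peak_name
}
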