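# Position weight matrices: construction, log-odds scoring, and the exact
# null distribution of scores under a 0-order background, computed by
# dynamic programming over discretized scores. This is what turns a score
# cutoff into the FIMO-style occurrence rule "null exceedance p < 1e-4".

DNA_BASES <- c("A", "C", "G", "T")

#' Build a PWM from a count matrix
#'
#' Probabilities are `(count + pseudocount * background) / (colsum +
#' pseudocount)`: the pseudocount is distributed over letters in
#' proportion to the background, so zero counts never produce -Inf
#' log-odds (unless `pseudocount = 0`).
#'
#' @param counts integer matrix, positions x 4 (columns A, C, G, T)
#' @param name motif identifier
#' @param pseudocount total pseudocount per position (default 0.1)
#' @param background length-4 background probabilities (default uniform)
#' @return a `pwm` object (list: `name`, `width`, `probs`, `background`,
#'   `pseudocount`)
#' @export
pwm_from_counts <- function(counts, name = "motif", pseudocount = 0.1,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 4L, nrow(counts) >= 1L, all(counts >= 0),
            pseudocount >= 0, length(background) == 4L,
            abs(sum(background) - 1) < 1e-9)
  rs <- rowSums(counts)
  if (pseudocount == 0 && any(rs == 0))
    stop("all-zero position with pseudocount 0")
  probs <- (counts + pseudocount * matrix(background, nrow(counts), 4,
                                          byrow = TRUE)) / (rs + pseudocount)
  colnames(probs) <- DNA_BASES
  structure(list(name = name, width = nrow(probs), probs = unname(probs),
                 background = unname(background), pseudocount = pseudocount),
            class = "pwm")
}

#' Build a PWM directly from a probability matrix
#' @param probs positions x 4 matrix of letter probabilities (rows sum to 1)
#' @inheritParams pwm_from_counts
#' @export
pwm_from_probs <- function(probs, name = "motif", background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4L, all(probs >= 0),
            all(abs(rowSums(probs) - 1) < 1e-6))
  structure(list(name = name, width = nrow(probs), probs = unname(probs),
                 background = unname(background), pseudocount = 0),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, consensus %s\n", x$name, x$width,
              pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable letter per position)
#' @param pwm a `pwm` object
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 1, which.max)], collapse = "")
}

#' Log-odds scoring matrix of a PWM, in bits
#' @param pwm a `pwm` object
#' @return positions x 4 matrix of log2(prob / background)
#' @export
pwm_log_odds <- function(pwm) {
  lo <- log2(sweep(pwm$probs, 2, pwm$background, "/"))
  colnames(lo) <- DNA_BASES
  lo
}

#' Reverse complement of a PWM
#'
#' Scanning the forward strand with the reverse-complemented PWM is
#' equivalent to scanning the reverse strand with the original.
#' @param pwm a `pwm` object
#' @export
pwm_reverse_complement <- function(pwm) {
  p <- pwm$probs[rev(seq_len(pwm$width)), rev(seq_len(4L)), drop = FALSE]
  structure(list(name = pwm$name, width = pwm$width, probs = unname(p),
                 background = pwm$background[4:1],
                 pseudocount = pwm$pseudocount), class = "pwm")
}

#' Score one sequence window against a PWM
#'
#' Sum over positions of log2(P_pwm(base) / P_background(base)), in bits.
#' Windows containing any non-ACGT letter score -Inf and can never be
#' occurrences.
#'
#' @param pwm a `pwm` object
#' @param seq character string of length `pwm$width`
#' @return log-odds score in bits
#' @export
score_window <- function(pwm, seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  if (length(s) != pwm$width) stop("sequence length must equal PWM width")
  idx <- match(s, DNA_BASES)
  if (anyNA(idx)) return(-Inf)
  lo <- pwm_log_odds(pwm)
  sum(lo[cbind(seq_len(pwm$width), idx)])
}

# Vectorized scoring of every window of an integer-coded sequence
# (codes 1..4 = A,C,G,T, NA for anything else). Returns one score per
# window start; windows containing NA get -Inf.
score_windows_int <- function(lo, codes) {
  w <- nrow(lo); L <- length(codes)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    na <- is.na(cj)
    bad <- bad | na
    cj[na] <- 1L
    scores <- scores + lo[j, cj]
  }
  scores[bad] <- -Inf
  scores
}

#' Quantized log-odds matrix
#'
#' The log-odds matrix with every entry rounded to `granularity` bits;
#' scanning uses this quantized matrix so that window scores live on the
#' same discrete grid as the null distribution from
#' [score_pvalue_table()], making score-to-p-value lookups exact.
#' @param pwm a `pwm` object
#' @param granularity score bin width in bits (default 0.001)
#' @export
pwm_log_odds_quantized <- function(pwm, granularity = 0.001) {
  round(pwm_log_odds(pwm) / granularity) * granularity
}

#' Exact null distribution of PWM scores
#'
#' Dynamic programming over PWM positions under the 0-order background
#' model, on log-odds entries quantized to `granularity`-bit bins (see
#' [pwm_log_odds_quantized()]), yields P(score >= s) for a random
#' width-mer. The returned table maps any score to its null exceedance
#' probability via [pwm_score_pvalue()].
#'
#' @param pwm a `pwm` object
#' @param granularity score bin width in bits (default 0.001)
#' @return a `pwm_pvalue_table` (list: `granularity`, `min_units`,
#'   `pvalue` vector indexed by discretized score)
#' @export
score_pvalue_table <- function(pwm, granularity = 0.001) {
  stopifnot(granularity > 0)
  lo <- pwm_log_odds(pwm)
  units <- round(lo / granularity)  # integer scores per (position, base)
  units[!is.finite(units)] <- round(-1000 / granularity)  # effective -Inf
  # running support bounds keep the convolution tight
  cur_min <- 0; cur_max <- 0
  dist <- 1  # P(sum = 0) before any position
  for (j in seq_len(nrow(units))) {
    u <- units[j, ]
    new_min <- cur_min + min(u); new_max <- cur_max + max(u)
    nd <- numeric(new_max - new_min + 1L)
    for (k in 1:4) {
      sh <- (cur_min + u[k]) - new_min
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + pwm$background[k] * dist
    }
    dist <- nd; cur_min <- new_min; cur_max <- new_max
  }
  sf <- rev(cumsum(rev(dist)))  # P(score_units >= cur_min + i - 1)
  sf <- pmin(sf, 1)
  structure(list(granularity = granularity, min_units = cur_min,
                 max_units = cur_max, pvalue = sf),
            class = "pwm_pvalue_table")
}

#' Null exceedance p-values for PWM scores
#'
#' Looks scores up in a [score_pvalue_table()]. Scores below the table's
#' support get p = 1; scores above it get the smallest tabulated p;
#' -Inf scores get p = 1.
#'
#' @param table a `pwm_pvalue_table`
#' @param scores numeric vector of log-odds scores (bits)
#' @return numeric vector of p-values in (0, 1]
#' @export
pwm_score_pvalue <- function(table, scores) {
  u <- round(scores / table$granularity)
  i <- pmin(pmax(u - table$min_units + 1, 1), length(table$pvalue))
  p <- table$pvalue[i]
  p[!is.finite(scores)] <- 1
  p[u < table$min_units] <- 1
  pmax(p, .Machine$double.xmin)
}

#' Minimum score reaching a target p-value
#' @param table a `pwm_pvalue_table`
#' @param p_threshold occurrence threshold (default 1e-4)
#' @return the smallest score (bits) with null p < `p_threshold`, or Inf
#'   if unattainable
#' @export
pwm_score_threshold <- function(table, p_threshold = 1e-4) {
  i <- which(table$pvalue < p_threshold)
  if (!length(i)) return(Inf)
  (table$min_units + min(i) - 1L) * table$granularity
}
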