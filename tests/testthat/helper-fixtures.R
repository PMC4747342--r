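# Shared in-code fixtures: tiny genomes, gene models and PWMs built at
# test time.

tiny_genes <- function() {
  # two genes on chr1 (one per strand), one on chr2
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    txStart = c(20000L, 60000L, 15000L),
    txEnd = c(24000L, 64000L, 17000L),
    cdsStart = c(20100L, 60100L, 15050L),
    cdsEnd = c(23900L, 63900L, 16950L),
    exonStarts = c("20000,21500,23000", "60000,62000", "15000"),
    exonEnds = c("20800,22200,24000", "60900,64000", "17000"),
    stringsAsFactors = FALSE)
}

tiny_chrom_lengths <- function() c(chr1 = 100000L, chr2 = 50000L)

make_peak <- function(chrom, mode, width = 300L, name = "p1") {
  h <- width %/% 2L
  data.frame(chrom = chrom, start = mode - h, end = mode + h,
             name = name, score = 1, mode = mode, stringsAsFactors = FALSE)
}

# strongly informative width-8 test PWM
strong_pwm <- function(name = "m1", background = rep(0.25, 4)) {
  consensus_counts <- function(bases) {
    t(vapply(bases, function(b) {
      r <- rep(1L, 4); r[match(b, c("A", "C", "G", "T"))] <- 97L; r
    }, integer(4)))
  }
  # non-palindromic consensus so plus and minus strands are distinct
  pwm_from_counts(consensus_counts(c("A", "A", "C", "G", "T", "A", "C", "C")),
                  name = name, background = background)
}

# independent per-region membership oracle for peak annotation: loops
# over genes and categories in priority order, no shared code with
# annotate_peaks() beyond the window constants
oracle_annotate <- function(peak, genes, cfg = annotation_config()) {
  ov <- function(s, e) peak$start < e && s < peak$end && s < e
  hit <- function(cat) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (g$chrom != peak$chrom) next
      tss <- if (g$strand == "+") g$txStart else g$txEnd - 1L
      es <- as.integer(strsplit(g$exonStarts, ",")[[1]])
      ee <- as.integer(strsplit(g$exonEnds, ",")[[1]])
      found <- switch(cat,
        TSS_1KB = ov(tss - cfg$tss_window, tss + cfg$tss_window),
        UP_1_5KB = if (g$strand == "+")
          ov(tss - cfg$upstream_near, tss - cfg$tss_window)
        else ov(tss + cfg$tss_window, tss + cfg$upstream_near),
        UP_5_10KB = if (g$strand == "+")
          ov(tss - cfg$upstream_far, tss - cfg$upstream_near)
        else ov(tss + cfg$upstream_near, tss + cfg$upstream_far),
        EXON = any(mapply(function(s, e)
          ov(max(s, g$cdsStart), min(e, g$cdsEnd)), es, ee)),
        UTR = any(mapply(function(s, e)
          ov(s, min(e, g$cdsStart)) || ov(max(s, g$cdsEnd), e), es, ee)),
        INTRON = length(es) > 1 && any(mapply(function(s, e) ov(s, e),
                                              ee[-length(ee)], es[-1])))
      if (isTRUE(found)) return(TRUE)
    }
    FALSE
  }
  for (cat in c("TSS_1KB", "UP_1_5KB", "UP_5_10KB", "EXON", "UTR", "INTRON"))
    if (hit(cat)) return(cat)
  "INTERGENIC"
}

# two-sided Fisher p by direct hypergeometric enumeration over all
# tables with the observed margins (point-probability rule)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  x <- lo:hi
  pr <- stats::dhyper(x, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
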