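test_that("Fisher 2x2 equals exhaustive hypergeometric enumeration", {
  # the worked example
  t1 <- fisher_2x2(40, 60, 20, 80)
  expect_equal(t1$fisher_p, oracle_fisher_p(40, 60, 20, 80), tolerance = 1e-10)

  # randomized tables with margins up to 200, plus degenerate margins
  set.seed(61)
  for (i in 1:200) {
    n <- sample(10:200, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c <- sample(0:(n - a - b), 1); d <- n - a - b - c
    expect_equal(fisher_2x2(a, b, c, d)$fisher_p,
                 oracle_fisher_p(a, b, c, d), tolerance = 1e-9)
  }
  # all small tables with both margins <= 12 (full enumeration)
  for (a in 0:6) for (b in 0:6) for (c in 0:6) for (d in 0:6) {
    if (a + b + c + d == 0) next
    expect_equal(fisher_2x2(a, b, c, d)$fisher_p,
                 oracle_fisher_p(a, b, c, d), tolerance = 1e-9)
  }
  # odds ratio bookkeeping
  expect_true(fisher_2x2(5, 0, 3, 2)$odds_ratio_undefined)
  expect_equal(fisher_2x2(10, 5, 2, 4)$odds_ratio, (10 * 4) / (5 * 2))
})

test_that("co-occurrence partition counts presence, not hit multiplicity", {
  peaks <- do.call(rbind, lapply(1:6, function(i)
    make_peak("chr1", 1000L * i, name = paste0("p", i))))
  hit <- function(names, motif = "mA") {
    if (!length(names)) return(data.frame(
      peak_name = character(), motif = character(), offset = integer(),
      strand = character(), score = numeric(), pvalue = numeric()))
    data.frame(peak_name = names, motif = motif, offset = 0L, strand = "+",
               score = 10, pvalue = 1e-6, stringsAsFactors = FALSE)
  }
  # disjoint plants -> n_both = 0
  co <- motif_cooccurrence(peaks, hit(c("p1", "p2")), hit(c("p3", "p4"), "mB"))
  expect_equal(unname(co$counts), c(0L, 2L, 2L, 2L))
  # both motifs everywhere -> n_both = total
  co2 <- motif_cooccurrence(peaks, hit(peaks$name), hit(peaks$name, "mB"))
  expect_equal(unname(co2$counts["n_both"]), 6L)
  # duplicated hits change nothing
  co3 <- motif_cooccurrence(peaks, rbind(hit(c("p1", "p1", "p1"))),
                            hit(c("p1", "p2"), "mB"))
  expect_equal(unname(co3$counts),
               unname(motif_cooccurrence(peaks, hit("p1"),
                                         hit(c("p1", "p2"), "mB"))$counts))
  # unknown peak in hits is rejected
  expect_error(motif_cooccurrence(peaks, hit("zz"), hit("p1", "mB")),
               "unknown peak")
  expect_equal(sum(co$counts), nrow(peaks))
})

test_that("independent planting gives n_both/total near p1*p2", {
  set.seed(62)
  n <- 5000
  peaks <- data.frame(chrom = "chr1", start = seq_len(n) * 400L,
                      end = seq_len(n) * 400L + 300L,
                      name = sprintf("p%05d", seq_len(n)),
                      score = 1, mode = seq_len(n) * 400L + 150L,
                      stringsAsFactors = FALSE)
  p1 <- 0.3; p2 <- 0.5
  a <- peaks$name[runif(n) < p1]
  b <- peaks$name[runif(n) < p2]
  hits <- function(names, motif) data.frame(
    peak_name = names, motif = motif, offset = 0L, strand = "+",
    score = 10, pvalue = 1e-6, stringsAsFactors = FALSE)
  co <- motif_cooccurrence(peaks, hits(a, "mA"), hits(b, "mB"))
  se <- sqrt(p1 * p2 * (1 - p1 * p2) / n)
  expect_lt(abs(co$counts[["n_both"]] / n - p1 * p2), 2 * se + 1e-9)
})

test_that("annotation enrichment is near 1 under the null and recovers planted bias", {
  genes <- tiny_genes()
  lens <- tiny_chrom_lengths()
  # null self-consistency: random peaks against random backgrounds
  null_peaks <- sample_random_intervals(lens, 800, 300, seed = 70)
  null_peaks$name <- as.character(seq_len(nrow(null_peaks)))
  enr <- annotation_enrichment(null_peaks, genes, lens, n_replicates = 20,
                               seed = 71)
  big <- subset(enr$categories, observed >= 30 & random_mean >= 30)
  expect_true(all(abs(big$ratio - 1) < 0.35))
  # counts over categories sum to the peak-set size
  expect_equal(sum(enr$categories$observed), nrow(null_peaks))
})

test_that("spatial profile concentrates planted central motifs and is flat under uniform planting", {
  set.seed(72)
  bases <- c("A", "C", "G", "T")
  L <- 200000L
  genome <- Biostrings::DNAStringSet(
    c(chrA = paste(sample(bases, L, replace = TRUE), collapse = "")))
  pwm <- strong_pwm()
  cons <- pwm_consensus(pwm)
  n <- 120
  start <- (seq_len(n) - 1L) * 420L + 10L
  peaks <- data.frame(chrom = "chrA", start = start, end = start + 300L,
                      name = sprintf("s%03d", seq_len(n)), score = 1,
                      mode = start + 150L, stringsAsFactors = FALSE)
  plant <- function(offsets) {
    g <- genome
    for (i in seq_len(n)) {
      s <- peaks$start[i] + 150L + offsets[i]
      Biostrings::subseq(g[["chrA"]], s + 1L, s + nchar(cons)) <-
        Biostrings::DNAString(cons)
    }
    g
  }
  # all plants exactly at the center: all mass in the central bin
  g_center <- plant(rep(0L, n))
  prof <- spatial_profile(peaks, pwm, g_center, null_n = 500, seed = 73)
  central <- prof$profile$bin_lo == 0
  expect_equal(sum(prof$profile$observed_density[central]),
               sum(prof$profile$observed_density), tolerance = 0.05)

  # uniform plants: no bin dominates (chi-square GOF does not reject hard)
  g_unif <- plant(sample(-140:120, n, replace = TRUE))
  prof_u <- spatial_profile(peaks, pwm, g_unif, null_n = 500, seed = 74)
  counts <- prof_u$profile$observed_density * n
  keep <- counts >= 0
  chi <- suppressWarnings(stats::chisq.test(counts[keep]))
  expect_gt(chi$p.value, 0.001)

  # null profile from random regions is flat: max bin not dominant
  nd <- prof$profile$null_density
  if (sum(nd) > 0) expect_lt(max(nd) / sum(nd), 0.5)

  # empty peak set gives an empty profile
  e <- spatial_profile(peaks[0, ], pwm, g_center, null_n = 10, seed = 1)
  expect_equal(nrow(e$profile), 0)
})

test_that("motif-conditioned overlap test detects planted association and stays null otherwise", {
  peaks_a <- data.frame(chrom = "chr1", start = seq_len(200) * 1000L,
                        end = seq_len(200) * 1000L + 300L,
                        name = sprintf("a%03d", 1:200), score = 1,
                        mode = seq_len(200) * 1000L + 150L,
                        stringsAsFactors = FALSE)
  overlapping <- peaks_a[1:100, ]
  peaks_b <- overlapping
  peaks_b$name <- sprintf("b%03d", 1:100)
  hits <- function(names) data.frame(
    peak_name = names, motif = "m2", offset = 0L, strand = "+", score = 10,
    pvalue = 1e-6, stringsAsFactors = FALSE)
  # motif 2 only in overlapping peaks: infinite OR flagged, tiny p
  t_ext <- motif_conditioned_overlap_test(peaks_a, peaks_b, hits(peaks_a$name[1:100]))
  expect_true(t_ext$odds_ratio_undefined)
  expect_lt(t_ext$fisher_p, 1e-6)
  expect_error(motif_conditioned_overlap_test(peaks_a[0, ], peaks_b,
                                              hits(character(0))), "empty")

  # independent planting: p approximately uniform over 500 replicates
  set.seed(63)
  ps <- replicate(500, {
    m2 <- peaks_a$name[runif(200) < 0.4]
    motif_conditioned_overlap_test(peaks_a, peaks_b, hits(m2))$fisher_p
  })
  # Fisher p is discrete and conservative; check uniformity loosely
  expect_gt(mean(ps < 0.05), 0)
  expect_lt(mean(ps < 0.05), 0.08)
  expect_gt(mean(ps > 0.5), 0.35)
})
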