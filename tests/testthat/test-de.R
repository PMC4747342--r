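de_row <- function(gene, l2fc, p = 0.001, fdr = p) {
  data.frame(gene_id = gene, log2fc = l2fc, pvalue = p, fdr = fdr,
             stringsAsFactors = FALSE)
}

test_that("DE classification applies FDR and linear fold-change cuts", {
  de <- rbind(de_row("g1", 2, fdr = 0.01),
              de_row("g2", 0.5, fdr = 0.01),
              de_row("g3", -1.2, fdr = 0.01),
              de_row("g4", 3, fdr = 0.2))
  cl <- classify_de(de, fdr_cut = 0.05, fc_cut = 2)
  expect_equal(cl$status, c("UP", "NC", "DOWN", "NC"))

  # threshold monotonicity: tightening cuts never adds DE genes
  set.seed(91)
  big <- data.frame(gene_id = sprintf("g%04d", 1:500),
                    log2fc = rnorm(500, 0, 2), pvalue = runif(500),
                    fdr = runif(500), stringsAsFactors = FALSE)
  loose <- de_genes(classify_de(big, 0.2, 1.5))
  tight1 <- de_genes(classify_de(big, 0.05, 1.5))
  tight2 <- de_genes(classify_de(big, 0.2, 2.5))
  expect_true(all(tight1 %in% loose))
  expect_true(all(tight2 %in% loose))

  # planted counts at the cut boundary are recovered exactly
  planted <- rbind(
    data.frame(gene_id = sprintf("up%03d", 1:100), log2fc = 1.1,
               pvalue = 1e-5, fdr = 1e-4),
    data.frame(gene_id = sprintf("dn%03d", 1:150), log2fc = -1.1,
               pvalue = 1e-5, fdr = 1e-4),
    data.frame(gene_id = sprintf("nc%03d", 1:50), log2fc = 0.9,
               pvalue = 1e-5, fdr = 1e-4))
  cnt <- de_counts(classify_de(planted, 0.05, 2))
  expect_equal(unname(cnt[c("UP", "DOWN")]), c(100L, 150L))

  expect_error(classify_de(rbind(de_row("g1", 1), de_row("g1", 2))),
               "duplicate")
})

test_that("Venn regions match brute-force set algebra", {
  u <- sprintf("g%03d", 1:300)
  set.seed(92)
  mk <- function() {
    structure(data.frame(
      gene_id = u,
      status = sample(c("UP", "DOWN", "NC"), 300, TRUE, c(.15, .15, .7)),
      stringsAsFactors = FALSE), class = c("de_class", "data.frame"))
  }
  a <- mk(); b <- mk(); c3 <- mk()
  v <- venn_comparisons(list(A = a, B = b, C = c3))
  sa <- de_genes(a); sb <- de_genes(b); sc <- de_genes(c3)
  expect_equal(v[["A"]], length(setdiff(sa, union(sb, sc))))
  expect_equal(v[["A&B"]], length(setdiff(intersect(sa, sb), sc)))
  expect_equal(v[["A&B&C"]], length(Reduce(intersect, list(sa, sb, sc))))
  expect_equal(sum(v), length(unique(c(sa, sb, sc))))

  # identical classifications: everything in the full intersection
  v2 <- venn_comparisons(list(A = a, B = a))
  expect_equal(unname(v2), c(0L, 0L, length(sa)))

  # disjoint DE sets: empty intersections
  d1 <- a; d2 <- a
  d2$status <- "NC"; d2$status[!(u %in% sa)] <- "UP"
  v3 <- venn_comparisons(list(A = d1, B = d2))
  expect_equal(v3[["A&B"]], 0L)

  # universe mismatch rejected
  bad <- b[-1, ]
  expect_error(venn_comparisons(list(A = a, B = bad)), "universe")
})

test_that("concordance analysis reproduces printed-table statistics", {
  conc <- concordance_from_counts(matrix(c(32, 62, 81, 47, 24, 50), 2,
                                         byrow = TRUE))
  expect_equal(unname(conc$row_percent[1, ]), c(18, 35, 46))
  expect_equal(unname(conc$row_percent[2, 1]), 39)
  expect_equal(unname(conc$row_totals), c(175, 121))
  expect_equal(signif(conc$fisher_p, 2), 1.5e-4)
  # the 2x2 of doubly-changed genes carries its own exact test
  expect_equal(conc$doubly_changed$fisher_p,
               oracle_fisher_p(32, 62, 47, 24), tolerance = 1e-9)

  # perfectly concordant toy table
  toy <- concordance_from_counts(matrix(c(50, 0, 0, 0, 50, 0), 2,
                                        byrow = TRUE))
  expect_lt(toy$fisher_p, 1e-6)
  expect_true(toy$doubly_changed$odds_ratio_undefined)  # zero off-diagonal

  # classification route agrees with the counts route
  genes <- sprintf("g%03d", 1:296)
  status_a <- rep(c("UP", "DOWN"), c(175, 121))
  status_b <- c(rep(c("UP", "DOWN", "NC"), c(32, 62, 81)),
                rep(c("UP", "DOWN", "NC"), c(47, 24, 50)))
  mk <- function(st) structure(
    data.frame(gene_id = genes, status = st, stringsAsFactors = FALSE),
    class = c("de_class", "data.frame"))
  conc2 <- concordance_analysis(mk(status_a), mk(status_b))
  expect_equal(conc2$counts, conc$counts)
  expect_equal(conc2$fisher_p, conc$fisher_p)
})

test_that("concordance Fisher p equals hypergeometric enumeration for margins <= 200", {
  set.seed(93)
  for (i in 1:50) {
    a <- sample(0:50, 1); b <- sample(0:50, 1)
    c2 <- sample(0:50, 1); d <- sample(0:50, 1)
    if ((a + b) == 0 || (c2 + d) == 0) next
    conc <- concordance_from_counts(matrix(c(a, b, 0, c2, d, 0), 2,
                                           byrow = TRUE))
    expect_equal(conc$doubly_changed$fisher_p, oracle_fisher_p(a, b, c2, d),
                 tolerance = 1e-9)
  }
})

test_that("reversal analysis counts shared direction agreement", {
  u <- sprintf("g%03d", 1:200)
  mk <- function(st) structure(
    data.frame(gene_id = u, status = st, stringsAsFactors = FALSE),
    class = c("de_class", "data.frame"))
  set.seed(94)
  st <- sample(c("UP", "DOWN", "NC"), 200, TRUE)
  a <- mk(st)
  expect_equal(reversal_analysis(a, a)$frac_same, 1)
  flip <- ifelse(st == "UP", "DOWN", ifelse(st == "DOWN", "UP", "NC"))
  expect_equal(reversal_analysis(a, mk(flip))$frac_opposite, 1)

  # planted 80/20 split recovered exactly
  st_a <- rep("UP", 200)
  st_b <- c(rep("UP", 80), rep("DOWN", 20), rep("NC", 100))
  r <- reversal_analysis(mk(st_a), mk(st_b))
  expect_equal(r$n_shared, 100)
  expect_equal(r$n_same_direction, 80)
  expect_equal(r$n_opposite, 20)
  expect_equal(r$n_same_direction + r$n_opposite, r$n_shared)
})

test_that("opposite-direction gene sets are found at the FDR cut", {
  mk <- function(dirs, qs) data.frame(
    set_id = sprintf("s%02d", seq_along(dirs)), description = "",
    n_genes = 10L, coefficient = ifelse(dirs == "induced", 1, -1),
    direction = dirs, pvalue = qs / 2, qvalue = qs,
    stringsAsFactors = FALSE)
  a <- mk(c("induced", "induced", "repressed"), c(0.01, 0.3, 0.01))
  b <- mk(c("repressed", "repressed", "repressed"), c(0.01, 0.01, 0.01))
  got <- opposite_direction_genesets(a, b, q_cut = 0.05)
  expect_equal(got$set_id, "s01")
  # no overlapping significant sets -> empty
  none <- opposite_direction_genesets(mk("induced", 0.5), mk("repressed", 0.5))
  expect_equal(nrow(none), 0L)
  expect_error(opposite_direction_genesets(a, b[-1, ]), "collections")
})

test_that("homolog binding overlap recovers planted proportions and calibrates", {
  set.seed(95)
  genes_a <- sprintf("rat%04d", 1:3000)
  gb <- sprintf("mus%04d", 1:3000)
  map <- data.frame(gene_a = genes_a, gene_b = gb, stringsAsFactors = FALSE)
  b1 <- gb[1:1500]; b2 <- gb[1501:3000]
  bound <- c(gb[1:1500][runif(1500) < 0.34], gb[1501:3000][runif(1500) < 0.25])
  bound_a <- map$gene_a[match(bound, map$gene_b)]
  r <- homolog_binding_overlap(bound_a, b1, b2, map)
  expect_equal(r$prop_b1, 0.34, tolerance = 0.1)
  expect_equal(r$prop_b2, 0.25, tolerance = 0.12)
  expect_lt(r$test$fisher_p, 0.01)

  # bound_a = all genes -> both proportions 1
  r_all <- homolog_binding_overlap(genes_a, b1, b2, map)
  expect_equal(c(r_all$prop_b1, r_all$prop_b2), c(1, 1))

  # power: planted 0.34 vs 0.25 at n = 1500/1500 rejects at alpha = 0.01
  # in >= 90% of replicates
  rej <- mean(replicate(60, {
    bound <- c(gb[1:1500][runif(1500) < 0.34],
               gb[1501:3000][runif(1500) < 0.25])
    homolog_binding_overlap(map$gene_a[match(bound, map$gene_b)],
                            b1, b2, map)$test$fisher_p < 0.01
  }))
  expect_gte(rej, 0.9)

  # calibration: equal planting rates give approximately uniform p
  ps <- replicate(300, {
    bound <- gb[runif(3000) < 0.3]
    homolog_binding_overlap(map$gene_a[match(bound, map$gene_b)],
                            b1, b2, map)$test$fisher_p
  })
  expect_lt(mean(ps < 0.05), 0.09)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.001)
})

test_that("cross-study overlap maps homologs before comparing", {
  u <- sprintf("rat%03d", 1:100)
  cl <- structure(data.frame(
    gene_id = u, status = rep(c("UP", "NC"), c(31, 69)),
    stringsAsFactors = FALSE), class = c("de_class", "data.frame"))
  map <- data.frame(gene_a = u, gene_b = sprintf("hum%03d", 1:100),
                    stringsAsFactors = FALSE)
  glist <- sprintf("hum%03d", 1:100)
  r <- cross_study_overlap(glist, cl, peak_genes = u[1:22], map = map)
  expect_equal(r$frac_de, 0.31)
  expect_equal(r$frac_bound, 0.22)
  # subset of DE genes -> overlap 1; empty intersection -> 0
  r2 <- cross_study_overlap(sprintf("hum%03d", 1:10), cl, u[50:60], map)
  expect_equal(r2$frac_de, 1)
  r3 <- cross_study_overlap(sprintf("hum%03d", 90:100), cl, character(0), map)
  expect_equal(r3$frac_de, 0)
  expect_equal(r3$frac_bound, 0)
})
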