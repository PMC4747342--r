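random_sets <- function(universe, n_sets, size_range = c(10, 40), seed = 101) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i)
      list(set_id = sprintf("s%03d", i), description = "",
           genes = sample(universe, sample(size_range[1]:size_range[2], 1))))
    stats::setNames(sets, vapply(sets, `[[`, character(1), "set_id"))
  })
}

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  # order invariance and monotonicity in p
  set.seed(102)
  p <- runif(50)
  o <- sample(50)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  q <- bh_fdr(p)
  expect_false(is.unsorted(q[order(p)]))  # weakly monotone in p
  expect_true(all(q >= p))
})

test_that("directional enrichment finds no signal in flat data and recovers planted sets", {
  universe <- sprintf("g%04d", 1:800)
  sets <- random_sets(universe, 40)
  # identical statistics for every gene: slope 0, p ~ 1
  flat <- data.frame(gene_id = universe, log2fc = 1, pvalue = 0.5,
                     fdr = 0.5, stringsAsFactors = FALSE)
  res_flat <- lrpath_directional(flat, sets)
  expect_true(all(res_flat$pvalue > 0.99))

  # planted induced set: members get tiny p and positive fold change
  set.seed(103)
  recovered <- replicate(50, {
    de <- data.frame(gene_id = universe,
                     log2fc = rnorm(800, 0, 0.5),
                     pvalue = runif(800), stringsAsFactors = FALSE)
    target <- sets[["s001"]]$genes
    de$pvalue[de$gene_id %in% target] <- 10^-runif(length(target), 4, 8)
    de$log2fc[de$gene_id %in% target] <- abs(rnorm(length(target), 2, 0.5))
    de$fdr <- bh_fdr(de$pvalue)
    res <- lrpath_directional(de, sets)
    r1 <- res[res$set_id == "s001", ]
    r1$qvalue < 0.05 && r1$direction == "induced"
  })
  expect_gte(mean(recovered), 0.95)
})

test_that("directional enrichment is antisymmetric in fold-change sign", {
  universe <- sprintf("g%04d", 1:400)
  sets <- random_sets(universe, 20, seed = 104)
  set.seed(105)
  de <- data.frame(gene_id = universe, log2fc = rnorm(400),
                   pvalue = runif(400), stringsAsFactors = FALSE)
  neg <- de; neg$log2fc <- -neg$log2fc
  a <- lrpath_directional(de, sets)
  b <- lrpath_directional(neg, sets)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-9)
  expect_true(all(a$direction != b$direction))
  expect_equal(a$coefficient, -b$coefficient, tolerance = 1e-9)
})

test_that("p-values are approximately uniform under independence nulls", {
  universe <- sprintf("g%04d", 1:600)
  one_set <- random_sets(universe, 1, size_range = c(40, 40), seed = 106)
  set.seed(107)
  # expression engine
  p_lr <- replicate(500, {
    de <- data.frame(gene_id = universe, log2fc = rnorm(600),
                     pvalue = runif(600), stringsAsFactors = FALSE)
    lrpath_directional(de, one_set)$pvalue
  })
  expect_gt(stats::ks.test(p_lr, "punif")$p.value, 0.01)

  # binding engine with varying lengths but independent peaks; a larger
  # universe and set keep the Wald normal approximation accurate
  u2 <- sprintf("g%04d", 1:1000)
  set2 <- random_sets(u2, 1, size_range = c(80, 80), seed = 120)
  set.seed(108)
  len <- round(10^runif(1000, 4, 5.5))
  p_ce <- replicate(500, {
    loci <- data.frame(gene_id = u2, locus_length = len,
                       n_peaks = 0L, has_peak = runif(1000) < 0.3,
                       stringsAsFactors = FALSE)
    chipenrich_ll(loci, set2, spline_df = 5)$pvalue
  })
  expect_gt(stats::ks.test(p_ce, "punif")$p.value, 0.01)
})

test_that("spline adjustment removes a planted locus-length confounder", {
  universe <- sprintf("g%04d", 1:600)
  set.seed(109)
  len <- sort(round(10^runif(600, 4, 6)))
  # tested set = the longest decile: a pure length artifact
  longest <- list(s_long = list(set_id = "s_long", description = "",
                                genes = universe[541:600]))
  reps <- 400
  naive_rej <- adj_rej <- logical(reps)
  for (r in seq_len(reps)) {
    pk <- runif(600) < stats::plogis(-3 + 1.2 * (log10(len) - 4.8))
    loci <- data.frame(gene_id = universe, locus_length = len,
                       n_peaks = as.integer(pk), has_peak = pk,
                       stringsAsFactors = FALSE)
    memb <- loci$gene_id %in% longest$s_long$genes
    naive_rej[r] <- stats::fisher.test(table(memb, pk))$p.value < 0.05
    adj_rej[r] <- chipenrich_ll(loci, longest, spline_df = 5)$pvalue < 0.05
  }
  expect_gt(mean(naive_rej), 0.2)   # the naive test is badly confounded
  expect_lt(mean(adj_rej), 0.12)    # the adjusted test is near nominal
})

test_that("equal locus lengths reduce the binding model to plain logistic", {
  universe <- sprintf("g%04d", 1:300)
  sets <- random_sets(universe, 5, seed = 110)
  set.seed(111)
  loci <- data.frame(gene_id = universe, locus_length = 50000L,
                     n_peaks = 0L, has_peak = runif(300) < 0.4,
                     stringsAsFactors = FALSE)
  res <- chipenrich_ll(loci, sets, spline_df = 10)
  for (id in res$set_id) {
    memb <- as.integer(universe %in% sets[[id]]$genes)
    plain <- stats::glm(loci$has_peak ~ memb, family = stats::binomial())
    expect_equal(res$coefficient[res$set_id == id],
                 unname(coef(plain)[2]), tolerance = 1e-6)
  }
})

test_that("set-size bounds are enforced", {
  universe <- sprintf("g%04d", 1:600)
  sets <- random_sets(universe, 5, seed = 112)
  sets$s_big <- list(set_id = "s_big", description = "",
                     genes = sprintf("g%04d", 1:501))
  sets$s_tiny <- list(set_id = "s_tiny", description = "",
                      genes = universe[1:3])
  de <- data.frame(gene_id = universe, log2fc = rnorm(600),
                   pvalue = runif(600), stringsAsFactors = FALSE)
  res <- lrpath_directional(de, sets)
  expect_false("s_big" %in% res$set_id)
  expect_false("s_tiny" %in% res$set_id)
  loci <- data.frame(gene_id = universe, locus_length = 10000L,
                     n_peaks = 0L, has_peak = runif(600) < 0.3,
                     stringsAsFactors = FALSE)
  res2 <- chipenrich_ll(loci, sets, spline_df = 3)
  expect_false("s_big" %in% res2$set_id)
})

test_that("separation falls back to a penalized fit and is flagged", {
  universe <- sprintf("g%04d", 1:200)
  sets <- list(s1 = list(set_id = "s1", description = "",
                         genes = universe[1:20]))
  loci <- data.frame(gene_id = universe, locus_length = 20000L,
                     n_peaks = 0L,
                     has_peak = c(rep(TRUE, 20), rep(FALSE, 180)),
                     stringsAsFactors = FALSE)
  res <- chipenrich_ll(loci, sets, spline_df = 3)
  expect_equal(res$flag, "firth")
  expect_true(is.finite(res$pvalue) && res$pvalue < 0.05)
})

test_that("GMT files round-trip", {
  universe <- sprintf("g%04d", 1:50)
  sets <- random_sets(universe, 8, seed = 113)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(names(back), names(sets))
  for (nm in names(sets))
    expect_identical(back[[nm]]$genes, sets[[nm]]$genes)
})
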