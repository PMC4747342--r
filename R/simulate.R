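# Synthetic data with planted ground truth. The generator emulates the
# structure of the study this package re-implements: a small
# multi-chromosome genome with strand-aware gene models; a cistrome of
# fixed-width peaks with a controllable annotation-category bias; two
# motifs (PAX8-like and PPARG-like stand-in PWMs) planted into peak
# sequences at controllable rates and offsets; four pairwise
# differential-expression comparisons with planted gene-set-level
# directional effects (the vehicle-control comparison is pure null); and
# a two-species homolog map with controllable binding-overlap fractions.
# Every stage's expected output is recoverable from the truth tables.

#' Synthetic-study configuration
#'
#' Defaults are desk-scale study conditions: a 2 Mb genome over four
#' chromosomes, 300 genes, 2,000 peaks of 300 bp (the +/-150 bp peak
#' convention), 500 gene sets. Motif plant rates default to 0.30
#' (PAX8) and 0.50 (PPARG), independent per peak, so that ~65% of peaks
#' carry either motif and ~50% of PAX8-motif peaks also carry a PPARG
#' motif; homolog bound fractions default to 0.34 vs 0.25.
#'
#' @param seed integer RNG seed recorded in every output
#' @param chrom_lengths named chromosome lengths (bp)
#' @param base_freqs background nucleotide frequencies (A, C, G, T)
#' @param n_genes genes to place (non-overlapping loci)
#' @param n_peaks peaks to place
#' @param peak_width peak width in bp (default 300)
#' @param category_weights named placement weights over annotation
#'   categories (must sum to 1)
#' @param motif_rates named per-peak plant probabilities for `pax8` and
#'   `pparg`
#' @param offset_dist `"centered"` (normal around the peak center) or
#'   `"uniform"` over the peak
#' @param offset_sd sd in bp of centered plant offsets (default 20)
#' @param plant_mode `"pwm"` (sample planted sites from the PWM) or
#'   `"consensus"`
#' @param n_sets number of gene sets
#' @param set_size_range inclusive range of set sizes
#' @param de_effect mean shift of the signed evidence statistic
#'   (-log p) for planted-set member genes (default 10, i.e. member
#'   p-values around 5e-5)
#' @param homolog_n_b number of species-B genes
#' @param homolog_bound_fracs bound-in-A fractions for homologs of the
#'   two species-B bound sets (default `c(b1 = 0.34, b2 = 0.25)`)
#' @return a `simulation_config` list
#' @export
simulation_config <- function(
    seed = 1L,
    chrom_lengths = c(chr1 = 600000L, chr2 = 550000L, chr3 = 500000L,
                      chr4 = 350000L),
    base_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
    n_genes = 300L,
    n_peaks = 2000L,
    peak_width = 300L,
    category_weights = c(TSS_1KB = 0.20, UP_1_5KB = 0.10, UP_5_10KB = 0.05,
                         EXON = 0.10, UTR = 0.05, INTRON = 0.15,
                         INTERGENIC = 0.35),
    motif_rates = c(pax8 = 0.30, pparg = 0.50),
    offset_dist = c("centered", "uniform"),
    offset_sd = 20,
    plant_mode = c("pwm", "consensus"),
    n_sets = 500L,
    set_size_range = c(5L, 60L),
    de_effect = 10,
    homolog_n_b = 1500L,
    homolog_bound_fracs = c(b1 = 0.34, b2 = 0.25)) {
  stopifnot(abs(sum(base_freqs) - 1) < 1e-9,
            abs(sum(category_weights) - 1) < 1e-9,
            all(motif_rates >= 0 & motif_rates <= 1),
            all(homolog_bound_fracs >= 0 & homolog_bound_fracs <= 1),
            peak_width > 0, n_peaks >= 0, n_genes >= 0)
  structure(list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    base_freqs = base_freqs, n_genes = as.integer(n_genes),
    n_peaks = as.integer(n_peaks), peak_width = as.integer(peak_width),
    category_weights = category_weights, motif_rates = motif_rates,
    offset_dist = match.arg(offset_dist), offset_sd = offset_sd,
    plant_mode = match.arg(plant_mode), n_sets = as.integer(n_sets),
    set_size_range = as.integer(set_size_range), de_effect = de_effect,
    homolog_n_b = as.integer(homolog_n_b),
    homolog_bound_fracs = homolog_bound_fracs),
    class = "simulation_config")
}

#' Stand-in PWMs for the PAX8 and PPARG motifs
#'
#' Synthetic position weight matrices with the qualitative character of
#' the real motifs (the PPARG-like one is a direct repeat of AGGTCA
#' half-sites; the PAX8-like one a GC-anchored paired-domain-style
#' site). They are stand-ins for testing and simulation, not the
#' published matrices; real PWMs can be supplied via [read_meme()].
#'
#' @param background length-4 background for log-odds scoring
#' @return named list of two `pwm` objects (`pax8`, `pparg`)
#' @export
standin_pwms <- function(background = rep(0.25, 4)) {
  strong <- 94L; mid <- 2L
  row_for <- function(base, w = strong) {
    r <- rep(mid, 4); r[match(base, DNA_BASES)] <- w; r
  }
  mixed <- function(b1, b2) {
    r <- rep(3, 4); r[match(b1, DNA_BASES)] <- 60; r[match(b2, DNA_BASES)] <- 34; r
  }
  # PPARG-like DR1: RGGTCA A AGGTCA
  pparg_counts <- rbind(
    mixed("A", "G"), row_for("G"), row_for("G"), row_for("T"),
    row_for("C"), row_for("A"), mixed("A", "T"),
    row_for("A"), row_for("G"), row_for("G"), row_for("T"),
    row_for("C"), row_for("A"))
  # PAX8-like paired-domain site
  pax8_counts <- rbind(
    row_for("G"), row_for("T"), row_for("C"), mixed("A", "C"),
    row_for("C"), row_for("G"), mixed("C", "G"), row_for("T"),
    row_for("G"), mixed("A", "G"), row_for("C"), row_for("G"))
  list(pax8 = pwm_from_counts(pax8_counts, "pax8", background = background),
       pparg = pwm_from_counts(pparg_counts, "pparg", background = background))
}

random_dna <- function(n, freqs) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = freqs), collapse = "")
}

#' Simulate a genome and non-overlapping gene models
#'
#' Background sequence is i.i.d. at the configured base frequencies.
#' Genes are placed left to right per chromosome with random gaps, so
#' transcripts never overlap; gene bodies pack the head of each
#' chromosome and the tail remains a gene desert, guaranteeing
#' intergenic space. Each gene has 2-4 exons with 5'/3' UTR portions on
#' the terminal exons and a random strand. Placement failure (density
#' too high for the genome) is an error suggesting a larger genome or
#' fewer genes.
#'
#' @param cfg a [simulation_config()]
#' @return list: `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (gene-model data frame)
#' @export
simulate_genome_and_genes <- function(cfg) {
  with_seed(cfg$seed, {
    genome <- Biostrings::DNAStringSet(vapply(
      cfg$chrom_lengths, function(L) random_dna(L, cfg$base_freqs),
      character(1)))
    names(genome) <- names(cfg$chrom_lengths)
    genes <- simulate_gene_table(cfg)
    list(genome = genome, genes = genes)
  })
}

simulate_gene_table <- function(cfg) {
  cols <- c("gene_id", "chrom", "strand", "txStart", "txEnd", "cdsStart",
            "cdsEnd", "exonStarts", "exonEnds")
  if (cfg$n_genes == 0L)
    return(stats::setNames(data.frame(character(), character(), character(),
                                      integer(), integer(), integer(),
                                      integer(), character(), character(),
                                      stringsAsFactors = FALSE), cols))
  lens <- cfg$chrom_lengths
  per_chrom <- round(cfg$n_genes * lens / sum(lens))
  per_chrom[1] <- per_chrom[1] + cfg$n_genes - sum(per_chrom)
  rows <- list(); gid <- 0L
  for (ch in names(lens)) {
    # genes pack the head of the chromosome (transcripts never overlap);
    # the tail stays gene-free, providing intergenic space as in real
    # genomes with gene deserts
    cursor <- 11000L
    for (k in seq_len(per_chrom[[ch]])) {
      n_ex <- sample(2:4, 1)
      ex_len <- sample(80:300, n_ex, replace = TRUE)
      in_len <- sample(200:800, max(0, n_ex - 1), replace = TRUE)
      span <- sum(ex_len) + sum(in_len)
      gap <- sample(800:2500, 1)
      tx_start <- cursor + gap
      tx_end <- tx_start + span
      if (tx_end + 11000L > 0.65 * lens[[ch]]) {
        if (k < per_chrom[[ch]])
          stop("cannot place requested gene density on ", ch,
               "; enlarge the genome or reduce n_genes")
        break
      }
      es <- tx_start + c(0L, cumsum(ex_len + c(in_len, 0L))[-n_ex])
      ee <- es + ex_len
      utr5 <- min(60L, ex_len[1] %/% 2L)
      utr3 <- min(60L, ex_len[n_ex] %/% 2L)
      strand <- sample(c("+", "-"), 1)
      gid <- gid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("g%04d", gid), chrom = ch, strand = strand,
        txStart = tx_start, txEnd = tx_end,
        cdsStart = es[1] + utr5, cdsEnd = ee[n_ex] - utr3,
        exonStarts = paste(es, collapse = ","),
        exonEnds = paste(ee, collapse = ","), stringsAsFactors = FALSE)
      cursor <- tx_end
    }
  }
  got <- length(rows)
  if (got < cfg$n_genes)
    stop(sprintf(
      "placed only %d of %d genes; enlarge the genome or reduce n_genes",
      got, cfg$n_genes))
  do.call(rbind, rows)
}

sample_from_pwm <- function(pwm) {
  paste(vapply(seq_len(pwm$width), function(i)
    sample(DNA_BASES, 1, prob = pwm$probs[i, ]), character(1)), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Draw one genomic mode position for a peak of the requested category.
sample_mode_for_category <- function(category, genes, regions, spans,
                                     chrom_lengths, halfwidth) {
  if (category == "INTERGENIC") {
    for (try in 1:200) {
      p <- sample_random_intervals(chrom_lengths, 1L, 2L * halfwidth)
      ov <- any(interval_overlaps(p$chrom, p$start, p$end,
                                  spans$chrom, spans$start, spans$end))
      if (!ov) return(list(chrom = p$chrom, mode = p$mode))
    }
    stop("could not place an intergenic peak; genome too gene-dense")
  }
  reg <- regions[regions$category == category, , drop = FALSE]
  if (!nrow(reg)) stop("no genomic capacity for category ", category)
  r <- reg[sample.int(nrow(reg), 1, prob = reg$end - reg$start), ]
  list(chrom = r$chrom, mode = r$start + sample.int(r$end - r$start, 1) - 1L)
}

#' Simulate peaks with planted motifs
#'
#' Places peaks according to the configured annotation-category weights
#' (a peak's mode is drawn inside a region of its target category), then
#' plants motif instances into the genome sequence: per peak and motif,
#' an independent Bernoulli draw at the configured rate; offsets are
#' centered (truncated normal) or uniform; strands random; planted site
#' sequences sampled from the PWM or its consensus. Both plants in a
#' peak never overlap each other. The returned truth table records
#' every plant.
#'
#' @param cfg a [simulation_config()]
#' @param genome a [Biostrings::DNAStringSet] (will be modified)
#' @param genes gene-model data frame
#' @param pwms named list of `pwm` objects (default [standin_pwms()])
#' @return list: `peaks` (data frame), `truth` (data frame: `name`,
#'   `target_category`, per-motif plant flags/offsets/strands),
#'   `genome` (modified sequences), `pwms`
#' @export
simulate_peaks_and_motifs <- function(cfg, genome, genes,
                                      pwms = standin_pwms()) {
  acfg <- annotation_config()
  regions <- gene_regions(genes, acfg)
  spans <- gene_locus_spans(genes, acfg$upstream_far)
  halfwidth <- cfg$peak_width %/% 2L
  seqs <- as.list(as.character(genome))
  with_seed(cfg$seed + 1L, {
    cats <- sample(names(cfg$category_weights), cfg$n_peaks, replace = TRUE,
                   prob = cfg$category_weights)
    peaks <- vector("list", cfg$n_peaks)
    truth <- vector("list", cfg$n_peaks)
    for (i in seq_len(cfg$n_peaks)) {
      pos <- sample_mode_for_category(cats[i], genes, regions, spans,
                                      cfg$chrom_lengths, halfwidth)
      mode <- min(max(pos$mode, halfwidth),
                  cfg$chrom_lengths[[pos$chrom]] - halfwidth - 1L)
      start <- mode - halfwidth; end <- mode + halfwidth
      name <- sprintf("peak%05d", i)
      peaks[[i]] <- data.frame(chrom = pos$chrom, start = start, end = end,
                               name = name, score = round(stats::rexp(1, 1/50), 1),
                               mode = mode, stringsAsFactors = FALSE)
      tr <- data.frame(name = name, target_category = cats[i],
                       stringsAsFactors = FALSE)
      used <- integer(0)  # occupied plant positions within the peak
      for (m in names(pwms)) {
        w <- pwms[[m]]$width
        plant <- stats::runif(1) < cfg$motif_rates[[m]]
        off <- NA_integer_; strand <- NA_character_
        if (plant) {
          for (try in 1:50) {
            off <- if (cfg$offset_dist == "centered")
              as.integer(round(stats::rnorm(1, 0, cfg$offset_sd)))
            else sample.int(2L * halfwidth - w, 1) - halfwidth - 1L
            off <- min(max(off, -halfwidth), halfwidth - w)
            site_rel <- (halfwidth + off + 1L):(halfwidth + off + w)
            if (!length(intersect(site_rel, used))) break
          }
          used <- c(used, site_rel)
          strand <- sample(c("+", "-"), 1)
          site <- if (cfg$plant_mode == "pwm") sample_from_pwm(pwms[[m]])
                  else pwm_consensus(pwms[[m]])
          if (strand == "-") site <- revcomp_chr(site)
          gs <- start + halfwidth + off  # genomic 0-based plant start
          substr(seqs[[pos$chrom]], gs + 1L, gs + w) <- site
        }
        tr[[paste0(m, "_planted")]] <- plant
        tr[[paste0(m, "_offset")]] <- if (plant) off else NA_integer_
        tr[[paste0(m, "_strand")]] <- strand
      }
      truth[[i]] <- tr
    }
    out_genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(out_genome) <- names(genome)
    list(peaks = do.call(rbind, peaks), truth = do.call(rbind, truth),
         genome = out_genome, pwms = pwms)
  })
}

#' Simulate a gene-set collection
#'
#' Random sets drawn uniformly from the gene universe with sizes uniform
#' over the configured range.
#'
#' @param cfg a [simulation_config()]
#' @param genes gene-model data frame
#' @return named list of gene sets (GMT-shaped)
#' @export
simulate_gene_sets <- function(cfg, genes) {
  with_seed(cfg$seed + 2L, {
    sizes <- sample(cfg$set_size_range[1]:min(cfg$set_size_range[2],
                                              nrow(genes)),
                    cfg$n_sets, replace = TRUE)
    sets <- lapply(seq_len(cfg$n_sets), function(i)
      list(set_id = sprintf("set%04d", i),
           description = sprintf("synthetic gene set %d", i),
           genes = sample(genes$gene_id, sizes[i])))
    stats::setNames(sets, vapply(sets, `[[`, character(1), "set_id"))
  })
}

#' Simulate four differential-expression comparisons
#'
#' Comparisons mirror a two-factor (construct x ligand) design:
#' `ppfp_vs_ev`, `ppfp_pio_vs_ev_pio`, `ppfp_pio_vs_ppfp`, and
#' `ev_pio_vs_ev`. Null genes get p ~ Uniform(0,1) and small symmetric
#' log2 fold changes; members of planted sets get a shifted signed
#' evidence statistic (and correspondingly large fold changes) in the
#' planted direction. The `ev_pio_vs_ev` vehicle-control comparison is
#' always pure null.
#'
#' @param cfg a [simulation_config()]
#' @param genes gene-model data frame
#' @param sets gene-set collection
#' @param effects data frame of planted effects (`comparison`, `set_id`,
#'   `direction` in {"up","down"}); `NULL` plants the defaults (two sets
#'   up and two down in each non-null comparison)
#' @return list: `tables` (named list of DE data frames), `effects`
#'   (the planted-effect truth table)
#' @export
simulate_de_tables <- function(cfg, genes, sets, effects = NULL) {
  comparisons <- c("ppfp_vs_ev", "ppfp_pio_vs_ev_pio", "ppfp_pio_vs_ppfp",
                   "ev_pio_vs_ev")
  if (is.null(effects)) {
    # per comparison, plant two induced and two repressed sets, chosen
    # greedily so the planted sets of one comparison share no genes
    ids <- names(sets)
    used <- character(0); eff <- list()
    for (cmp in comparisons[1:3]) {
      cand <- setdiff(ids, used)
      if (length(cand) < 4L)
        stop("not enough gene sets to plant effects; increase n_sets")
      # prefer larger sets: planted ground truth should be detectable,
      # and sets below ~15 members are underpowered for slope tests
      sizes <- vapply(sets[cand], function(s) length(s$genes), numeric(1))
      big <- cand[sizes >= 15]
      cand <- if (length(big) >= 4L) big[order(-sizes[sizes >= 15])]
              else cand[order(-sizes)]
      chosen <- character(0); genes_taken <- character(0)
      for (id in cand) {
        if (length(chosen) == 4L) break
        g <- sets[[id]]$genes
        if (length(intersect(g, genes_taken))) next
        chosen <- c(chosen, id)
        genes_taken <- c(genes_taken, g)
      }
      if (length(chosen) < 4L) {
        # fall back to the least-overlapping remaining candidates; genes
        # in more than one planted set keep their first effect
        rest <- setdiff(cand, chosen)
        ov <- vapply(rest, function(id)
          length(intersect(sets[[id]]$genes, genes_taken)) /
            length(sets[[id]]$genes), numeric(1))
        chosen <- c(chosen, rest[order(ov)][seq_len(4L - length(chosen))])
      }
      used <- c(used, chosen)
      eff[[cmp]] <- data.frame(comparison = cmp, set_id = chosen,
                               direction = c("up", "up", "down", "down"),
                               stringsAsFactors = FALSE)
    }
    effects <- do.call(rbind, eff)
    rownames(effects) <- NULL
  }
  bad <- setdiff(effects$set_id, names(sets))
  if (length(bad)) stop("planted effect on unknown set(s): ",
                        paste(bad, collapse = ", "))
  stopifnot(all(effects$comparison %in% comparisons[1:3]))
  n <- nrow(genes)
  with_seed(cfg$seed + 3L, {
    tables <- lapply(comparisons, function(cmp) {
      p <- stats::runif(n)
      l2fc <- stats::rnorm(n, 0, 0.3)
      ef <- effects[effects$comparison == cmp, , drop = FALSE]
      affected <- logical(n)  # first planted effect wins per gene
      for (j in seq_len(nrow(ef))) {
        members <- genes$gene_id %in% sets[[ef$set_id[j]]]$genes & !affected
        affected <- affected | members
        sgn <- if (ef$direction[j] == "up") 1 else -1
        stat <- cfg$de_effect + abs(stats::rnorm(sum(members), 0, 2))
        p[members] <- exp(-stat)
        l2fc[members] <- sgn * (1.2 + abs(stats::rnorm(sum(members), 0, 0.7)))
      }
      data.frame(gene_id = genes$gene_id, log2fc = l2fc, pvalue = p,
                 fdr = bh_fdr(p), stringsAsFactors = FALSE)
    })
    names(tables) <- comparisons
    list(tables = tables, effects = effects)
  })
}

#' Simulate a two-species homolog map with planted binding overlap
#'
#' Species-B genes map 1:1 onto sampled species-A genes (a configurable
#' fraction get a second A homolog, making the map many-to-many). Two
#' species-B bound sets are drawn, and each mapped homolog's species-A
#' gene is planted into the species-A bound set with the configured
#' per-set probability.
#'
#' @param cfg a [simulation_config()]
#' @param genes species-A gene-model data frame
#' @param frac_b1,frac_b2 fraction of species-B genes in each bound set
#' @param frac_second_homolog fraction of B genes with two A homologs
#' @return list: `map` (data frame `gene_a`, `gene_b`), `bound_b1`,
#'   `bound_b2`, `bound_a` (character vectors)
#' @export
simulate_homologs <- function(cfg, genes, frac_b1 = 0.4, frac_b2 = 0.4,
                              frac_second_homolog = 0.05) {
  with_seed(cfg$seed + 4L, {
    nb <- cfg$homolog_n_b
    gb <- sprintf("mus%05d", seq_len(nb))
    # species-A side: the simulated genes plus virtual ids when the map
    # is wider than the desk-scale genome, so the base map stays 1:1 and
    # planted bound fractions remain recoverable
    ga_pool <- genes$gene_id
    if (nb > length(ga_pool))
      ga_pool <- c(ga_pool, sprintf("gv%05d", seq_len(nb - length(ga_pool))))
    ga <- sample(ga_pool, nb)
    map <- data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
    extra <- stats::runif(nb) < frac_second_homolog
    if (any(extra))
      map <- rbind(map, data.frame(
        gene_a = sample(ga_pool, sum(extra), replace = TRUE),
        gene_b = gb[extra], stringsAsFactors = FALSE))
    b1 <- sample(gb, round(frac_b1 * nb))
    b2 <- sample(gb, round(frac_b2 * nb))
    pr <- rep(NA_real_, nb)
    in1 <- gb %in% b1; in2 <- gb %in% b2
    fr <- cfg$homolog_bound_fracs
    pr[in1 & !in2] <- fr[["b1"]]
    pr[!in1 & in2] <- fr[["b2"]]
    pr[in1 & in2] <- mean(fr)
    pr[!in1 & !in2] <- min(fr) / 2
    bound_b <- stats::runif(nb) < pr
    bound_a <- unique(map$gene_a[match(gb[bound_b], map$gene_b)])
    list(map = map, bound_b1 = b1, bound_b2 = b2, bound_a = bound_a)
  })
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper producing every pipeline input with one call.
#' @param cfg a [simulation_config()]
#' @return list: `cfg`, `genome`, `genes`, `peaks`, `truth`, `pwms`,
#'   `sets`, `de` (tables + effects), `homologs`
#' @export
simulate_study <- function(cfg = simulation_config()) {
  gg <- simulate_genome_and_genes(cfg)
  pm <- simulate_peaks_and_motifs(cfg, gg$genome, gg$genes)
  sets <- simulate_gene_sets(cfg, gg$genes)
  de <- simulate_de_tables(cfg, gg$genes, sets)
  hom <- simulate_homologs(cfg, gg$genes)
  list(cfg = cfg, genome = pm$genome, genes = gg$genes, peaks = pm$peaks,
       truth = pm$truth, pwms = pm$pwms, sets = sets, de = de,
       homologs = hom)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits FASTA, BED6+ peaks, refFlat-like gene TSV, MEME minimal motifs,
#' GMT sets, DE TSVs, homolog TSV, the truth tables, and a JSON manifest
#' recording the seed and file list.
#'
#' @param sim result of [simulate_study()]
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(sim$genome, fp("genome.fa"))
  write_peaks_bed(sim$peaks, fp("peaks.bed"))
  write_gene_models(sim$genes, fp("genes.tsv"))
  write_meme(sim$pwms, fp("motifs.meme"))
  write_gmt(sim$sets, fp("gene_sets.gmt"))
  for (cmp in names(sim$de$tables))
    write_tsv_meta(sim$de$tables[[cmp]], fp(paste0("de_", cmp, ".tsv")),
                   meta = c(seed = sim$cfg$seed, comparison = cmp))
  write_tsv_meta(sim$homologs$map, fp("homologs.tsv"),
                 meta = c(seed = sim$cfg$seed))
  write_tsv_meta(sim$truth, fp("truth_peaks.tsv"),
                 meta = c(seed = sim$cfg$seed))
  write_tsv_meta(sim$de$effects, fp("truth_de_effects.tsv"),
                 meta = c(seed = sim$cfg$seed))
  writeLines(sim$homologs$bound_b1, fp("bound_b1.txt"))
  writeLines(sim$homologs$bound_b2, fp("bound_b2.txt"))
  manifest <- fp("manifest.json")
  jsonlite::write_json(list(
    seed = sim$cfg$seed,
    n_genes = nrow(sim$genes), n_peaks = nrow(sim$peaks),
    n_sets = length(sim$sets),
    files = list.files(dir)), manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
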