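# Gene models: strand-aware transcripts with TSS, exons, UTRs and derived
# introns. The canonical in-memory form is a refFlat-like data frame with
# one row per gene:
#   gene_id, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#   exonStarts, exonEnds (comma-separated 0-based half-open coordinates).

#' Read gene models from a refFlat-like TSV
#'
#' Expects a header with columns `gene_id`, `chrom`, `strand`, `txStart`,
#' `txEnd`, `cdsStart`, `cdsEnd`, `exonStarts`, `exonEnds`; exon columns
#' are comma-separated lists. Coordinates are 0-based half-open natively;
#' set `one_based = TRUE` for tables using 1-based inclusive starts.
#'
#' @param path TSV path
#' @param one_based convert 1-based inclusive starts to 0-based on read
#' @return gene-model data frame
#' @export
read_gene_models <- function(path, one_based = FALSE) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  check_cols(g, c("gene_id", "chrom", "strand", "txStart", "txEnd",
                  "cdsStart", "cdsEnd", "exonStarts", "exonEnds"), "gene table")
  if (one_based) {
    g$txStart <- g$txStart - 1L
    g$cdsStart <- g$cdsStart - 1L
    g$exonStarts <- vapply(strsplit(g$exonStarts, ","), function(x)
      paste(as.integer(x) - 1L, collapse = ","), character(1))
  }
  validate_gene_models(g)
}

#' Read gene models from a GTF file
#'
#' Builds the same refFlat-like frame from `exon` and `CDS` features
#' grouped by `gene_id`. Requires the rtracklayer package.
#'
#' @param path GTF path
#' @return gene-model data frame
#' @export
read_gene_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("GTF contains no exon features")
  cds <- gr[gr$type == "CDS"]
  ids <- unique(ex$gene_id)
  rows <- lapply(ids, function(id) {
    e <- ex[ex$gene_id == id]
    e <- e[order(GenomicRanges::start(e))]
    s <- GenomicRanges::start(e) - 1L  # to 0-based half-open
    w <- GenomicRanges::end(e)
    cg <- cds[cds$gene_id == id]
    data.frame(
      gene_id = id,
      chrom = as.character(GenomicRanges::seqnames(e))[1],
      strand = as.character(GenomicRanges::strand(e))[1],
      txStart = min(s), txEnd = max(w),
      cdsStart = if (length(cg)) min(GenomicRanges::start(cg)) - 1L else min(s),
      cdsEnd = if (length(cg)) max(GenomicRanges::end(cg)) else max(w),
      exonStarts = paste(s, collapse = ","),
      exonEnds = paste(w, collapse = ","),
      stringsAsFactors = FALSE)
  })
  validate_gene_models(do.call(rbind, rows))
}

#' Write gene models as a refFlat-like TSV
#' @param genes gene-model data frame
#' @param path output path
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_gene_models <- function(g) {
  stopifnot(all(g$strand %in% c("+", "-")),
            all(g$txStart >= 0), all(g$txStart < g$txEnd))
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_id in gene table")
  g
}

parse_coord_list <- function(x) lapply(strsplit(x, ","), as.integer)

#' Transcription start sites of gene models
#'
#' TSS is `txStart` on the plus strand and `txEnd - 1` on the minus strand
#' (the strand-dependent 5' end, 0-based).
#'
#' @param genes gene-model data frame
#' @return integer vector of TSS positions, named by `gene_id`
#' @export
gene_tss <- function(genes) {
  tss <- ifelse(genes$strand == "+", genes$txStart, genes$txEnd - 1L)
  stats::setNames(as.integer(tss), genes$gene_id)
}

# Expand one gene into its annotation regions. Categories follow the
# fixed priority TSS_1KB > UP_1_5KB > UP_5_10KB > EXON > UTR > INTRON;
# upstream windows are strand-aware (5' of the TSS in transcription
# direction); EXON covers coding exon portions while UTR covers the
# 5'/3' untranslated portions; introns are numbered 1..n in
# transcription direction.
gene_region_rows <- function(gene, cfg) {
  tss <- if (gene$strand == "+") gene$txStart else gene$txEnd - 1L
  plus <- gene$strand == "+"
  up <- function(a, b) {
    # upstream window a..b bp 5' of the TSS, as 0-based half-open; tiles
    # contiguously with the symmetric TSS window on either strand
    if (plus) c(tss - b, tss - a) else c(tss + a, tss + b)
  }
  rows <- list()
  add <- function(cat, start, end, intron_index = NA_integer_) {
    if (end > start)
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = gene$gene_id, category = cat,
        start = max(0L, as.integer(start)), end = as.integer(end),
        intron_index = intron_index, stringsAsFactors = FALSE)
  }
  add("TSS_1KB", tss - cfg$tss_window, tss + cfg$tss_window)
  w <- up(cfg$tss_window, cfg$upstream_near); add("UP_1_5KB", w[1], w[2])
  w <- up(cfg$upstream_near, cfg$upstream_far); add("UP_5_10KB", w[1], w[2])
  es <- parse_coord_list(gene$exonStarts)[[1]]
  ee <- parse_coord_list(gene$exonEnds)[[1]]
  for (i in seq_along(es)) {
    cs <- max(es[i], gene$cdsStart); ce <- min(ee[i], gene$cdsEnd)
    add("EXON", cs, ce)
    add("UTR", es[i], min(ee[i], gene$cdsStart))        # 5' of CDS
    add("UTR", max(es[i], gene$cdsEnd), ee[i])          # 3' of CDS
  }
  if (length(es) > 1L) {
    is_ <- ee[-length(ee)]; ie <- es[-1]
    ord <- if (plus) seq_along(is_) else rev(seq_along(is_))
    for (k in seq_along(is_)) add("INTRON", is_[k], ie[k], ord[k])
  }
  do.call(rbind, rows)
}

#' Annotation region table for a set of gene models
#'
#' One row per (gene, category, interval), used by [annotate_peaks()] and
#' by locus-length computations.
#' @param genes gene-model data frame
#' @param cfg an [annotation_config()]
#' @return data frame with columns `gene_id`, `category`, `start`, `end`,
#'   `intron_index`, `chrom`, `tss`
#' @export
gene_regions <- function(genes, cfg = annotation_config()) {
  if (!nrow(genes))
    return(data.frame(gene_id = character(), category = character(),
                      start = integer(), end = integer(),
                      intron_index = integer(), chrom = character(),
                      tss = integer(), stringsAsFactors = FALSE))
  parts <- lapply(seq_len(nrow(genes)), function(i)
    gene_region_rows(genes[i, ], cfg))
  reg <- do.call(rbind, parts)
  reg$chrom <- genes$chrom[match(reg$gene_id, genes$gene_id)]
  reg$tss <- unname(gene_tss(genes)[reg$gene_id])
  reg
}

#' Gene locus spans and lengths
#'
#' A gene's locus runs from `upstream` bp 5' of its TSS to the 3' end of
#' the transcript (the 3'UTR end); its length is the locus-length
#' covariate used by the binding-enrichment model, and "intergenic"
#' means outside every locus span.
#'
#' @param genes gene-model data frame
#' @param upstream bp upstream of the TSS (default 10000)
#' @return data frame: `gene_id`, `chrom`, `start`, `end`, `locus_length`
#' @export
gene_locus_spans <- function(genes, upstream = 10000L) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$txStart - upstream), genes$txStart)
  end <- ifelse(plus, genes$txEnd, genes$txEnd + upstream)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             locus_length = as.integer(end - start),
             stringsAsFactors = FALSE)
}
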