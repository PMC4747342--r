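# Differential-expression classification and ChIP/RNA integration:
# multi-comparison Venn regions, direction-concordance testing against a
# second perturbation, reversal analysis, opposite-direction gene-set
# detection, homolog-mapped binding overlap, and cross-study summaries.

#' Read a differential-expression table
#'
#' TSV with header columns `gene_id`, `log2fc`, `pvalue`, `fdr`.
#' @param path TSV path
#' @return data frame of DE records
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  check_cols(de, c("gene_id", "log2fc", "pvalue", "fdr"), "DE table")
  de
}

#' Classify genes as up, down or unchanged
#'
#' A gene is UP when `fdr < fdr_cut`, linear fold change `2^|log2fc| >
#' fc_cut`, and `log2fc > 0`; DOWN symmetrically; otherwise NC. The
#' fold-change cut is on the linear scale and two-sided.
#'
#' @param de DE data frame (`gene_id`, `log2fc`, `pvalue`, `fdr`)
#' @param fdr_cut FDR threshold (default 0.05)
#' @param fc_cut linear fold-change threshold (default 2)
#' @return a `de_class` data frame (`gene_id`, `status`) with the
#'   thresholds stored as attributes
#' @export
classify_de <- function(de, fdr_cut = 0.05, fc_cut = 2) {
  check_cols(de, c("gene_id", "log2fc", "fdr"), "DE table")
  if (anyDuplicated(de$gene_id)) stop("duplicate gene_id in DE table")
  sig <- de$fdr < fdr_cut & 2^abs(de$log2fc) > fc_cut
  status <- ifelse(sig & de$log2fc > 0, "UP",
                   ifelse(sig & de$log2fc < 0, "DOWN", "NC"))
  structure(data.frame(gene_id = de$gene_id, status = status,
                       stringsAsFactors = FALSE),
            fdr_cut = fdr_cut, fc_cut = fc_cut,
            class = c("de_class", "data.frame"))
}

#' Counts of a DE classification
#' @param x a `de_class`
#' @export
de_counts <- function(x) {
  c(UP = sum(x$status == "UP"), DOWN = sum(x$status == "DOWN"),
    NC = sum(x$status == "NC"))
}

#' Differentially expressed genes (UP or DOWN) of a classification
#' @param x a `de_class`
#' @export
de_genes <- function(x) x$gene_id[x$status != "NC"]

check_same_universe <- function(classes) {
  u <- sort(classes[[1]]$gene_id)
  for (cl in classes[-1])
    if (!identical(sort(cl$gene_id), u))
      stop("classifications are not over the same gene universe")
  invisible(u)
}

#' Venn region counts of differentially expressed gene sets
#'
#' For 2 or 3 classifications over the same gene universe, counts every
#' intersection region of the DE (UP or DOWN) gene sets.
#'
#' @param classes named list of 2-3 `de_class` objects
#' @return named integer vector; names are membership patterns like
#'   `"A&B"` (in A and B but no other), ordered by pattern
#' @export
venn_comparisons <- function(classes) {
  stopifnot(length(classes) %in% 2:3)
  if (is.null(names(classes))) names(classes) <- LETTERS[seq_along(classes)]
  check_same_universe(classes)
  sets <- lapply(classes, de_genes)
  genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 0)
    member <- matrix(logical(0), 0, length(sets),
                     dimnames = list(NULL, names(classes)))
  if (length(genes) == 1) member <- matrix(member, 1,
                                           dimnames = list(NULL, names(classes)))
  pat <- apply(member, 1, function(r) paste(names(classes)[r], collapse = "&"))
  all_pats <- unlist(lapply(seq_along(classes), function(k)
    utils::combn(names(classes), k, paste, collapse = "&", simplify = TRUE)))
  out <- table(factor(pat, levels = all_pats))
  stats::setNames(as.integer(out), all_pats)
}

#' Direction-concordance analysis of two perturbations
#'
#' Restricts the first classification to its DE genes, tabulates them
#' against the second classification's UP/DOWN/NC calls (a 2x3 table with
#' row percentages), and tests whether direction in B is associated with
#' direction in A. The headline p-value is Fisher's exact test on the
#' full 2x3 table; the 2x2 of doubly-changed genes is also reported with
#' its own two-sided Fisher p.
#'
#' @param class_a,class_b `de_class` objects (need not share a universe;
#'   genes of A absent from B are dropped)
#' @return a `concordance_summary`
#' @export
concordance_analysis <- function(class_a, class_b) {
  a <- class_a[class_a$status != "NC", , drop = FALSE]
  b_status <- class_b$status[match(a$gene_id, class_b$gene_id)]
  keep <- !is.na(b_status)
  m <- table(factor(a$status[keep], levels = c("UP", "DOWN")),
             factor(b_status[keep], levels = c("UP", "DOWN", "NC")))
  concordance_from_counts(unclass(as.matrix(m)))
}

#' Concordance summary from printed 2x3 counts
#'
#' The direct form of [concordance_analysis()] for a pre-tabulated 2x3
#' table: rows = direction in perturbation A (up, down), columns =
#' UP/DOWN/NC in perturbation B.
#'
#' @param counts 2x3 numeric matrix
#' @return a `concordance_summary`: the counts, row percentages (rounded
#'   to integers as conventionally printed), the 2x3 Fisher exact p, the
#'   2x2 of doubly-changed genes with its Fisher test, and the
#'   discordant fraction among doubly-changed genes
#' @export
concordance_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2L, ncol(counts) == 3L, all(counts >= 0))
  counts <- matrix(as.numeric(counts), 2L, 3L,
                   dimnames = list(c("A_up", "A_down"),
                                   c("B_up", "B_down", "B_nc")))
  row_tot <- rowSums(counts)
  row_pct <- round(100 * sweep(counts, 1, row_tot, "/"))
  p_2x3 <- stats::fisher.test(counts)$p.value
  dd <- counts[, 1:2]
  two_by_two <- NULL; note <- NULL
  if (all(rowSums(dd) > 0) && sum(dd) > 0) {
    two_by_two <- fisher_2x2(dd[1, 1], dd[1, 2], dd[2, 1], dd[2, 2])
  } else note <- "no doubly-changed genes; 2x2 test skipped"
  discordant <- (dd[1, 2] + dd[2, 1]) / max(1, sum(dd))
  structure(list(counts = counts, row_totals = row_tot,
                 row_percent = row_pct, fisher_p = p_2x3,
                 doubly_changed = two_by_two,
                 frac_discordant = unname(discordant), note = note),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Direction concordance (rows: perturbation A; cols: perturbation B):\n")
  shown <- matrix(sprintf("%d (%d%%)", x$counts, x$row_percent),
                  2, 3, dimnames = dimnames(x$counts))
  print(shown, quote = FALSE)
  cat(sprintf("row totals: %d / %d (n = %d)\n", x$row_totals[1],
              x$row_totals[2], sum(x$row_totals)))
  cat(sprintf("Fisher exact p (2x3): %.3g; discordant among doubly-changed: %.0f%%\n",
              x$fisher_p, 100 * x$frac_discordant))
  if (!is.null(x$note)) cat(x$note, "\n")
  invisible(x)
}

#' Reversal analysis of two classifications
#'
#' Over genes differentially expressed in both comparisons, counts those
#' changing in the same versus the opposite direction.
#'
#' @param class_a,class_b `de_class` objects over the same universe
#' @return list: `n_shared`, `n_same_direction`, `n_opposite`,
#'   `frac_same`, `frac_opposite`
#' @export
reversal_analysis <- function(class_a, class_b) {
  check_same_universe(list(class_a, class_b))
  b <- class_b$status[match(class_a$gene_id, class_b$gene_id)]
  shared <- class_a$status != "NC" & b != "NC"
  same <- sum(shared & class_a$status == b)
  opp <- sum(shared & class_a$status != b)
  n <- sum(shared)
  list(n_shared = n, n_same_direction = same, n_opposite = opp,
       frac_same = if (n) same / n else NA_real_,
       frac_opposite = if (n) opp / n else NA_real_)
}

#' Gene sets significant in opposite directions in two enrichment runs
#'
#' @param enrich_a,enrich_b enrichment result frames (from
#'   [lrpath_directional()]) over the same gene-set collection
#' @param q_cut FDR threshold applied to both runs (default 0.05)
#' @return data frame of qualifying sets with both directions
#' @export
opposite_direction_genesets <- function(enrich_a, enrich_b, q_cut = 0.05) {
  if (!setequal(enrich_a$set_id, enrich_b$set_id))
    stop("enrichment runs cover different gene-set collections")
  b <- enrich_b[match(enrich_a$set_id, enrich_b$set_id), ]
  keep <- enrich_a$qvalue <= q_cut & b$qvalue <= q_cut &
    enrich_a$direction != b$direction
  out <- data.frame(set_id = enrich_a$set_id,
                    direction_a = enrich_a$direction,
                    qvalue_a = enrich_a$qvalue,
                    direction_b = b$direction, qvalue_b = b$qvalue,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a two-column homolog map TSV
#'
#' Columns `gene_a`, `gene_b`; many-to-many pairs allowed.
#' @param path TSV path
#' @export
read_homolog_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  check_cols(m, c("gene_a", "gene_b"), "homolog map")
  m
}

#' Restrict a homolog map to its 1:1 subset
#' @param map homolog map data frame
#' @export
homolog_map_one_to_one <- function(map) {
  map[!(map$gene_a %in% map$gene_a[duplicated(map$gene_a)]) &
        !(map$gene_b %in% map$gene_b[duplicated(map$gene_b)]), , drop = FALSE]
}

#' Homolog-mapped binding overlap between two species-B gene sets
#'
#' For two sets of species-B genes bound in two conditions, computes the
#' proportion of their mapped homologs bound in species A ("any homolog
#' bound" semantics for many-to-many maps) and tests the difference on
#' the 2x2 of set-exclusive homologs by two-sided Fisher exact.
#'
#' @param bound_a character vector of species-A bound gene ids
#' @param bound_b1,bound_b2 character vectors of species-B bound gene ids
#' @param map homolog map (`gene_a`, `gene_b`)
#' @param one_to_one restrict the map to its 1:1 subset first
#' @return list: `prop_b1`, `prop_b2`, `n_b1`, `n_b2`, `test`
#'   (a `contingency_2x2` over exclusive genes)
#' @export
homolog_binding_overlap <- function(bound_a, bound_b1, bound_b2, map,
                                    one_to_one = FALSE) {
  if (one_to_one) map <- homolog_map_one_to_one(map)
  bound_in_a <- function(gb) {
    vapply(split(map$gene_a[map$gene_b %in% gb], map$gene_b[map$gene_b %in% gb]),
           function(ga) any(ga %in% bound_a), logical(1))
  }
  m1 <- bound_in_a(bound_b1); m2 <- bound_in_a(bound_b2)
  if (!length(m1) || !length(m2)) stop("a species-B set has no mapped homologs")
  excl1 <- m1[!(names(m1) %in% bound_b2)]
  excl2 <- m2[!(names(m2) %in% bound_b1)]
  test <- fisher_2x2(sum(excl1), sum(!excl1), sum(excl2), sum(!excl2))
  list(prop_b1 = mean(m1), prop_b2 = mean(m2),
       n_b1 = length(m1), n_b2 = length(m2), test = test)
}

#' Cross-study overlap of an external gene list with DE and binding data
#'
#' Maps an external (species-B) gene list through homologs, then reports
#' the fraction of mapped genes differentially expressed and the
#' fraction with at least one assigned peak.
#'
#' @param gene_list character vector of species-B gene ids
#' @param de_class a `de_class` over species-A genes
#' @param peak_genes character vector of species-A genes with >= 1 peak
#' @param map homolog map (`gene_a`, `gene_b`); `NULL` if `gene_list`
#'   is already in species-A ids
#' @return list: `n_input`, `n_mapped`, `frac_de`, `frac_bound`
#' @export
cross_study_overlap <- function(gene_list, de_class, peak_genes, map = NULL) {
  if (!is.null(map)) {
    mapped <- split(map$gene_a[map$gene_b %in% gene_list],
                    map$gene_b[map$gene_b %in% gene_list])
  } else {
    mapped <- stats::setNames(as.list(gene_list), gene_list)
  }
  n_in <- length(unique(gene_list))
  if (!length(mapped))
    return(list(n_input = n_in, n_mapped = 0L, frac_de = 0, frac_bound = 0))
  deg <- de_genes(de_class)
  is_de <- vapply(mapped, function(ga) any(ga %in% deg), logical(1))
  is_bound <- vapply(mapped, function(ga) any(ga %in% peak_genes), logical(1))
  list(n_input = n_in, n_mapped = length(mapped),
       frac_de = mean(is_de), frac_bound = mean(is_bound))
}
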