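# Gene-set enrichment engines.
#
# Two logistic-regression tests, both Wald-based with BH FDR across sets
# and a <=500-gene size filter:
#   * lrpath_directional(): membership ~ sign(log2FC) * (-log p) over all
#     genes in a differential-expression comparison; the slope's sign
#     separates induced from repressed sets.
#   * chipenrich_ll(): peak presence ~ membership + spline(log10 locus
#     length), removing the locus-length confounder of binding-based
#     enrichment.

#' Read gene sets from a GMT file
#' @param path GMT path (set id, description, then member genes, tab-separated)
#' @return named list of `geneset` lists (`set_id`, `description`, `genes`)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    list(set_id = f[1], description = f[2], genes = unique(f[-(1:2)]))
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "set_id"))
}

#' Write gene sets in GMT format
#' @param sets named list as returned by [read_gmt()]
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(sets, function(s)
    paste(c(s$set_id, s$description, s$genes), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR control: `q_i = min_{p_j >= p_i} m * p_j / rank_j`, capped
#' at 1 and order-preserving with the input.
#' @param pvalues numeric vector of p-values in (0, 1]
#' @return q-values in input order
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

filter_sets <- function(sets, universe, min_size, max_size) {
  memb <- lapply(sets, function(s) unique(s$genes[s$genes %in% universe]))
  n <- lengths(memb)
  keep <- n >= min_size & n <= max_size
  list(members = memb[keep], sets = sets[keep])
}

wald_p <- function(coef, se) 2 * stats::pnorm(-abs(coef / se))

#' Directional gene-set enrichment of expression results
#'
#' For each gene set, fits membership (0/1) against the signed evidence
#' statistic `sign(log2fc) * (-log pvalue)` across all genes by logistic
#' regression. A positive slope means set members concentrate among
#' significantly induced genes ("induced"); negative means "repressed".
#' Two-sided Wald p on the slope; BH q across tested sets.
#'
#' @param de DE data frame (`gene_id`, `log2fc`, `pvalue`)
#' @param sets gene-set list from [read_gmt()]
#' @param min_size,max_size set-size bounds after intersection with the
#'   tested universe (defaults 5 and 500; only sets of at most 500 genes
#'   are reported)
#' @param test `"wald"` (default) or `"lrt"` (likelihood-ratio) for the
#'   slope p-value
#' @return `enrichment_result` data frame: `set_id`, `description`,
#'   `n_genes`, `coefficient`, `direction`, `pvalue`, `qvalue`
#' @export
lrpath_directional <- function(de, sets, min_size = 5L, max_size = 500L,
                               test = c("wald", "lrt")) {
  check_cols(de, c("gene_id", "log2fc", "pvalue"), "DE table")
  if (anyDuplicated(de$gene_id)) stop("duplicate gene_id in DE table")
  stat <- sign(de$log2fc) * (-log(pmax(de$pvalue, .Machine$double.xmin)))
  fs <- filter_sets(sets, de$gene_id, min_size, max_size)
  test <- match.arg(test)
  rows <- lapply(names(fs$members), function(id) {
    y <- as.integer(de$gene_id %in% fs$members[[id]])
    if (sum(y) == 0L || sum(y) == length(y)) return(NULL)  # degenerate
    X <- cbind(1, stat)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(w) {
        if (grepl("numerically 0 or 1|did not converge", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    sm <- summary_glmfit(fit)
    if (is.na(sm$coef[2]) || all(stat == stat[1])) {
      # constant statistic: no information, slope 0 by convention
      sm <- list(coef = c(sm$coef[1], 0), se = c(sm$se[1], Inf))
    } else if (sep || !fit$converged || !is.finite(sm$se[2]) ||
               abs(sm$coef[2] / sm$se[2]) < 1e-8 * abs(sm$coef[2])) {
      # (quasi-)separation inflates the Wald SE; Firth-penalized fit
      ff <- firth_logistic(X, y)
      sm <- list(coef = ff$coef, se = ff$se)
    }
    p <- if (test == "lrt" && sm$coef[2] != 0) {
      f0 <- stats::glm.fit(matrix(1, length(y)), y,
                           family = stats::binomial())
      stats::pchisq(f0$deviance - fit$deviance, 1, lower.tail = FALSE)
    } else wald_p(sm$coef[2], sm$se[2])
    data.frame(set_id = id, description = fs$sets[[id]]$description,
               n_genes = sum(y), coefficient = sm$coef[2],
               direction = if (sm$coef[2] >= 0) "induced" else "repressed",
               pvalue = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- empty_enrichment()
  res$qvalue <- bh_fdr(res$pvalue)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

empty_enrichment <- function() {
  data.frame(set_id = character(), description = character(),
             n_genes = integer(), coefficient = numeric(),
             direction = character(), pvalue = numeric(),
             stringsAsFactors = FALSE)
}

# Coefficients and standard errors from a glm.fit object.
summary_glmfit <- function(fit) {
  p <- fit$rank
  Qr <- fit$qr
  cov <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  list(coef = fit$coefficients, se = sqrt(diag(cov)))
}

#' Gene loci with peak assignment
#'
#' Builds the per-gene input of [chipenrich_ll()]: locus length (from
#' `upstream` bp 5' of the TSS to the transcript 3' end) and peak counts
#' under nearest-TSS assignment, optionally restricted to peaks within
#' `max_distance` bp of the assigned TSS.
#'
#' @param genes gene-model data frame
#' @param peaks peak data frame (may be `NULL` for zero counts)
#' @param upstream locus upstream extent in bp (default 10000)
#' @param max_distance only count peaks with |mode - TSS| at most this
#'   (default `Inf`)
#' @return data frame: `gene_id`, `locus_length`, `n_peaks`, `has_peak`
#' @export
gene_loci <- function(genes, peaks = NULL, upstream = 10000L,
                      max_distance = Inf) {
  spans <- gene_locus_spans(genes, upstream)
  n <- stats::setNames(integer(nrow(genes)), genes$gene_id)
  if (!is.null(peaks) && nrow(peaks)) {
    asn <- nearest_tss(peaks, genes)
    asn <- asn[!is.na(asn$gene_id) & asn$abs_distance <= max_distance, ]
    if (nrow(asn)) {
      tb <- table(asn$gene_id)
      n[names(tb)] <- as.integer(tb)
    }
  }
  data.frame(gene_id = genes$gene_id, locus_length = spans$locus_length,
             n_peaks = unname(n), has_peak = unname(n) >= 1L,
             stringsAsFactors = FALSE)
}

#' Locus-length-adjusted gene-set enrichment of binding data
#'
#' For each gene set, fits `has_peak ~ membership + ns(log10 locus
#' length, df)` by logistic regression, so that gene sets of atypically
#' long genes are not called enriched merely because long loci catch
#' more peaks. Wald p on the membership coefficient; BH q across sets;
#' sets larger than `max_size` genes are not reported. Fits with
#' complete separation fall back to Firth-penalized logistic regression
#' and are flagged.
#'
#' @param loci data frame from [gene_loci()]
#' @param sets gene-set list from [read_gmt()]
#' @param spline_df degrees of freedom of the natural cubic spline on
#'   log10 locus length (default 10, reduced automatically for small
#'   universes)
#' @param min_size,max_size set-size bounds (defaults 5 and 500)
#' @return `enrichment_result` data frame with an extra `flag` column
#' @export
chipenrich_ll <- function(loci, sets, spline_df = 10L, min_size = 5L,
                          max_size = 500L) {
  check_cols(loci, c("gene_id", "locus_length", "has_peak"), "loci")
  stopifnot(all(loci$locus_length > 0))
  y <- as.integer(loci$has_peak)
  ll <- log10(loci$locus_length)
  df_use <- min(spline_df, max(1L, length(unique(ll)) - 2L))
  S <- if (length(unique(ll)) > 1L) splines::ns(ll, df = df_use)
       else matrix(0, length(ll), 0)
  fs <- filter_sets(sets, loci$gene_id, min_size, max_size)
  rows <- lapply(names(fs$members), function(id) {
    memb <- as.integer(loci$gene_id %in% fs$members[[id]])
    if (sum(memb) == 0L || sum(memb) == length(memb)) return(NULL)
    X <- cbind(`(Intercept)` = 1, member = memb, S)
    flag <- ""
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    sm <- summary_glmfit(fit)
    if (sep || !fit$converged || is.na(sm$coef[2]) ||
        !is.finite(sm$se[2]) || abs(sm$coef[2]) > 15) {
      ff <- firth_logistic(X, y)
      sm <- list(coef = ff$coef, se = ff$se)
      flag <- "firth"
    }
    data.frame(set_id = id, description = fs$sets[[id]]$description,
               n_genes = sum(memb), coefficient = sm$coef[2],
               direction = if (sm$coef[2] >= 0) "enriched" else "depleted",
               pvalue = wald_p(sm$coef[2], sm$se[2]), flag = flag,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) { res <- empty_enrichment(); res$flag <- character(0) }
  res$qvalue <- bh_fdr(res$pvalue)
  res <- res[, c("set_id", "description", "n_genes", "coefficient",
                 "direction", "pvalue", "qvalue", "flag")]
  class(res) <- c("enrichment_result", "data.frame")
  res
}

# Firth-penalized logistic regression (Jeffreys prior) by adjusted-score
# IRLS; used only as the separation fallback of chipenrich_ll().
firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-6) {
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    XtWX <- crossprod(X, XW)
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((X %*% inv) * XW)  # hat diagonal
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  cov <- tryCatch(solve(crossprod(X, X * w)),
                  error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(coef = beta, se = sqrt(diag(cov)))
}

#' Motif- and distance-stratified binding enrichment
#'
#' Classifies peaks by which motif they contain and whether they lie
#' within `near_max` bp of a TSS or more than `near_max` bp upstream of
#' it, then runs [chipenrich_ll()] per stratum. When expression
#' enrichment results are supplied, each stratum's table is joined with
#' them to mark sets both bound and directionally regulated.
#'
#' @param peaks peak data frame
#' @param hits_list named list of hit frames (one per motif) from
#'   [scan_peaks()]
#' @param genes gene-model data frame
#' @param sets gene-set list
#' @param near_max near/far TSS distance boundary in bp (default 10000)
#' @param de_enrich optional `enrichment_result` from
#'   [lrpath_directional()] to join on `set_id`
#' @param q_cut significance threshold used for the joint marking
#'   (default 0.05)
#' @param spline_df passed to [chipenrich_ll()]
#' @return named list of per-stratum `enrichment_result` frames
#'   (strata named `<motif>_near_tss` / `<motif>_far_upstream`); empty
#'   strata are skipped with a message
#' @export
stratified_enrichment <- function(peaks, hits_list, genes, sets,
                                  near_max = 10000L, de_enrich = NULL,
                                  q_cut = 0.05, spline_df = 10L) {
  stopifnot(length(names(hits_list)) == length(hits_list))
  asn <- nearest_tss(peaks, genes)
  near <- !is.na(asn$abs_distance) & asn$abs_distance <= near_max
  far_up <- !is.na(asn$abs_distance) & asn$abs_distance > near_max &
    asn$upstream %in% TRUE
  out <- list()
  for (m in names(hits_list)) {
    has <- peak_has_motif(peaks, hits_list[[m]])
    for (stratum in c("near_tss", "far_upstream")) {
      sel <- has & if (stratum == "near_tss") near else far_up
      label <- paste0(m, "_", stratum)
      if (!any(sel)) {
        message("stratum ", label, " is empty; skipped")
        next
      }
      loci <- gene_loci(genes, peaks[sel, , drop = FALSE],
                        max_distance = Inf)
      res <- chipenrich_ll(loci, sets, spline_df = spline_df)
      if (!is.null(de_enrich)) {
        j <- de_enrich[match(res$set_id, de_enrich$set_id), ]
        res$de_direction <- j$direction
        res$de_qvalue <- j$qvalue
        res$enriched_and_regulated <- res$qvalue <= q_cut &
          !is.na(j$qvalue) & j$qvalue <= q_cut
      }
      out[[label]] <- res
    }
  }
  out
}
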