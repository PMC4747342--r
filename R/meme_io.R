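# MEME minimal motif format: letter-probability matrix blocks.

#' Read motifs from a MEME minimal format file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections and the
#' optional `Background letter frequencies` line. Returns PWMs carrying
#' that background (uniform if absent).
#'
#' @param path MEME minimal file
#' @return named list of `pwm` objects
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg <- rep(0.25, 4)
  bi <- grep("^Background letter frequencies", lines)
  if (length(bi) && bi[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bi[1] + 1L]), "\\s+")[[1]]
    if (length(tok) >= 8) {
      vals <- as.numeric(tok[seq(2, 8, by = 2)])
      names(vals) <- tok[seq(1, 7, by = 2)]
      bg <- unname(vals[DNA_BASES])
    }
  }
  mi <- grep("^MOTIF\\b", lines)
  if (!length(mi)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (m in mi) {
    name <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    hi <- grep("^letter-probability matrix", lines)
    hi <- hi[hi > m][1]
    if (is.na(hi)) stop("MOTIF '", name, "' has no letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hi]))
    rows <- lines[(hi + 1L):(hi + w)]
    probs <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])))
    out[[name]] <- pwm_from_probs(probs, name = name, background = bg)
  }
  out
}

#' Write motifs in MEME minimal format
#' @param pwms a `pwm` object or list of them
#' @param path output path
#' @param background length-4 background written to the header; defaults
#'   to the first motif's background
#' @export
write_meme <- function(pwms, path, background = NULL) {
  if (inherits(pwms, "pwm")) pwms <- stats::setNames(list(pwms), pwms$name)
  bg <- background %||% pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", p$width), con)
    writeLines(apply(p$probs, 1, function(r)
      sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}
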