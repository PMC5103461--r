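# Tabular similarity-search hits in the conventional 12-column layout:
# qseqid sseqid pident length mismatch gapopen qstart qend sstart send
# evalue bitscore.

HITS_COLS <- c("query", "subject", "pct_identity", "aln_length", "mismatch",
               "gapopen", "qstart", "qend", "sstart", "send", "evalue",
               "bitscore")

#' Read a 12-column tabular hits file
#'
#' @param path Path to a tab-separated hits table (no header).
#' @return Tibble with columns `query`, `subject`, `pct_identity`,
#'   `aln_length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`.
#' @export
read_hits_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- as_tibble(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), HITS_COLS))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12))
    abort(sprintf("hits line %d has %d columns (expected 12)",
                  which(nf != 12)[[1]], nf[nf != 12][[1]]))
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  out <- tibble(
    query = m[, 1], subject = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.numeric(m[, 4]),
    mismatch = as.numeric(m[, 5]), gapopen = as.numeric(m[, 6]),
    qstart = as.numeric(m[, 7]), qend = as.numeric(m[, 8]),
    sstart = as.numeric(m[, 9]), send = as.numeric(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]))
  validate_hits(out)
  out
}

validate_hits <- function(hits) {
  stopifnot(all(c("query", "subject", "pct_identity", "aln_length",
                  "evalue", "bitscore") %in% names(hits)))
  if (nrow(hits) == 0) return(invisible(hits))
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0))
    abort("evalue must be a non-negative number")
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    abort("pct_identity must lie in [0, 100]")
  if (any(hits$aln_length < 1)) abort("aln_length must be >= 1")
  invisible(hits)
}

#' Write a hits table in 12-column tabular layout
#'
#' @param hits Hits tibble as returned by [read_hits_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tab <- function(hits, path) {
  validate_hits(hits)
  df <- as.data.frame(hits[, HITS_COLS])
  df$evalue <- formatC(df$evalue, format = "g", digits = 6)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
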