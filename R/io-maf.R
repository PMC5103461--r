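# MAF (multiple alignment format) import, restricted to pairwise blocks:
# the first "s" line of each block is the reference row, the second the
# query. Coordinates follow the MAF convention (0-based start, size,
# strand, source length); minus-strand starts are converted to
# forward-strand starts. No installed R package parses MAF, so the block
# reader lives here.

#' Read pairwise alignment blocks from a MAF file
#'
#' @param path Path to a MAF file with two `s` lines per alignment block.
#' @return Tibble of alignment blocks: `ref_id`, `ref_start`, `query_id`,
#'   `query_start` (0-based, forward strand), `strand`, `ref_aln`,
#'   `query_aln` (gapped strings of equal length).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  s_idx <- which(startsWith(lines, "s"))
  a_idx <- which(startsWith(lines, "a"))
  blocks <- vector("list", length(a_idx))
  for (bi in seq_along(a_idx)) {
    from <- a_idx[bi]
    to <- if (bi < length(a_idx)) a_idx[bi + 1] - 1L else length(lines)
    rows <- s_idx[s_idx > from & s_idx <= to]
    if (length(rows) != 2)
      abort(sprintf("MAF block at line %d has %d 's' rows (expected 2)",
                    from, length(rows)))
    parse_s <- function(ln, lineno) {
      f <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      if (length(f) != 7)
        abort(sprintf("ragged MAF 's' row at line %d (%d fields)", ln, length(f)))
      list(src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
           strand = f[5], src_size = as.integer(f[6]), text = toupper(f[7]))
    }
    r <- parse_s(rows[1])
    q <- parse_s(rows[2])
    if (nchar(r$text) != nchar(q$text))
      abort(sprintf("MAF block at line %d: rows of unequal gapped length", from))
    fwd_start <- function(s) {
      if (s$strand == "-") s$src_size - s$start - s$size else s$start
    }
    blocks[[bi]] <- tibble(
      ref_id = r$src, ref_start = fwd_start(r),
      query_id = q$src, query_start = fwd_start(q),
      strand = if (r$strand == q$strand) "+" else "-",
      ref_aln = r$text, query_aln = q$text)
  }
  out <- dplyr::bind_rows(blocks)
  if (nrow(out) > 0) validate_blocks(out)
  out
}

validate_blocks <- function(blocks) {
  stopifnot(all(c("ref_id", "ref_start", "query_id", "query_start",
                  "strand", "ref_aln", "query_aln") %in% names(blocks)))
  if (any(nchar(blocks$ref_aln) != nchar(blocks$query_aln)))
    abort("alignment block rows have unequal gapped length")
  both_gap <- mapply(function(r, q) {
    rr <- charToRaw(r) == charToRaw("-")
    qq <- charToRaw(q) == charToRaw("-")
    any(rr & qq)
  }, blocks$ref_aln, blocks$query_aln)
  if (any(both_gap)) abort("alignment block has a column gapped in both rows")
  invisible(blocks)
}
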