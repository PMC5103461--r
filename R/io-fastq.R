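# FASTQ (4-line records, Phred+33) input/output for short-read sets.
# A read set is a tibble with columns `id`, `bases`, `quals`.

#' Read a FASTQ file
#'
#' @param path Path to an uncompressed FASTQ file (4 lines per record,
#'   Phred+33 qualities).
#' @return Tibble with columns `id`, `bases` (uppercase), `quals`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(tibble(id = character(), bases = character(), quals = character()))
  if (length(lines) %% 4 != 0)
    abort(sprintf("truncated FASTQ record at record %d in '%s'",
                  length(lines) %/% 4 + 1, path))
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  bases <- toupper(lines[seq(2, by = 4, length.out = n)])
  plus <- lines[seq(3, by = 4, length.out = n)]
  quals <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0)
    abort(sprintf("malformed FASTQ record %d in '%s'", bad[[1]], path))
  mism <- which(nchar(bases) != nchar(quals))
  if (length(mism) > 0)
    abort(sprintf("record %d: quality string length (%d) != read length (%d)",
                  mism[[1]], nchar(quals[[mism[[1]]]]), nchar(bases[[mism[[1]]]])))
  if (any(grepl("[^ACGTN]", bases))) {
    i <- which(grepl("[^ACGTN]", bases))[[1]]
    abort(sprintf("record %d contains characters outside {A,C,G,T,N}", i))
  }
  out <- tibble(id = sub("^@", "", sub("[[:space:]].*$", "", hdr)),
                bases = bases, quals = quals)
  validate_reads(out)
  out
}

validate_reads <- function(reads) {
  stopifnot(all(c("id", "bases", "quals") %in% names(reads)))
  if (any(nchar(reads$bases) != nchar(reads$quals)))
    abort("read and quality lengths differ")
  if (any(reads$id == "" | is.na(reads$id))) abort("read ids must be non-empty")
  invisible(reads)
}

#' Write reads to FASTQ
#'
#' @param reads Read tibble (`id`, `bases`, `quals`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    out <- rbind(paste0("@", reads$id), reads$bases, "+", reads$quals)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}
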