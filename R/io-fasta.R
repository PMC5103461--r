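# FASTA input/output. An assembly is an ordinary tibble with columns
# `id`, `desc`, `residues`; sequences are stored uppercase over the IUPAC
# nucleotide alphabet. Parsing is delegated to Biostrings; validation adds
# the position-level diagnostics the downstream modules rely on.

#' Construct a genome assembly tibble
#'
#' @param id Character vector of scaffold identifiers (no whitespace).
#' @param residues Character vector of nucleotide sequences (IUPAC letters;
#'   lowercase is normalized to uppercase).
#' @param desc Optional description per scaffold.
#' @return A tibble with columns `id`, `desc`, `residues`.
#' @export
#' @examples
#' assembly_tbl("s1", "acgtACGT")
assembly_tbl <- function(id, residues, desc = "") {
  out <- tibble(id = as.character(id),
                desc = rep_len(as.character(desc), length(id)),
                residues = toupper(as.character(residues)))
  validate_assembly(out)
  out
}

validate_assembly <- function(assembly) {
  if (nrow(assembly) == 0) abort("assembly has no records")
  if (anyNA(assembly$id) || any(assembly$id == ""))
    abort("sequence ids must be non-empty")
  if (any(grepl("[[:space:]]", assembly$id)))
    abort("sequence ids must not contain whitespace")
  dup <- assembly$id[duplicated(assembly$id)]
  if (length(dup) > 0)
    abort(sprintf("duplicate sequence id: '%s'", dup[[1]]))
  if (any(!nzchar(assembly$residues)))
    abort(sprintf("empty sequence for id '%s'",
                  assembly$id[!nzchar(assembly$residues)][[1]]))
  bad_re <- sprintf("[^%s]", paste(IUPAC_CHARS, collapse = ""))
  hit <- regexpr(bad_re, assembly$residues)
  if (any(hit > 0)) {
    i <- which(hit > 0)[[1]]
    abort(sprintf(
      "illegal character '%s' in sequence '%s' at position %d",
      substr(assembly$residues[[i]], hit[[i]], hit[[i]]),
      assembly$id[[i]], hit[[i]]))
  }
  invisible(assembly)
}

#' Read a FASTA file into an assembly tibble
#'
#' @param path Path to a FASTA file.
#' @return Assembly tibble (`id`, `desc`, `residues`), residues uppercased.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("no FASTA records in '%s'", path))
  headers <- names(set)
  id <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  assembly_tbl(id = id, residues = as.character(set), desc = desc)
}

#' Write an assembly tibble to FASTA
#'
#' @param assembly Assembly tibble.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path, wrap = 70L) {
  validate_assembly(assembly)
  set <- Biostrings::BStringSet(assembly$residues)
  names(set) <- ifelse(nzchar(assembly$desc),
                       paste(assembly$id, assembly$desc), assembly$id)
  Biostrings::writeXStringSet(set, path, width = as.integer(wrap))
  invisible(path)
}
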