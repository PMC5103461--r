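# Shared low-level helpers: alphabet handling, seeded RNG streams,
# random sequence generation.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes accepted on input; everything except ACGT is
# treated as uncallable downstream (like N).
IUPAC_CHARS <- c(DNA_BASES, "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors as the working currency.
#'
#' @param x Character vector of DNA sequences (IUPAC letters allowed).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic child seed derived from a root seed and a stage label, so
# sub-stage randomness is reproducible independently of call order.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# i.i.d. random DNA with P(G) + P(C) = gc; returns a single string.
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc > 0, gc < 1)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- sample.int(4L, n, replace = TRUE, prob = probs)
  rawToChar(charToRaw("ACGT")[codes])
}

# GC fraction over non-N bases of one or more sequences.
seq_gc <- function(x) {
  counts <- colSums(Biostrings::alphabetFrequency(Biostrings::DNAStringSet(x)))
  gc <- counts[["G"]] + counts[["C"]]
  acgt <- gc + counts[["A"]] + counts[["T"]]
  gc / acgt
}

# Concatenate scaffolds with a separator character that matches nothing.
concat_scaffolds <- function(assembly, sep = "#") {
  paste(assembly$residues, collapse = sep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
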