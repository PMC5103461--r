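# Whole-genome-shotgun read simulation over a multi-replicon plan
# (nuclear chromosome, mitochondrion, plasmid, tandem rDNA unit, ...).
# Expected depth per replicon is base_coverage * copy_number; circular
# replicons (and tandem repeat units, which behave identically for reads
# crossing a unit junction) are sampled across the origin.

#' Build a replicon plan
#'
#' @param replicon Character vector of replicon names.
#' @param length Replicon lengths (bp).
#' @param copy_number Copies per nuclear genome (>= 1).
#' @param circular Logical; circular replicons (or tandem units) are
#'   sampled across the origin.
#' @return Tibble with one row per replicon.
#' @export
#' @examples
#' replicon_plan(c("nuclear", "mito"), c(1e5, 2e4), c(1, 45), c(FALSE, TRUE))
replicon_plan <- function(replicon, length, copy_number = 1,
                          circular = FALSE) {
  out <- tibble(replicon = as.character(replicon),
                length = as.integer(round(length)),
                copy_number = rep_len(copy_number, base::length(replicon)),
                circular = rep_len(circular, base::length(replicon)))
  if (any(out$copy_number < 1)) abort("copy_number must be >= 1")
  if (any(out$length < 1)) abort("replicon length must be positive")
  if (anyDuplicated(out$replicon)) abort("replicon names must be unique")
  out
}

#' Simulate shotgun reads from a multi-replicon genome
#'
#' Reads are drawn uniformly from each replicon at expected depth
#' `base_coverage * copy_number`, with uniform per-base substitution
#' errors. Returns the reads, a truth table of per-read origins, and the
#' replicon sequences.
#'
#' @param plan A [replicon_plan()].
#' @param config A [sim_config()] (read length, base coverage, error rate,
#'   GC, seed).
#' @param sequences Optional assembly tibble supplying the replicon
#'   sequences (ids matching `plan$replicon`); generated at `config$gc`
#'   when absent.
#' @return List with `reads` (tibble `id`, `bases`, `quals`), `origins`
#'   (truth tibble: `read_id`, `replicon`, `start` 0-based, `end`,
#'   `strand`, `n_errors`), and `replicons` (assembly tibble).
#' @export
simulate_reads <- function(plan, config, sequences = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rl <- config$read_length
  if (any(rl > plan$length))
    abort("read_length exceeds a replicon length")
  with_seed(derive_seed(config$seed, "reads"), {
    if (is.null(sequences)) {
      sequences <- assembly_tbl(
        id = plan$replicon,
        residues = vapply(plan$length, random_dna, "", gc = config$gc))
    } else {
      validate_assembly(sequences)
      if (!all(plan$replicon %in% sequences$id))
        abort("sequences missing for some replicons")
      if (!all(nchar(sequences$residues[match(plan$replicon, sequences$id)]) ==
               plan$length))
        abort("sequence lengths disagree with the plan")
    }
    out <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      out[[i]] <- sample_replicon_reads(
        plan$replicon[[i]],
        sequences$residues[[match(plan$replicon[[i]], sequences$id)]],
        plan$circular[[i]],
        n_reads = round(config$base_coverage * plan$copy_number[[i]] *
                          plan$length[[i]] / rl),
        rl = rl, error_rate = config$error_rate)
    }
  })
  reads <- dplyr::bind_rows(lapply(out, `[[`, "reads"))
  origins <- dplyr::bind_rows(lapply(out, `[[`, "origins"))
  list(reads = reads, origins = origins, replicons = sequences)
}

sample_replicon_reads <- function(name, seq, circular, n_reads, rl,
                                  error_rate) {
  L <- nchar(seq)
  if (n_reads < 1)
    return(list(reads = tibble(id = character(), bases = character(),
                               quals = character()),
                origins = tibble(read_id = character(), replicon = character(),
                                 start = integer(), end = integer(),
                                 strand = character(), n_errors = integer())))
  if (circular) {
    starts <- sample.int(L, n_reads, replace = TRUE)          # 1-based
    template <- paste0(seq, substr(seq, 1L, rl - 1L))
  } else {
    starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
    template <- seq
  }
  bases <- substring(template, starts, starts + rl - 1L)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  neg <- strand == "-"
  if (any(neg)) bases[neg] <- revcomp(bases[neg])
  n_errors <- integer(n_reads)
  if (error_rate > 0) {
    # mutate positions in one concatenated raw vector
    raw <- charToRaw(paste(bases, collapse = ""))
    total <- length(raw)
    n_err <- rbinom(1, total, error_rate)
    if (n_err > 0) {
      posn <- sample.int(total, n_err)
      code <- integer(256)
      code[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
      old <- code[as.integer(raw[posn]) + 1L]
      newc <- (old + sample.int(3L, n_err, replace = TRUE)) %% 4L
      raw[posn] <- charToRaw("ACGT")[newc + 1L]
      n_errors <- tabulate((posn - 1L) %/% rl + 1L, nbins = n_reads)
    }
    bases <- substring(rawToChar(raw), (seq_len(n_reads) - 1L) * rl + 1L,
                       seq_len(n_reads) * rl)
  }
  ids <- sprintf("%s_read_%06d", name, seq_len(n_reads))
  list(
    reads = tibble(id = ids, bases = bases,
                   quals = strrep("I", rl)),
    origins = tibble(read_id = ids, replicon = name,
                     start = starts - 1L, end = starts - 1L + rl,
                     strand = strand, n_errors = n_errors))
}

#' Median per-position depth of each replicon from read origins
#'
#' Uses [IRanges::coverage()]; intervals of circular replicons are wrapped
#' at the origin.
#'
#' @param origins Origin truth tibble from [simulate_reads()] (or any table
#'   with `replicon`, `start`, `end` in 0-based half-open coordinates).
#' @param plan The matching [replicon_plan()].
#' @return Tibble `replicon`, `median_depth`.
#' @export
replicon_depth <- function(origins, plan) {
  purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    L <- plan$length[[i]]
    o <- origins[origins$replicon == plan$replicon[[i]], ]
    if (nrow(o) == 0) return(tibble(replicon = plan$replicon[[i]],
                                    median_depth = 0))
    s <- o$start + 1L    # 1-based closed
    e <- o$end
    if (plan$circular[[i]]) {
      wrap <- e > L
      ir <- c(IRanges::IRanges(s, pmin(e, L)),
              IRanges::IRanges(rep(1L, sum(wrap)), e[wrap] - L))
    } else {
      ir <- IRanges::IRanges(s, pmin(e, L))
    }
    cov <- IRanges::coverage(ir, width = L)
    tibble(replicon = plan$replicon[[i]],
           median_depth = median(as.integer(cov)))
  })
}
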