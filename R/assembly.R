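# Targeted seed-and-extend assembly. Reads are recruited to bait
# sequences by k-mer seeding plus (near-)diagonal comparison with the
# recruitment thresholds as the contract (identity >= 0.95 over >= 40% of
# the read); a maximum-depth seed read starts the contig; rounds of
# extension align the pool to the contig ends, stack overhanging bases
# into consensus columns, and fix the contiguous run of columns passing
# the information-content (IC > 0.5 bit) and coverage gates; circularity
# is detected from a suffix-prefix overlap and the rotation normalized.

# ---- read k-mer index -----------------------------------------------------

# both-orientation k-mer index over a read set; kmers sorted for binary
# range lookup
read_index <- function(reads, k = 12L) {
  validate_reads(reads)
  fwd <- toupper(reads$bases)
  rev <- revcomp(fwd)
  cat_fwd <- paste(fwd, collapse = "#")
  cat_rev <- paste(rev, collapse = "#")
  kf <- cpp_kmer_positions(cat_fwd, k)
  kr <- cpp_kmer_positions(cat_rev, k)
  offs <- cumsum(c(0L, head(nchar(fwd) + 1L, -1L)))
  locate <- function(kp) {
    ridx <- findInterval(kp$pos, offs)
    list(read = ridx, pos = kp$pos - offs[ridx])  # 0-based within read
  }
  lf <- locate(kf); lr <- locate(kr)
  kmer <- c(kf$kmer, kr$kmer)
  ord <- order(kmer)
  list(reads = reads, fwd = fwd, rev = rev, k = as.integer(k),
       kmer = kmer[ord],
       read = c(lf$read, lr$read)[ord],
       pos = c(lf$pos, lr$pos)[ord],
       strand = c(rep("+", length(kf$kmer)), rep("-", length(kr$kmer)))[ord])
}

# candidate (read, strand, offset) diagonals of index reads against a
# subject string; offset is the 0-based position of the read start in
# subject coordinates (may be negative)
index_candidates <- function(index, subject) {
  sk <- cpp_kmer_positions(subject, index$k)
  if (length(sk$kmer) == 0) return(NULL)
  lo <- findInterval(sk$kmer - 0.5, index$kmer) + 1L
  hi <- findInterval(sk$kmer + 0.5, index$kmer)
  keep <- hi >= lo
  if (!any(keep)) return(NULL)
  lo <- lo[keep]; hi <- hi[keep]
  spos <- sk$pos[keep]
  ii <- sequence(hi - lo + 1L, from = lo)
  srep <- rep(spos, hi - lo + 1L)
  cand <- tibble(read = index$read[ii], strand = index$strand[ii],
                 offset = srep - index$pos[ii])
  cand |>
    dplyr::count(.data$read, .data$strand, .data$offset) |>
    dplyr::group_by(.data$read, .data$strand) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

# gapless identity of oriented reads against the subject at the voted
# diagonals; returns one row per candidate with identity and coverage
score_candidates <- function(index, cand, subject) {
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  slen <- nchar(subject)
  rlen <- nchar(index$fwd)[cand$read]
  os <- pmax(cand$offset, 0L)                      # overlap start (0-based, subject)
  oe <- pmin(cand$offset + rlen, slen)             # overlap end
  ov <- oe - os
  keep <- ov > 0L
  cand <- cand[keep, ]; rlen <- rlen[keep]
  os <- os[keep]; oe <- oe[keep]; ov <- ov[keep]
  if (nrow(cand) == 0) return(NULL)
  oriented <- ifelse(cand$strand == "+", index$fwd[cand$read], index$rev[cand$read])
  matches <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rpart <- substr(oriented[i], os[i] - cand$offset[i] + 1L,
                    oe[i] - cand$offset[i])
    spart <- substr(subject, os[i] + 1L, oe[i])
    matches[i] <- sum(charToRaw(rpart) == charToRaw(spart))
  }
  tibble(read = cand$read, read_id = index$reads$id[cand$read],
         strand = cand$strand, offset = cand$offset,
         overlap_start = os, overlap_end = oe,
         identity = matches / ov, read_coverage = ov / rlen,
         bases = oriented)
}

# ---- recruitment ----------------------------------------------------------

#' Recruit reads matching a bait set
#'
#' A read is recruited when, in either orientation, it aligns to some bait
#' with identity at least `min_identity` over at least `min_read_coverage`
#' of its length. Alignment is k-mer-seeded diagonal comparison (the
#' simulated reads carry substitution errors only); the identity/coverage
#' thresholds are the algorithmic contract.
#'
#' @param reads Read tibble (`id`, `bases`, `quals`).
#' @param baits Assembly tibble of bait sequences.
#' @param min_identity Minimum alignment identity (default 0.95).
#' @param min_read_coverage Minimum aligned fraction of the read (0.40).
#' @param seed_k Seed k-mer length (default 12).
#' @return Tibble of recruited read alignments: `read_id`, `bait`,
#'   `strand`, `offset` (0-based read start in bait coordinates),
#'   `overlap_start`, `overlap_end`, `identity`, `read_coverage`, `bases`
#'   (bait-oriented read sequence). One best row per read.
#' @export
bait_reads <- function(reads, baits, min_identity = 0.95,
                       min_read_coverage = 0.40, seed_k = 12L) {
  if (is.null(baits) || nrow(baits) == 0) abort("empty bait set")
  validate_assembly(baits)
  index <- read_index(reads, seed_k)
  hits <- purrr::map_dfr(seq_len(nrow(baits)), function(b) {
    sc <- score_candidates(index,
                           index_candidates(index, baits$residues[[b]]),
                           baits$residues[[b]])
    if (is.null(sc)) return(NULL)
    dplyr::mutate(sc, bait = baits$id[[b]], .after = "read_id")
  })
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::filter(.data$identity >= min_identity,
                  .data$read_coverage >= min_read_coverage) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::slice_max(.data$identity * .data$read_coverage, n = 1,
                     with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"read")
}

#' Select the maximum-coverage seed read
#'
#' Depth is accumulated over the bait from all recruited alignments; the
#' seed is the read whose aligned footprint carries the largest summed
#' depth, ties broken by longer alignment, then lexicographically smaller
#' read id.
#'
#' @param pool Recruited alignments from [bait_reads()] (one bait).
#' @return The winning pool row (tibble of one row).
#' @export
select_seed <- function(pool) {
  if (is.null(pool) || nrow(pool) == 0) abort("empty read pool")
  if (length(unique(pool$bait)) > 1)
    pool <- pool[pool$bait == pool$bait[[1]], ]
  cov <- IRanges::coverage(IRanges::IRanges(pool$overlap_start + 1L,
                                            pool$overlap_end))
  depth <- as.integer(cov)
  score <- vapply(seq_len(nrow(pool)), function(i) {
    sum(depth[(pool$overlap_start[i] + 1L):pool$overlap_end[i]])
  }, 0L)
  ord <- order(-score, -(pool$overlap_end - pool$overlap_start), pool$read_id)
  pool[ord[1], ]
}

# ---- consensus columns ----------------------------------------------------

#' Shannon entropy and information content of consensus columns
#'
#' For base counts over {A,C,G,T}: H = -sum p_b log2 p_b and IC = 2 - H
#' (bits). Accepts a named count vector or a 4-row matrix (rows A,C,G,T;
#' one column per consensus position).
#'
#' @param counts Named numeric vector (names among A,C,G,T) or 4-row
#'   matrix.
#' @return Tibble with `coverage`, `H`, `IC` (one row per column).
#' @export
#' @examples
#' column_ic(c(A = 60, C = 40))
column_ic <- function(counts) {
  if (is.null(dim(counts))) {
    m <- matrix(0, 4, 1, dimnames = list(DNA_BASES, NULL))
    nm <- names(counts) %||% DNA_BASES[seq_along(counts)]
    m[nm, 1] <- counts
    counts <- m
  }
  if (nrow(counts) != 4) abort("counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) abort("counts must be non-negative")
  coverage <- colSums(counts)
  if (any(coverage == 0)) abort("all-zero count column")
  p <- sweep(counts, 2, coverage, "/")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  H <- -colSums(plogp)
  tibble(coverage = coverage, H = H, IC = 2 - H)
}

# ---- contig extension -----------------------------------------------------

#' Iterative consensus extension of a seed read
#'
#' Each round aligns the pool to the terminal window of the contig,
#' stacks overhanging read bases into columns beyond the end, and fixes
#' the contiguous run of columns with IC above `ic_min` and coverage at
#' least `cov_min`; the fixed base is the majority base (ties resolved in
#' the order A < C < G < T). A side stops at its first non-qualifying
#' column; extension terminates when neither end advances, `max_length`
#' is reached, or the contig closes into a circle.
#'
#' @param seed Seed sequence: a string, or a row from [select_seed()].
#' @param reads Read pool tibble.
#' @param pool Optional [bait_reads()] table. When given, the initial
#'   contig is the IC- and coverage-gated consensus of the recruited
#'   reads stacked at their bait-frame offsets over the run containing
#'   the seed footprint, so sequencing errors in the raw seed read do not
#'   persist; without it the raw seed sequence starts the contig.
#' @param ic_min Information-content gate in bits (default 0.5).
#' @param cov_min Column coverage gate (study default 100; set lower for
#'   desk-scale data).
#' @param min_identity,min_read_coverage,seed_k Recruitment thresholds as
#'   in [bait_reads()].
#' @param min_anchor Minimum bases a read must overlap the existing
#'   contig; extension advances at most `read_length - min_anchor`
#'   columns per side per round.
#' @param max_rounds,max_length Safety bounds; hitting `max_rounds`
#'   returns the partial contig with `incomplete = TRUE` and a warning.
#' @param check_circular Detect circular closure after each round.
#' @param min_overlap,circ_identity Circularity test thresholds (see
#'   [detect_circular()]).
#' @return Object of class `contig`: `consensus`, per-fixed-column
#'   `columns` tibble (`position`, `coverage`, `H`, `IC`, `base`),
#'   `circular`, `rounds`, `incomplete`.
#' @export
extend_contig <- function(seed, reads, pool = NULL, ic_min = 0.5,
                          cov_min = 100L,
                          min_identity = 0.95, min_read_coverage = 0.40,
                          seed_k = 12L, min_anchor = 20L,
                          max_rounds = 1000L, max_length = Inf,
                          check_circular = TRUE, min_overlap = 100L,
                          circ_identity = 0.98) {
  if (cov_min < 1) abort("cov_min must be >= 1")
  seed_seq <- if (is.data.frame(seed)) seed$bases[[1]] else as.character(seed)
  index <- read_index(reads, seed_k)
  if (!is.null(pool) && is.data.frame(seed)) {
    boot <- bootstrap_consensus(pool, seed, ic_min, cov_min)
    if (!is.null(boot)) seed_seq <- boot
  }
  contig <- toupper(seed_seq)
  rl_max <- max(nchar(index$fwd))
  columns <- list()
  circular <- FALSE
  incomplete <- FALSE
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    grew <- FALSE
    for (side in c("right", "left")) {
      work <- if (side == "right") contig else revcomp(contig)
      ext <- extend_one_end(work, index, ic_min, cov_min, min_identity,
                            min_read_coverage, min_anchor, rl_max)
      if (!is.null(ext)) {
        grew <- TRUE
        if (side == "right") {
          ext$cols$position <- nchar(contig) + seq_len(nrow(ext$cols))
          contig <- paste0(contig, ext$seq)
        } else {
          ext$cols$position <- -(nchar(contig) - 1L + seq_len(nrow(ext$cols)))
          ext$cols$base <- revcomp(ext$cols$base)
          contig <- paste0(revcomp(ext$seq), contig)
        }
        columns[[length(columns) + 1L]] <- ext$cols
      }
    }
    if (check_circular && nchar(contig) >= 2L * min_overlap) {
      circ <- detect_circular(contig, min_overlap = min_overlap,
                              min_identity = circ_identity)
      if (circ$circular) {
        contig <- circ$sequence
        circular <- TRUE
        break
      }
    }
    if (!grew) break
    if (nchar(contig) >= max_length) break
    if (rounds >= max_rounds) {
      incomplete <- TRUE
      warn("extension did not converge within max_rounds; returning partial contig")
      break
    }
  }
  cols <- dplyr::bind_rows(columns)
  structure(list(consensus = contig,
                 columns = if (nrow(cols) > 0) cols[order(cols$position), ] else cols,
                 circular = circular, rounds = rounds,
                 incomplete = incomplete),
            class = "contig")
}

# IC/coverage-gated consensus of the recruited pool stacked at bait-frame
# offsets, restricted to the contiguous qualifying run containing the
# seed footprint; NULL when no column qualifies there
bootstrap_consensus <- function(pool, seed_row, ic_min, cov_min) {
  pool <- pool[pool$bait == seed_row$bait[[1]], ]
  if (nrow(pool) == 0) return(NULL)
  rlen <- nchar(pool$bases)
  col0 <- min(pool$offset)                      # leftmost stacked column
  chars <- strsplit(pool$bases, "", fixed = TRUE)
  lens <- lengths(chars)
  col_idx <- sequence(lens) + rep(pool$offset - col0, lens)  # 1-based stack col
  base <- unlist(chars, use.names = FALSE)
  code <- match(base, DNA_BASES)
  okb <- !is.na(code)
  maxcol <- max(col_idx[okb])
  counts <- matrix(tabulate((col_idx[okb] - 1L) * 4L + code[okb],
                            nbins = 4L * maxcol), nrow = 4L,
                   dimnames = list(DNA_BASES, NULL))
  cov <- colSums(counts)
  qual <- logical(maxcol)
  nz <- cov > 0
  stats <- column_ic(counts[, nz, drop = FALSE])
  qual[nz] <- stats$IC > ic_min & stats$coverage >= cov_min
  seed_mid <- seed_row$offset[[1]] - col0 + nchar(seed_row$bases[[1]]) %/% 2
  runs <- rle(qual)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & starts <= seed_mid & ends >= seed_mid)
  if (length(hit) == 0) return(NULL)
  span <- starts[hit]:ends[hit]
  maj <- apply(counts[, span, drop = FALSE], 2,
               function(cnt) DNA_BASES[which.max(cnt)])
  paste(maj, collapse = "")
}

# extend the right end of `work`; returns NULL or list(seq, cols)
extend_one_end <- function(work, index, ic_min, cov_min, min_identity,
                           min_read_coverage, min_anchor, rl_max) {
  L <- nchar(work)
  w <- min(L, rl_max)
  window <- substr(work, L - w + 1L, L)
  cand <- index_candidates(index, window)
  if (is.null(cand)) return(NULL)
  cand$offset <- cand$offset + (L - w)   # to full-contig coordinates
  rlen <- nchar(index$fwd)[cand$read]
  cand <- cand[cand$offset + rlen > L, , drop = FALSE]   # overhanging only
  if (nrow(cand) == 0) return(NULL)
  sc <- score_candidates(index, cand, work)
  if (is.null(sc)) return(NULL)
  sc <- sc[sc$identity >= min_identity &
             sc$read_coverage >= min_read_coverage &
             (sc$overlap_end - sc$overlap_start) >= min_anchor, , drop = FALSE]
  if (nrow(sc) == 0) return(NULL)
  rlen <- nchar(sc$bases)
  over_len <- pmin(sc$offset + rlen - L, rlen - min_anchor)
  over_len <- pmin(over_len, nchar(sc$bases) - (L - sc$offset))
  keep <- over_len > 0
  sc <- sc[keep, , drop = FALSE]; over_len <- over_len[keep]
  if (nrow(sc) == 0) return(NULL)
  overhang <- substr(sc$bases, L - sc$offset + 1L, L - sc$offset + over_len)
  chars <- strsplit(overhang, "", fixed = TRUE)
  lens <- lengths(chars)
  col_idx <- sequence(lens)
  base <- unlist(chars, use.names = FALSE)
  code <- match(base, DNA_BASES)
  okb <- !is.na(code)
  maxcol <- max(col_idx[okb], 0L)
  if (maxcol == 0L) return(NULL)
  counts <- matrix(tabulate((col_idx[okb] - 1L) * 4L + code[okb],
                            nbins = 4L * maxcol), nrow = 4L,
                   dimnames = list(DNA_BASES, NULL))
  stats <- column_ic(pmax(counts, 0) + 0)  # errors if a column is empty
  pass <- stats$IC > ic_min & stats$coverage >= cov_min
  n_fix <- if (all(pass)) maxcol else (which(!pass)[1] - 1L)
  if (n_fix == 0L) return(NULL)
  maj <- apply(counts[, seq_len(n_fix), drop = FALSE], 2,
               function(cnt) DNA_BASES[which.max(cnt)])
  list(seq = paste(maj, collapse = ""),
       cols = tibble(position = seq_len(n_fix),
                     coverage = stats$coverage[seq_len(n_fix)],
                     H = stats$H[seq_len(n_fix)],
                     IC = stats$IC[seq_len(n_fix)],
                     base = maj))
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig> %d bp, %s, %d rounds%s\n", nchar(x$consensus),
              if (x$circular) "circular" else "linear", x$rounds,
              if (x$incomplete) " [incomplete]" else ""))
  invisible(x)
}

#' Detect circular closure of a contig
#'
#' The contig is circular iff a suffix of length at least `min_overlap`
#' matches a prefix at identity at least `min_identity`. On closure the
#' duplicated suffix is trimmed and the sequence is reported at its
#' lexicographically minimal rotation.
#'
#' @param contig A `contig` object or sequence string.
#' @param min_overlap Minimum suffix-prefix overlap (bp).
#' @param min_identity Minimum identity of the overlap.
#' @return List `circular` (logical), `sequence` (trimmed, normalized
#'   rotation if circular, the input otherwise), `overlap` (bp).
#' @export
detect_circular <- function(contig, min_overlap = 100L, min_identity = 0.98) {
  s <- if (inherits(contig, "contig")) contig$consensus else as.character(contig)
  L <- nchar(s)
  probe_len <- min(32L, min_overlap)
  if (L < 2L * min_overlap)
    return(list(circular = FALSE, sequence = s, overlap = 0L))
  probe <- substr(s, 1L, probe_len)
  hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(probe), Biostrings::DNAString(s)))
  hits <- hits[hits > 1L]
  for (pos in sort(hits, decreasing = TRUE)) {
    x <- L - pos + 1L                       # suffix length aligned to prefix
    if (x < min_overlap || x > L - min_overlap) next
    a <- charToRaw(substr(s, pos, L))
    b <- charToRaw(substr(s, 1L, x))
    if (mean(a == b) >= min_identity) {
      core <- substr(s, 1L, pos - 1L)
      rot <- cpp_min_rotation(core)
      normalized <- paste0(substr(core, rot + 1L, nchar(core)),
                           substr(core, 1L, rot))
      return(list(circular = TRUE, sequence = normalized, overlap = x))
    }
  }
  list(circular = FALSE, sequence = s, overlap = 0L)
}

#' Coverage-ratio copy-number estimate
#'
#' @param target_depth Median per-position depth of the target replicon.
#' @param nuclear_depth Median depth of the single-copy nuclear fraction.
#' @return Tibble `ratio` (unrounded) and `copies` (nearest integer).
#' @export
#' @examples
#' estimate_copy_number(1500, 33.3)
estimate_copy_number <- function(target_depth, nuclear_depth) {
  if (any(nuclear_depth <= 0)) abort("nuclear_depth must be > 0")
  if (any(target_depth <= 0)) abort("target_depth must be > 0")
  ratio <- target_depth / nuclear_depth
  tibble(ratio = ratio, copies = round(ratio))
}
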