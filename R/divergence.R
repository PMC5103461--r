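# Sliding-window genome divergence. A minimal anchor-chaining aligner
# produces pairwise blocks for collinear genome pairs (unique shared
# k-mers, longest-increasing-subsequence chaining, global alignment of
# short diagonal-changing gaps); pre-computed alignments can be imported
# from MAF instead. Blocks are projected onto the reference as a per
# -position call track (match / mismatch / uncalled), summarized in 1-kb
# windows with a minimum-called filter, smoothed with +/-5 flanking
# windows for plotting, and pooled into per-scaffold and genome-wide
# divergence.

#' Anchor-based alignment of a collinear genome pair
#'
#' Intended for closely related, collinear pairs (up to roughly 15%
#' divergence), forward strand only. K-mers unique in both genomes anchor
#' a longest-increasing-subsequence chain; consecutive anchors on the same
#' diagonal are bridged directly, diagonal-changing gaps up to `max_gap`
#' are closed with affine-gap global alignment, larger ones split the
#' block.
#'
#' @param ref,query Assembly tibbles.
#' @param k Anchor k-mer length.
#' @param max_gap Largest diagonal-changing gap closed by alignment.
#' @return Alignment-block tibble (see [read_maf()] for the columns);
#'   empty when no anchors are found.
#' @export
anchor_align <- function(ref, query, k = 16L, max_gap = 2000L) {
  validate_assembly(ref); validate_assembly(query)
  ref_cat <- concat_scaffolds(ref)
  query_cat <- concat_scaffolds(query)
  anchors <- cpp_kmer_anchors(ref_cat, query_cat, as.integer(k))
  if (nrow(anchors) == 0) return(empty_blocks())
  ref_off <- cumsum(c(0L, head(nchar(ref$residues) + 1L, -1L)))
  query_off <- cumsum(c(0L, head(nchar(query$residues) + 1L, -1L)))
  rs <- findInterval(anchors[, 1], ref_off)
  qs <- findInterval(anchors[, 2], query_off)
  rloc <- anchors[, 1] - ref_off[rs]
  qloc <- anchors[, 2] - query_off[qs]
  grp <- split(seq_len(nrow(anchors)), list(rs, qs), drop = TRUE)
  out <- lapply(grp, function(ii) {
    o <- ii[order(rloc[ii])]
    keep <- o[cpp_lis(qloc[o])]
    chain_blocks(rloc[keep], qloc[keep], k,
                 ref$residues[[rs[keep[1]]]], query$residues[[qs[keep[1]]]],
                 ref$id[[rs[keep[1]]]], query$id[[qs[keep[1]]]], max_gap)
  })
  blocks <- dplyr::bind_rows(out)
  validate_blocks(blocks)
  blocks
}

empty_blocks <- function() {
  tibble(ref_id = character(), ref_start = integer(),
         query_id = character(), query_start = integer(),
         strand = character(), ref_aln = character(), query_aln = character())
}

# build gapped blocks from a chained anchor list (0-based local coords)
chain_blocks <- function(r, q, k, ref_seq, query_seq, ref_id, query_id,
                         max_gap) {
  n <- length(r)
  diag_change <- if (n > 1) which(diff(r) != diff(q)) else integer(0)
  # segment boundaries: runs of constant diagonal
  seg_start <- c(1L, diag_change + 1L)
  seg_end <- c(diag_change, n)
  blocks <- list()
  cur_ref <- character(0); cur_query <- character(0)
  cur_ref_start <- NA_integer_; cur_query_start <- NA_integer_
  cur_ref_end <- NA_integer_; cur_query_end <- NA_integer_
  flush <- function() {
    if (length(cur_ref) == 0) return(NULL)
    tibble(ref_id = ref_id, ref_start = cur_ref_start,
           query_id = query_id, query_start = cur_query_start,
           strand = "+",
           ref_aln = paste(cur_ref, collapse = ""),
           query_aln = paste(cur_query, collapse = ""))
  }
  for (s in seq_along(seg_start)) {
    a <- seg_start[s]; b <- seg_end[s]
    seg_r0 <- r[a]; seg_r1 <- r[b] + k   # [seg_r0, seg_r1) on ref
    seg_q0 <- q[a]; seg_q1 <- q[b] + k
    if (length(cur_ref) > 0) {
      gap_r <- seg_r0 - cur_ref_end
      gap_q <- seg_q0 - cur_query_end
      if (gap_r < 0 || gap_q < 0 || gap_r > max_gap || gap_q > max_gap) {
        blocks[[length(blocks) + 1L]] <- flush()
        cur_ref <- character(0); cur_query <- character(0)
      } else if (gap_r > 0 || gap_q > 0) {
        gr <- substr(ref_seq, cur_ref_end + 1L, seg_r0)
        gq <- substr(query_seq, cur_query_end + 1L, seg_q0)
        if (nchar(gr) == 0) {
          cur_ref <- c(cur_ref, strrep("-", nchar(gq)))
          cur_query <- c(cur_query, gq)
        } else if (nchar(gq) == 0) {
          cur_ref <- c(cur_ref, gr)
          cur_query <- c(cur_query, strrep("-", nchar(gr)))
        } else {
          aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(gq), Biostrings::DNAString(gr),
            type = "global", gapOpening = 10, gapExtension = 0.5)
          cur_ref <- c(cur_ref, as.character(Biostrings::subject(aln)))
          cur_query <- c(cur_query, as.character(Biostrings::pattern(aln)))
        }
      }
    }
    if (length(cur_ref) == 0) {
      cur_ref_start <- seg_r0; cur_query_start <- seg_q0
    }
    cur_ref <- c(cur_ref, substr(ref_seq, seg_r0 + 1L, seg_r1))
    cur_query <- c(cur_query, substr(query_seq, seg_q0 + 1L, seg_q1))
    cur_ref_end <- seg_r1; cur_query_end <- seg_q1
  }
  blocks[[length(blocks) + 1L]] <- flush()
  dplyr::bind_rows(blocks)
}

#' Project alignment blocks onto the reference as a call track
#'
#' A reference position is match or mismatch for a query genome iff it is
#' covered by exactly one block column whose two residues are both in
#' {A,C,G,T}; positions that are unaligned, gapped, ambiguous (N/IUPAC) or
#' covered by more than one block are uncalled. Overlap-caused uncalled
#' positions are counted in attribute `"n_overlap_uncalled"`.
#'
#' @param blocks Alignment-block tibble, or a named list of them (one per
#'   query genome) for multi-query tracks.
#' @param ref Reference assembly tibble.
#' @return Object of class `call_track`.
#' @export
build_call_track <- function(blocks, ref) {
  validate_assembly(ref)
  if (is.data.frame(blocks)) blocks <- list(query = blocks)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    abort("multi-query blocks must be a named list")
  lens <- setNames(nchar(ref$residues), ref$id)
  n_overlap <- 0L
  states <- lapply(blocks, function(bl) {
    validate_blocks(bl)
    per_scaffold <- lapply(ref$id, function(sid) integer(lens[[sid]]))
    names(per_scaffold) <- ref$id
    cov <- lapply(ref$id, function(sid) integer(lens[[sid]]))
    names(cov) <- ref$id
    for (i in seq_len(nrow(bl))) {
      sid <- bl$ref_id[[i]]
      if (!sid %in% ref$id) abort(sprintf("block references unknown scaffold '%s'", sid))
      rr <- charToRaw(bl$ref_aln[[i]])
      qq <- charToRaw(bl$query_aln[[i]])
      nongap <- rr != charToRaw("-")
      pos <- bl$ref_start[[i]] + cumsum(nongap)  # 1-based ref positions
      if (pos[length(pos)] > lens[[sid]])
        abort("block exceeds reference scaffold bounds")
      pos <- pos[nongap]
      rb <- as.integer(rr[nongap]); qb <- as.integer(qq[nongap])
      acgt <- as.integer(charToRaw("ACGT"))
      callable <- (rb %in% acgt) & (qb %in% acgt)
      st <- integer(length(pos))
      st[callable] <- 1L + (rb[callable] != qb[callable])
      cov[[sid]][pos] <- cov[[sid]][pos] + 1L
      per_scaffold[[sid]][pos] <- st
    }
    for (sid in ref$id) {
      over <- cov[[sid]] > 1L
      n_overlap <<- n_overlap + sum(per_scaffold[[sid]][over] > 0L)
      per_scaffold[[sid]][over] <- 0L
    }
    per_scaffold
  })
  structure(list(ref_ids = ref$id, ref_lens = lens, states = states,
                 n_overlap_uncalled = n_overlap),
            class = "call_track")
}

#' @export
print.call_track <- function(x, ...) {
  cat(sprintf("<call_track> %d scaffolds (%d bp), %d quer%s\n",
              length(x$ref_ids), sum(x$ref_lens), length(x$states),
              if (length(x$states) == 1) "y" else "ies"))
  invisible(x)
}

#' Windowed divergence statistics
#'
#' Splits the reference into windows of `window` bp every `step` bp (the
#' trailing partial window is kept) and counts called sites and
#' mismatches per window and query. With several queries, a position
#' counts as called only when called for all of them (joint calledness);
#' set `joint = FALSE` to relax to per-query calledness. Windows with
#' fewer than `min_called` called sites are flagged `retained = FALSE`.
#'
#' @param track A [build_call_track()] result.
#' @param window,step Window size and step (bp).
#' @param min_called Minimum called sites for a window to be retained.
#' @param joint Require joint calledness across queries.
#' @return Tibble `query`, `scaffold`, `start` (0-based), `called`,
#'   `mismatches`, `value`, `retained`.
#' @export
window_stats <- function(track, window = 1000L, step = 1000L,
                         min_called = 500L, joint = TRUE) {
  stopifnot(inherits(track, "call_track"))
  if (window <= 0 || step <= 0) abort("window and step must be positive")
  if (min_called > window) abort("min_called cannot exceed window")
  queries <- names(track$states)
  purrr::map_dfr(track$ref_ids, function(sid) {
    L <- track$ref_lens[[sid]]
    joint_called <- NULL
    if (joint && length(queries) > 1) {
      joint_called <- rep(TRUE, L)
      for (qn in queries)
        joint_called <- joint_called & (track$states[[qn]][[sid]] > 0L)
    }
    starts <- seq(0L, max(L - 1L, 0L), by = step)
    purrr::map_dfr(queries, function(qn) {
      st <- track$states[[qn]][[sid]]
      called_vec <- if (is.null(joint_called)) st > 0L else joint_called
      mism_vec <- (st == 2L) & called_vec
      ccum <- c(0, cumsum(called_vec))
      mcum <- c(0, cumsum(mism_vec))
      ends <- pmin(starts + window, L)
      called <- ccum[ends + 1L] - ccum[starts + 1L]
      mism <- mcum[ends + 1L] - mcum[starts + 1L]
      tibble(query = qn, scaffold = sid, start = starts,
             called = as.integer(called), mismatches = as.integer(mism),
             value = ifelse(called > 0, mism / called, NA_real_),
             retained = called >= min_called)
    })
  })
}

#' Flank-smoothed divergence track
#'
#' For each retained window, the unweighted mean of its value and the
#' values of up to `flank` retained windows on each side within the same
#' scaffold (discarded windows are skipped, not averaged; fewer neighbours
#' are used near edges). Discarded windows yield no point.
#'
#' @param stats Output of [window_stats()].
#' @param flank Number of retained flanking windows per side.
#' @return Tibble `query`, `scaffold`, `start`, `value`, `smoothed`.
#' @export
smooth_windows <- function(stats, flank = 5L) {
  stats |>
    dplyr::filter(.data$retained) |>
    dplyr::arrange(.data$query, .data$scaffold, .data$start) |>
    dplyr::group_by(.data$query, .data$scaffold) |>
    dplyr::mutate(smoothed = {
      v <- .data$value
      n <- length(v)
      cs <- c(0, cumsum(v))
      i <- seq_len(n)
      lo <- pmax(i - flank, 1L); hi <- pmin(i + flank, n)
      (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("query", "scaffold", "start", "value", "smoothed")
}

#' Per-scaffold and genome-wide divergence
#'
#' Micro-averages (pooled counts): scaffold divergence is total mismatches
#' over total called sites across that scaffold's retained windows;
#' genome-wide is the same pool over all retained windows. Scaffolds (or
#' queries) with no retained window get `NA`, never 0.
#'
#' @param stats Output of [window_stats()].
#' @return Object of class `divergence_summary`; see [tidy()] for the
#'   per-scaffold table and [glance()] for the genome-wide rates.
#' @export
summarize_divergence <- function(stats) {
  retained <- dplyr::filter(stats, .data$retained)
  per_scaffold <- stats |>
    dplyr::group_by(.data$query, .data$scaffold) |>
    dplyr::summarise(
      windows = sum(retained),
      called = sum(called[retained]),
      mismatches = sum(mismatches[retained]),
      .groups = "drop") |>
    dplyr::mutate(divergence = ifelse(.data$called > 0,
                                      .data$mismatches / .data$called,
                                      NA_real_))
  genome <- retained |>
    dplyr::group_by(.data$query) |>
    dplyr::summarise(windows = dplyr::n(),
                     called = sum(called),
                     mismatches = sum(mismatches),
                     .groups = "drop") |>
    dplyr::mutate(divergence = ifelse(.data$called > 0,
                                      .data$mismatches / .data$called,
                                      NA_real_))
  # queries that lost every window still appear, flagged undefined
  missing <- setdiff(unique(stats$query), genome$query)
  if (length(missing) > 0)
    genome <- dplyr::bind_rows(genome,
      tibble(query = missing, windows = 0L, called = 0L,
             mismatches = 0L, divergence = NA_real_))
  structure(list(per_scaffold = per_scaffold, genome = genome),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("<divergence_summary>\n")
  for (i in seq_len(nrow(x$genome))) {
    cat(sprintf("  %s: divergence %.5g over %d retained windows (%d called sites)\n",
                x$genome$query[[i]],
                x$genome$divergence[[i]], x$genome$windows[[i]],
                x$genome$called[[i]]))
  }
  invisible(x)
}

#' @rdname summarize_divergence
#' @param x A `divergence_summary`.
#' @param ... Unused.
#' @method tidy divergence_summary
#' @export
tidy.divergence_summary <- function(x, ...) x$per_scaffold

#' @rdname summarize_divergence
#' @method glance divergence_summary
#' @export
glance.divergence_summary <- function(x, ...) x$genome
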