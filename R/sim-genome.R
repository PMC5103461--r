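# Seeded genome simulation: an i.i.d. ancestor at a target GC, and a
# derived genome obtained by per-site substitutions (single hit per site),
# optional indels and N-runs. The returned truth object records every
# planted event and the ancestor-to-derived coordinate map, so downstream
# estimators can be checked against exact ground truth.

#' Generate a random ancestor genome
#'
#' @param config A [sim_config()].
#' @return Assembly tibble with scaffolds `scf_1`, `scf_2`, ...
#' @export
make_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lens <- config$scaffold_lengths
  if (any(lens < 1)) abort("zero-length scaffold requested")
  with_seed(derive_seed(config$seed, "ancestor"), {
    residues <- vapply(lens, random_dna, "", gc = config$gc)
  })
  assembly_tbl(id = paste0("scf_", seq_along(lens)), residues = residues)
}

#' Evolve a genome to a planted divergence
#'
#' Each site is substituted independently with probability `p` (given
#' directly or via the Jukes-Cantor conversion of `d`) to a uniformly
#' chosen different base; indel events and N-runs, if enabled, are applied
#' afterwards. Substitutions are single-hit per site, so the planted truth
#' stays exact.
#'
#' @param genome Assembly tibble (the ancestor).
#' @param config A [sim_config()] carrying `d` or `p` and the indel/N knobs.
#' @return List with elements `genome` (the derived assembly) and `truth`,
#'   a `true_pair_alignment`: `segments` (monotone ancestor-to-derived
#'   coordinate map, 0-based), `substitutions`, `indels`, `n_runs`.
#' @export
evolve <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_assembly(genome)
  p <- config_p(config)
  if (p >= 0.75) abort("p >= 0.75: substitution process saturated")
  with_seed(derive_seed(config$seed, "evolve"), {
    per_scaffold <- lapply(seq_len(nrow(genome)), function(i) {
      evolve_one(genome$id[[i]], genome$residues[[i]], p, config)
    })
  })
  derived <- assembly_tbl(
    id = genome$id,
    residues = vapply(per_scaffold, function(x) x$residues, ""))
  truth <- structure(list(
    segments = dplyr::bind_rows(lapply(per_scaffold, `[[`, "segments")),
    substitutions = dplyr::bind_rows(lapply(per_scaffold, `[[`, "substitutions")),
    indels = dplyr::bind_rows(lapply(per_scaffold, `[[`, "indels")),
    n_runs = dplyr::bind_rows(lapply(per_scaffold, `[[`, "n_runs"))
  ), class = "true_pair_alignment")
  list(genome = derived, truth = truth)
}

evolve_one <- function(scaffold, seq, p, config) {
  n <- nchar(seq)
  raw <- charToRaw(seq)
  code <- integer(256)
  code[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
  # --- substitutions -------------------------------------------------------
  sub_pos <- if (p > 0) which(runif(n) < p) else integer(0)
  ok <- raw[sub_pos] %in% charToRaw("ACGT")
  sub_pos <- sub_pos[ok]
  from <- rawToChar(raw[sub_pos], multiple = TRUE)
  if (length(sub_pos) > 0) {
    old_code <- code[as.integer(raw[sub_pos]) + 1L]
    new_code <- (old_code + sample.int(3L, length(sub_pos), replace = TRUE)) %% 4L
    raw[sub_pos] <- charToRaw("ACGT")[new_code + 1L]
  }
  to <- rawToChar(raw[sub_pos], multiple = TRUE)
  subs <- tibble(scaffold = scaffold,
                 anc_pos = sub_pos - 1L, der_pos = sub_pos - 1L,
                 from = if (length(sub_pos)) from else character(0),
                 to = if (length(sub_pos)) to else character(0))
  # --- indels --------------------------------------------------------------
  segments <- tibble(scaffold = scaffold, anc_start = 0L, der_start = 0L, len = n)
  indels <- tibble(scaffold = character(), der_pos = integer(),
                   type = character(), len = integer())
  if (config$indel_rate > 0) {
    ev_pos <- which(runif(n) < config$indel_rate)
    if (length(ev_pos) > 0) {
      ev_len <- rgeom(length(ev_pos), prob = 1 / config$indel_mean_len) + 1L
      ev_ins <- runif(length(ev_pos)) < 0.5
      # drop overlapping deletions
      keep <- rep(TRUE, length(ev_pos))
      last_end <- -1L
      for (i in seq_along(ev_pos)) {
        if (ev_pos[i] <= last_end) { keep[i] <- FALSE; next }
        if (!ev_ins[i]) last_end <- ev_pos[i] + ev_len[i] - 1L
      }
      ev_pos <- ev_pos[keep]; ev_len <- ev_len[keep]; ev_ins <- ev_ins[keep]
      spliced <- splice_indels(raw, ev_pos, ev_len, ev_ins, config$gc)
      raw <- spliced$raw
      segments <- dplyr::mutate(spliced$segments, scaffold = scaffold,
                                .before = 1)
      indels <- tibble(scaffold = scaffold, der_pos = spliced$der_pos,
                       type = ifelse(ev_ins, "ins", "del"), len = ev_len)
      subs <- remap_substitutions(subs, segments)
    }
  }
  # --- N-runs --------------------------------------------------------------
  n_runs <- tibble(scaffold = character(), start = integer(), end = integer())
  if (config$n_run_rate > 0) {
    m <- length(raw)
    starts <- which(runif(m) < config$n_run_rate)
    if (length(starts) > 0) {
      lens <- rgeom(length(starts), prob = 1 / config$n_run_len) + 1L
      ends <- pmin(starts + lens - 1L, m)
      ir <- IRanges::reduce(IRanges::IRanges(starts, ends))
      for (k in seq_along(ir)) {
        raw[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <- charToRaw("N")
      }
      n_runs <- tibble(scaffold = scaffold,
                       start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
      masked <- subs$der_pos + 1L
      in_n <- IRanges::overlapsAny(IRanges::IRanges(masked, masked), ir)
      subs <- subs[!in_n, ]
    }
  }
  list(residues = rawToChar(raw), segments = segments,
       substitutions = subs, indels = indels, n_runs = n_runs)
}

# apply insertion/deletion events (1-based positions on the substituted
# ancestor) and return the new raw vector plus the monotone segment map
splice_indels <- function(raw, pos, len, is_ins, gc) {
  pieces <- list()
  seg_anc <- integer(0); seg_der <- integer(0); seg_len <- integer(0)
  der_pos <- integer(length(pos))
  cur_anc <- 1L   # 1-based cursor on ancestor
  cur_der <- 0L   # 0-based length of derived so far
  for (i in seq_along(pos)) {
    keep_len <- pos[i] - cur_anc   # bases before the event position
    if (is_ins[i]) keep_len <- keep_len + 1L  # insertion goes after pos
    if (keep_len > 0) {
      pieces[[length(pieces) + 1L]] <- raw[cur_anc:(cur_anc + keep_len - 1L)]
      seg_anc <- c(seg_anc, cur_anc - 1L)
      seg_der <- c(seg_der, cur_der)
      seg_len <- c(seg_len, keep_len)
      cur_anc <- cur_anc + keep_len
      cur_der <- cur_der + keep_len
    }
    if (is_ins[i]) {
      ins <- charToRaw(random_dna(len[i], gc))
      pieces[[length(pieces) + 1L]] <- ins
      der_pos[i] <- cur_der
      cur_der <- cur_der + len[i]
    } else {
      der_pos[i] <- cur_der
      cur_anc <- min(cur_anc + len[i], length(raw) + 1L)
    }
  }
  if (cur_anc <= length(raw)) {
    keep_len <- length(raw) - cur_anc + 1L
    pieces[[length(pieces) + 1L]] <- raw[cur_anc:length(raw)]
    seg_anc <- c(seg_anc, cur_anc - 1L)
    seg_der <- c(seg_der, cur_der)
    seg_len <- c(seg_len, keep_len)
  }
  list(raw = unlist(pieces),
       segments = tibble(anc_start = seg_anc, der_start = seg_der, len = seg_len),
       der_pos = der_pos)
}

# re-express substitution derived-coordinates through the segment map;
# substitutions falling in deleted segments are dropped
remap_substitutions <- function(subs, segments) {
  if (nrow(subs) == 0) return(subs)
  anc <- subs$anc_pos
  seg_i <- findInterval(anc, segments$anc_start)
  inside <- seg_i >= 1 &
    anc < segments$anc_start[seg_i] + segments$len[seg_i]
  subs <- subs[inside, ]
  seg_i <- seg_i[inside]
  subs$der_pos <- segments$der_start[seg_i] + (subs$anc_pos - segments$anc_start[seg_i])
  subs
}

#' @export
print.true_pair_alignment <- function(x, ...) {
  cat("<true_pair_alignment>\n")
  cat(sprintf("  segments:      %d\n", nrow(x$segments)))
  cat(sprintf("  substitutions: %d\n", nrow(x$substitutions)))
  cat(sprintf("  indels:        %d\n", nrow(x$indels)))
  cat(sprintf("  N-runs:        %d\n", nrow(x$n_runs)))
  invisible(x)
}
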