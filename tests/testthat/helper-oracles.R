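# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (enumeration / exhaustive scan) and never
# share code with the implementation paths they check.

# shortest absent prefix lengths by substring enumeration
brute_shulen <- function(x, y, revcomp_too = TRUE) {
  ys <- if (revcomp_too) c(y, revcomp(y)) else y
  subs_of_len <- function(l) {
    unique(unlist(lapply(ys, function(s) {
      if (nchar(s) >= l) substring(s, 1:(nchar(s) - l + 1), l:nchar(s))
    })))
  }
  n <- nchar(x)
  out <- integer(n)
  tabs <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    l <- 1L
    repeat {
      if (i + l - 1L > n) { out[i] <- n - i + 2L; break }
      key <- as.character(l)
      if (is.null(tabs[[key]])) tabs[[key]] <- subs_of_len(l)
      if (!(substr(x, i, i + l - 1L) %in% tabs[[key]])) { out[i] <- l; break }
      l <- l + 1L
    }
  }
  out
}

# exhaustive best-hit scan: thresholds then e-value, length, bitscore,
# subject id
brute_best_hits <- function(hits, max_evalue = 1e-5, min_identity = NULL) {
  keep <- hits$evalue < max_evalue
  if (!is.null(min_identity)) keep <- keep & hits$pct_identity > min_identity
  hits <- hits[keep, ]
  res <- list()
  for (q in sort(unique(hits$query))) {
    h <- hits[hits$query == q, ]
    best <- h[1, ]
    if (nrow(h) > 1) for (i in 2:nrow(h)) {
      cand <- h[i, ]
      better <- cand$evalue < best$evalue ||
        (cand$evalue == best$evalue && cand$aln_length > best$aln_length) ||
        (cand$evalue == best$evalue && cand$aln_length == best$aln_length &&
           cand$bitscore > best$bitscore) ||
        (cand$evalue == best$evalue && cand$aln_length == best$aln_length &&
           cand$bitscore == best$bitscore && cand$subject < best$subject)
      if (better) best <- cand
    }
    res[[q]] <- best$subject
  }
  res
}

random_hits_table <- function(n, n_query = 5, n_subject = 5) {
  tibble::tibble(
    query = sample(sprintf("q%02d", seq_len(n_query)), n, replace = TRUE),
    subject = sample(sprintf("s%02d", seq_len(n_subject)), n, replace = TRUE),
    pct_identity = round(runif(n, 20, 100), 1),
    aln_length = sample(50:500, n, replace = TRUE),
    mismatch = 0, gapopen = 0, qstart = 1, qend = 1, sstart = 1, send = 1,
    evalue = 10^-sample(0:30, n, replace = TRUE),
    bitscore = round(runif(n, 30, 500), 1))
}

# lexicographically minimal rotation of s and of its reverse complement,
# for strand/rotation-agnostic sequence comparison
rotation_forms <- function(s) {
  norm <- function(z) {
    r <- yeastcomp:::cpp_min_rotation(z)
    paste0(substr(z, r + 1, nchar(z)), substr(z, 1, r))
  }
  c(norm(s), norm(revcomp(s)))
}

# memoized 1-Mb Kr calibration shared by the Kr tests
calibration_cache <- new.env(parent = emptyenv())
get_calibration <- function(length, seed = 11L) {
  key <- sprintf("L%d_s%d", length, seed)
  if (is.null(calibration_cache[[key]]))
    calibration_cache[[key]] <- kr_calibrate(length, gc = 0.47, seed = seed)
  calibration_cache[[key]]
}

# small diverged pair with truth, for divergence tests
make_pair <- function(len, p, seed, ...) {
  cfg <- sim_config(seed = seed, scaffold_lengths = len, p = p,
                    error_rate = 0, ...)
  anc <- make_ancestor(cfg)
  ev <- evolve(anc, cfg)
  list(ancestor = anc, derived = ev$genome, truth = ev$truth, config = cfg)
}
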