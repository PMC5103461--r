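# Alignment-free Kr distance from shustrings. The per-position shulen
# l_i is the length of the shortest substring of X starting at i that is
# absent from Y (and, by default, from Y's reverse complement). Mean
# shulen shrinks as divergence grows; the estimator inverts a seeded
# Monte-Carlo calibration curve of expected mean shulen versus per-site
# difference probability at matched length and GC, then applies the
# Jukes-Cantor correction. Estimates above 0.3 substitutions/site are
# flagged unreliable (not nulled).

as_seq_string <- function(x) {
  if (is.data.frame(x)) concat_scaffolds(x) else as.character(x)
}

#' Per-position shulen profile of X against Y
#'
#' Exact by construction: the matching-statistics core (suffix automaton
#' over Y) reproduces the brute-force definition on every input. Positions
#' whose every prefix up to the end of X occurs in Y get the sentinel
#' value (remaining length + 1) and are excluded from the mean. Non-ACGT
#' characters in X match nothing (shulen 1); substrings of Y containing
#' them are never matched.
#'
#' @param x,y Assembly tibbles or single sequence strings. Multi-scaffold
#'   assemblies are concatenated with a separator that matches nothing.
#' @param include_revcomp Also index the reverse complement of Y.
#' @return Object of class `shulen_profile`: integer `lengths`, logical
#'   `sentinel`, the X length `n`, and the mean over non-sentinel sites.
#' @export
shulen_profile <- function(x, y, include_revcomp = TRUE) {
  xs <- as_seq_string(x)
  ys <- as_seq_string(y)
  if (nchar(xs) == 0 || nchar(ys) == 0) abort("empty sequence")
  subject <- if (include_revcomp) paste(ys, revcomp(ys), sep = "#") else ys
  ms <- cpp_matching_stats(xs, subject)
  n <- nchar(xs)
  pos_ok <- charToRaw(xs) != charToRaw("#")  # drop separator positions
  idx <- seq_len(n)
  sentinel <- (idx + ms) > n                 # no absent prefix before the end
  lengths <- ifelse(sentinel, n - idx + 1L + 1L, ms + 1L)
  structure(list(lengths = as.integer(lengths[pos_ok]),
                 sentinel = sentinel[pos_ok],
                 n = sum(pos_ok)),
            class = "shulen_profile")
}

#' Mean shulen over non-sentinel positions
#' @param profile A [shulen_profile()].
#' @return Numeric mean (NaN when every position is sentinel).
#' @export
mean_shulen <- function(profile) {
  stopifnot(inherits(profile, "shulen_profile"))
  mean(profile$lengths[!profile$sentinel])
}

#' @export
print.shulen_profile <- function(x, ...) {
  cat(sprintf("<shulen_profile> %d positions, %d sentinel, mean %.3f\n",
              x$n, sum(x$sentinel), mean_shulen(x)))
  invisible(x)
}

default_kr_grid <- function() {
  c(2e-4, 5e-4, 1e-3, 2e-3, 5e-3, 0.01, 0.02, 0.035, 0.05, 0.07, 0.1,
    0.15, 0.22, 0.3, 0.5)
}

# mean shulen of X against a pre-built subject (Y or Y+revcomp) without
# re-deriving the profile object; sentinel positions excluded
raw_mean_shulen <- function(x, subject) {
  ms <- cpp_matching_stats(x, subject)
  n <- nchar(x)
  idx <- seq_len(n)
  sent <- (idx + ms) > n
  mean(ms[!sent] + 1)
}

#' Monte-Carlo calibration of mean shulen versus divergence
#'
#' Simulates genome pairs at each grid difference probability `p` at the
#' given length and GC, records the direction-averaged mean shulen, and
#' fits a monotone interpolant in log(p) used for numeric inversion.
#'
#' @param length Sequence length (bp) matched to the data.
#' @param gc GC fraction matched to the data.
#' @param grid Difference probabilities to simulate (default log-spread
#'   2e-4 to 0.5).
#' @param seed Integer seed for the calibration simulations.
#' @param include_revcomp Match the setting used for the profiles.
#' @param n_rep Simulated replicates per grid point (averaged).
#' @return Object of class `kr_calibration` with the curve table and an
#'   inversion function.
#' @export
kr_calibrate <- function(length, gc = 0.47, grid = NULL, seed = 1L,
                         include_revcomp = TRUE, n_rep = 2L) {
  grid <- sort(grid %||% default_kr_grid())
  stopifnot(all(grid > 0), all(grid < 0.75), length >= 1000)
  # one ancestor per replicate, shared across grid points (common random
  # numbers smooth the curve); the derived genome is walked against the
  # fixed ancestor subject, by symmetry of the pair process
  ms_rep <- matrix(0, n_rep, base::length(grid))
  for (r in seq_len(n_rep)) {
    cfg0 <- sim_config(seed = derive_seed(seed, paste0("krcal_anc", r)),
                       scaffold_lengths = length, gc = gc, p = grid[[1]],
                       error_rate = 0)
    anc <- make_ancestor(cfg0)
    anc_str <- concat_scaffolds(anc)
    subject <- if (include_revcomp) paste(anc_str, revcomp(anc_str), sep = "#")
    else anc_str
    for (i in seq_along(grid)) {
      cfg <- sim_config(seed = derive_seed(seed, sprintf("krcal_%d_%d", r, i)),
                        scaffold_lengths = length, gc = gc, p = grid[[i]],
                        error_rate = 0)
      der <- evolve(anc, cfg)$genome
      ms_rep[r, i] <- raw_mean_shulen(concat_scaffolds(der), subject)
    }
  }
  ms <- colMeans(ms_rep)
  if (any(diff(ms) >= 0))
    warn("calibration curve is not strictly decreasing; estimates near flat regions may be unstable")
  fn <- splinefun(log(grid), ms, method = "monoH.FC")
  structure(list(table = tibble(p = grid, mean_shulen = ms),
                 length = length, gc = gc,
                 include_revcomp = include_revcomp,
                 curve = fn),
            class = "kr_calibration")
}

#' @export
print.kr_calibration <- function(x, ...) {
  cat(sprintf("<kr_calibration> length %d, GC %.3f, %d grid points\n",
              x$length, x$gc, nrow(x$table)))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

invert_calibration <- function(calibration, observed_mean) {
  tab <- calibration$table
  lo <- log(min(tab$p)); hi <- log(max(tab$p))
  if (observed_mean > calibration$curve(lo) || observed_mean < calibration$curve(hi))
    abort(sprintf(paste0("observed mean shulen %.2f outside the calibration ",
                         "range [%.2f, %.2f]: widen the grid"),
                  observed_mean, calibration$curve(hi), calibration$curve(lo)))
  root <- stats::uniroot(function(lp) calibration$curve(lp) - observed_mean,
                         interval = c(lo, hi), tol = 1e-10)
  exp(root$root)
}

#' Alignment-free Kr estimate for a genome pair
#'
#' Both directions (X against Y, and Y against X) are profiled; each mean
#' shulen is inverted through the calibration curve to a difference
#' probability, Jukes-Cantor corrected, and the two directions averaged.
#' Estimates above the reliability cap (0.3) are flagged, not removed.
#' Near-identical pairs whose profiles are almost entirely sentinel are
#' reported as Kr 0.
#'
#' @param x,y Assembly tibbles or sequence strings.
#' @param calibration Optional [kr_calibrate()] result; built at matched
#'   length and GC when absent.
#' @param seed Seed for calibration when it has to be built.
#' @param grid Optional calibration grid (see [kr_calibrate()]).
#' @param include_revcomp Index the reverse complement of the subject.
#' @param cap Reliability cap on Kr (default 0.3).
#' @return Object of class `kr_estimate`.
#' @export
estimate_kr <- function(x, y, calibration = NULL, seed = 1L, grid = NULL,
                        include_revcomp = TRUE, cap = 0.3) {
  xs <- as_seq_string(x); ys <- as_seq_string(y)
  if (is.null(calibration)) {
    len <- round((nchar(xs) + nchar(ys)) / 2)
    gc <- seq_gc(c(xs, ys))
    calibration <- kr_calibrate(len, gc = gc, grid = grid, seed = seed,
                                include_revcomp = include_revcomp)
  }
  prof_xy <- shulen_profile(xs, ys, include_revcomp)
  prof_yx <- shulen_profile(ys, xs, include_revcomp)
  est_dir <- function(prof) {
    informative <- sum(!prof$sentinel)
    if (informative < 10) return(list(mean = NA_real_, p = 0))
    m <- mean_shulen(prof)
    lo_curve <- calibration$curve(log(min(calibration$table$p)))
    if (m > lo_curve && informative / prof$n < 0.5)
      return(list(mean = m, p = 0))  # near-identical pair
    list(mean = m, p = invert_calibration(calibration, m))
  }
  dx <- est_dir(prof_xy); dy <- est_dir(prof_yx)
  pi_hat <- mean(c(dx$p, dy$p))
  if (pi_hat >= 0.75) abort("difference estimate saturated (p >= 0.75)")
  kr_dir <- jc_d_from_p(c(dx$p, dy$p))
  kr <- mean(kr_dir)
  n_sites <- min(nchar(xs), nchar(ys))
  structure(list(
    kr = kr, pi_hat = pi_hat,
    reliable = kr <= cap, cap = cap,
    low_confidence = pi_hat * n_sites < 100,
    directions = tibble(direction = c("x_vs_y", "y_vs_x"),
                        mean_shulen = c(dx$mean, dy$mean),
                        p_hat = c(dx$p, dy$p), kr = kr_dir),
    calibration = calibration), class = "kr_estimate")
}

#' @export
print.kr_estimate <- function(x, ...) {
  cat(sprintf("<kr_estimate> Kr = %.5g (pi = %.5g)%s%s\n", x$kr, x$pi_hat,
              if (x$reliable) "" else sprintf(" [unreliable: > %.2g cap]", x$cap),
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Pairwise Kr distance table for several assemblies
#'
#' @param assemblies Named list of assembly tibbles (>= 2).
#' @param calibration Optional shared [kr_calibrate()] object.
#' @param ... Passed to [estimate_kr()].
#' @return Tibble `a`, `b`, `kr`, `pi_hat`, `reliable`, `low_confidence`
#'   over unordered pairs; the symmetric matrix is in attribute `"matrix"`.
#' @export
kr_matrix <- function(assemblies, calibration = NULL, ...) {
  if (length(assemblies) < 2) abort("need at least two assemblies")
  nms <- names(assemblies) %||% paste0("g", seq_along(assemblies))
  pairs <- utils::combn(length(assemblies), 2)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    est <- estimate_kr(assemblies[[i1]], assemblies[[i2]],
                       calibration = calibration, ...)
    tibble(a = nms[i1], b = nms[i2], kr = est$kr, pi_hat = est$pi_hat,
           reliable = est$reliable, low_confidence = est$low_confidence)
  })
  m <- matrix(0, length(nms), length(nms), dimnames = list(nms, nms))
  for (j in seq_len(nrow(rows))) {
    m[rows$a[j], rows$b[j]] <- m[rows$b[j], rows$a[j]] <- rows$kr[j]
  }
  attr(rows, "matrix") <- m
  rows
}
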