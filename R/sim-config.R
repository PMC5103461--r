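# Simulation configuration. Defaults mirror the study conditions the
# pipeline is meant to recover: GC 0.47, 115-nt reads, 1-kb windows, and
# divergence expressed either as a Jukes-Cantor distance d or a raw
# per-site difference probability p (exactly one of the two).

#' Jukes-Cantor conversions between distance and difference probability
#'
#' `jc_p_from_d()` gives the expected per-site difference fraction for a
#' JC69 distance `d`; `jc_d_from_p()` is its inverse.
#'
#' @param d Substitutions per site (>= 0).
#' @param p Observed difference fraction (0 <= p < 0.75).
#' @return Numeric vector.
#' @export
#' @examples
#' jc_p_from_d(0.073)
jc_p_from_d <- function(d) {
  stopifnot(all(d >= 0))
  0.75 * (1 - exp(-4 * d / 3))
}

#' @rdname jc_p_from_d
#' @export
jc_d_from_p <- function(p) {
  stopifnot(all(p >= 0), all(p < 0.75))
  -0.75 * log(1 - 4 * p / 3)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. One root `seed`
#' drives all stages; each generator derives its own stream from a fixed
#' label so sub-stage randomness is independent of call order.
#'
#' @param seed Integer root seed.
#' @param scaffold_lengths Integer vector of scaffold lengths (bp).
#' @param gc GC fraction of the ancestor (default 0.47).
#' @param d Jukes-Cantor divergence for [evolve()] (exclusive with `p`).
#' @param p Per-site difference probability (exclusive with `d`).
#' @param indel_rate Per-site indel event rate (default 0: off).
#' @param indel_mean_len Mean of the geometric indel length distribution.
#' @param n_run_rate Per-site rate of N-run starts in the derived genome
#'   (default 0: off).
#' @param n_run_len Mean N-run length.
#' @param read_length Simulated read length (default 115).
#' @param base_coverage Sequencing depth of a single-copy replicon.
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @param n_genes,ipg_mean,intron_mean,exon_mean,noncanonical_fraction
#'   Gene-plan knobs for [plant_genes()]: gene count, mean introns per gene
#'   (Poisson), mean intron and exon lengths (shifted geometric), and the
#'   fraction of deliberately non-canonical CDS.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       scaffold_lengths = 1e6,
                       gc = 0.47,
                       d = NULL, p = NULL,
                       indel_rate = 0, indel_mean_len = 3,
                       n_run_rate = 0, n_run_len = 100,
                       read_length = 115L,
                       base_coverage = 20,
                       error_rate = 0.01,
                       n_genes = 200L,
                       ipg_mean = 7.5,
                       intron_mean = 110,
                       exon_mean = 199,
                       noncanonical_fraction = 0) {
  if (!is.null(d) && !is.null(p)) abort("give exactly one of d or p")
  if (!is.null(d) && d < 0) abort("d must be >= 0")
  if (!is.null(p) && (p < 0 || p >= 0.75)) abort("p must lie in [0, 0.75)")
  if (gc <= 0 || gc >= 1) abort("gc must lie in (0, 1)")
  if (any(scaffold_lengths < 1)) abort("scaffold lengths must be positive")
  if (base_coverage <= 0) abort("base_coverage must be > 0")
  if (read_length < 1) abort("read_length must be >= 1")
  if (error_rate < 0 || error_rate > 0.5) abort("error_rate must lie in [0, 0.5]")
  if (indel_rate < 0 || n_run_rate < 0) abort("rates must be >= 0")
  structure(list(
    seed = as.integer(seed),
    scaffold_lengths = as.integer(round(scaffold_lengths)),
    gc = gc, d = d, p = p,
    indel_rate = indel_rate, indel_mean_len = indel_mean_len,
    n_run_rate = n_run_rate, n_run_len = n_run_len,
    read_length = as.integer(read_length),
    base_coverage = base_coverage, error_rate = error_rate,
    n_genes = as.integer(n_genes), ipg_mean = ipg_mean,
    intron_mean = intron_mean, exon_mean = exon_mean,
    noncanonical_fraction = noncanonical_fraction
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flat <- x[!vapply(x, is.null, TRUE)]
  for (nm in names(flat))
    cat(sprintf("  %-22s %s\n", nm, paste(flat[[nm]], collapse = ", ")))
  invisible(x)
}

# effective difference probability of a config
config_p <- function(config) {
  if (!is.null(config$p)) config$p
  else if (!is.null(config$d)) jc_p_from_d(config$d)
  else abort("config has neither d nor p")
}
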