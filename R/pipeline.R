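# Pipeline front end: a single validated configuration object holding
# every module default, YAML round-trip, and a dispatcher that wires the
# modules into the standard stage sequences with structured logging.
# A thin command-line wrapper lives in inst/scripts/yeastcomp.

#' Pipeline configuration
#'
#' Aggregates the defaults of every stage; values are validated and
#' round-trip losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Object of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(window = 2000, seed = 42)
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    window = 1000L, step = 1000L, min_called = 500L, flank = 5L,
    anchor_k = 16L, max_gap = 2000L,
    ic_min = 0.5, cov_min = 100L,
    min_identity = 0.95, min_read_coverage = 0.40, seed_k = 12L,
    kr_cap = 0.3,
    max_evalue = 1e-5, min_identity_annot = 50,
    expr_min = 0.5,
    read_length = 115L, base_coverage = 20, error_rate = 0.01,
    gc = 0.47
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$window <= 0 || cfg$step <= 0) abort("window and step must be positive")
  if (cfg$min_called > cfg$window) abort("min_called cannot exceed window")
  if (cfg$flank < 0) abort("flank must be >= 0")
  if (cfg$ic_min < 0 || cfg$ic_min > 2) abort("ic_min must lie in [0, 2] bits")
  if (cfg$cov_min < 1) abort("cov_min must be >= 1")
  if (cfg$min_identity < 0 || cfg$min_identity > 1)
    abort("min_identity must lie in [0, 1]")
  if (cfg$min_read_coverage <= 0 || cfg$min_read_coverage > 1)
    abort("min_read_coverage must lie in (0, 1]")
  if (cfg$kr_cap <= 0) abort("kr_cap must be > 0")
  if (cfg$max_evalue <= 0) abort("max_evalue must be > 0")
  if (cfg$expr_min < 0 || cfg$expr_min > 1) abort("expr_min must lie in [0, 1]")
  if (cfg$gc <= 0 || cfg$gc >= 1) abort("gc must lie in (0, 1)")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_stage <- function(...) message(sprintf(...))

#' Run a pipeline stage
#'
#' Dispatches the standard stage sequences. `"divergence"` runs
#' anchor-alignment (or MAF import), call-track construction, window
#' statistics, smoothing and summary; `"kr"` runs the calibrated Kr
#' estimate for a pair of FASTA files; `"simulate"` writes a synthetic
#' diverged genome pair. Parameters, seed and per-stage counts are logged
#' to the message stream; identical inputs and configuration give
#' identical outputs.
#'
#' @param subcommand One of `"simulate"`, `"divergence"`, `"kr"`.
#' @param config A [pipeline_config()].
#' @param inputs Named list of input file paths (per subcommand:
#'   `simulate` needs `out_dir` and optionally `length`, `p`;
#'   `divergence` needs `ref`, `query` FASTA paths or a `maf`;
#'   `kr` needs `a` and `b` FASTA paths).
#' @param out_dir Directory for outputs (created if missing).
#' @return Named list of result objects (also written to `out_dir`).
#' @export
run_pipeline <- function(subcommand, config = pipeline_config(),
                         inputs = list(), out_dir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_stage("[%s] seed=%d", subcommand, config$seed)
  switch(subcommand,
    simulate = {
      len <- as.integer(inputs$length %||% 1e6)
      p <- inputs$p %||% 0.044
      cfg <- sim_config(seed = config$seed, scaffold_lengths = len,
                        gc = config$gc, p = p,
                        read_length = config$read_length,
                        base_coverage = config$base_coverage,
                        error_rate = config$error_rate)
      anc <- make_ancestor(cfg)
      ev <- evolve(anc, cfg)
      write_fasta(anc, file.path(out_dir, "ancestor.fasta"))
      write_fasta(ev$genome, file.path(out_dir, "derived.fasta"))
      readr::write_tsv(ev$truth$substitutions,
                       file.path(out_dir, "substitutions.tsv"))
      log_stage("[simulate] %d bp, %d planted substitutions", len,
                nrow(ev$truth$substitutions))
      list(ancestor = anc, derived = ev$genome, truth = ev$truth)
    },
    divergence = {
      ref <- read_fasta(inputs$ref)
      if (!is.null(inputs$maf)) {
        blocks <- read_maf(inputs$maf)
        log_stage("[divergence] imported %d MAF blocks", nrow(blocks))
      } else {
        query <- read_fasta(inputs$query)
        blocks <- anchor_align(ref, query, k = config$anchor_k,
                               max_gap = config$max_gap)
        log_stage("[divergence] %d alignment blocks", nrow(blocks))
      }
      track <- build_call_track(blocks, ref)
      stats <- window_stats(track, window = config$window, step = config$step,
                            min_called = config$min_called)
      log_stage("[divergence] %d windows, %d retained", nrow(stats),
                sum(stats$retained))
      smoothed <- smooth_windows(stats, flank = config$flank)
      summary <- summarize_divergence(stats)
      readr::write_tsv(stats, file.path(out_dir, "windows.tsv"))
      readr::write_tsv(smoothed, file.path(out_dir, "smoothed.tsv"))
      jsonlite::write_json(
        list(per_scaffold = tidy(summary), genome = glance(summary)),
        file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
      list(blocks = blocks, stats = stats, smoothed = smoothed,
           summary = summary)
    },
    kr = {
      a <- read_fasta(inputs$a)
      b <- read_fasta(inputs$b)
      est <- estimate_kr(a, b, seed = config$seed, cap = config$kr_cap)
      log_stage("[kr] kr=%.5g reliable=%s", est$kr, est$reliable)
      readr::write_tsv(tidy(est), file.path(out_dir, "kr.tsv"))
      list(estimate = est)
    },
    abort(sprintf("unknown subcommand '%s'", subcommand))
  )
}
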