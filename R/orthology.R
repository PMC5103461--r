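# Best-hit and reciprocal-best-hit orthology, three-way core/exclusive
# set construction, and the sequential orphan-gene filter chain.
# Ranking: minimal e-value, then maximal aligned length, then maximal
# bitscore, then lexicographically smallest subject (the last two declared
# for determinism).

#' Best hit per query
#'
#' Rows failing the e-value (and optional identity) thresholds are
#' removed before ranking; queries with no passing row are absent from
#' the result.
#'
#' @param hits Hits tibble (see [read_hits_tab()]).
#' @param max_evalue Keep hits with `evalue < max_evalue` (default 1e-5).
#' @param min_identity Optional: keep hits with `pct_identity >
#'   min_identity` (annotation mode uses 50).
#' @return Tibble `query`, `subject`, `evalue`, `aln_length`, `bitscore`
#'   with one row per query.
#' @export
best_hits <- function(hits, max_evalue = 1e-5, min_identity = NULL) {
  validate_hits(hits)
  passing <- dplyr::filter(hits, .data$evalue < max_evalue)
  if (!is.null(min_identity))
    passing <- dplyr::filter(passing, .data$pct_identity > min_identity)
  passing |>
    dplyr::arrange(.data$query, .data$evalue, dplyr::desc(.data$aln_length),
                   dplyr::desc(.data$bitscore), .data$subject) |>
    dplyr::distinct(.data$query, .keep_all = TRUE) |>
    dplyr::select("query", "subject", "evalue", "aln_length", "bitscore")
}

#' Reciprocal best hits between two genomes
#'
#' `(a, b)` is included iff `b` is the best hit of `a` in the A-to-B
#' table and `a` is the best hit of `b` in the B-to-A table.
#'
#' @param table_ab,table_ba Hit tibbles for the two search directions.
#' @param max_evalue,min_identity Thresholds as in [best_hits()].
#' @return Tibble `a`, `b` (a 1:1 matching).
#' @export
rbh <- function(table_ab, table_ba, max_evalue = 1e-5, min_identity = NULL) {
  ab <- best_hits(table_ab, max_evalue, min_identity)
  ba <- best_hits(table_ba, max_evalue, min_identity)
  out <- dplyr::inner_join(
    dplyr::select(ab, a = "query", b = "subject"),
    dplyr::select(ba, b = "query", a = "subject"),
    by = c("a", "b"))
  dplyr::arrange(out, .data$a)
}

#' Three-way ortholog sets from pairwise RBH links
#'
#' Core triples close all three reciprocal links; a pair-exclusive pair
#' has an RBH link between two genomes and neither member linked to the
#' third genome; triangles with two links whose closure contradicts the
#' third table are reported as inconsistent, not merged.
#'
#' @param rbh_ab,rbh_ac,rbh_bc RBH tibbles from [rbh()] (columns `a`,`b`
#'   read as first/second genome of each pair).
#' @return List: `core` (tibble `a`, `b`, `c`), `exclusive` (list of
#'   tibbles `ab`, `ac`, `bc`), `inconsistent` (tibble `a`, `b`, `c1`,
#'   `c2` of contradicting closures), `counts` (named integer vector).
#' @export
three_way_sets <- function(rbh_ab, rbh_ac, rbh_bc) {
  ab <- setNames(rbh_ab$b, rbh_ab$a)
  ac <- setNames(rbh_ac$b, rbh_ac$a)
  bc <- setNames(rbh_bc$b, rbh_bc$a)
  # candidate triangles: a linked to both b and c
  cand <- intersect(names(ab), names(ac))
  b_of <- ab[cand]; c_of <- ac[cand]
  closes <- !is.na(bc[b_of]) & bc[b_of] == c_of
  core <- tibble(a = cand[closes], b = unname(b_of[closes]),
                 c = unname(c_of[closes]))
  inconsistent <- tibble(a = cand[!closes], b = unname(b_of[!closes]),
                         c1 = unname(c_of[!closes]),
                         c2 = unname(bc[b_of[!closes]]))
  # two-link candidates missing the third genome entirely
  linked_b_to_c <- names(bc)
  linked_c <- unique(c(unname(ac), unname(bc)))
  excl <- list(
    ab = {
      i <- !(rbh_ab$a %in% names(ac)) & !(rbh_ab$b %in% linked_b_to_c)
      tibble(a = rbh_ab$a[i], b = rbh_ab$b[i])
    },
    ac = {
      i <- !(rbh_ac$a %in% names(ab)) & !(rbh_ac$b %in% unname(bc))
      tibble(a = rbh_ac$a[i], c = rbh_ac$b[i])
    },
    bc = {
      i <- !(rbh_bc$a %in% unname(ab)) & !(rbh_bc$b %in% unname(ac))
      tibble(b = rbh_bc$a[i], c = rbh_bc$b[i])
    })
  counts <- c(core = nrow(core),
              ab_exclusive = nrow(excl$ab),
              ac_exclusive = nrow(excl$ac),
              bc_exclusive = nrow(excl$bc),
              inconsistent = nrow(inconsistent))
  list(core = core, exclusive = excl, inconsistent = inconsistent,
       counts = counts)
}

#' Sequential orphan-gene filter chain
#'
#' Filters, in order: (1) membership in the three-strain core set;
#' (2) expression coverage at least `min_expression` (genes missing from
#' the expression table count as coverage 0); (3) no hit in any
#' relative-species table below `max_evalue`; (4) no hit in the nr-style
#' table below `max_evalue`. Survivors are the orphan set; the number
#' bearing at least one domain annotation is reported alongside.
#'
#' @param core_genes Character vector of core gene ids (reference strain).
#' @param expression Tibble `gene_id`, `coverage` (fraction 0-1).
#' @param relative_hits A hits tibble or list of them (searches against
#'   relative species).
#' @param nr_hits Hits tibble for the nr-style search.
#' @param domains Optional tibble `gene_id`, `domain`.
#' @param min_expression Expression-coverage threshold (default 0.5).
#' @param max_evalue Exclusion threshold for similarity hits (1e-5).
#' @return Tibble `gene_id`, `has_domain` of orphans, with attribute
#'   `"counts"`: genes surviving after each filter.
#' @export
orphan_filter <- function(core_genes, expression, relative_hits, nr_hits,
                          domains = NULL, min_expression = 0.5,
                          max_evalue = 1e-5) {
  if (max_evalue <= 0) abort("max_evalue must be > 0")
  if (is.data.frame(relative_hits)) relative_hits <- list(relative_hits)
  surv <- unique(as.character(core_genes))
  counts <- c(core = length(surv))
  cov <- setNames(expression$coverage, expression$gene_id)
  missing <- setdiff(surv, names(cov))
  if (length(missing) > 0)
    message(sprintf("%d core genes missing from the expression table; treated as coverage 0",
                    length(missing)))
  gene_cov <- ifelse(surv %in% names(cov), cov[surv], 0)
  surv <- surv[gene_cov >= min_expression]
  counts <- c(counts, expressed = length(surv))
  for (rel in relative_hits) {
    validate_hits(rel)
    hit_genes <- unique(rel$query[rel$evalue < max_evalue])
    surv <- setdiff(surv, hit_genes)
  }
  counts <- c(counts, no_relative_hit = length(surv))
  validate_hits(nr_hits)
  surv <- setdiff(surv, unique(nr_hits$query[nr_hits$evalue < max_evalue]))
  counts <- c(counts, no_nr_hit = length(surv))
  has_dom <- if (is.null(domains)) rep(NA, length(surv))
  else surv %in% domains$gene_id
  out <- tibble(gene_id = surv, has_domain = has_dom)
  attr(out, "counts") <- counts
  attr(out, "n_with_domain") <- if (is.null(domains)) NA_integer_ else sum(has_dom)
  out
}
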