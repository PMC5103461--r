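# Synthetic protein-similarity searches: builds cross-species hit tables
# with planted reciprocal-best orthologs and worse-scoring decoys, plus
# relative-species and nr-style tables, expression-coverage and domain
# tables with planted orphan genes, so the orthology and orphan-filter
# chain can be validated against exact truth.

empty_hits <- function() {
  as_tibble(setNames(
    c(list(character(), character()), rep(list(numeric()), 10)), HITS_COLS))
}

hit_rows <- function(query, subject, evalue, aln_length, pct_identity) {
  tibble(query = query, subject = subject,
         pct_identity = pct_identity, aln_length = aln_length,
         mismatch = round(aln_length * (100 - pct_identity) / 100),
         gapopen = 0, qstart = 1, qend = aln_length,
         sstart = 1, send = aln_length,
         evalue = evalue, bitscore = pmax(30, -10 * log10(evalue + 1e-300)))
}

#' Generate synthetic hit, expression, and domain tables
#'
#' Planted ortholog pairs receive reciprocal best-scoring rows (very low
#' e-values, long alignments); decoy rows are strictly worse and their
#' subjects are restricted to genes whose reciprocal best is their planted
#' partner, so the recovered RBH set equals the planted map exactly.
#' Planted orphans receive no relative-species or nr rows and expression
#' coverage at `orphan_expression`.
#'
#' @param gene_sets Named list of character vectors: gene ids per species.
#' @param ortholog_map Tibble with one column per species (same names as
#'   `gene_sets`); each row is an ortholog group, `NA` marking absence.
#' @param orphans Character vector of first-species gene ids whose groups
#'   are orphans (must be complete rows of `ortholog_map`).
#' @param seed Integer seed.
#' @param orphan_expression Expression coverage given to orphan genes.
#' @param orphan_domain_fraction Fraction of orphans given a domain row.
#' @param decoys_per_query Decoy rows added per query.
#' @return List with `cross` (named list of hit tibbles, one per ordered
#'   species pair, names like `"A_vs_B"`), `relatives`, `nr`, `expression`
#'   (`gene_id`, `coverage`), `domains` (`gene_id`, `domain`).
#' @export
make_hit_tables <- function(gene_sets, ortholog_map, orphans = character(),
                            seed = 1L, orphan_expression = 0.6,
                            orphan_domain_fraction = 0.66,
                            decoys_per_query = 2L) {
  species <- names(gene_sets)
  stopifnot(length(species) >= 2, !is.null(species),
            all(species %in% names(ortholog_map)))
  for (sp in species) {
    ids <- ortholog_map[[sp]]
    unknown <- setdiff(ids[!is.na(ids)], gene_sets[[sp]])
    if (length(unknown) > 0)
      abort(sprintf("ortholog map references unknown gene id '%s' in '%s'",
                    unknown[[1]], sp))
  }
  ref_sp <- species[[1]]
  if (!all(orphans %in% ortholog_map[[ref_sp]]))
    abort("orphans must be first-species members of the ortholog map")

  with_seed(derive_seed(seed, "hit_tables"), {
    cross <- list()
    for (a in species) for (b in setdiff(species, a)) {
      pairs <- ortholog_map[!is.na(ortholog_map[[a]]) &
                              !is.na(ortholog_map[[b]]), c(a, b)]
      n <- nrow(pairs)
      planted <- if (n > 0) {
        len <- round(runif(n, 300, 900))
        hit_rows(pairs[[a]], pairs[[b]],
                 evalue = 10^-runif(n, 50, 150),
                 aln_length = len, pct_identity = runif(n, 80, 100))
      } else empty_hits()
      # decoys: subjects restricted to planted partners of this table
      decoy_pool <- unique(pairs[[b]])
      dq <- rep(gene_sets[[a]], each = decoys_per_query)
      decoys <- if (length(decoy_pool) > 0 && length(dq) > 0) {
        len <- round(runif(length(dq), 60, 250))
        hit_rows(dq, sample(decoy_pool, length(dq), replace = TRUE),
                 evalue = 10^-runif(length(dq), 0, 8),
                 aln_length = len, pct_identity = runif(length(dq), 30, 70))
      } else empty_hits()
      tab <- dplyr::bind_rows(planted, decoys)
      cross[[paste0(a, "_vs_", b)]] <- tab[sample.int(nrow(tab)), ]
    }
    # relative-species and nr tables: every non-orphan mapped reference gene
    # gets a strong hit; orphans get nothing (or a weak, above-threshold row)
    core <- ortholog_map[stats::complete.cases(ortholog_map[species]), ][[ref_sp]]
    non_orphan <- setdiff(core, orphans)
    make_outgroup <- function(prefix) {
      strong <- if (length(non_orphan) > 0)
        hit_rows(non_orphan, paste0(prefix, "_", seq_along(non_orphan)),
                 evalue = 10^-runif(length(non_orphan), 10, 80),
                 aln_length = round(runif(length(non_orphan), 200, 800)),
                 pct_identity = runif(length(non_orphan), 40, 95))
      else empty_hits()
      weak_n <- min(length(orphans), ceiling(length(orphans) / 3))
      weak <- if (weak_n > 0)
        hit_rows(sample(orphans, weak_n), paste0(prefix, "_w", seq_len(weak_n)),
                 evalue = 10^-runif(weak_n, 0, 4.9),
                 aln_length = round(runif(weak_n, 40, 120)),
                 pct_identity = runif(weak_n, 25, 50))
      else empty_hits()
      dplyr::bind_rows(strong, weak)
    }
    relatives <- list(relative_1 = make_outgroup("rel"))
    nr <- make_outgroup("nr")
    expression <- tibble(
      gene_id = gene_sets[[ref_sp]],
      coverage = runif(length(gene_sets[[ref_sp]]), 0, 1))
    expression$coverage[expression$gene_id %in% orphans] <- orphan_expression
    dom_orphans <- sample(orphans, round(orphan_domain_fraction * length(orphans)))
    dom_others <- sample(non_orphan, min(length(non_orphan), 20))
    domains <- tibble(gene_id = c(dom_orphans, dom_others),
                      domain = paste0("PF", sprintf("%05d",
                        seq_len(length(dom_orphans) + length(dom_others)))))
  })
  list(cross = cross, relatives = relatives, nr = nr,
       expression = expression, domains = domains)
}
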