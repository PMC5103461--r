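# GFF3 input/output for CDS-level gene models. On disk GFF3 is 1-based
# closed; internally every interval is 0-based half-open, converted only
# here. A gene-model table has one row per CDS exon:
#   gene_id, scaffold, strand, exon_rank, start, end

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features (via [rtracklayer::import()]) and returns
#' the CDS exon table in internal 0-based half-open coordinates.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `gene_id`, `scaffold`, `strand`, `exon_rank`,
#'   `start`, `end` (0-based half-open), sorted by gene and coordinate.
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(body) > 0) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9))
      abort(sprintf("GFF3 line %d has %d columns (expected 9)",
                    which(nf != 9)[[1]], nf[nf != 9][[1]]))
    st <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    en <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    bad <- which(is.na(st) | is.na(en) | st > en)
    if (length(bad) > 0)
      abort(sprintf("feature '%s': start > end or non-numeric coordinates",
                    vapply(fields, `[[`, "", 9L)[[bad[[1]]]]))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(meta))
    vapply(meta$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  gene_ids <- ids[is_gene]
  # map any feature id to its owning gene id (one level of mRNA allowed)
  owner <- setNames(gene_ids, gene_ids)
  is_rna <- type %in% c("mRNA", "transcript")
  owner <- c(owner, setNames(parents[is_rna], ids[is_rna]))

  cds <- which(type == "CDS")
  if (length(cds) == 0)
    return(tibble(gene_id = character(), scaffold = character(),
                  strand = character(), exon_rank = integer(),
                  start = integer(), end = integer()))
  gid <- unname(owner[parents[cds]])
  gid[is.na(gid)] <- parents[cds][is.na(gid)]
  models <- tibble(
    gene_id = gid,
    scaffold = as.character(GenomicRanges::seqnames(gr))[cds],
    strand = as.character(BiocGenerics::strand(gr))[cds],
    start = BiocGenerics::start(gr)[cds] - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr)[cds]
  )
  models <- dplyr::arrange(models, .data$gene_id, .data$start)
  models <- dplyr::mutate(dplyr::group_by(models, .data$gene_id),
                          exon_rank = dplyr::row_number())
  models <- dplyr::ungroup(models)
  models <- models[, c("gene_id", "scaffold", "strand", "exon_rank", "start", "end")]
  # gene spans from the gene features, for containment checks
  if (any(is_gene)) {
    spans <- tibble(gene_id = gene_ids,
                    gstart = BiocGenerics::start(gr)[is_gene] - 1L,
                    gend = BiocGenerics::end(gr)[is_gene])
    chk <- dplyr::inner_join(models, spans, by = "gene_id")
    out_of <- chk$start < chk$gstart | chk$end > chk$gend
    if (any(out_of))
      abort(sprintf("CDS of gene '%s' extends outside its gene span",
                    chk$gene_id[out_of][[1]]))
  }
  validate_gene_models(models)
  models
}

validate_gene_models <- function(models, assembly = NULL) {
  need <- c("gene_id", "scaffold", "strand", "exon_rank", "start", "end")
  stopifnot(all(need %in% names(models)))
  if (nrow(models) == 0) return(invisible(models))
  if (any(models$start >= models$end))
    abort(sprintf("gene '%s' has an empty or inverted exon",
                  models$gene_id[models$start >= models$end][[1]]))
  if (!all(models$strand %in% c("+", "-")))
    abort("strand must be '+' or '-'")
  by_gene <- split(models, models$gene_id)
  for (g in by_gene) {
    if (length(unique(g$scaffold)) != 1 || length(unique(g$strand)) != 1)
      abort(sprintf("gene '%s' spans multiple scaffolds or strands", g$gene_id[[1]]))
    o <- order(g$start)
    if (any(g$start[o][-1] < g$end[o][-length(o)]))
      abort(sprintf("gene '%s' has overlapping exons", g$gene_id[[1]]))
  }
  if (!is.null(assembly)) {
    len <- setNames(nchar(assembly$residues), assembly$id)
    if (!all(models$scaffold %in% names(len)))
      abort(sprintf("gene '%s' references missing scaffold '%s'",
                    models$gene_id[!models$scaffold %in% names(len)][[1]],
                    models$scaffold[!models$scaffold %in% names(len)][[1]]))
    if (any(models$end > len[models$scaffold]))
      abort("exon interval exceeds scaffold bounds")
  }
  invisible(models)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, and CDS features in 1-based closed coordinates.
#'
#' @param models Gene-model tibble (internal 0-based half-open coordinates).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, source = "yeastcomp") {
  validate_gene_models(models)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in split(models, factor(models$gene_id, unique(models$gene_id)))) {
    g <- g[order(g$start), ]
    gid <- g$gene_id[[1]]
    span <- c(min(g$start) + 1L, max(g$end))
    head_lines <- c(
      sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$scaffold[[1]], source, span[1], span[2], g$strand[[1]], gid),
      sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$scaffold[[1]], source, span[1], span[2], g$strand[[1]], gid, gid))
    cds_lines <- sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
                         g$scaffold[[1]], source, g$start + 1L, g$end,
                         g$strand[[1]], gid, gid)
    writeLines(c(head_lines, cds_lines), con)
  }
  invisible(path)
}
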