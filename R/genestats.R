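# Assembly and gene/intron architecture statistics: size, N50/L50, %N,
# GC% (over non-N bases), gene density, intron-less gene fraction (ILG%),
# introns per gene (IPG), pooled mean intron/exon lengths, and the
# canonical-CDS rate.

#' Assembly summary statistics
#'
#' N50 is the length of the scaffold at which the cumulative
#' descending-sorted lengths first reach half the assembly size; L50 is
#' its rank. GC is computed over non-N bases; N over all bases.
#'
#' @param assembly Assembly tibble.
#' @return One-row tibble: `size`, `n_scaffolds`, `n50`, `l50`, `pct_n`,
#'   `pct_gc`.
#' @export
assembly_stats <- function(assembly) {
  validate_assembly(assembly)
  lens <- sort(nchar(assembly$residues), decreasing = TRUE)
  total <- sum(lens)
  l50 <- which(cumsum(lens) >= total / 2)[1]
  freq <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(assembly$residues)))
  n_count <- total - sum(freq[c("A", "C", "G", "T")])
  gc <- sum(freq[c("G", "C")])
  tibble(size = total, n_scaffolds = nrow(assembly),
         n50 = lens[l50], l50 = l50,
         pct_n = 100 * n_count / total,
         pct_gc = 100 * gc / sum(freq[c("A", "C", "G", "T")]))
}

#' Extract spliced CDS sequences
#'
#' Concatenates CDS exons in coordinate order and reverse-complements
#' minus-strand genes.
#'
#' @param models Gene-model tibble.
#' @param assembly Assembly tibble holding the scaffolds.
#' @return Tibble `gene_id`, `cds`.
#' @export
spliced_cds <- function(models, assembly) {
  validate_gene_models(models, assembly)
  seqs <- setNames(assembly$residues, assembly$id)
  models |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(cds = {
      parts <- substring(seqs[[.data$scaffold[[1]]]],
                         .data$start + 1L, .data$end)
      s <- paste(parts, collapse = "")
      if (.data$strand[[1]] == "-") revcomp(s) else s
    }, .groups = "drop")
}

#' Canonical-CDS filter
#'
#' Canonical: starts with ATG, ends with a stop codon (TAA/TAG/TGA),
#' length divisible by 3, and no internal stop codon.
#'
#' @param models Gene-model tibble.
#' @param assembly Assembly tibble.
#' @return Tibble `gene_id`, `cds`, `canonical`, `reason` (`NA` for
#'   canonical genes; the first failed check otherwise).
#' @export
canonical_cds_filter <- function(models, assembly) {
  cds <- spliced_cds(models, assembly)
  res <- purrr::map_chr(cds$cds, check_canonical)
  dplyr::mutate(cds, canonical = is.na(res), reason = res)
}

check_canonical <- function(s) {
  n <- nchar(s)
  if (n %% 3 != 0) return("length not divisible by 3")
  if (n < 6) return("shorter than start plus stop")
  if (substr(s, 1, 3) != "ATG") return("does not start with ATG")
  if (!substr(s, n - 2, n) %in% STOP_CODONS) return("no terminal stop codon")
  codons <- substring(s, seq(1, n - 3, by = 3), seq(3, n - 3, by = 3))
  if (any(codons[-1] %in% STOP_CODONS)) return("internal stop codon")
  if (grepl("[^ACGT]", s)) return("ambiguous nucleotide in CDS")
  NA_character_
}

#' Gene and intron architecture statistics
#'
#' Introns are the gaps between consecutive CDS exons of a gene. Mean
#' exon/intron lengths are pooled over all exons/introns (not per-gene
#' means of means); gene density uses the assembly size in Mb.
#'
#' @param models Gene-model tibble.
#' @param assembly Assembly tibble.
#' @return One-row tibble: `genes`, `genes_per_mb`, `ilg_count`,
#'   `pct_ilg`, `introns_per_gene`, `mean_intron_len`, `mean_exon_len`,
#'   `pct_canonical`.
#' @export
annotation_stats <- function(models, assembly) {
  validate_gene_models(models, assembly)
  size_mb <- sum(nchar(assembly$residues)) / 1e6
  per_gene <- models |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_exons = dplyr::n(),
                     exon_len = list(.data$end - .data$start),
                     intron_len = list(dplyr::lead(.data$start)[-dplyr::n()] -
                                         .data$end[-dplyr::n()]),
                     .groups = "drop")
  n_genes <- nrow(per_gene)
  exons <- unlist(per_gene$exon_len)
  introns <- unlist(per_gene$intron_len)
  ilg <- sum(per_gene$n_exons == 1)
  canon <- canonical_cds_filter(models, assembly)
  tibble(genes = n_genes,
         genes_per_mb = n_genes / size_mb,
         ilg_count = ilg,
         pct_ilg = 100 * ilg / n_genes,
         introns_per_gene = length(introns) / n_genes,
         mean_intron_len = if (length(introns)) mean(introns) else NA_real_,
         mean_exon_len = mean(exons),
         pct_canonical = 100 * mean(canon$canonical))
}

#' Combined statistics table for several genomes
#'
#' One row per genome with the assembly and annotation columns in a fixed
#' order; re-running on the same inputs is byte-identical. The repeat
#' -content column requires an external repeat masker and is emitted as
#' `NA`.
#'
#' @param genomes Named list; each element a list with `assembly` and
#'   `models`.
#' @return Tibble with one row per genome.
#' @export
stats_table <- function(genomes) {
  if (length(genomes) == 0) {
    return(tibble(genome = character(), size_mb = numeric(),
                  n_scaffolds = integer(), n50_kb = numeric(),
                  pct_n = numeric(), pct_gc = numeric(),
                  pct_repeat = numeric(), genes = integer(),
                  genes_per_mb = numeric(), pct_ilg = numeric(),
                  introns_per_gene = numeric(), mean_intron_len = numeric(),
                  mean_exon_len = numeric(), pct_canonical = numeric()))
  }
  nms <- names(genomes) %||% paste0("genome_", seq_along(genomes))
  purrr::map_dfr(seq_along(genomes), function(i) {
    a <- assembly_stats(genomes[[i]]$assembly)
    g <- annotation_stats(genomes[[i]]$models, genomes[[i]]$assembly)
    tibble(genome = nms[[i]],
           size_mb = round(a$size / 1e6, 2),
           n_scaffolds = a$n_scaffolds,
           n50_kb = round(a$n50 / 1e3, 1),
           pct_n = round(a$pct_n, 2),
           pct_gc = round(a$pct_gc, 1),
           pct_repeat = NA_real_,
           genes = g$genes,
           genes_per_mb = round(g$genes_per_mb, 1),
           pct_ilg = round(g$pct_ilg, 1),
           introns_per_gene = round(g$introns_per_gene, 1),
           mean_intron_len = round(g$mean_intron_len, 0),
           mean_exon_len = round(g$mean_exon_len, 0),
           pct_canonical = round(g$pct_canonical, 1))
  })
}

#' Write the statistics table as TSV
#'
#' @param table Output of [stats_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
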