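# Synthetic gene annotation: plants intron-bearing protein-coding genes
# with configurable introns-per-gene and length distributions into a
# genome, writing the gene sequences into the scaffolds so that spliced
# CDS extraction recovers the designed coding sequences exactly.

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(b1 = DNA_BASES, b2 = DNA_BASES, b3 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Plant synthetic gene models into a genome
#'
#' Gene structures are drawn from the configured distributions: introns
#' per gene ~ Poisson(`ipg_mean`), exon and intron lengths from shifted
#' geometric distributions with the configured means (minimum exon 3 bp,
#' minimum intron 20 bp). Coding sequences are canonical by construction
#' (ATG start, terminal stop, length divisible by 3, no internal stop)
#' except for a requested `noncanonical_fraction`, which get a corrupted
#' start, terminal stop, or a planted internal stop. Genes are laid out
#' left to right with geometric intergenic gaps; a gene that would exceed
#' the current scaffold moves to the next, and running out of scaffold
#' space is an error.
#'
#' @param genome Assembly tibble to annotate (sequences are overwritten at
#'   the planted loci).
#' @param config A [sim_config()] with the gene-plan knobs.
#' @return List with `genome` (modified assembly), `models` (gene-model
#'   tibble as in [read_gff3()]), and `cds` (truth tibble: `gene_id`,
#'   `cds`, `protein`, `canonical`).
#' @export
plant_genes <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_assembly(genome)
  n_genes <- config$n_genes
  with_seed(derive_seed(config$seed, "genes"), {
    structs <- lapply(seq_len(n_genes), function(i) draw_gene(i, config))
    placed <- place_genes(genome, structs)
  })
  placed
}

draw_gene <- function(i, config) {
  n_introns <- rpois(1, config$ipg_mean)
  n_exons <- n_introns + 1L
  exon_lens <- 3L + rgeom(n_exons, prob = 1 / max(config$exon_mean - 3, 1))
  total <- sum(exon_lens)
  pad <- (3L - total %% 3L) %% 3L
  exon_lens[n_exons] <- exon_lens[n_exons] + pad
  if (sum(exon_lens) < 6L) exon_lens[n_exons] <- exon_lens[n_exons] + 6L
  total <- sum(exon_lens)
  intron_lens <- if (n_introns > 0)
    20L + rgeom(n_introns, prob = 1 / max(config$intron_mean - 20, 1)) else integer(0)
  n_codons <- total %/% 3L
  coding <- setdiff(all_codons(), STOP_CODONS)
  body <- sample(coding, n_codons - 2L, replace = TRUE)
  cds <- paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
  canonical <- TRUE
  if (runif(1) < config$noncanonical_fraction) {
    canonical <- FALSE
    mode <- sample(3L, 1)
    if (mode == 1L) {
      substr(cds, 1, 3) <- "ATA"                       # broken start
    } else if (mode == 2L || n_codons < 4L) {
      substr(cds, total - 2, total) <- sample(coding, 1)  # no terminal stop
    } else {
      at <- 3 * sample(2:(n_codons - 1), 1) - 2        # internal stop
      substr(cds, at, at + 2) <- sample(STOP_CODONS, 1)
    }
  }
  list(gene_id = sprintf("gene_%04d", i), exon_lens = exon_lens,
       intron_lens = intron_lens, cds = cds, canonical = canonical,
       strand = sample(c("+", "-"), 1))
}

place_genes <- function(genome, structs) {
  residues <- genome$residues
  scaffold_idx <- 1L
  cursor <- 0L  # 0-based
  model_rows <- vector("list", length(structs))
  cds_rows <- vector("list", length(structs))
  gap_draw <- function() 50L + rgeom(1, prob = 1 / 250)
  for (g in structs) {
    # genomic sequence in transcript orientation: exons interleaved with introns
    n_ex <- length(g$exon_lens)
    exon_off <- cumsum(c(0L, head(g$exon_lens, -1L) +
                           c(g$intron_lens, 0L)[seq_len(max(n_ex - 1L, 0))]))
    span <- sum(g$exon_lens) + sum(g$intron_lens)
    pieces <- character(2L * n_ex - 1L)
    cds_cut <- cumsum(c(0L, g$exon_lens))
    for (k in seq_len(n_ex)) {
      pieces[2L * k - 1L] <- substr(g$cds, cds_cut[k] + 1L, cds_cut[k + 1L])
      if (k < n_ex)
        pieces[2L * k] <- random_dna(g$intron_lens[k], 0.5)
    }
    tx_seq <- paste(pieces, collapse = "")
    repeat {
      cursor <- cursor + gap_draw()
      if (scaffold_idx > length(residues))
        abort("scaffolds exhausted: not enough room to place the gene plan")
      if (cursor + span <= nchar(residues[[scaffold_idx]])) break
      scaffold_idx <- scaffold_idx + 1L
      cursor <- 0L
    }
    fwd_seq <- if (g$strand == "+") tx_seq else revcomp(tx_seq)
    substr(residues[[scaffold_idx]], cursor + 1L, cursor + span) <- fwd_seq
    if (g$strand == "+") {
      starts <- cursor + exon_off
    } else {
      starts <- cursor + span - (exon_off + g$exon_lens)
      ord <- order(starts)
      starts <- starts[ord]
      g$exon_lens <- g$exon_lens[ord]
    }
    model_rows[[match(g$gene_id, vapply(structs, `[[`, "", "gene_id"))]] <-
      tibble(gene_id = g$gene_id, scaffold = genome$id[[scaffold_idx]],
             strand = g$strand, exon_rank = seq_along(starts),
             start = as.integer(starts),
             end = as.integer(starts + g$exon_lens))
    cds_rows[[match(g$gene_id, vapply(structs, `[[`, "", "gene_id"))]] <-
      tibble(gene_id = g$gene_id, cds = g$cds,
             protein = as.character(suppressWarnings(
               Biostrings::translate(Biostrings::DNAString(g$cds),
                                     if.fuzzy.codon = "X"))),
             canonical = g$canonical)
    cursor <- cursor + span
  }
  genome$residues <- residues
  models <- dplyr::bind_rows(model_rows)
  validate_gene_models(models, genome)
  list(genome = genome, models = models, cds = dplyr::bind_rows(cds_rows))
}
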