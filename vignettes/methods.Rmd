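---
title: "Quantifying strain-level genome divergence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying strain-level genome divergence: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastcomp)
```

yeastcomp quantifies how far apart the genomes of closely related yeast
strains are, using two complementary routes — a sliding-window statistic
over whole-genome alignments and an alignment-free shustring distance —
plus the supporting machinery such studies need: targeted assembly of
high-copy replicons (mitochondrion, plasmid, tandem rDNA), coverage-ratio
copy-number estimates, gene/intron architecture tables, and
reciprocal-best-hit orthology with an orphan-gene filter chain. This
vignette explains the models, the tunable parameters, and the choices we
made where the design was genuinely open. Every number quoted here is
computed by the package's tests or its acceptance script; nothing is
imported from external data.

## The synthetic-data generators define the test bench

Real strain genomes are large external artifacts; the package instead
ships seeded generators that produce every input the pipeline consumes,
with the statistical structure the analyses assume. All generators hang
off a single `sim_config()`; one root seed is fanned out to per-stage
streams through fixed labels, so each stage is reproducible independently
of call order.

- `make_ancestor()` draws i.i.d. bases at a target GC (default 0.47, a
  typical basidiomycete yeast value and the regime the estimators are
  calibrated for).
- `evolve()` substitutes each site independently with probability `p`,
  chosen directly or through the Jukes–Cantor identity
  `p = (3/4)(1 − e^{−4d/3})` from a distance `d`. Substitutions are
  single-hit per site: at the divergences of interest (d ≤ 0.073) the
  multiple-hit correction is absorbed by the JC conversion while the
  planted truth stays exact — every planted site is guaranteed to differ,
  so recovery tests can assert equality rather than approximation.
  Indels (geometric lengths) and N-runs are available but default off:
  the window statistic and Kr both exclude gaps and ambiguous bases, so
  clean runs isolate the estimators; the indel path is exercised
  separately.
- `simulate_reads()` samples fixed-length reads (default 115 nt, a
  typical early-Illumina paired-end length) uniformly from a multi-replicon
  plan at expected depth `base_coverage × copy_number`, with uniform
  substitution errors (real Illumina error profiles are position- and
  context-dependent; a uniform rate is the simplest model that stresses
  the consensus machinery). Circular replicons are sampled across the
  origin; a tandem rDNA array is modeled as a circular 9-kb unit, which
  is exactly how reads crossing unit junctions behave in an array much
  longer than a read.
- `plant_genes()` writes intron-bearing genes into a genome: introns per
  gene ~ Poisson (default mean 7.5), exon/intron lengths from shifted
  geometric distributions (means 199 and 110, minima 3 and 20 bp),
  coding sequences canonical by construction (ATG…stop, length divisible
  by 3, no internal stop) except for a requested non-canonical fraction.
  Splice-site dinucleotides are not written because CDS-level extraction
  never reads them. Genes are laid out left to right with geometric
  intergenic gaps — adequate for statistics that only see exon intervals,
  though it reproduces no real gene-order structure.
- `make_hit_tables()` plants reciprocal best-scoring ortholog rows and
  strictly worse decoys whose subjects are restricted to genes already
  "owned" by a planted partner, which makes the recovered RBH set equal
  the planted map exactly — the property the orthology tests assert.

What passing these tests shows is parameter recovery under the stated
generative models; what it cannot show is robustness to repeat content,
rearrangement, context-dependent error, or annotation noise in real
assemblies, none of which the generators emulate.

## Sliding-window divergence

Pairwise alignments are projected onto a reference as a per-position call
track: a reference position is *called* (match or mismatch) for a query
iff it is covered by exactly one alignment column whose two residues are
both plain A/C/G/T. Gaps, Ns, IUPAC ambiguity codes, unaligned positions,
and positions covered by more than one block are *uncalled* — gap and
ambiguity exclusion mirrors how such window statistics are conventionally
computed, and multi-coverage is treated as ambiguity rather than signal.

Windows of 1 kb at 1-kb steps (both configurable) count called sites and
mismatches; windows with fewer than 500 called sites are discarded. For
plotting, each retained window is smoothed with the unweighted mean of up
to five retained windows on each side. Two design points were open and
are resolved as follows:

- **Summaries pool counts** (total mismatches over total called sites)
  rather than averaging window values. Pooling weights every called site
  equally, is robust to unequal calledness across windows, and matches
  "divergence" read as a per-site rate. The flank-smoothed values are for
  the plotted track only and never feed the summaries.
- **Smoothing skips discarded windows but never crosses a scaffold
  boundary**, since the track is drawn per scaffold.
- With two query genomes against one reference, a position must be called
  in **both** alignments to count (joint calledness); pairwise mode
  relaxes this to the single track.

A scaffold or genome with no retained window reports `NA`, never 0 — an
absence of evidence is not zero divergence.

The built-in `anchor_align()` is deliberately minimal: k-mers (default
16) unique in both genomes are chained by longest increasing subsequence;
same-diagonal neighbours are bridged directly; diagonal-changing gaps up
to 2 kb are closed with affine-gap global alignment
(`Biostrings::pairwiseAlignment`); larger ones split the block. It is
intended for collinear pairs up to roughly 15% divergence, forward strand
only — real rearranged genomes should be aligned externally and imported
via `read_maf()`.

## Alignment-free Kr from shustrings

For each position *i* of X, the shulen ℓᵢ is the length of the shortest
substring of X starting at *i* that is absent from Y (and from Y's
reverse complement by default, since genome distance should be
strand-agnostic). The core is computed by walking X through a generalized
suffix automaton of Y and is required — by test — to equal brute-force
enumeration on every input. Positions whose every prefix up to the end of
X occurs in Y take a sentinel value (remaining length + 1) and are
excluded from the mean; scaffolds are concatenated with a separator that
matches nothing; substrings containing N never match.

Mean shulen shrinks as divergence grows. Rather than transcribing a
closed-form expectation, the estimator inverts a **Monte-Carlo
calibration curve**: genome pairs are simulated at a log-spread grid of
difference probabilities (2×10⁻⁴ … 0.5) at the *matched* length and GC,
the direction-averaged mean shulen is recorded (two replicates per grid
point, with one shared ancestor per replicate as a common-random-numbers
variance reduction), and a monotone Hermite interpolant in log *p* is
inverted numerically for each direction of the observed pair. The two
directional difference estimates are Jukes–Cantor corrected and averaged,
which makes the estimate symmetric by construction. Self-calibration is
reproducible from the package alone and is validated by recovery tests:
across d = 0.005–0.15 at 1 Mb the estimate lands within a few percent of
truth, and at d = 7.6×10⁻⁴ on 2 Mb within the stochastic tolerance of the
~1,500 planted differences.

Estimates above 0.3 substitutions/site are flagged `reliable = FALSE`
but reported, not nulled — shustring distances degrade gradually and a
flagged value still carries ordering information. Near-identical pairs
whose profiles are almost entirely sentinel are reported as Kr 0. An
observation outside the calibration range is an error asking for a wider
grid, not a clamped value. Pairs whose expected mismatch count is under
~100 are flagged low-confidence.

## Targeted assembly and copy number

High-copy replicons are assembled from a whole-genome read set by
seed-and-extend:

1. **Recruitment** (`bait_reads()`): a read joins the pool when, in
   either orientation, it aligns to a bait with identity ≥ 0.95 over
   ≥ 40% of its length. Alignment is k-mer-seeded (k = 12) diagonal
   comparison; these two thresholds are the algorithmic contract, not the
   internals of any particular aligner.
2. **Seeding** (`select_seed()`): the read whose aligned footprint
   carries the largest summed depth wins; ties break by longer alignment,
   then lexicographic id, so output is deterministic.
3. **Consensus columns**: per column, Shannon entropy over base counts
   gives IC = 2 − H bits on the 4-letter alphabet. A column is fixed when
   IC > 0.5 *and* coverage ≥ `cov_min`. The bits definition is the only
   standard one for which an IC threshold of 0.5 is a meaningful
   mid-range gate (IC ranges 0–2); the coverage gate defaults to 100, the
   regime of organellar/rDNA depths, and is set to 20 in the desk-scale
   tests. Both gates are applied per column.
4. **Extension** (`extend_contig()`): each round aligns the pool to the
   terminal window of the contig, stacks overhanging bases into columns,
   and fixes the contiguous qualifying run, stopping a side at the first
   failing column; a round advances at most `read length − 20` columns so
   every fixed column is supported by reads anchored ≥ 20 bp in already
   -fixed sequence. Fixed bases are majority calls; ties resolve in fixed
   alphabet order for determinism. Gaps in read alignments contribute
   nothing to counts. When a pool is supplied, the initial contig is the
   IC-gated consensus of the recruited reads stacked in bait frame rather
   than the raw seed read — otherwise the seed's own sequencing errors
   would be frozen into the consensus and, at high error rates, would
   repel every other read at the 95% identity gate.
5. **Circularity** (`detect_circular()`): a contig closes when a suffix
   of ≥ 100 bp matches a prefix at ≥ 98% identity; the duplicated overlap
   is trimmed and the sequence normalized to its lexicographically
   minimal rotation so repeated runs produce identical output.

Copy number is the ratio of median per-position depths
(`estimate_copy_number()`), with the median making the estimate
insensitive to edge ramps on linear replicons and to local sampling
noise. On simulated plans spanning 1–200× the estimator is unbiased well
within 5% at base coverage ≥ 20.

## Gene architecture and orthology

Assembly statistics use the dominant community conventions: N50/L50 by
cumulative descending lengths reaching half the total; GC over non-N
bases with %N reported separately. Introns are the gaps between
consecutive CDS exons of a gene (UTR introns are invisible to CDS-only
models); mean exon/intron lengths are pooled over all features, not
per-gene means of means. The canonical-CDS rate uses the strict test
(ATG start, stop end, length divisible by 3, no internal stop). The
repeat-content column of the combined table is `NA` — measuring it needs
an external repeat masker, which is out of this package's scope.

Best hits rank by minimal e-value, then maximal aligned length — and,
purely for determinism where those tie, maximal bitscore then smallest
subject id. Thresholds are strict inequalities (e-value < 10⁻⁵; identity
> 50% in annotation mode) applied before ranking. RBH pairs require
reciprocity; three-way cores require the full triangle of links, and a
two-link candidate whose closing link points elsewhere is reported as
*inconsistent* rather than silently merged. The orphan chain filters, in
order: core membership, expression coverage ≥ 0.5, no relative-species
hit, no nr-style hit (both at e < 10⁻⁵); genes missing from the
expression table count as coverage 0 and are logged. Domains are counted
among survivors, never used as a filter.

## Numerical and scale choices

Internal coordinates are 0-based half-open everywhere; conversion happens
only at the GFF3/MAF format boundaries. IUPAC ambiguity codes are
accepted on input and treated as uncallable downstream. Test and
acceptance problem sizes are chosen as the smallest at which the binomial
error of the planted signal is far below the assertion tolerances: 2 Mb
and 5 Mb pairs for the window statistic at difference fractions 0.044 and
7.3×10⁻⁴, 1 Mb and 2 Mb pairs for Kr at d = 0.073 and 7.6×10⁻⁴, 100-kb
nuclear plus 20-kb/9-kb high-copy replicons at 45 and 182 copies for the
depth-ratio estimator, and a 10-kb circular replicon at 200× (error-free
and 5% error) for exact assembler reconstruction with `cov_min = 20`.

## Known limitations

- The anchor aligner assumes collinearity and the forward strand; it is a
  substrate for the window statistic, not a general-purpose aligner.
- Kr values are calibrated for the i.i.d.-background model; strong repeat
  structure shortens shulens for reasons other than divergence and will
  bias any shustring distance, this implementation included.
- Read simulation has no quality model, no PCR duplicates, and no
  insert-size structure; paired-end information is not used anywhere.
- The gene planter produces architecture statistics, not realistic gene
  content; codon usage is uniform over non-stop codons.
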