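# Synthetic-data generators: determinism, planted-truth conservation,
# configured-distribution recovery.

test_that("ancestor generation hits the target GC and is deterministic", {
  cfg <- sim_config(seed = 21, scaffold_lengths = 1e6, gc = 0.47)
  a1 <- make_ancestor(cfg)
  expect_equal(yeastcomp:::seq_gc(a1$residues), 0.47, tolerance = 0.002 / 0.47)
  a2 <- make_ancestor(cfg)
  expect_identical(a1, a2)

  pure_gc <- make_ancestor(sim_config(seed = 3, scaffold_lengths = 500,
                                      gc = 0.999))
  expect_false(grepl("[AT]", pure_gc$residues))

  expect_error(make_ancestor(sim_config(seed = 1, scaffold_lengths = 0)),
               "positive")
})

test_that("the Jukes-Cantor conversion matches the closed form", {
  expect_equal(jc_p_from_d(0.073), 0.75 * (1 - exp(-4 * 0.073 / 3)))
  expect_equal(jc_d_from_p(jc_p_from_d(0.2)), 0.2)
  expect_equal(jc_p_from_d(0), 0)
  expect_error(sim_config(d = 0.01, p = 0.01), "exactly one")
  expect_error(sim_config(p = 0.8), "0.75")
})

test_that("evolve plants the expected difference fraction with exact truth", {
  cfg <- sim_config(seed = 22, scaffold_lengths = 1e6, d = 0.073,
                    error_rate = 0)
  anc <- make_ancestor(cfg)
  ev <- evolve(anc, cfg)
  p_expect <- jc_p_from_d(0.073)
  n_sub <- nrow(ev$truth$substitutions)
  se <- sqrt(p_expect * (1 - p_expect) * 1e6)
  expect_lt(abs(n_sub - p_expect * 1e6), 3 * se)

  # conservation: planted substitutions equal column-wise mismatches
  a <- charToRaw(anc$residues[[1]])
  d <- charToRaw(ev$genome$residues[[1]])
  expect_identical(which(a != d) - 1L, ev$truth$substitutions$anc_pos)
  expect_true(all(ev$truth$substitutions$from != ev$truth$substitutions$to))

  zero <- evolve(anc, sim_config(seed = 1, scaffold_lengths = 1e6, d = 0))
  expect_identical(zero$genome$residues, anc$residues)
  expect_equal(nrow(zero$truth$substitutions), 0)
})

test_that("indels and N-runs keep the coordinate map and truth consistent", {
  cfg <- sim_config(seed = 23, scaffold_lengths = 5e4, p = 0.02,
                    indel_rate = 2e-4, indel_mean_len = 4,
                    n_run_rate = 5e-5, n_run_len = 30)
  anc <- make_ancestor(cfg)
  ev <- evolve(anc, cfg)
  segs <- ev$truth$segments
  # monotone map
  expect_true(all(diff(segs$anc_start) > 0))
  expect_true(all(diff(segs$der_start) > 0))
  # every mapped segment reproduces ancestor bases except at substitutions
  # and N-runs
  der <- ev$genome$residues[[1]]
  subs <- ev$truth$substitutions
  for (i in seq_len(nrow(segs))) {
    a_seg <- substr(anc$residues[[1]], segs$anc_start[i] + 1,
                    segs$anc_start[i] + segs$len[i])
    d_seg <- substr(der, segs$der_start[i] + 1, segs$der_start[i] + segs$len[i])
    diffs <- which(charToRaw(a_seg) != charToRaw(d_seg))
    der_diff_pos <- segs$der_start[i] + diffs - 1L
    planted_here <- subs$der_pos[subs$der_pos >= segs$der_start[i] &
                                   subs$der_pos < segs$der_start[i] + segs$len[i]]
    in_n <- vapply(der_diff_pos, function(p) {
      any(ev$truth$n_runs$start <= p & ev$truth$n_runs$end > p)
    }, TRUE)
    expect_setequal(der_diff_pos[!in_n], planted_here)
  }
  # every planted substitution column differs
  a_at <- substring(anc$residues[[1]], subs$anc_pos + 1, subs$anc_pos + 1)
  d_at <- substring(der, subs$der_pos + 1, subs$der_pos + 1)
  expect_true(all(a_at != d_at))
})

test_that("planted gene architecture matches the configured distributions", {
  cfg <- sim_config(seed = 24, scaffold_lengths = c(4e5, 4e5), n_genes = 200L,
                    ipg_mean = 7.5, intron_mean = 110, exon_mean = 199)
  pg <- plant_genes(make_ancestor(cfg), cfg)
  st <- annotation_stats(pg$models, pg$genome)
  expect_equal(st$genes, 200)
  expect_equal(st$introns_per_gene, 7.5, tolerance = 0.1)
  expect_equal(st$mean_intron_len, 110, tolerance = 0.1)
  expect_equal(st$mean_exon_len, 199, tolerance = 0.1)
  # spliced CDS extraction recovers the designed CDS exactly, both strands
  sc <- spliced_cds(pg$models, pg$genome)
  m <- dplyr::inner_join(sc, pg$cds, by = "gene_id")
  expect_true(all(m$cds.x == m$cds.y))
  expect_setequal(unique(pg$models$strand), c("+", "-"))

  single <- plant_genes(make_ancestor(cfg),
                        sim_config(seed = 25, scaffold_lengths = c(4e5, 4e5),
                                   n_genes = 50L, ipg_mean = 0))
  st1 <- annotation_stats(single$models, single$genome)
  expect_equal(st1$pct_ilg, 100)
  expect_equal(st1$introns_per_gene, 0)
})

test_that("requested non-canonical CDS fraction is realized", {
  cfg <- sim_config(seed = 26, scaffold_lengths = 1e6, n_genes = 300L,
                    ipg_mean = 3, noncanonical_fraction = 0.2)
  pg <- plant_genes(make_ancestor(cfg), cfg)
  cf <- canonical_cds_filter(pg$models, pg$genome)
  frac_bad <- mean(!cf$canonical)
  se <- sqrt(0.2 * 0.8 / 300)
  expect_lt(abs(frac_bad - 0.2), 3 * se)
  # checker agrees with the generator's own labels
  expect_equal(cf$canonical,
               pg$cds$canonical[match(cf$gene_id, pg$cds$gene_id)])
})

test_that("read simulation honours depth, copy number, and error rate", {
  cfg <- sim_config(seed = 27, base_coverage = 30, error_rate = 0)
  plan <- replicon_plan("chr", 1e5, 1, FALSE)
  sim <- simulate_reads(plan, cfg)
  d <- replicon_depth(sim$origins, plan)
  expect_equal(d$median_depth, 30, tolerance = 0.05)
  # error-free reads are exact substrings (modulo orientation)
  idx <- sample(nrow(sim$reads), 50)
  src <- sim$replicons$residues[[1]]
  for (i in idx) {
    o <- sim$origins[i, ]
    frag <- substr(src, o$start + 1, o$end)
    if (o$strand == "-") frag <- revcomp(frag)
    expect_identical(sim$reads$bases[[i]], frag)
  }
  expect_error(simulate_reads(replicon_plan("tiny", 50, 1, FALSE), cfg),
               "read_length exceeds")
})

test_that("realized depth is proportional to copy number", {
  cfg <- sim_config(seed = 28, base_coverage = 20, error_rate = 0.01)
  plan <- replicon_plan(c("nuclear", "m5", "m45", "m200"),
                        c(1e5, 2e4, 2e4, 1e4), c(1, 5, 45, 200),
                        c(FALSE, TRUE, TRUE, TRUE))
  sim <- simulate_reads(plan, cfg)
  d <- replicon_depth(sim$origins, plan)
  ratios <- d$median_depth / d$median_depth[d$replicon == "nuclear"]
  expect_equal(ratios, c(1, 5, 45, 200), tolerance = 0.05)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 29, scaffold_lengths = 6e4, p = 0.01,
                    n_genes = 8L, ipg_mean = 2)
  r1 <- simulate_reads(replicon_plan("r", 5e3, 2, TRUE), cfg)
  r2 <- simulate_reads(replicon_plan("r", 5e3, 2, TRUE), cfg)
  expect_identical(r1, r2)
  g1 <- plant_genes(make_ancestor(cfg), cfg)
  g2 <- plant_genes(make_ancestor(cfg), cfg)
  expect_identical(g1, g2)
  h1 <- make_hit_tables(list(A = c("a1", "a2"), B = c("b1", "b2")),
                        tibble::tibble(A = "a1", B = "b1"), seed = 5)
  h2 <- make_hit_tables(list(A = c("a1", "a2"), B = c("b1", "b2")),
                        tibble::tibble(A = "a1", B = "b1"), seed = 5)
  expect_identical(h1, h2)
})

test_that("hit-table generator plants recoverable orthologs and orphans", {
  gs <- list(A = sprintf("a%03d", 1:120), B = sprintf("b%03d", 1:110),
             C = sprintf("c%03d", 1:105))
  om <- tibble::tibble(A = sprintf("a%03d", 1:100),
                       B = sprintf("b%03d", 1:100),
                       C = sprintf("c%03d", 1:100))
  orph <- sprintf("a%03d", 1:10)
  ht <- make_hit_tables(gs, om, orphans = orph, seed = 31)
  r_ab <- rbh(ht$cross$A_vs_B, ht$cross$B_vs_A)
  r_ac <- rbh(ht$cross$A_vs_C, ht$cross$C_vs_A)
  r_bc <- rbh(ht$cross$B_vs_C, ht$cross$C_vs_B)
  tw <- three_way_sets(r_ab, r_ac, r_bc)
  expect_equal(nrow(tw$core), 100)
  orf <- orphan_filter(tw$core$a, ht$expression, ht$relatives, ht$nr,
                       ht$domains)
  expect_setequal(orf$gene_id, orph)

  # empty map: cross tables contain only decoys (all above planted scores)
  ht0 <- make_hit_tables(list(A = c("a1"), B = c("b1")),
                         tibble::tibble(A = character(), B = character()),
                         seed = 1)
  expect_true(all(ht0$cross$A_vs_B$evalue > 1e-9 |
                    nrow(ht0$cross$A_vs_B) == 0))

  expect_error(make_hit_tables(gs, tibble::tibble(A = "zzz", B = "b001",
                                                  C = "c001"), seed = 1),
               "unknown gene id")
})
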