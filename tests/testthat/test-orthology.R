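# Orthology: best-hit ranking against an exhaustive comparator, RBH
# reciprocity, three-way set construction, and the orphan filter chain.

test_that("best_hits applies thresholds then the declared tie chain", {
  expect_equal(nrow(best_hits(random_hits_table(0))), 0)

  tie <- tibble::tibble(query = "q", subject = c("s1", "s2"),
                        pct_identity = 90, aln_length = c(200, 300),
                        mismatch = 0, gapopen = 0, qstart = 1, qend = 1,
                        sstart = 1, send = 1,
                        evalue = 1e-10, bitscore = 100)
  expect_equal(best_hits(tie)$subject, "s2")   # longer alignment wins the tie

  # e-value threshold is strict; identity threshold is strict
  edge <- dplyr::mutate(tie, evalue = c(1e-5, 1e-6))
  expect_equal(best_hits(edge)$subject, "s2")
  ident <- dplyr::mutate(tie, pct_identity = c(45, 55))
  expect_equal(best_hits(ident, min_identity = 50)$subject, "s2")
})

test_that("best_hits equals the exhaustive comparator on random tables", {
  withr::local_seed(90)
  for (i in 1:300) {
    tab <- random_hits_table(sample(5:40, 1))
    got <- best_hits(tab)
    want <- brute_best_hits(tab)
    expect_equal(nrow(got), length(want))
    expect_equal(setNames(got$subject, got$query), unlist(want))
  }
})

test_that("rbh keeps only reciprocal pairs and forms a 1:1 matching", {
  ab <- tibble::tibble(query = c("a1", "a2"), subject = c("b1", "b2"),
                       pct_identity = 90, aln_length = 200, mismatch = 0,
                       gapopen = 0, qstart = 1, qend = 1, sstart = 1,
                       send = 1, evalue = 1e-20, bitscore = 100)
  ba_good <- tibble::tibble(query = c("b1", "b2"), subject = c("a1", "a2"),
                            pct_identity = 90, aln_length = 200, mismatch = 0,
                            gapopen = 0, qstart = 1, qend = 1, sstart = 1,
                            send = 1, evalue = 1e-20, bitscore = 100)
  expect_equal(nrow(rbh(ab, ba_good)), 2)
  # b1 points elsewhere: (a1, b1) excluded
  ba_bad <- dplyr::mutate(ba_good, subject = c("a9", "a2"))
  expect_equal(rbh(ab, ba_bad)$a, "a2")
  # identity gate in annotation mode
  expect_equal(nrow(rbh(dplyr::mutate(ab, pct_identity = 45), ba_good,
                        min_identity = 50)), 0)

  withr::local_seed(91)
  for (i in 1:50) {
    t1 <- random_hits_table(60, n_query = 12, n_subject = 12)
    t2 <- random_hits_table(60, n_query = 12, n_subject = 12)
    pairs <- rbh(t1, t2)
    expect_false(any(duplicated(pairs$a)))
    expect_false(any(duplicated(pairs$b)))
    bh1 <- brute_best_hits(t1); bh2 <- brute_best_hits(t2)
    for (j in seq_len(nrow(pairs))) {
      expect_equal(bh1[[pairs$a[j]]], pairs$b[j])
      expect_equal(bh2[[pairs$b[j]]], pairs$a[j])
    }
  }
})

test_that("three-way sets separate core, exclusive, and inconsistent links", {
  r_ab <- tibble::tibble(a = c("a1", "a2", "a3"), b = c("b1", "b2", "b3"))
  r_ac <- tibble::tibble(a = c("a1", "a3"), b = c("c1", "c3"))
  r_bc <- tibble::tibble(a = c("b1", "b3"), b = c("c1", "c9"))
  tw <- three_way_sets(r_ab, r_ac, r_bc)
  expect_equal(tw$core, tibble::tibble(a = "a1", b = "b1", c = "c1"))
  expect_equal(tw$exclusive$ab, tibble::tibble(a = "a2", b = "b2"))
  expect_equal(nrow(tw$inconsistent), 1)      # a3-b3, a3-c3 but b3->c9
  expect_equal(tw$inconsistent$a, "a3")

  none <- three_way_sets(r_ab[0, ], r_ac[0, ], r_bc[0, ])
  expect_equal(unname(none$counts), rep(0L, 5))
})

test_that("planted core and pair-exclusive sets are recovered exactly", {
  gs <- list(A = sprintf("a%03d", 1:130), B = sprintf("b%03d", 1:125),
             C = sprintf("c%03d", 1:120))
  om <- tibble::tibble(A = sprintf("a%03d", 1:110),
                       B = sprintf("b%03d", 1:110),
                       C = c(sprintf("c%03d", 1:100), rep(NA, 10)))
  ht <- make_hit_tables(gs, om, seed = 92)
  tw <- three_way_sets(rbh(ht$cross$A_vs_B, ht$cross$B_vs_A),
                       rbh(ht$cross$A_vs_C, ht$cross$C_vs_A),
                       rbh(ht$cross$B_vs_C, ht$cross$C_vs_B))
  expect_equal(unname(tw$counts["core"]), 100L)
  expect_equal(unname(tw$counts["ab_exclusive"]), 10L)
  expect_equal(unname(tw$counts["ac_exclusive"]), 0L)
  expect_equal(unname(tw$counts["inconsistent"]), 0L)
  # conservation: planted groups partition into core + ab-exclusive
  expect_equal(sum(tw$counts[c("core", "ab_exclusive")]), nrow(om))
})

test_that("the orphan filter applies its chain in order with strict gates", {
  core <- sprintf("g%02d", 1:20)
  expr <- tibble::tibble(gene_id = core,
                         coverage = c(rep(0.8, 10), 0.49, rep(0.9, 9)))
  rel <- hit_tbl <- tibble::tibble(
    query = c("g01", "g02"), subject = "rel_x", pct_identity = 80,
    aln_length = 300, mismatch = 0, gapopen = 0, qstart = 1, qend = 1,
    sstart = 1, send = 1, evalue = c(1e-30, 1e-4), bitscore = 200)
  nr <- dplyr::mutate(hit_tbl, query = c("g03", "g04"),
                      evalue = c(1e-10, 1))
  dom <- tibble::tibble(gene_id = c("g05", "g06"), domain = c("PF1", "PF2"))
  orf <- orphan_filter(core, expr, rel, nr, dom)
  # g01 (relative hit), g03 (nr hit), g11 (expression 0.49) excluded;
  # g02 and g04 survive because their hits are above threshold
  expect_setequal(orf$gene_id, setdiff(core, c("g01", "g03", "g11")))
  expect_equal(attr(orf, "n_with_domain"), 2)
  counts <- attr(orf, "counts")
  expect_equal(unname(counts), c(20L, 19L, 18L, 17L))

  # genes missing from the expression table count as coverage 0
  expect_message(
    orf2 <- orphan_filter(c(core, "absent"), expr, rel, nr, dom),
    "missing from the expression table")
  expect_false("absent" %in% orf2$gene_id)
})

test_that("tightening any threshold never grows the orphan set", {
  withr::local_seed(93)
  core <- sprintf("g%03d", 1:60)
  expr <- tibble::tibble(gene_id = core, coverage = runif(60))
  mk_hits <- function(n) tibble::tibble(
    query = sample(core, n, replace = TRUE), subject = "x",
    pct_identity = 70, aln_length = 100, mismatch = 0, gapopen = 0,
    qstart = 1, qend = 1, sstart = 1, send = 1,
    evalue = 10^-runif(n, 0, 12), bitscore = 100)
  rel <- mk_hits(40); nr <- mk_hits(40)
  base <- orphan_filter(core, expr, rel, nr, min_expression = 0.5,
                        max_evalue = 1e-5)
  tighter_expr <- orphan_filter(core, expr, rel, nr, min_expression = 0.7,
                                max_evalue = 1e-5)
  looser_e <- orphan_filter(core, expr, rel, nr, min_expression = 0.5,
                            max_evalue = 1e-3)
  expect_true(all(tighter_expr$gene_id %in% base$gene_id))
  expect_true(all(looser_e$gene_id %in% base$gene_id))
})
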