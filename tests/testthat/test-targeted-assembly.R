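# Targeted assembly: IC formula, recruitment against origin truth, seed
# selection, gated extension, circularity, copy number.

test_that("column IC matches direct entropy evaluation", {
  expect_equal(column_ic(c(A = 50))$H, 0)
  expect_equal(column_ic(c(A = 50))$IC, 2)
  r <- column_ic(c(A = 60, C = 40))
  expect_equal(r$H, -(0.6 * log2(0.6) + 0.4 * log2(0.4)))
  expect_equal(r$H, 0.9710, tolerance = 1e-4)
  expect_equal(r$IC, 1.0290, tolerance = 1e-4)
  flat <- column_ic(c(A = 30, C = 30, G = 20, T = 20))
  expect_equal(flat$IC, 2 + 2 * 0.3 * log2(0.3) + 2 * 0.2 * log2(0.2))
  expect_equal(round(flat$IC, 4), 0.0290)
  expect_lt(flat$IC, 0.5)
  expect_error(column_ic(c(A = 0, C = 0, G = 0, T = 0)), "all-zero")

  # brute-force entropy on random count vectors, exact to 1e-12
  withr::local_seed(5)
  for (i in 1:50) {
    cnt <- rpois(4, lambda = sample(1:80, 1)) + c(1, 0, 0, 0)
    got <- column_ic(setNames(cnt, c("A", "C", "G", "T")))
    p <- cnt / sum(cnt)
    h <- -sum(p[p > 0] * log2(p[p > 0]))
    expect_equal(got$H, h, tolerance = 1e-12)
    expect_equal(got$IC, 2 - h, tolerance = 1e-12)
  }
})

test_that("recruitment matches the origin truth table", {
  cfg <- sim_config(seed = 41, base_coverage = 200, error_rate = 0)
  plan <- replicon_plan("plasmid", 6e3, 1, FALSE)
  sim <- simulate_reads(plan, cfg)
  truth_seq <- sim$replicons$residues[[1]]
  bait <- assembly_tbl("bait", substr(truth_seq, 2001, 2500))
  pool <- bait_reads(sim$reads, bait)
  # error-free reads: recruited iff >= 40% of the read overlaps the locus
  ov <- pmin(sim$origins$end, 2500) - pmax(sim$origins$start, 2000)
  expected <- sim$origins$read_id[ov >= ceiling(0.4 * 115)]
  expect_setequal(pool$read_id, expected)
  expect_true(all(pool$identity == 1))

  # an exact bait substring is recruited; a 10%-mismatch read is not
  frag <- substr(truth_seq, 2100, 2214)
  noisy <- frag
  pos <- seq(1, 111, by = 10)
  for (p in pos) substr(noisy, p, p) <- chartr("ACGT", "CGTA", substr(noisy, p, p))
  reads2 <- tibble::tibble(id = c("exact", "noisy"), bases = c(frag, noisy),
                           quals = strrep("I", 115))
  pool2 <- bait_reads(reads2, bait)
  expect_equal(pool2$read_id, "exact")
  expect_error(bait_reads(reads2, assembly_tbl(character(0), character(0))))
})

test_that("seed selection maximizes footprint depth with declared ties", {
  pool <- tibble::tibble(
    read_id = c("deep_a", "deep_b", "shallow"),
    bait = "b", strand = "+",
    offset = c(100L, 110L, 400L),
    overlap_start = c(100L, 110L, 400L),
    overlap_end = c(215L, 225L, 515L),
    identity = 1, read_coverage = 1,
    bases = strrep("A", 115))
  picked <- select_seed(pool)
  expect_true(picked$read_id %in% c("deep_a", "deep_b"))  # 2x locus beats 1x
  # exact tie on depth and length: lexicographically smaller id
  tie <- pool[1:2, ]
  tie$offset <- c(100L, 100L); tie$overlap_start <- c(100L, 100L)
  tie$overlap_end <- c(215L, 215L)
  expect_equal(select_seed(tie)$read_id, "deep_a")
  expect_equal(select_seed(pool[3, ])$read_id, "shallow")
  expect_error(select_seed(pool[0, ]), "empty read pool")
})

test_that("extension reconstructs a linear replicon and stops at low coverage", {
  cfg <- sim_config(seed = 42, base_coverage = 200, error_rate = 0)
  plan <- replicon_plan("lin", 5e3, 1, FALSE)
  sim <- simulate_reads(plan, cfg)
  truth_seq <- sim$replicons$residues[[1]]
  bait <- assembly_tbl("bait", substr(truth_seq, 2301, 2800))
  pool <- bait_reads(sim$reads, bait)
  ctg <- extend_contig(select_seed(pool), sim$reads, pool = pool,
                       cov_min = 20, max_rounds = 100)
  expect_false(ctg$circular)
  # linear ends lose coverage below the gate, so the contig is the full
  # replicon minus short terminal ramps
  expect_true(grepl(ctg$consensus, truth_seq, fixed = TRUE) ||
                grepl(revcomp(ctg$consensus), truth_seq, fixed = TRUE))
  expect_gt(nchar(ctg$consensus), 5e3 - 300)
  expect_lt(nchar(ctg$consensus), 5e3 + 1)
  # all fixed columns pass the declared gates
  expect_true(all(ctg$columns$IC > 0.5))
  expect_true(all(ctg$columns$coverage >= 20))
})

test_that("raising the gates never lengthens the contig", {
  cfg <- sim_config(seed = 43, base_coverage = 60, error_rate = 0.02)
  plan <- replicon_plan("lin", 3e3, 1, FALSE)
  sim <- simulate_reads(plan, cfg)
  bait <- assembly_tbl("bait", substr(sim$replicons$residues[[1]], 1201, 1700))
  pool <- bait_reads(sim$reads, bait)
  seed <- select_seed(pool)
  len_at <- function(cov_min, ic_min) {
    nchar(extend_contig(seed, sim$reads, pool = pool, cov_min = cov_min,
                        ic_min = ic_min, max_rounds = 60)$consensus)
  }
  base <- len_at(15, 0.5)
  expect_lte(len_at(30, 0.5), base)
  expect_lte(len_at(15, 1.2), base)
})

test_that("circularity detection trims, normalizes, and respects thresholds", {
  withr::local_seed(44)
  core <- yeastcomp:::random_dna(3000, 0.5)
  wrapped <- paste0(core, substr(core, 1, 150))
  res <- detect_circular(wrapped, min_overlap = 100)
  expect_true(res$circular)
  expect_equal(nchar(res$sequence), 3000)
  expect_true(res$sequence %in% rotation_forms(core))

  linear <- yeastcomp:::random_dna(3000, 0.5)
  expect_false(detect_circular(linear, min_overlap = 100)$circular)

  short_repeat <- paste0(core, substr(core, 1, 50))  # 50 < min_overlap
  expect_false(detect_circular(short_repeat, min_overlap = 100)$circular)
})

test_that("copy-number estimation is exact arithmetic with guards", {
  est <- estimate_copy_number(1500, 33.3)
  expect_equal(est$ratio, 1500 / 33.3)
  expect_equal(est$ratio, 45.0, tolerance = 0.002)
  expect_equal(est$copies, 45)
  expect_equal(estimate_copy_number(20, 20)$ratio, 1)
  expect_error(estimate_copy_number(10, 0), "nuclear_depth")
})

test_that("copy-number recovery is unbiased across the 1-200x range", {
  cfg <- sim_config(seed = 45, base_coverage = 20, error_rate = 0.01)
  plan <- replicon_plan(c("nuclear", "c5", "c45", "c200"),
                        c(1e5, 1e4, 1e4, 5e3), c(1, 5, 45, 200),
                        c(FALSE, TRUE, TRUE, TRUE))
  sim <- simulate_reads(plan, cfg)
  d <- replicon_depth(sim$origins, plan)
  nuc <- d$median_depth[d$replicon == "nuclear"]
  for (i in 2:4) {
    est <- estimate_copy_number(d$median_depth[i], nuc)
    expect_equal(est$ratio, plan$copy_number[i],
                 tolerance = 0.05)
  }
})
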