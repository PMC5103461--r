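# Divergence pipeline: aligner recovery against planted truth, call-track
# semantics, window accounting, smoothing, and pooled summaries.

test_that("identical sequences give one block with zero mismatches", {
  withr::local_seed(51)
  a <- assembly_tbl("s1", yeastcomp:::random_dna(1e4, 0.5))
  blocks <- anchor_align(a, a)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$ref_aln, blocks$query_aln)
  track <- build_call_track(blocks, a)
  sm <- summarize_divergence(window_stats(track))
  expect_equal(glance(sm)$divergence, 0)
})

test_that("aligner recovers the planted mismatch fraction exactly on covered sites", {
  pair <- make_pair(2e5, p = 0.044, seed = 52)
  blocks <- anchor_align(pair$ancestor, pair$derived)
  track <- build_call_track(blocks, pair$ancestor)
  stats <- window_stats(track)
  # coverage >= 99% of sites
  expect_gt(sum(stats$called) / 2e5, 0.99)
  # oracle equivalence: mismatches == planted substitutions at called sites
  st <- track$states[[1]][[1]]
  called_pos <- which(st > 0L) - 1L
  planted_called <- intersect(pair$truth$substitutions$anc_pos, called_pos)
  expect_identical(sum(stats$mismatches), length(planted_called))
  expect_identical(which(st == 2L) - 1L, planted_called)
})

test_that("a planted insertion is bridged with gap columns, not mismatches", {
  pair <- make_pair(5e4, p = 0.01, seed = 53)
  cfg <- sim_config(seed = 53, scaffold_lengths = 5e4, p = 0.01,
                    indel_rate = 2e-5, indel_mean_len = 200)
  ev <- evolve(pair$ancestor, cfg)
  skip_if(nrow(ev$truth$indels) == 0, "no indel drawn at this seed")
  blocks <- anchor_align(pair$ancestor, ev$genome)
  expect_gt(nrow(blocks), 0)
  gapped <- sum(grepl("-", blocks$ref_aln, fixed = TRUE) |
                  grepl("-", blocks$query_aln, fixed = TRUE))
  expect_gt(gapped, 0)
  # gap columns are uncalled: mismatch total still matches planted truth
  track <- build_call_track(blocks, pair$ancestor)
  st <- track$states[[1]][[1]]
  called_pos <- which(st > 0L) - 1L
  expect_identical(which(st == 2L) - 1L,
                   intersect(ev$truth$substitutions$anc_pos, called_pos))
})

test_that("call-track rules: N runs, overlap ambiguity, hand-counted toys", {
  ref <- assembly_tbl("r", "ACGTACGTACNNNNNACGTACGTACGTACG")
  # block covering all 30 positions, 2 mismatches at positions 3 and 20 (0-based)
  q <- ref$residues
  substr(q, 4, 4) <- "G"; substr(q, 21, 21) <- "T"
  blocks <- tibble::tibble(ref_id = "r", ref_start = 0L, query_id = "q",
                           query_start = 0L, strand = "+",
                           ref_aln = ref$residues, query_aln = q)
  track <- build_call_track(blocks, ref)
  st <- track$states[[1]][[1]]
  expect_identical(which(st == 2L) - 1L, c(3L, 20L))
  expect_true(all(st[11:15] == 0L))          # N-run uncalled
  expect_equal(sum(st > 0), 30 - 5)

  # overlapping blocks: positions covered twice become uncalled
  two <- dplyr::bind_rows(blocks, dplyr::mutate(blocks, ref_start = 0L))
  track2 <- build_call_track(two, ref)
  expect_true(all(track2$states[[1]][[1]] == 0L))
  expect_gt(track2$n_overlap_uncalled, 0)
})

test_that("window accounting: retention rule, hand counts, conservation", {
  withr::local_seed(54)
  ref <- assembly_tbl("r", yeastcomp:::random_dna(3000, 0.5))
  q <- ref$residues
  mism_pos <- sample(1001:2000, 30)           # 30 mismatches in window 2
  for (p in mism_pos)
    substr(q, p, p) <- chartr("ACGT", "CGTA", substr(q, p, p))
  blocks <- tibble::tibble(ref_id = "r", ref_start = 0L, query_id = "q",
                           query_start = 0L, strand = "+",
                           ref_aln = ref$residues, query_aln = q)
  stats <- window_stats(build_call_track(blocks, ref))
  expect_equal(stats$value, c(0, 0.03, 0))
  expect_true(all(stats$retained))

  # a window with 499 called sites is discarded
  blocks499 <- dplyr::mutate(blocks, ref_aln = substr(ref_aln, 1, 499),
                             query_aln = substr(query_aln, 1, 499))
  s499 <- window_stats(build_call_track(blocks499, ref))
  expect_equal(s499$called[1], 499L)
  expect_false(s499$retained[1])

  # conservation: window sums equal track totals
  track <- build_call_track(blocks, ref)
  st <- track$states[[1]][[1]]
  expect_identical(sum(stats$called), sum(st > 0L))
  expect_identical(sum(stats$mismatches), sum(st == 2L))
  expect_error(window_stats(track, window = 0), "positive")
})

test_that("window statistics are invariant to block input order", {
  pair <- make_pair(3e4, p = 0.03, seed = 55)
  blocks <- anchor_align(pair$ancestor, pair$derived)
  # split the single block into pieces and shuffle
  b <- blocks[1, ]
  cuts <- c(0, 10000, 20000, nchar(b$ref_aln))
  pieces <- purrr::map_dfr(1:3, function(i) {
    piece_ref <- substr(b$ref_aln, cuts[i] + 1, cuts[i + 1])
    tibble::tibble(ref_id = b$ref_id,
                   ref_start = b$ref_start + cuts[i],
                   query_id = b$query_id,
                   query_start = b$query_start + cuts[i],
                   strand = "+",
                   ref_aln = piece_ref,
                   query_aln = substr(b$query_aln, cuts[i] + 1, cuts[i + 1]))
  })
  s1 <- window_stats(build_call_track(pieces, pair$ancestor))
  s2 <- window_stats(build_call_track(pieces[c(3, 1, 2), ], pair$ancestor))
  expect_identical(s1, s2)
})

test_that("smoothing is a contraction with constant fixed points", {
  mk <- function(values, retained = TRUE) {
    tibble::tibble(query = "q", scaffold = "s",
                   start = seq(0, by = 1000, length.out = length(values)),
                   called = 1000L, mismatches = as.integer(values * 1000),
                   value = values, retained = retained)
  }
  const <- smooth_windows(mk(rep(0.04, 20)))
  expect_equal(const$smoothed, rep(0.04, 20))

  vals <- seq(0, 0.10, by = 0.01)
  sm <- smooth_windows(mk(vals))
  expect_equal(sm$smoothed[6], 0.05)          # mean of all 11 values
  expect_true(all(sm$smoothed >= min(vals) & sm$smoothed <= max(vals)))

  # single retained window flanked by discarded ones keeps its raw value
  mixed <- mk(c(0.2, 0.05, 0.3), retained = c(FALSE, TRUE, FALSE))
  sm2 <- smooth_windows(mixed)
  expect_equal(nrow(sm2), 1)
  expect_equal(sm2$smoothed, 0.05)

  # property: contraction over random retained tracks
  withr::local_seed(56)
  for (i in 1:20) {
    v <- runif(sample(12:40, 1), 0, 0.2)
    smi <- smooth_windows(mk(v))
    expect_true(all(smi$smoothed >= min(v) - 1e-12 &
                      smi$smoothed <= max(v) + 1e-12))
  }
})

test_that("summaries pool counts and flag empty scaffolds as undefined", {
  stats <- tibble::tibble(
    query = "q",
    scaffold = rep(c("s1", "s2"), each = 2),
    start = rep(c(0L, 1000L), 2),
    called = c(1000L, 800L, 200L, 300L),
    mismatches = c(10L, 4L, 50L, 60L),
    value = c(0.01, 0.005, 0.25, 0.2),
    retained = c(TRUE, TRUE, FALSE, FALSE))
  sm <- summarize_divergence(stats)
  per <- tidy(sm)
  expect_equal(per$divergence[per$scaffold == "s1"], 14 / 1800)
  expect_true(is.na(per$divergence[per$scaffold == "s2"]))
  expect_equal(glance(sm)$divergence, 14 / 1800)  # pooled, not mean of means
})

test_that("three-way tracks use joint calledness", {
  withr::local_seed(57)
  ref <- assembly_tbl("r", yeastcomp:::random_dna(2000, 0.5))
  q1 <- ref$residues                          # full-length, identical
  q2 <- substr(ref$residues, 1, 1200)          # covers only the first 1200
  blk <- function(q, id) tibble::tibble(ref_id = "r", ref_start = 0L,
                                        query_id = id, query_start = 0L,
                                        strand = "+", ref_aln = substr(ref$residues, 1, nchar(q)),
                                        query_aln = q)
  track <- build_call_track(list(a = blk(q1, "a"), b = blk(q2, "b")), ref)
  joint <- window_stats(track, joint = TRUE)
  solo <- window_stats(track, joint = FALSE)
  # jointly-called sites limited by the shorter alignment, for both queries
  expect_equal(unique(joint$called[joint$start == 1000]), 200L)
  expect_equal(solo$called[solo$query == "a" & solo$start == 1000], 1000L)
})
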