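test_that("reverse complement follows Watson-Crick pairing with N self-complementary", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAGATC"), "GATCTT")
  expect_equal(reverse_complement("AAAN"), "NTTT")
  expect_equal(reverse_complement(c("A", "CG")), c("T", "CG"))
  # involution on random sequences
  set.seed(1)
  s <- random_seq(80, 20)
  expect_equal(reverse_complement(reverse_complement(s)), s)
})

test_that("mismatch counting is Hamming distance with N as always-mismatch", {
  expect_equal(count_mismatches("ACGT", "ACGT"), 0L)
  expect_equal(count_mismatches("ACGT", "ACGA"), 1L)
  expect_equal(count_mismatches("ANGT", "ACGT"), 1L)
  expect_equal(count_mismatches("NNNN", "NNNN"), 4L)
  expect_error(count_mismatches("ACG", "ACGT"), "unequal lengths")
})

test_that("stage-1 scan finds mismatch-tolerant reverse-complement occurrences", {
  p0 <- trimmer_params(L = 4, e1 = 0)
  expect_equal(as.integer(scan_candidates("ACGTTGAGAT", "CAACGTAGAT", p0)),
               6L)
  expect_equal(length(scan_candidates("AAAAAAAAAA", "CCCCCCCCCC", p0)), 0L)
  # one error within budget floor(4 * 0.25) = 1
  p1 <- trimmer_params(L = 4, e1 = 0.25)
  expect_equal(as.integer(scan_candidates("ACGTTGAGAT", "CAATGTAGAT", p1)),
               6L)
  # e1 = 1 disables the check: every start position qualifies
  pall <- trimmer_params(L = 4, e1 = 1)
  expect_equal(as.integer(scan_candidates("ACGTTGAGAT", "CCCCCCCCCC", pall)),
               4:10)
  expect_warning(out <- scan_candidates("ACG", "ACGTACGT", p0),
                 "shorter than L")
  expect_equal(length(out), 0L)
})

test_that("scan candidate sets grow monotonically with the stage-1 tolerance", {
  set.seed(7)
  for (i in 1:20) {
    s1 <- random_seq(60); s2 <- random_seq(60)
    prev <- integer()
    for (e1 in c(0, 0.2, 0.4, 0.7, 1)) {
      cur <- as.integer(scan_candidates(s1, s2, trimmer_params(L = 10,
                                                               e1 = e1)))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("candidate intersection is an ascending set intersection", {
  expect_equal(candidate_intersection(c(6, 40), 6), 6L)
  expect_equal(candidate_intersection(integer(), 6), integer())
  expect_equal(candidate_intersection(c(10, 30, 50), c(30, 50, 70)),
               c(30L, 50L))
})

test_that("stage-2 validation checks DNA reverse-complementarity and adapter equality", {
  p <- trimmer_params(L = 4)
  expect_true(validate_candidate("ACGTTGAGAT", "CAACGTAGAT", 6, p))
  # distinct adapter parts fail at e3 = 0.4 but pass with the check disabled
  p_off <- trimmer_params(L = 4, e3 = 1)
  expect_false(validate_candidate("ACGTTGAGAT", "CAACGTCTAG", 6, p))
  expect_true(validate_candidate("ACGTTGAGAT", "CAACGTCTAG", 6, p_off))
  # n = N: adapter check vacuous, DNA check spans the whole read
  expect_false(validate_candidate("ACGTTGAGAT", "CAACGTAGAT", 10, p))
  s <- random_seq(40)
  expect_true(validate_candidate(s, reverse_complement(s), 40,
                                 trimmer_params(L = 10)))
  expect_error(validate_candidate("ACGT", "ACGT", 2, p), "outside")
})

test_that("two-stage trimming recovers the junction on a constructed pair", {
  pairs <- pair_tbl("ACGTTGAGAT", "CAACGTAGAT")
  res <- trim_pairs(pairs, trimmer_params(L = 4))
  expect_true(res$trimmed)
  expect_equal(res$insert_length, 6L)
  expect_equal(res$seq1, "ACGTTG")
  expect_equal(res$seq2, "CAACGT")
  expect_equal(res$validated_candidate, 6L)
  expect_true(6L %in% res$candidates[[1]])
})

test_that("unrelated pairs stay untrimmed and a zero-length adapter removes nothing", {
  set.seed(9)
  rnd <- pair_tbl(random_seq(101, 30), random_seq(101, 30))
  res <- trim_pairs(rnd)
  expect_false(any(res$trimmed))
  # fully reverse-complementary mates: candidate n = N validates but
  # leaves nothing to cut
  s <- random_seq(101, 5)
  full <- pair_tbl(s, reverse_complement(s))
  res <- trim_pairs(full)
  expect_false(any(res$trimmed))
  expect_equal(res$validated_candidate, rep(101L, 5))
  expect_equal(res$seq1, s)
})

test_that("disabling every tolerance accepts the largest candidate N, hence no trimming", {
  set.seed(13)
  pairs <- pair_tbl(random_seq(50, 10), random_seq(50, 10))
  p <- trimmer_params(L = 10, e1 = 1, e2 = 1, e3 = 1)
  res <- trim_pairs(pairs, p)
  expect_false(any(res$trimmed))
  expect_equal(res$validated_candidate, rep(50L, 10))
  bf <- brute_force_trim(pairs, p)
  expect_equal(bf$trimmed, res$trimmed)
  expect_equal(bf$insert_length, res$insert_length)
})

test_that("a singleton candidate set is accepted as-is unless strict mode validates it", {
  # distinct adapters make the singleton fail the adapter-equality check
  set.seed(21)
  pairs <- contaminated_pair(70, 31, adapter_set("distinct"))
  default <- trim_pairs(pairs)
  expect_true(default$trimmed)
  expect_equal(default$n_validated, 0L)       # shortcut: no stage-2 work
  strict <- trim_pairs(pairs, trimmer_params(strict_singleton = TRUE))
  expect_false(strict$trimmed)
  expect_equal(strict$n_validated, 1L)
})

test_that("short or length-mismatched pairs are passed through with a warning", {
  pairs <- pair_tbl(c("ACGT", "ACGTACGTACGT"), c("ACGT", "ACGTACGTA"))
  expect_warning(res <- trim_pairs(pairs, trimmer_params(L = 8)),
                 "skipped")
  expect_true(all(res$skipped))
  expect_false(any(res$trimmed))
  expect_equal(res$seq1, pairs$seq1)  # untouched
})

test_that("trimmed mates keep equal lengths and prefix qualities", {
  set.seed(31)
  params <- preset_params("MED", n_pairs = 400, seed = 31,
                          reference_length = 20000L)
  sim <- sim_in_memory(params)
  res <- trim_pairs(sim$pairs)
  cut <- res[res$trimmed, ]
  orig <- sim$pairs[match(cut$pair_id, sim$pairs$pair_id), ]
  expect_true(all(nchar(cut$seq1) == cut$insert_length))
  expect_true(all(nchar(cut$seq2) == cut$insert_length))
  expect_true(all(nchar(cut$qual1) == cut$insert_length))
  expect_equal(substr(orig$qual1, 1, cut$insert_length), cut$qual1)
  expect_equal(substr(orig$seq2, 1, cut$insert_length), cut$seq2)
})

test_that("stage-1 comparisons stay within the 2*L*N work bound", {
  set.seed(41)
  params <- preset_params("HED", n_pairs = 300, seed = 41,
                          reference_length = 20000L)
  sim <- sim_in_memory(params)
  res <- trim_pairs(sim$pairs)
  bound <- 2 * 30 * 101
  expect_true(all(res$comparisons[!res$skipped] <= bound))
  expect_true(all(res$comparisons > 0 | res$skipped))
})

test_that("fast scanning agrees with the exhaustive oracle across conditions", {
  set.seed(51)
  check_agree <- function(pairs, params) {
    fast <- suppressWarnings(trim_pairs(pairs, params))
    slow <- suppressWarnings(brute_force_trim(pairs, params))
    expect_equal(slow$trimmed, fast$trimmed)
    expect_equal(slow$insert_length, fast$insert_length)
    expect_equal(slow$candidates, fast$candidates)
    expect_equal(slow$skipped, fast$skipped)
  }
  # simulated reads under several presets and parameter settings
  for (preset in c("MED", "dHED", "MED-o")) {
    sim <- sim_in_memory(preset_params(preset, n_pairs = 200, seed = 52,
                                       reference_length = 20000L))
    check_agree(sim$pairs, trimmer_params())
    check_agree(sim$pairs, trimmer_params(e3 = 1))
    check_agree(sim$pairs, trimmer_params(strict_singleton = TRUE))
    check_agree(sim$pairs, trimmer_params(L = 20, e1 = 0.25, e2 = 0.5))
  }
  # short random reads where candidate sets are dense
  dense <- pair_tbl(random_seq(15, 50), random_seq(15, 50))
  check_agree(dense, trimmer_params(L = 5, e1 = 0.6, e2 = 0.8, e3 = 0.6))
  # reads containing N
  withN <- pair_tbl(gsub("A", "N", random_seq(40, 20)), random_seq(40, 20))
  check_agree(withN, trimmer_params(L = 10, e1 = 0.5))
})

test_that("error-free contaminated pairs are trimmed exactly at the junction", {
  set.seed(61)
  for (i in 1:50) {
    insert <- sample(30:100, 1)
    pairs <- contaminated_pair(insert, 101 - insert)
    res <- trim_pairs(pairs)
    expect_true(res$trimmed)
    expect_equal(res$insert_length, insert)
  }
})

test_that("glance summarizes a trimming run", {
  pairs <- pair_tbl(c("ACGTTGAGAT", "AAAAAAAAAA"),
                    c("CAACGTAGAT", "CCCCCCCCCC"))
  g <- glance(trim_pairs(pairs, trimmer_params(L = 4)))
  expect_equal(g$n_pairs, 2L)
  expect_equal(g$n_trimmed, 1L)
  expect_equal(g$trimmed_untrimmed_ratio, 1)
})
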