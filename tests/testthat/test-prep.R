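test_that("quality trimming is ends-in and matches the boundary oracle", {
  r <- mk_reads("ACGTA", phred_encode(c(10, 10, 40, 40, 10)))
  out <- quality_trim(r, 25)
  expect_identical(out$seq, "GT")
  expect_identical(phred_decode(out$qual)[[1]], c(40L, 40L))

  r <- mk_reads("ACGT", phred_encode(rep(40, 4)))
  expect_identical(quality_trim(r, 25)$seq, "ACGT")

  set.seed(5)
  for (i in 1:50) {
    q <- sample(0:41, sample(1:40, 1), TRUE)
    r <- mk_reads(rand_seq(length(q)), phred_encode(q))
    out <- quality_trim(r, 25)
    pass <- which(q >= 25)
    expected <- if (length(pass)) substr(r$seq, min(pass), max(pass)) else ""
    expect_identical(out$seq, expected)
  }
})

test_that("head trimming removes exactly n 5' bases", {
  r <- mk_reads(rand_seq(75))
  expect_identical(nchar(head_trim(r, 10)$seq), 65L)
  expect_identical(head_trim(mk_reads(rand_seq(8)), 10)$seq, "")
  r <- mk_reads("ACGTACGT")
  expect_identical(head_trim(r, 0)$seq, r$seq)
})

test_that("poly-A/T tails of length >= k are trimmed", {
  expect_identical(polyat_trim(mk_reads("ACGTAAAAAA"), 5)$seq, "ACGT")
  expect_identical(polyat_trim(mk_reads("ACGT"), 5)$seq, "ACGT")
  expect_identical(polyat_trim(mk_reads("TTTTTTACGT"), 5)$seq, "ACGT")
  expect_identical(polyat_trim(mk_reads("ACGTAAAA"), 5)$seq, "ACGTAAAA")
  out <- polyat_trim(mk_reads("TTTTTGCGCGAAAAA"), 5)
  expect_identical(out$seq, "GCGCG")
  expect_identical(nchar(out$qual), 5L)
})

test_that("duplicate reads are removed by exact sequence identity", {
  r <- mk_reads(c("ACGT", "ACGT", "TTTT"))
  expect_identical(dedupe_reads(r)$id, c("r001", "r003"))
  pairrc <- mk_reads(c("ACGTACGTAC", rc_oracle("ACGTACGTAC")))
  expect_identical(nrow(dedupe_reads(pairrc)), 2L)
  r <- mk_reads(c("AC", "GT", "CA"))
  expect_identical(nrow(dedupe_reads(r)), 3L)
})

test_that("DUST drops homopolymers, keeps diverse sequence, matches oracle", {
  homo <- strrep("A", 64)
  expect_false(dust_keep(mk_reads(homo), 7))
  set.seed(8)
  diverse <- rand_seq(64)
  expect_true(dust_keep(mk_reads(diverse), 7))
  for (i in 1:25) {
    s <- rand_seq(sample(10:120, 1))
    expect_equal(dust_score(s), dust_oracle(s), tolerance = 1e-12)
  }
  ## low-complexity dinucleotide repeat also scores high
  expect_gt(dust_score(strrep("AT", 40)), 7)
})

test_that("length and ambiguity filters use the stated boundaries", {
  expect_false(length_ambiguity_keep(mk_reads(rand_seq(49)), 50, 1))
  expect_true(length_ambiguity_keep(mk_reads(rand_seq(50)), 50, 1))
  s <- paste0(rand_seq(59), "N")
  expect_true(length_ambiguity_keep(mk_reads(s), 50, 1))
  s2 <- paste0(rand_seq(58), "NN")
  expect_false(length_ambiguity_keep(mk_reads(s2), 50, 1))
})

test_that("pair merging reconstructs fragments and honours quality", {
  set.seed(13)
  frag <- rand_seq(120)
  r1 <- mk_reads(substr(frag, 1, 75))
  r2 <- mk_reads(rc_oracle(substr(frag, 46, 120)))
  m <- merge_pairs(r1, r2, 10, 0.1)
  expect_identical(nrow(m$merged), 1L)
  expect_identical(m$merged$seq, frag)

  ## non-overlapping pair stays a pair
  a <- mk_reads(rand_seq(60)); b <- mk_reads(rand_seq(60))
  m2 <- merge_pairs(a, b, 10, 0.1)
  expect_identical(nrow(m2$merged), 0L)
  expect_identical(m2$r1$seq, a$seq)

  ## planted mismatch in a 30-bp overlap: higher-quality base wins
  frag <- rand_seq(120)
  left <- substr(frag, 1, 75)
  right <- substr(frag, 46, 120)
  pos_in_right <- 10L                       # overlap position 55 of fragment
  wrong <- setdiff(BASES, substr(right, pos_in_right, pos_in_right))[1]
  right_bad <- paste0(substr(right, 1, pos_in_right - 1), wrong,
                      substr(right, pos_in_right + 1, nchar(right)))
  q1 <- phred_encode(rep(20L, 75))          # mate 1 low quality
  q2 <- phred_encode(rep(40L, 75))          # mate 2 high quality
  m3 <- merge_pairs(mk_reads(left, q1), mk_reads(rc_oracle(right_bad), q2),
                    10, 0.1)
  expect_identical(nrow(m3$merged), 1L)
  expect_identical(substr(m3$merged$seq, 55, 55), wrong)
})

test_that("every filter after the head trim is idempotent", {
  set.seed(21)
  params <- prep_params()
  reads <- mk_reads(
    vapply(1:60, function(i) rand_seq(sample(40:120, 1)), ""))
  reads$seq[1:5] <- paste0(reads$seq[1:5], strrep("A", 8))
  reads$qual <- vapply(nchar(reads$seq), function(l)
    phred_encode(sample(5:41, l, TRUE)), "")
  q1 <- quality_trim(reads, params$phred_min)
  expect_identical(quality_trim(q1, params$phred_min), q1)
  p1 <- polyat_trim(reads, params$k_polyat)
  expect_identical(polyat_trim(p1, params$k_polyat), p1)
  keep <- dust_keep(reads, params$dust_threshold)
  expect_identical(dust_keep(reads[keep, ], params$dust_threshold),
                   rep(TRUE, sum(keep)))
  d1 <- dedupe_reads(reads)
  expect_identical(dedupe_reads(d1), d1)
})

test_that("rerunning the cascade on its own output changes nothing", {
  ## poly-A tails here carry good-quality bases, so tail removal cannot
  ## expose a fresh low-quality end (the one situation where the fixed
  ## quality-then-tail order is not a fixed point)
  set.seed(22)
  params <- prep_params()
  once <- function(reads) {
    reads <- quality_trim(reads, params$phred_min)
    reads <- polyat_trim(reads, params$k_polyat)
    reads <- reads[nchar(reads$seq) > 0, , drop = FALSE]
    reads <- reads[dust_keep(reads, params$dust_threshold), , drop = FALSE]
    reads <- reads[length_ambiguity_keep(reads, params$min_len,
                                         params$max_ambiguous), , drop = FALSE]
    dedupe_reads(reads)
  }
  seqs <- vapply(1:60, function(i) rand_seq(sample(60:120, 1)), "")
  seqs[1:8] <- paste0(seqs[1:8], strrep("A", 8))
  quals <- vapply(nchar(seqs) - 12L, function(l)
    paste0(phred_encode(sample(5:24, 6, TRUE)),
           phred_encode(sample(26:41, l, TRUE)),
           phred_encode(sample(26:41, 6, TRUE))), "")
  reads <- mk_reads(seqs, quals)
  one <- once(head_trim(reads, 10))
  two <- once(one)
  rownames(one) <- rownames(two) <- NULL
  expect_identical(two, one)
})

test_that("error-free good-quality reads survive prep minus duplicates", {
  set.seed(34)
  seqs <- unique(vapply(1:80, function(i) rand_seq(100), ""))
  reads <- mk_reads(seqs)
  out <- prep_reads(reads, params = prep_params(head_trim = 0))
  expect_identical(nrow(out$single), length(seqs))
})
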