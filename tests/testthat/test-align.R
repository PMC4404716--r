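test_that("local alignment handles identity and disjoint alphabets", {
  a <- local_align("ACGTACGT", "ACGTACGT")
  expect_identical(a$identity, 1)
  expect_identical(c(a$q0, a$q1, a$s0, a$s1), c(0L, 8L, 0L, 8L))
  b <- local_align("AAAA", "CCCC", align_params(match = 1, mismatch = -2))
  expect_identical(b$score, 0L)
})

test_that("local alignment equals the exhaustive DP oracle (<=50 symbols)", {
  set.seed(101)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:60) {
    a <- rand_seq(sample(5:50, 1))
    b <- rand_seq(sample(5:50, 1))
    oracle <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    expect_identical(local_align(a, b)$score,
                     as.integer(Biostrings::score(oracle)))
  }
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:30) {
    a <- rand_seq(sample(5:50, 1), aas)
    b <- rand_seq(sample(5:50, 1), aas)
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = e$BLOSUM62, gapOpening = 5, gapExtension = 2)
    expect_identical(local_align(a, b, align_params("protein"))$score,
                     as.integer(Biostrings::score(oracle)))
  }
})

test_that("search finds exact copies, reverse complements and planted subjects", {
  set.seed(7)
  db <- setNames(vapply(1:8, function(i) rand_seq(300), ""),
                 sprintf("db%02d", 1:8))
  hits <- search_db(setNames(db[3], "q"), db)
  expect_identical(hits$subject[1], "db03")
  expect_identical(hits$identity[1], 1)

  hits_rc <- search_db(setNames(rc_oracle(db[5]), "q"), db)
  expect_identical(hits_rc$subject[1], "db05")
  expect_identical(hits_rc$strand[1], "-")

  ## planted 90%-identity subject among random decoys is always the top hit
  for (i in 1:20) {
    target <- rand_seq(400)
    mut <- strsplit(target, "")[[1]]
    idx <- sample(400, 40)
    mut[idx] <- vapply(mut[idx], function(b) sample(setdiff(BASES, b), 1), "")
    db2 <- c(setNames(vapply(1:6, function(j) rand_seq(400), ""),
                      sprintf("decoy%d", 1:6)),
             planted = paste(mut, collapse = ""))
    top <- search_db(c(q = target), db2, align_params(preset = "loose"))
    expect_identical(top$subject[1], "planted")
  }
})

test_that("search is deterministic and respects max_hits", {
  set.seed(9)
  base <- rand_seq(200)
  db <- setNames(rep(base, 5), sprintf("s%d", 1:5))
  h1 <- search_db(c(q = base), db, align_params(max_hits = 3L))
  h2 <- search_db(c(q = base), db, align_params(max_hits = 3L))
  expect_identical(h1, h2)
  expect_identical(nrow(h1), 3L)
  expect_identical(h1$subject, c("s1", "s2", "s3"))  # ties by subject id
})

test_that("translated search finds proteins through frames and shifts", {
  set.seed(15)
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), unname(gc_tab))
  prot <- paste0("M", rand_seq(120, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  nt <- paste(vapply(strsplit(prot, "")[[1]],
                     function(a) sample(by_aa[[a]], 1), ""), collapse = "")
  db <- c(P1 = prot, P2 = rand_seq(100, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  hits <- translated_search(c(q = nt), db)
  expect_identical(hits$subject[1], "P1")
  expect_identical(hits$frame[1], 1L)

  hits2 <- translated_search(c(q = paste0("G", nt)), db)
  expect_identical(hits2$subject[1], "P1")
  expect_identical(hits2$frame[1], 2L)

  ## scores match the unseeded DP oracle on the translated frame
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  seg <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt))), "*", fixed = TRUE)[[1]][1]
  oracle <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seg), Biostrings::AAString(prot), type = "local",
    substitutionMatrix = e$BLOSUM62, gapOpening = 5, gapExtension = 2)
  expect_identical(hits$score[1], as.integer(Biostrings::score(oracle)))
})

test_that("read mapping assigns the contracted mapping qualities", {
  set.seed(23)
  ref <- c(t1 = rand_seq(500), t2 = rand_seq(500))
  read <- substr(ref[["t1"]], 101, 175)
  mp <- map_reads(c(r1 = read), ref)
  expect_identical(mp$alignments$mapq, 60L)
  expect_true(mp$alignments$pass)

  ## perfect ambiguity: two identical references
  ref2 <- c(a = ref[["t1"]], b = ref[["t1"]])
  mp2 <- map_reads(c(r1 = read), ref2)
  expect_identical(mp2$alignments$mapq, 0L)
  expect_false(mp2$alignments$pass)

  ## 85% paralog with diagnostic bases: confident despite the second hit
  target <- ref[["t1"]]
  mut <- strsplit(target, "")[[1]]
  idx <- sample(500, 75)
  mut[idx] <- vapply(mut[idx], function(b) sample(setdiff(BASES, b), 1), "")
  ref3 <- c(t1 = target, par = paste(mut, collapse = ""))
  read3 <- substr(target, 201, 275)
  ndiag <- sum(idx >= 201 & idx <= 275)
  mp3 <- map_reads(c(r1 = read3), ref3)
  expect_identical(mp3$alignments$subject_id, "t1")
  if (ndiag >= 2) expect_gt(mp3$alignments$mapq, 25L)
})

test_that("overlap assembly merges dovetails and preserves inputs", {
  set.seed(31)
  src <- rand_seq(400)
  seqs <- c(f1 = substr(src, 1, 250), f2 = substr(src, 201, 400))
  asm <- overlap_assemble(seqs)
  expect_identical(length(asm$contigs), 1L)
  expect_identical(unname(asm$contigs[1]), src)
  expect_identical(sort(asm$members$member), c("f1", "f2"))

  unrelated <- c(a = rand_seq(200), b = rand_seq(200))
  asm2 <- overlap_assemble(unrelated)
  expect_identical(length(asm2$contigs), 2L)
  expect_identical(sort(unname(asm2$contigs)), sort(unname(unrelated)))

  ## a reverse-complemented fragment still joins its mate
  seqs_rc <- c(f1 = substr(src, 1, 250), f2 = rc_oracle(substr(src, 201, 400)))
  asm3 <- overlap_assemble(seqs_rc)
  expect_identical(length(asm3$contigs), 1L)
  expect_true(unname(asm3$contigs[1]) %in% c(src, rc_oracle(src)))
})

test_that("tiling fragments reassemble the source at >=99.9% identity", {
  set.seed(37)
  gene <- rand_seq(1000)
  starts <- sort(sample(0:900, 18))
  frags <- setNames(substring(gene, starts + 1, pmin(starts + 150, 1000)),
                    sprintf("f%02d", seq_along(starts)))
  frags <- c(frags, f99 = substr(gene, 851, 1000))
  asm <- overlap_assemble(frags)
  best <- asm$contigs[which.max(nchar(asm$contigs))]
  aln <- local_align(unname(best), gene)
  expect_gte(aln$identity, 0.999)
  ## no contig is shorter than its longest member
  for (ctg in names(asm$contigs)) {
    mem <- asm$members$member[asm$members$contig == ctg]
    expect_gte(nchar(asm$contigs[[ctg]]), max(nchar(frags[mem])))
  }
})
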