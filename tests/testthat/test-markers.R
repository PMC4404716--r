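## minimal call rows and a clean reference for cascade unit tests
mk_calls <- function(pos, ref, alt, transcript = "t0001",
                     snp_id = sprintf("K_1_%d", seq_along(pos))) {
  data.frame(transcript = transcript, pos = as.integer(pos), ref = ref,
             alt = alt, snp_id = snp_id, stringsAsFactors = FALSE)
}
no_vars <- data.frame(transcript = character(0), pos = integer(0),
                      type = character(0), stringsAsFactors = FALSE)

test_that("context extraction enforces clean 35-nt flanks", {
  set.seed(61)
  ref <- c(t0001 = rand_seq(100))
  calls <- mk_calls(40, substr(ref, 41, 41), "G")
  st <- extract_context(calls, ref, no_vars, 35)
  expect_identical(nrow(st$candidates), 1L)
  expect_identical(nchar(st$candidates$context), 71L)
  expect_identical(substr(st$candidates$context, 36, 36),
                   as.character(substr(ref, 41, 41)))

  edge <- extract_context(mk_calls(20, "A", "G"), ref, no_vars, 35)
  expect_identical(edge$rejected$reason, "transcript_edge")

  vars <- data.frame(transcript = "t0001", pos = c(40L, 50L),
                     type = "snp", stringsAsFactors = FALSE)
  near <- extract_context(mk_calls(40, "A", "G"), ref, vars, 35)
  expect_identical(near$rejected$reason, "variant_in_window")

  refN <- c(t0001 = paste0(substr(ref, 1, 59), "N", substr(ref, 61, 100)))
  amb <- extract_context(mk_calls(40, "A", "G"), refN, no_vars, 35)
  expect_identical(amb$rejected$reason, "ambiguous_base")
})

test_that("allele screen classifies and rejects strand-ambiguous SNPs", {
  cand <- mk_calls(1:3, c("C", "A", "A"), c("T", "T", "C"))
  st <- classify_and_screen_alleles(cand)
  expect_identical(st$candidates$snp_class, c("transition", "transversion"))
  expect_identical(st$rejected$snp_id, "K_1_2")
  cg <- classify_and_screen_alleles(mk_calls(1, "C", "G"))
  expect_identical(nrow(cg$candidates), 0L)
})

test_that("paralog filter discards transcripts with a second self-hit", {
  set.seed(67)
  uniq <- rand_seq(600)
  src <- rand_seq(600)
  par <- strsplit(src, "")[[1]]
  idx <- sample(600, 48)                     # 92% identity partner
  par[idx] <- vapply(par[idx], function(b) sample(setdiff(BASES, b), 1), "")
  ref <- c(t0001 = uniq, t0002 = src, t0003 = paste(par, collapse = ""))
  cands <- rbind(mk_calls(100, "A", "G", "t0001", "K_1_1"),
                 mk_calls(100, "A", "G", "t0002", "K_2_1"))
  st <- paralog_filter(cands, ref)
  expect_identical(st$candidates$snp_id, "K_1_1")
  expect_identical(st$rejected$snp_id, "K_2_1")

  ## transcript absent from the db: 0 hits, pass with warning
  expect_warning(
    st2 <- paralog_filter(mk_calls(100, "A", "G", "missing", "K_9_1"), ref),
    "absent")
  expect_identical(nrow(st2$candidates), 1L)
})

test_that("chloroplast screen removes organellar contexts only", {
  set.seed(71)
  chloro <- c(chloroplast = rand_seq(3000))
  cand <- mk_calls(1:2, "A", "G")
  cand$context <- c(substr(chloro, 501, 571), rand_seq(71))
  st <- chloroplast_screen(cand, chloro)
  expect_identical(st$rejected$snp_id, "K_1_1")
  expect_identical(st$candidates$snp_id, "K_1_2")

  st2 <- chloroplast_screen(cand, character(0))
  expect_identical(nrow(st2$candidates), 2L)
})

test_that("splice screen fails junction-spanning contexts at the 68-bp rule", {
  expect_identical(filter_params(flank = 35)$splice_min_match, 68L)
  expect_identical(filter_params(flank = 40)$splice_min_match, 77L)

  set.seed(73)
  exon1 <- rand_seq(200); exon2 <- rand_seq(200); intron <- rand_seq(150)
  genome <- c(sca = paste0(exon1, intron, exon2))
  transcript <- paste0(exon1, exon2)
  inside <- substr(transcript, 81, 151)       # fully inside exon 1
  spanning <- substr(transcript, 161, 231)    # 40 bases exon1 + 31 exon2
  cand <- mk_calls(1:2, "A", "G")
  cand$context <- c(inside, spanning)
  st <- splice_junction_screen(cand, genome)
  expect_identical(st$candidates$snp_id, "K_1_1")
  expect_identical(st$rejected$snp_id, "K_1_2")

  ## no genomic hit at all passes
  st2 <- splice_junction_screen(cand, c(sca = rand_seq(500)))
  expect_identical(nrow(st2$candidates), 2L)
})

test_that("cross-set dedup keeps the highest-priority copy", {
  set.seed(79)
  ctx <- rand_seq(71)
  cand <- rbind(
    data.frame(snp_id = "K_1_1", set = "K", context = ctx, alleles = "A/G",
               stringsAsFactors = FALSE),
    data.frame(snp_id = "G_1_1", set = "G", context = ctx, alleles = "A/G",
               stringsAsFactors = FALSE),
    data.frame(snp_id = "M_1_1", set = "M", context = rc_oracle(ctx),
               alleles = "C/T", stringsAsFactors = FALSE),
    data.frame(snp_id = "D_1_1", set = "D", context = rand_seq(71),
               alleles = "A/C", stringsAsFactors = FALSE))
  st <- cross_set_dedup(cand, c("K", "G", "M", "D"))
  expect_setequal(st$candidates$snp_id, c("K_1_1", "D_1_1"))
  expect_setequal(st$rejected$snp_id, c("G_1_1", "M_1_1"))

  disjoint <- cand[c(1, 4), ]
  st2 <- cross_set_dedup(disjoint, c("K", "G", "M", "D"))
  expect_identical(nrow(st2$candidates), 2L)
})

test_that("probe-similarity screen drops one of a near-identical pair", {
  set.seed(83)
  ctx <- rand_seq(71)
  near <- paste0(substr(ctx, 1, 30),
                 setdiff(BASES, substr(ctx, 31, 31))[1],
                 substr(ctx, 32, 71))
  cand <- data.frame(snp_id = c("K_1_1", "K_2_1", "K_3_1"),
                     set = "K",
                     context = c(ctx, near, rand_seq(71)),
                     alleles = "A/G", stringsAsFactors = FALSE)
  st <- probe_similarity_screen(cand, "K")
  expect_identical(st$rejected$snp_id, "K_2_1")
  expect_setequal(st$candidates$snp_id, c("K_1_1", "K_3_1"))

  rand_only <- cand[3, , drop = FALSE]
  st2 <- probe_similarity_screen(rand_only, "K")
  expect_identical(nrow(st2$rejected), 0L)
})

test_that("the array carries two probes per SNP and a sorted manifest", {
  set.seed(89)
  markers <- data.frame(
    snp_id = c("K_17_2", "K_3_1", "G_5_4"),
    transcript = c("t0017", "t0003", "t0005"),
    ref = "A", alt = "G", alleles = "A/G",
    context = vapply(1:3, function(i) rand_seq(71), ""),
    stringsAsFactors = FALSE)
  markers$context_bracket <- paste0(substr(markers$context, 1, 35), "[A/G]",
                                    substr(markers$context, 37, 71))
  arr <- build_array(markers)
  expect_identical(nrow(arr$probes), 6L)
  expect_identical(arr$manifest$snp_id, c("G_5_4", "K_17_2", "K_3_1"))
  expect_true(all(grepl("^[A-Z]_\\d+_\\d+$", arr$manifest$snp_id)))
  fwd <- arr$probes$seq[arr$probes$strand == "+"]
  rev <- arr$probes$seq[arr$probes$strand == "-"]
  expect_identical(rev, rc_oracle(fwd))

  empty <- build_array(markers[0, ])
  expect_identical(nrow(empty$manifest), 0L)
  expect_identical(nrow(empty$probes), 0L)
})

test_that("the full cascade logs every SNP exactly once", {
  set.seed(97)
  ref <- c(t0001 = rand_seq(300), t0002 = rand_seq(300))
  calls <- rbind(
    mk_calls(100, substr(ref[["t0001"]], 101, 101),
             setdiff(BASES, substr(ref[["t0001"]], 101, 101))[1],
             "t0001", "K_1_1"),
    mk_calls(10, "A", "G", "t0001", "K_1_2"),          # edge reject
    mk_calls(150, "C", "G", "t0002", "K_2_1"))          # strand-ambiguous
  sets <- list(K = list(calls = calls, reference = ref, variants = no_vars))
  des <- design_markers(sets)
  ids <- c(des$manifest$snp_id, des$rejections$snp_id)
  expect_setequal(ids, calls$snp_id)
  expect_identical(anyDuplicated(ids), 0L)
  expect_false(any(des$manifest$alleles %in% c("A/T", "T/A", "C/G", "G/C")))
})
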