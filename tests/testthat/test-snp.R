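## helper: pileup count matrix from explicit per-position base lists
counts_at <- function(len, spec) {
  m <- matrix(0L, 6, len)
  rownames(m) <- c("A", "C", "G", "T", "N", "-")
  for (p in names(spec)) for (b in names(spec[[p]]))
    m[b, as.integer(p) + 1L] <- spec[[p]][[b]]
  m
}

test_that("candidate sites need two alleles at the per-allele read floor", {
  m <- counts_at(10, list(`4` = list(A = 5L, G = 5L)))
  expect_identical(call_candidates(m, 5L), 4L)
  m2 <- counts_at(10, list(`4` = list(A = 100L, G = 4L)))
  expect_identical(length(call_candidates(m2, 5L)), 0L)
  ## ambiguous base counts never create a candidate
  m3 <- counts_at(10, list(`4` = list(A = 5L, G = 5L, N = 3L),
                           `7` = list(C = 9L, N = 9L)))
  expect_identical(call_candidates(m3, 5L), 4L)
})

test_that("haplotype clustering recovers planted haplotypes", {
  ## two haplotypes over three linked sites, 20 error-free reads each
  h1 <- c("A", "C", "G"); h2 <- c("G", "T", "G")
  am <- rbind(matrix(rep(h1, 20), ncol = 3, byrow = TRUE),
              matrix(rep(h2, 20), ncol = 3, byrow = TRUE))
  cl <- cluster_haplotypes(am, 0.8)
  expect_identical(length(cl), 2L)
  expect_identical(attr(cl, "n_hap_max"), 2L)
  cons <- lapply(cl, function(x) unname(x$consensus))
  expect_true(any(vapply(cons, identical, TRUE, h1)))
  expect_true(any(vapply(cons, identical, TRUE, h2)))

  ## all reads identical: one cluster
  am2 <- matrix(rep(c("A", "C"), 30), ncol = 2, byrow = TRUE)
  expect_identical(length(cluster_haplotypes(am2, 0.8)), 1L)

  ## sim_min = 1 with one erroneous read: the error read is a discarded
  ## singleton
  am3 <- rbind(matrix(rep(h1, 10), ncol = 3, byrow = TRUE),
               matrix(c("A", "T", "G"), ncol = 3))
  cl3 <- cluster_haplotypes(am3, 1.0)
  expect_identical(length(cl3), 1L)
  expect_identical(attr(cl3, "n_noise"), 1L)
})

test_that("unlinked site blocks do not inflate the haplotype count", {
  ## two independent blocks of two haplotypes each: reads never span both
  am <- matrix("", 40, 2)
  am[1:10, 1] <- "A"; am[11:20, 1] <- "G"
  am[21:30, 2] <- "C"; am[31:40, 2] <- "T"
  cl <- cluster_haplotypes(am, 0.8)
  expect_identical(length(cl), 4L)          # four clusters in total
  expect_identical(attr(cl, "n_hap_max"), 2L)  # but two per linkage block
})

test_that("the ploidy ceiling is applied at the stated boundary", {
  pm <- ploidy_model(4, 2)
  expect_identical(pm$max_haplotypes, 8L)
  expect_false(filter_by_ploidy(9L, pm))
  expect_true(filter_by_ploidy(8L, pm))
  expect_false(filter_by_ploidy(3L, ploidy_model(2, 1)))
})

test_that("reliable calls require depth and haplotype support end to end", {
  set.seed(47)
  ref <- rand_seq(400)
  hap1 <- ref
  alt <- setdiff(BASES, substr(ref, 201, 201))[1]
  hap2 <- paste0(substr(ref, 1, 200), alt, substr(ref, 202, 400))
  mk <- function(hap, n, id0) {
    starts <- floor(seq(0, 325, length.out = n))
    mk_reads(substring(hap, starts + 1, starts + 75),
             ids = sprintf("%s%03d", id0, 1:n))
  }
  reads <- rbind(mk(hap1, 60, "a"), mk(hap2, 60, "b"))
  out <- call_snps(reads, c(t1 = ref), ploidy_model(4, 2))
  expect_identical(nrow(out$calls), 1L)
  expect_identical(out$calls$pos, 200L)
  expect_setequal(c(out$calls$ref, out$calls$alt),
                  c(substr(ref, 201, 201), alt))
  expect_true(out$calls$reliable)

  ## an allele backed by only 4 reads (all covering the site) is never
  ## reliable
  alt4 <- mk_reads(substring(hap2, c(161, 171, 181, 191),
                             c(235, 245, 255, 265)),
                   ids = sprintf("b%03d", 1:4))
  out4 <- call_snps(rbind(mk(hap1, 60, "a"), alt4), c(t1 = ref),
                    ploidy_model(4, 2))
  expect_identical(nrow(out4$calls), 0L)
})

test_that("a paralog-collapsed contig exceeds the ceiling and is dropped", {
  set.seed(53)
  ## one reference contig carrying two recently duplicated gene copies
  ## (the near-identical case a 97%-overlap assembler genuinely merges),
  ## five haplotypes each: more haplotypes covering the variant sites
  ## than two pooled tetraploid parents can display
  ref <- rand_seq(300)
  v <- strsplit(ref, "")[[1]]
  flip <- function(chars, pos) {
    chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(BASES, b), 1), "")
    chars
  }
  par_sites <- c(61, 71, 76)                # fixed copy-B differences
  a_sites <- seq(81, 131, by = 10)          # within-copy haplotype sites
  b_sites <- seq(86, 136, by = 10)
  ## five patterns with pairwise Hamming distance >= 3, so profiles stay
  ## below the 0.8 merge similarity over the ~15 shared candidate sites
  pats <- list(c(), c(1, 2, 3), c(1, 4, 5), c(2, 4, 6), c(3, 5, 6))
  copies <- list()
  for (p in seq_along(pats)) {
    a <- flip(v, a_sites[pats[[p]]])
    b <- flip(flip(v, par_sites), b_sites[pats[[p]]])
    copies[[p]] <- paste(a, collapse = "")
    copies[[5 + p]] <- paste(b, collapse = "")
  }
  reads <- do.call(rbind, lapply(seq_along(copies), function(i) {
    starts <- floor(seq(0, 55, length.out = 25))
    mk_reads(substring(copies[[i]], starts + 1, starts + 200),
             ids = sprintf("c%d_%03d", i, 1:25))
  }))
  out <- call_snps(reads, c(t1 = ref), ploidy_model(4, 2),
                   params = snp_params(), align = align_params())
  expect_identical(nrow(out$calls), 0L)
  expect_gt(nrow(out$candidates), 0L)
  expect_true(all(out$candidates$reason == "haplotype_ceiling"))
})

test_that("snp statistics report density, transitions and the histogram", {
  stats_in <- data.frame(transcript = c("t1", "t2"), length = c(1000L, 500L),
                         n_reads = c(100L, 50L), mean_depth = c(30, 20),
                         n_clusters = c(4L, 2L), ceiling_ok = TRUE,
                         n_reliable = c(5L, 0L), stringsAsFactors = FALSE)
  calls <- data.frame(transcript = "t1", pos = 1:5 * 10L,
                      ref = c("C", "A", "A", "C", "G"),
                      alt = c("T", "G", "C", "A", "T"),
                      stringsAsFactors = FALSE)
  st <- snp_stats(calls, stats_in)
  expect_identical(st$per_transcript$density, 0.5)
  expect_identical(st$summary$n_transcripts, 1L)
  expect_identical(st$summary$transition_fraction, 2 / 5)
  expect_identical(st$histogram$n_snps, 5L)
})

test_that("marker ids follow the set_transcript_snp scheme", {
  ref <- c(t0001 = strrep("A", 100), t0017 = strrep("C", 100))
  calls <- data.frame(transcript = c("t0017", "t0017", "t0001"),
                      pos = c(50L, 20L, 10L), stringsAsFactors = FALSE)
  out <- assign_snp_ids(calls, ref, "K")
  expect_identical(out$snp_id, c("K_1_1", "K_2_1", "K_2_2"))
  expect_identical(out$snp_id[out$transcript == "t0017" & out$pos == 20L],
                   "K_2_1")
})
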