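small_sim <- function(...) {
  sim_params(n_genes = 8, n_chloro = 2, n_contaminants = 2,
             n_singletons = 1, seed = 11, ...)
}

test_that("truth generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_truth(small_sim(), dir = d1)
  make_truth(small_sim(), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("degenerate transition fraction plants only C/T and G/A SNPs", {
  truth <- make_truth(small_sim(transition_fraction = 1.0))
  pairs <- paste0(pmin(truth$snps$ref, truth$snps$alt),
                  pmax(truth$snps$ref, truth$snps$alt))
  expect_true(all(pairs %in% c("AG", "CT")))
  expect_true(all(truth$snps$transition))
})

test_that("planted SNP count stays within the binomial 99% interval", {
  truth <- make_truth(sim_params(n_genes = 60, gene_len_mean = 1000,
                                 gene_len_sd = 1e-6, n_chloro = 0,
                                 n_contaminants = 0, n_singletons = 0,
                                 paralog_fraction = 0, seed = 19))
  total_len <- sum(truth$genes$length)
  n <- sum(truth$snps$origin == "nuclear")
  p <- truth$params$snp_density
  bounds <- qbinom(c(0.005, 0.995), total_len, p)
  expect_gte(n, bounds[1])
  expect_lte(n, bounds[2])
  ## planted transition fraction lands within 5 pp of the target
  expect_lt(abs(mean(truth$snps$transition) - 0.60), 0.05)
})

test_that("haplotype structure respects the ploidy bound and the truth table", {
  truth <- tiny_truth()
  ## each individual has exactly ploidy haplotypes per expressed gene
  for (ind in truth$individuals) {
    for (g in truth$genes$gene[grepl(ind, truth$genes$expressed)]) {
      ids <- sprintf("%s|%s|h%d", ind, g, seq_len(truth$params$ploidy))
      expect_true(all(ids %in% names(truth$haplotypes)))
    }
  }
  ## truth round-trip: exhaustively diffing pooled haplotypes recovers the
  ## planted SNP table (brute-force oracle)
  for (g in truth$genes$gene[1:4]) {
    haps <- truth$haplotypes[grepl(paste0("\\|", g, "\\|"),
                                   names(truth$haplotypes))]
    mat <- do.call(rbind, strsplit(unname(haps), ""))
    poly <- which(apply(mat, 2, function(col) length(unique(col)) > 1))
    planted <- truth$snps[truth$snps$gene == g, ]
    expect_setequal(poly - 1L, planted$pos)
    for (r in seq_len(nrow(planted))) {
      col <- mat[, planted$pos[r] + 1L]
      expect_setequal(unique(col), c(planted$ref[r], planted$alt[r]))
      expect_identical(sum(col == planted$alt[r]),
                       as.integer(planted$dosage[r]))
    }
  }
})

test_that("error-free reads are exact substrings of their source unit", {
  truth <- tiny_truth()
  reads <- simulate_reads(truth, small_sim(read_error_rate = 0, coverage = 2))
  ind <- truth$individuals[1]
  r1 <- reads[[ind]]$r1; org <- reads[[ind]]$origin
  units <- setNames(truth$units$seq, truth$units$unit)
  take <- sample(nrow(r1), 50)
  for (i in take) {
    u <- units[[org$unit[i]]]
    hit <- grepl(r1$seq[i], u, fixed = TRUE) ||
      grepl(r1$seq[i], rc_oracle(u), fixed = TRUE)
    expect_true(hit, info = r1$id[i])
  }
})

test_that("read counts follow the coverage expectation within 3 sigma", {
  truth <- tiny_truth()
  cov <- 5
  reads <- simulate_reads(truth, small_sim(coverage = cov))
  for (ind in truth$individuals) {
    u <- truth$units[truth$units$individual == ind, ]
    expected <- sum(round(u$weight * cov * nchar(u$seq) /
                            (2 * truth$params$read_len)))
    n <- nrow(reads[[ind]]$r1)
    expect_lt(abs(n - expected), 3 * sqrt(expected) + 1)
  }
})

test_that("read simulation is byte-identical under a fixed seed", {
  truth <- tiny_truth()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_reads(truth, small_sim(coverage = 2), dir = d1)
  simulate_reads(truth, small_sim(coverage = 2), dir = d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
})

test_that("every planted SNP has read support for both alleles at 20x", {
  truth <- tiny_truth()
  reads <- simulate_reads(truth, small_sim(coverage = 20, read_error_rate = 0))
  org <- do.call(rbind, lapply(truth$individuals,
                               function(i) reads[[i]]$origin))
  ## per-unit coverage at planted positions: fragment spans [start,
  ## start+frag_len) on the unit
  snps <- truth$snps[truth$snps$origin == "nuclear", ]
  snps <- snps[sample(nrow(snps), min(40, nrow(snps))), ]
  units <- truth$units
  miss <- 0L
  for (r in seq_len(nrow(snps))) {
    gu <- units[units$gene == snps$gene[r] &
                  grepl("\\|h\\d$", units$unit), ]
    hap_seqs <- truth$haplotypes[gu$unit]
    carries_alt <- substr(hap_seqs, snps$pos[r] + 1, snps$pos[r] + 1) ==
      snps$alt[r]
    for (allele_units in list(gu$unit[carries_alt], gu$unit[!carries_alt])) {
      o <- org[org$unit %in% allele_units, ]
      covered <- sum(o$start <= snps$pos[r] &
                       o$start + o$frag_len > snps$pos[r])
      if (covered < 1) miss <- miss + 1L
    }
  }
  expect_lte(miss, 1L)
})

test_that("the long-read regime produces indel-bearing single-end reads", {
  truth <- make_truth(small_sim(regime = "long"))
  reads <- simulate_reads(truth, small_sim(regime = "long", coverage = 3))
  ind <- truth$individuals[1]
  expect_null(reads[[ind]]$r2)
  lens <- nchar(reads[[ind]]$r1$seq)
  expect_gt(mean(lens), 250)
  ## indel errors shift read lengths away from the sampled fragment length
  org <- reads[[ind]]$origin
  expect_gt(sd(lens - org$frag_len), 0)
})
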