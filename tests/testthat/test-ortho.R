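AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

back_translate <- function(prot) {
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), unname(gc_tab))
  paste(vapply(strsplit(prot, "")[[1]], function(a) sample(by_aa[[a]], 1), ""),
        collapse = "")
}

test_that("longest ORF handles the hand-checkable cases", {
  orf <- longest_orf("ATGAAATAG")
  expect_identical(c(orf$start, orf$end), c(0L, 9L))
  expect_identical(orf$protein, "MK")

  orf2 <- longest_orf("CCCATGAAATAGCCC")
  expect_identical(c(orf2$start, orf2$end), c(3L, 12L))
  expect_identical(orf2$nt, "ATGAAATAG")

  expect_null(longest_orf("CCCCCCCCC"))
  ## ORF on the minus strand is found and reported in input coordinates
  orf3 <- longest_orf(rc_oracle("CCCATGAAAGGGTAGCCC"))
  expect_identical(orf3$strand, "-")
  expect_identical(orf3$protein, "MKG")
})

test_that("longest ORF equals the exhaustive span enumeration (<=200 nt)", {
  set.seed(103)
  for (i in 1:60) {
    s <- rand_seq(sample(30:200, 1))
    mine <- longest_orf(s)
    oracle <- orf_oracle(s)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      expect_identical(nchar(mine$nt), oracle$len)
    }
  }
})

test_that("grouping assigns transcripts to their best guide protein", {
  set.seed(107)
  prots <- setNames(vapply(1:4, function(i)
    paste0("M", rand_seq(130, AAS)), ""), sprintf("FV%05d", 1:4))
  tx <- c(x1 = back_translate(prots[[2]]),
          x2 = back_translate(prots[[2]]),
          noise = rand_seq(400))
  gg <- group_by_guide(tx, prots)
  expect_identical(names(gg$groups), "FV00002")
  expect_setequal(gg$groups$FV00002, c("x1", "x2"))
  expect_identical(gg$unassigned, "noise")
})

test_that("within-group assembly and reciprocal checks behave as contracted", {
  set.seed(109)
  src <- rand_seq(600)
  frags <- c(a = substr(src, 1, 350), b = substr(src, 291, 600))
  asm <- assemble_group(frags)
  expect_identical(unname(asm$contigs[1]), src)
  apart <- assemble_group(c(a = substr(src, 1, 200), b = substr(src, 401, 600)))
  expect_identical(length(apart$contigs), 2L)

  prot <- paste0("M", rand_seq(150, AAS))
  decoy <- strsplit(prot, "")[[1]]
  idx <- sample(151, 45)                     # ~70% identity paralog protein
  decoy[idx] <- vapply(decoy[idx], function(a) sample(setdiff(AAS, a), 1), "")
  prots <- c(P = prot, Pprime = paste(decoy, collapse = ""))
  contig <- back_translate(prot)
  expect_true(reciprocal_check(c(ctg = contig), prots, "P"))
  expect_false(reciprocal_check(c(ctg = contig), prots, "Pprime"))
  expect_true(reciprocal_check(c(ctg = contig), prots["P"], "P"))
})

test_that("trimmed reassembly names finals and flags full length", {
  set.seed(113)
  prot <- paste0("M", rand_seq(160, AAS))
  cds <- paste0(back_translate(prot), "TAA")
  finals <- reassemble_trimmed(c(o1 = cds, o2 = cds), "FV00007")
  expect_identical(names(finals), "FV00007.m1")
  expect_identical(unname(finals[1]), cds)

  expect_true(call_full_length(cds, prot))
  expect_false(call_full_length(substr(cds, 4, nchar(cds)), prot))  # no ATG
  short <- paste0("ATG", substr(cds, 154, nchar(cds)))  # tiny tail of the CDS
  expect_false(call_full_length(short, prot))
})

test_that("annotation join copies text and rejects duplicate keys", {
  rep0 <- data.frame(rhfv = c("FV1.m1", "FV2.m1"), guide = c("FV1", "FV2"),
                     stringsAsFactors = FALSE)
  ann <- data.frame(protein = "FV1", annotation = "putative kinase",
                    stringsAsFactors = FALSE)
  out <- annotate_orthologs(rep0, ann)
  expect_identical(out$annotation, c("putative kinase", ""))
  dup <- rbind(ann, ann)
  expect_error(annotate_orthologs(rep0, dup), "duplicate key")
})

test_that("ortholog assembly discards singletons and recovers planted genes", {
  set.seed(127)
  prots <- setNames(vapply(1:3, function(i)
    paste0("M", rand_seq(140, AAS)), ""), sprintf("FV%05d", 1:3))
  cds1 <- paste0(back_translate(prots[[1]]), "TAA")
  full1 <- paste0(rand_seq(40), cds1, rand_seq(60))
  tx <- c(`i1|g1|f1` = substr(full1, 1, 300),
          `i2|g1|f1` = substr(full1, 251, nchar(full1)),
          `i1|g2|f1` = back_translate(prots[[2]]))  # singleton group
  res <- ortholog_assembly(tx, prots)
  expect_identical(names(res$sequences), "FV00001.m1")
  expect_true(res$report$full_length)
  expect_identical(res$report$n_members, 2L)
  expect_true("FV00002" %in% res$dropped$guide)
  expect_identical(res$dropped$reason[res$dropped$guide == "FV00002"],
                   "singleton")
  ## the final sequence's reciprocal top hit is its guide
  expect_true(reciprocal_check(res$sequences["FV00001.m1"], prots, "FV00001"))
})
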