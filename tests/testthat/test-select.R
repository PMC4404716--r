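test_that("component grouping follows shared multi-mapped reads", {
  tr <- c(t1 = "A", t2 = "A", t3 = "A")   # ids only; hits drive grouping
  no_share <- data.frame(query = c("r1", "r2", "r3"),
                         subject = c("t1", "t2", "t3"),
                         score = c(10L, 10L, 10L), stringsAsFactors = FALSE)
  comp <- build_components(tr, no_share)
  expect_identical(length(unique(comp$component)), 3L)

  share <- rbind(no_share,
                 data.frame(query = "r4", subject = c("t1", "t2"),
                            score = 20L, stringsAsFactors = FALSE))
  comp2 <- build_components(tr, share)
  expect_identical(comp2$component[comp2$transcript == "t1"],
                   comp2$component[comp2$transcript == "t2"])
  expect_false(comp2$component[comp2$transcript == "t3"] ==
                 comp2$component[comp2$transcript == "t1"])
})

test_that("component grouping equals the brute-force union-find oracle", {
  set.seed(41)
  for (trial in 1:15) {
    n <- sample(4:12, 1)
    ids <- sprintf("t%02d", 1:n)
    tr <- setNames(rep("A", n), ids)
    hit_rows <- list()
    edges <- data.frame(from = character(0), to = character(0))
    for (r in 1:sample(3:10, 1)) {
      targets <- sample(ids, sample(1:3, 1))
      hit_rows[[r]] <- data.frame(query = sprintf("r%02d", r),
                                  subject = targets, score = 50L,
                                  stringsAsFactors = FALSE)
      if (length(targets) > 1) {
        st <- sort(targets)
        edges <- rbind(edges, data.frame(from = st[-length(st)], to = st[-1]))
      }
    }
    hits <- do.call(rbind, hit_rows)
    comp <- build_components(tr, hits)
    oracle <- uf_oracle(ids, edges)
    ## same partition: equal label co-membership
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_identical(comp$component[i] == comp$component[j],
                       unname(oracle[i] == oracle[j]))
    }
  }
})

test_that("IsoPct filter uses strict <1% and keeps the top isoform", {
  comp <- data.frame(transcript = c("big", "small"), component = 1L,
                     stringsAsFactors = FALSE)
  lens <- c(big = 1000L, small = 500L)
  ## 10 of 1000 reads is exactly 1.0% - survives the <1% drop, then loses
  ## as non-top
  tab <- isopct_filter(comp, c(big = 990, small = 10), lens)
  expect_identical(tab$reason[tab$transcript == "small"], "not_top_isoform")
  expect_identical(tab$iso_pct[tab$transcript == "small"], 1)
  ## without the top-isoform rule the boundary case is retained
  tab_noTop <- isopct_filter(comp, c(big = 990, small = 10), lens,
                             keep_top = FALSE)
  expect_true(all(tab_noTop$retained))

  tab2 <- isopct_filter(comp, c(big = 995, small = 5), lens)
  expect_identical(tab2$reason[tab2$transcript == "small"], "isopct")

  single <- isopct_filter(data.frame(transcript = "only", component = 1L),
                          c(only = 3), c(only = 100L))
  expect_true(single$retained)
})

test_that("isopct retention is monotone in read count", {
  comp <- data.frame(transcript = c("a", "b", "c"), component = 1L,
                     stringsAsFactors = FALSE)
  lens <- c(a = 900L, b = 800L, c = 700L)
  base <- c(a = 500, b = 300, c = 3)
  t1 <- isopct_filter(comp, base, lens)
  expect_false(t1$retained[t1$transcript == "c"])
  raised <- base; raised["a"] <- 900
  t2 <- isopct_filter(comp, raised, lens)
  expect_true(t2$retained[t2$transcript == "a"])
  expect_lte(sum(t2$retained), 1L)  # at most one transcript per component
})

test_that("contaminant screen flags back-translations, spares the rest", {
  set.seed(43)
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), unname(gc_tab))
  prot <- paste0("M", rand_seq(150, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  nt <- paste(vapply(strsplit(prot, "")[[1]],
                     function(a) sample(by_aa[[a]], 1), ""), collapse = "")
  tx <- c(fungal = nt, plant = rand_seq(450))
  cs <- contaminant_screen(tx, c(FP1 = prot))
  expect_identical(cs$flagged$transcript, "fungal")
  expect_identical(names(cs$clean), "plant")
  expect_gte(cs$mean_identity, 0.99)

  cs2 <- contaminant_screen(tx, character(0))
  expect_identical(length(cs2$clean), 2L)
  expect_identical(nrow(cs2$flagged), 0L)
})
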