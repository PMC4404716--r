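# Shared fixtures: random sequences, tiny read sets, and brute-force
# oracles kept independent of the implementation paths they check.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mk_reads <- function(seqs, qual = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  if (is.null(qual)) qual <- vapply(nchar(seqs), function(l) strrep("I", l), "")
  data.frame(id = ids, seq = seqs, qual = qual, meta = "",
             stringsAsFactors = FALSE)
}

## revcomp without touching the package kernel
rc_oracle <- function(s) {
  chartr("ACGT", "TGCA", vapply(strsplit(s, NULL), function(v)
    paste(rev(v), collapse = ""), ""))
}

## exhaustive longest-ORF oracle: scan every frame of both strands codon by
## codon, collect every ATG..stop span, return the longest (frame order
## +1,+2,+3,-1,-2,-3, then smallest start, as tie-breaks)
orf_oracle <- function(seq, require_atg = TRUE) {
  gc_tab <- Biostrings::GENETIC_CODE
  best <- NULL
  strands <- list(`+` = seq, `-` = rc_oracle(seq))
  for (sdx in 1:2) {
    s <- strands[[sdx]]
    for (off in 0:2) {
      codons <- substring(s, seq(off + 1, nchar(s) - 2, by = 3),
                          seq(off + 3, nchar(s), by = 3))
      if (!length(codons)) next
      aa <- unname(gc_tab[codons])
      aa[is.na(aa)] <- "X"
      starts <- if (require_atg) which(codons == "ATG") else
        c(1L, which(aa == "*") + 1L)
      stops <- which(aa == "*")
      for (st in starts) {
        nxt <- stops[stops >= st]
        if (!length(nxt)) next
        len <- (nxt[1] - st + 1L) * 3L
        if (is.null(best) || len > best$len) best <- list(len = len)
      }
    }
  }
  best
}

## brute-force union-find for component grouping
uf_oracle <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- find(edges$from[i]); b <- find(edges$to[i])
    if (a != b) parent[[max(a, b)]] <- min(a, b)
  }
  vapply(ids, find, "")
}

## DUST triplet score recomputed directly
dust_oracle <- function(seq, window = 64L) {
  n <- nchar(seq)
  if (n < 3) return(0)
  tri <- substring(seq, 1:(n - 2), 3:n)
  w <- min(window, n)
  wt <- w - 2
  denom <- max(w - 3, 1)
  best <- 0
  for (s in 1:(max(1, (n - 2) - wt + 1))) {
    cnt <- table(tri[s:(s + wt - 1)])
    cnt <- cnt[!grepl("[^ACGT]", names(cnt))]
    best <- max(best, sum(cnt * (cnt - 1) / 2) / denom)
  }
  best
}

tiny_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_truth(sim_params(n_genes = 8, n_chloro = 2,
                                      n_contaminants = 2, n_singletons = 1,
                                      seed = 11))
    cache
  }
})
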