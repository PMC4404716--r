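# Read pre-processing: ends-in quality trimming, 5' head trimming, poly-A/T
# tail removal, duplicate removal, DUST low-complexity and length/ambiguity
# filters, and overlap-merging of read pairs. Filter order in prep_reads():
# head -> quality -> polyA/T -> dust -> length/ambiguity -> dedupe -> merge.

#' Pre-processing parameters
#'
#' @param phred_min minimum terminal base quality retained (default 25).
#' @param head_trim bases removed from the 5' end (default 10; corrects
#'   random-hexamer priming bias).
#' @param min_len minimum read length after trimming (50 for short-read
#'   data; use 100 for long single-end data).
#' @param max_ambiguous maximum number of ambiguous bases tolerated.
#' @param k_polyat minimum terminal A (3') or T (5') run length removed.
#' @param dust_threshold DUST triplet-score threshold above which a read is
#'   dropped as low-complexity.
#' @param merge_min_overlap minimum pair overlap for merging.
#' @param merge_max_mismatch_rate maximum mismatch rate within the overlap.
#' @param quality_trim_mode `"both"` trims low-quality bases from both ends;
#'   `"three_prime"` trims only the 3' end.
#' @return list of class `prep_params`.
#' @export
prep_params <- function(phred_min = 25L, head_trim = 10L, min_len = 50L,
                        max_ambiguous = 1L, k_polyat = 5L,
                        dust_threshold = 7, merge_min_overlap = 10L,
                        merge_max_mismatch_rate = 0.1,
                        quality_trim_mode = c("both", "three_prime")) {
  stopifnot(phred_min >= 0, head_trim >= 0, min_len >= 0, max_ambiguous >= 0)
  structure(list(phred_min = as.integer(phred_min),
                 head_trim = as.integer(head_trim),
                 min_len = as.integer(min_len),
                 max_ambiguous = as.integer(max_ambiguous),
                 k_polyat = as.integer(k_polyat),
                 dust_threshold = dust_threshold,
                 merge_min_overlap = as.integer(merge_min_overlap),
                 merge_max_mismatch_rate = merge_max_mismatch_rate,
                 quality_trim_mode = match.arg(quality_trim_mode)),
            class = "prep_params")
}

#' Ends-in quality trimming
#'
#' Removes the maximal prefix and suffix of bases with quality below
#' `phred_min`; interior bases are never touched, so the result is the
#' largest interval whose boundary bases pass.
#'
#' @param reads reads data.frame.
#' @param phred_min quality threshold.
#' @param mode `"both"` or `"three_prime"` (3'-only trimming).
#' @return trimmed reads data.frame (reads may become empty).
#' @export
quality_trim <- function(reads, phred_min = 25L, mode = c("both", "three_prime")) {
  mode <- match.arg(mode)
  if (nrow(reads) == 0) return(reads)
  bounds <- cpp_qtrim(reads$qual, as.integer(phred_min))
  from <- if (mode == "both") bounds[, 1] else ifelse(bounds[, 2] >= 1L, 1L, 0L)
  to <- bounds[, 2]
  reads$seq <- substring(reads$seq, from, to)
  reads$qual <- substring(reads$qual, from, to)
  reads
}

#' Trim the 5' head of each read
#'
#' @param reads reads data.frame.
#' @param n number of 5' bases removed (reads shorter than `n` become empty).
#' @return trimmed reads data.frame.
#' @export
head_trim <- function(reads, n = 10L) {
  if (nrow(reads) == 0 || n <= 0) return(reads)
  reads$seq <- substring(reads$seq, n + 1L)
  reads$qual <- substring(reads$qual, n + 1L)
  reads
}

#' Trim poly-A (3') and poly-T (5') tails
#'
#' A terminal run of at least `k` identical A (3' end) or T (5' end) bases
#' is removed; shorter runs are untouched.
#'
#' @param reads reads data.frame.
#' @param k minimum tail run length (default 5).
#' @return trimmed reads data.frame.
#' @export
polyat_trim <- function(reads, k = 5L) {
  if (nrow(reads) == 0) return(reads)
  tail_re <- sprintf("A{%d,}$", k)
  head_re <- sprintf("^T{%d,}", k)
  m <- regexpr(tail_re, reads$seq)
  cut3 <- ifelse(m > 0, m - 1L, nchar(reads$seq))
  reads$seq <- substring(reads$seq, 1L, cut3)
  reads$qual <- substring(reads$qual, 1L, cut3)
  m <- attr(regexpr(head_re, reads$seq), "match.length")
  cut5 <- ifelse(m > 0, m + 1L, 1L)
  reads$seq <- substring(reads$seq, cut5)
  reads$qual <- substring(reads$qual, cut5)
  reads
}

#' Remove duplicate reads
#'
#' Among reads with identical sequence the first by input order is kept;
#' reverse complements are not considered duplicates.
#'
#' @param reads reads data.frame.
#' @return deduplicated reads data.frame.
#' @export
dedupe_reads <- function(reads) {
  reads[!duplicated(reads$seq), , drop = FALSE]
}

#' DUST low-complexity scores
#'
#' Classic triplet statistic: over sliding 64-base windows,
#' `sum_t c_t (c_t - 1) / 2 / (w - 3)` for triplet counts `c_t`; the read
#' score is the window maximum. A homopolymer scores ~31, random sequence
#' well below 1.
#'
#' @param seqs character vector of sequences.
#' @param window window size (default 64).
#' @return numeric scores.
#' @export
dust_score <- function(seqs, window = 64L) {
  cpp_dust(as.character(seqs), as.integer(window))
}

#' Filter low-complexity reads by DUST score
#'
#' @param reads reads data.frame.
#' @param threshold reads with score strictly above it are dropped.
#' @return logical keep mask.
#' @export
dust_keep <- function(reads, threshold = 7) {
  dust_score(reads$seq) <= threshold
}

#' Length and ambiguity filter
#'
#' @param reads reads data.frame.
#' @param min_len reads shorter than this are dropped.
#' @param max_ambiguous reads with more than this many ambiguous bases are
#'   dropped.
#' @return logical keep mask.
#' @export
length_ambiguity_keep <- function(reads, min_len = 50L, max_ambiguous = 1L) {
  n_amb <- nchar(reads$seq) - nchar(gsub("[^ACGT]", "", reads$seq))
  nchar(reads$seq) >= min_len & n_amb <= max_ambiguous
}

#' Overlap-merge read pairs
#'
#' Mate 2 is reverse-complemented and its best suffix-prefix overlap with
#' mate 1 of length at least `min_overlap` and mismatch rate at most
#' `max_mismatch_rate` is merged into a single read, conflicting bases
#' taking the higher-quality call. Pairs without an acceptable overlap are
#' returned unchanged.
#'
#' @param r1,r2 paired reads data.frames (row i of `r2` is the mate of row i
#'   of `r1`, in sequencing orientation).
#' @param min_overlap minimum overlap length.
#' @param max_mismatch_rate maximum overlap mismatch rate.
#' @return list with `merged` (single-end reads), `r1`, `r2` (unmerged
#'   pairs).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_rate = 0.1) {
  stopifnot(nrow(r1) == nrow(r2))
  if (nrow(r1) == 0) return(list(merged = empty_reads(), r1 = r1, r2 = r2))
  res <- cpp_merge_pairs(r1$seq, r1$qual, r2$seq, r2$qual,
                         as.integer(min_overlap), max_mismatch_rate)
  ok <- res$merged
  merged <- as_reads(r1$id[ok], res$seq[ok], res$qual[ok], r1$meta[ok])
  list(merged = merged,
       r1 = r1[!ok, , drop = FALSE],
       r2 = r2[!ok, , drop = FALSE])
}

prep_single <- function(reads, params, do_head = TRUE) {
  counts <- c(input = nrow(reads))
  if (do_head) reads <- head_trim(reads, params$head_trim)
  reads <- quality_trim(reads, params$phred_min, params$quality_trim_mode)
  reads <- polyat_trim(reads, params$k_polyat)
  nonempty <- nchar(reads$seq) > 0L
  reads <- reads[nonempty, , drop = FALSE]
  keep <- dust_keep(reads, params$dust_threshold)
  counts["dust_dropped"] <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]
  keep <- length_ambiguity_keep(reads, params$min_len, params$max_ambiguous)
  counts["length_ambiguity_dropped"] <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]
  list(reads = reads, counts = counts)
}

#' Pre-process a read set
#'
#' Applies the full filter cascade, then duplicate removal, then (for
#' paired-end input) overlap merging. Pairs in which one mate was dropped
#' contribute the surviving mate as a single-end read, mirroring the
#' downstream convention that merged pairs and singletons are used as
#' single-end reads and unmerged pairs as normal paired-end reads.
#'
#' @param r1 reads data.frame (or single-end reads when `r2` is `NULL`).
#' @param r2 optional mate reads data.frame.
#' @param params [prep_params()].
#' @return list with `merged`, `single`, `paired_r1`, `paired_r2` reads
#'   data.frames and a `counts` summary data.frame.
#' @export
prep_reads <- function(r1, r2 = NULL, params = prep_params()) {
  p1 <- prep_single(r1, params)
  if (is.null(r2)) {
    reads <- dedupe_reads(p1$reads)
    counts <- data.frame(stage = c("input", "after_filters", "after_dedupe"),
                         n = c(nrow(r1), nrow(p1$reads), nrow(reads)),
                         stringsAsFactors = FALSE)
    return(list(merged = empty_reads(), single = reads,
                paired_r1 = empty_reads(), paired_r2 = empty_reads(),
                counts = counts))
  }
  stopifnot(nrow(r1) == nrow(r2))
  p2 <- prep_single(r2, params)
  k1 <- dedupe_reads(p1$reads)
  k2 <- dedupe_reads(p2$reads)
  in1 <- setNames(seq_len(nrow(k1)), k1$id)
  in2 <- setNames(seq_len(nrow(k2)), k2$id)
  common <- intersect(k1$id, k2$id)
  single <- rbind(k1[!(k1$id %in% common), , drop = FALSE],
                  k2[!(k2$id %in% common), , drop = FALSE])
  m <- merge_pairs(k1[in1[common], , drop = FALSE],
                   k2[in2[common], , drop = FALSE],
                   params$merge_min_overlap, params$merge_max_mismatch_rate)
  counts <- data.frame(
    stage = c("input_pairs", "r1_after_filters", "r2_after_filters",
              "pairs_intact", "merged", "single", "paired"),
    n = c(nrow(r1), nrow(k1), nrow(k2), length(common), nrow(m$merged),
          nrow(single), nrow(m$r1)),
    stringsAsFactors = FALSE)
  list(merged = m$merged, single = single,
       paired_r1 = m$r1, paired_r2 = m$r2, counts = counts)
}
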