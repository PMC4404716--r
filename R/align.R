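# Self-contained alignment and assembly kernels used by all downstream
# stages: affine-gap local alignment (Gotoh), k-mer seeded banded search
# over both strands or six translated frames, best-location read mapping
# with a score-gap mapping quality, and a greedy overlap-layout-consensus
# assembler.

#' Alignment parameters and hit-filter presets
#'
#' The presets replace database-size dependent e-value cut-offs with
#' identity/length thresholds: `loose` (0.80, 50), `standard` (0.85, 60),
#' `strict` (0.90, 100) as (min identity, min aligned columns).
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param k seed length (default 12 for nucleotide, 4 for protein).
#' @param match,mismatch nucleotide match/mismatch scores.
#' @param gap_open,gap_extend affine gap costs (gap of length L costs
#'   `gap_open + gap_extend * L`).
#' @param preset optional name of a hit-filter preset (see above).
#' @param min_identity minimum hit identity (matches / aligned columns).
#' @param min_matched_len minimum aligned columns of a hit.
#' @param min_hit_score minimum hit score.
#' @param max_hits maximum hits returned per query (default 250).
#' @param band_pad slack added around the seeded diagonal band.
#' @param band_gap diagonal gap that splits seed clusters.
#' @param min_seeds minimum shared k-mers to attempt an alignment.
#' @return list of class `align_params`.
#' @export
align_params <- function(mode = c("nucleotide", "protein"), k = NULL,
                         match = 2L, mismatch = -3L, gap_open = 5L,
                         gap_extend = 2L, preset = NULL, min_identity = 0,
                         min_matched_len = 0L, min_hit_score = 20L,
                         max_hits = 250L, band_pad = 16L, band_gap = 32L,
                         min_seeds = 1L) {
  mode <- match.arg(mode)
  if (!is.null(preset)) {
    p <- hit_preset(preset)
    min_identity <- p$min_identity
    min_matched_len <- p$min_matched_len
  }
  if (is.null(k)) k <- if (mode == "nucleotide") 12L else 4L
  if (mode == "nucleotide" && k < 8L) stop("nucleotide seeding requires k >= 8")
  if (mode == "protein" && k < 4L) stop("protein seeding requires k >= 4")
  structure(list(mode = mode, k = as.integer(k), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_identity = min_identity,
                 min_matched_len = as.integer(min_matched_len),
                 min_hit_score = as.integer(min_hit_score),
                 max_hits = as.integer(max_hits),
                 band_pad = as.integer(band_pad),
                 band_gap = as.integer(band_gap),
                 min_seeds = as.integer(min_seeds)),
            class = "align_params")
}

#' @rdname align_params
#' @param name preset name.
#' @export
hit_preset <- function(name = c("loose", "standard", "strict")) {
  name <- match.arg(name)
  switch(name,
         loose = list(min_identity = 0.80, min_matched_len = 50L),
         standard = list(min_identity = 0.85, min_matched_len = 60L),
         strict = list(min_identity = 0.90, min_matched_len = 100L))
}

scoring_args <- function(params) {
  if (params$mode == "protein") {
    bl <- blosum62()
    alpha <- paste(rownames(bl), collapse = "")
    list(match = 0L, mismatch = -4L, protein = TRUE,
         submat = matrix(as.integer(bl), nrow(bl)), alphabet = alpha)
  } else {
    list(match = params$match, mismatch = params$mismatch, protein = FALSE,
         submat = NULL, alphabet = "")
  }
}

seed_alphabet <- function(params) {
  if (params$mode == "protein") AA_ALPHABET_SEED else "ACGT"
}

align_pairs <- function(qseqs, sseqs, qi, si, dlo, dhi, params,
                        want_proj = FALSE) {
  sc <- scoring_args(params)
  cpp_align_pairs(unname(qseqs), unname(sseqs), as.integer(qi),
                  as.integer(si), as.integer(dlo), as.integer(dhi),
                  sc$match, sc$mismatch, params$gap_open, params$gap_extend,
                  sc$protein, sc$submat, sc$alphabet, want_proj)
}

#' Optimal local alignment of two sequences
#'
#' Exhaustive affine-gap dynamic programming (no seeding). Intervals are
#' 0-based half-open; identity is matches over aligned columns.
#'
#' @param a,b sequences (single strings), nucleotide or protein depending on
#'   `params$mode`.
#' @param params [align_params()].
#' @param ids optional `c(query_id, subject_id)` for the output record.
#' @return one-row alignment data.frame (`query_id`, `subject_id`, `q0`,
#'   `q1`, `s0`, `s1`, `strand`, `cigar`, `score`, `identity`, `mapq`).
#' @export
local_align <- function(a, b, params = align_params(), ids = c("query", "subject")) {
  stopifnot(nzchar(a), nzchar(b))
  r <- align_pairs(a, b, 1L, 1L, NA_integer_, NA_integer_, params)
  data.frame(query_id = ids[1], subject_id = ids[2],
             q0 = r$q0, q1 = r$q1, s0 = r$s0, s1 = r$s1, strand = "+",
             cigar = r$cigar, score = r$score,
             identity = ifelse(r$cols > 0, r$matches / r$cols, 0),
             mapq = NA_integer_, stringsAsFactors = FALSE)
}

empty_hits <- function(frame = FALSE) {
  out <- data.frame(query = character(0), subject = character(0),
                    strand = character(0), score = integer(0),
                    identity = numeric(0), matches = integer(0),
                    cols = integer(0), q0 = integer(0), q1 = integer(0),
                    s0 = integer(0), s1 = integer(0), cigar = character(0),
                    stringsAsFactors = FALSE)
  if (frame) out$frame <- integer(0)
  out
}

## Raw seeded banded hits; one row per (query, subject, strand, diagonal
## cluster).  Coordinates are on the given (possibly reverse-complemented)
## query orientation until flipped below.
seeded_hits <- function(queries, db, params, both_strands, want_proj = FALSE) {
  check_named_seqs(queries, "query set")
  check_named_seqs(db, "subject database")
  if (length(queries) == 0 || length(db) == 0) return(empty_hits())
  seeds <- cpp_seed_pairs(unname(queries), unname(db), params$k, both_strands,
                          seed_alphabet(params), params$band_gap,
                          params$min_seeds)
  if (nrow(seeds) == 0) return(empty_hits())
  qseqs <- unname(queries)
  qi <- seeds$qi
  neg <- seeds$strand < 0L
  if (any(neg)) {
    rc_idx <- sort(unique(qi[neg]))
    rc_seqs <- cpp_revcomp(qseqs[rc_idx])
    qseqs <- c(qseqs, rc_seqs)
    qi[neg] <- length(queries) + match(qi[neg], rc_idx)
  }
  aln <- align_pairs(qseqs, db, qi, seeds$si,
                     seeds$dmin - params$band_pad,
                     seeds$dmax + params$band_pad, params, want_proj)
  qlen <- nchar(unname(queries))[seeds$qi]
  q0 <- ifelse(neg, qlen - aln$q1, aln$q0)
  q1 <- ifelse(neg, qlen - aln$q0, aln$q1)
  out <- data.frame(query = names(queries)[seeds$qi],
                    subject = names(db)[seeds$si],
                    strand = ifelse(neg, "-", "+"),
                    score = aln$score,
                    identity = ifelse(aln$cols > 0, aln$matches / aln$cols, 0),
                    matches = aln$matches, cols = aln$cols,
                    q0 = q0, q1 = q1, s0 = aln$s0, s1 = aln$s1,
                    cigar = aln$cigar, stringsAsFactors = FALSE)
  if (want_proj) out$proj <- aln$proj
  out$qi <- seeds$qi
  out$si <- seeds$si
  out
}

filter_hits <- function(hits, params) {
  hits[hits$score >= params$min_hit_score &
       hits$identity >= params$min_identity &
       hits$cols >= params$min_matched_len, , drop = FALSE]
}

## deterministic hit ordering: score desc, subject id (C locale), strand, s0
order_hits <- function(hits) {
  order_c(-hits$score, hits$subject, hits$strand, hits$s0)
}

#' Search queries against a sequence database
#'
#' k-mer seeded, banded local alignment over both strands (nucleotide mode).
#' At most one hit per (query, subject) pair is kept - the best scoring.
#' Hits are filtered by the preset thresholds in `params`, sorted by score
#' (ties by subject id), and capped at `params$max_hits` per query.
#'
#' @param queries,db named character vectors.
#' @param params [align_params()].
#' @return hits data.frame (`query`, `subject`, `strand`, `score`,
#'   `identity`, `matches`, `cols`, `q0`, `q1`, `s0`, `s1`, `cigar`).
#' @export
search_db <- function(queries, db, params = align_params()) {
  hits <- seeded_hits(queries, db, params, params$mode == "nucleotide")
  if (nrow(hits) == 0) return(empty_hits())
  hits <- filter_hits(hits, params)
  if (nrow(hits) == 0) return(empty_hits())
  hits <- hits[order_hits(hits), , drop = FALSE]
  hits <- hits[!duplicated(paste0(hits$query, "\r", hits$subject)), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query),
                        function(i) i[seq_len(min(length(i), params$max_hits))]),
                 use.names = FALSE)
  hits <- hits[sort(keep), , drop = FALSE]
  ## order by query (input order), then score desc / subject
  qord <- match(hits$query, names(queries))
  hits <- hits[order(qord, -hits$score, hits$subject, method = "radix"), ,
               drop = FALSE]
  hits$qi <- NULL; hits$si <- NULL
  rownames(hits) <- NULL
  hits
}

#' Translated search of nucleotide queries against a protein database
#'
#' Queries are translated in six frames (standard code); stops split each
#' frame into segments which are searched in protein mode, so alignments
#' never cross a stop. The best segment hit per (query, subject) is
#' reported with its frame.
#'
#' @param queries named nucleotide character vector.
#' @param protein_db named protein character vector.
#' @param params [align_params()] in protein mode (a nucleotide `params` is
#'   converted, keeping the preset thresholds).
#' @return hits data.frame as [search_db()] plus a `frame` column
#'   (+1,+2,+3,-1,-2,-3).
#' @export
translated_search <- function(queries, protein_db, params = align_params("protein", preset = "loose")) {
  check_named_seqs(queries, "query set")
  check_named_seqs(protein_db, "protein database")
  if (params$mode != "protein")
    params <- align_params("protein", min_identity = params$min_identity,
                           min_matched_len = params$min_matched_len,
                           min_hit_score = params$min_hit_score,
                           max_hits = params$max_hits)
  if (length(queries) == 0 || length(protein_db) == 0)
    return(empty_hits(frame = TRUE))
  seg_seq <- character(0); seg_query <- character(0); seg_frame <- integer(0)
  for (qn in names(queries)) {
    fr <- six_frame(queries[[qn]])
    for (i in seq_len(nrow(fr))) {
      segs <- strsplit(fr$aa[i], "*", fixed = TRUE)[[1]]
      segs <- segs[nchar(segs) >= params$k]
      if (length(segs)) {
        seg_seq <- c(seg_seq, segs)
        seg_query <- c(seg_query, rep(qn, length(segs)))
        seg_frame <- c(seg_frame, rep(fr$frame[i], length(segs)))
      }
    }
  }
  if (!length(seg_seq)) return(empty_hits(frame = TRUE))
  names(seg_seq) <- sprintf("seg%06d", seq_along(seg_seq))
  hits <- seeded_hits(seg_seq, protein_db, params, both_strands = FALSE)
  if (nrow(hits) == 0) return(empty_hits(frame = TRUE))
  hits <- filter_hits(hits, params)
  if (nrow(hits) == 0) return(empty_hits(frame = TRUE))
  idx <- match(hits$query, names(seg_seq))
  hits$query <- seg_query[idx]
  hits$frame <- seg_frame[idx]
  hits$strand <- ifelse(hits$frame > 0, "+", "-")
  hits <- hits[order_c(-hits$score, hits$subject, hits$frame), , drop = FALSE]
  hits <- hits[!duplicated(paste0(hits$query, "\r", hits$subject)), , drop = FALSE]
  qord <- match(hits$query, names(queries))
  hits <- hits[order(qord, -hits$score, hits$subject, method = "radix"), ,
               drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), qord),
                        function(i) i[seq_len(min(length(i), params$max_hits))]),
                 use.names = FALSE)
  hits <- hits[sort(keep), , drop = FALSE]
  hits$qi <- NULL; hits$si <- NULL
  rownames(hits) <- NULL
  hits
}

#' Map reads to a reference and assign mapping qualities
#'
#' Seeded banded local alignment of each read (both strands); the mapping
#' quality is a score-gap surrogate `min(60, round(-10 log10 p))` with
#' `p = 10^(-0.3 (s1 - s2))` from the best (`s1`) and second-best (`s2`)
#' candidate locations; a read with no second candidate gets 60, a perfect
#' tie gets 0. Reads with `mapq <= mapq_min` are flagged non-passing.
#'
#' Low-scoring unique alignments are not trusted: when the best alignment
#' has identity below `min_pass_identity` (default 0.97, roughly the point
#' where an end-to-end aligner's unique-hit confidence falls through the
#' `>25` filter at 3-4 mismatches per 100 bp) or covers less than
#' `min_read_cov` of the read, the mapq is capped at 20.
#'
#' @param reads reads data.frame or named character vector of sequences.
#' @param reference named character vector of reference sequences.
#' @param params [align_params()].
#' @param mapq_min mapq filter threshold (exclusive; default 25).
#' @param min_seeds minimum shared k-mers to consider a candidate location.
#' @param min_pass_identity,min_read_cov alignment-quality floor for full
#'   mapping confidence (see above).
#' @return list with `alignments` (best location per mapped read, with
#'   `mapq` and `pass`) and `hits` (all candidate locations).
#' @export
map_reads <- function(reads, reference, params = align_params(),
                      mapq_min = 25L, min_seeds = 2L,
                      min_pass_identity = 0.97, min_read_cov = 0.9) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$id)
  check_named_seqs(reads, "read set")
  params$min_seeds <- as.integer(min_seeds)
  params$min_hit_score <- max(params$min_hit_score, 2L * params$k)
  hits <- seeded_hits(reads, reference, params, both_strands = TRUE,
                      want_proj = TRUE)
  if (nrow(hits) == 0)
    return(list(alignments = empty_alignments(), hits = empty_hits()))
  hits <- hits[hits$score >= params$min_hit_score, , drop = FALSE]
  if (nrow(hits) == 0)
    return(list(alignments = empty_alignments(), hits = empty_hits()))
  ord <- order(hits$qi, -hits$score, hits$subject, hits$strand, hits$s0,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$qi)
  grp_n <- tabulate(match(hits$qi, hits$qi[first]))
  best <- hits[first, , drop = FALSE]
  ## second-best score per read (0 when only one candidate location)
  idx_first <- which(first)
  s2 <- rep(NA_integer_, nrow(best))
  has2 <- grp_n >= 2L
  s2[has2] <- hits$score[idx_first[has2] + 1L]
  mapq <- ifelse(is.na(s2), 60L,
                 pmin(60L, as.integer(round(3 * (best$score - s2)))))
  read_len <- nchar(reads)[best$qi]
  weak <- best$identity < min_pass_identity |
    (best$q1 - best$q0) < min_read_cov * read_len
  mapq[weak] <- pmin(mapq[weak], 20L)
  aln <- data.frame(query_id = best$query, subject_id = best$subject,
                    q0 = best$q0, q1 = best$q1, s0 = best$s0, s1 = best$s1,
                    strand = best$strand, cigar = best$cigar,
                    score = best$score, identity = best$identity,
                    mapq = as.integer(mapq), stringsAsFactors = FALSE)
  aln$pass <- aln$mapq > mapq_min
  aln$proj <- best$proj
  hits$qi <- NULL; hits$si <- NULL; hits$proj <- NULL
  rownames(aln) <- NULL
  rownames(hits) <- NULL
  list(alignments = aln, hits = hits)
}

#' Overlap-assembly parameters
#'
#' @param min_overlap_len minimum overlap length (default 40).
#' @param min_overlap_identity minimum overlap identity (default 0.97,
#'   mirroring a 97% assembly-overlap setting).
#' @param end_slack maximum unaligned overhang for an overlap to count as a
#'   dovetail or containment.
#' @param k seed length for overlap detection.
#' @return list of class `asm_params`.
#' @export
asm_params <- function(min_overlap_len = 40L, min_overlap_identity = 0.97,
                       end_slack = 10L, k = 12L) {
  stopifnot(min_overlap_identity > 0, min_overlap_identity <= 1)
  structure(list(min_overlap_len = as.integer(min_overlap_len),
                 min_overlap_identity = min_overlap_identity,
                 end_slack = as.integer(end_slack), k = as.integer(k)),
            class = "asm_params")
}

#' Greedy overlap-layout-consensus assembly
#'
#' Pairwise suffix-prefix (or containment) overlaps on either strand with
#' length and identity above the thresholds are merged best-overlap-first;
#' the consensus takes the per-column majority base, ties to the
#' lexicographically smaller base. The layout is ungapped (offsets from the
#' overlap alignments), which is exact for substitution-level divergence.
#'
#' @param seqs named character vector of input sequences.
#' @param params [asm_params()].
#' @return list with `contigs` (named character vector) and `members`
#'   (data.frame `contig`, `member`, `offset`, `orient`).
#' @export
overlap_assemble <- function(seqs, params = asm_params()) {
  check_named_seqs(seqs, "assembly input")
  n <- length(seqs)
  if (n == 0) return(list(contigs = character(0),
                          members = data.frame(contig = character(0),
                                               member = character(0),
                                               offset = integer(0),
                                               orient = integer(0),
                                               stringsAsFactors = FALSE)))
  lens <- nchar(seqs)
  ov <- NULL
  if (n > 1) {
    ap <- align_params(k = params$k, band_gap = 32L, band_pad = 16L)
    hits <- seeded_hits(seqs, seqs, ap, both_strands = TRUE)
    if (nrow(hits)) {
      hits <- hits[hits$qi < hits$si, , drop = FALSE]
      la <- lens[hits$qi]; lb <- lens[hits$si]
      ## dovetail/containment: the alignment must reach an end of each
      ## sequence (which ends depends on the relative orientation)
      ok <- hits$cols >= params$min_overlap_len &
        hits$identity >= params$min_overlap_identity &
        (hits$q0 <= params$end_slack | hits$q1 >= la - params$end_slack) &
        (hits$s0 <= params$end_slack | hits$s1 >= lb - params$end_slack)
      ov <- hits[ok, , drop = FALSE]
      if (nrow(ov))
        ov <- ov[order_c(-ov$matches, -ov$identity, ov$qi, ov$si, ov$strand), ,
                 drop = FALSE]
    }
  }
  ## layout state: one entry per live contig
  contig_of <- seq_len(n)
  members <- lapply(seq_len(n), function(i)
    data.frame(idx = i, offset = 0L, orient = 1L))
  if (!is.null(ov) && nrow(ov)) {
    for (r in seq_len(nrow(ov))) {
      x <- ov$qi[r]; y <- ov$si[r]
      cx <- contig_of[x]; cy <- contig_of[y]
      if (cx == cy) next
      s <- if (ov$strand[r] == "-") -1L else 1L
      ## placement of y (oriented `orel`) in x's original frame; the layout
      ## is ungapped so the alignment offset fixes it
      if (s == 1L) {
        rel <- ov$q0[r] - ov$s0[r]
        orel <- 1L
      } else {
        q0a <- lens[x] - ov$q1[r]    # start on the rc-oriented query
        rel <- lens[x] - (q0a - ov$s0[r]) - lens[y]
        orel <- -1L
      }
      mx <- members[[cx]]
      ex <- mx[mx$idx == x, ]
      if (ex$orient == 1L) {
        start_y <- ex$offset + rel
        o_y <- orel
      } else {
        start_y <- ex$offset + lens[x] - rel - lens[y]
        o_y <- -orel
      }
      my <- members[[cy]]
      ey <- my[my$idx == y, ]
      if (o_y == ey$orient) {
        delta <- start_y - ey$offset
        my$offset <- my$offset + delta
      } else {
        K <- start_y + ey$offset + lens[y]
        my$offset <- K - (my$offset + lens[my$idx])
        my$orient <- -my$orient
      }
      merged <- rbind(mx, my)
      shift <- min(merged$offset)
      merged$offset <- merged$offset - shift
      members[[cx]] <- merged
      members[cy] <- list(NULL)
      contig_of[contig_of == cy] <- cx
    }
  }
  live <- sort(unique(contig_of))
  contigs <- character(length(live))
  mem_out <- vector("list", length(live))
  for (ci in seq_along(live)) {
    m <- members[[live[ci]]]
    m <- m[order(m$offset, m$idx), , drop = FALSE]
    oriented <- ifelse(m$orient == 1L, seqs[m$idx], cpp_revcomp(seqs[m$idx]))
    clen <- max(m$offset + lens[m$idx])
    counts <- cpp_pileup(clen, m$offset, unname(oriented))
    cons <- consensus_from_counts(counts)
    contigs[ci] <- cons
    mem_out[[ci]] <- data.frame(contig = ci, member = names(seqs)[m$idx],
                                offset = m$offset, orient = m$orient,
                                stringsAsFactors = FALSE)
  }
  names(contigs) <- sprintf("ctg%04d", seq_along(live))
  mem <- do.call(rbind, mem_out)
  mem$contig <- names(contigs)[mem$contig]
  rownames(mem) <- NULL
  list(contigs = contigs, members = mem)
}

## majority base per column from a cpp_pileup count matrix (rows A,C,G,T,N,-)
consensus_from_counts <- function(counts) {
  acgt <- counts[1:4, , drop = FALSE]
  tot <- colSums(acgt)
  best <- max.col(t(acgt), ties.method = "first")  # first = lexicographic
  base <- c("A", "C", "G", "T")[best]
  base[tot == 0] <- "N"
  paste(base, collapse = "")
}
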