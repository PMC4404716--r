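# Orthology-guided assembly: transcripts are grouped by their best
# translated hit against a guide proteome, assembled within groups,
# reciprocally checked against the whole proteome, reduced to their
# longest ORF (UTRs trimmed), reassembled, named after the guide gene,
# and flagged full-length when the coding region is complete and covers
# most of the guide protein.

#' Orthology-assembly parameters
#'
#' @param group_preset hit preset for grouping transcripts under guide
#'   proteins (default `loose`).
#' @param reciprocal_preset hit preset for the reciprocal check (default
#'   `standard`).
#' @param flcov minimum fraction of the guide protein covered by the
#'   translated final sequence for a full-length call (default 0.9).
#' @param require_atg ORFs must start at ATG (default TRUE; FALSE gives
#'   stop-to-stop ORFs).
#' @param max_hits maximum hits scanned per query (default 250).
#' @return list of class `ortho_params`.
#' @export
ortho_params <- function(group_preset = "loose",
                         reciprocal_preset = "standard", flcov = 0.9,
                         require_atg = TRUE, max_hits = 250L) {
  structure(list(group_preset = group_preset,
                 reciprocal_preset = reciprocal_preset, flcov = flcov,
                 require_atg = require_atg, max_hits = as.integer(max_hits)),
            class = "ortho_params")
}

#' Group transcripts by their best guide-protein hit
#'
#' @param transcripts named nucleotide character vector.
#' @param guide_proteome named protein character vector.
#' @param params [ortho_params()].
#' @return list `groups` (named list guide -> member transcript ids) and
#'   `unassigned` (character vector).
#' @export
group_by_guide <- function(transcripts, guide_proteome,
                           params = ortho_params()) {
  stopifnot(length(guide_proteome) > 0)
  ap <- align_params("protein", preset = params$group_preset,
                     max_hits = params$max_hits)
  hits <- translated_search(transcripts, guide_proteome, ap)
  if (!nrow(hits))
    return(list(groups = list(), unassigned = names(transcripts)))
  ## best hit per transcript; ties broken by protein id (already ordered)
  best <- hits[!duplicated(hits$query), , drop = FALSE]
  groups <- split(best$query, best$subject)
  groups <- groups[sort_c(names(groups))]
  groups <- lapply(groups, sort_c)
  list(groups = groups,
       unassigned = setdiff(names(transcripts), best$query))
}

#' Assemble the transcripts of one ortholog group
#'
#' @param members named character vector of member transcripts.
#' @param params [asm_params()].
#' @return [overlap_assemble()] result.
#' @export
assemble_group <- function(members, params = asm_params()) {
  overlap_assemble(members, params)
}

#' Reciprocal check of an assembled contig
#'
#' The contig is searched against the whole guide proteome; it is kept
#' only when the top-scoring protein is the guide originally used for
#' grouping (score ties are ambiguous and drop the contig).
#'
#' @param contig single named character vector (or plain string).
#' @param guide_proteome named protein character vector.
#' @param original_guide guide protein id used for grouping.
#' @param params [ortho_params()].
#' @return TRUE (keep) or FALSE (drop).
#' @export
reciprocal_check <- function(contig, guide_proteome, original_guide,
                             params = ortho_params()) {
  if (is.null(names(contig))) names(contig) <- "contig"
  ap <- align_params("protein", preset = params$reciprocal_preset,
                     max_hits = params$max_hits)
  hits <- translated_search(contig, guide_proteome, ap)
  if (!nrow(hits)) return(FALSE)
  top <- hits$score[1]
  tied <- hits$subject[hits$score == top]
  length(tied) == 1L && tied == original_guide
}

#' Longest open reading frame over six frames
#'
#' Scans all six frames for ATG...stop spans (or stop-to-stop when
#' `require_atg = FALSE`) and returns the longest; ties prefer the frame
#' order +1,+2,+3,-1,-2,-3, then the smaller start.
#'
#' @param seq nucleotide string.
#' @param require_atg require an ATG start (default TRUE).
#' @return `NULL` when no complete ORF exists, else a list with `start`,
#'   `end` (0-based half-open on the input sequence; for negative frames
#'   the interval is on the input but the ORF reads on the minus strand),
#'   `frame`, `strand`, `nt` (coding sequence incl. stop codon) and
#'   `protein`.
#' @export
longest_orf <- function(seq, require_atg = TRUE) {
  L <- nchar(seq)
  if (L < 6L) return(NULL)
  fr <- six_frame(seq)
  best <- NULL
  for (i in seq_len(nrow(fr))) {
    aa <- fr$aa[i]
    if (!nzchar(aa)) next
    offset <- fr$offset[i]
    stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"))
    aa_chars <- strsplit(aa, "")[[1]]
    for (si in seq_len(length(stops) - 1L)) {
      seg_start <- stops[si] + 1L           # first codon index of segment
      seg_stop <- stops[si + 1L]            # the stop codon index
      if (seg_stop <= seg_start) next
      start_cod <- seg_start
      if (require_atg) {
        atg <- which(aa_chars[seg_start:(seg_stop - 1L)] == "M")
        if (!length(atg)) next
        start_cod <- seg_start + atg[1] - 1L
      }
      len_nt <- (seg_stop - start_cod + 1L) * 3L
      if (is.null(best) || len_nt > best$len_nt) {
        best <- list(frame = fr$frame[i], offset = offset,
                     start_cod = start_cod, stop_cod = seg_stop,
                     len_nt = len_nt)
      }
    }
  }
  if (is.null(best)) return(NULL)
  ## map codon indices to input coordinates
  s_f <- best$offset + (best$start_cod - 1L) * 3L      # on the read frame
  e_f <- best$offset + best$stop_cod * 3L
  if (best$frame > 0) {
    start <- s_f; end <- e_f; strand <- "+"
    nt <- substr(seq, start + 1L, end)
  } else {
    start <- L - e_f; end <- L - s_f; strand <- "-"
    nt <- substr(revcomp(seq), s_f + 1L, e_f)
  }
  prot <- cpp_translate(substr(nt, 1L, nchar(nt) - 3L))
  list(start = start, end = end, frame = best$frame, strand = strand,
       nt = nt, protein = prot)
}

#' Reassemble UTR-trimmed coding sequences of a group
#'
#' Final contigs are named `{guide}.m{k}` with `k` assigned by descending
#' length.
#'
#' @param orf_seqs named character vector of trimmed coding sequences.
#' @param guide guide protein id.
#' @param params [asm_params()].
#' @return named character vector of final sequences.
#' @export
reassemble_trimmed <- function(orf_seqs, guide, params = asm_params()) {
  if (!length(orf_seqs)) return(character(0))
  asm <- overlap_assemble(orf_seqs, params)
  contigs <- asm$contigs
  ord <- order(-nchar(contigs), names(contigs), method = "radix")
  contigs <- contigs[ord]
  names(contigs) <- sprintf("%s.m%d", guide, seq_along(contigs))
  contigs
}

#' Full-length call for a final sequence
#'
#' Full length requires an ATG start, a terminal in-frame stop codon, and
#' a translated alignment covering at least `flcov` of the guide protein.
#'
#' @param final_seq coding sequence (string).
#' @param guide_protein guide protein sequence (string).
#' @param flcov guide coverage threshold (default 0.9).
#' @return logical flag.
#' @export
call_full_length <- function(final_seq, guide_protein, flcov = 0.9) {
  L <- nchar(final_seq)
  if (L < 6L || L %% 3L != 0L) return(FALSE)
  if (substr(final_seq, 1L, 3L) != "ATG") return(FALSE)
  last <- substr(final_seq, L - 2L, L)
  if (!(last %in% c("TAA", "TAG", "TGA"))) return(FALSE)
  prot <- cpp_translate(substr(final_seq, 1L, L - 3L))
  if (grepl("*", prot, fixed = TRUE)) return(FALSE)
  ap <- align_params("protein", min_hit_score = 0L)
  aln <- local_align(prot, guide_protein, ap)
  (aln$s1 - aln$s0) / nchar(guide_protein) >= flcov
}

#' Join external annotation onto final sequences
#'
#' @param report ortholog report data.frame with a `guide` column.
#' @param annotation data.frame with columns `protein`, `annotation`.
#' @return `report` with an `annotation` column (empty when absent).
#' @export
annotate_orthologs <- function(report, annotation) {
  if (is.null(annotation) || !nrow(annotation)) {
    report$annotation <- ""
    return(report)
  }
  if (anyDuplicated(annotation$protein))
    stop("annotation integrity error: duplicate key '",
         annotation$protein[anyDuplicated(annotation$protein)][1], "'",
         call. = FALSE)
  idx <- match(report$guide, annotation$protein)
  report$annotation <- ifelse(is.na(idx), "", annotation$annotation[idx])
  report
}

#' Orthology-guided assembly of a non-redundant transcriptome
#'
#' Runs grouping, within-group assembly, the reciprocal check, longest-ORF
#' calling with UTR trimming, reassembly, naming, full-length calling and
#' the annotation join. Groups with a single member transcript
#' (singletons) are discarded.
#'
#' @param transcripts named character vector (all retained transcripts).
#' @param guide_proteome named protein character vector.
#' @param annotation optional annotation data.frame (`protein`,
#'   `annotation`).
#' @param params [ortho_params()].
#' @param asm [asm_params()] for both assembly passes.
#' @return list with `sequences` (named final sequences), `report` (one
#'   row per final sequence), `groups`, `unassigned`, and `dropped`
#'   (per-group failure reasons).
#' @export
ortholog_assembly <- function(transcripts, guide_proteome, annotation = NULL,
                              params = ortho_params(), asm = asm_params()) {
  gg <- group_by_guide(transcripts, guide_proteome, params)
  sequences <- character(0)
  report_rows <- list()
  dropped <- list()
  for (guide in names(gg$groups)) {
    member_ids <- gg$groups[[guide]]
    if (length(member_ids) < 2L) {
      dropped[[guide]] <- data.frame(guide = guide, reason = "singleton",
                                     n_members = length(member_ids),
                                     stringsAsFactors = FALSE)
      next
    }
    asm_res <- assemble_group(transcripts[member_ids], asm)
    orf_seqs <- character(0)
    for (cn in names(asm_res$contigs)) {
      contig <- asm_res$contigs[cn]
      if (!reciprocal_check(contig, guide_proteome, guide, params)) {
        dropped[[paste0(guide, ".", cn)]] <-
          data.frame(guide = guide, reason = "reciprocal_failure",
                     n_members = length(member_ids), stringsAsFactors = FALSE)
        next
      }
      orf <- longest_orf(contig[[1]], params$require_atg)
      if (is.null(orf)) {
        dropped[[paste0(guide, ".", cn)]] <-
          data.frame(guide = guide, reason = "no_orf",
                     n_members = length(member_ids), stringsAsFactors = FALSE)
        next
      }
      orf_seqs[cn] <- orf$nt
    }
    if (!length(orf_seqs)) next
    finals <- reassemble_trimmed(orf_seqs, guide, asm)
    for (fn in names(finals)) {
      fl <- call_full_length(finals[[fn]], guide_proteome[[guide]],
                             params$flcov)
      sequences[fn] <- finals[[fn]]
      report_rows[[fn]] <- data.frame(
        rhfv = fn, guide = guide, n_members = length(member_ids),
        length = nchar(finals[[fn]]), full_length = fl,
        stringsAsFactors = FALSE)
    }
  }
  report <- if (length(report_rows)) do.call(rbind, report_rows) else
    data.frame(rhfv = character(0), guide = character(0),
               n_members = integer(0), length = integer(0),
               full_length = logical(0), stringsAsFactors = FALSE)
  rownames(report) <- NULL
  report <- annotate_orthologs(report, annotation)
  drop_df <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(guide = character(0), reason = character(0),
               n_members = integer(0), stringsAsFactors = FALSE)
  rownames(drop_df) <- NULL
  list(sequences = sequences, report = report, groups = gg$groups,
       unassigned = gg$unassigned, dropped = drop_df)
}
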