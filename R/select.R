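# Transcript selection: isoform components from shared multi-mapped reads,
# the strict <1% IsoPct drop plus most-abundant-per-component rule, and the
# translated contaminant screen.

#' Build isoform components from read-sharing
#'
#' Transcripts that share at least one multi-mapped read (equal-best
#' alignment score at several transcripts) form one connected component;
#' unlinked transcripts are singleton components.
#'
#' @param transcripts named character vector (or character vector of ids).
#' @param hits candidate-location hits from [map_reads()].
#' @param margin score margin within which locations count as tied
#'   (default 0: exact ties).
#' @return data.frame `transcript`, `component`.
#' @export
build_components <- function(transcripts, hits, margin = 0L) {
  ids <- if (is.null(names(transcripts))) transcripts else names(transcripts)
  edges <- multimap_targets(hits, margin)
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (nrow(edges))
    g <- g + igraph::edges(rbind(edges$from, edges$to))
  comp <- igraph::components(g)$membership
  data.frame(transcript = ids, component = as.integer(comp[ids]),
             stringsAsFactors = FALSE)
}

## per-read sets of tied best targets -> unique edges between transcripts
multimap_targets <- function(hits, margin = 0L) {
  if (nrow(hits) == 0)
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  best <- tapply(hits$score, hits$query, max)
  top <- hits[hits$score >= best[hits$query] - margin, , drop = FALSE]
  tsets <- lapply(split(top$subject, top$query), unique)
  tsets <- tsets[lengths(tsets) > 1L]
  if (!length(tsets))
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  from <- character(0); to <- character(0)
  for (s in tsets) {
    s <- sort_c(s)
    from <- c(from, s[-length(s)])
    to <- c(to, s[-1L])
  }
  unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

#' Fractional read counts per transcript
#'
#' Multi-mapped reads (tied best locations) are split equally across their
#' targets.
#'
#' @param transcripts named character vector.
#' @param hits candidate-location hits from [map_reads()].
#' @param margin tie margin, as in [build_components()].
#' @return named numeric vector of counts.
#' @export
transcript_counts <- function(transcripts, hits, margin = 0L) {
  ids <- names(transcripts)
  counts <- setNames(numeric(length(ids)), ids)
  if (nrow(hits) == 0) return(counts)
  best <- tapply(hits$score, hits$query, max)
  top <- hits[hits$score >= best[hits$query] - margin, , drop = FALSE]
  ## unique (read, transcript) pairs, weight 1/n_targets
  key <- paste0(top$query, "\r", top$subject)
  top <- top[!duplicated(key), , drop = FALSE]
  ntarg <- table(top$query)
  w <- 1 / as.numeric(ntarg[top$query])
  agg <- tapply(w, top$subject, sum)
  counts[names(agg)] <- as.numeric(agg)
  counts
}

#' IsoPct and most-abundant-isoform filter
#'
#' Within each component, transcripts attracting strictly less than 1% of
#' the component's reads (IsoPct < 1) are dropped; of the remainder only
#' the most abundant transcript is retained (ties to the longer transcript,
#' then the lexicographically smaller id).
#'
#' @param components data.frame from [build_components()].
#' @param counts named numeric vector from [transcript_counts()].
#' @param lengths named integer vector of transcript lengths.
#' @param isopct_min IsoPct threshold in percent (default 1; strict `<`).
#' @param keep_top retain only the most abundant surviving transcript per
#'   component (default TRUE).
#' @return data.frame `transcript`, `component`, `count`, `iso_pct`,
#'   `retained`, `reason`.
#' @export
isopct_filter <- function(components, counts, lengths, isopct_min = 1,
                          keep_top = TRUE) {
  df <- components
  df$count <- as.numeric(counts[df$transcript])
  df$count[is.na(df$count)] <- 0
  total <- tapply(df$count, df$component, sum)
  tot <- as.numeric(total[as.character(df$component)])
  df$iso_pct <- ifelse(tot > 0, 100 * df$count / tot, 0)
  df$retained <- TRUE
  df$reason <- ""
  low <- df$iso_pct < isopct_min & tot > 0
  df$retained[low] <- FALSE
  df$reason[low] <- "isopct"
  if (keep_top) {
    len <- as.integer(lengths[df$transcript])
    for (comp in unique(df$component)) {
      idx <- which(df$component == comp & df$retained)
      if (length(idx) <= 1L) next
      ord <- order(-df$count[idx], -len[idx],
                   df$transcript[idx], method = "radix")
      drop <- idx[ord][-1L]
      df$retained[drop] <- FALSE
      df$reason[drop] <- "not_top_isoform"
    }
  }
  df
}

#' Keep only read-complete, high-identity candidate locations
#'
#' Abundance estimation treats a read as mapped to a transcript only when
#' the read aligns (near-)end-to-end at high identity, as an end-to-end
#' transcript mapper would; clipped alignments of reads that run past a
#' transcript's boundary count for nothing and in particular cannot create
#' spurious score ties between overlapping partial transcripts.
#'
#' @param hits candidate-location hits from [map_reads()].
#' @param reads the mapped reads (data.frame or named character vector).
#' @param min_read_cov minimum fraction of the read that must align.
#' @param min_identity minimum alignment identity.
#' @return filtered hits.
#' @export
filter_mapped_hits <- function(hits, reads, min_read_cov = 0.9,
                               min_identity = 0.95) {
  if (nrow(hits) == 0) return(hits)
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$id)
  qlen <- nchar(reads)[hits$query]
  hits[(hits$q1 - hits$q0) >= min_read_cov * qlen &
         hits$identity >= min_identity, , drop = FALSE]
}

#' Translated contaminant screen
#'
#' Transcripts whose best translated hit against the contaminant protein
#' set passes the `standard` preset are flagged and removed.
#'
#' @param transcripts named character vector.
#' @param contaminant_proteins named character vector (may be empty).
#' @param params protein-mode [align_params()]; defaults to the `standard`
#'   preset.
#' @return list with `clean` (named character vector), `flagged`
#'   (data.frame `transcript`, `subject`, `identity`) and `mean_identity`
#'   of the flagged set.
#' @export
contaminant_screen <- function(transcripts, contaminant_proteins,
                               params = align_params("protein", preset = "standard")) {
  if (length(transcripts) == 0 || length(contaminant_proteins) == 0)
    return(list(clean = transcripts,
                flagged = data.frame(transcript = character(0),
                                     subject = character(0),
                                     identity = numeric(0),
                                     stringsAsFactors = FALSE),
                mean_identity = NA_real_))
  hits <- translated_search(transcripts, contaminant_proteins, params)
  if (nrow(hits) == 0)
    return(list(clean = transcripts,
                flagged = data.frame(transcript = character(0),
                                     subject = character(0),
                                     identity = numeric(0),
                                     stringsAsFactors = FALSE),
                mean_identity = NA_real_))
  top <- hits[!duplicated(hits$query), , drop = FALSE]
  flagged <- data.frame(transcript = top$query, subject = top$subject,
                        identity = top$identity, stringsAsFactors = FALSE)
  clean <- transcripts[!(names(transcripts) %in% flagged$transcript)]
  list(clean = clean, flagged = flagged,
       mean_identity = mean(flagged$identity))
}

#' Select biologically relevant transcripts for one individual
#'
#' Maps the individual's reads to its transcripts, groups isoforms into
#' components, applies the IsoPct and most-abundant rules, then removes
#' contaminant transcripts.
#'
#' @param transcripts named character vector of assembled transcripts.
#' @param reads reads data.frame (all prepped reads of the individual).
#' @param contaminant_proteins optional named character vector.
#' @param align_params [align_params()] for the read mapping.
#' @param isopct_min,keep_top see [isopct_filter()].
#' @return list with `retained` (named character vector), `table` (the
#'   isopct table), `contaminants` (flagged data.frame),
#'   `contaminant_mean_identity`.
#' @export
select_transcripts <- function(transcripts, reads, contaminant_proteins = NULL,
                               align_params = polymine::align_params(),
                               isopct_min = 1, keep_top = TRUE) {
  mp <- map_reads(reads, transcripts, align_params)
  hits <- filter_mapped_hits(mp$hits, reads)
  comps <- build_components(transcripts, hits)
  counts <- transcript_counts(transcripts, hits)
  tab <- isopct_filter(comps, counts, nchar(transcripts),
                       isopct_min = isopct_min, keep_top = keep_top)
  retained <- transcripts[tab$transcript[tab$retained]]
  cs <- contaminant_screen(retained, contaminant_proteins %||% character(0))
  if (nrow(cs$flagged)) {
    idx <- match(cs$flagged$transcript, tab$transcript)
    tab$retained[idx] <- FALSE
    tab$reason[idx] <- "contaminant"
  }
  list(retained = cs$clean, table = tab, contaminants = cs$flagged,
       contaminant_mean_identity = cs$mean_identity)
}
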