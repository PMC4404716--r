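# Marker design: the filter cascade that turns reliable SNPs into
# array-ready markers. Fixed cascade order: context -> allele screen ->
# paralog -> chloroplast -> splice junction -> cross-set dedup -> probe
# similarity -> array. Every input SNP ends in exactly one of the manifest
# or the rejection log (with its failing stage).

rej_df <- function(snp_id, stage, reason) {
  data.frame(snp_id = snp_id, stage = rep_len(stage, length(snp_id)),
             reason = rep_len(reason, length(snp_id)),
             stringsAsFactors = FALSE)
}

#' Marker-filter parameters
#'
#' @param flank clean-flank length on each side of the SNP (default 35; the
#'   marker context is `2 * flank + 1` bases).
#' @param splice_frac fraction of the context that must align contiguously
#'   to the genome (default 0.95; with flank 35 the threshold is
#'   `ceil(0.95 * 71) = 68` bp).
#' @param paralog_preset hit preset for the self-search paralog filter
#'   (default `standard`: the e-value criterion this surrogate replaces
#'   flags a 92%-identity paralog sharing only a few hundred bases with
#'   enormous margin, whereas a 0.90 identity gate sits within sampling
#'   noise of such a pair; 0.85 over >=60 columns keeps that robustness
#'   while unrelated transcripts never reach it).
#' @param chloro_preset hit preset for the chloroplast screen (default
#'   `loose`).
#' @param splice_preset hit preset for the genome search of the splice
#'   screen (default `loose`).
#' @param probe_min_identity,probe_min_len probe-similarity screen: contexts
#'   aligning at or above this identity over at least this many columns
#'   (but not identical) interfere, and the lower-priority marker is
#'   dropped.
#' @param paralog_count_self whether the self-hit counts toward the
#'   "two or more hits" paralog rule (default TRUE).
#' @param splice_total_hsps use the summed aligned length across hits
#'   rather than the best contiguous hit (default FALSE).
#' @return list of class `filter_params`; `splice_min_match` is derived
#'   from `flank` and `splice_frac`.
#' @export
filter_params <- function(flank = 35L, splice_frac = 0.95,
                          paralog_preset = "standard", chloro_preset = "loose",
                          splice_preset = "loose",
                          probe_min_identity = 0.90, probe_min_len = 60L,
                          paralog_count_self = TRUE,
                          splice_total_hsps = FALSE) {
  flank <- as.integer(flank)
  structure(list(flank = flank, splice_frac = splice_frac,
                 splice_min_match = as.integer(ceiling(splice_frac * (2L * flank + 1L))),
                 paralog_preset = paralog_preset,
                 chloro_preset = chloro_preset,
                 splice_preset = splice_preset,
                 probe_min_identity = probe_min_identity,
                 probe_min_len = as.integer(probe_min_len),
                 paralog_count_self = paralog_count_self,
                 splice_total_hsps = splice_total_hsps),
            class = "filter_params")
}

#' Extract the clean-flank marker context
#'
#' Emits the `2*flank+1`-mer centred on the SNP unless the SNP is within
#' `flank` of a transcript end, another variant (candidate SNP or indel)
#' lies inside the window, or the window contains an ambiguous base.
#'
#' @param calls reliable calls with `snp_id` ([assign_snp_ids()]).
#' @param reference named reference transcriptome.
#' @param variants per-transcript variant table from [call_snps()]
#'   (candidate SNPs and indels).
#' @param flank flank length (default 35).
#' @return list `candidates` (with `context`, `context_bracket`, `alleles`)
#'   and `rejected` (`snp_id`, `stage`, `reason`).
#' @export
extract_context <- function(calls, reference, variants, flank = 35L) {
  n <- nrow(calls)
  keep <- logical(n); reason <- character(n)
  context <- character(n)
  tlen <- nchar(reference)[calls$transcript]
  var_by_t <- split(variants$pos, variants$transcript)
  for (i in seq_len(n)) {
    p <- calls$pos[i]
    if (p < flank || p > tlen[i] - flank - 1L) {
      reason[i] <- "transcript_edge"
      next
    }
    vp <- var_by_t[[calls$transcript[i]]]
    other <- vp[vp != p]
    if (length(other) && any(abs(other - p) <= flank)) {
      reason[i] <- "variant_in_window"
      next
    }
    ctx <- substr(reference[[calls$transcript[i]]], p - flank + 1L,
                  p + flank + 1L)
    if (grepl("[^ACGT]", ctx)) {
      reason[i] <- "ambiguous_base"
      next
    }
    keep[i] <- TRUE
    context[i] <- ctx
  }
  cand <- calls[keep, , drop = FALSE]
  cand$context <- context[keep]
  if (nrow(cand)) {
    cand$context_bracket <- paste0(
      substr(cand$context, 1L, flank),
      "[", cand$ref, "/", cand$alt, "]",
      substr(cand$context, flank + 2L, 2L * flank + 1L))
    cand$alleles <- paste0(cand$ref, "/", cand$alt)
  } else {
    cand$context_bracket <- character(0)
    cand$alleles <- character(0)
  }
  rownames(cand) <- NULL
  list(candidates = cand,
       rejected = rej_df(calls$snp_id[!keep], "context", reason[!keep]))
}

#' Classify alleles and drop strand-ambiguous SNPs
#'
#' A<->G and C<->T are transitions; A/T and C/G read the same on both
#' strands (they would need twice the probes) and are rejected; the rest
#' are transversions.
#'
#' @param candidates candidates from [extract_context()].
#' @return list `candidates` (with `snp_class`) and `rejected`.
#' @export
classify_and_screen_alleles <- function(candidates) {
  pair <- paste0(pmin(candidates$ref, candidates$alt),
                 pmax(candidates$ref, candidates$alt))
  cls <- ifelse(pair %in% c("AG", "CT"), "transition",
                ifelse(pair %in% c("AT", "CG"), "strand-ambiguous",
                       "transversion"))
  keep <- cls != "strand-ambiguous"
  cand <- candidates[keep, , drop = FALSE]
  cand$snp_class <- cls[keep]
  rownames(cand) <- NULL
  list(candidates = cand,
       rejected = rej_df(candidates$snp_id[!keep], "allele_screen",
                         "strand_ambiguous"))
}

#' Paralog filter: self-search of source transcripts
#'
#' Each marker's source transcript is searched against its own set's
#' reference transcriptome at the `strict` preset; the self-hit is
#' expected, and any second hit fails the marker (configurable to ignore
#' the self-hit).
#'
#' @param candidates candidates data.frame.
#' @param reference the set's own reference transcriptome.
#' @param params [filter_params()].
#' @param align base [align_params()].
#' @return list `candidates`, `rejected`.
#' @export
paralog_filter <- function(candidates, reference, params = filter_params(),
                           align = align_params()) {
  if (!nrow(candidates))
    return(list(candidates = candidates,
                rejected = data.frame(snp_id = character(0),
                                      stage = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)))
  tids <- unique(candidates$transcript)
  p <- hit_preset(params$paralog_preset)
  ap <- align
  ap$min_identity <- p$min_identity
  ap$min_matched_len <- p$min_matched_len
  hits <- search_db(reference[intersect(tids, names(reference))], reference, ap)
  nh <- table(hits$query)
  nh_self <- table(hits$query[hits$query != hits$subject])
  n_hits <- if (params$paralog_count_self)
    as.integer(nh[candidates$transcript]) else
    as.integer(nh_self[candidates$transcript])
  n_hits[is.na(n_hits)] <- 0L
  missing_t <- !(candidates$transcript %in% names(reference))
  if (any(missing_t))
    warning("transcript(s) absent from the reference database: ",
            paste(unique(candidates$transcript[missing_t]), collapse = ", "))
  fail <- if (params$paralog_count_self) n_hits >= 2L else n_hits >= 1L
  list(candidates = candidates[!fail, , drop = FALSE],
       rejected = rej_df(candidates$snp_id[fail], "paralog",
                         "multiple_self_hits"))
}

#' Chloroplast screen of marker contexts
#'
#' The 71-mer context is searched against the chloroplast genome at the
#' `loose` preset; any hit fails the marker.
#'
#' @param candidates candidates data.frame.
#' @param chloro_genome named character vector (may be empty).
#' @param params [filter_params()].
#' @param align base [align_params()].
#' @return list `candidates`, `rejected`.
#' @export
chloroplast_screen <- function(candidates, chloro_genome,
                               params = filter_params(),
                               align = align_params()) {
  empty_rej <- data.frame(snp_id = character(0), stage = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  if (!nrow(candidates) || !length(chloro_genome))
    return(list(candidates = candidates, rejected = empty_rej))
  p <- hit_preset(params$chloro_preset)
  ap <- align
  ap$min_identity <- p$min_identity
  ap$min_matched_len <- p$min_matched_len
  ctx <- setNames(candidates$context, candidates$snp_id)
  hits <- search_db(ctx, chloro_genome, ap)
  fail <- candidates$snp_id %in% hits$query
  list(candidates = candidates[!fail, , drop = FALSE],
       rejected = rej_df(candidates$snp_id[fail], "chloroplast",
                         "chloroplast_hit"))
}

#' Splice-junction screen of marker contexts
#'
#' Contexts are aligned to the (intron-containing) genome; a context whose
#' best hit aligns fewer than `splice_min_match` contiguous bases likely
#' spans an exon junction and is discarded. Contexts with no genomic hit
#' pass.
#'
#' @param candidates candidates data.frame.
#' @param genome named character vector of genomic scaffolds (may be empty).
#' @param params [filter_params()].
#' @param align base [align_params()].
#' @return list `candidates`, `rejected`.
#' @export
splice_junction_screen <- function(candidates, genome,
                                   params = filter_params(),
                                   align = align_params()) {
  empty_rej <- data.frame(snp_id = character(0), stage = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  if (!nrow(candidates) || !length(genome))
    return(list(candidates = candidates, rejected = empty_rej))
  p <- hit_preset(params$splice_preset)
  ap <- align
  ap$min_identity <- p$min_identity
  ap$min_matched_len <- 0L          # short junction pieces must be seen
  ap$min_hit_score <- 2L * ap$k
  ctx <- setNames(candidates$context, candidates$snp_id)
  hits <- search_db(ctx, genome, ap)
  fail <- logical(nrow(candidates))
  if (nrow(hits)) {
    span <- hits$q1 - hits$q0
    matched <- if (params$splice_total_hsps)
      tapply(span, hits$query, sum) else tapply(span, hits$query, max)
    m <- as.integer(matched[candidates$snp_id])
    fail <- !is.na(m) & m < params$splice_min_match
  }
  list(candidates = candidates[!fail, , drop = FALSE],
       rejected = rej_df(candidates$snp_id[fail], "splice_junction",
                         "junction_spanning"))
}

canonical_context <- function(context, alleles) {
  rc <- cpp_revcomp(context)
  rc_alleles <- vapply(strsplit(alleles, "/", fixed = TRUE), function(a) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(sort(comp[a]), collapse = "/")
  }, "")
  fwd_alleles <- vapply(strsplit(alleles, "/", fixed = TRUE), function(a)
    paste(sort(a), collapse = "/"), "")
  fwd <- paste0(context, "|", fwd_alleles)
  rev <- paste0(rc, "|", rc_alleles)
  ifelse(fwd <= rev, fwd, rev)
}

#' Remove markers redundant across sample sets
#'
#' Two markers are redundant when their contexts (or reverse complements)
#' are identical and their alleles match; the copy from the
#' highest-priority set (the order of `set_priority`) is kept, ties broken
#' by snp_id.
#'
#' @param candidates candidates data.frame with a `set` column.
#' @param set_priority character vector of set codes, highest priority
#'   first.
#' @return list `candidates`, `rejected`.
#' @export
cross_set_dedup <- function(candidates, set_priority) {
  if (!nrow(candidates))
    return(list(candidates = candidates,
                rejected = data.frame(snp_id = character(0),
                                      stage = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)))
  key <- canonical_context(candidates$context, candidates$alleles)
  pri <- match(candidates$set, set_priority)
  ord <- order(pri, candidates$snp_id, method = "radix")
  dup <- duplicated(key[ord])[order(ord)]  # back to original row order
  keep <- !dup
  list(candidates = candidates[keep, , drop = FALSE],
       rejected = rej_df(candidates$snp_id[!keep], "cross_set_dedup",
                         "redundant_across_sets"))
}

#' Probe-similarity screen
#'
#' Near-identical (but non-identical) contexts on either strand interfere
#' during hybridisation; of each offending pair the lower-priority marker
#' (by set priority, then snp_id) is dropped.
#'
#' @param candidates candidates data.frame with a `set` column.
#' @param set_priority set codes, highest priority first.
#' @param params [filter_params()].
#' @param align base [align_params()].
#' @return list `candidates`, `rejected`.
#' @export
probe_similarity_screen <- function(candidates, set_priority,
                                    params = filter_params(),
                                    align = align_params()) {
  empty_rej <- data.frame(snp_id = character(0), stage = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  if (nrow(candidates) < 2L)
    return(list(candidates = candidates, rejected = empty_rej))
  ctx <- setNames(candidates$context, candidates$snp_id)
  ap <- align
  ap$min_identity <- params$probe_min_identity
  ap$min_matched_len <- params$probe_min_len
  ap$min_hit_score <- 2L * ap$k
  hits <- search_db(ctx, ctx, ap)
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  if (!nrow(hits))
    return(list(candidates = candidates, rejected = empty_rej))
  pri <- setNames(order(order(match(candidates$set, set_priority),
                              candidates$snp_id, method = "radix")),
                  candidates$snp_id)
  a <- ifelse(pri[hits$query] <= pri[hits$subject], hits$query, hits$subject)
  b <- ifelse(pri[hits$query] <= pri[hits$subject], hits$subject, hits$query)
  pairs <- unique(data.frame(keep = a, drop = b, stringsAsFactors = FALSE))
  pairs <- pairs[order_c(pri[pairs$keep], pri[pairs$drop]), , drop = FALSE]
  dropped <- character(0)
  for (r in seq_len(nrow(pairs))) {
    if (pairs$keep[r] %in% dropped) next
    if (pairs$drop[r] %in% dropped) next
    dropped <- c(dropped, pairs$drop[r])
  }
  keep <- !(candidates$snp_id %in% dropped)
  list(candidates = candidates[keep, , drop = FALSE],
       rejected = rej_df(candidates$snp_id[!keep], "probe_similarity",
                         "similar_context"))
}

#' Build the array manifest from surviving markers
#'
#' Two probes per SNP - the context and its reverse complement - with
#' probe ids `{snp_id}_F` / `{snp_id}_R`.
#'
#' @param markers surviving candidates data.frame.
#' @param rhfv optional named map transcript -> Rh-Fv ortholog id.
#' @param protein optional named map transcript -> guide protein id.
#' @param annotation optional named map protein -> annotation text.
#' @return list `manifest` (data.frame in manifest column order) and
#'   `probes` (two rows per marker).
#' @export
build_array <- function(markers, rhfv = NULL, protein = NULL,
                        annotation = NULL) {
  n <- nrow(markers)
  if (n == 0) {
    manifest <- data.frame(snp_id = character(0),
                           probe_id_fwd = character(0),
                           probe_id_rev = character(0),
                           context = character(0), alleles = character(0),
                           transcript = character(0), rhfv = character(0),
                           protein = character(0), annotation = character(0),
                           stringsAsFactors = FALSE)
    probes <- data.frame(probe_id = character(0), snp_id = character(0),
                         strand = character(0), seq = character(0),
                         stringsAsFactors = FALSE)
    return(list(manifest = manifest, probes = probes))
  }
  lookup <- function(map, key) {
    if (is.null(map) || !length(map)) return(rep("", length(key)))
    v <- unname(map[key]); v[is.na(v)] <- ""; v
  }
  prot <- lookup(protein, markers$transcript)
  manifest <- data.frame(
    snp_id = markers$snp_id,
    probe_id_fwd = paste0(markers$snp_id, "_F"),
    probe_id_rev = paste0(markers$snp_id, "_R"),
    context = markers$context_bracket,
    alleles = markers$alleles,
    transcript = markers$transcript,
    rhfv = lookup(rhfv, markers$transcript),
    protein = prot,
    annotation = lookup(annotation, prot),
    stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$snp_id))
    stop("duplicate snp_id in manifest: ",
         manifest$snp_id[anyDuplicated(manifest$snp_id)][1], call. = FALSE)
  manifest <- manifest[order_c(manifest$snp_id), , drop = FALSE]
  rownames(manifest) <- NULL
  probes <- data.frame(
    probe_id = c(rbind(manifest$probe_id_fwd, manifest$probe_id_rev)),
    snp_id = rep(manifest$snp_id, each = 2L),
    strand = rep(c("+", "-"), n),
    seq = c(rbind(sub("\\[([ACGT])/[ACGT]\\]", "\\1", manifest$context),
                  cpp_revcomp(sub("\\[([ACGT])/[ACGT]\\]", "\\1",
                                  manifest$context)))),
    stringsAsFactors = FALSE)
  list(manifest = manifest, probes = probes)
}

#' Run the whole marker-design cascade
#'
#' Applies, per set: context extraction, allele screen, paralog filter,
#' chloroplast screen, splice screen; then across sets: redundancy
#' removal, probe-similarity screen, and manifest construction.
#'
#' @param sets named list (by set code) with elements `calls` (with
#'   snp_id), `reference`, `variants`.
#' @param chloro_genome,genome named character vectors (either may be
#'   empty).
#' @param params [filter_params()].
#' @param align [align_params()].
#' @param rhfv,protein,annotation optional manifest lookup maps (see
#'   [build_array()]).
#' @return list `manifest`, `probes`, `markers`, `rejections`, and
#'   per-stage `counts`.
#' @export
design_markers <- function(sets, chloro_genome = character(0),
                           genome = character(0), params = filter_params(),
                           align = align_params(), rhfv = NULL,
                           protein = NULL, annotation = NULL) {
  rejections <- list()
  per_set <- list()
  for (code in names(sets)) {
    s <- sets[[code]]
    st <- extract_context(s$calls, s$reference, s$variants, params$flank)
    rejections[[paste0(code, "_context")]] <- st$rejected
    st2 <- classify_and_screen_alleles(st$candidates)
    rejections[[paste0(code, "_allele")]] <- st2$rejected
    st3 <- paralog_filter(st2$candidates, s$reference, params, align)
    rejections[[paste0(code, "_paralog")]] <- st3$rejected
    st4 <- chloroplast_screen(st3$candidates, chloro_genome, params, align)
    rejections[[paste0(code, "_chloro")]] <- st4$rejected
    st5 <- splice_junction_screen(st4$candidates, genome, params, align)
    rejections[[paste0(code, "_splice")]] <- st5$rejected
    cand <- st5$candidates
    if (nrow(cand)) cand$set <- code
    per_set[[code]] <- cand
  }
  all_cand <- do.call(rbind, per_set[vapply(per_set, nrow, 0L) > 0])
  if (is.null(all_cand))
    all_cand <- data.frame(snp_id = character(0), set = character(0),
                           context = character(0), alleles = character(0),
                           stringsAsFactors = FALSE)
  rownames(all_cand) <- NULL
  dd <- cross_set_dedup(all_cand, names(sets))
  rejections[["cross_set"]] <- dd$rejected
  ps <- probe_similarity_screen(dd$candidates, names(sets), params, align)
  rejections[["probe_similarity"]] <- ps$rejected
  arr <- build_array(ps$candidates, rhfv, protein, annotation)
  rej <- do.call(rbind, rejections)
  rownames(rej) <- NULL
  stage_order <- c("context", "allele_screen", "paralog", "chloroplast",
                   "splice_junction", "cross_set_dedup", "probe_similarity")
  counts <- data.frame(stage = c("input", stage_order, "manifest"),
                       n = c(sum(vapply(sets, function(s) nrow(s$calls), 0L)),
                             vapply(stage_order, function(st)
                               sum(rej$stage == st), 0L),
                             nrow(arr$manifest)),
                       stringsAsFactors = FALSE)
  list(manifest = arr$manifest, probes = arr$probes,
       markers = ps$candidates, rejections = rej, counts = counts)
}
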