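# Haplotype-aware reliable-SNP mining: per-set reference construction,
# mapq-filtered pileups, candidate sites with a per-allele read floor,
# agglomerative haplotype clustering over polymorphic sites, ploidy
# ceilings, and the reliable-call rule (each major allele backed by >= 5
# reads and at least one haplotype cluster).

#' Ploidy model for a pooled sample set
#'
#' @param ploidy haplotypes per individual (default 4).
#' @param n_individuals individuals pooled (default 2).
#' @return list with `ploidy`, `n_individuals` and the haplotype ceiling
#'   `max_haplotypes = ploidy * n_individuals` (8 for two tetraploid
#'   parents).
#' @export
ploidy_model <- function(ploidy = 4L, n_individuals = 2L) {
  stopifnot(ploidy >= 1L, n_individuals >= 1L)
  list(ploidy = as.integer(ploidy),
       n_individuals = as.integer(n_individuals),
       max_haplotypes = as.integer(ploidy) * as.integer(n_individuals))
}

#' SNP-calling parameters
#'
#' @param min_reads_per_allele minimum reads per allele (default 5).
#' @param sim_min minimum similarity over shared polymorphic sites for two
#'   read clusters to merge (default 0.8).
#' @param mapq_min mapping-quality filter, exclusive (default 25).
#' @param min_shared_sites minimum shared covered polymorphic sites for two
#'   reads/clusters to be comparable; incomparable clusters never merge.
#' @param min_indel_reads deletion evidence (reads) for a position to count
#'   as an indel variant in the flank screen.
#' @return list of class `snp_params`.
#' @export
snp_params <- function(min_reads_per_allele = 5L, sim_min = 0.8,
                       mapq_min = 25L, min_shared_sites = 1L,
                       min_indel_reads = 5L) {
  structure(list(min_reads_per_allele = as.integer(min_reads_per_allele),
                 sim_min = sim_min, mapq_min = as.integer(mapq_min),
                 min_shared_sites = as.integer(min_shared_sites),
                 min_indel_reads = as.integer(min_indel_reads)),
            class = "snp_params")
}

#' Assemble per-sample transcripts into a reference transcriptome
#'
#' Greedy overlap-consensus assembly at 97% overlap identity across the
#' samples of a set; the membership map records which input transcript
#' entered which reference contig at which offset/orientation.
#'
#' @param sample_transcripts named list (per sample) of named character
#'   vectors; ids are prefixed with the sample name when not already
#'   unique.
#' @param params [asm_params()].
#' @return list `reference` (named character vector) and `members`
#'   (data.frame).
#' @export
build_reference <- function(sample_transcripts, params = asm_params()) {
  stopifnot(length(sample_transcripts) >= 1)
  pool <- character(0)
  for (s in names(sample_transcripts)) {
    x <- sample_transcripts[[s]]
    check_named_seqs(x, paste0("transcripts of ", s))
    pool <- c(pool, x)
  }
  if (anyDuplicated(names(pool)))
    stop("transcript ids collide across samples; prefix them with the sample name")
  asm <- overlap_assemble(pool, params)
  names(asm$contigs) <- sprintf("t%04d", seq_along(asm$contigs))
  asm$members$contig <- sprintf("t%04d", match(asm$members$contig,
                                               unique(asm$members$contig)))
  list(reference = asm$contigs, members = asm$members)
}

#' Candidate polymorphic positions from a pileup
#'
#' A position is a candidate when at least two distinct unambiguous bases
#' each have at least `min_reads` passing reads.
#'
#' @param counts 6 x L pileup count matrix (rows A,C,G,T,N,-) as returned
#'   by the internal pileup kernel.
#' @param min_reads per-allele read floor (default 5).
#' @return integer vector of 0-based candidate positions.
#' @export
call_candidates <- function(counts, min_reads = 5L) {
  acgt <- counts[1:4, , drop = FALSE]
  which(colSums(acgt >= min_reads) >= 2L) - 1L
}

#' Cluster reads into haplotypes over candidate positions
#'
#' Reads are collapsed to identical allele profiles, then clustered
#' agglomeratively: the pair of clusters with the highest similarity
#' (fraction of agreeing consensus alleles over shared covered candidate
#' positions, requiring at least `min_shared` shared sites) merges while
#' that similarity is at least `sim_min`. Clusters with fewer than two
#' reads are discarded as noise.
#'
#' @param alleles character matrix reads x candidate positions, `""` where
#'   a read does not cover the position.
#' @param sim_min merge threshold (default 0.8).
#' @param min_shared minimum shared covered sites (default 1).
#' @param min_hap_reads read floor for a cluster to count as an observed
#'   haplotype toward the ceiling (default 5, the same confidence floor
#'   the per-allele read rule uses; clusters of 2-4 reads still exist and
#'   can support alleles but are not evidence of an extra haplotype).
#' @return list of clusters, each `list(consensus =` named character vector
#'   over covered positions`, n_reads, profile_ids)`; the full set is in
#'   `attr(, "all_clusters")` with the noise clusters included.
#' @export
cluster_haplotypes <- function(alleles, sim_min = 0.8, min_shared = 1L,
                               min_hap_reads = 5L) {
  if (is.null(dim(alleles)) || nrow(alleles) == 0 || ncol(alleles) == 0)
    return(structure(list(), n_noise = 0L))
  npos <- ncol(alleles)
  covered <- alleles != ""
  keep <- rowSums(covered) >= 1L
  alleles <- alleles[keep, , drop = FALSE]
  covered <- covered[keep, , drop = FALSE]
  if (nrow(alleles) == 0) return(structure(list(), n_noise = 0L))
  prof_key <- apply(alleles, 1L, paste, collapse = "\r")
  uniq <- !duplicated(prof_key)
  profs <- alleles[uniq, , drop = FALSE]
  weights <- as.integer(table(factor(prof_key, levels = prof_key[uniq])))
  np <- nrow(profs)
  bases <- c("A", "C", "G", "T")
  ## cluster state: weighted base counts, cached consensus, similarity matrix
  counts <- lapply(seq_len(np), function(i) {
    cnt <- matrix(0L, 4L, npos, dimnames = list(bases, NULL))
    for (p in which(profs[i, ] != "")) {
      b <- profs[i, p]
      if (b %in% bases) cnt[b, p] <- weights[i]
    }
    cnt
  })
  consensus_of <- function(cnt) {
    tot <- colSums(cnt)
    cons <- rep(NA_character_, npos)
    idx <- which(tot > 0)
    if (length(idx))
      cons[idx] <- bases[apply(cnt[, idx, drop = FALSE], 2L, which.max)]
    cons
  }
  cons <- lapply(counts, consensus_of)
  n_reads <- weights
  members <- as.list(seq_len(np))
  alive <- rep(TRUE, np)
  pair_sim <- function(a, b) {
    sh <- !is.na(a) & !is.na(b)
    if (sum(sh) < min_shared) return(NA_real_)
    mean(a[sh] == b[sh])
  }
  simmat <- matrix(NA_real_, np, np)
  if (np > 1) {
    for (i in seq_len(np - 1L))
      for (j in (i + 1L):np)
        simmat[i, j] <- pair_sim(cons[[i]], cons[[j]])
  }
  repeat {
    if (sum(alive) < 2L) break
    best_sim <- suppressWarnings(max(simmat, na.rm = TRUE))
    if (!is.finite(best_sim) || best_sim < sim_min) break
    w <- which(simmat == best_sim)
    w <- w[1]  # column-major first => smallest (j, then i): deterministic
    j <- ((w - 1L) %/% np) + 1L
    i <- ((w - 1L) %% np) + 1L
    counts[[i]] <- counts[[i]] + counts[[j]]
    cons[[i]] <- consensus_of(counts[[i]])
    n_reads[i] <- n_reads[i] + n_reads[j]
    members[[i]] <- c(members[[i]], members[[j]])
    alive[j] <- FALSE
    simmat[j, ] <- NA_real_; simmat[, j] <- NA_real_
    for (k in which(alive)) {
      if (k == i) next
      s <- pair_sim(cons[[i]], cons[[k]])
      if (k < i) simmat[k, i] <- s else simmat[i, k] <- s
    }
  }
  ## linkage components over candidate positions: two positions are linked
  ## when some read covers both; clusters never span components (merging
  ## requires shared sites), so the observable haplotype count of the
  ## transcript is the maximum cluster count within one component
  pos_comp <- seq_len(npos)
  for (i in seq_len(np)) {
    cov_i <- which(profs[i, ] != "")
    if (length(cov_i) > 1L) {
      tgt <- min(pos_comp[cov_i])
      pos_comp[pos_comp %in% pos_comp[cov_i]] <- tgt
    }
  }
  res <- lapply(which(alive), function(i) {
    idx <- which(!is.na(cons[[i]]))
    list(consensus = setNames(cons[[i]][idx], idx), n_reads = n_reads[i],
         profile_ids = members[[i]], component = pos_comp[idx[1]])
  })
  good <- vapply(res, function(cl) cl$n_reads >= 2L, TRUE)
  res <- res[good]
  ## observable haplotype count: the maximum number of strong clusters
  ## covering any single site. Regional fragments of one haplotype (reads
  ## that cannot be chained across a sparse stretch) never co-cover a
  ## site, so they do not double-count; collapsed paralogs stack their
  ## cluster sets on the same dense sites and still exceed the ceiling.
  strong <- vapply(res, function(cl) cl$n_reads >= min_hap_reads, TRUE)
  n_eff <- 0L
  if (any(strong)) {
    per_site <- integer(npos)
    for (cl in res[strong]) {
      idx <- as.integer(names(cl$consensus))
      per_site[idx] <- per_site[idx] + 1L
    }
    n_eff <- max(per_site)
  }
  structure(res, n_noise = sum(!good), n_hap_max = n_eff,
            position_components = pos_comp)
}

#' Haplotype-ceiling filter
#'
#' All SNPs of a transcript whose surviving cluster count exceeds the
#' ceiling are discarded.
#'
#' @param n_clusters surviving cluster count of a transcript.
#' @param ploidy_model [ploidy_model()].
#' @return TRUE to keep the transcript's SNPs.
#' @export
filter_by_ploidy <- function(n_clusters, ploidy_model) {
  n_clusters <= ploidy_model$max_haplotypes
}

#' Call reliable SNPs on one sample set
#'
#' Maps all reads of the set to the reference, keeps alignments with
#' `mapq > mapq_min`, finds candidate sites, clusters reads into
#' haplotypes, applies the ploidy ceiling, and flags a candidate reliable
#' when each of its two most frequent alleles is backed by at least
#' `min_reads_per_allele` reads and is the consensus allele of at least
#' one surviving cluster.
#'
#' @param reads reads data.frame (pooled reads of the set).
#' @param reference named character vector (reference transcriptome).
#' @param ploidy ploidy model from [ploidy_model()].
#' @param params [snp_params()].
#' @param align [align_params()] for the mapping.
#' @return list with `calls` (reliable SNP data.frame), `candidates`
#'   (including non-reliable ones and their failure reason), `variants`
#'   (per-transcript candidate + indel positions for the flank screen),
#'   `transcript_stats`, and `mapping` summary.
#' @export
call_snps <- function(reads, reference, ploidy = ploidy_model(),
                      params = snp_params(), align = align_params()) {
  mp <- map_reads(reads, reference, align, mapq_min = params$mapq_min)
  aln <- mp$alignments
  aln <- aln[aln$pass, , drop = FALSE]
  calls <- list(); cands <- list(); variants <- list(); stats <- list()
  idx_by_subject <- split(seq_len(nrow(aln)), aln$subject_id)
  for (tid in names(reference)) {
    sub <- aln[idx_by_subject[[tid]] %||% integer(0), , drop = FALSE]
    tlen <- nchar(reference[[tid]])
    if (nrow(sub) == 0) next
    counts <- cpp_pileup(tlen, sub$s0, sub$proj)
    cand <- call_candidates(counts, params$min_reads_per_allele)
    dels <- which(counts[6, ] >= params$min_indel_reads) - 1L
    if (length(cand) + length(dels))
      variants[[tid]] <- data.frame(
        transcript = tid,
        pos = c(cand, dels),
        type = rep(c("snp", "indel"), c(length(cand), length(dels))),
        stringsAsFactors = FALSE)
    depth <- colSums(counts[1:5, , drop = FALSE])
    if (length(cand) == 0) {
      stats[[tid]] <- data.frame(transcript = tid, length = tlen,
                                 n_reads = nrow(sub),
                                 mean_depth = mean(depth),
                                 n_clusters = 0L, ceiling_ok = TRUE,
                                 n_reliable = 0L, stringsAsFactors = FALSE)
      next
    }
    am <- cpp_alleles_at(sub$s0, sub$proj, cand)
    cl <- cluster_haplotypes(am, params$sim_min, params$min_shared_sites,
                             params$min_reads_per_allele)
    n_cl <- attr(cl, "n_hap_max") %||% length(cl)
    ceiling_ok <- filter_by_ploidy(n_cl, ploidy)
    rows <- lapply(seq_along(cand), function(ci) {
      p <- cand[ci]
      cnt <- counts[1:4, p + 1L]
      ord <- order(-cnt, c("A", "C", "G", "T"), method = "radix")
      a1 <- c("A", "C", "G", "T")[ord[1]]; n1 <- cnt[ord[1]]
      a2 <- c("A", "C", "G", "T")[ord[2]]; n2 <- cnt[ord[2]]
      key <- as.character(ci)
      hap1 <- sum(vapply(cl, function(x)
        !is.na(x$consensus[key]) && identical(unname(x$consensus[key]), a1),
        TRUE))
      hap2 <- sum(vapply(cl, function(x)
        !is.na(x$consensus[key]) && identical(unname(x$consensus[key]), a2),
        TRUE))
      reliable <- ceiling_ok && n1 >= params$min_reads_per_allele &&
        n2 >= params$min_reads_per_allele && hap1 >= 1L && hap2 >= 1L
      reason <- if (reliable) "" else if (!ceiling_ok) "haplotype_ceiling"
        else if (n2 < params$min_reads_per_allele) "allele_depth"
        else "haplotype_support"
      data.frame(transcript = tid, pos = p, ref = a1, alt = a2,
                 n_ref = as.integer(n1), n_alt = as.integer(n2),
                 hap_ref = hap1, hap_alt = hap2, n_clusters = n_cl,
                 reliable = reliable, reason = reason,
                 stringsAsFactors = FALSE)
    })
    tc <- do.call(rbind, rows)
    cands[[tid]] <- tc
    rel <- tc[tc$reliable, , drop = FALSE]
    if (nrow(rel)) calls[[tid]] <- rel
    stats[[tid]] <- data.frame(transcript = tid, length = tlen,
                               n_reads = nrow(sub), mean_depth = mean(depth),
                               n_clusters = n_cl, ceiling_ok = ceiling_ok,
                               n_reliable = nrow(rel), stringsAsFactors = FALSE)
  }
  bindf <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  proto_calls <- data.frame(transcript = character(0), pos = integer(0),
                            ref = character(0), alt = character(0),
                            n_ref = integer(0), n_alt = integer(0),
                            hap_ref = integer(0), hap_alt = integer(0),
                            n_clusters = integer(0), reliable = logical(0),
                            reason = character(0), stringsAsFactors = FALSE)
  out_calls <- bindf(calls, proto_calls)
  rownames(out_calls) <- NULL
  out_cands <- bindf(cands, proto_calls)
  rownames(out_cands) <- NULL
  out_vars <- bindf(variants, data.frame(transcript = character(0),
                                         pos = integer(0), type = character(0),
                                         stringsAsFactors = FALSE))
  out_stats <- bindf(stats, data.frame())
  rownames(out_stats) <- NULL
  list(calls = out_calls, candidates = out_cands, variants = out_vars,
       transcript_stats = out_stats,
       mapping = data.frame(n_reads = length(unique(mp$alignments$query_id)),
                            n_pass = nrow(aln)))
}

#' Per-transcript SNP statistics
#'
#' Density is reliable SNPs x 100 / transcript length; transitions are
#' A<->G and C<->T.
#'
#' @param calls reliable calls from [call_snps()].
#' @param transcript_stats per-transcript stats from [call_snps()].
#' @return list with `per_transcript` (transcripts with >= 1 reliable SNP),
#'   `summary` (one row: transcript count, mean length/coverage, SNP range,
#'   density mean/sd, transition fraction) and `histogram`
#'   (SNPs-per-transcript counts).
#' @export
snp_stats <- function(calls, transcript_stats) {
  ts <- transcript_stats[transcript_stats$n_reliable > 0, , drop = FALSE]
  per <- ts
  if (nrow(per)) {
    per$density <- per$n_reliable * 100 / per$length
  } else per$density <- numeric(0)
  trans <- if (nrow(calls))
    mean(paste0(pmin(calls$ref, calls$alt), pmax(calls$ref, calls$alt)) %in%
           c("AG", "CT")) else NA_real_
  summary <- data.frame(
    n_transcripts = nrow(per),
    mean_length = if (nrow(per)) mean(per$length) else NA_real_,
    sd_length = if (nrow(per)) stats::sd(per$length) else NA_real_,
    mean_coverage = if (nrow(per)) mean(per$mean_depth) else NA_real_,
    sd_coverage = if (nrow(per)) stats::sd(per$mean_depth) else NA_real_,
    snp_min = if (nrow(per)) min(per$n_reliable) else NA_integer_,
    snp_max = if (nrow(per)) max(per$n_reliable) else NA_integer_,
    density_mean = if (nrow(per)) mean(per$density) else NA_real_,
    density_sd = if (nrow(per)) stats::sd(per$density) else NA_real_,
    transition_fraction = trans)
  hist <- if (nrow(per)) {
    h <- table(per$n_reliable)
    data.frame(n_snps = as.integer(names(h)), n_transcripts = as.integer(h))
  } else data.frame(n_snps = integer(0), n_transcripts = integer(0))
  list(per_transcript = per, summary = summary, histogram = hist)
}

#' Assign marker ids to reliable calls
#'
#' Ids follow `{set_code}_{transcript number}_{SNP number}`; transcript
#' numbers are the reference contig indices, SNP numbers the 1-based rank
#' of the SNP position within its transcript.
#'
#' @param calls reliable calls data.frame.
#' @param reference named reference used to number transcripts.
#' @param set_code one-letter set code.
#' @return `calls` with an `snp_id` column.
#' @export
assign_snp_ids <- function(calls, reference, set_code) {
  if (!nrow(calls)) { calls$snp_id <- character(0); return(calls) }
  tnum <- match(calls$transcript, names(reference))
  ord <- order(tnum, calls$pos, method = "radix")
  calls <- calls[ord, , drop = FALSE]
  tnum <- tnum[ord]
  snum <- stats::ave(calls$pos, calls$transcript, FUN = seq_along)
  calls$snp_id <- sprintf("%s_%d_%d", set_code, tnum, as.integer(snum))
  rownames(calls) <- NULL
  calls
}
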