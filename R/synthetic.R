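# Synthetic-data generator: tetraploid gene models with planted haplotypes
# and SNPs, paralog pairs, exon-skipping splice variants, chloroplast and
# fungal-contaminant decoys, fragment "assemblies" per individual, a guide
# proteome, and seeded read simulation with a per-read origin table.

#' Simulation parameters
#'
#' Defaults emulate a mapping-population sample set: two pooled tetraploid
#' individuals, ~0.5 SNPs per 100 bp with 60% transitions, paralog pairs at
#' 92% identity, exon-skipping isoforms, chloroplast windows and fungal
#' decoys, 2 x 100 bp paired-end reads at 30x per-haplotype coverage with a
#' 0.5% substitution error rate.
#'
#' @param n_genes number of nuclear genes (paralog partners and singleton
#'   genes are added on top).
#' @param gene_len_mean,gene_len_sd transcript length distribution (bp).
#' @param ploidy haplotypes per individual (default 4, tetraploid).
#' @param n_individuals individuals pooled per set (default 2).
#' @param snp_density planted SNP probability per base (default 0.005,
#'   i.e. 0.5 per 100 bp).
#' @param transition_fraction fraction of planted SNPs that are transitions.
#' @param paralog_fraction fraction of genes given a paralog partner.
#' @param paralog_identity nucleotide identity of paralog partners.
#' @param splice_variant_fraction fraction of >=3-exon genes given an
#'   exon-skipping isoform.
#' @param iso_share read share of the skipped isoform.
#' @param multi_exon_fraction fraction of genes with 2-4 exons.
#' @param tiled_fraction,truncated_fraction gene presentation mix: `tiled`
#'   genes arrive as 2-3 overlapping fragments, `truncated` ones in
#'   addition lack the 5' start (never full length); the rest arrive as one
#'   full transcript.
#' @param n_singletons genes expressed in a single individual as a single
#'   transcript (ortholog-group singletons).
#' @param n_chloro,chloro_genome_len chloroplast decoy windows and genome
#'   size.
#' @param n_contaminants fungal decoy proteins/transcripts.
#' @param contaminant_divergence nucleotide divergence of contaminant
#'   transcripts from their proteins' coding sequence.
#' @param protein_divergence amino-acid divergence of the guide proteome
#'   from the planted coding sequences.
#' @param read_len,insert_mean,insert_sd,read_error_rate,coverage read
#'   simulation settings; coverage is per haplotype copy.
#' @param regime `"illumina"` (paired-end) or `"long"` (single-end,
#'   indel-biased errors).
#' @param set_name,set_code sample-set label and one-letter code.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 100L, gene_len_mean = 1000, gene_len_sd = 200,
                       ploidy = 4L, n_individuals = 2L, snp_density = 0.005,
                       transition_fraction = 0.60, paralog_fraction = 0.06,
                       paralog_identity = 0.92,
                       splice_variant_fraction = 0.3, iso_share = 0.10,
                       multi_exon_fraction = 0.7,
                       tiled_fraction = 0.35, truncated_fraction = 0.30,
                       n_singletons = 3L,
                       n_chloro = 6L, chloro_genome_len = 12000L,
                       n_contaminants = 6L, contaminant_divergence = 0.02,
                       protein_divergence = 0.05,
                       read_len = 100L, insert_mean = 200, insert_sd = 40,
                       read_error_rate = 0.005, coverage = 30,
                       regime = c("illumina", "long"),
                       set_name = "K5", set_code = "K", seed = 1L) {
  rates <- c(snp_density, transition_fraction, paralog_fraction,
             splice_variant_fraction, iso_share, multi_exon_fraction,
             tiled_fraction, truncated_fraction, contaminant_divergence,
             protein_divergence, read_error_rate)
  stopifnot(all(rates >= 0 & rates <= 1), paralog_identity > 0,
            paralog_identity <= 1, coverage >= 0)
  structure(as.list(environment())[c(
    "n_genes", "gene_len_mean", "gene_len_sd", "ploidy", "n_individuals",
    "snp_density", "transition_fraction", "paralog_fraction",
    "paralog_identity", "splice_variant_fraction", "iso_share",
    "multi_exon_fraction", "tiled_fraction", "truncated_fraction",
    "n_singletons", "n_chloro", "chloro_genome_len", "n_contaminants",
    "contaminant_divergence", "protein_divergence", "read_len",
    "insert_mean", "insert_sd", "read_error_rate", "coverage",
    "set_name", "set_code", "seed")] |>
      c(list(regime = match.arg(regime))),
    class = "sim_params")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

sense_codons <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      cache <<- list(sense = names(gc_tab)[gc_tab != "*"],
                     stops = names(gc_tab)[gc_tab == "*"],
                     by_aa = split(names(gc_tab), unname(gc_tab)))
    }
    cache
  }
})

## substitute characters at positions (1-based) in a string
subst_chars <- function(seq, pos, chars) {
  if (!length(pos)) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  v[pos] <- chars
  paste(v, collapse = "")
}

## pick an alternative allele for each ref base
pick_alt <- function(ref, transition_fraction) {
  n <- length(ref)
  is_ts <- runif(n) < transition_fraction
  alt <- character(n)
  alt[is_ts] <- TRANSITION[ref[is_ts]]
  if (any(!is_ts)) {
    tv <- vapply(ref[!is_ts], function(b) {
      opts <- setdiff(c("A", "C", "G", "T"), c(b, TRANSITION[[b]]))
      opts[sample.int(2L, 1L)]
    }, "")
    alt[!is_ts] <- tv
  }
  alt
}

## mutate a transcript at exactly round(rate * L) positions without
## introducing in-frame stops in [cds_start, cds_end) (0-based); the fixed
## substitution count keeps the planted divergence at its declared value
## (binomial per-base noise can drift a 92%-identity pair across the 90%
## paralog-filter boundary). Substitution positions are rejection-sampled
## so no conserved run exceeds max_run: a perfectly identical stretch
## longer than a read would let reads tie-multimap across the two genes,
## which collapses transcripts of different genes into one "isoform
## component" - something a graph-based assembler would not do.
mutate_keep_orf <- function(seq, rate, cds_start, cds_end, max_run = 80L) {
  L <- nchar(seq)
  n_sub <- min(L, round(rate * L))
  if (n_sub < 1L) return(seq)
  pos <- sample.int(L, n_sub)
  for (try in 1:50) {
    gaps <- diff(c(0L, sort(pos), L + 1L))
    if (max(gaps) <= max_run) break
    pos <- sample.int(L, n_sub)
  }
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  orig <- v
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    v[p] <- sample(setdiff(bases, v[p]), 1L)
  }
  ## revert codons that became stops (keep the planted terminal stop)
  stops <- sense_codons()$stops
  cs <- cds_start + 1L
  ncod <- (cds_end - cds_start) %/% 3L
  for (ci in seq_len(ncod - 1L)) {
    a <- cs + (ci - 1L) * 3L
    cod <- paste(v[a:(a + 2L)], collapse = "")
    if (cod %in% stops) v[a:(a + 2L)] <- orig[a:(a + 2L)]
  }
  paste(v, collapse = "")
}

mutate_protein <- function(aa, rate) {
  L <- nchar(aa)
  if (L < 3L) return(aa)
  pos <- which(runif(L) < rate)
  pos <- pos[pos > 1L]  # keep the initial M
  if (!length(pos)) return(aa)
  aas <- strsplit(AA_ALPHABET_SEED, "")[[1]]
  v <- strsplit(aa, "", fixed = TRUE)[[1]]
  for (p in pos) v[p] <- sample(setdiff(aas, v[p]), 1L)
  paste(v, collapse = "")
}

## draw a presence/absence pattern over n haplotypes, rejecting monomorphic
snp_pattern <- function(n) {
  repeat {
    pat <- rbinom(n, 1L, 0.5)
    s <- sum(pat)
    if (s > 0L && s < n) return(pat)
  }
}

#' Generate a labelled synthetic truth set
#'
#' Builds gene models on a toy genome (exons/introns, UTRs, coding
#' sequence), plants SNPs on pooled tetraploid haplotypes, derives
#' per-individual consensus transcripts and their fragment presentations,
#' adds paralog partners, exon-skipping isoforms, chloroplast windows and
#' fungal-contaminant decoys, and emits the guide proteome plus truth
#' tables. Deterministic under `params$seed`.
#'
#' @param params [sim_params()].
#' @param dir optional directory; when given, FASTA/TSV truth files are
#'   written there.
#' @return list of class `polymine_truth`.
#' @export
make_truth <- function(params = sim_params(), dir = NULL) {
  set.seed(params$seed)
  sc <- sense_codons()
  individuals <- sprintf("%s_i%d", params$set_name, seq_len(params$n_individuals))

  n_par <- round(params$paralog_fraction * params$n_genes)
  n_total <- params$n_genes + n_par + params$n_singletons
  gene_ids <- sprintf("g%04d", seq_len(n_total))
  par_src <- if (n_par > 0) sample(seq_len(params$n_genes), n_par) else integer(0)
  par_idx <- params$n_genes + seq_len(n_par)
  singleton_idx <- params$n_genes + n_par + seq_len(params$n_singletons)

  genes <- vector("list", n_total)
  exp_snp <- params$snp_density * params$gene_len_mean
  if (exp_snp < 1 && n_total < 20)
    warning("snp_density x gene length is below one SNP per gene; ",
            "many genes will carry no planted SNP")

  build_gene <- function(gene, transcript = NULL, utr5 = NULL, cds_len = NULL,
                         junctions = NULL) {
    if (is.null(transcript)) {
      L <- round(rnorm(1, params$gene_len_mean, params$gene_len_sd))
      L <- max(L, 500L)
      utr5 <- max(30L, min(120L, round(rnorm(1, 60, 15))))
      utr3 <- max(40L, min(150L, round(rnorm(1, 90, 20))))
      cds_len <- ((L - utr5 - utr3) %/% 3L) * 3L
      if (cds_len < 300L) cds_len <- 300L
      ncod <- cds_len %/% 3L
      cds <- paste0("ATG", paste(sample(sc$sense, ncod - 2L, TRUE), collapse = ""),
                    sample(sc$stops, 1L))
      transcript <- paste0(random_dna(utr5), cds, random_dna(utr3))
    }
    L <- nchar(transcript)
    if (is.null(junctions)) {
      n_ex <- if (runif(1) < params$multi_exon_fraction) sample(2:4, 1L) else 1L
      junctions <- integer(0)
      if (n_ex > 1L) {
        for (try in 1:50) {
          j <- sort(sample(60:(L - 60L), n_ex - 1L))
          if (all(diff(c(0L, j, L)) >= 60L)) { junctions <- j; break }
        }
      }
    }
    bounds <- c(0L, junctions, L)
    exons <- substring(transcript, head(bounds, -1L) + 1L, bounds[-1L])
    introns <- if (length(junctions))
      vapply(seq_along(junctions), function(i) random_dna(sample(80:250, 1L)), "")
    else character(0)
    pieces <- character(0)
    for (i in seq_along(exons)) {
      pieces <- c(pieces, exons[i])
      if (i <= length(introns)) pieces <- c(pieces, introns[i])
    }
    scaffold <- paste0(random_dna(100L), paste(pieces, collapse = ""),
                       random_dna(100L))
    list(gene = gene, transcript = transcript, length = L, utr5 = utr5,
         cds_start = utr5, cds_end = utr5 + cds_len + 3L,
         junctions = junctions, scaffold = scaffold,
         n_exons = length(junctions) + 1L)
  }

  for (i in seq_len(n_total)) {
    if (i %in% par_idx) {
      src <- genes[[par_src[match(i, par_idx)]]]
      mut <- mutate_keep_orf(src$transcript, 1 - params$paralog_identity,
                             src$cds_start, src$cds_end)
      genes[[i]] <- build_gene(gene_ids[i], transcript = mut,
                               utr5 = src$utr5, junctions = src$junctions)
      genes[[i]]$cds_start <- src$cds_start
      genes[[i]]$cds_end <- src$cds_end
      genes[[i]]$paralog_of <- src$gene
    } else {
      genes[[i]] <- build_gene(gene_ids[i])
      genes[[i]]$paralog_of <- NA_character_
    }
  }

  ## guide proteome (one protein per gene, diverged)
  proteome <- character(n_total)
  for (i in seq_len(n_total)) {
    g <- genes[[i]]
    cds <- substr(g$transcript, g$cds_start + 1L, g$cds_end - 3L)
    aa <- cpp_translate(cds)
    proteome[i] <- mutate_protein(aa, params$protein_divergence)
    genes[[i]]$guide <- sprintf("FV%05d", i)
  }
  names(proteome) <- vapply(genes, `[[`, "", "guide")

  ## expression / presentation
  for (i in seq_len(n_total)) {
    g <- genes[[i]]
    g$expressed <- if (i %in% singleton_idx) individuals[1] else individuals
    if (i %in% singleton_idx) {
      g$presentation <- "full"
    } else {
      u <- runif(1)
      g$presentation <- if (u < params$tiled_fraction) "tiled"
        else if (u < params$tiled_fraction + params$truncated_fraction) "truncated"
        else "full"
    }
    L <- g$length
    if (g$presentation == "full") {
      frag <- data.frame(frag = "f1", start = 0L, end = L)
    } else {
      nfrag <- sample(2:3, 1L)
      cuts <- round(L * seq_len(nfrag - 1L) / nfrag +
                      runif(nfrag - 1L, -0.08, 0.08) * L)
      ## overlaps at the assembler minimum but below the shortest read
      ## surviving the length filter, so no read is contained in the
      ## overlap and fragments of one gene never tie-multimap
      ov <- sample(40:45, nfrag - 1L, replace = TRUE)
      starts <- c(0L, as.integer(cuts))
      ends <- c(as.integer(pmin(L, cuts + ov)), L)
      if (g$presentation == "truncated") {
        ## lose a substantial 5' stretch of coding sequence (not just the
        ## start codon), so the missing-full-length label is unambiguous
        starts[1] <- g$cds_start + sample(60:200, 1L)
        bump <- which(starts[-1] < starts[1] + 80L) + 1L
        if (length(bump)) {
          starts[bump] <- starts[1] + 80L
          ends[bump - 1L] <- pmin(ends[bump - 1L],
                                  starts[bump] + ov[bump - 1L])
          ends[bump - 1L] <- pmax(ends[bump - 1L], starts[bump] + 40L)
        }
      }
      frag <- data.frame(frag = sprintf("f%d", seq_len(nfrag)),
                         start = starts, end = ends)
    }
    g$fragments <- frag
    genes[[i]] <- g
  }

  ## planted SNPs and haplotypes
  n_hap <- params$ploidy
  snp_rows <- list()
  haplotypes <- list()
  consensus <- list()
  isoform_genes <- character(0)
  iso_drop <- list()
  for (i in seq_len(n_total)) {
    g <- genes[[i]]
    L <- g$length
    inds <- g$expressed
    nh <- n_hap * length(inds)
    pos <- which(runif(L) < params$snp_density)  # 1-based
    chars <- strsplit(g$transcript, "", fixed = TRUE)[[1]]
    ref <- chars[pos]
    alt <- pick_alt(ref, params$transition_fraction)
    pat <- if (length(pos)) t(vapply(seq_along(pos),
                                     function(x) snp_pattern(nh),
                                     integer(nh))) else
      matrix(0L, 0, nh)
    for (ii in seq_along(inds)) {
      cols <- (ii - 1L) * n_hap + seq_len(n_hap)
      for (h in seq_len(n_hap)) {
        hv <- chars
        carr <- which(pat[, cols[h]] == 1L)
        hv[pos[carr]] <- alt[carr]
        haplotypes[[sprintf("%s|%s|h%d", inds[ii], g$gene, h)]] <-
          paste(hv, collapse = "")
      }
      dos <- if (length(pos)) rowSums(pat[, cols, drop = FALSE]) else integer(0)
      cv <- chars
      cv[pos[dos > n_hap / 2]] <- alt[dos > n_hap / 2]
      consensus[[sprintf("%s|%s", inds[ii], g$gene)]] <- paste(cv, collapse = "")
    }
    if (length(pos)) {
      snp_rows[[g$gene]] <- data.frame(
        gene = g$gene, pos = pos - 1L, ref = ref, alt = alt,
        transition = alt == unname(TRANSITION[ref]),
        ambiguous = paste0(pmin(ref, alt), pmax(ref, alt)) %in% c("AT", "CG"),
        dosage = as.integer(rowSums(pat)), n_hap = nh,
        origin = "nuclear",
        paralog = !is.na(g$paralog_of) | g$gene %in%
          vapply(genes, `[[`, "", "paralog_of")[!is.na(vapply(genes, `[[`, "", "paralog_of"))],
        stringsAsFactors = FALSE)
    }
    ## exon-skipping isoform (only where the main transcript is present in
    ## one piece, so the most-abundant-isoform rule has a defined winner)
    if (g$n_exons >= 3L && !i %in% singleton_idx &&
        g$presentation == "full" &&
        runif(1) < params$splice_variant_fraction) {
      isoform_genes <- c(isoform_genes, g$gene)
      iso_drop[[g$gene]] <- c(g$junctions[1], g$junctions[2])  # drop exon 2
    }
  }
  paralog_partner <- vapply(genes, `[[`, "", "paralog_of")
  paralog_genes <- unique(c(gene_ids[!is.na(paralog_partner)],
                            paralog_partner[!is.na(paralog_partner)]))
  snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(gene = character(0), pos = integer(0), ref = character(0),
               alt = character(0), transition = logical(0),
               ambiguous = logical(0), dosage = integer(0), n_hap = integer(0),
               origin = character(0), paralog = logical(0),
               stringsAsFactors = FALSE)
  if (nrow(snps)) snps$paralog <- snps$gene %in% paralog_genes

  ## chloroplast decoys
  chloro_genome <- setNames(random_dna(params$chloro_genome_len), "chloroplast")
  chloro_units <- list()
  if (params$n_chloro > 0) {
    ## non-overlapping windows: distinct plastid transcripts are distinct
    ## loci, not isoforms of each other
    slot_len <- params$chloro_genome_len %/% params$n_chloro
    if (slot_len < 950L)
      stop("chloro_genome_len too small for n_chloro non-overlapping windows")
    for (ci in seq_len(params$n_chloro)) {
      wlen <- sample(600:900, 1L)
      wstart <- (ci - 1L) * slot_len + sample.int(slot_len - wlen, 1L)
      wseq <- substr(chloro_genome[[1]], wstart, wstart + wlen - 1L)
      cid <- sprintf("chl%02d", ci)
      pos <- which(runif(wlen) < params$snp_density)
      chars <- strsplit(wseq, "", fixed = TRUE)[[1]]
      ref <- chars[pos]
      alt <- pick_alt(ref, params$transition_fraction)
      pat <- if (length(pos)) t(vapply(seq_along(pos),
                                       function(x) snp_pattern(length(individuals)),
                                       integer(length(individuals)))) else
        matrix(0L, 0, length(individuals))
      for (ii in seq_along(individuals)) {
        cv <- chars
        carr <- which(pat[, ii] == 1L)
        cv[pos[carr]] <- alt[carr]
        chloro_units[[sprintf("%s|%s", individuals[ii], cid)]] <-
          paste(cv, collapse = "")
      }
      if (length(pos))
        snps <- rbind(snps, data.frame(
          gene = cid, pos = pos - 1L, ref = ref, alt = alt,
          transition = alt == unname(TRANSITION[ref]),
          ambiguous = paste0(pmin(ref, alt), pmax(ref, alt)) %in% c("AT", "CG"),
          dosage = as.integer(rowSums(pat)),
          n_hap = length(individuals), origin = "chloroplast",
          paralog = FALSE, stringsAsFactors = FALSE))
    }
  }

  ## fungal contaminants
  cont_proteins <- character(0)
  cont_units <- list()
  if (params$n_contaminants > 0) {
    aas <- strsplit(AA_ALPHABET_SEED, "")[[1]]
    for (ci in seq_len(params$n_contaminants)) {
      plen <- sample(250:350, 1L)
      aa <- paste0("M", paste(sample(aas, plen - 1L, TRUE), collapse = ""))
      pid <- sprintf("MBP%03d", ci)
      cont_proteins[pid] <- aa
      codons <- vapply(strsplit(aa, "")[[1]],
                       function(a) sample(sc$by_aa[[a]], 1L), "")
      nt <- paste0(paste(codons, collapse = ""), sample(sc$stops, 1L))
      nt <- cpp_mutate(nt, params$contaminant_divergence, 0, 0)
      for (ind in individuals)
        cont_units[[sprintf("%s|cnt%02d", ind, ci)]] <- nt
    }
  }

  ## per-individual transcript sets and fragment truth table
  transcripts <- setNames(vector("list", length(individuals)), individuals)
  frag_rows <- list()
  for (ind in individuals) transcripts[[ind]] <- character(0)
  for (i in seq_len(n_total)) {
    g <- genes[[i]]
    for (ind in g$expressed) {
      cons <- consensus[[sprintf("%s|%s", ind, g$gene)]]
      fr <- g$fragments
      for (fi in seq_len(nrow(fr))) {
        id <- sprintf("%s|%s|%s", ind, g$gene, fr$frag[fi])
        transcripts[[ind]][id] <- substr(cons, fr$start[fi] + 1L, fr$end[fi])
        frag_rows[[id]] <- data.frame(member = id, individual = ind,
                                      gene = g$gene, frag = fr$frag[fi],
                                      start = fr$start[fi], end = fr$end[fi],
                                      stringsAsFactors = FALSE)
      }
      if (g$gene %in% isoform_genes) {
        dr <- iso_drop[[g$gene]]
        iso <- paste0(substr(cons, 1L, dr[1]),
                      substr(cons, dr[2] + 1L, g$length))
        id <- sprintf("%s|%s|iso1", ind, g$gene)
        transcripts[[ind]][id] <- iso
      }
    }
  }
  for (uid in names(chloro_units)) {
    ind <- sub("\\|.*$", "", uid)
    unit <- sub("^[^|]+\\|", "", uid)
    id <- sprintf("%s|%s|f1", ind, unit)
    transcripts[[ind]][id] <- chloro_units[[uid]]
    frag_rows[[id]] <- data.frame(member = id, individual = ind, gene = unit,
                                  frag = "f1", start = 0L,
                                  end = nchar(chloro_units[[uid]]),
                                  stringsAsFactors = FALSE)
  }
  for (uid in names(cont_units)) {
    ind <- sub("\\|.*$", "", uid)
    unit <- sub("^[^|]+\\|", "", uid)
    id <- sprintf("%s|%s|f1", ind, unit)
    transcripts[[ind]][id] <- cont_units[[uid]]
  }
  fragments <- do.call(rbind, frag_rows)
  rownames(fragments) <- NULL

  ## read-simulation units: haplotypes, isoforms, organelle + contaminants
  unit_rows <- list()
  for (i in seq_len(n_total)) {
    g <- genes[[i]]
    has_iso <- g$gene %in% isoform_genes
    wt_hap <- if (has_iso) 1 - params$iso_share else 1
    for (ind in g$expressed) {
      for (h in seq_len(n_hap)) {
        uid <- sprintf("%s|%s|h%d", ind, g$gene, h)
        unit_rows[[uid]] <- data.frame(unit = uid, individual = ind,
                                       gene = g$gene, weight = wt_hap,
                                       seq = haplotypes[[uid]],
                                       stringsAsFactors = FALSE)
      }
      if (has_iso) {
        id <- sprintf("%s|%s|iso1", ind, g$gene)
        unit_rows[[id]] <- data.frame(unit = id, individual = ind,
                                      gene = g$gene,
                                      weight = params$iso_share * n_hap,
                                      seq = transcripts[[ind]][[id]],
                                      stringsAsFactors = FALSE)
      }
    }
  }
  for (uid in names(chloro_units))
    unit_rows[[uid]] <- data.frame(unit = uid,
                                   individual = sub("\\|.*$", "", uid),
                                   gene = sub("^[^|]+\\|", "", uid),
                                   weight = n_hap,
                                   seq = chloro_units[[uid]],
                                   stringsAsFactors = FALSE)
  for (uid in names(cont_units))
    unit_rows[[uid]] <- data.frame(unit = uid,
                                   individual = sub("\\|.*$", "", uid),
                                   gene = sub("^[^|]+\\|", "", uid),
                                   weight = 2,
                                   seq = cont_units[[uid]],
                                   stringsAsFactors = FALSE)
  units <- do.call(rbind, unit_rows)
  rownames(units) <- NULL

  genes_df <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g$gene, length = g$length, cds_start = g$cds_start,
               cds_end = g$cds_end, n_exons = g$n_exons, guide = g$guide,
               paralog_of = g$paralog_of, presentation = g$presentation,
               n_fragments = nrow(g$fragments),
               expressed = paste(g$expressed, collapse = ","),
               has_isoform = g$gene %in% isoform_genes,
               stringsAsFactors = FALSE)))
  rownames(genes_df) <- NULL
  genes_df$paralog <- genes_df$gene %in% paralog_genes

  snps <- annotate_snp_truth(snps, genes, fragments)

  genome <- setNames(vapply(genes, `[[`, "", "scaffold"),
                     sprintf("sca_%s", gene_ids))
  junctions <- setNames(lapply(genes, `[[`, "junctions"), gene_ids)

  ## guide-protein annotation table (for the join stage)
  vocab <- c("protein kinase", "transcription factor", "disease resistance protein",
             "pentatricopeptide repeat protein", "cytochrome P450",
             "MYB domain protein", "F-box protein", "heat shock protein",
             "ABC transporter", "pectinesterase")
  ann_sel <- sort(sample(names(proteome), round(0.8 * length(proteome))))
  annotation <- data.frame(protein = ann_sel,
                           annotation = paste("putative",
                                              sample(vocab, length(ann_sel),
                                                     replace = TRUE)),
                           stringsAsFactors = FALSE)

  truth <- structure(list(
    params = params, individuals = individuals,
    set = list(name = params$set_name, code = params$set_code,
               ploidy = params$ploidy, n_individuals = params$n_individuals),
    genes = genes_df, junctions = junctions, snps = snps,
    fragments = fragments, haplotypes = unlist(haplotypes),
    consensus = unlist(consensus), transcripts = transcripts,
    units = units, guide_proteome = proteome,
    annotation = annotation,
    chloro_genome = chloro_genome, contaminant_proteins = cont_proteins,
    genome = genome,
    paralog_pairs = data.frame(
      gene_a = paralog_partner[!is.na(paralog_partner)],
      gene_b = gene_ids[!is.na(paralog_partner)],
      identity = rep(params$paralog_identity, sum(!is.na(paralog_partner))),
      stringsAsFactors = FALSE),
    isoform_genes = isoform_genes), class = "polymine_truth")
  if (!is.null(dir)) write_truth(truth, dir)
  truth
}

## derived truth columns used by the recovery evaluations
annotate_snp_truth <- function(snps, genes, fragments) {
  if (!nrow(snps)) {
    snps$covered <- logical(0); snps$dist_end <- integer(0)
    snps$junction_span <- logical(0); snps$near_other <- logical(0)
    snps$clean <- logical(0)
    return(snps)
  }
  gmap <- setNames(genes, vapply(genes, `[[`, "", "gene"))
  frag_by_gene <- split(fragments, fragments$gene)
  covered <- logical(nrow(snps)); dist_end <- integer(nrow(snps))
  junction_span <- logical(nrow(snps))
  for (r in seq_len(nrow(snps))) {
    gn <- snps$gene[r]; p <- snps$pos[r]
    fr <- frag_by_gene[[gn]]
    if (is.null(fr)) { covered[r] <- FALSE; dist_end[r] <- NA_integer_; next }
    covered[r] <- any(p >= fr$start & p < fr$end)
    eff0 <- min(fr$start); eff1 <- max(fr$end)
    dist_end[r] <- min(p - eff0, eff1 - 1L - p)
    g <- gmap[[gn]]
    ## must-fail junction label: both context pieces at most 63 bp, so a
    ## few chance matches across the junction cannot rescue the 68-bp rule
    if (!is.null(g) && length(g$junctions))
      junction_span[r] <- any(g$junctions >= p - 27L & g$junctions <= p + 28L)
  }
  near_other <- logical(nrow(snps))
  for (gn in unique(snps$gene)) {
    idx <- which(snps$gene == gn)
    if (length(idx) > 1L) {
      pp <- snps$pos[idx]
      d <- vapply(seq_along(pp), function(i) min(abs(pp[i] - pp[-i])), 0L)
      near_other[idx] <- d <= 35L
    }
  }
  snps$covered <- covered
  snps$dist_end <- dist_end
  snps$junction_span <- junction_span
  snps$near_other <- near_other
  snps$clean <- snps$origin == "nuclear" & !snps$paralog & !snps$ambiguous &
    snps$covered & !is.na(snps$dist_end) & snps$dist_end >= 35L &
    !snps$junction_span & !near_other
  snps
}

#' Write truth tables and FASTA inputs of a truth set
#'
#' @param truth [make_truth()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(truth$genes, "truth_genes.tsv")
  tsv(truth$snps, "truth_snps.tsv")
  tsv(truth$fragments, "truth_fragments.tsv")
  tsv(truth$annotation, "annotation.tsv")
  write_fasta(truth$guide_proteome, file.path(dir, "guide_proteome.faa"))
  write_fasta(truth$chloro_genome, file.path(dir, "chloroplast.fa"))
  write_fasta(truth$genome, file.path(dir, "genome.fa"))
  if (length(truth$contaminant_proteins))
    write_fasta(truth$contaminant_proteins, file.path(dir, "contaminants.faa"))
  for (ind in truth$individuals)
    write_fasta(truth$transcripts[[ind]],
                file.path(dir, sprintf("%s.transcripts.fa", ind)))
  invisible(dir)
}

#' Simulate reads from a truth set
#'
#' Uniform-start fragments over each expression unit (haplotype, isoform or
#' decoy copy); paired-end reads with a Gaussian insert for the
#' `"illumina"` regime, long single-end reads with indel-biased errors for
#' the `"long"` regime. Per-haplotype coverage `c` over total unit length
#' `L` yields about `c L / (2 r)` pairs per mate file. Deterministic under
#' the truth seed.
#'
#' @param truth [make_truth()] result.
#' @param params simulation parameters (defaults to `truth$params`).
#' @param dir optional directory for FASTQ + origin-table output.
#' @return list per individual with `r1`, `r2` (or `NULL`), `origin`.
#' @export
simulate_reads <- function(truth, params = truth$params, dir = NULL) {
  set.seed(params$seed + 999983L)
  r <- params$read_len
  out <- list()
  qual_profiles <- qual_profile_set(r)
  for (ind in truth$individuals) {
    u <- truth$units[truth$units$individual == ind, , drop = FALSE]
    ulen <- nchar(u$seq)
    if (params$regime == "illumina") {
      npairs <- pmax(0L, as.integer(round(u$weight * params$coverage * ulen /
                                            (2 * r))))
      ui <- rep(seq_len(nrow(u)), npairs)
      n <- length(ui)
      if (n == 0) {
        out[[ind]] <- list(r1 = empty_reads(), r2 = empty_reads(),
                           origin = data.frame())
        next
      }
      L <- ulen[ui]
      flen <- as.integer(round(rnorm(n, params$insert_mean, params$insert_sd)))
      flen <- pmin(pmax(flen, r + 10L), L)
      start <- as.integer(floor(runif(n) * (L - flen + 1)))
      frag <- substring(u$seq[ui], start + 1L, start + flen)
      flip <- runif(n) < 0.5
      frag[flip] <- cpp_revcomp(frag[flip])
      r1s <- substring(frag, 1L, r)
      r2s <- cpp_revcomp(substring(frag, flen - r + 1L, flen))
      if (params$read_error_rate > 0) {
        r1s <- cpp_mutate(r1s, params$read_error_rate, 0, 0)
        r2s <- cpp_mutate(r2s, params$read_error_rate, 0, 0)
      }
      offs <- sample.int(length(qual_profiles), 2L * n, replace = TRUE)
      ids <- sprintf("%s_%07d", ind, seq_len(n))
      r1 <- as_reads(ids, r1s, qual_profiles[offs[seq_len(n)]], "/1")
      r2 <- as_reads(ids, r2s, qual_profiles[offs[n + seq_len(n)]], "/2")
      origin <- data.frame(id = ids, individual = ind, unit = u$unit[ui],
                           gene = u$gene[ui], start = start, frag_len = flen,
                           flipped = flip, stringsAsFactors = FALSE)
      out[[ind]] <- list(r1 = r1, r2 = r2, origin = origin)
    } else {
      mean_len <- 360; sd_len <- 60
      nreads <- pmax(0L, as.integer(round(u$weight * params$coverage * ulen /
                                            mean_len)))
      ui <- rep(seq_len(nrow(u)), nreads)
      n <- length(ui)
      if (n == 0) {
        out[[ind]] <- list(r1 = empty_reads(), r2 = NULL,
                           origin = data.frame())
        next
      }
      L <- ulen[ui]
      rlen <- pmin(pmax(as.integer(round(rnorm(n, mean_len, sd_len))), 150L), L)
      start <- as.integer(floor(runif(n) * (L - rlen + 1)))
      seqs <- substring(u$seq[ui], start + 1L, start + rlen)
      flip <- runif(n) < 0.5
      seqs[flip] <- cpp_revcomp(seqs[flip])
      seqs <- cpp_mutate(seqs, 0.002, 0.004, 0.004)
      ids <- sprintf("%s_%07d", ind, seq_len(n))
      qual <- vapply(nchar(seqs), function(l)
        phred_encode(rep(34L, l)), "")
      r1 <- as_reads(ids, seqs, qual, "")
      origin <- data.frame(id = ids, individual = ind, unit = u$unit[ui],
                           gene = u$gene[ui], start = start, frag_len = rlen,
                           flipped = flip, stringsAsFactors = FALSE)
      out[[ind]] <- list(r1 = r1, r2 = NULL, origin = origin)
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (ind in names(out)) {
      write_fastq(out[[ind]]$r1, file.path(dir, sprintf("%s_R1.fastq", ind)))
      if (!is.null(out[[ind]]$r2))
        write_fastq(out[[ind]]$r2, file.path(dir, sprintf("%s_R2.fastq", ind)))
      write.table(out[[ind]]$origin,
                  file.path(dir, sprintf("%s.origin.tsv", ind)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

## small family of plausible quality strings: a 3'-decaying profile with a
## per-read additive offset
qual_profile_set <- function(read_len, offsets = -3:3) {
  base <- 38 - 6 * ((seq_len(read_len) - 1) / max(read_len - 1, 1))^2
  vapply(offsets, function(o)
    phred_encode(pmin(pmax(round(base + o), 2L), 40L)), "")
}
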