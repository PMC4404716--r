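# Recovery evaluation against a synthetic truth set: maps reference-contig
# calls back to planted gene coordinates through the assembly membership
# map, then scores SNP precision/recall, decoy leakage in the manifest,
# clean-marker retention, and ortholog/full-length recovery.

## contig -> gene coordinate map from the reference membership table.
## Returns, per contig, the gene and a function-free affine mapping via the
## member whose interval covers a position.
contig_gene_map <- function(members, fragments) {
  fr <- fragments[match(members$member, fragments$member), , drop = FALSE]
  data.frame(contig = members$contig, member = members$member,
             offset = members$offset, orient = members$orient,
             gene = fr$gene, frag_start = fr$start, frag_end = fr$end,
             stringsAsFactors = FALSE)
}

## translate contig positions to (gene, pos); NA when unmappable
map_contig_pos <- function(cmap, contig, pos) {
  gene <- rep(NA_character_, length(pos))
  gpos <- rep(NA_integer_, length(pos))
  flip <- rep(FALSE, length(pos))
  for (i in seq_along(pos)) {
    rows <- cmap[cmap$contig == contig[i] & !is.na(cmap$gene), , drop = FALSE]
    if (!nrow(rows)) next
    len <- rows$frag_end - rows$frag_start
    cover <- pos[i] >= rows$offset & pos[i] < rows$offset + len
    if (!any(cover)) next
    r <- rows[which(cover)[1], ]
    if (r$orient == 1L) {
      gpos[i] <- r$frag_start + (pos[i] - r$offset)
    } else {
      gpos[i] <- r$frag_start + (r$frag_end - r$frag_start - 1L) -
        (pos[i] - r$offset)
      flip[i] <- TRUE
    }
    gene[i] <- r$gene
  }
  data.frame(gene = gene, pos = gpos, flip = flip, stringsAsFactors = FALSE)
}

#' Score called SNPs against the planted truth
#'
#' @param calls reliable calls data.frame (from [call_snps()]).
#' @param members reference membership map (from [build_reference()]).
#' @param truth [make_truth()] result.
#' @return list with `precision`, `recall`, `n_calls`, `n_truth`,
#'   `transition_fraction`, and the per-call mapping (`detail`).
#' @export
evaluate_snp_calls <- function(calls, members, truth) {
  cmap <- contig_gene_map(members, truth$fragments)
  det <- map_contig_pos(cmap, calls$transcript, calls$pos)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- ifelse(det$flip, comp[calls$ref], calls$ref)
  alt <- ifelse(det$flip, comp[calls$alt], calls$alt)
  truth_key <- paste0(truth$snps$gene, ":", truth$snps$pos, ":",
                      pmin(truth$snps$ref, truth$snps$alt), "/",
                      pmax(truth$snps$ref, truth$snps$alt))
  call_key <- paste0(det$gene, ":", det$pos, ":",
                     pmin(ref, alt), "/", pmax(ref, alt))
  tp <- call_key %in% truth_key
  ## recall denominator: planted SNPs on units that entered calling and
  ## are covered by at least one fragment
  t_ok <- truth$snps$covered %in% TRUE & truth$snps$origin != "contaminant"
  recovered <- truth_key[t_ok] %in% call_key
  trans <- if (nrow(calls))
    mean(paste0(pmin(calls$ref, calls$alt), pmax(calls$ref, calls$alt)) %in%
           c("AG", "CT")) else NA_real_
  list(precision = if (nrow(calls)) mean(tp) else NA_real_,
       recall = if (any(t_ok)) mean(recovered) else NA_real_,
       n_calls = nrow(calls), n_truth = sum(t_ok),
       transition_fraction = trans,
       detail = cbind(calls[, c("transcript", "pos", "ref", "alt")],
                      data.frame(gene = det$gene, gene_pos = det$pos,
                                 flip = det$flip, tp = tp)))
}

#' Score the marker manifest against the planted truth
#'
#' Counts decoy leakage (chloroplast-, paralog-, junction-derived markers
#' present in the manifest) and the fraction of clean planted SNPs that
#' survived to the manifest.
#'
#' @param manifest manifest data.frame.
#' @param set_members named list (by set code) of reference membership
#'   maps.
#' @param set_calls named list (by set code) of id-assigned call tables.
#' @param truth [make_truth()] result.
#' @return list with `n_chloro_leaked`, `n_paralog_leaked`,
#'   `n_junction_leaked`, `clean_retention`, `n_clean`, `detail`.
#' @export
evaluate_manifest <- function(manifest, set_members, set_calls, truth) {
  rows <- list()
  for (code in names(set_calls)) {
    calls <- set_calls[[code]]
    hit <- calls[calls$snp_id %in% manifest$snp_id, , drop = FALSE]
    if (!nrow(hit)) next
    cmap <- contig_gene_map(set_members[[code]], truth$fragments)
    det <- map_contig_pos(cmap, hit$transcript, hit$pos)
    rows[[code]] <- cbind(hit[, c("snp_id", "transcript", "pos")],
                          data.frame(gene = det$gene, gene_pos = det$pos,
                                     flip = det$flip))
  }
  det <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), transcript = character(0),
               pos = integer(0), gene = character(0),
               gene_pos = integer(0), flip = logical(0))
  key <- paste0(det$gene, ":", det$gene_pos)
  tkey <- paste0(truth$snps$gene, ":", truth$snps$pos)
  idx <- match(key, tkey)
  matched <- truth$snps[idx[!is.na(idx)], , drop = FALSE]
  n_chloro <- sum(matched$origin == "chloroplast")
  n_paralog <- sum(matched$paralog)
  n_junction <- sum(matched$junction_span)
  clean <- truth$snps[truth$snps$clean, , drop = FALSE]
  ckey <- paste0(clean$gene, ":", clean$pos)
  retention <- if (nrow(clean)) mean(ckey %in% key) else NA_real_
  list(n_chloro_leaked = n_chloro, n_paralog_leaked = n_paralog,
       n_junction_leaked = n_junction, clean_retention = retention,
       n_clean = nrow(clean), detail = det)
}

#' Score the orthology-guided assembly against the planted truth
#'
#' @param ogasm [ortholog_assembly()] result.
#' @param truth [make_truth()] result.
#' @return list with `multi_fragment_recovery` (fraction of multi-fragment
#'   genes yielding a final sequence under their guide),
#'   `full_length_flag_precision` (fraction of full-length-flagged
#'   sequences whose gene truly is complete), `full_length_accuracy`,
#'   `n_multi_fragment`.
#' @export
evaluate_ogasm <- function(ogasm, truth) {
  g <- truth$genes
  nuclear <- g[!startsWith(g$gene, "chl") & !startsWith(g$gene, "cnt"), ,
               drop = FALSE]
  multi <- nuclear[nuclear$n_fragments >= 2L, , drop = FALSE]
  recovered_guides <- unique(ogasm$report$guide)
  rec <- multi$guide %in% recovered_guides
  fl_capable <- setNames(nuclear$presentation != "truncated", nuclear$guide)
  rep_fl <- ogasm$report$full_length
  rep_capable <- fl_capable[ogasm$report$guide]
  prec <- if (any(rep_fl)) mean(rep_capable[rep_fl], na.rm = TRUE) else NA_real_
  acc <- if (nrow(ogasm$report))
    mean(rep_fl == rep_capable, na.rm = TRUE) else NA_real_
  list(multi_fragment_recovery = if (nrow(multi)) mean(rec) else NA_real_,
       full_length_flag_precision = prec,
       full_length_accuracy = acc,
       n_multi_fragment = nrow(multi))
}
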