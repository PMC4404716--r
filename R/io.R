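# Readers/writers for the external representations the pipeline touches.
# All internal coordinates are 0-based half-open; 1-based appears only at
# serialization boundaries that require it (SAM POS, VCF POS).

#' Read a FASTA file
#'
#' Accepts wrapped or unwrapped sequence lines. Record ids are the header
#' token up to the first whitespace; the remainder is kept as description.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, with per-record descriptions
#'   in `attr(, "meta")`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  lnum <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- character(0)
    attr(out, "meta") <- character(0)
    return(out)
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stop("FASTA parse error at line ", lnum[1],
         ": expected '>' header", call. = FALSE)
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  meta <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    bad <- which(is_hdr)[!nzchar(ids)][1]
    stop("FASTA parse error at line ", lnum[bad], ": empty id", call. = FALSE)
  }
  if (anyDuplicated(ids))
    stop("FASTA integrity error: duplicate id '",
         ids[anyDuplicated(ids)][1], "'", call. = FALSE)
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste, "", collapse = "")
  out <- setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- unname(seqs)
  if (any(!nzchar(out)))
    stop("FASTA parse error: record '", ids[!nzchar(out)][1],
         "' has no sequence", call. = FALSE)
  names(out) <- ids
  attr(out, "meta") <- setNames(meta, ids)
  out
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (0 for unwrapped).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  check_named_seqs(seqs, "FASTA")
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attr(seqs, "meta")
  for (i in seq_along(seqs)) {
    desc <- if (!is.null(meta) && nzchar(meta[i] %||% "")) paste0(" ", meta[i]) else ""
    writeLines(paste0(">", names(seqs)[i], desc), con)
    s <- seqs[[i]]
    if (width > 0L && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}

#' Read a FASTQ file (4-line records, phred+33)
#'
#' @param path path to a FASTQ file.
#' @return a reads data.frame with columns `id`, `seq`, `qual` (phred+33
#'   string), `meta`. Use [phred_decode()] for integer scores.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_reads())
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error: ", length(lines),
         " lines is not a multiple of 4", call. = FALSE)
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1] - 1L) * 4L + 1L,
         ": expected '@' header", call. = FALSE)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1] - 1L) * 4L + 3L,
         ": expected '+' separator", call. = FALSE)
  mism <- which(nchar(seq) != nchar(qual))
  if (length(mism))
    stop("FASTQ parse error at line ", (mism[1] - 1L) * 4L + 1L,
         ": sequence and quality lengths differ", call. = FALSE)
  hdr <- sub("^@", "", hdr)
  ids <- sub("\\s.*$", "", hdr)
  meta <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  as_reads(ids, seq, qual, meta)
}

#' Write a FASTQ file (phred+33)
#'
#' @param reads reads data.frame (`id`, `seq`, `qual`, `meta`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    hdr <- ifelse(nzchar(reads$meta), paste0("@", reads$id, " ", reads$meta),
                  paste0("@", reads$id))
    writeLines(rbind(hdr, reads$seq, "+", reads$qual), con)
  }
  invisible(path)
}

empty_alignments <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             q0 = integer(0), q1 = integer(0), s0 = integer(0),
             s1 = integer(0), strand = character(0), cigar = character(0),
             score = integer(0), identity = numeric(0), mapq = integer(0),
             stringsAsFactors = FALSE)
}

#' Write alignments as SAM-lite
#'
#' A strict subset of SAM: `@SQ` header lines, columns 1-9, then the tags
#' `AS:i` (score), `XI:f` (identity), `XQ:i`/`XL:i` (0-based half-open query
#' interval). POS is 1-based as SAM requires; FLAG carries only strand (16).
#'
#' @param alignments alignment data.frame (see [local_align()] for columns).
#' @param subject_lengths named integer vector of subject lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam_lite <- function(alignments, subject_lengths, path) {
  unknown <- setdiff(unique(alignments$subject_id), names(subject_lengths))
  if (length(unknown))
    stop("SAM-lite integrity error: unknown subject '", unknown[1], "'",
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(subject_lengths),
                     as.integer(subject_lengths)), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    writeLines(paste(alignments$query_id, flag, alignments$subject_id,
                     alignments$s0 + 1L, alignments$mapq, alignments$cigar,
                     "*", 0L, 0L,
                     paste0("AS:i:", alignments$score),
                     paste0("XI:f:", sprintf("%.17g", alignments$identity)),
                     paste0("XQ:i:", alignments$q0),
                     paste0("XL:i:", alignments$q1),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a SAM-lite file
#'
#' @param path path written by [write_sam_lite()].
#' @return alignment data.frame with the subject lengths in
#'   `attr(, "subject_lengths")`.
#' @export
read_sam_lite <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  subject_lengths <- setNames(ln, sn)
  if (length(body) == 0) {
    out <- empty_alignments()
    attr(out, "subject_lengths") <- subject_lengths
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 13L))
    stop("SAM-lite parse error at record ", which(nf < 13L)[1], call. = FALSE)
  get <- function(i) vapply(f, `[[`, "", i)
  tagval <- function(prefix) {
    vapply(f, function(x) {
      hit <- x[startsWith(x, prefix)]
      if (!length(hit)) NA_character_ else sub(prefix, "", hit[1], fixed = TRUE)
    }, "")
  }
  subj <- get(3)
  unknown <- setdiff(unique(subj), names(subject_lengths))
  if (length(unknown))
    stop("SAM-lite integrity error: unknown subject '", unknown[1], "'",
         call. = FALSE)
  cigar <- get(6)
  ref_span <- cigar_ref_span(cigar)
  out <- data.frame(
    query_id = get(1), subject_id = subj,
    q0 = as.integer(tagval("XQ:i:")), q1 = as.integer(tagval("XL:i:")),
    s0 = as.integer(get(4)) - 1L,
    s1 = as.integer(get(4)) - 1L + ref_span,
    strand = ifelse(bitwAnd(as.integer(get(2)), 16L) > 0L, "-", "+"),
    cigar = cigar,
    score = as.integer(tagval("AS:i:")),
    identity = as.numeric(tagval("XI:f:")),
    mapq = as.integer(get(5)),
    stringsAsFactors = FALSE)
  attr(out, "subject_lengths") <- subject_lengths
  out
}

## reference span of a cigar (M and D consume the reference)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || !nzchar(cg)) return(0L)
    n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[MID]", cg))[[1]]
    sum(n[op != "I"])
  }, 0L, USE.NAMES = FALSE)
}

manifest_columns <- c("snp_id", "probe_id_fwd", "probe_id_rev", "context",
                      "alleles", "transcript", "rhfv", "protein", "annotation")

#' Write the array marker manifest
#'
#' One TSV row per SNP, sorted by `snp_id`, with the bracketed-allele 71-mer
#' context and the two per-strand probe ids.
#'
#' @param rows manifest data.frame with columns `snp_id`, `probe_id_fwd`,
#'   `probe_id_rev`, `context`, `alleles`, `transcript`, `rhfv`, `protein`,
#'   `annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_manifest <- function(rows, path) {
  missing_cols <- setdiff(manifest_columns, names(rows))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(rows$snp_id))
    stop("manifest integrity error: duplicate snp_id '",
         rows$snp_id[anyDuplicated(rows$snp_id)][1], "'", call. = FALSE)
  bad <- which(!grepl("^[A-Z]_.+_.+$", rows$snp_id))
  if (length(bad))
    stop("manifest integrity error: malformed snp_id '", rows$snp_id[bad[1]],
         "'", call. = FALSE)
  rows <- rows[order_c(rows$snp_id), manifest_columns, drop = FALSE]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker manifest written by [write_marker_manifest()]
#'
#' @param path manifest TSV path.
#' @return manifest data.frame.
#' @export
read_marker_manifest <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Write reliable SNP calls as a VCF-like table
#'
#' CHROM is the transcript id, POS is 1-based; INFO carries per-allele read
#' counts (`RC`) and supporting haplotype-cluster counts (`HAP`).
#'
#' @param calls SNP call data.frame from [call_snps()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=RC,Number=2,Type=Integer,Description=\"Reads per allele\">",
               "##INFO=<ID=HAP,Number=2,Type=Integer,Description=\"Haplotype clusters per allele\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    id <- if ("snp_id" %in% names(calls)) calls$snp_id else "."
    writeLines(paste(calls$transcript, calls$pos + 1L, id, calls$ref,
                     calls$alt, ".", "PASS",
                     sprintf("RC=%d,%d;HAP=%d,%d", calls$n_ref, calls$n_alt,
                             calls$hap_ref, calls$hap_alt),
                     sep = "\t"), con)
  }
  invisible(path)
}
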