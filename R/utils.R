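#' @useDynLib polymine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement nucleotide sequences
#'
#' Vectorised over character sequences; non-ACGT symbols become `N`.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- cpp_revcomp(as.character(x))
  names(out) <- names(x)
  out
}

## locale-stable (C collation) sort/order used everywhere determinism matters
sort_c <- function(x) sort(x, method = "radix")
order_c <- function(...) order(..., method = "radix")

#' Decode phred+33 quality strings
#'
#' @param qual character vector of phred+33 encoded quality strings.
#' @return list of integer vectors of per-base phred scores.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(integer(0))
    as.integer(utf8ToInt(q)) - 33L
  })
}

#' Encode phred scores as a phred+33 string
#'
#' @param scores integer vector of phred scores (0-93).
#' @return single character string.
#' @export
phred_encode <- function(scores) {
  if (length(scores) == 0) return("")
  intToUtf8(pmin(pmax(as.integer(scores), 0L), 93L) + 33L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## empty reads data.frame
empty_reads <- function() {
  data.frame(id = character(0), seq = character(0), qual = character(0),
             meta = character(0), stringsAsFactors = FALSE)
}

as_reads <- function(id, seq, qual, meta = "") {
  data.frame(id = as.character(id), seq = as.character(seq),
             qual = as.character(qual),
             meta = rep_len(as.character(meta), length(id)),
             stringsAsFactors = FALSE)
}

check_named_seqs <- function(x, what = "sequence set") {
  if (length(x) == 0) return(invisible(x))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a named character vector", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate sequence id in ", what, ": ",
         names(x)[anyDuplicated(names(x))], call. = FALSE)
  invisible(x)
}

## amino-acid alphabet used for protein k-mer seeding
AA_ALPHABET_SEED <- "ACDEFGHIKLMNPQRSTVWY"

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

## Translate a nucleotide string in one forward frame (offset 0..2),
## returning the amino-acid string with '*' at stops ('X' at ambiguity).
translate_frame <- function(seq, offset) {
  n <- nchar(seq)
  len <- ((n - offset) %/% 3L) * 3L
  if (len < 3L) return("")
  cpp_translate(substr(seq, offset + 1L, offset + len))
}

## Six-frame translation: returns data.frame(frame, offset, aa)
## frames +1,+2,+3 on the sequence, -1,-2,-3 on its reverse complement.
six_frame <- function(seq) {
  rc <- revcomp(seq)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  aa <- character(6)
  for (i in 1:3) aa[i] <- translate_frame(seq, i - 1L)
  for (i in 1:3) aa[i + 3L] <- translate_frame(rc, i - 1L)
  data.frame(frame = frames, offset = rep(0:2, 2), aa = aa,
             stringsAsFactors = FALSE)
}
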