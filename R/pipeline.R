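# End-to-end orchestration: a YAML-serialisable run configuration, the
# prep -> select -> reference -> SNP calling -> marker design -> orthology
# assembly pipeline, and study-style summary tables.

#' Build a run configuration
#'
#' @param sets list of sample-set definitions; each is a list with `name`,
#'   `code` (single uppercase letter), `ploidy`, and `individuals` - a
#'   list of lists with `name`, `r1`, optionally `r2`, and `transcripts`
#'   (FASTA path).
#' @param references list with optional paths `chloroplast`, `genome`,
#'   `proteome`, `contaminants`, `annotation`.
#' @param outdir output directory.
#' @param seed RNG seed recorded with the run.
#' @param params list of parameter blocks: `prep` ([prep_params()]),
#'   `align` ([align_params()]), `assembly` ([asm_params()]), `snp`
#'   ([snp_params()]), `markers` ([filter_params()]), `ortho`
#'   ([ortho_params()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(sets, references = list(), outdir = tempfile("polymine_"),
                       seed = 1L, params = list()) {
  if (length(sets) == 0) stop("config must define at least one sample set")
  codes <- vapply(sets, `[[`, "", "code")
  if (anyDuplicated(codes) || any(!grepl("^[A-Z]$", codes)))
    stop("set codes must be unique single uppercase letters")
  defaults <- list(prep = prep_params(), align = align_params(),
                   assembly = asm_params(), snp = snp_params(),
                   markers = filter_params(), ortho = ortho_params())
  for (nm in names(defaults))
    if (!is.null(params[[nm]]))
      defaults[[nm]][names(params[[nm]])] <- params[[nm]]
  structure(list(sets = sets, references = references, outdir = outdir,
                 seed = as.integer(seed), params = defaults),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param config [run_config()].
#' @param path YAML file path.
#' @return `path` / the restored `run_config`.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$params <- lapply(x$params, function(p) lapply(unclass(p), identity))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(sets = x$sets, references = x$references, outdir = x$outdir,
             seed = x$seed %||% 1L, params = x$params)
}

read_reference_seqs <- function(references) {
  rd <- function(p) if (!is.null(p) && file.exists(p)) read_fasta(p) else character(0)
  list(chloroplast = rd(references$chloroplast),
       genome = rd(references$genome),
       proteome = rd(references$proteome),
       contaminants = rd(references$contaminants),
       annotation = if (!is.null(references$annotation) &&
                        file.exists(references$annotation))
         read.delim(references$annotation, stringsAsFactors = FALSE)
       else NULL)
}

## pool every prepped read of one individual as single-end input
pool_prepped <- function(pp) {
  rbind(pp$merged, pp$single, pp$paired_r1, pp$paired_r2)
}

#' Run the complete pipeline
#'
#' Per set and individual: read pre-processing and transcript selection;
#' per set: reference assembly and reliable-SNP calling; across sets:
#' the marker filter cascade and manifest; finally the orthology-guided
#' assembly over all retained transcripts. All outputs are written under
#' `config$outdir`.
#'
#' @param config [run_config()].
#' @param verbose print stage progress.
#' @return list of class `polymine_run` with per-set results, the design,
#'   the orthology assembly, and summary tables.
#' @export
run_all <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  refs <- read_reference_seqs(config$references)
  p <- config$params
  set_results <- list()
  prep_summary <- list()
  all_retained <- character(0)
  guide_of_transcript <- character(0)
  for (s in config$sets) {
    say("set %s: pre-processing and transcript selection", s$name)
    set_reads <- list()
    retained_by_ind <- list()
    for (ind in s$individuals) {
      r1 <- read_fastq(ind$r1)
      r2 <- if (!is.null(ind$r2)) read_fastq(ind$r2) else NULL
      pp <- prep_reads(r1, r2, p$prep)
      reads <- pool_prepped(pp)
      ## mate rows share ids; suffix them for unique mapping keys
      reads$id <- sprintf("%s#%06d", reads$id, seq_len(nrow(reads)))
      set_reads[[ind$name]] <- reads
      transcripts <- read_fasta(ind$transcripts)
      sel <- select_transcripts(transcripts, reads, refs$contaminants,
                                align_params = p$align)
      retained_by_ind[[ind$name]] <- sel$retained
      prep_summary[[paste(s$name, ind$name)]] <- data.frame(
        set = s$name, individual = ind$name,
        reads_in = nrow(r1) + if (is.null(r2)) 0L else nrow(r2),
        reads_out = nrow(reads),
        merged = sum(nrow(pp$merged)),
        transcripts_in = length(transcripts),
        transcripts_retained = length(sel$retained),
        contaminants_flagged = nrow(sel$contaminants),
        stringsAsFactors = FALSE)
    }
    say("set %s: reference assembly", s$name)
    ref <- build_reference(retained_by_ind, p$assembly)
    say("set %s: SNP calling", s$name)
    pooled <- do.call(rbind, set_reads)
    pm <- ploidy_model(s$ploidy %||% 4L, length(s$individuals))
    sc <- call_snps(pooled, ref$reference, pm, p$snp, p$align)
    calls <- assign_snp_ids(sc$calls, ref$reference, s$code)
    stats <- snp_stats(calls, sc$transcript_stats)
    set_results[[s$code]] <- list(
      name = s$name, code = s$code, reference = ref$reference,
      members = ref$members, calls = calls, candidates = sc$candidates,
      variants = sc$variants, transcript_stats = sc$transcript_stats,
      stats = stats, retained = retained_by_ind, ploidy = pm)
    for (ind in names(retained_by_ind))
      all_retained <- c(all_retained, retained_by_ind[[ind]])
    write_snp_vcf(calls, file.path(config$outdir,
                                   sprintf("snps_%s.vcf", s$code)))
  }
  say("marker design across %d set(s)", length(set_results))
  ogasm <- NULL
  rhfv_map <- NULL; protein_map <- NULL; annot_map <- NULL
  if (length(refs$proteome)) {
    say("orthology-guided assembly (%d transcripts)", length(all_retained))
    ogasm <- ortholog_assembly(all_retained, refs$proteome,
                               refs$annotation, p$ortho, p$assembly)
    if (nrow(ogasm$report)) {
      ## transcript -> guide / rhfv through group membership
      t2g <- unlist(lapply(names(ogasm$groups), function(g)
        setNames(rep(g, length(ogasm$groups[[g]])), ogasm$groups[[g]])))
      g2r <- setNames(ogasm$report$rhfv, ogasm$report$guide)
      g2r <- g2r[!duplicated(names(g2r))]
      ## reference contigs inherit annotations through their members
      protein_map <- character(0); rhfv_map <- character(0)
      for (code in names(set_results)) {
        mem <- set_results[[code]]$members
        mg <- t2g[mem$member]
        ok <- !is.na(mg)
        if (any(ok)) {
          first <- !duplicated(mem$contig[ok])
          protein_map[mem$contig[ok][first]] <- mg[ok][first]
        }
      }
      rhfv_map <- setNames(unname(g2r[protein_map]), names(protein_map))
      rhfv_map <- rhfv_map[!is.na(rhfv_map)]
      if (!is.null(refs$annotation) && nrow(refs$annotation))
        annot_map <- setNames(refs$annotation$annotation,
                              refs$annotation$protein)
    }
    write_fasta(ogasm$sequences, file.path(config$outdir, "rhfv.fa"))
    write.table(ogasm$report, file.path(config$outdir, "ogasm_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  design <- design_markers(
    setNames(lapply(set_results, function(x)
      list(calls = x$calls, reference = x$reference, variants = x$variants)),
      names(set_results)),
    chloro_genome = refs$chloroplast, genome = refs$genome,
    params = p$markers, align = p$align,
    rhfv = rhfv_map, protein = protein_map, annotation = annot_map)
  write_marker_manifest(design$manifest,
                        file.path(config$outdir, "manifest.tsv"))
  write.table(design$rejections, file.path(config$outdir, "rejections.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ## summary tables
  prep_tab <- do.call(rbind, prep_summary)
  rownames(prep_tab) <- NULL
  snp_tab <- do.call(rbind, lapply(set_results, function(x)
    cbind(set = x$name, x$stats$summary)))
  rownames(snp_tab) <- NULL
  hist_tab <- do.call(rbind, lapply(set_results, function(x)
    if (nrow(x$stats$histogram))
      cbind(set = x$name, x$stats$histogram) else NULL))
  marker_counts <- summarize_counts(setNames(
    lapply(names(set_results), function(code)
      sum(startsWith(design$manifest$snp_id, paste0(code, "_")))),
    names(set_results)))
  write.table(prep_tab, file.path(config$outdir, "prep_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(snp_tab, file.path(config$outdir, "snp_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(hist_tab))
    write.table(hist_tab, file.path(config$outdir, "snp_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(marker_counts, file.path(config$outdir, "marker_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(config = config, sets = set_results, design = design,
                 ogasm = ogasm, prep_summary = prep_tab,
                 snp_summary = snp_tab, histogram = hist_tab,
                 marker_counts = marker_counts),
            class = "polymine_run")
}

#' Per-set and total marker counts
#'
#' @param set_counts named list/vector of per-set counts.
#' @return data.frame with one row per set plus a `total` row; the total
#'   is asserted to equal the sum of the parts.
#' @export
summarize_counts <- function(set_counts) {
  n <- vapply(set_counts, as.numeric, 0)
  total <- sum(n)
  stopifnot(isTRUE(all.equal(total, sum(n))))
  data.frame(set = c(names(set_counts), "total"), n_markers = c(n, total),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.polymine_run <- function(x, ...) {
  cat("polymine run:", length(x$sets), "set(s)\n")
  cat("  manifest markers:", nrow(x$design$manifest),
      " probes:", nrow(x$design$probes), "\n")
  if (!is.null(x$ogasm))
    cat("  ortholog sequences:", length(x$ogasm$sequences),
        " full-length:", sum(x$ogasm$report$full_length), "\n")
  invisible(x)
}

#' Generate a synthetic study and run the pipeline on it
#'
#' Writes the truth set and simulated reads under `dir`, builds the
#' matching [run_config()] and executes [run_all()].
#'
#' @param sim [sim_params()].
#' @param dir working directory for inputs and outputs.
#' @param params optional pipeline parameter overrides (see
#'   [run_config()]).
#' @param verbose print stage progress.
#' @return list with `truth`, `reads`, `config`, `run`.
#' @export
run_synthetic <- function(sim = sim_params(), dir = tempfile("polymine_sim_"),
                          params = list(), verbose = TRUE) {
  indir <- file.path(dir, "inputs")
  truth <- make_truth(sim, dir = indir)
  reads <- simulate_reads(truth, sim, dir = indir)
  individuals <- lapply(truth$individuals, function(ind) {
    list(name = ind,
         r1 = file.path(indir, sprintf("%s_R1.fastq", ind)),
         r2 = if (sim$regime == "illumina")
           file.path(indir, sprintf("%s_R2.fastq", ind)) else NULL,
         transcripts = file.path(indir, sprintf("%s.transcripts.fa", ind)))
  })
  prep_over <- if (sim$regime == "long") list(min_len = 100L) else list()
  config <- run_config(
    sets = list(list(name = sim$set_name, code = sim$set_code,
                     ploidy = sim$ploidy, individuals = individuals)),
    references = list(chloroplast = file.path(indir, "chloroplast.fa"),
                      genome = file.path(indir, "genome.fa"),
                      proteome = file.path(indir, "guide_proteome.faa"),
                      contaminants = file.path(indir, "contaminants.faa"),
                      annotation = file.path(indir, "annotation.tsv")),
    outdir = file.path(dir, "out"), seed = sim$seed,
    params = utils::modifyList(list(prep = prep_over), params))
  run <- run_all(config, verbose = verbose)
  list(truth = truth, reads = reads, config = config, run = run)
}
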