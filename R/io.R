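#' Read a cohort of per-individual variant calls
#'
#' `format = "tsv-dir"` reads a directory of per-individual TSV files
#' (one file per individual; the `individual` column, when absent, is
#' taken from the file name without extension). Expected columns:
#' individual, gene, chrom, pos, ref, alt, score, alt_cov, ref_cov,
#' phase_group — optional columns may be empty or missing. Malformed rows
#' (non-numeric position, score outside [0, 1)) abort with line numbers
#' unless `skipBadLines = TRUE`, which drops them with a warning.
#'
#' `format = "vcf"` reads a multi-sample VCF: genotypes 0/1 and 0|1 map to
#' one heterozygous call, 1/1 and 1|1 to two copies of the call (so
#' recessive scoring sees both alleles). Gene assignment requires
#' `geneBed`, a 0-based half-open BED file of gene intervals (converted
#' internally to 1-based), and scores are left `NA` for a subsequent
#' [applyScoreTable()]. VCF support needs the VariantAnnotation,
#' GenomicRanges and rtracklayer packages.
#'
#' @param path directory of TSVs, or a VCF file.
#' @param format `"tsv-dir"` or `"vcf"`.
#' @param label cohort label.
#' @param skipBadLines drop malformed rows instead of aborting.
#' @param geneBed BED file of gene intervals (VCF input only; the 4th
#'   column is the gene id).
#' @return a [VariantCohort].
#' @export
readCohort <- function(path, format = c("tsv-dir", "vcf"),
                       label = "cohort", skipBadLines = FALSE,
                       geneBed = NULL) {
  format <- match.arg(format)
  if (format == "vcf")
    return(.readCohortVcf(path, geneBed, label))
  files <- list.files(path, pattern = "\\.tsv(\\.gz)?$", full.names = TRUE)
  if (!length(files)) stop("no per-individual TSV files found in ", path)
  pieces <- lapply(files, function(f) {
    df <- as.data.frame(data.table::fread(f, sep = "\t", colClasses = list(
      character = intersect(c("chrom", "ref", "alt", "phase_group"),
                            names(data.table::fread(f, nrows = 0)))),
      showProgress = FALSE, na.strings = c("NA", "")))
    if (is.null(df$individual))
      df$individual <- sub("\\.tsv(\\.gz)?$", "", basename(f))
    pos <- suppressWarnings(as.integer(df$pos))
    sc <- suppressWarnings(as.numeric(df$score))
    bad <- which(is.na(pos) | (!is.na(sc) & (sc < 0 | sc >= 1)))
    if (length(bad)) {
      msg <- paste0(basename(f), ": malformed rows at lines ",
                    paste(utils::head(bad + 1L, 10), collapse = ", "))
      if (!skipBadLines) stop(msg)
      warning(msg, " (skipped)")
      df <- df[-bad, , drop = FALSE]
    }
    df
  })
  calls <- canonicalCalls(do.call(rbind, lapply(pieces, function(p)
    canonicalCalls(p))))
  roster <- unique(c(sub("\\.tsv(\\.gz)?$", "", basename(files)),
                     calls$individual))
  VariantCohort(calls, individuals = sort(roster), label = label)
}

.readCohortVcf <- function(path, geneBed, label) {
  for (pkg in c("VariantAnnotation", "GenomicRanges", "rtracklayer"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("VCF input requires the ", pkg, " package")
  if (is.null(geneBed))
    stop("VCF input requires a gene-interval BED file (geneBed)")
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  genes <- rtracklayer::import(geneBed)  # BED import is 1-based GRanges
  hits <- GenomicRanges::findOverlaps(rr, genes)
  geneOf <- rep(NA_character_, length(rr))
  geneOf[S4Vectors::queryHits(hits)] <-
    genes$name[S4Vectors::subjectHits(hits)]
  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  rows <- list()
  for (j in seq_along(samples)) {
    copies <- ifelse(gt[, j] %in% c("0/1", "0|1", "1/0", "1|0"), 1L,
                     ifelse(gt[, j] %in% c("1/1", "1|1"), 2L, 0L))
    idx <- rep(which(copies > 0), copies[copies > 0])
    if (!length(idx)) next
    rows[[length(rows) + 1L]] <- data.frame(
      individual = samples[j], gene = geneOf[idx],
      chrom = as.character(GenomicRanges::seqnames(rr))[idx],
      pos = GenomicRanges::start(rr)[idx],
      ref = as.character(VariantAnnotation::ref(vcf))[idx],
      alt = as.character(VariantAnnotation::alt(vcf))[idx],
      score = NA_real_, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  calls <- calls[!is.na(calls$gene), , drop = FALSE]
  VariantCohort(calls, individuals = samples, label = label)
}

#' Write a cohort as a directory of per-individual TSV files
#'
#' Inverse of [readCohort()]'s `tsv-dir` format: one TSV per individual in
#' the roster (individuals without calls get a header-only file, so the
#' roster round-trips), calls sorted canonically.
#'
#' @param cohort a [VariantCohort].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "VariantCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls <- cohort@calls
  calls <- calls[order(calls$individual, calls$chrom, calls$pos,
                       calls$ref, calls$alt), , drop = FALSE]
  for (ind in cohort@individuals) {
    sub <- calls[calls$individual == ind, , drop = FALSE]
    data.table::fwrite(sub, file.path(dir, paste0(ind, ".tsv")),
                       sep = "\t", na = "NA")
  }
  invisible(dir)
}

#' Write a ranked gene table to TSV
#'
#' Columns: rank, gene, n_case_nonzero, n_control_nonzero, Z1, p1, p2,
#' chi2, p, log10_p, significant.
#'
#' @param results ranked data.frame from [burdenTest()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
  out <- data.frame(rank = results$rank, gene = results$gene,
                    n_case_nonzero = results$n1,
                    n_control_nonzero = results$n2,
                    Z1 = results$Z1, p1 = results$p1, p2 = results$p2,
                    chi2 = results$chi2, p = results$p,
                    log10_p = results$logP / log(10),
                    significant = results$significant)
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Run the whole case-control ranking pipeline from a configuration
#'
#' Reads case and control cohorts, optionally annotates scores from a
#' table and applies cis preprocessing to the cases, builds both gene
#' score matrices, runs [burdenTest()], writes the ranked table and a JSON
#' run manifest (tool version, configuration snapshot, input checksums,
#' seed), and returns the ranked table invisibly. The run is fully
#' deterministic: re-running with identical inputs produces a
#' byte-identical results table.
#'
#' @param config named list (or path to a YAML file mirroring it) with
#'   elements: `cases`, `controls` (cohort directories), `model`,
#'   optional `scoreTable` + `scoreDialect` + `missingScore`, optional
#'   logical `preprocessCis` and `cooccurrence`, `alpha` (default
#'   2.7e-6), `out` (output TSV path), optional `manifest` path and
#'   `seed`.
#' @return the ranked results data.frame, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  for (need in c("cases", "controls", "model", "out"))
    if (is.null(config[[need]])) stop("config lacks required field: ", need)
  alpha <- config$alpha %||% 2.7e-6
  cases <- readCohort(config$cases, label = "case")
  controls <- readCohort(config$controls, label = "control")
  if (!is.null(config$scoreTable)) {
    tab <- loadScoreTable(config$scoreTable,
                          dialect = config$scoreDialect %||% "generic-tsv")
    missingPolicy <- config$missingScore %||% "drop"
    cases <- applyScoreTable(cases, tab, missing = missingPolicy)
    controls <- applyScoreTable(controls, tab, missing = missingPolicy)
  }
  if (isTRUE(config$preprocessCis))
    cases <- preprocessCis(cases,
                           window = config$window %||% 100,
                           cisP = config$cisP %||% 0.4,
                           cooccurrence = config$cooccurrence %||% TRUE)
  cm <- buildGeneScoreMatrix(cases, config$model)
  km <- buildGeneScoreMatrix(controls, config$model)
  res <- burdenTest(cm, km, alpha = alpha)
  if (!nrow(res) || all(res$p == 1))
    stop("no testable genes in these cohorts")
  writeResults(res, config$out)
  manifestPath <- config$manifest %||% paste0(config$out, ".manifest.json")
  manifest <- list(
    tool = "burdenRank",
    version = as.character(utils::packageVersion("burdenRank")),
    command = "runPipeline",
    config = config[setdiff(names(config), "manifest")],
    inputChecksums = list(
      cases = unname(tools::md5sum(sort(list.files(config$cases,
                                                   full.names = TRUE)))),
      controls = unname(tools::md5sum(sort(list.files(config$controls,
                                                      full.names = TRUE))))),
    seed = config$seed %||% NA,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}
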