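#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
NULL

#' ScoreTable: a variant deleteriousness score catalog
#'
#' Maps variant alleles, keyed by (chrom, pos, ref, alt) in 1-based VCF
#' convention, to a PHRED-like scaled deleteriousness score such as CADD.
#' Tables whose scores are already on a ranked 0-1 scale (DANN, REVEL) are
#' flagged `prenormalized` and bypass PHRED normalization at lookup time.
#'
#' @slot scores data.frame with columns chrom, pos, ref, alt, raw.
#' @slot provenance character label, e.g. `"CADD"` or `"synthetic"`.
#' @slot prenormalized logical; `TRUE` when `raw` is already in [0, 1).
#' @export
setClass("ScoreTable",
  representation(scores = "data.frame", provenance = "character",
                 prenormalized = "logical"),
  prototype(provenance = "unknown", prenormalized = FALSE))

setValidity("ScoreTable", function(object) {
  df <- object@scores
  need <- c("chrom", "pos", "ref", "alt", "raw")
  if (!all(need %in% names(df)))
    return(paste("score table needs columns:", paste(need, collapse = ", ")))
  if (nrow(df)) {
    if (anyNA(df$pos) || any(df$pos < 1))
      return("positions must be positive 1-based integers")
    key <- variantKey(df$chrom, df$pos, df$ref, df$alt)
    if (anyDuplicated(key))
      return("duplicate (chrom,pos,ref,alt) keys in score table")
    if (anyNA(df$raw))
      return("missing raw scores")
    if (object@prenormalized) {
      if (any(df$raw < 0 | df$raw >= 1))
        return("prenormalized scores must lie in [0, 1)")
    } else if (any(df$raw < 0)) {
      return("PHRED-like scores must be non-negative")
    }
  }
  TRUE
})

#' @describeIn ScoreTable display a summary
#' @param object a `ScoreTable`
#' @export
setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable [%s%s] with %d variants\n", object@provenance,
              if (object@prenormalized) ", prenormalized" else "",
              nrow(object@scores)))
})

#' VariantCohort: per-individual filtered variant calls for one cohort
#'
#' Holds the post-filtering variant calls of every individual in a case or
#' control cohort, plus the full individual roster (individuals without any
#' surviving call still count toward cohort size). A homozygous genotype is
#' represented as two identical call rows, so recessive scoring sees both
#' allele copies.
#'
#' @slot calls data.frame in the canonical call schema (individual, gene,
#'   chrom, pos, ref, alt, score, alt_cov, ref_cov, phase_group). `score` is
#'   the normalized deleteriousness s in [0, 1); it may be NA until a
#'   `ScoreTable` is applied.
#' @slot individuals character vector: the complete cohort roster.
#' @slot label cohort label, e.g. `"case"` or `"control"`.
#' @slot sex optional named character vector ("male"/"female") per
#'   individual, used by X-linked scoring options.
#' @slot metadata list of provenance details (simulation spec, seeds,
#'   spiked individual ids, ...).
#' @export
setClass("VariantCohort",
  representation(calls = "data.frame", individuals = "character",
                 label = "character", sex = "character", metadata = "list"),
  prototype(label = "cohort", sex = character(0), metadata = list()))

setValidity("VariantCohort", function(object) {
  df <- object@calls
  if (!all(.CALL_COLS %in% names(df)))
    return(paste("calls need columns:", paste(.CALL_COLS, collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$individual %in% object@individuals))
      return("calls reference individuals absent from the roster")
    ok <- is.na(df$score) | (df$score >= 0 & df$score < 1)
    if (!all(ok))
      return("normalized scores must lie in [0, 1) or be NA")
    cov <- c(df$alt_cov, df$ref_cov)
    if (any(cov < 0, na.rm = TRUE))
      return("read coverages must be non-negative")
  }
  if (anyDuplicated(object@individuals))
    return("duplicated individual ids in roster")
  TRUE
})

#' @describeIn VariantCohort display a summary
#' @param object a `VariantCohort`
#' @export
setMethod("show", "VariantCohort", function(object) {
  cat(sprintf("VariantCohort '%s': %d individuals, %d calls, %d genes\n",
              object@label, length(object@individuals), nrow(object@calls),
              length(unique(object@calls$gene))))
})

#' VariantCohort constructor
#'
#' @param calls data.frame of variant calls; missing optional columns are
#'   filled with NA.
#' @param individuals full cohort roster; defaults to the individuals seen
#'   in `calls`.
#' @param label cohort label.
#' @param sex optional named character vector of "male"/"female".
#' @param metadata list of provenance details.
#' @return a `VariantCohort`
#' @export
VariantCohort <- function(calls, individuals = NULL, label = "cohort",
                          sex = character(0), metadata = list()) {
  calls <- canonicalCalls(calls)
  if (is.null(individuals))
    individuals <- unique(calls$individual)
  new("VariantCohort", calls = calls,
      individuals = as.character(individuals), label = label,
      sex = sex, metadata = metadata)
}

#' GeneScoreMatrix: gene-by-individual deleterious mutation load
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `score` assay
#' holds the per-individual gene score (sparse): the sum of the two highest
#' normalized variant scores under recessive models (range [0, 2]), or the
#' single highest under dominant models (range [0, 1]). Rows are genes with
#' `chrom` recorded in `rowData`; columns are individuals. This matrix is
#' the sole input of the case-control test.
#'
#' @slot model inheritance model, one of `"AR"`, `"AD"`, `"XR"`, `"XD"`.
#' @export
setClass("GeneScoreMatrix",
  contains = "SummarizedExperiment",
  representation(model = "character"))

setValidity("GeneScoreMatrix", function(object) {
  if (!object@model %in% c("AR", "AD", "XR", "XD"))
    return("model must be one of AR, AD, XR, XD")
  if (!"score" %in% SummarizedExperiment::assayNames(object))
    return("assay 'score' is required")
  m <- SummarizedExperiment::assay(object, "score")
  top <- if (isRecessive(object@model)) 2 else 1
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(vals) && (min(vals) < 0 || max(vals) > top))
    return(sprintf("gene scores must lie in [0, %d] under the %s model",
                   top, object@model))
  if (!"chrom" %in% names(SummarizedExperiment::rowData(object)))
    return("rowData must record each gene's chromosome")
  TRUE
})

#' @describeIn GeneScoreMatrix display a summary
#' @param object a `GeneScoreMatrix`
#' @export
setMethod("show", "GeneScoreMatrix", function(object) {
  m <- SummarizedExperiment::assay(object, "score")
  nz <- if (methods::is(m, "sparseMatrix")) Matrix::nnzero(m) else sum(m != 0)
  cat(sprintf("GeneScoreMatrix (%s model): %d genes x %d individuals, %d non-zero scores\n",
              object@model, nrow(object), ncol(object), nz))
})

#' FrequencyPanel: allele-frequency and score catalog driving simulation
#'
#' One row per alternate allele: site coordinates, gene assignment, a
#' PHRED-like deleteriousness score, and the allele frequency in each
#' population (columns `freq_<population>`). At any one site the alternate
#' allele frequencies within a population must sum to at most 1, since an
#' individual draws at most one alternate allele per site.
#'
#' @slot sites data.frame with columns chrom, pos, ref, alt, gene, score and
#'   one `freq_<pop>` column per population.
#' @slot populations character vector of population labels.
#' @export
setClass("FrequencyPanel",
  representation(sites = "data.frame", populations = "character"))

setValidity("FrequencyPanel", function(object) {
  df <- object@sites
  need <- c("chrom", "pos", "ref", "alt", "gene", "score")
  if (!all(need %in% names(df)))
    return(paste("panel needs columns:", paste(need, collapse = ", ")))
  fcols <- paste0("freq_", object@populations)
  if (!all(fcols %in% names(df)))
    return("missing freq_<population> columns")
  if (nrow(df)) {
    key <- variantKey(df$chrom, df$pos, df$ref, df$alt)
    if (anyDuplicated(key))
      return("duplicate alleles in panel")
    for (fc in fcols) {
      f <- df[[fc]]
      if (anyNA(f) || any(f < 0 | f > 1))
        return(sprintf("%s must lie in [0, 1]", fc))
      sums <- tapply(f, paste(normChrom(df$chrom), df$pos, df$ref), sum)
      if (any(sums > 1 + 1e-12))
        return(sprintf("alternate-allele frequencies in %s sum to > 1 at a site", fc))
    }
    if (any(df$score < 0))
      return("panel scores must be non-negative PHRED-like values")
  }
  TRUE
})

#' @describeIn FrequencyPanel display a summary
#' @param object a `FrequencyPanel`
#' @export
setMethod("show", "FrequencyPanel", function(object) {
  cat(sprintf("FrequencyPanel: %d alleles, %d genes, populations: %s\n",
              nrow(object@sites), length(unique(object@sites$gene)),
              paste(object@populations, collapse = ", ")))
})

#' FrequencyPanel constructor
#'
#' @param sites data.frame of alleles (see class description).
#' @param populations population labels; defaults to those inferred from
#'   `freq_<pop>` columns.
#' @return a `FrequencyPanel`
#' @export
FrequencyPanel <- function(sites, populations = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (is.null(populations)) {
    fcols <- grep("^freq_", names(sites), value = TRUE)
    populations <- sub("^freq_", "", fcols)
  }
  sites$chrom <- normChrom(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  rownames(sites) <- NULL
  new("FrequencyPanel", sites = sites, populations = populations)
}

#' SimulationSpec: one cohort-simulation scenario
#'
#' Bundles every knob of a case/control simulation: cohort sizes, the
#' inheritance model, the MAF filtering cutoff applied to the panel, the
#' population admixture of each cohort, the spiked disease gene with its
#' pathogenic variant list and the fraction of cases receiving a spike, the
#' number of replicates, and the master seed from which every replicate's
#' seed is derived.
#'
#' @slot nCases,nControls cohort sizes (individuals).
#' @slot model inheritance model ("AR", "AD", "XR", "XD").
#' @slot mafCutoff maximum across-population allele frequency retained
#'   (fraction; 0.005 for recessive, 1e-4 for dominant defaults).
#' @slot frequencyField population whose frequencies drive sampling when a
#'   cohort's admixture is not given explicitly (default "adjusted").
#' @slot caseAdmixture,controlAdmixture named numeric weights over
#'   populations, summing to 1.
#' @slot spikeGene gene id receiving pathogenic spike-in.
#' @slot spikeProportion fraction of cases spiked, in [0, 1].
#' @slot pathogenicVariants data.frame chrom, pos, ref, alt, gene, score
#'   (PHRED-like) of candidate pathogenic alleles.
#' @slot spikeMode "random" (independent draws) or "fixed-pair" (the first
#'   two listed variants inserted together into every selected case).
#' @slot sexRatio fraction of males (used by X-linked scenarios).
#' @slot nReplicates number of independent replicates.
#' @slot seed master seed (integer < 2^31).
#' @export
setClass("SimulationSpec",
  representation(nCases = "numeric", nControls = "numeric",
                 model = "character", mafCutoff = "numeric",
                 frequencyField = "character",
                 caseAdmixture = "numeric", controlAdmixture = "numeric",
                 spikeGene = "character", spikeProportion = "numeric",
                 pathogenicVariants = "data.frame", spikeMode = "character",
                 sexRatio = "numeric", nReplicates = "numeric",
                 seed = "numeric"))

setValidity("SimulationSpec", function(object) {
  if (object@nCases < 1 || object@nControls < 1)
    return("cohort sizes must be at least 1")
  if (!object@model %in% c("AR", "AD", "XR", "XD"))
    return("model must be one of AR, AD, XR, XD")
  if (object@mafCutoff <= 0 || object@mafCutoff > 1)
    return("mafCutoff must lie in (0, 1]")
  if (object@spikeProportion < 0 || object@spikeProportion > 1)
    return("spikeProportion must lie in [0, 1]")
  for (w in list(object@caseAdmixture, object@controlAdmixture)) {
    if (length(w) == 0 || is.null(names(w)) || abs(sum(w) - 1) > 1e-8)
      return("admixture weights must be named and sum to 1")
  }
  if (!object@spikeMode %in% c("random", "fixed-pair"))
    return("spikeMode must be 'random' or 'fixed-pair'")
  if (object@nReplicates < 0)
    return("nReplicates must be non-negative")
  TRUE
})

#' @describeIn SimulationSpec display a summary
#' @param object a `SimulationSpec`
#' @export
setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(paste0("SimulationSpec: %d cases / %d controls, %s model, ",
                     "MAF <= %g,\n  spike %s in %.1f%% of cases (%s), ",
                     "%d replicates, seed %d\n"),
              object@nCases, object@nControls, object@model,
              object@mafCutoff, object@spikeGene,
              100 * object@spikeProportion, object@spikeMode,
              object@nReplicates, as.integer(object@seed)))
})

#' SimulationSpec constructor
#'
#' @param nCases,nControls cohort sizes.
#' @param model inheritance model.
#' @param spikeGene gene receiving the pathogenic spike-in.
#' @param pathogenicVariants data.frame of candidate pathogenic alleles
#'   (chrom, pos, ref, alt, gene, score).
#' @param spikeProportion fraction of cases spiked.
#' @param mafCutoff panel MAF filter; defaults to 0.005 for recessive and
#'   1e-4 for dominant models.
#' @param frequencyField default population label.
#' @param caseAdmixture,controlAdmixture named weights over populations.
#' @param spikeMode "random" or "fixed-pair".
#' @param sexRatio fraction of males.
#' @param nReplicates number of replicates.
#' @param seed master seed.
#' @return a `SimulationSpec`
#' @export
SimulationSpec <- function(nCases, nControls, model, spikeGene = NA_character_,
                           pathogenicVariants = data.frame(),
                           spikeProportion = 0,
                           mafCutoff = if (isRecessive(model)) 0.005 else 1e-4,
                           frequencyField = "adjusted",
                           caseAdmixture = stats::setNames(1, frequencyField),
                           controlAdmixture = caseAdmixture,
                           spikeMode = "random", sexRatio = 0.5,
                           nReplicates = 30, seed = 1L) {
  new("SimulationSpec", nCases = nCases, nControls = nControls,
      model = model, mafCutoff = mafCutoff, frequencyField = frequencyField,
      caseAdmixture = caseAdmixture, controlAdmixture = controlAdmixture,
      spikeGene = spikeGene, spikeProportion = spikeProportion,
      pathogenicVariants = as.data.frame(pathogenicVariants),
      spikeMode = spikeMode, sexRatio = sexRatio,
      nReplicates = nReplicates, seed = seed)
}
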