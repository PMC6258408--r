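#' Collapse variants asserted in cis within one phase group
#'
#' Within each explicit `phase_group` label (variants known to reside on
#' the same chromosome copy of one individual), only the call with the
#' highest normalized score is kept, since a recessive genotype requires
#' hits on both copies. Calls without a phase group pass through unchanged.
#' Ties are broken toward the smallest (chrom, pos, ref, alt) tuple, so the
#' result is deterministic. The operation groups by individual and gene, so
#' it can be applied to a whole call table at once; it is idempotent.
#'
#' @param calls data.frame of calls in the canonical schema.
#' @return the collapsed data.frame.
#' @export
collapseCis <- function(calls) {
  calls <- canonicalCalls(calls)
  if (!nrow(calls)) return(calls)
  grouped <- !is.na(calls$phase_group)
  if (!any(grouped)) return(calls)
  dt <- data.table::as.data.table(calls[grouped, , drop = FALSE])
  data.table::setorder(dt, individual, gene, phase_group,
                       -score, chrom, pos, ref, alt)
  keep <- dt[!duplicated(dt, by = c("individual", "gene", "phase_group"))]
  out <- rbind(calls[!grouped, , drop = FALSE], as.data.frame(keep))
  canonicalCalls(out)
}

#' Recessive gene score: sum of the two highest variant scores
#'
#' The deleterious mutation load of one gene in one individual under a
#' recessive model: the sum of the two largest normalized variant scores
#' after cis collapsing, or 0 when fewer than two variant copies remain
#' (a single heterozygous hit cannot produce a biallelic genotype). A
#' homozygous variant contributes two copies of its score. Result in
#' [0, 2].
#'
#' @param scores numeric vector of normalized scores in [0, 1).
#' @return a single gene score.
#' @examples
#' geneScoreRecessive(c(0.9, 0.99))  # 1.89
#' geneScoreRecessive(0.95)          # 0
#' @export
geneScoreRecessive <- function(scores) {
  if (length(scores) < 2) return(0)
  s <- sort(scores, decreasing = TRUE)
  s[1] + s[2]
}

#' Dominant gene score: the highest variant score
#'
#' A single deleterious allele suffices under a dominant model, so the gene
#' score is the maximum normalized variant score, or 0 with no variants.
#' Result in [0, 1].
#'
#' @param scores numeric vector of normalized scores in [0, 1).
#' @return a single gene score.
#' @examples
#' geneScoreDominant(c(0.3, 0.7))  # 0.7
#' @export
geneScoreDominant <- function(scores) {
  if (!length(scores)) return(0)
  max(scores)
}

#' Build the gene-by-individual score matrix for a cohort
#'
#' For every (gene, individual) pair: collapse phase-grouped cis variants,
#' then apply the inheritance model's scoring rule (top-two sum for AR/XR,
#' maximum for AD/XD). Genes outside the model's chromosome scope are
#' excluded: autosomal models keep chromosomes 1-22, X-linked models keep
#' X; calls on Y, MT or unplaced contigs are skipped with a warning.
#' Individuals without qualifying calls contribute all-zero columns; the
#' result is sparse.
#'
#' Under the XR model with `doubleHemizygous = TRUE`, a male individual's
#' single highest X variant counts twice (hemizygous, effectively
#' biallelic); by default two distinct variant records are required, as for
#' AR.
#'
#' @param cohort a [VariantCohort] with scores attached.
#' @param model inheritance model: `"AR"`, `"AD"`, `"XR"`, `"XD"`.
#' @param doubleHemizygous logical; see Details. Only consulted for XR.
#' @return a [GeneScoreMatrix].
#' @export
buildGeneScoreMatrix <- function(cohort, model = c("AR", "AD", "XR", "XD"),
                                 doubleHemizygous = FALSE) {
  model <- match.arg(model)
  stopifnot(is(cohort, "VariantCohort"))
  calls <- cohort@calls
  if (anyNA(calls$score))
    stop("cohort has unscored calls; apply a ScoreTable first")
  scope <- modelChroms(model)
  known <- c(.AUTOSOMES, "X", "Y", "MT", "M")
  unknown <- !(calls$chrom %in% known)
  if (any(unknown))
    warning("skipping ", sum(unknown), " call(s) on unrecognized contigs: ",
            paste(utils::head(unique(calls$chrom[unknown]), 5), collapse = ", "))
  calls <- calls[calls$chrom %in% scope, , drop = FALSE]
  calls <- collapseCis(calls)

  inds <- cohort@individuals
  dt <- data.table::as.data.table(calls)
  if (nrow(dt)) {
    if (isRecessive(model)) {
      gs <- dt[, {
        s <- sort(score, decreasing = TRUE)
        list(chrom = chrom[1L],
             value = if (length(s) >= 2) s[1L] + s[2L] else
               if (model == "XR" && doubleHemizygous &&
                   identical(unname(cohort@sex[individual[1L]]), "male"))
                 2 * s[1L] else 0)
      }, by = c("gene", "individual")]
    } else {
      gs <- dt[, list(chrom = chrom[1L], value = max(score)),
               by = c("gene", "individual")]
    }
    gs <- gs[value > 0]
  } else {
    gs <- data.table::data.table(gene = character(0),
                                 individual = character(0),
                                 chrom = character(0), value = numeric(0))
  }
  genes <- sort(unique(c(unique(calls$gene), gs$gene)))
  chromMap <- dt[, list(chrom = chrom[1L]), by = "gene"]
  rowChrom <- chromMap$chrom[match(genes, chromMap$gene)]
  mat <- Matrix::sparseMatrix(
    i = match(gs$gene, genes), j = match(gs$individual, inds),
    x = gs$value, dims = c(length(genes), length(inds)),
    dimnames = list(genes, inds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = mat),
    rowData = S4Vectors::DataFrame(chrom = rowChrom, row.names = genes))
  new("GeneScoreMatrix", se, model = model)
}
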