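#' Score and test one simulated replicate end-to-end
#'
#' Runs gene scoring and the case-control burden test on one case/control
#' cohort pair and extracts the three performance metrics for a known
#' target (spiked) gene: its rank, its combined p-value, and the number of
#' significant autosomal candidate genes at `alpha`. A target gene absent
#' from the ranked table (untestable in both cohorts) is assigned the
#' worst possible rank G + 1 with a warning, so power summaries stay
#' defined.
#'
#' @param cases,controls scored [VariantCohort] objects.
#' @param targetGene the spiked disease gene id.
#' @param model inheritance model.
#' @param alpha genome-wide significance cutoff.
#' @param preprocess run [preprocessCis()] on the case cohort first
#'   (default FALSE; simulated background variants are unphased singleton
#'   sites, so there is nothing to collapse).
#' @param ... forwarded to [burdenTest()].
#' @return one-row data.frame: `targetRank`, `targetP`,
#'   `nSignificantAutosomal`.
#' @export
evaluateReplicate <- function(cases, controls, targetGene, model,
                              alpha = 2.7e-6, preprocess = FALSE, ...) {
  if (preprocess) cases <- preprocessCis(cases)
  cm <- buildGeneScoreMatrix(cases, model)
  km <- buildGeneScoreMatrix(controls, model)
  res <- burdenTest(cm, km, alpha = alpha, ...)
  i <- match(targetGene, res$gene)
  if (is.na(i)) {
    warning("target gene ", targetGene,
            " untestable in this replicate; rank set to G + 1")
    targetRank <- nrow(res) + 1L
    targetP <- 1
  } else {
    targetRank <- res$rank[i]
    targetP <- res$p[i]
  }
  nSig <- sum(res$significant & res$chrom %in% .AUTOSOMES, na.rm = TRUE)
  data.frame(targetRank = targetRank, targetP = targetP,
             nSignificantAutosomal = nSig)
}

#' Summarize replicate outcomes of one simulation scenario
#'
#' Aggregates per-replicate outcomes into the scenario-level performance
#' metrics: mean and median target-gene rank (sensitivity), power — the
#' fraction of replicates in which the target gene's p-value passes
#' `alpha` — and the mean number of significant autosomal candidates
#' (specificity).
#'
#' @param outcomes data.frame of rows from [evaluateReplicate()].
#' @param alpha significance cutoff used for the power metric.
#' @return one-row data.frame: `nReplicates`, `meanRank`, `medianRank`,
#'   `power`, `meanSignificant`.
#' @export
summarizeScenario <- function(outcomes, alpha = 2.7e-6) {
  if (!nrow(outcomes)) stop("no replicate outcomes to summarize")
  data.frame(nReplicates = nrow(outcomes),
             meanRank = mean(outcomes$targetRank),
             medianRank = stats::median(outcomes$targetRank),
             power = mean(outcomes$targetP < alpha),
             meanSignificant = mean(outcomes$nSignificantAutosomal))
}

#' Run a full simulation scenario and summarize it
#'
#' Simulates `nReplicates` case/control pairs with [simulateReplicates()],
#' evaluates each with [evaluateReplicate()], and summarizes with
#' [summarizeScenario()].
#'
#' @param spec a [SimulationSpec].
#' @param panel a [FrequencyPanel].
#' @param alpha genome-wide significance cutoff.
#' @param preprocess forwarded to [evaluateReplicate()].
#' @return list with `outcomes` (per-replicate data.frame, one row per
#'   replicate in order) and `summary` (one row).
#' @export
runScenario <- function(spec, panel, alpha = 2.7e-6, preprocess = FALSE) {
  reps <- simulateReplicates(spec, panel)
  outcomes <- do.call(rbind, lapply(seq_along(reps), function(k) {
    out <- evaluateReplicate(reps[[k]]$cases, reps[[k]]$controls,
                             targetGene = spec@spikeGene,
                             model = spec@model, alpha = alpha,
                             preprocess = preprocess)
    cbind(data.frame(replicate = k), out)
  }))
  list(outcomes = outcomes, summary = summarizeScenario(outcomes, alpha))
}

#' Summarize an external per-gene p-value table with the same metrics
#'
#' Third-party tools are not reimplemented here; to compare them on equal
#' footing, their per-gene p-values can be summarized with the same rank /
#' power / candidate-count metrics. Genes are ranked by ascending p with
#' ties broken by gene id.
#'
#' @param pvalues data.frame with columns `gene`, `p` and optionally
#'   `chrom` (needed for the autosomal candidate count).
#' @param targetGene target gene id.
#' @param alpha significance cutoff.
#' @return one-row data.frame as from [evaluateReplicate()].
#' @export
externalToolOutcome <- function(pvalues, targetGene, alpha = 2.7e-6) {
  stopifnot(all(c("gene", "p") %in% names(pvalues)))
  ord <- order(pvalues$p, pvalues$gene)
  pvalues <- pvalues[ord, , drop = FALSE]
  i <- match(targetGene, pvalues$gene)
  nSig <- if ("chrom" %in% names(pvalues)) {
    sum(pvalues$p < alpha & normChrom(pvalues$chrom) %in% .AUTOSOMES)
  } else {
    sum(pvalues$p < alpha)
  }
  data.frame(targetRank = if (is.na(i)) nrow(pvalues) + 1L else i,
             targetP = if (is.na(i)) 1 else pvalues$p[i],
             nSignificantAutosomal = nSig)
}
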