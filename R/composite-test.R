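#' Binomial component: proportion of non-zero gene scores
#'
#' Tests whether the fraction of individuals carrying a non-zero gene score
#' is higher in cases than controls. With `N1` cases, `N2` controls,
#' `r = N2/N1`, and `n1`, `n2` the non-zero counts, `n1` is approximately
#' `Binomial(n1 + n2, 1/(1 + r))` under the null, which standardizes to
#' \deqn{Z_1 = \frac{n_1/(n_1+n_2) - 1/(1+r)}
#'                  {\sqrt{r / ((1+r)^2 (n_1+n_2))}}}
#' and a one-tailed p-value from the upper normal tail. The approximation
#' treats carriers as a small fraction of each cohort (the rare-variant
#' regime); `exact = TRUE` replaces the normal tail by the exact binomial
#' upper tail `P(X >= n1)`, useful for very small `n1 + n2`.
#'
#' @param n1,n2 non-zero score counts in cases and controls.
#' @param nCases,nControls cohort sizes N1 and N2.
#' @param exact use the exact binomial tail instead of the normal
#'   approximation for the p-value (Z1 is still reported).
#' @return list with elements `Z1` and `p1`.
#' @export
binomialComponent <- function(n1, n2, nCases, nControls, exact = FALSE) {
  stopifnot(n1 >= 0, n2 >= 0, n1 <= nCases, n2 <= nControls,
            nCases >= 1, nControls >= 1)
  n <- n1 + n2
  if (n == 0)
    stop("binomialComponent requires n1 + n2 >= 1; short-circuit upstream")
  r <- nControls / nCases
  p0 <- 1 / (1 + r)
  Z1 <- (n1 / n - p0) / sqrt(r / ((1 + r)^2 * n))
  p1 <- if (exact) {
    stats::pbinom(n1 - 1, n, p0, lower.tail = FALSE)
  } else {
    stats::pnorm(Z1, lower.tail = FALSE)
  }
  list(Z1 = Z1, p1 = max(p1, 1e-300))
}

#' Wilcoxon component: magnitude of the non-zero gene scores
#'
#' One-tailed (cases greater) standardized Wilcoxon rank-sum test comparing
#' the strictly positive gene scores of cases against those of controls —
#' the proportion of zeros is the binomial component's job, so zeros are
#' excluded here. The rank-sum statistic is standardized with the tied-rank
#' variance adjustment and a 0.5 continuity correction, and the p-value is
#' the upper normal tail. If either side has no positive scores, or all
#' pooled values are identical (zero rank variance), the component is
#' uninformative and `p2 = 1`.
#'
#' @param caseScores,controlScores strictly positive gene scores.
#' @param continuity apply the 0.5 continuity correction.
#' @return list with elements `Z2` and `p2`.
#' @export
wilcoxonComponent <- function(caseScores, controlScores, continuity = TRUE) {
  m <- length(caseScores); n <- length(controlScores)
  if (m == 0L || n == 0L)
    return(list(Z2 = NA_real_, p2 = 1))
  if (any(caseScores <= 0) || any(controlScores <= 0))
    stop("wilcoxonComponent expects strictly positive scores")
  rk <- rank(c(caseScores, controlScores))
  U <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  N <- m + n
  ties <- table(rk)
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(Z2 = NA_real_, p2 = 1))
  cc <- if (continuity) 0.5 else 0
  Z2 <- (U - m * n / 2 - cc) / sqrt(sigma2)
  list(Z2 = Z2, p2 = max(stats::pnorm(Z2, lower.tail = FALSE), 1e-300))
}

#' Combine two one-tailed p-values by Fisher's method
#'
#' The combined statistic is `-2 (ln p1 + ln p2)` (equivalently
#' `-4 ln sqrt(p1 p2)`), referred to a chi-square distribution with 4
#' degrees of freedom. All arithmetic is in log space so the returned
#' `logP` stays finite when `p` underflows; inputs are floored at 1e-300
#' upstream so their logs are finite.
#'
#' @param p1,p2 component p-values in (0, 1].
#' @return list with elements `chi2`, `p` and `logP` (natural log of `p`).
#' @examples
#' fisherCombine(0.5, 0.5)  # chi2 ~ 2.77, p ~ 0.597
#' @export
fisherCombine <- function(p1, p2) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) > 1))
    stop("component p-values must lie in (0, 1]")
  chi2 <- -2 * (log(p1) + log(p2))
  logP <- stats::pchisq(chi2, df = 4, lower.tail = FALSE, log.p = TRUE)
  list(chi2 = chi2, p = exp(logP), logP = logP)
}

#' Two-part case-control test of one gene
#'
#' Composes the binomial and Wilcoxon components on the full score vectors
#' of one gene (length N1 and N2, zeros included) and combines them by
#' Fisher's method, testing the one-tailed composite alternative that cases
#' carry a higher deleterious load. A gene with no non-zero score in either
#' cohort is untestable and reported with `p = 1`.
#'
#' @param caseScores,controlScores numeric vectors of all gene scores
#'   (entries >= 0), one per individual.
#' @param exactBinomial forward to [binomialComponent()].
#' @param continuity forward to [wilcoxonComponent()].
#' @return a one-row data.frame with columns `n1`, `n2`, `Z1`, `p1`, `p2`,
#'   `chi2`, `p`, `logP`.
#' @export
testGene <- function(caseScores, controlScores, exactBinomial = FALSE,
                     continuity = TRUE) {
  if (any(caseScores < 0) || any(controlScores < 0))
    stop("gene scores must be non-negative")
  N1 <- length(caseScores); N2 <- length(controlScores)
  if (N1 < 1 || N2 < 1) stop("both cohorts must be non-empty")
  xs <- caseScores[caseScores > 0]
  ys <- controlScores[controlScores > 0]
  n1 <- length(xs); n2 <- length(ys)
  if (n1 + n2 == 0L)
    return(data.frame(n1 = 0L, n2 = 0L, Z1 = NA_real_, p1 = NA_real_,
                      p2 = NA_real_, chi2 = 0, p = 1, logP = 0))
  bc <- binomialComponent(n1, n2, N1, N2, exact = exactBinomial)
  wc <- wilcoxonComponent(xs, ys, continuity = continuity)
  fc <- fisherCombine(bc$p1, wc$p2)
  data.frame(n1 = n1, n2 = n2, Z1 = bc$Z1, p1 = bc$p1, p2 = wc$p2,
             chi2 = fc$chi2, p = fc$p, logP = fc$logP)
}

#' Rank gene test results genome-wide
#'
#' Sorts ascending by log p-value, breaking ties by descending combined
#' chi-square statistic, then descending case carrier count `n1`, then
#' lexicographic gene id, and assigns ranks 1..G without gaps. Ranking on
#' the natural-log p keeps the order well defined when p-values underflow.
#'
#' @param results data.frame of per-gene results (from [burdenTest()]).
#' @return the data.frame sorted with a `rank` column.
#' @export
rankGenes <- function(results) {
  ord <- order(results$logP, -results$chi2, -results$n1, results$gene)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Subset a ranked table to genes passing a significance cutoff
#'
#' @param ranked ranked results from [rankGenes()] or [burdenTest()].
#' @param alpha significance cutoff; genes with `p < alpha` are kept in
#'   rank order. The default is the genome-wide significance level
#'   0.05 / 18500 rounded to 2.7e-6 (Bonferroni over ~18,500 autosomal
#'   protein-coding genes).
#' @return the significant subset of `ranked`.
#' @export
significantGenes <- function(ranked, alpha = 2.7e-6) {
  stopifnot(alpha >= 0)
  ranked[ranked$p < alpha, , drop = FALSE]
}

#' Case-control burden test over whole gene score matrices
#'
#' Applies [testGene()] to every gene of a case and a control
#' [GeneScoreMatrix] built under the same inheritance model, then ranks
#' genes with [rankGenes()] and flags significance at `alpha`. Genes absent
#' from one cohort's matrix are treated as all-zero there.
#'
#' @param caseMatrix,controlMatrix [GeneScoreMatrix] objects for cases and
#'   controls.
#' @param alpha genome-wide significance cutoff (see [significantGenes()]).
#' @param exactBinomial,continuity forwarded to [testGene()].
#' @return a ranked data.frame with columns `gene`, `chrom`, `n1`, `n2`,
#'   `Z1`, `p1`, `p2`, `chi2`, `p`, `logP`, `rank`, `significant`.
#' @export
burdenTest <- function(caseMatrix, controlMatrix, alpha = 2.7e-6,
                       exactBinomial = FALSE, continuity = TRUE) {
  stopifnot(is(caseMatrix, "GeneScoreMatrix"),
            is(controlMatrix, "GeneScoreMatrix"))
  if (!identical(inheritanceModel(caseMatrix),
                 inheritanceModel(controlMatrix)))
    stop("case and control matrices were built under different models")
  genes <- sort(union(rownames(caseMatrix), rownames(controlMatrix)))
  N1 <- ncol(caseMatrix); N2 <- ncol(controlMatrix)

  # Column-compressed transposes give O(carriers) access to each gene's
  # non-zero scores.
  colScores <- function(gsm) {
    m <- Matrix::t(SummarizedExperiment::assay(gsm, "score"))
    methods::as(m, "CsparseMatrix")
  }
  mc <- colScores(caseMatrix)
  mk <- colScores(controlMatrix)
  geneNonzero <- function(m, gene) {
    j <- match(gene, colnames(m))
    if (is.na(j)) return(numeric(0))
    x <- m@x[seq.int(m@p[j] + 1L, length.out = m@p[j + 1L] - m@p[j])]
    x[x > 0]
  }
  chromOf <- function(gsm) {
    stats::setNames(as.character(SummarizedExperiment::rowData(gsm)$chrom),
                    rownames(gsm))
  }
  chromMap <- c(chromOf(caseMatrix), chromOf(controlMatrix))

  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    xs <- geneNonzero(mc, g)
    ys <- geneNonzero(mk, g)
    n1 <- length(xs); n2 <- length(ys)
    if (n1 + n2 == 0L) {
      rows[[i]] <- data.frame(n1 = 0L, n2 = 0L, Z1 = NA_real_,
                              p1 = NA_real_, p2 = NA_real_,
                              chi2 = 0, p = 1, logP = 0)
      next
    }
    bc <- binomialComponent(n1, n2, N1, N2, exact = exactBinomial)
    wc <- wilcoxonComponent(xs, ys, continuity = continuity)
    fc <- fisherCombine(bc$p1, wc$p2)
    rows[[i]] <- data.frame(n1 = n1, n2 = n2, Z1 = bc$Z1, p1 = bc$p1,
                            p2 = wc$p2, chi2 = fc$chi2, p = fc$p,
                            logP = fc$logP)
  }
  res <- do.call(rbind, rows)
  res <- cbind(data.frame(gene = genes,
                          chrom = unname(chromMap[genes]),
                          stringsAsFactors = FALSE), res)
  res <- rankGenes(res)
  res$significant <- res$p < alpha
  res
}
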