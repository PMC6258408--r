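#' Classify a nearby variant pair as cis or trans from read coverages
#'
#' Two variants within `window` bp of each other in the same individual are
#' usually covered by the same sequencing reads. If they lie on the same
#' chromosome copy (cis), their alternate/reference read-coverage ratios
#' are concordant; on opposite copies (trans) the ratios differ. A
#' two-sided Fisher's exact test on the 2x2 table
#' `[altA, refA; altB, refB]` quantifies concordance: a large p-value
#' (>= `cisP`, default 0.4) calls the pair cis, a small one trans. Pairs
#' farther apart than `window` bp or lacking coverage on either side are
#' `"untested"`.
#'
#' @param posA,posB 1-based positions of the two variants (same chromosome).
#' @param altA,refA,altB,refB alternate/reference read counts.
#' @param window maximum distance in bp for testing (default 100).
#' @param cisP p-value cutoff at or above which the pair is called cis
#'   (default 0.4).
#' @return `"cis"`, `"trans"` or `"untested"`.
#' @export
coverageCisTest <- function(posA, altA, refA, posB, altB, refB,
                            window = 100, cisP = 0.4) {
  counts <- c(altA, refA, altB, refB)
  if (any(!is.na(counts) & counts < 0))
    stop("read counts must be non-negative")
  if (abs(posA - posB) > window) return("untested")
  if (anyNA(counts)) return("untested")
  if (altA + refA == 0 || altB + refB == 0) return("untested")
  p <- stats::fisher.test(matrix(counts, nrow = 2,
                                 dimnames = list(c("alt", "ref"),
                                                 c("A", "B"))))$p.value
  if (p >= cisP) "cis" else "trans"
}

# Merge pairwise cis relations transitively (union-find) and keep the
# highest-scoring member of each group; ties go to the smallest
# (chrom, pos, ref, alt) tuple. `calls` are one individual's calls in one
# gene.
.collapseCisGroups <- function(calls, window, cisP) {
  n <- nrow(calls)
  if (n < 2) return(calls)
  ord <- order(calls$pos, calls$ref, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keys <- variantKey(calls$chrom, calls$pos, calls$ref, calls$alt)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (calls$pos[j] - calls$pos[i] > window) break
      # Identical records are copies of a homozygous genotype, never a
      # cis pair.
      if (keys[i] == keys[j]) next
      verdict <- coverageCisTest(calls$pos[i], calls$alt_cov[i],
                                 calls$ref_cov[i], calls$pos[j],
                                 calls$alt_cov[j], calls$ref_cov[j],
                                 window = window, cisP = cisP)
      if (verdict == "cis") {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (g in unique(root)) {
    members <- which(root == g)
    best <- members[order(-calls$score[members], calls$chrom[members],
                          calls$pos[members], calls$ref[members],
                          calls$alt[members])][1]
    keep[best] <- TRUE
  }
  calls[keep, , drop = FALSE]
}

#' Collapse coverage-inferred cis variants within each individual and gene
#'
#' Scans each individual's calls in each gene left-to-right, tests every
#' pair within `window` bp with [coverageCisTest()], merges cis relations
#' transitively into groups, and keeps only the highest-scoring variant of
#' each group. Trans and untested pairs are left intact. Explicit
#' `phase_group` labels take precedence: labelled calls are excluded from
#' coverage inference and handled later by [collapseCis()].
#'
#' @param cohort a [VariantCohort] whose calls carry read coverages.
#' @param window pair distance cutoff in bp (default 100).
#' @param cisP Fisher's exact p cutoff for calling cis (default 0.4).
#' @return the collapsed [VariantCohort].
#' @export
applyCoverageCollapse <- function(cohort, window = 100, cisP = 0.4) {
  stopifnot(is(cohort, "VariantCohort"))
  calls <- cohort@calls
  if (!nrow(calls)) return(cohort)
  labelled <- !is.na(calls$phase_group)
  work <- calls[!labelled, , drop = FALSE]
  if (nrow(work)) {
    dt <- data.table::as.data.table(work)
    dt <- dt[order(individual, gene, chrom, pos, ref, alt)]
    out <- dt[, .collapseCisGroups(.SD, window, cisP),
              by = c("individual", "gene"),
              .SDcols = setdiff(names(dt), c("individual", "gene"))]
    work <- as.data.frame(out)
  }
  res <- rbind(canonicalCalls(work), calls[labelled, , drop = FALSE])
  methods::initialize(cohort, calls = canonicalCalls(res))
}

#' Drop concurrent variant sets that betray unrecognized cis haplotypes
#'
#' Two or more rare variants of one gene observed together in two or more
#' unrelated individuals are very unlikely to be independent biallelic
#' genotypes; they almost certainly travel on one shared haplotype. For
#' each gene, every pair of individuals sharing >= 2 identical variants
#' defines a concurrent set; within each such set only the
#' highest-scoring variant is kept in those carriers and the rest are
#' dropped. Decisions are taken on the original call sets in one pass, so
#' the result does not depend on input ordering.
#'
#' This deliberately removes signal from diseases truly caused by a
#' specific variant combination on one haplotype; disable the filter for
#' such allele-complex scenarios.
#'
#' @param cohort a [VariantCohort] (intended for the case cohort, where
#'   shared pathogenic haplotypes concentrate).
#' @return the filtered [VariantCohort].
#' @export
cooccurrenceFilter <- function(cohort) {
  stopifnot(is(cohort, "VariantCohort"))
  calls <- cohort@calls
  if (!nrow(calls)) return(cohort)
  key <- variantKey(calls$chrom, calls$pos, calls$ref, calls$alt)
  drop <- logical(nrow(calls))
  for (g in unique(calls$gene)) {
    gi <- which(calls$gene == g)
    byInd <- split(gi, calls$individual[gi])
    inds <- names(byInd)
    if (length(inds) < 2) next
    # distinct variant keys per individual (homozygous copies collapse)
    keySets <- lapply(byInd, function(ix) unique(key[ix]))
    for (a in seq_len(length(inds) - 1)) {
      for (b in (a + 1):length(inds)) {
        shared <- intersect(keySets[[a]], keySets[[b]])
        if (length(shared) < 2) next
        rows <- c(byInd[[a]], byInd[[b]])
        rows <- rows[key[rows] %in% shared]
        best <- shared[which.max(calls$score[match(shared, key)])]
        drop[rows[key[rows] != best]] <- TRUE
      }
    }
  }
  methods::initialize(cohort,
                      calls = canonicalCalls(calls[!drop, , drop = FALSE]))
}

#' Full cis preprocessing of a cohort
#'
#' Runs [applyCoverageCollapse()] (read-coverage concordance within
#' `window` bp) and, optionally, [cooccurrenceFilter()] (cohort-level
#' concurrent-set removal) ahead of gene scoring. Explicit `phase_group`
#' labels are honoured downstream by [collapseCis()].
#'
#' @param cohort a [VariantCohort].
#' @param window,cisP forwarded to [applyCoverageCollapse()].
#' @param cooccurrence apply [cooccurrenceFilter()] as well (default TRUE;
#'   set FALSE for allele-complex disease scenarios).
#' @return the preprocessed [VariantCohort].
#' @export
preprocessCis <- function(cohort, window = 100, cisP = 0.4,
                          cooccurrence = TRUE) {
  out <- applyCoverageCollapse(cohort, window = window, cisP = cisP)
  if (cooccurrence) out <- cooccurrenceFilter(out)
  out
}
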