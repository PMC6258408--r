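#' Simulate one cohort of whole-exome variant calls from a panel
#'
#' Each individual is first assigned a population drawn from the admixture
#' weights. Then, site by site, one multinomial draw over the site's
#' alternate alleles (each with its frequency in that population) and the
#' reference (with the remaining probability) emits at most one alternate
#' allele per site per individual. Frequencies are therefore used
#' per-individual, not per-haplotype: background variants are all
#' heterozygous and mutually in trans, and no phase groups are emitted.
#' Sampling is vectorized per population: biallelic sites draw carrier
#' counts binomially and multi-allelic sites draw a single multinomial
#' split across disjoint carrier subsets, which is distributionally
#' identical to per-individual draws.
#'
#' Scores carried on the calls are the panel's PHRED-like values passed
#' through [normalizeScore()].
#'
#' @param panel a [FrequencyPanel], already MAF-filtered as desired.
#' @param n number of individuals.
#' @param admixture named weights over the panel's populations, summing
#'   to 1.
#' @param label cohort label.
#' @param sexRatio fraction of males (recorded per individual for
#'   X-linked scoring; autosomal sampling ignores it).
#' @param seed RNG seed; fixed seed reproduces the cohort exactly.
#' @param idPrefix prefix of generated individual ids.
#' @return a [VariantCohort].
#' @export
simulateCohort <- function(panel, n, admixture = NULL, label = "cohort",
                           sexRatio = 0.5, seed = 1L, idPrefix = "ind") {
  stopifnot(is(panel, "FrequencyPanel"), n >= 1)
  if (is.null(admixture))
    admixture <- stats::setNames(1, panel@populations[1])
  if (!all(names(admixture) %in% panel@populations))
    stop("admixture names absent from panel populations")
  if (abs(sum(admixture) - 1) > 1e-8)
    stop("admixture weights must sum to 1")
  set.seed(seed)
  ids <- sprintf("%s%05d", idPrefix, seq_len(n))
  pops <- sample(names(admixture), n, replace = TRUE, prob = admixture)
  sex <- stats::setNames(
    sample(c("male", "female"), n, replace = TRUE,
           prob = c(sexRatio, 1 - sexRatio)), ids)

  sites <- panel@sites
  siteKey <- paste(sites$chrom, sites$pos, sites$ref)
  multi <- siteKey %in% siteKey[duplicated(siteKey)]

  parts <- list()
  for (p in unique(pops)) {
    members <- which(pops == p)
    m <- length(members)
    f <- sites[[paste0("freq_", p)]]

    # biallelic sites: carrier counts are Binomial(m, f)
    bi <- which(!multi & f > 0)
    k <- stats::rbinom(length(bi), m, f[bi])
    hit <- which(k > 0)
    if (length(hit)) {
      carriers <- lapply(hit, function(h) sample.int(m, k[h]))
      rowIdx <- rep(bi[hit], lengths(carriers))
      indIdx <- members[unlist(carriers)]
      parts[[length(parts) + 1L]] <-
        data.frame(row = rowIdx, ind = indIdx)
    }

    # multi-allelic sites: one multinomial draw per site, alternate
    # alleles assigned disjoint carrier subsets
    if (any(multi)) {
      for (sk in unique(siteKey[multi])) {
        rowsAt <- which(siteKey == sk)
        fa <- f[rowsAt]
        if (sum(fa) <= 0) next
        counts <- as.vector(stats::rmultinom(1, m, c(fa, 1 - sum(fa))))
        nAlt <- sum(counts[seq_along(rowsAt)])
        if (nAlt == 0) next
        chosen <- sample.int(m, nAlt)
        alloc <- rep(rowsAt, counts[seq_along(rowsAt)])
        parts[[length(parts) + 1L]] <-
          data.frame(row = alloc, ind = members[chosen])
      }
    }
  }

  if (length(parts)) {
    hits <- do.call(rbind, parts)
    calls <- data.frame(individual = ids[hits$ind],
                        gene = sites$gene[hits$row],
                        chrom = sites$chrom[hits$row],
                        pos = sites$pos[hits$row],
                        ref = sites$ref[hits$row],
                        alt = sites$alt[hits$row],
                        score = normalizeScore(sites$score[hits$row]),
                        stringsAsFactors = FALSE)
    calls <- calls[order(calls$individual, calls$chrom, calls$pos,
                         calls$alt), , drop = FALSE]
  } else {
    calls <- data.frame(individual = character(0), gene = character(0),
                        chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  }
  VariantCohort(calls, individuals = ids, label = label, sex = sex,
                metadata = list(seed = seed,
                                admixture = as.list(admixture),
                                population = stats::setNames(pops, ids)))
}

#' Spike pathogenic variants into a fraction of a case cohort
#'
#' Selects `round(proportion * n)` individuals uniformly without
#' replacement and inserts pathogenic alleles: under recessive models two
#' independent draws with replacement from the pathogenic list per
#' selected individual (two equal draws make a homozygote, recorded as two
#' identical call rows); under dominant models one draw. The
#' `"fixed-pair"` mode instead inserts the first two listed variants
#' together into every selected individual (the allele-complex,
#' modest-effect scenario). Controls must never be spiked — callers apply
#' this to the case cohort only.
#'
#' Pathogenic variants present in the panel are validated to have maximum
#' population frequency at or below 0.005, the rare-disease bound on
#' plausible pathogenic alleles.
#'
#' @param cohort the case [VariantCohort].
#' @param pathogenicVariants data.frame with columns chrom, pos, ref, alt,
#'   gene, score (PHRED-like).
#' @param proportion fraction of individuals spiked, in [0, 1].
#' @param model inheritance model driving the per-individual allele count.
#' @param mode `"random"` or `"fixed-pair"`.
#' @param seed RNG seed.
#' @param panel optional [FrequencyPanel] against which pathogenic allele
#'   frequencies are validated.
#' @return the spiked [VariantCohort]; spiked ids are recorded in
#'   `metadata(x)$spiked`.
#' @export
spikePathogenic <- function(cohort, pathogenicVariants, proportion,
                            model = c("AR", "AD", "XR", "XD"),
                            mode = c("random", "fixed-pair"), seed = 1L,
                            panel = NULL) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  stopifnot(is(cohort, "VariantCohort"),
            proportion >= 0, proportion <= 1)
  pv <- as.data.frame(pathogenicVariants)
  meta <- cohort@metadata
  if (proportion == 0) {
    meta$spiked <- character(0)
    return(methods::initialize(cohort, metadata = meta))
  }
  if (!nrow(pv)) stop("pathogenicVariants must be non-empty")
  if (!is.null(panel)) {
    fcols <- paste0("freq_", panel@populations)
    pk <- variantKey(panel@sites$chrom, panel@sites$pos,
                     panel@sites$ref, panel@sites$alt)
    qk <- variantKey(pv$chrom, pv$pos, pv$ref, pv$alt)
    hit <- match(qk, pk)
    fmax <- do.call(pmax, panel@sites[fcols])[hit[!is.na(hit)]]
    if (any(fmax > 0.005))
      stop("pathogenic variants must have maximum population frequency <= 0.005")
  }
  n <- length(cohort@individuals)
  nSpike <- round(proportion * n)
  if (nSpike < 1) {
    warning("proportion * cohort size < 1: no individuals spiked")
    meta$spiked <- character(0)
    return(methods::initialize(cohort, metadata = meta))
  }
  set.seed(seed)
  selected <- sample(cohort@individuals, nSpike)
  perInd <- if (isRecessive(model)) 2L else 1L
  draws <- if (mode == "fixed-pair") {
    if (nrow(pv) < 2) stop("fixed-pair mode needs at least two variants")
    rep(1:2, times = nSpike)
  } else {
    as.vector(vapply(seq_len(nSpike),
                     function(i) sample.int(nrow(pv), perInd, replace = TRUE),
                     integer(perInd)))
  }
  who <- rep(selected, each = if (mode == "fixed-pair") 2L else perInd)
  add <- data.frame(individual = who,
                    gene = pv$gene[draws], chrom = pv$chrom[draws],
                    pos = pv$pos[draws], ref = pv$ref[draws],
                    alt = pv$alt[draws],
                    score = normalizeScore(pv$score[draws]),
                    stringsAsFactors = FALSE)
  meta$spiked <- sort(selected)
  methods::initialize(cohort,
                      calls = canonicalCalls(rbind(cohort@calls[, names(canonicalCalls(add)), drop = FALSE],
                                                   canonicalCalls(add))),
                      metadata = meta)
}

#' Simulate replicate case/control cohort pairs from a scenario spec
#'
#' Applies the spec's MAF filter to the panel once, then generates
#' `nReplicates` independent pairs: a case cohort with pathogenic spike-in
#' and an unspiked control cohort. Replicate k draws its seeds
#' deterministically from the spec's master seed (see [deriveSeed()]),
#' with separate streams for cases, controls and the spike, so identical
#' specs reproduce identical cohorts bit for bit.
#'
#' @param spec a [SimulationSpec].
#' @param panel a [FrequencyPanel].
#' @return list of length `nReplicates`; each element a list with
#'   elements `cases` and `controls`.
#' @export
simulateReplicates <- function(spec, panel) {
  stopifnot(is(spec, "SimulationSpec"), is(panel, "FrequencyPanel"))
  fp <- filterPanel(panel, spec@mafCutoff)
  lapply(seq_len(spec@nReplicates), function(k) {
    cases <- simulateCohort(fp, spec@nCases,
                            admixture = spec@caseAdmixture,
                            label = "case", sexRatio = spec@sexRatio,
                            seed = deriveSeed(spec@seed, 3 * k),
                            idPrefix = "case")
    cases <- spikePathogenic(cases, spec@pathogenicVariants,
                             spec@spikeProportion, model = spec@model,
                             mode = spec@spikeMode,
                             seed = deriveSeed(spec@seed, 3 * k + 1),
                             panel = fp)
    controls <- simulateCohort(fp, spec@nControls,
                               admixture = spec@controlAdmixture,
                               label = "control", sexRatio = spec@sexRatio,
                               seed = deriveSeed(spec@seed, 3 * k + 2),
                               idPrefix = "ctrl")
    list(cases = cases, controls = controls)
  })
}

#' Fabricate a pathogenic variant list for a panel gene
#'
#' Draws `n` novel alleles at unoccupied positions inside the gene's
#' block, with PHRED scores uniform on `[minC, maxC]` — stand-ins for
#' curated pathogenic mutations of a disease gene. Being absent from the
#' panel, they trivially satisfy the rare-frequency bound.
#'
#' @param panel a [FrequencyPanel].
#' @param gene a gene id present in the panel.
#' @param n number of variants (default 20).
#' @param minC,maxC PHRED score range (defaults 25 and 40).
#' @param seed RNG seed.
#' @return data.frame chrom, pos, ref, alt, gene, score.
#' @export
makePathogenicVariants <- function(panel, gene, n = 20, minC = 25,
                                   maxC = 40, seed = 1L) {
  stopifnot(is(panel, "FrequencyPanel"), n >= 1)
  df <- panel@sites[panel@sites$gene == gene, , drop = FALSE]
  if (!nrow(df)) stop("gene not present in panel: ", gene)
  set.seed(seed)
  lo <- min(df$pos); hi <- max(df$pos) + 1000L
  free <- setdiff(seq.int(lo, hi), df$pos)
  pos <- sort(sample(free, n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  data.frame(chrom = df$chrom[1], pos = pos, ref = ref, alt = alt,
             gene = gene, score = stats::runif(n, minC, maxC),
             stringsAsFactors = FALSE)
}
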