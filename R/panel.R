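#' Generate a synthetic rare-variant allele-frequency panel
#'
#' Fabricates a [FrequencyPanel] emulating the site-frequency spectrum and
#' deleteriousness-score mix of filtered exome variation, for use when a
#' real population catalog is unavailable or a self-contained fixture is
#' wanted. Genes are laid out round-robin on autosomes 1-22 (plus an
#' optional X block), each with `Poisson(meanVariantsPerGene)` distinct
#' sites (at least one). Alternate-allele frequencies are drawn from a
#' `Beta(freqShape1, freqShape2)` capped at `maxFreq`, concentrating mass
#' well below 0.5%. Scores are a two-component mixture: a benign component
#' with exponentially distributed PHRED values (mean `benignMeanC`) and a
#' deleterious component, normal around `deleteriousMeanC`, truncated at 0.
#' A small fraction of sites receive a second alternate allele so
#' multi-allelic multinomial sampling is exercised.
#'
#' With several populations, each allele by default shares one frequency
#' across populations; `privateFraction` makes that fraction of alleles
#' private to a single population (frequency 0 elsewhere), which is how
#' population-stratification scenarios are constructed.
#'
#' @param nGenes number of genes.
#' @param meanVariantsPerGene Poisson mean of sites per gene (default 25).
#' @param freqShape1,freqShape2 Beta parameters of the allele-frequency
#'   distribution (defaults 0.3 and 400).
#' @param maxFreq frequency cap (default 0.005).
#' @param benignProportion mixture weight of the benign score component
#'   (default 0.7).
#' @param benignMeanC mean PHRED score of benign alleles (default 3).
#' @param deleteriousMeanC,deleteriousSdC normal parameters of the
#'   deleterious component (defaults 25 and 5).
#' @param multiAltFraction fraction of sites carrying a second alternate
#'   allele (default 0.02).
#' @param populations population labels (default `"adjusted"`).
#' @param privateFraction fraction of alleles private to one population
#'   when several populations are present (default 0).
#' @param nXGenes number of additional X-chromosome genes (default 0).
#' @param seed RNG seed; a fixed seed reproduces the panel exactly.
#' @return a [FrequencyPanel] with genes `G0001`, `G0002`, ... (X genes
#'   `XG0001`, ...).
#' @export
makeSyntheticPanel <- function(nGenes = 2000, meanVariantsPerGene = 25,
                               freqShape1 = 0.3, freqShape2 = 400,
                               maxFreq = 0.005, benignProportion = 0.7,
                               benignMeanC = 3, deleteriousMeanC = 25,
                               deleteriousSdC = 5, multiAltFraction = 0.02,
                               populations = "adjusted",
                               privateFraction = 0, nXGenes = 0,
                               seed = 1L) {
  stopifnot(nGenes >= 1, meanVariantsPerGene > 0, maxFreq > 0, maxFreq <= 1,
            benignProportion >= 0, benignProportion <= 1,
            multiAltFraction >= 0, multiAltFraction < 1,
            privateFraction >= 0, privateFraction <= 1,
            length(populations) >= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  geneIds <- c(sprintf("G%04d", seq_len(nGenes)),
               if (nXGenes > 0) sprintf("XG%04d", seq_len(nXGenes)))
  chroms <- c(as.character(((seq_len(nGenes) - 1) %% 22) + 1),
              rep("X", nXGenes))
  nvar <- pmax(stats::rpois(length(geneIds), meanVariantsPerGene), 1L)

  rows <- vector("list", length(geneIds))
  for (i in seq_along(geneIds)) {
    k <- nvar[i]
    # gene i occupies a 200 kb block; blocks never overlap within a
    # chromosome because gene indices on one chromosome are distinct
    blockStart <- 1e6 + (i - 1) * 2e5
    pos <- sort(sample.int(150000L, k)) + as.integer(blockStart)
    ref <- sample(bases, k, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    rows[[i]] <- data.frame(chrom = chroms[i], pos = pos, ref = ref,
                            alt = alt, gene = geneIds[i],
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)

  # second alternate allele at a fraction of sites
  nMulti <- round(multiAltFraction * nrow(df))
  if (nMulti > 0) {
    ix <- sample.int(nrow(df), nMulti)
    extra <- df[ix, , drop = FALSE]
    extra$alt <- vapply(seq_len(nMulti), function(j) {
      sample(setdiff(bases, c(extra$ref[j], df$alt[ix[j]])), 1)
    }, "")
    df <- rbind(df, extra)
  }

  n <- nrow(df)
  df$score <- ifelse(stats::runif(n) < benignProportion,
                     stats::rexp(n, rate = 1 / benignMeanC),
                     pmax(stats::rnorm(n, deleteriousMeanC, deleteriousSdC),
                          0))
  f <- pmin(stats::rbeta(n, freqShape1, freqShape2), maxFreq)
  for (p in populations) df[[paste0("freq_", p)]] <- f
  if (length(populations) > 1 && privateFraction > 0) {
    priv <- which(stats::runif(n) < privateFraction)
    home <- sample(populations, length(priv), replace = TRUE)
    for (p in populations) {
      zero <- priv[home != p]
      df[[paste0("freq_", p)]][zero] <- 0
    }
  }
  df <- df[order(match(df$chrom, c(.AUTOSOMES, "X")), df$pos, df$alt), ]
  FrequencyPanel(df, populations = populations)
}

#' Filter a frequency panel by maximum population frequency
#'
#' Retains alleles whose maximum frequency across all populations is at or
#' below `mafCutoff` — the rare-variant filtering step applied before
#' simulation and analysis (0.5% default for recessive scenarios, 0.01%
#' for dominant ones).
#'
#' @param panel a [FrequencyPanel].
#' @param mafCutoff frequency cutoff in (0, 1]; 1 keeps everything.
#' @return the filtered [FrequencyPanel].
#' @export
filterPanel <- function(panel, mafCutoff) {
  stopifnot(is(panel, "FrequencyPanel"), mafCutoff > 0, mafCutoff <= 1)
  df <- panel@sites
  fcols <- paste0("freq_", panel@populations)
  fmax <- do.call(pmax, df[fcols])
  FrequencyPanel(df[fmax <= mafCutoff, , drop = FALSE],
                 populations = panel@populations)
}

#' Read a frequency panel from TSV
#'
#' Expects columns chrom, pos, ref, alt, gene, score and one
#' `freq_<population>` column per population; gzipped files are read
#' transparently. This is also the layout a converter from a real
#' population catalog (e.g. an ExAC-style VCF annotated with scores and
#' gene assignments) would have to produce.
#'
#' @param path TSV path.
#' @return a [FrequencyPanel].
#' @export
readPanel <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        showProgress = FALSE))
  FrequencyPanel(df)
}

#' Write a frequency panel to TSV
#'
#' @param panel a [FrequencyPanel].
#' @param path output TSV path (".gz" suffix compresses).
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
  data.table::fwrite(panel@sites, path, sep = "\t")
  invisible(path)
}
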