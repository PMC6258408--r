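# burdenRank

Case-control gene ranking for Mendelian disease gene discovery.

## The problem

Mendelian disorders are genetically heterogeneous: the same clinical
phenotype can arise from mutations in many different genes, so in a
patient cohort any single disease gene may explain only a few percent of
cases. burdenRank prioritizes candidate genes by asking, for every gene,
whether its *rare deleterious mutation load* is higher in patients than
in matched controls — a signal that survives even extreme locus
heterogeneity. It is aimed at researchers analysing case/control exome
cohorts for recessive or dominant disease genes, and at methodologists
who want a self-contained simulation harness for this class of test.

## The method

Each variant's PHRED-like deleteriousness score *C* (e.g. CADD) is
normalized to `s = 1 − 10^(−C/10) ∈ [0, 1)`. Under a recessive model a
gene's score in an individual is the sum of its two highest variant
scores (0 with fewer than two variant copies; range [0, 2]); under a
dominant model it is the single highest score (range [0, 1]). Likely-cis
variant pairs are collapsed first, using read-coverage concordance
(two-sided Fisher's exact test on alt/ref coverages of pairs within
100 bp, cis when p ≥ 0.4) and cohort-level co-occurrence.

Gene score distributions are zero-inflated, so each gene is tested with
a two-part statistic:

* **Z1** — carrier proportion: with N1 cases, N2 controls, r = N2/N1 and
  n1, n2 non-zero counts, n1 ~ Binomial(n1 + n2, 1/(1 + r)) under the
  null;
* **Z2** — carrier magnitude: one-tailed standardized Wilcoxon rank-sum
  on the non-zero scores only;

combined by Fisher's method, `χ² = −2(ln p1 + ln p2) ~ χ²₄`, with all
arithmetic in log space so ranking stays exact under underflow. Genes
are ranked by combined p, and significance uses the genome-wide level
`α = 0.05/18,500 ≈ 2.7e−6`.

The package also ships the full evaluation apparatus: a synthetic
allele-frequency panel generator, a whole-exome cohort simulator with
per-site multinomial sampling and pathogenic spike-in, and replicate
metrics (target-gene rank, power at the genome-wide level, significant
autosomal candidate count).

## Worked example

Simulate a 600-case / 5,000-control recessive scenario on a 500-gene
synthetic panel, spiking 2% of cases with pathogenic alleles of gene
`G0123`, then rank genes:

```r
library(burdenRank)

panel <- makeSyntheticPanel(nGenes = 500, seed = 11)
pathogenic <- makePathogenicVariants(panel, "G0123", minC = 25, seed = 12)
spec <- SimulationSpec(nCases = 600, nControls = 5000, model = "AR",
                       spikeGene = "G0123",
                       pathogenicVariants = pathogenic,
                       spikeProportion = 0.02, nReplicates = 1, seed = 13)
rep1 <- simulateReplicates(spec, panel)[[1]]

caseMat <- buildGeneScoreMatrix(rep1$cases, "AR")
caseMat
#> GeneScoreMatrix (AR model): 500 genes x 600 individuals, 47 non-zero scores

res <- burdenTest(caseMat, buildGeneScoreMatrix(rep1$controls, "AR"))
head(res[, c("rank", "gene", "n1", "n2", "Z1", "p1", "p2", "chi2", "p")], 5)
#>   rank  gene n1 n2       Z1           p1         p2      chi2            p
#> 1    1 G0123 12  1 9.511612 9.386497e-22 0.07051582 102.13904 3.446463e-21
#> 2    2 G0008  1  0 2.886751 1.946209e-03 1.00000000  12.48374 1.409419e-02
#> 3    3 G0125  1  0 2.886751 1.946209e-03 1.00000000  12.48374 1.409419e-02
#> 4    4 G0184  1  0 2.886751 1.946209e-03 1.00000000  12.48374 1.409419e-02
#> 5    5 G0206  1  0 2.886751 1.946209e-03 1.00000000  12.48374 1.409419e-02
```

The spiked gene lands at rank 1: its 12 spiked carriers (n1 = 12 of 600
cases, versus one background carrier among 5,000 controls) drive
Z1 = 9.5, and Fisher's combination puts the gene 19 orders of magnitude
past the genome-wide cutoff, while every unspiked gene stays far from
significance. Scenario-level metrics aggregate replicates:

```r
summarizeScenario(runScenario(spec, panel)$outcomes)
#>   nReplicates meanRank medianRank power meanSignificant
#> 1           1        1          1     1               1
```

A thin command-line dispatcher over the same functions is installed at
`inst/cli/burden-rank.R` (subcommands `make-panel`, `simulate`, `score`,
`preprocess-cis`, `test`, `evaluate`).

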