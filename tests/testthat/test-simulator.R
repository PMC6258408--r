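test_that("panel MAF filtering keeps alleles at or below the cutoff", {
  df <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                   ref = "A", alt = "T", gene = "G1",
                   score = 10, freq_adjusted = c(0.004, 0.02, 0.005))
  panel <- FrequencyPanel(df)
  kept <- panelSites(filterPanel(panel, 0.005))
  expect_equal(sort(kept$pos), c(100L, 300L))
  expect_equal(nrow(panelSites(filterPanel(panel, 1.0))), 3)
})

test_that("panel validity rejects per-site frequency sums above 1", {
  df <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = c("T", "G"),
                   gene = "G1", score = 10, freq_adjusted = c(0.6, 0.5))
  expect_error(FrequencyPanel(df), "sum to > 1")
})

test_that("synthetic panels are reproducible and well-formed", {
  p1 <- makeSyntheticPanel(nGenes = 100, seed = 5)
  p2 <- makeSyntheticPanel(nGenes = 100, seed = 5)
  expect_identical(panelSites(p1), panelSites(p2))
  expect_equal(length(unique(panelSites(p1)$gene)), 100)
  expect_true(all(panelSites(p1)$freq_adjusted <= 0.005))
  expect_true(all(panelSites(p1)$chrom %in% as.character(1:22)))
  # some multi-allelic sites exist to exercise multinomial sampling
  key <- with(panelSites(p1), paste(chrom, pos, ref))
  expect_gt(sum(duplicated(key)), 0)
})

test_that("per-site sampling follows the panel's allele frequencies", {
  # one site with two alternates at 0.2% and 0.5%: emission fractions
  # over many simulated individuals converge within 3 binomial SDs
  df <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = c("T", "G"),
                   gene = "G1", score = 10,
                   freq_adjusted = c(0.002, 0.005))
  panel <- FrequencyPanel(df)
  n <- 20000
  cohort <- simulateCohort(panel, n, seed = 77)
  calls <- variantCalls(cohort)
  for (i in 1:2) {
    f <- df$freq_adjusted[i]
    got <- sum(calls$alt == df$alt[i]) / n
    expect_lt(abs(got - f), 3 * sqrt(f * (1 - f) / n))
  }
  # at most one alternate per site per individual
  expect_false(any(duplicated(calls[c("individual", "chrom", "pos")])))
})

test_that("zero-frequency panels emit nothing and seeds fix the output", {
  df <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "T",
                   gene = "G1", score = 10, freq_adjusted = 0)
  expect_equal(nrow(variantCalls(simulateCohort(FrequencyPanel(df), 50,
                                                seed = 1))), 0)
  panel <- smallPanel()
  a <- simulateCohort(panel, 200, seed = 9)
  b <- simulateCohort(panel, 200, seed = 9)
  expect_identical(variantCalls(a), variantCalls(b))
  expect_false(identical(variantCalls(a),
                         variantCalls(simulateCohort(panel, 200, seed = 10))))
})

test_that("empirical allele frequencies recover panel values", {
  df <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                   ref = "A", alt = "T", gene = "G1", score = 10,
                   freq_adjusted = c(1e-4, 5e-4, 2e-3, 5e-3))
  panel <- FrequencyPanel(df)
  n <- 20000
  calls <- variantCalls(simulateCohort(panel, n, seed = 2026))
  for (i in seq_len(nrow(df))) {
    f <- df$freq_adjusted[i]
    got <- sum(calls$pos == df$pos[i]) / n
    expect_lt(abs(got - f), 4 * sqrt(f * (1 - f) / n))
  }
})

test_that("admixture weights drive population assignment", {
  df <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "T",
                   gene = "G1", score = 10, freq_A = 0.001, freq_B = 0.001)
  panel <- FrequencyPanel(df)
  n <- 5000
  cohort <- simulateCohort(panel, n, admixture = c(A = 0.6, B = 0.4),
                           seed = 3)
  fracA <- mean(cohort@metadata$population == "A")
  expect_lt(abs(fracA - 0.6), 3 * sqrt(0.6 * 0.4 / n))
  expect_error(simulateCohort(panel, 10, admixture = c(A = 0.5, B = 0.4),
                              seed = 1), "sum to 1")
})

test_that("population-private alleles create stratification burden", {
  panel <- makeSyntheticPanel(nGenes = 40, populations = c("A", "B"),
                              privateFraction = 0.8, seed = 6)
  sites <- panelSites(panel)
  privateA <- sites$freq_A > 0 & sites$freq_B == 0
  privateB <- sites$freq_B > 0 & sites$freq_A == 0
  expect_gt(sum(privateA), 0)
  expect_gt(sum(privateB), 0)
  # an all-A cohort draws no B-private alleles
  calls <- variantCalls(simulateCohort(panel, 300,
                                       admixture = c(A = 1), seed = 8))
  keys <- paste(calls$chrom, calls$pos, calls$alt)
  bKeys <- with(sites[privateB, ], paste(chrom, pos, alt))
  expect_equal(sum(keys %in% bKeys), 0)
})

test_that("spike-in selects the stated number of cases, cases only", {
  panel <- smallPanel()
  pv <- makePathogenicVariants(panel, "G0010", seed = 4)
  cohort <- simulateCohort(filterPanel(panel, 0.005), 600, seed = 21,
                           label = "case")
  spiked <- spikePathogenic(cohort, pv, 0.02, model = "AR", seed = 22)
  ids <- spiked@metadata$spiked
  expect_length(ids, 12)  # round(0.02 * 600)
  added <- variantCalls(spiked)
  addedRows <- added[added$gene == "G0010" &
                       added$pos %in% pv$pos, , drop = FALSE]
  expect_setequal(unique(addedRows$individual), ids)
  # recessive spike: exactly two pathogenic copies per selected case
  expect_true(all(table(addedRows$individual) == 2))

  unspiked <- spikePathogenic(cohort, pv, 0, model = "AR", seed = 22)
  expect_identical(variantCalls(unspiked), variantCalls(cohort))
  expect_warning(spikePathogenic(cohort, pv, 1e-4, model = "AR", seed = 1),
                 "no individuals spiked")
})

test_that("equal recessive draws produce a homozygote scoring 2s", {
  panel <- smallPanel()
  pv <- makePathogenicVariants(panel, "G0010", n = 1, seed = 4)
  cohort <- VariantCohort(makeCalls(character(0), character(0),
                                    pos = integer(0)),
                          individuals = c("i1", "i2"), label = "case")
  spiked <- spikePathogenic(cohort, pv, 1, model = "AR", seed = 5)
  m <- buildGeneScoreMatrix(spiked, "AR")
  s <- normalizeScore(pv$score[1])
  expect_equal(as.numeric(SummarizedExperiment::assay(m)["G0010", ]),
               rep(2 * s, 2))
})

test_that("dominant spike inserts one allele per selected case", {
  panel <- smallPanel()
  pv <- makePathogenicVariants(panel, "G0010", seed = 4)
  cohort <- simulateCohort(filterPanel(panel, 0.005), 100, seed = 31)
  spiked <- spikePathogenic(cohort, pv, 0.1, model = "AD", seed = 32)
  added <- variantCalls(spiked)
  addedRows <- added[added$pos %in% pv$pos & added$gene == "G0010", ]
  expect_true(all(table(addedRows$individual) == 1))
  expect_length(spiked@metadata$spiked, 10)
})

test_that("fixed-pair mode inserts both specified variants together", {
  panel <- smallPanel()
  pv <- makePathogenicVariants(panel, "G0010", n = 5, seed = 4)
  cohort <- simulateCohort(filterPanel(panel, 0.005), 50, seed = 41)
  spiked <- spikePathogenic(cohort, pv, 0.2, model = "AR",
                            mode = "fixed-pair", seed = 42)
  added <- variantCalls(spiked)
  for (id in spiked@metadata$spiked) {
    mine <- added[added$individual == id & added$pos %in% pv$pos[1:2], ]
    expect_setequal(mine$pos, pv$pos[1:2])
  }
})

test_that("replicate simulation is sized, seeded and bitwise reproducible", {
  panel <- smallPanel()
  pv <- makePathogenicVariants(panel, "G0010", seed = 4)
  spec <- SimulationSpec(30, 100, "AR", spikeGene = "G0010",
                         pathogenicVariants = pv, spikeProportion = 0.1,
                         nReplicates = 3, seed = 7)
  reps <- simulateReplicates(spec, panel)
  expect_length(reps, 3)
  reps2 <- simulateReplicates(spec, panel)
  expect_identical(lapply(reps, function(r) variantCalls(r$cases)),
                   lapply(reps2, function(r) variantCalls(r$cases)))
  expect_false(identical(variantCalls(reps[[1]]$cases),
                         variantCalls(reps[[2]]$cases)))
  expect_length(simulateReplicates(
    SimulationSpec(30, 100, "AR", spikeGene = "G0010",
                   pathogenicVariants = pv, spikeProportion = 0.1,
                   nReplicates = 0, seed = 7), panel), 0)
})

test_that("spiked gene scores equal the sum of the drawn variant scores", {
  panel <- smallPanel()
  pv <- makePathogenicVariants(panel, "G0010", seed = 4)
  spec <- SimulationSpec(50, 50, "AR", spikeGene = "G0010",
                         pathogenicVariants = pv, spikeProportion = 0.2,
                         nReplicates = 1, seed = 13)
  rep1 <- simulateReplicates(spec, panel)[[1]]
  cases <- rep1$cases
  calls <- variantCalls(cases)
  m <- buildGeneScoreMatrix(cases, "AR")
  for (id in cases@metadata$spiked) {
    mine <- calls[calls$individual == id & calls$gene == "G0010", ]
    top2 <- sum(sort(mine$score, decreasing = TRUE)[1:2])
    expect_equal(as.numeric(SummarizedExperiment::assay(m)["G0010", id]),
                 top2)
    expect_lte(top2, 2)
  }
})
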