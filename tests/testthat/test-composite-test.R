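test_that("binomial component matches its closed form and symmetry", {
  # balanced cohorts with equal carrier counts carry no signal
  bal <- binomialComponent(7, 7, 100, 100)
  expect_equal(bal$Z1, 0)
  expect_equal(bal$p1, 0.5)

  # direct evaluation of the standardized proportion statistic
  z <- binomialComponent(13, 5, 600, 5000)$Z1
  expect_equal(z, 8.436, tolerance = 1e-3)

  # no case carriers: negative statistic, p above one half
  lo <- binomialComponent(0, 5, 100, 100)
  expect_lt(lo$Z1, 0)
  expect_gt(lo$p1, 0.5)

  expect_error(binomialComponent(0, 0, 10, 10), "n1 \\+ n2")
})

test_that("normal-approximation p1 tracks exact binomial tails for n >= 30", {
  # documented approximation bound: max abs error <= 0.09 on the lattice,
  # decreasing with n (worst near n = 30)
  for (cfg in list(c(200, 200), c(600, 5000))) {
    N1 <- cfg[1]; N2 <- cfg[2]
    for (n in c(30, 60, 120)) {
      for (n1 in seq(0, n, by = 3)) {
        appr <- binomialComponent(n1, n - n1, N1, N2)$p1
        exact <- binomialComponent(n1, n - n1, N1, N2, exact = TRUE)$p1
        expect_lt(abs(appr - exact), 0.09)
      }
    }
  }
})

test_that("wilcoxon component is calibrated and matches exact enumeration", {
  # exchangeable inputs: p near one half (continuity correction and the
  # fully tied pairs push it slightly above)
  set.seed(8)
  x <- runif(20)
  expect_equal(wilcoxonComponent(x, x)$p2, 0.5, tolerance = 0.05)

  # complete separation, 7 cases above 5 controls: exact p = 1/C(12,5);
  # the normal approximation is documented to agree within 0.005 absolute
  # in this extreme tail
  xs <- seq(0.6, 0.9, length.out = 7)
  ys <- seq(0.1, 0.5, length.out = 5)
  expect_equal(exactWilcoxonP(xs, ys), 1 / choose(12, 5))
  expect_lt(abs(wilcoxonComponent(xs, ys)$p2 - 1 / choose(12, 5)), 0.005)

  # mid-range configuration agrees much more closely
  x2 <- c(0.9, 0.5, 0.7); y2 <- c(0.3, 0.6, 0.2, 0.4)
  expect_equal(wilcoxonComponent(x2, y2)$p2, exactWilcoxonP(x2, y2),
               tolerance = 0.05)

  # either side empty: uninformative component
  expect_equal(wilcoxonComponent(numeric(0), x)$p2, 1)
  expect_equal(wilcoxonComponent(x, numeric(0))$p2, 1)
  # zero rank variance (all values identical): uninformative
  expect_equal(wilcoxonComponent(rep(0.5, 3), rep(0.5, 4))$p2, 1)
})

test_that("wilcoxon component agrees with the reference implementation", {
  set.seed(31)
  for (rep in 1:20) {
    x <- runif(sample(3:30, 1)); y <- runif(sample(3:30, 1))
    ours <- wilcoxonComponent(x, y)$p2
    ref <- stats::wilcox.test(x, y, alternative = "greater",
                              exact = FALSE, correct = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Fisher combination matches the chi-square(4) closed form", {
  one <- fisherCombine(1, 1)
  expect_equal(one$chi2, 0)
  expect_equal(one$p, 1)

  half <- fisherCombine(0.5, 0.5)
  expect_equal(half$chi2, -4 * log(sqrt(0.25)))
  expect_equal(half$chi2, 2.7726, tolerance = 1e-4)
  expect_equal(half$p, chisq4Survival(half$chi2), tolerance = 1e-12)
  expect_equal(half$p, 0.5966, tolerance = 1e-4)

  mix <- fisherCombine(0.05, 1)
  expect_equal(mix$p, chisq4Survival(-2 * log(0.05)), tolerance = 1e-12)

  expect_error(fisherCombine(0, 0.5), "\\(0, 1\\]")
})

test_that("chi-square(4) survival matches e^(-x/2)(1 + x/2) to 1e-12", {
  x <- seq(0, 200, by = 0.5)
  ours <- exp(pchisq(x, df = 4, lower.tail = FALSE, log.p = TRUE))
  expect_equal(ours, chisq4Survival(x), tolerance = 1e-12)
})

test_that("Fisher combination is symmetric and monotone in each argument", {
  set.seed(13)
  p <- runif(50, 1e-12, 1)
  q <- runif(50, 1e-12, 1)
  for (i in 1:50) {
    expect_equal(fisherCombine(p[i], q[i])$p, fisherCombine(q[i], p[i])$p)
    bigger <- min(1, q[i] * 1.5)
    expect_gte(fisherCombine(p[i], bigger)$p, fisherCombine(p[i], q[i])$p)
  }
})

test_that("log-space combination survives extreme underflow", {
  res <- fisherCombine(1e-300, 1e-300)
  expect_true(is.finite(res$logP))
  expect_lt(res$logP, -1000)
  expect_equal(res$p, 0)  # underflows, but logP still ranks it
})

test_that("testGene composes the parts and short-circuits untestable genes", {
  allZero <- testGene(rep(0, 10), rep(0, 50))
  expect_equal(allZero$p, 1)
  expect_equal(allZero$n1 + allZero$n2, 0)

  # a strongly loaded gene must beat a background gene
  hot <- testGene(c(rep(1.9, 8), rep(0, 92)), c(0.4, rep(0, 499)))
  cold <- testGene(c(0.5, rep(0, 99)), c(0.6, 0.3, rep(0, 498)))
  expect_lt(hot$p, cold$p)

  expect_error(testGene(c(-0.1, 0.5), c(0, 0)), "non-negative")
})

test_that("type-I error is nominal under a zero-inflated null", {
  # rare-carrier regime the binomial approximation is designed for:
  # carriers are a small fraction of each cohort
  set.seed(1903)
  G <- 2000; N1 <- 600; N2 <- 2000; pnz <- 0.03
  pv <- vapply(seq_len(G), function(g) {
    cs <- ifelse(runif(N1) < pnz, rbeta(N1, 2, 2), 0)
    ks <- ifelse(runif(N2) < pnz, rbeta(N2, 2, 2), 0)
    testGene(cs, ks)$p
  }, numeric(1))
  for (alpha in c(0.05, 0.005)) {
    ci <- qbinom(c(0.005, 0.995), G, alpha) / G
    got <- mean(pv < alpha)
    expect_gte(got, ci[1])
    expect_lte(got, ci[2])
  }
})

test_that("ranking is deterministic with documented tie-breaks", {
  res <- data.frame(gene = c("B", "A", "C", "D"),
                    n1 = c(5L, 5L, 7L, 2L),
                    chi2 = c(40, 50, 50, 10),
                    p = c(1e-3, 1e-9, 1e-9, 0.5),
                    logP = log(c(1e-3, 1e-9, 1e-9, 0.5)))
  ranked <- rankGenes(res)
  # equal p: larger chi2 would win, here equal, so larger n1 wins
  expect_equal(ranked$gene, c("C", "A", "B", "D"))
  expect_equal(ranked$rank, 1:4)

  shuffled <- rankGenes(res[c(3, 1, 4, 2), ])
  expect_equal(shuffled$gene, ranked$gene)
})

test_that("significance subsetting respects the threshold strictly", {
  ranked <- rankGenes(data.frame(gene = c("A", "B"), n1 = c(3L, 2L),
                                 chi2 = c(60, 30), p = c(1e-7, 1e-5),
                                 logP = log(c(1e-7, 1e-5))))
  expect_equal(significantGenes(ranked, alpha = 2.7e-6)$gene, "A")
  expect_equal(nrow(significantGenes(ranked, alpha = 0)), 0)
  expect_equal(nrow(significantGenes(ranked, alpha = 1)), 2)
})

test_that("burdenTest aligns matrices, ranks genes and flags significance", {
  caseCalls <- rbind(
    makeCalls(sprintf("c%02d", 1:8), "G1", pos = 100L + 0:7, score = 0.95),
    makeCalls(sprintf("c%02d", 1:8), "G1", pos = 200L + 0:7, score = 0.9),
    makeCalls("c01", "G2", pos = 5000L, score = 0.5))
  ctrlCalls <- makeCalls("k01", "G3", pos = 900L, score = 0.4)
  cm <- buildGeneScoreMatrix(
    VariantCohort(caseCalls, individuals = sprintf("c%02d", 1:20)), "AR")
  km <- buildGeneScoreMatrix(
    VariantCohort(ctrlCalls, individuals = sprintf("k%02d", 1:100)), "AR")
  res <- burdenTest(cm, km, alpha = 1e-4)
  expect_equal(res$gene[1], "G1")
  expect_true(res$significant[1])
  expect_equal(sort(res$gene), c("G1", "G2", "G3"))
  # G2 and G3 are untestable under AR (single heterozygous variants)
  expect_equal(res$p[res$gene %in% c("G2", "G3")], c(1, 1))

  ad <- buildGeneScoreMatrix(
    VariantCohort(caseCalls, individuals = sprintf("c%02d", 1:20)), "AD")
  expect_error(burdenTest(ad, km), "different models")
})
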