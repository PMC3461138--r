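test_that("unbiased heterozygosity matches hand evaluation and limits", {
  ## two alleles at 0.5/0.5 in 10 diploids: (20/19) * 0.5
  s <- sample_from_genotypes(rep(list(c(1, 2)), 10))
  expect_equal(unbiasedHet(alleleFreqs(s, "L1")), 20 / 19 * 0.5,
               tolerance = 1e-12)
  ## monomorphic locus has no heterozygosity
  mono <- sample_from_genotypes(rep(list(c(3, 3)), 6))
  expect_equal(unbiasedHet(alleleFreqs(mono, "L1")), 0)
  ## four equifrequent alleles, large N: approaches 0.75
  big <- sample_from_genotypes(rep(list(c(1, 2), c(3, 4)), 500))
  expect_equal(unbiasedHet(alleleFreqs(big, "L1")), 0.75, tolerance = 1e-3)
  ## undefined below 2 gene copies
  g <- array(NA_integer_, dim = c(2, 1, 2), dimnames = list(NULL, "L1", NULL))
  g[1, 1, ] <- c(1L, 2L)
  tiny <- GenotypeSample("X", 2000, "contemporary", g)
  ft <- alleleFreqs(tiny, "L1")
  expect_equal(ft$N, 2L)
  expect_true(is.na(unbiasedHet(list(locus = "L1", freq = 1, N = 1L, n = 1L))))
})

test_that("unbiased heterozygosity is unbiased under binomial resampling", {
  set.seed(21)
  p <- c(0.5, 0.3, 0.2)
  target <- 1 - sum(p^2)
  hh <- replicate(4000, {
    copies <- sample.int(3, 20, replace = TRUE, prob = p)
    f <- table(copies) / 20
    20 / 19 * (1 - sum(f^2))
  })
  expect_equal(mean(hh), target, tolerance = 3 * sd(hh) / sqrt(4000))
})

test_that("rarefied allelic richness equals subsample enumeration", {
  ## counts {3,1}, g = 2: oracle over all C(4,2) subsamples gives 1.5
  s31 <- sample_from_genotypes(list(c(1, 1), c(1, 2)))
  expect_equal(allelicRichness(alleleFreqs(s31, "L1"), 2), 1.5)
  expect_equal(oracle_richness(c(3, 1), 2), 1.5)
  ## counts {2,2}, g = 2: 2 - 2/6
  s22 <- sample_from_genotypes(list(c(1, 2), c(1, 2)))
  expect_equal(allelicRichness(alleleFreqs(s22, "L1"), 2), 2 - 2 / 6)
  ## full-sample rarefaction returns the observed allele count
  expect_equal(allelicRichness(alleleFreqs(s31, "L1"), 4), 2)
  ## random tables up to 6 copies against the enumeration oracle
  set.seed(5)
  for (rep in 1:20) {
    counts <- as.numeric(table(sample.int(3, 6, replace = TRUE)))
    ft <- list(locus = "L1", allele = seq_along(counts),
               count = counts, freq = counts / 6, N = 6L, n = 3L)
    for (g in 2:6)
      expect_equal(allelicRichness(ft, g), oracle_richness(counts, g),
                   tolerance = 1e-12)
  }
  ## monotone non-decreasing in g
  set.seed(6)
  for (rep in 1:10) {
    counts <- as.numeric(table(sample.int(5, 30, replace = TRUE)))
    ft <- list(locus = "L1", allele = seq_along(counts), count = counts,
               freq = counts / 30, N = 30L, n = 15L)
    ar <- vapply(2:30, function(g) allelicRichness(ft, g), numeric(1))
    expect_true(all(diff(ar) >= -1e-12))
  }
  ## g beyond N names the locus
  expect_error(allelicRichness(alleleFreqs(s31, "L1"), 10), "L1")
})

test_that("Hardy-Weinberg Monte-Carlo p-value tracks the enumerated exact p", {
  ## all-heterozygote AB sample: enumerate every pairing of the 8 copies
  s <- sample_from_genotypes(rep(list(c(1, 2)), 4))
  ## with 4+4 copies of two alleles the configuration is determined by the
  ## heterozygote count; Levene's conditional probabilities enumerate the
  ## full null distribution
  lp_config <- function(het) {
    ## het must have same parity as 4; pairs: (4-het)/2 homAA, het AB, rest BB
    n11 <- (4 - het) / 2
    n22 <- (4 - het) / 2
    lgamma(4 + 1) + 2 * lgamma(4 + 1) + het * log(2) -
      lgamma(8 + 1) - (lgamma(n11 + 1) + lgamma(het + 1) + lgamma(n22 + 1))
  }
  hets <- c(0, 2, 4)
  lps <- vapply(hets, lp_config, numeric(1))
  probs <- exp(lps)
  ## number of pairings realising each het count is proportional to probs
  p_exact <- sum(probs[exp(lps) <= exp(lps[3]) + 1e-12]) / sum(probs)
  res <- hweExactTest(s, "L1", nMc = 20000, seed = 1)
  expect_equal(res$p, p_exact, tolerance = 4 * sqrt(p_exact / 20000) + 0.01)
  ## monomorphic locus
  mono <- sample_from_genotypes(rep(list(c(1, 1)), 4))
  expect_warning(rm <- hweExactTest(mono, "L1", nMc = 10), "monomorphic")
  expect_equal(rm$p, 1)
  expect_error(hweExactTest(s, "L1", nMc = 0), "nMc")
  ## determinism under a fixed seed
  expect_equal(hweExactTest(s, "L1", nMc = 500, seed = 7)$p,
               hweExactTest(s, "L1", nMc = 500, seed = 7)$p)
})

test_that("signed-rank test matches enumeration, base R, and symmetry", {
  ## nine uniformly positive differences, one-sided: p = 1/2^9
  a <- 1:9 + 10; b <- 1:9
  w <- wilcoxonPairedByLocus(a, b, alternative = "greater")
  expect_equal(w$p, 1 / 512)
  expect_gt(w$statistic, 0)
  ## identical vectors
  eqv <- wilcoxonPairedByLocus(a, a)
  expect_equal(eqv$p, 1)
  expect_equal(eqv$statistic, 0)
  ## antisymmetry
  wr <- wilcoxonPairedByLocus(b, a, alternative = "greater")
  expect_equal(abs(w$statistic), abs(wr$statistic))
  expect_equal(sign(w$statistic), -sign(wr$statistic))
  ## random cases vs the 2^n enumeration oracle (ties included)
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(5:11, 1)
    x <- round(rnorm(n), 1); y <- round(rnorm(n), 1)
    for (alt in c("two.sided", "greater", "less")) {
      suppressWarnings(p_pkg <- wilcoxonPairedByLocus(x, y, alt)$p)
      expect_equal(p_pkg, oracle_wilcoxon(x, y, alt), tolerance = 1e-9,
                   label = sprintf("rep %d alt %s", rep, alt))
    }
  }
  ## tie-free case agrees with stats::wilcox.test exact p
  set.seed(32)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxonPairedByLocus(x, y, "two.sided")$p,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("blocked rank test matches hand ranking and is null-calibrated", {
  ## identical columns: no signal
  m <- matrix(rep(1:9, 3), ncol = 3)
  r0 <- blockedRankTest(m)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  ## one group always highest, one always lowest over 9 blocks: H = 18
  m2 <- cbind(high = rep(3, 9), mid = rep(2, 9), low = rep(1, 9))
  r <- blockedRankTest(m2)
  expect_equal(r$statistic, 18)
  expect_equal(r$p, pchisq(18, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(r$p, 2e-4)
  ## agreement with stats::friedman.test on random data
  set.seed(41)
  y <- matrix(rnorm(27), 9, 3)
  ft <- friedman.test(y)
  expect_equal(blockedRankTest(y)$statistic, unname(ft$statistic))
  expect_equal(blockedRankTest(y)$p, ft$p.value)
  ## column permutation leaves the statistic's null distribution invariant
  expect_equal(blockedRankTest(y[, c(2, 3, 1)])$statistic,
               blockedRankTest(y)$statistic)
  expect_error(blockedRankTest(y[, 1:2]), "k >= 3")
  yna <- y; yna[1, 1] <- NA
  expect_error(blockedRankTest(yna), "ncomplete")
})

test_that("diversity table rarefies to the smallest sample and reports SEs", {
  set.seed(51)
  s1 <- rand_sample(8, nloci = 4, nAlleles = 6, site = "A", year = 1910,
                    epoch = "historical")
  s2 <- rand_sample(20, nloci = 4, nAlleles = 6, site = "A", year = 2005,
                    epoch = "contemporary")
  ds <- TemporalDataset(loci = lociNames(s1), samples = list(s1, s2))
  dt <- diversityTable(ds)
  expect_equal(nrow(dt$summary), 2L)
  expect_equal(unique(dt$summary$g), 16)
  expect_true(all(dt$perLocus$Ar <= dt$perLocus$A + 1e-9))
  expect_true(all(dt$perLocus$Hexp >= 0 & dt$perLocus$Hexp <= 1))
  expect_true(all(is.finite(dt$summary$Hexp_se)))
})
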