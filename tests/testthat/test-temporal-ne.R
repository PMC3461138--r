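test_that("generation counts follow the year gap and generation length", {
  expect_equal(generationsBetween(1910, 2005, 1), 95)
  expect_equal(generationsBetween(1915, 2005, 1), 90)
  expect_equal(generationsBetween(1910, 2005, 2), 48)
  expect_equal(generationsBetween(1910, 2005, 1.5), 63)
  expect_error(generationsBetween(2005, 1910, 1), "after")
  expect_error(generationsBetween(1910, 2005, 0), "positive")
})

## helper: TemporalPair with exact allele frequencies at one locus
pair_with_freqs <- function(x_counts, y_counts, tGen = 10) {
  geno0 <- split(rep(seq_along(x_counts), x_counts),
                 rep(seq_len(sum(x_counts) / 2), each = 2))
  genoT <- split(rep(seq_along(y_counts), y_counts),
                 rep(seq_len(sum(y_counts) / 2), each = 2))
  s0 <- sample_from_genotypes(unname(geno0), year = 1915, epoch = "historical")
  st <- sample_from_genotypes(unname(genoT), year = 2005, epoch = "contemporary")
  temporalPair(s0, st, tGen = tGen)
}

test_that("Fc matches hand evaluation and is time-symmetric", {
  ## x = (0.6, 0.4), y = (0.4, 0.6): Fc = 0.04/0.26
  pr <- pair_with_freqs(c(60, 40), c(40, 60))
  fc <- fcStatistic(pr)
  expect_equal(fc$Fc, 0.04 / 0.26, tolerance = 1e-12)
  expect_equal(fc$df, 1)
  ## no change: Fc = 0
  expect_equal(fcStatistic(pair_with_freqs(c(60, 40), c(60, 40)))$Fc, 0)
  ## swapping the time labels leaves Fc unchanged
  rev <- pair_with_freqs(c(40, 60), c(60, 40))
  expect_equal(fcStatistic(rev)$Fc, fc$Fc)
})

test_that("moment Ne continues the Fc example and handles the no-signal case", {
  pr <- pair_with_freqs(c(60, 40), c(40, 60), tGen = 10)
  est <- momentNe(pr)
  expect_equal(est$Ne, 10 / (2 * (0.04 / 0.26 - 0.01 - 0.01)),
               tolerance = 1e-9)
  expect_equal(round(est$Ne, 2), 37.36)
  expect_true(est$ci["lower"] <= est$Ne && est$Ne <= est$ci["upper"])
  ## doubling tGen doubles Ne for fixed Fc
  pr2 <- pair_with_freqs(c(60, 40), c(40, 60), tGen = 20)
  expect_equal(momentNe(pr2)$Ne, 2 * est$Ne, tolerance = 1e-9)
  ## identical frequencies: drift signal below sampling noise, Ne = Inf
  expect_equal(momentNe(pair_with_freqs(c(60, 40), c(60, 40)))$Ne, Inf)
})

test_that("moment estimator recovers a known Wright-Fisher truth", {
  set.seed(111)
  est <- replicate(120, {
    fx <- wfForwardSim(Ne = 100, tGen = 10, nLoci = 9, nAlleles = 10,
                       S0 = 50, St = 50)
    pr <- temporalPair(getSamples(fx$dataset, "historical")[[1]],
                       getSamples(fx$dataset, "contemporary")[[1]], tGen = 10)
    momentNe(pr)$Ne
  })
  expect_lt(abs(median(est) - 100) / 100, 0.3)
})

test_that("source pools average gene-copy counts, order-invariantly", {
  a <- sample_from_genotypes(list(c(1, 1), c(1, 2)))   # counts A:3 B:1
  b <- sample_from_genotypes(list(c(1, 2), c(2, 2)))   # counts A:1 B:3
  src <- buildSource(list(a, b))
  expect_equal(src$L1$freq, c(0.5, 0.5))
  src2 <- buildSource(list(b, a))
  expect_equal(src2$L1$freq, src$L1$freq)
  one <- buildSource(list(a))
  expect_equal(one$L1$freq, c(0.75, 0.25))
  expect_error(buildSource(list()), "at least one")
})

test_that("pseudo-likelihood matches the exact transition-matrix oracle", {
  ## small state spaces (2Ne <= 40): the grid chain must reproduce the
  ## brute-force Wright-Fisher matrix-power likelihood
  for (cfg in list(list(Ne = 10, m = 0, ps = 0),
                   list(Ne = 20, m = 0, ps = 0),
                   list(Ne = 15, m = 0.1, ps = 0.7))) {
    twoNe <- 2 * cfg$Ne
    pgrid <- (0:twoNe) / twoNe
    for (case in list(c(10, 40, 14, 40, 5), c(3, 30, 1, 36, 8))) {
      got <- chronopop:::pml_chain_loglik_cpp(case[1], case[2], case[3],
                                              case[4], case[5], twoNe,
                                              cfg$m, cfg$ps, pgrid, TRUE)
      want <- oracle_wf_loglik(case[1], case[2], case[3], case[4], case[5],
                               cfg$Ne, cfg$m, cfg$ps)
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("the grid maximum tracks the oracle's maximum for small Ne", {
  set.seed(112)
  fx <- wfForwardSim(Ne = 15, tGen = 6, nLoci = 6, nAlleles = 3,
                     S0 = 25, St = 25)
  pr <- temporalPair(getSamples(fx$dataset, "historical")[[1]],
                     getSamples(fx$dataset, "contemporary")[[1]], tGen = 6)
  neGrid <- c(5, 8, 12, 15, 20, 30, 50, 80)
  est <- suppressWarnings(pmlNe(pr, neGrid = neGrid))
  ## oracle surface over the same grid using the same chain construction
  oll <- vapply(neGrid, function(Ne) {
    tot <- 0
    for (loc in sprintf("L%d", 1:6)) {
      pf <- chronopop:::.pair_freqs(pr, loc)
      cls <- chronopop:::.collapse_alleles(pf)
      if (is.null(cls)) next
      for (cl in cls)
        tot <- tot + oracle_wf_loglik(cl$a0, pf$N0, cl$at, pf$Nt, 6, Ne)
    }
    tot
  }, numeric(1))
  expect_equal(est$Ne, neGrid[which.max(oll)])
})

test_that("closed likelihood increases with Ne for more similar samples", {
  ## matched fixture family: the same earlier sample, later samples with
  ## increasing frequency change
  ll_at <- function(shift) {
    pr <- pair_with_freqs(c(50, 50), c(50 - shift, 50 + shift), tGen = 8)
    est <- suppressWarnings(pmlNe(pr, neGrid = c(10, 25, 50, 100, 250, 500,
                                                 1000, 2500)))
    est$Ne
  }
  ne_small_change <- ll_at(2)
  ne_big_change <- ll_at(30)
  expect_gt(ne_small_change, ne_big_change)
})

test_that("the joint model nests the closed model at m = 0", {
  set.seed(113)
  fx <- wfForwardSim(Ne = 50, tGen = 8, nLoci = 5, nAlleles = 4,
                     S0 = 30, St = 30, m = 0.05)
  pr <- temporalPair(getSamples(fx$dataset, "historical")[[1]],
                     getSamples(fx$dataset, "contemporary")[[1]], tGen = 8)
  src <- source_from_truth(fx$truth)
  grid <- c(10, 20, 40, 80, 160, 320)
  closed <- suppressWarnings(pmlNe(pr, neGrid = grid))
  joint0 <- suppressWarnings(pmlNe(pr, source = src, neGrid = grid,
                                   mGrid = 0))
  expect_equal(joint0$logLik[, 1], closed$logLik[, 1], tolerance = 1e-10)
  expect_equal(joint0$Ne, closed$Ne)
  ## joint estimation without a source is refused
  expect_error(pmlNe(pr, mGrid = c(0, 0.05)), "source")
})

test_that("temporal-Ne reports cover sites, methods and T values", {
  set.seed(114)
  mk <- function(site, year, epoch, n) {
    g <- array(sample.int(5, n * 4 * 2, replace = TRUE), dim = c(n, 4, 2),
               dimnames = list(NULL, paste0("L", 1:4), NULL))
    GenotypeSample(site, year, epoch, g)
  }
  ds <- TemporalDataset(loci = paste0("L", 1:4),
                        samples = list(mk("A", 1915, "historical", 12),
                                       mk("B", 1915, "historical", 12),
                                       mk("A", 2005, "contemporary", 15),
                                       mk("B", 2005, "contemporary", 15)))
  rep <- temporalNeReport(ds, T = 2, joint = TRUE,
                          neGrid = c(50, 200, 800, 3200),
                          mGrid = c(0, 0.05, 0.2))
  expect_equal(sort(unique(rep$site)), c("A", "B"))
  expect_setequal(unique(rep$method), c("moment", "pml_closed", "pml_joint"))
  expect_equal(unique(rep$tGen), 45)
  expect_true(all(is.na(rep$m[rep$method == "moment"])))
  expect_true(all(!is.na(rep$m[rep$method == "pml_joint"])))
})
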