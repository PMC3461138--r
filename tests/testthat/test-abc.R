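test_that("prior draws respect bounds, means and constraints", {
  sc8 <- bottleneckScenarios()[[8]]
  set.seed(81)
  draws <- t(replicate(20000, drawPrior(sc8)))
  expect_true(all(draws[, "Ncur"] >= 200 & draws[, "Ncur"] <= 1000))
  expect_true(all(draws[, "tbot"] >= 10 & draws[, "tbot"] <= 80))
  expect_true(all(draws[, "Nanc"] == 5000))
  expect_equal(mean(draws[, "tbot"]), 45, tolerance = 0.7)
  ## scenario 1's constant-or-increasing constraint holds in every draw
  sc1 <- bottleneckScenarios()[[1]]
  d1 <- t(replicate(2000, drawPrior(sc1)))
  expect_true(all(d1[, "Nanc"] <= d1[, "Ncur"]))
  ## degenerate bounds are constants
  scfix <- demographicScenario(99, 4000, 500, 30)
  expect_equal(drawPrior(scfix), c(Nanc = 4000, Ncur = 500, tbot = 30))
  ## unsatisfiable constraints fail loudly
  bad <- demographicScenario(98, 10, 5000, 30, constraint = ">")
  bad@ancestral <- c(10, 10); bad@current <- c(5000, 5000)
  expect_error(drawPrior(bad, maxTries = 50), "unsatisfiable")
})

test_that("summary statistics match their definitions on a known fixture", {
  h <- sample_from_genotypes(list(c(1, 2), c(1, 1)), site = "S", year = 1915,
                             epoch = "historical")
  cc <- sample_from_genotypes(list(c(2, 2), c(2, 3)), site = "S", year = 2005,
                              epoch = "contemporary")
  ds <- TemporalDataset(loci = "L1", samples = list(h, cc),
                        generationOffset = 90)
  st <- summarizeDataset(ds)
  expect_equal(length(st), 11L)
  expect_equal(unname(st["A_hist"]), 2)
  expect_equal(unname(st["A_cont"]), 2)
  ## unbiased Hexp: hist copies (1,2,1,1): 4/3 * (1 - (9+1)/16)
  expect_equal(unname(st["Hexp_hist"]), 4 / 3 * (1 - 10 / 16))
  expect_equal(unname(st["Vsize_hist"]), var(c(1, 2, 1, 1)))
  ## shared alleles: hist {1,2}, cont {2,3}: |{2}| / |{1,2,3}|
  expect_equal(unname(st["sharedAlleles"]), 1 / 3)
  expect_equal(unname(st["dmu2"]), (mean(c(1, 2, 1, 1)) - mean(c(2, 2, 2, 3)))^2)
  ## theta equals the genotype-level estimator on the same samples
  expect_equal(unname(st["theta"]), thetaWc(h, cc)$theta)
})

test_that("duplicated samples give zero differentiation statistics", {
  set.seed(82)
  s <- rand_sample(50, nloci = 3, nAlleles = 5, epoch = "historical",
                   year = 1915)
  s2 <- GenotypeSample("X", 2005, "contemporary", genotypes(s))
  ds <- TemporalDataset(loci = lociNames(s), samples = list(s, s2),
                        generationOffset = 90)
  st <- summarizeDataset(ds)
  expect_equal(unname(st["sharedAlleles"]), 1)
  expect_lt(abs(st["theta"]), 0.02)
  expect_equal(unname(st["dmu2"]), 0)
  ## single-epoch datasets are refused
  ds1 <- TemporalDataset(loci = lociNames(s), samples = list(s))
  expect_error(summarizeDataset(ds1), "both")
})

test_that("reference tables are balanced, reproducible and NaN-free", {
  scs <- list(demographicScenario(1, 2000, 2000, NA, constraint = "none"),
              bottleneckScenarios()[[8]])
  sched <- sampleSchedule(12, 8)
  t1 <- buildReferenceTable(scs, 80, sched, nLoci = 4, seed = 7)
  t2 <- buildReferenceTable(scs, 80, sched, nLoci = 4, seed = 7)
  expect_equal(t1@stats, t2@stats)
  expect_equal(t1@params, t2@params)
  expect_equal(as.vector(table(t1@scenario)), c(80, 80))
  expect_false(anyNA(t1@stats))
  expect_equal(length(t1@center), 11L)
})

test_that("a deep bottleneck lowers simulated contemporary allele counts", {
  sched <- sampleSchedule(20, 12)
  tnull <- buildReferenceTable(
    list(demographicScenario(1, 3000, 3000, NA, constraint = "none")),
    60, sched, nLoci = 6, seed = 8)
  tbot <- buildReferenceTable(
    list(demographicScenario(8, 5000, 300, c(40, 70))),
    60, sched, nLoci = 6, seed = 9)
  expect_gt(mean(tnull@stats[, "A_cont"]), mean(tbot@stats[, "A_cont"]))
})

test_that("rejection keeps the nearest rows, monotonically in tolerance", {
  set.seed(91)
  ns <- length(chronopop:::.STAT_NAMES)
  stats <- matrix(rnorm(500 * ns), 500, ns,
                  dimnames = list(NULL, chronopop:::.STAT_NAMES))
  tab <- new("ReferenceTable", scenario = rep(1:2, each = 250),
             params = matrix(runif(1500), 500, 3,
                             dimnames = list(NULL, c("Nanc", "Ncur", "tbot"))),
             stats = stats, center = apply(stats, 2, median),
             scale = apply(stats, 2, mad), seed = 1)
  obs <- stats[137, ]
  acc <- rejectClosest(obs, tab, tolerance = 0.02)
  expect_equal(length(acc$index), 10L)       # ceiling(0.02 * 500)
  expect_true(137 %in% acc$index)
  expect_equal(min(acc$dist), 0)
  ## tolerance 1 retains everything
  expect_equal(length(rejectClosest(obs, tab, tolerance = 1)$index), 500L)
  ## nesting of acceptance sets across tolerances
  a1 <- rejectClosest(obs, tab, tolerance = 0.05)
  a2 <- rejectClosest(obs, tab, tolerance = 0.2)
  expect_true(all(a1$index %in% a2$index))
  expect_error(rejectClosest(obs, tab, tolerance = 0), "tolerance")
})

test_that("scenario posteriors are symmetric when stats carry no signal", {
  set.seed(92)
  ns <- length(chronopop:::.STAT_NAMES)
  stats <- matrix(rnorm(600 * ns), 600, ns,
                  dimnames = list(NULL, chronopop:::.STAT_NAMES))
  tab <- new("ReferenceTable", scenario = rep(1:3, each = 200),
             params = matrix(runif(1800), 600, 3,
                             dimnames = list(NULL, c("Nanc", "Ncur", "tbot"))),
             stats = stats, center = apply(stats, 2, median),
             scale = apply(stats, 2, mad), seed = 1)
  acc <- rejectClosest(rep(0, ns), tab, tolerance = 0.5)
  pr <- scenarioPosterior(acc)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_true(all(abs(pr - 1 / 3) < 0.15))
  ## duplicating every row leaves the posterior essentially unchanged
  tab2 <- new("ReferenceTable", scenario = rep(tab@scenario, 2),
              params = rbind(tab@params, tab@params),
              stats = rbind(tab@stats, tab@stats),
              center = tab@center, scale = tab@scale, seed = 1)
  acc2 <- rejectClosest(rep(0, ns), tab2, tolerance = 0.5)
  pr2 <- scenarioPosterior(acc2)
  expect_equal(unname(pr2), unname(pr), tolerance = 0.05)
  ## single-scenario acceptance warns and returns probability 1
  acc1 <- acc; acc1$scenario <- rep(2L, length(acc$scenario))
  expect_warning(p1 <- scenarioPosterior(acc1), "only scenario")
  expect_equal(unname(p1), 1)
})

test_that("parameter posteriors collapse on constants and track the prior
           when the statistics are uninformative", {
  sc <- demographicScenario(8, 5000, c(200, 1000), c(10, 80))
  set.seed(93)
  n <- 400
  acc <- list(index = seq_len(n),
              dist = runif(n),
              delta = matrix(rnorm(n * 11, 0, 1e-8), n, 11),
              weights = rep(1, n),
              scenario = rep(8L, n),
              params = cbind(Nanc = rep(5000, n),
                             Ncur = runif(n, 200, 1000),
                             tbot = runif(n, 10, 80)))
  ## constant parameter: point estimate at the constant, zero-width CI
  accC <- acc; accC$params[, "Ncur"] <- 450
  pc <- parameterPosterior(accC, sc)
  expect_equal(pc$params$Ncur$median, 450, tolerance = 1e-6)
  expect_lt(diff(range(pc$params$Ncur$ci)), 1e-6)
  ## uninformative deltas: posterior tracks the prior
  pu <- parameterPosterior(acc, sc)
  expect_equal(pu$params$tbot$median, 45, tolerance = 4)
  expect_lt(pu$params$tbot$ci["lower"], 16)
  expect_gt(pu$params$tbot$ci["upper"], 74)
  expect_error(parameterPosterior(list(index = 1:10), sc), "50 accepted")
})

test_that("weighted quantiles interpolate the cumulative weight", {
  x <- c(1, 2, 3, 4)
  expect_equal(weightedQuantile(x, rep(1, 4), 0.5), 2.5)
  expect_equal(weightedQuantile(x, c(1, 0, 0, 1), 0.25), 1.5, tolerance = 0.6)
  expect_equal(weightedQuantile(x, rep(1, 4), c(0, 1)), c(1, 4))
  ## heavier weight drags the median
  expect_lt(weightedQuantile(x, c(10, 1, 1, 1), 0.5),
            weightedQuantile(x, c(1, 1, 1, 10), 0.5))
})

test_that("the ABC fit recovers parameters of a simulated bottleneck", {
  ## small-scale recovery: observed simulated under scenario 8 with known
  ## parameters; reduced table for runtime, so generous bands
  sched <- sampleSchedule(40, 25)
  sc8 <- bottleneckScenarios()[[8]]
  obs <- simulateDataset(c(Nanc = 5000, Ncur = 450, tbot = 67, offset = 90),
                         sched, nLoci = 9, seed = 101)
  tab <- buildReferenceTable(list(sc8), 1500, sched, nLoci = 9, seed = 102)
  fit <- abcFit(obs, tab, list(sc8), tolerance = 0.05, seed = 103)
  expect_equal(fit$chosen, 8L)
  expect_gt(fit$params$Ncur$median, 200)
  expect_lt(fit$params$Ncur$median, 1000)
  expect_true(fit$params$Ncur$ci["lower"] <= fit$params$Ncur$median)
  expect_true(fit$params$Ncur$ci["upper"] >= fit$params$Ncur$median)
  ## the adjusted posterior should sit well inside the prior around truth
  expect_lt(abs(fit$params$Ncur$median - 450), 300)
  expect_lt(abs(fit$params$tbot$median - 67), 30)
})
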