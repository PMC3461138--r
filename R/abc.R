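## Approximate Bayesian computation: summary statistics, reference table,
## rejection, logistic-regression scenario posteriors, regression-adjusted
## parameter posteriors.

.STAT_NAMES <- c("A_hist", "Hexp_hist", "Vsize_hist", "M_hist",
                 "A_cont", "Hexp_cont", "Vsize_cont", "M_cont",
                 "theta", "sharedAlleles", "dmu2")

## Summary statistics from raw per-locus gene-copy vectors.
## Conventions for degenerate loci (documented): unbiased Hexp of a
## monomorphic locus is 0; allele-size variance of a single copy class is
## 0; theta contributions of loci monomorphic across both samples are
## skipped, and theta = 0 if every locus is such; shared-allele proportion
## is the Jaccard overlap of allele sets.
.summarize_raw <- function(raw) {
  nc2 <- 2L * raw$nCont
  persamp <- function(pick) {
    A <- H <- V <- M <- numeric(length(raw$states))
    for (l in seq_along(raw$states)) {
      st <- raw$states[[l]][pick]
      tab <- tabulate(st)
      tab <- tab[tab > 0]
      N <- length(st)
      p <- tab / N
      A[l] <- length(tab)
      H[l] <- if (N >= 2) N / (N - 1) * (1 - sum(p^2)) else 0
      V[l] <- if (N >= 2) var(st) else 0
      ## Garza-Williamson M: allele count over allele-size span
      M[l] <- A[l] / (max(st) - min(st) + 1)
    }
    c(mean(A), mean(H), mean(V), mean(M))
  }
  ih <- nc2 + seq_len(2L * raw$nHist)
  ic <- seq_len(nc2)
  sh <- persamp(ih); sc <- persamp(ic)
  ## theta from variance components over gene copies paired sequentially
  sumA <- 0; sumABC <- 0
  shared <- dmu <- numeric(length(raw$states))
  for (l in seq_along(raw$states)) {
    st <- raw$states[[l]]
    h <- st[ih]; cst <- st[ic]
    ah <- sort(unique(h)); ac <- sort(unique(cst))
    shared[l] <- length(intersect(ah, ac)) / length(union(ah, ac))
    dmu[l] <- (mean(h) - mean(cst))^2
    if (length(union(ah, ac)) < 2L) next
    cmp <- .wc_components_copies(h, cst)
    sumA <- sumA + sum(cmp$a)
    sumABC <- sumABC + sum(cmp$a + cmp$b + cmp$c)
  }
  theta <- if (sumABC > 0) sumA / sumABC else 0
  setNames(c(sh, sc, theta, mean(shared), mean(dmu)), .STAT_NAMES)
}

## Weir-Cockerham components from two gene-copy vectors (sequentially
## paired into diploids). Mirrors .wc_components_locus without the S4
## container, for the simulation hot path.
.wc_components_copies <- function(copies1, copies2) {
  m1 <- matrix(copies1, ncol = 2, byrow = TRUE)
  m2 <- matrix(copies2, ncol = 2, byrow = TRUE)
  n <- c(nrow(m1), nrow(m2)); r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(c(copies1, copies2)))
  a <- b <- cc <- numeric(length(alleles))
  for (i in seq_along(alleles)) {
    al <- alleles[i]
    p <- c(sum(copies1 == al) / (2 * n[1]), sum(copies2 == al) / (2 * n[2]))
    h <- c(sum((m1[, 1] == al) != (m1[, 2] == al)) / n[1],
           sum((m2[, 1] == al) != (m2[, 2] == al)) / n[2])
    pbar <- sum(n * p) / (r * nbar)
    s2v <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a[i] <- nbar / nc * (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v -
                                  hbar / 4) / (nbar - 1))
    b[i] <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2v -
                                   (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[i] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

#' Summary-statistic vector for a two-epoch dataset
#'
#' Fixed ordered vector used by the ABC engine: per epoch the mean (over
#' loci) allele count, unbiased expected heterozygosity, allele-size
#' variance and Garza-Williamson M-ratio (allele count over allele-size
#' span, sensitive to bottleneck duration); between epochs the multilocus
#' Weir-Cockerham theta, the mean Jaccard shared-allele proportion, and
#' the mean squared difference of mean allele sizes ((delta mu)^2).
#' Samples are pooled by epoch if the dataset holds more than one sample
#' per epoch. Degenerate (monomorphic) loci follow documented zero
#' conventions, so the vector is NaN-free.
#'
#' @param dataset A [TemporalDataset] with both epochs present.
#' @return Named numeric vector of length 11.
#' @export
summarizeDataset <- function(dataset) {
  hs <- getSamples(dataset, "historical")
  cs <- getSamples(dataset, "contemporary")
  if (length(hs) == 0L || length(cs) == 0L)
    stop("summary statistics need both a historical and a contemporary sample")
  h <- if (length(hs) > 1L) poolSamples(hs, "hist") else hs[[1]]
  cn <- if (length(cs) > 1L) poolSamples(cs, "cont") else cs[[1]]
  tostates <- function(s) lapply(seq_along(dataset@loci), function(l) {
    g <- s@genotypes[, l, ]
    as.integer(t(g))            # copy1, copy2 per individual, sequential
  })
  sh <- tostates(h); sc <- tostates(cn)
  raw <- list(states = lapply(seq_along(sh), function(l) {
    x <- c(sc[[l]], sh[[l]])
    x[is.na(x)] <- -1L          # placeholder; dropped below
    x
  }), nCont = nInd(cn), nHist = nInd(h), offset = dataset@generationOffset)
  ## missing data: .summarize_raw assumes complete copies, so drop missing
  ## individuals per locus by imputing nothing -- instead compute directly:
  if (any(vapply(raw$states, function(x) any(x < 0), logical(1))))
    return(.summarize_missing(sh, sc))
  .summarize_raw(raw)
}

## Slow path tolerating missing genotypes (observed data; not the sim loop).
.summarize_missing <- function(sh, sc) {
  persamp <- function(states) {
    A <- H <- V <- M <- numeric(length(states))
    for (l in seq_along(states)) {
      st <- states[[l]]; st <- st[!is.na(st)]
      tab <- table(st); p <- as.numeric(tab) / length(st)
      A[l] <- length(tab)
      H[l] <- if (length(st) >= 2) length(st) / (length(st) - 1) * (1 - sum(p^2)) else 0
      V[l] <- if (length(st) >= 2) var(st) else 0
      M[l] <- A[l] / (max(st) - min(st) + 1)
    }
    c(mean(A), mean(H), mean(V), mean(M))
  }
  stats_h <- persamp(sh); stats_c <- persamp(sc)
  sumA <- 0; sumABC <- 0
  shared <- dmu <- numeric(length(sh))
  for (l in seq_along(sh)) {
    h <- sh[[l]]; cst <- sc[[l]]
    hp <- matrix(h, ncol = 2, byrow = TRUE); hp <- hp[!is.na(hp[, 1]), , drop = FALSE]
    cp <- matrix(cst, ncol = 2, byrow = TRUE); cp <- cp[!is.na(cp[, 1]), , drop = FALSE]
    hv <- as.integer(t(hp)); cv <- as.integer(t(cp))
    ah <- unique(hv); ac <- unique(cv)
    shared[l] <- length(intersect(ah, ac)) / length(union(ah, ac))
    dmu[l] <- (mean(hv) - mean(cv))^2
    if (length(union(ah, ac)) < 2L || nrow(hp) < 2 || nrow(cp) < 2) next
    cmp <- .wc_components_copies(hv, cv)
    sumA <- sumA + sum(cmp$a)
    sumABC <- sumABC + sum(cmp$a + cmp$b + cmp$c)
  }
  theta <- if (sumABC > 0) sumA / sumABC else 0
  setNames(c(stats_h, stats_c, theta, mean(shared), mean(dmu)), .STAT_NAMES)
}

#' Build an ABC reference table
#'
#' For each scenario, draws `nPerScenario` parameter vectors from the
#' priors (respecting size-order constraints), simulates a two-epoch
#' dataset under each, and records its summary statistics. Per-statistic
#' robust scaling constants (median, MAD) are stored with the table; rows
#' whose statistics are undefined are resimulated (abort if the failure
#' rate exceeds 1%).
#'
#' @param scenarios List of [DemographicScenario-class] objects.
#' @param nPerScenario Simulated datasets per scenario.
#' @param schedule A `SampleSchedule`.
#' @param model A `MutationModel`.
#' @param nLoci Loci per dataset (default 9).
#' @param seed RNG seed (reproducible tables).
#' @return A [ReferenceTable-class].
#' @export
buildReferenceTable <- function(scenarios, nPerScenario, schedule,
                                model = mutationModel(), nLoci = 9,
                                seed = NULL) {
  if (length(scenarios) < 1L) stop("need at least one scenario")
  if (is(scenarios, "DemographicScenario")) scenarios <- list(scenarios)
  if (!is.null(seed)) set.seed(seed)
  ntot <- length(scenarios) * nPerScenario
  stats <- matrix(NA_real_, ntot, length(.STAT_NAMES),
                  dimnames = list(NULL, .STAT_NAMES))
  params <- matrix(NA_real_, ntot, 3,
                   dimnames = list(NULL, c("Nanc", "Ncur", "tbot")))
  scen <- integer(ntot)
  row <- 0L; fails <- 0L
  for (sc in scenarios) {
    for (i in seq_len(nPerScenario)) {
      row <- row + 1L
      repeat {
        pv <- drawPrior(sc)
        raw <- .simulate_raw(c(pv, offset = sc@sampleOffset), schedule,
                             model, nLoci = nLoci)
        st <- .summarize_raw(raw)
        if (!anyNA(st) && all(is.finite(st))) break
        fails <- fails + 1L
        if (fails > max(10, 0.01 * ntot))
          stop("simulation failure rate exceeds 1%; check scenario priors")
      }
      stats[row, ] <- st
      params[row, ] <- pv
      scen[row] <- sc@id
    }
  }
  ctr <- apply(stats, 2, median)
  scl <- apply(stats, 2, mad)
  scl[scl < 1e-12] <- pmax(apply(stats, 2, sd), 1e-12)[scl < 1e-12]
  new("ReferenceTable", scenario = scen, params = params, stats = stats,
      center = ctr, scale = scl, seed = if (is.null(seed)) NA_real_ else seed)
}

#' Rejection step: retain the simulations closest to the observed data
#'
#' Euclidean distance on median/MAD-standardized summary statistics;
#' retains the `ceiling(tolerance * nrow)` nearest rows. Distance ties are
#' broken by row order after a seeded shuffle.
#'
#' @param observed Observed summary-statistic vector ([summarizeDataset()]).
#' @param table A [ReferenceTable-class].
#' @param tolerance Acceptance fraction in (0, 1] (default 0.01).
#' @param seed Seed for the tie-break shuffle.
#' @return List: `index` (accepted row indices), `dist`, `delta` (accepted
#'   stats minus observed, standardized), `weights` (Epanechnikov on the
#'   acceptance radius), `scenario`, `params`.
#' @export
rejectClosest <- function(observed, table, tolerance = 0.01, seed = 1) {
  stopifnot(is(table, "ReferenceTable"))
  if (!(tolerance > 0 && tolerance <= 1)) stop("tolerance must be in (0, 1]")
  n <- nrow(table@stats)
  if (n == 0L) stop("empty reference table")
  if (!is.null(names(observed))) observed <- observed[.STAT_NAMES]
  if (length(observed) != ncol(table@stats) || anyNA(observed))
    stop("observed statistics do not match the reference table's columns")
  obs <- (observed - table@center) / table@scale
  z <- sweep(sweep(table@stats, 2, table@center), 2, table@scale, "/")
  d <- sqrt(rowSums(sweep(z, 2, obs)^2))
  keep <- ceiling(tolerance * n)
  ord <- .seeded_order(d, seed)
  idx <- ord[seq_len(keep)]
  dmax <- max(d[idx])
  wts <- if (dmax > 0) 1 - (d[idx] / dmax)^2 else rep(1, keep)
  wts[wts <= 0] <- min(wts[wts > 0], 1e-6)   # boundary row keeps tiny weight
  list(index = idx, dist = d[idx],
       delta = sweep(z[idx, , drop = FALSE], 2, obs),
       weights = wts,
       scenario = table@scenario[idx],
       params = table@params[idx, , drop = FALSE])
}

## order() with a seeded random tie-break, leaving the caller's RNG
## stream untouched.
.seeded_order <- function(d, seed) {
  rs <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, .GlobalEnv))
  set.seed(seed)
  jit <- sample.int(length(d))
  order(d, jit)
}

#' Scenario posterior probabilities by local logistic regression
#'
#' Multinomial logistic regression of scenario id on the standardized
#' (simulated - observed) statistic deltas over the accepted rows,
#' Epanechnikov-weighted by distance and evaluated at delta = 0. Falls back
#' to weighted acceptance frequencies if the regression fails.
#'
#' @param accepted Result of [rejectClosest()].
#' @return Named numeric vector of scenario probabilities (sums to 1).
#' @export
scenarioPosterior <- function(accepted) {
  scen <- accepted$scenario
  ids <- sort(unique(scen))
  if (length(ids) == 1L) {
    warning("only scenario ", ids, " among accepted rows")
    return(setNames(1, ids))
  }
  freq <- vapply(ids, function(s)
    sum(accepted$weights[scen == s]), numeric(1))
  freq <- freq / sum(freq)
  names(freq) <- ids
  df <- as.data.frame(accepted$delta)
  df$scen <- factor(scen, levels = ids)
  probs <- tryCatch({
    fit <- nnet::multinom(scen ~ ., data = df, weights = accepted$weights,
                          trace = FALSE, maxit = 200)
    zero <- as.data.frame(matrix(0, 1, ncol(accepted$delta),
                                 dimnames = list(NULL, colnames(df)[seq_len(ncol(accepted$delta))])))
    pr <- predict(fit, newdata = zero, type = "probs")
    if (length(ids) == 2L) pr <- c(1 - pr, pr)
    setNames(as.numeric(pr), ids)
  }, error = function(e) freq)
  if (anyNA(probs) || any(!is.finite(probs))) probs <- freq
  probs / sum(probs)
}

#' Regression-adjusted parameter posterior
#'
#' Beaumont-style local-linear adjustment: each parameter (sizes on the log
#' scale, times on the natural scale) is regressed on the statistic deltas
#' with Epanechnikov weights; adjusted draws are the fit at delta = 0 plus
#' residuals. Point estimate is the weighted median; the credibility
#' interval the weighted 0.025/0.975 quantiles, truncated to the prior
#' support.
#'
#' @param accepted Result of [rejectClosest()], usually restricted to the
#'   winning scenario's rows.
#' @param scenario The [DemographicScenario-class] supplying prior support
#'   (used for truncation and for dropping fixed parameters).
#' @return List of class `PosteriorResult`: per free parameter `draws`,
#'   `median`, `ci` (2.5/97.5%), plus `nAccepted`.
#' @export
parameterPosterior <- function(accepted, scenario) {
  if (length(accepted$index) < 50)
    stop("need at least 50 accepted rows for the regression adjustment")
  support <- list(Nanc = scenario@ancestral, Ncur = scenario@current,
                  tbot = scenario@tBottleneck)
  free <- names(support)[vapply(support, function(b) b[1] < b[2], logical(1))]
  X <- accepted$delta
  w <- accepted$weights
  out <- list(nAccepted = length(accepted$index), params = list())
  for (pn in free) {
    y <- accepted$params[, pn]
    logscale <- pn %in% c("Nanc", "Ncur")
    yt <- if (logscale) log(y) else y
    fit <- tryCatch(lm(yt ~ X, weights = w), error = function(e) NULL)
    adj <- if (!is.null(fit) && !anyNA(coef(fit)[1])) {
      cf <- coef(fit); cf[is.na(cf)] <- 0   # rank-deficient columns dropped
      as.numeric(cf[1]) + (yt - (cf[1] + as.numeric(X %*% cf[-1])))
    } else yt
    if (logscale) adj <- exp(adj)
    adj <- pmin(pmax(adj, support[[pn]][1]), support[[pn]][2])
    out$params[[pn]] <- list(
      draws = adj,
      median = weightedQuantile(adj, w, 0.5),
      ci = c(lower = weightedQuantile(adj, w, 0.025),
             upper = weightedQuantile(adj, w, 0.975)))
  }
  class(out) <- "PosteriorResult"
  out
}

#' @export
print.PosteriorResult <- function(x, ...) {
  cat(sprintf("PosteriorResult (%d accepted rows)\n", x$nAccepted))
  if (!is.null(x$scenarioProbs)) {
    cat("  scenario posterior probabilities:\n")
    pr <- sort(x$scenarioProbs, decreasing = TRUE)
    for (i in seq_along(pr))
      cat(sprintf("    scenario %-3s %.4f\n", names(pr)[i], pr[i]))
  }
  for (pn in names(x$params)) {
    p <- x$params[[pn]]
    cat(sprintf("  %-5s median %.4g  (95%% CI %.4g - %.4g)\n", pn,
                p$median, p$ci["lower"], p$ci["upper"]))
  }
  invisible(x)
}

#' Weighted quantile (cumulative-weight interpolation)
#'
#' @param x Numeric values.
#' @param w Non-negative weights.
#' @param probs Quantile levels.
#' @return Weighted quantiles of `x`.
#' @export
weightedQuantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    stats::approx(cw, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

#' Fit the full ABC analysis to an observed dataset
#'
#' Rejection at the given tolerance, logistic-regression scenario
#' posterior, then regression-adjusted parameter posterior for the winning
#' (or a requested) scenario using that scenario's accepted rows.
#'
#' @param observed A [TemporalDataset] or a summary-statistic vector.
#' @param table A [ReferenceTable-class].
#' @param scenarios The scenario list used to build the table.
#' @param tolerance Acceptance fraction (default 0.01).
#' @param whichScenario Optional scenario id to force for parameter
#'   estimation (default: highest posterior probability).
#' @param seed Seed for the rejection tie-break.
#' @return `PosteriorResult` with `scenarioProbs`, `chosen`, `params`.
#' @export
abcFit <- function(observed, table, scenarios, tolerance = 0.01,
                   whichScenario = NULL, seed = 1) {
  obs <- if (is(observed, "TemporalDataset")) summarizeDataset(observed)
         else observed
  acc <- rejectClosest(obs, table, tolerance = tolerance, seed = seed)
  probs <- if (length(unique(table@scenario)) > 1L)
    scenarioPosterior(acc)
  else setNames(1, unique(table@scenario))
  chosen <- if (is.null(whichScenario))
    as.integer(names(probs)[which.max(probs)])
  else as.integer(whichScenario)
  ## parameter posterior from the chosen scenario's accepted rows
  sub <- acc$scenario == chosen
  if (sum(sub) < 50) {
    ## re-reject within the chosen scenario only
    keep <- table@scenario == chosen
    subtab <- new("ReferenceTable", scenario = table@scenario[keep],
                  params = table@params[keep, , drop = FALSE],
                  stats = table@stats[keep, , drop = FALSE],
                  center = table@center, scale = table@scale,
                  seed = table@seed)
    accP <- rejectClosest(obs, subtab, tolerance = tolerance, seed = seed)
  } else {
    accP <- lapply(acc, function(z)
      if (is.matrix(z)) z[sub, , drop = FALSE] else z[sub])
    accP$index <- acc$index[sub]
  }
  scen_obj <- NULL
  for (sc in scenarios) if (sc@id == chosen) scen_obj <- sc
  if (is.null(scen_obj)) stop("chosen scenario ", chosen, " not in scenario list")
  res <- parameterPosterior(accP, scen_obj)
  res$scenarioProbs <- probs
  res$chosen <- chosen
  res
}
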