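## Temporal-method effective population size: Fc moment estimator and
## pseudo-maximum-likelihood Ne, closed or jointly with migration from a
## fixed (infinite) source pool.

#' Generations between two sampling years
#'
#' @param year0,yearT Earlier and later calendar years (`yearT > year0`).
#' @param T Generation length in years (the study's sensitivity values are
#'   1, 1.5 and 2, but any positive value is accepted).
#' @return `round((yearT - year0) / T)` generations.
#' @examples
#' generationsBetween(1910, 2005, 1)   # 95
#' generationsBetween(1910, 2005, 2)   # 48
#' @export
generationsBetween <- function(year0, yearT, T = 1) {
  if (yearT <= year0) stop("yearT must be after year0")
  if (T <= 0) stop("generation length T must be positive")
  round((yearT - year0) / T)
}

#' Pair two samples for temporal estimation
#'
#' @param sample0,sampleT Earlier and later [GenotypeSample] objects with a
#'   shared locus list.
#' @param T Generation length in years.
#' @param tGen Generations between the samples; default
#'   `generationsBetween(year(sample0), year(sampleT), T)`.
#' @return List of class `TemporalPair`.
#' @export
temporalPair <- function(sample0, sampleT, T = 1, tGen = NULL) {
  if (!identical(colnames(sample0@genotypes), colnames(sampleT@genotypes)))
    stop("samples have mismatched locus lists")
  if (is.null(tGen))
    tGen <- generationsBetween(sample0@year, sampleT@year, T)
  if (tGen < 1) stop("tGen must be >= 1")
  out <- list(sample0 = sample0, sampleT = sampleT, tGen = tGen, T = T,
              S0 = nInd(sample0), St = nInd(sampleT))
  class(out) <- "TemporalPair"
  out
}

## Per-locus allele frequencies at both time points over the union of
## alleles seen at either (alleles absent at both are dropped by
## construction). Returns NULL for loci without data at either point.
.pair_freqs <- function(pair, locus) {
  f0 <- alleleFreqs(pair$sample0, locus)
  ft <- alleleFreqs(pair$sampleT, locus)
  if (f0$N < 2 || ft$N < 2) return(NULL)
  alleles <- sort(unique(c(f0$allele, ft$allele)))
  x <- setNames(numeric(length(alleles)), alleles)
  y <- x
  x[as.character(f0$allele)] <- f0$freq
  y[as.character(ft$allele)] <- ft$freq
  c0 <- setNames(integer(length(alleles)), alleles)
  ct <- c0
  c0[as.character(f0$allele)] <- f0$count
  ct[as.character(ft$allele)] <- ft$count
  list(alleles = alleles, x = x, y = y, count0 = c0, countT = ct,
       N0 = f0$N, Nt = ft$N)
}

#' Temporal variance statistic Fc
#'
#' Per locus, with frequencies `x` (earlier) and `y` (later) over the `K`
#' alleles present at either time point:
#' \deqn{F_c = \frac{1}{K} \sum_i \frac{(x_i - y_i)^2}{(x_i + y_i)/2 - x_i y_i}.}
#' The multilocus value weights loci by their number of independent alleles
#' `K - 1`.
#'
#' @param pair A `TemporalPair`.
#' @return List: `perLocus` (locus, K, Fc), `Fc` (weighted mean), `df`
#'   (`sum(K - 1)`), and the harmonic-mean gene-copy sample sizes.
#' @export
fcStatistic <- function(pair) {
  loci <- colnames(pair$sample0@genotypes)
  rows <- list(); N0s <- NtS <- numeric(0)
  for (loc in loci) {
    pf <- .pair_freqs(pair, loc)
    if (is.null(pf) || length(pf$alleles) < 2L) next
    z <- (pf$x + pf$y) / 2 - pf$x * pf$y
    ok <- z > 0
    fc <- mean((pf$x[ok] - pf$y[ok])^2 / z[ok])
    rows[[loc]] <- data.frame(locus = loc, K = sum(ok), Fc = fc)
    N0s <- c(N0s, pf$N0); NtS <- c(NtS, pf$Nt)
  }
  if (!length(rows)) stop("no shared polymorphic locus between the samples")
  perLocus <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  wts <- perLocus$K - 1
  list(perLocus = perLocus,
       Fc = sum(wts * perLocus$Fc) / sum(wts),
       df = sum(wts),
       S0 = 1 / mean(2 / N0s) , St = 1 / mean(2 / NtS))
}

#' Moment (temporal F-statistic) estimator of Ne
#'
#' Plan II sampling (sampled individuals are not removed from the
#' population): \deqn{\hat N_e = \frac{t}{2\,[F_c - 1/(2S_0) - 1/(2S_t)]}}
#' with `S0`, `St` the harmonic-mean diploid sample sizes across loci.
#' A non-positive denominator (drift signal below sampling noise) yields
#' `Ne = Inf`. The 95% CI comes from chi-square bounds on `Fc` with
#' `sum(K - 1)` degrees of freedom.
#'
#' @param pair A `TemporalPair`.
#' @return List of class `NeEstimate`: `method`, `Ne`, `ci`, `Fc`, `df`.
#' @export
momentNe <- function(pair) {
  if (pair$tGen < 1) stop("tGen must be >= 1")
  fc <- fcStatistic(pair)
  ne_from_fc <- function(F) {
    den <- 2 * (F - 1 / (2 * fc$S0) - 1 / (2 * fc$St))
    if (den <= 0) Inf else pair$tGen / den
  }
  Flo <- fc$df * fc$Fc / qchisq(0.975, fc$df)
  Fhi <- fc$df * fc$Fc / qchisq(0.025, fc$df)
  out <- list(method = "moment", Ne = ne_from_fc(fc$Fc),
              ci = c(lower = ne_from_fc(Fhi), upper = ne_from_fc(Flo)),
              Fc = fc$Fc, df = fc$df, S0 = fc$S0, St = fc$St,
              tGen = pair$tGen)
  class(out) <- "NeEstimate"
  out
}

#' @export
print.NeEstimate <- function(x, ...) {
  cat(sprintf("NeEstimate (%s): Ne = %s", x$method,
              if (is.infinite(x$Ne)) "Inf" else format(round(x$Ne, 1))))
  if (!is.null(x$ci))
    cat(sprintf("  [95%% CI %s - %s]",
                format(round(x$ci[1], 1)), format(round(x$ci[2], 1))))
  if (!is.null(x[["m"]])) {
    cat(sprintf("\n  m = %.4g", x[["m"]]))
    if (!is.null(x[["mCi"]]))
      cat(sprintf("  [95%% CI %.4g - %.4g]", x[["mCi"]][1], x[["mCi"]][2]))
  }
  cat("\n")
  invisible(x)
}

#' Fixed source-pool allele frequencies
#'
#' Pools gene-copy counts across samples (e.g. the two non-focal
#' populations) into per-locus frequencies treated as an infinitely large,
#' constant migrant source.
#'
#' @param others Non-empty list of [GenotypeSample] objects sharing loci.
#' @return Named list of `AlleleFreqTable`s, one per locus.
#' @export
buildSource <- function(others) {
  if (length(others) < 1L) stop("need at least one source sample")
  pooled <- if (length(others) == 1L) others[[1]]
            else poolSamples(others, "source",
                             epoch = others[[1]]@epoch)
  loci <- colnames(pooled@genotypes)
  setNames(lapply(loci, function(l) alleleFreqs(pooled, l)), loci)
}

## Collapse alleles with < minCount copies in the earlier sample into one
## pooled class (transition modelling is unstable for rare alleles).
.collapse_alleles <- function(pf, minCount = 3) {
  rare <- pf$count0 < minCount
  if (sum(!rare) == 0L) return(NULL)         # nothing stable to model
  if (any(rare)) {
    classes <- c(as.list(which(!rare)), list(which(rare)))
  } else classes <- as.list(seq_along(pf$alleles))
  lapply(classes, function(ix) list(
    a0 = sum(pf$count0[ix]), at = sum(pf$countT[ix]),
    members = pf$alleles[ix]))
}

#' Pseudo-maximum-likelihood temporal Ne (closed or joint with migration)
#'
#' Grid likelihood for the temporal method. Per locus, alleles with fewer
#' than 3 copies in the earlier sample are pooled into one class; each
#' class is treated as biallelic (class vs rest). For each candidate
#' `(Ne, m)` the class frequency evolves on a Wright-Fisher grid (exact
#' `2Ne + 1` count states when `2Ne <= 400`, else 401 equispaced states
#' with a normal drift kernel): each generation applies the deterministic
#' migration pull `p' = (1 - m) p + m p_source` toward the fixed source
#' frequencies, then binomial drift with `2Ne` draws. The earlier sample
#' enters through its binomial sampling posterior; the later sample's
#' binomial likelihood is integrated over the propagated distribution.
#' Class log-likelihoods are summed over loci; the grid maximum is the
#' estimate and the 95% CI is the profile-likelihood set within 1.92
#' log-units of it.
#'
#' @param pair A `TemporalPair`.
#' @param source Named per-locus `AlleleFreqTable` list from
#'   [buildSource()], required iff `mGrid` is supplied (joint estimation).
#' @param neGrid Candidate Ne values (default log-spaced 10 to 5000).
#' @param mGrid Candidate migration rates in `[0, 1]`, or `NULL` for the
#'   closed model (`m = 0`).
#' @return `NeEstimate` with `Ne`, `ci`, `m`/`mCi` (joint model),
#'   `logLik` (the Ne x m grid), and an `edge` flag when the maximum sits
#'   on the grid boundary.
#' @export
pmlNe <- function(pair, source = NULL,
                  neGrid = round(exp(seq(log(10), log(5000), length.out = 24))),
                  mGrid = NULL) {
  joint <- !is.null(mGrid)
  if (joint && is.null(source))
    stop("joint estimation (mGrid given) requires a source pool")
  if (any(neGrid < 2) || any(neGrid > 1e5))
    stop("neGrid values must lie in [2, 1e5]")
  if (joint && (any(mGrid < 0) || any(mGrid > 1)))
    stop("mGrid values must lie in [0, 1]")
  if (!joint) mGrid <- 0
  loci <- colnames(pair$sample0@genotypes)
  chains <- list()
  for (loc in loci) {
    pf <- .pair_freqs(pair, loc)
    if (is.null(pf) || length(pf$alleles) < 2L) next
    cls <- .collapse_alleles(pf)
    if (is.null(cls)) next
    for (cl in cls) {
      ps <- 0
      if (joint) {
        sf <- source[[loc]]
        if (is.null(sf) || sf$N == 0)
          stop("source pool has no data at locus ", loc)
        ps <- sum(sf$freq[sf$allele %in% cl$members])
      }
      chains[[length(chains) + 1L]] <-
        list(a0 = cl$a0, n0 = pf$N0, at = cl$at, nt = pf$Nt, ps = ps)
    }
  }
  if (!length(chains)) stop("no usable locus for the pseudo-likelihood")
  ll <- matrix(NA_real_, length(neGrid), length(mGrid),
               dimnames = list(Ne = neGrid, m = mGrid))
  a0v <- vapply(chains, `[[`, numeric(1), "a0")
  n0v <- vapply(chains, `[[`, numeric(1), "n0")
  atv <- vapply(chains, `[[`, numeric(1), "at")
  ntv <- vapply(chains, `[[`, numeric(1), "nt")
  psv <- vapply(chains, `[[`, numeric(1), "ps")
  for (i in seq_along(neGrid)) {
    twoNe <- 2 * neGrid[i]
    exact <- twoNe <= 400
    pgrid <- if (exact) (0:twoNe) / twoNe else seq(0, 1, length.out = 401)
    for (j in seq_along(mGrid))
      ll[i, j] <- pml_loglik_cpp(as.integer(a0v), as.integer(n0v),
                                 as.integer(atv), as.integer(ntv),
                                 psv, pair$tGen, twoNe, mGrid[j],
                                 pgrid, exact)
  }
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  ne_hat <- neGrid[best[1]]; m_hat <- mGrid[best[2]]
  prof_ne <- apply(ll, 1, max)
  in_ci <- prof_ne >= max(ll) - 1.92
  edge <- best[1] %in% c(1L, length(neGrid)) ||
    (joint && best[2] %in% c(1L, length(mGrid)) && m_hat > 0)
  if (edge) warning("likelihood maximum on the grid edge; widen the grid")
  out <- list(method = if (joint) "pml_joint" else "pml_closed",
              Ne = ne_hat,
              ci = c(lower = min(neGrid[in_ci]), upper = max(neGrid[in_ci])),
              logLik = ll, tGen = pair$tGen, edge = edge,
              nChains = length(chains))
  if (joint) {
    prof_m <- apply(ll, 2, max)
    m_in <- prof_m >= max(ll) - 1.92
    out$m <- m_hat
    out$mCi <- c(lower = min(mGrid[m_in]), upper = max(mGrid[m_in]))
  }
  class(out) <- "NeEstimate"
  out
}

#' Temporal-Ne report across sites and generation lengths
#'
#' Runs the moment and pseudo-likelihood estimators (closed, and joint
#' with migration when `joint = TRUE`) for each site present in both
#' epochs, at each assumed generation length. Joint runs build the source
#' pool from the remaining sites' samples of the earlier epoch.
#'
#' @param dataset A [TemporalDataset].
#' @param T Generation lengths in years to scan (default `c(1, 1.5, 2)`).
#' @param joint Also estimate `(Ne, m)` jointly.
#' @param neGrid,mGrid Grids passed to [pmlNe()].
#' @param path Optional TSV output path.
#' @return data.frame: site, T, tGen, method, Ne, CI bounds, m and its CI.
#' @export
temporalNeReport <- function(dataset, T = c(1, 1.5, 2), joint = TRUE,
                             neGrid = round(exp(seq(log(10), log(5000),
                                                    length.out = 24))),
                             mGrid = c(0, 0.005, 0.01, 0.025, 0.05, 0.075,
                                       0.1, 0.15, 0.25),
                             path = NULL) {
  ep <- vapply(dataset@samples, epochOf, character(1))
  sites <- vapply(dataset@samples, siteOf, character(1))
  both <- intersect(unique(sites[ep == "historical"]),
                    unique(sites[ep == "contemporary"]))
  rows <- list()
  for (st in both) {
    hsel <- dataset@samples[ep == "historical" & sites == st]
    hist <- hsel[[which.max(vapply(hsel, yearOf, 1))]]  # latest historical
    csel <- dataset@samples[ep == "contemporary" & sites == st]
    cont <- csel[[which.min(vapply(csel, yearOf, 1))]]  # earliest contemporary
    for (Tv in T) {
      pair <- temporalPair(hist, cont, T = Tv)
      addrow <- function(est) {
        rows[[length(rows) + 1L]] <<- data.frame(
          site = st, T = Tv, tGen = pair$tGen, method = est$method,
          Ne = est$Ne, Ne_lo = est$ci["lower"], Ne_hi = est$ci["upper"],
          m = if (is.null(est[["m"]])) NA_real_ else est[["m"]],
          m_lo = if (is.null(est[["mCi"]])) NA_real_ else est[["mCi"]]["lower"],
          m_hi = if (is.null(est[["mCi"]])) NA_real_ else est[["mCi"]]["upper"])
      }
      addrow(momentNe(pair))
      addrow(suppressWarnings(pmlNe(pair, neGrid = neGrid)))
      if (joint) {
        others <- dataset@samples[ep == "historical" & sites != st]
        if (length(others)) {
          src <- buildSource(others)
          addrow(suppressWarnings(
            pmlNe(pair, source = src, neGrid = neGrid, mGrid = mGrid)))
        }
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
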