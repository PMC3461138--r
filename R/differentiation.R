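## Pairwise population differentiation: Weir-Cockerham theta variance
## components, the heterozygosity-based G_ST family, permutation
## significance, and the historical-vs-contemporary epoch comparison.

## Per-locus Weir & Cockerham (1984) variance components for two samples.
## Returns per-allele components a (among populations), b (among
## individuals within populations), c (within individuals), or NULL when
## the locus is monomorphic across both samples or lacks data.
.wc_components_locus <- function(s1, s2, locus) {
  r <- 2
  g1 <- s1@genotypes[, locus, , drop = FALSE]
  g2 <- s2@genotypes[, locus, , drop = FALSE]
  a1 <- cbind(g1[, 1, 1], g1[, 1, 2]); a1 <- a1[!is.na(a1[, 1]), , drop = FALSE]
  a2 <- cbind(g2[, 1, 1], g2[, 1, 2]); a2 <- a2[!is.na(a2[, 1]), , drop = FALSE]
  n1 <- nrow(a1); n2 <- nrow(a2)
  if (n1 < 2 || n2 < 2) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(NULL)
  n <- c(n1, n2)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  comp <- vapply(alleles, function(al) {
    p <- c((sum(a1 == al)) / (2 * n1), (sum(a2 == al)) / (2 * n2))
    h <- c(sum((a1[, 1] == al) != (a1[, 2] == al)) / n1,
           sum((a2[, 1] == al) != (a2[, 2] == al)) / n2)
    pbar <- sum(n * p) / (r * nbar)
    s2v <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc * (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2v -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a = a, b = b, c = cc)
  }, numeric(3))
  list(a = comp[1, ], b = comp[2, ], c = comp[3, ], alleles = alleles)
}

#' Weir-Cockerham theta (F_ST) between two samples
#'
#' Variance-components estimator of F_ST for two population samples:
#' per-allele components are computed from genotype counts (observed
#' heterozygosity enters the within-individual component), per-locus theta
#' is the ratio of summed components over alleles, and the multilocus value
#' is the ratio of sums over loci. Loci monomorphic across both samples are
#' excluded. Estimates can be slightly negative when true differentiation
#' is near zero; they are reported as computed.
#'
#' @param s1,s2 [GenotypeSample] objects sharing a locus list.
#' @return List of class `DifferentiationResult`: `perLocus` (data.frame
#'   locus/theta), `theta` (multilocus), `excluded` (monomorphic loci).
#' @export
thetaWc <- function(s1, s2) {
  loci <- colnames(s1@genotypes)
  if (!identical(loci, colnames(s2@genotypes)))
    stop("samples have mismatched locus lists")
  if (nInd(s1) < 2 || nInd(s2) < 2)
    stop("need at least 2 individuals per sample")
  pt <- numeric(0); names(pt) <- character(0)
  sumA <- 0; sumABC <- 0
  excluded <- character(0)
  for (loc in loci) {
    cmp <- .wc_components_locus(s1, s2, loc)
    if (is.null(cmp)) { excluded <- c(excluded, loc); next }
    A <- sum(cmp$a); ABC <- sum(cmp$a + cmp$b + cmp$c)
    pt[loc] <- if (ABC > 0) A / ABC else NA_real_
    sumA <- sumA + A; sumABC <- sumABC + ABC
  }
  theta <- if (sumABC > 0) sumA / sumABC else NA_real_
  out <- list(perLocus = data.frame(locus = names(pt), theta = unname(pt)),
              theta = theta, excluded = excluded)
  class(out) <- "DifferentiationResult"
  out
}

#' @export
print.DifferentiationResult <- function(x, ...) {
  cat("DifferentiationResult\n")
  for (nm in c("theta", "Gst", "GstStd", "Dest"))
    if (!is.null(x[[nm]]) && length(x[[nm]]) == 1L)
      cat(sprintf("  multilocus %-6s = %.5f\n", nm, x[[nm]]))
  if (!is.null(x$p))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n", x$p, x$nPerm))
  invisible(x)
}

#' Permutation p-value for multilocus theta
#'
#' Whole multilocus genotypes (individuals) are permuted between the two
#' samples preserving sample sizes; the p-value is
#' `(1 + #{theta_perm >= theta_obs}) / (1 + nPerm)`.
#'
#' @param s1,s2 [GenotypeSample] objects.
#' @param nPerm Number of permutations (default 3000).
#' @param seed Optional RNG seed.
#' @return List with `theta` (observed), `p`, `nPerm`.
#' @export
permutationPvalue <- function(s1, s2, nPerm = 3000, seed = NULL) {
  if (nPerm < 100) stop("nPerm must be >= 100")
  if (nInd(s1) < 2 || nInd(s2) < 2)
    stop("need at least 2 individuals per sample")
  if (!is.null(seed)) set.seed(seed)
  obs <- thetaWc(s1, s2)$theta
  n1 <- nInd(s1); n2 <- nInd(s2)
  pool <- abind_samples(s1, s2)
  hits <- 0L
  for (r in seq_len(nPerm)) {
    idx <- sample.int(n1 + n2)
    p1 <- subset_sample(pool, idx[seq_len(n1)])
    p2 <- subset_sample(pool, idx[n1 + seq_len(n2)])
    th <- thetaWc(p1, p2)$theta
    if (!is.na(th) && th >= obs - 1e-12) hits <- hits + 1L
  }
  list(theta = obs, p = (hits + 1) / (nPerm + 1), nPerm = nPerm)
}

## internal: concatenate two samples (epoch/site irrelevant for permutation)
abind_samples <- function(s1, s2) {
  poolSamples(list(s1, s2), label = "pool",
              epoch = s1@epoch, year = s1@year)
}

## internal: row subset of a GenotypeSample
subset_sample <- function(s, idx) {
  GenotypeSample(site = s@site, year = s@year, epoch = s@epoch,
                 genotypes = s@genotypes[idx, , , drop = FALSE],
                 ids = s@ids[idx])
}

#' Heterozygosity-based differentiation measures (G_ST family)
#'
#' Nei-Chesser small-sample estimates for `k = 2` demes. With `ñ` the
#' harmonic mean sample size, `H_S` the frequency-based within-sample gene
#' diversity corrected by `2ñ/(2ñ-1)`, and
#' `H_T = 1 - sum(pbar^2) + H_S/(2ñk)` the total diversity from mean allele
#' frequencies:
#' \itemize{
#'   \item `Gst  = (H_T - H_S)/H_T`
#'   \item `GstH = Gst (k-1+H_S) / ((k-1)(1-H_S))` (Hedrick's G'_ST)
#'   \item `GstStd = k(H_T - H_S) / ((kH_T - H_S)(1-H_S))` (Meirmans-Hedrick
#'     standardized G''_ST)
#'   \item `Dest = (k/(k-1)) (H_T - H_S)/(1 - H_S)` (Jost's D)
#' }
#' Multilocus `Dest` is a ratio of locus-averaged numerator and denominator
#' terms (stable for near-fixed loci); multilocus `Gst` likewise averages
#' `(H_T - H_S)` and `H_T` before the ratio. `Dest` is clipped at 0;
#' `Gst` is reported as computed.
#'
#' @param s1,s2 [GenotypeSample] objects.
#' @return `DifferentiationResult` with per-locus and multilocus `Gst`,
#'   `GstH`, `GstStd`, `Dest`, plus `Hs`/`Ht` per locus.
#' @export
gstFamily <- function(s1, s2) {
  loci <- colnames(s1@genotypes)
  if (!identical(loci, colnames(s2@genotypes)))
    stop("samples have mismatched locus lists")
  k <- 2
  rows <- list()
  for (loc in loci) {
    f1 <- alleleFreqs(s1, loc); f2 <- alleleFreqs(s2, loc)
    if (f1$N < 2 || f2$N < 2) next
    n1 <- f1$N / 2; n2 <- f2$N / 2       # diploid equivalents with data
    ntilde <- k / (1 / n1 + 1 / n2)
    alleles <- sort(unique(c(f1$allele, f2$allele)))
    p1 <- setNames(numeric(length(alleles)), alleles)
    p2 <- p1
    p1[as.character(f1$allele)] <- f1$freq
    p2[as.character(f2$allele)] <- f2$freq
    Hs <- (2 * ntilde / (2 * ntilde - 1)) *
      (1 - mean(c(sum(p1^2), sum(p2^2))))
    pbar <- (p1 + p2) / 2
    Ht <- 1 - sum(pbar^2) + Hs / (2 * ntilde * k)
    Hs <- min(Hs, 1); Ht <- min(Ht, 1)
    rows[[loc]] <- c(Hs = Hs, Ht = Ht)
  }
  if (!length(rows)) stop("no locus with data in both samples")
  m <- do.call(rbind, rows)
  Hs <- m[, "Hs"]; Ht <- m[, "Ht"]
  num <- Ht - Hs
  gst <- ifelse(Ht > 0, num / Ht, 0)
  denom1 <- 1 - Hs
  gsth <- ifelse(denom1 > 0 & Ht > 0,
                 gst * (k - 1 + Hs) / ((k - 1) * denom1), NA_real_)
  gstd <- ifelse(denom1 > 0,
                 k * num / ((k * Ht - Hs) * denom1), NA_real_)
  dest <- ifelse(denom1 > 0, pmax(0, (k / (k - 1)) * num / denom1), NA_real_)
  perLocus <- data.frame(locus = rownames(m), Hs = Hs, Ht = Ht,
                         Gst = gst, GstH = gsth, GstStd = gstd, Dest = dest,
                         row.names = NULL)
  mGst <- mean(num) / mean(Ht)
  mHs <- mean(Hs); mHt <- mean(Ht)
  mGstH <- if (mHs < 1) mGst * (k - 1 + mHs) / ((k - 1) * (1 - mHs)) else NA_real_
  mGstStd <- if (mHs < 1) k * mean(num) / ((k * mHt - mHs) * (1 - mHs)) else NA_real_
  mDest <- if (mHs < 1) max(0, (k / (k - 1)) * mean(num) / mean(denom1)) else NA_real_
  out <- list(perLocus = perLocus, Gst = mGst, GstH = mGstH,
              GstStd = mGstStd, Dest = mDest,
              flagged = any(denom1 <= 0))
  if (out$flagged)
    warning("H_S = 1 at some locus; standardized measures undefined there")
  class(out) <- "DifferentiationResult"
  out
}

#' Compare differentiation between epochs, paired by locus
#'
#' Wilcoxon signed-rank test on per-locus differentiation values for the
#' same site pair measured in two epochs (loci as replicates), one-sided
#' for an increase in the later epoch by default.
#'
#' @param histPairs Per-locus differentiation values, historical epoch.
#' @param contPairs Per-locus values for the same loci, contemporary epoch.
#' @param alternative Default `"greater"`: contemporary exceeds historical.
#' @return `RankTestResult` (signed Z and p).
#' @export
compareDifferentiationEpochs <- function(histPairs, contPairs,
                                         alternative = "greater") {
  if (length(histPairs) != length(contPairs))
    stop("epoch vectors must be paired by locus")
  if (length(histPairs) < 5)
    warning("fewer than 5 loci; exact test still run")
  wilcoxonPairedByLocus(contPairs, histPairs, alternative = alternative)
}

#' Pairwise differentiation report for a dataset
#'
#' All within-epoch site pairs: multilocus theta with permutation p-value,
#' the G_ST family, and (for site pairs present in both epochs) the
#' locus-paired epoch comparison.
#'
#' @param dataset A [TemporalDataset]; samples are pooled per site within
#'   epoch before comparison.
#' @param nPerm Permutations for theta significance.
#' @param seed RNG seed.
#' @param path Optional TSV output path.
#' @return List with `pairs` (data.frame per pair x epoch) and
#'   `epochComparison` (data.frame per pair: Z, p for theta and Dest).
#' @export
pairwiseDifferentiation <- function(dataset, nPerm = 3000, seed = NULL,
                                    path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ep <- vapply(dataset@samples, epochOf, character(1))
  sites <- vapply(dataset@samples, siteOf, character(1))
  pooled <- list()
  for (e in unique(ep)) for (st in unique(sites[ep == e]))
    pooled[[paste(e, st)]] <-
      poolSamples(dataset@samples[ep == e & sites == st], label = st)
  rows <- list(); percomp <- list()
  for (e in unique(ep)) {
    sts <- unique(sites[ep == e])
    if (length(sts) < 2) next
    for (i in seq_len(length(sts) - 1)) for (j in seq(i + 1, length(sts))) {
      a <- pooled[[paste(e, sts[i])]]; b <- pooled[[paste(e, sts[j])]]
      th <- thetaWc(a, b)
      pp <- permutationPvalue(a, b, nPerm = nPerm)
      gf <- gstFamily(a, b)
      key <- paste(sts[i], sts[j], sep = "-")
      rows[[paste(e, key)]] <- data.frame(
        pair = key, epoch = e, theta = th$theta, p = pp$p, nPerm = nPerm,
        Gst = gf$Gst, GstStd = gf$GstStd, Dest = gf$Dest)
      percomp[[paste(e, key)]] <- list(theta = th$perLocus,
                                       dest = gf$perLocus[, c("locus", "Dest")])
    }
  }
  pairs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cmp <- list()
  if (!is.null(pairs) && all(c("historical", "contemporary") %in% pairs$epoch)) {
    for (key in unique(pairs$pair)) {
      hk <- paste("historical", key); ck <- paste("contemporary", key)
      if (is.null(percomp[[hk]]) || is.null(percomp[[ck]])) next
      mrg <- merge(percomp[[hk]]$theta, percomp[[ck]]$theta, by = "locus",
                   suffixes = c(".h", ".c"))
      wt <- compareDifferentiationEpochs(mrg$theta.h, mrg$theta.c)
      mrgd <- merge(percomp[[hk]]$dest, percomp[[ck]]$dest, by = "locus",
                    suffixes = c(".h", ".c"))
      wd <- compareDifferentiationEpochs(mrgd$Dest.h, mrgd$Dest.c)
      cmp[[key]] <- data.frame(pair = key, Z_theta = wt$statistic,
                               p_theta = wt$p, Z_Dest = wd$statistic,
                               p_Dest = wd$p)
    }
  }
  out <- list(pairs = pairs,
              epochComparison = if (length(cmp)) do.call(rbind, c(cmp, list(make.row.names = FALSE))) else NULL)
  if (!is.null(path) && !is.null(pairs))
    write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
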