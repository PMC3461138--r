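## Within-sample diversity statistics and locus-paired rank tests.

#' Unbiased expected heterozygosity
#'
#' Nei's small-sample-corrected gene diversity
#' \eqn{H_{EXP} = \frac{N}{N-1}\left(1 - \sum_a p_a^2\right)}
#' with `N` the number of non-missing gene copies. Requires `N >= 2`;
#' returns `NA` otherwise. The estimate is clipped to `[0, 1]`.
#'
#' @param freqs An `AlleleFreqTable` from [alleleFreqs()].
#' @return Unbiased expected heterozygosity in `[0, 1]`, or `NA`.
#' @examples
#' g <- array(rep(c(1L, 2L), each = 10), dim = c(10, 1, 2),
#'            dimnames = list(NULL, "L1", NULL))
#' unbiasedHet(alleleFreqs(GenotypeSample("X", 2000, "contemporary", g), "L1"))
#' @export
unbiasedHet <- function(freqs) {
  N <- freqs$N
  if (N < 2) return(NA_real_)
  h <- N / (N - 1) * (1 - sum(freqs$freq^2))
  min(max(h, 0), 1)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies (FSTAT-style rarefaction), which removes the dependence of raw
#' allele counts on unequal sample sizes:
#' \deqn{A_R(g) = \sum_a \left[1 - \binom{N - N_a}{g} / \binom{N}{g}\right].}
#'
#' @param freqs An `AlleleFreqTable`.
#' @param g Rarefaction gene-copy count, `2 <= g <= N`. Callers comparing
#'   several samples should pass the smallest `N` among them.
#' @return Expected allele count, between 1 and the observed count; equals
#'   the observed count when `g == N`.
#' @export
allelicRichness <- function(freqs, g) {
  N <- freqs$N
  if (g < 2 || g > N)
    stop(sprintf("rarefaction size g = %s outside [2, N = %d] at locus %s",
                 format(g), N, as.character(freqs$locus)))
  ## hypergeometric tail via log-binomials for numerical stability
  terms <- vapply(freqs$count, function(Na) {
    if (N - Na < g) return(1)   # allele cannot be missed
    1 - exp(lchoose(N - Na, g) - lchoose(N, g))
  }, numeric(1))
  sum(terms)
}

## Log conditional probability of a genotype configuration given allele
## counts under Hardy-Weinberg (Levene's exact distribution):
##   P = n! prod_a Na! 2^h / ((2n)! prod_{a<=b} n_ab!)
.hwe_log_prob <- function(het_count, n, allele_counts, pair_counts) {
  lgamma(n + 1) + sum(lgamma(allele_counts + 1)) + het_count * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(pair_counts + 1))
}

.pair_key <- function(a1, a2) {
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  paste(lo, hi, sep = "/")
}

#' Monte-Carlo exact test for Hardy-Weinberg proportions
#'
#' Conditional exact test at one multi-allelic locus: the observed gene
#' copies are randomly re-paired `nMc` times and the p-value is the
#' proportion of arrangements (observed one included) whose conditional
#' probability under Hardy-Weinberg is no larger than the observed one.
#'
#' @param sample A [GenotypeSample].
#' @param locus Locus name.
#' @param nMc Number of Monte-Carlo re-pairings (default 1e5).
#' @param seed Optional RNG seed.
#' @return List with `p`, observed heterozygote count `het`, and `nMc`.
#' @export
hweExactTest <- function(sample, locus, nMc = 1e5, seed = NULL) {
  if (nMc < 1) stop("nMc must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  a1 <- sample@genotypes[, locus, 1]; a2 <- sample@genotypes[, locus, 2]
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (2 * n < 4) stop("need at least 4 gene copies at locus ", locus)
  copies <- c(a1, a2)
  acounts <- table(copies)
  if (length(acounts) < 2L) {
    warning("locus ", locus, " is monomorphic; p = 1")
    return(list(p = 1, het = 0L, nMc = nMc))
  }
  obs_pairs <- table(.pair_key(a1, a2))
  obs_het <- sum(a1 != a2)
  lp_obs <- .hwe_log_prob(obs_het, n, as.integer(acounts), as.integer(obs_pairs))
  hits <- 0L
  eps <- 1e-9
  for (r in seq_len(nMc)) {
    perm <- sample.int(2 * n)
    b1 <- copies[perm[seq_len(n)]]; b2 <- copies[perm[n + seq_len(n)]]
    lp <- .hwe_log_prob(sum(b1 != b2), n, as.integer(acounts),
                        as.integer(table(.pair_key(b1, b2))))
    if (lp <= lp_obs + eps) hits <- hits + 1L
  }
  list(p = (hits + 1) / (nMc + 1), het = obs_het, nMc = nMc)
}

## Exact null distribution of the signed-rank statistic by enumeration of
## all 2^n sign assignments over the (possibly tied) ranks.
.signrank_enum_p <- function(ranks, Wobs, alternative) {
  n <- length(ranks)
  grid <- expand.grid(rep(list(c(0, 1)), n))
  W <- as.matrix(grid) %*% ranks
  switch(alternative,
    greater = mean(W >= Wobs - 1e-9),
    less    = mean(W <= Wobs + 1e-9),
    two.sided = {
      mu <- sum(ranks) / 2
      mean(abs(W - mu) >= abs(Wobs - mu) - 1e-9)
    })
}

#' Wilcoxon signed-rank test paired by locus
#'
#' Tests whether paired per-locus values (e.g. `H_EXP` at two time points,
#' loci as replicates) share a median. Zero differences are dropped; the
#' exact null distribution is used for `n <= 25` (enumeration over sign
#' assignments when ties are present), and a normal approximation with tie
#' correction above. The signed `Z` is reported so direction is explicit.
#'
#' @param a,b Equal-length numeric vectors paired by locus.
#' @param alternative `"two.sided"`, `"greater"` (a > b) or `"less"`.
#' @return List of class `RankTestResult`: `statistic` (signed Z), `W`
#'   (signed-rank sum of positive differences), `p`, `nBlocks`, `method`,
#'   `alternative`.
#' @examples
#' wilcoxonPairedByLocus(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6),
#'                       alternative = "greater")$p
#' @export
wilcoxonPairedByLocus <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) == length(b))
  if (length(a) < 5) warning("fewer than 5 locus pairs; test has little power")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  mkres <- function(stat, W, p, method) {
    out <- list(statistic = stat, W = W, p = min(max(p, 0), 1),
                nBlocks = length(a), nUsed = n, method = method,
                alternative = alternative)
    class(out) <- "RankTestResult"
    out
  }
  if (n == 0) return(mkres(0, 0, 1, "degenerate (all differences zero)"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  has_ties <- any(tie_tab > 1)
  if (n <= 25 && !has_ties) {
    p <- switch(alternative,
      greater   = 1 - psignrank(W - 1, n),
      less      = psignrank(W, n),
      two.sided = {
        pl <- psignrank(min(W, n * (n + 1) / 2 - W), n)
        min(1, 2 * pl)
      })
    return(mkres(z, W, p, "exact signed-rank"))
  }
  if (n <= 16) {
    p <- .signrank_enum_p(r, W, alternative)
    return(mkres(z, W, p, "exact signed-rank (tie enumeration)"))
  }
  p <- switch(alternative,
    greater   = pnorm(z, lower.tail = FALSE),
    less      = pnorm(z),
    two.sided = 2 * pnorm(-abs(z)))
  mkres(z, W, p, "normal approximation with tie correction")
}

#' @export
print.RankTestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, %d blocks)\n",
              x$method, x$statistic, x$p, x$alternative, x$nBlocks))
  invisible(x)
}

#' Rank test for k groups blocked by locus
#'
#' Friedman-style test for comparing `k >= 3` sampling periods with loci as
#' blocks: values are mid-ranked within each locus across groups and
#' \deqn{H = \frac{12}{bk(k+1)} \sum_j R_j^2 - 3b(k+1)}
#' (with the usual tie variance correction) is referred to a chi-square
#' distribution on `k - 1` df.
#'
#' @param values Numeric matrix, loci (blocks) x groups; complete blocks.
#' @return `RankTestResult` with `statistic` (H), `p`, `nBlocks`.
#' @export
blockedRankTest <- function(values) {
  values <- as.matrix(values)
  b <- nrow(values); k <- ncol(values)
  if (k < 3) stop("need k >= 3 groups; use wilcoxonPairedByLocus for pairs")
  if (anyNA(values)) stop("incomplete blocks (NA values)")
  R <- t(apply(values, 1, rank))
  H <- 12 / (b * k * (k + 1)) * sum(colSums(R)^2) - 3 * b * (k + 1)
  ## tie correction
  corr <- 1 - sum(apply(values, 1, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  })) / (b * k * (k^2 - 1))
  if (corr > 0) H <- H / corr else H <- 0
  p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  out <- list(statistic = H, W = NA_real_, p = p, nBlocks = b,
              nUsed = b, method = "rank test blocked by locus (Friedman-type)",
              alternative = "two.sided")
  class(out) <- "RankTestResult"
  out
}

#' Unblocked Kruskal-Wallis comparison of per-locus values
#'
#' Companion to [blockedRankTest()]: ignores the locus blocking and ranks
#' all values jointly (wrapper around [stats::kruskal.test()]).
#'
#' @param values Numeric matrix, loci x groups.
#' @return `RankTestResult` with the Kruskal-Wallis H and p.
#' @export
kruskalByGroup <- function(values) {
  values <- as.matrix(values)
  kt <- kruskal.test(as.vector(values),
                     factor(rep(seq_len(ncol(values)), each = nrow(values))))
  out <- list(statistic = unname(kt$statistic), W = NA_real_,
              p = kt$p.value, nBlocks = nrow(values), nUsed = nrow(values),
              method = "Kruskal-Wallis (unblocked)", alternative = "two.sided")
  class(out) <- "RankTestResult"
  out
}

#' Per-sample diversity table
#'
#' Per-locus unbiased expected heterozygosity and rarefied allelic richness
#' for each sample, with multilocus means and standard errors (SE over
#' loci). The rarefaction size defaults to the smallest per-locus gene-copy
#' count across the samples being compared, so richness is comparable
#' across unequal sample sizes.
#'
#' @param dataset A [TemporalDataset].
#' @param g Rarefaction gene-copy count; `NULL` (default) uses the smallest
#'   non-missing per-locus `N` over all samples and loci.
#' @param path Optional TSV output path for the summary table.
#' @return List with `perLocus` (data.frame site/year/locus/N/A/Hexp/Ar)
#'   and `summary` (per-sample multilocus means with SEs).
#' @export
diversityTable <- function(dataset, g = NULL, path = NULL) {
  ft <- list()
  for (si in seq_along(dataset@samples)) for (loc in dataset@loci)
    ft[[paste(si, loc)]] <- alleleFreqs(dataset@samples[[si]], loc)
  Ns <- vapply(ft, function(f) f$N, integer(1))
  if (is.null(g)) g <- max(2L, min(Ns[Ns > 0]))
  rows <- list()
  for (si in seq_along(dataset@samples)) {
    s <- dataset@samples[[si]]
    for (loc in dataset@loci) {
      f <- ft[[paste(si, loc)]]
      gl <- min(g, f$N)
      rows[[length(rows) + 1L]] <- data.frame(
        site = s@site, year = s@year, epoch = s@epoch, locus = loc,
        n = f$n, N = f$N,
        A = length(f$allele),
        Ar = if (f$N >= 2 && gl >= 2) allelicRichness(f, gl) else NA_real_,
        Hexp = unbiasedHet(f))
    }
  }
  perLocus <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       se = sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  key <- paste(perLocus$site, perLocus$year)
  summ <- do.call(rbind, lapply(unique(key), function(k) {
    sub <- perLocus[key == k, ]
    data.frame(site = sub$site[1], year = sub$year[1], epoch = sub$epoch[1],
               n = max(sub$n), g = g,
               Ar = agg(sub$Ar)[1], Ar_se = agg(sub$Ar)[2],
               Hexp = agg(sub$Hexp)[1], Hexp_se = agg(sub$Hexp)[2])
  }))
  if (!is.null(path))
    write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(perLocus = perLocus, summary = summ)
}
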