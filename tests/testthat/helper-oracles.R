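## Shared fixtures and independent oracle implementations used across the
## suite. Oracles are deliberately written as direct transcriptions
## (enumeration, matrix powers, explicit component formulas) independent of
## the package's code paths.

## random GenotypeSample with alleles 1..nAlleles
rand_sample <- function(n, nloci = 3, nAlleles = 4, site = "X", year = 2000,
                        epoch = "contemporary", missRate = 0) {
  loci <- sprintf("L%d", seq_len(nloci))
  g <- array(sample.int(nAlleles, n * nloci * 2, replace = TRUE),
             dim = c(n, nloci, 2), dimnames = list(NULL, loci, NULL))
  if (missRate > 0) {
    drop <- which(matrix(runif(n * nloci) < missRate, n, nloci), arr.ind = TRUE)
    for (k in seq_len(nrow(drop))) g[drop[k, 1], drop[k, 2], ] <- NA_integer_
  }
  GenotypeSample(site = site, year = year, epoch = epoch, genotypes = g)
}

## sample with given per-individual genotype list: list of c(a1, a2) per locus
sample_from_genotypes <- function(genolist, site = "X", year = 2000,
                                  epoch = "contemporary") {
  n <- length(genolist)
  nloci <- length(genolist[[1]]) / 2
  g <- array(NA_integer_, dim = c(n, nloci, 2),
             dimnames = list(NULL, sprintf("L%d", seq_len(nloci)), NULL))
  for (i in seq_len(n)) {
    m <- matrix(genolist[[i]], nrow = nloci, byrow = TRUE)
    g[i, , 1] <- m[, 1]; g[i, , 2] <- m[, 2]
  }
  GenotypeSample(site = site, year = year, epoch = epoch, genotypes = g)
}

## brute-force rarefied allele count: average distinct alleles over ALL
## g-subsets of the N gene copies
oracle_richness <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

## exact one/two-sided signed-rank p by enumeration over all sign vectors
oracle_wilcoxon <- function(a, b, alternative) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  Wobs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- signs %*% r
  switch(alternative,
         greater = mean(W >= Wobs - 1e-9),
         less = mean(W <= Wobs + 1e-9),
         two.sided = {
           mu <- sum(r) / 2
           mean(abs(W - mu) >= abs(Wobs - mu) - 1e-9)
         })
}

## independent Weir & Cockerham (1984) theta: explicit per-population
## loops over genotype tables, multilocus ratio of summed components
oracle_theta <- function(s1, s2) {
  loci <- colnames(genotypes(s1))
  TA <- TB <- 0
  for (loc in loci) {
    pops <- list(genotypes(s1)[, loc, , drop = FALSE],
                 genotypes(s2)[, loc, , drop = FALSE])
    mats <- lapply(pops, function(g) {
      m <- cbind(g[, 1, 1], g[, 1, 2])
      m[!is.na(m[, 1]), , drop = FALSE]
    })
    ns <- vapply(mats, nrow, integer(1))
    if (any(ns < 2)) next
    alleles <- sort(unique(unlist(mats)))
    if (length(alleles) < 2) next
    r <- 2
    nbar <- mean(ns)
    CV <- (ns[1]^2 + ns[2]^2) / (r * nbar)
    nc <- (r * nbar - CV) / (r - 1)
    for (al in alleles) {
      p <- h <- numeric(r)
      for (k in 1:r) {
        m <- mats[[k]]
        p[k] <- sum(m == al) / (2 * ns[k])
        h[k] <- sum(xor(m[, 1] == al, m[, 2] == al)) / ns[k]
      }
      pbar <- sum(ns * p) / (r * nbar)
      ssq <- sum(ns * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ns * h) / (r * nbar)
      a <- (nbar / nc) *
        (ssq - (pbar * (1 - pbar) - ((r - 1) / r) * ssq - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * ssq -
           ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      TA <- TA + a
      TB <- TB + a + b + cc
    }
  }
  TA / TB
}

## exact Wright-Fisher transition-matrix log-likelihood for one biallelic
## chain (matrix powers; feasible for 2Ne <= 40)
oracle_wf_loglik <- function(a0, n0, at, nt, tgen, Ne, m = 0, ps = 0) {
  twoNe <- 2 * Ne
  states <- 0:twoNe
  p <- states / twoNe
  v <- dbinom(a0, n0, p)
  v <- v / sum(v)
  TM <- outer(seq_along(p), seq_along(p), function(i, j) {
    pp <- (1 - m) * p[i] + m * ps
    dbinom(states[j], twoNe, pp)
  })
  for (g in seq_len(tgen)) v <- as.numeric(v %*% TM)
  log(sum(v * dbinom(at, nt, p)))
}

## AlleleFreqTable built directly from a frequency vector (fixed source)
freq_table <- function(freqs, locus = "L1", Nbig = 1e6) {
  out <- list(locus = locus, allele = seq_along(freqs),
              count = round(freqs * Nbig), freq = freqs,
              N = as.integer(Nbig), n = as.integer(Nbig / 2),
              allMissing = FALSE)
  class(out) <- "AlleleFreqTable"
  out
}

## source pool list for all loci of a wfForwardSim truth record
source_from_truth <- function(truth) {
  src <- lapply(seq_len(truth$nLoci), function(l)
    freq_table(truth$sourceFreqs[[l]], sprintf("L%d", l)))
  names(src) <- sprintf("L%d", seq_len(truth$nLoci))
  src
}
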