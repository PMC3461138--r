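## Synthetic-data generators with recorded truth: forward Wright-Fisher
## temporal fixtures for the Ne estimators, and a full study-shaped
## bottleneck dataset (3 sites, two epochs, 9 loci).

#' Forward Wright-Fisher temporal fixture
#'
#' Per locus, allele frequencies evolve `tGen` generations by multinomial
#' resampling of `2 Ne` gene copies, optionally preceded each generation by
#' a deterministic migration pull toward fixed source frequencies
#' (`p' = (1 - m) p + m p_source`). Samples of the stated diploid sizes are
#' drawn binomially (plan II) at the two time points: the earlier sample
#' from the initial frequencies, the later from the final ones. `Ne = Inf`
#' disables drift (sampling noise only).
#'
#' @param Ne True diploid effective size (`>= 2`, or `Inf`).
#' @param tGen Generations between samples.
#' @param nLoci Number of loci.
#' @param nAlleles Alleles per locus; initial frequencies are symmetric
#'   Dirichlet(1) draws (high-diversity microsatellite-like loci) unless
#'   `initFreqs` is given.
#' @param S0,St Diploid sample sizes at the two time points.
#' @param m Migration rate per generation (0 = closed).
#' @param sourceFreqs Optional per-locus list of source frequency vectors
#'   (defaults to fresh Dirichlet draws when `m > 0`).
#' @param initFreqs Optional per-locus list of initial frequency vectors.
#' @param years Sampling years for labelling, `c(early, late)`.
#' @param seed Optional RNG seed.
#' @param minMaf Initial-frequency floor: initial draws are resampled until
#'   every allele starts above this frequency (avoids loci fixed before
#'   sampling; resampling is counted in the truth record).
#' @return List: `dataset` (a [TemporalDataset]), `truth` (all generating
#'   parameters incl. initial/final/source frequencies).
#' @export
wfForwardSim <- function(Ne, tGen, nLoci = 9, nAlleles = 10, S0 = 50,
                         St = 50, m = 0, sourceFreqs = NULL,
                         initFreqs = NULL, years = c(1915, 2005),
                         seed = NULL, minMaf = 0.02) {
  if (!is.infinite(Ne) && Ne < 2) stop("Ne must be >= 2 (or Inf)")
  if (tGen < 0) stop("tGen must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rdirichlet1 <- function(k) { g <- rgamma(k, 1); g / sum(g) }
  resampled <- 0L
  p0 <- vector("list", nLoci); ps <- vector("list", nLoci)
  pt <- vector("list", nLoci)
  for (l in seq_len(nLoci)) {
    if (!is.null(initFreqs)) p0[[l]] <- initFreqs[[l]]
    else repeat {
      p0[[l]] <- rdirichlet1(nAlleles)
      if (min(p0[[l]]) >= minMaf) break
      resampled <- resampled + 1L
    }
    k <- length(p0[[l]])
    ps[[l]] <- if (!is.null(sourceFreqs)) sourceFreqs[[l]]
               else if (m > 0) rdirichlet1(k) else rep(NA_real_, k)
    p <- p0[[l]]
    if (tGen > 0) for (g in seq_len(tGen)) {
      if (m > 0) p <- (1 - m) * p + m * ps[[l]]
      if (is.finite(Ne)) p <- as.numeric(rmultinom(1, 2 * Ne, p)) / (2 * Ne)
    }
    pt[[l]] <- p
  }
  draw_sample <- function(freqs, n, year, epoch) {
    loci <- sprintf("L%d", seq_len(nLoci))
    g <- array(NA_integer_, dim = c(n, nLoci, 2),
               dimnames = list(NULL, loci, NULL))
    for (l in seq_len(nLoci)) {
      copies <- sample.int(length(freqs[[l]]), 2 * n, replace = TRUE,
                           prob = freqs[[l]])
      g[, l, 1] <- copies[seq(1, 2 * n, 2)]
      g[, l, 2] <- copies[seq(2, 2 * n, 2)]
    }
    GenotypeSample(site = "WF", year = year, epoch = epoch, genotypes = g)
  }
  s0 <- draw_sample(p0, S0, years[1], "historical")
  st <- draw_sample(pt, St, years[2], "contemporary")
  ds <- TemporalDataset(loci = sprintf("L%d", seq_len(nLoci)),
                        samples = list(s0, st), generationOffset = tGen,
                        title = "forward Wright-Fisher fixture")
  list(dataset = ds,
       truth = list(Ne = Ne, tGen = tGen, m = m, nLoci = nLoci,
                    S0 = S0, St = St, initFreqs = p0, finalFreqs = pt,
                    sourceFreqs = ps, resampledInits = resampled,
                    seed = seed))
}

#' Study-shaped synthetic bottleneck dataset
#'
#' Emulates the sampling design of a three-site, two-epoch songbird
#' study: historical samples (1900-1915, n = 8-20 per site) drawn from one
#' panmictic pre-bottleneck pool, and contemporary samples (2005-2008,
#' n = 17-34) taken after each site has drifted independently at the
#' bottleneck size since the decline (fragmentation modelled as
#' independent post-bottleneck drift rather than an explicit divergence
#' tree). Pool allele frequencies at 9 microsatellite loci come from a
#' serial coalescent simulation at the ancestral size. A truth manifest
#' records every generating parameter.
#'
#' @param Nanc Ancestral (pre-bottleneck) diploid size.
#' @param Nbot Species-wide post-bottleneck diploid size. Fragmentation is
#'   modelled by splitting this size equally across the contemporary
#'   sites, each fragment drifting independently at `Nbot / nSites` (so
#'   the pooled contemporary population has the effective size the
#'   two-epoch scenario describes). `Inf` gives the no-bottleneck
#'   control: sites stay panmictic and the common pool keeps drifting at
#'   `Nanc`, so epoch differences reflect sampling noise only.
#' @param tBot Bottleneck time, generations before 2005.
#' @param model A `MutationModel` for the equilibrium pool.
#' @param design Data.frame site/year/epoch/n; default mirrors the
#'   three-site historical/contemporary grid (9 samples).
#' @param dir Optional directory: writes one Genepop file per site plus a
#'   JSON truth manifest.
#' @param seed Optional RNG seed.
#' @return List: `dataset` ([TemporalDataset] with one sample per
#'   site x year), `truth`, and `files` when `dir` is given.
#' @export
makePaperStudy <- function(Nanc = 5000, Nbot = 450, tBot = 67,
                           model = mutationModel(), design = NULL,
                           dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(design))
    design <- data.frame(
      site = c("Kerr", "Kerr", "Kerr", "Bexar", "Oklahoma",
               "Kerr", "Kerr", "Bexar", "Oklahoma"),
      year = c(1900, 1910, 1915, 1910, 1910, 2005, 2008, 2005, 2006),
      epoch = rep(c("historical", "contemporary"), c(5, 4)),
      n = c(8, 15, 20, 9, 8, 17, 25, 33, 34))
  nLoci <- 9
  loci <- sprintf("L%d", seq_len(nLoci))
  ## equilibrium pool at the ancestral size: large serial-coalescent sample
  poolN <- 250  # diploids; 500 gene copies per locus
  pool <- .simulate_raw(c(Nanc = Nanc, Ncur = Nanc, tbot = 1, offset = 1),
                        sampleSchedule(poolN, 1), model, nLoci)
  poolFreq <- lapply(seq_len(nLoci), function(l) {
    st <- pool$states[[l]][seq_len(2 * poolN)]
    tab <- table(st)
    list(allele = as.integer(names(tab)), freq = as.numeric(tab) / sum(tab))
  })
  drift <- function(freq, N, gens) {
    if (gens < 1 || is.infinite(N)) return(freq)
    for (g in seq_len(gens))
      freq <- as.numeric(rmultinom(1, 2 * N, freq)) / (2 * N)
    freq
  }
  ## the common pool itself keeps drifting at Nanc up to each sampling year
  refYear <- 2005
  sampleFrom <- function(freqs, alleles, n, site, year, epoch) {
    g <- array(NA_integer_, dim = c(n, nLoci, 2),
               dimnames = list(NULL, loci, NULL))
    for (l in seq_len(nLoci)) {
      idx <- sample.int(length(freqs[[l]]), 2 * n, replace = TRUE,
                        prob = freqs[[l]])
      copies <- alleles[[l]][idx]
      g[, l, 1] <- copies[seq(1, 2 * n, 2)]
      g[, l, 2] <- copies[seq(2, 2 * n, 2)]
    }
    GenotypeSample(site = site, year = year, epoch = epoch, genotypes = g)
  }
  alleles <- lapply(poolFreq, `[[`, "allele")
  basefreq <- lapply(poolFreq, `[[`, "freq")
  samples <- list()
  ## historical: straight from the panmictic pool
  for (i in which(design$epoch == "historical"))
    samples[[i]] <- sampleFrom(basefreq, alleles, design$n[i],
                               design$site[i], design$year[i], "historical")
  if (is.infinite(Nbot)) {
    ## no-bottleneck control: the species stays one panmictic pool at Nanc;
    ## all contemporary samples share a single drifted trajectory
    rows <- which(design$epoch == "contemporary")
    yrs <- design$year[rows]
    freq <- basefreq
    lastGen <- 0
    for (k in order(yrs)) {
      i <- rows[k]
      gens <- tBot + (design$year[i] - refYear) - lastGen
      freq <- lapply(freq, drift, N = Nanc, gens = gens)
      lastGen <- lastGen + max(gens, 0)
      samples[[i]] <- sampleFrom(freq, alleles, design$n[i],
                                 design$site[i], design$year[i],
                                 "contemporary")
    }
  } else {
    ## contemporary: fragmentation splits the species-wide post-bottleneck
    ## size across sites; each fragment drifts independently at its share
    contSites <- unique(design$site[design$epoch == "contemporary"])
    NbotSite <- Nbot / length(contSites)
    for (st in contSites) {
      rows <- which(design$epoch == "contemporary" & design$site == st)
      yrs <- design$year[rows]
      freq <- basefreq
      lastGen <- 0
      for (k in order(yrs)) {
        i <- rows[k]
        gens <- tBot + (design$year[i] - refYear) - lastGen
        freq <- lapply(freq, drift, N = NbotSite, gens = gens)
        lastGen <- lastGen + max(gens, 0)
        samples[[i]] <- sampleFrom(freq, alleles, design$n[i],
                                   design$site[i], design$year[i],
                                   "contemporary")
      }
    }
  }
  ds <- TemporalDataset(loci = loci, samples = samples,
                        title = "synthetic three-site bottleneck study")
  truth <- list(Nanc = Nanc, Nbot = Nbot, tBot = tBot, nLoci = nLoci,
                design = design, poolCopies = 2 * poolN,
                mutation = unclass(model), seed = seed,
                refYear = refYear)
  out <- list(dataset = ds, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (st in unique(design$site)) {
      sub <- TemporalDataset(loci = loci,
                             samples = samples[design$site == st],
                             title = sprintf("synthetic study site %s", st))
      f <- file.path(dir, sprintf("%s.gen", st))
      writeGenepop(sub, f)
      files <- c(files, f)
    }
    mf <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, mf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$files <- c(files, mf)
  }
  out
}
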