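## S4 containers for heterochronous microsatellite datasets.
##
## A GenotypeSample is one population x time-point block of diploid
## multilocus genotypes; a TemporalDataset bundles samples sharing a locus
## list, with the generation offset separating its two sampling epochs.

#' One population sample of diploid microsatellite genotypes
#'
#' A single population x time-point block. Genotypes are stored as an
#' integer array of dimension `n x loci x 2`; allele states are positive
#' integers (repeat numbers or fragment sizes), `NA` marks a missing
#' genotype (both gene copies `NA`).
#'
#' @slot site Site label.
#' @slot year Calendar year of sampling.
#' @slot epoch Either `"historical"` or `"contemporary"`.
#' @slot ids Individual identifiers (length `n`).
#' @slot genotypes Integer array `n x loci x 2` with locus dimnames.
#'
#' @examples
#' g <- array(c(102L, 98L, 104L, 98L), dim = c(1, 2, 2),
#'            dimnames = list(NULL, c("L1", "L2"), NULL))
#' s <- GenotypeSample(site = "Kerr", year = 1900, epoch = "historical",
#'                     ids = "Kerr_1900_01", genotypes = g)
#' nInd(s)
#' @export
setClass("GenotypeSample",
  representation(
    site      = "character",
    year      = "numeric",
    epoch     = "character",
    ids       = "character",
    genotypes = "array"
  )
)

setValidity("GenotypeSample", function(object) {
  msg <- character()
  g <- object@genotypes
  if (length(dim(g)) != 3L || dim(g)[3] != 2L)
    msg <- c(msg, "genotypes must be an n x loci x 2 array")
  if (!is.null(dim(g)) && length(dim(g)) == 3L) {
    if (dim(g)[1] < 1L) msg <- c(msg, "at least one individual required")
    if (length(object@ids) != dim(g)[1])
      msg <- c(msg, "length(ids) must equal the number of individuals")
    a1 <- is.na(g[, , 1, drop = FALSE]); a2 <- is.na(g[, , 2, drop = FALSE])
    if (any(a1 != a2))
      msg <- c(msg, "each cell must hold 2 allele states or be fully missing")
    if (any(g[!is.na(g)] < 1))
      msg <- c(msg, "allele states must be positive integers")
  }
  if (length(object@epoch) != 1L ||
      !object@epoch %in% c("historical", "contemporary"))
    msg <- c(msg, "epoch must be 'historical' or 'contemporary'")
  if (length(msg)) msg else TRUE
})

#' Heterochronous multilocus microsatellite dataset
#'
#' An ordered locus list plus one or more [GenotypeSample] objects sharing
#' that list, with the number of generations separating the two sampling
#' epochs (when both are present).
#'
#' @slot title Dataset title (Genepop first line).
#' @slot loci Ordered locus names.
#' @slot samples List of [GenotypeSample] objects.
#' @slot generationOffset Generations separating the historical and
#'   contemporary epochs (e.g. 90 for samples ~90 generations apart).
#' @export
setClass("TemporalDataset",
  representation(
    title            = "character",
    loci             = "character",
    samples          = "list",
    generationOffset = "numeric"
  ),
  prototype(title = "chronopop dataset", generationOffset = NA_real_)
)

setValidity("TemporalDataset", function(object) {
  msg <- character()
  if (length(object@samples) < 1L)
    msg <- c(msg, "at least one sample required")
  if (anyDuplicated(object@loci))
    msg <- c(msg, "locus names must be unique")
  for (s in object@samples) {
    if (!is(s, "GenotypeSample")) {
      msg <- c(msg, "samples must be GenotypeSample objects"); break
    }
    if (!identical(colnames(s@genotypes), object@loci)) {
      msg <- c(msg, "all samples must share the dataset locus list"); break
    }
  }
  ep <- vapply(object@samples, function(s) s@epoch, character(1))
  if (all(c("historical", "contemporary") %in% ep) &&
      (is.na(object@generationOffset) || object@generationOffset <= 0))
    msg <- c(msg, "generationOffset must be > 0 when both epochs are present")
  if (length(msg)) msg else TRUE
})

#' Simulated reference table for approximate Bayesian computation
#'
#' Rows of (scenario id, drawn parameters, summary statistics) produced by
#' [buildReferenceTable()], with robust per-statistic scaling constants
#' (median and MAD) used for the Euclidean rejection distance.
#'
#' @slot scenario Integer scenario id per row.
#' @slot params Numeric matrix of drawn parameters (`Nanc`, `Ncur`, `tbot`).
#' @slot stats Numeric matrix of summary statistics (one column per stat).
#' @slot center Per-statistic medians.
#' @slot scale Per-statistic MADs (floored to avoid zero divisors).
#' @slot seed Seed used to build the table.
#' @export
setClass("ReferenceTable",
  representation(
    scenario = "integer",
    params   = "matrix",
    stats    = "matrix",
    center   = "numeric",
    scale    = "numeric",
    seed     = "numeric"
  )
)

setValidity("ReferenceTable", function(object) {
  msg <- character()
  if (nrow(object@stats) != length(object@scenario) ||
      nrow(object@params) != length(object@scenario))
    msg <- c(msg, "scenario, params and stats must have matching rows")
  if (anyNA(object@stats))
    msg <- c(msg, "summary statistics must be NaN-free")
  if (length(object@center) != ncol(object@stats) ||
      length(object@scale) != ncol(object@stats))
    msg <- c(msg, "scaling constants must match the statistic columns")
  if (length(msg)) msg else TRUE
})

#' Two-epoch bottleneck demography
#'
#' Piecewise-constant demography with a single size change `tBottleneck`
#' generations before present: diploid size `current` from the present back
#' to the change, `ancestral` beyond it. Prior bounds are length-2 numeric
#' ranges (equal bounds fix the value).
#'
#' @slot id Scenario identifier (1..11 for the built-in set).
#' @slot ancestral Prior range for the ancestral diploid size.
#' @slot current Prior range for the current (post-change) diploid size.
#' @slot tBottleneck Prior range for the size-change time in generations
#'   (both entries equal to `sampleOffset` for a no-bottleneck scenario).
#' @slot sampleOffset Generations before present of the historical sample.
#' @slot constraint `">"` (decline: ancestral > current), `"<="`
#'   (constant/increase) or `"none"`.
#' @export
setClass("DemographicScenario",
  representation(
    id           = "integer",
    ancestral    = "numeric",
    current      = "numeric",
    tBottleneck  = "numeric",
    sampleOffset = "numeric",
    constraint   = "character"
  )
)

setValidity("DemographicScenario", function(object) {
  msg <- character()
  for (sl in c("ancestral", "current", "tBottleneck")) {
    v <- slot(object, sl)
    if (length(v) != 2L || any(is.na(v)) || v[1] > v[2])
      msg <- c(msg, sprintf("%s must be a length-2 range lo <= hi", sl))
  }
  if (any(object@ancestral < 2) || any(object@current < 2))
    msg <- c(msg, "population sizes must be >= 2")
  if (object@sampleOffset <= 0)
    msg <- c(msg, "sampleOffset must be > 0")
  if (!object@constraint %in% c(">", "<=", "none"))
    msg <- c(msg, "constraint must be one of '>', '<=', 'none'")
  if (length(msg)) msg else TRUE
})

## ---- generics and accessors -------------------------------------------

#' @rdname GenotypeSample-class
#' @param object,x A `GenotypeSample` or `TemporalDataset`.
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname GenotypeSample-class
#' @export
setMethod("nInd", "GenotypeSample", function(x) dim(x@genotypes)[1])

#' @rdname TemporalDataset-class
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))
#' @rdname TemporalDataset-class
#' @export
setMethod("lociNames", "TemporalDataset", function(x) x@loci)
#' @rdname GenotypeSample-class
#' @export
setMethod("lociNames", "GenotypeSample", function(x) colnames(x@genotypes))

#' @rdname TemporalDataset-class
#' @export
setGeneric("getSamples", function(x, epoch = NULL) standardGeneric("getSamples"))
#' @rdname TemporalDataset-class
#' @param epoch Optional epoch filter (`"historical"` or `"contemporary"`).
#' @export
setMethod("getSamples", "TemporalDataset", function(x, epoch = NULL) {
  s <- x@samples
  if (!is.null(epoch)) s <- Filter(function(z) z@epoch == epoch, s)
  s
})

#' @rdname GenotypeSample-class
#' @export
setGeneric("epochOf", function(x) standardGeneric("epochOf"))
#' @rdname GenotypeSample-class
#' @export
setMethod("epochOf", "GenotypeSample", function(x) x@epoch)

#' @rdname GenotypeSample-class
#' @export
setGeneric("siteOf", function(x) standardGeneric("siteOf"))
#' @rdname GenotypeSample-class
#' @export
setMethod("siteOf", "GenotypeSample", function(x) x@site)

#' @rdname GenotypeSample-class
#' @export
setGeneric("yearOf", function(x) standardGeneric("yearOf"))
#' @rdname GenotypeSample-class
#' @export
setMethod("yearOf", "GenotypeSample", function(x) x@year)

#' @rdname GenotypeSample-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname GenotypeSample-class
#' @export
setMethod("genotypes", "GenotypeSample", function(x) x@genotypes)

#' @rdname TemporalDataset-class
#' @export
setGeneric("generationOffset", function(x) standardGeneric("generationOffset"))
#' @rdname TemporalDataset-class
#' @export
setMethod("generationOffset", "TemporalDataset", function(x) x@generationOffset)

setMethod("show", "GenotypeSample", function(object) {
  cat(sprintf("GenotypeSample '%s' (%d), %s epoch: %d individuals x %d loci\n",
              object@site, round(object@year), object@epoch,
              nInd(object), dim(object@genotypes)[2]))
})

setMethod("show", "TemporalDataset", function(object) {
  ep <- vapply(object@samples, epochOf, character(1))
  cat(sprintf("TemporalDataset: %d loci, %d samples (%d historical, %d contemporary)\n",
              length(object@loci), length(object@samples),
              sum(ep == "historical"), sum(ep == "contemporary")))
  if (!is.na(object@generationOffset))
    cat(sprintf("  epochs separated by %g generations\n", object@generationOffset))
  for (s in object@samples)
    cat(sprintf("  %-12s %-6s %-13s n = %d\n", s@site, format(round(s@year)),
                s@epoch, nInd(s)))
})

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf("ReferenceTable: %d rows, %d scenarios, %d summary statistics\n",
              length(object@scenario), length(unique(object@scenario)),
              ncol(object@stats)))
})

setMethod("show", "DemographicScenario", function(object) {
  fmt <- function(v) if (v[1] == v[2]) format(v[1]) else
    sprintf("U[%g, %g]", v[1], v[2])
  cat(sprintf("Scenario %d: ancestral %s -> current %s, change at %s gen (constraint %s)\n",
              object@id, fmt(object@ancestral), fmt(object@current),
              fmt(object@tBottleneck), object@constraint))
})

## ---- constructors ------------------------------------------------------

#' @rdname GenotypeSample-class
#' @param site,year,epoch,ids,genotypes Slots; see class description. `ids`
#'   defaults to `site_year_<i>` labels.
#' @export
GenotypeSample <- function(site, year, epoch, genotypes, ids = NULL) {
  storage.mode(genotypes) <- "integer"
  if (is.null(ids))
    ids <- sprintf("%s_%d_%02d", site, round(year), seq_len(dim(genotypes)[1]))
  new("GenotypeSample", site = site, year = as.numeric(year), epoch = epoch,
      ids = ids, genotypes = genotypes)
}

#' @rdname TemporalDataset-class
#' @param loci,samples,generationOffset,title Slots; see class description.
#'   `generationOffset` defaults to the rounded gap between the mean
#'   contemporary and mean historical sampling years (one generation per
#'   year) when both epochs are present.
#' @export
TemporalDataset <- function(loci, samples, generationOffset = NULL,
                            title = "chronopop dataset") {
  ep <- vapply(samples, function(s) s@epoch, character(1))
  if (is.null(generationOffset)) {
    generationOffset <- if (all(c("historical", "contemporary") %in% ep)) {
      yh <- mean(vapply(samples[ep == "historical"], function(s) s@year, 1))
      yc <- mean(vapply(samples[ep == "contemporary"], function(s) s@year, 1))
      round(yc - yh)
    } else NA_real_
  }
  new("TemporalDataset", title = title, loci = loci, samples = samples,
      generationOffset = as.numeric(generationOffset))
}
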