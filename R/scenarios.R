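## Two-epoch demographic scenarios and their uniform priors.

#' Construct a two-epoch demographic scenario
#'
#' @param id Integer scenario id.
#' @param ancestral Ancestral diploid size: a single value or `c(lo, hi)`
#'   uniform prior bounds.
#' @param current Current (post-change) diploid size, value or bounds.
#' @param tBottleneck Size-change time in generations before present, value
#'   or bounds; `NA` places the change at `sampleOffset` (no-bottleneck
#'   scenario: the historical sample sits exactly at the size change, so the
#'   ancestral size governs everything older).
#' @param sampleOffset Generations before present of the historical sample.
#' @param constraint `">"` for decline (ancestral > current), `"<="` for
#'   constant-or-increasing, `"none"`.
#' @return A [DemographicScenario-class] object.
#' @export
demographicScenario <- function(id, ancestral, current, tBottleneck = NA,
                                sampleOffset = 90, constraint = ">") {
  rng <- function(v, default = NULL) {
    if (length(v) == 1L && is.na(v)) v <- default
    if (length(v) == 1L) v <- c(v, v)
    as.numeric(v)
  }
  new("DemographicScenario", id = as.integer(id),
      ancestral = rng(ancestral), current = rng(current),
      tBottleneck = rng(tBottleneck, default = sampleOffset),
      sampleOffset = as.numeric(sampleOffset),
      constraint = constraint)
}

#' The built-in set of 11 bottleneck scenarios
#'
#' Eleven candidate two-epoch demographies for a population sampled ~90
#' generations apart: scenario 1 is the constant-or-increasing null
#' (both sizes on wide uniform priors), scenarios 2-4 fix both sizes and
#' estimate only the decline time, scenarios 5-8 fix the ancestral size
#' (2000-5000) and estimate the post-decline size on U[200, 1000] plus the
#' decline time on U[10, 80], and scenarios 9-11 put priors on both sizes.
#'
#' @param sampleOffset Generations before present of the historical sample
#'   (default 90).
#' @return Named list of [DemographicScenario-class] objects.
#' @export
bottleneckScenarios <- function(sampleOffset = 90) {
  s <- list(
    demographicScenario(1, c(10, 100000), c(10, 100000), NA,
                        sampleOffset, constraint = "<="),
    demographicScenario(2, 4000, 500, c(10, 80), sampleOffset),
    demographicScenario(3, 5000, 650, c(10, 80), sampleOffset),
    demographicScenario(4, 6000, 700, c(10, 80), sampleOffset),
    demographicScenario(5, 2000, c(200, 1000), c(10, 80), sampleOffset),
    demographicScenario(6, 3000, c(200, 1000), c(10, 80), sampleOffset),
    demographicScenario(7, 4000, c(200, 1000), c(10, 80), sampleOffset),
    demographicScenario(8, 5000, c(200, 1000), c(10, 80), sampleOffset),
    demographicScenario(9, c(2500, 15000), c(100, 1000), c(10, 80), sampleOffset),
    demographicScenario(10, c(2500, 15000), c(100, 1000), c(10, 80), sampleOffset),
    demographicScenario(11, c(2000, 10000), c(500, 750), c(10, 80), sampleOffset)
  )
  names(s) <- paste0("scenario", seq_along(s))
  s
}

#' Draw one constraint-satisfying parameter vector from a scenario's priors
#'
#' Independent uniforms on each parameter's bounds, rejection-resampled
#' until the scenario's size-order constraint holds.
#'
#' @param scenario A [DemographicScenario-class].
#' @param seed Optional RNG seed.
#' @param maxTries Attempts before giving up on the constraint.
#' @return Named numeric vector `c(Nanc, Ncur, tbot)`.
#' @export
drawPrior <- function(scenario, seed = NULL, maxTries = 10000) {
  if (!is.null(seed)) set.seed(seed)
  draw1 <- function(b) if (b[1] == b[2]) b[1] else runif(1, b[1], b[2])
  for (i in seq_len(maxTries)) {
    nanc <- draw1(scenario@ancestral)
    ncur <- draw1(scenario@current)
    tbot <- draw1(scenario@tBottleneck)
    ok <- switch(scenario@constraint,
                 ">" = nanc > ncur, "<=" = nanc <= ncur, none = TRUE)
    if (ok) return(c(Nanc = nanc, Ncur = ncur, tbot = tbot))
  }
  stop("constraint '", scenario@constraint, "' unsatisfiable for scenario ",
       scenario@id, " after ", maxTries, " attempts")
}

#' Microsatellite mutation model
#'
#' Generalized stepwise model (GSM): mutations occur as a Poisson process
#' along branches; each mutation changes the repeat count by a geometric
#' step (`P(step = k) = gsmP^(k-1) (1 - gsmP)`, sign equiprobable),
#' reflected at the boundaries of a contiguous allowed state range.
#' Per-locus rates are Gamma-distributed around the mean rate. Defaults
#' follow common practice for avian microsatellite panels: mean rate 5e-4
#' mutations/locus/generation, geometric parameter 0.22, 40 allele states,
#' Gamma shape 2 for across-locus rate variation.
#'
#' @param meanRate Mean mutation rate per locus per generation.
#' @param rateShape Gamma shape of across-locus rate variation (`Inf` for
#'   equal rates).
#' @param gsmP Geometric step parameter in `[0, 1)`; 0 = strict stepwise.
#' @param nStates Number of allowed allele states (contiguous, >= 2).
#' @return List of class `MutationModel`.
#' @export
mutationModel <- function(meanRate = 5e-4, rateShape = 2, gsmP = 0.22,
                          nStates = 40) {
  stopifnot(meanRate > 0, nStates >= 2, gsmP >= 0, gsmP < 1, rateShape > 0)
  out <- list(meanRate = meanRate, rateShape = rateShape, gsmP = gsmP,
              nStates = as.integer(nStates))
  class(out) <- "MutationModel"
  out
}

#' @export
print.MutationModel <- function(x, ...) {
  cat(sprintf("GSM mutation model: mean rate %g, gsmP = %g, %d states, rate shape %g\n",
              x$meanRate, x$gsmP, x$nStates, x$rateShape))
  invisible(x)
}

#' Sampling schedule for a two-epoch dataset
#'
#' @param nContemporary Diploid individuals sampled at generation 0.
#' @param nHistorical Diploid individuals sampled `sampleOffset` generations
#'   before present.
#' @return List of class `SampleSchedule`.
#' @export
sampleSchedule <- function(nContemporary, nHistorical) {
  stopifnot(nContemporary >= 1, nHistorical >= 1)
  out <- list(nContemporary = as.integer(nContemporary),
              nHistorical = as.integer(nHistorical))
  class(out) <- "SampleSchedule"
  out
}
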