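## Serial-sample coalescent simulation of microsatellite datasets.

#' Simulate one microsatellite locus under a two-epoch demography
#'
#' Coalescent genealogy with contemporary gene copies entering at time 0
#' and historical copies at `scenario@sampleOffset` generations before
#' present; pairs coalesce at rate `C(k,2)/(2N)` with the diploid size
#' switching from the current to the ancestral value at the bottleneck
#' time. Mutations follow the generalized stepwise model of `model`.
#'
#' @param scenario A [DemographicScenario-class] with concrete (point)
#'   parameter values, or a list `c(Nanc, Ncur, tbot)` plus `sampleOffset`.
#' @param schedule A `SampleSchedule` from [sampleSchedule()].
#' @param model A `MutationModel` from [mutationModel()]; the locus rate
#'   may be overridden with `rate`.
#' @param rate Optional concrete mutation rate for this locus (otherwise
#'   `model$meanRate`).
#' @param seed Optional RNG seed.
#' @param returnTree Also return parent pointers and node times.
#' @return List with `states` (integer allele states per gene copy;
#'   contemporary copies first), `epoch` (tag per copy), and optionally
#'   `parent`/`time`.
#' @export
simulateLocus <- function(scenario, schedule, model = mutationModel(),
                          rate = NULL, seed = NULL, returnTree = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  par <- .scenario_point(scenario)
  if (is.null(rate)) rate <- model$meanRate
  res <- sim_msat_locus_cpp(schedule$nContemporary, schedule$nHistorical,
                            par["offset"], par["Ncur"], par["Nanc"],
                            par["tbot"], rate, model$gsmP, model$nStates,
                            returnTree)
  res$epoch <- rep(c("contemporary", "historical"),
                   c(2 * schedule$nContemporary, 2 * schedule$nHistorical))
  res
}

## Concrete parameter vector (Nanc, Ncur, tbot, offset) from a scenario or
## a named numeric vector. Prior scenarios must be instantiated first.
.scenario_point <- function(scenario, params = NULL) {
  if (is(scenario, "DemographicScenario")) {
    if (is.null(params)) {
      fixed <- function(b, what) {
        if (b[1] != b[2])
          stop("scenario ", scenario@id, " has a prior on ", what,
               "; draw parameters first (drawPrior)")
        b[1]
      }
      params <- c(Nanc = fixed(scenario@ancestral, "the ancestral size"),
                  Ncur = fixed(scenario@current, "the current size"),
                  tbot = fixed(scenario@tBottleneck, "the bottleneck time"))
    }
    return(c(params[c("Nanc", "Ncur", "tbot")],
             offset = scenario@sampleOffset))
  }
  if (is.numeric(scenario) &&
      all(c("Nanc", "Ncur", "tbot", "offset") %in% names(scenario)))
    return(scenario[c("Nanc", "Ncur", "tbot", "offset")])
  stop("scenario must be a DemographicScenario or a named parameter vector")
}

#' Simulate a two-sample multilocus microsatellite dataset
#'
#' `nLoci` independent loci under [simulateLocus()]; per-locus mutation
#' rates are Gamma-distributed around the model's mean rate. Gene copies
#' are paired sequentially into diploid genotypes (equivalent to random
#' pairing by exchangeability of the coalescent tips), yielding one
#' historical and one contemporary [GenotypeSample].
#'
#' @param scenario Concrete [DemographicScenario-class] or named parameter
#'   vector (see [simulateLocus()]).
#' @param schedule A `SampleSchedule`.
#' @param model A `MutationModel`.
#' @param nLoci Number of loci (default 9).
#' @param seed Optional RNG seed.
#' @param years Length-2 sampling years `c(historical, contemporary)` used
#'   for labelling only.
#' @return A [TemporalDataset] with two samples (historical first).
#' @examples
#' sc <- demographicScenario(8, 5000, 450, 67)
#' ds <- simulateDataset(sc, sampleSchedule(20, 10), nLoci = 3, seed = 1)
#' ds
#' @export
simulateDataset <- function(scenario, schedule, model = mutationModel(),
                            nLoci = 9, seed = NULL,
                            years = c(1915, 2005)) {
  if (!is.null(seed)) set.seed(seed)
  raw <- .simulate_raw(scenario, schedule, model, nLoci)
  .raw_to_dataset(raw, schedule, years)
}

## Fast path used by the ABC engine: per-locus gene-copy state matrices
## without S4 container overhead. Returns list(states = loci-list of
## integer vectors, nCont, nHist, offset).
.simulate_raw <- function(scenario, schedule, model, nLoci) {
  par <- .scenario_point(scenario)
  rates <- if (is.finite(model$rateShape))
    rgamma(nLoci, shape = model$rateShape,
           rate = model$rateShape / model$meanRate)
  else rep(model$meanRate, nLoci)
  states <- lapply(seq_len(nLoci), function(l)
    sim_msat_locus_cpp(schedule$nContemporary, schedule$nHistorical,
                       par["offset"], par["Ncur"], par["Nanc"], par["tbot"],
                       rates[l], model$gsmP, model$nStates, FALSE)$states)
  list(states = states, nCont = schedule$nContemporary,
       nHist = schedule$nHistorical, offset = unname(par["offset"]))
}

.raw_to_dataset <- function(raw, schedule, years) {
  nLoci <- length(raw$states)
  loci <- sprintf("L%d", seq_len(nLoci))
  mk <- function(idx, n) {
    g <- array(NA_integer_, dim = c(n, nLoci, 2),
               dimnames = list(NULL, loci, NULL))
    for (l in seq_len(nLoci)) {
      st <- raw$states[[l]][idx]
      g[, l, 1] <- st[seq(1, 2 * n, by = 2)]
      g[, l, 2] <- st[seq(2, 2 * n, by = 2)]
    }
    g
  }
  nc <- raw$nCont; nh <- raw$nHist
  cont <- GenotypeSample(site = "Sim", year = years[2],
                         epoch = "contemporary",
                         genotypes = mk(seq_len(2 * nc), nc))
  hist <- GenotypeSample(site = "Sim", year = years[1],
                         epoch = "historical",
                         genotypes = mk(2 * nc + seq_len(2 * nh), nh))
  TemporalDataset(loci = loci, samples = list(hist, cont),
                  generationOffset = raw$offset,
                  title = "simulated two-epoch dataset")
}
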