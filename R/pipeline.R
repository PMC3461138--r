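## Config-driven orchestration of the full analysis: diversity report,
## differentiation report, ABC posterior report, temporal-Ne report.

.derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) + 1000003 * stage) %% 2147483647)
}

#' Run the full temporal study pipeline
#'
#' Sequences the analysis stages on a set of Genepop inputs: per-sample
#' diversity with epoch comparisons, pairwise differentiation with
#' permutation significance and the epoch contrast, an optional ABC fit of
#' the two-epoch bottleneck scenarios, and the temporal-Ne estimators.
#' Reports are written as TSV with JSON twins plus a run log; a single
#' master seed deterministically spawns independent per-stage seeds. A
#' stage failure preserves the outputs produced so far and re-raises.
#'
#' @param config Path to a YAML file or an equivalent named list with
#'   entries: `inputs` (character vector of Genepop paths), `outdir`,
#'   `seed`, `nPerm` (permutations, default 3000), and optionally `abc`
#'   (list: `nPerScenario`, `tolerance`, `scenarios` = integer ids of the
#'   built-in scenario set to fit, `sampleOffset`), `ne` (list: `T` values,
#'   `joint`), `requireSamples` (character `site_year` labels that must be
#'   present).
#' @return Invisibly, a list with all stage results and output paths.
#' @export
runStudy <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (need in c("inputs", "outdir", "seed"))
    if (is.null(config[[need]])) stop("config is missing '", need, "'")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  cat("", file = logfile)
  logmsg("chronopop %s | master seed %s",
         as.character(utils::packageVersion("chronopop")), config$seed)

  ## stage 0: load and merge inputs
  dss <- lapply(config$inputs, readGenepop)
  loci <- lociNames(dss[[1]])
  samples <- list()
  for (d in dss) {
    if (!identical(lociNames(d), loci))
      stop("input files disagree on the locus list")
    samples <- c(samples, getSamples(d))
  }
  ds <- TemporalDataset(loci = loci, samples = samples)
  labels <- vapply(samples, function(s)
    sprintf("%s_%d", siteOf(s), round(yearOf(s))), character(1))
  if (!is.null(config$requireSamples)) {
    missing <- setdiff(config$requireSamples, labels)
    if (length(missing))
      stop("config references missing sample(s): ",
           paste(missing, collapse = ", "))
  }
  logmsg("loaded %d samples x %d loci from %d file(s)",
         length(samples), length(loci), length(config$inputs))

  results <- list(dataset = ds, outputs = character(0))
  emit <- function(obj, name) {
    tsv <- file.path(outdir, paste0(name, ".tsv"))
    jsn <- file.path(outdir, paste0(name, ".json"))
    if (is.data.frame(obj))
      write.table(obj, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(obj, jsn, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    results$outputs <<- c(results$outputs, tsv, jsn)
  }
  nPerm <- if (is.null(config$nPerm)) 3000 else config$nPerm

  run_stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    val <- tryCatch(expr, error = function(e) {
      logmsg("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop("stage ", name, " failed: ", conditionMessage(e),
           " (partial outputs in ", outdir, ")", call. = FALSE)
    })
    logmsg("stage %s: done", name)
    val
  }

  ## stage 1: diversity
  results$diversity <- run_stage("diversity", {
    div <- diversityTable(ds)
    ep <- vapply(samples, epochOf, character(1))
    sites <- vapply(samples, siteOf, character(1))
    cmp <- list()
    for (st in intersect(sites[ep == "historical"], sites[ep == "contemporary"])) {
      hsub <- div$perLocus[div$perLocus$site == st &
                             div$perLocus$epoch == "historical", ]
      csub <- div$perLocus[div$perLocus$site == st &
                             div$perLocus$epoch == "contemporary", ]
      hy <- max(hsub$year); cy <- min(csub$year)
      h <- hsub[hsub$year == hy, ]; cc <- csub[csub$year == cy, ]
      for (stat in c("Hexp", "Ar")) {
        w <- wilcoxonPairedByLocus(h[[stat]], cc[[stat]],
                                   alternative = "greater")
        cmp[[paste(st, stat)]] <- data.frame(
          site = st, statistic = stat, yearH = hy, yearC = cy,
          Z = w$statistic, p = w$p)
      }
    }
    out <- list(summary = div$summary,
                epochTests = do.call(rbind, c(cmp, list(make.row.names = FALSE))))
    emit(out$summary, "diversity_summary")
    if (!is.null(out$epochTests)) emit(out$epochTests, "diversity_epoch_tests")
    out
  })

  ## stage 2: differentiation
  results$differentiation <- run_stage("differentiation", {
    d <- pairwiseDifferentiation(ds, nPerm = nPerm,
                                 seed = .derive_seed(config$seed, 2))
    if (!is.null(d$pairs)) emit(d$pairs, "differentiation_pairs")
    if (!is.null(d$epochComparison))
      emit(d$epochComparison, "differentiation_epoch_tests")
    d
  })

  ## stage 3: ABC (optional)
  if (!is.null(config$abc)) {
    results$abc <- run_stage("abc", {
      ac <- config$abc
      offset <- if (is.null(ac$sampleOffset)) 90 else ac$sampleOffset
      all_sc <- bottleneckScenarios(sampleOffset = offset)
      ids <- if (is.null(ac$scenarios)) seq_along(all_sc) else ac$scenarios
      scen <- all_sc[ids]
      ep <- vapply(samples, epochOf, character(1))
      nh <- sum(vapply(samples[ep == "historical"], nInd, integer(1)))
      nc <- sum(vapply(samples[ep == "contemporary"], nInd, integer(1)))
      set.seed(.derive_seed(config$seed, 3))
      tab <- buildReferenceTable(
        scen, nPerScenario = if (is.null(ac$nPerScenario)) 1000 else ac$nPerScenario,
        schedule = sampleSchedule(nc, nh), nLoci = length(loci))
      fit <- abcFit(ds, tab, scen,
                    tolerance = if (is.null(ac$tolerance)) 0.01 else ac$tolerance,
                    seed = .derive_seed(config$seed, 4))
      rpt <- list(scenarioProbs = as.list(fit$scenarioProbs),
                  chosen = fit$chosen,
                  params = lapply(fit$params, function(p)
                    list(median = p$median, ci = as.list(p$ci))))
      emit(rpt, "abc_posterior")
      fit
    })
  }

  ## stage 4: temporal Ne
  results$ne <- run_stage("temporal_ne", {
    necfg <- if (is.null(config$ne)) list() else config$ne
    set.seed(.derive_seed(config$seed, 5))
    rep <- temporalNeReport(
      ds, T = if (is.null(necfg$T)) c(1, 1.5, 2) else necfg$T,
      joint = if (is.null(necfg$joint)) TRUE else necfg$joint)
    emit(rep, "ne_report")
    rep
  })

  logmsg("pipeline complete; %d output files", length(results$outputs))
  invisible(results)
}
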