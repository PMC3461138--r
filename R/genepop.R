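## Genepop-format I/O and allele-frequency tabulation.
##
## Dialect: title line; one locus name per line (or a single comma-separated
## line); case-insensitive "POP" separators; individual rows
## "id , 102104 098098" with fixed-width 3-digit alleles and 000 = missing.
## Site/year metadata ride in the individual ids as "<site>_<year>_<k>";
## the last id of each POP block names the block.

.EPOCH_CUTOFF_YEAR <- 1950  # samples up to this year are "historical"

.parse_pop_id <- function(id) {
  parts <- strsplit(id, "_", fixed = TRUE)[[1]]
  yr <- suppressWarnings(as.numeric(parts))
  iy <- which(!is.na(yr) & yr >= 1000 & yr <= 3000)
  if (length(iy) == 0L)
    return(list(site = parts[1], year = NA_real_))
  iy <- iy[length(iy)]
  list(site = paste(parts[seq_len(iy - 1L)], collapse = "_"), year = yr[iy])
}

#' Read a Genepop file into a TemporalDataset
#'
#' Parses the 3-digit diploid Genepop dialect (`000` = missing). Each `POP`
#' block becomes one [GenotypeSample]; its site and year are taken from the
#' last individual id in the block via the `site_year` naming convention,
#' and the epoch is assigned by sampling year (historical up to 1950 unless
#' overridden).
#'
#' @param path Path to a Genepop text file.
#' @param epochCutoff Year at or below which a sample is classed historical.
#' @return A [TemporalDataset].
#' @examples
#' f <- tempfile(fileext = ".gen")
#' writeLines(c("two loci", "L1", "L2", "POP",
#'              "KerrA_1900_01 , 102104 098098"), f)
#' ds <- readGenepop(f)
#' nInd(getSamples(ds)[[1]])
#' @export
readGenepop <- function(path, epochCutoff = .EPOCH_CUTOFF_YEAR) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 1L]
  if (length(lines) < 3L) stop("not a Genepop file (too few lines): ", path)
  title <- lines[1]
  body <- lines[-1]
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found in ", path)
  loci <- body[seq_len(first_pop - 1L)]
  if (length(loci) == 1L && grepl(",", loci))
    loci <- trimws(strsplit(loci, ",")[[1]])
  loci <- trimws(loci)
  if (length(loci) < 1L) stop("no locus names before first POP in ", path)

  blocks <- cumsum(is_pop)
  samples <- list()
  for (b in seq_len(max(blocks))) {
    rows <- body[blocks == b & !is_pop]
    if (length(rows) == 0L) stop("empty POP block ", b, " in ", path)
    n <- length(rows)
    geno <- array(NA_integer_, dim = c(n, length(loci), 2),
                  dimnames = list(NULL, loci, NULL))
    ids <- character(n)
    for (i in seq_len(n)) {
      parts <- strsplit(rows[i], ",")[[1]]
      if (length(parts) < 2L)
        stop("malformed individual row (no comma): '", rows[i], "'")
      ids[i] <- trimws(parts[1])
      al <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(al) != length(loci))
        stop(sprintf("row '%s' has %d genotypes but %d loci declared",
                     ids[i], length(al), length(loci)))
      if (any(nchar(al) != 6L))
        stop(sprintf("malformed allele width (expect 6 digits) in row '%s': '%s'",
                     ids[i], al[which(nchar(al) != 6L)[1]]))
      a1 <- as.integer(substr(al, 1, 3))
      a2 <- as.integer(substr(al, 4, 6))
      miss <- a1 == 0L | a2 == 0L
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
      geno[i, , 1] <- a1; geno[i, , 2] <- a2
    }
    meta <- .parse_pop_id(ids[n])
    year <- if (is.na(meta$year)) NA_real_ else meta$year
    epoch <- if (!is.na(year) && year <= epochCutoff) "historical" else "contemporary"
    samples[[b]] <- GenotypeSample(site = meta$site, year = year,
                                   epoch = epoch, genotypes = geno, ids = ids)
  }
  TemporalDataset(loci = loci, samples = samples, title = title)
}

#' Write a TemporalDataset as a Genepop file
#'
#' Emits the canonical form read by [readGenepop()]: title, one locus name
#' per line, `POP` before each sample, rows `id , aaabbb ...` with 3-digit
#' alleles and `000000` for missing genotypes. Output is byte-stable for a
#' fixed dataset, and `readGenepop(writeGenepop(x))` recovers `x`.
#'
#' @param dataset A [TemporalDataset].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGenepop <- function(dataset, path) {
  stopifnot(is(dataset, "TemporalDataset"))
  if (length(dataset@samples) == 0L) stop("dataset has no samples")
  mx <- suppressWarnings(max(unlist(lapply(dataset@samples, function(s)
    s@genotypes[!is.na(s@genotypes)])), na.rm = TRUE))
  if (is.finite(mx) && mx > 999)
    stop("allele state ", mx, " not representable in 3 digits")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(dataset@title, dataset@loci), con)
  for (s in dataset@samples) {
    writeLines("POP", con)
    g <- s@genotypes
    for (i in seq_len(nInd(s))) {
      a1 <- g[i, , 1]; a2 <- g[i, , 2]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      writeLines(paste0(s@ids[i], " , ",
                        paste(sprintf("%03d%03d", a1, a2), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Allele counts and frequencies at one locus
#'
#' Tabulates gene copies over non-missing genotypes. The result carries the
#' gene-copy total `N` (`<= 2n`), the diploid sample size `n`, and relative
#' frequencies summing to one when `N > 0`.
#'
#' @param sample A [GenotypeSample].
#' @param locus Locus name (or index).
#' @return A list of class `AlleleFreqTable`: `locus`, `allele` (sorted
#'   integer states), `count`, `freq`, `N`, `n`, and `allMissing` flag.
#' @examples
#' g <- array(c(102L, 102L, 104L, 102L), dim = c(2, 1, 2),
#'            dimnames = list(NULL, "L1", NULL))
#' s <- GenotypeSample("X", 2000, "contemporary", g)
#' alleleFreqs(s, "L1")$freq
#' @export
alleleFreqs <- function(sample, locus) {
  stopifnot(is(sample, "GenotypeSample"))
  if (is.character(locus) && !locus %in% colnames(sample@genotypes))
    stop("locus '", locus, "' not in sample")
  copies <- c(sample@genotypes[, locus, 1], sample@genotypes[, locus, 2])
  copies <- copies[!is.na(copies)]
  n <- dim(sample@genotypes)[1]
  if (length(copies) == 0L) {
    out <- list(locus = locus, allele = integer(0), count = integer(0),
                freq = numeric(0), N = 0L, n = n, allMissing = TRUE)
    class(out) <- "AlleleFreqTable"
    return(out)
  }
  tab <- table(copies)
  allele <- as.integer(names(tab))
  count <- as.integer(tab)
  out <- list(locus = locus, allele = allele, count = count,
              freq = count / sum(count), N = sum(count), n = n,
              allMissing = FALSE)
  class(out) <- "AlleleFreqTable"
  out
}

#' @export
print.AlleleFreqTable <- function(x, ...) {
  cat(sprintf("AlleleFreqTable locus %s: N = %d gene copies (n = %d diploids)\n",
              as.character(x$locus), x$N, x$n))
  if (x$N > 0)
    print(setNames(round(x$freq, 4), x$allele))
  invisible(x)
}

#' Export allele-frequency tables for all sample x locus combinations
#'
#' @param dataset A [TemporalDataset].
#' @param path Optional TSV output path.
#' @return A data.frame with columns site, year, epoch, locus, allele,
#'   count, freq, N, n (written to `path` if given).
#' @export
exportFreqTable <- function(dataset, path = NULL) {
  rows <- list()
  for (s in dataset@samples) for (loc in dataset@loci) {
    ft <- alleleFreqs(s, loc)
    if (ft$N == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      site = s@site, year = s@year, epoch = s@epoch, locus = loc,
      allele = ft$allele, count = ft$count, freq = ft$freq,
      N = ft$N, n = ft$n)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Pool several samples into one
#'
#' Concatenates individuals across samples sharing a locus list (e.g. to
#' combine all historical site samples into a single temporal sample). The
#' epoch is inherited when uniform; otherwise it must be given explicitly.
#'
#' @param samples List of [GenotypeSample] objects with identical loci.
#' @param label Site label for the pooled sample.
#' @param epoch Epoch of the pool; required if the inputs mix epochs.
#' @param year Year of the pool; defaults to the n-weighted mean year.
#' @return A [GenotypeSample] with `n = sum(n_i)`.
#' @export
poolSamples <- function(samples, label, epoch = NULL, year = NULL) {
  stopifnot(length(samples) >= 1L)
  loci <- colnames(samples[[1]]@genotypes)
  for (s in samples)
    if (!identical(colnames(s@genotypes), loci))
      stop("samples have mismatched locus lists")
  eps <- unique(vapply(samples, function(s) s@epoch, character(1)))
  if (is.null(epoch)) {
    if (length(eps) > 1L)
      stop("samples span epochs ", paste(eps, collapse = "/"),
           "; supply `epoch` explicitly")
    epoch <- eps
  }
  ns <- vapply(samples, nInd, integer(1))
  if (is.null(year))
    year <- sum(vapply(samples, function(s) s@year, 1) * ns) / sum(ns)
  g <- array(NA_integer_, dim = c(sum(ns), length(loci), 2),
             dimnames = list(NULL, loci, NULL))
  ids <- character(sum(ns))
  at <- 0L
  for (s in samples) {
    idx <- at + seq_len(nInd(s))
    g[idx, , ] <- s@genotypes
    ids[idx] <- s@ids
    at <- at + nInd(s)
  }
  GenotypeSample(site = label, year = year, epoch = epoch,
                 genotypes = g, ids = ids)
}
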