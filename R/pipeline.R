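## Pipeline plumbing: context-table TSV readers/writers, run manifests with
## reconciling counts, and the command-level entry points chaining the
## modules (simulate -> profile -> compare / methylome). A thin Rscript
## dispatcher over these functions ships in inst/scripts/flankpref.R.

#' Write / read a context table as TSV
#'
#' Columns: context, nTotal, nMeth, levelRaw, levelSmoothed; half-width and
#' central dinucleotide are carried in `#`-prefixed header lines so the
#' table round-trips.
#'
#' @param table A [ContextTable].
#' @param file Output path.
#' @return Invisibly `file`; `readContextTable()` returns the
#'   [ContextTable].
#' @export
writeContextTable <- function(table, file) {
  stopifnot(is(table, "ContextTable"))
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(sprintf("# k=%d central=%s", table@k, table@central), con)
  utils::write.table(table@counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeContextTable
#' @export
readContextTable <- function(file) {
  hdr <- readLines(file, n = 1L)
  m <- regmatches(hdr, regexec("^# k=(\\d+) central=([ACGT]{2})$", hdr))[[1]]
  if (length(m) != 3L)
    stop("not a context table (missing header): ", file)
  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("context", "nTotal", "nMeth", "levelRaw", "levelSmoothed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("context table ", file, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df$context <- as.character(df$context)
  new("ContextTable", counts = df, k = as.integer(m[2]), central = m[3])
}

## Write a run manifest (config snapshot, seed, per-stage counts) as YAML.
writeManifest <- function(file, config, seed, counts) {
  stopifnot(all(counts >= 0))
  yaml::write_yaml(list(
    package = "flankPref",
    version = as.character(utils::packageVersion("flankPref")),
    seed = if (is.null(seed)) NA else seed,
    counts = as.list(counts),
    config = unclass(config)), file)
  invisible(file)
}

#' @rdname cmdSimulate
#' @export
readManifest <- function(file) yaml::read_yaml(file)

.log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Pipeline commands
#'
#' Command-level entry points chaining the package modules, each writing
#' its outputs plus a run manifest (`manifest.yaml`) whose per-stage counts
#' reconcile (input = accepted + sum of rejections). All commands are
#' deterministic for a fixed config and seed.
#'
#' `cmdSimulate()` generates a substrate pool, methylates it under a
#' preference model and writes `reads.fastq` + `truth.tsv`.
#' `cmdProfile()` processes a hairpin FASTQ into `molecules.tsv`,
#' per-dinucleotide context tables (`context_<DN>_k<k>.tsv`),
#' `enrichment.tsv`, `pfm.tsv`, `plus1.tsv` and `qc.tsv`.
#' `cmdCompare()` turns two context tables into `ratio.tsv` and `ranks.tsv`
#' (plus `bins.tsv` given a reference site and `repeat_report.tsv` given a
#' FASTA of repeats). `cmdMethylome()` aggregates a cytosine report over a
#' genome into the same table format.
#'
#' @param config Configuration from [flankPrefConfig()].
#' @param outDir Output directory (created if needed).
#' @param n Number of molecules to simulate.
#' @param model [PreferenceModel] for the simulation.
#' @param seed Integer seed.
#' @param verbose Log progress to standard error.
#' @return Invisibly, a list of the main in-memory results of the command.
#' @export
cmdSimulate <- function(config = flankPrefConfig(), outDir, n, model,
                        seed = NULL, verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  config <- validateConfig(config)
  pool <- generatePool(n, config, seed = seed)
  outcomes <- simulateMethylation(pool, model,
                                  seed = if (is.null(seed)) NULL else seed + 1L)
  fastq <- file.path(outDir, "reads.fastq")
  nReads <- emitHairpinFastq(pool, outcomes, fastq, config = config,
                             seed = if (is.null(seed)) NULL else seed + 2L)
  writeTruthTable(pool, outcomes, file.path(outDir, "truth.tsv"))
  stopifnot(nReads == poolSize(pool))  # conservation: no silent drops
  writeManifest(file.path(outDir, "manifest.yaml"), config, seed,
                c(molecules = poolSize(pool), reads = nReads,
                  strandEvents = nrow(outcomes)))
  .log(verbose, "simulate: %d molecules -> %s (seed=%s)", nReads, fastq,
       format(if (is.null(seed)) NA else seed))
  invisible(list(pool = pool, outcomes = outcomes, fastq = fastq))
}

#' @rdname cmdSimulate
#' @param fastq Input hairpin FASTQ path.
#' @param topK Top contexts for the position frequency matrix (skipped if
#'   fewer eligible contexts exist).
#' @export
cmdProfile <- function(fastq, config = flankPrefConfig(), outDir,
                       topK = 100L, verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  config <- validateConfig(config)
  res <- processHairpinReads(fastq, config)
  mol <- res$molecules
  utils::write.table(as.data.frame(mol)[, c("readId", "originalTop",
                                            "stateTop", "stateBottom",
                                            "nPairMismatches", "qcPass")],
                     file.path(outDir, "molecules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tables <- splitByDinucleotide(mol, config$contextK, config)
  for (d in names(tables))
    writeContextTable(tables[[d]],
                      file.path(outDir, sprintf("context_%s_k%d.tsv", d,
                                                config$contextK)))
  qc <- tryCatch(estimateConversion(mol, config = config),
                 error = function(e) list(nControl = 0L, nConverted = 0L,
                                          conversionRate = NA_real_))
  main <- centralMotifOfMolecules(mol, config)
  enr <- tryCatch(positionalEnrichment(mol, central = main, config = config),
                  error = function(e) NULL)
  if (!is.null(enr))
    utils::write.table(enr, file.path(outDir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  eligible <- sum(contextCounts(tables[[main]])$nTotal >= config$minCoverage)
  if (eligible >= topK) {
    pfm <- topSiteMatrix(tables[[main]], topK, config$minCoverage)
    utils::write.table(data.frame(base = rownames(pfm), pfm,
                                  check.names = FALSE),
                       file.path(outDir, "pfm.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(plus1Summary(tables), file.path(outDir, "plus1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(metric = c(names(res$counts), "conversionRate"),
               value = c(unname(res$counts), qc$conversionRate)),
    file.path(outDir, "qc.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  counts <- res$counts
  stopifnot(counts[["readsIn"]] ==
              counts[["accepted"]] + counts[["no-linker"]] +
              counts[["truncated-antisense"]] + counts[["arm-mismatch"]])
  writeManifest(file.path(outDir, "manifest.yaml"), config, NULL, counts)
  .log(verbose, "profile: %d reads in, %d accepted, %d qc-pass",
       counts[["readsIn"]], counts[["accepted"]], counts[["qcPass"]])
  invisible(list(molecules = mol, tables = tables, conversion = qc,
                 enrichment = enr, counts = counts))
}

## Most frequent central dinucleotide among qc-passing molecules; "CG" for
## empty input.
centralMotifOfMolecules <- function(mol, config) {
  mol <- mol[mol$qcPass, ]
  if (nrow(mol) == 0L) return("CG")
  off <- centralOffset(config)
  central <- substr(mol$originalTop, off + 1L, off + 2L)
  central <- central[central %in% c("CG", "CA", "CT", "CC")]
  if (!length(central)) return("CG")
  names(sort(table(central), decreasing = TRUE))[1]
}

#' @rdname cmdSimulate
#' @param tableBFile,tableAFile Paths of context tables written by
#'   [writeContextTable()] (enzyme B and enzyme A).
#' @param reference Optional reference site (e.g. `"ATTCGATG"`) for
#'   similarity binning.
#' @param repeatFasta Optional FASTA of repeat sequences for the rank
#'   analysis.
#' @param minCoverage Coverage threshold for the ratio profile.
#' @export
cmdCompare <- function(tableBFile, tableAFile, outDir, reference = NULL,
                       repeatFasta = NULL, minCoverage = 10L,
                       verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tb <- readContextTable(tableBFile)
  ta <- readContextTable(tableAFile)
  ratio <- preferenceRatio(tb, ta, minCoverage)
  ranks <- rankProfile(ratio)
  long <- data.frame(context = names(ratio), ratio = unname(ratio),
                     rank = unname(ranks), stringsAsFactors = FALSE)
  utils::write.table(long, file.path(outDir, "ratio.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rA <- rankProfile(methylationLevels(ta, "smoothed", minCoverage))
  rB <- rankProfile(methylationLevels(tb, "smoothed", minCoverage))
  counts <- c(contexts = length(ratio))
  if (!is.null(reference)) {
    bins <- similarityBins(ratio, reference)
    utils::write.table(bins, file.path(outDir, "bins.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  rep <- NULL
  if (!is.null(repeatFasta)) {
    if (!file.exists(repeatFasta))
      stop("repeat FASTA not found: ", repeatFasta)
    rep <- repeatRankAnalysis(repeatFasta, rA, rB)
    utils::write.table(rep$sites, file.path(outDir, "repeat_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- c(counts, repeatSites = rep$nSites,
                repeatSkipped = rep$nSkipped)
  }
  writeManifest(file.path(outDir, "manifest.yaml"), flankPrefConfig(), NULL,
                counts)
  .log(verbose, "compare: %d shared contexts", length(ratio))
  invisible(list(ratio = ratio, ranks = ranks, repeatReport = rep))
}

#' @rdname cmdSimulate
#' @param cytosineReport Path of a Bismark-style cytosine report.
#' @param genomeFasta Path of the genome FASTA.
#' @param controlChrom Name of the spike-in control contig (QC only;
#'   `NULL` to skip).
#' @export
cmdMethylome <- function(cytosineReport, genomeFasta,
                         config = flankPrefConfig(), outDir,
                         controlChrom = NULL, verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  config <- validateConfig(config)
  rec <- readCytosineReport(cytosineReport)
  qc <- NULL
  if (!is.null(controlChrom)) {
    ctl <- rec[rec$chrom == controlChrom, , drop = FALSE]
    if (sum(ctl$depth) > 0)
      qc <- lambdaConversionQC(ctl, config$conversionBound)
    rec <- rec[rec$chrom != controlChrom, , drop = FALSE]
  }
  summ <- genomicContextSummary(rec, genomeFasta, k = config$contextK,
                                minDepth = config$minDepth)
  for (d in names(summ$tables))
    writeContextTable(summ$tables[[d]],
                      file.path(outDir, sprintf("context_%s_k%d.tsv", d,
                                                config$contextK)))
  utils::write.table(summ$plus1, file.path(outDir, "plus1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(qc))
    utils::write.table(
      data.frame(metric = c("nCalls", "nMethylated", "conversionRate",
                            "belowBound"),
                 value = c(qc$nCalls, qc$nMethylated, qc$conversionRate,
                           as.integer(qc$belowBound))),
      file.path(outDir, "conversion_qc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  used <- nrow(rec) - sum(summ$skipped)
  writeManifest(file.path(outDir, "manifest.yaml"), config, NULL,
                c(records = nrow(rec), used = used, summ$skipped))
  .log(verbose, "methylome: %d records, %d aggregated", nrow(rec), used)
  invisible(list(summary = summ, conversionQC = qc))
}
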