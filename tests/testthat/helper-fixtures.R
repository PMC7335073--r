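## Shared fixtures: everything is built in code at test time.

## Small, fast layout used by most tests.
testConfig <- function(...) {
  flankPrefConfig(flankLen = 4L, contextK = 2L, ...)
}

## Noise-free simulator settings: perfect conversion, no errors, no
## low-quality tails. Under these settings reconstruction must be exact.
perfectConfig <- function(...) {
  testConfig(conversionRate = 1, inappropriateConversion = 0, seqError = 0,
             lowTailFrac = 0, ...)
}

## Assemble a QualityScaledDNAStringSet from sequences + integer qualities.
makeReads <- function(seqs, quals, ids = sprintf("r%02d", seq_along(seqs))) {
  q <- vapply(quals, function(x) rawToChar(as.raw(x + 33L)), character(1))
  r <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(q))
  names(r) <- ids
  r
}

## The noise-free hairpin read of a top strand: sense + linker + bottom
## strand 5'->3' (independent of the package's emitter).
perfectRead <- function(top, cfg) {
  bottom <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(top)))
  paste0(top, cfg$linker, bottom)
}

## Build a reconstructed-molecule table directly from known truth, for
## tests that target downstream statistics rather than the read pipeline.
moleculesFromTruth <- function(tops, stateTop, stateBottom,
                               ids = sprintf("m%03d", seq_along(tops))) {
  S4Vectors::DataFrame(readId = ids, originalTop = tops,
                       stateTop = stateTop, stateBottom = stateBottom,
                       nPairMismatches = 0L, qcPass = TRUE,
                       sense = tops, antisenseOriented = tops,
                       row.names = ids)
}

## Same, from a pool + simulated outcomes (perfect reconstruction truth).
moleculesFromOutcomes <- function(pool, outcomes) {
  oc <- as.data.frame(outcomes)
  ids <- names(topSequences(pool))
  tops <- as.character(topSequences(pool))
  st <- setNames(rep("absent", length(ids)), ids)
  sb <- setNames(rep("absent", length(ids)), ids)
  t <- oc[oc$strand == "top", ]
  st[t$moleculeId] <- ifelse(t$methylated, "methylated", "unmethylated")
  b <- oc[oc$strand == "bottom", ]
  if (nrow(b))
    sb[b$moleculeId] <- ifelse(b$methylated, "methylated", "unmethylated")
  moleculesFromTruth(tops, unname(st[ids]), unname(sb[ids]), ids)
}

## Hand-rolled ContextTable from explicit counts (bypasses the event path).
makeTable <- function(contexts, nTotal, nMeth, central = "CG",
                      k = nchar(contexts[1]) / 2) {
  o <- order(contexts)
  df <- data.frame(context = contexts[o], nTotal = nTotal[o],
                   nMeth = nMeth[o], stringsAsFactors = FALSE)
  df$levelRaw <- ifelse(df$nTotal > 0, df$nMeth / df$nTotal, NA_real_)
  df$levelSmoothed <- (df$nMeth + 0.5) / (df$nTotal + 1)
  new("ContextTable", counts = df, k = as.integer(k), central = central)
}

## All 4^(2k) flank contexts, built independently of the package internals.
allContexts <- function(k) {
  b <- c("A", "C", "G", "T")
  g <- do.call(expand.grid, c(rep(list(b), 2 * k),
                              stringsAsFactors = FALSE))
  sort(do.call(paste0, g))
}

## Independent reverse complement (chartr + string reversal).
rcOracle <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Write a toy genome FASTA + Bismark-style cytosine report; returns paths.
writeToyMethylome <- function(dir, genomeSeqs, records) {
  fa <- file.path(dir, "genome.fa")
  writeLines(unlist(lapply(names(genomeSeqs), function(nm)
    c(paste0(">", nm), genomeSeqs[[nm]]))), fa)
  rep <- file.path(dir, "cytosine_report.tsv")
  utils::write.table(records, rep, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(genome = fa, report = rep)
}
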