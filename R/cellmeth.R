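## Bespoke cellular-methylome computations downstream of a standard
## bisulfite aligner: positional clipping constants, the read-level
## non-conversion filter, exact binomial methylation calling with FDR
## control, spike-in conversion QC, and depth-filtered genomic context
## aggregation into tables comparable with the in-vitro profiles.

#' Read a cytosine report
#'
#' Parses a Bismark-style per-cytosine report: tab-separated columns
#' chromosome, 1-based position of the cytosine, strand (+/-), methylated
#' count, unmethylated count, context class (CpG/CHG/CHH), trinucleotide.
#'
#' @param file Path to the (uncompressed) report.
#' @return data.frame with columns `chrom`, `pos`, `strand`, `methCount`,
#'   `unmethCount`, `contextClass`, `trinucleotide`, plus `depth`.
#' @export
readCytosineReport <- function(file) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "pos", "strand", "methCount", "unmethCount",
                  "contextClass", "trinucleotide"))
  if (nrow(df) && (!all(df$strand %in% c("+", "-")) ||
                   any(df$methCount < 0) || any(df$unmethCount < 0)))
    stop("malformed cytosine report: ", file)
  df$depth <- df$methCount + df$unmethCount
  df
}

#' Read-level bisulfite non-conversion filter
#'
#' A read end carrying `limit` or more methylated cytosines in non-CpG
#' context is assumed to have escaped bisulfite conversion (genuine non-CpG
#' methylation is rare) and is discarded.
#'
#' @param methylated Logical vector: per-cytosine methylation state along
#'   the read.
#' @param contextClass Character vector of the same length: context class
#'   per cytosine ("CpG", "CHG", "CHH"; anything other than "CpG" counts as
#'   non-CpG).
#' @param limit Discard threshold (default 3).
#' @return `TRUE` to keep the read, `FALSE` to discard it.
#' @export
nonconversionReadFilter <- function(methylated, contextClass, limit = 3L) {
  stopifnot(length(methylated) == length(contextClass))
  sum(methylated & contextClass != "CpG") < limit
}

#' Positional clipping rules
#'
#' Number of 5' bases ignored per read of a pair — 4 for read 1, 2 for
#' read 2 — reflecting positional methylation bias at read starts; the
#' companion 3' clip applied to every read is exposed as
#' `threePrimeClip()`.
#'
#' @param readIndex 1 or 2.
#' @return Integer number of bases to ignore.
#' @export
clipPositions <- function(readIndex) {
  if (!readIndex %in% c(1L, 2L)) stop("readIndex must be 1 or 2")
  c(4L, 2L)[readIndex]
}

#' @rdname clipPositions
#' @export
threePrimeClip <- function() 5L

#' Exact binomial significance of methylation at a site
#'
#' Upper-tail probability `P(X >= methCount)` for
#' `X ~ Binomial(depth, errorRate)`, computed by exact summation of the
#' binomial mass — the probability of observing at least the seen number of
#' methylated reads if the site were unmethylated and apparent methylation
#' arose only from bisulfite non-conversion/error at rate `errorRate`.
#'
#' @param methCount Methylated read count (vectorized).
#' @param depth Total read count (>= 1).
#' @param errorRate Null methylation rate, typically the measured spike-in
#'   non-conversion rate; strictly inside (0, 1).
#' @return Numeric vector of p-values.
#' @export
binomialCall <- function(methCount, depth, errorRate) {
  stopifnot(length(errorRate) == 1L, errorRate > 0, errorRate < 1)
  n <- max(length(methCount), length(depth))
  methCount <- rep_len(methCount, n); depth <- rep_len(depth, n)
  if (any(depth < 1L)) stop("depth must be >= 1")
  if (any(methCount < 0L | methCount > depth))
    stop("methCount must satisfy 0 <= methCount <= depth")
  vapply(seq_len(n), function(i) {
    ks <- methCount[i]:depth[i]
    sum(exp(lchoose(depth[i], ks) + ks * log(errorRate) +
              (depth[i] - ks) * log1p(-errorRate)))
  }, numeric(1))
}

#' Binomial methylation calling over a cytosine report
#'
#' Applies [binomialCall()] to every record and controls the false
#' discovery rate by Benjamini-Hochberg. Calls below significance are
#' retained with their p-values, never zeroed.
#'
#' @param records data.frame from [readCytosineReport()] (needs
#'   `methCount`, `depth`).
#' @param errorRate Null rate (e.g. the measured spike-in non-conversion
#'   rate from [lambdaConversionQC()]).
#' @param fdr Benjamini-Hochberg threshold for the `significant` flag.
#' @return `records` with added columns `pValue`, `qValue`, `significant`.
#' @export
callMethylation <- function(records, errorRate, fdr = 0.05) {
  keep <- records$depth >= 1L
  p <- rep(NA_real_, nrow(records))
  p[keep] <- binomialCall(records$methCount[keep], records$depth[keep],
                          errorRate)
  records$pValue <- p
  records$qValue <- p.adjust(p, method = "BH")
  records$significant <- !is.na(records$qValue) & records$qValue <= fdr
  records
}

#' Spike-in bisulfite conversion QC
#'
#' Conversion rate estimated from records of an unmethylated spike-in
#' control genome (classically phage lambda): `1 - sum(methCount) /
#' sum(depth)` over its cytosines. Apparent methylation on the control can
#' only be non-conversion or error, so this bounds the assay's conversion
#' efficiency; a run is flagged when the rate falls below `bound`.
#'
#' @param records data.frame with `methCount` and `depth` (already
#'   restricted to the control genome, e.g. by chromosome name).
#' @param bound Minimal acceptable conversion rate.
#' @return List with `nCalls` (total depth), `nMethylated`,
#'   `conversionRate` and `belowBound` flag.
#' @export
lambdaConversionQC <- function(records, bound = 0.99) {
  tot <- sum(records$depth)
  if (tot == 0) stop("zero control depth; conversion rate undefined")
  met <- sum(records$methCount)
  rate <- 1 - met / tot
  list(nCalls = tot, nMethylated = met, conversionRate = rate,
       belowBound = rate < bound)
}

#' Collapse symmetric CpG strand records
#'
#' Sums the counts of the two records of each symmetric CpG pair (the C at
#' position p on + and the C at position p+1 on -) into one +-strand
#' record. Non-CpG records and unpaired CpG records pass through unchanged.
#'
#' @param records data.frame from [readCytosineReport()].
#' @return Collapsed data.frame.
#' @export
collapseStrands <- function(records) {
  cpg <- records$contextClass == "CpG"
  plus <- records[cpg & records$strand == "+", , drop = FALSE]
  minus <- records[cpg & records$strand == "-", , drop = FALSE]
  key <- function(ch, p) paste(ch, p, sep = ":")
  mKey <- key(minus$chrom, minus$pos - 1L)
  pKey <- key(plus$chrom, plus$pos)
  hit <- match(pKey, mKey)
  paired <- !is.na(hit)
  plus$methCount[paired] <- plus$methCount[paired] +
    minus$methCount[hit[paired]]
  plus$unmethCount[paired] <- plus$unmethCount[paired] +
    minus$unmethCount[hit[paired]]
  plus$depth <- plus$methCount + plus$unmethCount
  orphanMinus <- minus[!seq_len(nrow(minus)) %in% hit[paired], , drop = FALSE]
  out <- rbind(records[!cpg, , drop = FALSE], plus, orphanMinus)
  rownames(out) <- NULL
  out
}

#' Depth-filtered genomic context aggregation
#'
#' Aggregates per-cytosine methylation into flanking-context tables
#' comparable with the in-vitro deep-enzymology profiles: for every record
#' with `depth >= minDepth` the strand-oriented context of half-width `k`
#' is extracted from the genome (reverse-complement window for - strand
#' records), the site's methylation level `methCount/depth` is computed,
#' and sites are averaged per context and per (central dinucleotide,
#' +1 base) cell. Each site contributes once with its level (site-weighted
#' means): `nTotal` counts sites and `nMeth` accumulates their levels, so
#' `levelRaw` is the mean site level and the output is shape-compatible
#' with [buildContextTable()] output for [correlateTables()].
#'
#' @param records data.frame from [readCytosineReport()].
#' @param genome Named [Biostrings::DNAStringSet] (or FASTA path) covering
#'   the record coordinates.
#' @param k Context half-width.
#' @param minDepth Minimum site coverage (default 10).
#' @return List with `tables` (named list of [ContextTable]s per central
#'   dinucleotide), `plus1` (the [plus1Summary()] data.frame), and
#'   `skipped` (named counts: `lowDepth`, `outOfRange`, `withN`).
#' @export
genomicContextSummary <- function(records, genome, k = 3L, minDepth = 10L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  lowDepth <- sum(records$depth < minDepth)
  rec <- records[records$depth >= minDepth, , drop = FALSE]
  chrOK <- rec$chrom %in% names(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))
  inRange <- chrOK & rec$pos - k >= 1L &
    rec$pos + 1L + k <= ifelse(chrOK, lens[rec$chrom], 0L)
  outOfRange <- sum(!inRange)
  rec <- rec[inRange, , drop = FALSE]
  win <- character(nrow(rec))
  for (ch in unique(rec$chrom)) {
    sel <- rec$chrom == ch
    s <- as.character(genome[[ch]])
    ## - strand: the C sits on the reverse strand, genome shows G at pos;
    ## take the window whose reverse complement centers the dinucleotide.
    p <- rec$pos[sel]
    minus <- rec$strand[sel] == "-"
    w <- substr(rep(s, sum(sel)), p - k, p + 1L + k)
    wm <- substr(rep(s, sum(sel)), p - k - 1L, p + k)
    w[minus] <- revcompChar(wm[minus])
    win[sel] <- w
  }
  hasN <- grepl("N", win, fixed = TRUE)
  withN <- sum(hasN)
  rec <- rec[!hasN, , drop = FALSE]; win <- win[!hasN]
  central <- substr(win, k + 1L, k + 2L)
  ctx <- paste0(substr(win, 1L, k), substr(win, k + 3L, 2L * k + 2L))
  lev <- rec$methCount / rec$depth
  tables <- lapply(c(CG = "CG", CA = "CA", CT = "CT", CC = "CC"),
                   function(d) {
    sel <- central == d
    if (!any(sel))
      return(.makeContextTable(character(0), logical(0), k, d))
    f <- factor(ctx[sel])
    nSites <- as.integer(table(f))
    sumLev <- as.numeric(rowsum(lev[sel], f))
    ctxs <- levels(f); o <- order(ctxs)
    df <- data.frame(context = ctxs[o], nTotal = nSites[o],
                     nMeth = sumLev[o], stringsAsFactors = FALSE)
    df$levelRaw <- df$nMeth / df$nTotal
    df$levelSmoothed <- (df$nMeth + 0.5) / (df$nTotal + 1)
    new("ContextTable", counts = df, k = as.integer(k), central = d)
  })
  list(tables = tables, plus1 = plus1Summary(tables),
       skipped = c(lowDepth = lowDepth, outOfRange = outOfRange,
                   withN = withN))
}
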