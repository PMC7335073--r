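## Flanking-sequence preference statistics from reconstructed molecules:
## per-context methylation tables (NNCGNN / NNNCGNNN averages), CpN splits,
## positional base enrichment among methylated events, position frequency
## matrices of the most-preferred sites, +1-base summaries, profile
## correlations and CpN/CpG specificity ratios.

## ---------------------------------------------------------------------------
## Strand events
## ---------------------------------------------------------------------------

## Expand QC-passing molecules into strand-level events: one row per scored
## cytosine, with the flank context read 5'->3' on the strand carrying it.
## Events with undetermined state or an N inside the context window are
## dropped (the molecule-level qcPass already excludes undetermined states).
strandEvents <- function(molecules, k, config = flankPrefConfig()) {
  mol <- as.data.frame(molecules[molecules$qcPass, , drop = FALSE])
  off <- centralOffset(config)          # 0-based central C
  if (k > config$flankLen) stop("k exceeds the available flank length")
  s <- mol$originalTop
  central <- substr(s, off + 1L, off + 2L)
  ctxTop <- paste0(substr(s, off - k + 1L, off),
                   substr(s, off + 3L, off + 2L + k))
  ev <- data.frame(readId = mol$readId, strand = "top", central = central,
                   context = ctxTop,
                   methylated = mol$stateTop == "methylated",
                   stringsAsFactors = FALSE)
  ev <- ev[mol$stateTop %in% c("methylated", "unmethylated"), ]
  isCG <- central == "CG" & mol$stateBottom %in% c("methylated", "unmethylated")
  if (any(isCG)) {
    win <- substr(s[isCG], off - k + 1L, off + 2L + k)
    rc <- revcompChar(win)
    ctxBot <- paste0(substr(rc, 1L, k), substr(rc, k + 3L, 2L * k + 2L))
    evB <- data.frame(readId = mol$readId[isCG], strand = "bottom",
                      central = "CG", context = ctxBot,
                      methylated = mol$stateBottom[isCG] == "methylated",
                      stringsAsFactors = FALSE)
    ev <- rbind(ev, evB)
  }
  ev[!grepl("N", ev$context, fixed = TRUE), , drop = FALSE]
}

.makeContextTable <- function(contexts, methylated, k, central) {
  if (length(contexts)) {
    f <- factor(contexts)
    nTotal <- as.integer(table(f))
    nMeth <- as.integer(rowsum(as.integer(methylated), f))
    ctx <- levels(f)
    o <- order(ctx)
    df <- data.frame(context = ctx[o], nTotal = nTotal[o], nMeth = nMeth[o],
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(context = character(0), nTotal = integer(0),
                     nMeth = integer(0), stringsAsFactors = FALSE)
  }
  df$levelRaw <- ifelse(df$nTotal > 0, df$nMeth / df$nTotal, NA_real_)
  df$levelSmoothed <- (df$nMeth + 0.5) / (df$nTotal + 1)
  new("ContextTable", counts = df, k = as.integer(k), central = central)
}

#' Build a per-context methylation table
#'
#' Tabulates methylation over flanking contexts of half-width `k`: every
#' QC-passing strand event (a scored cytosine on the top or, for CpG
#' targets, bottom strand) contributes once, keyed by its context read
#' 5'->3' on the strand carrying the cytosine (bottom-strand events use the
#' reverse-complement window). This produces the average NNCGNN (`k = 2`) or
#' NNNCGNNN (`k = 3`) methylation levels at the heart of the analysis.
#'
#' @param molecules Output of [reconstructMolecules()].
#' @param k Context half-width (2 or 3 in routine use; any
#'   `k <= flankLen`).
#' @param central Central dinucleotide to score ("CG", "CA", "CT", "CC").
#' @param config Configuration from [flankPrefConfig()].
#' @return A [ContextTable].
#' @export
buildContextTable <- function(molecules, k, central = "CG",
                              config = flankPrefConfig()) {
  ev <- strandEvents(molecules, k, config)
  ev <- ev[ev$central == central, , drop = FALSE]
  .makeContextTable(ev$context, ev$methylated, k, central)
}

#' Split molecules into per-dinucleotide context tables
#'
#' Partitions the scored events of a (possibly mixed-motif) molecule set by
#' their central dinucleotide — CpG, CpA, CpT, CpC — and builds one
#' [ContextTable] per class. Empty tables are returned for absent classes,
#' and the four tables partition the events.
#'
#' @inheritParams buildContextTable
#' @return Named list of four [ContextTable]s (`CG`, `CA`, `CT`, `CC`).
#' @export
splitByDinucleotide <- function(molecules, k, config = flankPrefConfig()) {
  ev <- strandEvents(molecules, k, config)
  out <- lapply(c(CG = "CG", CA = "CA", CT = "CT", CC = "CC"), function(d) {
    sub <- ev[ev$central == d, , drop = FALSE]
    .makeContextTable(sub$context, sub$methylated, k, d)
  })
  out
}

## ---------------------------------------------------------------------------
## ContextTable accessors
## ---------------------------------------------------------------------------

#' @rdname ContextTable-class
#' @export
setMethod("contextCounts", "ContextTable", function(x) x@counts)

#' @rdname ContextTable-class
#' @export
setMethod("flankWidth", "ContextTable", function(x) x@k)

#' @rdname ContextTable-class
#' @export
setMethod("centralDinucleotide", "ContextTable", function(x) x@central)

#' @rdname methylationLevels
#' @export
setMethod("methylationLevels", "ContextTable",
  function(x, estimator = c("raw", "smoothed"), minCoverage = 0L) {
    estimator <- match.arg(estimator)
    cc <- x@counts[x@counts$nTotal >= minCoverage, , drop = FALSE]
    v <- if (estimator == "raw") cc$levelRaw else cc$levelSmoothed
    setNames(v, cc$context)
  })

#' @rdname ContextTable-class
#' @export
setMethod("show", "ContextTable", function(object) {
  cc <- object@counts
  cat(sprintf(
    "ContextTable: %s target, half-width k = %d, %d/%d contexts observed\n",
    object@central, object@k, nrow(cc), contextUniverseSize(object@k)))
  if (nrow(cc))
    cat(sprintf("  %d events, %d methylated (overall level %.3f)\n",
                sum(cc$nTotal), sum(cc$nMeth),
                sum(cc$nMeth) / sum(cc$nTotal)))
})

## ---------------------------------------------------------------------------
## Positional enrichment
## ---------------------------------------------------------------------------

#' Positional base enrichment among methylated events
#'
#' For every flank position the observed/expected base-composition ratio is
#' computed — the frequency of each base at that position among methylated
#' strand events divided by its frequency among all events — and summarized
#' as the population standard deviation of the four ratios. A position that
#' the enzyme reads out shows skewed composition among methylated molecules
#' and hence a large standard deviation; a position it ignores gives ratios
#' near 1 and a standard deviation near 0. Profiles are reported raw and
#' normalized to the maximum across positions.
#'
#' Using the all-event composition (rather than a theoretical 0.25) as the
#' expectation controls for base-composition bias of the synthesized pool.
#'
#' @param molecules Output of [reconstructMolecules()].
#' @param flankWidth Number of flank positions per side to profile
#'   (default: full flank).
#' @param central Central dinucleotide to score.
#' @param config Configuration from [flankPrefConfig()].
#' @return data.frame with one row per position (`-flankWidth`..`-1`,
#'   `+1`..`+flankWidth`): `position`, `rawSD`, `normalized`, `valid`
#'   (FALSE where a base is absent among all events so the ratio is
#'   undefined; such positions are excluded from the normalizing maximum).
#' @export
positionalEnrichment <- function(molecules, flankWidth = NULL,
                                 central = "CG",
                                 config = flankPrefConfig()) {
  if (is.null(flankWidth)) flankWidth <- config$flankLen
  ev <- strandEvents(molecules, flankWidth, config)
  ev <- ev[ev$central == central, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no scored events")
  if (!any(ev$methylated))
    stop("no methylated events; enrichment profile undefined")
  M <- seqToMatrix(ev$context)
  .enrichmentFromMatrix(M, ev$methylated, flankWidth)
}

## Core enrichment computation on a context character matrix; shared with
## the permutation-null helper.
.enrichmentFromMatrix <- function(M, methylated, flankWidth) {
  nPos <- ncol(M)
  rawSD <- numeric(nPos)
  valid <- logical(nPos)
  for (j in seq_len(nPos)) {
    all_f <- tabulate(factor(M[, j], levels = DNA_BASES), nbins = 4L)
    met_f <- tabulate(factor(M[methylated, j], levels = DNA_BASES),
                      nbins = 4L)
    if (any(all_f == 0L)) { rawSD[j] <- NA_real_; valid[j] <- FALSE; next }
    ratio <- (met_f / sum(met_f)) / (all_f / sum(all_f))
    rawSD[j] <- popSD(ratio)
    valid[j] <- TRUE
  }
  mx <- suppressWarnings(max(rawSD[valid]))
  normalized <- if (is.finite(mx) && mx > 0) rawSD / mx else rep(0, nPos)
  data.frame(position = flankPositionLabels(flankWidth), rawSD = rawSD,
             normalized = normalized, valid = valid,
             stringsAsFactors = FALSE)
}

#' Permutation null for the enrichment profile
#'
#' Re-computes the per-position raw enrichment standard deviation after
#' randomly permuting the methylated/unmethylated labels across events,
#' `n` times, and returns the null distribution of the maximum raw SD over
#' positions. Under sequence-independent methylation the observed profile is
#' a draw from this null, so every observed position should fall below its
#' upper quantiles.
#'
#' @inheritParams positionalEnrichment
#' @param n Number of permutations.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`: max-over-positions raw SD per
#'   permutation.
#' @export
enrichmentPermutationNull <- function(molecules, n = 200L, flankWidth = NULL,
                                      central = "CG",
                                      config = flankPrefConfig(),
                                      seed = NULL) {
  if (is.null(flankWidth)) flankWidth <- config$flankLen
  ev <- strandEvents(molecules, flankWidth, config)
  ev <- ev[ev$central == central, , drop = FALSE]
  M <- seqToMatrix(ev$context)
  lab <- ev$methylated
  withSeed(seed, vapply(seq_len(n), function(i) {
    prof <- .enrichmentFromMatrix(M, sample(lab), flankWidth)
    max(prof$rawSD[prof$valid])
  }, numeric(1)))
}

## ---------------------------------------------------------------------------
## Top-site position frequency matrix
## ---------------------------------------------------------------------------

#' Position frequency matrix of the most-preferred contexts
#'
#' Ranks contexts by methylation level (smoothed estimator; ties broken
#' lexicographically for determinism), takes the `topK` best with at least
#' `minCoverage` events, and returns the per-position base frequencies —
#' the matrix behind a sequence logo of the preferred sites. The 50-200
#' most preferred sites are the usual operating range.
#'
#' @param table A [ContextTable].
#' @param topK Number of top contexts (unweighted).
#' @param minCoverage Minimum events per eligible context.
#' @return 4 x 2k matrix of base probabilities (rows A,C,G,T; columns flank
#'   positions); every column sums to 1.
#' @export
topSiteMatrix <- function(table, topK, minCoverage = 10L) {
  stopifnot(is(table, "ContextTable"))
  cc <- table@counts[table@counts$nTotal >= minCoverage, , drop = FALSE]
  if (topK > nrow(cc))
    stop(sprintf("topK = %d exceeds the %d contexts meeting minCoverage",
                 topK, nrow(cc)))
  if (topK < 1L) stop("topK must be >= 1")
  o <- order(-cc$levelSmoothed, cc$context)
  top <- cc$context[o][seq_len(topK)]
  M <- seqToMatrix(top)
  pfm <- apply(M, 2L, function(col)
    tabulate(factor(col, levels = DNA_BASES), nbins = 4L) / length(col))
  dimnames(pfm) <- list(DNA_BASES, flankPositionLabels(table@k))
  pfm
}

## ---------------------------------------------------------------------------
## Correlation, +1 summaries, CpN specificity
## ---------------------------------------------------------------------------

#' Pearson correlation of two context tables
#'
#' Correlates the raw methylation levels of the contexts shared by two
#' tables, restricted to contexts with at least `minCoverage` events in
#' both. This is the replicate/enzyme comparison statistic for NNNCGNNN
#' profiles.
#'
#' @param t1,t2 [ContextTable]s of identical half-width.
#' @param minCoverage Minimum events per context in both tables.
#' @return List with `estimate` (Pearson r) and `nContexts` (shared rows
#'   used).
#' @export
correlateTables <- function(t1, t2, minCoverage = 10L) {
  stopifnot(is(t1, "ContextTable"), is(t2, "ContextTable"))
  if (t1@k != t2@k) stop("tables have different half-widths")
  l1 <- methylationLevels(t1, "raw", minCoverage)
  l2 <- methylationLevels(t2, "raw", minCoverage)
  shared <- intersect(names(l1), names(l2))
  if (length(shared) < 3L)
    stop("fewer than 3 shared contexts meet the coverage threshold")
  x <- l1[shared]; y <- l2[shared]
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in one table; correlation undefined")
  list(estimate = cor(x, y), nContexts = length(shared))
}

#' Mean methylation by central dinucleotide and +1 base
#'
#' Event-weighted mean methylation level for each (central dinucleotide,
#' +1 flanking base) cell — the first base 3' of the target dinucleotide
#' being the key specificity determinant. Cells with no events are reported
#' as `NA`.
#'
#' @param tables A [ContextTable] or (typically) the named list produced by
#'   [splitByDinucleotide()].
#' @return data.frame with columns `central`, `plus1`, `nEvents`, `level`
#'   (sum of methylated events over sum of events).
#' @export
plus1Summary <- function(tables) {
  if (is(tables, "ContextTable")) tables <- setNames(list(tables),
                                                     tables@central)
  out <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    stopifnot(is(tb, "ContextTable"))
    cc <- tb@counts
    p1 <- if (nrow(cc)) substr(cc$context, tb@k + 1L, tb@k + 1L)
          else character(0)
    res <- lapply(DNA_BASES, function(b) {
      sel <- p1 == b
      n <- sum(cc$nTotal[sel]); m <- sum(cc$nMeth[sel])
      data.frame(central = nm, plus1 = b, nEvents = n,
                 level = if (n > 0) m / n else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  do.call(rbind, out)
}

#' CpN/CpG specificity ratios
#'
#' Per-context ratio of non-CpG to CpG methylation (smoothed levels), for
#' CpA/CpG and CpT/CpG (optionally CpC/CpG), with the median ratio as the
#' global specificity summary. Contexts missing from either table are
#' skipped and counted.
#'
#' @param tables Named list of [ContextTable]s containing at least `CG` and
#'   one of `CA`, `CT`, `CC` (e.g. from [splitByDinucleotide()]).
#' @param numerators Which non-CpG classes to ratio against CG.
#' @param minCoverage Minimum events per context in both tables.
#' @return Named list, one entry per numerator class: list with `ratios`
#'   (data.frame context, ratio), `median`, `nSkipped`.
#' @export
cpnSpecificity <- function(tables, numerators = c("CA", "CT"),
                           minCoverage = 0L) {
  stopifnot("CG" %in% names(tables))
  cg <- methylationLevels(tables$CG, "smoothed", minCoverage)
  out <- lapply(numerators, function(d) {
    lv <- methylationLevels(tables[[d]], "smoothed", minCoverage)
    shared <- intersect(names(lv), names(cg))
    skipped <- length(union(names(lv), names(cg))) - length(shared)
    ratio <- lv[shared] / cg[shared]
    list(ratios = data.frame(context = shared, ratio = unname(ratio),
                             stringsAsFactors = FALSE),
         median = if (length(ratio)) median(ratio) else NA_real_,
         nSkipped = skipped)
  })
  names(out) <- numerators
  out
}
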