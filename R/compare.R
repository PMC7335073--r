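## Enzyme-versus-enzyme comparison: normalized preference ratios (the "B/A
## preference"), deterministic context rankings, similarity-to-motif
## binning, and strand-resolved CpG-site rank analysis of repeat sequences.

#' Normalized enzyme-versus-enzyme preference ratio
#'
#' Computes, per shared context, the ratio of the two enzymes' normalized
#' methylation profiles: each table's smoothed levels are first divided by
#' that table's mean level over the shared eligible contexts (so each
#' profile has mean 1, making the ratio invariant to overall activity and
#' exposure differences between experiments), then divided element-wise.
#' With a DNMT3B table as `tableB` and a DNMT3A table as `tableA` this is
#' the B/A preference: values above 1 mark DNMT3B-favored contexts.
#'
#' @param tableB,tableA [ContextTable]s of identical half-width and central
#'   dinucleotide.
#' @param minCoverage Minimum events per context in both tables.
#' @return Named numeric vector (the ratio profile), lexicographic context
#'   order, all values finite and positive.
#' @export
preferenceRatio <- function(tableB, tableA, minCoverage = 10L) {
  stopifnot(is(tableB, "ContextTable"), is(tableA, "ContextTable"))
  if (tableB@k != tableA@k || tableB@central != tableA@central)
    stop("tables must share half-width and central dinucleotide")
  lb <- methylationLevels(tableB, "smoothed", minCoverage)
  la <- methylationLevels(tableA, "smoothed", minCoverage)
  shared <- sort(intersect(names(lb), names(la)))
  if (!length(shared))
    stop("tables share no contexts at the coverage threshold")
  nb <- lb[shared] / mean(lb[shared])
  na <- la[shared] / mean(la[shared])
  nb / na
}

#' Rank a preference profile
#'
#' Deterministic descending ranking: rank 1 is the most preferred context
#' (largest value), ties are broken lexicographically by context name.
#'
#' @param profile Named numeric vector (e.g. from [preferenceRatio()] or
#'   [methylationLevels()]); values must be finite.
#' @return Named integer vector of ranks — a permutation of
#'   `1..length(profile)` — in the same order as `profile`.
#' @export
rankProfile <- function(profile) {
  if (!length(profile)) stop("cannot rank an empty profile")
  if (any(!is.finite(profile))) stop("profile values must be finite")
  o <- order(-profile, names(profile))
  r <- integer(length(profile))
  r[o] <- seq_along(profile)
  setNames(r, names(profile))
}

#' Closed-form similarity bin sizes
#'
#' Number of length-`2k` contexts sharing exactly `m` of their `2k` flank
#' positions with a reference: `choose(2k, m) * 3^(2k - m)`. For `k = 3`
#' (bins 0..6) the sizes are 729, 1458, 1215, 540, 135, 18, 1.
#'
#' @param k Context half-width.
#' @return Integer vector indexed by bins `0..2k`.
#' @export
similarityBinSizes <- function(k) {
  m <- 0:(2L * k)
  setNames(as.integer(choose(2L * k, m) * 3^(2L * k - m)), m)
}

#' Bin a preference profile by similarity to a reference site
#'
#' Groups contexts by how many of their flank positions match a reference
#' site (for NNNCGNNN profiles, the 6 flank positions of an 8-mer such as
#' the SatII consensus ATTCGATG; the central CG matches by construction and
#' is not counted) and summarizes the preference values of every bin by
#' median and first/third quartile. A monotone trend across bins shows
#' adaptation of the enzyme toward the reference motif.
#'
#' @param profile Named numeric vector over the complete context universe
#'   (e.g. a B/A preference from [preferenceRatio()]).
#' @param reference Reference site as a `2k+2`-mer with central CG (e.g.
#'   `"ATTCGATG"`), or a bare `2k`-mer of flanks.
#' @return data.frame with one row per bin `0..2k`: `bin`, `count`,
#'   `median`, `q1`, `q3`.
#' @export
similarityBins <- function(profile, reference) {
  if (!length(profile)) stop("empty profile")
  k <- unique(nchar(names(profile))) / 2
  if (length(k) != 1L || k != as.integer(k))
    stop("profile names must be equal-length 2k contexts")
  k <- as.integer(k)
  if (nchar(reference) == 2L * k + 2L) {
    if (substr(reference, k + 1L, k + 2L) != "CG")
      stop("reference must carry a central CG")
    reference <- paste0(substr(reference, 1L, k),
                        substr(reference, k + 3L, 2L * k + 2L))
  }
  if (nchar(reference) != 2L * k || !grepl("^[ACGT]+$", reference))
    stop("malformed reference context")
  refv <- strsplit(reference, "")[[1]]
  M <- seqToMatrix(names(profile))
  matches <- rowSums(M == matrix(refv, nrow = nrow(M), ncol = 2L * k,
                                 byrow = TRUE))
  bins <- 0:(2L * k)
  out <- lapply(bins, function(b) {
    v <- profile[matches == b]
    data.frame(bin = b, count = length(v),
               median = if (length(v)) median(v) else NA_real_,
               q1 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
               q3 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_)
  })
  do.call(rbind, out)
}

#' Enumerate CpG sites of a sequence with both strand contexts
#'
#' Finds every CG dinucleotide on the forward strand of each input sequence
#' and extracts the flanking context of the cytosine on both strands (the
#' reverse-strand context is the reverse complement window, since a CpG is
#' self-symmetric). Sites closer than `k` bases to a sequence end are
#' skipped and counted, unless `circular = TRUE`, in which case contexts
#' wrap around (satellite consensus monomers are tandem repeats).
#'
#' @param sequences A [Biostrings::DNAStringSet] (or named character
#'   vector).
#' @param k Context half-width.
#' @param circular Treat each sequence as circular.
#' @return List with `sites` (data.frame: `seqName`, `position` 1-based
#'   position of the forward-strand C, `fwdContext`, `revContext`) and
#'   `nSkipped` (edge sites dropped).
#' @export
countCpGSites <- function(sequences, k = 3L, circular = FALSE) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  nm <- if (!is.null(names(sequences))) names(sequences)
        else sprintf("seq%d", seq_along(sequences))
  allSites <- list(); nSkipped <- 0L
  for (i in seq_along(sequences)) {
    s <- as.character(sequences[[i]])
    len <- nchar(s)
    if (len < 2L) next
    pos <- gregexpr("(?=CG)", s, perl = TRUE)[[1]]
    if (length(pos) == 1L && pos[1] == -1L) next
    pos <- as.integer(pos)
    if (circular) {
      ext <- paste0(substr(s, len - k + 1L, len), s, substr(s, 1L, k))
      win <- substr(rep(ext, length(pos)), pos, pos + 2L * k + 1L)
      keep <- rep(TRUE, length(pos))
    } else {
      keep <- pos - k >= 1L & pos + 1L + k <= len
      nSkipped <- nSkipped + sum(!keep)
      win <- substr(rep(s, sum(keep)), pos[keep] - k, pos[keep] + 1L + k)
      pos <- pos[keep]
    }
    if (!any(keep)) next
    fwd <- paste0(substr(win, 1L, k), substr(win, k + 3L, 2L * k + 2L))
    rcwin <- revcompChar(win)
    rev <- paste0(substr(rcwin, 1L, k), substr(rcwin, k + 3L, 2L * k + 2L))
    allSites[[length(allSites) + 1L]] <-
      data.frame(seqName = nm[i], position = pos, fwdContext = fwd,
                 revContext = rev, stringsAsFactors = FALSE)
  }
  sites <- if (length(allSites)) do.call(rbind, allSites)
           else data.frame(seqName = character(0), position = integer(0),
                           fwdContext = character(0),
                           revContext = character(0))
  list(sites = sites, nSkipped = nSkipped)
}

#' Strand-resolved rank analysis of repeat CpG sites
#'
#' For every CpG site of the input sequences, looks up the rank of both
#' strand contexts in each enzyme's preference ranking and keeps, per
#' enzyme, the better (smaller) rank — only the more preferred DNA strand is
#' considered, because maintenance methylation in cells propagates a mark
#' regardless of which strand received it first. Reports per-site chosen
#' ranks, per-enzyme median ranks, and the median-rank ratio
#' `medianA / medianB`: a high ratio means the sites rank much better
#' (smaller) under enzyme B, i.e. the repeat is B-preferred.
#'
#' @param sequences Repeat sequences ([Biostrings::DNAStringSet], named
#'   character vector, or a FASTA file path).
#' @param ranksA,ranksB Named integer rank tables from [rankProfile()],
#'   built on the full context universe at the same half-width.
#' @param circular Treat sequences as circular monomers.
#' @return List with `sites` (data.frame: site coordinates, both contexts,
#'   `rankA`, `rankB`), `medianRankA`, `medianRankB`,
#'   `rankRatio` (= medianA / medianB), `nSites`, `nSkipped`.
#' @export
repeatRankAnalysis <- function(sequences, ranksA, ranksB, circular = FALSE) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  k <- unique(nchar(names(ranksA))) / 2
  if (length(k) != 1L) stop("rank table contexts must have equal length")
  k <- as.integer(k)
  if (!identical(sort(names(ranksA)), sort(names(ranksB))))
    stop("the two rank tables must cover the same contexts")
  enum <- countCpGSites(sequences, k = k, circular = circular)
  sites <- enum$sites
  nSkipped <- enum$nSkipped
  if (nrow(sites)) {
    ok <- sites$fwdContext %in% names(ranksA) &
      sites$revContext %in% names(ranksA)
    nSkipped <- nSkipped + sum(!ok)
    sites <- sites[ok, , drop = FALSE]
  }
  if (nrow(sites) == 0L)
    return(list(sites = sites, medianRankA = NA_real_,
                medianRankB = NA_real_, rankRatio = NA_real_, nSites = 0L,
                nSkipped = nSkipped))
  sites$rankA <- unname(pmin(ranksA[sites$fwdContext],
                             ranksA[sites$revContext]))
  sites$rankB <- unname(pmin(ranksB[sites$fwdContext],
                             ranksB[sites$revContext]))
  medA <- median(sites$rankA); medB <- median(sites$rankB)
  list(sites = sites, medianRankA = medA, medianRankB = medB,
       rankRatio = medA / medB, nSites = nrow(sites), nSkipped = nSkipped)
}
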