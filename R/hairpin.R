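## Hairpin bisulfite read processing: quality trimming, full-length molecule
## selection, duplex reconstruction, and conversion QC.
##
## A hairpin read carries both strands of one substrate duplex:
##
##     5'-[ sense = bisulfite(top strand) ][ linker ][ antisense ]-3'
##
## where the antisense segment is the bisulfite image of the bottom strand
## read 5'->3' from the hairpin, i.e. the bottom strand traversed 3'->5'
## along the duplex. Reversing the antisense segment (no complementation)
## aligns it with the sense segment position-by-position: at duplex position
## i the pair (sense[i], orientedAntisense[i]) is (top image, bottom image)
## of one base pair, which resolves bisulfite ambiguity: a T paired with G
## was an unmethylated C, a C paired with G was a methylated C, and
## symmetrically on the bottom strand.

#' Read hairpin FASTQ reads
#'
#' @param file FASTQ path (Sanger Phred+33).
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
readHairpinFastq <- function(file) {
  ## Biostrings warns about dropping the (unused) mcols it attaches itself.
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file))
}

#' Trim low-quality 3' ends
#'
#' Removes from each read the longest suffix in which every base has a
#' quality below `qmin`; nothing else changes, so internal low-quality bases
#' are retained and the operation is idempotent.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param qmin Quality threshold (bases with quality >= `qmin` stop the
#'   trim).
#' @return The trimmed reads (possibly zero-width).
#' @export
trimQuality <- function(reads, qmin = 20L) {
  stopifnot(qmin >= 0)
  if (length(reads) == 0L) return(reads)
  w <- Biostrings::width(reads)
  if (length(unique(w)) == 1L) {
    ## equal widths: one matrix scan instead of a per-read loop
    qm <- as(Biostrings::quality(reads), "matrix")
    ok <- qm >= qmin
    keep <- max.col(cbind(TRUE, ok), ties.method = "last") - 1L
  } else {
    qs <- as(Biostrings::quality(reads), "IntegerList")
    keep <- vapply(qs, function(q) {
      ok <- which(q >= qmin)
      if (length(ok)) ok[length(ok)] else 0L
    }, integer(1))
  }
  suppressWarnings(IRanges::narrow(reads, start = 1L, width = keep))
}

## Bisulfite image of an anchor as it appears on the antisense segment as
## read (5'->3' from the hairpin): reverse complement of the duplex-oriented
## top sequence spanning it.
.antisenseAnchor <- function(topAnchor) revcompChar(topAnchor)

#' Select full-length hairpin molecules
#'
#' Checks each (quality-trimmed) read against the designed fixed layout:
#' the C-free linker must sit exactly between two full-length segments, and
#' the four arm anchors (5' and 3' arm on the sense segment, their reverse
#' complements on the antisense segment) must match with at most
#' `config$anchorMismatch` mismatches each. Anchor comparison is
#' bisulfite-aware: a read T matches a reference C, since unmethylated
#' anchor cytosines convert. Reads failing any check are rejected with a
#' typed reason, never silently dropped.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] (or
#'   `DNAStringSet`).
#' @param config Configuration from [flankPrefConfig()].
#' @return A [S4Vectors::DataFrame] with one row per read: `readId`,
#'   `accepted` (logical), `reason` ("ok", "no-linker",
#'   "truncated-antisense", "arm-mismatch"), and for accepted reads the
#'   `sense` and `antisense` segment sequences (as read, 5'->3').
#' @export
selectFullLength <- function(reads, config = flankPrefConfig()) {
  D <- designedLength(config)
  lk <- nchar(config$linker)
  ids <- if (!is.null(names(reads))) names(reads)
         else sprintf("read%06d", seq_along(reads))
  s <- as.character(reads)
  n <- length(s)
  w <- nchar(s)
  reason <- rep("ok", n)
  ## linker must be present in full at its designed position
  linkWin <- substr(s, D + 1L, D + lk)
  noLinker <- w < D + lk |
    bisulfiteHamming(linkWin, config$linker) > config$anchorMismatch
  reason[noLinker] <- "no-linker"
  ## both segments must have the full designed length
  short <- !noLinker & w < 2L * D + lk
  reason[short] <- "truncated-antisense"
  ## arm anchors, bisulfite-aware
  a5 <- config$arm5; a3 <- config$arm3
  n5 <- nchar(a5); n3 <- nchar(a3)
  cand <- reason == "ok"
  if (any(cand)) {
    sc <- s[cand]
    mm <- bisulfiteHamming(substr(sc, 1L, n5), a5) > config$anchorMismatch |
      bisulfiteHamming(substr(sc, D - n3 + 1L, D), a3) > config$anchorMismatch |
      bisulfiteHamming(substr(sc, D + lk + 1L, D + lk + n3),
                       .antisenseAnchor(a3)) > config$anchorMismatch |
      bisulfiteHamming(substr(sc, D + lk + D - n5 + 1L, D + lk + D),
                       .antisenseAnchor(a5)) > config$anchorMismatch
    reason[cand][mm] <- "arm-mismatch"
  }
  acc <- reason == "ok"
  sense <- ifelse(acc, substr(s, 1L, D), NA_character_)
  antisense <- ifelse(acc, substr(s, D + lk + 1L, D + lk + D), NA_character_)
  S4Vectors::DataFrame(readId = ids, accepted = acc, reason = reason,
                       sense = sense, antisense = antisense)
}

## The six legal (sense, oriented-antisense) base pairs of the
## reconstruction decision table, mapping to the original top-strand base;
## all other ordered pairs are pair-mismatches.
.pairTopBase <- c(AT = "A", TA = "T", GC = "G", GT = "G", CG = "C", TG = "C")

#' Reconstruct original duplexes from hairpin segments
#'
#' Applies the per-position decision table to the sense segment and the
#' oriented antisense segment (antisense reversed so position i is the
#' bottom-strand base at duplex position i):
#' (A,T) -> top A; (T,A) -> top T; (G,C) -> top G, bottom C methylated;
#' (G,T) -> top G, bottom C unmethylated; (C,G) -> top C methylated;
#' (T,G) -> top C unmethylated. Any other pair is a pair-mismatch: the
#' position is masked with N and counted. The methylation states of the two
#' target cytosines are read off the central positions.
#'
#' @param sense,antisense Character vectors of equal-length segments as
#'   returned by [selectFullLength()] (`antisense` as read; it is
#'   re-oriented internally).
#' @param config Configuration (supplies the central offset and the
#'   `maxPairMismatch` QC limit).
#' @param readId Optional read identifiers.
#' @return A [S4Vectors::DataFrame] with one row per molecule: `readId`,
#'   `originalTop` (reconstructed top strand, N at masked positions),
#'   `stateTop` and `stateBottom` ("methylated", "unmethylated",
#'   "undetermined"; `stateBottom` is "absent" for non-CpG targets),
#'   `nPairMismatches`, `qcPass`, plus the aligned `sense` and
#'   `antisenseOriented` strings used for conversion QC.
#' @export
reconstructMolecules <- function(sense, antisense,
                                 config = flankPrefConfig(),
                                 readId = NULL) {
  stopifnot(length(sense) == length(antisense))
  n <- length(sense)
  if (is.null(readId)) readId <- sprintf("read%06d", seq_len(n))
  if (n == 0L)
    return(S4Vectors::DataFrame(
      readId = character(0), originalTop = character(0),
      stateTop = character(0), stateBottom = character(0),
      nPairMismatches = integer(0), qcPass = logical(0),
      sense = character(0), antisenseOriented = character(0)))
  if (any(nchar(sense) != nchar(antisense)))
    stop("sense and antisense segments must have equal length")
  D <- unique(nchar(sense))
  if (length(D) != 1L)
    stop("all segments must share the designed length")
  if (D != designedLength(config))
    stop("segment length does not match the designed duplex length")
  anti <- reverseChar(antisense)
  S <- seqToMatrix(sense)
  A <- seqToMatrix(anti)
  pair <- matrix(paste0(S, A), nrow = n)
  top <- matrix(.pairTopBase[pair], nrow = n)
  nMis <- rowSums(is.na(top))
  top[is.na(top)] <- "N"
  orig <- matrixToSeq(top)

  cC <- centralOffset(config) + 1L   # 1-based column of the top central C
  cG <- cC + 1L                      # partner position (G for CpG targets)
  stateTop <- rep("undetermined", n)
  stateTop[pair[, cC] == "CG"] <- "methylated"
  stateTop[pair[, cC] == "TG"] <- "unmethylated"
  partnerBase <- top[, cG]
  stateBottom <- rep("undetermined", n)
  stateBottom[partnerBase %in% c("A", "C", "T")] <- "absent"  # non-CpG target
  isCpG <- partnerBase == "G"
  stateBottom[isCpG & pair[, cG] == "GC"] <- "methylated"
  stateBottom[isCpG & pair[, cG] == "GT"] <- "unmethylated"

  qc <- nMis <= config$maxPairMismatch &
    stateTop != "undetermined" & stateBottom != "undetermined"
  S4Vectors::DataFrame(readId = readId, originalTop = orig,
                       stateTop = stateTop, stateBottom = stateBottom,
                       nPairMismatches = as.integer(nMis), qcPass = qc,
                       sense = sense, antisenseOriented = anti)
}

#' Full hairpin processing pipeline for a FASTQ file
#'
#' Chains [trimQuality()], [selectFullLength()] and
#' [reconstructMolecules()], and tallies rejection reasons.
#'
#' @param fastq Path to a hairpin FASTQ file.
#' @param config Configuration from [flankPrefConfig()].
#' @return A list with `molecules` (the [reconstructMolecules()] output for
#'   accepted reads), `selection` (per-read acceptance table) and `counts`
#'   (named vector: reads in, accepted, one entry per rejection reason,
#'   qcPass).
#' @export
processHairpinReads <- function(fastq, config = flankPrefConfig()) {
  reads <- readHairpinFastq(fastq)
  trimmed <- trimQuality(reads, config$qmin)
  sel <- selectFullLength(trimmed, config)
  acc <- sel[sel$accepted, ]
  mol <- reconstructMolecules(acc$sense, acc$antisense, config,
                              readId = acc$readId)
  reasons <- table(factor(sel$reason,
    levels = c("ok", "no-linker", "truncated-antisense", "arm-mismatch")))
  counts <- c(readsIn = length(reads), accepted = sum(sel$accepted),
              `no-linker` = unname(reasons[["no-linker"]]),
              `truncated-antisense` = unname(reasons[["truncated-antisense"]]),
              `arm-mismatch` = unname(reasons[["arm-mismatch"]]),
              qcPass = sum(mol$qcPass))
  list(molecules = mol, selection = sel, counts = counts)
}

#' Control positions for conversion QC
#'
#' Positions (1-based, duplex coordinates) of fixed-arm cytosines on either
#' strand: top-strand arm Cs and bottom-strand arm Cs (i.e. top-strand arm
#' Gs). These are guaranteed unmethylated — the enzyme only sees the central
#' target — so every one of them measures bisulfite conversion. Flank
#' cytosines are deliberately excluded: flank CpG/CpH sites can be genuine
#' enzymatic targets.
#'
#' @param config Configuration from [flankPrefConfig()].
#' @return Integer vector of control positions.
#' @export
armControlPositions <- function(config = flankPrefConfig()) {
  D <- designedLength(config)
  n5 <- nchar(config$arm5)
  a5 <- strsplit(config$arm5, "")[[1]]
  a3 <- strsplit(config$arm3, "")[[1]]
  pos5 <- which(a5 %in% c("C", "G"))
  pos3 <- (D - nchar(config$arm3)) + which(a3 %in% c("C", "G"))
  sort(c(pos5, pos3))
}

#' Estimate bisulfite conversion from reconstructed molecules
#'
#' Over the QC-passing molecules, classifies each control-position cytosine
#' as converted (read as T) or unconverted (read as C): for a top-strand
#' control C the sense base decides, for a bottom-strand control C (a
#' top-strand G) the oriented antisense base decides. The conversion rate is
#' converted / total.
#'
#' @param molecules Output of [reconstructMolecules()].
#' @param controlPositions Integer positions, typically
#'   [armControlPositions()].
#' @param config Configuration (identifies the reference arm bases).
#' @return A list with `nControl`, `nConverted` and `conversionRate`.
#' @export
estimateConversion <- function(molecules,
                               controlPositions = armControlPositions(config),
                               config = flankPrefConfig()) {
  mol <- molecules[molecules$qcPass, ]
  D <- designedLength(config)
  refTop <- rep(NA_character_, D)
  a5 <- strsplit(config$arm5, "")[[1]]
  a3 <- strsplit(config$arm3, "")[[1]]
  refTop[seq_along(a5)] <- a5
  refTop[(D - length(a3) + 1L):D] <- a3
  nConv <- 0L; nTot <- 0L
  for (p in controlPositions) {
    ref <- refTop[p]
    if (is.na(ref) || !ref %in% c("C", "G")) next
    b <- if (ref == "C") substr(mol$sense, p, p)
         else substr(mol$antisenseOriented, p, p)
    nConv <- nConv + sum(b == "T")
    nTot <- nTot + sum(b %in% c("C", "T"))
  }
  if (nTot == 0L)
    stop("no control cytosine observations; conversion rate undefined")
  list(nControl = nTot, nConverted = nConv, conversionRate = nConv / nTot)
}
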