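#' @import methods
NULL

## ---------------------------------------------------------------------------
## Preference models
## ---------------------------------------------------------------------------

#' Preference models for simulated enzymatic methylation
#'
#' A `PreferenceModel` maps a flanking-sequence context to the probability
#' that the enzyme methylates the target cytosine on one strand in one
#' reaction. It is the simulator's ground truth against which downstream
#' parameter recovery is judged. Two concrete models are provided:
#' [lookupModel()] (an explicit context-to-probability table, optionally with
#' a default) and [positionalModel()] (a base rate multiplied by independent
#' per-position, per-base weights, clamped to `[0, 1]`).
#'
#' @slot k Context half-width the model is defined on (0 for a constant
#'   model).
#' @name PreferenceModel-class
#' @aliases PreferenceModel
#' @exportClass PreferenceModel
setClass("PreferenceModel", representation("VIRTUAL", k = "integer"))

#' @rdname PreferenceModel-class
#' @slot probs Named numeric vector of methylation probabilities, one per
#'   length-`2k` context.
#' @slot default Probability used for contexts absent from `probs`
#'   (`NA` means no default: missing contexts are an error).
#' @exportClass LookupModel
setClass("LookupModel", contains = "PreferenceModel",
  representation(probs = "numeric", default = "numeric"),
  validity = function(object) {
    p <- c(object@probs, object@default)
    p <- p[!is.na(p)]
    if (any(p < 0 | p > 1))
      return("all probabilities must be in [0, 1]")
    if (object@k > 0L && length(object@probs) &&
        any(nchar(names(object@probs)) != 2L * object@k))
      return("context names must have length 2k")
    n <- contextUniverseSize(object@k)
    if (is.na(object@default) && length(object@probs) < n)
      return(sprintf(
        "lookup without default must cover all %d contexts (has %d)",
        n, length(object@probs)))
    TRUE
  })

#' @rdname PreferenceModel-class
#' @slot baseRate Methylation probability of a context with unit weights.
#' @slot weights 4 x 2k matrix of multiplicative weights; rows A,C,G,T,
#'   columns flank positions -k..-1,+1..+k.
#' @exportClass PositionalModel
setClass("PositionalModel", contains = "PreferenceModel",
  representation(baseRate = "numeric", weights = "matrix"),
  validity = function(object) {
    if (object@baseRate < 0 || object@baseRate > 1)
      return("baseRate must be in [0, 1]")
    if (!identical(rownames(object@weights), DNA_BASES))
      return("weights rows must be A, C, G, T")
    if (ncol(object@weights) != 2L * object@k)
      return("weights must have 2k columns")
    if (any(object@weights < 0))
      return("weights must be nonnegative")
    TRUE
  })

## ---------------------------------------------------------------------------
## Substrate pool
## ---------------------------------------------------------------------------

#' Pool of randomized-flank methylation substrates
#'
#' A `SubstratePool` holds the top strands of a set of double-stranded
#' substrates in which a central target dinucleotide (CpG, CpA, CpT or CpC)
#' is flanked on both sides by `flankLen` random nucleotides, themselves
#' embedded between fixed primer arms. All molecules of a pool share the
#' same arms, linker and layout; only the flanks differ.
#'
#' @slot sequences [Biostrings::DNAStringSet] of full-length top strands
#'   (5' arm + left flank + central dinucleotide + right flank + 3' arm),
#'   named by molecule id.
#' @slot flankLen Number of randomized bases on each side of the target.
#' @slot centralMotif Target dinucleotide, one of CG, CA, CT, CC.
#' @slot arm5,arm3 Fixed primer arms (top strand 5' and 3').
#' @slot linker Hairpin linker sequence (C-free so it is invariant under
#'   bisulfite conversion and usable as an anchor).
#'
#' @seealso [generatePool()], [simulateMethylation()], [emitHairpinFastq()]
#' @name SubstratePool-class
#' @aliases SubstratePool
#' @exportClass SubstratePool
setClass("SubstratePool",
  representation(sequences = "DNAStringSet", flankLen = "integer",
                 centralMotif = "character", arm5 = "character",
                 arm3 = "character", linker = "character"),
  validity = function(object) {
    if (!object@centralMotif %in% c("CG", "CA", "CT", "CC"))
      return("centralMotif must start with C and be one of CG, CA, CT, CC")
    if (object@flankLen < 0L)
      return("flankLen must be >= 0")
    L <- nchar(object@arm5) + nchar(object@arm3) + 2L * object@flankLen + 2L
    if (length(object@sequences) &&
        !all(Biostrings::width(object@sequences) == L))
      return("all top strands must have the designed duplex length")
    if (length(object@sequences)) {
      off <- nchar(object@arm5) + object@flankLen  # 0-based central offset
      central <- substr(as.character(object@sequences), off + 1L, off + 2L)
      if (!all(central == object@centralMotif))
        return("central dinucleotide must equal centralMotif in every molecule")
    }
    if (grepl("C", object@linker, fixed = TRUE))
      return("linker must be C-free (bisulfite-invariant anchor)")
    TRUE
  })

## ---------------------------------------------------------------------------
## Context table
## ---------------------------------------------------------------------------

#' Per-context methylation count table
#'
#' A `ContextTable` summarizes strand-level methylation events by their
#' flanking-sequence context: for every observed length-`2k` flank context it
#' records the number of scored events, the number methylated, and the
#' methylation level under two estimators — the raw fraction `m/n` (used for
#' reporting) and the smoothed fraction `(m + 0.5)/(n + 1)` (used wherever a
#' ratio or rank is subsequently taken, so that empty or extreme rows stay
#' finite).
#'
#' @slot counts data.frame with columns `context`, `nTotal`, `nMeth`,
#'   `levelRaw`, `levelSmoothed`, one row per observed context, sorted
#'   lexicographically.
#' @slot k Context half-width.
#' @slot central Central target dinucleotide the events share.
#'
#' @seealso [buildContextTable()], [correlateTables()], [preferenceRatio()]
#' @name ContextTable-class
#' @aliases ContextTable
#' @exportClass ContextTable
setClass("ContextTable",
  representation(counts = "data.frame", k = "integer", central = "character"),
  validity = function(object) {
    need <- c("context", "nTotal", "nMeth", "levelRaw", "levelSmoothed")
    if (!all(need %in% names(object@counts)))
      return(paste("counts must have columns:", paste(need, collapse = ", ")))
    cc <- object@counts
    if (any(cc$nMeth < 0 | cc$nMeth > cc$nTotal))
      return("0 <= nMeth <= nTotal violated")
    if (nrow(cc) && any(nchar(cc$context) != 2L * object@k))
      return("context strings must have length 2k")
    if (anyDuplicated(cc$context))
      return("duplicate context rows")
    TRUE
  })
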