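#' Methylation probability of contexts under a preference model
#'
#' @param model A [PreferenceModel].
#' @param contexts Character vector of flank contexts. Contexts may be wider
#'   than the model's own half-width `k`; the central `2k` window is used.
#' @return Numeric vector of probabilities in `[0, 1]`, one per context.
#' @export
setGeneric("methylationProb", function(model, contexts)
  standardGeneric("methylationProb"))

#' @describeIn SubstratePool-class Number of molecules in the pool.
#' @param x,object A `SubstratePool`.
#' @export
setGeneric("poolSize", function(x) standardGeneric("poolSize"))

#' @describeIn SubstratePool-class Top strands as a
#'   [Biostrings::DNAStringSet].
#' @export
setGeneric("topSequences", function(x) standardGeneric("topSequences"))

#' @describeIn SubstratePool-class Flank length of the design.
#' @export
setGeneric("flankLen", function(x) standardGeneric("flankLen"))

#' @describeIn SubstratePool-class Central target dinucleotide.
#' @export
setGeneric("centralMotif", function(x) standardGeneric("centralMotif"))

#' Strand-oriented flanking contexts of pool molecules
#'
#' Extracts, for every molecule, the flank context of half-width `k` read
#' 5'->3' on the requested strand. The bottom-strand context is the reverse
#' complement of the corresponding top-strand window and exists only for CpG
#' targets (no symmetric cytosine otherwise).
#'
#' @param x A [SubstratePool].
#' @param k Context half-width (`k <= flankLen(x)`).
#' @param strand `"top"` or `"bottom"`.
#' @return Named character vector of length-`2k` contexts.
#' @export
setGeneric("strandContexts", function(x, k, strand = "top")
  standardGeneric("strandContexts"))

#' @describeIn ContextTable-class The per-context count data.frame.
#' @param x,object A `ContextTable`.
#' @export
setGeneric("contextCounts", function(x) standardGeneric("contextCounts"))

#' @describeIn ContextTable-class Context half-width `k`.
#' @export
setGeneric("flankWidth", function(x) standardGeneric("flankWidth"))

#' @describeIn ContextTable-class Central dinucleotide of the scored events.
#' @export
setGeneric("centralDinucleotide", function(x)
  standardGeneric("centralDinucleotide"))

#' Methylation levels of a context table
#'
#' @param x A [ContextTable].
#' @param estimator `"raw"` for `m/n` or `"smoothed"` for `(m+0.5)/(n+1)`.
#' @param minCoverage Drop contexts with fewer than this many events.
#' @return Named numeric vector of levels, lexicographic context order.
#' @export
setGeneric("methylationLevels",
  function(x, estimator = c("raw", "smoothed"), minCoverage = 0L)
    standardGeneric("methylationLevels"))
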