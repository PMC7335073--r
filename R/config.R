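## Pipeline configuration: a validated named list, round-tripped through YAML.

.configDefaults <- list(
  ## substrate layout
  arm5            = "ACGTCCAGTTGGATCACTGA",  # fixed 5' primer arm (top strand)
  arm3            = "TCAGGATCCTGAACTGGTCA",  # fixed 3' primer arm (top strand)
  linker          = "GATTAGGA",              # hairpin linker; must be C-free
  flankLen        = 10L,                     # randomized bases per side
  centralMotif    = "CG",
  ## simulation rates
  conversionRate  = 0.998,   # P(unmethylated C read as T)
  inappropriateConversion = 0.002,  # P(methylated C read as T)
  seqError        = 0.001,   # per-base substitution rate
  qualHigh        = 37L,     # Phred of ordinary bases
  qualLow         = 10L,     # Phred of low-quality 3' tails
  lowTailFrac     = 0.05,    # fraction of reads carrying a low-quality tail
  lowTailMaxLen   = 6L,      # maximal tail length
  ## read processing
  qmin            = 20L,     # 3' quality-trim threshold
  anchorMismatch  = 1L,      # Hamming tolerance per anchor (arms, linker)
  maxPairMismatch = 1L,      # masked positions tolerated per molecule
  ## profiling
  contextK        = 3L,      # default context half-width (NNNCGNNN)
  minCoverage     = 10L,     # events per context for ranking/correlation
  ## cellular methylome
  minDepth        = 10L,     # site coverage threshold for aggregation
  conversionBound = 0.99,    # QC bound on spike-in conversion rate
  fdr             = 0.05     # Benjamini-Hochberg threshold for calls
)

.configDomains <- list(
  flankLen = c(0, Inf), conversionRate = c(0, 1),
  inappropriateConversion = c(0, 1), seqError = c(0, 1),
  qualHigh = c(0, 93), qualLow = c(0, 93), lowTailFrac = c(0, 1),
  lowTailMaxLen = c(0, Inf), qmin = c(0, Inf), anchorMismatch = c(0, Inf),
  maxPairMismatch = c(0, Inf), contextK = c(1, Inf), minCoverage = c(0, Inf),
  minDepth = c(1, Inf), conversionBound = c(0, 1), fdr = c(0, 1)
)

#' Pipeline configuration
#'
#' Builds the validated configuration list used by the simulator, the hairpin
#' read processor and the profiling stages. Call with no arguments for the
#' defaults; named arguments override individual entries. Unknown keys are
#' rejected, every threshold is checked against its documented domain, and
#' the substrate layout invariants (DNA-only arms, C-free linker, central
#' motif starting with C) are enforced.
#'
#' @param ... Named overrides of the default entries.
#' @return Named list with class `"flankPrefConfig"`.
#' @examples
#' cfg <- flankPrefConfig(flankLen = 4L, seqError = 0)
#' cfg$flankLen
#' @export
flankPrefConfig <- function(...) {
  over <- list(...)
  cfg <- .configDefaults
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  }
  validateConfig(cfg)
}

#' @rdname flankPrefConfig
#' @param cfg A configuration list to validate.
#' @export
validateConfig <- function(cfg) {
  unknown <- setdiff(names(cfg), names(.configDefaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(.configDefaults), names(cfg))
  if (length(missing))
    stop("missing configuration key(s): ", paste(missing, collapse = ", "))
  for (nm in names(.configDomains)) {
    v <- cfg[[nm]]
    dom <- .configDomains[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < dom[1] || v > dom[2])
      stop(sprintf("configuration key '%s' must be a number in [%s, %s]",
                   nm, dom[1], dom[2]))
  }
  for (nm in c("flankLen", "qualHigh", "qualLow", "lowTailMaxLen", "qmin",
               "anchorMismatch", "maxPairMismatch", "contextK", "minCoverage",
               "minDepth"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  for (nm in c("arm5", "arm3", "linker")) {
    s <- cfg[[nm]]
    if (!is.character(s) || length(s) != 1L || !grepl("^[ACGT]+$", s))
      stop(sprintf("configuration key '%s' must be a non-empty A/C/G/T string", nm))
  }
  if (grepl("C", cfg$linker, fixed = TRUE))
    stop("linker must be C-free so it is invariant under bisulfite conversion")
  if (!cfg$centralMotif %in% c("CG", "CA", "CT", "CC"))
    stop("centralMotif must be one of CG, CA, CT, CC")
  if (cfg$contextK > cfg$flankLen)
    stop("contextK cannot exceed flankLen")
  structure(cfg, class = "flankPrefConfig")
}

#' @rdname flankPrefConfig
#' @param file Path of a YAML configuration file.
#' @export
readConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  base <- .configDefaults
  for (nm in intersect(names(cfg), names(base))) base[[nm]] <- cfg[[nm]]
  unknown <- setdiff(names(cfg), names(.configDefaults))
  if (length(unknown))
    stop("unknown configuration key(s) in ", file, ": ",
         paste(unknown, collapse = ", "))
  validateConfig(base)
}

#' @rdname flankPrefConfig
#' @export
writeConfig <- function(cfg, file) {
  cfg <- validateConfig(cfg)
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' @rdname flankPrefConfig
#' @export
showConfig <- function(cfg = flankPrefConfig()) {
  cat(yaml::as.yaml(unclass(validateConfig(cfg))))
  invisible(cfg)
}

## Designed duplex (= sense segment) length for a config.
designedLength <- function(cfg) {
  nchar(cfg$arm5) + nchar(cfg$arm3) + 2L * cfg$flankLen + 2L
}

## 0-based offset of the central cytosine on the top strand.
centralOffset <- function(cfg) {
  nchar(cfg$arm5) + cfg$flankLen
}
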