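## Synthetic substrate pools, enzymatic methylation under a known preference
## model, and hairpin bisulfite read emission. This module is the testable
## stand-in for the wet-lab stages of the deep-enzymology workflow: pool
## synthesis with randomized flanks, single-turnover methylation, hairpin
## ligation, bisulfite conversion and sequencing.

## ---------------------------------------------------------------------------
## Preference model constructors and methods
## ---------------------------------------------------------------------------

#' Construct preference models
#'
#' `lookupModel()` builds an explicit context-to-probability table;
#' `constantModel()` is the sequence-independent special case;
#' `positionalModel()` multiplies a base rate by independent per-position,
#' per-base weights (clamped to `[0, 1]`); `randomPreferenceModel()` draws a
#' reproducible random positional model, used as ground truth in
#' parameter-recovery experiments. Log-normal weights give such a model a
#' clearly separated most-preferred context, mimicking the graded but
#' structured preferences of real DNA methyltransferases.
#'
#' @param probs Named numeric vector: methylation probability per
#'   length-`2k` context.
#' @param default Probability for contexts absent from `probs`; `NA` (the
#'   default) makes missing contexts an error.
#' @param k Context half-width.
#' @param p Constant methylation probability.
#' @param baseRate Probability scale of the positional model.
#' @param weights 4 x 2k numeric matrix (rows A,C,G,T).
#' @param sdlog Log-normal standard deviation of the random weights.
#' @param seed Integer seed for the random draw.
#' @return A [PreferenceModel] object.
#' @examples
#' m <- constantModel(0.3)
#' methylationProb(m, c("ACGT", "TTTT"))
#' @export
lookupModel <- function(probs, default = NA_real_, k = NULL) {
  if (is.null(k)) {
    if (!length(probs)) stop("k must be given for an empty lookup")
    k <- as.integer(nchar(names(probs)[1]) / 2L)
  }
  new("LookupModel", k = as.integer(k), probs = probs,
      default = as.numeric(default))
}

#' @rdname lookupModel
#' @export
constantModel <- function(p) {
  new("LookupModel", k = 0L, probs = setNames(numeric(0), character(0)),
      default = as.numeric(p))
}

#' @rdname lookupModel
#' @export
positionalModel <- function(baseRate, weights, k = ncol(weights) / 2L) {
  new("PositionalModel", k = as.integer(k), baseRate = as.numeric(baseRate),
      weights = weights)
}

#' @rdname lookupModel
#' @export
randomPreferenceModel <- function(k, baseRate = 0.35, sdlog = 0.4,
                                  seed = NULL) {
  withSeed(seed, {
    w <- matrix(exp(rnorm(4L * 2L * k, mean = 0, sd = sdlog)), nrow = 4L,
                dimnames = list(DNA_BASES, flankPositionLabels(k)))
    positionalModel(baseRate, w, k)
  })
}

## Central 2k window of possibly wider contexts.
.centerContext <- function(contexts, k) {
  w <- nchar(contexts)
  if (any(w < 2L * k))
    stop("contexts narrower than the model's half-width")
  half <- w / 2L
  paste0(substr(contexts, half - k + 1L, half),
         substr(contexts, half + 1L, half + k))
}

#' @rdname methylationProb
#' @export
setMethod("methylationProb", "LookupModel", function(model, contexts) {
  if (model@k == 0L)
    return(rep(model@default, length(contexts)))
  ctx <- .centerContext(contexts, model@k)
  p <- unname(model@probs[ctx])
  miss <- is.na(p)
  if (any(miss)) {
    if (is.na(model@default))
      stop("context(s) missing from defaultless lookup model: ",
           paste(unique(ctx[miss])[seq_len(min(5, sum(miss)))], collapse = ", "))
    p[miss] <- model@default
  }
  p
})

#' @rdname methylationProb
#' @export
setMethod("methylationProb", "PositionalModel", function(model, contexts) {
  if (!length(contexts)) return(numeric(0))
  ctx <- .centerContext(contexts, model@k)
  m <- seqToMatrix(ctx)
  p <- rep(model@baseRate, length(ctx))
  for (j in seq_len(ncol(m)))
    p <- p * model@weights[m[, j], j]
  pmin(pmax(unname(p), 0), 1)
})

setMethod("show", "PreferenceModel", function(object) {
  cat(sprintf("%s preference model, half-width k = %d\n",
              class(object), object@k))
  if (is(object, "LookupModel"))
    cat(sprintf("  %d explicit contexts, default = %s\n",
                length(object@probs), format(object@default)))
  if (is(object, "PositionalModel"))
    cat(sprintf("  base rate %.3f, weight range [%.3f, %.3f]\n",
                object@baseRate, min(object@weights), max(object@weights)))
})

## ---------------------------------------------------------------------------
## Pool generation
## ---------------------------------------------------------------------------

#' Generate a pool of randomized-flank substrates
#'
#' Draws `n` double-stranded substrate molecules whose top strand is
#' 5' arm + left flank + central dinucleotide + right flank + 3' arm, with
#' every flank base i.i.d. uniform over A/C/G/T — the in-silico image of a
#' synthesized oligonucleotide pool in which the target site sits in a
#' random sequence context.
#'
#' @param n Number of molecules (>= 0).
#' @param config Configuration from [flankPrefConfig()]; supplies the fixed
#'   arms, linker, flank length and central motif.
#' @param flankLen,centralMotif Optional overrides of the config values.
#' @param seed Integer seed; a fixed seed gives a byte-identical pool.
#' @return A [SubstratePool].
#' @examples
#' pool <- generatePool(5, config = flankPrefConfig(flankLen = 3L), seed = 1)
#' poolSize(pool)
#' @export
generatePool <- function(n, config = flankPrefConfig(), flankLen = NULL,
                         centralMotif = NULL, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("n must be a nonnegative count")
  n <- as.integer(n)
  if (!is.null(flankLen)) config$flankLen <- as.integer(flankLen)
  if (!is.null(centralMotif)) config$centralMotif <- centralMotif
  config <- validateConfig(config)
  if (substr(config$centralMotif, 1L, 1L) != "C")
    stop("centralMotif must start with C (the scored cytosine)")
  f <- config$flankLen
  seqs <- withSeed(seed, {
    if (n == 0L || f == 0L) {
      flanksL <- rep("", n); flanksR <- rep("", n)
    } else {
      m <- matrix(sample(DNA_BASES, n * 2L * f, replace = TRUE), nrow = n)
      flanksL <- matrixToSeq(m[, seq_len(f), drop = FALSE])
      flanksR <- matrixToSeq(m[, f + seq_len(f), drop = FALSE])
    }
    paste0(config$arm5, flanksL, config$centralMotif, flanksR, config$arm3)
  })
  if (n == 0L) seqs <- character(0)
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- sprintf("mol%06d", seq_len(n))
  new("SubstratePool", sequences = dss, flankLen = f,
      centralMotif = config$centralMotif, arm5 = config$arm5,
      arm3 = config$arm3, linker = config$linker)
}

#' @rdname SubstratePool-class
#' @export
setMethod("poolSize", "SubstratePool", function(x) length(x@sequences))

#' @rdname SubstratePool-class
#' @export
setMethod("topSequences", "SubstratePool", function(x) x@sequences)

#' @rdname SubstratePool-class
#' @export
setMethod("flankLen", "SubstratePool", function(x) x@flankLen)

#' @rdname SubstratePool-class
#' @export
setMethod("centralMotif", "SubstratePool", function(x) x@centralMotif)

#' @rdname SubstratePool-class
#' @export
setMethod("show", "SubstratePool", function(object) {
  cat(sprintf(
    "SubstratePool: %d molecules, %s target, %d-nt random flanks\n",
    poolSize(object), object@centralMotif, object@flankLen))
  cat(sprintf("  arms %d/%d nt, linker %s, duplex length %d\n",
              nchar(object@arm5), nchar(object@arm3), object@linker,
              nchar(object@arm5) + nchar(object@arm3) +
                2L * object@flankLen + 2L))
})

#' @rdname strandContexts
#' @export
setMethod("strandContexts", "SubstratePool",
  function(x, k, strand = "top") {
    strand <- match.arg(strand, c("top", "bottom"))
    k <- as.integer(k)
    if (k < 1L || k > x@flankLen)
      stop("k must be between 1 and flankLen")
    if (strand == "bottom" && x@centralMotif != "CG")
      stop("bottom-strand target context exists only for CG substrates")
    off <- nchar(x@arm5) + x@flankLen  # 0-based central C offset
    s <- as.character(x@sequences)
    if (strand == "top") {
      ctx <- paste0(substr(s, off - k + 1L, off),
                    substr(s, off + 3L, off + 2L + k))
    } else {
      win <- substr(s, off - k + 1L, off + 2L + k)
      rc <- revcompChar(win)
      ctx <- paste0(substr(rc, 1L, k), substr(rc, k + 3L, 2L * k + 2L))
    }
    setNames(ctx, names(x@sequences))
  })

## ---------------------------------------------------------------------------
## Enzymatic methylation
## ---------------------------------------------------------------------------

#' Simulate enzymatic methylation of a substrate pool
#'
#' Models one round of de novo methylation as a single Bernoulli event per
#' eligible strand-site: for every molecule the top-strand target cytosine
#' is methylated with probability `model(context)`, where the context is
#' read 5'->3' on the top strand; for CpG substrates the symmetric
#' bottom-strand cytosine is drawn independently, conditioned on its own
#' (reverse-complement) strand context. Non-CpG targets have no symmetric
#' cytosine, so only top-strand outcomes exist.
#'
#' @param pool A [SubstratePool].
#' @param model A [PreferenceModel] covering every context in the pool.
#' @param seed Integer seed.
#' @return A [S4Vectors::DataFrame] with one row per strand-site:
#'   `moleculeId`, `strand` ("top"/"bottom"), `context` (full-flank-width
#'   strand context) and `methylated` (logical).
#' @export
simulateMethylation <- function(pool, model, seed = NULL) {
  stopifnot(is(pool, "SubstratePool"), is(model, "PreferenceModel"))
  if (model@k > pool@flankLen)
    stop("model half-width exceeds the pool's flank length")
  n <- poolSize(pool)
  kFull <- max(pool@flankLen, 1L)
  hasBottom <- pool@centralMotif == "CG" && pool@flankLen >= 1L
  if (pool@flankLen == 0L) {
    ctxTop <- rep("", n)
    strands <- rep("top", n)
    ids <- names(pool@sequences)
    ctx <- ctxTop
  } else {
    ctxTop <- strandContexts(pool, kFull, "top")
    if (hasBottom) {
      ctxBot <- strandContexts(pool, kFull, "bottom")
      ids <- c(names(ctxTop), names(ctxBot))
      strands <- rep(c("top", "bottom"), each = n)
      ctx <- c(unname(ctxTop), unname(ctxBot))
    } else {
      ids <- names(ctxTop)
      strands <- rep("top", n)
      ctx <- unname(ctxTop)
    }
  }
  p <- methylationProb(model, ctx)
  meth <- withSeed(seed, runif(length(p)) < p)
  S4Vectors::DataFrame(moleculeId = ids, strand = strands, context = ctx,
                       methylated = meth)
}

## ---------------------------------------------------------------------------
## Hairpin read emission
## ---------------------------------------------------------------------------

## Bisulfite image of a character matrix of strand sequences: every C is
## converted to T with the probability appropriate to its methylation state.
## methCols: n-vector of the column index (or NA) of the single potentially
## methylated C per row; methState: logical n-vector.
.bisulfiteMatrix <- function(m, methCols, methState, conversionRate,
                             inappropriateConversion) {
  if (nrow(m) == 0L) return(m)
  isC <- m == "C"
  pConv <- matrix(0, nrow(m), ncol(m))
  pConv[isC] <- conversionRate
  sel <- !is.na(methCols) & methState
  if (any(sel))
    pConv[cbind(which(sel), methCols[sel])] <- inappropriateConversion
  conv <- isC & (matrix(runif(length(m)), nrow(m)) < pConv)
  m[conv] <- "T"
  m
}

#' Emit hairpin bisulfite-converted FASTQ reads
#'
#' Turns a pool plus simulated strand methylation outcomes into one
#' sequencing read per molecule, emulating hairpin ligation followed by
#' bisulfite conversion: the sense segment is the bisulfite image of the top
#' strand, the C-free linker follows, and the antisense segment is the
#' bisulfite image of the bottom strand read 5'->3' through the hairpin
#' (i.e. the bottom strand traversed 3'->5' along the duplex). Unmethylated
#' cytosines convert to T with probability `conversionRate`; methylated
#' cytosines convert (inappropriately) with probability
#' `inappropriateConversion`. Substitution sequencing errors are applied at
#' rate `seqError`; base qualities are constant high, with a configurable
#' fraction of low-quality 3' tails to exercise quality trimming.
#'
#' @param pool A [SubstratePool].
#' @param outcomes Outcomes from [simulateMethylation()].
#' @param file FASTQ output path (Sanger Phred+33).
#' @param conversionRate,inappropriateConversion,seqError Probabilities;
#'   defaults from `config`.
#' @param config Configuration list (quality model, linker).
#' @param seed Integer seed.
#' @return Invisibly, the number of reads written (= number of molecules).
#' @export
emitHairpinFastq <- function(pool, outcomes, file,
                             conversionRate = config$conversionRate,
                             inappropriateConversion = config$inappropriateConversion,
                             seqError = config$seqError,
                             config = flankPrefConfig(), seed = NULL) {
  stopifnot(is(pool, "SubstratePool"))
  for (p in c(conversionRate, inappropriateConversion, seqError))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("conversion and error rates must be probabilities in [0, 1]")
  n <- poolSize(pool)
  ids <- names(pool@sequences)
  topMeth <- setNames(rep(FALSE, n), ids)
  botMeth <- setNames(rep(FALSE, n), ids)
  oc <- as.data.frame(outcomes)
  t <- oc[oc$strand == "top", ]
  topMeth[t$moleculeId] <- t$methylated
  b <- oc[oc$strand == "bottom", ]
  if (nrow(b)) botMeth[b$moleculeId] <- b$methylated

  off <- nchar(pool@arm5) + pool@flankLen   # 0-based top central C offset
  L <- if (n) unique(Biostrings::width(pool@sequences)) else 0L
  linkerChars <- strsplit(pool@linker, "")[[1]]

  res <- withSeed(seed, {
    M <- seqToMatrix(as.character(pool@sequences))
    ## sense: top strand, central C at column off+1
    sense <- .bisulfiteMatrix(M, rep(off + 1L, n), unname(topMeth[ids]),
                              conversionRate, inappropriateConversion)
    ## bottom strand 5'->3' = revcomp(top); its target C (CG only) pairs the
    ## top G at column off+2, i.e. bottom column L - (off+2) + 1.
    B <- seqToMatrix(revcompChar(as.character(pool@sequences)))
    botCol <- if (pool@centralMotif == "CG") rep(L - off - 1L, n)
              else rep(NA_integer_, n)
    anti <- .bisulfiteMatrix(B, botCol, unname(botMeth[ids]),
                             conversionRate, inappropriateConversion)
    reads <- cbind(sense,
                   matrix(rep(linkerChars, each = n), nrow = n),
                   anti)
    ## substitution errors anywhere in the read
    if (seqError > 0 && length(reads)) {
      err <- matrix(runif(length(reads)) < seqError, nrow = n)
      if (any(err)) {
        idx <- which(err)
        shift <- sample(1:3, length(idx), replace = TRUE)
        cur <- match(reads[idx], DNA_BASES)
        reads[idx] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
      }
    }
    W <- ncol(reads)
    quals <- matrix(config$qualHigh, nrow = n, ncol = W)
    if (config$lowTailFrac > 0 && n > 0L) {
      hasTail <- runif(n) < config$lowTailFrac
      tailLen <- ifelse(hasTail,
                        sample(seq_len(max(config$lowTailMaxLen, 1L)), n,
                               replace = TRUE), 0L)
      for (i in which(tailLen > 0L))
        quals[i, (W - tailLen[i] + 1L):W] <- config$qualLow
    }
    list(seq = matrixToSeq(reads),
         qual = if (n) apply(quals, 1L, function(q)
                  rawToChar(as.raw(q + 33L))) else character(0))
  })

  con <- file(file, open = "wt")
  on.exit(close(con))
  if (n > 0L) {
    out <- character(4L * n)
    out[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
    out[seq(2L, by = 4L, length.out = n)] <- res$seq
    out[seq(3L, by = 4L, length.out = n)] <- "+"
    out[seq(4L, by = 4L, length.out = n)] <- res$qual
    writeLines(out, con)
  }
  invisible(n)
}

#' Write / read the simulator truth table
#'
#' The truth table records, per molecule, the designed top strand and the
#' simulated methylation state of each strand target — the ground truth that
#' downstream reconstruction is checked against.
#'
#' @param pool A [SubstratePool].
#' @param outcomes Outcomes from [simulateMethylation()].
#' @param file Tab-separated output path.
#' @return Invisibly, `file` (write) or the truth data.frame (read).
#' @export
writeTruthTable <- function(pool, outcomes, file) {
  n <- poolSize(pool)
  ids <- names(pool@sequences)
  oc <- as.data.frame(outcomes)
  topMeth <- setNames(rep(NA, n), ids)
  botMeth <- setNames(rep(NA, n), ids)
  t <- oc[oc$strand == "top", ]; topMeth[t$moleculeId] <- t$methylated
  b <- oc[oc$strand == "bottom", ]; if (nrow(b)) botMeth[b$moleculeId] <- b$methylated
  df <- data.frame(moleculeId = ids,
                   topSequence = as.character(pool@sequences),
                   methTop = unname(topMeth[ids]),
                   methBottom = unname(botMeth[ids]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}
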