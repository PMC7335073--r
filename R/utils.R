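# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom methods is new validObject slot
#' @importFrom stats cor median quantile runif rbinom setNames sd p.adjust
NULL

## Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Reverse complement for plain character vectors (vectorized).
revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Reverse (no complement) for plain character vectors.
reverseChar <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

## Character matrix (one column per position) from equal-width strings.
seqToMatrix <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0L, ncol = 0L))
  w <- unique(nchar(x))
  if (length(w) != 1L)
    stop("sequences must have equal width")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = w, byrow = TRUE)
}

matrixToSeq <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## Hamming distance of read windows against a reference anchor, treating a read
## T as matching a reference C (bisulfite image of an unmethylated anchor).
bisulfiteHamming <- function(windows, ref) {
  refv <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(windows)
  d <- integer(n)
  for (i in seq_along(refv)) {
    b <- substr(windows, i, i)
    ok <- b == refv[i] | (refv[i] == "C" & b == "T")
    d <- d + as.integer(!ok)
  }
  d
}

## All 4^(2k) flank contexts, lexicographically ordered.
contextUniverse <- function(k) {
  stopifnot(k >= 1L)
  g <- expand.grid(rep(list(DNA_BASES), 2L * k), stringsAsFactors = FALSE)
  ## expand.grid varies the first factor fastest; reorder so the first
  ## position is the slowest, giving lexicographic order.
  ctx <- do.call(paste0, rev(g))
  sort(ctx)
}

#' Size of the flanking-context universe
#'
#' Number of distinct flank contexts at half-width `k`: four bases at each of
#' the `2k` flanking positions, i.e. `4^(2k)`. At `k = 3` (NNNCGNNN sites)
#' this is 4096.
#'
#' @param k Context half-width (number of flanking bases on each side).
#' @return Integer count of possible contexts.
#' @examples
#' contextUniverseSize(3)  # 4096
#' @export
contextUniverseSize <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  as.integer(4^(2 * k))
}

## Population (divide-by-n) standard deviation.
popSD <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

## Position labels -k..-1, +1..+k used throughout.
flankPositionLabels <- function(k) {
  c(paste0("-", k:1), paste0("+", 1:k))
}
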