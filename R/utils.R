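#' @import methods
#' @importFrom stats quantile cor median rnorm runif setNames phyper plogis sd
#' @importFrom utils read.delim write.table combn head
NULL

PAIR_SEP <- "|"

#' Canonical ordering of pair identifiers
#'
#' Unordered pairs (isoform pairs, gene pairs) are stored once, under
#' lexicographic order of their two identifiers. `canonicalPair()` sorts the
#' two id vectors elementwise; `pairKey()` additionally joins them with a
#' `"|"` separator into a single key string used to index feature tables and
#' networks.
#'
#' @param a,b character vectors of identifiers (recycled to common length).
#' @return `canonicalPair()`: a list with elements `a` and `b` (elementwise
#'   sorted so `a <= b`); `pairKey()`: a character vector of keys.
#' @examples
#' pairKey("NM_2", "NM_1")  # "NM_1|NM_2"
#' @export
canonicalPair <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
  }
  swap <- b < a
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  list(a = lo, b = hi)
}

#' @rdname canonicalPair
#' @export
pairKey <- function(a, b) {
  p <- canonicalPair(a, b)
  paste(p$a, p$b, sep = PAIR_SEP)
}

## inverse of pairKey()
splitPairKey <- function(key) {
  parts <- strsplit(key, PAIR_SEP, fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed pair key: ", key[which(bad)[1L]])
  list(a = vapply(parts, `[`, "", 1L), b = vapply(parts, `[`, "", 2L))
}

## Uniform sample of `n` unordered pairs (i < j) from a universe of `nItems`
## items, by linear pair index.  Exhaustive when the universe is small.
samplePairIndices <- function(nItems, n, exclude = integer(0)) {
  nPairs <- as.double(nItems) * (nItems - 1) / 2
  if (nPairs > .Machine$integer.max)
    stop("pair universe too large to index")
  nPairs <- as.integer(nPairs)
  avail <- nPairs - length(exclude)
  if (avail < n) n <- avail
  if (n <= 0L) return(integer(0))
  if (length(exclude)) {
    keep <- setdiff(seq_len(nPairs), exclude)
    keep[sample.int(length(keep), n)]
  } else {
    sample.int(nPairs, n)
  }
}

## linear pair index (1-based, (1,2),(1,3),...,(1,n),(2,3),...) -> (i, j)
pairIndexToIJ <- function(idx, nItems) {
  offs <- c(0, cumsum(seq(nItems - 1L, 1L)))
  i <- findInterval(idx - 1L, offs)
  j <- idx - offs[i] + i
  list(i = as.integer(i), j = as.integer(j))
}

ijToPairIndex <- function(i, j, nItems) {
  swap <- j < i
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  offs <- c(0, cumsum(seq(nItems - 1L, 1L)))
  as.integer(offs[i] + (j - i))
}

## Run `expr` under a temporary RNG state seeded with `seed` (NULL = leave
## the global stream alone).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## derive a stream of child seeds from one seed, all < 2^31
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

isOneString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
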