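AA_ORDER <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Canonical physicochemical property triple used by the sequence-order
## terms of the pseudo-amino-acid composition: hydrophobicity,
## hydrophilicity (Hopp-Woods) and side-chain mass.
.PSEAAC_RAW <- rbind(
  hydrophobicity = c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                     E = -0.74, Q = -0.85, G = 0.48, H = -0.40, I = 1.38,
                     L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                     S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08),
  hydrophilicity = c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
                     E = 3.0, Q = 0.2, G = 0.0, H = -0.5, I = -1.8,
                     L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
                     S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
  sideChainMass = c(A = 15.0, R = 101.0, N = 58.0, D = 59.0, C = 47.0,
                    E = 73.0, Q = 72.0, G = 1.0, H = 82.0, I = 57.0,
                    L = 57.0, K = 73.0, M = 75.0, F = 91.0, P = 42.0,
                    S = 31.0, T = 45.0, W = 130.0, Y = 107.0, V = 43.0))

#' Physicochemical property tables behind the PseAAC descriptor
#'
#' @param normalized if `TRUE` (default) each property is standardized to
#'   zero mean and unit (population) standard deviation over the 20 amino
#'   acids, as used in the sequence-order correlation terms; `FALSE`
#'   returns the raw literature values.
#' @return a 3 x 20 numeric matrix (properties x amino acids).
#' @export
pseaacProperties <- function(normalized = TRUE) {
  m <- .PSEAAC_RAW[, AA_ORDER]
  if (!normalized) return(m)
  t(apply(m, 1L, function(h) (h - mean(h)) / sqrt(mean((h - mean(h))^2))))
}

#' Pseudo-amino-acid composition of a protein sequence
#'
#' Computes the classic composition/sequence-order descriptor: the first 20
#' entries are proportional to amino-acid frequencies, the last `lambda`
#' entries to weighted tier-1..tier-lambda sequence-order correlation
#' factors computed from three standardized physicochemical properties
#' (hydrophobicity, hydrophilicity, side-chain mass). The vector is
#' normalized to sum to 1:
#' \deqn{x_u = f_u / (1 + w \sum\theta), \quad
#'       x_{20+\tau} = w \theta_\tau / (1 + w \sum\theta)}
#' with \eqn{\theta_\tau} the mean squared property difference between
#' residues `tau` positions apart.
#'
#' @param sequence a single amino-acid sequence (character or
#'   `AAString`-coercible) over the 20 standard residues.
#' @param lambda number of sequence-order tiers (default 10); the sequence
#'   must be longer than `lambda`.
#' @param w weight of the sequence-order terms (default 0.05).
#' @param nonStandard `"skip"` (default; drop non-standard residues with a
#'   warning) or `"error"`.
#' @return numeric vector of length `20 + lambda`, named
#'   `A, R, ..., V, theta1, ...`; entries are non-negative and sum to 1.
#' @examples
#' pseAAC("AAAA", lambda = 0)  # pure composition: 1 at A
#' @export
pseAAC <- function(sequence, lambda = 10L, w = 0.05,
                   nonStandard = c("skip", "error")) {
  nonStandard <- match.arg(nonStandard)
  s <- toupper(as.character(sequence))
  if (length(s) != 1L) stop("one sequence at a time")
  res <- strsplit(s, "")[[1L]]
  bad <- !(res %in% AA_ORDER)
  if (any(bad)) {
    if (nonStandard == "error")
      stop("non-standard residue(s): ",
           paste(unique(res[bad]), collapse = ", "))
    warning("skipping ", sum(bad), " non-standard residue(s)")
    res <- res[!bad]
  }
  L <- length(res)
  if (L <= lambda)
    stop("sequence length (", L, ") must exceed lambda (", lambda, ")")
  f <- tabulate(match(res, AA_ORDER), 20L) / L
  names(f) <- AA_ORDER
  theta <- numeric(0)
  if (lambda > 0L) {
    H <- pseaacProperties(normalized = TRUE)
    hseq <- H[, res, drop = FALSE]                 # 3 x L
    theta <- vapply(seq_len(lambda), function(tau) {
      d <- hseq[, seq_len(L - tau) + tau, drop = FALSE] -
           hseq[, seq_len(L - tau), drop = FALSE]
      mean(colMeans(d^2))
    }, numeric(1))
  }
  denom <- 1 + w * sum(theta)
  out <- c(f, w * theta) / denom
  if (lambda > 0L) names(out)[20L + seq_len(lambda)] <-
    paste0("theta", seq_len(lambda))
  out
}

#' Pairwise Pearson correlation feature from an expression dataset
#'
#' For each requested isoform pair, the correlation of the two expression
#' profiles over their shared non-missing samples. Pairs with fewer than
#' `minShared` complete sample pairs, with an isoform absent from the
#' matrix, or with a zero-variance profile get a missing value (`NA`),
#' never a propagated `NaN`.
#'
#' @param exprMatrix numeric matrix, isoforms x samples (missing entries
#'   allowed).
#' @param pairs data.frame/list with elements `isoformA`, `isoformB`, or a
#'   character vector of pair keys.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param minShared minimum number of shared non-missing samples
#'   (default 3).
#' @return named numeric vector (names are canonical pair keys).
#' @export
pairwiseCorrelation <- function(exprMatrix, pairs, method = c("pearson",
                                "spearman"), minShared = 3L) {
  method <- match.arg(method)
  if (ncol(exprMatrix) < 2L)
    stop("need >= 2 samples for correlation")
  if (is.character(pairs)) pairs <- splitPairKey(pairs)
  cp <- canonicalPair(pairs$isoformA %||% pairs$a, pairs$isoformB %||% pairs$b)
  keys <- paste(cp$a, cp$b, sep = PAIR_SEP)
  ia <- match(cp$a, rownames(exprMatrix))
  ib <- match(cp$b, rownames(exprMatrix))
  out <- rep(NA_real_, length(keys))
  ok <- !is.na(ia) & !is.na(ib)
  for (idx in which(ok)) {
    xa <- exprMatrix[ia[idx], ]; xb <- exprMatrix[ib[idx], ]
    shared <- !is.na(xa) & !is.na(xb)
    if (sum(shared) < minShared) next
    xa <- xa[shared]; xb <- xb[shared]
    if (sd(xa) == 0 || sd(xb) == 0) next      # degenerate profile: missing
    out[idx] <- cor(xa, xb, method = method)
  }
  stats::setNames(out, keys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Docking-score feature column
#'
#' Direct lookup of pairwise docking scores under canonical pair ordering;
#' pairs absent from the table are missing. The same pair listed twice
#' with conflicting scores is an error.
#'
#' @param dockingTable data.frame with columns `isoformA`, `isoformB`,
#'   `score` (see [readDockingTable()]).
#' @param pairs pairs to extract, as in [pairwiseCorrelation()].
#' @return named numeric vector (canonical pair keys).
#' @export
dockingFeature <- function(dockingTable, pairs) {
  tk <- pairKey(dockingTable$isoformA, dockingTable$isoformB)
  if (anyDuplicated(tk)) {
    dup <- split(dockingTable$score, tk)
    conflict <- names(dup)[vapply(dup, function(s)
      length(unique(s)) > 1L, logical(1))]
    if (length(conflict))
      stop("conflicting docking scores for pair ", conflict[1L])
    keep <- !duplicated(tk)
    tk <- tk[keep]; dockingTable <- dockingTable[keep, , drop = FALSE]
  }
  if (is.character(pairs)) pairs <- splitPairKey(pairs)
  keys <- pairKey(pairs$isoformA %||% pairs$a, pairs$isoformB %||% pairs$b)
  stats::setNames(dockingTable$score[match(keys, tk)], keys)
}

#' Assemble feature columns into a FeatureTable
#'
#' Outer join over pair keys: no pair present in any column is dropped;
#' cells absent from a column stay missing. Column order follows the
#' arguments; duplicated feature ids are an error.
#'
#' @param ... named numeric vectors (names = canonical pair keys), as
#'   returned by [pairwiseCorrelation()], [dockingFeature()], or a single
#'   named list of such vectors.
#' @return a [FeatureTable-class].
#' @export
assembleFeatures <- function(...) {
  cols <- list(...)
  if (length(cols) == 1L && is.list(cols[[1L]]) &&
      !is.numeric(cols[[1L]])) cols <- cols[[1L]]
  if (is.null(names(cols)) || any(names(cols) == ""))
    stop("every feature column needs a feature id (name)")
  if (anyDuplicated(names(cols)))
    stop("duplicated feature id: ",
         names(cols)[duplicated(names(cols))][1L])
  allKeys <- unique(unlist(lapply(cols, names), use.names = FALSE))
  if (is.null(allKeys) || !length(allKeys))
    stop("no pairs in any feature column")
  m <- vapply(cols, function(col) unname(col[match(allKeys, names(col))]),
              numeric(length(allKeys)))
  m <- matrix(m, nrow = length(allKeys),
              dimnames = list(allKeys, names(cols)))
  FeatureTable(m)
}

#' Composition-similarity feature from protein sequences
#'
#' Convenience wrapper: computes [pseAAC()] descriptors for all isoforms
#' involved in `pairs` and returns, per pair, the Pearson correlation of
#' the two descriptors (pairs with a missing or too-short sequence are
#' missing).
#'
#' @param proteins an `AAStringSet` named by isoform accession.
#' @param pairs pairs as in [pairwiseCorrelation()].
#' @param lambda,w PseAAC parameters, see [pseAAC()].
#' @return named numeric vector (canonical pair keys).
#' @export
pseaacFeature <- function(proteins, pairs, lambda = 10L, w = 0.05) {
  if (is.character(pairs)) pairs <- splitPairKey(pairs)
  cp <- canonicalPair(pairs$isoformA %||% pairs$a,
                      pairs$isoformB %||% pairs$b)
  keys <- paste(cp$a, cp$b, sep = PAIR_SEP)
  need <- unique(c(cp$a, cp$b))
  seqs <- as.character(proteins)
  vecs <- lapply(stats::setNames(need, need), function(id) {
    if (!id %in% names(seqs)) return(NULL)
    tryCatch(suppressWarnings(pseAAC(seqs[[id]], lambda = lambda, w = w)),
             error = function(e) NULL)
  })
  out <- rep(NA_real_, length(keys))
  for (idx in seq_along(keys)) {
    va <- vecs[[cp$a[idx]]]; vb <- vecs[[cp$b[idx]]]
    if (is.null(va) || is.null(vb)) next
    if (sd(va) == 0 || sd(vb) == 0) next
    out[idx] <- cor(va, vb)
  }
  stats::setNames(out, keys)
}
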