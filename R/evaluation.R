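#' Area under the ROC curve
#'
#' Rank-statistic AUC (equivalent to the Wilcoxon/Mann-Whitney statistic)
#' with midrank handling of score ties.
#'
#' @param scores numeric prediction scores.
#' @param labels logical or 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  y <- as.logical(labels)
  if (anyNA(y) || anyNA(scores)) stop("NA in scores or labels")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)                       # midranks for ties
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' The PR curve is evaluated at every distinct score threshold (ties
#' grouped), and the area is the step integral
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over thresholds in decreasing order.
#' Under random scores the area approaches the positive class fraction.
#'
#' @param scores numeric prediction scores.
#' @param labels logical or 0/1 labels; both classes must be present.
#' @return list with `auprc` and `curve` (data.frame with `threshold`,
#'   `recall`, `precision`; recall is non-decreasing).
#' @export
auprcScore <- function(scores, labels) {
  y <- as.logical(labels)
  if (anyNA(y) || anyNA(scores)) stop("NA in scores or labels")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUPRC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  tp <- cumsum(y); npred <- seq_along(y)
  last <- !duplicated(s, fromLast = TRUE)        # last index of each tie
  tp <- tp[last]; npred <- npred[last]; thr <- s[last]
  recall <- tp / n1
  precision <- tp / npred
  area <- sum(diff(c(0, recall)) * precision)
  list(auprc = area,
       curve = data.frame(threshold = thr, recall = recall,
                          precision = precision))
}

#' k-fold cross-validation of SIB-MIL at the bag level
#'
#' Splits gene-pair bags into k folds; per fold, fits SIB-MIL on the
#' remaining bags and evaluates the held-out fold in two strata:
#' single-isoform gene pairs (one instance per bag -- the bag label *is*
#' the isoform-level truth) are scored directly, and multi-isoform gene
#' pairs are scored by the maximum over their instances (bag-level
#' evaluation).
#'
#' @param bags a [BagSet-class].
#' @param k number of folds (>= 2, default 5).
#' @param control a [sibmilControl()].
#' @param seed integer seed for the fold assignment.
#' @return data.frame with columns `fold`, `stratum`
#'   (`"single_isoform"` / `"multi_isoform"`), `auc`, `auprc`, `n`. Strata
#'   with a single class in a fold are reported as `NA` with a warning.
#' @export
kfoldCV <- function(bags, k = 5L, control = sibmilControl(), seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  nB <- nBags(bags)
  lab <- bagLabels(bags)
  m <- bagSizes(bags)
  seeds <- childSeeds(seed, 20L)
  fold <- NULL
  for (try in seq_len(20L)) {
    fold <- withSeed(seeds[try], sample(rep_len(seq_len(k), nB)))
    ok <- all(vapply(seq_len(k), function(f) {
      tr <- fold != f
      any(lab[tr] == 1L & m[tr] == 1L) && any(lab[tr] == 0L)
    }, logical(1)))
    if (ok) break
    warning("fold assignment left a training fold degenerate; resplitting")
  }
  ib <- instanceBag(bags)
  out <- vector("list", 2L * k)
  for (f in seq_len(k)) {
    trainIdx <- which(fold != f)
    fit <- sibmilFit(bags[trainIdx], control)
    testBags <- which(fold == f)
    strata <- list(single_isoform = testBags[m[testBags] == 1L],
                   multi_isoform = testBags[m[testBags] > 1L])
    for (sName in names(strata)) {
      tb <- strata[[sName]]
      row <- data.frame(fold = f, stratum = sName, auc = NA_real_,
                        auprc = NA_real_, n = length(tb))
      if (length(tb) && length(unique(lab[tb])) == 2L) {
        inst <- which(ib %in% tb)
        s <- posteriorScores(fit@model,
                             featureValues(bags)[inst, , drop = FALSE])
        bagMax <- tapply(s, ib[inst], max)
        yb <- lab[as.integer(names(bagMax))] == 1L
        row$auc <- aucScore(as.numeric(bagMax), yb)
        row$auprc <- auprcScore(as.numeric(bagMax), yb)$auprc
      } else if (length(tb)) {
        warning("fold ", f, " stratum ", sName,
                " has one class; metrics NA")
      }
      out[[(f - 1L) * 2L + match(sName, names(strata))]] <- row
    }
  }
  do.call(rbind, out)
}

#' Build an isoform-level validation set from interaction data
#'
#' Mirrors the construction used with experimentally tested
#' isoform-isoform interactions: same-isoform pairs are dropped;
#' cross-gene interacting pairs become positives; then *all* isoform pairs
#' of the implicated gene pairs are enumerated and the ones not listed as
#' interacting become negatives. (E.g. 629 interacting pairs of which 15
#' are same-isoform give 614 positives; if the implicated gene pairs span
#' 1304 isoform pairs, the remaining 690 are negatives.)
#'
#' @param interactingPairs data.frame with columns `isoformA`, `isoformB`
#'   of experimentally interacting isoform pairs.
#' @param geneModels a [GeneModels-class]; pairs with an isoform missing
#'   from the models are dropped with a message.
#' @return a [ValidationSet-class].
#' @export
buildInteractionValidationSet <- function(interactingPairs, geneModels) {
  ip <- data.frame(isoformA = as.character(interactingPairs$isoformA),
                   isoformB = as.character(interactingPairs$isoformB))
  same <- ip$isoformA == ip$isoformB
  nSame <- sum(same)
  ip <- ip[!same, , drop = FALSE]
  known <- isoformIds(geneModels)
  ok <- ip$isoformA %in% known & ip$isoformB %in% known
  if (any(!ok))
    message(sum(!ok), " interacting pairs dropped (unknown isoform)")
  ip <- ip[ok, , drop = FALSE]
  gA <- geneOf(geneModels, ip$isoformA)
  gB <- geneOf(geneModels, ip$isoformB)
  cross <- gA != gB
  ip <- ip[cross, , drop = FALSE]
  posKeys <- unique(pairKey(ip$isoformA, ip$isoformB))
  genePairs <- unique(pairKey(gA[cross], gB[cross]))
  ## enumerate every isoform pair of the implicated gene pairs
  gp <- splitPairKey(genePairs)
  allA <- character(0); allB <- character(0)
  for (i in seq_along(genePairs)) {
    isoA <- isoformIds(geneModels, gp$a[i])
    isoB <- isoformIds(geneModels, gp$b[i])
    allA <- c(allA, rep(isoA, times = length(isoB)))
    allB <- c(allB, rep(isoB, each = length(isoA)))
  }
  allKeys <- pairKey(allA, allB)
  negKeys <- setdiff(allKeys, posKeys)
  pk <- splitPairKey(posKeys); nk <- splitPairKey(negKeys)
  methods::new("ValidationSet",
               positives = data.frame(isoformA = pk$a, isoformB = pk$b),
               negatives = data.frame(isoformA = nk$a, isoformB = nk$b),
               provenance = "isoform-interaction screen",
               nSameIsoformDropped = as.integer(nSame))
}

#' Shuffled-gold-standard random network control
#'
#' Permutes the bag labels (preserving class counts), refits SIB-MIL and
#' rescores every instance; reports the mean and standard deviation of the
#' resulting null score distribution and the non-randomness threshold
#' mean + 3 sd. (E.g. a null with mean 0.050 and sd 0.023 yields the
#' threshold 0.119.)
#'
#' @param bags a [BagSet-class].
#' @param control a [sibmilControl()].
#' @param seed integer seed for the label permutation.
#' @return list with `mu`, `sigma`, `threshold` (= mu + 3 sigma) and
#'   `scores` (the null instance scores).
#' @export
randomNetworkControl <- function(bags, control = sibmilControl(),
                                 seed = 1L) {
  perm <- withSeed(seed, sample(bagLabels(bags)))
  shuffled <- bags
  shuffled@bagLabels <- perm
  shuffled@truth <- logical(0)              # truth is void after shuffling
  fit <- sibmilFit(shuffled, control)
  s <- posteriorScores(fit@model, featureValues(bags))
  mu <- mean(s); sigma <- sd(s)
  list(mu = mu, sigma = sigma, threshold = mu + 3 * sigma, scores = s)
}

#' Overlap of novel high-confidence predictions with reference pair sets
#'
#' Aggregates the network to gene level (bag max), selects novel gene
#' pairs scoring above `threshold` (gold-standard pairs excluded), and
#' counts how many are supported by each reference pair set. Significance
#' is assessed against `nRandom` equally sized random draws from the
#' scored gene-pair universe; the empirical p-value is (r + 1) /
#' (nRandom + 1) where r counts random draws with at least as many
#' supported pairs.
#'
#' @param network an [IsoformNetwork-class] with gene mapping (or supply
#'   `geneModels`).
#' @param referenceSets named list of data.frames with columns `geneA`,
#'   `geneB`.
#' @param threshold gene-level score cutoff (default 0.95).
#' @param exclude data.frame of gene pairs to exclude (the training gold
#'   standard), or NULL.
#' @param nRandom number of random draws (default 1000).
#' @param seed integer seed.
#' @param geneModels optional [GeneModels-class].
#' @return data.frame with one row per reference set plus a `total` row
#'   (support by any set): columns `reference`, `nPredicted`, `validated`,
#'   `randomMean`, `randomSD`, `foldChange`, `pValue`.
#' @export
novelPredictionOverlap <- function(network, referenceSets,
                                   threshold = 0.95, exclude = NULL,
                                   nRandom = 1000L, seed = 1L,
                                   geneModels = NULL) {
  map <- isoformGeneMap(network)
  if (!length(map)) {
    if (is.null(geneModels))
      stop("network has no gene mapping; supply geneModels")
    map <- stats::setNames(rep(geneIds(geneModels),
                               lengths(geneModels@isoforms)),
                           unlist(geneModels@isoforms, use.names = FALSE))
  }
  e <- networkEdges(network)
  gKey <- pairKey(unname(map[e$isoformA]), unname(map[e$isoformB]))
  self <- {
    gp <- splitPairKey(gKey)
    gp$a == gp$b
  }
  gScore <- tapply(e$score[!self], gKey[!self], max)   # bag max
  universe <- names(gScore)
  if (!is.null(exclude) && nrow(exclude)) {
    exKeys <- pairKey(exclude$geneA, exclude$geneB)
    gScore <- gScore[!universe %in% exKeys]
    universe <- names(gScore)
  }
  predicted <- universe[gScore > threshold]
  refKeys <- lapply(referenceSets, function(r)
    unique(pairKey(r$geneA, r$geneB)))
  refKeys$total <- unique(unlist(refKeys, use.names = FALSE))
  nPred <- length(predicted)
  draws <- withSeed(seed, replicate(nRandom,
    sample(universe, nPred), simplify = FALSE))
  rows <- lapply(names(refKeys), function(nm) {
    val <- sum(predicted %in% refKeys[[nm]])
    rnd <- vapply(draws, function(d) sum(d %in% refKeys[[nm]]), 0)
    data.frame(reference = nm, nPredicted = nPred, validated = val,
               randomMean = mean(rnd), randomSD = sd(rnd),
               foldChange = if (mean(rnd) > 0) val / mean(rnd)
                            else if (val > 0) Inf else NA_real_,
               pValue = (sum(rnd >= val) + 1) / (nRandom + 1))
  })
  do.call(rbind, rows)
}
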