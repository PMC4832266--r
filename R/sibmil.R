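#' Control parameters for SIB-MIL fitting
#'
#' @param nBins equal-frequency bins per feature for the base learner
#'   (default 5).
#' @param pseudocount Laplace smoothing constant (default 1).
#' @param prior optional override of the class prior P(y = 1); default is
#'   the empirical fraction of the current training rows.
#' @param tol convergence tolerance on the monitoring metric (default
#'   1e-4).
#' @param maxIter maximum witness-update iterations (default 20).
#' @param monitorFraction fraction of bags held out (bag-level) to monitor
#'   convergence; single-isoform bags are scored directly, multi-isoform
#'   bags by their instance maximum (default 0.2; 0 monitors on the
#'   training bags themselves).
#' @param missingMode missing-data handling of the base learner, see
#'   [fitNaiveBayes()].
#' @param negativeMode `"hardest"` (default; from the second iteration on,
#'   only the highest-scored instance of each negative bag is retained as
#'   a Class-0 row) or `"all"` (keep every negative-bag instance
#'   throughout).
#' @param seed integer seed governing the internal monitor split.
#' @return a named list of class parameters for [sibmilFit()].
#' @export
sibmilControl <- function(nBins = 5L, pseudocount = 1, prior = NULL,
                          tol = 1e-4, maxIter = 20L, monitorFraction = 0.2,
                          missingMode = c("bin", "drop"),
                          negativeMode = c("hardest", "all"), seed = 1L) {
  stopifnot(nBins >= 2L, pseudocount >= 0, tol >= 0, maxIter >= 1L,
            monitorFraction >= 0, monitorFraction < 1)
  list(nBins = as.integer(nBins), pseudocount = pseudocount, prior = prior,
       tol = tol, maxIter = as.integer(maxIter),
       monitorFraction = monitorFraction,
       missingMode = match.arg(missingMode),
       negativeMode = match.arg(negativeMode), seed = seed)
}

#' Initial witness labeling from single-instance positive bags
#'
#' The SIB-MIL initialization: the sole instances of single-instance
#' positive bags are the starting witnesses (Class 1) -- they must be
#' functionally related by construction, so no false positives enter the
#' first model. All instances of negative bags are Class 0.
#' Multi-instance positive bags contribute no training rows yet.
#'
#' @param bags a [BagSet-class].
#' @param bagMask optional logical/integer subset of bags to use.
#' @return list with integer instance-row vectors `witnessRows` and
#'   `negativeRows`.
#' @export
initializeWitnesses <- function(bags, bagMask = NULL) {
  use <- rep(FALSE, nBags(bags))
  use[if (is.null(bagMask)) seq_len(nBags(bags)) else bagMask] <- TRUE
  m <- bagSizes(bags)
  lab <- bagLabels(bags)
  singlePos <- use & lab == 1L & m == 1L
  if (!any(singlePos))
    stop("no single-instance positive bag available for initialization; ",
         "adjust the simulation/fixture so some positive gene pairs are ",
         "single-isoform on both sides")
  if (!any(use & lab == 0L))
    stop("no negative bag available")
  ib <- instanceBag(bags)
  list(witnessRows = which(singlePos[ib]),
       negativeRows = which((use & lab == 0L)[ib]))
}

#' Witness update: per-bag argmax under the current model
#'
#' For each positive bag the highest-scored instance is reselected as the
#' witness (Class 1); for each negative bag only the highest-scored
#' ("hardest") instance is retained as a Class-0 row. Score ties break
#' deterministically toward the lexicographically lowest instance key.
#'
#' @param bags a [BagSet-class].
#' @param scores numeric vector of instance scores (aligned with the
#'   instances of `bags`).
#' @param bagMask optional subset of bags (logical or integer).
#' @return list with named integer vectors `witnessRows` (per positive
#'   bag) and `hardestNegativeRows` (per negative bag); names are bag ids.
#' @export
updateWitnesses <- function(bags, scores, bagMask = NULL) {
  if (length(scores) != nrow(featureValues(bags)))
    stop("scores must be per-instance")
  use <- rep(FALSE, nBags(bags))
  use[if (is.null(bagMask)) seq_len(nBags(bags)) else bagMask] <- TRUE
  ib <- instanceBag(bags)
  rows <- which(use[ib])
  keys <- instanceKeys(bags)[rows]
  ord <- rows[order(ib[rows], -scores[rows], keys, method = "radix")]
  top <- ord[!duplicated(ib[ord])]           # argmax instance per used bag
  lab <- bagLabels(bags)[ib[top]]
  ids <- bagIds(bags)[ib[top]]
  list(witnessRows = stats::setNames(top[lab == 1L], ids[lab == 1L]),
       hardestNegativeRows = stats::setNames(top[lab == 0L],
                                             ids[lab == 0L]))
}

#' Fit the SIB-MIL model
#'
#' Runs the three-step single-instance-bag multiple-instance learning
#' procedure: (1) initialize witnesses from single-instance positive bags
#' and label all negative-bag instances Class 0; (2) iterate
#' \{fit the discretized naive Bayes learner on the current witnesses and
#' selected negatives; rescore all instances; reselect per-bag argmax
#' witnesses and hardest negatives\}; (3) stop when the monitoring AUC on
#' an internal bag-level holdout changes by less than `tol` (or the
#' witness assignment reaches a fixed point), returning the final
#' instance-level classifier.
#'
#' Bin edges are fitted once, on all training-bag instances, and reused
#' across iterations. If `maxIter` is reached while the metric still
#' oscillates, the best-monitoring-AUC iteration is returned with a
#' warning.
#'
#' @param bags a [BagSet-class].
#' @param control a [sibmilControl()] list.
#' @return a [SIBMILFit-class].
#' @examples
#' cfg <- simulationConfig(md = 1, nGenes = 60, nBags = 300, nFeatures = 10,
#'                         nPartitions = 1, seed = 7)
#' fit <- sibmilFit(simulateBags(cfg))
#' fit
#' @export
sibmilFit <- function(bags, control = sibmilControl()) {
  stopifnot(methods::is(bags, "BagSet"))
  nB <- nBags(bags)
  lab <- bagLabels(bags)
  m <- bagSizes(bags)

  ## internal bag-level monitor split
  nMon <- floor(control$monitorFraction * nB)
  seeds <- childSeeds(control$seed, 25L)
  monitor <- integer(0)
  for (try in seq_len(25L)) {
    monitor <- if (nMon > 0L)
      withSeed(seeds[try], sort(sample.int(nB, nMon))) else integer(0)
    train <- setdiff(seq_len(nB), monitor)
    okTrain <- any(lab[train] == 1L & m[train] == 1L) &&
      any(lab[train] == 0L)
    okMon <- nMon == 0L ||
      (any(lab[monitor] == 1L) && any(lab[monitor] == 0L))
    if (okTrain && okMon) break
    if (try == 25L)
      stop("could not find a monitor split with both classes and a ",
           "single-instance positive training bag")
  }
  trainMaskB <- rep(FALSE, nB); trainMaskB[train] <- TRUE
  ib <- instanceBag(bags)
  instTrain <- trainMaskB[ib]

  ## bin edges: fitted once on training-bag instances, reused throughout
  X <- featureValues(bags)
  fids <- colnames(X) %||% paste0("F", seq_len(ncol(X)))
  dz <- discretizeFeatures(X[instTrain, , drop = FALSE],
                           nBins = control$nBins)
  binAll <- binWithBreaks(dz$breaks, X)

  monBags <- if (nMon > 0L) monitor else train
  monInst <- which(ib %in% monBags)
  monitorAUC <- function(model) {
    s <- .nbScoreBinned(model, binAll[monInst, , drop = FALSE])
    bagMax <- tapply(s, ib[monInst], max)
    aucScore(as.numeric(bagMax), lab[as.integer(names(bagMax))] == 1L)
  }

  init <- initializeWitnesses(bags, bagMask = train)
  rows1 <- init$witnessRows
  rows0 <- init$negativeRows
  fitRows <- function(r1, r0)
    .nbFitBinned(binAll[c(r1, r0), , drop = FALSE],
                 rep(1:0, c(length(r1), length(r0))), dz$breaks, dz$nBins,
                 control$pseudocount, control$prior, control$missingMode,
                 fids)

  history <- data.frame(iteration = integer(0), monitorAUC = numeric(0),
                        witnessChanges = integer(0))
  firstModel <- model <- NULL
  bestModel <- NULL; bestAUC <- -Inf
  witness <- stats::setNames(rows1,
                             bagIds(bags)[ib[rows1]])
  hardneg <- integer(0)
  converged <- FALSE
  prevAUC <- NA_real_

  for (it in seq_len(control$maxIter)) {
    model <- fitRows(rows1, rows0)
    if (it == 1L) firstModel <- model
    auc <- monitorAUC(model)
    if (auc > bestAUC) { bestAUC <- auc; bestModel <- model }
    sel <- updateWitnesses(bags,
                           .nbScoreBinned(model, binAll),
                           bagMask = train)
    changes <- sum(!sel$witnessRows %in% rows1) +
      (length(sel$witnessRows) - length(rows1))
    history <- rbind(history,
                     data.frame(iteration = it, monitorAUC = auc,
                                witnessChanges = changes))
    if (!is.na(prevAUC) && abs(auc - prevAUC) < control$tol) {
      converged <- TRUE
      witness <- sel$witnessRows; hardneg <- sel$hardestNegativeRows
      break
    }
    prevAUC <- auc
    newRows0 <- if (control$negativeMode == "hardest")
      unname(sel$hardestNegativeRows) else init$negativeRows
    if (identical(sort(unname(sel$witnessRows)), sort(rows1)) &&
        identical(sort(newRows0), sort(rows0))) {
      ## fixed point: the next model would be identical
      converged <- TRUE
      witness <- sel$witnessRows; hardneg <- sel$hardestNegativeRows
      break
    }
    rows1 <- unname(sel$witnessRows)
    rows0 <- newRows0
    witness <- sel$witnessRows; hardneg <- sel$hardestNegativeRows
  }
  if (!converged) {
    warning("witness updates still changing after maxIter = ",
            control$maxIter, "; returning the best-monitored iteration")
    model <- bestModel
  }
  methods::new("SIBMILFit", model = model, firstModel = firstModel,
               witness = witness, hardestNegative = hardneg,
               history = history, converged = converged,
               trainBags = as.integer(train), control = control)
}

#' Score isoform pairs into a network
#'
#' Applies a fitted classifier to every requested isoform pair and returns
#' the scored network. Pairs whose features are entirely missing are
#' scored by the class prior and flagged (an `allMissing` edge column plus
#' a message).
#'
#' @param model a [NaiveBayesModel-class] or [SIBMILFit-class].
#' @param x a [FeatureTable-class] or [BagSet-class] whose row keys are
#'   isoform-pair keys.
#' @param isoformGene optional named character gene mapping to attach.
#' @return an [IsoformNetwork-class].
#' @export
scoreNetwork <- function(model, x, isoformGene = character(0)) {
  if (methods::is(model, "SIBMILFit")) model <- model@model
  X <- .asFeatureMatrix(x)
  keys <- rownames(X)
  if (is.null(keys)) stop("x needs isoform-pair row keys")
  s <- posteriorScores(model, X)
  allMiss <- rowSums(!is.na(X)) == 0L
  if (any(allMiss)) {
    s[allMiss] <- model@prior
    message(sum(allMiss), " pair(s) had no observed features; ",
            "scored by the prior")
  }
  ab <- splitPairKey(keys)
  keep <- !duplicated(pairKey(ab$a, ab$b))       # bags may repeat pairs
  net <- isoformNetwork(ab$a[keep], ab$b[keep], s[keep],
                        isoformGene = isoformGene)
  if (any(allMiss)) net@edges$allMissing <- allMiss[keep]
  net
}

#' Gene-pair (bag-level) score of a network
#'
#' The score of a gene pair is the maximum over the scores of all its
#' isoform pairs.
#'
#' @param network an [IsoformNetwork-class] with a gene mapping attached
#'   (or supply `geneModels`).
#' @param geneA,geneB gene ids.
#' @param geneModels optional [GeneModels-class] used when the network
#'   carries no mapping.
#' @return the maximum instance score (a single number).
#' @export
bagScore <- function(network, geneA, geneB, geneModels = NULL) {
  map <- isoformGeneMap(network)
  if (!length(map)) {
    if (is.null(geneModels))
      stop("network has no gene mapping; supply geneModels")
    map <- stats::setNames(rep(geneIds(geneModels),
                               lengths(geneModels@isoforms)),
                           unlist(geneModels@isoforms, use.names = FALSE))
  }
  e <- networkEdges(network)
  gA <- unname(map[e$isoformA]); gB <- unname(map[e$isoformB])
  hit <- (gA == geneA & gB == geneB) | (gA == geneB & gB == geneA)
  hit[is.na(hit)] <- FALSE
  if (!any(hit))
    stop("no scored isoform pairs between ", geneA, " and ", geneB)
  max(e$score[hit])
}
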