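#' Build a simulation configuration
#'
#' Defines one condition of the Gaussian-feature MIL simulation: features
#' of planted witness instances are drawn from Normal(`md`, 1), every
#' other instance (including all negative-bag instances) from
#' Normal(0, 1), with features independent given the instance label. A
#' fixed fraction of gene-pair bags is positive (default 0.05) and the
#' multi-isoform gene ratio is controlled exactly (`round(mgr * nGenes)`
#' genes receive 2-3 isoforms).
#'
#' The size defaults (3000 genes, 100000 bags, 50 features, 50/50
#' train/test partitions repeated 20 times) are the package's desk-scale
#' study conditions; see the methods vignette for their rationale.
#'
#' @param md mean difference between witness and background feature
#'   distributions, in units of the (unit) feature standard deviation.
#' @param mgr multi-isoform gene ratio in [0, 1].
#' @param nGenes,nBags,nFeatures,nPartitions problem sizes.
#' @param positiveBagFraction fraction of bags labeled positive.
#' @param isoformCountProbs named probabilities of isoform counts for
#'   multi-isoform genes (default: 2 with probability 0.7, 3 with 0.3).
#' @param nWitnesses planted witnesses per positive bag (default 1, the
#'   minimal reading of "at least one").
#' @param trainFraction bag-level training fraction per partition.
#' @param seed integer seed; the same seed reproduces the bags exactly.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(md = 0.2, mgr = 0.3, nGenes = 3000L,
                             nBags = 100000L, nFeatures = 50L,
                             positiveBagFraction = 0.05,
                             isoformCountProbs = c("2" = 0.7, "3" = 0.3),
                             nWitnesses = 1L, nPartitions = 20L,
                             trainFraction = 0.5, seed = 1L) {
  methods::new("SimulationConfig", md = md, mgr = mgr,
               nGenes = as.integer(nGenes), nBags = as.integer(nBags),
               nFeatures = as.integer(nFeatures),
               positiveBagFraction = positiveBagFraction,
               isoformCountProbs = isoformCountProbs,
               nWitnesses = as.integer(nWitnesses),
               nPartitions = as.integer(nPartitions),
               trainFraction = trainFraction, seed = as.integer(seed))
}

#' Generate simulated MIL bags with planted witnesses
#'
#' @param config a [SimulationConfig-class].
#' @return a [BagSet-class] with per-instance ground truth attached
#'   (`truthLabels()`).
#' @examples
#' bags <- simulateBags(simulationConfig(nGenes = 50, nBags = 200,
#'                                       nFeatures = 5))
#' bags
#' @export
simulateBags <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  nG <- config@nGenes
  maxPairs <- as.double(nG) * (nG - 1) / 2
  if (config@nBags > maxPairs)
    stop("nBags exceeds the number of available gene pairs")
  withSeed(config@seed, {
    ## exact multi-isoform count so the realized MGR equals mgr
    nMulti <- round(config@mgr * nG)
    counts <- as.integer(names(config@isoformCountProbs))
    iso <- rep(1L, nG)
    if (nMulti > 0L)
      iso[seq_len(nMulti)] <- sample(counts, nMulti, replace = TRUE,
                                     prob = config@isoformCountProbs)
    iso <- sample(iso)

    idx <- samplePairIndices(nG, config@nBags)
    ij <- pairIndexToIJ(idx, nG)
    mA <- iso[ij$i]; mB <- iso[ij$j]
    m <- mA * mB
    nBagsReal <- length(idx)
    lab <- integer(nBagsReal)
    lab[sample.int(nBagsReal,
                   round(config@positiveBagFraction * nBagsReal))] <- 1L

    ## Cartesian-product instances
    bag <- rep(seq_len(nBagsReal), m)
    within <- sequence(m) - 1L
    aIdx <- within %% rep(mA, m) + 1L
    bIdx <- within %/% rep(mA, m) + 1L
    isoId <- function(g, t) sprintf("SG%05d.%d", g, t)
    instA <- isoId(rep(ij$i, m), aIdx)
    instB <- isoId(rep(ij$j, m), bIdx)
    keys <- paste(instA, instB, sep = PAIR_SEP)   # i < j: already canonical

    nInst <- length(bag)
    X <- matrix(rnorm(nInst * config@nFeatures), nInst, config@nFeatures,
                dimnames = list(keys,
                                paste0("F", seq_len(config@nFeatures))))
    ## plant witnesses in positive bags
    truth <- logical(nInst)
    starts <- c(0L, cumsum(m))
    for (b in which(lab == 1L)) {
      k <- min(config@nWitnesses, m[b])
      w <- starts[b] + sample.int(m[b], k)
      truth[w] <- TRUE
    }
    X[truth, ] <- X[truth, , drop = FALSE] + config@md

    geneId <- sprintf("SG%05d", seq_len(nG))
    bs <- BagSet(features = X, instanceBag = bag,
                 bagIds = paste(geneId[ij$i], geneId[ij$j],
                                sep = PAIR_SEP),
                 bagLabels = lab, truth = truth)
    bs
  })
}

#' Run the partitioned simulation experiment
#'
#' Generates one simulated bag collection from `config`, then repeats
#' `nPartitions` random disjoint train/test splits of the gene-pair bags.
#' Per partition a SIB-MIL model is fitted on the training bags and
#' instance-level AUC/AUPRC are computed on the test instances against the
#' planted ground truth, both for the converged model and for the
#' first-iteration model.
#'
#' @param config a [SimulationConfig-class].
#' @param control a [sibmilControl()]; its seed is re-derived per
#'   partition from `config@seed`.
#' @return list with elements `results` (data.frame with columns `md`,
#'   `mgr`, `partition`, `auc`, `auprc`, `auc_iter1`, `auc_converged`),
#'   `medianAUC`, `medianAUPRC` and `meanGain` (mean of
#'   `auc_converged - auc_iter1`).
#' @export
runPartitionedExperiment <- function(config, control = sibmilControl()) {
  bags <- simulateBags(config)
  nB <- nBags(bags)
  lab <- bagLabels(bags)
  m <- bagSizes(bags)
  ib <- instanceBag(bags)
  truth <- truthLabels(bags)
  seeds <- childSeeds(config@seed + 1L, 4L * config@nPartitions)
  rows <- vector("list", config@nPartitions)
  for (p in seq_len(config@nPartitions)) {
    trainIdx <- NULL
    for (try in 0:2) {
      cand <- withSeed(seeds[p + try * config@nPartitions],
                       sort(sample.int(nB,
                                       round(config@trainFraction * nB))))
      testIdx <- setdiff(seq_len(nB), cand)
      okTr <- any(lab[cand] == 1L & m[cand] == 1L) && any(lab[cand] == 0L)
      okTe <- any(lab[testIdx] == 1L) && any(lab[testIdx] == 0L)
      if (okTr && okTe) { trainIdx <- cand; break }
      message("partition ", p, ": degenerate split, resampling")
    }
    if (is.null(trainIdx)) stop("could not find a usable partition")
    ctrl <- control
    ctrl$seed <- seeds[p + 3L * config@nPartitions]
    fit <- sibmilFit(bags[trainIdx], ctrl)
    testInst <- which(!(ib %in% trainIdx))
    Xte <- featureValues(bags)[testInst, , drop = FALSE]
    yte <- truth[testInst]
    sFinal <- posteriorScores(fit@model, Xte)
    sFirst <- posteriorScores(fit@firstModel, Xte)
    rows[[p]] <- data.frame(md = config@md, mgr = config@mgr,
                            partition = p,
                            auc = aucScore(sFinal, yte),
                            auprc = auprcScore(sFinal, yte)$auprc,
                            auc_iter1 = aucScore(sFirst, yte),
                            auc_converged = aucScore(sFinal, yte))
  }
  res <- do.call(rbind, rows)
  list(results = res, medianAUC = median(res$auc),
       medianAUPRC = median(res$auprc),
       meanGain = mean(res$auc_converged - res$auc_iter1))
}

#' Full factorial MD x MGR simulation grid
#'
#' @param mdValues,mgrValues numeric grids (non-empty).
#' @param config base [SimulationConfig-class]; each grid cell gets its
#'   own derived seed.
#' @param control a [sibmilControl()].
#' @return tidy long-format data.frame: one row per (md, mgr, partition)
#'   with columns as in [runPartitionedExperiment()]; per-cell medians and
#'   gains are attached as attribute `"summary"`.
#' @export
mdMgrGrid <- function(mdValues, mgrValues, config = simulationConfig(),
                      control = sibmilControl()) {
  if (!length(mdValues) || !length(mgrValues))
    stop("empty grid")
  cells <- expand.grid(md = mdValues, mgr = mgrValues,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- childSeeds(config@seed, nrow(cells))
  out <- vector("list", nrow(cells))
  summ <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg@md <- cells$md[i]; cfg@mgr <- cells$mgr[i]
    cfg@seed <- seeds[i]
    r <- runPartitionedExperiment(cfg, control)
    out[[i]] <- r$results
    summ[[i]] <- data.frame(md = cells$md[i], mgr = cells$mgr[i],
                            medianAUC = r$medianAUC,
                            medianAUPRC = r$medianAUPRC,
                            meanGain = r$meanGain)
  }
  res <- do.call(rbind, out)
  attr(res, "summary") <- do.call(rbind, summ)
  res
}
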