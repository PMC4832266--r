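#' GeneModels: isoform-to-gene mapping with optional protein sequences
#'
#' Container for a gene build: each gene owns a non-empty, duplicate-free set
#' of transcript (isoform) accessions, and each isoform belongs to exactly
#' one gene. Optionally carries protein sequences (an
#' [Biostrings::AAStringSet] named by isoform accession) for
#' composition-based features.
#'
#' @slot isoforms named list; one character vector of isoform accessions per
#'   gene id.
#' @slot proteins an `AAStringSet` named by isoform accession, or `NULL`.
#' @seealso [parseGeneModels()], [computeMGR()]
#' @export
setClass("GeneModels",
  representation(isoforms = "list", proteins = "ANY"),
  prototype(isoforms = list(), proteins = NULL))

setValidity("GeneModels", function(object) {
  iso <- object@isoforms
  if (length(iso) == 0L) return(TRUE)
  if (is.null(names(iso)) || anyNA(names(iso)) || any(names(iso) == ""))
    return("every gene needs a gene id")
  if (anyDuplicated(names(iso)))
    return("duplicated gene ids")
  if (any(lengths(iso) == 0L))
    return("genes with empty isoform sets")
  all <- unlist(iso, use.names = FALSE)
  if (anyDuplicated(all)) {
    dup <- all[duplicated(all)][1L]
    return(sprintf("isoform '%s' maps to more than one gene", dup))
  }
  if (!is.null(object@proteins) && !methods::is(object@proteins, "AAStringSet"))
    return("proteins must be NULL or an AAStringSet")
  TRUE
})

#' FeatureTable: pairwise feature matrix with explicit missingness
#'
#' Rows are canonically ordered isoform pairs (keys from [pairKey()]),
#' columns are feature ids (one per expression dataset, per composition
#' configuration, per docking source). Missing values are `NA`, never
#' silently imputed.
#'
#' @slot values numeric matrix; rownames are pair keys, colnames feature ids.
#' @seealso [assembleFeatures()], [writeFeatureTable()]
#' @export
setClass("FeatureTable", representation(values = "matrix"))

setValidity("FeatureTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("feature values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("feature matrix needs pair-key rownames and feature-id colnames")
  if (anyDuplicated(rownames(v))) return("duplicated pair keys")
  if (anyDuplicated(colnames(v))) return("duplicated feature ids")
  TRUE
})

#' GoldStandard: gene-level positive and negative pairs
#'
#' Functionally related gene pairs (co-annotated to a shared biological
#' process or pathway) and randomly drawn unrelated pairs. Pairs are
#' canonically ordered, self-pairs are excluded, and the two sets are
#' disjoint.
#'
#' @slot positives data.frame with columns `geneA`, `geneB`, `source`.
#' @slot negatives data.frame with columns `geneA`, `geneB`.
#' @slot evidenceFiltered logical; whether the experimental evidence-code
#'   filter was applied to the GO annotations.
#' @seealso [coAnnotationPositives()], [sampleNegatives()], [goldStandard()]
#' @export
setClass("GoldStandard",
  representation(positives = "data.frame", negatives = "data.frame",
                 evidenceFiltered = "logical"),
  prototype(evidenceFiltered = FALSE))

setValidity("GoldStandard", function(object) {
  p <- object@positives; n <- object@negatives
  if (!all(c("geneA", "geneB", "source") %in% names(p)))
    return("positives need columns geneA, geneB, source")
  if (!all(c("geneA", "geneB") %in% names(n)))
    return("negatives need columns geneA, geneB")
  for (d in list(p, n)) {
    if (nrow(d) == 0L) next
    if (any(d$geneA == d$geneB)) return("self-pairs are not allowed")
    if (any(d$geneB < d$geneA)) return("pairs must be canonically ordered")
  }
  pk <- pairKey(p$geneA, p$geneB); nk <- pairKey(n$geneA, n$geneB)
  if (anyDuplicated(pk)) return("duplicated positive pairs")
  if (anyDuplicated(nk)) return("duplicated negative pairs")
  if (length(intersect(pk, nk)))
    return("positive and negative sets overlap")
  TRUE
})

#' BagSet: gene-pair bags of isoform-pair instances
#'
#' The multiple-instance learning view of the data: every gene pair is a
#' bag carrying a label (1 = functionally related), and its instances are
#' the isoform pairs formed by the Cartesian product of the two genes'
#' isoforms. Instances carry the pairwise feature vectors. For simulated
#' data the per-instance ground truth (planted witness indicator) travels
#' along in `truth`.
#'
#' @slot features numeric matrix, instances x features; rownames are
#'   instance (isoform-pair) keys, `NA` marks missing values.
#' @slot instanceBag integer; bag index of each instance.
#' @slot bagIds character; one gene-pair key per bag.
#' @slot bagLabels integer 0/1; one label per bag.
#' @slot truth logical; per-instance witness indicator (length 0 when
#'   unknown, as for real data).
#' @seealso [buildBags()], [simulateBags()], [sibmilFit()]
#' @export
setClass("BagSet",
  representation(features = "matrix", instanceBag = "integer",
                 bagIds = "character", bagLabels = "integer",
                 truth = "logical"),
  prototype(truth = logical(0)))

setValidity("BagSet", function(object) {
  nI <- nrow(object@features); nB <- length(object@bagIds)
  if (length(object@instanceBag) != nI)
    return("instanceBag must have one entry per feature row")
  if (length(object@bagLabels) != nB)
    return("one label per bag required")
  if (!all(object@bagLabels %in% c(0L, 1L)))
    return("bag labels must be 0/1")
  if (nI > 0L && (min(object@instanceBag) < 1L || max(object@instanceBag) > nB))
    return("instanceBag indices out of range")
  if (nB > 0L && !all(tabulate(object@instanceBag, nB) >= 1L))
    return("every bag must keep at least one instance")
  if (anyDuplicated(object@bagIds)) return("duplicated bag ids")
  if (!length(object@truth)) return(TRUE)
  if (length(object@truth) != nI)
    return("truth must be per-instance (or empty)")
  witPerBag <- tabulate(object@instanceBag[object@truth], nB)
  if (any(witPerBag[object@bagLabels == 1L] < 1L))
    return("every positive bag needs at least one true witness")
  if (any(witPerBag[object@bagLabels == 0L] > 0L))
    return("negative bags cannot contain witnesses")
  TRUE
})

#' NaiveBayesModel: discretized naive Bayes classifier
#'
#' The base learner: per-feature equal-frequency bin edges fitted on
#' training rows, conditional probability tables \eqn{P(bin \mid y)} for
#' both classes (with a dedicated missing-data bin), a Laplace pseudocount
#' and the class prior \eqn{P(y=1)}. Posteriors are computed in log space
#' and renormalized over \eqn{y \in \{0, 1\}}.
#'
#' @slot prior numeric; \eqn{P(y = 1)}.
#' @slot breaks list; per feature, the inner bin edges (length k-1 for k
#'   bins).
#' @slot cpt1,cpt0 numeric matrices `(maxBins + 1) x nFeatures`; row 1 is
#'   the missing bin, rows 2..(k+1) the value bins. Unused rows (features
#'   with fewer bins) are `NA`. Each used column block sums to 1.
#' @slot nBins integer; realized bin count per feature.
#' @slot pseudocount numeric; Laplace smoothing constant.
#' @slot missingMode `"bin"` (missing data get their own likelihood bin) or
#'   `"drop"` (missing features are skipped in the product).
#' @slot featureIds character.
#' @seealso [fitNaiveBayes()], [posteriorScores()], [writeNBModel()]
#' @export
setClass("NaiveBayesModel",
  representation(prior = "numeric", breaks = "list",
                 cpt1 = "matrix", cpt0 = "matrix", nBins = "integer",
                 pseudocount = "numeric", missingMode = "character",
                 featureIds = "character"))

setValidity("NaiveBayesModel", function(object) {
  nf <- length(object@featureIds)
  if (length(object@breaks) != nf || length(object@nBins) != nf)
    return("breaks/nBins must match featureIds")
  if (!identical(dim(object@cpt1), dim(object@cpt0)))
    return("cpt1 and cpt0 must have identical shape")
  if (ncol(object@cpt1) != nf) return("one CPT column per feature")
  if (object@prior <= 0 || object@prior >= 1)
    return("prior must be in (0, 1)")
  if (!object@missingMode %in% c("bin", "drop"))
    return("missingMode must be 'bin' or 'drop'")
  for (f in seq_len(nf)) {
    used <- seq_len(object@nBins[f] + 1L)
    if (object@missingMode == "drop") used <- used[-1L]
    for (cpt in list(object@cpt1, object@cpt0)) {
      p <- cpt[used, f]
      if (anyNA(p) || any(p < 0)) return("CPT entries must be non-negative")
      if (object@pseudocount > 0 && any(p == 0))
        return("CPT entries must be positive after smoothing")
      if (abs(sum(p) - 1) > 1e-9) return("CPT columns must sum to 1")
    }
  }
  TRUE
})

#' SIBMILFit: a fitted SIB-MIL model with its witness state
#'
#' Result of [sibmilFit()]: the final instance-level classifier, the
#' first-iteration classifier (trained only on single-instance positive
#' bags and all negative instances), the converged witness assignment and
#' the monitoring-metric history.
#'
#' @slot model,firstModel [NaiveBayesModel-class] objects.
#' @slot witness named integer; per positive training bag, the row index
#'   (into the bag set's features) of its selected witness instance.
#' @slot hardestNegative named integer; per negative training bag, the row
#'   index of the retained hardest negative instance.
#' @slot history data.frame with columns `iteration`, `monitorAUC`,
#'   `witnessChanges`.
#' @slot converged logical.
#' @slot trainBags integer; indices of bags used for witness training (the
#'   remainder form the internal monitoring holdout).
#' @slot control list; the [sibmilControl()] used.
#' @export
setClass("SIBMILFit",
  representation(model = "NaiveBayesModel", firstModel = "NaiveBayesModel",
                 witness = "integer", hardestNegative = "integer",
                 history = "data.frame", converged = "logical",
                 trainBags = "integer", control = "list"))

#' IsoformNetwork: scored isoform pairs with gene mapping
#'
#' An undirected network whose edges are canonically ordered isoform pairs
#' scored with the posterior probability of a functional relationship
#' (in [0, 1]). An optional isoform-to-gene mapping supports gene-pair
#' (bag-level) queries.
#'
#' @slot edges data.frame with columns `isoformA`, `isoformB`, `score`.
#' @slot isoformGene named character; gene id per isoform accession (may be
#'   empty).
#' @seealso [isoformNetwork()], [writeIsoformNetwork()], [bagScore()],
#'   [topKNeighbors()]
#' @export
setClass("IsoformNetwork",
  representation(edges = "data.frame", isoformGene = "character"),
  prototype(isoformGene = character(0)))

setValidity("IsoformNetwork", function(object) {
  e <- object@edges
  if (!all(c("isoformA", "isoformB", "score") %in% names(e)))
    return("edges need columns isoformA, isoformB, score")
  if (nrow(e) == 0L) return(TRUE)
  if (any(e$isoformA == e$isoformB)) return("self-edges are not allowed")
  if (any(e$isoformB < e$isoformA))
    return("edges must be canonically ordered (isoformA < isoformB)")
  if (anyDuplicated(pairKey(e$isoformA, e$isoformB)))
    return("duplicated edges")
  if (anyNA(e$score) || any(e$score < 0 | e$score > 1))
    return("scores must lie in [0, 1]")
  TRUE
})

#' SimulationConfig: parameters of the Gaussian-feature MIL simulation
#'
#' Defines one simulation condition: the per-feature mean difference `md`
#' between planted witness instances (features ~ Normal(md, 1)) and all
#' other instances (Normal(0, 1)); the multi-isoform gene ratio `mgr`; the
#' numbers of genes, gene-pair bags and features; the positive-bag
#' fraction; and the train/test partitioning scheme.
#'
#' @slot md numeric; mean difference in feature units (sd fixed at 1).
#' @slot mgr numeric in [0, 1]; fraction of genes with >= 2 isoforms.
#' @slot nGenes,nBags,nFeatures,nPartitions integers.
#' @slot positiveBagFraction numeric in (0, 1).
#' @slot isoformCountProbs named numeric; distribution of isoform counts
#'   for multi-isoform genes (names are the counts).
#' @slot nWitnesses integer; planted witnesses per positive bag.
#' @slot trainFraction numeric in (0, 1); bag-level train split per
#'   partition.
#' @slot seed integer.
#' @seealso [simulationConfig()], [simulateBags()],
#'   [runPartitionedExperiment()]
#' @export
setClass("SimulationConfig",
  representation(md = "numeric", mgr = "numeric", nGenes = "integer",
                 nBags = "integer", nFeatures = "integer",
                 positiveBagFraction = "numeric",
                 isoformCountProbs = "numeric", nWitnesses = "integer",
                 nPartitions = "integer", trainFraction = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@mgr < 0 || object@mgr > 1) return("mgr must be in [0, 1]")
  if (object@positiveBagFraction <= 0 || object@positiveBagFraction >= 1)
    return("positiveBagFraction must be in (0, 1)")
  if (object@nPartitions < 1L) return("nPartitions must be >= 1")
  if (object@nGenes < 2L) return("need at least 2 genes")
  if (object@nBags < 2L) return("need at least 2 bags")
  if (object@nFeatures < 1L) return("need at least 1 feature")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must be in (0, 1)")
  if (is.null(names(object@isoformCountProbs)) ||
      anyNA(suppressWarnings(as.integer(names(object@isoformCountProbs)))) ||
      any(as.integer(names(object@isoformCountProbs)) < 2L))
    return("isoformCountProbs names must be integer counts >= 2")
  if (any(object@isoformCountProbs < 0) || sum(object@isoformCountProbs) <= 0)
    return("isoformCountProbs must be a non-negative, non-zero weighting")
  if (object@nWitnesses < 1L) return("nWitnesses must be >= 1")
  TRUE
})

#' ValidationSet: isoform-level positives and negatives
#'
#' An external validation set built from experimentally tested
#' isoform-isoform interactions: cross-gene interacting pairs are
#' positives; the remaining isoform pairs of the implicated gene pairs are
#' negatives.
#'
#' @slot positives,negatives data.frames with columns `isoformA`,
#'   `isoformB`.
#' @slot provenance character; free-text origin tag.
#' @slot nSameIsoformDropped integer; same-isoform input pairs excluded.
#' @seealso [buildInteractionValidationSet()]
#' @export
setClass("ValidationSet",
  representation(positives = "data.frame", negatives = "data.frame",
                 provenance = "character", nSameIsoformDropped = "integer"))

setValidity("ValidationSet", function(object) {
  pk <- pairKey(object@positives$isoformA, object@positives$isoformB)
  nk <- pairKey(object@negatives$isoformA, object@negatives$isoformB)
  if (length(intersect(pk, nk)))
    return("positives and negatives overlap")
  if (any(object@positives$isoformA == object@positives$isoformB) ||
      any(object@negatives$isoformA == object@negatives$isoformB))
    return("same-isoform pairs are not allowed")
  TRUE
})

#' LocalNetwork: the top-k neighborhood of one isoform
#'
#' @slot focal character; the focal isoform accession.
#' @slot neighbors data.frame with columns `isoform`, `score`, sorted by
#'   descending score.
#' @slot k integer; the requested neighborhood size.
#' @slot truncated logical; `TRUE` when fewer than `k` partners exist.
#' @seealso [topKNeighbors()], [sharedNeighborCount()]
#' @export
setClass("LocalNetwork",
  representation(focal = "character", neighbors = "data.frame",
                 k = "integer", truncated = "logical"))
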