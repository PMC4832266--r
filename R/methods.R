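## ---- constructors -------------------------------------------------------

#' Construct a GeneModels object
#'
#' @param isoforms named list mapping gene ids to character vectors of
#'   isoform accessions.
#' @param proteins optional [Biostrings::AAStringSet] named by isoform
#'   accession.
#' @return a [GeneModels-class] object.
#' @examples
#' GeneModels(list(A = c("t1", "t2"), B = "t3"))
#' @export
GeneModels <- function(isoforms, proteins = NULL) {
  isoforms <- lapply(isoforms, function(x) unique(as.character(x)))
  methods::new("GeneModels", isoforms = isoforms, proteins = proteins)
}

#' Construct a FeatureTable from a pair-by-feature matrix
#'
#' @param values numeric matrix with pair-key rownames (see [pairKey()])
#'   and feature-id colnames.
#' @return a [FeatureTable-class] object.
#' @export
FeatureTable <- function(values) {
  methods::new("FeatureTable", values = values)
}

#' Construct a GoldStandard from positive and negative gene pairs
#'
#' @param positives data.frame with columns `geneA`, `geneB` and optionally
#'   `source` (provenance, e.g. "GO"/"KEGG"/"BioCyc").
#' @param negatives data.frame with columns `geneA`, `geneB`.
#' @param evidenceFiltered logical flag recording whether GO annotations
#'   were restricted to experimental evidence codes upstream.
#' @return a [GoldStandard-class] object.
#' @export
goldStandard <- function(positives, negatives, evidenceFiltered = FALSE) {
  if (is.null(positives$source)) positives$source <- NA_character_
  cp <- canonicalPair(positives$geneA, positives$geneB)
  positives <- data.frame(geneA = cp$a, geneB = cp$b,
                          source = as.character(positives$source))
  cn <- canonicalPair(negatives$geneA, negatives$geneB)
  negatives <- data.frame(geneA = cn$a, geneB = cn$b)
  methods::new("GoldStandard", positives = positives, negatives = negatives,
               evidenceFiltered = evidenceFiltered)
}

#' Construct an IsoformNetwork from scored isoform pairs
#'
#' Edges are brought into canonical order; an already-present duplicate of
#' an edge (in either orientation) is an error.
#'
#' @param isoformA,isoformB character vectors of isoform accessions.
#' @param score numeric vector of probabilities in [0, 1].
#' @param isoformGene optional named character vector mapping isoform
#'   accessions to gene ids.
#' @return an [IsoformNetwork-class] object.
#' @export
isoformNetwork <- function(isoformA, isoformB, score,
                           isoformGene = character(0)) {
  cp <- canonicalPair(isoformA, isoformB)
  edges <- data.frame(isoformA = cp$a, isoformB = cp$b,
                      score = as.numeric(score))
  methods::new("IsoformNetwork", edges = edges, isoformGene = isoformGene)
}

#' Construct a BagSet
#'
#' @param features instance-by-feature numeric matrix with instance-key
#'   rownames.
#' @param instanceBag integer bag index per instance.
#' @param bagIds character gene-pair key per bag.
#' @param bagLabels integer (0/1) label per bag.
#' @param truth optional logical per-instance witness indicator.
#' @return a [BagSet-class] object.
#' @export
BagSet <- function(features, instanceBag, bagIds, bagLabels,
                   truth = logical(0)) {
  methods::new("BagSet", features = features,
               instanceBag = as.integer(instanceBag),
               bagIds = as.character(bagIds),
               bagLabels = as.integer(bagLabels), truth = truth)
}

## ---- GeneModels ---------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneModels", function(x) names(x@isoforms))

#' @rdname accessors
#' @export
setMethod("isoformIds", "GeneModels", function(x, gene = NULL) {
  if (is.null(gene)) return(unlist(x@isoforms, use.names = FALSE))
  if (!gene %in% names(x@isoforms)) stop("unknown gene: ", gene)
  x@isoforms[[gene]]
})

#' @rdname accessors
#' @export
setMethod("geneOf", "GeneModels", function(x, isoform) {
  map <- rep(names(x@isoforms), lengths(x@isoforms))
  names(map) <- unlist(x@isoforms, use.names = FALSE)
  out <- map[isoform]
  if (anyNA(out)) stop("unknown isoform: ", isoform[is.na(out)][1L])
  unname(out)
})

#' @rdname accessors
#' @export
setMethod("proteins", "GeneModels", function(x) x@proteins)

#' @export
#' @describeIn computeMGR fraction of multi-isoform genes in a gene build
setMethod("computeMGR", "GeneModels", function(x) {
  if (length(x@isoforms) == 0L)
    stop("cannot compute MGR of an empty gene collection")
  mean(lengths(x@isoforms) >= 2L)
})

setMethod("show", "GeneModels", function(object) {
  n <- length(object@isoforms)
  cat(sprintf("GeneModels: %d genes, %d isoforms", n,
              sum(lengths(object@isoforms))))
  if (n) cat(sprintf(", MGR = %.3f", computeMGR(object)))
  cat(sprintf("; proteins: %s\n",
              if (is.null(object@proteins)) "none"
              else length(object@proteins)))
})

## ---- FeatureTable -------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("featureIds", "FeatureTable", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("pairKeys", "FeatureTable", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)

#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

setMethod("show", "FeatureTable", function(object) {
  v <- object@values
  cat(sprintf("FeatureTable: %d isoform pairs x %d features (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
})

## ---- GoldStandard -------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("positivePairs", "GoldStandard", function(x) x@positives)

#' @rdname accessors
#' @export
setMethod("negativePairs", "GoldStandard", function(x) x@negatives)

setMethod("show", "GoldStandard", function(object) {
  cat(sprintf("GoldStandard: %d positive, %d negative gene pairs%s\n",
              nrow(object@positives), nrow(object@negatives),
              if (object@evidenceFiltered)
                " (experimental evidence codes only)" else ""))
})

## ---- BagSet -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("nBags", "BagSet", function(x) length(x@bagIds))

#' @rdname accessors
#' @export
setMethod("bagIds", "BagSet", function(x) x@bagIds)

#' @rdname accessors
#' @export
setMethod("bagLabels", "BagSet", function(x) x@bagLabels)

#' @rdname accessors
#' @export
setMethod("bagSizes", "BagSet",
          function(x) tabulate(x@instanceBag, length(x@bagIds)))

#' @rdname accessors
#' @export
setMethod("instanceKeys", "BagSet", function(x) rownames(x@features))

#' @rdname accessors
#' @export
setMethod("instanceBag", "BagSet", function(x) x@instanceBag)

#' @rdname accessors
#' @export
setMethod("truthLabels", "BagSet", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("featureValues", "BagSet", function(x) x@features)

#' Subset a BagSet by bag index
#'
#' Keeps the selected bags with all their instances.
#'
#' @param x a [BagSet-class].
#' @param i integer or logical index over bags.
#' @param j,drop,... ignored.
#' @return a [BagSet-class] with the selected bags.
#' @export
setMethod("[", "BagSet", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(nBags(x))[i]
  keep <- x@instanceBag %in% i
  newIdx <- match(x@instanceBag[keep], i)
  methods::new("BagSet", features = x@features[keep, , drop = FALSE],
               instanceBag = newIdx, bagIds = x@bagIds[i],
               bagLabels = x@bagLabels[i],
               truth = if (length(x@truth)) x@truth[keep] else logical(0))
})

setMethod("show", "BagSet", function(object) {
  m <- bagSizes(object)
  cat(sprintf(paste0("BagSet: %d bags (%d positive), %d instances, ",
                     "%d features\n  bag size: min %d / median %s / max %d; ",
                     "truth labels: %s\n"),
              nBags(object), sum(object@bagLabels == 1L),
              nrow(object@features), ncol(object@features),
              min(m), format(stats::median(m)), max(m),
              if (length(object@truth)) "present" else "absent"))
})

## ---- IsoformNetwork -----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("networkEdges", "IsoformNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("isoformGeneMap", "IsoformNetwork", function(x) x@isoformGene)

setMethod("show", "IsoformNetwork", function(object) {
  e <- object@edges
  cat(sprintf("IsoformNetwork: %d edges over %d isoforms%s\n", nrow(e),
              length(unique(c(e$isoformA, e$isoformB))),
              if (length(object@isoformGene)) " (gene mapping attached)"
              else ""))
  if (nrow(e))
    cat(sprintf("  score range: [%.3f, %.3f]\n", min(e$score), max(e$score)))
})

setMethod("show", "ValidationSet", function(object) {
  cat(sprintf(paste0("ValidationSet (%s): %d positives, %d negatives; ",
                     "%d same-isoform pairs dropped\n"),
              object@provenance, nrow(object@positives),
              nrow(object@negatives), object@nSameIsoformDropped))
})

setMethod("show", "LocalNetwork", function(object) {
  cat(sprintf("LocalNetwork of %s: top %d neighbors%s\n", object@focal,
              nrow(object@neighbors),
              if (object@truncated) sprintf(" (fewer than k = %d available)",
                                            object@k) else ""))
})

setMethod("show", "NaiveBayesModel", function(object) {
  cat(sprintf(paste0("NaiveBayesModel: %d features, %s bins each ",
                     "(+ missing bin), prior P(y=1) = %.4f\n",
                     "  pseudocount %.3g, missing data mode: %s\n"),
              length(object@featureIds),
              paste(range(object@nBins), collapse = "-"),
              object@prior, object@pseudocount, object@missingMode))
})

setMethod("show", "SIBMILFit", function(object) {
  h <- object@history
  cat(sprintf(paste0("SIBMILFit: %d iterations, %sconverged\n",
                     "  final monitoring AUC %.4f over %d witness bags\n"),
              nrow(h), if (object@converged) "" else "NOT ",
              h$monitorAUC[nrow(h)], length(object@witness)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: MD = %.3g, MGR = %.2f, %d genes, ",
                     "%d bags,\n  %d features, positive fraction %.3g, ",
                     "%d partitions (train fraction %.2f), seed %d\n"),
              object@md, object@mgr, object@nGenes, object@nBags,
              object@nFeatures, object@positiveBagFraction,
              object@nPartitions, object@trainFraction, object@seed))
})
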