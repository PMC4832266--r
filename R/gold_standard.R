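EXPERIMENTAL_CODES <- c("EXP", "IMP", "IPI", "IGI", "IEP", "IDA")

#' Restrict GO annotations to experimental evidence codes
#'
#' GO-sourced rows are kept only when their evidence code is one of EXP,
#' IMP, IPI, IGI, IEP, IDA; rows from pathway databases (KEGG, BioCyc)
#' pass through unchanged. GO rows with any other (or unknown) code are
#' dropped, with the count reported via `message()`.
#'
#' @param annotations annotation data.frame with columns `gene`, `term`,
#'   `evidence`, `source` (see [readGAF()], [readPathwayTable()]).
#' @return the filtered annotation data.frame.
#' @export
filterExperimental <- function(annotations) {
  isGO <- annotations$source == "GO"
  keep <- !isGO | annotations$evidence %in% EXPERIMENTAL_CODES
  nDropped <- sum(!keep)
  if (nDropped)
    message(nDropped, " GO annotation rows dropped (non-experimental or ",
            "unknown evidence code)")
  annotations[keep, , drop = FALSE]
}

#' Co-annotation positive gene pairs
#'
#' Two genes form a positive (functionally related) pair when they are
#' co-annotated to at least one shared biological-process term or pathway.
#' GO annotations are restricted to the biological_process aspect; pathway
#' rows (KEGG/BioCyc) always count. Terms annotating more than
#' `maxTermSize` genes are excluded by default because very large terms
#' yield vacuous positives (`maxTermSize = Inf` disables the ceiling).
#'
#' @param annotations annotation data.frame (`gene`, `term`, `evidence`,
#'   `aspect`, `source`).
#' @param terms optional character vector restricting to specific terms.
#' @param maxTermSize exclude terms annotating more than this many genes
#'   (default 300).
#' @param bpOnly restrict GO rows to aspect "P" (default `TRUE`).
#' @return data.frame with columns `geneA`, `geneB`, `source` (provenance
#'   of the first shared term, collapsed with ";" when several sources
#'   support a pair), canonically ordered and deduplicated.
#' @export
coAnnotationPositives <- function(annotations, terms = NULL,
                                  maxTermSize = 300L, bpOnly = TRUE) {
  if (!nrow(annotations)) {
    warning("empty annotation table: no positive pairs")
    return(data.frame(geneA = character(0), geneB = character(0),
                      source = character(0)))
  }
  a <- annotations
  if (bpOnly) {
    isGO <- a$source == "GO"
    a <- a[!isGO | (!is.na(a$aspect) & a$aspect == "P"), , drop = FALSE]
  }
  if (!is.null(terms)) a <- a[a$term %in% terms, , drop = FALSE]
  a <- unique(a[, c("gene", "term", "source")])
  genesPerTerm <- split(a$gene, a$term)
  sourcePerTerm <- vapply(split(a$source, a$term), `[`, "", 1L)
  sizes <- lengths(genesPerTerm)
  keep <- sizes >= 2L & sizes <= maxTermSize
  genesPerTerm <- genesPerTerm[keep]
  if (!length(genesPerTerm))
    return(data.frame(geneA = character(0), geneB = character(0),
                      source = character(0)))
  pieces <- lapply(names(genesPerTerm), function(tm) {
    g <- sort(unique(genesPerTerm[[tm]]))
    cb <- combn(g, 2L)
    data.frame(geneA = cb[1L, ], geneB = cb[2L, ],
               source = sourcePerTerm[[tm]])
  })
  pairs <- do.call(rbind, pieces)
  key <- pairKey(pairs$geneA, pairs$geneB)
  src <- vapply(split(pairs$source, key), function(s)
    paste(sort(unique(s)), collapse = ";"), "")
  first <- !duplicated(key)
  out <- pairs[first, , drop = FALSE]
  out$source <- unname(src[key[first]])
  out <- out[order(out$geneA, out$geneB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomly sampled negative gene pairs
#'
#' Draws unordered gene pairs uniformly from the universe, excluding
#' self-pairs and the positive set. When fewer than `ratio * nPositives`
#' pairs remain, all remaining pairs are returned.
#'
#' @param geneUniverse character vector of gene ids.
#' @param positives positive pairs (data.frame `geneA`/`geneB` or a
#'   [GoldStandard-class]).
#' @param ratio negatives per positive (default 19, i.e. a 5\% positive
#'   fraction).
#' @param seed integer RNG seed.
#' @return data.frame with columns `geneA`, `geneB`.
#' @export
sampleNegatives <- function(geneUniverse, positives, ratio = 19, seed = 1L) {
  if (ratio <= 0) stop("ratio must be > 0")
  genes <- sort(unique(as.character(geneUniverse)))
  n <- length(genes)
  if (n < 2L) stop("gene universe too small to sample pairs")
  if (methods::is(positives, "GoldStandard"))
    positives <- positivePairs(positives)
  pa <- match(positives$geneA, genes); pb <- match(positives$geneB, genes)
  if (anyNA(pa) || anyNA(pb))
    stop("positive pair gene outside the universe")
  excl <- if (nrow(positives)) ijToPairIndex(pa, pb, n) else integer(0)
  nWant <- ceiling(ratio * max(nrow(positives), 1L))
  idx <- withSeed(seed, samplePairIndices(n, nWant, exclude = excl))
  ij <- pairIndexToIJ(idx, n)
  out <- data.frame(geneA = genes[ij$i], geneB = genes[ij$j])
  out[order(out$geneA, out$geneB), , drop = FALSE]
}

#' Build MIL bags from a gold standard and a feature table
#'
#' One bag per gold-standard gene pair; its instances are the Cartesian
#' product of the two genes' isoforms, so a 3-isoform x 2-isoform pair
#' yields m = 6 instances. Instances whose feature row is entirely missing
#' (or absent from the feature table) are dropped; a bag left without
#' instances is dropped and counted via `message()`.
#'
#' @param gold a [GoldStandard-class].
#' @param geneModels a [GeneModels-class].
#' @param features a [FeatureTable-class] keyed by isoform-pair keys.
#' @return a [BagSet-class] (no truth labels: real data carry none).
#' @export
buildBags <- function(gold, geneModels, features) {
  stopifnot(methods::is(gold, "GoldStandard"),
            methods::is(geneModels, "GeneModels"),
            methods::is(features, "FeatureTable"))
  pos <- positivePairs(gold); neg <- negativePairs(gold)
  pairs <- data.frame(geneA = c(pos$geneA, neg$geneA),
                      geneB = c(pos$geneB, neg$geneB),
                      label = rep(c(1L, 0L), c(nrow(pos), nrow(neg))))
  known <- geneIds(geneModels)
  ok <- pairs$geneA %in% known & pairs$geneB %in% known
  if (any(!ok))
    message(sum(!ok), " gold-standard pairs dropped (gene not in models)")
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs)) stop("no gold-standard pairs left to build bags from")
  isoA <- geneModels@isoforms[pairs$geneA]
  isoB <- geneModels@isoforms[pairs$geneB]
  mA <- lengths(isoA); mB <- lengths(isoB)
  m <- mA * mB
  bag <- rep(seq_len(nrow(pairs)), m)
  instA <- unlist(mapply(function(a, b) rep(a, times = length(b)),
                         isoA, isoB, SIMPLIFY = FALSE), use.names = FALSE)
  instB <- unlist(mapply(function(a, b) rep(b, each = length(a)),
                         isoA, isoB, SIMPLIFY = FALSE), use.names = FALSE)
  keys <- pairKey(instA, instB)
  fv <- featureValues(features)
  rows <- match(keys, rownames(fv))
  X <- fv[ifelse(is.na(rows), 1L, rows), , drop = FALSE]
  X[is.na(rows), ] <- NA_real_
  rownames(X) <- keys
  keep <- rowSums(!is.na(X)) > 0L
  if (any(!keep))
    message(sum(!keep), " instances dropped (no observed features)")
  X <- X[keep, , drop = FALSE]; bag <- bag[keep]
  left <- tabulate(bag, nrow(pairs))
  if (any(left == 0L))
    message(sum(left == 0L), " bags dropped (all instances missing)")
  keepBag <- which(left > 0L)
  newIdx <- match(bag, keepBag)
  BagSet(features = X, instanceBag = newIdx,
         bagIds = pairKey(pairs$geneA, pairs$geneB)[keepBag],
         bagLabels = pairs$label[keepBag])
}
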