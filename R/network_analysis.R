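.genePairEdges <- function(network, geneA, geneB, geneModels = NULL) {
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
  e[hit, , drop = FALSE]
}

#' Disparity ratio of a gene pair
#'
#' The ratio of the maximum to the minimum predicted probability among all
#' isoform pairs of a gene pair -- the network's measure of isoform-level
#' functional differentiation. Instance scores \{0.999, 0.233, 0.084,
#' 0.045\} give 0.999/0.045 = 22.2; a single isoform pair gives 1.
#'
#' @param network an [IsoformNetwork-class] with gene mapping (or supply
#'   `geneModels`).
#' @param geneA,geneB gene ids.
#' @param geneModels optional [GeneModels-class].
#' @return ratio >= 1; `Inf` (with a warning flag attribute
#'   `"zeroMinimum"`) when the minimum score is 0.
#' @export
disparityRatio <- function(network, geneA, geneB, geneModels = NULL) {
  e <- .genePairEdges(network, geneA, geneB, geneModels)
  if (!nrow(e))
    stop("no scored isoform pairs between ", geneA, " and ", geneB)
  lo <- min(e$score); hi <- max(e$score)
  if (lo == 0) {
    out <- Inf
    attr(out, "zeroMinimum") <- TRUE
    return(out)
  }
  hi / lo
}

#' Disparity-ratio distribution over multi-instance gene pairs
#'
#' Computes the max/min score ratio for every gene pair represented by at
#' least two isoform pairs, and summarizes the spread: the fraction of
#' gene pairs exceeding `threshold` (default 3) and the observed range.
#'
#' @param network an [IsoformNetwork-class] with gene mapping (or supply
#'   `geneModels`).
#' @param threshold fold-change threshold to report the exceeding fraction
#'   for (default 3).
#' @param geneModels optional [GeneModels-class].
#' @return list with `table` (data.frame `geneA`, `geneB`, `nInstances`,
#'   `ratio`), `fractionAbove`, `threshold` and `range`.
#' @export
disparityDistribution <- function(network, threshold = 3,
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
  gA <- unname(map[e$isoformA]); gB <- unname(map[e$isoformB])
  ok <- !is.na(gA) & !is.na(gB) & gA != gB
  key <- pairKey(gA[ok], gB[ok])
  grp <- split(e$score[ok], key)
  grp <- grp[lengths(grp) >= 2L]
  if (!length(grp))
    return(list(table = data.frame(geneA = character(0),
                                   geneB = character(0),
                                   nInstances = integer(0),
                                   ratio = numeric(0)),
                fractionAbove = NA_real_, threshold = threshold,
                range = c(NA_real_, NA_real_)))
  ratio <- vapply(grp, function(s)
    if (min(s) == 0) Inf else max(s) / min(s), numeric(1))
  ab <- splitPairKey(names(grp))
  tab <- data.frame(geneA = ab$a, geneB = ab$b,
                    nInstances = lengths(grp), ratio = unname(ratio))
  list(table = tab, fractionAbove = mean(ratio > threshold),
       threshold = threshold,
       range = range(ratio[is.finite(ratio)]))
}

#' Top-k neighborhood of an isoform
#'
#' The k highest-scoring partners of an isoform in the network, ties
#' broken toward the lexicographically lowest accession.
#'
#' @param network an [IsoformNetwork-class].
#' @param isoform isoform accession (must be present in the network).
#' @param k neighborhood size (default 25).
#' @return a [LocalNetwork-class]; `truncated` is `TRUE` when fewer than
#'   `k` partners exist.
#' @export
topKNeighbors <- function(network, isoform, k = 25L) {
  e <- networkEdges(network)
  hitA <- e$isoformA == isoform
  hitB <- e$isoformB == isoform
  if (!any(hitA | hitB)) stop("isoform not in network: ", isoform)
  partner <- c(e$isoformB[hitA], e$isoformA[hitB])
  score <- c(e$score[hitA], e$score[hitB])
  ord <- order(-score, partner, method = "radix")
  take <- head(ord, k)
  methods::new("LocalNetwork", focal = isoform,
               neighbors = data.frame(isoform = partner[take],
                                      score = score[take]),
               k = as.integer(k), truncated = length(partner) < k)
}

#' Shared top-k neighbors of two isoforms
#'
#' Counts the isoforms common to the top-k neighborhoods of two isoforms
#' (for example, two isoforms of the same gene sharing 13 of their top 25
#' neighbors). With `level = "gene"` neighborhoods are first collapsed to
#' gene sets via the network's mapping.
#'
#' @param network an [IsoformNetwork-class].
#' @param isoformA,isoformB isoform accessions.
#' @param k neighborhood size (default 25).
#' @param level `"isoform"` (default) or `"gene"`.
#' @return integer in [0, k]; symmetric in the two isoforms.
#' @export
sharedNeighborCount <- function(network, isoformA, isoformB, k = 25L,
                                level = c("isoform", "gene")) {
  level <- match.arg(level)
  na <- topKNeighbors(network, isoformA, k)@neighbors$isoform
  nb <- topKNeighbors(network, isoformB, k)@neighbors$isoform
  if (level == "gene") {
    map <- isoformGeneMap(network)
    if (!length(map)) stop("gene-level counting needs a gene mapping")
    na <- unique(unname(map[na])); nb <- unique(unname(map[nb]))
  }
  length(intersect(na, nb))
}

#' GO-term enrichment of a local network
#'
#' One-sided hypergeometric test for over-representation of each
#' annotation term among the genes of a neighborhood, against a background
#' gene universe (by default the genes of the network under study):
#' P(X >= x) with X ~ Hypergeometric(termSize, N - termSize, nNeighbors).
#' Raw p-values are reported (Benjamini-Hochberg adjustment optional).
#'
#' @param localNetwork a [LocalNetwork-class], or a character vector of
#'   neighbor genes.
#' @param annotations data.frame with columns `gene`, `term`.
#' @param background character vector of background genes (non-empty).
#' @param isoformGene named character mapping used to collapse a
#'   neighborhood of isoforms to genes (required when `localNetwork` is a
#'   `LocalNetwork` of isoform accessions).
#' @param adjust if `TRUE`, add a BH-adjusted `padj` column.
#' @return data.frame with columns `term`, `overlap`, `neighborhood`,
#'   `termSize`, `background`, `p` sorted by ascending p.
#' @export
enrichmentTest <- function(localNetwork, annotations, background,
                           isoformGene = NULL, adjust = FALSE) {
  if (!length(background)) stop("empty background universe")
  genes <- if (methods::is(localNetwork, "LocalNetwork")) {
    iso <- localNetwork@neighbors$isoform
    if (is.null(isoformGene))
      stop("mapping isoforms to genes requires isoformGene")
    unique(unname(isoformGene[iso]))
  } else unique(as.character(localNetwork))
  background <- unique(as.character(background))
  genes <- intersect(genes, background)
  ann <- unique(annotations[annotations$gene %in% background,
                            c("gene", "term")])
  N <- length(background)
  n <- length(genes)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    annGenes <- ann$gene[ann$term == tm]
    K <- length(annGenes)
    x <- sum(genes %in% annGenes)
    data.frame(term = tm, overlap = x, neighborhood = n, termSize = K,
               background = N,
               p = phyper(x - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust) out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}
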