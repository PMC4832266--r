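#' @name accessors
#' @title Accessors for isomil classes
#'
#' @description Slot access for the package's S4 containers goes through
#' these generics; the slots themselves are implementation detail.
#'
#' @param x an isomil object.
#' @param gene optional gene id to restrict [isoformIds()] to.
#' @param isoform an isoform accession.
#' @return The obvious vector/data.frame for each accessor (see the class
#'   documentation).
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("isoformIds", function(x, gene = NULL) standardGeneric("isoformIds"))
#' @rdname accessors
#' @export
setGeneric("geneOf", function(x, isoform) standardGeneric("geneOf"))
#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("pairKeys", function(x) standardGeneric("pairKeys"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("nBags", function(x) standardGeneric("nBags"))
#' @rdname accessors
#' @export
setGeneric("bagIds", function(x) standardGeneric("bagIds"))
#' @rdname accessors
#' @export
setGeneric("bagLabels", function(x) standardGeneric("bagLabels"))
#' @rdname accessors
#' @export
setGeneric("bagSizes", function(x) standardGeneric("bagSizes"))
#' @rdname accessors
#' @export
setGeneric("instanceKeys", function(x) standardGeneric("instanceKeys"))
#' @rdname accessors
#' @export
setGeneric("instanceBag", function(x) standardGeneric("instanceBag"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("isoformGeneMap", function(x) standardGeneric("isoformGeneMap"))
#' @rdname accessors
#' @export
setGeneric("positivePairs", function(x) standardGeneric("positivePairs"))
#' @rdname accessors
#' @export
setGeneric("negativePairs", function(x) standardGeneric("negativePairs"))

#' Multi-isoform gene ratio (MGR)
#'
#' The fraction of genes carrying two or more annotated isoforms,
#' MGR = (# multi-isoform genes) / (# genes). For instance a build with
#' 3505 multi-isoform and 22287 single-isoform genes has
#' MGR = 3505/25792, about 13.5\%.
#'
#' @param x a [GeneModels-class] object.
#' @return a fraction in [0, 1].
#' @examples
#' gm <- GeneModels(list(A = c("t1", "t2"), B = "t3"))
#' computeMGR(gm)  # 0.5
#' @export
setGeneric("computeMGR", function(x) standardGeneric("computeMGR"))
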