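#' Parse gene models from a GTF file
#'
#' Reads a GTF (1-based, inclusive coordinates) and groups transcripts under
#' their genes; only the `gene_id` and `transcript_id` attributes are used
#' (coordinates play no further role). Optionally attaches protein sequences
#' from a FASTA file whose record names are isoform accessions.
#'
#' @param gtf path to a GTF file (gzip-transparent).
#' @param proteinFasta optional path to an amino-acid FASTA file.
#' @param codingOnly if `TRUE`, keep only isoforms with a protein sequence
#'   in `proteinFasta` (non-coding transcripts filtered out; default off).
#' @return a [GeneModels-class] object.
#' @details A transcript listed under two different `gene_id`s is a
#'   consistency error. Lines without both attributes (beyond plain
#'   gene-level records) are a parse error naming the offending transcript
#'   row.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "isomil")
#' gm <- parseGeneModels(gtf)
#' computeMGR(gm)
#' @export
parseGeneModels <- function(gtf, proteinFasta = NULL, codingOnly = FALSE) {
  firstLines <- readLines(gtf, n = 100L)
  if (!any(nzchar(firstLines) & !startsWith(firstLines, "#")))
    return(GeneModels(stats::setNames(list(), character(0))))
  gr <- tryCatch(rtracklayer::import(gtf, format = "gtf"),
                 error = function(e)
                   stop("GTF parse error in '", gtf, "': ",
                        conditionMessage(e), call. = FALSE))
  meta <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(meta))
    stop("GTF has no gene_id attribute")
  if (!"transcript_id" %in% names(meta))
    stop("GTF has no transcript_id attribute")
  g <- as.character(meta$gene_id)
  t <- as.character(meta$transcript_id)
  hasT <- !is.na(t) & t != ""
  bad <- which(hasT & (is.na(g) | g == ""))
  if (length(bad))
    stop("GTF record ", bad[1L], " has a transcript_id but no gene_id")
  g <- g[hasT]; t <- t[hasT]
  if (!length(t)) {
    gm <- GeneModels(stats::setNames(list(), character(0)))
    return(gm)
  }
  map <- unique(data.frame(gene = g, tx = t))
  dup <- map$tx[duplicated(map$tx)]
  if (length(dup))
    stop("transcript '", dup[1L], "' is assigned to more than one gene")
  prot <- NULL
  if (!is.null(proteinFasta)) {
    prot <- Biostrings::readAAStringSet(proteinFasta)
    names(prot) <- sub("\\s.*$", "", names(prot))
    if (codingOnly) {
      keep <- map$tx %in% names(prot)
      map <- map[keep, , drop = FALSE]
      if (!nrow(map)) stop("codingOnly left no transcripts")
    }
    prot <- prot[names(prot) %in% map$tx]
  } else if (codingOnly) {
    stop("codingOnly requires a proteinFasta")
  }
  GeneModels(split(map$tx, map$gene), proteins = prot)
}

#' Read an isoform-by-sample expression matrix
#'
#' Expects a TSV with isoform accessions in the first column and one column
#' per sample; empty cells or "NA" are missing. Files may be gzipped.
#'
#' @param path TSV path.
#' @return numeric matrix with isoform rownames.
#' @export
readExpressionMatrix <- function(path) {
  d <- read.delim(path, header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(d) < 3L)
    stop("expression matrix needs >= 2 sample columns for correlation")
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1L]])
  if (anyDuplicated(rownames(m))) stop("duplicated isoform rows")
  m
}

#' Read a pairwise docking-score table
#'
#' @param path TSV path with columns `isoform_a`, `isoform_b`, `score` (or
#'   any three columns in that order).
#' @return data.frame with columns `isoformA`, `isoformB`, `score`.
#' @export
readDockingTable <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop("docking table needs 3 columns")
  data.frame(isoformA = as.character(d[[1L]]),
             isoformB = as.character(d[[2L]]),
             score = as.numeric(d[[3L]]))
}

#' Read GO annotations from a GAF 2.x file
#'
#' Comment lines (`!`) are skipped. The gene identifier is taken from the
#' DB Object Symbol column (column 3) by default.
#'
#' @param path GAF path (gzip-transparent).
#' @param idColumn 2 for DB Object ID, 3 for DB Object Symbol.
#' @return annotation data.frame with columns `gene`, `term`, `evidence`,
#'   `aspect`, `source` (all rows tagged "GO").
#' @export
readGAF <- function(path, idColumn = 3L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene = character(0), term = character(0),
                      evidence = character(0), aspect = character(0),
                      source = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 9L)
  if (length(short))
    stop("GAF line ", short[1L], " has fewer than 9 columns")
  col <- function(i) vapply(parts, `[`, "", i)
  data.frame(gene = col(idColumn), term = col(5L), evidence = col(7L),
             aspect = col(9L), source = "GO")
}

#' Read pathway membership as annotations
#'
#' Two-column (gene, pathway) TSV, e.g. KEGG or BioCyc exports.
#'
#' @param path TSV path (a header line is expected).
#' @param source provenance tag, e.g. "KEGG" or "BioCyc".
#' @return annotation data.frame in the same shape as [readGAF()] (evidence
#'   and aspect are `NA` for pathway rows).
#' @export
readPathwayTable <- function(path, source = "KEGG") {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("pathway table needs 2 columns (gene, pathway)")
  data.frame(gene = as.character(d[[1L]]), term = as.character(d[[2L]]),
             evidence = NA_character_, aspect = NA_character_,
             source = source)
}

#' Write / read an isoform network as TSV
#'
#' The on-disk format has columns `isoform_a`, `isoform_b`, `score`, one
#' canonically ordered edge per line, scores printed with 6 decimals.
#' `readIsoformNetwork(writeIsoformNetwork(x))` restores the network
#' exactly at that precision. Paths ending in `.gz` are compressed.
#'
#' @param network an [IsoformNetwork-class].
#' @param path output/input TSV path.
#' @param isoformGene optional named character gene mapping to attach on
#'   read.
#' @return `writeIsoformNetwork()` returns `path` invisibly;
#'   `readIsoformNetwork()` returns an [IsoformNetwork-class].
#' @export
writeIsoformNetwork <- function(network, path) {
  stopifnot(methods::is(network, "IsoformNetwork"))
  methods::validObject(network)
  e <- networkEdges(network)
  out <- data.frame(isoform_a = e$isoformA, isoform_b = e$isoformB,
                    score = sprintf("%.6f", e$score))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIsoformNetwork
#' @export
readIsoformNetwork <- function(path, isoformGene = character(0)) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  net <- isoformNetwork(d$isoform_a, d$isoform_b, as.numeric(d$score),
                        isoformGene = isoformGene)
  methods::validObject(net)
  net
}

#' Write / read a feature table as TSV
#'
#' Pair keys are split into two id columns; missing cells serialize as
#' "NA".
#'
#' @param x a [FeatureTable-class].
#' @param path TSV path (gz-transparent on read; `.gz` suffix compresses on
#'   write).
#' @return `writeFeatureTable()` returns `path` invisibly;
#'   `readFeatureTable()` a [FeatureTable-class].
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(methods::is(x, "FeatureTable"))
  v <- featureValues(x)
  ab <- splitPairKey(rownames(v))
  out <- data.frame(isoform_a = ab$a, isoform_b = ab$b, v,
                    check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  d <- read.delim(path, header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- pairKey(d[[1L]], d[[2L]])
  FeatureTable(m)
}
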