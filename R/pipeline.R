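#' Generate miniature, internally consistent pipeline fixtures
#'
#' Writes a toy gene build (GTF), protein FASTA, expression matrices, GO
#' (GAF 2.2) and pathway annotations, and a docking-score table into
#' `dir`. The data contain planted functional modules: genes of a module
#' are co-annotated and their *first* isoform co-expresses with (and docks
#' well against) the first isoforms of the other module members, so the
#' full pipeline has real signal while non-functional isoforms stay at
#' background. Everything is synthetic; the same seed reproduces the
#' files byte for byte.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param scale `"tiny"` (40 genes, default) or `"small"` (120 genes).
#' @return invisible named list of file paths.
#' @export
generateFixtures <- function(dir, seed = 1L, scale = c("tiny", "small")) {
  scale <- match.arg(scale)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nGenes <- if (scale == "tiny") 40L else 120L
  nModules <- if (scale == "tiny") 4L else 8L
  moduleSize <- if (scale == "tiny") 5L else 6L
  nSamples <- c(expr_rnaseq = 12L, expr_exonarray = 16L)
  withSeed(seed, {
    genes <- sprintf("GENE%03d", seq_len(nGenes))
    nIso <- ifelse(runif(nGenes) < 0.35, 2L, 1L)
    isoforms <- lapply(seq_len(nGenes), function(g)
      sprintf("%s.%d", genes[g], seq_len(nIso[g])))
    names(isoforms) <- genes
    allIso <- unlist(isoforms, use.names = FALSE)
    module <- rep(NA_integer_, nGenes)
    module[seq_len(nModules * moduleSize)] <- rep(seq_len(nModules),
                                                  each = moduleSize)
    module <- sample(module)

    ## GTF: one transcript + one exon record per isoform
    paths <- list()
    start <- cumsum(c(1L, rep(2000L, length(allIso) - 1L)))
    gtf <- character(0)
    k <- 0L
    for (g in seq_len(nGenes)) for (t in seq_len(nIso[g])) {
      k <- k + 1L
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                       genes[g], isoforms[[g]][t])
      gtf <- c(gtf,
               paste("chr1", "toy", "transcript", start[k],
                     start[k] + 1499L, ".", "+", ".", attrs, sep = "\t"),
               paste("chr1", "toy", "exon", start[k], start[k] + 1499L,
                     ".", "+", ".", attrs, sep = "\t"))
    }
    paths$gtf <- file.path(dir, "models.gtf")
    writeLines(gtf, paths$gtf)

    ## protein FASTA
    aa <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1L]]
    paths$proteins <- file.path(dir, "proteins.fa")
    fasta <- unlist(lapply(allIso, function(id) {
      c(paste0(">", id),
        paste(sample(aa, sample(60:120, 1L), replace = TRUE),
              collapse = ""))
    }))
    writeLines(fasta, paths$proteins)

    ## expression: module factor drives the first isoform of module genes
    geneOfIso <- rep(seq_len(nGenes), nIso)
    isFirst <- unlist(lapply(nIso, function(n) c(TRUE, rep(FALSE, n - 1L))))
    for (ds in names(nSamples)) {
      ns <- nSamples[[ds]]
      z <- matrix(rnorm(nModules * ns), nModules, ns)
      m <- matrix(rnorm(length(allIso) * ns, sd = 1), length(allIso), ns)
      drive <- !is.na(module[geneOfIso]) & isFirst
      m[drive, ] <- 0.45 * m[drive, , drop = FALSE] +
        0.9 * z[module[geneOfIso[drive]], , drop = FALSE]
      tab <- data.frame(isoform = allIso, round(m, 4),
                        check.names = FALSE)
      colnames(tab)[-1L] <- sprintf("S%02d", seq_len(ns))
      paths[[ds]] <- file.path(dir, paste0(ds, ".tsv"))
      write.table(tab, paths[[ds]], sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }

    ## docking: strong scores for first-isoform pairs within modules
    dk <- list()
    for (mo in seq_len(nModules)) {
      mg <- which(module == mo)
      cb <- combn(mg, 2L)
      for (c1 in seq_len(ncol(cb))) {
        ia <- isoforms[[cb[1L, c1]]]; ib <- isoforms[[cb[2L, c1]]]
        for (a in ia) for (b in ib) {
          strong <- endsWith(a, ".1") && endsWith(b, ".1")
          dk[[length(dk) + 1L]] <- data.frame(
            isoform_a = a, isoform_b = b,
            score = round(rnorm(1L, if (strong) 0.8 else 0.25, 0.08), 4))
        }
      }
    }
    bgPairs <- matrix(sample(allIso, 2L * 60L, replace = TRUE), ncol = 2L)
    bgPairs <- bgPairs[bgPairs[, 1L] != bgPairs[, 2L], , drop = FALSE]
    dk[[length(dk) + 1L]] <- data.frame(
      isoform_a = bgPairs[, 1L], isoform_b = bgPairs[, 2L],
      score = round(rnorm(nrow(bgPairs), 0.25, 0.08), 4))
    dock <- do.call(rbind, dk)
    key <- pairKey(dock$isoform_a, dock$isoform_b)
    dock <- dock[!duplicated(key), , drop = FALSE]
    paths$docking <- file.path(dir, "docking.tsv")
    write.table(dock, paths$docking, sep = "\t", quote = FALSE,
                row.names = FALSE)

    ## GO annotations (GAF 2.2): one BP term per module, experimental
    ## codes, plus IEA noise rows that the evidence filter removes
    gafRow <- function(gene, term, evidence) {
      paste("TOYDB", gene, gene, "", term, "TOY:0001", evidence, "", "P",
            gene, "", "protein", "taxon:10090", "20160101", "TOYDB", "",
            "", sep = "\t")
    }
    gaf <- c("!gaf-version: 2.2")
    for (mo in seq_len(nModules)) {
      mg <- genes[which(module == mo)]
      code <- EXPERIMENTAL_CODES[(mo - 1L) %% 6L + 1L]
      gaf <- c(gaf, vapply(mg, gafRow, "",
                           term = sprintf("GO:%07d", 6900L + mo),
                           evidence = code))
    }
    iea <- sample(genes, 10L)
    gaf <- c(gaf, vapply(iea, gafRow, "", term = "GO:0008150",
                         evidence = "IEA"))
    paths$gaf <- file.path(dir, "annotations.gaf")
    writeLines(gaf, paths$gaf)

    ## pathways: half the modules double as pathways
    pw <- do.call(rbind, lapply(seq_len(max(1L, nModules %/% 2L)),
      function(mo) data.frame(gene = genes[which(module == mo)],
                              pathway = sprintf("path%02d", mo))))
    paths$pathways <- file.path(dir, "pathways.tsv")
    write.table(pw, paths$pathways, sep = "\t", quote = FALSE,
                row.names = FALSE)

    invisible(paths)
  })
}

.PIPELINE_KEYS <- c("gtf", "proteins", "expression", "docking", "gaf",
                    "pathways", "negativeRatio", "maxTermSize", "lambda",
                    "w", "nBins", "pseudocount", "tol", "maxIter",
                    "cvFolds", "disparityThreshold", "seed")

#' Run the full inference pipeline on file inputs
#'
#' Wires every stage together: gene models -> pairwise features (one
#' correlation column per expression dataset, one composition-similarity
#' column, one docking column) -> co-annotation gold standard -> MIL bags
#' -> SIB-MIL training -> genome-wide scoring -> evaluation and disparity
#' analysis. Artifacts written to `outDir`: `network.tsv.gz`,
#' `model.json`, `features.tsv.gz`, `goldstandard.tsv`, `cv_metrics.tsv`,
#' `disparity.tsv` and `config.yaml` (the echoed configuration).
#'
#' @param config named list or path to a YAML file. Recognized keys:
#'   `gtf`, `proteins`, `expression` (character vector), `docking`,
#'   `gaf`, `pathways` (file paths; the last two optional),
#'   `negativeRatio` (default 19), `maxTermSize` (default 300), `lambda`,
#'   `w` (PseAAC), `nBins`, `pseudocount`, `tol`, `maxIter` (learner),
#'   `cvFolds` (default 3), `disparityThreshold` (default 3), `seed`.
#'   Unknown keys are rejected.
#' @param outDir output directory.
#' @return invisible named list of artifact paths.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults <- list(negativeRatio = 19, maxTermSize = 300L, lambda = 10L,
                   w = 0.05, nBins = 5L, pseudocount = 1, tol = 1e-4,
                   maxIter = 20L, cvFolds = 3L, disparityThreshold = 3,
                   seed = 1L)
  config <- utils::modifyList(defaults, config)
  for (key in c("gtf", "proteins", "expression", "gaf"))
    if (is.null(config[[key]]))
      stop("config key '", key, "' is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  gm <- stage("gene_models",
              parseGeneModels(config$gtf, proteinFasta = config$proteins))
  ## candidate pairs: all isoform pairs across distinct genes
  allIso <- isoformIds(gm)
  geneOfAll <- geneOf(gm, allIso)
  cb <- combn(seq_along(allIso), 2L)
  cross <- geneOfAll[cb[1L, ]] != geneOfAll[cb[2L, ]]
  pairs <- list(isoformA = allIso[cb[1L, cross]],
                isoformB = allIso[cb[2L, cross]])

  feats <- stage("features", {
    cols <- list()
    for (p in config$expression) {
      id <- sub("\\.tsv(\\.gz)?$", "", basename(p))
      cols[[id]] <- pairwiseCorrelation(readExpressionMatrix(p), pairs)
    }
    cols$pseaac <- pseaacFeature(proteins(gm), pairs,
                                 lambda = config$lambda, w = config$w)
    if (!is.null(config$docking))
      cols$docking <- dockingFeature(readDockingTable(config$docking),
                                     pairs)
    assembleFeatures(cols)
  })

  gold <- stage("gold_standard", {
    ann <- readGAF(config$gaf)
    if (!is.null(config$pathways))
      ann <- rbind(ann, readPathwayTable(config$pathways))
    ann <- filterExperimental(ann)
    pos <- coAnnotationPositives(ann, maxTermSize = config$maxTermSize)
    neg <- sampleNegatives(geneIds(gm), pos, ratio = config$negativeRatio,
                           seed = config$seed)
    goldStandard(pos, neg, evidenceFiltered = TRUE)
  })

  bags <- stage("bags", buildBags(gold, gm, feats))
  ctrl <- sibmilControl(nBins = config$nBins,
                        pseudocount = config$pseudocount,
                        tol = config$tol, maxIter = config$maxIter,
                        seed = config$seed)
  fit <- stage("train", sibmilFit(bags, ctrl))

  isoGene <- stats::setNames(geneOfAll, allIso)
  net <- stage("predict",
               suppressMessages(scoreNetwork(fit, feats,
                                             isoformGene = isoGene)))
  cv <- stage("evaluate", kfoldCV(bags, k = config$cvFolds, ctrl,
                                  seed = config$seed))
  disp <- stage("analyze",
                disparityDistribution(net,
                                      threshold = config$disparityThreshold))

  paths <- list(network = file.path(outDir, "network.tsv.gz"),
                model = file.path(outDir, "model.json"),
                features = file.path(outDir, "features.tsv.gz"),
                goldstandard = file.path(outDir, "goldstandard.tsv"),
                cv = file.path(outDir, "cv_metrics.tsv"),
                disparity = file.path(outDir, "disparity.tsv"),
                config = file.path(outDir, "config.yaml"))
  writeIsoformNetwork(net, paths$network)
  writeNBModel(fit@model, paths$model)
  writeFeatureTable(feats, paths$features)
  gsTab <- rbind(cbind(positivePairs(gold)[c("geneA", "geneB")], label = 1L),
                 cbind(negativePairs(gold), label = 0L))
  write.table(gsTab, paths$goldstandard, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cv, paths$cv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(disp$table, paths$disparity, sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(config, paths$config)
  invisible(paths)
}
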