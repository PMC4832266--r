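#' Equal-frequency discretization of a feature table
#'
#' Fits per-feature equal-frequency bin edges (quantiles of the observed
#' training values) and assigns integer bin codes. Missing values get the
#' dedicated code 0, never a value bin. Features with fewer distinct
#' values than `nBins` get fewer bins (a constant feature collapses to a
#' single bin).
#'
#' @param x numeric matrix (rows = instances, cols = features) or a
#'   [FeatureTable-class] / [BagSet-class].
#' @param nBins target number of bins per feature (>= 2, default 5).
#' @return list with elements `binned` (integer matrix; 0 = missing,
#'   1..k = bins), `breaks` (per-feature inner edges, reused verbatim at
#'   prediction time via [binWithBreaks()]) and `nBins` (realized bin
#'   count per feature).
#' @export
discretizeFeatures <- function(x, nBins = 5L) {
  x <- .asFeatureMatrix(x)
  if (nBins < 2L) stop("nBins must be >= 2")
  breaks <- lapply(seq_len(ncol(x)), function(f) {
    v <- x[, f]
    v <- v[!is.na(v)]
    if (!length(v)) return(numeric(0))
    q <- unique(quantile(v, probs = seq(0, 1, length.out = nBins + 1L),
                         names = FALSE, type = 7))
    inner <- q[-c(1L, length(q))]
    inner[inner > min(v) & inner <= max(v)]
  })
  names(breaks) <- colnames(x)
  k <- vapply(breaks, length, 0L) + 1L
  if (any(k < nBins))
    message(sum(k < nBins), " feature(s) realized fewer than ", nBins,
            " bins (ties or constants)")
  list(binned = binWithBreaks(breaks, x), breaks = breaks, nBins = k)
}

#' @rdname discretizeFeatures
#' @param breaks per-feature inner bin edges from a previous fit.
#' @export
binWithBreaks <- function(breaks, x) {
  x <- .asFeatureMatrix(x)
  if (length(breaks) != ncol(x))
    stop("breaks do not match the feature columns")
  B <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (f in seq_len(ncol(x))) {
    v <- x[, f]
    b <- findInterval(v, breaks[[f]]) + 1L
    b[is.na(v)] <- 0L
    B[, f] <- b
  }
  B
}

.asFeatureMatrix <- function(x) {
  if (methods::is(x, "FeatureTable") || methods::is(x, "BagSet"))
    x <- featureValues(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Fit the discretized naive Bayes base learner
#'
#' Discretizes the training rows with equal-frequency bins and estimates,
#' per feature and class, the conditional probability table
#' \eqn{P(bin \mid y)} with Laplace smoothing:
#' `(count + pseudocount) / (class total + pseudocount * nBins)`, the
#' missing-data bin included. The prior defaults to the empirical class
#' fraction.
#'
#' @param x training features (matrix, [FeatureTable-class] or
#'   [BagSet-class] -- for a BagSet the *bag* labels are not used; pass
#'   instance labels explicitly).
#' @param labels integer/logical vector of instance labels (1/TRUE =
#'   positive); both classes must be present.
#' @param nBins bins per feature (default 5).
#' @param pseudocount Laplace smoothing constant (default 1; 0 allows
#'   degenerate 0/1 probabilities).
#' @param prior optional override of P(y = 1).
#' @param missingMode `"bin"` (default) or `"drop"`, see
#'   [NaiveBayesModel-class].
#' @return a [NaiveBayesModel-class].
#' @examples
#' x <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(NULL, "f"))
#' m <- fitNaiveBayes(x, c(0, 0, 1, 1), nBins = 2)
#' posteriorScores(m, x)
#' @export
fitNaiveBayes <- function(x, labels, nBins = 5L, pseudocount = 1,
                          prior = NULL, missingMode = c("bin", "drop")) {
  missingMode <- match.arg(missingMode)
  x <- .asFeatureMatrix(x)
  d <- discretizeFeatures(x, nBins = nBins)
  .nbFitBinned(d$binned, labels, d$breaks, d$nBins, pseudocount, prior,
               missingMode,
               colnames(x) %||% paste0("F", seq_len(ncol(x))))
}

## core estimator on pre-binned codes (0 = missing, 1..k = bins)
.nbFitBinned <- function(binned, labels, breaks, nBinsVec, pseudocount = 1,
                         prior = NULL, missingMode = "bin", featureIds) {
  y <- as.integer(as.logical(labels))
  if (length(y) != nrow(binned)) stop("labels must match rows")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to fit the classifier")
  nf <- ncol(binned)
  maxK <- max(nBinsVec)
  cpt1 <- matrix(NA_real_, maxK + 1L, nf)
  cpt0 <- matrix(NA_real_, maxK + 1L, nf)
  i1 <- y == 1L
  for (f in seq_len(nf)) {
    nb <- nBinsVec[f] + 1L                       # value bins + missing bin
    c1 <- tabulate(binned[i1, f] + 1L, nb)
    c0 <- tabulate(binned[!i1, f] + 1L, nb)
    if (missingMode == "drop") {
      ## missing data are skipped at scoring time, so the CPT normalizes
      ## over the value bins only; missing counts are excluded
      use <- seq_len(nb)[-1L]
      cpt1[use, f] <- (c1[-1L] + pseudocount) /
        (sum(c1[-1L]) + pseudocount * (nb - 1L))
      cpt0[use, f] <- (c0[-1L] + pseudocount) /
        (sum(c0[-1L]) + pseudocount * (nb - 1L))
    } else {
      cpt1[seq_len(nb), f] <- (c1 + pseudocount) / (n1 + pseudocount * nb)
      cpt0[seq_len(nb), f] <- (c0 + pseudocount) / (n0 + pseudocount * nb)
    }
  }
  if (is.null(prior)) prior <- n1 / (n1 + n0)
  methods::new("NaiveBayesModel", prior = prior, breaks = breaks,
               cpt1 = cpt1, cpt0 = cpt0, nBins = as.integer(nBinsVec),
               pseudocount = pseudocount, missingMode = missingMode,
               featureIds = as.character(featureIds))
}

#' Posterior probability of a functional relationship
#'
#' Scores instances with the Bayes formula
#' \deqn{P(y=1 \mid E) = \frac{P(y=1)\prod_i P(E_i \mid y=1)}
#'   {P(y=1)\prod_i P(E_i \mid y=1) + P(y=0)\prod_i P(E_i \mid y=0)}}
#' computed in log space (no underflow for hundreds of features). Missing
#' features contribute the missing-bin likelihood (`missingMode = "bin"`)
#' or are skipped (`"drop"`).
#'
#' @param model a [NaiveBayesModel-class].
#' @param x features to score (matrix / [FeatureTable-class] /
#'   [BagSet-class]); raw values are binned with the model's stored edges.
#' @return numeric vector of posteriors in [0, 1].
#' @export
posteriorScores <- function(model, x) {
  x <- .asFeatureMatrix(x)
  if (ncol(x) != length(model@featureIds))
    stop("feature columns do not match the model")
  .nbScoreBinned(model, binWithBreaks(model@breaks, x))
}

#' @describeIn posteriorScores `predict` method; `newdata` as `x` above.
#' @param object a [NaiveBayesModel-class].
#' @param newdata features to score.
#' @param ... ignored.
#' @export
setMethod("predict", "NaiveBayesModel",
          function(object, newdata, ...) posteriorScores(object, newdata))

.nbScoreBinned <- function(model, binned) {
  nf <- ncol(binned)
  logit <- rep(log(model@prior) - log1p(-model@prior), nrow(binned))
  for (f in seq_len(nf)) {
    b <- binned[, f]
    if (any(b > model@nBins[f]) || any(b < 0L))
      stop("unseen bin code for feature ", model@featureIds[f])
    d <- log(model@cpt1[, f]) - log(model@cpt0[, f])
    if (model@missingMode == "drop") d[1L] <- 0
    logit <- logit + d[b + 1L]
  }
  plogis(logit)
}

#' Serialize / restore a naive Bayes model as versioned JSON
#'
#' @param model a [NaiveBayesModel-class].
#' @param path JSON file path.
#' @return `writeNBModel()` returns `path` invisibly; `readNBModel()` the
#'   restored [NaiveBayesModel-class].
#' @export
writeNBModel <- function(model, path) {
  feats <- lapply(seq_along(model@featureIds), function(f) {
    used <- seq_len(model@nBins[f] + 1L)
    ## bin edges as %.17g strings: lossless for doubles, so instances on
    ## an edge bin identically after reload
    list(id = model@featureIds[f],
         breaks = sprintf("%.17g", model@breaks[[f]]),
         p1 = model@cpt1[used, f], p0 = model@cpt0[used, f])
  })
  doc <- list(format = "isomil-nb-model", version = 1L,
              prior = model@prior, pseudocount = model@pseudocount,
              missingMode = model@missingMode, features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeNBModel
#' @export
readNBModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "isomil-nb-model"))
    stop("not an isomil model file")
  fl <- doc$features
  if (is.data.frame(fl)) fl <- split(fl, seq_len(nrow(fl)))
  ids <- vapply(fl, function(f) as.character(f$id), "")
  breaks <- lapply(fl, function(f) as.numeric(unlist(f$breaks)))
  p1 <- lapply(fl, function(f) as.numeric(unlist(f$p1)))
  p0 <- lapply(fl, function(f) as.numeric(unlist(f$p0)))
  k <- vapply(p1, length, 0L) - 1L
  maxK <- max(k)
  cpt1 <- matrix(NA_real_, maxK + 1L, length(ids))
  cpt0 <- matrix(NA_real_, maxK + 1L, length(ids))
  for (f in seq_along(ids)) {
    cpt1[seq_len(k[f] + 1L), f] <- p1[[f]]
    cpt0[seq_len(k[f] + 1L), f] <- p0[[f]]
  }
  methods::new("NaiveBayesModel", prior = doc$prior,
               breaks = stats::setNames(breaks, ids), cpt1 = cpt1,
               cpt0 = cpt0, nBins = as.integer(k),
               pseudocount = doc$pseudocount,
               missingMode = doc$missingMode, featureIds = ids)
}
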