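## Small in-code fixtures shared across test files.

## A hand-sized BagSet: bag1 positive single-instance, bag2 positive with
## 4 instances, bag3 negative with 2, bag4 negative single-instance.
makeToyBags <- function(nFeatures = 3L, seed = 11L) {
  withr::local_seed(seed)
  keys <- c("a1|b1",
            "c1|d1", "c1|d2", "c2|d1", "c2|d2",
            "e1|f1", "e1|f2",
            "g1|h1")
  X <- matrix(rnorm(length(keys) * nFeatures), length(keys), nFeatures,
              dimnames = list(keys, paste0("F", seq_len(nFeatures))))
  BagSet(X, instanceBag = c(1L, 2L, 2L, 2L, 2L, 3L, 3L, 4L),
         bagIds = c("A|B", "C|D", "E|F", "G|H"),
         bagLabels = c(1L, 1L, 0L, 0L))
}

## toy network: one multi-isoform gene pair with the worked-example score
## spread, plus a single-instance pair
ptbp1BanfNetwork <- function() {
  isoformNetwork(
    isoformA = c("P.1", "P.1", "P.2", "P.2", "Q.1"),
    isoformB = c("B.1", "B.2", "B.1", "B.2", "R.1"),
    score = c(0.999, 0.233, 0.084, 0.045, 0.7),
    isoformGene = c(P.1 = "Ptbp1", P.2 = "Ptbp1", B.1 = "Banf1",
                    B.2 = "Banf1", Q.1 = "Q", R.1 = "R"))
}

writeToyGTF <- function(path, lines = NULL) {
  if (is.null(lines))
    lines <- c(
      paste("chr1", "src", "transcript", "1", "100", ".", "+", ".",
            'gene_id "A"; transcript_id "t1";', sep = "\t"),
      paste("chr1", "src", "exon", "1", "50", ".", "+", ".",
            'gene_id "A"; transcript_id "t1";', sep = "\t"),
      paste("chr1", "src", "transcript", "200", "300", ".", "+", ".",
            'gene_id "A"; transcript_id "t2";', sep = "\t"),
      paste("chr1", "src", "transcript", "400", "500", ".", "-", ".",
            'gene_id "B"; transcript_id "t3";', sep = "\t"))
  writeLines(lines, path)
  path
}

## brute-force AUC oracle: fraction of concordant positive/negative score
## pairs, ties counted half
bruteForceAUC <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

## brute-force step-integral AUPRC oracle over descending thresholds
bruteForceAUPRC <- function(scores, labels) {
  y <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  prevRec <- 0; area <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(y & sel) / sum(sel)
    rec <- sum(y & sel) / sum(y)
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
  }
  area
}

## exact hypergeometric upper-tail oracle via binomial coefficients
bruteForceHyperP <- function(x, K, N, n) {
  ivals <- x:min(K, n)
  sum(choose(K, ivals) * choose(N - K, n - ivals)) / choose(N, n)
}
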