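test_that("equal-frequency bins match a sort-based oracle on 1..100", {
  x <- matrix(sample(1:100), 100, 1, dimnames = list(NULL, "f"))
  d <- discretizeFeatures(x, nBins = 4)
  expect_identical(d$nBins[["f"]], 4L)
  ## sort-based oracle: each quartile bin holds exactly 25 values and
  ## bins are ordered blocks of the sorted data
  counts <- tabulate(d$binned[, 1], 4)
  expect_identical(counts, rep(25L, 4))
  ord <- order(x[, 1])
  expect_identical(d$binned[ord, 1], rep(1:4, each = 25))
  ## edges are reused verbatim at prediction time
  expect_identical(binWithBreaks(d$breaks, x), d$binned)
})

test_that("constants collapse to one bin and missing gets its own code", {
  x <- cbind(const = rep(3, 10), v = c(NA, 1:9))
  expect_message(d <- discretizeFeatures(x, nBins = 5), "fewer than 5")
  expect_identical(d$nBins[["const"]], 1L)
  expect_identical(unique(d$binned[, "const"]), 1L)
  expect_identical(unname(d$binned[1, "v"]), 0L)  # missing code, never a bin
  expect_true(all(d$binned[-1, "v"] >= 1L))
})

test_that("CPT estimation matches the hand-counted Laplace formula", {
  ## 2 instances per class, one binary feature, counts split across bins:
  ## (1 + 1) / (2 + 1 * 2) = 0.5 for every cell
  x <- matrix(c(0, 1, 0, 1), 4, 1, dimnames = list(NULL, "f"))
  m <- fitNaiveBayes(x, c(1, 1, 0, 0), nBins = 2, pseudocount = 1,
                     missingMode = "drop")
  expect_equal(m@cpt1[2:3, 1], c(0.5, 0.5))
  expect_equal(m@cpt0[2:3, 1], c(0.5, 0.5))
  expect_equal(m@prior, 0.5)
  ## with the missing bin in the smoothing (bin mode): (1+1)/(2+1*3)
  mb <- fitNaiveBayes(x, c(1, 1, 0, 0), nBins = 2, pseudocount = 1,
                      missingMode = "bin")
  expect_equal(mb@cpt1[1:3, 1], c(0.2, 0.4, 0.4))
})

test_that("a perfectly separated feature degenerates without smoothing", {
  x <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(NULL, "f"))
  m <- fitNaiveBayes(x, c(0, 0, 1, 1), nBins = 2, pseudocount = 0,
                     missingMode = "drop")
  expect_equal(sort(m@cpt1[2:3, 1]), c(0, 1))
  expect_equal(posteriorScores(m, x), c(0, 0, 1, 1))
})

test_that("the model is invariant to instance order and needs 2 classes", {
  withr::local_seed(8)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("F", 1:3)))
  y <- rep(c(0, 1), 10)
  m1 <- fitNaiveBayes(x, y)
  p <- sample(20)
  m2 <- fitNaiveBayes(x[p, ], y[p])
  expect_equal(m1@cpt1, m2@cpt1)
  expect_equal(m1@cpt0, m2@cpt0)
  expect_equal(m1@breaks, m2@breaks)
  expect_error(fitNaiveBayes(x, rep(1, 20)), "both classes")
})

test_that("posterior equals the prior when every feature is uninformative", {
  ## identical feature distribution in both classes -> equal CPTs
  x <- matrix(rep(c(1, 2), 10), 20, 1, dimnames = list(NULL, "f"))
  m <- fitNaiveBayes(x, rep(c(0, 1), each = 10), nBins = 2,
                     prior = 0.3)
  expect_equal(posteriorScores(m, x), rep(0.3, 20), tolerance = 1e-12)
})

test_that("posterior matches a brute-force Bayes computation", {
  withr::local_seed(13)
  x <- matrix(sample(c(10, 20, 30), 60, replace = TRUE), 30, 2,
              dimnames = list(NULL, c("F1", "F2")))
  y <- rep(c(1, 0), 15)
  m <- fitNaiveBayes(x, y, nBins = 3, pseudocount = 1)
  got <- posteriorScores(m, x)
  ## independent oracle: count bins, smooth, multiply, renormalize
  binned <- binWithBreaks(m@breaks, x)
  prior <- mean(y)
  oracle <- vapply(seq_len(nrow(x)), function(i) {
    l1 <- prior; l0 <- 1 - prior
    for (f in 1:2) {
      nb <- m@nBins[f] + 1L
      for (cls in c(1, 0)) {
        cnt <- sum(binned[y == cls, f] == binned[i, f])
        p <- (cnt + 1) / (sum(y == cls) + nb)
        if (cls == 1) l1 <- l1 * p else l0 <- l0 * p
      }
    }
    l1 / (l1 + l0)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("a likelihood ratio above 1 strictly increases the posterior", {
  mk <- function(nf, p1, p0) {
    cpt1 <- rbind(0.2, matrix(p1, 2, nf))
    cpt0 <- rbind(0.2, matrix(p0, 2, nf))
    cpt1 <- sweep(cpt1, 2, colSums(cpt1), "/")
    cpt0 <- sweep(cpt0, 2, colSums(cpt0), "/")
    new("NaiveBayesModel", prior = 0.5,
        breaks = rep(list(0.5), nf), cpt1 = cpt1, cpt0 = cpt0,
        nBins = rep(2L, nf), pseudocount = 1, missingMode = "bin",
        featureIds = paste0("F", seq_len(nf)))
  }
  m1 <- mk(1, c(0.6, 0.2), c(0.4, 0.4))
  m2 <- mk(2, c(0.6, 0.2), c(0.4, 0.4))
  x1 <- matrix(0, 1, 1); x2 <- matrix(0, 1, 2)
  expect_gt(posteriorScores(m2, x2), posteriorScores(m1, x1))
})

test_that("posterior and its complement sum to one", {
  withr::local_seed(21)
  x <- matrix(rnorm(100), 25, 4, dimnames = list(NULL, paste0("F", 1:4)))
  y <- rep(c(0, 1), length.out = 25)
  m <- fitNaiveBayes(x, y)
  flip <- new("NaiveBayesModel", prior = 1 - m@prior, breaks = m@breaks,
              cpt1 = m@cpt0, cpt0 = m@cpt1, nBins = m@nBins,
              pseudocount = m@pseudocount, missingMode = m@missingMode,
              featureIds = m@featureIds)
  tot <- posteriorScores(m, x) + posteriorScores(flip, x)
  expect_true(all(abs(tot - 1) < 1e-9))
})

test_that("log-space scoring survives 200 tiny-likelihood features", {
  nf <- 200L
  cpt1 <- rbind(1e-6, 2e-6, 1 - 3e-6)[, rep(1, nf)]
  cpt0 <- rbind(1e-6, 1e-6, 1 - 2e-6)[, rep(1, nf)]
  m <- new("NaiveBayesModel", prior = 0.5, breaks = rep(list(0.5), nf),
           cpt1 = cpt1, cpt0 = cpt0, nBins = rep(2L, nf),
           pseudocount = 1, missingMode = "bin",
           featureIds = paste0("F", seq_len(nf)))
  x <- matrix(0, 1, nf)           # every feature in the 2e-6 vs 1e-6 bin
  got <- posteriorScores(m, x)
  want <- plogis(nf * log(2))     # direct log-odds arithmetic
  expect_equal(got, want, tolerance = 1e-9)
  expect_false(is.nan(got))
})

test_that("missing features use the missing bin or are dropped", {
  x <- matrix(c(0, 0, 1, 1, NA, NA, 0, 1), 4, 2,
              dimnames = list(NULL, c("F1", "F2")))
  y <- c(1, 1, 0, 0)
  mBin <- fitNaiveBayes(x, y, nBins = 2, missingMode = "bin")
  mDrop <- fitNaiveBayes(x, y, nBins = 2, missingMode = "drop")
  xNew <- matrix(c(0, NA), 1, 2)
  ## drop mode: only F1 contributes; bin mode adds the missing-bin term
  expect_false(isTRUE(all.equal(posteriorScores(mBin, xNew),
                                posteriorScores(mDrop, xNew))))
  ## all-missing instance scores at the prior in drop mode
  expect_equal(posteriorScores(mDrop, matrix(NA_real_, 1, 2)),
               mDrop@prior)
})

test_that("models round-trip through JSON in both missing modes", {
  withr::local_seed(30)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("F", 1:4)))
  x[sample(80, 8)] <- NA
  y <- rep(c(0, 1), 10)
  for (mode in c("bin", "drop")) {
    m <- fitNaiveBayes(x, y, missingMode = mode)
    f <- withr::local_tempfile(fileext = ".json")
    writeNBModel(m, f)
    back <- readNBModel(f)
    expect_equal(posteriorScores(back, x), posteriorScores(m, x),
                 tolerance = 1e-12)
    expect_equal(back@prior, m@prior)
  }
})
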