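test_that("AUC handles separation, constants and ties correctly", {
  expect_equal(aucScore(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(aucScore(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  ## 6-point tied example against the exhaustive pairwise oracle
  s <- c(0.1, 0.5, 0.5, 0.7, 0.5, 0.2)
  y <- c(0, 0, 1, 1, 0, 1)
  expect_equal(aucScore(s, y), bruteForceAUC(s, y))
  expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC equals the concordant-pair fraction on random inputs", {
  withr::local_seed(44)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # heavy ties
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(aucScore(s, y), bruteForceAUC(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(45)
  s <- rnorm(60)
  y <- sample(0:1, 60, replace = TRUE, prob = c(0.7, 0.3))
  expect_equal(aucScore(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("AUPRC matches the hand-summed step integral", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  r <- auprcScore(s, y)
  expect_equal(r$auprc, bruteForceAUPRC(s, y), tolerance = 1e-12)
  ## hand sum: thresholds descending, precision at each new recall step
  want <- 0.25 * 1 + 0.25 * (2 / 3) + 0.25 * (3 / 4) + 0.25 * (4 / 7)
  expect_equal(r$auprc, want, tolerance = 1e-12)
  expect_true(all(diff(r$curve$recall) >= 0))
  expect_equal(auprcScore(c(2, 3, 1), c(0, 1, 0))$auprc, 1)
})

test_that("random-score AUPRC approaches the positive fraction", {
  withr::local_seed(46)
  s <- runif(4000)
  y <- rep(c(1, 0), c(200, 3800))
  expect_lt(abs(auprcScore(s, y)$auprc - 0.05), 0.02)
})

test_that("k-fold CV tests every bag once and is seed-stable", {
  cfg <- simulationConfig(md = 1.5, mgr = 0.3, nGenes = 150, nBags = 600,
                          nFeatures = 10, seed = 51)
  bags <- simulateBags(cfg)
  cv <- kfoldCV(bags, k = 2, seed = 6)
  expect_identical(sum(cv$n), nBags(bags))
  expect_identical(kfoldCV(bags, k = 2, seed = 6), cv)
  ## strongly separable data: the single-isoform stratum (true
  ## isoform-level gold standard) is well classified
  single <- cv[cv$stratum == "single_isoform", ]
  expect_true(all(single$auc > 0.9))
  expect_error(kfoldCV(bags, k = 1), "k must be")
})

test_that("interaction validation sets split implicated pairs exactly", {
  gm <- GeneModels(list(G1 = c("a1", "a2"), G2 = c("b1", "b2"),
                        G3 = "c1"))
  inter <- data.frame(isoformA = c("a1", "a1", "a2"),
                      isoformB = c("b1", "a1", "c1"))
  vs <- buildInteractionValidationSet(inter, gm)
  expect_identical(vs@nSameIsoformDropped, 1L)
  posKeys <- pairKey(vs@positives$isoformA, vs@positives$isoformB)
  negKeys <- pairKey(vs@negatives$isoformA, vs@negatives$isoformB)
  expect_setequal(posKeys, c("a1|b1", "a2|c1"))
  ## implicated gene pairs G1-G2 (4 isoform pairs) and G1-G3 (2)
  expect_identical(length(posKeys) + length(negKeys), 6L)
  expect_setequal(negKeys, c("a1|b2", "a2|b1", "a2|b2", "a1|c1"))
  expect_length(intersect(posKeys, negKeys), 0L)
})

test_that("validation-set construction reproduces the published counts", {
  ## synthetic stand-in shaped like the interaction screen: 326 gene
  ## pairs, both genes with 2 isoforms (4 isoform pairs each); 288 pairs
  ## have 2 interacting isoform pairs, 38 have 1; plus 15 same-isoform
  ## records -> 629 input pairs, 614 positives, 1304 enumerated, 690
  ## negatives
  nA <- 288L; nB <- 38L
  genes <- sprintf("G%03d", seq_len(2L * (nA + nB)))
  iso <- lapply(genes, function(g) paste0(g, ".", 1:2))
  names(iso) <- genes
  gm <- GeneModels(iso)
  gA <- genes[seq_len(nA + nB) * 2L - 1L]
  gB <- genes[seq_len(nA + nB) * 2L]
  inter <- rbind(
    data.frame(isoformA = paste0(gA, ".1"), isoformB = paste0(gB, ".1")),
    data.frame(isoformA = paste0(gA[seq_len(nA)], ".2"),
               isoformB = paste0(gB[seq_len(nA)], ".2")),
    data.frame(isoformA = paste0(gA[1:15], ".1"),
               isoformB = paste0(gA[1:15], ".1")))
  expect_identical(nrow(inter), 629L)
  vs <- buildInteractionValidationSet(inter, gm)
  expect_identical(nrow(vs@positives), 614L)    # 629 - 15 same-isoform
  expect_identical(nrow(vs@negatives), 690L)    # 1304 - 614
  expect_identical(vs@nSameIsoformDropped, 15L)
})

test_that("the permutation control reports a mean + 3 sd threshold", {
  cfg <- simulationConfig(md = 0.8, mgr = 0.3, nGenes = 150, nBags = 800,
                          nFeatures = 8, seed = 61)
  bags <- simulateBags(cfg)
  ctl <- suppressWarnings(randomNetworkControl(bags, sibmilControl(seed = 2),
                                               seed = 3))
  expect_identical(ctl$threshold, ctl$mu + 3 * ctl$sigma)
  expect_length(ctl$scores, nrow(featureValues(bags)))
  ## on separable data the true model pushes witnesses past the null
  ## threshold
  fit <- sibmilFit(bags, sibmilControl(seed = 2))
  s <- posteriorScores(fit@model, featureValues(bags))
  expect_gt(mean(s[truthLabels(bags)] > ctl$threshold), 0.5)
})

test_that("novel-prediction overlap counts match brute force", {
  withr::local_seed(71)
  iso <- sprintf("G%02d.1", 1:12)
  map <- setNames(sub("\\.1$", "", iso), iso)
  cb <- combn(iso, 2)
  net <- isoformNetwork(cb[1, ], cb[2, ], runif(ncol(cb)),
                        isoformGene = map)
  refAll <- data.frame(geneA = sub("\\.1$", "", cb[1, ]),
                       geneB = sub("\\.1$", "", cb[2, ]))
  refNone <- data.frame(geneA = "X1", geneB = "X2")
  refSome <- refAll[1:10, ]
  out <- novelPredictionOverlap(net,
                                list(all = refAll, none = refNone,
                                     some = refSome),
                                threshold = 0.5, nRandom = 200, seed = 4)
  e <- networkEdges(net)
  predKeys <- pairKey(map[e$isoformA], map[e$isoformB])[e$score > 0.5]
  expect_identical(out$validated[out$reference == "all"],
                   length(predKeys))
  expect_identical(out$foldChange[out$reference == "all"], 1)
  expect_identical(out$validated[out$reference == "none"], 0L)
  wantSome <- sum(predKeys %in% pairKey(refSome$geneA, refSome$geneB))
  expect_identical(out$validated[out$reference == "some"], wantSome)
  expect_true(all(out$pValue > 0 & out$pValue <= 1))
})
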