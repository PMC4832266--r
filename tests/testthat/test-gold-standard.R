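annRow <- function(gene, term, evidence = "IDA", aspect = "P",
                   source = "GO") {
  data.frame(gene = gene, term = term, evidence = evidence,
             aspect = aspect, source = source)
}

test_that("co-annotation yields all pairs sharing a term", {
  ann <- rbind(annRow(c("g1", "g2", "g3"), "T1"),
               annRow("g4", "T2"))
  pos <- coAnnotationPositives(ann)
  expect_identical(pairKey(pos$geneA, pos$geneB),
                   c("g1|g2", "g1|g3", "g2|g3"))   # 3 choose 2
  expect_false("g1|g4" %in% pairKey(pos$geneA, pos$geneB))
})

test_that("co-annotation matches brute-force enumeration on a toy table", {
  ann <- rbind(annRow(c("g1", "g2"), "T1"),
               annRow(c("g2", "g3", "g4"), "T2"),
               annRow(c("g5", "g1"), "T3", source = "KEGG",
                      evidence = NA, aspect = NA))
  pos <- coAnnotationPositives(ann)
  got <- sort(pairKey(pos$geneA, pos$geneB))
  ## brute force over all unordered gene pairs
  genes <- sort(unique(ann$gene))
  want <- character(0)
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i >= j) next
    ti <- ann$term[ann$gene == genes[i]]
    tj <- ann$term[ann$gene == genes[j]]
    if (length(intersect(ti, tj)))
      want <- c(want, pairKey(genes[i], genes[j]))
  }
  expect_identical(got, sort(want))
})

test_that("term-size ceiling and empty annotations are handled", {
  big <- annRow(sprintf("g%03d", 1:10), "HUGE")
  pos <- coAnnotationPositives(big, maxTermSize = 5)
  expect_identical(nrow(pos), 0L)
  expect_identical(nrow(coAnnotationPositives(big, maxTermSize = Inf)),
                   45L)
  empty <- data.frame(gene = character(0), term = character(0),
                      evidence = character(0), aspect = character(0),
                      source = character(0))
  expect_warning(out <- coAnnotationPositives(empty), "empty")
  expect_identical(nrow(out), 0L)
})

test_that("evidence filter keeps the six experimental codes for GO only", {
  ann <- rbind(annRow("g1", "T1", "IDA"), annRow("g2", "T1", "IEA"),
               annRow("g3", "T1", "EXP"), annRow("g4", "T1", "ND"),
               annRow("g5", "T1", "IMP"), annRow("g6", "T1", "IPI"),
               annRow("g7", "T1", "IGI"), annRow("g8", "T1", "IEP"),
               annRow("g9", "T1", "ISS"),
               annRow("g10", "P1", evidence = NA, aspect = NA,
                      source = "KEGG"))
  expect_message(out <- filterExperimental(ann), "3 GO annotation rows")
  ## hand filter: experimental GO rows plus the pathway row
  expect_setequal(out$gene,
                  c("g1", "g3", "g5", "g6", "g7", "g8", "g10"))
})

test_that("negative sampling excludes positives and exhausts correctly", {
  pos <- data.frame(geneA = c("a", "a"), geneB = c("b", "c"))
  neg <- sampleNegatives(c("a", "b", "c"), pos, ratio = 10, seed = 1)
  expect_identical(pairKey(neg$geneA, neg$geneB), "b|c")
  ## determinism
  u <- sprintf("g%02d", 1:12)
  pos2 <- data.frame(geneA = "g01", geneB = "g02")
  n1 <- sampleNegatives(u, pos2, ratio = 5, seed = 99)
  n2 <- sampleNegatives(u, pos2, ratio = 5, seed = 99)
  expect_identical(n1, n2)
  expect_identical(nrow(n1), 5L)
  expect_error(sampleNegatives("a", pos2), "too small")
})

test_that("negatives never overlap positives across many draws", {
  withr::local_seed(5)
  u <- sprintf("g%02d", 1:15)
  for (i in 1:40) {
    a <- sample(u, 20, replace = TRUE)
    b <- sample(u, 20, replace = TRUE)
    keep <- a != b
    cp <- canonicalPair(a[keep], b[keep])
    pos <- unique(data.frame(geneA = cp$a, geneB = cp$b))
    neg <- sampleNegatives(u, pos, ratio = 3, seed = i)
    expect_length(intersect(pairKey(pos$geneA, pos$geneB),
                            pairKey(neg$geneA, neg$geneB)), 0L)
    expect_true(all(neg$geneA != neg$geneB))
  }
})

test_that("bags are Cartesian products of the genes' isoforms", {
  gm <- GeneModels(list(G1 = c("g1.1", "g1.2", "g1.3"),
                        G2 = c("g2.1", "g2.2"),
                        G3 = "g3.1", G4 = "g4.1"))
  allPairs <- expand.grid(a = isoformIds(gm), b = isoformIds(gm),
                          stringsAsFactors = FALSE)
  allPairs <- allPairs[allPairs$a < allPairs$b, ]
  ft <- assembleFeatures(f1 = stats::setNames(
    seq_len(nrow(allPairs)) / nrow(allPairs),
    pairKey(allPairs$a, allPairs$b)))
  gold <- goldStandard(
    positives = data.frame(geneA = "G1", geneB = "G2", source = "GO"),
    negatives = data.frame(geneA = "G3", geneB = "G4"))
  bags <- buildBags(gold, gm, ft)
  expect_identical(nBags(bags), 2L)
  m <- bagSizes(bags)
  names(m) <- bagIds(bags)
  expect_identical(unname(m[["G1|G2"]]), 6L)   # 3 x 2 isoforms
  expect_identical(unname(m[["G3|G4"]]), 1L)   # single x single
  ## instance keys equal the brute-force product
  want <- pairKey(rep(c("g1.1", "g1.2", "g1.3"), 2),
                  rep(c("g2.1", "g2.2"), each = 3))
  got <- instanceKeys(bags)[instanceBag(bags) ==
                              match("G1|G2", bagIds(bags))]
  expect_setequal(got, want)
})

test_that("instances and bags without features are dropped with a count", {
  gm <- GeneModels(list(G1 = c("a1", "a2"), G2 = "b1", G3 = "c1",
                        G4 = "d1"))
  ft <- assembleFeatures(f1 = c("a1|b1" = 0.5, "c1|d1" = 0.1))
  gold <- goldStandard(
    positives = data.frame(geneA = "G1", geneB = "G2", source = "GO"),
    negatives = data.frame(geneA = "G3", geneB = "G4"))
  expect_message(bags <- buildBags(gold, gm, ft), "instances dropped")
  expect_identical(nBags(bags), 2L)
  expect_identical(sum(bagSizes(bags)), 2L)    # a2|b1 had no features
  ## a gold pair with no feature coverage at all loses its bag
  gold2 <- goldStandard(
    positives = data.frame(geneA = c("G1", "G3"), geneB = c("G2", "G4"),
                           source = "GO"),
    negatives = data.frame(geneA = "G2", geneB = "G3"))
  expect_message(bags2 <- buildBags(gold2, gm, ft), "bags dropped")
  expect_identical(nBags(bags2), 2L)
})

test_that("gold standards assert disjointness and canonical order", {
  expect_error(goldStandard(
    positives = data.frame(geneA = "a", geneB = "b", source = "GO"),
    negatives = data.frame(geneA = "b", geneB = "a")), "overlap")
  gs <- goldStandard(
    positives = data.frame(geneA = "b", geneB = "a", source = "GO"),
    negatives = data.frame(geneA = "d", geneB = "c"))
  expect_identical(positivePairs(gs)$geneA, "a")
  expect_identical(negativePairs(gs)$geneA, "c")
})
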