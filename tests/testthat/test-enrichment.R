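test_that("log2 fold enrichment follows the post/pre mean ratio", {
  x <- makeExperiment(pre = cbind(c(1, 2, 0), c(3, 2, 0)),
                      post = cbind(c(8, 2, 1), c(8, 2, 1)),
                      p = c(0.01, 0.5, 0.9))
  fc <- computeFoldChanges(x)
  expect_equal(fc$log2_fc[fc$gene_id == "g1"], 2)        # log2(8/2)
  expect_equal(fc$log2_fc[fc$gene_id == "g2"], 0)        # pre == post
  fc2 <- computeFoldChanges(x, pseudocount = 0.1)
  expect_equal(fc2$log2_fc[fc2$gene_id == "g3"], log2(1.1 / 0.1))
  expect_error(computeFoldChanges(x, pseudocount = -1), "non-negative")
})

test_that("all-zero genes are dropped with a logged count", {
  x <- makeExperiment(pre = cbind(c(1, 0)), post = cbind(c(2, 0)))
  expect_message(fc <- computeFoldChanges(x), "1 removed")
  expect_equal(fc$gene_id, "g1")
})

test_that("fold changes are invariant to a common FPKM rescaling", {
  set.seed(11)
  for (i in 1:5) {
    pre <- matrix(runif(20, 0.1, 50), 10)
    post <- matrix(runif(20, 0.1, 50), 10)
    k <- runif(1, 0.01, 100)
    a <- computeFoldChanges(makeExperiment(pre, post))
    b <- computeFoldChanges(makeExperiment(k * pre, k * post))
    expect_equal(b$log2_fc, a$log2_fc)
  }
})

test_that("combined fold changes compare the two post-enrichment means", {
  a <- makeExperiment(pre = cbind(c(1, 1), c(1, 1)),
                      post = cbind(c(8, 4), c(8, 4)),
                      ids = c("n1", "n2"))
  b <- makeExperiment(pre = cbind(c(1, 1), c(1, 1)),
                      post = cbind(c(2, 4), c(2, 4)),
                      ids = c("n1", "n2"))
  fc <- computeCombinedFoldChanges(a, b)
  expect_equal(fc$log2_fc, c(2, 0))
  # antisymmetry under swapping the constructs
  swapped <- computeCombinedFoldChanges(b, a)
  expect_equal(swapped$log2_fc, -fc$log2_fc)
  # disjoint gene universes
  d <- makeExperiment(pre = cbind(1), post = cbind(1), ids = "other")
  expect_error(computeCombinedFoldChanges(a, d), "share no gene")
})

test_that("significance filter applies inclusive p and abundance cutoffs", {
  rec <- makeRecords(c("a", "b", "c"), log2_fc = 1,
                     p_value = c(0.01, 0.06, NA))
  expect_equal(filterSignificant(rec, alpha = 0.05)$gene_id, "a")
  rec2 <- makeRecords(c("a", "b", "c"), log2_fc = 1,
                      mean_pre = c(9.9, 10, 11), p_value = 0.01)
  expect_equal(filterSignificant(rec2, 0.05, min_pre_fpkm = 10)$gene_id,
               c("b", "c"))
  rec3 <- makeRecords(c("a", "b", "c"), log2_fc = 1,
                      p_value = c(0.2, 0.9, 1))
  expect_equal(nrow(filterSignificant(rec3, alpha = 1, min_pre_fpkm = 0)),
               3L)
})

test_that("ROC picks the Youden-optimal threshold on worked cases", {
  rec <- makeRecords(c("t1", "t2", "f1", "f2"), log2_fc = c(2, 3, 0, 1))
  roc <- rocCurve(rec, ReferenceSets(c("t1", "t2"), c("f1", "f2")))
  expect_equal(chosenThreshold(roc), 2)
  expect_equal(chosenJ(roc), 1)
  expect_equal(length(roc@thresholds), 5L)  # 4 observed + sentinel

  # indistinguishable classes: J = 0
  rec2 <- makeRecords(c("t1", "t2", "f1", "f2"), log2_fc = c(1, 2, 1, 2))
  roc2 <- rocCurve(rec2, ReferenceSets(c("t1", "t2"), c("f1", "f2")))
  expect_equal(chosenJ(roc2), 0)

  # inverted separation: nothing is worth calling, sentinel chosen
  rec3 <- makeRecords(c("t1", "f1"), log2_fc = c(0, 5))
  roc3 <- rocCurve(rec3, ReferenceSets("t1", "f1"))
  expect_equal(chosenJ(roc3), 0)
  expect_equal(chosenThreshold(roc3), Inf)
})

test_that("ROC curves are monotone and reference drop-out is handled", {
  rec <- makeRecords(sprintf("g%d", 1:8), log2_fc = c(3, 2, 2, 1, 0, 0, -1, 4))
  refs <- ReferenceSets(c("g1", "g2", "g3", "absent1"),
                        c("g5", "g6", "g7", "absent2"))
  expect_message(roc <- rocCurve(rec, refs), "absent")
  expect_equal(roc@nTruePositives, 3L)
  expect_equal(roc@nFalsePositives, 3L)
  expect_true(all(diff(roc@tpr) <= 0) && all(diff(roc@fpr) <= 0))
  expect_error(rocCurve(rec, ReferenceSets("nope", "g5")),
               "true-positive")
})

test_that("chosen threshold and J match exhaustive brute force on random instances", {
  set.seed(42)
  for (i in 1:50) {
    nTp <- sample(1:10, 1); nFp <- sample(1:10, 1)
    # mix of continuous values and ties
    pool <- c(round(rnorm(12), 1), rnorm(8))
    fcTp <- sample(pool, nTp, replace = TRUE) + rnorm(1)
    fcFp <- sample(pool, nFp, replace = TRUE)
    ids <- sprintf("g%d", seq_len(nTp + nFp))
    rec <- makeRecords(ids, log2_fc = c(fcTp, fcFp))
    roc <- rocCurve(rec, ReferenceSets(ids[seq_len(nTp)],
                                       ids[nTp + seq_len(nFp)]))
    oracle <- rocBruteForce(fcTp, fcFp)
    expect_equal(chosenJ(roc), oracle$j)
    expect_equal(chosenThreshold(roc), oracle$threshold)
  }
})

test_that("ROC maximal J agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  fcTp <- rnorm(25, 1.5); fcFp <- rnorm(25)
  ids <- sprintf("g%d", 1:50)
  rec <- makeRecords(ids, log2_fc = c(fcTp, fcFp))
  roc <- rocCurve(rec, ReferenceSets(ids[1:25], ids[26:50]))
  ext <- pROC::roc(response = rep(c(1, 0), each = 25),
                   predictor = c(fcTp, fcFp), quiet = TRUE,
                   direction = "<")
  extJ <- max(ext$sensitivities + ext$specificities - 1)
  expect_equal(chosenJ(roc), extJ, tolerance = 1e-12)
})

test_that("calling respects threshold and significance, inclusively", {
  rec <- makeRecords(c("a", "b", "c", "d"), log2_fc = c(-1, 0.5, 1.2, 3))
  el <- callEnriched(rec, threshold = 1.0, alpha = 0.05)
  expect_setequal(enrichedGenes(el), c("c", "d"))
  expect_equal(length(callEnriched(rec, -Inf, alpha = 0.05)), 4L)
  expect_equal(length(callEnriched(rec, 10, alpha = 0.05)), 0L)
  # boundary: threshold comparison is inclusive
  expect_true("c" %in% enrichedGenes(callEnriched(rec, 1.2, alpha = 0.05)))
  # missing p-values are never called when alpha is active
  recNA <- makeRecords("x", log2_fc = 5, p_value = NA)
  expect_equal(length(callEnriched(recNA, 0, alpha = 0.05)), 0L)
  expect_equal(length(callEnriched(recNA, 0, alpha = NULL)), 1L)
})

test_that("raising the threshold never adds a gene (monotonicity)", {
  set.seed(5)
  rec <- makeRecords(sprintf("g%d", 1:40), log2_fc = rnorm(40, 1, 2))
  thresholds <- sort(c(-Inf, rnorm(8), Inf))
  prev <- NULL
  for (t in thresholds) {
    cur <- enrichedGenes(callEnriched(rec, t, alpha = 0.05))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("bidirectional calling partitions well-separated compartments", {
  ids <- c(sprintf("n%d", 1:4), sprintf("c%d", 1:4), sprintf("b%d", 1:4))
  rec <- makeRecords(ids, log2_fc = c(rep(2, 4), rep(-2, 4), rep(0, 4)))
  refsN <- ReferenceSets(c("n1", "n2"), c("b1", "b2"), label = "nuclear")
  refsC <- ReferenceSets(c("c1", "c2"), c("b3", "b4"), label = "cytosolic")
  out <- callBidirectional(rec, refsN, refsC, alpha = 0.05)
  expect_equal(chosenThreshold(out$roc$nuclear), 2)
  expect_equal(chosenThreshold(out$roc$cytosolic), 2)  # on negated scale
  expect_setequal(enrichedGenes(out$nuclear), sprintf("n%d", 1:4))
  expect_setequal(enrichedGenes(out$cytosolic), sprintf("c%d", 1:4))
  expect_length(intersect(enrichedGenes(out$nuclear),
                          enrichedGenes(out$cytosolic)), 0)
  # cytosolic genes satisfy log2_fc <= -threshold on the original scale
  expect_true(all(rec$log2_fc[rec$gene_id %in%
                                enrichedGenes(out$cytosolic)] <= -2))
})

test_that("bidirectional lists stay disjoint even with degenerate separation", {
  ids <- sprintf("g%d", 1:6)
  rec <- makeRecords(ids, log2_fc = rep(0, 6))
  refsN <- ReferenceSets("g1", "g4", label = "nuclear")
  refsC <- ReferenceSets("g2", "g5", label = "cytosolic")
  out <- suppressMessages(callBidirectional(rec, refsN, refsC,
                                            alpha = 0.05))
  expect_length(intersect(enrichedGenes(out$nuclear),
                          enrichedGenes(out$cytosolic)), 0)
})
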