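test_that("contamination frequency is the off-target fraction of the list", {
  el <- makeEnriched(c("a", "b", "c", "d"), log2_fc = 1)
  expect_equal(contaminationFrequency(el, c("c", "x")), 0.25)
  expect_equal(contaminationFrequency(el, c("y", "z")), 0)
  expect_equal(contaminationFrequency(el, letters[1:4]), 1)
  empty <- makeEnriched(character(0), log2_fc = numeric(0))
  expect_warning(v <- contaminationFrequency(empty, "a"), "empty")
  expect_true(is.na(v))
})

test_that("secretory specificity ORs the four flags over the list's mRNAs", {
  el <- makeEnriched(c("m1", "m2", "m3", "m4", "l1"), log2_fc = 1,
                     biotype = c(rep("protein_coding", 4), "lincRNA"))
  annot <- makeAnnotation(c("m1", "m2", "m3", "m4"))
  annot$secretory_phobius <- c(TRUE, FALSE, FALSE, TRUE)
  annot$secretory_tmhmm <- c(FALSE, TRUE, FALSE, TRUE)
  annot$secretory_signalp <- c(FALSE, FALSE, FALSE, TRUE)
  annot$secretory_gocc <- c(FALSE, FALSE, FALSE, TRUE)
  s <- suppressMessages(secretorySpecificity(el, annot))
  expect_equal(as.numeric(s), 0.75)     # lincRNA excluded from denominator
  expect_equal(attr(s, "n_mrna"), 4L)

  allFalse <- makeAnnotation(c("m1", "m2", "m3", "m4"))
  expect_equal(as.numeric(suppressMessages(
    secretorySpecificity(el, allFalse))), 0)

  lnc <- makeEnriched("l1", log2_fc = 1, biotype = "lincRNA")
  expect_warning(v <- secretorySpecificity(lnc, annot),
                 "no protein-coding")
  expect_true(is.na(v))
})

test_that("unmatched mRNAs lower the inclusive specificity but not the matched-only one", {
  el <- makeEnriched(c("m1", "m2"), log2_fc = 1,
                     biotype = rep("protein_coding", 2))
  annot <- makeAnnotation("m1", phobius = TRUE)
  s <- suppressMessages(secretorySpecificity(el, annot))
  expect_equal(as.numeric(s), 0.5)
  expect_equal(attr(s, "matched_only"), 1)
  expect_equal(attr(s, "n_unmatched"), 1L)
})

test_that("recall counts the recovered fraction of the reference", {
  el <- makeEnriched(c("a", "b", "c"), log2_fc = 1)
  expect_equal(recall(el, c("a", "b", "x", "y")), 0.5)
  expect_equal(recall(el, c("a.1", "b.2")), 1)  # version-normalized join
  expect_error(recall(el, character(0)), "non-empty")
})

test_that("recall is monotone non-decreasing under list growth", {
  set.seed(3)
  reference <- sprintf("g%d", sample(100, 30))
  pool <- sprintf("g%d", sample(100, 60))
  for (i in 1:10) {
    n1 <- sample(0:59, 1)
    small <- makeEnriched(pool[seq_len(n1)], log2_fc = 1)
    big <- makeEnriched(pool[seq_len(min(60, n1 + 10))], log2_fc = 1)
    expect_lte(recall(small, reference), recall(big, reference))
  }
})

test_that("sensitivity floor is the interpolated input-abundance quantile", {
  same <- makeEnriched(sprintf("g%d", 1:5), log2_fc = 1, mean_pre = 2)
  expect_equal(sensitivityFloor(same, 0.05), 2)
  expect_equal(sensitivityFloor(same, 0.9), 2)
  ladder <- makeEnriched(sprintf("g%d", 1:100), log2_fc = 1,
                         mean_pre = 1:100)
  expect_equal(sensitivityFloor(ladder, 0.05), 5.95)
  # adding one huge gene moves the 5% floor by at most one interpolation step
  plus <- makeEnriched(sprintf("g%d", 1:101), log2_fc = 1,
                       mean_pre = c(1:100, 1e6))
  delta <- sensitivityFloor(plus, 0.05) - sensitivityFloor(ladder, 0.05)
  expect_gte(delta, 0)
  expect_lte(delta, 1)  # step between adjacent order statistics
})

test_that("biotype composition conserves the list size", {
  el <- makeEnriched(c("a", "b", "c", "d"), log2_fc = 1,
                     biotype = c("protein_coding", "protein_coding",
                                 "protein_coding", "lincRNA"))
  comp <- biotypeComposition(el)
  expect_equal(comp[["protein_coding"]], 3L)
  expect_equal(comp[["lincRNA"]], 1L)
  expect_equal(sum(comp), length(el))
  expect_length(biotypeComposition(
    makeEnriched(character(0), log2_fc = numeric(0))), 0)
  # missing biotypes are binned as unknown
  el2 <- makeEnriched(c("a", "b"), log2_fc = 1)
  expect_equal(sum(biotypeComposition(el2)), 2L)
  expect_named(biotypeComposition(el2), "unknown")
})

test_that("sub-mitochondrial fractions cover annotated genes and sum to one", {
  ids <- sprintf("m%d", 1:6)
  el <- makeEnriched(ids, log2_fc = 1)
  annot <- makeAnnotation(ids, is_mito = TRUE,
                          submito = c("OMM", "OMM", "IMM", "matrix",
                                      "unknown", "unknown"))
  f <- suppressMessages(submitoComposition(el, annot))
  expect_equal(f[["OMM"]], 0.5)
  expect_equal(sum(f), 1)
  expect_equal(attr(f, "n_annotated"), 4L)
  single <- makeEnriched("m1", log2_fc = 1)
  f1 <- suppressMessages(submitoComposition(single, annot))
  expect_equal(f1[["OMM"]], 1)
  none <- makeEnriched("m5", log2_fc = 1)
  expect_warning(v <- submitoComposition(none, annot), "no genes")
  expect_true(all(is.na(v)))
})

test_that("transmembrane enrichment compares list and background fractions", {
  ids <- sprintf("m%d", 1:7)
  annot <- makeAnnotation(ids, is_mito = TRUE)
  annot$secretory_tmhmm <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  el <- makeEnriched(ids[1:3], log2_fc = 1)
  out <- transmembraneEnrichment(el, annot, background = ids[4:7])
  expect_equal(as.numeric(out), c(2 / 3, 0.25))
  same <- transmembraneEnrichment(el, annot, background = ids[1:3])
  expect_equal(as.numeric(same[1]), as.numeric(same[2]))
})

test_that("benchmark rates match an independent set-algebra oracle on random instances", {
  set.seed(99)
  for (i in 1:20) {
    universe <- sprintf("g%d", 1:50)
    genes <- sample(universe, sample(1:50, 1))
    offT <- sample(universe, sample(1:50, 1))
    ref <- sample(universe, sample(1:50, 1))
    el <- makeEnriched(genes, log2_fc = 1)
    # oracle: explicit element-by-element membership counting
    inOff <- sum(vapply(genes, function(g) any(g == offT), logical(1)))
    inRef <- sum(vapply(ref, function(r) any(r == genes), logical(1)))
    expect_equal(contaminationFrequency(el, offT), inOff / length(genes))
    expect_equal(recall(el, ref), inRef / length(ref))
    expect_equal(contaminationFrequency(el, offT) +
                   sum(vapply(genes, function(g) !any(g == offT),
                              logical(1))) / length(genes), 1)
  }
})

test_that("benchmarkReport aggregates metrics with denominators and serializes", {
  ids <- sprintf("g%d", 1:6)
  el <- EnrichedList(makeRecords(ids, log2_fc = 2, mean_pre = c(1:6),
                                 biotype = c(rep("protein_coding", 5),
                                             "lincRNA")),
                     label = "ER", threshold = 1, alpha = 0.05)
  annot <- makeAnnotation(ids,
                          biotype = c(rep("protein_coding", 5), "lincRNA"),
                          phobius = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  rep <- suppressMessages(benchmarkReport(
    el, annot = annot, off_target = c("g6", "zz"), reference = c("g1", "qq"),
    quantile = 0.05))
  expect_s4_class(rep, "BenchmarkReport")
  expect_equal(rep@nEnriched, 6L)
  expect_equal(rep@contaminationFrequency, 1 / 6)
  expect_equal(rep@secretorySpecificity, 0.8)
  expect_equal(rep@recall, 0.5)
  expect_equal(sum(rep@biotypeCounts), 6L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeBenchmarkReport(rep, tf)
  lines <- readLines(tf)
  expect_true(any(grepl("^contamination_frequency\t", lines)))
  expect_true(any(grepl("denominator", lines)))
})
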