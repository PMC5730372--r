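test_that("invalid simulation configurations are rejected before sampling", {
  expect_error(simulationConfig(fraction_enriched = 0.8,
                                fraction_off_target = 0.3), "exceed 1")
  expect_error(simulationConfig(replicate_cv = -0.1), "non-negative")
  expect_error(simulationConfig(n_replicates = 1), "at least 2")
  expect_error(simulationConfig(biotype_mix = c(protein_coding = 0.5)),
               "sum to 1")
})

test_that("the same seed reproduces every simulated table exactly", {
  cfg <- simulationConfig(n_genes = 300, seed = 42)
  s1 <- suppressMessages(simulateExpression(cfg))
  s2 <- suppressMessages(simulateExpression(cfg))
  expect_identical(fpkmPre(s1$experiment), fpkmPre(s2$experiment))
  expect_identical(fpkmPost(s1$experiment), fpkmPost(s2$experiment))
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(truePositives(s1$refs), truePositives(s2$refs))
  expect_identical(s1$truth, s2$truth)
  s3 <- suppressMessages(simulateExpression(
    simulationConfig(n_genes = 300, seed = 43)))
  expect_false(identical(fpkmPre(s1$experiment), fpkmPre(s3$experiment)))
})

test_that("noise-free simulations hit the closed-form fold changes", {
  cfg <- simulationConfig(n_genes = 500, replicate_cv = 0, effect_log2 = 2,
                          contaminant_log2 = 0, fraction_off_target = 0,
                          seed = 9)
  sim <- suppressMessages(simulateExpression(cfg))
  fc <- suppressMessages(computeFoldChanges(sim$experiment))
  truth <- sim$truth[match(fc$gene_id, sim$truth$gene_id), ]
  # every gene's empirical fold change equals its true effect exactly
  expect_equal(fc$log2_fc, truth$true_log2_effect, tolerance = 1e-12)
  expect_true(all(fc$log2_fc[!truth$is_target] == 0))
  # target effects are centred on 2 with small per-gene jitter
  tfc <- fc$log2_fc[truth$is_target]
  expect_equal(mean(tfc), 2, tolerance = 0.05)
  expect_true(all(abs(tfc - 2) <= 0.5))
})

test_that("simulated structure matches the configured generative model", {
  cfg <- simulationConfig(n_genes = 4000, seed = 3)
  sim <- suppressMessages(simulateExpression(cfg))
  truth <- sim$truth
  expect_equal(sum(truth$is_target), round(4000 * cfg$fraction_enriched))
  expect_equal(sum(truth$is_off_target),
               round(4000 * cfg$fraction_off_target))
  expect_false(any(truth$is_target & truth$is_off_target))
  # about half the genes exceed 1 FPKM under the default abundance model
  frac1 <- mean(rowMeans(fpkmPre(sim$experiment)) >= 1)
  expect_gt(frac1, 0.4); expect_lt(frac1, 0.6)
  # replicate CV is near its configured value for abundant genes
  pre <- fpkmPre(sim$experiment)
  cv <- apply(pre, 1, sd) / rowMeans(pre)
  expect_equal(median(cv), 0.2, tolerance = 0.25)
  # annotation invariant holds by construction
  expect_true(all(sim$annotation$is_mito[
    sim$annotation$submito_location != "unknown"]))
})

test_that("null-gene p-values are approximately uniform", {
  pooled <- unlist(lapply(1:5, function(s) {
    cfg <- simulationConfig(n_genes = 2000, fraction_enriched = 0,
                            fraction_off_target = 0, seed = s)
    sim <- suppressMessages(simulateExpression(cfg))
    unname(pValues(sim$experiment))
  }))
  ks <- suppressWarnings(ks.test(pooled, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("a null simulation gives no usable ROC separation", {
  js <- vapply(1:10, function(s) {
    cfg <- simulationConfig(n_genes = 1000, fraction_enriched = 0,
                            fraction_off_target = 0, seed = s)
    sim <- suppressMessages(simulateExpression(cfg))
    fc <- suppressMessages(computeFoldChanges(sim$experiment))
    # no significance filter: the null J is a property of the fold changes
    chosenJ(suppressMessages(rocCurve(fc, sim$refs)))
  }, numeric(1))
  expect_lt(mean(js), 0.2)  # small-sample maxima stay near zero
})

test_that("recovery degrades as the effect shrinks or noise grows", {
  grid <- expand.grid(effect = c(1, 2, 4), cv = c(0.1, 0.2))
  seeds <- 1:5
  res <- vapply(seq_len(nrow(grid)), function(i) {
    rec <- vapply(seeds, function(s) {
      out <- runRecoveryPipeline(seed = s, n_genes = 1500,
                                 effect_log2 = grid$effect[i],
                                 replicate_cv = grid$cv[i])
      c(out$recall, out$contamination)
    }, numeric(2))
    rowMeans(rec)
  }, numeric(2))
  recallAt <- function(e, cv) res[1, grid$effect == e & grid$cv == cv]
  # strong effects are recovered essentially completely
  expect_gt(recallAt(4, 0.1), 0.95)
  expect_gt(recallAt(2, 0.2), 0.9)
  # smaller effect or larger noise never helps (within sampling tolerance)
  for (cv in c(0.1, 0.2)) {
    expect_lte(recallAt(1, cv), recallAt(2, cv) + 0.03)
    expect_lte(recallAt(2, cv), recallAt(4, cv) + 0.03)
  }
  for (e in c(1, 2, 4))
    expect_lte(recallAt(e, 0.2), recallAt(e, 0.1) + 0.03)
  # contamination degrades (grows) as the effect shrinks toward the
  # leakage level, and is controlled at effects of 2 log2 units and above
  contamAt <- function(e, cv) res[2, grid$effect == e & grid$cv == cv]
  for (cv in c(0.1, 0.2)) {
    expect_lte(contamAt(4, cv), contamAt(2, cv) + 0.03)
    expect_lte(contamAt(2, cv), contamAt(1, cv) + 0.03)
    expect_lte(contamAt(2, cv), 0.05)
    expect_lte(contamAt(4, cv), 0.05)
  }
})
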