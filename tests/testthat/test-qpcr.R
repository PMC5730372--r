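test_that("volume correction lowers the input Ct by the aliquot-equivalent cycles", {
  # full lysate as input: no correction
  full <- correctedCt(c(20, 20.4), efficiency = 0.9, sample = "input",
                      input_fraction = 1)
  expect_equal(full$value, 20.2)
  # perfect efficiency, 25% input: exactly log2(4) = 2 cycles
  quarter <- correctedCt(20, efficiency = 1, sample = "input",
                         input_fraction = 0.25)
  expect_equal(quarter$value, 18)
  # epsilon = 0.9, 20% input: ln(5)/ln(1.9) cycles
  fifth <- correctedCt(20, efficiency = 0.9, sample = "input",
                       input_fraction = 0.2)
  expect_equal(fifth$value, 20 - log(5) / log(1.9))
  # RIP samples are left uncorrected; replicate sd uses n-1
  rip <- correctedCt(c(18, 19), efficiency = 0.9, sample = "RIP")
  expect_equal(rip$value, 18.5)
  expect_equal(rip$sd, sd(c(18, 19)))
  expect_error(correctedCt(20, 0.9, "input", input_fraction = 0),
               "input_fraction")
  expect_error(correctedCt(c(20, -1), 0.9), "positive")
})

test_that("percent yield follows the efficiency-scaled delta-Ct formula", {
  expect_equal(percentYield(20, 20, efficiency = 0.9)$yield_percent, 100)
  expect_equal(percentYield(19, 20, efficiency = 1)$yield_percent, 50)
  y <- percentYield(list(value = 17, sd = 0.1), list(value = 20, sd = 0.1732),
                    efficiency = 0.9)
  expect_equal(y$delta_ct, -3)
  expect_equal(y$yield_percent, 100 * 1.9^-3)
  sdDelta <- sqrt(0.1^2 + 0.1732^2)
  expect_equal(y$delta_ct_sd, sdDelta)
  expect_equal(y$yield_sd, sdDelta * y$yield_percent * log(1.9))
})

test_that("percent yield is strictly increasing in delta-Ct and in efficiency", {
  dts <- seq(-3, 3, by = 0.5)
  ys <- vapply(dts, function(d)
    percentYield(20 + d, 20, efficiency = 0.9)$yield_percent, numeric(1))
  expect_true(all(diff(ys) > 0))
  eff <- seq(0.5, 1, by = 0.1)
  yUp <- vapply(eff, function(e)
    percentYield(22, 20, efficiency = e)$yield_percent, numeric(1))
  expect_true(all(diff(yUp) > 0))  # delta-Ct > 0
})

test_that("error propagation rules reproduce worked values", {
  expect_equal(propagateDifference(1, 2, 3, 4)$sd, 5)
  expect_equal(propagateDifference(1, 2, 3, 0)$sd, 3)
  expect_equal(propagateDifference(1, 2, 1, 1)$sd, sqrt(2))
  p <- propagateProduct(10, 10, 1, 1)
  expect_equal(p$value, 100)
  expect_equal(p$sd, 100 * sqrt(0.02))
  expect_equal(propagateProduct(5, 4, 0, 0)$sd, 0)
  q <- propagateProduct(3, 3, 0.3, 0.3, op = "divide")
  expect_equal(q$value, 1)
  expect_equal(q$sd, sqrt(2) * 0.1)
  expect_error(propagateProduct(0, 1, 1, 1), "zero")
  expect_equal(propagateFunction(3, 0.1, function(x) x^2)$sd, 0.6)
  expect_equal(propagateFunction(5, 0.4, identity)$sd, 0.4)
  expect_equal(propagateFunction(0, 0.5, function(x) 2^x,
                                 dfdx = function(x) 2^x * log(2))$sd,
               0.5 * log(2))
  # central difference agrees with the analytic derivative
  expect_equal(propagateFunction(0, 0.5, function(x) 2^x)$sd,
               0.5 * log(2), tolerance = 1e-8)
})

test_that("difference propagation is symmetric under negation", {
  d1 <- propagateDifference(3, 7, 0.2, 0.5)
  d2 <- propagateDifference(7, 3, 0.5, 0.2)
  expect_equal(d1$value, -d2$value)
  expect_equal(d1$sd, d2$sd)
})

test_that("fold enrichment over a reference applies the quotient rule", {
  t30 <- list(yield_percent = 30, yield_sd = 3)
  r2 <- list(yield_percent = 2, yield_sd = 0.2)
  f <- foldEnrichmentVsReference(t30, r2)
  expect_equal(f$fold, 15)
  expect_equal(f$sd, 15 * sqrt(0.02))
  equal <- foldEnrichmentVsReference(t30, t30)
  expect_equal(equal$fold, 1)
  exact <- foldEnrichmentVsReference(list(yield_percent = 50, yield_sd = 0),
                                     list(yield_percent = 1, yield_sd = 0))
  expect_equal(exact$fold, 50)
  expect_equal(exact$sd, 0)
  expect_error(foldEnrichmentVsReference(
    t30, list(yield_percent = 0, yield_sd = 0)), "positive")
})

test_that("first-order sigma matches Monte-Carlo sd for the composed yield pipeline", {
  set.seed(123)
  n <- 2e5
  eps <- 0.9
  sdIn <- 0.12; sdRip <- 0.1
  muIn <- 18; muRip <- 20
  y <- percentYield(list(value = muIn, sd = sdIn),
                    list(value = muRip, sd = sdRip), efficiency = eps)
  draws <- 100 * (1 + eps)^((muIn + rnorm(n, 0, sdIn)) -
                              (muRip + rnorm(n, 0, sdRip)))
  expect_equal(y$yield_sd, sd(draws), tolerance = 0.05)
  # fold over a reference with its own error
  ref <- percentYield(list(value = 19, sd = 0.08),
                      list(value = 20, sd = 0.08), efficiency = eps)
  f <- foldEnrichmentVsReference(y, ref)
  refDraws <- 100 * (1 + eps)^((19 + rnorm(n, 0, 0.08)) -
                                 (20 + rnorm(n, 0, 0.08)))
  expect_equal(f$sd, sd(draws / refDraws), tolerance = 0.1)
})

test_that("plate-level yields join primers, flag low efficiencies and use the reference", {
  ct <- rbind(
    data.frame(sample = "input", target = "ND1", replicate = 1:2,
               ct = c(20, 20)),
    data.frame(sample = "RIP", target = "ND1", replicate = 1:2,
               ct = c(19, 19)),
    data.frame(sample = "input", target = "GAPDH", replicate = 1:2,
               ct = c(15, 15)),
    data.frame(sample = "RIP", target = "GAPDH", replicate = 1:2,
               ct = c(21, 21)))
  primers <- primerPairs(c("ND1", "GAPDH"), c(1, 1))
  out <- qpcrYields(ct, primers, input_fraction = 1, reference = "GAPDH")
  nd1 <- out[out$target == "ND1", ]
  expect_equal(nd1$delta_ct, 1)
  expect_equal(nd1$yield_percent, 200)      # RIP one cycle ahead of input
  expect_equal(nd1$fold_vs_reference, 2^7)  # GAPDH yield 2^-6
  expect_false(any(out$flagged))
  low <- primerPairs("X", 0.8)
  expect_true(low$flagged)
  expect_error(qpcrYields(ct, primerPairs("ND1", 1)), "GAPDH")
})

test_that("simulated plates invert the yield equation exactly at zero noise", {
  sim <- simulateQpcr(c(A = 100, B = 50, C = 12.5),
                      c(A = 0.95, B = 1, C = 0.9), ct_noise_sd = 0)
  out <- qpcrYields(sim$ct, sim$primers, input_fraction = 0.2)
  expect_equal(out$yield_percent[match(c("A", "B", "C"), out$target)],
               c(100, 50, 12.5))
  expect_equal(out$yield_sd, rep(0, 3))
  # same seed reproduces the same plate
  s1 <- simulateQpcr(c(A = 30), c(A = 0.9), ct_noise_sd = 0.2, seed = 5)
  s2 <- simulateQpcr(c(A = 30), c(A = 0.9), ct_noise_sd = 0.2, seed = 5)
  expect_identical(s1$ct, s2$ct)
  expect_error(simulateQpcr(c(A = -1), c(A = 0.9)), "positive")
})

test_that("noisy plates recover the true yield on average with honest uncertainty", {
  truths <- 12.5; eps <- 0.9
  rec <- vapply(1:200, function(s) {
    sim <- simulateQpcr(c(A = truths), c(A = eps), ct_noise_sd = 0.1,
                        n_replicates = 4, seed = s)
    out <- qpcrYields(sim$ct, sim$primers, input_fraction = 0.2)
    c(out$yield_percent, out$yield_sd)
  }, numeric(2))
  expect_equal(mean(rec[1, ]), truths, tolerance = 0.02)
  # propagated sigma tracks the empirical spread across plates
  expect_equal(mean(rec[2, ]), sd(rec[1, ]), tolerance = 0.15)
})
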