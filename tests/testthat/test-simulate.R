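test_that("identical seed and config give byte-identical output files", {
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulatedPanel(simulatePanel(k = 15, nOutliers = 2, seed = 99), d1)
  writeSimulatedPanel(simulatePanel(k = 15, nOutliers = 2, seed = 99), d2)
  for (f in c("exposure.tsv", "outcome.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  ## different seed differs
  d3 <- tempfile()
  writeSimulatedPanel(simulatePanel(k = 15, nOutliers = 2, seed = 100), d3)
  expect_false(identical(readLines(file.path(d1, "exposure.tsv")),
                         readLines(file.path(d3, "exposure.tsv"))))
})

test_that("observed exposure betas converge to the planted effects as n grows", {
  sim <- simulatePanel(k = 20, nExp = 1e12, seed = 5)
  expect_equal(sim$exposure$beta, sim$truth$bTrue, tolerance = 1e-3)
  ## and the observed outcome equals truth under huge outcome n
  sim2 <- simulatePanel(k = 20, trueBeta = 0.3, nOut = 1e12, seed = 6)
  expect_equal(sim2$outcome$beta, sim2$truth$outTrue, tolerance = 1e-3)
  expect_equal(sim2$truth$outTrue, 0.3 * sim2$truth$bTrue)
})

test_that("replicate noise matches the analytic standard errors", {
  base <- simulatePanel(k = 39, seed = 17)
  nrep <- 3000
  draws <- matrix(NA_real_, nrep, 39)
  for (r in seq_len(nrep))
    draws[r, ] <- simulatePanel(k = 39, seed = 200000 + r,
                                truth = base$truth)$exposure$beta
  emp <- apply(draws, 2, sd)
  expect_true(all(abs(emp / base$truth$seExp - 1) < 0.05))
  expect_lt(abs(mean(emp / base$truth$seExp) - 1), 0.01)
  ## unbiasedness of the observation step
  expect_true(all(abs(colMeans(draws) - base$truth$bTrue) <
                    4 * base$truth$seExp / sqrt(nrep)))
})

test_that("realized variance explained sits near the calibration target", {
  ## analytic expectation of per-SNP R2 under the generator defaults
  m <- 0.015; s <- 0.015                       # minExpBeta, expBetaScale
  Eb2 <- m^2 + 2 * m * s * sqrt(2 / pi) + s^2
  Emaf <- integrate(function(x) x * (1 - x), 0.05, 0.5)$value / 0.45
  target <- 39 * 2 * Eb2 * Emaf                # ~1.2% for 39 SNPs
  realized <- vapply(1:12, function(r) {
    tr <- simulatePanel(k = 39, seed = 3000 + r)$truth
    sum(snpR2(tr$bTrue, tr$seExp, tr$maf, 1477325))
  }, 0)
  expect_lt(abs(mean(realized) / target - 1), 0.2)
  ## the paper-scale panel of 34 instruments explains about 1% of variance
  expect_equal(mean(realized) * 34 / 39, 0.01, tolerance = 0.2)
})

test_that("planted outliers and pleiotropy land where configured", {
  sim <- simulatePanel(k = 39, nOutliers = 5, outlierSize = 15, seed = 8)
  expect_equal(sum(sim$truth$outlier), 5L)
  disp <- abs(sim$truth$outTrue - sim$truth$pleiotropy -
                0 * sim$truth$bTrue)[sim$truth$outlier]
  expect_equal(disp, 15 * sim$truth$seOut[sim$truth$outlier])
  simd <- simulatePanel(k = 400, pleiotropy = "directional",
                        pleiotropyDelta = 0.02, seed = 9)
  expect_equal(mean(simd$truth$pleiotropy), 0.02, tolerance = 0.1)
  expect_equal(sd(simd$truth$pleiotropy), 0.01, tolerance = 0.15)
  expect_error(simulatePanel(k = 5, nOutliers = 6), "degenerate")
  expect_error(simulatePanel(k = 5, pleiotropy = "balanced",
                             pleiotropyDelta = 0), "pleiotropyDelta")
})

test_that("winner's-curse selection inflates observed exposure effects", {
  ## weak instruments at a mild threshold so selection bites
  cfg <- list(k = 60, nExp = 2e4, minExpBeta = 0.01, expBetaScale = 0.005,
              sigThreshold = 0.05)
  plain <- do.call(simulatePanel, c(cfg, list(seed = 41)))
  cursed <- do.call(simulatePanel, c(cfg, list(winnersCurse = TRUE,
                                               seed = 41)))
  expect_gt(mean(cursed$exposure$beta), mean(plain$truth$bTrue))
  expect_true(all(cursed$exposure$pval < 0.05))
  ## impractically strong selection is refused rather than hanging
  expect_error(simulatePanel(k = 5, nExp = 2e4, minExpBeta = 0.002,
                             expBetaScale = 0.001, winnersCurse = TRUE,
                             seed = 1),
               "too strong")
})
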