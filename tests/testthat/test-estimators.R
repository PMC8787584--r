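test_that("Wald ratios divide outcome by exposure with first-order SE", {
  iv <- make_iv(bx = c(0.1, -0.2), by = c(0.05, 0.05),
                sy = c(0.01, 0.01))
  wr <- waldRatios(iv)
  expect_equal(wr$ratio, c(0.5, -0.25))
  expect_equal(wr$se, c(0.1, 0.05))
})

test_that("null Wald ratios scatter like standard normal z-scores", {
  zs <- unlist(lapply(1:20, function(s) {
    sim <- simulatePanel(k = 30, trueBeta = 0, seed = 100 + s)
    wr <- waldRatios(InstrumentSet(sim$exposure, sim$outcome))
    wr$ratio / wr$se
  }))
  ## E|z| = sqrt(2/pi) ~ 0.798 for N(0,1); 600 pooled draws
  expect_equal(mean(abs(zs)), sqrt(2 / pi), tolerance = 0.08)
  expect_lt(abs(mean(zs)), 3 / sqrt(length(zs)))
})

test_that("IVW equals the ratio on perfectly proportional data and refuses k = 1", {
  iv <- make_iv(bx = c(0.1, 0.2), by = c(0.03, 0.06))
  fit <- mrIVW(iv)
  expect_equal(mrBeta(fit), 0.3, tolerance = 1e-14)
  expect_equal(unname(heterogeneity(fit)[["Q"]]), 0, tolerance = 1e-20)
  expect_error(mrIVW(make_iv(0.1, 0.05)), "at least 2")
})

test_that("IVW matches the weighted normal-equations oracle on random panels", {
  for (s in 1:30) {
    iv <- random_iv(k = 15 + (s %% 10), seed = s)
    x <- exposureData(iv)$beta
    y <- outcomeData(iv)$beta
    w <- 1 / outcomeData(iv)$se^2
    fit <- mrIVW(iv)
    oracle <- lm(y ~ 0 + x, weights = w)   # independent QR path
    expect_equal(mrBeta(fit), unname(coef(oracle)), tolerance = 1e-12)
    ## the MRE dispersion scaling sqrt(Q/(k-1)) is exactly lm's sigma-hat,
    ## so the MRE SE must equal lm's reported slope SE
    expect_equal(mrSE(fit), unname(summary(oracle)$coefficients[1, 2]),
                 tolerance = 1e-10)
  }
})

test_that("Egger interpolates exact linear data and reduces to IVW at zero intercept", {
  bx <- seq(0.05, 0.3, length.out = 8)
  ## exact line with intercept
  iv <- make_iv(bx, by = 0.013 + 0.4 * bx)
  fit <- mrEgger(iv)
  expect_equal(mrBeta(fit), 0.4, tolerance = 1e-10)
  expect_equal(unname(eggerIntercept(fit)[["intercept"]]), 0.013,
               tolerance = 1e-10)
  ## exact line through the origin: Egger slope == IVW slope
  iv0 <- make_iv(bx, by = 0.4 * bx)
  expect_equal(mrBeta(mrEgger(iv0)), mrBeta(mrIVW(iv0)), tolerance = 1e-10)
  expect_error(mrEgger(make_iv(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("Egger orients instruments to positive exposure betas before fitting", {
  set.seed(42)
  bx <- runif(9, 0.05, 0.3)
  by <- 0.01 + 0.25 * bx + rnorm(9, 0, 0.01)
  iv <- make_iv(bx, by)
  flip <- c(2, 5, 7)
  iv_flipped <- make_iv(replace(bx, flip, -bx[flip]),
                        replace(by, flip, -by[flip]))
  expect_equal(mrBeta(mrEgger(iv_flipped)), mrBeta(mrEgger(iv)))
  expect_equal(eggerIntercept(mrEgger(iv_flipped)),
               eggerIntercept(mrEgger(iv)))
})

test_that("Egger intercept tracks the pleiotropy regime over replicates", {
  ints_bal <- ints_dir <- numeric(60)
  for (r in 1:60) {
    simb <- simulatePanel(k = 30, trueBeta = 0.1, pleiotropy = "balanced",
                          pleiotropyDelta = 0.01, seed = 500 + r)
    simd <- simulatePanel(k = 30, trueBeta = 0.1, pleiotropy = "directional",
                          pleiotropyDelta = 0.01, seed = 900 + r)
    ints_bal[r] <- eggerIntercept(
      mrEgger(InstrumentSet(simb$exposure, simb$outcome)))[["intercept"]]
    ints_dir[r] <- eggerIntercept(
      mrEgger(InstrumentSet(simd$exposure, simd$outcome)))[["intercept"]]
  }
  expect_lt(abs(mean(ints_bal)), 3 * sd(ints_bal) / sqrt(60))
  expect_equal(mean(ints_dir), 0.01,
               tolerance = max(3 * sd(ints_dir) / sqrt(60) / 0.01, 0.12))
})

test_that("the weighted median interpolates the 50% weight boundary", {
  ## equal weights {1, 2, 100}: median robust to the outlier
  iv <- make_iv(bx = rep(1, 3), by = c(1, 2, 100), sy = rep(1, 3))
  expect_equal(mrBeta(mrWeightedMedian(iv, nBoot = 100, seed = 1)), 2)
  ## all ratios equal: estimate exact, bootstrap SE small
  iv2 <- make_iv(bx = rep(0.1, 4), by = rep(0.03, 4), sy = rep(0.001, 4))
  fit2 <- mrWeightedMedian(iv2, nBoot = 200, seed = 1)
  expect_equal(mrBeta(fit2), 0.3, tolerance = 1e-12)
  expect_lt(mrSE(fit2), 0.02)
  expect_warning(mrWeightedMedian(iv2, nBoot = 10, seed = 1), "nBoot")
  expect_error(mrWeightedMedian(make_iv(c(1, 1), c(1, 1))), "at least 3")
})

test_that("mode estimators find the majority cluster and weight by precision", {
  ## {2,2,2,9}: the mode sits at the cluster, not the outlier
  iv <- make_iv(bx = rep(1, 4), by = c(2, 2, 2, 9), sy = rep(1, 4))
  modes <- mrModeEstimators(iv, nBoot = 100, seed = 1, gridPoints = 2000)
  expect_lt(abs(mrBeta(modes$simple) - 2), 1)
  expect_lt(abs(mrBeta(modes$simple) - 2), abs(mrBeta(modes$simple) - 9))
  ## weighted mode: tiny SEs on the cluster, huge on the outlier
  iv2 <- make_iv(bx = rep(1, 4), by = c(2, 2.1, 1.9, 9),
                 sy = c(0.1, 0.1, 0.1, 5))
  modes2 <- mrModeEstimators(iv2, nBoot = 200, seed = 2, gridPoints = 2000)
  expect_lt(abs(mrBeta(modes2$weighted) - 2), 0.3)
  expect_lt(mrSE(modes2$weighted), mrSE(modes2$simple))
  expect_error(mrModeEstimators(iv, bandwidthFactor = 0), "bandwidthFactor")
})

test_that("all estimators are scale- and sign-equivariant in the outcome", {
  for (s in 1:5) {
    iv <- random_iv(k = 12, seed = 300 + s)
    run <- function(v) {
      modes <- mrModeEstimators(v, nBoot = 150, seed = 7, gridPoints = 1500)
      list(ivw = mrIVW(v), egger = mrEgger(v),
           wm = mrWeightedMedian(v, nBoot = 150, seed = 7),
           sm = modes$simple, wmode = modes$weighted,
           gsmr = suppressMessages(gsmrEstimate(v)))
    }
    scale_iv <- function(v, c1) {
      out <- outcomeData(v)
      out$beta <- out$beta * c1
      out$se <- out$se * abs(c1)
      InstrumentSet(exposureData(v), out)
    }
    base <- run(iv)
    up <- run(scale_iv(iv, 2.5))
    neg <- run(scale_iv(iv, -1))
    for (nm in names(base)) {
      expect_equal(mrBeta(up[[nm]]), 2.5 * mrBeta(base[[nm]]),
                   tolerance = 1e-9, label = paste(nm, "scale beta"))
      expect_equal(mrSE(up[[nm]]), 2.5 * mrSE(base[[nm]]),
                   tolerance = 1e-9, label = paste(nm, "scale se"))
      expect_equal(mrBeta(neg[[nm]]), -mrBeta(base[[nm]]),
                   tolerance = 1e-9, label = paste(nm, "sign beta"))
      ## analytic SEs are exactly invariant; bootstrap SEs only up to
      ## resampling noise (the resamples are not mirrored draws)
      tol <- if (nm %in% c("ivw", "egger", "gsmr")) 1e-9 else 0.25
      expect_equal(mrSE(neg[[nm]]), mrSE(base[[nm]]), tolerance = tol,
                   label = paste(nm, "sign se"))
    }
  }
})
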