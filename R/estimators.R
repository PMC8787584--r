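#' Per-SNP Wald ratio estimates
#'
#' The per-variant causal estimate: outcome beta divided by exposure beta,
#' with the first-order delta-method standard error
#' `out_se / |exp_beta|`. Variants with a zero exposure beta are dropped
#' with a message (none arise from a significance-filtered set).
#'
#' @param iv an [InstrumentSet-class].
#' @return data.frame with columns `snp_id`, `ratio`, `se`.
#' @export
waldRatios <- function(iv) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  bx <- iv@exposure$beta
  usable <- bx != 0
  if (!any(usable)) stop("no usable instruments: all exposure betas are zero")
  if (!all(usable))
    message(sprintf("waldRatios: dropped %d SNP(s) with zero exposure beta",
                    sum(!usable)))
  data.frame(snp_id = iv@exposure$snp_id[usable],
             ratio = iv@outcome$beta[usable] / bx[usable],
             se = iv@outcome$se[usable] / abs(bx[usable]),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimate (multiplicative random effects)
#'
#' Zero-intercept weighted regression of outcome betas on exposure betas
#' with weights `1/out_se^2`:
#' `beta = sum(w x y) / sum(w x^2)`, fixed-effect
#' `se = sqrt(1 / sum(w x^2))`. Under the multiplicative random-effects
#' model the SE is rescaled by `sqrt(Q / (k - 1))`, where Q is Cochran's
#' statistic `sum(w (y - beta x)^2)`. By default the rescaling is applied
#' without flooring at 1, so the SE can deflate when the fit is
#' under-dispersed; set `floorDispersion = TRUE` for the common
#' `max(1, .)` variant. P-value from a two-sided normal test.
#'
#' @param iv an [InstrumentSet-class] with k >= 2.
#' @param floorDispersion floor the dispersion factor at 1 (default FALSE).
#' @return An [MRResult-class] with method `ivw_mre`.
#' @export
mrIVW <- function(iv, floorDispersion = FALSE) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  k <- nInstruments(iv)
  if (k < 2) stop("IVW requires at least 2 instruments; use waldRatios()")
  x <- iv@exposure$beta
  y <- iv@outcome$beta
  if (all(x == 0)) stop("all exposure betas are zero")
  w <- 1 / iv@outcome$se^2
  beta <- sum(w * x * y) / sum(w * x^2)
  se_fixed <- sqrt(1 / sum(w * x^2))
  Q <- sum(w * (y - beta * x)^2)
  disp <- sqrt(Q / (k - 1))
  if (floorDispersion) disp <- max(1, disp)
  se <- se_fixed * disp
  .mrResult("ivw_mre", beta, se, .norm_p(beta / se), k, Q, k - 1)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure betas **with** a free
#' intercept (weights `1/out_se^2`), after orienting every instrument to a
#' positive exposure beta (both betas of a negative-exposure SNP are
#' sign-flipped). The slope is the causal estimate; the intercept measures
#' average directional pleiotropy. Both standard errors carry the
#' multiplicative random-effects scaling `sqrt(Q_egger / (k - 2))` without
#' flooring, and p-values use the t distribution on k - 2 degrees of
#' freedom (standard practice for the intercept-including fit at small k).
#'
#' @param iv an [InstrumentSet-class] with k >= 3.
#' @param floorDispersion floor the dispersion factor at 1 (default FALSE).
#' @return An [MRResult-class] with method `egger` and the intercept triple
#'   retrievable via [eggerIntercept()].
#' @export
mrEgger <- function(iv, floorDispersion = FALSE) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  k <- nInstruments(iv)
  if (k < 3) stop("MR-Egger requires at least 3 instruments")
  x <- iv@exposure$beta
  y <- iv@outcome$beta
  flip <- x < 0
  x[flip] <- -x[flip]
  y[flip] <- -y[flip]
  w <- 1 / iv@outcome$se^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- summary(fit)$coefficients       # sigma-hat scaling == sqrt(Q/(k-2))
  Q <- sum(w * stats::residuals(fit)^2)
  scale <- 1
  if (floorDispersion && summary(fit)$sigma < 1)
    scale <- 1 / summary(fit)$sigma     # undo deflation: floor at sigma = 1
  slope <- cf["x", "Estimate"]
  slope_se <- cf["x", "Std. Error"] * scale
  int <- cf["(Intercept)", "Estimate"]
  int_se <- cf["(Intercept)", "Std. Error"] * scale
  t_p <- function(est, se) {
    max(2 * stats::pt(-abs(est / se), df = k - 2), 1e-300)
  }
  .mrResult("egger", slope, slope_se, t_p(slope, slope_se), k, Q, k - 2,
            intercept = int, interceptSE = int_se,
            interceptP = t_p(int, int_se))
}

## Weighted median with linear interpolation across the 50% cumulative
## weight boundary.
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  s <- (cumsum(w) - 0.5 * w) / sum(w)
  if (s[1] >= 0.5) return(x[1])
  below <- max(which(s < 0.5))
  if (below == length(x)) return(x[length(x)])
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - s[below]) / (s[below + 1] - s[below])
}

## Parametric bootstrap resamples of the Wald ratios: B x k matrix.
.boot_ratios <- function(ratio, se, nBoot) {
  k <- length(ratio)
  matrix(stats::rnorm(nBoot * k, mean = rep(ratio, each = nBoot),
                      sd = rep(se, each = nBoot)), nrow = nBoot)
}

.cochran_q <- function(ratio, se, beta) sum((ratio - beta)^2 / se^2)

#' Weighted median estimator
#'
#' The weighted median of the per-SNP Wald ratios with weights proportional
#' to the inverse ratio variances, interpolated linearly across the 50%
#' cumulative-weight boundary. Consistent when instruments carrying up to
#' half the weight are invalid. The standard error comes from a seeded
#' parametric bootstrap (`ratio_i* ~ Normal(ratio_i, se_i)`); p-value from
#' a two-sided normal test.
#'
#' @param iv an [InstrumentSet-class] with k >= 3.
#' @param nBoot bootstrap resamples (default 5000; values below 100 are
#'   raised to 100 with a warning).
#' @param seed RNG seed for the bootstrap; the caller's RNG state is
#'   restored afterwards.
#' @return An [MRResult-class] with method `weighted_median`.
#' @export
mrWeightedMedian <- function(iv, nBoot = 5000, seed = 1) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  if (nInstruments(iv) < 3)
    stop("weighted median requires at least 3 instruments")
  if (nBoot < 100) {
    warning("nBoot below 100 is unreliable; using 100")
    nBoot <- 100
  }
  wr <- waldRatios(iv)
  w <- 1 / wr$se^2
  beta <- .weighted_median(wr$ratio, w)
  boots <- .withSeed(seed, {
    M <- .boot_ratios(wr$ratio, wr$se, nBoot)
    apply(M, 1, .weighted_median, w = w)
  })
  se <- stats::sd(boots)
  .mrResult("weighted_median", beta, se, .norm_p(beta / se), nrow(wr),
            .cochran_q(wr$ratio, wr$se, beta), nrow(wr) - 1)
}

## Modified Silverman bandwidth on the Wald ratios.
.mode_bandwidth <- function(r, factor) {
  spread <- c(stats::sd(r), stats::mad(r))
  spread <- spread[spread > 0]
  if (!length(spread)) return(0)       # degenerate: all ratios identical
  factor * 0.9 * min(spread) * length(r)^(-1 / 5)
}

## Gaussian-kernel mode of ratios r with normalized weights; ties in the
## density argmax break toward the value closest to `anchor`.
.kernel_mode <- function(r, wts, h, grid, anchor) {
  if (h == 0) return(r[1])
  dens <- as.vector(exp(-0.5 * (outer(grid, r, "-") / h)^2) %*% wts)
  top <- which(dens >= max(dens) - 1e-12)
  if (length(top) > 1) top <- top[which.min(abs(grid[top] - anchor))]
  grid[top]
}

#' Simple and weighted mode estimators
#'
#' Mode-based estimation: a Gaussian kernel-smoothed density is built over
#' the per-SNP Wald ratios — unweighted for the simple mode, inverse-
#' variance weighted for the weighted mode — with bandwidth
#' `bandwidthFactor` times a modified Silverman rule
#' (`0.9 min(sd, mad) k^(-1/5)`). The causal estimate is the density argmax
#' on a fine grid spanning the ratios plus/minus three bandwidths; argmax
#' ties break toward the value closest to the weighted median. Standard
#' errors by the same seeded parametric bootstrap as [mrWeightedMedian()]
#' (both modes share the bootstrap resamples); p-values two-sided normal.
#'
#' @param iv an [InstrumentSet-class] with k >= 3.
#' @param bandwidthFactor positive bandwidth multiplier (default 1).
#' @param nBoot bootstrap resamples (default 5000, floored at 100 with a
#'   warning).
#' @param seed RNG seed for the bootstrap.
#' @param gridPoints number of density evaluation points (default 10000).
#' @return list with elements `simple` and `weighted`, each an
#'   [MRResult-class].
#' @export
mrModeEstimators <- function(iv, bandwidthFactor = 1, nBoot = 5000,
                             seed = 1, gridPoints = 10000) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  if (nInstruments(iv) < 3)
    stop("mode estimators require at least 3 instruments")
  if (!is.numeric(bandwidthFactor) || bandwidthFactor <= 0)
    stop("bandwidthFactor must be positive")
  if (nBoot < 100) {
    warning("nBoot below 100 is unreliable; using 100")
    nBoot <- 100
  }
  wr <- waldRatios(iv)
  k <- nrow(wr)
  w_simple <- rep(1 / k, k)
  w_inv <- (1 / wr$se^2) / sum(1 / wr$se^2)
  anchor <- .weighted_median(wr$ratio, 1 / wr$se^2)

  point <- function(r, wts) {
    h <- .mode_bandwidth(r, bandwidthFactor)
    grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = gridPoints)
    .kernel_mode(r, wts, h, grid, anchor)
  }
  beta_s <- point(wr$ratio, w_simple)
  beta_w <- point(wr$ratio, w_inv)

  boots <- .withSeed(seed, {
    M <- .boot_ratios(wr$ratio, wr$se, nBoot)
    bs <- bw <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      r <- M[b, ]
      h <- .mode_bandwidth(r, bandwidthFactor)
      grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = gridPoints)
      if (h == 0) {
        bs[b] <- bw[b] <- r[1]
      } else {
        K <- exp(-0.5 * (outer(grid, r, "-") / h)^2)
        ds <- as.vector(K %*% w_simple)
        dw <- as.vector(K %*% w_inv)
        bs[b] <- grid[which.max(ds)]
        bw[b] <- grid[which.max(dw)]
      }
    }
    list(simple = bs, weighted = bw)
  })
  se_s <- stats::sd(boots$simple)
  se_w <- stats::sd(boots$weighted)
  list(
    simple = .mrResult("simple_mode", beta_s, se_s, .norm_p(beta_s / se_s),
                       k, .cochran_q(wr$ratio, wr$se, beta_s), k - 1),
    weighted = .mrResult("weighted_mode", beta_w, se_w,
                         .norm_p(beta_w / se_w), k,
                         .cochran_q(wr$ratio, wr$se, beta_w), k - 1))
}
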