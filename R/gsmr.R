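#' HEIDI-outlier filtering
#'
#' Iterative removal of heterogeneous outlier instruments. At each round a
#' reference causal estimate is taken as the current set's
#' multiplicative-random-effects IVW beta; each SNP's deviation
#' `d_i = ratio_i - beta_ref` is tested against the variance
#' `var(ratio_i) + var(beta_ref)` as a 1-df chi-square. The single most
#' extreme SNP whose p-value falls below `pThreshold` is removed and the
#' reference refitted, until no SNP is below the threshold or removal would
#' leave fewer than 3 instruments.
#'
#' With `pThreshold = 0.01`, roughly `k x 0.01` well-behaved instruments
#' are expected to be flagged per round in a homogeneous set; the threshold
#' trades outlier sensitivity against such false exclusions.
#'
#' @param iv an [InstrumentSet-class] with k >= 3.
#' @param pThreshold HEIDI exclusion threshold (default 0.01).
#' @return list with elements `retained` (an [InstrumentSet-class]) and
#'   `excluded` (snp ids in removal order).
#' @export
heidiFilter <- function(iv, pThreshold = 0.01) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  if (nInstruments(iv) < 3) stop("HEIDI filtering requires >= 3 instruments")
  excluded <- character()
  current <- iv
  repeat {
    wr <- waldRatios(current)
    ref <- mrIVW(current)
    stat <- (wr$ratio - mrBeta(ref))^2 / (wr$se^2 + mrSE(ref)^2)
    worst <- which.max(stat)
    p_worst <- stats::pchisq(stat[worst], df = 1, lower.tail = FALSE)
    if (p_worst >= pThreshold || nInstruments(current) - 1L < 3L) break
    excluded <- c(excluded, wr$snp_id[worst])
    keep <- current@exposure$snp_id != wr$snp_id[worst]
    current <- .subset_iv(current, keep, "heidi_outlier")
  }
  if (length(excluded))
    message(sprintf("heidiFilter: excluded %d SNP(s) as heterogeneous outliers",
                    length(excluded)))
  list(retained = current, excluded = excluded)
}

#' GSMR-style precision-weighted estimate with HEIDI filtering
#'
#' Applies [heidiFilter()], then combines the surviving Wald ratios with
#' weights `1 / var(ratio_i)`, where the ratio variance uses the
#' second-order delta method that also carries the uncertainty of the
#' exposure beta — the feature that distinguishes this estimator from
#' plain IVW on the ratios:
#'
#' \deqn{var(ratio_i) \approx \frac{se_{out,i}^2}{\beta_{exp,i}^2}
#'   + \frac{\beta_{out,i}^2\, se_{exp,i}^2}{\beta_{exp,i}^4}}
#'
#' `beta = sum(ratio_i / var_i) / sum(1 / var_i)`,
#' `se = sqrt(1 / sum(1 / var_i))`; p two-sided normal. When exposure SEs
#' vanish this reduces exactly to fixed-effect IVW on the ratios.
#'
#' @param iv an [InstrumentSet-class] with k >= 3.
#' @param heidiP HEIDI exclusion threshold (default 0.01).
#' @return An [MRResult-class] with method `gsmr`; HEIDI-excluded SNPs in
#'   [excludedSnps()].
#' @export
gsmrEstimate <- function(iv, heidiP = 0.01) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  hf <- heidiFilter(iv, pThreshold = heidiP)
  kept <- hf$retained
  if (nInstruments(kept) < 3)
    stop("fewer than 3 instruments remain after HEIDI filtering")
  bx <- kept@exposure$beta
  by <- kept@outcome$beta
  sx <- kept@exposure$se
  sy <- kept@outcome$se
  ratio <- by / bx
  v <- sy^2 / bx^2 + by^2 * sx^2 / bx^4
  w <- 1 / v
  beta <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  .mrResult("gsmr", beta, se, .norm_p(beta / se), nInstruments(kept),
            sum(w * (ratio - beta)^2), nInstruments(kept) - 1,
            excluded = hf$excluded)
}

#' Run all six estimators on one instrument set
#'
#' Applies HEIDI filtering once, then runs IVW (multiplicative random
#' effects), MR-Egger, weighted median, simple mode and weighted mode on
#' the surviving instruments, plus the GSMR precision-weighted estimator
#' (whose own HEIDI pass on the already-filtered set is a no-op in all but
#' pathological cases). The HEIDI exclusion list is recorded on the GSMR
#' result.
#'
#' @param iv an [InstrumentSet-class] with k >= 3.
#' @param heidiP HEIDI exclusion threshold (default 0.01).
#' @param nBoot bootstrap resamples for the median/mode SEs (default 5000).
#' @param seed RNG seed for the bootstraps.
#' @param bandwidthFactor mode-estimator bandwidth multiplier (default 1).
#' @param gridPoints mode-estimator density grid size (default 10000).
#' @param floorDispersion floor the IVW/Egger dispersion factor at 1.
#' @return list with elements `estimates` (named list of six
#'   [MRResult-class] objects), `retained` (the filtered
#'   [InstrumentSet-class]) and `excluded` (snp ids).
#' @export
mrAll <- function(iv, heidiP = 0.01, nBoot = 5000, seed = 1,
                  bandwidthFactor = 1, gridPoints = 10000,
                  floorDispersion = FALSE) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  hf <- heidiFilter(iv, pThreshold = heidiP)
  kept <- hf$retained
  modes <- mrModeEstimators(kept, bandwidthFactor = bandwidthFactor,
                            nBoot = nBoot, seed = seed,
                            gridPoints = gridPoints)
  est <- list(
    ivw_mre = mrIVW(kept, floorDispersion = floorDispersion),
    egger = mrEgger(kept, floorDispersion = floorDispersion),
    weighted_median = mrWeightedMedian(kept, nBoot = nBoot, seed = seed),
    simple_mode = modes$simple,
    weighted_mode = modes$weighted,
    gsmr = gsmrEstimate(kept, heidiP = heidiP))
  est$gsmr@excluded <- unique(c(hf$excluded, est$gsmr@excluded))
  list(estimates = est, retained = kept, excluded = hf$excluded)
}
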