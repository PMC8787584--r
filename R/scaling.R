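#' Rescale a binary-exposure MR estimate to per-doubling-of-odds
#'
#' A causal log-OR estimated per unit of exposure liability (log-odds) is
#' multiplied by ln(2) (about 0.693) so that the exponentiated estimate
#' reads as the outcome odds ratio per doubling of the odds of exposure:
#' `beta_scaled = beta * ln 2`, `se_scaled = se * ln 2`,
#' `OR = exp(beta_scaled)`, 95% CI `exp(beta_scaled -/+ ciZ * se_scaled)`.
#'
#' @param beta unscaled causal log-OR (or an [MRResult-class], from which
#'   beta/se/method are taken).
#' @param se its standard error (> 0); ignored when `beta` is an
#'   [MRResult-class].
#' @param method estimator label carried through to the result.
#' @param ciZ normal quantile for the CI half-width (default 1.96, the
#'   conventional 95% constant rather than the exact `qnorm(0.975)`).
#' @return A [ScaledOR-class].
#' @examples
#' scaleToDoubling(-0.07, 0.09)   # OR 0.95, 95% CI 0.84-1.08
#' @export
scaleToDoubling <- function(beta, se = NULL, method = "ivw_mre",
                            ciZ = 1.96) {
  if (methods::is(beta, "MRResult")) {
    method <- mrMethod(beta)
    se <- mrSE(beta)
    beta <- mrBeta(beta)
  }
  if (is.null(se) || !is.finite(se) || se <= 0) stop("se must be > 0")
  b <- beta * log(2)
  s <- se * log(2)
  methods::new("ScaledOR", method = method, beta = b, se = s,
               or = exp(b), ciLow = exp(b - ciZ * s),
               ciHigh = exp(b + ciZ * s))
}

#' Convert a published ratio estimate to a log-scale beta and SE
#'
#' Derives the log-scale effect and standard error from a published odds
#' or hazard ratio with its 95% CI: `beta = ln(point)`,
#' `se = (ln(hi) - ln(lo)) / (2 * 1.96)` (i.e. the 3.92 denominator implied
#' by symmetric 95% bounds). Hazard ratios are treated as OR-like for
#' comparison purposes.
#'
#' @param label study identifier.
#' @param measure "OR" or "HR".
#' @param point ratio point estimate.
#' @param ciLow,ciHigh 95% bounds, with `0 < ciLow < point < ciHigh`.
#' @param ciZ CI normal quantile (default 1.96).
#' @return An [ObsEstimate-class].
#' @examples
#' observationalEstimate("case-control meta", "OR", 1.96, 1.37, 2.80)
#' @export
observationalEstimate <- function(label, measure = c("OR", "HR"), point,
                                  ciLow, ciHigh, ciZ = 1.96) {
  measure <- match.arg(measure)
  if (!(0 < ciLow && ciLow < point && point < ciHigh))
    stop("require 0 < ciLow < point < ciHigh")
  methods::new("ObsEstimate", label = label, measure = measure,
               point = point, ciLow = ciLow, ciHigh = ciHigh,
               beta = log(point),
               se = (log(ciHigh) - log(ciLow)) / (2 * ciZ))
}

#' Read a table of observational estimates
#'
#' TSV with columns `label`, `measure`, `point`, `ci_low`, `ci_high`.
#'
#' @param path file path; defaults to the table of published sleep
#'   apnea / glaucoma observational estimates shipped with the package.
#' @return list of [ObsEstimate-class] objects.
#' @export
readObservational <- function(path = defaultObservational()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "measure", "point", "ci_low", "ci_high")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("observational table missing column(s): ",
         paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    observationalEstimate(df$label[i], df$measure[i], df$point[i],
                          df$ci_low[i], df$ci_high[i]))
}

#' @rdname readObservational
#' @export
defaultObservational <- function() {
  system.file("extdata", "observational_estimates.tsv",
              package = "liabilityMR", mustWork = TRUE)
}

#' Z-difference test between an MR and an observational estimate
#'
#' Two-sided normal test of the difference between a (scaled) MR log-OR
#' and an observational log-ratio:
#' `Z = (beta_MR - beta_Obs) / sqrt(se_MR^2 + se_Obs^2)`,
#' `p = 2 Phi(-|Z|)`. By default the MR side is on the doubling-of-odds
#' scale (a [ScaledOR-class]); pass an unscaled [MRResult-class] to test on
#' the liability scale instead.
#'
#' @param mr a [ScaledOR-class] (or [MRResult-class] for the unscaled
#'   variant).
#' @param obs an [ObsEstimate-class].
#' @return An [MRComparison-class].
#' @export
zDifference <- function(mr, obs) {
  stopifnot(methods::is(obs, "ObsEstimate"))
  if (methods::is(mr, "MRResult"))
    mr <- methods::new("ScaledOR", method = mrMethod(mr), beta = mrBeta(mr),
                       se = mrSE(mr), or = exp(mrBeta(mr)),
                       ciLow = exp(mrBeta(mr) - 1.96 * mrSE(mr)),
                       ciHigh = exp(mrBeta(mr) + 1.96 * mrSE(mr)))
  stopifnot(methods::is(mr, "ScaledOR"))
  if (mr@se <= 0 || obs@se <= 0) stop("both SEs must be > 0")
  z <- (mr@beta - obs@beta) / sqrt(mr@se^2 + obs@se^2)
  methods::new("MRComparison", z = z, pval = .norm_p(z), mr = mr, obs = obs)
}
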