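#' @include AllGenerics.R
NULL

## canonical column set for a per-variant GWAS summary-association table
.SUMMARY_COLS <- c("snp_id", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## two-sided normal p floored away from exact zero so that p in (0, 1]
.norm_p <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

.check_summary_df <- function(df, what, allow_na_eaf = TRUE) {
  msgs <- character()
  missing <- setdiff(.SUMMARY_COLS, names(df))
  if (length(missing)) {
    return(sprintf("%s is missing columns: %s", what,
                   paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$snp_id))
    msgs <- c(msgs, sprintf("%s has duplicated snp_id values", what))
  if (!all(df$effect_allele %in% .BASES) || !all(df$other_allele %in% .BASES))
    msgs <- c(msgs, sprintf("%s has non-ACGT alleles", what))
  if (any(df$effect_allele == df$other_allele))
    msgs <- c(msgs, sprintf("%s has identical effect/other alleles", what))
  eaf <- df$eaf
  bad_eaf <- if (allow_na_eaf) !is.na(eaf) & (eaf <= 0 | eaf >= 1) else
    is.na(eaf) | eaf <= 0 | eaf >= 1
  if (any(bad_eaf))
    msgs <- c(msgs, sprintf("%s has eaf outside (0,1)", what))
  if (any(!is.finite(df$beta)))
    msgs <- c(msgs, sprintf("%s has non-finite beta", what))
  if (any(!is.finite(df$se) | df$se <= 0))
    msgs <- c(msgs, sprintf("%s has se <= 0", what))
  if (any(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1))
    msgs <- c(msgs, sprintf("%s has pval outside (0,1]", what))
  if (any(!is.finite(df$n) | df$n <= 0))
    msgs <- c(msgs, sprintf("%s has non-positive n", what))
  msgs
}

#' InstrumentSet: harmonized exposure/outcome instruments
#'
#' Container for a set of k genetic instruments after allele harmonization:
#' one exposure and one outcome summary association per SNP, aligned to the
#' same effect allele, plus a log of dropped variants and provenance
#' metadata (study labels, palindrome MAF limit, upstream LD-clumping
#' R-squared recorded as metadata only).
#'
#' @slot exposure data.frame of exposure associations (columns `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`).
#' @slot outcome data.frame of outcome associations, same columns, same
#'   row order and alleles as `exposure`.
#' @slot dropLog data.frame with columns `snp_id`, `reason` recording every
#'   variant removed on the way to this set.
#' @slot metadata list of provenance fields.
#'
#' @seealso [harmonizeInstruments()], [filterInstruments()], [waldRatios()]
#' @export
setClass("InstrumentSet",
  slots = c(exposure = "data.frame", outcome = "data.frame",
            dropLog = "data.frame", metadata = "list"))

setValidity("InstrumentSet", function(object) {
  msgs <- character()
  exp <- object@exposure
  out <- object@outcome
  msgs <- c(msgs, .check_summary_df(exp, "exposure"))
  msgs <- c(msgs, .check_summary_df(out, "outcome"))
  if (length(msgs)) return(msgs)
  if (nrow(exp) != nrow(out))
    msgs <- c(msgs, "exposure and outcome have different numbers of SNPs")
  else {
    if (!identical(exp$snp_id, out$snp_id))
      msgs <- c(msgs, "exposure and outcome snp_id columns are not aligned")
    if (!all(exp$effect_allele == out$effect_allele &
             exp$other_allele == out$other_allele))
      msgs <- c(msgs, "alleles are not harmonized between exposure and outcome")
  }
  dl <- object@dropLog
  if (!all(c("snp_id", "reason") %in% names(dl)))
    msgs <- c(msgs, "dropLog must have columns snp_id and reason")
  if (length(msgs)) msgs else TRUE
})

#' Construct an InstrumentSet
#'
#' Builds a validated [InstrumentSet-class] from already-harmonized
#' exposure and outcome tables (same SNPs, same order, same alleles). Most
#' users should obtain instrument sets from [harmonizeInstruments()], which
#' performs the allele alignment; this constructor is for data that are
#' known to be aligned (e.g. simulator output).
#'
#' @param exposure,outcome data.frames with the canonical summary-statistic
#'   columns (`snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n`).
#' @param dropLog optional data.frame (`snp_id`, `reason`).
#' @param metadata optional list of provenance fields.
#' @return An [InstrumentSet-class].
#' @examples
#' sim <- simulatePanel(k = 5, seed = 1)
#' iv <- InstrumentSet(sim$exposure, sim$outcome)
#' nInstruments(iv)
#' @export
InstrumentSet <- function(exposure, outcome,
                          dropLog = data.frame(snp_id = character(),
                                               reason = character()),
                          metadata = list()) {
  rownames(exposure) <- NULL
  rownames(outcome) <- NULL
  methods::new("InstrumentSet", exposure = exposure, outcome = outcome,
               dropLog = dropLog, metadata = metadata)
}

#' MRResult: one estimator's causal-effect estimate
#'
#' Output of a single Mendelian-randomization estimator: the causal log-OR
#' per unit change in exposure liability, its standard error and p-value,
#' the number of instruments used, Cochran's Q heterogeneity statistic,
#' and (for MR-Egger) the intercept, or (for GSMR/HEIDI) the excluded SNPs.
#'
#' P-values are floored at 1e-300 so extreme Z statistics never produce an
#' exact zero.
#'
#' @slot method one of `ivw_mre`, `egger`, `weighted_median`,
#'   `simple_mode`, `weighted_mode`, `gsmr`.
#' @slot beta,se,pval estimate, standard error, two-sided p.
#' @slot kUsed number of instruments entering the fit.
#' @slot intercept,interceptSE,interceptP Egger intercept triple (length 0
#'   for other methods).
#' @slot excluded character vector of HEIDI-excluded SNP ids (GSMR only).
#' @slot Q,Qdf Cochran's Q and its degrees of freedom.
#' @export
setClass("MRResult",
  slots = c(method = "character", beta = "numeric", se = "numeric",
            pval = "numeric", kUsed = "integer",
            intercept = "numeric", interceptSE = "numeric",
            interceptP = "numeric", excluded = "character",
            Q = "numeric", Qdf = "numeric"))

setValidity("MRResult", function(object) {
  msgs <- character()
  ok_methods <- c("ivw_mre", "egger", "weighted_median", "simple_mode",
                  "weighted_mode", "gsmr")
  if (length(object@method) != 1L || !object@method %in% ok_methods)
    msgs <- c(msgs, "method must be one of the six estimator labels")
  if (!is.finite(object@beta)) msgs <- c(msgs, "beta must be finite")
  if (!is.finite(object@se) || object@se <= 0)
    msgs <- c(msgs, "se must be > 0")
  if (!is.finite(object@pval) || object@pval <= 0 || object@pval > 1)
    msgs <- c(msgs, "pval must be in (0,1]")
  if (object@kUsed < 1L) msgs <- c(msgs, "kUsed must be >= 1")
  if (length(object@intercept) != length(object@interceptSE) ||
      length(object@intercept) != length(object@interceptP))
    msgs <- c(msgs, "intercept fields must have equal length")
  if (length(msgs)) msgs else TRUE
})

.mrResult <- function(method, beta, se, pval, kUsed, Q, Qdf,
                      intercept = numeric(), interceptSE = numeric(),
                      interceptP = numeric(), excluded = character()) {
  se <- max(se, 1e-300)   # exact interpolation can yield a zero residual SE
  methods::new("MRResult", method = method, beta = as.numeric(beta),
               se = as.numeric(se), pval = as.numeric(pval),
               kUsed = as.integer(kUsed), intercept = intercept,
               interceptSE = interceptSE, interceptP = interceptP,
               excluded = excluded, Q = as.numeric(Q), Qdf = as.numeric(Qdf))
}

#' InstrumentStrength: variance explained and F statistic
#'
#' Per-instrument and combined variance explained on the observed scale and
#' the combined instrument F statistic. The combined R-squared is the simple
#' sum of per-SNP values (independent, pre-clumped instruments); instruments
#' with a combined F above 10 are conventionally considered strong.
#'
#' @slot perSnpR2 named numeric vector of per-SNP R-squared.
#' @slot totalR2 their sum.
#' @slot fStat combined F statistic.
#' @slot k instrument count.
#' @slot n exposure sample size used for F (median per-SNP n).
#' @seealso [instrumentStrength()], [snpR2()], [combinedF()]
#' @export
setClass("InstrumentStrength",
  slots = c(perSnpR2 = "numeric", totalR2 = "numeric", fStat = "numeric",
            k = "integer", n = "numeric"))

setValidity("InstrumentStrength", function(object) {
  msgs <- character()
  if (any(object@perSnpR2 < 0 | object@perSnpR2 >= 1))
    msgs <- c(msgs, "per-SNP R2 must lie in [0,1)")
  if (object@totalR2 < 0 || object@totalR2 >= 1)
    msgs <- c(msgs, "total R2 must lie in [0,1)")
  if (abs(object@totalR2 - sum(object@perSnpR2)) > 1e-12)
    msgs <- c(msgs, "total R2 must equal the sum of per-SNP values")
  if (object@fStat < 0) msgs <- c(msgs, "F statistic must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' ScaledOR: doubling-of-odds odds ratio
#'
#' A binary-exposure MR estimate rescaled to the effect per doubling of the
#' odds of exposure: beta and SE multiplied by ln(2), exponentiated to an
#' odds ratio with a 95\% confidence interval.
#'
#' @slot method source estimator label.
#' @slot beta,se scaled log-OR and SE.
#' @slot or,ciLow,ciHigh odds ratio and 95\% bounds.
#' @seealso [scaleToDoubling()]
#' @export
setClass("ScaledOR",
  slots = c(method = "character", beta = "numeric", se = "numeric",
            or = "numeric", ciLow = "numeric", ciHigh = "numeric"))

setValidity("ScaledOR", function(object) {
  if (object@se <= 0) return("se must be > 0")
  if (!(object@ciLow < object@or && object@or < object@ciHigh))
    return("confidence interval must bracket the odds ratio")
  TRUE
})

#' ObsEstimate: a published observational ratio estimate
#'
#' An observational odds or hazard ratio with its 95\% CI, converted to a
#' log-scale beta and SE: beta = ln(point), se = (ln(hi) - ln(lo)) / (2 x
#' 1.96).
#'
#' @slot label study identifier.
#' @slot measure "OR" or "HR".
#' @slot point,ciLow,ciHigh ratio estimate and 95\% bounds.
#' @slot beta,se derived log-scale effect and SE.
#' @seealso [observationalEstimate()], [zDifference()]
#' @export
setClass("ObsEstimate",
  slots = c(label = "character", measure = "character", point = "numeric",
            ciLow = "numeric", ciHigh = "numeric", beta = "numeric",
            se = "numeric"))

setValidity("ObsEstimate", function(object) {
  msgs <- character()
  if (!object@measure %in% c("OR", "HR"))
    msgs <- c(msgs, "measure must be OR or HR")
  if (!(0 < object@ciLow && object@ciLow < object@point &&
        object@point < object@ciHigh))
    msgs <- c(msgs, "must satisfy 0 < ciLow < point < ciHigh")
  if (length(object@se) && object@se <= 0) msgs <- c(msgs, "se must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' MRComparison: Z-difference between an MR and an observational estimate
#'
#' Result of the two-sided Z test comparing a (doubling-of-odds scaled) MR
#' estimate against a published observational estimate:
#' Z = (beta_MR - beta_Obs) / sqrt(se_MR^2 + se_Obs^2), p = 2 Phi(-|Z|).
#'
#' @slot z Z statistic.
#' @slot pval two-sided normal p.
#' @slot mr the [ScaledOR-class] side.
#' @slot obs the [ObsEstimate-class] side.
#' @seealso [zDifference()]
#' @export
setClass("MRComparison",
  slots = c(z = "numeric", pval = "numeric", mr = "ScaledOR",
            obs = "ObsEstimate"))

## ---------------------------------------------------------------- accessors

#' @rdname accessors
#' @export
setMethod("nInstruments", "InstrumentSet", function(x) nrow(x@exposure))

#' @rdname accessors
#' @export
setMethod("snpIds", "InstrumentSet", function(x) x@exposure$snp_id)

#' @rdname accessors
#' @export
setMethod("exposureData", "InstrumentSet", function(x) x@exposure)

#' @rdname accessors
#' @export
setMethod("outcomeData", "InstrumentSet", function(x) x@outcome)

#' @rdname accessors
#' @export
setMethod("dropLog", "InstrumentSet", function(x) x@dropLog)

#' @rdname accessors
#' @export
setMethod("ivMetadata", "InstrumentSet", function(x) x@metadata)

#' @rdname accessors
#' @export
setMethod("mrMethod", "MRResult", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("mrBeta", "MRResult", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("mrSE", "MRResult", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("mrPval", "MRResult", function(x) x@pval)

#' @rdname accessors
#' @export
setMethod("kUsed", "MRResult", function(x) x@kUsed)

#' @rdname accessors
#' @export
setMethod("eggerIntercept", "MRResult", function(x) {
  if (!length(x@intercept)) return(NULL)
  c(intercept = x@intercept, se = x@interceptSE, pval = x@interceptP)
})

#' @rdname accessors
#' @export
setMethod("excludedSnps", "MRResult", function(x) x@excluded)

#' @rdname accessors
#' @export
setMethod("heterogeneity", "MRResult", function(x) c(Q = x@Q, df = x@Qdf))

#' @rdname accessors
#' @export
setMethod("perSnpR2", "InstrumentStrength", function(x) x@perSnpR2)

#' @rdname accessors
#' @export
setMethod("totalR2", "InstrumentStrength", function(x) x@totalR2)

#' @rdname accessors
#' @export
setMethod("fStatistic", "InstrumentStrength", function(x) x@fStat)

#' @rdname accessors
#' @export
setMethod("kUsed", "InstrumentStrength", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("mrBeta", "ScaledOR", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("mrSE", "ScaledOR", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("mrMethod", "ScaledOR", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("oddsRatio", "ScaledOR",
          function(x) c(or = x@or, ciLow = x@ciLow, ciHigh = x@ciHigh))

#' @rdname accessors
#' @export
setMethod("mrBeta", "ObsEstimate", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("mrSE", "ObsEstimate", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("oddsRatio", "ObsEstimate",
          function(x) c(or = x@point, ciLow = x@ciLow, ciHigh = x@ciHigh))

#' @rdname accessors
#' @export
setMethod("mrPval", "MRComparison", function(x) x@pval)

## ---------------------------------------------------------------- show

setMethod("show", "InstrumentSet", function(object) {
  md <- object@metadata
  cat("InstrumentSet with", nInstruments(object), "harmonized instruments\n")
  if (!is.null(md$exposure))
    cat("  exposure:", md$exposure, "\n")
  if (!is.null(md$outcome))
    cat("  outcome: ", md$outcome, "\n")
  if (nrow(object@dropLog))
    cat("  dropped: ", nrow(object@dropLog), "variant(s); see dropLog()\n")
  invisible(NULL)
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult [%s]  k = %d\n", object@method, object@kUsed))
  cat(sprintf("  beta = %.4g  se = %.4g  p = %.3g\n",
              object@beta, object@se, object@pval))
  if (length(object@intercept))
    cat(sprintf("  intercept = %.4g  se = %.4g  p = %.3g\n",
                object@intercept, object@interceptSE, object@interceptP))
  if (length(object@excluded))
    cat("  HEIDI-excluded:", paste(object@excluded, collapse = ", "), "\n")
  cat(sprintf("  Cochran Q = %.3g on %g df\n", object@Q, object@Qdf))
  invisible(NULL)
})

setMethod("show", "InstrumentStrength", function(object) {
  cat(sprintf("InstrumentStrength: k = %d, n = %g\n", object@k, object@n))
  cat(sprintf("  total R2 = %.4g (%.3g%%), combined F = %.4g\n",
              object@totalR2, 100 * object@totalR2, object@fStat))
  invisible(NULL)
})

setMethod("show", "ScaledOR", function(object) {
  cat(sprintf("ScaledOR [%s] per doubling of exposure odds\n", object@method))
  cat(sprintf("  OR = %.2f (95%% CI %.2f-%.2f)\n",
              object@or, object@ciLow, object@ciHigh))
  invisible(NULL)
})

setMethod("show", "ObsEstimate", function(object) {
  cat(sprintf("ObsEstimate [%s] %s = %.2f (95%% CI %.2f-%.2f)\n",
              object@label, object@measure, object@point, object@ciLow,
              object@ciHigh))
  cat(sprintf("  beta = %.4g  se = %.4g\n", object@beta, object@se))
  invisible(NULL)
})

setMethod("show", "MRComparison", function(object) {
  cat(sprintf("MRComparison: %s vs %s\n", object@mr@method, object@obs@label))
  cat(sprintf("  Z = %.3f, p = %.3g\n", object@z, object@pval))
  invisible(NULL)
})
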