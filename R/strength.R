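#' Observed-scale variance explained by one instrument
#'
#' Proportion of phenotypic variance in the exposure explained by a single
#' variant on the observed scale:
#'
#' \deqn{R^2 = \frac{2\beta^2 MAF(1-MAF)}
#'   {2\beta^2 MAF(1-MAF) + se(\beta)^2\, 2n\, MAF(1-MAF)}}
#'
#' The formula is symmetric in `maf` vs `1 - maf`; callers should fold the
#' effect-allele frequency to the minor-allele frequency
#' (`min(eaf, 1 - eaf)`) before use, as [instrumentStrength()] does.
#'
#' @param beta per-allele log-odds effect estimate.
#' @param se its standard error (> 0).
#' @param maf minor-allele frequency in (0, 0.5].
#' @param n sample size (>= 2).
#' @return Fraction in [0, 1). Vectorized over all arguments.
#' @examples
#' snpR2(beta = 0.1, se = 0.01, maf = 0.3, n = 1e4)
#' @export
snpR2 <- function(beta, se, maf, n) {
  if (any(!is.finite(maf) | maf <= 0 | maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  if (any(!is.finite(se) | se <= 0)) stop("se must be > 0")
  if (any(!is.finite(n) | n < 2)) stop("n must be >= 2")
  num <- 2 * beta^2 * maf * (1 - maf)
  num / (num + se^2 * 2 * n * maf * (1 - maf))
}

#' Combined instrument F statistic
#'
#' \deqn{F = \frac{R^2 (n - 1 - k)}{(1 - R^2)\, k}}
#'
#' where \eqn{R^2} is the total variance explained by the k instruments and
#' n the exposure sample size. A combined F above 10 is the conventional
#' bar for strong instruments; this function only reports the value.
#'
#' @param totalR2 total variance explained, in [0, 1).
#' @param n exposure sample size (> k + 1).
#' @param k instrument count (>= 1).
#' @return Non-negative F statistic.
#' @examples
#' combinedF(totalR2 = 0.0102, n = 1477325, k = 34)
#' @export
combinedF <- function(totalR2, n, k) {
  if (any(totalR2 < 0 | totalR2 >= 1)) stop("totalR2 must lie in [0, 1)")
  if (any(k < 1)) stop("k must be >= 1")
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  totalR2 * (n - 1 - k) / ((1 - totalR2) * k)
}

#' Instrument strength report for an instrument set
#'
#' Computes per-SNP observed-scale R-squared from the exposure associations
#' (frequency folded to MAF, each SNP using its own sample size), their sum
#' as the combined R-squared (instruments assumed independent), and the
#' combined F statistic using the median per-SNP n.
#'
#' @param iv an [InstrumentSet-class].
#' @return An [InstrumentStrength-class].
#' @export
instrumentStrength <- function(iv) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  exp <- iv@exposure
  if (anyNA(exp$eaf)) stop("instrument strength requires eaf")
  maf <- pmin(exp$eaf, 1 - exp$eaf)
  r2 <- snpR2(exp$beta, exp$se, maf, exp$n)
  names(r2) <- exp$snp_id
  n_comb <- stats::median(exp$n)
  methods::new("InstrumentStrength", perSnpR2 = r2, totalR2 = sum(r2),
               fStat = combinedF(sum(r2), n_comb, nrow(exp)),
               k = nrow(exp), n = n_comb)
}

#' Write an instrument strength report
#'
#' Per-SNP R-squared as TSV plus a one-line summary (total R2, F, k, n)
#' appended as a commented footer mirror of the run log.
#'
#' @param x an [InstrumentStrength-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeStrengthReport <- function(x, path) {
  stopifnot(methods::is(x, "InstrumentStrength"))
  utils::write.table(
    data.frame(snp_id = names(x@perSnpR2), r2 = .fmt_num(x@perSnpR2)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# total_r2=%s\tf_stat=%s\tk=%d\tn=%s\n",
              .fmt_num(x@totalR2), .fmt_num(x@fStat), x@k, .fmt_num(x@n)),
      file = path, append = TRUE)
  invisible(path)
}
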