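## Non-palindromic ordered allele pairs (palindromes only when asked for).
.NONPAL_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates an exposure and an outcome summary-statistic panel emulating a
#' curated set of independent, replicated, genome-wide-significant
#' instruments for a binary exposure, together with the ground truth that
#' produced them — so every pipeline stage can be tested without any real
#' data.
#'
#' Per SNP i: `maf_i ~ Uniform(mafRange)`; the true exposure log-odds
#' effect is `b_i = minExpBeta + |Normal(0, expBetaScale)|` (a sign-
#' oriented-positive effect bounded away from zero, emulating a replicated
#' genome-wide-significant hit; the defaults calibrate a 34-SNP panel to
#' about 1% of observed-scale variance at the default exposure sample
#' size). Standard errors use the binary-trait log-odds approximation
#' `se = 1 / sqrt(2 n maf (1 - maf))`; observed betas are Normal(truth,
#' se); p-values are two-sided normal (floored at 1e-300). The true
#' outcome effect is `trueBeta * b_i + pleiotropy_i`, plus a displacement
#' of `outlierSize` outcome-SE units with random sign for each of
#' `nOutliers` planted heterogeneous outliers. Balanced pleiotropy draws
#' `Normal(0, delta)`; directional draws `Normal(delta, delta / 2)`.
#'
#' The effect-allele frequency reported in the tables is randomly the
#' minor or the major allele frequency, so downstream MAF folding is
#' exercised. Optionally a fraction of outcome rows is stored with
#' reversed alleles and/or on the opposite strand (the same associations,
#' encoded differently) to exercise harmonization; truth flags record
#' which.
#'
#' Winner's curse is NOT simulated by default, mirroring a two-sample
#' replication design; `winnersCurse = TRUE` re-draws each observed
#' exposure beta until it passes `sigThreshold`, demonstrating the
#' selection bias.
#'
#' @param k number of instruments (default 39).
#' @param trueBeta causal log-OR of outcome per unit exposure liability.
#' @param expBetaScale spread of exposure effects (default 0.015).
#' @param minExpBeta lower bound of exposure effects (default 0.015).
#' @param nExp,nOut exposure / outcome GWAS sample sizes (defaults
#'   1,477,325 and 139,900: a very large case-control exposure study and a
#'   well-powered outcome meta-analysis).
#' @param pleiotropy pleiotropy regime: `none`, `balanced`, `directional`.
#' @param pleiotropyDelta pleiotropy magnitude (outcome log-OR units).
#' @param nOutliers planted gross heterogeneous outliers (default 0).
#' @param outlierSize outlier displacement in outcome-SE units (default 15).
#' @param mafRange minor-allele frequency interval (default 0.05-0.5).
#' @param propReversed,propFlipped fractions of outcome rows stored
#'   allele-reversed / strand-flipped (default 0).
#' @param winnersCurse,sigThreshold see above.
#' @param seed RNG seed; identical seed and config give identical output.
#'   The caller's RNG state is restored.
#' @param truth optionally reuse the truth record of a previous run (new
#'   observation noise over the same planted values).
#' @return list with `exposure` and `outcome` (canonical summary-statistic
#'   data.frames), `truth` (data.frame of planted values and flags) and
#'   `config`.
#' @examples
#' sim <- simulatePanel(k = 39, nOutliers = 5, seed = 7)
#' table(sim$truth$outlier)
#' @export
simulatePanel <- function(k = 39, trueBeta = 0, expBetaScale = 0.015,
                          minExpBeta = 0.015, nExp = 1477325, nOut = 139900,
                          pleiotropy = c("none", "balanced", "directional"),
                          pleiotropyDelta = 0, nOutliers = 0,
                          outlierSize = 15, mafRange = c(0.05, 0.5),
                          propReversed = 0, propFlipped = 0,
                          winnersCurse = FALSE, sigThreshold = 5e-8,
                          seed = 1, truth = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  if (k < 1 || nOutliers > k || expBetaScale <= 0 || minExpBeta < 0 ||
      nExp < 2 || nOut < 2 || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("degenerate simulation config")
  if (pleiotropy != "none" && pleiotropyDelta <= 0)
    stop("pleiotropyDelta must be positive for a pleiotropy regime")

  .withSeed(seed, {
    if (is.null(truth)) {
      maf <- stats::runif(k, mafRange[1], mafRange[2])
      eaf <- ifelse(stats::runif(k) < 0.5, maf, 1 - maf)
      b <- minExpBeta + abs(stats::rnorm(k, 0, expBetaScale))
      pl <- switch(pleiotropy,
        none = rep(0, k),
        balanced = stats::rnorm(k, 0, pleiotropyDelta),
        directional = stats::rnorm(k, pleiotropyDelta, pleiotropyDelta / 2))
      outlier <- rep(FALSE, k)
      outlier[sample.int(k, nOutliers)] <- TRUE
      out_sign <- sample(c(-1, 1), k, replace = TRUE)
      pair_idx <- sample.int(nrow(.NONPAL_PAIRS), k, replace = TRUE)
      alleles <- .NONPAL_PAIRS[pair_idx, , drop = FALSE]
      reversed <- stats::runif(k) < propReversed
      flipped <- stats::runif(k) < propFlipped
      truth <- data.frame(
        snp_id = sprintf("rs%d", 1000000 + seq_len(k) * 37),
        maf = maf, eaf = eaf,
        effect_allele = alleles[, 1], other_allele = alleles[, 2],
        bTrue = b, pleiotropy = pl, outlier = outlier,
        outlierSign = out_sign, reversed = reversed, flipped = flipped,
        stringsAsFactors = FALSE)
    }
    k <- nrow(truth)
    se_exp <- 1 / sqrt(2 * nExp * truth$maf * (1 - truth$maf))
    se_out <- 1 / sqrt(2 * nOut * truth$maf * (1 - truth$maf))
    truth$seExp <- se_exp
    truth$seOut <- se_out
    truth$outTrue <- trueBeta * truth$bTrue + truth$pleiotropy +
      ifelse(truth$outlier, truth$outlierSign * outlierSize * se_out, 0)

    beta_exp <- stats::rnorm(k, truth$bTrue, se_exp)
    if (winnersCurse) {
      ## selection on observed significance (rejection sampling); refuse
      ## configs where acceptance is so rare the draw is impractical
      zc <- -stats::qnorm(sigThreshold / 2)
      z_true <- truth$bTrue / se_exp
      p_acc <- stats::pnorm(z_true - zc) + stats::pnorm(-z_true - zc)
      if (any(p_acc < 1e-4))
        stop("winner's-curse selection too strong to sample at this ",
             "threshold; use a milder sigThreshold or stronger instruments")
      for (iter in 1:100000) {
        miss <- .norm_p(beta_exp / se_exp) >= sigThreshold
        if (!any(miss)) break
        beta_exp[miss] <- stats::rnorm(sum(miss), truth$bTrue[miss],
                                       se_exp[miss])
      }
    }
    beta_out <- stats::rnorm(k, truth$outTrue, se_out)

    exposure <- data.frame(
      snp_id = truth$snp_id,
      effect_allele = truth$effect_allele,
      other_allele = truth$other_allele,
      eaf = truth$eaf, beta = beta_exp, se = se_exp,
      pval = .norm_p(beta_exp / se_exp), n = nExp,
      stringsAsFactors = FALSE)
    outcome <- data.frame(
      snp_id = truth$snp_id,
      effect_allele = truth$effect_allele,
      other_allele = truth$other_allele,
      eaf = truth$eaf, beta = beta_out, se = se_out,
      pval = .norm_p(beta_out / se_out), n = nOut,
      stringsAsFactors = FALSE)

    ## effect sizes were drawn for the minor/major encoding in `eaf`; a
    ## reversed row reports the other allele as effect allele, a flipped
    ## row reports the opposite strand -- same association, re-encoded
    rev_rows <- which(truth$reversed)
    outcome$effect_allele[rev_rows] <- truth$other_allele[rev_rows]
    outcome$other_allele[rev_rows] <- truth$effect_allele[rev_rows]
    outcome$beta[rev_rows] <- -outcome$beta[rev_rows]
    outcome$eaf[rev_rows] <- 1 - outcome$eaf[rev_rows]
    flip_rows <- which(truth$flipped)
    outcome$effect_allele[flip_rows] <-
      unname(.COMPLEMENT[outcome$effect_allele[flip_rows]])
    outcome$other_allele[flip_rows] <-
      unname(.COMPLEMENT[outcome$other_allele[flip_rows]])

    attr(exposure, "label") <- "simulated exposure GWAS"
    attr(outcome, "label") <- "simulated outcome GWAS"
    list(exposure = exposure, outcome = outcome, truth = truth,
         config = list(k = k, trueBeta = trueBeta,
                       expBetaScale = expBetaScale,
                       minExpBeta = minExpBeta, nExp = nExp, nOut = nOut,
                       pleiotropy = pleiotropy,
                       pleiotropyDelta = pleiotropyDelta,
                       nOutliers = nOutliers, outlierSize = outlierSize,
                       mafRange = mafRange, propReversed = propReversed,
                       propFlipped = propFlipped,
                       winnersCurse = winnersCurse,
                       sigThreshold = sigThreshold, seed = seed))
  })
}

#' Write a simulated panel to disk
#'
#' Exposure and outcome TSVs in the default summary-statistic dialect plus
#' a truth record as JSON.
#'
#' @param sim result of [simulatePanel()].
#' @param dir output directory (created if needed).
#' @return character vector of the three paths, invisibly.
#' @export
writeSimulatedPanel <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             truth = file.path(dir, "truth.json"))
  writeSummaryStats(sim$exposure, paths[["exposure"]])
  writeSummaryStats(sim$outcome, paths[["outcome"]])
  jsonlite::write_json(list(truth = sim$truth, config = sim$config),
                       paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
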