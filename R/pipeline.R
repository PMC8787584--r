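## Flatten an MRResult for tabular output.
.est_row <- function(e) {
  ic <- eggerIntercept(e)
  data.frame(
    method = mrMethod(e), beta = mrBeta(e), se = mrSE(e), pval = mrPval(e),
    k_used = kUsed(e),
    intercept = if (is.null(ic)) NA_real_ else ic[["intercept"]],
    intercept_se = if (is.null(ic)) NA_real_ else ic[["se"]],
    intercept_p = if (is.null(ic)) NA_real_ else ic[["pval"]],
    Q = heterogeneity(e)[["Q"]], df = heterogeneity(e)[["df"]],
    excluded_snps = paste(excludedSnps(e), collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Estimator results as a data.frame
#'
#' One row per estimator: method, beta, se, pval, k_used, Egger intercept
#' triple, Cochran Q with df, and semicolon-joined excluded SNPs.
#'
#' @param estimates list of [MRResult-class] objects (e.g.
#'   `mrAll(iv)$estimates`).
#' @return data.frame.
#' @export
estimatorTable <- function(estimates) {
  do.call(rbind, lapply(estimates, .est_row))
}

#' Run the full two-sample MR pipeline
#'
#' Orchestrates the complete analysis: read and validate both summary
#' files, harmonize alleles, filter on exposure significance, report
#' instrument strength, HEIDI-filter heterogeneous outliers, run all six
#' estimators, rescale each to the doubling-of-odds OR, and compare the
#' scaled IVW estimate against each published observational estimate with
#' the Z-difference test.
#'
#' Writes to `outDir`: `estimators.tsv`, `scaled_or.tsv`,
#' `comparisons.tsv`, `strength.tsv`, `instruments.tsv`, `drop_log.tsv`,
#' scatter-plot data (`scatter_points.tsv` per-SNP betas with SEs,
#' `scatter_lines.tsv` per-method slope/intercept), forest-plot data
#' (`forest_data.tsv`: label, or, ci_low, ci_high, source MR or
#' observational), a `summary.json` holding every reported number at full
#' precision, and `run.log` with per-stage counts. The run is a pure
#' function of the input files and the configuration (including `seed`),
#' so a repeated run reproduces every output byte-for-byte.
#'
#' @param exposureFile,outcomeFile summary-statistic TSVs (see
#'   [readSummaryStats()]).
#' @param observationalFile TSV of published estimates; defaults to the
#'   table shipped with the package.
#' @param outDir output directory, created if needed.
#' @param pThreshold exposure significance threshold (default 5e-8).
#' @param heidiP HEIDI exclusion threshold (default 0.01).
#' @param palindromeMafLimit see [harmonizeInstruments()].
#' @param replication optional named logical replication filter.
#' @param nBoot,bandwidthFactor,gridPoints,floorDispersion estimator
#'   settings, see [mrAll()].
#' @param seed RNG seed, recorded in every output.
#' @param dialect column dialect for both input files.
#' @return invisibly, a list with the instrument set, strength report,
#'   estimates, scaled ORs, comparisons, and output paths.
#' @export
runPipeline <- function(exposureFile, outcomeFile, observationalFile = NULL,
                        outDir = tempfile("mr_run_"), pThreshold = 5e-8,
                        heidiP = 0.01, palindromeMafLimit = 0.42,
                        replication = NULL, nBoot = 5000,
                        bandwidthFactor = 1, gridPoints = 10000,
                        floorDispersion = FALSE, seed = 1,
                        dialect = defaultDialect()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stop_stage(name, conditionMessage(e)))
  }

  exposure <- stage("read_exposure",
                    suppressMessages(readSummaryStats(exposureFile,
                                                      dialect = dialect)))
  outcome <- stage("read_outcome",
                   suppressMessages(readSummaryStats(outcomeFile,
                                                     dialect = dialect)))
  log("read: %d exposure, %d outcome variants (rejected: %d / %d)",
      nrow(exposure), nrow(outcome),
      nrow(attr(exposure, "rejected")), nrow(attr(outcome, "rejected")))

  iv <- stage("harmonize",
              suppressMessages(harmonizeInstruments(
                exposure, outcome,
                palindromeMafLimit = palindromeMafLimit)))
  log("harmonize: %d instrument(s), %d dropped", nInstruments(iv),
      nrow(dropLog(iv)))

  iv <- stage("filter",
              suppressMessages(filterInstruments(iv, pThreshold,
                                                 replication = replication)))
  log("filter (p < %g): %d candidate instrument(s)", pThreshold,
      nInstruments(iv))

  strength <- stage("strength", instrumentStrength(iv))
  log("strength: total R2 = %.4g%%, combined F = %.4g",
      100 * totalR2(strength), fStatistic(strength))

  fit <- stage("estimators",
               suppressMessages(mrAll(iv, heidiP = heidiP, nBoot = nBoot,
                                      seed = seed,
                                      bandwidthFactor = bandwidthFactor,
                                      gridPoints = gridPoints,
                                      floorDispersion = floorDispersion)))
  log("heidi: excluded %d SNP(s) as heterogeneous outliers; %d analyzed",
      length(fit$excluded), nInstruments(fit$retained))
  for (e in fit$estimates)
    log("  %s: beta = %.4g, se = %.4g, p = %.3g", mrMethod(e), mrBeta(e),
        mrSE(e), mrPval(e))

  scaled <- stage("scaling", lapply(fit$estimates, scaleToDoubling))
  obs <- stage("observational", {
    path <- if (is.null(observationalFile)) defaultObservational() else
      observationalFile
    readObservational(path)
  })
  comparisons <- stage("z_test",
                       lapply(obs, function(o)
                         zDifference(scaled$ivw_mre, o)))
  for (cmp in comparisons)
    log("z-test vs %s: Z = %.3f, p = %.3g", cmp@obs@label, cmp@z, cmp@pval)

  ## ---- outputs -----------------------------------------------------------
  paths <- list(
    estimators = file.path(outDir, "estimators.tsv"),
    scaled = file.path(outDir, "scaled_or.tsv"),
    comparisons = file.path(outDir, "comparisons.tsv"),
    strength = file.path(outDir, "strength.tsv"),
    instruments = file.path(outDir, "instruments.tsv"),
    dropLog = file.path(outDir, "drop_log.tsv"),
    scatterPoints = file.path(outDir, "scatter_points.tsv"),
    scatterLines = file.path(outDir, "scatter_lines.tsv"),
    forest = file.path(outDir, "forest_data.tsv"),
    json = file.path(outDir, "summary.json"),
    log = file.path(outDir, "run.log"))

  est_tab <- estimatorTable(fit$estimates)
  utils::write.table(est_tab, paths$estimators, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  scaled_tab <- do.call(rbind, lapply(scaled, function(s)
    data.frame(method = mrMethod(s), beta_scaled = mrBeta(s),
               se_scaled = mrSE(s), or = oddsRatio(s)[["or"]],
               ci_low = oddsRatio(s)[["ciLow"]],
               ci_high = oddsRatio(s)[["ciHigh"]],
               stringsAsFactors = FALSE)))
  utils::write.table(scaled_tab, paths$scaled, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cmp_tab <- do.call(rbind, lapply(comparisons, function(cmp)
    data.frame(label = cmp@obs@label, z = cmp@z, pval = cmp@pval,
               stringsAsFactors = FALSE)))
  utils::write.table(cmp_tab, paths$comparisons, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  writeStrengthReport(strength, paths$strength)
  writeInstrumentSet(fit$retained, paths$instruments, paths$dropLog)

  kept <- fit$retained
  utils::write.table(
    data.frame(snp_id = snpIds(kept),
               exp_beta = exposureData(kept)$beta,
               exp_se = exposureData(kept)$se,
               out_beta = outcomeData(kept)$beta,
               out_se = outcomeData(kept)$se),
    paths$scatterPoints, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    do.call(rbind, lapply(fit$estimates, function(e) {
      ic <- eggerIntercept(e)
      data.frame(method = mrMethod(e), slope = mrBeta(e),
                 intercept = if (is.null(ic)) 0 else ic[["intercept"]])
    })),
    paths$scatterLines, sep = "\t", quote = FALSE, row.names = FALSE)

  forest <- rbind(
    do.call(rbind, lapply(scaled, function(s)
      data.frame(label = paste0("MR ", mrMethod(s)),
                 or = oddsRatio(s)[["or"]],
                 ci_low = oddsRatio(s)[["ciLow"]],
                 ci_high = oddsRatio(s)[["ciHigh"]], source = "MR",
                 stringsAsFactors = FALSE))),
    do.call(rbind, lapply(obs, function(o)
      data.frame(label = o@label, or = o@point, ci_low = o@ciLow,
                 ci_high = o@ciHigh, source = "observational",
                 stringsAsFactors = FALSE))))
  utils::write.table(forest, paths$forest, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  summary <- list(
    config = list(exposureFile = exposureFile, outcomeFile = outcomeFile,
                  pThreshold = pThreshold, heidiP = heidiP,
                  palindromeMafLimit = palindromeMafLimit, nBoot = nBoot,
                  bandwidthFactor = bandwidthFactor,
                  gridPoints = gridPoints,
                  floorDispersion = floorDispersion, seed = seed),
    counts = list(
      exposure_read = nrow(exposure), outcome_read = nrow(outcome),
      candidates = length(fit$excluded) + nInstruments(kept),
      heidi_excluded = length(fit$excluded),
      analyzed = nInstruments(kept)),
    heidi_excluded_snps = fit$excluded,
    strength = list(total_r2 = totalR2(strength),
                    f_stat = fStatistic(strength), k = kUsed(strength),
                    n = strength@n),
    estimators = est_tab, scaled = scaled_tab, comparisons = cmp_tab)
  jsonlite::write_json(summary, paths$json, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  writeLines(c(sprintf("seed=%d", seed), log_lines), paths$log)

  invisible(list(instruments = kept, strength = strength,
                 estimates = fit$estimates, excluded = fit$excluded,
                 scaled = scaled, observational = obs,
                 comparisons = comparisons, summary = summary,
                 paths = paths))
}
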