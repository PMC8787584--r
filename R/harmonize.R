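.is_palindromic <- function(a1, a2) .COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two summary-statistic tables on shared variants so that both
#' report effects for the same effect allele. For each shared SNP:
#'
#' * identical allele pairs are kept as-is;
#' * reversed pairs (outcome effect allele equals exposure other allele)
#'   have the outcome beta negated, eaf complemented and alleles swapped;
#' * strand flips are resolved through the base complement, including the
#'   complement-and-reversed case;
#' * palindromic variants (A/T or G/C) carry no strand information in their
#'   alleles, so orientation is inferred from allele frequency — and the
#'   variant is dropped as unresolvable when the minor-allele frequency in
#'   either study exceeds `palindromeMafLimit` (frequency-based inference
#'   is unreliable near 0.5);
#' * anything else is dropped as an allele mismatch.
#'
#' Every dropped variant is recorded in the drop log with a reason code.
#' Inputs are never mutated. Instruments are assumed independent
#' (pre-clumped upstream); the clumping threshold is recorded as provenance
#' metadata only.
#'
#' @param exposure,outcome canonical summary-statistic data.frames (from
#'   [readSummaryStats()] or [simulatePanel()]).
#' @param palindromeMafLimit drop palindromic SNPs whose MAF exceeds this
#'   in either study (default 0.42). `NA` disables palindrome handling
#'   entirely (palindromic SNPs are then kept if their alleles match), which
#'   is also the only mode in which missing eaf is tolerated.
#' @param ldR2 upstream LD-clumping threshold, stored as metadata.
#' @return An [InstrumentSet-class].
#' @examples
#' sim <- simulatePanel(k = 10, propReversed = 0.3, seed = 2)
#' iv <- harmonizeInstruments(sim$exposure, sim$outcome)
#' nInstruments(iv)
#' @export
harmonizeInstruments <- function(exposure, outcome,
                                 palindromeMafLimit = 0.42, ldR2 = 0.05) {
  if (!nrow(exposure) || !nrow(outcome))
    stop("exposure and outcome tables must both be non-empty")
  if (anyDuplicated(exposure$snp_id) || anyDuplicated(outcome$snp_id))
    stop("duplicated snp_id values; multi-allelic variants are unsupported")
  handle_palindromes <- !is.na(palindromeMafLimit)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) stop("no shared snp_id between exposure and outcome")

  drops <- list()
  note_drop <- function(id, reason)
    drops[[length(drops) + 1L]] <<- data.frame(snp_id = id, reason = reason)
  for (id in setdiff(exposure$snp_id, shared))
    note_drop(id, "missing_in_outcome")

  exp <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  out <- outcome[match(shared, outcome$snp_id), , drop = FALSE]
  if (handle_palindromes && (anyNA(exp$eaf) || anyNA(out$eaf)))
    stop("missing eaf: frequencies are required unless palindrome ",
         "handling is disabled (palindromeMafLimit = NA)")

  keep <- logical(length(shared))
  for (i in seq_along(shared)) {
    ea_x <- exp$effect_allele[i]; oa_x <- exp$other_allele[i]
    ea_y <- out$effect_allele[i]; oa_y <- out$other_allele[i]
    pal <- .is_palindromic(ea_x, oa_x)

    if (pal && handle_palindromes) {
      ## allele labels cannot distinguish strands; require same pair and
      ## infer orientation from frequency
      same_pair <- (ea_y == ea_x && oa_y == oa_x) ||
        (ea_y == oa_x && oa_y == ea_x) ||
        (.COMPLEMENT[ea_y] == ea_x && .COMPLEMENT[oa_y] == oa_x) ||
        (.COMPLEMENT[ea_y] == oa_x && .COMPLEMENT[oa_y] == ea_x)
      if (!same_pair) { note_drop(shared[i], "allele_mismatch"); next }
      maf_x <- min(exp$eaf[i], 1 - exp$eaf[i])
      maf_y <- min(out$eaf[i], 1 - out$eaf[i])
      if (max(maf_x, maf_y) > palindromeMafLimit) {
        note_drop(shared[i], "palindromic_ambiguous"); next
      }
      aligned <- (exp$eaf[i] < 0.5) == (out$eaf[i] < 0.5)
      if (!aligned) {
        out$beta[i] <- -out$beta[i]
        out$eaf[i] <- 1 - out$eaf[i]
      }
      out$effect_allele[i] <- ea_x
      out$other_allele[i] <- oa_x
      keep[i] <- TRUE
      next
    }

    if (ea_y == ea_x && oa_y == oa_x) {           # already aligned
      keep[i] <- TRUE
    } else if (ea_y == oa_x && oa_y == ea_x) {    # reversed
      out$beta[i] <- -out$beta[i]
      if (!is.na(out$eaf[i])) out$eaf[i] <- 1 - out$eaf[i]
      out$effect_allele[i] <- ea_x
      out$other_allele[i] <- oa_x
      keep[i] <- TRUE
    } else if (.COMPLEMENT[ea_y] == ea_x && .COMPLEMENT[oa_y] == oa_x) {
      out$effect_allele[i] <- ea_x                # strand flip
      out$other_allele[i] <- oa_x
      keep[i] <- TRUE
    } else if (.COMPLEMENT[ea_y] == oa_x && .COMPLEMENT[oa_y] == ea_x) {
      out$beta[i] <- -out$beta[i]                 # strand flip + reversed
      if (!is.na(out$eaf[i])) out$eaf[i] <- 1 - out$eaf[i]
      out$effect_allele[i] <- ea_x
      out$other_allele[i] <- oa_x
      keep[i] <- TRUE
    } else {
      note_drop(shared[i], "allele_mismatch")
    }
  }

  if (!any(keep)) stop("no variants survive harmonization")
  dropLog <- if (length(drops)) do.call(rbind, drops) else
    data.frame(snp_id = character(), reason = character())
  if (nrow(dropLog))
    message(sprintf("harmonizeInstruments: dropped %d variant(s): %s",
                    nrow(dropLog),
                    paste(unique(dropLog$reason), collapse = "; ")))
  InstrumentSet(
    exposure = exp[keep, , drop = FALSE],
    outcome = out[keep, , drop = FALSE],
    dropLog = dropLog,
    metadata = list(
      exposure = attr(exposure, "label"),
      outcome = attr(outcome, "label"),
      palindromeMafLimit = palindromeMafLimit,
      ldClumpR2 = ldR2))
}

#' Filter instruments on exposure significance and replication
#'
#' Retains instruments whose exposure association p-value is strictly below
#' `pThreshold` (strict inequality: a SNP at exactly the threshold is
#' removed) and, when a replication status is supplied, which replicated.
#' Order is preserved; removals are appended to the drop log.
#'
#' @param iv an [InstrumentSet-class].
#' @param pThreshold exposure significance threshold in (0,1); default the
#'   genome-wide 5e-8.
#' @param replication optional named logical vector (names are snp ids);
#'   instruments mapping to `FALSE` (or absent from the vector) are removed.
#' @return A filtered [InstrumentSet-class].
#' @export
filterInstruments <- function(iv, pThreshold = 5e-8, replication = NULL) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  if (!is.numeric(pThreshold) || pThreshold <= 0 || pThreshold >= 1)
    stop("pThreshold must lie in (0,1)")
  exp <- iv@exposure
  keep <- exp$pval < pThreshold
  reason <- ifelse(keep, NA_character_, "exposure_p_not_below_threshold")
  if (!is.null(replication)) {
    rep_ok <- !is.na(replication[exp$snp_id]) & replication[exp$snp_id]
    reason[keep & !rep_ok] <- "failed_replication"
    keep <- keep & rep_ok
  }
  if (!any(keep)) stop("no instruments pass the filters")
  dropped <- data.frame(snp_id = exp$snp_id[!keep], reason = reason[!keep])
  if (nrow(dropped))
    message(sprintf("filterInstruments: removed %d instrument(s)",
                    nrow(dropped)))
  InstrumentSet(
    exposure = exp[keep, , drop = FALSE],
    outcome = iv@outcome[keep, , drop = FALSE],
    dropLog = rbind(iv@dropLog, dropped),
    metadata = c(iv@metadata, list(pThreshold = pThreshold)))
}

## Internal subset keeping the drop log, appending a reason for removals.
.subset_iv <- function(iv, keep, reason) {
  dropped <- data.frame(snp_id = iv@exposure$snp_id[!keep],
                        reason = rep(reason, sum(!keep)))
  InstrumentSet(
    exposure = iv@exposure[keep, , drop = FALSE],
    outcome = iv@outcome[keep, , drop = FALSE],
    dropLog = rbind(iv@dropLog, dropped),
    metadata = iv@metadata)
}

#' Write a harmonized instrument table and its drop log
#'
#' Writes the instrument set as TSV with the two studies' columns prefixed
#' `exp_` / `out_`, and optionally the drop log as a second TSV.
#'
#' @param iv an [InstrumentSet-class].
#' @param path output TSV path.
#' @param dropLogPath optional path for the drop log TSV.
#' @return `path`, invisibly.
#' @export
writeInstrumentSet <- function(iv, path, dropLogPath = NULL) {
  stopifnot(methods::is(iv, "InstrumentSet"))
  exp <- iv@exposure
  out <- iv@outcome
  tab <- data.frame(snp_id = exp$snp_id, stringsAsFactors = FALSE)
  for (col in setdiff(.SUMMARY_COLS, "snp_id")) {
    tab[[paste0("exp_", col)]] <- if (is.numeric(exp[[col]]))
      .fmt_num(exp[[col]]) else exp[[col]]
    tab[[paste0("out_", col)]] <- if (is.numeric(out[[col]]))
      .fmt_num(out[[col]]) else out[[col]]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dropLogPath))
    utils::write.table(iv@dropLog, dropLogPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
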