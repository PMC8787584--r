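#' Default column dialect for GWAS summary-statistic files
#'
#' Mapping from the canonical field names used internally to the column
#' names expected in the file. Override entries to read files with other
#' headers, e.g. `defaultDialect(snp_id = "rsid", pval = "p")`.
#'
#' @param ... named overrides, one per canonical field.
#' @return Named character vector mapping canonical field -> file column.
#' @examples
#' defaultDialect()
#' defaultDialect(snp_id = "MarkerName", eaf = "Freq1")
#' @export
defaultDialect <- function(...) {
  d <- c(snp_id = "snp", effect_allele = "effect_allele",
         other_allele = "other_allele", eaf = "eaf", beta = "beta",
         se = "se", pval = "pval", n = "n")
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(d))
    if (length(bad))
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(overrides)] <- overrides
  }
  d
}

## Row-level validation; returns list(valid = df, rejected = df(row, snp_id, reason))
.validate_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[bad & is.na(reason)] <<- why
  }
  flag(is.na(df$snp_id) | !nzchar(df$snp_id), "missing snp_id")
  flag(!(df$effect_allele %in% .BASES), "effect_allele not a single ACGT base")
  flag(!(df$other_allele %in% .BASES), "other_allele not a single ACGT base")
  flag(!is.na(df$effect_allele) & !is.na(df$other_allele) &
         df$effect_allele == df$other_allele, "alleles identical")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0,1)")
  flag(!is.finite(df$beta), "beta not a finite number")
  flag(!is.finite(df$se) | df$se <= 0, "se not > 0")
  flag(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1, "pval outside (0,1]")
  flag(!is.finite(df$n) | df$n <= 0, "n not a positive number")
  ok <- is.na(reason)
  list(valid = df[ok, , drop = FALSE],
       rejected = data.frame(row = which(!ok),
                             snp_id = as.character(df$snp_id[!ok]),
                             reason = reason[!ok]))
}

#' Read and validate GWAS summary statistics
#'
#' Reads a tab-separated summary-statistic file (gzip transparently
#' supported), maps its columns through a dialect, coerces types, and
#' validates every row against the per-variant invariants (single ACGT
#' alleles that differ, eaf in (0,1), se > 0, pval in (0,1], positive n).
#' Rows violating any invariant are rejected with a recorded reason, never
#' silently skipped; the rejected rows are attached as
#' `attr(x, "rejected")` and counts are reported via `message()`.
#'
#' A missing `eaf` is tolerated at read time (some studies do not publish
#' frequencies) but [harmonizeInstruments()] refuses it unless palindrome
#' handling is disabled.
#'
#' @param path path to a TSV (optionally .gz) file with a header row.
#' @param dialect column-name mapping, see [defaultDialect()].
#' @param label free-text study label stored with the data.
#' @return data.frame with canonical columns `snp_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`; attributes
#'   `rejected` (data.frame of row, snp_id, reason) and `label`.
#' @examples
#' sim <- simulatePanel(k = 5, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeSummaryStats(sim$exposure, f)
#' x <- readSummaryStats(f)
#' nrow(x)
#' @export
readSummaryStats <- function(path, dialect = defaultDialect(),
                             label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  missing <- dialect[!dialect %in% names(raw)]
  if (length(missing))
    stop("mapped column(s) not present in ", path, ": ",
         paste(missing, collapse = ", "))
  df <- data.frame(
    snp_id = as.character(raw[[dialect[["snp_id"]]]]),
    effect_allele = toupper(trimws(raw[[dialect[["effect_allele"]]]])),
    other_allele = toupper(trimws(raw[[dialect[["other_allele"]]]])),
    eaf = suppressWarnings(as.numeric(raw[[dialect[["eaf"]]]])),
    beta = suppressWarnings(as.numeric(raw[[dialect[["beta"]]]])),
    se = suppressWarnings(as.numeric(raw[[dialect[["se"]]]])),
    pval = suppressWarnings(as.numeric(raw[[dialect[["pval"]]]])),
    n = suppressWarnings(as.numeric(raw[[dialect[["n"]]]])),
    stringsAsFactors = FALSE)
  v <- .validate_rows(df)
  if (nrow(v$rejected))
    message(sprintf("readSummaryStats: rejected %d of %d row(s): %s",
                    nrow(v$rejected), nrow(df),
                    paste(unique(v$rejected$reason), collapse = "; ")))
  if (!nrow(v$valid))
    stop("no valid rows in ", path)
  message(sprintf("readSummaryStats: %d valid row(s) from %s",
                  nrow(v$valid), path))
  out <- v$valid
  rownames(out) <- NULL
  attr(out, "rejected") <- v$rejected
  attr(out, "label") <- label
  out
}

#' Write GWAS summary statistics
#'
#' Writes a canonical summary-statistic data.frame as TSV using a column
#' dialect. Numeric fields are formatted with 17 significant digits so a
#' read/write/read round trip preserves every value exactly. A `.gz` path
#' writes a gzip stream.
#'
#' @param x data.frame with the canonical columns.
#' @param path output path; compressed when it ends in `.gz`.
#' @param dialect column-name mapping, see [defaultDialect()].
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path, dialect = defaultDialect()) {
  stopifnot(all(.SUMMARY_COLS %in% names(x)))
  out <- data.frame(
    x$snp_id, x$effect_allele, x$other_allele,
    .fmt_num(x$eaf), .fmt_num(x$beta), .fmt_num(x$se),
    .fmt_num(x$pval), .fmt_num(x$n),
    stringsAsFactors = FALSE)
  names(out) <- unname(dialect[.SUMMARY_COLS])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
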