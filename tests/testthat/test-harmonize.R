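exp_row <- function(id = "rs1", ea = "A", oa = "G", eaf = 0.3, beta = 0.1) {
  data.frame(snp_id = id, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = 0.01, pval = 1e-10, n = 1e5,
             stringsAsFactors = FALSE)
}

test_that("reversed, strand-flipped and mismatched alleles are resolved", {
  exposure <- rbind(exp_row("rs1", "A", "G"), exp_row("rs2", "C", "T"),
                    exp_row("rs3", "A", "G"), exp_row("rs4", "A", "G"))
  outcome <- rbind(
    exp_row("rs1", "G", "A", eaf = 0.7, beta = 0.05),   # reversed
    exp_row("rs2", "G", "A", eaf = 0.3, beta = 0.04),   # strand flip
    exp_row("rs3", "C", "T", eaf = 0.7, beta = 0.03),   # flip + reversed
    exp_row("rs4", "A", "C", beta = 0.02))              # mismatch
  iv <- suppressMessages(harmonizeInstruments(exposure, outcome))
  out <- outcomeData(iv)
  expect_equal(snpIds(iv), c("rs1", "rs2", "rs3"))
  expect_equal(out$beta, c(-0.05, 0.04, -0.03))
  expect_equal(out$eaf, c(0.3, 0.3, 0.3))
  expect_equal(out$effect_allele, c("A", "C", "A"))
  expect_equal(dropLog(iv)$reason[dropLog(iv)$snp_id == "rs4"],
               "allele_mismatch")
})

test_that("palindromic SNPs: frequency-aligned below the MAF limit, dropped above", {
  exposure <- rbind(exp_row("rs1", "A", "T", eaf = 0.2),
                    exp_row("rs2", "C", "G", eaf = 0.50),
                    exp_row("rs3", "A", "T", eaf = 0.2),
                    exp_row("rs4", "A", "G"))
  outcome <- rbind(
    exp_row("rs1", "A", "T", eaf = 0.25, beta = 0.07),  # same orientation
    exp_row("rs2", "C", "G", eaf = 0.50, beta = 0.06),  # MAF 0.5 > limit
    exp_row("rs3", "T", "A", eaf = 0.85, beta = 0.05),  # opposite side
    exp_row("rs4", "A", "G", beta = 0.04))
  iv <- suppressMessages(harmonizeInstruments(exposure, outcome))
  expect_equal(snpIds(iv), c("rs1", "rs3", "rs4"))
  expect_equal(outcomeData(iv)$beta, c(0.07, -0.05, 0.04))
  expect_equal(dropLog(iv)$reason[dropLog(iv)$snp_id == "rs2"],
               "palindromic_ambiguous")
  ## disabling palindrome handling keeps rs2
  iv2 <- suppressMessages(
    harmonizeInstruments(exposure, outcome, palindromeMafLimit = NA))
  expect_true("rs2" %in% snpIds(iv2))
})

test_that("missing eaf is an error unless palindrome handling is disabled", {
  exposure <- exp_row("rs1", "A", "G", eaf = NA)
  outcome <- exp_row("rs1", "A", "G", beta = 0.05)
  expect_error(harmonizeInstruments(exposure, outcome), "missing eaf")
  iv <- harmonizeInstruments(exposure, outcome, palindromeMafLimit = NA)
  expect_equal(nInstruments(iv), 1L)
})

test_that("planted reversals and strand flips are recovered to truth signs", {
  sim0 <- simulatePanel(k = 40, seed = 21)                     # clean encoding
  sim1 <- simulatePanel(k = 40, propReversed = 0.4,
                        propFlipped = 0.4, seed = 21)          # same draws
  expect_identical(sim1$outcome$beta,
                   ifelse(sim1$truth$reversed, -sim0$outcome$beta,
                          sim0$outcome$beta))
  iv <- suppressMessages(harmonizeInstruments(sim1$exposure, sim1$outcome))
  expect_equal(nInstruments(iv), 40L)
  m <- match(snpIds(iv), sim0$outcome$snp_id)
  expect_equal(outcomeData(iv)$beta, sim0$outcome$beta[m])
  expect_equal(outcomeData(iv)$effect_allele, sim0$outcome$effect_allele[m])
})

test_that("harmonization is idempotent and does not mutate its inputs", {
  sim <- simulatePanel(k = 20, propReversed = 0.5, seed = 5)
  exp_before <- sim$exposure
  out_before <- sim$outcome
  iv1 <- suppressMessages(harmonizeInstruments(sim$exposure, sim$outcome))
  expect_identical(sim$exposure, exp_before)
  expect_identical(sim$outcome, out_before)
  iv2 <- suppressMessages(
    harmonizeInstruments(exposureData(iv1), outcomeData(iv1)))
  expect_identical(exposureData(iv2), exposureData(iv1))
  expect_identical(outcomeData(iv2)$beta, outcomeData(iv1)$beta)
})

test_that("significance filtering is strict and respects replication", {
  sim <- simulatePanel(k = 39, seed = 31)
  iv <- InstrumentSet(sim$exposure, sim$outcome)
  ## all simulated instruments are genome-wide significant
  expect_equal(nInstruments(suppressMessages(filterInstruments(iv))), 39L)

  ## plant 3 sub-threshold SNPs -> 36 retained
  weak <- c(4, 17, 30)
  exp2 <- sim$exposure
  exp2$pval[weak] <- c(5e-8, 1e-6, 0.2)   # first sits exactly at threshold
  iv2 <- InstrumentSet(exp2, sim$outcome)
  kept <- suppressMessages(filterInstruments(iv2, pThreshold = 5e-8))
  expect_equal(nInstruments(kept), 36L)
  expect_false(any(sim$exposure$snp_id[weak] %in% snpIds(kept)))
  expect_true(all(dropLog(kept)$reason == "exposure_p_not_below_threshold"))

  ## replication filter
  repl <- setNames(rep(TRUE, 39), sim$exposure$snp_id)
  repl[c("rs1000037", "rs1000074")] <- FALSE
  kept2 <- suppressMessages(filterInstruments(iv, replication = repl))
  expect_equal(nInstruments(kept2), 37L)
  expect_error(suppressMessages(filterInstruments(iv, pThreshold = 1e-300)),
               "no instruments")
  expect_error(filterInstruments(iv, pThreshold = 1), "pThreshold")
})

test_that("the instrument table and drop log export with exp_/out_ prefixes", {
  sim <- simulatePanel(k = 8, seed = 3)
  iv <- suppressMessages(harmonizeInstruments(sim$exposure, sim$outcome))
  f <- tempfile(); g <- tempfile()
  writeInstrumentSet(iv, f, g)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 8L)
  expect_true(all(c("snp_id", "exp_beta", "out_beta", "exp_se", "out_se")
                  %in% names(tab)))
  expect_equal(tab$exp_beta, exposureData(iv)$beta)
  expect_identical(names(read.delim(g)), c("snp_id", "reason"))
})
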