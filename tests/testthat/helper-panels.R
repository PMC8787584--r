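# Build a harmonized InstrumentSet directly from effect vectors (A/G
# alleles, shared eaf), bypassing file IO and harmonization.
make_iv <- function(bx, by, sx = rep(0.01, length(bx)),
                    sy = rep(0.01, length(bx)), eaf = 0.3, n = 1e5) {
  k <- length(bx)
  stopifnot(length(by) == k, length(sx) == k, length(sy) == k)
  tab <- function(beta, se) data.frame(
    snp_id = sprintf("snp%03d", seq_len(k)),
    effect_allele = "A", other_allele = "G",
    eaf = rep(eaf, k), beta = beta, se = se,
    pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = rep(n, k),
    stringsAsFactors = FALSE)
  InstrumentSet(tab(bx, sx), tab(by, sy))
}

# A small random but well-behaved instrument panel.
random_iv <- function(k = 20, seed = 1, b = 0.1) {
  set.seed(seed)
  bx <- runif(k, 0.05, 0.3)
  sy <- runif(k, 0.005, 0.02)
  by <- b * bx + rnorm(k, 0, sy)
  make_iv(bx, by, sx = runif(k, 0.002, 0.01), sy = sy)
}

# Deterministic 39-instrument panel reproducing the candidate/outlier
# accounting: 34 instruments share one Wald ratio up to sub-threshold
# jitter, 5 are grossly displaced heterogeneous outliers.
accounting_panel <- function(ratio = -0.07, k = 39, n_out = 5,
                             displacement = 15) {
  bx <- seq(0.02, 0.05, length.out = k)
  sy <- rep(0.005, k)
  jitter <- rep(c(0.3, -0.3), length.out = k) * sy   # well under threshold
  by <- ratio * bx + jitter
  out_idx <- seq(3, by = 8, length.out = n_out)      # spread through panel
  by[out_idx] <- ratio * bx[out_idx] +
    rep(c(1, -1), length.out = n_out) * displacement * sy[out_idx]
  iv <- make_iv(bx, by, sx = rep(0.0015, k), sy = sy)
  list(iv = iv, outliers = snpIds(iv)[out_idx])
}
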