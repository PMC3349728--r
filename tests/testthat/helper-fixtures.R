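# Small in-code fixtures shared across test files.

toy_calls <- function(df, provenance = "callerA", build = "hg18") {
  cnv_calls(df, provenance = provenance, genome_build = build)
}

# quick call-table builder: one row per string "sample chrom start end cn"
calls_from_strings <- function(x, ...) {
  f <- do.call(rbind, strsplit(x, "\\s+"))
  toy_calls(data.frame(sample_id = f[, 1], chrom = f[, 2],
                       start = as.numeric(f[, 3]), end = as.numeric(f[, 4]),
                       cn = as.integer(f[, 5]), stringsAsFactors = FALSE), ...)
}

toy_samples <- function(n_cases, n_controls, quality = TRUE, seed = 42) {
  set.seed(seed)
  n <- n_cases + n_controls
  df <- data.frame(
    sample_id = c(sprintf("case%03d", seq_len(n_cases)),
                  sprintf("control%03d", seq_len(n_controls))),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    stringsAsFactors = FALSE)
  df$syndromic <- c(rep(c(TRUE, FALSE), length.out = n_cases),
                    rep(NA, n_controls))
  df$down_syndrome <- FALSE
  if (quality) {
    df$lrr_sd <- rlnorm(n, log(0.15), 0.25)
    df$baf_drift <- rlnorm(n, log(0.005), 0.4)
    df$mad <- rlnorm(n, log(0.13), 0.25)
  } else {
    df$lrr_sd <- df$baf_drift <- df$mad <- NA_real_
  }
  df$wave <- 0.01
  df
}

# random interval set on a small genome
random_intervals <- function(n, chroms = c("1", "2"), max_pos = 1e5,
                             max_len = 2e4) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + sample.int(max_len, n, replace = TRUE) - 1,
             stringsAsFactors = FALSE)
}

# 1-based closed overlap, the oracle-side primitive used by several suites
overlaps1 <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
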