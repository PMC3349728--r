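# independent enumeration oracle: sort the fixed-margin distribution and
# accumulate point probabilities <= the observed one
fisher_oracle <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, n1)
  pr <- stats::dhyper(support, n1, n2, k)
  obs <- pr[support == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

test_that("two-sided Fisher reproduces the frozen carrier tables", {
  # discovery: 5/129 case carriers vs 0/331
  expect_equal(fisher_exact_two_sided(5, 124, 0, 331), 1.64e-3,
               tolerance = 5e-3)
  # replication, deletions only (duplication carriers excluded): 9/94 vs 5/220
  expect_equal(fisher_exact_two_sided(9, 85, 5, 215), 6.92e-3,
               tolerance = 5e-3)
  # empty carrier margin
  expect_equal(fisher_exact_two_sided(0, 10, 0, 10), 1)
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p agrees with enumeration, fisher.test, and symmetries", {
  set.seed(61)
  for (i in 1:200) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    a <- sample(0:n1, 1); c_ <- sample(0:n2, 1)
    b <- n1 - a; d <- n2 - c_
    p <- fisher_exact_two_sided(a, b, c_, d)
    expect_equal(p, fisher_oracle(a, b, c_, d), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                              byrow = TRUE))$p.value,
                 tolerance = 1e-7)
    # row swap and transpose leave the two-sided p unchanged
    expect_equal(p, fisher_exact_two_sided(c_, d, a, b))
    if (a + c_ > 0 && b + d > 0)  # transpose needs non-empty rows
      expect_equal(p, fisher_exact_two_sided(a, c_, b, d))
  }
})

test_that("carrier frequencies and fold enrichment", {
  f <- carrier_frequencies(5, 124, 0, 331)
  expect_equal(round(100 * f$case_freq, 2), 3.88)
  expect_true(f$fold_infinite)
  f2 <- carrier_frequencies(14, 209, 5, 546)
  expect_equal(round(100 * f2$control_freq, 2), 0.91)
  expect_equal(round(f2$fold), 7)
})

test_that("weighted Stouffer combination", {
  p1 <- fisher_exact_two_sided(5, 124, 0, 331)
  p2 <- fisher_exact_two_sided(9, 85, 5, 215)
  comb <- stouffer_combine(c(p1, p2), n = c(460, 316))
  expect_equal(comb$p, 3.36e-5, tolerance = 5e-3)

  # single phase: combination returns the phase's own p
  expect_equal(stouffer_combine(0.0123, n = 460)$p, 0.0123)

  # two identical phases p0 = 0.05, equal n: Z = sqrt(2) z(0.05)
  z0 <- qnorm(1 - 0.05 / 2)
  expect_equal(stouffer_combine(c(0.05, 0.05), c(100, 100))$p,
               2 * pnorm(sqrt(2) * z0, lower.tail = FALSE))
  expect_lt(stouffer_combine(c(0.05, 0.05), c(100, 100))$p, 0.05)

  # strictly decreasing in the number of identical phases
  pk <- sapply(1:5, function(k)
    stouffer_combine(rep(0.2, k), rep(50, k))$p)
  expect_true(all(diff(pk) < 0))

  # invariant to phase ordering
  expect_equal(stouffer_combine(c(p1, p2), c(460, 316))$p,
               stouffer_combine(c(p2, p1), c(316, 460))$p)

  # signed directions can cancel
  opp <- stouffer_combine(c(0.01, 0.01), c(100, 100), direction = c(1, -1))
  expect_equal(opp$z, 0)

  expect_error(stouffer_combine(c(0, 0.5), c(10, 10)), "p = 0")
  expect_error(stouffer_combine(c(0.5, 0.5), c(10, 10), direction = c(1, 0)),
               "direction")
})

test_that("phase_result + combine_phases wire tables to the combiner", {
  ph <- list(phase_result("discovery", 5, 124, 0, 331),
             phase_result("replication", 9, 85, 5, 215))
  expect_equal(ph[[1]]$direction, 1)
  res <- combine_phases(ph)
  expect_equal(res$p,
               stouffer_combine(c(ph[[1]]$p_two_sided, ph[[2]]$p_two_sided),
                                c(460, 314))$p)  # n = table totals
})

test_that("association scan finds planted case-exclusive CNVRs", {
  planted <- data.frame(chrom = "7", start = 5e5, end = 5.2e5, type = "del",
                        case_freq = 0.10, control_freq = 0)
  # low background rate: on the 100x-scaled genome the default rate would
  # chain background calls across the planted locus (see methods vignette)
  coh <- generate_cohort(cohort_spec(n_cases = 129, n_controls = 331,
                                     baseline_cnv_rate = 0.3,
                                     planted_cnvrs = planted, seed = 62))
  cnvrs <- build_cnvrs(consensus_segments(coh$calls_a, coh$calls_b),
                       coh$samples)
  scan <- cnvr_association_scan(cnvrs, coh$samples)
  top <- scan[1, ]
  expect_equal(top$chrom, "7")
  expect_true(top$start <= 5.2e5 && top$end >= 5e5)
  expect_equal(min(scan$p), top$p)
})

test_that("single-carrier CNVR p equals the carrier-margin closed form", {
  samples <- data.frame(sample_id = c(sprintf("case%03d", 1:129),
                                      sprintf("ctrl%03d", 1:331)),
                        group = rep(c("case", "control"), c(129, 331)))
  calls <- calls_from_strings("case001 1 100 200 1")
  scan <- cnvr_association_scan(build_cnvrs(calls, samples), samples)
  # one carrier: p = P(the carrier is a case) = 129/460
  expect_equal(scan$p, 129 / 460)
})

test_that("null scan p-values are not anti-conservative", {
  set.seed(63)
  coh <- generate_cohort(cohort_spec(n_cases = 100, n_controls = 100,
                                     case_rate_multiplier = 1, seed = 63))
  scan <- cnvr_association_scan(build_cnvrs(coh$calls_a, coh$samples),
                                coh$samples)
  # discrete exact p: under the null, P(p <= a) <= a; check at two levels
  expect_lte(mean(scan$p <= 0.05), 0.08)
  expect_gte(mean(scan$p > 0.5), 0.3)
})
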