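test_that("per-sample metrics aggregate filtered calls", {
  samples <- toy_samples(2, 1)
  samples$sample_id <- c("s1", "s2", "s3")
  genes <- data.frame(name = c("A", "B"), chrom = "1",
                      start = c(100000, 300000), end = c(120000, 320000),
                      strand = "+")
  calls <- calls_from_strings(c("s1 1 100000 109999 1",    # 10 kb, gene A
                                "s1 1 300000 329999 1"))   # 30 kb, gene B
  met <- compute_burden_metrics(calls, samples, burden_filter(), genes)
  expect_equal(met$n_cnv, c(2L, 0L, 0L))
  expect_equal(met$total_kb, c(40, 0, 0))
  expect_equal(met$mean_kb, c(20, 0, 0))
  expect_equal(met$gene_count, c(2L, 0L, 0L))

  # filter "del > 100 kb" with only a 50 kb del -> zeros, sample retained
  calls2 <- calls_from_strings("s1 1 1 50000 1")
  met2 <- compute_burden_metrics(calls2, samples,
                                 burden_filter(direction = "del",
                                               min_length = 1e5))
  expect_equal(met2$n_cnv, c(0L, 0L, 0L))
  expect_equal(nrow(met2), 3)

  # distinct genes are deduplicated across a sample's calls
  calls3 <- calls_from_strings(c("s1 1 100000 110000 1", "s1 1 111000 125000 1"))
  met3 <- compute_burden_metrics(calls3, samples, burden_filter(), genes)
  expect_equal(met3$gene_count[1], 1L)  # both calls hit gene A only

  expect_error(compute_burden_metrics(calls, samples,
                                      burden_filter(freq_class = "rare")),
               "unclassified")
})

test_that("printed cohort totals give the ~1.5x rate ratio", {
  # 866 calls over 129 cases vs 1515 over 331 controls
  expect_equal(round((866 / 129) / (1515 / 331), 1), 1.5)
})

test_that("exhaustive permutation equals the enumeration oracle (3v3 and 10 samples)", {
  set.seed(51)
  for (rep in 1:5) {
    x <- rpois(6, 3)
    is_case <- rep(c(TRUE, FALSE), each = 3)
    r <- permutation_test(x, is_case, exhaustive = TRUE)
    expect_equal(r$n_perm, choose(6, 3))
    # independent oracle: enumerate relabelings directly
    sets <- combn(6, 3)
    obs <- mean(x[is_case]) / mean(x[!is_case])
    stats <- apply(sets, 2, function(ii) mean(x[ii]) / mean(x[-ii]))
    expect_equal(r$p, mean(stats >= obs - 1e-12))
  }
  # 10-sample cohort, unbalanced groups
  x <- rpois(10, 2); is_case <- c(rep(TRUE, 4), rep(FALSE, 6))
  r <- permutation_test(x, is_case, exhaustive = TRUE)
  sets <- combn(10, 4)
  obs <- mean(x[is_case]) / mean(x[!is_case])
  stats <- apply(sets, 2, function(ii) mean(x[ii]) / mean(x[-ii]))
  expect_equal(r$p, mean(stats >= obs - 1e-12))
})

test_that("permutation p is seed-reproducible and scale-invariant", {
  set.seed(52)
  x <- rgamma(60, 2); is_case <- rep(c(TRUE, FALSE), 30)
  r1 <- permutation_test(x, is_case, 500, seed = 7)
  r2 <- permutation_test(x, is_case, 500, seed = 7)
  expect_identical(r1$p, r2$p)
  r_kb <- permutation_test(x / 1000, is_case, 500, seed = 7)
  expect_identical(r1$p, r_kb$p)   # kb vs bp rescaling
  expect_equal(r_kb$ratio, r1$ratio)
})

test_that("mirrored case/control metrics are unexceptional under exchange", {
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  is_case <- rep(c(TRUE, FALSE), each = 4)
  r <- permutation_test(x, is_case, exhaustive = TRUE)
  expect_equal(r$ratio, 1)
  expect_gte(r$p, 0.4)
})

test_that("all-zero metrics give p = 1 with a warning", {
  expect_warning(r <- permutation_test(rep(0, 10), rep(c(TRUE, FALSE), 5), 99),
                 "all-zero")
  expect_equal(r$p, 1)
})

test_that("identical quality collapses conditional to unconditional", {
  set.seed(53)
  x <- rpois(40, 3); is_case <- rep(c(TRUE, FALSE), 20)
  samples <- toy_samples(20, 20)
  samples$lrr_sd <- 0.15; samples$baf_drift <- 0.005; samples$mad <- 0.13
  rc <- conditional_permutation_test(x, is_case, samples, n_perm = 300, seed = 9)
  ru <- permutation_test(x, is_case, n_perm = 300, seed = 9)
  expect_equal(rc$n_strata, 1)
  expect_identical(rc$p, ru$p)
})

test_that("single-class strata merge with a neighbour", {
  # all cases sit in the top score stratum, which is then pure-case
  samples <- toy_samples(4, 16)
  set.seed(55)
  x <- rpois(20, 2); is_case <- c(rep(TRUE, 4), rep(FALSE, 16))
  samples$lrr_sd <- c(rep(5, 4), rep(0.5, 16))
  samples$baf_drift <- samples$lrr_sd / 10
  samples$mad <- samples$lrr_sd
  expect_message(
    rc <- conditional_permutation_test(x, is_case, samples, n_strata = 5,
                                       n_perm = 99, seed = 2),
    "merging")
  expect_lt(rc$n_strata, 5)
})

test_that("conditional test retains power on a planted 2x rate (scaled run)", {
  set.seed(54)
  hits <- 0L
  n_rep <- 20
  for (i in 1:n_rep) {
    coh <- generate_cohort(cohort_spec(case_rate_multiplier = 2,
                                       seed = 54000 + i))
    x <- as.numeric(table(factor(coh$calls_a$sample_id,
                                 levels = coh$samples$sample_id)))
    ic <- coh$samples$group == "case"
    p <- suppressMessages(conditional_permutation_test(
      x, ic, coh$samples, n_perm = 199, seed = i)$p)
    hits <- hits + (p <= 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("subgroup burden attributes planted effects to the right subgroup", {
  # longer CNVs in syndromic cases only
  coh <- generate_cohort(cohort_spec(n_cases = 60, n_controls = 120,
                                     case_rate_multiplier = 1,
                                     syndromic_fraction = 0.5,
                                     syndromic_size_mult = 6, seed = 60))
  cnvrs <- build_cnvrs(coh$calls_a, coh$samples,
                       frequency_params(rare_threshold = 0.03))
  calls <- classify_calls(coh$calls_a, cnvrs)
  res <- subgroup_burden(calls, coh$samples, metric = "size",
                         filter = burden_filter(freq_class = "rare"),
                         n_perm = 499, seed = 3)
  p_syn <- res$p[res$group1 == "syndromic" & res$group2 == "control"]
  p_non <- res$p[res$group1 == "non_syndromic" & res$group2 == "control"]
  expect_lte(p_syn, 0.05)
  expect_gt(p_non, 0.05)

  # higher rate in non-syndromic cases only
  coh2 <- generate_cohort(cohort_spec(n_cases = 60, n_controls = 120,
                                      case_rate_multiplier = 1,
                                      syndromic_fraction = 0.5,
                                      nonsyndromic_rate_mult = 2.5, seed = 61))
  cnvrs2 <- build_cnvrs(coh2$calls_a, coh2$samples,
                        frequency_params(rare_threshold = 0.03))
  calls2 <- classify_calls(coh2$calls_a, cnvrs2)
  res2 <- subgroup_burden(calls2, coh2$samples, metric = "rate",
                          filter = burden_filter(freq_class = "rare"),
                          n_perm = 499, seed = 4)
  expect_lte(res2$p[res2$group1 == "non_syndromic" & res2$group2 == "control"],
             0.05)
  expect_gt(res2$p[res2$group1 == "syndromic" & res2$group2 == "control"],
            0.05)
})

test_that("chromosome exclusion for flagged samples drops only their calls", {
  samples <- toy_samples(2, 2)
  samples$sample_id <- c("s1", "s2", "s3", "s4")
  samples$syndromic <- c(TRUE, FALSE, NA, NA)
  samples$down_syndrome <- c(TRUE, FALSE, FALSE, FALSE)
  calls <- calls_from_strings(c("s1 21 100 200 3", "s2 21 100 200 3",
                                "s1 1 100 200 1"))
  res <- subgroup_burden(calls, samples, metric = "rate",
                         filter = burden_filter(), n_perm = 20, seed = 1,
                         exclude_chrom = "21")
  # s1 keeps only its chr1 call; metrics enter the test, nothing errors
  expect_equal(nrow(res), 3)
})
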