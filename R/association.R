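#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with both margins fixed, two-sided by the
#' point-probability rule: the p-value is the sum, over all tables with the
#' observed margins, of the probabilities not exceeding the observed table's
#' (up to a 1e-7 relative tolerance). Probabilities are computed in log-space
#' from `lchoose` for stability at large counts.
#'
#' @param a,b case carriers and non-carriers.
#' @param c,d control carriers and non-carriers.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_two_sided(5, 124, 0, 331)  # 1.64e-3
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  n1 <- a + b; n2 <- c + d; k <- a + c; N <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("empty row margin")
  support <- max(0, k - n2):min(k, n1)
  logp <- lchoose(n1, support) + lchoose(n2, k - support) - lchoose(N, k)
  lobs <- logp[support == a]
  min(1, sum(exp(logp[logp <= lobs + 1e-7])))
}

#' Carrier frequencies and fold enrichment
#'
#' @inheritParams fisher_exact_two_sided
#' @return list with `case_freq` = a/(a+b), `control_freq` = c/(c+d), `fold`
#'   = case/control frequency ratio (`Inf`, flagged, when no control
#'   carriers).
#' @export
carrier_frequencies <- function(a, b, c, d) {
  stopifnot(a + b > 0, c + d > 0)
  cf <- a / (a + b); tf <- c / (c + d)
  list(case_freq = cf, control_freq = tf,
       fold = if (tf == 0) Inf else cf / tf, fold_infinite = tf == 0)
}

#' Sample-size-weighted Stouffer combination of phase p-values
#'
#' Each (two-sided, exact) phase p-value is converted to a signed z-score,
#' `z_i = qnorm(1 - p_i/2) * direction_i`, and combined as
#' `Z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))` (the `"sqrt_n"` rule;
#' `"n"` uses weights `n_i` with normalizer `sqrt(sum(n_i^2))`). The combined
#' two-sided p is `2 * pnorm(-|Z|)`. Pass exact, unrounded phase p-values;
#' `p = 0` is refused.
#'
#' @param p numeric vector of two-sided phase p-values (length >= 1).
#' @param n phase sample sizes (weights).
#' @param direction sign of each phase's effect (+1 case-enriched, -1
#'   control-enriched); recycled.
#' @param weight_rule `"sqrt_n"` (default) or `"n"`.
#' @return list with `z` (combined Z) and `p` (combined two-sided p).
#' @examples
#' p1 <- fisher_exact_two_sided(5, 124, 0, 331)
#' p2 <- fisher_exact_two_sided(9, 85, 5, 215)
#' stouffer_combine(c(p1, p2), n = c(460, 316))  # p = 3.36e-5
#' @export
stouffer_combine <- function(p, n, direction = 1, weight_rule = c("sqrt_n", "n")) {
  weight_rule <- match.arg(weight_rule)
  stopifnot(length(p) >= 1, length(n) == length(p))
  if (any(p <= 0)) stop("p = 0 is not a valid exact p-value; pass unrounded p")
  if (any(p > 1)) stop("p > 1")
  direction <- rep_len(sign(direction), length(p))
  if (any(direction == 0)) stop("direction must be +1 or -1")
  z <- stats::qnorm(p / 2, lower.tail = FALSE) * direction
  w <- switch(weight_rule, sqrt_n = sqrt(n), n = n)
  norm <- switch(weight_rule, sqrt_n = sqrt(sum(n)), n = sqrt(sum(n^2)))
  Z <- sum(w * z) / norm
  list(z = Z, p = 2 * stats::pnorm(abs(Z), lower.tail = FALSE))
}

#' Phase result for meta-analysis
#'
#' Bundles one phase's 2x2 table with its exact Fisher p and direction of
#' effect, the unit combined by [stouffer_combine()].
#'
#' @param label phase label.
#' @inheritParams fisher_exact_two_sided
#' @return list with `label`, cell counts, `p_two_sided`, `direction`
#'   (sign of case freq - control freq; +1 on ties), `n_total`.
#' @export
phase_result <- function(label, a, b, c, d) {
  p <- fisher_exact_two_sided(a, b, c, d)
  fr <- carrier_frequencies(a, b, c, d)
  dir <- if (fr$case_freq >= fr$control_freq) 1 else -1
  list(label = label, a = a, b = b, c = c, d = d, p_two_sided = p,
       direction = dir, n_total = a + b + c + d)
}

#' Combine phase results
#'
#' @param phases list of [phase_result()] objects (>= 1).
#' @param weight_rule see [stouffer_combine()].
#' @return list with per-phase summary and combined `z`, `p`.
#' @export
combine_phases <- function(phases, weight_rule = "sqrt_n") {
  p <- vapply(phases, `[[`, 0, "p_two_sided")
  n <- vapply(phases, `[[`, 0, "n_total")
  dir <- vapply(phases, `[[`, 0, "direction")
  res <- stouffer_combine(p, n, dir, weight_rule)
  list(phases = data.frame(label = vapply(phases, `[[`, "", "label"),
                           p = p, n = n, direction = dir),
       z = res$z, p = res$p)
}

#' CNVR-level case-control association scan
#'
#' For every CNVR, builds the carrier 2x2 table (a carrier is a sample with at
#' least one member call) and applies the two-sided Fisher exact test. A
#' Benjamini-Hochberg q-value is reported as a convenience column (an
#' extension beyond the unadjusted per-locus p).
#'
#' @param cnvrs output of [build_cnvrs()].
#' @param samples sample table.
#' @return data frame: `cnvr_id`, coordinates, `type`, carrier counts,
#'   `case_freq`, `control_freq`, `direction`, `p`, `q_bh`.
#' @export
cnvr_association_scan <- function(cnvrs, samples) {
  cases <- samples$sample_id[samples$group == "case"]
  controls <- samples$sample_id[samples$group == "control"]
  a <- vapply(cnvrs$carriers, function(cc) sum(cc %in% cases), 0L)
  c_ <- vapply(cnvrs$carriers, function(cc) sum(cc %in% controls), 0L)
  b <- length(cases) - a; d <- length(controls) - c_
  p <- mapply(fisher_exact_two_sided, a, b, c_, d)
  out <- data.frame(cnvr_id = cnvrs$cnvr_id, chrom = cnvrs$chrom,
                    start = cnvrs$start, end = cnvrs$end, type = cnvrs$type,
                    case_carriers = a, control_carriers = c_,
                    case_freq = a / length(cases),
                    control_freq = c_ / length(controls),
                    direction = ifelse(a / length(cases) >= c_ / length(controls),
                                       1, -1),
                    p = p, q_bh = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}
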