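#' Burden filter specification
#'
#' @param freq_class `"rare"`, `"common"`, or `NULL` for both (calls must
#'   carry `freq_class`, see [classify_calls()]).
#' @param direction `"del"`, `"dup"`, or `"both"`.
#' @param min_length keep calls strictly longer than this many bp (0 keeps
#'   all; 1e5 gives the "long", 1e6 the "large" stratum).
#' @param occurrence_class `"singleton"`, `"two_to_four"`, `"more"`, or
#'   `NULL`.
#' @return a filter list for [compute_burden_metrics()].
#' @export
burden_filter <- function(freq_class = NULL, direction = "both",
                          min_length = 0, occurrence_class = NULL) {
  stopifnot(direction %in% c("del", "dup", "both"))
  list(freq_class = freq_class, direction = direction,
       min_length = min_length, occurrence_class = occurrence_class)
}

#' Per-sample CNV burden metrics
#'
#' For each sample, over the calls passing `filter`: the number of CNVs
#' (`n_cnv`, the "rate" numerator), total and mean CNV length in kb, and the
#' number of distinct genes hit (union over the sample's filtered calls,
#' genes flanked per `params`). Samples with no qualifying call get zeros and
#' remain in any downstream test: the denominator is all individuals.
#'
#' @param calls classified calls (see [classify_calls()]) when the filter
#'   touches `freq_class`/`occurrence_class`.
#' @param samples sample table; defines the output rows.
#' @param filter see [burden_filter()].
#' @param genes optional gene models; without them `gene_count` is `NA`.
#' @param params see [frequency_params()].
#' @return data frame with columns `sample_id`, `n_cnv`, `total_kb`,
#'   `mean_kb`, `gene_count`.
#' @export
compute_burden_metrics <- function(calls, samples, filter = burden_filter(),
                                   genes = NULL, params = frequency_params()) {
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(filter$freq_class)) {
    if (!"freq_class" %in% names(calls))
      stop("filter uses freq_class but calls are unclassified; run classify_calls()")
    keep <- keep & calls$freq_class %in% filter$freq_class
  }
  if (!is.null(filter$occurrence_class)) {
    if (!"occurrence_class" %in% names(calls))
      stop("filter uses occurrence_class but calls are unclassified")
    keep <- keep & calls$occurrence_class %in% filter$occurrence_class
  }
  if (filter$direction != "both")
    keep <- keep & cnv_direction(calls) == filter$direction
  if (filter$min_length > 0)
    keep <- keep & (calls$end - calls$start + 1) > filter$min_length
  sub <- calls[keep, , drop = FALSE]
  if (!is.null(genes)) sub <- annotate_genic(sub, genes, params)

  out <- data.frame(sample_id = samples$sample_id, n_cnv = 0L, total_kb = 0,
                    mean_kb = 0,
                    gene_count = if (is.null(genes)) NA_integer_ else 0L,
                    stringsAsFactors = FALSE)
  if (nrow(sub)) {
    len_kb <- (sub$end - sub$start + 1) / 1000
    n <- table(sub$sample_id)
    tot <- tapply(len_kb, sub$sample_id, sum)
    m <- match(names(n), out$sample_id)
    out$n_cnv[m] <- as.integer(n)
    out$total_kb[m] <- as.numeric(tot[names(n)])
    out$mean_kb[m] <- out$total_kb[m] / out$n_cnv[m]
    if (!is.null(genes)) {
      gc <- tapply(sub$genes, sub$sample_id,
                   function(gl) length(unique(unlist(gl))))
      out$gene_count[m] <- as.integer(gc[names(n)])
    }
  }
  out
}

# case-mean / control-mean ratio; Inf when only the control mean is zero,
# NaN when both are zero (handled by callers)
#' @keywords internal
mean_ratio <- function(x, is_case) mean(x[is_case]) / mean(x[!is_case])

# core permutation machinery shared by the unconditional and stratified tests;
# strata = NULL means free relabeling, otherwise labels are shuffled within
# each stratum. exhaustive = TRUE enumerates all C(n, n_case) relabelings
# (unstratified only) and returns the exact enumeration p.
#' @keywords internal
perm_pvalue <- function(x, is_case, n_perm, seed = NULL, strata = NULL,
                        exhaustive = FALSE) {
  stopifnot(any(is_case), any(!is_case))
  if (!is.null(seed)) set.seed(seed)
  obs <- mean_ratio(x, is_case)
  if (all(x == 0)) {
    warning("all-zero metric vector; p = 1")
    return(list(observed = NaN, p = 1, n_perm = n_perm, exhaustive = FALSE))
  }
  tol <- 1e-12 * max(1, abs(if (is.finite(obs)) obs else 0))
  if (exhaustive) {
    if (!is.null(strata)) stop("exhaustive enumeration is unstratified-only")
    n <- length(x)
    sets <- utils::combn(n, sum(is_case))
    stats <- apply(sets, 2, function(ii) {
      lab <- seq_len(n) %in% ii
      mean_ratio(x, lab)
    })
    b <- sum(stats >= obs - tol | (is.infinite(obs) & is.infinite(stats)))
    return(list(observed = obs, p = b / ncol(sets), n_perm = ncol(sets),
                exhaustive = TRUE))
  }
  stopifnot(n_perm >= 1)
  idx <- if (is.null(strata)) list(seq_along(x)) else split(seq_along(x), strata)
  b <- 0L
  lab <- is_case
  for (k in seq_len(n_perm)) {
    for (ii in idx) lab[ii] <- is_case[ii][sample.int(length(ii))]
    st <- mean_ratio(x, lab)
    if (is.nan(st)) st <- -Inf
    if (st >= obs - tol) b <- b + 1L
  }
  list(observed = obs, p = (1 + b) / (n_perm + 1), n_perm = n_perm,
       exhaustive = FALSE)
}

#' One-sided permutation burden test
#'
#' Tests whether the case mean of a per-sample burden metric exceeds the
#' control mean. The statistic is the case-mean / control-mean ratio; labels
#' are permuted preserving group sizes and the one-sided empirical p uses the
#' add-one rule `(1 + b) / (n_perm + 1)`. With `exhaustive = TRUE` all
#' relabelings are enumerated instead and the exact enumeration p is returned
#' (feasible for small cohorts).
#'
#' @param x numeric per-sample metric (one value per sample, zeros included).
#' @param is_case logical case indicator aligned with `x`.
#' @param n_perm number of permutations.
#' @param seed RNG seed (results are bit-reproducible under a fixed seed).
#' @param exhaustive enumerate all relabelings instead of sampling.
#' @param metric label stored on the result.
#' @return a `burden_test` list: `metric`, `baseline` (control mean), `ratio`,
#'   `p`, `n_perm`, `seed`, `exhaustive`.
#' @export
permutation_test <- function(x, is_case, n_perm = 1000, seed = NULL,
                             exhaustive = FALSE, metric = "metric") {
  r <- perm_pvalue(x, is_case, n_perm, seed = seed, exhaustive = exhaustive)
  structure(list(metric = metric, baseline = mean(x[!is_case]),
                 ratio = r$observed, p = r$p, n_perm = r$n_perm, seed = seed,
                 exhaustive = r$exhaustive, conditional = FALSE),
            class = "burden_test")
}

#' Composite intensity-quality score
#'
#' Equal-weight (configurable) sum of rank-normalized LRR_SD, BAF drift and
#' MAD; higher means worse intensity quality. Ranks are mapped to
#' `rank / (n + 1)` so each component lies in (0, 1).
#'
#' @param samples sample table with `lrr_sd`, `baf_drift`, `mad`.
#' @param weights length-3 numeric weights.
#' @return numeric score per sample.
#' @export
quality_score <- function(samples, weights = c(1, 1, 1)) {
  cols <- c("lrr_sd", "baf_drift", "mad")
  m <- as.matrix(samples[cols])
  if (anyNA(m))
    stop("quality metrics (", paste(cols, collapse = ", "),
         ") must be present for all samples")
  n <- nrow(m)
  rk <- apply(m, 2, rank) / (n + 1)
  as.numeric(rk %*% weights)
}

#' Quality-stratified (conditional) permutation burden test
#'
#' As [permutation_test()], but case/control labels are permuted only within
#' strata of the composite quality score, breaking confounding between
#' intensity quality and call yield. Samples are binned into `n_strata`
#' score quantiles; a stratum containing only cases or only controls is
#' merged with its neighbour (message logged).
#'
#' @inheritParams permutation_test
#' @param samples sample table providing `lrr_sd`, `baf_drift`, `mad`.
#' @param n_strata number of quantile strata (default 5).
#' @param weights component weights for [quality_score()].
#' @return a `burden_test` list with `conditional = TRUE` and `n_strata`.
#' @export
conditional_permutation_test <- function(x, is_case, samples, n_strata = 5,
                                         n_perm = 1000, seed = NULL,
                                         weights = c(1, 1, 1),
                                         metric = "metric") {
  score <- quality_score(samples, weights)
  strata <- make_strata(score, is_case, n_strata)
  r <- perm_pvalue(x, is_case, n_perm, seed = seed, strata = strata)
  structure(list(metric = metric, baseline = mean(x[!is_case]),
                 ratio = r$observed, p = r$p, n_perm = r$n_perm, seed = seed,
                 exhaustive = FALSE, conditional = TRUE,
                 n_strata = length(unique(strata))),
            class = "burden_test")
}

# quantile bins on the score; single-class bins merged with the neighbour
#' @keywords internal
make_strata <- function(score, is_case, n_strata) {
  qs <- unique(stats::quantile(score, probs = seq(0, 1, length.out = n_strata + 1)))
  if (length(qs) < 2) return(rep(1L, length(score)))  # constant score: 1 stratum
  strata <- cut(score, qs, include.lowest = TRUE, labels = FALSE)
  strata <- match(strata, sort(unique(strata)))
  repeat {
    levs <- sort(unique(strata))
    if (length(levs) <= 1) break
    onecls <- levs[vapply(levs, function(l) {
      s <- is_case[strata == l]; all(s) || all(!s)
    }, TRUE)]
    if (!length(onecls)) break
    l <- onecls[1]
    nb <- if (l == max(levs)) max(levs[levs < l]) else min(levs[levs > l])
    message("merging single-class quality stratum ", l, " into ", nb)
    strata[strata == l] <- nb
    strata <- match(strata, sort(unique(strata)))
  }
  strata
}

#' Subgroup burden comparisons
#'
#' Runs the three pairwise one-sided burden tests (syndromic vs control,
#' non-syndromic vs control, syndromic vs non-syndromic) for one metric.
#' Optionally drops calls on a given chromosome for flagged samples (e.g.
#' chromosome 21 for Down-syndrome patients) before computing metrics.
#'
#' @param calls classified calls.
#' @param samples sample table with `syndromic` set for every case.
#' @param metric one of `"size"` (mean kb), `"rate"` (CNV count),
#'   `"gene_count"`.
#' @param filter see [burden_filter()].
#' @param genes gene models (required for `metric = "gene_count"`).
#' @param n_perm,seed permutation settings.
#' @param exclude_chrom chromosome to drop for flagged samples, or `NULL`.
#' @param flag_col logical sample-table column marking the flagged samples
#'   (default `"down_syndrome"`).
#' @param params see [frequency_params()].
#' @return data frame with one row per comparison: groups, baseline, ratio,
#'   p.
#' @export
subgroup_burden <- function(calls, samples, metric = "rate",
                            filter = burden_filter(freq_class = "rare"),
                            genes = NULL, n_perm = 1000, seed = NULL,
                            exclude_chrom = NULL, flag_col = "down_syndrome",
                            params = frequency_params()) {
  stopifnot(metric %in% c("size", "rate", "gene_count"))
  if (metric == "gene_count" && is.null(genes))
    stop("gene models required for the gene_count metric")
  if (!is.null(exclude_chrom) && flag_col %in% names(samples)) {
    flagged <- samples$sample_id[isTRUE_vec(samples[[flag_col]])]
    drop <- calls$sample_id %in% flagged &
      norm_chrom(calls$chrom) == norm_chrom(exclude_chrom)
    calls <- calls[!drop, , drop = FALSE]
  }
  met <- compute_burden_metrics(calls, samples, filter, genes, params)
  x <- switch(metric, size = met$mean_kb, rate = met$n_cnv,
              gene_count = met$gene_count)
  grp <- ifelse(samples$group == "control", "control",
                ifelse(isTRUE_vec(samples$syndromic), "syndromic",
                       "non_syndromic"))
  pairs <- list(c("syndromic", "control"), c("non_syndromic", "control"),
                c("syndromic", "non_syndromic"))
  out <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    sel <- grp %in% pr
    if (!any(grp == pr[1]) || !any(grp == pr[2]))
      stop("empty subgroup: ", pr[1], " vs ", pr[2])
    r <- permutation_test(x[sel], grp[sel] == pr[1], n_perm = n_perm,
                          seed = if (is.null(seed)) NULL else seed + i,
                          metric = metric)
    data.frame(group1 = pr[1], group2 = pr[2], metric = metric,
               baseline = r$baseline, ratio = r$ratio, p = r$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.burden_test <- function(x, ...) {
  cat(sprintf("One-sided %sburden test (%s): ratio = %.3g, baseline = %.3g\n",
              if (x$conditional) "conditional " else "", x$metric,
              x$ratio, x$baseline))
  cat(sprintf("  empirical p = %.4g (%s%d permutations)\n", x$p,
              if (x$exhaustive) "exhaustive, " else "", x$n_perm))
  invisible(x)
}
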