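#' Cohort simulation specification
#'
#' States the world the synthetic cohort emulates. Defaults mirror the
#' discovery cohort the pipeline targets: 129 cases vs 331 controls, a
#' control call rate of ~4.6 CNVs/individual with a 1.47x case multiplier,
#' lognormal event sizes with medians near 34 kb (cases) and 58 kb
#' (controls), and deletion fractions of 0.59 / 0.52. The genome is 22
#' autosome-like contigs with lengths scaled down 100x for speed.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param baseline_cnv_rate mean true CNVs per control (Poisson).
#' @param case_rate_multiplier multiplies the rate for cases.
#' @param size_meanlog,size_sdlog per-group lognormal size parameters, named
#'   vectors with entries `case` and `control` (bp scale).
#' @param p_deletion per-group probability that an event is a deletion.
#' @param genic_bias fraction of events placed to overlap a gene.
#' @param quality_confounding mean artifact calls added per unit of the
#'   (0,1)-scaled composite quality score; 0 disables confounding.
#' @param quality_case_shift log-scale shift applied to case quality metrics
#'   (worse quality for cases when > 0).
#' @param caller_jitter_sd SD (bp) of each caller's boundary jitter.
#' @param caller_miss_prob per-caller probability of missing a true event.
#' @param planted_cnvrs optional data frame `chrom`, `start`, `end`, `type`
#'   (`del`/`dup`), `case_freq`, `control_freq`; carriers are drawn as
#'   exactly `round(freq * group size)` samples so planted contingency
#'   tables are exact by construction.
#' @param syndromic_fraction fraction of cases flagged syndromic.
#' @param down_fraction fraction of syndromic cases flagged Down syndrome.
#' @param syndromic_size_mult multiplies event sizes for syndromic cases.
#' @param nonsyndromic_rate_mult multiplies the event rate for non-syndromic
#'   cases.
#' @param gene_length,gene_spacing tiled gene models: one `gene_length`-bp
#'   gene every `gene_spacing` bp, so the genic fraction is controllable
#'   analytically.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 129, n_controls = 331,
                        baseline_cnv_rate = 4.6, case_rate_multiplier = 1.47,
                        size_meanlog = c(case = log(34390), control = log(57900)),
                        size_sdlog = c(case = 0.8, control = 0.8),
                        p_deletion = c(case = 0.5936, control = 0.5168),
                        genic_bias = 0.5, quality_confounding = 0,
                        quality_case_shift = 0, caller_jitter_sd = 500,
                        caller_miss_prob = 0.05, planted_cnvrs = NULL,
                        syndromic_fraction = 29 / 129,
                        down_fraction = 8 / 29,
                        syndromic_size_mult = 1, nonsyndromic_rate_mult = 1,
                        gene_length = 2e4, gene_spacing = 1e5, seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1, baseline_cnv_rate > 0,
            case_rate_multiplier > 0, genic_bias >= 0, genic_bias <= 1,
            quality_confounding >= 0, caller_jitter_sd >= 0,
            caller_miss_prob >= 0, caller_miss_prob < 1)
  if (!is.null(planted_cnvrs)) {
    stopifnot(all(c("chrom", "start", "end", "type", "case_freq",
                    "control_freq") %in% names(planted_cnvrs)))
    if (any(planted_cnvrs$case_freq > 1 | planted_cnvrs$control_freq > 1 |
            planted_cnvrs$case_freq < 0 | planted_cnvrs$control_freq < 0))
      stop("planted carrier frequencies must lie in [0,1]")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

# hg18-like autosome lengths (Mb), scaled down 100x
#' @keywords internal
sim_genome <- function() {
  mb <- c(247, 243, 199, 191, 181, 171, 159, 146, 140, 135, 134, 132,
          114, 106, 100, 89, 79, 76, 64, 62, 47, 50)
  data.frame(chrom = as.character(1:22), length = mb * 1e4,
             stringsAsFactors = FALSE)
}

#' @keywords internal
sim_genes <- function(genome, gene_length, gene_spacing) {
  out <- lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(1e4 + 1, genome$length[i] - gene_length, by = gene_spacing)
    data.frame(name = sprintf("g%s_%04d", genome$chrom[i], seq_along(starts)),
               chrom = genome$chrom[i], start = starts,
               end = starts + gene_length - 1, strand = "+",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a two-caller case-control CNV cohort
#'
#' Draws per-sample true CNVs under the spec's group parameters, adds
#' quality-driven artifact calls when confounding is enabled, inserts planted
#' CNVRs at their stated carrier frequencies, and has each of two callers
#' observe every event with independent miss probability and boundary
#' jitter. Everything planted is recorded in `truth`.
#'
#' @param spec a [cohort_spec()].
#' @return list with [cnv_calls()] tables `calls_a` and `calls_b`, the
#'   `samples` table, tiled `genes`, the `genome` contig table, and `truth`
#'   (`events` data frame with an `origin` column in
#'   \{true, artifact, planted\}, `planted` carrier sets, and the spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  genome <- sim_genome()
  genes <- sim_genes(genome, spec$gene_length, spec$gene_spacing)

  n <- spec$n_cases + spec$n_controls
  samples <- data.frame(
    sample_id = c(sprintf("case%03d", seq_len(spec$n_cases)),
                  sprintf("control%03d", seq_len(spec$n_controls))),
    group = rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
    stringsAsFactors = FALSE)
  n_syn <- round(spec$syndromic_fraction * spec$n_cases)
  samples$syndromic <- c(rep(TRUE, n_syn), rep(FALSE, spec$n_cases - n_syn),
                         rep(NA, spec$n_controls))
  n_down <- round(spec$down_fraction * n_syn)
  samples$down_syndrome <- c(rep(TRUE, n_down), rep(FALSE, n - n_down))
  samples$subtype <- c(sample(c("S", "L", "TCA"), spec$n_cases, TRUE,
                             prob = c(0.8, 0.15, 0.05)),
                       rep(NA_character_, spec$n_controls))
  is_case <- samples$group == "case"
  shift <- ifelse(is_case, exp(spec$quality_case_shift), 1)
  samples$lrr_sd <- stats::rlnorm(n, log(0.15), 0.25) * shift
  samples$baf_drift <- stats::rlnorm(n, log(0.005), 0.4) * shift
  samples$mad <- stats::rlnorm(n, log(0.13), 0.25) * shift
  samples$wave <- abs(stats::rnorm(n, 0, 0.01))

  draw_events <- function(n_ev, group, size_mult = 1, origin = "true",
                          sample_ids) {
    if (n_ev == 0)
      return(data.frame(sample_id = character(), chrom = character(),
                        start = numeric(), end = numeric(), cn = integer(),
                        origin = character(), stringsAsFactors = FALSE))
    size <- pmax(1000, round(stats::rlnorm(n_ev, spec$size_meanlog[[group]],
                                           spec$size_sdlog[[group]]) * size_mult))
    genic <- stats::runif(n_ev) < spec$genic_bias
    chrom <- character(n_ev); start <- numeric(n_ev)
    gidx <- sample.int(nrow(genes), n_ev, replace = TRUE)
    cidx <- sample.int(nrow(genome), n_ev, replace = TRUE,
                       prob = genome$length)
    for (i in seq_len(n_ev)) {
      if (genic[i]) {
        g <- genes[gidx[i], ]
        chrom[i] <- g$chrom
        start[i] <- round(stats::runif(1, max(1, g$start - size[i] + 1), g$end))
      } else {
        chrom[i] <- genome$chrom[cidx[i]]
        start[i] <- round(stats::runif(1, 1,
                                       max(1, genome$length[cidx[i]] - size[i])))
      }
    }
    clen <- genome$length[match(chrom, genome$chrom)]
    end <- pmin(start + size - 1, clen)
    del <- stats::runif(n_ev) < spec$p_deletion[[group]]
    cn <- ifelse(del, ifelse(stats::runif(n_ev) < 0.9, 1L, 0L),
                 ifelse(stats::runif(n_ev) < 0.9, 3L, 4L))
    data.frame(sample_id = sample_ids, chrom = chrom, start = start,
               end = end, cn = cn, origin = origin, stringsAsFactors = FALSE)
  }

  # true events per sample
  rate <- ifelse(is_case, spec$baseline_cnv_rate * spec$case_rate_multiplier,
                 spec$baseline_cnv_rate)
  rate[is_case & !isTRUE_vec(samples$syndromic)] <-
    rate[is_case & !isTRUE_vec(samples$syndromic)] * spec$nonsyndromic_rate_mult
  n_ev <- stats::rpois(n, rate)
  size_mult <- ifelse(is_case & isTRUE_vec(samples$syndromic),
                      spec$syndromic_size_mult, 1)
  ev <- lapply(seq_len(n), function(i)
    draw_events(n_ev[i], samples$group[i], size_mult[i], "true",
                rep(samples$sample_id[i], n_ev[i])))
  events <- do.call(rbind, ev)

  # quality-driven artifact calls (both groups; rate tracks the score)
  if (spec$quality_confounding > 0) {
    score01 <- quality_score(samples) / 3
    n_art <- stats::rpois(n, spec$quality_confounding * score01)
    art <- lapply(seq_len(n), function(i) {
      if (n_art[i] == 0) return(NULL)
      a <- draw_events(n_art[i], samples$group[i], 1, "artifact",
                       rep(samples$sample_id[i], n_art[i]))
      a$start <- pmax(1, a$start)
      a
    })
    events <- rbind(events, do.call(rbind, art))
  }

  # planted CNVRs with exact carrier counts
  planted <- list()
  if (!is.null(spec$planted_cnvrs)) {
    pc <- spec$planted_cnvrs
    for (i in seq_len(nrow(pc))) {
      ncar_case <- round(pc$case_freq[i] * spec$n_cases)
      ncar_ctrl <- round(pc$control_freq[i] * spec$n_controls)
      carr <- c(sample(samples$sample_id[is_case], ncar_case),
                sample(samples$sample_id[!is_case], ncar_ctrl))
      if (length(carr)) {
        events <- rbind(events, data.frame(
          sample_id = carr, chrom = norm_chrom(pc$chrom[i]),
          start = pc$start[i], end = pc$end[i],
          cn = if (pc$type[i] == "del") 1L else 3L,
          origin = "planted", stringsAsFactors = FALSE))
      }
      planted[[i]] <- list(chrom = norm_chrom(pc$chrom[i]),
                           start = pc$start[i], end = pc$end[i],
                           type = pc$type[i], carriers = carr)
    }
  }
  rownames(events) <- NULL

  observe <- function(label) {
    keep <- stats::runif(nrow(events)) >= spec$caller_miss_prob
    obs <- events[keep, , drop = FALSE]
    if (nrow(obs) && spec$caller_jitter_sd > 0) {
      clen <- genome$length[match(obs$chrom, genome$chrom)]
      js <- round(stats::rnorm(nrow(obs), 0, spec$caller_jitter_sd))
      je <- round(stats::rnorm(nrow(obs), 0, spec$caller_jitter_sd))
      s2 <- pmax(1, pmin(obs$start + js, obs$end))
      e2 <- pmin(clen, pmax(obs$end + je, s2))
      obs$start <- s2; obs$end <- e2
    }
    obs$origin <- NULL
    cnv_calls(obs, provenance = label, genome_build = "sim1")
  }
  calls_a <- observe("callerA")
  calls_b <- observe("callerB")

  list(calls_a = calls_a, calls_b = calls_b, samples = samples,
       genes = genes, genome = genome,
       truth = list(events = events, planted = planted, spec = spec))
}

#' Generate trio qPCR cycle-threshold tables
#'
#' Emulates TaqMan comparative-CT validation data: reference CTs are
#' `N(mu_ref, sd)`, target CTs sit `base_offset - log2(cn / 2)` cycles away,
#' in `n_replicates` replicates, for child/father/mother of each trio.
#'
#' @param cn_patterns list (or 3-column matrix) of integer copy-number
#'   states `c(child, father, mother)`, states in \{1, 2, 3\}.
#' @param ct_noise_sd replicate CT noise SD in cycles.
#' @param n_replicates replicates per probe (default 4, quadruplicates).
#' @param mu_ref mean reference CT.
#' @param base_offset target-minus-reference CT offset at copy number 2.
#' @param seed RNG seed.
#' @return list with `table` (long data frame: `sample_id`, `probe_id`,
#'   `role`, `ct`) and `truth` (sample_id, trio, member, cn).
#' @export
generate_qpcr_trios <- function(cn_patterns, ct_noise_sd = 0.1,
                                n_replicates = 4, mu_ref = 25,
                                base_offset = 0.5, seed = 1) {
  if (is.matrix(cn_patterns))
    cn_patterns <- lapply(seq_len(nrow(cn_patterns)), function(i) cn_patterns[i, ])
  stopifnot(all(unlist(cn_patterns) %in% 1:3))
  set.seed(seed)
  members <- c("child", "father", "mother")
  rows <- list(); truth <- list()
  for (t in seq_along(cn_patterns)) {
    for (m in 1:3) {
      sid <- sprintf("trio%02d_%s", t, members[m])
      cn <- cn_patterns[[t]][m]
      ref <- stats::rnorm(n_replicates, mu_ref, ct_noise_sd)
      tgt <- stats::rnorm(n_replicates, mu_ref + base_offset - log2(cn / 2),
                          ct_noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, probe_id = rep(c("targetProbe", "RNaseP"),
                                        each = n_replicates),
        role = rep(c("target", "reference"), each = n_replicates),
        ct = c(tgt, ref), stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(sample_id = sid, trio = t,
                                               member = members[m], cn = cn,
                                               stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Generate a single-probe qPCR cohort table
#'
#' Same CT model as [generate_qpcr_trios()] for a flat cohort with known
#' per-sample copy numbers; used for state-recovery simulations.
#'
#' @param true_cn integer vector of true copy numbers (states 1-3).
#' @inheritParams generate_qpcr_trios
#' @return list with `table` (long qPCR data frame) and `truth`.
#' @export
generate_qpcr_cohort <- function(true_cn, ct_noise_sd = 0.1, n_replicates = 4,
                                 mu_ref = 25, base_offset = 0.5, seed = 1) {
  stopifnot(all(true_cn %in% 1:3))
  set.seed(seed)
  ids <- sprintf("s%03d", seq_along(true_cn))
  rows <- lapply(seq_along(true_cn), function(i) {
    ref <- stats::rnorm(n_replicates, mu_ref, ct_noise_sd)
    tgt <- stats::rnorm(n_replicates,
                        mu_ref + base_offset - log2(true_cn[i] / 2),
                        ct_noise_sd)
    data.frame(sample_id = ids[i],
               probe_id = rep(c("targetProbe", "RNaseP"), each = n_replicates),
               role = rep(c("target", "reference"), each = n_replicates),
               ct = c(tgt, ref), stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows),
       truth = data.frame(sample_id = ids, cn = true_cn,
                          stringsAsFactors = FALSE))
}

#' Generate a reference sequence carrying an engineered deletion
#'
#' Builds a random sequence with a deletion whose junction exhibits exactly
#' `microhomology_len` bases of homology (the homology fails at k + 1 by
#' construction), for end-to-end breakpoint tests.
#'
#' @param flank_len retained sequence on each side of the deletion (bp).
#' @param del_len deleted length (junction-difference convention).
#' @param microhomology_len planted homology length k (must be smaller than
#'   both `flank_len` and `del_len`).
#' @param seed RNG seed.
#' @param fasta optional path; when given the sequence is written there as
#'   single-record FASTA.
#' @return list with `seq` (character), `chrom`, `breakpoint`
#'   (`upstream`, `downstream`), `homology_len`, and `fasta` (path or NULL).
#' @export
generate_reference_with_deletion <- function(flank_len = 25000,
                                             del_len = 19652,
                                             microhomology_len = 4, seed = 1,
                                             fasta = NULL) {
  k <- microhomology_len
  stopifnot(k >= 0, k < min(flank_len, del_len), flank_len > k + 1)
  set.seed(seed)
  total <- 2 * flank_len + del_len
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, total, replace = TRUE)
  up <- flank_len
  down <- up + del_len
  if (k > 0) s[(down - k + 1):down] <- s[(up - k + 1):up]
  # force the scan to stop exactly at k
  s[down - k] <- sample(setdiff(bases, s[up - k]), 1)
  seq <- paste(s, collapse = "")
  if (!is.null(fasta)) {
    writeLines(c(">chrSim engineered deletion",
                 substring(seq, seq(1, total, 70),
                           pmin(seq(1, total, 70) + 69, total))), fasta)
  }
  list(seq = seq, chrom = "chrSim",
       breakpoint = list(upstream = up, downstream = down),
       homology_len = k, fasta = fasta)
}
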