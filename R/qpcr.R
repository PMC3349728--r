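#' Comparative-CT copy-number estimation
#'
#' Implements relative quantification from TaqMan-style replicate cycle
#' thresholds. Per record, `delta_ct = mean(target CTs) - mean(reference
#' CTs)`; normalizing against a calibrator of known copy number 2 gives
#' `ddct = delta_ct - delta_ct_calibrator` and the continuous estimate
#' `cn = 2 * 2^(-ddct)`. An integer state in 0..4 is assigned when the
#' continuous estimate lies within `guard_band` of an integer, otherwise the
#' record is a no-call (`cn_state = NA`).
#'
#' The calibrator is either a named sample (its own `delta_ct`, averaged over
#' its records) or `"cohort_median"`: the cohort median `delta_ct`, assumed to
#' represent copy number 2 — robust whenever CNV carriers are a minority.
#'
#' @param records qPCR records (see [read_qpcr_table()]).
#' @param calibrator `"cohort_median"` or a sample id present in `records`.
#' @param guard_band half-width, in copies, of the window around each integer
#'   state (default 0.35).
#' @param max_replicate_sd replicate CT standard deviation above which a
#'   record is flagged unreliable (default 0.5 cycles).
#' @return data frame: `sample_id`, `probe_id`, `delta_ct`, `cn_continuous`,
#'   `cn_state` (NA = no-call), `unreliable`, plus attribute
#'   `calibrator_delta_ct`.
#' @examples
#' # ddCT of +1 cycle halves the dosage: cn = 2 * 2^-1 = 1 (hemizygous)
#' @export
estimate_copy_number <- function(records, calibrator = "cohort_median",
                                 guard_band = 0.35, max_replicate_sd = 0.5) {
  stopifnot(nrow(records) > 0, guard_band > 0, guard_band < 0.5)
  dct <- vapply(seq_len(nrow(records)), function(i)
    mean(records$target_cts[[i]]) - mean(records$reference_cts[[i]]), 0)
  spread <- vapply(seq_len(nrow(records)), function(i)
    max(stats::sd(records$target_cts[[i]]), stats::sd(records$reference_cts[[i]])), 0)
  calib <- if (identical(calibrator, "cohort_median")) stats::median(dct)
  else {
    ii <- records$sample_id == calibrator
    if (!any(ii)) stop("calibrator sample '", calibrator, "' not in records")
    mean(dct[ii])
  }
  cn <- 2 * 2^(-(dct - calib))
  state <- ifelse(abs(cn - round(cn)) <= guard_band & round(cn) <= 4,
                  as.integer(round(cn)), NA_integer_)
  out <- data.frame(sample_id = records$sample_id, probe_id = records$probe_id,
                    delta_ct = dct, cn_continuous = cn, cn_state = state,
                    unreliable = spread > max_replicate_sd,
                    stringsAsFactors = FALSE)
  if (any(out$unreliable))
    warning(sum(out$unreliable), " record(s) with replicate CT SD > ",
            max_replicate_sd, " flagged unreliable")
  structure(out, calibrator_delta_ct = calib)
}

#' Cross-probe verification of copy-number calls
#'
#' A CNV is "verified" only when two independent probes agree on the same
#' non-diploid state for a sample. Samples typed by both probes with
#' disagreeing states are listed as discordant.
#'
#' @param est1,est2 outputs of [estimate_copy_number()] for two probes.
#' @return list with `concordance` (fraction of shared samples agreeing),
#'   `verified` (sample ids with agreeing non-2 state), `discordant`
#'   (data frame of disagreeing samples with both states).
#' @export
verify_with_second_probe <- function(est1, est2) {
  shared <- intersect(est1$sample_id, est2$sample_id)
  s1 <- est1$cn_state[match(shared, est1$sample_id)]
  s2 <- est2$cn_state[match(shared, est2$sample_id)]
  agree <- !is.na(s1) & !is.na(s2) & s1 == s2
  list(concordance = mean(agree),
       verified = shared[agree & s1 != 2L],
       discordant = data.frame(sample_id = shared[!agree],
                               state_probe1 = s1[!agree],
                               state_probe2 = s2[!agree],
                               stringsAsFactors = FALSE))
}

#' Trio transmission classification for a CNV carrier child
#'
#' Classifies a child's non-diploid copy-number state against the parents:
#' inherited from whichever parent shares the state, de novo when both
#' parents are typed diploid, unresolved when a needed parent is missing or
#' any required state is a no-call.
#'
#' @param child,father,mother integer copy-number states (from
#'   [estimate_copy_number()]'s `cn_state`); `NA` = no-call, `NULL` = parent
#'   not typed.
#' @return one of `"inherited_paternal"`, `"inherited_maternal"`,
#'   `"de_novo"`, `"unresolved"`.
#' @export
classify_transmission <- function(child, father = NULL, mother = NULL) {
  if (is.null(child) || is.na(child)) stop("child state must be a typed integer")
  if (child == 2L) stop("child is copy-neutral (state 2); nothing to classify")
  f <- if (is.null(father)) NA_integer_ else as.integer(father)
  m <- if (is.null(mother)) NA_integer_ else as.integer(mother)
  if (!is.na(f) && f == child) return("inherited_paternal")
  if (!is.na(m) && m == child) return("inherited_maternal")
  if (!is.na(f) && !is.na(m) && f == 2L && m == 2L) return("de_novo")
  "unresolved"
}
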