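#' Consensus CNV segments from two callers
#'
#' High-confidence calls are restricted to segments consistently reported by
#' both callers: within each sample, every pair of overlapping calls with the
#' same direction (both deletions or both duplications) yields one consensus
#' segment equal to their intersection. A call of one caller overlapping two
#' calls of the other yields two consensus segments; gaps are never bridged.
#'
#' The callers need not agree on copy-number magnitude (cn=0 vs cn=1): the
#' consensus records caller A's integer state and flags the disagreement in a
#' `cn_mismatch` column, since only the del/dup direction drives downstream
#' analyses.
#'
#' @param a,b [cnv_calls()] tables from the two callers. Their `genome_build`
#'   attributes, when both set, must match.
#' @param min_consensus_length drop consensus segments shorter than this many
#'   bp (default 1, i.e. keep all, including 1-bp intersections).
#' @param require_same_direction when `TRUE` (default and the only mode the
#'   consensus definition supports) calls must agree on del/dup direction.
#' @return a [cnv_calls()] table with `caller = "consensus"`.
#' @export
consensus_segments <- function(a, b, min_consensus_length = 1,
                               require_same_direction = TRUE) {
  stopifnot(min_consensus_length >= 1)
  ba <- attr(a, "genome_build"); bb <- attr(b, "genome_build")
  if (!is.na(ba %||% NA) && !is.na(bb %||% NA) && !identical(ba, bb))
    stop("genome build mismatch: '", ba, "' vs '", bb, "'")
  empty <- cnv_calls(data.frame(sample_id = character(), chrom = character(),
                                start = numeric(), end = numeric(),
                                cn = integer()),
                     provenance = "consensus", genome_build = ba %||% bb)
  if (!nrow(a) || !nrow(b)) return(empty)

  # key overlap queries by sample (+ direction) so only compatible pairs match
  key <- function(x) {
    k <- paste(x$sample_id, x$chrom, sep = "\r")
    if (require_same_direction) k <- paste(k, cnv_direction(x), sep = "\r")
    k
  }
  ra <- IRanges::IRanges(a$start, a$end); rb <- IRanges::IRanges(b$start, b$end)
  hits <- IRanges::findOverlaps(ra, rb)
  ia <- S4Vectors::queryHits(hits); ib <- S4Vectors::subjectHits(hits)
  keep <- key(a)[ia] == key(b)[ib]
  ia <- ia[keep]; ib <- ib[keep]
  if (!length(ia)) return(empty)
  s <- pmax(a$start[ia], b$start[ib])
  e <- pmin(a$end[ia], b$end[ib])
  out <- data.frame(sample_id = a$sample_id[ia], chrom = a$chrom[ia],
                    start = s, end = e, cn = a$cn[ia], caller = "consensus",
                    confidence = pmin(a$confidence[ia], b$confidence[ib]),
                    cn_mismatch = a$cn[ia] != b$cn[ib],
                    stringsAsFactors = FALSE)
  out <- out[(out$end - out$start + 1) >= min_consensus_length, , drop = FALSE]
  out <- out[order(out$sample_id, out$chrom, out$start, out$end), , drop = FALSE]
  cnv_calls(out, provenance = "consensus", genome_build = ba %||% bb)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x
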