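#' Genomic intervals
#'
#' All coordinates in this package are 1-based and fully closed (the PennCNV
#' convention): an interval `start..end` contains both endpoints and has
#' length `end - start + 1`. BED input/output converts at the boundary.
#'
#' `gi()` builds a validated interval table; most package functions accept any
#' data frame carrying `chrom`, `start`, `end` columns.
#'
#' @param chrom chromosome labels; a leading `"chr"` prefix is stripped
#'   internally and re-emitted by writers.
#' @param start,end 1-based inclusive positions, `1 <= start <= end`.
#' @return a data frame with columns `chrom`, `start`, `end`.
#' @examples
#' gi("chr10", 84034612, 84048907)
#' @export
gi <- function(chrom, start, end) {
  iv <- data.frame(chrom = norm_chrom(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

#' @keywords internal
norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' @keywords internal
validate_intervals <- function(iv, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(iv)))
    stop(what, " table must have chrom/start/end columns")
  bad <- which(!is.finite(iv$start) | !is.finite(iv$end) |
                 iv$start < 1 | iv$end < iv$start)
  if (length(bad))
    stop("invalid ", what, " at row ", bad[1], ": start=", iv$start[bad[1]],
         " end=", iv$end[bad[1]], " (need 1 <= start <= end)")
  invisible(iv)
}

#' Interval length in base pairs
#'
#' Length under the 1-based closed convention: `end - start + 1`.
#'
#' @param iv a data frame with `start`/`end` (and usually `chrom`) columns.
#' @return numeric vector of lengths, one per row.
#' @examples
#' interval_length(gi("chr10", 84034612, 84048907))  # 14296
#' @export
interval_length <- function(iv) {
  validate_intervals(iv)
  iv$end - iv$start + 1
}

#' Intersection of two genomic intervals
#'
#' Returns the overlap `max(starts)..min(ends)` when the two intervals share a
#' chromosome and at least one base, and a zero-row table otherwise. Under
#' closed coordinates, adjacency (`end + 1 == start`) is not overlap.
#'
#' @param a,b single-row interval tables (see [gi()]).
#' @return a `gi()`-style data frame with one row, or zero rows when disjoint.
#' @examples
#' interval_intersect(gi("1", 10, 20), gi("1", 15, 30))  # 1:15-20
#' @export
interval_intersect <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  empty <- a[0, c("chrom", "start", "end")]
  if (norm_chrom(a$chrom) != norm_chrom(b$chrom)) return(empty)
  s <- max(a$start, b$start); e <- min(a$end, b$end)
  if (s > e) return(empty)
  gi(a$chrom, s, e)
}

#' Does a CNV call overlap a gene within a flank?
#'
#' A call is counted as hitting a gene when it shares at least 1 bp with the
#' gene's transcription span extended by `flank` bp on both sides (clipped at
#' position 1). The flank is applied symmetrically regardless of strand.
#'
#' @param call_iv single-row interval table for the call.
#' @param genes gene-model table with `chrom`, `start`, `end` (see
#'   [read_gene_models()]); may have several rows.
#' @param flank non-negative flank in bp (default 10000).
#' @return logical vector, one element per gene row.
#' @export
overlaps_with_flank <- function(call_iv, genes, flank = 10000) {
  stopifnot(nrow(call_iv) == 1, flank >= 0)
  validate_intervals(call_iv); validate_intervals(genes, "gene")
  same <- norm_chrom(genes$chrom) == norm_chrom(call_iv$chrom)
  gs <- pmax(1, genes$start - flank)
  ge <- genes$end + flank
  same & call_iv$start <= ge & call_iv$end >= gs
}

# GRanges view of an interval table; extra columns become mcols.
#' @keywords internal
as_granges <- function(iv) {
  validate_intervals(iv)
  gr <- GenomicRanges::GRanges(
    seqnames = norm_chrom(iv$chrom),
    ranges = IRanges::IRanges(start = iv$start, end = iv$end))
  extra <- setdiff(names(iv), c("chrom", "start", "end"))
  if (length(extra))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(iv[extra])
  gr
}
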