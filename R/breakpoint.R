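#' Minimal overlapping region of a set of calls
#'
#' The interval shared by every call: `max(starts)..min(ends)`. All calls
#' must be on one chromosome and pairwise overlapping; the first disjoint
#' pair found is named in the error otherwise.
#'
#' @param calls interval table (>= 1 row), e.g. deletion calls from several
#'   carriers.
#' @return single-row [gi()] interval.
#' @export
minimal_overlap_region <- function(calls) {
  validate_intervals(calls, "call")
  stopifnot(nrow(calls) >= 1)
  if (length(unique(norm_chrom(calls$chrom))) > 1)
    stop("calls span multiple chromosomes")
  s <- max(calls$start); e <- min(calls$end)
  if (s > e) {
    i <- which.max(calls$start); j <- which.min(calls$end)
    stop("no common overlap: rows ", j, " (ends ", calls$end[j],
         ") and ", i, " (starts ", calls$start[i], ") are disjoint")
  }
  gi(calls$chrom[1], s, e)
}

#' Deleted length from a breakpoint pair
#'
#' Breakpoints follow the junction-difference convention: `upstream` is the
#' last retained base before the deletion and `downstream` the junction
#' coordinate, so the deleted length is `downstream - upstream` — one less
#' than the inclusive length of the interval `upstream..downstream`. Both
#' views of the same event are thus available without silent off-by-one
#' confusion.
#'
#' @param upstream,downstream 1-based boundary coordinates,
#'   `downstream > upstream`.
#' @return deleted length in bp.
#' @examples
#' breakpoint_span(84032610, 84052262)  # 19652
#' @export
breakpoint_span <- function(upstream, downstream) {
  stopifnot(downstream > upstream)
  downstream - upstream
}

#' Junction microhomology at a deletion breakpoint
#'
#' Finds the longest `k <= max_len` such that the `k` reference bases ending
#' at the upstream boundary equal the `k` bases ending at the downstream
#' boundary (case-insensitive, reference strand only). Such microhomology is
#' a signature of the repair mechanism that formed the deletion.
#'
#' @param ref reference sequence: a character string, a named character
#'   vector / `Biostrings::DNAStringSet` keyed by chromosome, or a FASTA
#'   path.
#' @param chrom chromosome of the breakpoints (ignored for a bare string).
#' @param upstream,downstream boundary coordinates as in
#'   [breakpoint_span()].
#' @param max_len maximum homology length scanned (default 20).
#' @return list with `length` (k, 0 when the junctions share no suffix),
#'   `seq` (the homologous bases, `""` when k = 0), and `n_truncated`
#'   (`TRUE` when an N in a flank truncated the scan).
#' @export
microhomology <- function(ref, chrom = NULL, upstream, downstream,
                          max_len = 20) {
  seq <- fetch_reference(ref, chrom)
  stopifnot(downstream > upstream, upstream >= 1, downstream <= nchar(seq))
  k_max <- min(max_len, upstream, downstream - upstream)
  up <- toupper(substr(seq, upstream - k_max + 1, upstream))
  dn <- toupper(substr(seq, downstream - k_max + 1, downstream))
  k <- 0L; truncated <- FALSE
  for (i in seq_len(k_max)) {
    cu <- substr(up, k_max - i + 1, k_max - i + 1)
    cd <- substr(dn, k_max - i + 1, k_max - i + 1)
    if (cu == "N" || cd == "N") { truncated <- TRUE; break }
    if (cu != cd) break
    k <- i
  }
  list(length = k,
       seq = if (k > 0) substr(toupper(dn), k_max - k + 1, k_max) else "",
       n_truncated = truncated)
}

# resolve the reference argument to one chromosome's sequence string
#' @keywords internal
fetch_reference <- function(ref, chrom = NULL) {
  if (methods::is(ref, "DNAStringSet")) ref <- as.character(ref)
  if (is.character(ref) && length(ref) == 1 && file.exists(ref) &&
      grepl("\\.(fa|fasta|fna)$", ref, ignore.case = TRUE))
    ref <- as.character(Biostrings::readDNAStringSet(ref))
  if (is.character(ref) && length(ref) == 1 && is.null(names(ref)))
    return(ref)
  if (is.null(chrom)) {
    if (length(ref) == 1) return(unname(ref))
    stop("chrom required for a multi-sequence reference")
  }
  nm <- names(ref)
  hit <- which(norm_chrom(sub("\\s.*$", "", nm)) == norm_chrom(chrom))
  if (!length(hit)) stop("chromosome '", chrom, "' not in reference")
  unname(ref[hit[1]])
}
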