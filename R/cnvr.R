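#' Frequency and annotation parameters
#'
#' @param rare_threshold carrier-frequency threshold below which a CNVR is
#'   rare; the denominator is the combined sample (cases + controls).
#' @param long_threshold bp above which a CNV is "long" (default 100 kb).
#' @param large_threshold bp above which a CNV is "large" (default 1 Mb).
#' @param genic_flank bp added to both ends of a gene span for genic overlap
#'   (default 10 kb).
#' @return a parameter list.
#' @export
frequency_params <- function(rare_threshold = 0.01, long_threshold = 1e5,
                             large_threshold = 1e6, genic_flank = 1e4) {
  stopifnot(rare_threshold > 0, rare_threshold < 1,
            long_threshold > 0, large_threshold > 0, genic_flank >= 0)
  list(rare_threshold = rare_threshold, long_threshold = long_threshold,
       large_threshold = large_threshold, genic_flank = genic_flank)
}

#' Build copy-number variable regions (CNVRs)
#'
#' Calls are clustered per chromosome by transitive single-linkage on >= 1 bp
#' overlap, separately for deletions and duplications (a del cluster and a dup
#' cluster sharing a span give two CNVRs). The CNVR interval is the union span
#' of its member calls; carriers are the distinct samples among members, and
#' carrier frequency is computed over the combined sample size.
#'
#' @param calls a [cnv_calls()] table.
#' @param samples sample table (see [read_sample_table()]); every call's
#'   sample must be present.
#' @param params see [frequency_params()].
#' @return data frame with one row per CNVR: `cnvr_id`, `chrom`, `start`,
#'   `end`, `type`, `n_carriers`, `n_calls`, `freq`, plus list-columns
#'   `carriers` and `member_idx` (row indices into `calls`), and the
#'   classification columns of [classify_frequency()].
#' @export
build_cnvrs <- function(calls, samples, params = frequency_params()) {
  if (!nrow(calls)) stop("empty call set")
  missing <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(missing))
    stop("call sample absent from sample table: ", missing[1])
  dir <- cnv_direction(calls)
  key <- paste(calls$chrom, dir, sep = "\r")
  idx <- seq_len(nrow(calls))
  pieces <- lapply(split(idx, key), function(ii) {
    r <- IRanges::IRanges(calls$start[ii], calls$end[ii])
    # min.gapwidth = 0: merge only true overlaps, not touching intervals
    red <- IRanges::reduce(r, min.gapwidth = 0L)
    h <- IRanges::findOverlaps(r, red)
    comp <- S4Vectors::subjectHits(h)[order(S4Vectors::queryHits(h))]
    data.frame(call_idx = ii, comp = comp,
               chrom = calls$chrom[ii][1], type = dir[ii[1]],
               rstart = IRanges::start(red)[comp], rend = IRanges::end(red)[comp],
               stringsAsFactors = FALSE)
  })
  maps <- do.call(rbind, pieces)
  grp <- split(maps, paste(maps$chrom, maps$type, maps$comp, sep = "\r"))
  out <- lapply(grp, function(m) {
    carr <- unique(calls$sample_id[m$call_idx])
    df <- data.frame(chrom = m$chrom[1], start = m$rstart[1], end = m$rend[1],
                     type = m$type[1], n_carriers = length(carr),
                     n_calls = nrow(m),
                     freq = length(carr) / nrow(samples),
                     stringsAsFactors = FALSE)
    df$carriers <- list(carr)
    df$member_idx <- list(sort(m$call_idx))
    df
  })
  cnvrs <- do.call(rbind, out)
  cnvrs <- cnvrs[order(suppressWarnings(as.numeric(cnvrs$chrom)), cnvrs$chrom,
                       cnvrs$start, cnvrs$end, cnvrs$type), , drop = FALSE]
  cnvrs$cnvr_id <- sprintf("CNVR%04d.%s", seq_len(nrow(cnvrs)),
                           ifelse(cnvrs$type == "del", "1", "2"))
  rownames(cnvrs) <- NULL
  classify_frequency(cnvrs, nrow(samples), params)
}

#' Classify CNVR frequency and occurrence
#'
#' `freq_class` is `"rare"` iff carriers / `n_total` is below the rare
#' threshold, `"common"` otherwise. `occurrence_class` counts member calls:
#' `"singleton"` for exactly one, `"two_to_four"` for 2-4, `"more"` above.
#'
#' @param cnvrs output of [build_cnvrs()].
#' @param n_total combined number of individuals (cases + controls).
#' @param params see [frequency_params()].
#' @return `cnvrs` with `freq`, `freq_class`, `occurrence_class` columns.
#' @export
classify_frequency <- function(cnvrs, n_total, params = frequency_params()) {
  stopifnot(n_total > 0)
  cnvrs$freq <- cnvrs$n_carriers / n_total
  cnvrs$freq_class <- ifelse(cnvrs$freq < params$rare_threshold, "rare", "common")
  cnvrs$occurrence_class <- cut(cnvrs$n_calls, c(0, 1, 4, Inf),
                                labels = c("singleton", "two_to_four", "more"))
  cnvrs$occurrence_class <- as.character(cnvrs$occurrence_class)
  cnvrs
}

#' Propagate CNVR classes down to member calls
#'
#' Burden filters operate on calls; rare/common status is assigned at CNVR
#' level and inherited by each member call.
#'
#' @param calls the call table CNVRs were built from.
#' @param cnvrs output of [build_cnvrs()].
#' @return `calls` with `cnvr_id`, `freq_class`, `occurrence_class` columns.
#' @export
classify_calls <- function(calls, cnvrs) {
  calls$cnvr_id <- NA_character_
  calls$freq_class <- NA_character_
  calls$occurrence_class <- NA_character_
  for (i in seq_len(nrow(cnvrs))) {
    ii <- cnvrs$member_idx[[i]]
    calls$cnvr_id[ii] <- cnvrs$cnvr_id[i]
    calls$freq_class[ii] <- cnvrs$freq_class[i]
    calls$occurrence_class[ii] <- cnvrs$occurrence_class[i]
  }
  calls
}

#' Annotate records with overlapping genes
#'
#' A record is genic when it shares >= 1 bp with any gene span extended by
#' `genic_flank` on both sides; gene names are deduplicated per record.
#'
#' @param x interval table (calls or CNVRs).
#' @param genes gene models (see [read_gene_models()]).
#' @param params see [frequency_params()] (`genic_flank` is used).
#' @return `x` with list-column `genes`, and columns `gene_count`, `genic`.
#' @export
annotate_genic <- function(x, genes, params = frequency_params()) {
  if (!nrow(x)) {
    x$genes <- list(); x$gene_count <- integer(); x$genic <- logical()
    return(x)
  }
  x$genes <- rep(list(character()), nrow(x))
  if (nrow(genes)) {
    gg <- genes
    gg$start <- pmax(1, gg$start - params$genic_flank)
    gg$end <- gg$end + params$genic_flank
    hits <- GenomicRanges::findOverlaps(as_granges(x), as_granges(gg))
    qh <- S4Vectors::queryHits(hits)
    nm <- genes$name[S4Vectors::subjectHits(hits)]
    got <- lapply(split(nm, qh), function(v) sort(unique(v)))
    x$genes[as.integer(names(got))] <- got
  }
  x$gene_count <- lengths(x$genes)
  x$genic <- x$gene_count > 0
  x
}

#' Case-exclusive rare genic CNVRs
#'
#' The catalog of interest: CNVRs that are rare, genic, and whose carriers are
#' all cases. The returned subset carries attributes `n_cnvrs` and `n_calls`
#' (non-redundant regions vs unique structural variants).
#'
#' @param cnvrs CNVRs processed by [classify_frequency()] and
#'   [annotate_genic()].
#' @param samples sample table.
#' @return subset of `cnvrs`.
#' @export
catalog_specific_cnvrs <- function(cnvrs, samples) {
  if (!"genic" %in% names(cnvrs))
    stop("run annotate_genic() on the CNVRs first")
  cases <- samples$sample_id[samples$group == "case"]
  excl <- vapply(cnvrs$carriers, function(cc) all(cc %in% cases), TRUE)
  out <- cnvrs[cnvrs$freq_class == "rare" & cnvrs$genic & excl, , drop = FALSE]
  structure(out, n_cnvrs = nrow(out), n_calls = sum(out$n_calls))
}

#' Overlap CNVRs with a known-CNV catalog
#'
#' @param cnvrs CNVR table.
#' @param catalog interval table with a `name` column (e.g. from
#'   [read_bed()]), such as a DGV-like BED.
#' @return data frame of hits: `cnvr_id`, `catalog_name`, catalog coordinates
#'   (>= 1 bp overlap).
#' @export
overlap_known_catalog <- function(cnvrs, catalog) {
  empty <- data.frame(cnvr_id = character(), catalog_name = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(cnvrs) || !nrow(catalog)) return(empty)
  hits <- GenomicRanges::findOverlaps(as_granges(cnvrs), as_granges(catalog))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (!length(qh)) return(empty)
  data.frame(cnvr_id = cnvrs$cnvr_id[qh], catalog_name = catalog$name[sh],
             chrom = catalog$chrom[sh], start = catalog$start[sh],
             end = catalog$end[sh], stringsAsFactors = FALSE)
}
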