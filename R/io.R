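#' Construct a CNV call set
#'
#' The in-memory currency for CNV calls: a data frame with one row per call
#' and columns `sample_id`, `chrom`, `start`, `end`, `cn`, `caller`,
#' `confidence`. Copy-number state 2 is copy-neutral and is never stored as a
#' call; a call is a deletion iff `cn < 2` and a duplication iff `cn > 2`.
#'
#' @param df data frame with at least `sample_id`, `chrom`, `start`, `end`,
#'   `cn` columns.
#' @param provenance caller label (`"callerA"`, `"callerB"`, `"consensus"`,
#'   or free text).
#' @param genome_build free-text build tag (e.g. `"hg18"`), used only as a
#'   consistency check by [consensus_segments()].
#' @return a `cnv_calls` data frame with `provenance` and `genome_build`
#'   attributes.
#' @export
cnv_calls <- function(df, provenance = "unknown", genome_build = NA_character_) {
  need <- c("sample_id", "chrom", "start", "end", "cn")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("call table missing columns: ", paste(miss, collapse = ", "))
  df$chrom <- norm_chrom(df$chrom)
  df$cn <- as.integer(df$cn)
  if (!"caller" %in% names(df)) df$caller <- rep(provenance, nrow(df))
  if (!"confidence" %in% names(df)) df$confidence <- rep(NA_real_, nrow(df))
  df <- df[c("sample_id", "chrom", "start", "end", "cn", "caller", "confidence",
             setdiff(names(df), c("sample_id", "chrom", "start", "end", "cn",
                                  "caller", "confidence")))]
  if (nrow(df)) {
    validate_intervals(df, "CNV call")
    bad <- which(!(df$cn %in% 0:4) | df$cn == 2L)
    if (length(bad))
      stop("call row ", bad[1], ": cn=", df$cn[bad[1]],
           " (must be in {0,1,3,4}; state 2 is copy-neutral)")
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance, genome_build = genome_build,
            class = c("cnv_calls", "data.frame"))
}

#' Deletion/duplication direction of calls
#' @param calls a `cnv_calls` table (or anything with a `cn` column).
#' @return character vector, `"del"` or `"dup"`.
#' @export
cnv_direction <- function(calls) ifelse(calls$cn < 2, "del", "dup")

#' Read CNV calls from disk
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`pennCNV_rawcnv`}{whitespace-separated PennCNV output:
#'     `chr10:84034612-84048907 numsnp=8 length=14,296 state2,cn=1 sampleA ...`}
#'   \item{`plink_cnv`}{PLINK `.cnv`: `FID IID CHR BP1 BP2 TYPE [SCORE SITES]`,
#'     `TYPE` being the integer copy number; an optional header row is skipped.}
#'   \item{`bed_tsv`}{headerless TSV of `chrom, start (0-based), end,
#'     sample_id, cn[, confidence]`; coordinates converted to 1-based closed.}
#' }
#' Chromosome labels are normalized (leading `"chr"` stripped). Records with
#' copy-number state 2 or invalid coordinates are rejected with the offending
#' line number.
#'
#' @param path file to read.
#' @param dialect one of `"pennCNV_rawcnv"`, `"plink_cnv"`, `"bed_tsv"`.
#' @param provenance caller label stored on the result.
#' @param genome_build build tag stored on the result.
#' @return a [cnv_calls()] table.
#' @export
read_cnv_calls <- function(path, dialect = c("pennCNV_rawcnv", "plink_cnv", "bed_tsv"),
                           provenance = dialect, genome_build = NA_character_) {
  dialect <- match.arg(dialect)
  if (identical(provenance, dialect)) provenance <- dialect
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("no CNV records in ", path)
    return(cnv_calls(data.frame(sample_id = character(), chrom = character(),
                                start = numeric(), end = numeric(),
                                cn = integer()),
                     provenance = provenance, genome_build = genome_build))
  }
  parse_fail <- function(i, why)
    stop("parse error in ", path, " line ", i, " [", dialect, "]: ", why)

  rows <- switch(dialect,
    pennCNV_rawcnv = lapply(seq_along(lines), function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 5) parse_fail(i, "expected >= 5 fields")
      m <- regmatches(f[1], regexec("^(chr)?([^:]+):([0-9,]+)-([0-9,]+)$", f[1]))[[1]]
      if (!length(m)) parse_fail(i, paste0("bad locus '", f[1], "'"))
      cnm <- regmatches(f[4], regexec("cn=([0-9]+)", f[4]))[[1]]
      if (length(cnm) < 2) parse_fail(i, paste0("no cn= in '", f[4], "'"))
      conf <- NA_real_
      cf <- grep("^conf=", f, value = TRUE)
      if (length(cf)) conf <- as.numeric(sub("^conf=", "", cf[1]))
      data.frame(sample_id = f[5], chrom = m[3],
                 start = as.numeric(gsub(",", "", m[4])),
                 end = as.numeric(gsub(",", "", m[5])),
                 cn = as.integer(cnm[2]), confidence = conf,
                 stringsAsFactors = FALSE)
    }),
    plink_cnv = {
      body <- lines
      if (grepl("\\bIID\\b", body[1]) || grepl("\\bBP1\\b", body[1]))
        body <- body[-1]
      lapply(seq_along(body), function(i) {
        f <- strsplit(trimws(body[i]), "\\s+")[[1]]
        if (length(f) < 6) parse_fail(i, "expected >= 6 fields")
        pos <- suppressWarnings(as.numeric(f[4:5]))
        cn <- suppressWarnings(as.integer(f[6]))
        if (anyNA(pos) || is.na(cn)) parse_fail(i, "non-numeric BP1/BP2/TYPE")
        conf <- if (length(f) >= 7) suppressWarnings(as.numeric(f[7])) else NA_real_
        data.frame(sample_id = f[2], chrom = f[3], start = pos[1], end = pos[2],
                   cn = cn, confidence = conf, stringsAsFactors = FALSE)
      })
    },
    bed_tsv = lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[i], "\t")[[1]]
      if (length(f) < 5) parse_fail(i, "expected >= 5 tab-separated fields")
      s0 <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
      cn <- suppressWarnings(as.integer(f[5]))
      if (anyNA(c(s0, e)) || is.na(cn)) parse_fail(i, "non-numeric coordinates/cn")
      conf <- if (length(f) >= 6) suppressWarnings(as.numeric(f[6])) else NA_real_
      data.frame(sample_id = f[4], chrom = f[1], start = s0 + 1, end = e,
                 cn = cn, confidence = conf, stringsAsFactors = FALSE)
    })
  )
  cnv_calls(do.call(rbind, rows), provenance = provenance,
            genome_build = genome_build)
}

#' Write CNV calls as generic BED+cn TSV
#'
#' Emits the `bed_tsv` dialect of [read_cnv_calls()] (0-based half-open,
#' `chr`-prefixed); `read_cnv_calls(write_cnv_calls(x), "bed_tsv")`
#' round-trips coordinates and copy numbers exactly.
#'
#' @param calls a [cnv_calls()] table.
#' @param path output file.
#' @export
write_cnv_calls <- function(calls, path) {
  lines <- if (nrow(calls)) {
    conf <- ifelse(is.na(calls$confidence), ".", format(calls$confidence))
    paste(paste0("chr", calls$chrom), format(calls$start - 1, scientific = FALSE,
                                             trim = TRUE),
          format(calls$end, scientific = FALSE, trim = TRUE),
          calls$sample_id, calls$cn, conf, sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read the sample table
#'
#' TSV with a header; required columns `sample_id` and `group` (values
#' `case`/`control`). Recognized optional columns: `syndromic` (logical or
#' 0/1), `subtype` (`S`, `L`, `TCA`, `NA`), the intensity-quality metrics
#' `lrr_sd`, `baf_drift`, `mad`, `wave`, and `down_syndrome`. Missing quality
#' columns are filled with `NA` (conditional permutation then refuses to run).
#'
#' @param path TSV file.
#' @return data frame of samples, one row each.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample table needs sample_id and group columns")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicated sample_id: ", dup[1])
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad)) stop("unknown group label: ", bad[1])
  for (col in c("lrr_sd", "baf_drift", "mad", "wave"))
    if (!col %in% names(df)) df[[col]] <- NA_real_ else {
      df[[col]] <- as.numeric(df[[col]])
      if (any(df[[col]] < 0, na.rm = TRUE)) stop("negative ", col)
    }
  if (!"syndromic" %in% names(df)) df$syndromic <- NA
  df$syndromic <- as.logical(df$syndromic)
  if (!"subtype" %in% names(df)) df$subtype <- NA_character_
  if (!"down_syndrome" %in% names(df)) df$down_syndrome <- FALSE
  df$down_syndrome <- isTRUE_vec(df$down_syndrome)
  df
}

#' @keywords internal
isTRUE_vec <- function(x) {
  out <- as.logical(x)
  out[is.na(out)] <- FALSE
  out
}

#' Read gene models
#'
#' @param path input file.
#' @param dialect `"refflat_tsv"` (columns geneName, name, chrom, strand,
#'   txStart, txEnd, ...; txStart 0-based) or `"bed"` (chrom, start, end,
#'   name\[, score, strand\]). Coordinates are converted to the internal
#'   1-based closed convention.
#' @return data frame with columns `name`, `chrom`, `start`, `end`, `strand`.
#'   Duplicate names are kept; genic counting deduplicates by name.
#' @export
read_gene_models <- function(path, dialect = c("refflat_tsv", "bed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character()))
  f <- strsplit(lines, "\t")
  g <- if (dialect == "refflat_tsv") {
    data.frame(name = vapply(f, `[`, "", 1),
               chrom = norm_chrom(vapply(f, `[`, "", 3)),
               start = as.numeric(vapply(f, `[`, "", 5)) + 1,
               end = as.numeric(vapply(f, `[`, "", 6)),
               strand = vapply(f, `[`, "", 4), stringsAsFactors = FALSE)
  } else {
    data.frame(name = vapply(f, function(x) if (length(x) >= 4) x[4] else NA_character_, ""),
               chrom = norm_chrom(vapply(f, `[`, "", 1)),
               start = as.numeric(vapply(f, `[`, "", 2)) + 1,
               end = as.numeric(vapply(f, `[`, "", 3)),
               strand = vapply(f, function(x) if (length(x) >= 6) x[6] else "+", ""),
               stringsAsFactors = FALSE)
  }
  if (anyNA(g$name) || any(!nzchar(g$name))) stop("gene model with empty name")
  validate_intervals(g, "gene model")
  g
}

#' Write intervals (or CNVRs) as BED
#'
#' 0-based half-open output with `chr`-prefixed chromosomes; the `name` BED
#' column is taken from a `name` or `cnvr_id` column when present.
#' `read_bed(write_bed(x))` round-trips coordinates exactly.
#'
#' @param iv interval table.
#' @param path output file.
#' @export
write_bed <- function(iv, path) {
  lines <- if (nrow(iv)) {
    nm <- if ("name" %in% names(iv)) iv$name
          else if ("cnvr_id" %in% names(iv)) iv$cnvr_id else NULL
    base <- paste(paste0("chr", norm_chrom(iv$chrom)),
                  format(iv$start - 1, scientific = FALSE, trim = TRUE),
                  format(iv$end, scientific = FALSE, trim = TRUE), sep = "\t")
    if (is.null(nm)) base else paste(base, nm, sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED4 file as an interval table
#' @param path BED file (0-based half-open; converted on read).
#' @return data frame with `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character()))
  f <- strsplit(lines, "\t")
  out <- data.frame(chrom = norm_chrom(vapply(f, `[`, "", 1)),
                    start = as.numeric(vapply(f, `[`, "", 2)) + 1,
                    end = as.numeric(vapply(f, `[`, "", 3)),
                    name = vapply(f, function(x) if (length(x) >= 4) x[4] else NA_character_, ""),
                    stringsAsFactors = FALSE)
  validate_intervals(out, "BED record")
  out
}

#' Read a qPCR cycle-threshold table
#'
#' TSV with header and columns `sample_id`, `probe_id`, `role`
#' (`target`/`reference`), `ct`; one row per replicate. Replicates are grouped
#' by (sample, target probe) and paired with the sample's reference replicates.
#'
#' @param path TSV file.
#' @param min_replicates minimum replicates per (sample, probe, role) group.
#' @return data frame with one row per (sample, target probe) and list-columns
#'   `target_cts`, `reference_cts`.
#' @export
read_qpcr_table <- function(path, min_replicates = 2) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "probe_id", "role", "ct")
  if (!all(need %in% names(df))) stop("qPCR table needs columns ",
                                      paste(need, collapse = ", "))
  ct <- suppressWarnings(as.numeric(df$ct))
  bad <- which(is.na(ct))
  if (length(bad)) stop("non-numeric CT '", df$ct[bad[1]], "' at data row ", bad[1])
  df$ct <- ct
  bad <- setdiff(unique(df$role), c("target", "reference"))
  if (length(bad)) stop("unknown probe role: ", bad[1])
  qpcr_records(df, min_replicates = min_replicates)
}

#' Group long-format qPCR replicates into records
#' @param df data frame with `sample_id`, `probe_id`, `role`, `ct`.
#' @param min_replicates minimum replicates per group.
#' @return see [read_qpcr_table()].
#' @export
qpcr_records <- function(df, min_replicates = 2) {
  out <- list()
  for (sid in unique(df$sample_id)) {
    d <- df[df$sample_id == sid, ]
    ref <- d$ct[d$role == "reference"]
    tg <- d[d$role == "target", ]
    if (!nrow(tg)) stop("sample ", sid, " has no target rows")
    if (!length(ref)) stop("sample ", sid, " has target rows but no reference rows")
    if (length(ref) < min_replicates)
      stop("sample ", sid, ": only ", length(ref), " reference replicates")
    for (pid in unique(tg$probe_id)) {
      tc <- tg$ct[tg$probe_id == pid]
      if (length(tc) < min_replicates)
        stop("sample ", sid, " probe ", pid, ": only ", length(tc),
             " target replicates")
      out[[length(out) + 1]] <- data.frame(sample_id = sid, probe_id = pid,
                                           stringsAsFactors = FALSE)
      out[[length(out)]]$target_cts <- list(tc)
      out[[length(out)]]$reference_cts <- list(ref)
    }
  }
  do.call(rbind, out)
}
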