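#' Pipeline configuration
#'
#' A plain list validated and given defaults; round-trips losslessly through
#' JSON (`jsonlite`). Paths: `caller_a`, `caller_b` (call files),
#' `caller_a_dialect`/`caller_b_dialect`, `samples`, `genes`,
#' `genes_dialect`, optional `catalog` (BED), and `out_dir`. Analysis
#' settings: `rare_threshold`, `genic_flank`, `min_consensus_length`,
#' `n_perm`, `seed`, `large_threshold`.
#'
#' @param ... configuration fields (see above), or a single list.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && is.null(names(args)))
    args <- args[[1]]
  defaults <- list(caller_a = NULL, caller_b = NULL,
                   caller_a_dialect = "bed_tsv", caller_b_dialect = "bed_tsv",
                   samples = NULL, genes = NULL, genes_dialect = "bed",
                   catalog = NULL, out_dir = ".", rare_threshold = 0.01,
                   genic_flank = 1e4, min_consensus_length = 1,
                   n_perm = 1000, seed = 1, large_threshold = 1e6)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) stop("unknown config field: ", unknown[1])
  cfg <- utils::modifyList(defaults, args)
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline config as JSON
#' @param path JSON file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config)[!vapply(config, is.null, TRUE)],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full CNV analysis pipeline
#'
#' consensus -> CNVR construction/classification -> genic annotation ->
#' burden table -> CNVR association scan -> large-CNV report. All outputs
#' are plain TSV/BED under `config$out_dir` plus a run log recording the
#' resolved configuration and seed; outputs are a pure function of (inputs,
#' config, seed). Inputs are pre-flight checked so a failure leaves no
#' partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of result tables: `consensus`, `cnvrs`,
#'   `burden`, `association`, `large`, and output `paths`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("caller_a", "caller_b", "samples", "genes")) {
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(config[[f]])) stop("input not readable: ", f, " = ",
                                        config[[f]])
  }
  params <- frequency_params(rare_threshold = config$rare_threshold,
                             large_threshold = config$large_threshold,
                             genic_flank = config$genic_flank)
  a <- read_cnv_calls(config$caller_a, config$caller_a_dialect, "callerA")
  b <- read_cnv_calls(config$caller_b, config$caller_b_dialect, "callerB")
  samples <- read_sample_table(config$samples)
  genes <- read_gene_models(config$genes, config$genes_dialect)

  cons <- consensus_segments(a, b, config$min_consensus_length)
  cnvrs <- build_cnvrs(cons, samples, params)
  cnvrs <- annotate_genic(cnvrs, genes, params)
  calls <- classify_calls(cons, cnvrs)

  filters <- list(all_rare = burden_filter(freq_class = "rare"),
                  rare_del = burden_filter("rare", "del"),
                  rare_dup = burden_filter("rare", "dup"),
                  common = burden_filter(freq_class = "common"))
  burden_rows <- lapply(names(filters), function(nm) {
    met <- compute_burden_metrics(calls, samples, filters[[nm]], genes, params)
    is_case <- samples$group == "case"
    do.call(rbind, lapply(c(size = "mean_kb", rate = "n_cnv",
                            gene_count = "gene_count"), function(col) NULL))
    out <- lapply(c("size", "rate", "gene_count"), function(metric) {
      x <- switch(metric, size = met$mean_kb, rate = met$n_cnv,
                  gene_count = met$gene_count)
      r <- suppressWarnings(
        permutation_test(x, is_case, config$n_perm, seed = config$seed,
                         metric = metric))
      rc <- suppressMessages(suppressWarnings(
        conditional_permutation_test(x, is_case, samples,
                                     n_perm = config$n_perm,
                                     seed = config$seed, metric = metric)))
      data.frame(filter = nm, metric = metric, baseline = r$baseline,
                 ratio = r$ratio, p = r$p, p_conditional = rc$p,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  burden <- do.call(rbind, burden_rows)

  assoc <- cnvr_association_scan(cnvrs, samples)
  large <- filter_large_cnvs(calls, samples, genes,
                             threshold = config$large_threshold,
                             params = params)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    consensus = file.path(config$out_dir, "consensus_calls.tsv"),
    cnvr_tsv = file.path(config$out_dir, "cnvr.tsv"),
    cnvr_bed = file.path(config$out_dir, "cnvr.bed"),
    burden = file.path(config$out_dir, "burden.tsv"),
    assoc = file.path(config$out_dir, "association.tsv"),
    large = file.path(config$out_dir, "large_cnvs.tsv"),
    log = file.path(config$out_dir, "run_log.txt"))
  write_cnv_calls(cons, paths$consensus)
  cn_flat <- cnvrs
  cn_flat$carriers <- vapply(cn_flat$carriers, paste, "", collapse = ",")
  cn_flat$genes <- vapply(cn_flat$genes, paste, "", collapse = ",")
  cn_flat$member_idx <- NULL
  utils::write.table(cn_flat, paths$cnvr_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed(cnvrs, paths$cnvr_bed)
  utils::write.table(burden, paths$burden, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(assoc, paths$assoc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(large, paths$large, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(paste("cnvburden run", format(Sys.time())),
               paste("seed:", config$seed),
               "resolved config:",
               utils::capture.output(utils::str(unclass(config)))),
             paths$log)
  invisible(list(consensus = cons, cnvrs = cnvrs, burden = burden,
                 association = assoc, large = large, paths = paths))
}

#' Large rare CNV report
#'
#' Rare calls longer than `threshold` bp (default 1 Mb), annotated with
#' carrier, group, syndromic flag and overlapped genes — the shape of a
#' "large, rare CNVs in patients" table.
#'
#' @param calls classified calls (see [classify_calls()]).
#' @param samples sample table.
#' @param genes gene models.
#' @param threshold length threshold in bp; calls strictly longer pass.
#' @param params see [frequency_params()].
#' @return data frame: sample, group, syndromic, coordinates, length_mb,
#'   cn, genes.
#' @export
filter_large_cnvs <- function(calls, samples, genes = NULL, threshold = 1e6,
                              params = frequency_params()) {
  if (!"freq_class" %in% names(calls))
    stop("calls must be classified (classify_calls) before filtering")
  keep <- calls$freq_class == "rare" &
    (calls$end - calls$start + 1) > threshold
  sub <- calls[keep, , drop = FALSE]
  if (!is.null(genes)) sub <- annotate_genic(sub, genes, params)
  m <- match(sub$sample_id, samples$sample_id)
  out <- data.frame(sample_id = sub$sample_id, group = samples$group[m],
                    syndromic = samples$syndromic[m], chrom = sub$chrom,
                    start = sub$start, end = sub$end,
                    length_mb = round((sub$end - sub$start + 1) / 1e6, 2),
                    cn = sub$cn, stringsAsFactors = FALSE)
  out$genes <- if (is.null(genes)) rep("", nrow(out)) else
    vapply(sub$genes, paste, "", collapse = ",")
  out[order(-out$length_mb), , drop = FALSE]
}
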