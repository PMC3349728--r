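test_that("transitive chaining and type separation", {
  samples <- toy_samples(3, 1)
  samples$sample_id <- c("s1", "s2", "s3", "s4")
  calls <- calls_from_strings(c("s1 1 100 200 1", "s2 1 150 300 1",
                                "s3 1 290 400 1"))
  cnvrs <- build_cnvrs(calls, samples)
  expect_equal(nrow(cnvrs), 1)
  expect_equal(cnvrs$start, 100)
  expect_equal(cnvrs$end, 400)
  expect_equal(cnvrs$n_carriers, 3)

  # same span, opposite directions: two CNVRs
  calls2 <- calls_from_strings(c("s1 1 100 200 1", "s2 1 100 200 3"))
  cnvrs2 <- build_cnvrs(calls2, samples)
  expect_equal(nrow(cnvrs2), 2)
  expect_setequal(cnvrs2$type, c("del", "dup"))

  # touching but not overlapping calls stay separate
  calls3 <- calls_from_strings(c("s1 1 100 200 1", "s2 1 201 300 1"))
  expect_equal(nrow(build_cnvrs(calls3, samples)), 2)

  expect_error(build_cnvrs(calls_from_strings("ghost 1 1 10 1"), samples),
               "absent from sample table")
})

test_that("frequency classification at the 1% boundary", {
  cnvrs <- data.frame(chrom = "1", start = 1, end = 10, type = "del",
                      n_carriers = c(5L, 4L), n_calls = c(5L, 1L))
  out <- classify_frequency(cnvrs, 460)
  # 5/460 = 1.087% -> common; 4/460 = 0.87% -> rare
  expect_equal(out$freq, c(5, 4) / 460)
  expect_equal(out$freq_class, c("common", "rare"))
  expect_equal(out$occurrence_class, c("more", "singleton"))
  expect_equal(classify_frequency(data.frame(chrom = "1", start = 1, end = 2,
                                             type = "del", n_carriers = 1L,
                                             n_calls = 3L), 1000)$occurrence_class,
               "two_to_four")
})

test_that("rare set grows monotonically with the threshold", {
  set.seed(41)
  cnvrs <- data.frame(chrom = "1", start = 1, end = 10, type = "del",
                      n_carriers = sample.int(30, 50, TRUE), n_calls = 1L)
  last <- 0
  for (thr in c(0.005, 0.01, 0.02, 0.05)) {
    nr <- sum(classify_frequency(cnvrs, 500,
                                 frequency_params(rare_threshold = thr))$freq_class == "rare")
    expect_gte(nr, last)
    last <- nr
  }
})

test_that("cluster assignment matches the graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(42)
  n <- 200
  iv <- random_intervals(n, chroms = c("1", "2"), max_pos = 3e5, max_len = 3e4)
  calls <- toy_calls(data.frame(sample_id = sprintf("s%03d", sample.int(150, n, TRUE)),
                                iv, cn = sample(c(1L, 3L), n, TRUE)))
  samples <- data.frame(sample_id = sprintf("s%03d", 1:150),
                        group = rep(c("case", "control"), 75))
  cnvrs <- build_cnvrs(calls, samples)

  # oracle: connected components of the pairwise-overlap graph,
  # within chromosome and direction
  adj <- which(outer(seq_len(n), seq_len(n), function(i, j)
    i < j & calls$chrom[i] == calls$chrom[j] &
      (calls$cn[i] < 2) == (calls$cn[j] < 2) &
      overlaps1(calls$start[i], calls$end[i], calls$start[j], calls$end[j])),
    arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  # same partition of calls into clusters?
  mine <- integer(n)
  for (i in seq_len(nrow(cnvrs))) mine[cnvrs$member_idx[[i]]] <- i
  expect_true(all(mine > 0))
  expect_equal(length(unique(comp)), nrow(cnvrs))
  expect_equal(as.vector(table(comp, mine) > 0) |> sum(),
               nrow(cnvrs))  # one-to-one correspondence of partitions

  # CNVR span is the union span of members; members overlap the CNVR
  for (i in seq_len(nrow(cnvrs))) {
    m <- cnvrs$member_idx[[i]]
    expect_equal(min(calls$start[m]), cnvrs$start[i])
    expect_equal(max(calls$end[m]), cnvrs$end[i])
  }
})

test_that("genic annotation equals a quadratic scan oracle", {
  set.seed(43)
  genes <- random_intervals(500, chroms = c("1", "2", "3"), max_pos = 2e6,
                            max_len = 5e4)
  genes$name <- sprintf("g%03d", sample.int(400, 500, TRUE))  # some duplicates
  genes$strand <- "+"
  cn <- random_intervals(100, chroms = c("1", "2", "3"), max_pos = 2e6,
                         max_len = 1e5)
  ann <- annotate_genic(cn, genes)
  flank <- frequency_params()$genic_flank
  for (i in seq_len(100)) {
    hit <- genes$chrom == cn$chrom[i] &
      overlaps1(cn$start[i], cn$end[i],
                pmax(1, genes$start - flank), genes$end + flank)
    expect_equal(ann$genes[[i]], sort(unique(genes$name[hit])))
  }
  expect_equal(ann$gene_count, lengths(ann$genes))

  # examples: spanning 2 genes + 1 within 10 kb -> 3; far away -> non-genic
  g3 <- data.frame(name = c("A", "B", "C"), chrom = "9",
                   start = c(1e5, 2e5, 3.05e5), end = c(1.2e5, 2.2e5, 3.1e5),
                   strand = "+")
  r <- annotate_genic(data.frame(chrom = "9", start = 9e4, end = 3e5), g3)
  expect_equal(r$genes[[1]], c("A", "B", "C"))
  r2 <- annotate_genic(data.frame(chrom = "9", start = 5e5, end = 6e5), g3)
  expect_false(r2$genic)
})

test_that("case-exclusive rare genic catalog and planted recovery", {
  samples <- data.frame(sample_id = c(sprintf("case%02d", 1:10),
                                      sprintf("ctrl%02d", 1:190)),
                        group = rep(c("case", "control"), c(10, 190)))
  genes <- data.frame(name = "G1", chrom = "1", start = 1000, end = 2000,
                      strand = "+")
  calls <- calls_from_strings(c(
    "case01 1 1500 1800 1",      # rare genic case-exclusive
    "case02 1 50000 60000 1",    # rare non-genic case-exclusive
    "case03 1 1100 1700 3",      # rare genic case-exclusive (dup CNVR)
    "case04 2 500 900 1",        # shared with a control -> excluded
    "ctrl01 2 600 800 1"))
  cnvrs <- annotate_genic(build_cnvrs(calls, samples), genes)
  cat_sp <- catalog_specific_cnvrs(cnvrs, samples)
  expect_equal(attr(cat_sp, "n_cnvrs"), 2)
  expect_equal(attr(cat_sp, "n_calls"), 2)
  expect_setequal(cat_sp$type, c("del", "dup"))
  expect_error(catalog_specific_cnvrs(build_cnvrs(calls, samples), samples),
               "annotate_genic")
})

test_that("known-catalog overlap equals a brute-force scan", {
  set.seed(44)
  cnvrs <- random_intervals(40, chroms = "10", max_pos = 1e6, max_len = 3e4)
  cnvrs$cnvr_id <- sprintf("CNVR%02d", 1:40)
  catalog <- random_intervals(25, chroms = "10", max_pos = 1e6, max_len = 5e4)
  catalog$name <- sprintf("DGV%02d", 1:25)
  hits <- overlap_known_catalog(cnvrs, catalog)
  want <- sum(outer(seq_len(40), seq_len(25), function(i, j)
    overlaps1(cnvrs$start[i], cnvrs$end[i], catalog$start[j], catalog$end[j])))
  expect_equal(nrow(hits), want)
  expect_equal(nrow(overlap_known_catalog(cnvrs, catalog[0, ])), 0)

  # toy example around a known locus
  toy <- data.frame(chrom = "10", start = 84034612, end = 84048907,
                    cnvr_id = "X")
  dgv <- data.frame(chrom = "10", start = 84030000, end = 84060000,
                    name = "dgv2882")
  expect_equal(overlap_known_catalog(toy, dgv)$catalog_name, "dgv2882")
})
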