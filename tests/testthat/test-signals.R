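make_coverage <- function(df, chrom = "chrT") {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(df$start + 1L, df$end),
                         score = df$value)
}

make_peaks <- function(df, chrom = "chrT", names = NULL) {
  gr <- GenomicRanges::GRanges(seqnames = chrom,
                               ranges = IRanges::IRanges(df$start + 1L,
                                                         df$end))
  if (!is.null(names)) gr$name <- names
  gr
}

test_that("TSS profiles reproduce constant tracks exactly and orient by
           strand", {
  gs <- tiny_gene_set()
  cov <- make_coverage(data.frame(start = 0, end = 1e6, value = 2.0))
  prof <- tss_profile(cov, gs, flank = 1000, binsize = 100)
  expect_equal(dim(prof$matrix), c(4L, 20L))
  expect_true(all(prof$matrix == 2.0))
  expect_equal(prof$aggregate, rep(2.0, 20))
  expect_equal(prof$positions, seq(-950, 950, by = 100))

  # minus-strand gene (LINC_B, TSS at 260000): a peak 100 bp genomically
  # to the right of the TSS must appear at negative (upstream) offsets
  cov2 <- make_coverage(data.frame(start = c(0, 260100),
                                   end = c(1e6, 260150),
                                   value = c(0, 10)))
  prof2 <- tss_profile(cov2, gs, genes = "LINC_B", flank = 1000,
                       binsize = 50)
  hit <- which(prof2$matrix[1, ] > 0)
  expect_true(all(prof2$positions[hit] < 0))

  # a sub-binsize delta bump stays confined to the bin containing offset 0
  gs_plus <- gene_set(gs$records[gs$records$gene_id == "PCG_C", 1:7],
                      gs$chrom_sizes)
  tss <- 400000
  cov3 <- make_coverage(data.frame(start = tss + 5, end = tss + 15,
                                   value = 7))
  prof3 <- tss_profile(cov3, gs_plus, flank = 500, binsize = 100)
  expect_equal(which(prof3$matrix[1, ] > 0),
               which(prof3$positions == 50))
})

test_that("genes with unprofileable windows are dropped with a warning", {
  gs <- tiny_gene_set()
  cov <- make_coverage(data.frame(start = 0, end = 1e6, value = 1),
                       chrom = "other")
  expect_error(expect_warning(tss_profile(cov, gs), "dropping"),
               "no genes")
})

test_that("R-loop classification partitions protein-coding genes by network
           partner and promoter peak overlap", {
  gs <- tiny_gene_set()
  prom <- derive_promoters(gs)
  # network: PCG_C has a lincRNA partner, PCG_D does not
  g <- igraph::graph_from_edgelist(rbind(c("LINC_A", "PCG_C"),
                                         c("PCG_D", "PCG_C")),
                                   directed = FALSE)
  igraph::V(g)$gene_class <-
    gs$records$gene_class[match(igraph::V(g)$name, gs$records$gene_id)]
  pc <- prom[prom$gene_id == "PCG_C", ]
  pd <- prom[prom$gene_id == "PCG_D", ]
  peaks <- make_peaks(data.frame(start = c(pc$start + 10, pd$start + 10),
                                 end = c(pc$start + 60, pd$start + 60)))
  cls <- classify_rloop_targets(g, prom, peaks, gs)
  expect_equal(cls$rloop_genes, "PCG_C")
  expect_equal(cls$other_genes, "PCG_D")   # peak but no lincRNA partner
  pcg <- gs$records$gene_id[gs$records$gene_class == "protein_coding"]
  expect_setequal(c(cls$rloop_genes, cls$other_genes), pcg)

  # a peak abutting the promoter end (half-open) has zero overlap
  peaks2 <- make_peaks(data.frame(start = pc$end, end = pc$end + 100))
  cls2 <- classify_rloop_targets(g, prom, peaks2, gs)
  expect_false("PCG_C" %in% cls2$rloop_genes)
})

test_that("promoter peak counting honours multiplicity and TF filters", {
  gs <- tiny_gene_set()
  prom <- derive_promoters(gs, classes = "protein_coding")
  pc <- prom[prom$gene_id == "PCG_C", ]
  starts <- pc$start + c(10, 10, 200)       # duplicated + nested records
  peaks <- make_peaks(data.frame(start = starts, end = starts + 50),
                      names = c("YY1", "YY1", "CTCF"))
  counts <- count_peaks_per_promoter(peaks, prom)
  expect_equal(counts[["PCG_C"]], 3L)
  expect_equal(counts[["PCG_D"]], 0L)
  yy1 <- count_peaks_per_promoter(peaks, prom, tf_filter = "YY1")
  expect_equal(yy1[["PCG_C"]], 2L)
  expect_warning(none <- count_peaks_per_promoter(peaks, prom,
                                                  tf_filter = "ZNF000"),
                 "no peaks match")
  expect_true(all(none == 0L))
  # invariance to record order
  counts_rev <- count_peaks_per_promoter(rev(peaks), prom)
  expect_equal(counts_rev, counts)
})

test_that("group comparison flags planted mean shifts and handles
           degenerate input", {
  set.seed(5)
  a <- rnorm(200, 3, 1); b <- rnorm(200, 0, 1)
  cmp <- compare_groups(a, b)
  expect_gt(cmp$mean_a, cmp$mean_b)
  expect_lt(cmp$p_value, 1e-10)
  same <- c(1, 2, 3, 4)
  cmp2 <- compare_groups(same, same)
  expect_equal(cmp2$p_value, 1)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  const <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
})
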