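# netbuild: Eq.-style aggregation, per-distance binomial null, BH filter,
# and graph assembly.

norm_matrix_from <- function(entries, n) {
  m <- matrix(0, n, n)
  for (e in entries) { m[e[1] + 1, e[2] + 1] <- m[e[2] + 1, e[1] + 1] <- e[3] }
  contact_matrix(m, "chrT", 2e4, stage = "distance_normalized")
}

test_that("aggregate_strength sums over the bin cross product, no diagonal", {
  cm <- norm_matrix_from(list(c(1, 5, 0.5), c(2, 5, 1.5)), 8)
  expect_equal(aggregate_strength(cm, c(1, 2), 5), 2.0)
  expect_equal(aggregate_strength(cm, c(6, 7), c(0, 3)), 0.0)
  expect_equal(aggregate_strength(cm, 3, 3), 0.0)  # diagonal excluded
  expect_error(aggregate_strength(cm, 99, 1), "out of range")
  expect_error(aggregate_strength(cm, integer(0), 1), "nonempty")
})

test_that("enumerate_pairs emits each positive pair once with the three
           pair classes", {
  gs <- tiny_gene_set()
  n_bins <- 50
  m <- matrix(1, n_bins, n_bins); diag(m) <- 0
  nn <- contact_matrix(m, "chrT", 2e4, stage = "distance_normalized")
  raw <- contact_matrix(m * 3, "chrT", 2e4, stage = "raw")
  pairs <- enumerate_pairs(gs, nn, raw)
  expect_equal(nrow(pairs), 6L)                       # C(4,2)
  expect_false(any(duplicated(pair_key(pairs$gene_x, pairs$gene_y))))
  classes <- paste(pmin(pairs$class_x, pairs$class_y),
                   pmax(pairs$class_x, pairs$class_y))
  expect_setequal(unique(classes),
                  c("lincRNA lincRNA", "lincRNA protein_coding",
                    "protein_coding protein_coding"))
  # lincRNAs enter as bodies, protein-coding genes as promoters
  expect_true(all(pairs$kind_x[pairs$class_x == "lincRNA"] == "body"))
  expect_true(all(pairs$kind_x[pairs$class_x == "protein_coding"] ==
                  "promoter"))
  # zero matrix -> empty stream
  zero <- contact_matrix(matrix(0, n_bins, n_bins), "chrT", 2e4,
                         stage = "distance_normalized")
  expect_equal(nrow(enumerate_pairs(gs, zero, raw)), 0L)
})

test_that("raw counts across pairs never exceed the matrix mass for
           non-overlapping elements", {
  sc <- simulate_scenario(small_params())
  bal <- kr_balance(sc$cm)
  nn <- normalize_by_distance(bal)
  pairs <- enumerate_pairs(sc$gene_set, nn, sc$cm)
  upper_mass <- sum(sc$cm$mat) / 2
  # each covered unordered bin pair contributes at most once per pair, so a
  # generous bound: every pair's count is at most the total upper-tri mass
  expect_true(all(pairs$raw_count <= upper_mass))
  expect_true(all(pairs$strength > 0))
})

test_that("binomial tail matches the exact-enumeration oracle", {
  expect_equal(binom_tail(0, 100, 0.01), 1)
  expect_equal(binom_tail(5, 100, 0.01), 0.003432322, tolerance = 1e-6)
  expect_equal(binom_tail(5, 100, 0.01),
               oracle_binom_tail(5, 100, 0.01), tolerance = 1e-12)
  expect_error(binom_tail(1, 0, 0.1), "positive")
})

test_that("significance_test is calibrated: smaller p for planted pairs,
           p = 1 at k = 0", {
  sc <- simulate_scenario(small_params())
  bal <- kr_balance(sc$cm)
  nn <- normalize_by_distance(bal)
  pairs <- enumerate_pairs(sc$gene_set, nn, sc$cm)
  pairs <- significance_test(pairs, sc$cm, bias = bal$bias)
  expect_true(all(pairs$p_value >= 0 & pairs$p_value <= 1))
  planted <- pair_key(pairs$gene_x, pairs$gene_y) %in%
    pair_key(sc$truth$planted_pairs$hub, sc$truth$planted_pairs$target)
  expect_gt(sum(planted), 0)
  expect_lt(median(pairs$p_value[planted]),
            median(pairs$p_value[!planted]))
})

test_that("BH filter applies the closed-form step-up jointly", {
  pairs <- data.frame(gene_x = c("a", "b"), gene_y = c("c", "d"),
                      p_value = c(0.0001, 0.5))
  flt <- fdr_filter(pairs, threshold = 0.001)
  expect_equal(flt$gene_x, "a")
  expect_equal(flt$q_value, 0.0002)          # 2 * 0.0001 / 1
  all_one <- data.frame(gene_x = "a", gene_y = "b", p_value = 1)
  expect_equal(nrow(fdr_filter(all_one)), 0L)
  expect_equal(nrow(fdr_filter(pairs, threshold = 1.0)), 2L)
  expect_equal(nrow(fdr_filter(pairs[0, ])), 0L)
})

test_that("build_network assembles class-labelled weighted graphs", {
  gs <- tiny_gene_set()
  pairs <- data.frame(
    gene_x = c("LINC_A", "LINC_A", "LINC_B"),
    gene_y = c("PCG_C", "PCG_D", "PCG_C"),
    strength = c(2, 3, 4), raw_count = c(20, 30, 40),
    distance = c(1e5, 2e5, 3e5), p_value = c(1e-9, 1e-8, 1e-7),
    q_value = c(1e-6, 1e-6, 1e-6), stringsAsFactors = FALSE)
  g <- build_network(pairs, gs)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_true(all(igraph::E(g)$weight > 0))
  expect_equal(sort(unique(igraph::V(g)$gene_class)),
               c("lincRNA", "protein_coding"))
  expect_error(build_network(rbind(pairs, pairs[1, ]), gs), "duplicate")
  g_iso <- build_network(pairs[1:2, ], gs, include_isolated = TRUE)
  expect_equal(igraph::vcount(g_iso), 4L)
  expect_equal(igraph::degree(g_iso)[["LINC_B"]], 0)
})

test_that("network edge lists round-trip to TSV with class annotations", {
  sc <- simulate_scenario(small_params())
  net <- build_scenario_network(sc)
  f <- tempfile()
  write_network_tsv(net$graph, f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(df), igraph::ecount(net$graph))
  expect_true(all(c("gene_x", "gene_y", "class_x", "class_y", "strength",
                    "raw_count", "q_value") %in% names(df)))
})
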