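# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately avoid the code paths they check.

# --- tiny annotation -------------------------------------------------------

tiny_gene_set <- function() {
  rec <- data.frame(
    gene_id = c("LINC_A", "LINC_B", "PCG_C", "PCG_D"),
    name = c("lincA", "lincB", "geneC", "geneD"),
    chrom = "chrT",
    start = c(10000, 200000, 400000, 600000),
    end = c(60000, 260000, 450000, 640000),
    strand = c("+", "-", "+", "-"),
    gene_class = c("lincRNA", "lincRNA", "protein_coding",
                   "protein_coding"),
    stringsAsFactors = FALSE)
  gene_set(rec, c(chrT = 1e6))
}

# small scenario shared by module tests (200 bins, a few genes)
small_params <- function(seed = 7, ...) {
  simulation_params(chrom_len = 4e6, resolution = 2e4, n_linc = 15,
                    n_protein = 35, n_hubs = 3, targets_per_hub = 5,
                    hub_distance_bins = c(10, 100), seed = seed, ...)
}

# --- independent oracles ---------------------------------------------------

# exact binomial upper tail by term-wise summation (choose-based, not pbinom)
oracle_binom_tail <- function(k, size, q) {
  if (k <= 0) return(1)
  j <- k:size
  sum(exp(lchoose(size, j) + j * log(q) + (size - j) * log1p(-q)))
}

# exact hypergeometric upper tail by pmf enumeration (choose-based)
oracle_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# closed-form BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# average precision of a ranking (ties broken by a pre-shuffled index so the
# comparison is fair for both score vectors)
average_precision <- function(score, label, tie_break) {
  o <- order(score, tie_break, decreasing = TRUE)
  lab <- label[o]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec * lab) / sum(lab)
}

# unordered gene-pair keys
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# --- matrix helpers --------------------------------------------------------

# flat-base matrix with planted multiplicative biases and Poisson noise
biased_poisson_matrix <- function(n, base = 10, sigma = 0.4, seed = 1) {
  set.seed(seed)
  b <- rlnorm(n, 0, sigma)
  mu <- base * outer(b, b)
  A <- matrix(rpois(n * n, mu), n, n)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  list(cm = contact_matrix(A, "chrX", 2e4), bias = b)
}

# run the network-construction stages on a simulated scenario
build_scenario_network <- function(sc) {
  bal <- kr_balance(sc$cm)
  norm <- normalize_by_distance(bal)
  pairs <- enumerate_pairs(sc$gene_set, norm, sc$cm)
  pairs <- significance_test(pairs, sc$cm, bias = bal$bias)
  flt <- fdr_filter(pairs)
  list(bal = bal, norm = norm, pairs = pairs, filtered = flt,
       graph = build_network(flt, sc$gene_set))
}
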