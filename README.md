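# lincnet

Long intergenic non-coding RNAs (lincRNAs) are transcribed far from
protein-coding genes, yet in the three-dimensional folding of the genome
their loci sit in physical contact with many promoters. `lincnet` builds
that contact landscape into an analysable object: starting from an
intra-chromosomal Hi-C contact matrix and a GENCODE-style annotation, it
constructs an undirected, weighted **lincRNA–protein-coding gene interaction
network**, denoises it, and profiles its topology and the epigenomic state
of the promoters that lincRNAs touch. It is aimed at regulatory genomicists
who want to nominate hub lincRNAs and their targets (e.g. candidate disease
biomarkers) from chromatin-conformation data.

## The model

For each chromosome, with bins of fixed size:

1. **Balancing.** The raw count matrix *M* is normalized with Knight–Ruiz
   matrix balancing: find *x* > 0 with diag(*x*) *M* diag(*x*) doubly
   stochastic, removing multiplicative per-bin biases (the inverse scale
   factors are the bias estimates `b`).
2. **Distance normalization.** For every bin distance *d*, the expected
   intensity is `E_d = N/n`, where *n* is the number of positional bin
   pairs at distance *d* and *N* the sum of observed values there; every
   entry is divided by the `E_d` of its distance, giving observed/expected
   values whose per-distance mean is exactly 1.
3. **Aggregation.** A lincRNA enters as its full gene body *X*, a
   protein-coding gene as its promoter *Y* (2 kb upstream to 0.5 kb
   downstream of the TSS). The pair's interaction strength is
   `M_X,Y = Σ m_ij (i ∈ X, j ∈ Y)` over normalized entries.
4. **Significance.** Each pair's raw count *k* is tested against a
   distance-stratified binomial null, `p = Pr[X ≥ k]`,
   `X ~ Binomial(T, q)`, with *T* the total intra-chromosomal read count
   and *q* the summed raw distance expectation of the covered bin pairs,
   refined by the KR bias product (the fit-HiC idea without spline
   smoothing). Pairs are filtered at Benjamini–Hochberg FDR ≤ 0.001.
5. **Enhancement.** The surviving weighted network is denoised by network
   enhancement: a k-NN-localized, doubly stochastic operator *T* is
   diffused as `W ← α T W T' + (1−α) T` until convergence.
6. **Analysis.** Topology summaries (degree, path lengths, diameter,
   clustering, centralities), lincRNA-vs-protein-coding degree comparison,
   degree-ranked biomarker candidates, sub-network extraction,
   hypergeometric gene-set over-representation of top-degree genes, and
   promoter profiling (R-loop target classification from DRIP-seq peaks,
   TSS metaprofiles, per-promoter peak counts).

A seeded generator (`simulate_scenario()`) produces the whole input bundle
— annotation, Hi-C counts with power-law decay, lognormal bin biases and
planted hub lincRNAs, coverage/peak tracks with planted promoter signal,
and gene sets — together with the ground truth, so every stage can be
validated end to end.

## Worked example

```r
library(lincnet)

params <- simulation_params(seed = 42)        # 20 Mb @ 20 kb, 200 genes,
sc     <- simulate_scenario(params)           # 10 planted hub lincRNAs

balanced   <- kr_balance(sc$cm)
normalized <- normalize_by_distance(balanced)
pairs      <- enumerate_pairs(sc$gene_set, normalized, sc$cm)
pairs      <- significance_test(pairs, sc$cm, bias = balanced$bias)
network    <- build_network(fdr_filter(pairs, threshold = 0.001),
                            sc$gene_set)

summarize_topology(network)
#> TopologySummary: 111 nodes, 170 edges, 1 component(s)
#>   diameter (largest comp.): 8
#>   mean degree: 3.06   mean clustering: 0.0176

compare_degree_by_class(network)
#> Student's t-test, degree: lincRNA mean = 14.64 (n=11) vs
#>   protein_coding mean = 1.79 (n=100)
#>   t = 21.13, p = 2.389e-40

rank_by_degree(network, top_k = 5)[, c("gene_id", "gene_class", "degree")]
#>    gene_id gene_class degree
#> 1 LINC0015    lincRNA     20
#> 2 LINC0029    lincRNA     17
#> 3 LINC0011    lincRNA     16
#> 4 LINC0058    lincRNA     16
#> 5 LINC0028    lincRNA     16
```

The 170 surviving edges are dominated by the planted hub lincRNAs: the
degree ranking is headed exclusively by lincRNAs (all ten planted hubs land
in the top ten), and the class comparison shows the lincRNA-over-protein
degree excess the network is designed to expose. `run_pipeline(config)`
performs the same stages (plus enhancement, enrichment and promoter
signals) from a YAML/list config and writes a checksummed artifact
manifest.

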