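---
title: "lincnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `lincnet` computes, why the defaults are what
they are, and what the synthetic validation scenario does and does not
demonstrate. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The statistical model

### Coordinates and elements

All internal coordinates are 0-based half-open; GTF is converted on read
and write, BED passes through unchanged. A single convention end to end is
the cheapest insurance against off-by-one drift between annotation,
bins and peak overlaps.

The network element of a **lincRNA** is its full gene body; the element of
a **protein-coding gene** is its promoter, the strand-aware window 2 kb
upstream to 0.5 kb downstream of the TSS. The asymmetry mirrors the
biology being probed: the question is whether transcription across a
lincRNA locus places that locus near the regulatory ends of coding genes.
For lincRNA–lincRNA pairs, body–body aggregation is used so that all three
pair classes (lincRNA–lincRNA, promoter–promoter, cross) are defined.
Genes are treated at gene level with a single TSS (the 5' gene end);
isoform-resolved promoters are out of scope.

### Matrix normalization

Knight–Ruiz balancing finds `x > 0` with `diag(x) M diag(x)` doubly
stochastic. The implementation is the inner–outer Newton iteration with a
conjugate-gradient inner solve; if the Newton residual stalls for 50 outer
steps (which can happen on awkward sparsity patterns) a damped symmetric
Sinkhorn iteration takes over, guaranteeing termination behaviour.
Zero-marginal bins are masked before balancing (KR is undefined on empty
rows); `mask_quantile` can additionally mask the sparsest covered bins.
The balanced matrix is rescaled to the input's total mass so that
downstream sums stay on the count scale, and the per-bin multiplicative
bias estimate `b = (1/x) / mean(1/x)` is retained.

The distance expectation is computed **after** balancing (the pipeline
order is balance, then expectation, then divide, then aggregate). The
alternative — expectation on raw counts — would mix bias removal and decay
removal in one step; doing them in sequence keeps each correction
interpretable and testable on its own. `E_d = N/n` counts *all* positional
bin pairs at distance `d`, zeros included, which makes the per-stratum
mean of the normalized matrix exactly 1 — an identity the tests assert at
1e-9. The diagonal (`d = 0`) is excluded throughout: self-bin counts are
dominated by unligated artifacts and no gene pair spans them meaningfully.
Only intra-chromosomal matrices are handled; trans contacts have no
defined distance and are out of scope.

### Pair significance

The pair filter is a distance-stratified binomial test in the fit-HiC
spirit, not a wrapper around an external caller. For a pair with raw count
`k` covering bin pairs `C`:

    p = Pr[X >= k],  X ~ Binomial(T, q),
    q = (1/T) * sum_{(i,j) in C} E_d(i,j)^raw * b_i b_j / m_d

where `T` is the total intra-chromosomal read count, `E^raw` the raw-count
distance expectation and `m_d` the per-distance mean of the bias product.
The bias factor matters: per-bin coverage biases are multiplicative, so a
purely distance-based null is anti-conservative exactly at high-bias bins,
and in a scenario with lognormal biases (sigma 0.4) and no planted signal
the uncorrected test calls about 1% of pairs significant at FDR 0.001,
while the bias-refined null stays at effectively zero. Setting
`bias = NULL` recovers the plain stratified null. BH adjustment is
computed jointly over all enumerated pairs (a single network is being
filtered; per-chromosome correction would be less conservative), and
pairs above FDR 0.001 are removed.

Overlapping elements (a promoter inside another gene's body) contribute
their shared bin pairs to both pairs independently: the aggregation is a
pure sum over index sets, with no exclusivity rule.

### Network enhancement

Edge weights entering the diffusion are raw interaction counts (the
convention for this denoiser). The operator is the k-NN-localized weight
matrix — entry kept iff either endpoint ranks the other in its top *k*,
rows rescaled, symmetrized — made doubly stochastic by symmetric Sinkhorn
scaling. The second-order update

    W_{t+1} = alpha * T W_t T' + (1 - alpha) * T

contracts geometrically at rate about `alpha`, so with `alpha = 0.9` and
`tol = 1e-8` roughly 175 iterations are needed; the default `max_iter` is
200 for that reason. Where the published method leaves output scaling
open, total-mass preservation is imposed so pre/post degree statistics
remain comparable, and enhanced entries below 1e-6 of the maximum are
dropped because diffusion densifies the graph and a floor keeps topology
metrics meaningful. Non-convergence returns the last iterate with a
warning and a flag rather than failing the pipeline.

### Topology, enrichment, signals

Path statistics and the diameter are computed on the unweighted skeleton
(path lengths are reported as integer edge counts); on disconnected graphs
they refer to the largest component, with the component count reported.
Betweenness is exact up to 2,000 nodes and switches to a bounded-path
(cutoff 6) approximation above that. Degree ranking breaks ties by total
incident weight, then lexicographic gene id, so rankings are
reproducible.

Enrichment is a hypergeometric upper tail of the top-degree query inside
`background ∪ query`, where the background is a seeded, without-replacement
sample from the supplied universe (the full annotation's gene list; the
union means query genes are never excluded from their own universe). The
module is generic over flat GMT sets; ontology ancestor propagation is the
caller's responsibility.

Promoter signal analysis consumes already-normalized coverage and called
peaks (alignment and peak calling are published-tool territory). The
overlap rule everywhere is at least 1 bp on half-open intervals,
strand-ignorant for peaks; an interval abutting a promoter boundary does
not overlap it. R-loop targets are protein-coding genes with at least one
lincRNA network neighbour **and** a promoter peak; the complement is all
remaining protein-coding genes in the annotation (not expression-matched
controls — a deliberate simplification). TSS metaprofiles default to a
2 kb flank with 50 bp bins, strand-oriented so upstream is negative.

## 2. The synthetic scenario

`simulate_scenario()` emulates the input bundle the pipeline expects. The
reference conditions: a 20 Mb chromosome at 20 kb resolution (1,000 bins),
60 lincRNA and 140 protein-coding genes with uniform lengths 5–60 kb
placed without overlap, contact decay `d^-1`, lognormal per-bin biases
(sigma 0.4), Poisson counts, 10 hub lincRNAs with 15 protein-coding
targets each boosted 5-fold, hub-target distances restricted to 10–200
bins so that recovery is driven by distance normalization rather than
proximity, and R-loop coverage bumps (Gaussian, height 3, sigma 300 bp,
on a |N(0.2, 0.05)| baseline) on 80% of unique hub targets with matching
peak intervals.

`base_intensity = 300` expected counts per adjacent bin pair corresponds
to a deeply sequenced library at this resolution and was fixed once, by a
design-time power calculation: at 5-fold enrichment and the planted
distance band, it puts most planted pairs comfortably past a
genome-wide-style FDR threshold while leaving null pairs unremarkable.
The null-calibration harness (`simulate_null_pairs`) draws pair counts by
Poisson thinning of the distance-decay expectation itself at depth 3000
and distances 10–50 bins; the depth is chosen so expected counts are in
the hundreds, which makes the exact binomial p-values effectively
continuous — the precondition for comparing them to U(0,1) with a KS
test. Counts are Poisson rather than negative binomial for analytic
tractability of that null; an overdispersion knob is a non-goal.

What passing these tests shows: the normalization identities hold, the
significance machinery is calibrated against its own null, planted
structure of realistic effect size is recovered, and the stages compose
deterministically. What it does not show: robustness to
overdispersion, TAD/loop-level structure, trans contacts, annotation
errors, or the scale of a real genome (a real run has ~25,000 genes and
hundreds of thousands of edges; the topology code paths are the same but
runtimes are not).

## 3. Numerical and degenerate-input choices

- KR convergence is declared on the max row-sum residual (`tol = 1e-6`
  relative to the common target); the Newton solve is capped by
  matrix-vector products (`max_iter = 3000`) before falling back.
- Duplicate COO entries are summed and mirrored; a negative count or an
  out-of-range bin index is an error naming the offending row; an empty
  contacts file yields an all-zero matrix with a warning.
- `significance_test` errors when the total read count is zero; a pair
  with `k = 0` gets `p = 1` exactly.
- Empty promoter windows after chromosome-edge clipping are an error
  naming the gene; clipped promoters still contain their TSS.
- Co-binned element pairs (identical bin sets) are skipped — their cis
  contacts are undefined under the no-diagonal rule.
- `compare_groups` on two constant identical groups reports statistic 0,
  p = 1 instead of erroring; groups of fewer than 2 values are refused.
- Ranking ties and the enrichment background are the only places the
  analysis stages consume randomness, and both are seeded; sampling
  inside `summarize_topology` saves and restores the caller's RNG state.

## 4. Known limitations

- fit-HiC2's spline smoothing of the distance expectation and its
  refinement iterations are not implemented; the empirical stratified
  expectation is used directly. On sparse strata this is noisier than a
  smoothed fit.
- The FDR is controlled per matrix (per chromosome in real data), jointly
  over all enumerated pairs of that matrix; multi-chromosome runs
  currently concatenate per-chromosome results upstream of the filter
  only if the caller does so explicitly.
- The enhancement operator treats isolated nodes as fixed points; very
  small components (< k neighbours) are localized trivially and their
  weights only rescale.
- bigWig output is not written (bedGraph only); `.hic`/cooler binary
  parsing and ICE normalization are out of scope.
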