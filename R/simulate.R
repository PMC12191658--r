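# length-safe sample(): never falls into sample()'s scalar-x surprise
sample_safe <- function(x, size, replace = FALSE, prob = NULL) {
  if (size == 0L) return(x[integer(0)])
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Seeded synthetic-data generator. Produces an annotation, a Hi-C contact
# matrix with power-law distance decay, multiplicative per-bin biases and
# planted lincRNA-hub contact enrichment, plus peak/coverage tracks and gene
# sets with planted promoter signal - all with recorded ground truth so each
# pipeline stage can be validated against what was planted.

#' Parameters for the synthetic scenario
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: a 20 Mb chromosome binned at 20 kb, 60 lincRNA and 140
#' protein-coding genes, power-law contact decay with exponent 1, lognormal
#' per-bin biases (sigma 0.4), 10 planted hub lincRNAs with 15 targets each
#' at 5-fold contact enrichment, and R-loop signal on 80\% of hub targets.
#'
#' @param chrom_len chromosome length in bp.
#' @param resolution Hi-C bin size in bp.
#' @param n_linc,n_protein gene counts per class.
#' @param decay_alpha power-law exponent of contact decay with bin distance.
#' @param base_intensity expected raw count of an adjacent, bias-free bin
#'   pair (sequencing depth knob; 300 emulates a deeply sequenced library).
#' @param bias_sigma lognormal sigma of per-bin multiplicative biases.
#' @param n_hubs planted hub lincRNAs.
#' @param targets_per_hub protein-coding targets per hub.
#' @param hub_enrichment multiplicative contact boost (lambda) on planted
#'   hub-target bin pairs; 1 disables planting (null scenario).
#' @param rloop_fraction fraction of unique hub targets given a promoter
#'   R-loop bump.
#' @param hub_distance_bins admissible hub-target distance range (bins), so
#'   detection is driven by distance-normalized enrichment, not proximity.
#' @param gene_length_range gene length range in bp (uniform).
#' @param upstream,downstream promoter window in bp.
#' @param seed root RNG seed; each generator derives its own stream from it.
#' @return list of class \code{SimulationParams}.
#' @export
simulation_params <- function(chrom_len = 2e7, resolution = 2e4,
                              n_linc = 60, n_protein = 140,
                              decay_alpha = 1.0, base_intensity = 300,
                              bias_sigma = 0.4, n_hubs = 10,
                              targets_per_hub = 15, hub_enrichment = 5.0,
                              rloop_fraction = 0.8,
                              hub_distance_bins = c(10, 200),
                              gene_length_range = c(5e3, 6e4),
                              upstream = 2000, downstream = 500, seed = 1) {
  p <- list(chrom = "chrS", chrom_len = chrom_len, resolution = resolution,
            n_linc = n_linc, n_protein = n_protein,
            decay_alpha = decay_alpha, base_intensity = base_intensity,
            bias_sigma = bias_sigma, n_hubs = n_hubs,
            targets_per_hub = targets_per_hub,
            hub_enrichment = hub_enrichment,
            rloop_fraction = rloop_fraction,
            hub_distance_bins = hub_distance_bins,
            gene_length_range = gene_length_range,
            upstream = upstream, downstream = downstream, seed = seed)
  stopifnot(p$chrom_len > 0, p$resolution > 0, p$n_linc >= 0,
            p$n_protein >= 0, p$base_intensity > 0, p$bias_sigma >= 0,
            p$n_hubs >= 0, p$targets_per_hub >= 0, p$hub_enrichment >= 1,
            p$rloop_fraction >= 0, p$rloop_fraction <= 1)
  structure(p, class = "SimulationParams")
}

#' Simulate the gene annotation
#'
#' Places \code{n_linc + n_protein} non-overlapping genes along the
#' chromosome with uniform lengths, random strands and shuffled class labels
#' at the requested proportions.
#'
#' @param params \code{\link{simulation_params}}.
#' @return a \code{GeneSet}.
#' @export
simulate_genome <- function(params) {
  if (params$n_linc == 0L || params$n_protein == 0L)
    stop("both gene classes are required (n_linc and n_protein > 0)")
  set.seed(params$seed)
  n <- params$n_linc + params$n_protein
  len <- round(runif(n, params$gene_length_range[1],
                     params$gene_length_range[2]))
  free <- params$chrom_len - sum(len)
  if (free <= n)
    stop("chromosome too short for the requested genes")
  gaps <- runif(n + 1)
  gaps <- floor(gaps / sum(gaps) * free)
  start <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(len[seq_len(n - 1L)]))
  classes <- sample(c(rep("lincRNA", params$n_linc),
                      rep("protein_coding", params$n_protein)))
  ids <- character(n)
  ids[classes == "lincRNA"] <-
    sprintf("LINC%04d", seq_len(params$n_linc))
  ids[classes == "protein_coding"] <-
    sprintf("PCG%04d", seq_len(params$n_protein))
  rec <- data.frame(gene_id = ids, name = ids, chrom = params$chrom,
                    start = start, end = start + len,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    gene_class = classes, stringsAsFactors = FALSE)
  gene_set(rec, setNames(params$chrom_len, params$chrom))
}

#' Simulate a raw Hi-C contact matrix with planted hubs
#'
#' Expected counts for bins \code{i < j} are
#' \deqn{\mu_{ij} = base \cdot |i-j|^{-\alpha} \cdot b_i b_j
#'       \cdot (1 + (\lambda - 1) H_{ij})}
#' with lognormal biases \code{b} and \code{H} the indicator of planted
#' hub-body x target-promoter bin pairs; observed counts are Poisson.
#' Hub targets are drawn at mid-range bin distances
#' (\code{hub_distance_bins}) so that detection exercises the distance
#' normalization rather than linear proximity.
#'
#' @param gs \code{GeneSet} from \code{\link{simulate_genome}}.
#' @param params \code{\link{simulation_params}}.
#' @return list: \code{cm} (raw \code{ContactMatrix}) and \code{truth}
#'   (hub gene ids, planted hub-target gene pairs, per-bin bias vector).
#' @export
simulate_hic <- function(gs, params) {
  set.seed(params$seed + 1L)
  nb <- as.integer(ceiling(params$chrom_len / params$resolution))
  b <- rlnorm(nb, 0, params$bias_sigma)
  el <- gene_elements(gs, params$resolution, chrom = params$chrom,
                      upstream = params$upstream,
                      downstream = params$downstream)
  linc <- el[el$gene_class == "lincRNA", , drop = FALSE]
  prot <- el[el$gene_class == "protein_coding", , drop = FALSE]
  hubs <- character(0)
  planted <- data.frame(hub = character(0), target = character(0),
                        distance_bins = numeric(0))
  Hkey <- numeric(0)
  if (params$n_hubs > 0 && params$hub_enrichment > 1) {
    hubs <- sort(sample(linc$gene_id, min(params$n_hubs, nrow(linc))))
    mid_bin <- function(e) floor(e$mid / params$resolution)
    linc_mid <- mid_bin(linc); prot_mid <- mid_bin(prot)
    for (h in hubs) {
      hrow <- which(linc$gene_id == h)
      dd <- abs(prot_mid - linc_mid[hrow])
      cand <- which(dd >= params$hub_distance_bins[1] &
                    dd <= params$hub_distance_bins[2])
      if (length(cand) == 0L) next
      tgt <- sample_safe(cand, min(params$targets_per_hub, length(cand)))
      for (t in tgt) {
        planted <- rbind(planted, data.frame(
          hub = h, target = prot$gene_id[t], distance_bins = dd[t],
          stringsAsFactors = FALSE))
        cp <- covered_bin_pairs(linc$bins[[hrow]], prot$bins[[t]])
        Hkey <- c(Hkey, cp[, 1L] * nb + cp[, 2L])
      }
    }
    Hkey <- unique(Hkey)
  }
  # all upper-triangle bin pairs, by distance
  d_seq <- seq_len(nb - 1L)
  i_all <- unlist(lapply(d_seq, function(d) seq_len(nb - d)))  # 1-based
  j_all <- unlist(lapply(d_seq, function(d) seq_len(nb - d) + d))
  d_all <- j_all - i_all
  mu <- params$base_intensity * d_all^(-params$decay_alpha) *
    b[i_all] * b[j_all]
  if (length(Hkey) > 0) {
    boosted <- ((i_all - 1L) * nb + (j_all - 1L)) %in% Hkey
    mu[boosted] <- mu[boosted] * params$hub_enrichment
  }
  counts <- rpois(length(mu), mu)
  keep <- counts > 0
  m <- Matrix::sparseMatrix(i = c(i_all[keep], j_all[keep]),
                            j = c(j_all[keep], i_all[keep]),
                            x = as.numeric(c(counts[keep], counts[keep])),
                            dims = c(nb, nb))
  cm <- contact_matrix(m, params$chrom, params$resolution, stage = "raw")
  list(cm = cm,
       truth = list(hubs = hubs, planted_pairs = planted, bias = b))
}

#' Simulate promoter signal tracks and gene sets
#'
#' Emits (in memory, optionally to files via
#' \code{\link{simulate_scenario}}):
#' \itemize{
#'   \item a coverage track: baseline noise \code{|N(0.2, 0.05)|} genome-wide
#'     (2 kb windows away from promoters, 50 bp bins across every
#'     protein-coding promoter region), plus a Gaussian bump (height 3,
#'     sigma 300 bp, centred on the TSS) on R-loop-positive promoters;
#'   \item matching R-loop peak intervals (TSS +/- 450 bp);
#'   \item a gene-set collection with one planted term (hub genes plus
#'     frequently-targeted promoters plus decoys) and random decoy terms.
#' }
#'
#' @param gs \code{GeneSet}.
#' @param truth truth list from \code{\link{simulate_hic}}.
#' @param params \code{\link{simulation_params}}.
#' @return list: \code{coverage} (GRanges with score), \code{peaks}
#'   (GRanges), \code{gmt} (list), and updated \code{truth} gaining
#'   \code{rloop_genes} and \code{planted_term}.
#' @export
simulate_tracks <- function(gs, truth, params) {
  set.seed(params$seed + 2L)
  targets <- unique(truth$planted_pairs$target)
  n_pos <- round(params$rloop_fraction * length(targets))
  rloop_pos <- sort(sample_safe(targets, n_pos))
  r <- gs$records
  pc <- r[r$gene_class == "protein_coding", , drop = FALSE]
  fine_flank <- 2500L
  binw <- 50L
  # fine 50-bp bins across every protein-coding promoter neighbourhood
  fine <- do.call(rbind, lapply(seq_len(nrow(pc)), function(k) {
    tss <- pc$tss[k]
    s <- seq(max(0, tss - fine_flank), tss + fine_flank - binw, by = binw)
    centre <- s + binw / 2
    val <- abs(rnorm(length(s), 0.2, 0.05))
    if (pc$gene_id[k] %in% rloop_pos)
      val <- val + 3 * exp(-(centre - tss)^2 / (2 * 300^2))
    data.frame(start = s, end = s + binw, value = val)
  }))
  coarse_starts <- seq(0, params$chrom_len - 2000L, by = 2000L)
  coarse <- data.frame(start = coarse_starts, end = coarse_starts + 2000L,
                       value = abs(rnorm(length(coarse_starts), 0.2, 0.05)))
  fine_ir <- IRanges::IRanges(fine$start + 1L, fine$end)
  coarse_ir <- IRanges::IRanges(coarse$start + 1L, coarse$end)
  hit <- IRanges::overlapsAny(coarse_ir, fine_ir)
  track <- rbind(coarse[!hit, , drop = FALSE], fine)
  track <- track[order(track$start), , drop = FALSE]
  coverage <- GenomicRanges::GRanges(
    seqnames = params$chrom,
    ranges = IRanges::IRanges(track$start + 1L, track$end),
    score = track$value)
  peaks <- if (n_pos > 0) {
    tss <- pc$tss[match(rloop_pos, pc$gene_id)]
    GenomicRanges::GRanges(
      seqnames = params$chrom,
      ranges = IRanges::IRanges(pmax(0, tss - 450L) + 1L, tss + 450L),
      name = paste0("rloop_", rloop_pos))
  } else {
    GenomicRanges::GRanges()
  }
  # planted term: hubs + frequently-targeted promoters + decoys
  tab <- table(truth$planted_pairs$target)
  wt <- as.numeric(tab[targets])
  n_tgt_members <- min(30L, length(targets))
  members <- c(truth$hubs,
               sample_safe(targets, n_tgt_members, prob = wt),
               sample_safe(setdiff(r$gene_id, c(truth$hubs, targets)), 10L))
  gmt <- list(PLANTED_HUB_TERM = list(
    name = "planted hub-derived gene set", genes = unique(members)))
  for (k in seq_len(20L)) {
    gmt[[sprintf("RANDOM_TERM_%03d", k)]] <-
      list(name = sprintf("random decoy set %d", k),
           genes = sample(r$gene_id, 50L))
  }
  truth$rloop_genes <- rloop_pos
  truth$planted_term <- list(id = "PLANTED_HUB_TERM",
                             genes = gmt$PLANTED_HUB_TERM$genes)
  list(coverage = coverage, peaks = peaks, gmt = gmt, truth = truth)
}

#' Generate the full synthetic scenario
#'
#' Runs \code{\link{simulate_genome}}, \code{\link{simulate_hic}} and
#' \code{\link{simulate_tracks}} off a single root seed and, when
#' \code{outdir} is given, writes the standard input files: \code{genes.gtf},
#' \code{chrom.sizes}, \code{contacts.tsv} (COO), \code{coverage.bedGraph},
#' \code{peaks.bed}, \code{genesets.gmt} and \code{truth.json}.
#'
#' @param params \code{\link{simulation_params}}.
#' @param outdir output directory, or \code{NULL} for in-memory only.
#' @return list: \code{gene_set}, \code{cm} (raw contacts), \code{coverage},
#'   \code{peaks}, \code{gmt}, \code{truth}, \code{files} (named paths when
#'   written).
#' @export
simulate_scenario <- function(params = simulation_params(), outdir = NULL) {
  gs <- simulate_genome(params)
  hic <- simulate_hic(gs, params)
  trk <- simulate_tracks(gs, hic$truth, params)
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(gtf = file.path(outdir, "genes.gtf"),
               chrom_sizes = file.path(outdir, "chrom.sizes"),
               contacts = file.path(outdir, "contacts.tsv"),
               coverage = file.path(outdir, "coverage.bedGraph"),
               peaks = file.path(outdir, "peaks.bed"),
               gmt = file.path(outdir, "genesets.gmt"),
               truth = file.path(outdir, "truth.json"))
    write_gtf(gs, files[["gtf"]])
    write_chrom_sizes(gs$chrom_sizes, files[["chrom_sizes"]])
    write_contacts(hic$cm, files[["contacts"]])
    cov_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(trk$coverage)),
      start = GenomicRanges::start(trk$coverage) - 1L,
      end = GenomicRanges::end(trk$coverage),
      value = sprintf("%.6g", trk$coverage$score))
    write.table(cov_df, files[["coverage"]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    if (length(trk$peaks) > 0) {
      peak_df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(trk$peaks)),
        start = GenomicRanges::start(trk$peaks) - 1L,
        end = GenomicRanges::end(trk$peaks),
        name = trk$peaks$name)
      write.table(peak_df, files[["peaks"]], sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    } else {
      file.create(files[["peaks"]])
    }
    write_gmt(trk$gmt, files[["gmt"]])
    jsonlite::write_json(trk$truth, files[["truth"]], auto_unbox = TRUE,
                         digits = NA)
  }
  list(gene_set = gs, cm = hic$cm, coverage = trk$coverage,
       peaks = trk$peaks, gmt = trk$gmt, truth = trk$truth, files = files)
}

#' Null pair counts by Poisson thinning of expected values
#'
#' Calibration harness for the significance test: draws gene-pair style
#' counts directly from the distance-decay null (no biases, no planted
#' enrichment), i.e. \code{k ~ Poisson(mu)} with
#' \code{mu = n_bin_pairs * depth / d} summed over a pair's covered bin
#' pairs, and evaluates the upper-tail binomial p-value at the matching null
#' probability \code{q = mu / T}. Distances are drawn from a mid-range band
#' and the depth emulates a deeply sequenced library so that expected counts
#' are large enough for the discrete p-values to be effectively continuous.
#'
#' @param n_pairs number of null pairs (default 2000).
#' @param depth expected count of an adjacent bin pair (default 3000).
#' @param d_range distance band in bins (default 10-50).
#' @param bin_pairs_range covered-bin-pair count range per pair (default
#'   2-6).
#' @param total total read count T (default 5e7).
#' @param seed RNG seed.
#' @return data.frame: \code{d}, \code{n_bin_pairs}, \code{mu}, \code{k},
#'   \code{q}, \code{p_value}.
#' @export
simulate_null_pairs <- function(n_pairs = 2000, depth = 3000,
                                d_range = c(10, 50),
                                bin_pairs_range = c(2, 6), total = 5e7,
                                seed = 1) {
  set.seed(seed)
  d <- sample(seq(d_range[1], d_range[2]), n_pairs, replace = TRUE)
  nbp <- sample(seq(bin_pairs_range[1], bin_pairs_range[2]), n_pairs,
                replace = TRUE)
  mu <- nbp * depth / d
  k <- rpois(n_pairs, mu)
  q <- mu / total
  data.frame(d = d, n_bin_pairs = nbp, mu = mu, k = k, q = q,
             p_value = binom_tail(k, total, q))
}

#' Planted two-community weighted network
#'
#' Fixture for denoising checks: two equal blocks; within-block edges appear
#' with probability \code{p_within} and weight \code{U(1, 2)}, cross-block
#' noise edges with probability \code{p_cross} and weight \code{U(0, 0.5)}.
#' The ground truth labels every within-block pair as planted.
#'
#' @param n nodes (even; default 60).
#' @param p_within,p_cross edge probabilities.
#' @param w_within,w_cross weight ranges.
#' @param seed RNG seed.
#' @return list: \code{W} (symmetric weight matrix, zero diagonal),
#'   \code{within} (logical matrix marking within-community pairs).
#' @export
simulate_community_network <- function(n = 60, p_within = 0.3,
                                       p_cross = 0.05,
                                       w_within = c(1, 2),
                                       w_cross = c(0, 0.5), seed = 1) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  block <- rep(c(1L, 2L), each = n / 2)
  W <- matrix(0, n, n)
  within <- outer(block, block, "==")
  diag(within) <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (within[i, j]) {
        if (runif(1) < p_within)
          W[i, j] <- W[j, i] <- runif(1, w_within[1], w_within[2])
      } else if (runif(1) < p_cross) {
        W[i, j] <- W[j, i] <- runif(1, w_cross[1], w_cross[2])
      }
    }
  }
  list(W = W, within = within, block = block)
}
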