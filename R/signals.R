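# Promoter epigenomic profiling: TSS-centred coverage metaprofiles, R-loop
# target classification from network + peaks, per-promoter peak counting,
# and two-group comparisons.
#
# Overlap rule everywhere: >= 1 bp on half-open intervals, strand-ignorant
# for peaks. BED/bedGraph input goes through rtracklayer.

#' Read a bedGraph coverage track
#' @param path bedGraph file (chrom, start, end, value).
#' @return \code{GRanges} with a \code{score} column.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Read a BED peak file
#'
#' 3-6 column BED; column 4, when present, is the peak/TF name (TF ChIP
#' catalogs put the factor name there).
#'
#' @param path BED file.
#' @return \code{GRanges} (with \code{name} metadata when present).
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

# GRanges for promoter intervals (internal 0-based half-open -> 1-based)
promoter_granges <- function(promoters) {
  GenomicRanges::GRanges(
    seqnames = promoters$chrom,
    ranges = IRanges::IRanges(start = promoters$start + 1L,
                              end = promoters$end),
    gene_id = promoters$gene_id)
}

#' TSS-centred coverage metaprofile
#'
#' Per gene, mean coverage in strand-oriented bins over
#' \code{[-flank, +flank)} around the TSS (upstream negative; minus-strand
#' genes are flipped). Genes whose chromosome is absent from the coverage
#' track, or whose window runs off the chromosome, are dropped with a
#' warning.
#'
#' @param coverage \code{GRanges} with \code{score} (see
#'   \code{\link{read_bedgraph}}) or a bedGraph path.
#' @param gs a \code{GeneSet}.
#' @param genes optional gene ids to profile (default: all records).
#' @param flank half-window in bp (default 2000).
#' @param binsize bin width in bp (default 50); must divide \code{2*flank}.
#' @return list of class \code{SignalProfile}: \code{genes},
#'   \code{positions} (bin centres relative to the TSS), \code{matrix}
#'   (genes x positions), \code{aggregate} (per-position mean).
#' @export
tss_profile <- function(coverage, gs, genes = NULL, flank = 2000,
                        binsize = 50) {
  if (is.character(coverage)) coverage <- read_bedgraph(coverage)
  stopifnot(flank > 0, binsize > 0, (2 * flank) %% binsize == 0)
  r <- gs$records
  if (!is.null(genes)) r <- r[r$gene_id %in% genes, , drop = FALSE]
  cov_rle <- GenomicRanges::coverage(coverage, weight = "score")
  have <- r$chrom %in% names(cov_rle)
  inside <- r$tss - flank >= 0 &
    r$tss + flank <= gs$chrom_sizes[r$chrom]
  ok <- have & inside
  if (any(!ok))
    warning("dropping ", sum(!ok), " gene(s): chromosome absent from ",
            "coverage or TSS window outside chromosome")
  r <- r[ok, , drop = FALSE]
  if (nrow(r) == 0L) stop("no genes left to profile")
  nbin <- as.integer(2 * flank / binsize)
  mat <- matrix(NA_real_, nrow = nrow(r), ncol = nbin)
  for (chr in unique(r$chrom)) {
    sel <- which(r$chrom == chr)
    rl <- cov_rle[[chr]]
    chrom_len <- gs$chrom_sizes[[chr]]
    if (length(rl) < chrom_len)  # track may stop early; pad with zeros
      rl <- c(rl, S4Vectors::Rle(0, chrom_len - length(rl)))
    # bin starts, 1-based, for all genes on this chromosome at once
    win_start <- r$tss[sel] - flank + 1L
    starts <- rep(win_start, each = nbin) +
      rep(seq_len(nbin) - 1L, times = length(sel)) * binsize
    v <- IRanges::Views(rl, start = starts, width = binsize)
    means <- IRanges::viewMeans(v)
    mat[sel, ] <- matrix(means, ncol = nbin, byrow = TRUE)
  }
  flip <- r$strand == "-"
  mat[flip, ] <- mat[flip, rev(seq_len(nbin)), drop = FALSE]
  positions <- seq(-flank + binsize / 2, flank - binsize / 2, by = binsize)
  structure(list(genes = r$gene_id, positions = positions, matrix = mat,
                 aggregate = colMeans(mat)),
            class = "SignalProfile")
}

#' Classify protein-coding genes as R-loop targets
#'
#' A protein-coding gene is an R-loop target when (a) it has at least one
#' lincRNA neighbour in the interaction network and (b) its promoter overlaps
#' at least one R-loop peak by >= 1 bp. All remaining protein-coding genes in
#' the annotation form the complement, so the two sets partition the
#' annotation's protein-coding genes.
#'
#' @param g igraph interaction network with \code{gene_class} labels.
#' @param promoters promoter data.frame (\code{\link{derive_promoters}}).
#' @param peaks \code{GRanges} of R-loop (DRIP-seq) peaks, or a BED path.
#' @param gs the \code{GeneSet}.
#' @return list with \code{rloop_genes} and \code{other_genes}.
#' @export
classify_rloop_targets <- function(g, promoters, peaks, gs) {
  if (is.character(peaks)) peaks <- read_bed(peaks)
  pc <- gs$records$gene_id[gs$records$gene_class == "protein_coding"]
  cls <- igraph::V(g)$gene_class
  in_net <- intersect(pc, igraph::V(g)$name)
  has_linc <- vapply(in_net, function(gene) {
    nb <- igraph::neighbors(g, gene)
    any(cls[as.integer(nb)] == "lincRNA")
  }, logical(1))
  linc_partnered <- in_net[has_linc]
  pr <- promoters[promoters$gene_id %in% pc, , drop = FALSE]
  hits <- GenomicRanges::countOverlaps(promoter_granges(pr), peaks,
                                       minoverlap = 1L)
  with_peak <- pr$gene_id[hits > 0]
  rloop <- intersect(linc_partnered, with_peak)
  list(rloop_genes = sort(rloop), other_genes = sort(setdiff(pc, rloop)))
}

#' Count peaks overlapping each promoter
#'
#' Each BED record overlapping a promoter by >= 1 bp counts once (nested or
#' duplicated records each count). \code{tf_filter} restricts the catalog to
#' records whose name column matches a given factor (e.g. \code{"YY1"}).
#'
#' @param peaks \code{GRanges} (name column optional) or BED path.
#' @param promoters promoter data.frame.
#' @param tf_filter factor name to keep, or \code{NULL} for all records.
#' @return named integer vector: gene_id -> peak count.
#' @export
count_peaks_per_promoter <- function(peaks, promoters, tf_filter = NULL) {
  if (is.character(peaks)) peaks <- read_bed(peaks)
  if (!is.null(tf_filter)) {
    nm <- if ("name" %in% names(S4Vectors::mcols(peaks)))
      S4Vectors::mcols(peaks)$name else character(0)
    peaks <- peaks[!is.na(nm) & nm == tf_filter]
    if (length(peaks) == 0L)
      warning("no peaks match tf_filter '", tf_filter,
              "'; all counts are 0")
  }
  counts <- GenomicRanges::countOverlaps(promoter_granges(promoters), peaks,
                                         minoverlap = 1L)
  setNames(as.integer(counts), promoters$gene_id)
}

#' Two-group comparison of signal values
#'
#' Two-sample t-test (pooled-variance Student by default, Welch selectable)
#' with per-group means reported. Identical groups give statistic 0 and
#' p = 1.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @param test \code{"student"} or \code{"welch"}.
#' @param label_a,label_b,what labels carried into the result.
#' @return list of class \code{ClassComparison}: \code{mean_a},
#'   \code{mean_b}, \code{statistic}, \code{p_value}, \code{test_name},
#'   \code{n_a}, \code{n_b}.
#' @export
compare_groups <- function(values_a, values_b, test = c("student", "welch"),
                           label_a = "group_a", label_b = "group_b",
                           what = "signal") {
  test <- match.arg(test)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(c(values_a, values_b)) == 0) {
    stat <- 0; p <- 1
  } else {
    tt <- t.test(values_a, values_b, var.equal = (test == "student"))
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(mean_a = mean(values_a), mean_b = mean(values_b),
                 statistic = stat, p_value = p,
                 test_name = if (test == "student") "Student's t-test"
                             else "Welch's t-test",
                 label_a = label_a, label_b = label_b, what = what,
                 n_a = length(values_a), n_b = length(values_b)),
            class = "ClassComparison")
}

#' @export
print.ClassComparison <- function(x, ...) {
  cat(sprintf("%s, %s: %s mean = %.4g (n=%d) vs %s mean = %.4g (n=%d)\n",
              x$test_name, x$what, x$label_a, x$mean_a, x$n_a,
              x$label_b, x$mean_b, x$n_b))
  cat(sprintf("  t = %.4g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Mean promoter coverage per gene
#'
#' Convenience for group comparisons: mean of the coverage track over each
#' promoter interval.
#'
#' @param coverage \code{GRanges} with \code{score}, or bedGraph path.
#' @param promoters promoter data.frame.
#' @return named numeric vector gene_id -> mean coverage (genes on
#'   chromosomes absent from the track get \code{NA}).
#' @export
promoter_mean_coverage <- function(coverage, promoters) {
  if (is.character(coverage)) coverage <- read_bedgraph(coverage)
  cov_rle <- GenomicRanges::coverage(coverage, weight = "score")
  out <- rep(NA_real_, nrow(promoters))
  for (chr in unique(promoters$chrom)) {
    if (!chr %in% names(cov_rle)) next
    sel <- which(promoters$chrom == chr)
    rl <- cov_rle[[chr]]
    s <- pmax(promoters$start[sel] + 1L, 1L)
    e <- pmin(promoters$end[sel], length(rl))
    keep <- e >= s
    v <- IRanges::Views(rl, start = s[keep], end = e[keep])
    out[sel[keep]] <- IRanges::viewMeans(v)
  }
  setNames(out, promoters$gene_id)
}
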