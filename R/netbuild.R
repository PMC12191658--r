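# Network construction: aggregate normalized contacts into gene-pair
# strengths, distance-stratified binomial significance, BH-FDR filtering,
# and the weighted interaction graph.
#
# The element representing a protein-coding gene is its promoter; the element
# representing a lincRNA is its full gene body. The aggregated strength of a
# pair is the plain sum of normalized contacts over the cross product of the
# two elements' bin sets, diagonal excluded.

#' Element table for network construction
#'
#' Maps every gene of a \code{GeneSet} to the genomic element that enters the
#' network: the full gene body for lincRNAs, the promoter window for
#' protein-coding genes. Each element carries its Hi-C bin set.
#'
#' @param gs a \code{GeneSet}.
#' @param resolution Hi-C bin size in bp.
#' @param chrom restrict to one chromosome (required when the GeneSet spans
#'   several and a single contact matrix is analysed).
#' @param upstream,downstream promoter window (bp) for protein-coding genes.
#' @return data.frame with \code{gene_id}, \code{gene_class}, \code{kind}
#'   (\code{body}/\code{promoter}), \code{start}, \code{end}, \code{mid} and a
#'   list-column \code{bins}.
#' @export
gene_elements <- function(gs, resolution, chrom = NULL,
                          upstream = 2000, downstream = 500) {
  r <- gs$records
  if (!is.null(chrom)) r <- r[r$chrom == chrom, , drop = FALSE]
  if (nrow(r) == 0L) stop("no genes on chromosome ", chrom)
  is_pc <- r$gene_class == "protein_coding"
  start <- r$start; end <- r$end
  if (any(is_pc)) {
    sub <- r[is_pc, , drop = FALSE]
    prom <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i)
      derive_promoter(sub[i, ], upstream, downstream,
                      gs$chrom_sizes[[sub$chrom[i]]])))
    start[is_pc] <- prom$start
    end[is_pc] <- prom$end
  }
  data.frame(gene_id = r$gene_id, gene_class = r$gene_class,
             kind = ifelse(is_pc, "promoter", "body"),
             chrom = r$chrom, start = start, end = end,
             mid = (start + end) / 2,
             bins = I(lapply(seq_along(start), function(i)
               map_to_bins(start[i], end[i], resolution))),
             stringsAsFactors = FALSE)
}

#' Aggregated interaction strength between two bin sets
#'
#' Sum of matrix values over \code{bins_x} x \code{bins_y}; bin pairs with
#' \code{i == j} never contribute (no self-bin contacts).
#'
#' @param cm distance-normalized \code{ContactMatrix}.
#' @param bins_x,bins_y 0-based bin index vectors.
#' @return scalar strength (0 when no stored entries are covered).
#' @export
aggregate_strength <- function(cm, bins_x, bins_y) {
  stopifnot(is(cm, "ContactMatrix"))
  if (cm$stage != "distance_normalized")
    stop("aggregate_strength expects a distance-normalized matrix")
  if (length(bins_x) == 0L || length(bins_y) == 0L)
    stop("bin sets must be nonempty")
  if (any(c(bins_x, bins_y) < 0L) || any(c(bins_x, bins_y) >= cm$n_bins))
    stop("bin index out of range")
  g <- expand.grid(i = bins_x, j = bins_y)
  g <- g[g$i != g$j, , drop = FALSE]
  if (nrow(g) == 0L) return(0)
  sum(cm$mat[cbind(g$i + 1L, g$j + 1L)])
}

# Unordered covered bin pairs (i < j, i != j) for an element pair, as a
# 2-column matrix; the same unordered pair reached through both orientations
# (overlapping elements) collapses to one row.
covered_bin_pairs <- function(bins_x, bins_y) {
  i <- rep(bins_x, times = length(bins_y))
  j <- rep(bins_y, each = length(bins_x))
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- !duplicated(lo * 2147483647 + hi)
  cbind(i = lo[key], j = hi[key])
}

#' Enumerate candidate gene-pair interactions
#'
#' Emits every unordered pair of elements with positive aggregated strength,
#' exactly once, with the aggregated normalized strength, the raw count sum,
#' and the bp distance between element midpoints. Pairs whose bin sets are
#' identical (co-binned elements, for which cis contacts are undefined) are
#' skipped, as are pairs farther apart than \code{max_span}.
#'
#' @param gs a \code{GeneSet}.
#' @param cm_norm distance-normalized \code{ContactMatrix}.
#' @param cm_raw the matching raw-stage \code{ContactMatrix} (for raw counts).
#' @param max_span maximum midpoint distance in bp (\code{NULL} = all cis).
#' @param upstream,downstream promoter window for protein-coding genes.
#' @return data.frame: \code{gene_x}, \code{gene_y}, \code{class_x},
#'   \code{class_y}, \code{kind_x}, \code{kind_y}, \code{strength},
#'   \code{raw_count}, \code{distance}, plus a list-column \code{bin_pairs}
#'   (covered unordered bin pairs) consumed by
#'   \code{\link{significance_test}}.
#' @export
enumerate_pairs <- function(gs, cm_norm, cm_raw, max_span = NULL,
                            upstream = 2000, downstream = 500) {
  stopifnot(is(cm_norm, "ContactMatrix"), is(cm_raw, "ContactMatrix"))
  el <- gene_elements(gs, cm_norm$resolution, chrom = cm_norm$chrom,
                      upstream = upstream, downstream = downstream)
  n <- nrow(el)
  Mn <- as.matrix(cm_norm$mat)  # dense for fast cross sums at desk scale
  Mr <- as.matrix(cm_raw$mat)
  cap <- n * (n - 1L) %/% 2L
  ax <- integer(cap); bx <- integer(cap)
  sv <- numeric(cap); rv <- numeric(cap); dv <- numeric(cap)
  cps <- vector("list", cap)
  idx <- 0L
  for (a in seq_len(max(n - 1L, 0L))) {
    ba <- el$bins[[a]]
    for (b in (a + 1L):n) {
      bb <- el$bins[[b]]
      if (length(ba) == length(bb) && all(ba == bb)) next
      if (!is.null(max_span) && abs(el$mid[a] - el$mid[b]) > max_span) next
      cp <- covered_bin_pairs(ba, bb)
      if (nrow(cp) == 0L) next
      ij <- cp + 1L
      s <- sum(Mn[ij])
      if (s <= 0) next
      idx <- idx + 1L
      ax[idx] <- a; bx[idx] <- b
      sv[idx] <- s
      rv[idx] <- sum(Mr[ij])
      dv[idx] <- abs(el$mid[a] - el$mid[b])
      cps[[idx]] <- cp
    }
  }
  sel <- seq_len(idx)
  out <- data.frame(
    gene_x = el$gene_id[ax[sel]], gene_y = el$gene_id[bx[sel]],
    class_x = el$gene_class[ax[sel]], class_y = el$gene_class[bx[sel]],
    kind_x = el$kind[ax[sel]], kind_y = el$kind[bx[sel]],
    strength = sv[sel], raw_count = rv[sel], distance = dv[sel],
    stringsAsFactors = FALSE)
  out$bin_pairs <- cps[sel]
  rownames(out) <- NULL
  out
}

#' Upper-tail binomial p-value for contact counts
#'
#' \code{Pr[X >= k]} with \code{X ~ Binomial(T, q)}; \code{k = 0} gives 1.
#'
#' @param k observed count (vectorized).
#' @param size total intra-chromosomal read count T.
#' @param q null contact probability (vectorized).
#' @return p-values in \code{[0, 1]}.
#' @export
binom_tail <- function(k, size, q) {
  if (size <= 0) stop("total read count T must be positive")
  pbinom(k - 1, size = size, prob = q, lower.tail = FALSE)
}

#' Distance-stratified binomial significance test for gene pairs
#'
#' Assigns each candidate pair the upper-tail binomial probability of its raw
#' count under a distance-decay null: \code{p = Pr[X >= k]},
#' \code{X ~ Binomial(T, q)}, where \code{T} is the total intra-chromosomal
#' read count and \code{q} sums, over the pair's covered bin pairs, the raw
#' distance expectation \code{E_d} divided by \code{T}. When the balanced
#' matrix's bias vector is supplied, each term is additionally scaled by
#' \code{b_i * b_j} relative to the stratum mean of that product, refining
#' the null for bin-specific coverage bias in the way fit-HiC-style callers
#' do; \code{bias = NULL} gives the plain stratified null.
#'
#' @param pairs data.frame from \code{\link{enumerate_pairs}}.
#' @param cm_raw raw-stage \code{ContactMatrix} the counts came from.
#' @param expd_raw \code{\link{distance_expectation}} of \code{cm_raw}.
#' @param bias per-bin bias vector (mean 1 on unmasked bins, \code{NA}
#'   elsewhere), e.g. the \code{bias} field after \code{\link{kr_balance}}.
#' @return \code{pairs} with a \code{p_value} column.
#' @export
significance_test <- function(pairs, cm_raw, expd_raw = NULL, bias = NULL) {
  stopifnot(is(cm_raw, "ContactMatrix"))
  if (is.null(expd_raw)) expd_raw <- distance_expectation(cm_raw)
  total <- (sum(cm_raw$mat) + sum(Matrix::diag(cm_raw$mat))) / 2
  if (total <= 0) stop("total read count T must be positive")
  if (nrow(pairs) == 0L) {
    pairs$p_value <- numeric(0)
    return(pairs)
  }
  nb <- cm_raw$n_bins
  if (!is.null(bias)) {
    b <- ifelse(is.na(bias), 0, bias)
    # per-distance mean of b_i * b_(i+d) over all positional pairs (masked
    # bins contribute 0, matching their 0 contribution to N_d)
    bb_mean <- vapply(seq_len(nb - 1L), function(d) {
      sum(b[seq_len(nb - d)] * b[seq_len(nb - d) + d]) / (nb - d)
    }, numeric(1))
  }
  q <- vapply(pairs$bin_pairs, function(cp) {
    d <- cp[, 2L] - cp[, 1L]
    term <- expd_raw$E[d]
    if (!is.null(bias)) {
      w <- b[cp[, 1L] + 1L] * b[cp[, 2L] + 1L] / bb_mean[d]
      w[!is.finite(w)] <- 0
      term <- term * w
    }
    sum(term) / total
  }, numeric(1))
  q <- pmin(pmax(q, 0), 1)
  pairs$p_value <- binom_tail(pairs$raw_count, total, q)
  pairs
}

#' Benjamini-Hochberg filter on candidate pairs
#'
#' Computes BH-adjusted q-values jointly over all tested pairs and removes
#' those with \code{q > threshold}.
#'
#' @param pairs data.frame with a \code{p_value} column.
#' @param threshold FDR cutoff (default 0.001).
#' @return the surviving pairs with a \code{q_value} column.
#' @export
fdr_filter <- function(pairs, threshold = 0.001) {
  if (nrow(pairs) == 0L) {
    pairs$q_value <- numeric(0)
    return(pairs)
  }
  pairs$q_value <- bh_adjust(pairs$p_value)
  out <- pairs[pairs$q_value <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the interaction network from filtered pairs
#'
#' Nodes are genes (class-labelled), edges the surviving pairs. Both the
#' Eq.-style aggregated strength and the raw interaction count are stored on
#' every edge; \code{weight} selects which one populates igraph's
#' \code{weight} attribute (the raw count is what the enhancement stage
#' diffuses).
#'
#' @param pairs filtered pairs from \code{\link{fdr_filter}}.
#' @param gs the \code{GeneSet} (class lookup; supplies isolated nodes when
#'   \code{include_isolated}).
#' @param weight \code{"strength"} or \code{"raw_count"}.
#' @param include_isolated keep genes without any surviving edge as isolated
#'   nodes (default \code{FALSE}).
#' @return an \code{igraph} graph with vertex attributes \code{name},
#'   \code{gene_class}, edge attributes \code{weight}, \code{strength},
#'   \code{raw_count}, \code{distance}, \code{p_value}, \code{q_value}, and
#'   graph attribute \code{provenance = "raw"}.
#' @export
build_network <- function(pairs, gs, weight = c("raw_count", "strength"),
                          include_isolated = FALSE) {
  weight <- match.arg(weight)
  key <- paste(pmin(pairs$gene_x, pairs$gene_y),
               pmax(pairs$gene_x, pairs$gene_y))
  if (anyDuplicated(key))
    stop("duplicate gene pair in input: ", key[duplicated(key)][1L])
  if (any(pairs$gene_x == pairs$gene_y)) stop("self-loop pair in input")
  nodes <- if (include_isolated) gs$records$gene_id else
    sort(unique(c(pairs$gene_x, pairs$gene_y)))
  cls <- gs$records$gene_class[match(nodes, gs$records$gene_id)]
  if (anyNA(cls)) stop("pair references gene absent from the GeneSet")
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs$gene_x, to = pairs$gene_y,
               weight = pairs[[weight]],
               strength = pairs$strength, raw_count = pairs$raw_count,
               distance = pairs$distance, p_value = pairs$p_value,
               q_value = pairs$q_value, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, gene_class = cls,
                          stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "provenance", "raw")
  g
}

#' Write a network edge list as TSV
#' @param g igraph network from \code{\link{build_network}} (possibly
#'   enhanced).
#' @param path output path.
#' @export
write_network_tsv <- function(g, path) {
  ed <- igraph::as_data_frame(g, what = "edges")
  cls <- igraph::V(g)$gene_class
  names(cls) <- igraph::V(g)$name
  ed <- cbind(gene_x = ed$from, gene_y = ed$to,
              class_x = unname(cls[ed$from]), class_y = unname(cls[ed$to]),
              ed[setdiff(names(ed), c("from", "to"))])
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#' @param g igraph network.
#' @param path output path.
#' @export
write_network_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
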