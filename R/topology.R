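# Graph topology: summary statistics, class-wise degree comparison,
# sub-network extraction and degree-based biomarker ranking.
#
# Path statistics are computed on the unweighted skeleton; on disconnected
# graphs, diameter and path-length histograms refer to the largest connected
# component (component count is reported alongside).

#' Topology summary of an interaction network
#'
#' Degrees, shortest-path statistics, clustering and centralities. The
#' diameter is the maximum eccentricity over the largest connected component;
#' local clustering of degree-<2 nodes counts as 0 in the mean. Betweenness
#' is the unnormalized shortest-path pair count.
#'
#' @param g igraph network (nonempty).
#' @param sample_paths number of seeded source nodes for the path-length
#'   histogram (\code{NULL} = all sources; sampling bounds runtime on large
#'   graphs).
#' @param seed seed used when \code{sample_paths} is set.
#' @param exact_betweenness_max above this node count betweenness is
#'   approximated with a shortest-path length cutoff of 6 (default 2000
#'   nodes for the exact computation).
#' @return list of class \code{TopologySummary}: \code{n_nodes},
#'   \code{n_edges}, \code{n_components}, \code{diameter},
#'   \code{mean_clustering}, \code{mean_degree}, \code{degree_histogram},
#'   \code{path_length_histogram}, and per-node data.frame \code{nodes}
#'   (degree, clustering, betweenness, closeness, class).
#' @export
summarize_topology <- function(g, sample_paths = NULL, seed = 1,
                               exact_betweenness_max = 2000) {
  if (igraph::vcount(g) == 0L) stop("cannot summarize an empty graph")
  deg <- igraph::degree(g)
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))
  diam <- if (igraph::ecount(giant) > 0L)
    igraph::diameter(giant, weights = NA) else 0L
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[!is.finite(cl)] <- 0
  sources <- igraph::V(giant)
  if (!is.null(sample_paths) && sample_paths < length(sources)) {
    old <- .Random.seed_save()
    set.seed(seed)
    sources <- sample(sources, sample_paths)
    .Random.seed_restore(old)
  }
  dm <- igraph::distances(giant, v = sources, weights = NA)
  dvals <- dm[is.finite(dm) & dm > 0]
  plh <- if (length(dvals) > 0) table(dvals) else table(integer(0))
  btw <- if (igraph::vcount(g) <= exact_betweenness_max)
    igraph::betweenness(g, weights = NA)
  else  # bounded-path approximation keeps large graphs tractable
    igraph::betweenness(g, weights = NA, cutoff = 6)
  clo <- suppressWarnings(igraph::closeness(g, weights = NA))
  nodes <- data.frame(gene_id = igraph::V(g)$name, degree = deg,
                      clustering = cl, betweenness = btw, closeness = clo,
                      gene_class = igraph::V(g)$gene_class,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    n_components = comps$no, diameter = diam,
    mean_clustering = mean(cl), mean_degree = mean(deg),
    degree_histogram = table(deg), path_length_histogram = plh,
    nodes = nodes), class = "TopologySummary")
}

#' @export
print.TopologySummary <- function(x, ...) {
  cat(sprintf(paste0("TopologySummary: %d nodes, %d edges, %d component(s)\n",
                     "  diameter (largest comp.): %d\n",
                     "  mean degree: %.2f   mean clustering: %.4f\n"),
              x$n_nodes, x$n_edges, x$n_components, x$diameter,
              x$mean_degree, x$mean_clustering))
  invisible(x)
}

# save/restore the RNG state so seeded sampling inside summaries does not
# perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Compare node degree between gene classes
#'
#' Two-sample t-test on per-node degrees of two classes (lincRNA hubs versus
#' protein-coding genes, classically).
#'
#' @param g igraph network with \code{gene_class} vertex attribute.
#' @param class_a,class_b the two classes.
#' @param test \code{"student"} (pooled variance) or \code{"welch"}.
#' @return list of class \code{ClassComparison}: per-class means, statistic,
#'   p-value, test name and group sizes.
#' @export
compare_degree_by_class <- function(g, class_a = "lincRNA",
                                    class_b = "protein_coding",
                                    test = c("student", "welch")) {
  test <- match.arg(test)
  deg <- igraph::degree(g)
  cls <- igraph::V(g)$gene_class
  a <- deg[cls == class_a]
  b <- deg[cls == class_b]
  compare_groups(a, b, test = test,
                 label_a = class_a, label_b = class_b,
                 what = "degree")
}

#' Extract a sub-network
#'
#' \code{neighbors} mode: the seeds plus all their direct neighbours, with
#' induced edges (a seed-centred neighbourhood such as a single lincRNA's
#' partners). \code{induced_panel} mode: the panel genes plus every lincRNA
#' partner of a panel gene, with induced edges (a receptor-panel view).
#'
#' @param g igraph network.
#' @param seeds gene ids; every seed must be present in \code{g}.
#' @param mode \code{"neighbors"} or \code{"induced_panel"}.
#' @return induced igraph sub-network.
#' @export
extract_subnetwork <- function(g, seeds,
                               mode = c("neighbors", "induced_panel")) {
  mode <- match.arg(mode)
  absent <- setdiff(seeds, igraph::V(g)$name)
  if (length(absent) > 0L)
    stop("seed gene(s) absent from network: ", paste(absent, collapse = ", "))
  partners <- unique(unlist(lapply(seeds, function(s)
    igraph::neighbors(g, s)$name)))
  keep <- if (mode == "neighbors") {
    union(seeds, partners)
  } else {
    cls <- igraph::V(g)$gene_class[match(partners, igraph::V(g)$name)]
    union(seeds, partners[cls == "lincRNA"])
  }
  igraph::induced_subgraph(g, keep)
}

#' Rank genes by network degree
#'
#' Descending by degree; ties broken by total incident weight, then
#' lexicographically by gene id (so the ordering is deterministic).
#'
#' @param g igraph network.
#' @param restrict \code{NULL}, a gene class (\code{"lincRNA"} /
#'   \code{"protein_coding"}), or a vector of gene ids to rank within.
#' @param top_k rows to return (default 10).
#' @return data.frame: gene_id, gene_class, degree, total_weight,
#'   clustering, betweenness, closeness.
#' @export
rank_by_degree <- function(g, restrict = NULL, top_k = 10) {
  deg <- igraph::degree(g)
  stg <- igraph::strength(g)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[!is.finite(cl)] <- 0
  btw <- igraph::betweenness(g, weights = NA)
  clo <- suppressWarnings(igraph::closeness(g, weights = NA))
  df <- data.frame(gene_id = igraph::V(g)$name,
                   gene_class = igraph::V(g)$gene_class,
                   degree = deg, total_weight = stg, clustering = cl,
                   betweenness = btw, closeness = clo,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(restrict)) {
    df <- if (length(restrict) == 1L &&
              restrict %in% c("lincRNA", "protein_coding"))
      df[df$gene_class == restrict, , drop = FALSE]
    else df[df$gene_id %in% restrict, , drop = FALSE]
  }
  df <- df[order(-df$degree, -df$total_weight, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  head(df, top_k)
}
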