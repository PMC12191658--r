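# End-to-end orchestration: validated config, staged execution with logging,
# and a checksummed artifact manifest for reproducibility.

default_config <- function() {
  list(
    paths = list(gtf = NULL, chrom_sizes = NULL, contacts = NULL,
                 peaks = NULL, coverage = NULL, gmt = NULL),
    outdir = NULL,
    seed = 1,
    resolution = 2e4,
    contacts_format = "coo_tsv",
    chrom = "chrS",
    annotation = list(upstream = 2000, downstream = 500,
                      classes = c("lincRNA", "protein_coding")),
    kr = list(tol = 1e-6, max_iter = 3000, mask_quantile = 0.0),
    netbuild = list(fdr_threshold = 0.001, max_span = NULL,
                    weight = "raw_count", bias_correction = TRUE),
    enhance = list(skip = FALSE, k_neighbors = 20, alpha = 0.9, order = 2,
                   max_iter = 200, tol = 1e-8),
    topology = list(sample_paths = NULL),
    enrichment = list(top_n = 50, background_n = 150),
    signals = list(flank = 2000, binsize = 50))
}

#' Validate a pipeline configuration
#'
#' Accepts a nested list or a YAML file path, merges it over the defaults,
#' rejects unknown keys, and checks that every referenced input path exists.
#' All validation errors are reported at once, before any compute.
#'
#' @param config nested list or path to a YAML config file. Required:
#'   \code{paths$gtf}, \code{paths$contacts}, \code{paths$chrom_sizes},
#'   \code{outdir}. Optional inputs: \code{paths$peaks},
#'   \code{paths$coverage}, \code{paths$gmt} (stages needing them are
#'   skipped when absent).
#' @return the merged, validated config (class \code{PipelineConfig}).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_config()
  errs <- character(0)
  unknown_top <- setdiff(names(config), names(def))
  if (length(unknown_top) > 0L)
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown_top, collapse = ", ")))
  for (sect in intersect(names(config), names(def))) {
    if (is.list(def[[sect]]) && !is.null(names(def[[sect]])) &&
        is.list(config[[sect]])) {
      unknown <- setdiff(names(config[[sect]]), names(def[[sect]]))
      if (length(unknown) > 0L)
        errs <- c(errs, paste0("unknown key(s) under '", sect, "': ",
                               paste(unknown, collapse = ", ")))
    }
  }
  cfg <- modifyList(def, config)
  for (req in c("gtf", "contacts", "chrom_sizes"))
    if (is.null(cfg$paths[[req]]))
      errs <- c(errs, paste0("paths$", req, " is required"))
  if (is.null(cfg$outdir)) errs <- c(errs, "outdir is required")
  for (key in c("gtf", "contacts", "chrom_sizes", "peaks", "coverage",
                "gmt")) {
    p <- cfg$paths[[key]]
    if (!is.null(p) && !file.exists(p))
      errs <- c(errs, paste0("paths$", key, " does not exist: ", p))
  }
  if (length(errs) > 0L)
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  class(cfg) <- "PipelineConfig"
  cfg
}

log_stage <- function(stage, msg, t0 = NULL) {
  elapsed <- if (!is.null(t0))
    sprintf(" [%.1fs]", as.numeric(Sys.time()) - t0) else ""
  message(sprintf("[%s] %s%s", stage, msg, elapsed))
}

run_stage <- function(stage, expr) {
  t0 <- as.numeric(Sys.time())
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  log_stage(stage, "done", t0)
  res
}

#' Run the full network-construction and analysis pipeline
#'
#' Stages, in order: annotation, contacts (KR balancing + distance
#' normalization), netbuild (pair aggregation, binomial significance,
#' BH-FDR filter), enhance (network enhancement; skippable), topology,
#' enrichment (when a GMT is configured) and signals (when peaks/coverage
#' are configured). Every artifact is written under \code{outdir} and listed
#' with its MD5 checksum in \code{manifest.json}; any stage failure aborts
#' with the failing stage named.
#'
#' @param config list or YAML path accepted by \code{\link{pipeline_config}}.
#' @return the manifest (invisibly): list with \code{artifacts}
#'   (name/path/md5), per-stage wall times and the provenance of the
#'   topology statistics.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(cfg$outdir, name)
  artifacts <- character(0)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    r <- run_stage(stage, expr)
    timings[[stage]] <<- round(as.numeric(Sys.time()) - t0, 3)
    r
  }

  gs <- clock("annotation", {
    chrom_sizes <- read_chrom_sizes(cfg$paths$chrom_sizes)
    parse_gtf(cfg$paths$gtf, classes = cfg$annotation$classes,
              chrom_sizes = chrom_sizes)
  })
  promoters <- derive_promoters(gs, cfg$annotation$upstream,
                                cfg$annotation$downstream)
  write.table(gs$records, art("genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  promoters_to_bed(promoters, gs, art("promoters.bed"))
  artifacts <- c(artifacts, "genes.tsv", "promoters.bed")

  norm <- clock("contacts", {
    cm_raw <- load_contacts(cfg$paths$contacts,
                            format = cfg$contacts_format,
                            resolution = cfg$resolution,
                            chrom_len = gs$chrom_sizes[[cfg$chrom]],
                            chrom = cfg$chrom)
    cm_bal <- kr_balance(cm_raw, tol = cfg$kr$tol,
                         max_iter = cfg$kr$max_iter,
                         mask_quantile = cfg$kr$mask_quantile)
    expd <- distance_expectation(cm_bal)
    cm_norm <- normalize_by_distance(cm_bal, expd)
    write_bias(cm_bal, art("bias.tsv"))
    write.table(expd, art("expected.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(raw = cm_raw, bal = cm_bal, norm = cm_norm)
  })
  artifacts <- c(artifacts, "bias.tsv", "expected.tsv")

  filtered <- clock("netbuild", {
    pairs <- enumerate_pairs(gs, norm$norm, norm$raw,
                             max_span = cfg$netbuild$max_span,
                             upstream = cfg$annotation$upstream,
                             downstream = cfg$annotation$downstream)
    pairs <- significance_test(
      pairs, norm$raw, distance_expectation(norm$raw),
      bias = if (cfg$netbuild$bias_correction) norm$bal$bias else NULL)
    flt <- fdr_filter(pairs, threshold = cfg$netbuild$fdr_threshold)
    drop_cols <- function(df) df[, setdiff(names(df), "bin_pairs")]
    all_out <- drop_cols(pairs)
    all_out$q_value <- bh_adjust(pairs$p_value)
    write.table(all_out, art("pairs_all.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(drop_cols(flt), art("pairs_significant.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    flt
  })
  artifacts <- c(artifacts, "pairs_all.tsv", "pairs_significant.tsv")

  g <- clock("netbuild_graph", {
    g <- build_network(filtered, gs, weight = cfg$netbuild$weight)
    write_network_tsv(g, art("network_edges.tsv"))
    write_network_graphml(g, art("network.graphml"))
    g
  })
  artifacts <- c(artifacts, "network_edges.tsv", "network.graphml")

  g_enh <- NULL
  if (!isTRUE(cfg$enhance$skip) && igraph::ecount(g) > 0) {
    g_enh <- clock("enhance", {
      ge <- enhance_network(g, k_neighbors = cfg$enhance$k_neighbors,
                            alpha = cfg$enhance$alpha,
                            order = cfg$enhance$order,
                            max_iter = cfg$enhance$max_iter,
                            tol = cfg$enhance$tol)
      write_network_tsv(ge, art("network_enhanced.tsv"))
      ge
    })
    artifacts <- c(artifacts, "network_enhanced.tsv")
  }

  topo <- clock("topology", {
    topo_g <- if (!is.null(g_enh)) g_enh else g
    ts <- summarize_topology(g, sample_paths = cfg$topology$sample_paths,
                             seed = cfg$seed)
    ts_lab <- list(
      provenance = "raw",
      n_nodes = ts$n_nodes, n_edges = ts$n_edges,
      n_components = ts$n_components, diameter = ts$diameter,
      mean_degree = ts$mean_degree, mean_clustering = ts$mean_clustering,
      degree_histogram = as.list(ts$degree_histogram),
      path_length_histogram = as.list(ts$path_length_histogram))
    out <- list(raw = ts_lab)
    if (!is.null(g_enh)) {
      ts2 <- summarize_topology(g_enh,
                                sample_paths = cfg$topology$sample_paths,
                                seed = cfg$seed)
      out$enhanced <- list(
        provenance = "enhanced",
        n_nodes = ts2$n_nodes, n_edges = ts2$n_edges,
        n_components = ts2$n_components, diameter = ts2$diameter,
        mean_degree = ts2$mean_degree,
        mean_clustering = ts2$mean_clustering)
    }
    jsonlite::write_json(out, art("topology_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(ts$nodes, art("node_metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rank <- rank_by_degree(g, top_k = 10)
    write.table(rank, art("degree_rank.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ts
  })
  artifacts <- c(artifacts, "topology_summary.json", "node_metrics.tsv",
                 "degree_rank.tsv")

  if (!is.null(cfg$paths$gmt)) {
    clock("enrichment", {
      db <- read_gmt(cfg$paths$gmt)
      top_n <- min(cfg$enrichment$top_n, igraph::vcount(g))
      bg_n <- min(cfg$enrichment$background_n, nrow(gs$records))
      enr <- enrich_top_degree(g, db, universe = gs$records$gene_id,
                               top_n = top_n, background_n = bg_n,
                               seed = cfg$seed)
      write.table(enr, art("enrichment.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
    artifacts <- c(artifacts, "enrichment.tsv")
  }

  if (!is.null(cfg$paths$peaks) && !is.null(cfg$paths$coverage)) {
    clock("signals", {
      peaks <- read_bed(cfg$paths$peaks)
      cls <- classify_rloop_targets(g, promoters, peaks, gs)
      cls_df <- data.frame(
        gene_id = c(cls$rloop_genes, cls$other_genes),
        group = rep(c("rloop", "other"),
                    c(length(cls$rloop_genes), length(cls$other_genes))))
      write.table(cls_df, art("rloop_classes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      mc <- promoter_mean_coverage(cfg$paths$coverage, promoters)
      cmp <- if (length(cls$rloop_genes) >= 2 &&
                 length(cls$other_genes) >= 2) {
        compare_groups(mc[cls$rloop_genes], mc[cls$other_genes],
                       label_a = "rloop", label_b = "other",
                       what = "mean promoter coverage")
      } else NULL
      counts <- count_peaks_per_promoter(peaks, promoters)
      sig <- list(
        n_rloop = length(cls$rloop_genes),
        n_other = length(cls$other_genes),
        mean_peaks_rloop = mean(counts[cls$rloop_genes]),
        mean_peaks_other = mean(counts[cls$other_genes]),
        comparison = if (!is.null(cmp)) unclass(cmp) else NULL)
      jsonlite::write_json(sig, art("signals_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
    })
    artifacts <- c(artifacts, "rloop_classes.tsv", "signals_comparison.json")
  }

  paths <- vapply(artifacts, art, character(1))
  manifest <- list(
    artifacts = data.frame(name = artifacts, path = unname(paths),
                           md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE),
    seed = cfg$seed,
    topology_provenance = if (!is.null(g_enh)) c("raw", "enhanced")
                          else "raw",
    timings = timings)
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  log_stage("pipeline", paste0("wrote ", length(artifacts),
                               " artifact(s) to ", cfg$outdir))
  invisible(manifest)
}
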