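# Gene annotation: GTF parsing, gene classes, promoter derivation, bin maps.
# Internal coordinates are 0-based half-open throughout; GTF is converted on
# read and write, BED passes through unchanged.

#' Construct a GeneSet
#'
#' A \code{GeneSet} bundles gene records (one row per gene) with the
#' chromosome sizes they live on. Coordinates are 0-based half-open.
#'
#' @param records data.frame with columns \code{gene_id}, \code{name},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand} (\code{+}/\code{-})
#'   and \code{gene_class} (\code{lincRNA} or \code{protein_coding}).
#' @param chrom_sizes named numeric vector, chromosome name -> length in bp.
#' @return An object of class \code{GeneSet}: a list with elements
#'   \code{records} (with a derived \code{tss} column: 5' end of the gene)
#'   and \code{chrom_sizes}.
#' @export
gene_set <- function(records, chrom_sizes) {
  required <- c("gene_id", "name", "chrom", "start", "end", "strand",
                "gene_class")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (anyDuplicated(records$gene_id))
    stop("duplicate gene_id in records: ",
         paste(unique(records$gene_id[duplicated(records$gene_id)]),
               collapse = ", "))
  if (!all(records$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(records$gene_class %in% c("lincRNA", "protein_coding")))
    stop("gene_class must be 'lincRNA' or 'protein_coding'")
  if (any(records$start >= records$end))
    stop("gene records must satisfy start < end")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  absent <- setdiff(unique(records$chrom), names(chrom_sizes))
  if (length(absent) > 0L)
    stop("chromosome(s) absent from chrom_sizes: ",
         paste(absent, collapse = ", "))
  lens <- chrom_sizes[records$chrom]
  if (any(records$start < 0L) || any(records$end > lens))
    stop("gene span outside chromosome bounds for: ",
         paste(records$gene_id[records$start < 0L | records$end > lens],
               collapse = ", "))
  records$tss <- ifelse(records$strand == "+", records$start, records$end)
  rownames(records) <- NULL
  structure(list(records = records, chrom_sizes = chrom_sizes),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet:", nrow(x$records), "genes on",
      length(unique(x$records$chrom)), "chromosome(s)\n")
  print(table(x$records$gene_class))
  invisible(x)
}

gtf_attr <- function(attr_field, key) {
  m <- regmatches(attr_field,
                  regexec(paste0(key, ' "([^"]*)"'), attr_field))
  vapply(m, function(g) if (length(g) == 2L) g[2L] else NA_character_,
         character(1))
}

#' Parse a GENCODE-style GTF into a GeneSet
#'
#' Retains only \code{gene}-level features whose \code{gene_type} attribute is
#' in \code{classes}. GTF's 1-based inclusive coordinates are converted to the
#' package-internal 0-based half-open convention. The TSS is the 5' end of the
#' gene (start for \code{+}, end for \code{-}); genes are treated at gene
#' level with a single TSS each.
#'
#' @param path path to a GTF file.
#' @param classes character vector of \code{gene_type} values to keep.
#' @param chrom_sizes named vector chrom -> length (bp). When supplied,
#'   records on chromosomes absent from it are skipped with a warning;
#'   when \code{NULL}, sizes are inferred as the per-chromosome maximum end.
#' @return A \code{\link{gene_set}}.
#' @export
parse_gtf <- function(path, classes = c("lincRNA", "protein_coding"),
                      chrom_sizes = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF line ", idx[which(nf != 9L)[1L]],
         ": expected 9 tab-separated fields, found ", nf[nf != 9L][1L])
  f <- function(k) vapply(fields, `[[`, character(1), k)
  feature <- f(3L)
  is_gene <- feature == "gene"
  chrom <- f(1L)[is_gene]
  start1 <- suppressWarnings(as.integer(f(4L)[is_gene]))
  end1 <- suppressWarnings(as.integer(f(5L)[is_gene]))
  strand <- f(7L)[is_gene]
  attrs <- f(9L)[is_gene]
  bad <- which(is.na(start1) | is.na(end1) | !(strand %in% c("+", "-")))
  if (length(bad) > 0L)
    stop("malformed GTF line ", idx[is_gene][bad[1L]],
         ": non-numeric coordinates or invalid strand")
  gene_type <- gtf_attr(attrs, "gene_type")
  gene_id <- gtf_attr(attrs, "gene_id")
  gene_name <- gtf_attr(attrs, "gene_name")
  gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
  sel <- !is.na(gene_type) & gene_type %in% classes & !is.na(gene_id)
  rec <- data.frame(gene_id = gene_id[sel], name = gene_name[sel],
                    chrom = chrom[sel],
                    start = start1[sel] - 1L,  # GTF 1-based -> 0-based
                    end = end1[sel],
                    strand = strand[sel], gene_class = gene_type[sel],
                    stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes)) {
    unknown <- !(rec$chrom %in% names(chrom_sizes))
    if (any(unknown)) {
      warning("skipping ", sum(unknown),
              " record(s) on chromosome(s) absent from chrom_sizes: ",
              paste(unique(rec$chrom[unknown]), collapse = ", "))
      rec <- rec[!unknown, , drop = FALSE]
    }
  } else {
    chrom_sizes <- tapply(rec$end, rec$chrom, max)
    chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  gene_set(rec, chrom_sizes)
}

#' Write a GeneSet back to GTF
#'
#' Inverse of \code{\link{parse_gtf}}: emits one \code{gene} feature per
#' record with 1-based inclusive coordinates and \code{gene_id},
#' \code{gene_name}, \code{gene_type} attributes.
#'
#' @param gs a \code{GeneSet}.
#' @param path output file path.
#' @export
write_gtf <- function(gs, path) {
  r <- gs$records
  lines <- sprintf(
    '%s\tlincnet\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_type "%s";',
    r$chrom, r$start + 1L, r$end, r$strand, r$gene_id, r$name, r$gene_class)
  writeLines(lines, path)
  invisible(path)
}

#' Derive a strand-aware promoter window
#'
#' The promoter is the window from \code{upstream} bp upstream to
#' \code{downstream} bp downstream of the TSS, oriented by strand and clipped
#' to the chromosome: \code{[tss-upstream, tss+downstream)} on \code{+},
#' \code{[tss-downstream, tss+upstream)} on \code{-}.
#'
#' @param gene single-row data.frame (a \code{GeneSet} record).
#' @param upstream,downstream window extents in bp (defaults 2000 and 500).
#' @param chrom_len chromosome length used for clipping.
#' @return data.frame row with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{tss} (0-based half-open).
#' @export
derive_promoter <- function(gene, upstream = 2000, downstream = 500,
                            chrom_len) {
  stopifnot(upstream >= 0, downstream >= 0)
  tss <- if (gene$strand == "+") gene$start else gene$end
  if (gene$strand == "+") {
    s <- tss - upstream; e <- tss + downstream
  } else {
    s <- tss - downstream; e <- tss + upstream
  }
  s <- max(0, s); e <- min(chrom_len, e)
  if (e <= s)
    stop("empty promoter window for gene ", gene$gene_id,
         " after clipping at chromosome edge")
  data.frame(gene_id = gene$gene_id, chrom = gene$chrom, start = s, end = e,
             tss = tss, stringsAsFactors = FALSE)
}

#' Promoters for every gene in a GeneSet
#'
#' @param gs a \code{GeneSet}.
#' @param upstream,downstream see \code{\link{derive_promoter}}.
#' @param classes gene classes to derive promoters for (default: all).
#' @return data.frame of promoter intervals, one row per gene.
#' @export
derive_promoters <- function(gs, upstream = 2000, downstream = 500,
                             classes = NULL) {
  r <- gs$records
  if (!is.null(classes)) r <- r[r$gene_class %in% classes, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(r)), function(i)
    derive_promoter(r[i, ], upstream, downstream,
                    gs$chrom_sizes[[r$chrom[i]]])))
  rownames(out) <- NULL
  out
}

#' Map an interval onto fixed-resolution bins
#'
#' Returns every bin index \code{b} whose window
#' \code{[b*resolution, (b+1)*resolution)} overlaps the (0-based half-open)
#' interval by at least 1 bp, in ascending order.
#'
#' @param start,end interval in bp, 0-based half-open.
#' @param resolution bin size in bp.
#' @return integer vector of bin indices (0-based).
#' @export
map_to_bins <- function(start, end, resolution) {
  if (resolution <= 0) stop("resolution must be positive")
  if (end <= start) stop("cannot bin an empty interval")
  seq.int(floor(start / resolution), floor((end - 1) / resolution))
}

#' Export promoters as BED6
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' pass through unchanged. Score is 0; name is the gene id.
#'
#' @param promoters data.frame from \code{\link{derive_promoters}}.
#' @param gs the originating \code{GeneSet} (for strand lookup).
#' @param path output path.
#' @export
promoters_to_bed <- function(promoters, gs, path) {
  strand <- gs$records$strand[match(promoters$gene_id, gs$records$gene_id)]
  df <- data.frame(promoters$chrom, promoters$start, promoters$end,
                   promoters$gene_id, 0L, strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#' @param path TSV with columns chrom, length.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "len"),
                   colClasses = c("character", "numeric"))
  setNames(df$len, df$chrom)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes named numeric vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), unname(chrom_sizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
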