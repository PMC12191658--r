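# Gene-set over-representation of top-degree genes: hypergeometric upper
# tail against a seeded random background, BH-corrected across terms.

#' Read a GMT gene-set file
#'
#' Tab-separated: term id, description, then member gene ids.
#'
#' @param path GMT file.
#' @return named list of terms; each element is
#'   \code{list(name = description, genes = character vector)}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line (need term, description, >= 1 gene): ", l)
    list(name = f[2L], genes = unique(f[-(1:2)]))
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  out
}

#' Write a GMT gene-set file
#' @param db named list as returned by \code{\link{read_gmt}}.
#' @param path output path.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db), function(id)
    paste(c(id, db[[id]]$name, db[[id]]$genes), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' \code{Pr[X >= k]} for \code{X ~ Hypergeometric(N, K, n)}: the chance of
#' at least \code{k} annotated genes in a size-\code{n} draw from a universe
#' of \code{N} genes of which \code{K} are annotated.
#'
#' @param k observed hits in the query.
#' @param K term members in the universe.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail probability (1 when \code{k = 0}).
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("inconsistent hypergeometric arguments")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: \code{q_(i) = min_(j >= i) m p_(j) / j}, capped at
#' 1 and mapped back to input order.
#'
#' @param p p-values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Over-representation of top-degree genes
#'
#' Takes the \code{top_n} genes by network degree (the deterministic
#' \code{\link{rank_by_degree}} ordering) as the query, draws a seeded random
#' background of \code{background_n} genes without replacement from
#' \code{universe}, and tests every gene set against
#' \code{query} within \code{background + query} with
#' \code{\link{hypergeom_upper}}, BH-correcting across terms. Terms with no
#' member in the working universe are skipped.
#'
#' @param g igraph network.
#' @param db gene-set list from \code{\link{read_gmt}}.
#' @param universe character vector of gene ids the background is drawn from
#'   (typically the full annotation).
#' @param top_n query size (classically 3000 on a genome-scale network);
#'   must not exceed the node count.
#' @param background_n background sample size (classically 10,000); must not
#'   exceed the universe size.
#' @param seed RNG seed for the background draw.
#' @return data.frame sorted by \code{q} then \code{p}: term, name, k, K, n,
#'   N, p, q, fold.
#' @export
enrich_top_degree <- function(g, db, universe, top_n = 3000,
                              background_n = 10000, seed = 1) {
  if (top_n > igraph::vcount(g))
    stop("top_n exceeds the number of network nodes (", igraph::vcount(g),
         ")")
  if (background_n > length(universe))
    stop("background larger than universe (", length(universe),
         " genes); reduce background_n")
  query <- rank_by_degree(g, top_k = top_n)$gene_id
  old <- .Random.seed_save()
  set.seed(seed)
  background <- sample(universe, background_n)
  .Random.seed_restore(old)
  uni <- union(background, query)
  N <- length(uni)
  n <- length(query)
  rows <- lapply(names(db), function(id) {
    members <- intersect(db[[id]]$genes, uni)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, query))
    p <- hypergeom_upper(k, K, n, N)
    data.frame(term = id, name = db[[id]]$name, k = k, K = K, n = n, N = N,
               p = p, fold = (k / n) / (K / N), stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0L)
    message(skipped, " term(s) skipped: no members in the working universe")
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      fold = numeric(0)))
  res$q <- bh_adjust(res$p)
  res <- res[order(res$q, res$p, res$term), ,
             drop = FALSE]
  res <- res[, c("term", "name", "k", "K", "n", "N", "p", "q", "fold")]
  rownames(res) <- NULL
  res
}
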