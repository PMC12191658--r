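# Hi-C contact matrices: I/O, Knight-Ruiz balancing, distance expectation,
# observed/expected normalization.

#' Construct a ContactMatrix
#'
#' A per-chromosome symmetric contact matrix at fixed resolution. The matrix
#' is stored as a full symmetric sparse \code{Matrix::dgCMatrix}; \code{stage}
#' tracks the normalization state.
#'
#' @param mat symmetric non-negative matrix (dense or sparse).
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param stage one of \code{raw}, \code{balanced}, \code{distance_normalized}.
#' @return object of class \code{ContactMatrix}: list with \code{chrom},
#'   \code{resolution}, \code{n_bins}, \code{mat}, \code{stage}, plus
#'   \code{bias}/\code{mask}/\code{total_raw} after balancing.
#' @export
contact_matrix <- function(mat, chrom, resolution, stage = "raw") {
  mat <- as(as(as(mat, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  if (!isTRUE(all.equal(max(abs(mat - Matrix::t(mat))), 0, tolerance = 1e-8)))
    stop("contact matrix must be symmetric")
  if (any(mat@x < 0)) stop("contact matrix must be non-negative")
  stage <- match.arg(stage, c("raw", "balanced", "distance_normalized"))
  structure(list(chrom = chrom, resolution = resolution,
                 n_bins = nrow(mat), mat = mat, stage = stage),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix %s: %d bins @ %g bp, stage=%s, mass=%.4g\n",
              x$chrom, x$n_bins, x$resolution, x$stage, sum(x$mat)))
  invisible(x)
}

#' Load a Hi-C contact matrix
#'
#' Two text formats are supported. \code{coo_tsv}: three columns
#' \code{bin_i bin_j count} with 0-based bin indices; entries are
#' symmetrized by summing \code{(i,j)} and \code{(j,i)} duplicates.
#' \code{dense_txt}: a whitespace-separated square matrix.
#'
#' @param path input file.
#' @param format \code{"coo_tsv"} or \code{"dense_txt"}.
#' @param resolution bin size in bp.
#' @param chrom_len chromosome length in bp (fixes \code{n_bins}).
#' @param chrom chromosome name to record.
#' @return a raw-stage \code{\link{contact_matrix}}.
#' @export
load_contacts <- function(path, format = c("coo_tsv", "dense_txt"),
                          resolution, chrom_len, chrom = "chr1") {
  format <- match.arg(format)
  n_bins <- as.integer(ceiling(chrom_len / resolution))
  if (format == "coo_tsv") {
    if (file.size(path) == 0L) {
      warning("empty contact file; returning all-zero matrix")
      m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n_bins, n_bins))
      return(contact_matrix(m, chrom, resolution))
    }
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("i", "j", "x"))
    if (any(df$x < 0)) stop("negative count at row ", which(df$x < 0)[1L])
    out_of_range <- df$i < 0 | df$j < 0 | df$i >= n_bins | df$j >= n_bins
    if (any(out_of_range))
      stop("bin index out of range (n_bins = ", n_bins, ") at row ",
           which(out_of_range)[1L])
    # canonicalize to upper triangle, summing duplicates, then mirror
    lo <- pmin(df$i, df$j); hi <- pmax(df$i, df$j)
    agg <- rowsum(df$x, paste(lo, hi))
    key <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
    i <- as.integer(key[, 1L]); j <- as.integer(key[, 2L]); x <- agg[, 1L]
    off <- i != j
    m <- Matrix::sparseMatrix(i = c(i, j[off]) + 1L, j = c(j, i[off]) + 1L,
                              x = c(x, x[off]), dims = c(n_bins, n_bins))
  } else {
    m <- as.matrix(read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != n_bins)
      stop("dense matrix has ", nrow(m), " rows; expected ", n_bins)
  }
  contact_matrix(m, chrom, resolution)
}

#' Write a contact matrix as COO TSV (upper triangle incl. diagonal)
#' @param cm a \code{ContactMatrix}.
#' @param path output path.
#' @export
write_contacts <- function(cm, path) {
  tt <- as(cm$mat, "TsparseMatrix")
  sel <- tt@i <= tt@j
  df <- data.frame(i = tt@i[sel], j = tt@j[sel], x = tt@x[sel])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# Knight-Ruiz inner-outer Newton iteration (translation of the published
# bnewt pseudocode, conjugate-gradient inner solve). Finds x > 0 with
# diag(x) A diag(x) doubly stochastic. Returns NULL when the iteration
# stalls or exceeds max_iter so the caller can fall back to Sinkhorn.
kr_newton <- function(A, tol = 1e-6, max_iter = 3000, delta = 0.1,
                      Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  n_mv <- 0L
  best <- Inf; stall <- 0L
  while (max(abs(rk)) > tol) {
    k <- 0L; y <- e
    innertol <- max(eta^2 * rout, tol^2)
    rho_km2 <- rho_km1
    Z <- p <- w <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      denom <- sum(p * w)
      if (!is.finite(denom) || denom <= 0) return(NULL)
      alpha <- rho_km1 / denom
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > n) break
    }
    x <- x * y
    if (any(!is.finite(x)) || any(x <= 0)) return(NULL)
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    n_mv <- n_mv + k + 1L
    if (n_mv > max_iter) return(NULL)
    if (rout < best - 1e-30) { best <- rout; stall <- 0L } else {
      stall <- stall + 1L
      if (stall >= 50L) return(NULL)
    }
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / max(res_norm, .Machine$double.xmin))
  }
  x
}

# Damped symmetric Sinkhorn-Knopp: x <- x / sqrt(x * (A x)). Linear but
# robust; used when the Newton iteration stalls on awkward sparsity.
kr_sinkhorn <- function(A, tol = 1e-6, max_iter = 50000) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    r <- x * as.vector(A %*% x)
    if (max(abs(r - 1)) <= tol) return(x)
    x <- x / sqrt(r)
  }
  NULL
}

#' Knight-Ruiz balancing of a contact matrix
#'
#' Finds per-bin scale factors \code{x} such that
#' \code{diag(x) \%*\% M \%*\% diag(x)} has equal row sums on unmasked bins
#' (doubly stochastic up to a uniform scale), using the Knight-Ruiz
#' inner-outer Newton iteration with a symmetric Sinkhorn fallback when the
#' Newton step stalls. The balanced matrix is rescaled so its total mass
#' equals the input's. Bins with zero marginal (and, optionally, the sparsest
#' covered bins) are masked out and left at zero.
#'
#' @param cm raw-stage \code{ContactMatrix}.
#' @param tol convergence tolerance on the max row-sum residual (relative to
#'   the common target).
#' @param max_iter cap on matrix-vector products in the Newton solve.
#' @param mask_quantile additionally mask covered bins whose marginal is below
#'   this quantile of the nonzero marginals (default 0: mask only empty bins).
#' @return the balanced \code{ContactMatrix} (stage \code{balanced}) with
#'   attached fields: \code{bias} (per-bin multiplicative bias estimate,
#'   mean 1 on unmasked bins, \code{NA} on masked ones), \code{mask} (logical,
#'   \code{TRUE} = excluded), \code{total_raw} (input mass) and
#'   \code{residual}.
#' @export
kr_balance <- function(cm, tol = 1e-6, max_iter = 3000, mask_quantile = 0.0) {
  stopifnot(is(cm, "ContactMatrix"))
  if (cm$stage != "raw") stop("kr_balance expects a raw-stage matrix")
  M <- cm$mat
  marg <- Matrix::rowSums(M)
  if (all(marg == 0)) stop("cannot balance an all-zero matrix")
  mask <- marg == 0
  if (mask_quantile > 0) {
    thr <- quantile(marg[!mask], mask_quantile)
    mask <- mask | marg < thr
  }
  keep <- which(!mask)
  A <- M[keep, keep, drop = FALSE]
  x <- kr_newton(A, tol = tol, max_iter = max_iter)
  if (is.null(x)) x <- kr_sinkhorn(A, tol = tol)
  if (is.null(x))
    stop("KR balancing did not converge (residual above ", tol,
         " after Newton and Sinkhorn fallback)")
  B <- Matrix::Diagonal(x = x) %*% A %*% Matrix::Diagonal(x = x)
  resid <- max(abs(Matrix::rowSums(B) - 1))
  total <- sum(M)
  B <- B * (total / sum(B))
  out <- M * 0
  out[keep, keep] <- B
  bias <- rep(NA_real_, cm$n_bins)
  bias[keep] <- (1 / x) / mean(1 / x)  # multiplicative bias, mean 1
  res <- contact_matrix(out, cm$chrom, cm$resolution, stage = "balanced")
  res$bias <- bias
  res$mask <- mask
  res$total_raw <- total
  res$residual <- resid
  res
}

#' Distance-decay expected contact intensity
#'
#' For every bin offset \code{d >= 1} counts the number of positional bin
#' pairs \code{n = n_bins - d} (zero entries included), sums the observed
#' values \code{N} at that offset, and forms the expected intensity
#' \code{E_d = N / n}. The diagonal (\code{d = 0}) is excluded.
#'
#' @param cm a \code{ContactMatrix} (the normalization path applies this to
#'   the balanced matrix; raw matrices are accepted for the significance
#'   null).
#' @return data.frame with columns \code{d}, \code{n}, \code{N}, \code{E}.
#' @export
distance_expectation <- function(cm) {
  stopifnot(is(cm, "ContactMatrix"))
  nb <- cm$n_bins
  if (nb < 2L) stop("need at least 2 bins for a distance expectation")
  tt <- as(cm$mat, "TsparseMatrix")
  sel <- tt@i < tt@j
  d <- tt@j[sel] - tt@i[sel]
  N <- numeric(nb - 1L)
  if (any(sel)) {
    s <- rowsum(tt@x[sel], d)
    N[as.integer(rownames(s))] <- s[, 1L]
  }
  dd <- seq_len(nb - 1L)
  data.frame(d = dd, n = nb - dd, N = N, E = N / (nb - dd))
}

#' Observed/expected distance normalization
#'
#' Divides every off-diagonal entry by the expected intensity at its distance.
#' Entries at distances with \code{E_d = 0} and diagonal entries are dropped.
#' By construction the mean of the normalized values over each distance
#' stratum (zeros included) is exactly 1.
#'
#' @param cm balanced-stage \code{ContactMatrix}.
#' @param expd output of \code{\link{distance_expectation}} on \code{cm}.
#' @return \code{ContactMatrix} at stage \code{distance_normalized}; carries
#'   over \code{bias}/\code{mask}/\code{total_raw} when present.
#' @export
normalize_by_distance <- function(cm, expd = NULL) {
  stopifnot(is(cm, "ContactMatrix"))
  if (cm$stage != "balanced")
    stop("normalize_by_distance expects a balanced matrix")
  if (is.null(expd)) expd <- distance_expectation(cm)
  tt <- as(cm$mat, "TsparseMatrix")
  sel <- tt@i < tt@j
  i <- tt@i[sel]; j <- tt@j[sel]; x <- tt@x[sel]
  E <- expd$E[j - i]  # expd$d == seq, so index by offset
  ok <- E > 0
  i <- i[ok]; j <- j[ok]; x <- x[ok] / E[ok]
  m <- Matrix::sparseMatrix(i = c(i, j) + 1L, j = c(j, i) + 1L, x = c(x, x),
                            dims = c(cm$n_bins, cm$n_bins))
  res <- contact_matrix(m, cm$chrom, cm$resolution,
                        stage = "distance_normalized")
  res$bias <- cm$bias
  res$mask <- cm$mask
  res$total_raw <- cm$total_raw
  res
}

#' Export the bias vector as TSV
#' @param cm balanced \code{ContactMatrix}.
#' @param path output path.
#' @export
write_bias <- function(cm, path) {
  if (is.null(cm$bias)) stop("matrix has no bias vector; run kr_balance first")
  write.table(data.frame(bin = seq_along(cm$bias) - 1L, bias = cm$bias,
                         masked = cm$mask),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
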