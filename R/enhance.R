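# Network enhancement: diffusion-based denoising of the weighted interaction
# network through a k-NN-localized, doubly stochastic transition operator.

#' k-nearest-neighbour localization of a weight matrix
#'
#' Keeps entry \code{(i, j)} iff \code{j} is among \code{i}'s \code{k}
#' largest-weight neighbours or \code{i} is among \code{j}'s; kept entries
#' are rescaled row-wise (rows sum to 1 where nonzero) and the result is
#' symmetrized as \code{(A + t(A)) / 2}.
#'
#' @param W symmetric non-negative weight matrix with zero diagonal.
#' @param k neighbourhood size; \code{k >= n} returns \code{W} unchanged
#'   with a warning.
#' @return localized symmetric matrix.
#' @export
localize_knn <- function(W, k) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(n == ncol(W), k >= 1)
  if (any(abs(diag(W)) > 0)) stop("W must have a zero diagonal")
  if (max(abs(W - t(W))) > 1e-12 * max(1, max(abs(W))))
    stop("W must be symmetric")
  if (k >= n) {
    warning("k >= number of nodes; localization is a no-op")
    keep <- W > 0
  } else {
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      o <- order(W[i, ], decreasing = TRUE)[seq_len(k)]
      o <- o[W[i, o] > 0]
      keep[i, o] <- TRUE
    }
    keep <- keep | t(keep)
  }
  A <- W * keep
  rs <- rowSums(A)
  A <- A / ifelse(rs > 0, rs, 1)
  (A + t(A)) / 2
}

# Symmetric Sinkhorn scaling to (approximately) unit row/column sums on the
# nonzero support; zero rows (isolated nodes) are left untouched.
ds_scale <- function(A, tol = 1e-10, max_iter = 1000) {
  nz <- rowSums(A) > 0
  x <- rep(1, nrow(A))
  for (it in seq_len(max_iter)) {
    r <- x * as.vector(A %*% x)
    if (max(abs(r[nz] - 1)) <= tol) break
    x[nz] <- x[nz] / sqrt(r[nz])
  }
  diag(x) %*% A %*% diag(x)
}

#' Network-enhancement diffusion of a weight matrix
#'
#' Builds the localized, doubly stochastic transition operator \code{T} from
#' \code{W} (\code{\link{localize_knn}} then symmetric Sinkhorn scaling) and
#' iterates the second-order diffusion
#' \deqn{W_{t+1} = \alpha T W_t T' + (1 - \alpha) T}
#' from \code{W_0 = T} until the largest entry change falls below \code{tol}
#' or \code{max_iter} is hit (then the last iterate is returned with a
#' warning and \code{attr(, "converged") = FALSE}). The result is
#' symmetrized, its diagonal zeroed, rescaled to the input's total weight
#' (so degree statistics stay comparable pre/post), and sparsified by
#' dropping entries below \code{1e-6} of the maximum.
#'
#' @param W symmetric non-negative weight matrix, zero diagonal.
#' @param k_neighbors localization neighbourhood size (default 20).
#' @param alpha regularization weight in (0, 1) (default 0.9); small values
#'   keep the output close to the one-step operator \code{T}.
#' @param order diffusion order; 2 (default) uses \code{T W T'}, 1 uses the
#'   one-sided \code{T W} followed by symmetrization.
#' @param max_iter,tol iteration controls.
#' @param rescale_total rescale output mass to the input mass (default
#'   \code{TRUE}).
#' @return enhanced weight matrix (dense), with attribute \code{converged}.
#' @export
enhance_matrix <- function(W, k_neighbors = 20, alpha = 0.9, order = 2,
                           max_iter = 200, tol = 1e-8,
                           rescale_total = TRUE) {
  stopifnot(alpha > 0, alpha < 1, order %in% c(1, 2))
  W <- as.matrix(W)
  n <- nrow(W)
  Tm <- suppressWarnings(localize_knn(W, min(k_neighbors, n)))
  Tm <- ds_scale(Tm)
  Wt <- Tm
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Wn <- if (order == 2) alpha * Tm %*% Wt %*% t(Tm) + (1 - alpha) * Tm
          else alpha * Tm %*% Wt + (1 - alpha) * Tm
    delta <- max(abs(Wn - Wt))
    Wt <- Wn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("network enhancement did not converge within ", max_iter,
            " iterations")
  Wt <- (Wt + t(Wt)) / 2
  diag(Wt) <- 0
  if (rescale_total && sum(Wt) > 0) Wt <- Wt * (sum(W) / sum(Wt))
  mx <- max(Wt)
  if (mx > 0) Wt[Wt < 1e-6 * mx] <- 0
  attr(Wt, "converged") <- converged
  Wt
}

#' Enhance an interaction network
#'
#' Applies \code{\link{enhance_matrix}} to the graph's weighted adjacency
#' matrix (raw interaction counts are the conventional input weight) and
#' returns a graph on the same node set whose edges carry the enhanced
#' weights (edges whose enhanced weight was sparsified away are dropped; no
#' new edges appear at isolated nodes).
#'
#' @param g igraph network from \code{\link{build_network}}.
#' @param k_neighbors,alpha,order,max_iter,tol see
#'   \code{\link{enhance_matrix}}.
#' @param weight_attr edge attribute to diffuse (default \code{raw_count}).
#' @return igraph graph, \code{provenance = "enhanced"}; edge attribute
#'   \code{weight} (= enhanced weight) plus \code{enhanced_weight}.
#' @export
enhance_network <- function(g, k_neighbors = 20, alpha = 0.9, order = 2,
                            max_iter = 200, tol = 1e-8,
                            weight_attr = "raw_count") {
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = weight_attr,
                                             sparse = TRUE))
  We <- enhance_matrix(W, k_neighbors = k_neighbors, alpha = alpha,
                       order = order, max_iter = max_iter, tol = tol)
  dimnames(We) <- list(igraph::V(g)$name, igraph::V(g)$name)
  ge <- igraph::graph_from_adjacency_matrix(We, mode = "undirected",
                                            weighted = TRUE)
  igraph::V(ge)$gene_class <-
    igraph::V(g)$gene_class[match(igraph::V(ge)$name, igraph::V(g)$name)]
  igraph::E(ge)$enhanced_weight <- igraph::E(ge)$weight
  ge <- igraph::set_graph_attr(ge, "provenance", "enhanced")
  ge <- igraph::set_graph_attr(ge, "converged",
                               isTRUE(attr(We, "converged")))
  ge
}
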