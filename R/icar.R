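#' Intrinsic CAR precision matrix
#'
#' For an undirected area graph the intrinsic conditional autoregressive
#' (ICAR / Gaussian Markov random field) prior on the structured spatial
#' effect has precision `Q = diag(degree) - A`, where `A` is the 0/1
#' adjacency matrix. `Q` is symmetric, its rows sum to zero, and for a
#' connected graph its rank is `n_areas - 1` (the null space is the constant
#' vector, which is why a sum-to-zero constraint is imposed on the effect).
#'
#' @param graph an [adjacency_graph()]; must be connected.
#' @return An object of class `icar_precision`: list with `matrix`
#'   (dense `n x n`) and `n_areas`.
#' @export
icar_precision <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (!is_connected(graph)) {
    comp <- graph_components(graph)
    stop(sprintf(
      "graph is disconnected (%d components; sizes %s): ICAR precision would have rank deficiency > 1",
      max(comp), paste(tabulate(comp), collapse = ", ")))
  }
  n <- graph$n_areas
  Q <- matrix(0, n, n)
  if (nrow(graph$edges) > 0L) {
    i <- graph$edges[, 1L]; j <- graph$edges[, 2L]
    Q[cbind(i, j)] <- -1
    Q[cbind(j, i)] <- -1
  }
  diag(Q) <- graph_degrees(graph)
  if (!is.null(graph$area_labels)) dimnames(Q) <- list(graph$area_labels, graph$area_labels)
  structure(list(matrix = Q, n_areas = n), class = "icar_precision")
}

#' Draw a structured spatial field from the intrinsic GMRF
#'
#' Samples a zero-centred Gaussian field with precision `Q / sigma^2`
#' restricted to the sum-to-zero subspace: the ICAR precision is
#' eigendecomposed, the null eigenvector (constant) is dropped, and
#' independent normals with variance `sigma^2 / lambda_k` are mapped back
#' through the remaining eigenvectors. The resulting draw sums to zero by
#' construction and has covariance `sigma^2 * pinv(Q)`.
#'
#' @param graph a connected [adjacency_graph()].
#' @param sigma marginal scale (standard deviation multiplier), `>= 0`.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of length `n_areas`, summing to zero.
#' @export
sample_icar_field <- function(graph, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  Q <- icar_precision(graph)$matrix   # errors on disconnected graphs
  n <- nrow(Q)
  if (sigma == 0 || n == 1L) return(numeric(n))
  if (!is.null(seed)) set.seed(as.integer(seed))
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values[seq_len(n - 1L)]   # positive part; last is the ~0 null mode
  V <- eg$vectors[, seq_len(n - 1L), drop = FALSE]
  z <- stats::rnorm(n - 1L, sd = sigma / sqrt(lam))
  x <- drop(V %*% z)
  x - mean(x)   # remove numerical residue of the null mode
}
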