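#' B-spline basis on an equidistant knot grid
#'
#' Builds the P-spline design for the nonlinear age effect: `n_interior`
#' equidistant interior knots over the observed range, boundary knots
#' extended equidistantly so that every basis function is fully supported,
#' giving `m = n_interior + degree + 1` basis columns. Rows satisfy the
#' partition of unity (sum to one) over the data range.
#'
#' @param x numeric vector of evaluation points (e.g. mother's age).
#' @param degree B-spline degree (default 3, cubic).
#' @param n_interior number of interior knots (default 20).
#' @param range optional length-2 numeric giving the knot range; defaults to
#'   `range(x)`. Supply it to evaluate a fitted smooth on a new grid with
#'   the same basis.
#' @return object of class `bspline_basis`: list with `basis` (matrix
#'   `length(x) x m`), `knots` (the full extended knot vector), `degree`,
#'   `n_interior`, `range`.
#' @export
bspline_basis <- function(x, degree = 3L, n_interior = 20L, range = NULL) {
  if (any(!is.finite(x))) stop("x must be finite")
  if (n_interior < 1L) stop("need at least one interior knot")
  if (is.null(range)) range <- base::range(x)
  lo <- range[1L]; hi <- range[2L]
  if (hi <= lo) stop("degenerate range: x must span an interval")
  h <- (hi - lo) / (n_interior + 1)
  knots <- seq(lo - degree * h, hi + degree * h, by = h)
  # guard against floating-point undershoot of the last knot
  if (length(knots) < n_interior + 2L * degree + 2L)
    knots <- c(knots, knots[length(knots)] + h)
  B <- splines::splineDesign(knots, x, ord = degree + 1L, outer.ok = TRUE)
  structure(list(basis = B, knots = knots, degree = degree,
                 n_interior = as.integer(n_interior), range = range),
            class = "bspline_basis")
}

#' Evaluate an existing basis at new points
#' @param basis a [bspline_basis()].
#' @param x new evaluation points (clamped to the basis range).
#' @return matrix `length(x) x m`.
#' @export
evaluate_basis <- function(basis, x) {
  x <- pmin(pmax(x, basis$range[1L]), basis$range[2L])
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1L, outer.ok = TRUE)
}

#' Random-walk difference penalty matrix
#'
#' `K = t(D_r) %*% D_r` with `D_r` the r-th order difference operator on
#' `m` coefficients: the (improper) precision of the Bayesian P-spline
#' random-walk prior. `K` is symmetric positive semidefinite with rank
#' `m - r`; polynomials of degree `< r` span its null space.
#'
#' @param m number of basis coefficients.
#' @param order difference order `r >= 1` (default 2).
#' @return object of class `penalty_matrix`: list with `matrix`, `order`,
#'   `rank`.
#' @export
difference_penalty <- function(m, order = 2L) {
  m <- as.integer(m); order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (m <= order) stop("need m > order coefficients")
  D <- diff(diag(m), differences = order)
  K <- crossprod(D)
  structure(list(matrix = K, order = order, rank = m - order),
            class = "penalty_matrix")
}
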