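# Independent oracles used to check package computations. These are
# deliberately naive re-derivations (enumeration, textbook recursions,
# Newton-Raphson) kept separate from the implementation paths they verify.

# Two-sided Fisher exact p-value by full enumeration over tables with the
# observed margins: sum hypergeometric probabilities <= P(observed).
fisher_enumeration_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  amin <- max(0L, r1 + c1 - n); amax <- min(r1, c1)
  pr <- function(x) stats::dhyper(x, c1, n - c1, r1)
  p_obs <- pr(a)
  xs <- amin:amax
  sum(pr(xs)[pr(xs) <= p_obs * (1 + 1e-7)])
}

# Cox-de Boor recursion, one basis function at a time.
deboor_basis <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  N0 <- function(i, x) as.numeric(knots[i] <= x & x < knots[i + 1L])
  Nrec <- function(i, d, x) {
    if (d == 0L) return(N0(i, x))
    left <- 0
    if (knots[i + d] > knots[i])
      left <- (x - knots[i]) / (knots[i + d] - knots[i]) * Nrec(i, d - 1L, x)
    right <- 0
    if (knots[i + d + 1L] > knots[i + 1L])
      right <- (knots[i + d + 1L] - x) / (knots[i + d + 1L] - knots[i + 1L]) *
        Nrec(i + 1L, d - 1L, x)
    left + right
  }
  sapply(seq_len(nb), function(i) Nrec(i, degree, x))
}

# Probit maximum likelihood by Newton-Raphson on the log-likelihood.
probit_mle_nr <- function(y, X, tol = 1e-10, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
    phi <- dnorm(eta)
    score_i <- phi * (y - p) / (p * (1 - p))
    grad <- drop(crossprod(X, score_i))
    w <- phi^2 / (p * (1 - p))           # expected information weights
    H <- crossprod(X * w, X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, vcov = solve(H))
}

# Moore-Penrose pseudoinverse via symmetric eigendecomposition.
sym_pinv <- function(A, tol = 1e-10) {
  eg <- eigen(A, symmetric = TRUE)
  keep <- abs(eg$values) > tol * max(abs(eg$values))
  eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / eg$values[keep], sum(keep)) %*%
    t(eg$vectors[, keep, drop = FALSE])
}

# Small test cohort shared across model tests.
make_test_cohort <- function(n_mothers = 1200, seed = 42, graph = NULL, ...) {
  if (is.null(graph)) graph <- make_lattice_adjacency(4, 4)
  cfg <- simulation_config(n_mothers = n_mothers, seed = seed, ...)
  simulate_cohort(cfg, graph)
}
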