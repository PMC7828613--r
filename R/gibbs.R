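#' MCMC schedule
#'
#' @param n_iter total iterations (default 25,000).
#' @param burn_in discarded warm-up iterations (default 5,000).
#' @param thin keep every `thin`-th post-burn-in draw (default 10).
#' @param seed integer RNG seed.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 25000L, burn_in = 5000L, thin = 10L, seed = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# One-sided truncated-normal draws via inverse-CDF, vectorised over
# observations: z_i ~ N(eta_i, 1) truncated to z > 0 where y = 1 and
# z < 0 where y = 0 (Albert-Chib augmentation).
draw_latent <- function(y, eta) {
  p0 <- stats::pnorm(-eta)                 # P(z < 0)
  un <- stats::runif(length(y))
  u <- ifelse(y == 1L, p0 + un * (1 - p0), un * p0)
  u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  z <- eta + stats::qnorm(u)
  pmin(pmax(z, eta - 8), eta + 8)          # numerical guard in extreme tails
}

probit_deviance <- function(y, eta) {
  p <- stats::pnorm(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log1p(-p))
}

#' Gibbs sampler for the Bayesian probit STAR model
#'
#' Albert-Chib data augmentation: latent Gaussian utilities are drawn from
#' their truncated-normal full conditionals, after which every coefficient
#' block has a Gaussian full conditional and every variance an
#' inverse-gamma one. Blocks: fixed effects (flat prior, precision 1e-8);
#' P-spline coefficients with random-walk penalty precision `K / tau2`;
#' i.i.d. mother random intercepts; structured spatial effect with ICAR
#' precision `Q / sigma2_str`; i.i.d. unstructured spatial effect. The
#' spline fit and the structured spatial effect are re-centred to mean zero
#' every iteration, the shift being absorbed into the intercept
#' (identifiability under the improper RW/ICAR priors). Variance updates
#' use shape `a + rank/2` and scale `b + quadratic_form/2`. The probit
#' deviance is recorded at every stored draw.
#'
#' @param design a [assemble_design()] result.
#' @param mcmc an [mcmc_config()].
#' @param verbose print deviance every 100 iterations?
#' @return list of class `posterior_draws`: matrices `gamma`, `beta`,
#'   `mother`, `structured`, `unstructured` (stored draws x block size;
#'   NULL when the block is absent), `variances` (stored draws x component),
#'   `deviance` vector, `n_stored`, and the `mcmc` and `design` metadata
#'   needed to summarise. A warning is raised if any variance draw exceeded
#'   1e6 (divergence guard); affected iterations are flagged in
#'   `divergent_iterations`.
#' @export
gibbs_probit <- function(design, mcmc = mcmc_config(), verbose = FALSE) {
  stopifnot(inherits(design, "star_design"), inherits(mcmc, "mcmc_config"))
  set.seed(mcmc$seed)
  y <- design$y
  n <- length(y)
  if (n == 0L) stop("empty design")
  spec <- design$spec
  a0 <- spec$hyper_a; b0 <- spec$hyper_b

  X <- design$X; p <- ncol(X)
  XtX <- crossprod(X)
  ch_gamma <- chol(XtX + diag(1e-8, p))
  gamma <- numeric(p)
  ybar <- min(max(mean(y), 1e-3), 1 - 1e-3)
  gamma[1L] <- stats::qnorm(ybar)

  has_spline <- !is.null(design$B)
  if (has_spline) {
    B <- design$B; m <- ncol(B)
    BtB <- crossprod(B)
    K <- difference_penalty(m, spec$penalty_order)$matrix
    rank_K <- m - spec$penalty_order
    beta <- numeric(m); tau2 <- 0.1
  }
  has_mother <- !is.null(design$mother_index)
  if (has_mother) {
    im <- design$mother_index; M <- design$n_mothers
    nm <- tabulate(im, M)
    b <- numeric(M); s2b <- 0.1
  }
  has_spatial <- !is.null(design$area_index)
  if (has_spatial) {
    ia <- design$area_index
    Q <- design$Q; S <- nrow(Q)
    na_cnt <- tabulate(ia, S)
    u <- numeric(S); s2u <- 0.1
    v <- numeric(S); s2v <- 0.1
  }

  # running linear-predictor components
  ef <- drop(X %*% gamma)
  fs <- if (has_spline) drop(B %*% beta) else 0
  fm <- if (has_mother) b[im] else 0
  fu <- if (has_spatial) u[ia] else 0
  fv <- if (has_spatial) v[ia] else 0

  n_stored <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  G <- matrix(NA_real_, n_stored, p, dimnames = list(NULL, colnames(X)))
  Bd <- if (has_spline) matrix(NA_real_, n_stored, m) else NULL
  Md <- if (has_mother) matrix(NA_real_, n_stored, M) else NULL
  Ud <- if (has_spatial) matrix(NA_real_, n_stored, S) else NULL
  Vd <- if (has_spatial) matrix(NA_real_, n_stored, S) else NULL
  vn <- c(if (has_spline) "tau2_spline",
          if (has_mother) "sigma2_mother",
          if (has_spatial) c("sigma2_structured", "sigma2_unstructured"))
  VV <- matrix(NA_real_, n_stored, length(vn), dimnames = list(NULL, vn))
  dev <- numeric(n_stored)
  divergent <- integer(0)

  rsum_full <- function(r, idx, nbin) {
    out <- numeric(nbin)
    rs <- rowsum(r, idx)
    out[as.integer(rownames(rs))] <- rs
    out
  }

  s <- 0L
  for (it in seq_len(mcmc$n_iter)) {
    eta <- ef + fs + fm + fu + fv
    z <- draw_latent(y, eta)

    # fixed block
    r <- z - fs - fm - fu - fv
    ghat <- backsolve(ch_gamma, forwardsolve(t(ch_gamma), crossprod(X, r)))
    gamma <- drop(ghat) + backsolve(ch_gamma, stats::rnorm(p))
    ef <- drop(X %*% gamma)

    # spline block
    if (has_spline) {
      r <- z - ef - fm - fu - fv
      P <- BtB + K / tau2
      ch <- chol(P)
      bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(B, r)))
      beta <- drop(bhat) + backsolve(ch, stats::rnorm(m))
      fs <- drop(B %*% beta)
      ctr <- mean(fs)               # partition of unity: shift beta, shift fit
      beta <- beta - ctr
      fs <- fs - ctr
      gamma[1L] <- gamma[1L] + ctr
      ef <- ef + ctr
      tau2 <- 1 / stats::rgamma(1L, a0 + rank_K / 2,
                                b0 + drop(crossprod(beta, K %*% beta)) / 2)
    }

    # mother random intercepts
    if (has_mother) {
      r <- z - ef - fs - fu - fv
      prec <- nm + 1 / s2b
      b <- rsum_full(r, im, M) / prec + stats::rnorm(M) / sqrt(prec)
      fm <- b[im]
      s2b <- 1 / stats::rgamma(1L, a0 + M / 2, b0 + sum(b^2) / 2)
    }

    if (has_spatial) {
      # structured (ICAR) block
      r <- z - ef - fs - fm - fv
      P <- Q / s2u
      diag(P) <- diag(P) + na_cnt
      ch <- chol(P)
      uhat <- backsolve(ch, forwardsolve(t(ch), rsum_full(r, ia, S)))
      u <- drop(uhat) + backsolve(ch, stats::rnorm(S))
      ctr <- mean(u)
      u <- u - ctr
      gamma[1L] <- gamma[1L] + ctr
      ef <- ef + ctr
      fu <- u[ia]
      s2u <- 1 / stats::rgamma(1L, a0 + (S - 1) / 2,
                               b0 + drop(crossprod(u, Q %*% u)) / 2)

      # unstructured block
      r <- z - ef - fs - fm - fu
      prec <- na_cnt + 1 / s2v
      v <- rsum_full(r, ia, S) / prec + stats::rnorm(S) / sqrt(prec)
      fv <- v[ia]
      s2v <- 1 / stats::rgamma(1L, a0 + S / 2, b0 + sum(v^2) / 2)
    }

    vars_now <- c(if (has_spline) tau2,
                  if (has_mother) s2b,
                  if (has_spatial) c(s2u, s2v))
    if (length(vars_now) && any(vars_now > 1e6)) divergent <- c(divergent, it)

    store <- it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L
    if (store) {
      s <- s + 1L
      G[s, ] <- gamma
      if (has_spline) Bd[s, ] <- beta
      if (has_mother) Md[s, ] <- b
      if (has_spatial) { Ud[s, ] <- u; Vd[s, ] <- v }
      if (length(vn)) VV[s, ] <- vars_now
      dev[s] <- probit_deviance(y, ef + fs + fm + fu + fv)
    }
    if (verbose && it %% 100L == 0L)
      message(sprintf("iter %d: deviance %.1f", it,
                      probit_deviance(y, ef + fs + fm + fu + fv)))
  }

  if (length(divergent))
    warning(sprintf("divergence guard: variance draw exceeded 1e6 at %d iteration(s)",
                    length(divergent)), call. = FALSE)

  structure(list(gamma = G, beta = Bd, mother = Md,
                 structured = Ud, unstructured = Vd,
                 variances = VV, deviance = dev, n_stored = n_stored,
                 divergent_iterations = divergent,
                 mcmc = mcmc, outcome = design$outcome),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d stored draws (%d iter, burn-in %d, thin %d); mean deviance %.1f\n",
              x$n_stored, x$mcmc$n_iter, x$mcmc$burn_in, x$mcmc$thin,
              mean(x$deviance)))
  invisible(x)
}
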