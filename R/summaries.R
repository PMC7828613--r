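#' Deviance information criterion from stored draws
#'
#' `Dbar` is the mean stored deviance; `D_hat` is the deviance at the
#' posterior means of all coefficient blocks; `pD = Dbar - D_hat` is the
#' effective number of parameters and `DIC = Dbar + pD`.
#'
#' @param draws a [gibbs_probit()] result.
#' @param design the matching [assemble_design()] result.
#' @return list with `dic`, `pd`, `dbar`, `dhat`.
#' @export
compute_dic <- function(draws, design) {
  stopifnot(inherits(draws, "posterior_draws"), inherits(design, "star_design"))
  if (draws$n_stored < 2L) stop("need at least 2 stored draws")
  dbar <- mean(draws$deviance)
  eta <- drop(design$X %*% colMeans(draws$gamma))
  if (!is.null(draws$beta)) eta <- eta + drop(design$B %*% colMeans(draws$beta))
  if (!is.null(draws$mother)) eta <- eta + colMeans(draws$mother)[design$mother_index]
  if (!is.null(draws$structured))
    eta <- eta + colMeans(draws$structured)[design$area_index] +
      colMeans(draws$unstructured)[design$area_index]
  dhat <- probit_deviance(design$y, eta)
  pd <- dbar - dhat
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

eqtail <- function(x, probs) unname(stats::quantile(x, probs, names = FALSE))

summary_block <- function(mat, names = NULL) {
  if (is.null(names)) names <- colnames(mat)
  if (is.null(names)) names <- paste0("par", seq_len(ncol(mat)))
  data.frame(
    name = names,
    mean = colMeans(mat),
    ci_low = apply(mat, 2L, function(x) eqtail(x, 0.025)),
    ci_high = apply(mat, 2L, function(x) eqtail(x, 0.975)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# split-chain potential scale reduction factor (two halves of one chain)
split_rhat <- function(x) {
  S <- length(x)
  half <- S %/% 2L
  ch <- cbind(x[seq_len(half)], x[(S - half + 1L):S])
  mns <- colMeans(ch); vrs <- apply(ch, 2L, stats::var)
  W <- mean(vrs)
  Bv <- half * stats::var(mns)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + Bv / half) / W)
}

# initial-positive-sequence effective sample size
ess_basic <- function(x) {
  S <- length(x)
  if (stats::var(x) == 0) return(S)
  ac <- stats::acf(x, lag.max = min(S - 1L, 200L), plot = FALSE)$acf[-1L]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0) break
    s <- s + ac[k]
  }
  S / (1 + 2 * s)
}

#' Posterior summaries for a fitted STAR model
#'
#' Equal-tailed posterior means and 95% credible intervals for every fixed
#' effect and variance component; the age smooth evaluated on a grid with
#' 80% and 95% bands; per-area structured, unstructured and total (sum)
#' spatial effects; DIC components; and basic convergence diagnostics
#' (split-chain Rhat and effective sample size per fixed effect and for
#' the deviance).
#'
#' @param draws a [gibbs_probit()] result.
#' @param design the matching [assemble_design()] result.
#' @param age_grid numeric grid for the smooth summary (empty/NULL to skip).
#' @return list of class `fit_result` with `fixed`, `variances`, `smooth`,
#'   `spatial`, `dic`, `pd`, `dbar`, `diagnostics`, `audit`, `outcome`.
#' @export
summarize_posterior <- function(draws, design, age_grid = NULL) {
  stopifnot(inherits(draws, "posterior_draws"), inherits(design, "star_design"))
  fixed <- summary_block(draws$gamma)
  variances <- if (!is.null(draws$variances) && ncol(draws$variances))
    summary_block(draws$variances) else NULL

  smooth <- NULL
  if (!is.null(draws$beta) && !is.null(age_grid) && length(age_grid)) {
    Bg <- evaluate_basis(design$basis, age_grid)
    fg <- draws$beta %*% t(Bg)           # stored draws x grid
    smooth <- data.frame(
      age = age_grid,
      mean = colMeans(fg),
      lo80 = apply(fg, 2L, function(x) eqtail(x, 0.10)),
      hi80 = apply(fg, 2L, function(x) eqtail(x, 0.90)),
      lo95 = apply(fg, 2L, function(x) eqtail(x, 0.025)),
      hi95 = apply(fg, 2L, function(x) eqtail(x, 0.975)),
      row.names = NULL)
  }

  spatial <- NULL
  if (!is.null(draws$structured)) {
    tot <- draws$structured + draws$unstructured
    labels <- design$graph$area_labels
    if (is.null(labels)) labels <- as.character(seq_len(ncol(tot)))
    spatial <- data.frame(
      area_id = seq_len(ncol(tot)),
      area = labels,
      structured = colMeans(draws$structured),
      unstructured = colMeans(draws$unstructured),
      total = colMeans(tot),
      total_ci_low = apply(tot, 2L, function(x) eqtail(x, 0.025)),
      total_ci_high = apply(tot, 2L, function(x) eqtail(x, 0.975)),
      row.names = NULL, stringsAsFactors = FALSE)
  }

  dic <- compute_dic(draws, design)
  diagnostics <- data.frame(
    name = c(fixed$name, "deviance"),
    rhat = c(apply(draws$gamma, 2L, split_rhat), split_rhat(draws$deviance)),
    ess = c(apply(draws$gamma, 2L, ess_basic), ess_basic(draws$deviance)),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(fixed = fixed, variances = variances, smooth = smooth,
                 spatial = spatial, dic = dic$dic, pd = dic$pd,
                 dbar = dic$dbar, diagnostics = diagnostics,
                 audit = design$audit, outcome = design$outcome),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): DIC %.1f (Dbar %.1f, pD %.1f)\n",
              x$outcome, x$dic, x$dbar, x$pd))
  print(within(x$fixed, {
    mean <- round(mean, 3); ci_low <- round(ci_low, 3); ci_high <- round(ci_high, 3)
  }))
  invisible(x)
}

#' Fit one probit STAR model end to end
#'
#' Convenience wrapper: assemble the design, run the Gibbs sampler and
#' summarise the posterior.
#'
#' @param births birth records data frame.
#' @param spec a [model_spec()].
#' @param graph a connected [adjacency_graph()].
#' @param outcome `"stillbirth"`, `"lbw"` or `"preterm"`.
#' @param mcmc an [mcmc_config()].
#' @param age_grid grid for the smooth summary (default 15..49).
#' @param verbose progress messages from the sampler.
#' @return a `fit_result` (with the raw `draws` attached as attribute
#'   `"draws"` and the design as `"design"`).
#' @export
fit_star_model <- function(births, spec, graph, outcome = "stillbirth",
                           mcmc = mcmc_config(), age_grid = 15:49,
                           verbose = FALSE) {
  design <- assemble_design(births, spec, graph, outcome)
  draws <- gibbs_probit(design, mcmc, verbose = verbose)
  out <- summarize_posterior(draws, design, age_grid)
  attr(out, "draws") <- draws
  attr(out, "design") <- design
  out
}
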