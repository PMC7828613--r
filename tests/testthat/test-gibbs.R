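make_fixed_design <- function(n, gamma0, gamma1, seed) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.6)
  eta <- gamma0 + gamma1 * x
  y <- rbinom(n, 1, pnorm(eta))
  births <- data.frame(
    birth_id = seq_len(n), mother_id = seq_len(n), area_id = 1L,
    region = "R1", outcome_stillbirth = y, fuel_unclean = x,
    mother_age = runif(n, 15, 49), education = "none",
    wealth = 1L, smoker = 0L)
  g1 <- adjacency_graph(2, rbind(c(1, 2)))  # unused when spatial = FALSE
  assemble_design(births, model_spec(fixed = "fuel", spatial = FALSE), g1,
                  "stillbirth")
}

test_that("all-ones outcome forces a positive intercept", {
  births <- data.frame(
    birth_id = 1:50, mother_id = 1:50, area_id = 1L, region = "R1",
    outcome_stillbirth = 1L, fuel_unclean = 0L, mother_age = 30,
    education = "none", wealth = 1L, smoker = 0L)
  d <- assemble_design(births, model_spec(fixed = NULL, spatial = FALSE),
                       adjacency_graph(1, matrix(integer(), ncol = 2)),
                       "stillbirth")
  draws <- gibbs_probit(d, mcmc_config(400, 100, 2, seed = 1))
  expect_gt(mean(draws$gamma[, "intercept"]), 0)
})

test_that("sampler is bit-reproducible under a fixed seed", {
  co <- make_test_cohort(n_mothers = 300, seed = 19)
  sp <- model_spec(fixed = "fuel", mother_effect = TRUE, smooth_age = TRUE)
  d <- assemble_design(co$births, sp, co$graph, "stillbirth")
  mc <- mcmc_config(300, 100, 4, seed = 77)
  d1 <- gibbs_probit(d, mc)
  d2 <- gibbs_probit(d, mc)
  expect_identical(d1$gamma, d2$gamma)
  expect_identical(d1$deviance, d2$deviance)
  expect_equal(d1$n_stored, 50)
  expect_true(all(d1$variances > 0))
})

test_that("posterior mean tracks the probit MLE for a fixed-effects fit", {
  d <- make_fixed_design(4000, -1.0, 0.5, seed = 55)
  mle <- probit_mle_nr(d$y, d$X)
  draws <- gibbs_probit(d, mcmc_config(1500, 300, 2, seed = 5))
  pm <- colMeans(draws$gamma)
  psd <- apply(draws$gamma, 2, sd)
  expect_lt(abs(pm[1] - mle$coef[1]), 3 * psd[1])
  expect_lt(abs(pm[2] - mle$coef[2]), 3 * psd[2])
  # posterior sd close to the frequentist standard error under flat priors
  expect_lt(abs(psd[2] / sqrt(mle$vcov[2, 2]) - 1), 0.35)
})

test_that("spline fit and structured spatial draws are centred at every stored draw", {
  co <- make_test_cohort(n_mothers = 500, seed = 23)
  sp <- model_spec(fixed = "fuel", smooth_age = TRUE, mother_effect = TRUE,
                   spatial = TRUE)
  d <- assemble_design(co$births, sp, co$graph, "stillbirth")
  draws <- gibbs_probit(d, mcmc_config(400, 100, 3, seed = 3))
  fs <- draws$beta %*% t(d$B)       # stored draws x n: spline fit values
  expect_lt(max(abs(rowMeans(fs))), 1e-8)
  expect_lt(max(abs(rowMeans(draws$structured))), 1e-8)
})

test_that("DIC identity holds and pD matches the flat-prior parameter count", {
  d <- make_fixed_design(2500, -0.8, 0.4, seed = 31)
  draws <- gibbs_probit(d, mcmc_config(4200, 200, 1, seed = 9))
  dic <- compute_dic(draws, d)
  expect_equal(dic$dic, dic$dbar + dic$pd, tolerance = 1e-12)
  expect_equal(dic$pd, dic$dbar - dic$dhat, tolerance = 1e-12)
  # two flat-prior fixed effects: effective parameter count ~ 2
  expect_lt(abs(dic$pd - 2), 0.2)
})

test_that("posterior summaries have coherent intervals and nested bands", {
  co <- make_test_cohort(n_mothers = 500, seed = 29)
  sp <- model_spec(fixed = "fuel", smooth_age = TRUE, mother_effect = TRUE)
  d <- assemble_design(co$births, sp, co$graph, "stillbirth")
  draws <- gibbs_probit(d, mcmc_config(500, 100, 4, seed = 13))
  fr <- summarize_posterior(draws, d, age_grid = 15:49)
  expect_true(all(fr$fixed$ci_low <= fr$fixed$mean + 1e-12))
  expect_true(all(fr$fixed$mean <= fr$fixed$ci_high + 1e-12))
  expect_true(all(fr$smooth$lo95 <= fr$smooth$lo80))
  expect_true(all(fr$smooth$hi80 <= fr$smooth$hi95))
  expect_equal(fr$spatial$total,
               fr$spatial$structured + fr$spatial$unstructured,
               tolerance = 1e-12)
  expect_true(all(c("rhat", "ess") %in% names(fr$diagnostics)))
  # degenerate draws: constant vector summarised as (c, c, c)
  cm <- matrix(2.5, 40, 1, dimnames = list(NULL, "k"))
  sb <- hapstar:::summary_block(cm)
  expect_equal(unlist(sb[, c("mean", "ci_low", "ci_high")], use.names = FALSE),
               c(2.5, 2.5, 2.5))
})

test_that("empty age grid omits the smooth summary without error", {
  co <- make_test_cohort(n_mothers = 300, seed = 41)
  sp <- model_spec(fixed = "fuel", smooth_age = TRUE)
  d <- assemble_design(co$births, sp, co$graph, "stillbirth")
  draws <- gibbs_probit(d, mcmc_config(200, 50, 3, seed = 2))
  fr <- summarize_posterior(draws, d, age_grid = NULL)
  expect_null(fr$smooth)
  expect_false(is.null(fr$fixed))
})
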