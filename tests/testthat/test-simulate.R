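test_that("invalid configurations are rejected before any sampling", {
  expect_error(simulation_config(unclean_prevalence = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(missing_frac_bw = -0.1), "\\[0, 1\\]")
  expect_error(simulation_config(sigma_mother = -1), "nonnegative")
  expect_error(simulation_config(wealth_probs = c(0.5, 0.5, 0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("same seed gives identical cohorts; links resolve", {
  g <- make_lattice_adjacency(3, 4)
  cfg <- simulation_config(n_mothers = 400, seed = 31)
  c1 <- simulate_cohort(cfg, g)
  c2 <- simulate_cohort(cfg, g)
  expect_identical(c1$births, c2$births)
  expect_identical(c1$truth$structured, c2$truth$structured)
  expect_silent(validate_cohort(c1))
  expect_true(all(c1$births$mother_id %in% c1$mothers$mother_id))
  expect_true(all(c1$mothers$area_id %in% seq_len(g$n_areas)))
  expect_lt(abs(sum(c1$truth$structured)), 1e-8)
})

test_that("null-effect generator hits the configured marginal rates", {
  g <- make_lattice_adjacency(4, 4)
  cfg <- simulation_config(
    n_mothers = 8000, seed = 12,
    coef_fuel = 0, coef_education = c(0, 0, 0),
    age_effect = function(a) rep(0, length(a)),
    sigma_mother = 0, sigma_structured = 0, sigma_unstructured = 0,
    intercept = qnorm(0.143),
    unclean_prevalence = 0.893, fuel_wealth_log_odds = 0)
  co <- simulate_cohort(cfg, g)
  n <- nrow(co$births)
  p_still <- mean(co$births$outcome_stillbirth)
  expect_lt(abs(p_still - 0.143), 3 * sqrt(0.143 * 0.857 / n))
  p_unclean <- mean(co$mothers$fuel_unclean)
  expect_lt(abs(p_unclean - 0.893), 3 * sqrt(0.893 * 0.107 / 8000))
})

test_that("marginal unclean prevalence is preserved under collinearity", {
  g <- make_lattice_adjacency(4, 4)
  cfg <- simulation_config(n_mothers = 20000, seed = 3,
                           unclean_prevalence = 0.893,
                           fuel_wealth_log_odds = -1.5)
  co <- simulate_cohort(cfg, g)
  expect_lt(abs(mean(co$mothers$fuel_unclean) - 0.893),
            3 * sqrt(0.893 * 0.107 / 20000))
  # collinearity direction: richest quintile uses clean fuel far more often
  by_w <- tapply(co$mothers$fuel_unclean, co$mothers$wealth, mean)
  expect_true(all(diff(by_w) < 0))
  expect_gt(by_w[[1]] - by_w[[5]], 0.3)
})

test_that("outcome mechanism is calibrated: rate per eta-decile matches pnorm", {
  co <- make_test_cohort(n_mothers = 6000, seed = 8)
  eta <- co$truth$eta_stillbirth
  y <- co$births$outcome_stillbirth
  dec <- cut(eta, quantile(eta, 0:10 / 10), include.lowest = TRUE)
  obs <- tapply(y, dec, mean)
  expct <- tapply(pnorm(eta), dec, mean)
  nn <- tapply(y, dec, length)
  tol <- 3 * sqrt(expct * (1 - expct) / nn) + 1e-6
  expect_true(all(abs(obs - expct) < tol))
})

test_that("missingness masks hit their rates and are independent of outcome", {
  co <- make_test_cohort(n_mothers = 12000, seed = 21)
  b <- co$births
  n <- nrow(b)
  expect_lt(abs(mean(is.na(b$outcome_lbw)) - 0.939), 3 * sqrt(0.939 * 0.061 / n))
  expect_lt(abs(mean(is.na(b$outcome_preterm)) - 0.688), 3 * sqrt(0.688 * 0.312 / n))
  # missingness rate of the preterm flag should not depend on stillbirth status
  m1 <- is.na(b$outcome_preterm)[b$outcome_stillbirth == 1]
  m0 <- is.na(b$outcome_preterm)[b$outcome_stillbirth == 0]
  pt <- prop.test(c(sum(m1), sum(m0)), c(length(m1), length(m0)))
  expect_gt(pt$p.value, 0.001)
})

test_that("cohort CSV writer and reader round-trip the birth records", {
  co <- make_test_cohort(n_mothers = 200, seed = 14)
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(co$births))
  expect_equal(back$outcome_stillbirth, co$births$outcome_stillbirth)
  expect_equal(back$outcome_lbw, co$births$outcome_lbw)
  expect_equal(back$mother_age, co$births$mother_age, tolerance = 1e-12)
  expect_error(read_cohort({
    p <- tempfile(fileext = ".csv")
    write.csv(data.frame(x = 1), p, row.names = FALSE)
    p
  }), "missing columns")
})
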