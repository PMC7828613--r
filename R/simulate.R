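#' Configuration for the synthetic DHS-like cohort generator
#'
#' Defaults emulate the scale and marginal structure of a large national
#' demographic survey of women of reproductive age: ~41,821 mothers with
#' ~127,545 births nested within them across 37 areas, ~89.3% unclean-fuel
#' prevalence, 14.3% stillbirth prevalence, strong fuel-wealth collinearity,
#' and heavy missingness in birth weight (93.9%) and pregnancy duration
#' (68.8%). Effect-size defaults (probit scale) are anchored to the
#' multivariable stillbirth model: +0.14 for unclean fuel and
#' (-0.07, -0.23, -0.39) for primary/secondary/higher education versus none.
#'
#' @param n_mothers number of mothers.
#' @param births_per_mother_mean mean of the 1 + geometric births-per-mother
#'   distribution (truncated at `births_per_mother_max`).
#' @param births_per_mother_max truncation point for births per mother.
#' @param unclean_prevalence target marginal probability a household cooks
#'   with unclean fuel.
#' @param fuel_wealth_log_odds log-odds shift in unclean-fuel use per wealth
#'   quintile step (negative: richer households use cleaner fuel). The
#'   intercept of the fuel model is solved numerically so the marginal
#'   prevalence equals `unclean_prevalence` regardless of this value.
#' @param intercept probit-scale intercept of the stillbirth mechanism;
#'   default `qnorm(0.143)` so the null-effects prevalence is 14.3%.
#' @param coef_fuel probit-scale unclean-fuel effect on stillbirth.
#' @param coef_education length-3 probit effects of primary/secondary/higher
#'   education (reference: no education) on stillbirth.
#' @param age_effect function of age giving the nonlinear (probit-scale) age
#'   contribution; it is re-centred to mean zero over the 15..49 grid so the
#'   intercept keeps its interpretation. Default: increasing scaled logistic.
#' @param sigma_mother,sigma_structured,sigma_unstructured standard
#'   deviations of the mother random intercept, ICAR structured spatial
#'   field, and exchangeable unstructured spatial field.
#' @param intercept_lbw,coef_fuel_lbw,intercept_preterm,coef_fuel_preterm
#'   probit intercepts and fuel effects for the low-birth-weight and preterm
#'   mechanisms (random effects and age effect are shared across outcomes).
#' @param education_probs,wealth_probs marginal category probabilities
#'   (must each sum to 1).
#' @param smoker_prob marginal probability a mother smokes.
#' @param age_mean,age_sd mother's age distribution, normal truncated to
#'   15..49 years.
#' @param missing_frac_bw,missing_frac_dur fractions of births with missing
#'   birth-weight and pregnancy-duration outcomes (missing completely at
#'   random, independent of the outcome value).
#' @param seed master integer seed; all sampling streams derive from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_mothers = 41821L,
                              births_per_mother_mean = 127545 / 41821,
                              births_per_mother_max = 15L,
                              unclean_prevalence = 0.893,
                              fuel_wealth_log_odds = -1.5,
                              intercept = stats::qnorm(0.143),
                              coef_fuel = 0.14,
                              coef_education = c(primary = -0.07,
                                                 secondary = -0.23,
                                                 higher = -0.39),
                              age_effect = NULL,
                              sigma_mother = 0.5,
                              sigma_structured = 0.35,
                              sigma_unstructured = 0.15,
                              intercept_lbw = stats::qnorm(0.073),
                              coef_fuel_lbw = -0.09,
                              intercept_preterm = stats::qnorm(0.01),
                              coef_fuel_preterm = -0.01,
                              education_probs = c(0.3443, 0.1526, 0.3993, 0.1038),
                              wealth_probs = c(0.1852, 0.1996, 0.2118, 0.2113, 0.1920),
                              smoker_prob = 0.0023,
                              age_mean = 35.9, age_sd = 7.9,
                              missing_frac_bw = 0.939,
                              missing_frac_dur = 0.688,
                              seed = 1L) {
  cfg <- list(
    n_mothers = as.integer(n_mothers),
    births_per_mother_mean = births_per_mother_mean,
    births_per_mother_max = as.integer(births_per_mother_max),
    unclean_prevalence = unclean_prevalence,
    fuel_wealth_log_odds = fuel_wealth_log_odds,
    intercept = intercept, coef_fuel = coef_fuel,
    coef_education = coef_education,
    age_effect = if (is.null(age_effect)) default_age_effect else age_effect,
    sigma_mother = sigma_mother,
    sigma_structured = sigma_structured,
    sigma_unstructured = sigma_unstructured,
    intercept_lbw = intercept_lbw, coef_fuel_lbw = coef_fuel_lbw,
    intercept_preterm = intercept_preterm, coef_fuel_preterm = coef_fuel_preterm,
    education_probs = education_probs,
    wealth_probs = wealth_probs,
    smoker_prob = smoker_prob,
    age_mean = age_mean, age_sd = age_sd,
    missing_frac_bw = missing_frac_bw, missing_frac_dur = missing_frac_dur,
    seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  chk_prop <- function(x, nm) {
    if (any(x < 0 | x > 1)) stop(sprintf("%s must be in [0, 1]", nm))
  }
  if (cfg$n_mothers < 1L) stop("n_mothers must be positive")
  if (cfg$births_per_mother_mean < 1) stop("births_per_mother_mean must be >= 1")
  chk_prop(cfg$unclean_prevalence, "unclean_prevalence")
  chk_prop(cfg$smoker_prob, "smoker_prob")
  chk_prop(cfg$missing_frac_bw, "missing_frac_bw")
  chk_prop(cfg$missing_frac_dur, "missing_frac_dur")
  chk_prop(cfg$education_probs, "education_probs")
  chk_prop(cfg$wealth_probs, "wealth_probs")
  # printed survey marginals round to 1 within ~1e-3
  if (abs(sum(cfg$education_probs) - 1) > 1e-3)
    stop("education_probs must sum to 1")
  if (abs(sum(cfg$wealth_probs) - 1) > 1e-3)
    stop("wealth_probs must sum to 1")
  if (cfg$sigma_mother < 0 || cfg$sigma_structured < 0 || cfg$sigma_unstructured < 0)
    stop("standard deviations must be nonnegative")
  if (length(cfg$coef_education) != 3L)
    stop("coef_education must have length 3 (primary, secondary, higher)")
  invisible(cfg)
}

# Monotone increasing age effect on [15, 49], centred to mean zero on the
# integer age grid so it is identified separately from the intercept.
default_age_effect <- function(age) {
  raw <- function(a) 0.6 * stats::plogis((a - 32) / 5)
  raw(age) - mean(raw(15:49))
}

education_levels <- function() c("none", "primary", "secondary", "higher")

# Intercept of the household fuel model such that the marginal unclean-fuel
# prevalence matches the target given the wealth mixture and log-odds slope.
solve_fuel_intercept <- function(prevalence, wealth_probs, delta) {
  if (prevalence <= 0) return(-Inf)
  if (prevalence >= 1) return(Inf)
  if (delta == 0) return(stats::qlogis(prevalence))
  marg <- function(alpha)
    sum(wealth_probs * stats::plogis(alpha + delta * (seq_along(wealth_probs) - 3))) -
      prevalence
  stats::uniroot(marg, c(-50, 50), tol = 1e-12)$root
}

#' Simulate a DHS-like birth cohort with known generating truth
#'
#' Draws mothers (area, age, education, wealth, smoking), household cooking
#' fuel with wealth-driven collinearity, births nested within mothers, and
#' per-birth adverse outcomes from the probit structured additive mechanism:
#' linear predictor = intercept + fuel effect + education effects +
#' nonlinear age effect + mother random intercept + structured (ICAR) +
#' unstructured area effects, with outcome ~ Bernoulli(pnorm(eta)).
#' Birth-weight and pregnancy-duration outcomes are masked missing
#' completely at random at the configured rates.
#'
#' @param config a [simulation_config()].
#' @param graph a connected [adjacency_graph()] of the study areas.
#' @return A list of class `synthetic_cohort` with `births` (one row per
#'   birth), `mothers` (one row per mother) and `truth` (the generating
#'   parameter values, per-area spatial fields, per-mother intercepts, the
#'   centred age-effect grid, and the per-birth stillbirth linear predictor).
#' @export
simulate_cohort <- function(config, graph) {
  validate_simulation_config(config)
  stopifnot(inherits(graph, "adjacency_graph"))
  if (!is_connected(graph)) stop("graph must be connected")
  set.seed(config$seed)

  n_areas <- graph$n_areas
  regions <- graph$regions
  if (is.null(regions))
    regions <- paste0("R", as.integer(cut(seq_len(n_areas), breaks = min(6L, n_areas))))

  # area-level truth
  u <- sample_icar_field(graph, config$sigma_structured)
  v <- stats::rnorm(n_areas, 0, config$sigma_unstructured)

  # mothers
  M <- config$n_mothers
  area <- sample.int(n_areas, M, replace = TRUE)
  age <- truncnorm(M, config$age_mean, config$age_sd, 15, 49)
  education <- sample(education_levels(), M, replace = TRUE,
                      prob = config$education_probs)
  wealth <- sample.int(5L, M, replace = TRUE, prob = config$wealth_probs)
  alpha_fuel <- solve_fuel_intercept(config$unclean_prevalence,
                                     config$wealth_probs,
                                     config$fuel_wealth_log_odds)
  p_unclean <- stats::plogis(alpha_fuel + config$fuel_wealth_log_odds * (wealth - 3))
  fuel_unclean <- stats::rbinom(M, 1L, p_unclean)
  smoker <- stats::rbinom(M, 1L, config$smoker_prob)
  b <- stats::rnorm(M, 0, config$sigma_mother)

  # births nested in mothers: 1 + geometric, truncated
  p_geom <- 1 / config$births_per_mother_mean
  n_births_m <- pmin(1L + stats::rgeom(M, p_geom), config$births_per_mother_max)
  mother_of <- rep.int(seq_len(M), n_births_m)
  n <- length(mother_of)

  edu_idx <- match(education, education_levels()) - 1L      # 0 = none
  coef_edu_full <- c(0, config$coef_education)
  f_age <- config$age_effect(age)

  eta_shared <- coef_edu_full[edu_idx + 1L] + f_age + b + u[area] + v[area]
  eta_still_m <- config$intercept + config$coef_fuel * fuel_unclean + eta_shared
  eta_lbw_m <- config$intercept_lbw + config$coef_fuel_lbw * fuel_unclean + eta_shared
  eta_pre_m <- config$intercept_preterm + config$coef_fuel_preterm * fuel_unclean + eta_shared

  eta_still <- eta_still_m[mother_of]
  y_still <- stats::rbinom(n, 1L, stats::pnorm(eta_still))
  y_lbw <- stats::rbinom(n, 1L, stats::pnorm(eta_lbw_m[mother_of]))
  y_pre <- stats::rbinom(n, 1L, stats::pnorm(eta_pre_m[mother_of]))

  # MCAR outcome missingness
  y_lbw[stats::runif(n) < config$missing_frac_bw] <- NA_integer_
  y_pre[stats::runif(n) < config$missing_frac_dur] <- NA_integer_

  births <- data.frame(
    birth_id = seq_len(n),
    mother_id = mother_of,
    area_id = area[mother_of],
    region = regions[area[mother_of]],
    outcome_stillbirth = y_still,
    outcome_lbw = y_lbw,
    outcome_preterm = y_pre,
    fuel_unclean = fuel_unclean[mother_of],
    mother_age = age[mother_of],
    education = education[mother_of],
    wealth = wealth[mother_of],
    smoker = smoker[mother_of],
    stringsAsFactors = FALSE)

  mothers <- data.frame(
    mother_id = seq_len(M), area_id = area, region = regions[area],
    age = age, education = education, wealth = wealth,
    fuel_unclean = fuel_unclean, smoker = smoker, n_births = n_births_m,
    stringsAsFactors = FALSE)

  age_grid <- 15:49
  truth <- list(
    intercept = config$intercept, coef_fuel = config$coef_fuel,
    coef_education = config$coef_education,
    age_grid = age_grid, age_effect = config$age_effect(age_grid),
    mother_effects = b, structured = u, unstructured = v,
    sigma_mother = config$sigma_mother,
    sigma_structured = config$sigma_structured,
    sigma_unstructured = config$sigma_unstructured,
    eta_stillbirth = eta_still)

  cohort <- structure(list(births = births, mothers = mothers, truth = truth,
                           config = config, graph = graph),
                      class = "synthetic_cohort")
  validate_cohort(cohort)
  cohort
}

truncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Check referential integrity of a cohort
#'
#' Every birth must reference an existing mother, every mother an existing
#' area; the structured spatial truth must sum to zero.
#' @param cohort a `synthetic_cohort`.
#' @return the cohort, invisibly; errors if a link does not resolve.
#' @export
validate_cohort <- function(cohort) {
  b <- cohort$births; m <- cohort$mothers
  if (!all(b$mother_id %in% m$mother_id))
    stop("birth references a missing mother")
  n_areas <- cohort$graph$n_areas
  if (!all(m$area_id >= 1L & m$area_id <= n_areas))
    stop("mother references a missing area")
  if (!is.null(cohort$truth)) {
    if (length(cohort$truth$structured) != n_areas)
      stop("structured truth has wrong length")
    if (abs(sum(cohort$truth$structured)) > 1e-8)
      stop("structured truth does not sum to zero")
  }
  invisible(cohort)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d births from %d mothers in %d areas (unclean fuel %.1f%%, stillbirth %.1f%%)\n",
    nrow(x$births), nrow(x$mothers), x$graph$n_areas,
    100 * mean(x$mothers$fuel_unclean), 100 * mean(x$births$outcome_stillbirth)))
  invisible(x)
}

#' Write a cohort's birth records to CSV
#' @param cohort a `synthetic_cohort` or a births data frame.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  births <- if (inherits(cohort, "synthetic_cohort")) cohort$births else cohort
  utils::write.csv(births, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read birth records from CSV
#' @param path CSV written by [write_cohort()] (schema: birth_id, mother_id,
#'   area_id, region, outcome_stillbirth, outcome_lbw, outcome_preterm,
#'   fuel_unclean, mother_age, education, wealth, smoker).
#' @return data frame of birth records.
#' @export
read_cohort <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("birth_id", "mother_id", "area_id", "outcome_stillbirth",
            "fuel_unclean", "mother_age", "education")
  miss <- setdiff(need, names(b))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "))
  b
}
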