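test_that("complete-case filtering keeps all rows when nothing is missing", {
  co <- make_test_cohort(n_mothers = 500, seed = 4,
                         missing_frac_bw = 0, missing_frac_dur = 0)
  d <- assemble_design(co$births, model_spec(fixed = "fuel"),
                       co$graph, "stillbirth")
  expect_equal(unname(d$audit["kept"]), nrow(co$births))
  expect_equal(unname(d$audit["dropped"]), 0)
  expect_equal(colnames(d$X), c("intercept", "fuel_unclean"))
})

test_that("heavy outcome missingness leaves the expected complete-case fraction", {
  co <- make_test_cohort(n_mothers = 4000, seed = 16)   # 93.9% missing LBW
  d <- assemble_design(co$births, model_spec(fixed = "fuel"), co$graph, "lbw")
  kept_frac <- d$audit["kept"] / d$audit["total"]
  expect_lt(abs(kept_frac - 0.061), 0.01)
  expect_true(all(!is.na(d$y)))
})

test_that("requesting wealth together with fuel warns about collinearity", {
  co <- make_test_cohort(n_mothers = 400, seed = 2)
  expect_warning(
    assemble_design(co$births, model_spec(fixed = c("fuel", "wealth")),
                    co$graph, "stillbirth"),
    "collinear")
})

test_that("dummy coding uses declared references; absent levels error", {
  co <- make_test_cohort(n_mothers = 800, seed = 6)
  sp <- model_spec(fixed = c("fuel", "education"))
  d <- assemble_design(co$births, sp, co$graph, "stillbirth")
  expect_false("education_none" %in% colnames(d$X))
  expect_true(all(c("education_higher", "education_primary",
                    "education_secondary") %in% colnames(d$X)))

  b2 <- co$births[co$births$education != "higher", ]
  expect_error(assemble_design(b2, model_spec(
    fixed = c("fuel", "education"), education_ref = "higher"),
    co$graph, "stillbirth"), "reference level")

  expect_error(assemble_design(co$births, sp, co$graph, "gestation"),
               "outcome must be")
})

test_that("random-effect blocks index every kept row exactly once", {
  co <- make_test_cohort(n_mothers = 600, seed = 10)
  sp <- model_spec(fixed = "fuel", mother_effect = TRUE,
                   smooth_age = TRUE, spatial = TRUE)
  d <- assemble_design(co$births, sp, co$graph, "stillbirth")
  expect_equal(length(d$mother_index), length(d$y))
  expect_equal(length(d$area_index), length(d$y))
  expect_equal(max(d$mother_index), d$n_mothers)
  expect_equal(nrow(d$B), length(d$y))
  expect_equal(rowSums(d$B), rep(1, length(d$y)), tolerance = 1e-10)
  expect_equal(nrow(d$Q), co$graph$n_areas)
})
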