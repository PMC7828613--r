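# Published 2x2 counts used as fixed inputs throughout:
# stillbirth (17598 unclean / 503 clean; alive 100669 / 7626),
# preterm (345/59; term 35972/2856), LBW (442/113; normal 5373/1633),
# smoker (75/18; non-smoker 36771/4392),
# education vs none (none 14173 unclean / 115 clean).

test_that("prevalence ratios and Katz intervals reproduce the printed rows", {
  still <- prevalence_ratio(table2x2(17598, 100669, 503, 7626))
  expect_equal(round(still$estimate, 2), 2.40)
  expect_equal(round(still$ci_low, 2), 2.21)
  expect_equal(round(still$ci_high, 2), 2.62)

  pre <- prevalence_ratio(table2x2(345, 35972, 59, 2856))
  expect_equal(round(pre$estimate, 2), 0.47)
  expect_equal(round(pre$ci_low, 2), 0.36)
  expect_equal(round(pre$ci_high, 2), 0.62)

  lbw <- prevalence_ratio(table2x2(442, 5373, 113, 1633))
  expect_equal(round(lbw$estimate, 2), 1.17)

  smo <- prevalence_ratio(table2x2(75, 36771, 18, 4392))
  expect_equal(round(smo$estimate, 2), 0.50)

  sym <- prevalence_ratio(table2x2(10, 90, 10, 90))
  expect_equal(sym$estimate, 1)
  expect_lt(sym$ci_low, 1); expect_gt(sym$ci_high, 1)

  expect_error(prevalence_ratio(table2x2(0, 10, 5, 5)), "undefined PR")
})

test_that("odds ratios with Woolf intervals reproduce the education rows", {
  prim <- odds_ratio(table2x2(6062, 252, 14173, 115))
  expect_equal(round(prim$estimate, 2), 0.20)
  expect_equal(round(prim$ci_low, 2), 0.16)
  expect_equal(round(prim$ci_high, 2), 0.24)

  sec <- odds_ratio(table2x2(14219, 2189, 14173, 115))
  expect_equal(round(sec$estimate, 2), 0.05)

  flat <- odds_ratio(table2x2(20, 10, 40, 20))
  expect_equal(flat$estimate, 1)
  expect_error(odds_ratio(table2x2(0, 10, 5, 5)), "zero cell")
})

test_that("swapping exposure columns inverts ratio estimates and their CIs", {
  set.seed(77)
  for (i in 1:25) {
    cnt <- rpois(4, lambda = c(40, 160, 25, 175)) + 1
    t1 <- table2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    t2 <- table2x2(cnt[3], cnt[4], cnt[1], cnt[2])
    p1 <- prevalence_ratio(t1); p2 <- prevalence_ratio(t2)
    expect_equal(p2$estimate, 1 / p1$estimate, tolerance = 1e-12)
    expect_equal(p2$ci_low, 1 / p1$ci_high, tolerance = 1e-12)
    expect_equal(p2$ci_high, 1 / p1$ci_low, tolerance = 1e-12)
    o1 <- odds_ratio(t1)
    o2 <- odds_ratio(table2x2(cnt[2], cnt[1], cnt[4], cnt[3]))
    expect_equal(o2$estimate, 1 / o1$estimate, tolerance = 1e-12)
  }
})

test_that("OR approximates PR for rare outcomes", {
  set.seed(123)
  ok <- 0
  for (i in 1:30) {
    n1 <- 30000; n0 <- 10000
    a <- rbinom(1, n1, 0.012); c <- rbinom(1, n0, 0.008)
    if (a == 0 || c == 0) next
    pr <- prevalence_ratio(table2x2(a, n1 - a, c, n0 - c))$estimate
    or <- odds_ratio(table2x2(a, c, n1 - a, n0 - c))$estimate
    expect_lt(abs(or - pr) / pr, 0.05)
    ok <- ok + 1
  }
  expect_gt(ok, 20)
})

test_that("Pearson chi-square matches direct formula; permutation invariant", {
  prop <- pearson_chi_square(rbind(c(10, 20), c(30, 60)))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)

  m <- rbind(c(10, 20), c(20, 10))
  # direct formula: n (ad - bc)^2 / (r1 r2 c1 c2)
  want <- 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30)
  got <- pearson_chi_square(m)
  expect_equal(got$statistic, want, tolerance = 1e-12)
  expect_equal(got$df, 1)
  expect_equal(got$p_value, pchisq(want, 1, lower.tail = FALSE))

  perm <- pearson_chi_square(m[2:1, 2:1])
  expect_equal(perm$statistic, got$statistic)

  still <- pearson_chi_square(rbind(c(17598, 503), c(100669, 7626)))
  expect_lt(still$p_value, 1e-4)

  expect_error(pearson_chi_square(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("Fisher exact matches enumeration oracle", {
  cases <- list(c(1, 9, 9, 1), c(0, 10, 10, 0), c(3, 7, 5, 5), c(2, 3, 4, 1))
  for (cs in cases) {
    got <- fisher_exact(table2x2(cs[1], cs[2], cs[3], cs[4]))$p_value
    want <- fisher_enumeration_p(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_equal(fisher_exact(table2x2(5, 5, 5, 5))$p_value, 1)
})

test_that("Welch t-test matches the closed form and is shift invariant", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- welch_t_test(x, y)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_want <- (mean(x) - mean(y)) / se
  df_want <- (var(x) / 3 + var(y) / 3)^2 /
    ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(got$statistic, t_want, tolerance = 1e-12)
  expect_equal(got$df, df_want, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(t_want, df_want), tolerance = 1e-12)

  shifted <- welch_t_test(x + 100, y + 100)
  expect_equal(shifted$statistic, got$statistic, tolerance = 1e-10)

  same <- welch_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2, 2)), "zero variance")
})

test_that("association test switches to Fisher when expected cells are small", {
  small <- matrix(c(2, 8, 9, 1), 2)
  expect_equal(association_test(small)$method, "fisher_exact")
  big <- matrix(c(200, 800, 900, 100), 2)
  expect_equal(association_test(big)$method, "pearson_chi_square")
})

test_that("table1 report has the declared schema and row-appropriate estimators", {
  co <- make_test_cohort(n_mothers = 3000, seed = 9)
  t1 <- make_table1(co$births)
  expect_named(t1, c("characteristic", "level", "n_overall", "n_clean",
                     "n_unclean", "estimate", "ci_low", "ci_high",
                     "estimator_kind", "p_value"))
  expect_true(all(t1$estimator_kind[t1$characteristic == "birth_status"] %in%
                    c("ref", "prevalence_ratio")))
  expect_true(all(t1$estimator_kind[t1$characteristic == "education"] %in%
                    c("ref", "odds_ratio")))
  # counts are consistent
  expect_equal(t1$n_overall, t1$n_clean + t1$n_unclean)
  bs <- t1[t1$characteristic == "birth_status", ]
  expect_equal(sum(bs$n_overall), nrow(co$births))
})
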