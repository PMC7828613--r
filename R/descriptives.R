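#' 2x2 contingency table of a characteristic against cooking-fuel exposure
#'
#' Layout follows the ratio estimators: `a` = characteristic present &
#' exposed (unclean fuel), `b` = absent & exposed, `c` = present &
#' unexposed (clean fuel), `d` = absent & unexposed.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @return object of class `table2x2`.
#' @export
table2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) == 0) stop("table total must be positive")
  structure(as.list(counts), class = "table2x2")
}

as_matrix_2x2 <- function(t) {
  # rows: characteristic present/absent; columns: unclean/clean
  matrix(c(t$a, t$b, t$c, t$d), 2, 2,
         dimnames = list(c("present", "absent"), c("unclean", "clean")))
}

#' Prevalence ratio with Katz log confidence interval
#'
#' PR = \[a/(a+b)\] / \[c/(c+d)\]: the prevalence of the characteristic in the
#' exposed (unclean-fuel) group relative to the unexposed (clean-fuel)
#' group. The confidence interval is the Katz log-scale interval
#' `exp(log PR +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. No continuity
#' correction is applied; a zero numerator cell is an error.
#'
#' @param table a [table2x2()].
#' @param level confidence level (default 0.95).
#' @return list of class `ratio_estimate` with `estimate`, `ci_low`,
#'   `ci_high`, `level`, `kind = "prevalence_ratio"`.
#' @export
prevalence_ratio <- function(table, level = 0.95) {
  stopifnot(inherits(table, "table2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if ((a + b) == 0 || (c + d) == 0) stop("both exposure columns need nonzero totals")
  if (a == 0 || c == 0) stop("undefined PR: zero numerator cell")
  pr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(estimate = pr,
                 ci_low = exp(log(pr) - z * se),
                 ci_high = exp(log(pr) + z * se),
                 level = level, kind = "prevalence_ratio"),
            class = "ratio_estimate")
}

#' Odds ratio with Woolf log confidence interval
#'
#' OR = (a*d)/(b*c) with `a` = exposed (unclean) & category, `b` = unexposed
#' (clean) & category, `c` = exposed & reference, `d` = unexposed &
#' reference; Woolf interval `exp(log OR +/- z*sqrt(1/a+1/b+1/c+1/d))`.
#' No Haldane correction: any zero cell is an error.
#'
#' @param table a [table2x2()] in the category/reference layout above.
#' @param level confidence level (default 0.95).
#' @return `ratio_estimate` with `kind = "odds_ratio"`.
#' @export
odds_ratio <- function(table, level = 0.95) {
  stopifnot(inherits(table, "table2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (any(c(a, b, c, d) == 0)) stop("odds ratio undefined: zero cell")
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(estimate = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 level = level, kind = "odds_ratio"),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("%s %.2f (%.0f%% CI: %.2f, %.2f)\n",
              if (x$kind == "prevalence_ratio") "PR" else "OR",
              x$estimate, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Pearson chi-square test of independence (no continuity correction)
#'
#' @param counts an r x c matrix of counts (or a [table2x2()]).
#' @return list of class `assoc_test` with `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
pearson_chi_square <- function(counts) {
  if (inherits(counts, "table2x2")) counts <- as_matrix_2x2(counts)
  counts <- as.matrix(counts)
  if (sum(counts) <= 0) stop("table total must be positive")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), method = "pearson_chi_square"),
            class = "assoc_test")
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table.
#' @param table a [table2x2()] or 2x2 count matrix.
#' @return `assoc_test` (df = 0 by convention for an exact test).
#' @export
fisher_exact <- function(table) {
  m <- if (inherits(table, "table2x2")) as_matrix_2x2(table) else as.matrix(table)
  ft <- stats::fisher.test(m)
  structure(list(statistic = unname(ft$estimate %||% NA_real_), df = 0,
                 p_value = unname(ft$p.value), method = "fisher_exact"),
            class = "assoc_test")
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom;
#' two-sided p-value.
#' @param x,y numeric vectors (each with >= 2 observations).
#' @return `assoc_test`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 observations per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both samples")
  tt <- stats::t.test(x, y)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = unname(tt$p.value), method = "welch_t"),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Association test with expected-cell switch rule
#'
#' Pearson chi-square unless any expected cell count is below 5, in which
#' case Fisher's exact test is used (2x2 only).
#' @param counts count matrix or [table2x2()].
#' @return `assoc_test`.
#' @export
association_test <- function(counts) {
  m <- if (inherits(counts, "table2x2")) as_matrix_2x2(counts) else as.matrix(counts)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5) && all(dim(m) == 2L)) fisher_exact(m)
  else pearson_chi_square(m)
}

#' Table-1-style descriptive report for a cohort
#'
#' Builds the descriptive summary that a survey report prints: for each
#' characteristic, counts overall and by cooking-fuel exposure, the
#' row-appropriate ratio estimate with 95% CI, and an association p-value.
#' Binary outcome/exposure rows (smoking, birth status, birth weight,
#' pregnancy duration) are summarised with prevalence ratios across fuel
#' columns; mother-level categorical rows (education, wealth, region) with
#' odds ratios against a reference category.
#'
#' @param births data frame of birth records (see [read_cohort()]).
#' @param education_ref,region_ref reference categories for the odds-ratio
#'   rows.
#' @return data frame with columns `characteristic`, `level`, `n_overall`,
#'   `n_clean`, `n_unclean`, `estimate`, `ci_low`, `ci_high`,
#'   `estimator_kind`, `p_value`.
#' @export
make_table1 <- function(births, education_ref = "none", region_ref = NULL) {
  mothers <- births[!duplicated(births$mother_id), , drop = FALSE]
  rows <- list()

  add_or_block <- function(characteristic, values, fuel, ref) {
    lev <- unique(values)
    if (is.null(ref)) ref <- lev[1L]
    lev <- c(ref, setdiff(sort(lev), ref))
    tab <- table(factor(values, levels = lev), factor(fuel, levels = c(1, 0)))
    p <- association_test(as.matrix(tab))$p_value
    for (l in lev) {
      n1 <- tab[l, "1"]; n0 <- tab[l, "0"]
      if (l == ref) {
        est <- cilo <- cihi <- NA_real_; kind <- "ref"
      } else {
        o <- tryCatch(
          odds_ratio(table2x2(a = n1, b = n0, c = tab[ref, "1"], d = tab[ref, "0"])),
          error = function(e) NULL)   # zero cell in a sparse stratum
        est <- if (is.null(o)) NA_real_ else o$estimate
        cilo <- if (is.null(o)) NA_real_ else o$ci_low
        cihi <- if (is.null(o)) NA_real_ else o$ci_high
        kind <- "odds_ratio"
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        characteristic = characteristic, level = as.character(l),
        n_overall = n1 + n0, n_clean = n0, n_unclean = n1,
        estimate = est, ci_low = cilo, ci_high = cihi,
        estimator_kind = kind, p_value = p, stringsAsFactors = FALSE)
    }
  }

  add_pr_block <- function(characteristic, present, fuel,
                           level_present, level_absent) {
    keep <- !is.na(present)
    present <- present[keep]; fuel <- fuel[keep]
    a <- sum(present == 1 & fuel == 1); b <- sum(present == 0 & fuel == 1)
    c <- sum(present == 1 & fuel == 0); d <- sum(present == 0 & fuel == 0)
    p <- association_test(matrix(c(a, b, c, d), 2))$p_value
    pr <- tryCatch(prevalence_ratio(table2x2(a, b, c, d)),
                   error = function(e) NULL)
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = characteristic, level = level_absent,
      n_overall = b + d, n_clean = d, n_unclean = b,
      estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      estimator_kind = "ref", p_value = p, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = characteristic, level = level_present,
      n_overall = a + c, n_clean = c, n_unclean = a,
      estimate = if (is.null(pr)) NA_real_ else pr$estimate,
      ci_low = if (is.null(pr)) NA_real_ else pr$ci_low,
      ci_high = if (is.null(pr)) NA_real_ else pr$ci_high,
      estimator_kind = "prevalence_ratio", p_value = p, stringsAsFactors = FALSE)
  }

  if ("smoker" %in% names(mothers))
    add_pr_block("smoking_status", mothers$smoker, mothers$fuel_unclean,
                 "smoker", "non_smoker")
  add_or_block("education", mothers$education, mothers$fuel_unclean, education_ref)
  if ("wealth" %in% names(mothers))
    add_or_block("wealth", mothers$wealth, mothers$fuel_unclean, 1)
  if ("region" %in% names(mothers))
    add_or_block("region", mothers$region, mothers$fuel_unclean, region_ref)

  add_pr_block("birth_status", births$outcome_stillbirth, births$fuel_unclean,
               "stillbirth", "alive")
  if ("outcome_lbw" %in% names(births))
    add_pr_block("birth_weight", births$outcome_lbw, births$fuel_unclean,
                 "low_birth_weight", "normal_weight")
  if ("outcome_preterm" %in% names(births))
    add_pr_block("pregnancy_duration", births$outcome_preterm, births$fuel_unclean,
                 "preterm", "term")

  do.call(rbind, rows)
}
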