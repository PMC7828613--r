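#' Specification of a probit structured additive regression model
#'
#' Declares which blocks of the additive predictor are present:
#' `eta = gamma0 + gamma_fuel * fuel + ... + f(age) + b_mother + u_str(area)
#' + v_unstr(area)`, with a probit link. Fixed effects get essentially flat
#' Gaussian priors (precision 1e-8); the P-spline age smooth, the mother
#' random intercept and both spatial blocks get Gaussian (ICAR for the
#' structured block) priors whose variances carry inverse-gamma
#' `IG(hyper_a, hyper_b)` hyperpriors.
#'
#' @param fixed character vector of fixed-effect terms among
#'   `"fuel"`, `"education"`, `"region"`, `"wealth"` (intercept always
#'   included).
#' @param smooth_age include the nonlinear P-spline effect of mother's age?
#' @param mother_effect include the per-mother random intercept?
#' @param spatial include the structured (ICAR) + unstructured area effects?
#' @param hyper_a,hyper_b inverse-gamma hyperprior shape/scale for all
#'   variance components (default 0.001/0.001, weakly informative).
#' @param spline_degree,spline_knots,penalty_order P-spline settings
#'   (cubic, 20 interior knots, second-order random-walk penalty).
#' @param education_ref,region_ref reference categories for dummy coding;
#'   `region_ref = NULL` uses the first sorted region present (North-Central
#'   on the bundled Nigeria fixture).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(fixed = "fuel",
                       smooth_age = FALSE,
                       mother_effect = FALSE,
                       spatial = TRUE,
                       hyper_a = 0.001, hyper_b = 0.001,
                       spline_degree = 3L, spline_knots = 20L,
                       penalty_order = 2L,
                       education_ref = "none",
                       region_ref = NULL) {
  if (hyper_a <= 0 || hyper_b <= 0) stop("hyperprior parameters must be > 0")
  allowed <- c("fuel", "education", "region", "wealth")
  bad <- setdiff(fixed, allowed)
  if (length(bad)) stop("unknown fixed terms: ", paste(bad, collapse = ", "))
  structure(list(fixed = fixed, smooth_age = smooth_age,
                 mother_effect = mother_effect, spatial = spatial,
                 hyper_a = hyper_a, hyper_b = hyper_b,
                 spline_degree = as.integer(spline_degree),
                 spline_knots = as.integer(spline_knots),
                 penalty_order = as.integer(penalty_order),
                 education_ref = education_ref, region_ref = region_ref),
            class = "model_spec")
}

outcome_column <- function(outcome) {
  switch(outcome,
         stillbirth = "outcome_stillbirth",
         lbw = "outcome_lbw",
         preterm = "outcome_preterm",
         stop("outcome must be one of stillbirth, lbw, preterm"))
}

#' Assemble design matrices for a STAR probit fit
#'
#' Performs the complete-case filtering (rows with a missing outcome or a
#' missing required covariate are dropped, with a kept/dropped audit),
#' dummy-codes categorical fixed effects against their declared references,
#' builds the P-spline basis for mother's age, and indexes the mother and
#' area random-effect blocks. Requesting `wealth` together with `fuel`
#' records a collinearity warning (household wealth strongly determines
#' cooking-fuel type) but proceeds.
#'
#' @param births data frame of birth records.
#' @param spec a [model_spec()].
#' @param graph a connected [adjacency_graph()].
#' @param outcome `"stillbirth"`, `"lbw"` or `"preterm"`.
#' @return list of class `star_design`: `y`, `X` (fixed block with
#'   intercept), `basis`/`B` (spline block or NULL), `mother_index`,
#'   `n_mothers`, `area_index`, `Q` (ICAR precision or NULL), `graph`,
#'   `spec`, `outcome`, `audit` (kept/dropped counts), `age`.
#' @export
assemble_design <- function(births, spec, graph, outcome = "stillbirth") {
  stopifnot(inherits(spec, "model_spec"), inherits(graph, "adjacency_graph"))
  ycol <- outcome_column(outcome)
  if (!ycol %in% names(births)) stop("outcome column not found: ", ycol)

  if (all(c("wealth", "fuel") %in% spec$fixed))
    warning("wealth and cooking fuel are collinear in DHS-like data; ",
            "estimates for both may be unstable", call. = FALSE)

  need <- c(ycol, "mother_id", "area_id")
  if ("fuel" %in% spec$fixed) need <- c(need, "fuel_unclean")
  if ("education" %in% spec$fixed) need <- c(need, "education")
  if ("region" %in% spec$fixed) need <- c(need, "region")
  if ("wealth" %in% spec$fixed) need <- c(need, "wealth")
  if (spec$smooth_age) need <- c(need, "mother_age")
  miss <- setdiff(need, names(births))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  keep <- stats::complete.cases(births[, need, drop = FALSE])
  kept <- births[keep, , drop = FALSE]
  audit <- c(total = nrow(births), kept = sum(keep), dropped = sum(!keep))
  if (nrow(kept) == 0L) stop("no complete-case rows left for outcome ", outcome)

  y <- as.integer(kept[[ycol]])
  X <- matrix(1, nrow(kept), 1, dimnames = list(NULL, "intercept"))
  if ("fuel" %in% spec$fixed)
    X <- cbind(X, fuel_unclean = as.numeric(kept$fuel_unclean))
  dummy <- function(x, ref, prefix) {
    lev <- unique(as.character(x))
    if (is.null(ref)) ref <- sort(lev)[1L]
    if (!ref %in% lev)
      stop(sprintf("reference level '%s' absent after filtering (%s)", ref, prefix))
    other <- setdiff(sort(lev), ref)
    empty <- other[vapply(other, function(l) !any(x == l), logical(1))]
    if (length(empty))
      stop(sprintf("levels collapsed to zero rows after filtering: %s",
                   paste(empty, collapse = ", ")))
    m <- sapply(other, function(l) as.numeric(x == l))
    colnames(m) <- paste0(prefix, other)
    m
  }
  if ("education" %in% spec$fixed)
    X <- cbind(X, dummy(kept$education, spec$education_ref, "education_"))
  if ("region" %in% spec$fixed)
    X <- cbind(X, dummy(kept$region, spec$region_ref, "region_"))
  if ("wealth" %in% spec$fixed)
    X <- cbind(X, dummy(kept$wealth, "1", "wealth_"))

  basis <- NULL; B <- NULL; age <- NULL
  if (spec$smooth_age) {
    age <- kept$mother_age
    basis <- bspline_basis(age, degree = spec$spline_degree,
                           n_interior = spec$spline_knots)
    B <- basis$basis
  }

  mother_index <- NULL; n_mothers <- 0L
  if (spec$mother_effect) {
    mf <- factor(kept$mother_id)
    mother_index <- as.integer(mf)
    n_mothers <- nlevels(mf)
  }

  area_index <- NULL; Q <- NULL
  if (spec$spatial) {
    if (any(kept$area_id < 1L | kept$area_id > graph$n_areas))
      stop("area_id outside 1..n_areas")
    area_index <- as.integer(kept$area_id)
    Q <- icar_precision(graph)$matrix
  }

  structure(list(y = y, X = X, basis = basis, B = B,
                 mother_index = mother_index, n_mothers = n_mothers,
                 area_index = area_index, Q = Q, graph = graph,
                 spec = spec, outcome = outcome, audit = audit, age = age),
            class = "star_design")
}

#' @export
print.star_design <- function(x, ...) {
  cat(sprintf(
    "star_design (%s): %d rows kept, %d dropped; %d fixed cols%s%s%s\n",
    x$outcome, x$audit["kept"], x$audit["dropped"], ncol(x$X),
    if (!is.null(x$B)) sprintf(", %d spline cols", ncol(x$B)) else "",
    if (x$n_mothers) sprintf(", %d mothers", x$n_mothers) else "",
    if (!is.null(x$Q)) sprintf(", %d areas", nrow(x$Q)) else ""))
  invisible(x)
}
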