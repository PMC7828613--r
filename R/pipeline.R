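#' The four-model ladder
#'
#' Nested model sequence used for DIC-based selection, from simple to
#' complex: Model 1 = cooking fuel + structured and unstructured spatial
#' effects; Model 2 adds the mother random intercept; Model 3 adds the
#' nonlinear age smooth; Model 4 adds education and geopolitical region
#' fixed effects. Household wealth is deliberately excluded from Model 4
#' because wealth and cooking-fuel type are strongly collinear.
#'
#' @param region_ref reference region for Model 4 dummy coding (NULL: first
#'   sorted region present, North-Central on the Nigeria fixture).
#' @return named list of four [model_spec()] objects.
#' @export
ladder_specs <- function(region_ref = NULL) {
  list(
    model1 = model_spec(fixed = "fuel", spatial = TRUE),
    model2 = model_spec(fixed = "fuel", spatial = TRUE, mother_effect = TRUE),
    model3 = model_spec(fixed = "fuel", spatial = TRUE, mother_effect = TRUE,
                        smooth_age = TRUE),
    model4 = model_spec(fixed = c("fuel", "education", "region"),
                        spatial = TRUE, mother_effect = TRUE,
                        smooth_age = TRUE, region_ref = region_ref))
}

#' Fit the model ladder for one outcome and select by DIC
#'
#' Runs the four nested model fits with a shared master seed (per-model
#' offsets keep the chains independent), collects DIC/pD/Dbar per model and
#' flags the smallest-DIC model. A failing fit is recorded in the manifest
#' and the ladder continues.
#'
#' @param births birth records data frame.
#' @param graph a connected [adjacency_graph()].
#' @param outcome `"stillbirth"`, `"lbw"` or `"preterm"`.
#' @param mcmc an [mcmc_config()]; its seed is the ladder master seed.
#' @param specs list of model specs, default [ladder_specs()].
#' @param age_grid grid for smooth summaries.
#' @param verbose sampler progress.
#' @return list of class `run_manifest`: `outcome`, `seed`, `dic_table`
#'   (data frame model/dic/pd/dbar/status), `selected` (name of the
#'   smallest-DIC completed model), `fits` (named list of `fit_result`).
#' @export
run_ladder <- function(births, graph, outcome = "stillbirth",
                       mcmc = mcmc_config(), specs = ladder_specs(),
                       age_grid = 15:49, verbose = FALSE) {
  fits <- list()
  rows <- list()
  for (k in seq_along(specs)) {
    nm <- names(specs)[k]
    mc <- mcmc_config(mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                      seed = mcmc$seed + 1000L * k)
    fit <- tryCatch(
      fit_star_model(births, specs[[k]], graph, outcome, mc,
                     age_grid = age_grid, verbose = verbose),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[k]] <- data.frame(model = nm, dic = NA_real_, pd = NA_real_,
                              dbar = NA_real_, status = conditionMessage(fit),
                              stringsAsFactors = FALSE)
    } else {
      fits[[nm]] <- fit
      rows[[k]] <- data.frame(model = nm, dic = fit$dic, pd = fit$pd,
                              dbar = fit$dbar, status = "ok",
                              stringsAsFactors = FALSE)
    }
  }
  dic_table <- do.call(rbind, rows)
  ok <- !is.na(dic_table$dic)
  selected <- if (any(ok)) dic_table$model[ok][which.min(dic_table$dic[ok])] else NA_character_
  structure(list(outcome = outcome, seed = mcmc$seed,
                 dic_table = dic_table, selected = selected, fits = fits),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest (%s, seed %d): selected %s\n",
              x$outcome, x$seed, x$selected))
  print(x$dic_table)
  invisible(x)
}

#' Write the report bundle for one or more ladder runs
#'
#' Emits the analysis tables as plain CSV/JSON under `out_dir`:
#' `table1.csv` (descriptives), `table2.csv` (posterior mean and 95% CrI
#' per fixed effect of each outcome's selected model), per-outcome
#' `smooth_age_<outcome>.csv` and `spatial_<outcome>.csv`,
#' `dic_ladder.csv` (models x outcomes) and `manifest.json`.
#' Missing fits leave a gap that is noted in the manifest, not an error.
#'
#' @param manifests list of `run_manifest` (one per outcome).
#' @param table1 data frame from [make_table1()] (optional).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
make_report <- function(manifests, table1 = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(manifests, "run_manifest")) manifests <- list(manifests)
  written <- character(0)
  wr <- function(df, f) {
    path <- file.path(out_dir, f)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(table1)) wr(table1, "table1.csv")

  t2 <- list(); dic <- list(); gaps <- list()
  for (mf in manifests) {
    dic[[mf$outcome]] <- cbind(outcome = mf$outcome, mf$dic_table)
    sel <- mf$selected
    if (is.na(sel) || is.null(mf$fits[[sel]])) {
      gaps[[mf$outcome]] <- "no completed fit"
      next
    }
    fit <- mf$fits[[sel]]
    t2[[mf$outcome]] <- cbind(outcome = mf$outcome, model = sel, fit$fixed)
    if (!is.null(fit$smooth))
      wr(fit$smooth, sprintf("smooth_age_%s.csv", mf$outcome))
    if (!is.null(fit$spatial))
      wr(fit$spatial, sprintf("spatial_%s.csv", mf$outcome))
  }
  if (length(t2)) {
    t2 <- do.call(rbind, t2)
    t2$mean <- round(t2$mean, 2); t2$ci_low <- round(t2$ci_low, 2)
    t2$ci_high <- round(t2$ci_high, 2)
    wr(t2, "table2.csv")
  }
  if (length(dic)) wr(do.call(rbind, dic), "dic_ladder.csv")

  manifest <- list(
    seed = manifests[[1L]]$seed,
    outcomes = vapply(manifests, `[[`, "", "outcome"),
    selected = lapply(stats::setNames(manifests,
                                      vapply(manifests, `[[`, "", "outcome")),
                      `[[`, "selected"),
    gaps = gaps,
    files = basename(written),
    package_version = as.character(utils::packageVersion("hapstar")))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, mpath)
  invisible(written)
}
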