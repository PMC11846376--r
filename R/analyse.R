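#' End-to-end heterogeneous-treatment-effect analysis of one trial
#'
#' Runs the full single-dataset pipeline: covariate screening (missingness
#' then correlation filters), missing-data handling, one-hot encoding and
#' standardisation, the univariable interaction screen, the
#' strong-hierarchy interaction lasso with cross-validated penalty, the
#' honest causal forest with omnibus heterogeneity test and variable
#' importance, root-split extraction, and subgroup GATEs at the data-driven
#' threshold. Stage failures are isolated: downstream stages that depend on
#' a failed stage are skipped and the cause recorded.
#'
#' @param data a [trial_data].
#' @param impute_method missing-data strategy, see [impute()].
#' @param n_trees causal forest size, default 2000.
#' @param nuisance_trees trees per nuisance forest, default 500.
#' @param seed integer seed governing every stochastic stage.
#' @param max_missing,max_cor filter cut points (defaults 0.3 and 0.7).
#' @param folds,n_lambda lasso cross-validation settings.
#' @param fix_propensity optional known randomisation probability.
#' @param out_dir optional directory: tabular results are written there as
#'   CSV/JSON alongside a frozen copy of the resolved settings.
#' @return object of class `trial_analysis`: list with `preprocess`
#'   (reports), `screen`, `volcano`, `lasso`, `forest`, `calibration`,
#'   `importance`, `root_splits`, `gates`, `errors`, `settings`.
#' @export
analyse_trial <- function(data, impute_method = "missforest",
                          n_trees = 2000L, nuisance_trees = 500L, seed = 1L,
                          max_missing = 0.3, max_cor = 0.7,
                          folds = 5L, n_lambda = 50L,
                          fix_propensity = NULL, out_dir = NULL) {
  stopifnot(inherits(data, "trial_data"))
  settings <- list(impute_method = impute_method, n_trees = n_trees,
                   nuisance_trees = nuisance_trees, seed = seed,
                   max_missing = max_missing, max_cor = max_cor,
                   folds = folds, n_lambda = n_lambda,
                   fix_propensity = fix_propensity)
  errors <- list()
  note_error <- function(stage, e) errors[[stage]] <<- conditionMessage(e)

  fm <- filter_high_missingness(data, max_missing)
  fc <- filter_correlated(fm$data, max_cor)
  im <- impute(fc$data, method = impute_method, seed = seed)
  es <- encode_and_scale(im$data)
  enc <- es$data
  pre <- list(missingness = fm$report, correlation = fc$report,
              imputation = im$report, encoding = es$report)

  screen <- tryCatch(run_screen(enc), error = function(e) {
    note_error("screen", e); NULL
  })
  volcano <- if (!is.null(screen)) volcano_table(screen) else NULL

  lasso <- tryCatch(
    cv_select_lambda(enc, folds = folds, seed = seed, n_lambda = n_lambda),
    error = function(e) { note_error("lasso", e); NULL })

  forest <- tryCatch(
    causal_forest(enc, n_trees = n_trees, nuisance_trees = nuisance_trees,
                  seed = seed, fix_propensity = fix_propensity),
    error = function(e) { note_error("forest", e); NULL })

  calibration <- importance <- rs <- gates <- NULL
  if (!is.null(forest)) {
    calibration <- tryCatch(test_calibration(forest),
                            error = function(e) { note_error("calibration", e); NULL })
    importance <- tryCatch(variable_importance(forest),
                           error = function(e) { note_error("importance", e); NULL })
    rs <- tryCatch(root_splits(forest),
                   error = function(e) { note_error("root_splits", e); NULL })
    if (!is.null(rs) && !is.na(rs$modal_variable) && !is.na(rs$mean_threshold)) {
      gates <- tryCatch(
        partition_and_gate(forest, rs$modal_variable, rs$mean_threshold),
        error = function(e) { note_error("gates", e); NULL })
    }
  }

  out <- structure(list(preprocess = pre, screen = screen, volcano = volcano,
                        lasso = lasso, forest = forest,
                        calibration = calibration, importance = importance,
                        root_splits = rs, gates = gates,
                        errors = errors, settings = settings),
                   class = "trial_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat("Heterogeneous treatment effect analysis\n")
  if (!is.null(x$screen)) print(x$screen)
  if (!is.null(x$lasso)) print(x$lasso)
  if (!is.null(x$forest)) print(x$forest)
  if (!is.null(x$calibration)) print(x$calibration)
  if (!is.null(x$root_splits)) print(x$root_splits)
  if (!is.null(x$gates)) print(x$gates)
  for (nm in names(x$errors)) {
    cat(sprintf("  stage '%s' failed: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

write_analysis <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x$settings, file.path(out_dir, "settings.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(x$volcano)) {
    utils::write.csv(x$volcano, file.path(out_dir, "volcano.csv"),
                     row.names = FALSE)
  }
  if (!is.null(x$screen)) {
    utils::write.csv(x$screen$results, file.path(out_dir, "screen.csv"),
                     row.names = FALSE)
  }
  if (!is.null(x$lasso)) {
    jsonlite::write_json(
      list(selected_lambda = x$lasso$selected_lambda,
           lambda_path = x$lasso$lambda_path,
           cv_error_path = x$lasso$cv_error_path,
           coefficients = as.list(x$lasso$coefficients),
           selected_interactions = x$lasso$selected_interactions,
           standardized_or = as.list(x$lasso$standardized_or)),
      file.path(out_dir, "lasso.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(x$forest)) {
    utils::write.csv(data.frame(tau_oob = x$forest$tau_oob),
                     file.path(out_dir, "cate.csv"), row.names = FALSE)
    write_forest_json(x$forest, file.path(out_dir, "forest.json"))
  }
  if (!is.null(x$root_splits)) {
    pv <- x$root_splits$per_variable
    pv$thresholds <- vapply(pv$thresholds, function(t) {
      paste(signif(t, 6), collapse = ";")
    }, character(1))
    utils::write.csv(pv, file.path(out_dir, "root_splits.csv"),
                     row.names = FALSE)
  }
  if (!is.null(x$gates)) {
    g <- rbind(as.data.frame(unclass(x$gates$low)[1:6]),
               as.data.frame(unclass(x$gates$high)[1:6]))
    utils::write.csv(g, file.path(out_dir, "gates.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' Serialise a fitted forest as a JSON tree interchange
#'
#' Writes per-tree split records, leaf memberships and subsample indices so
#' external tools (or the root-split extractor) can consume the ensemble.
#'
#' @param model a [causal_forest()] fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(model, path) {
  trees <- lapply(model$trees, function(tr) {
    list(root = tr$root, var = tr$var, threshold = tr$threshold,
         left = tr$left, right = tr$right, depth = tr$depth,
         members = tr$members, grow_idx = tr$grow_idx, est_idx = tr$est_idx)
  })
  jsonlite::write_json(list(features = model$feature_names,
                            params = model$params, trees = trees),
                       path, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}
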