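#' Run one simulation replicate
#'
#' Generates a single trial from the configured process and analyses it
#' with all three approaches on identical data: (a) an honest causal forest
#' with root-split extraction and subgroup GATEs at the recovered
#' threshold, (b) univariable treatment-interaction logistic models for the
#' continuous modifier and for the modifier dichotomised at a hypothesised
#' clinical threshold, and (c) the strong-hierarchy interaction lasso in
#' both covariate codings with the refit Wald post-selection test. Any
#' method failure is recorded as an NA sentinel; the replicate never
#' aborts.
#'
#' @param dgp a calibrated [dgp_config].
#' @param seed replicate seed; all method-level seeds derive from it.
#' @param methods list of method settings: `n_trees` (forest size, default
#'   500), `nuisance_trees` (default 500), `folds`, `n_lambda`,
#'   `clinical_threshold` (default 5.4), `modifier` (default "X2").
#' @return one-row data frame (`replicate_result`).
#' @export
run_replicate <- function(dgp, seed, methods = list()) {
  m <- utils::modifyList(list(n_trees = 500L, nuisance_trees = 500L,
                              folds = 5L, n_lambda = 50L,
                              clinical_threshold = 5.4, modifier = "X2"),
                         methods)
  cfg <- dgp
  cfg$seed <- as.integer(seed)
  data <- generate_trial(cfg)
  mod <- m$modifier
  res <- data.frame(seed = as.integer(seed), modal_variable = NA_character_,
                    mean_threshold = NA_real_, cf_dfp = NA_real_,
                    cf_dfp_p = NA_real_, univ_continuous_p = NA_real_,
                    univ_dichot_p = NA_real_,
                    lasso_kept_continuous = NA, lasso_p_continuous = NA_real_,
                    lasso_kept_dichot = NA, lasso_p_dichot = NA_real_,
                    gate_low = NA_real_, gate_high = NA_real_,
                    stringsAsFactors = FALSE)

  ## (a) causal forest + root splits + GATEs
  try({
    fit <- causal_forest(data, n_trees = m$n_trees, seed = seed,
                         nuisance_trees = m$nuisance_trees)
    rs <- root_splits(fit)
    res$modal_variable <- rs$modal_variable
    res$mean_threshold <- rs$mean_threshold
    cal <- test_calibration(fit)
    res$cf_dfp <- cal$differential_forest_prediction
    res$cf_dfp_p <- cal$dfp_p_value
    if (!is.na(rs$mean_threshold)) {
      gates <- partition_and_gate(fit, rs$modal_variable, rs$mean_threshold)
      res$gate_low <- gates$low$gate
      res$gate_high <- gates$high$gate
    }
  }, silent = TRUE)

  ## (b) univariable interaction tests
  try({
    res$univ_continuous_p <- fit_interaction_logistic(data, mod)$p3
  }, silent = TRUE)
  try({
    dich <- dichotomize(data, mod, m$clinical_threshold, name = ".Z")
    res$univ_dichot_p <- fit_interaction_logistic(dich, ".Z")$p3
  }, silent = TRUE)

  ## (c) hierarchical lasso, continuous and dichotomised codings
  try({
    enc <- encode_and_scale(data)$data
    hl <- cv_select_lambda(enc, folds = m$folds, seed = seed + 1L,
                           n_lambda = m$n_lambda)
    res$lasso_kept_continuous <- mod %in% hl$selected_interactions
    pst <- post_selection_test(hl, enc, mod)
    res$lasso_p_continuous <- pst$p_value
  }, silent = TRUE)
  try({
    ddata <- data
    ddata$X[[mod]] <- as.numeric(ddata$X[[mod]] > m$clinical_threshold)
    ddata$meta$kind[ddata$meta$name == mod] <- "binary"
    encd <- encode_and_scale(ddata)$data
    hld <- cv_select_lambda(encd, folds = m$folds, seed = seed + 2L,
                            n_lambda = m$n_lambda)
    res$lasso_kept_dichot <- mod %in% hld$selected_interactions
    pstd <- post_selection_test(hld, encd, mod)
    res$lasso_p_dichot <- pstd$p_value
  }, silent = TRUE)

  res
}

#' Run the simulation study
#'
#' Repeats [run_replicate()] `n_reps` times. Replicate seeds are drawn up
#' front from the root seed, so results are independent of scheduling
#' order; with `cores > 1` replicates run in parallel via forked workers
#' and yield a report identical to the serial run.
#'
#' @param dgp a calibrated [dgp_config].
#' @param n_reps number of replicates (default 100; the full-scale study
#'   uses 1000).
#' @param seed root integer seed.
#' @param methods see [run_replicate()].
#' @param cores forked workers, default 1.
#' @return object of class `simulation_report`; see [aggregate_replicates()].
#' @export
run_simulation <- function(dgp, n_reps = 100L, seed = 1L, methods = list(),
                           cores = 1L) {
  rep_seeds <- withr_seed(seed, sample.int(2147483600L, n_reps))
  runner <- function(i) run_replicate(dgp, rep_seeds[i], methods)
  reps <- if (cores > 1L) {
    parallel::mclapply(seq_len(n_reps), runner, mc.cores = cores,
                       mc.preschedule = FALSE)
  } else {
    lapply(seq_len(n_reps), runner)
  }
  replicates <- do.call(rbind, reps)
  aggregate_replicates(replicates,
                       true_threshold = dgp$true_threshold,
                       modifier = (utils::modifyList(
                         list(modifier = "X2"), methods))$modifier)
}

#' Aggregate replicate results into performance metrics
#'
#' Computes the study-level metrics: how often the forest's modal root
#' split identified the true modifier; the mean, SD, mean squared error
#' (population form, relative to the true threshold) and empirical 95\%
#' range (2.5th-97.5th percentiles) of the per-replicate mean thresholds
#' among replicates that identified the modifier; and the detection powers
#' of the univariable and lasso comparators at the 5\% level, with binomial
#' Monte-Carlo standard errors on every percentage.
#'
#' @param replicates data frame of [run_replicate()] rows.
#' @param true_threshold true subgroup threshold, default 4.68.
#' @param modifier true effect modifier name, default `"X2"`.
#' @param alpha detection level, default 0.05.
#' @return object of class `simulation_report`.
#' @export
aggregate_replicates <- function(replicates, true_threshold = 4.68,
                                 modifier = "X2", alpha = 0.05) {
  stopifnot(nrow(replicates) >= 2)
  n <- nrow(replicates)
  pct <- function(flag) 100 * mean(flag, na.rm = TRUE)
  mcse <- function(flag) {
    p <- mean(flag, na.rm = TRUE)
    100 * sqrt(p * (1 - p) / sum(!is.na(flag)))
  }
  correct <- !is.na(replicates$modal_variable) &
    replicates$modal_variable == modifier
  thr <- replicates$mean_threshold[correct & !is.na(replicates$mean_threshold)]
  thr_mean <- mean(thr); thr_sd <- stats::sd(thr)
  thr_mse <- mean((thr - true_threshold)^2)
  out <- list(
    n_reps = n,
    pct_modal_correct = pct(correct), se_modal_correct = mcse(correct),
    threshold_mean = thr_mean, threshold_sd = thr_sd,
    threshold_mse_vs_true = thr_mse,
    threshold_95_range = stats::quantile(thr, c(0.025, 0.975), names = FALSE),
    power_univ_continuous = pct(replicates$univ_continuous_p < alpha),
    se_univ_continuous = mcse(replicates$univ_continuous_p < alpha),
    power_univ_dichot = pct(replicates$univ_dichot_p < alpha),
    se_univ_dichot = mcse(replicates$univ_dichot_p < alpha),
    lasso_retention_continuous = pct(replicates$lasso_kept_continuous %in% TRUE),
    power_lasso_continuous = pct(!is.na(replicates$lasso_p_continuous) &
                                   replicates$lasso_p_continuous < alpha),
    se_lasso_continuous = mcse(!is.na(replicates$lasso_p_continuous) &
                                 replicates$lasso_p_continuous < alpha),
    lasso_retention_dichot = pct(replicates$lasso_kept_dichot %in% TRUE),
    power_lasso_dichot = pct(!is.na(replicates$lasso_p_dichot) &
                               replicates$lasso_p_dichot < alpha),
    true_threshold = true_threshold,
    modifier = modifier,
    replicates = replicates)
  class(out) <- "simulation_report"
  out
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf("simulation_report: %d replicates\n", x$n_reps))
  cat(sprintf("  modal root split = %s: %.1f%% (MC SE %.1f)\n",
              x$modifier, x$pct_modal_correct, x$se_modal_correct))
  cat(sprintf("  threshold: mean %.4g, SD %.3g, MSE vs %.4g = %.3g, 95%% range [%.4g, %.4g]\n",
              x$threshold_mean, x$threshold_sd, x$true_threshold,
              x$threshold_mse_vs_true, x$threshold_95_range[1],
              x$threshold_95_range[2]))
  cat(sprintf("  univariable power: continuous %.1f%%, dichotomised %.1f%%\n",
              x$power_univ_continuous, x$power_univ_dichot))
  cat(sprintf("  lasso: retention %.1f%%, power %.1f%% (continuous); retention %.1f%%, power %.1f%% (dichotomised)\n",
              x$lasso_retention_continuous, x$power_lasso_continuous,
              x$lasso_retention_dichot, x$power_lasso_dichot))
  invisible(x)
}
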