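#' Root-split summary of a causal forest
#'
#' The first (root) split of each honest causal tree maximises the
#' difference in estimated treatment effects between the two halves of its
#' subsample, so the variable that most trees choose at the root — and the
#' average of the thresholds they apply — defines the most likely
#' "first-order" subgroup boundary. This extracts every tree's root split,
#' tallies the counts per variable, identifies the modal variable (ties
#' broken towards the lower column index, with a flag) and averages the
#' modal variable's thresholds. Thresholds on standardised covariates are
#' mapped back to raw units using the stored centring metadata; root splits
#' on one-hot indicator levels are tallied under the parent categorical
#' variable, for which no threshold mean is defined (the split is a level
#' set).
#'
#' @param model a [causal_forest()] fit.
#' @param summarise `"mean"` (default, matching the procedure) or
#'   `"median"` for a robustness variant.
#' @return object of class `root_split_summary`: `per_variable` (data frame
#'   of `variable`, `count`, plus a list-column `thresholds` in raw units),
#'   `modal_variable`, `mean_threshold`, `threshold_sd`,
#'   `n_trees_with_root`, `n_stumps`, `tie` flag.
#' @export
root_splits <- function(model, summarise = c("mean", "median")) {
  stopifnot(inherits(model, "causal_forest"))
  summarise <- match.arg(summarise)
  feats <- model$feature_names
  meta <- model$data$meta
  vars <- integer(0); thrs <- numeric(0)
  n_stumps <- 0L
  for (tr in model$trees) {
    root <- tr$root
    if (is.na(tr$var[root])) { n_stumps <- n_stumps + 1L; next }
    vars <- c(vars, tr$var[root])
    thrs <- c(thrs, tr$threshold[root])
  }
  if (!length(vars)) {
    out <- list(per_variable = data.frame(variable = character(0),
                                          count = integer(0)),
                modal_variable = NA_character_, mean_threshold = NA_real_,
                threshold_sd = NA_real_, n_trees_with_root = 0L,
                n_stumps = n_stumps, tie = FALSE)
    class(out) <- "root_split_summary"
    return(out)
  }
  name <- feats[vars]
  ## fold one-hot levels back onto the parent categorical variable
  parent <- vapply(name, function(nm) {
    i <- match(nm, meta$name)
    if (!is.na(i) && meta$kind[i] == "binary" && grepl(".", nm, fixed = TRUE)) {
      stem <- sub("\\.[^.]*$", "", nm)
      if (sum(startsWith(meta$name, paste0(stem, "."))) >= 2) return(stem)
    }
    nm
  }, character(1), USE.NAMES = FALSE)
  ## back-transform thresholds to raw units
  raw_thr <- vapply(seq_along(thrs), function(i) {
    unscale_threshold(meta, name[i], thrs[i])
  }, numeric(1))
  counts <- table(parent)
  best <- max(counts)
  winners <- names(counts)[counts == best]
  ## tie-break: lower column index in the feature layout
  ord_idx <- vapply(winners, function(v) {
    m <- match(v, feats)
    if (is.na(m)) min(match(name[parent == v], feats)) else m
  }, numeric(1))
  modal <- winners[which.min(ord_idx)]
  tie <- length(winners) > 1
  modal_is_cont <- {
    i <- match(modal, meta$name)
    !is.na(i) && meta$kind[i] == "continuous"
  }
  modal_thr <- raw_thr[parent == modal]
  per_var <- data.frame(variable = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  per_var <- per_var[order(-per_var$count), , drop = FALSE]
  rownames(per_var) <- NULL
  per_var$thresholds <- lapply(per_var$variable,
                               function(v) raw_thr[parent == v])
  out <- list(per_variable = per_var,
              modal_variable = modal,
              mean_threshold = if (modal_is_cont) {
                if (summarise == "mean") mean(modal_thr)
                else stats::median(modal_thr)
              } else NA_real_,
              threshold_sd = if (modal_is_cont) stats::sd(modal_thr) else NA_real_,
              n_trees_with_root = length(vars),
              n_stumps = n_stumps, tie = tie)
  class(out) <- "root_split_summary"
  out
}

#' @export
print.root_split_summary <- function(x, ...) {
  cat(sprintf("  root splits: %d trees split at the root (%d stumps)\n",
              x$n_trees_with_root, x$n_stumps))
  if (is.na(x$modal_variable)) {
    cat("  no root splits available\n")
    return(invisible(x))
  }
  cat(sprintf("  modal root variable: %s%s", x$modal_variable,
              if (x$tie) " (tied)" else ""))
  if (!is.na(x$mean_threshold)) {
    cat(sprintf(", mean threshold %.4g (SD %.3g)", x$mean_threshold,
                x$threshold_sd))
  }
  cat("\n")
  invisible(x)
}

#' Partition the population at a threshold and estimate subgroup effects
#'
#' Splits the trial population into `value <= threshold` (low) and
#' `value > threshold` (high) on the named covariate (raw units) and
#' estimates the group average treatment effect in each side from the
#' forest's doubly robust scores.
#'
#' @param model a [causal_forest()] fit.
#' @param variable covariate name.
#' @param threshold cut point in the covariate's raw units.
#' @return list of class `gate_pair` with elements `low` and `high`
#'   ([average_treatment_effect()] results), plus `variable`, `threshold`.
#' @export
partition_and_gate <- function(model, variable, threshold) {
  stopifnot(inherits(model, "causal_forest"))
  if (!variable %in% model$feature_names) stop("unknown covariate: ", variable)
  meta <- model$data$meta
  x <- model$data$X[[variable]]
  i <- match(variable, meta$name)
  if (!is.na(i) && !is.na(meta$center[i])) {
    x <- meta$center[i] + x * meta$scale[i]  # back to raw units
  }
  lo <- x <= threshold
  if (!any(lo)) stop("empty low subgroup: no values at or below ", threshold)
  if (all(lo)) stop("empty high subgroup: no values above ", threshold)
  g <- dr_scores(model)
  out <- list(low = average_treatment_effect(
                g, lo, sprintf("%s <= %.4g", variable, threshold)),
              high = average_treatment_effect(
                g, !lo, sprintf("%s > %.4g", variable, threshold)),
              variable = variable, threshold = threshold)
  class(out) <- "gate_pair"
  out
}

#' @export
print.gate_pair <- function(x, ...) {
  cat(sprintf("Data-driven subgroups on %s at %.4g\n", x$variable, x$threshold))
  print(x$low); print(x$high)
  invisible(x)
}
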