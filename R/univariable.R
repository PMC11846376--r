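#' Single-covariate treatment-interaction logistic model
#'
#' The classical subgroup screen: for one candidate effect modifier `x`,
#' fits the logistic model
#' \deqn{logit E[Y | W, x] = \beta_0 + \beta_1 W + \beta_2 x + \beta_3 W x}
#' by maximum likelihood (weighted when IPW weights are present) and reports
#' Wald inference on the interaction coefficient \eqn{\beta_3}. An intercept
#' is always included. Separation or non-convergence is detected and
#' reported with an infinite-confidence-interval sentinel instead of
#' failing.
#'
#' @param data a [trial_data].
#' @param covariate name of the covariate to screen. Factors are re-encoded
#'   with a reference level and each non-reference level screened as its own
#'   indicator; this helper expects a single numeric column (see
#'   [run_screen()] for the expansion).
#' @return a one-row data frame with columns `covariate`, `beta1`, `beta2`,
#'   `beta3`, `se3`, `or3`, `ci3_low`, `ci3_high`, `p3`, `converged`.
#' @export
fit_interaction_logistic <- function(data, covariate) {
  stopifnot(inherits(data, "trial_data"))
  if (!covariate %in% names(data$X)) stop("unknown covariate: ", covariate)
  x <- data$X[[covariate]]
  if (is.factor(x)) stop("factor covariates must be expanded before fitting")
  df <- data.frame(Y = data$Y, W = data$W, x = x)
  fit <- suppressWarnings(
    stats::glm(Y ~ W * x, data = df, family = stats::binomial(),
               weights = data$weights)
  )
  cf <- stats::coef(fit)
  vc <- suppressWarnings(stats::vcov(fit))
  b3 <- cf["W:x"]
  se3 <- sqrt(vc["W:x", "W:x"])
  ## separation / non-convergence sentinel: huge coefficients or SEs
  converged <- isTRUE(fit$converged) && is.finite(b3) && is.finite(se3) &&
    abs(b3) < 15 && se3 < 100
  if (!converged) {
    return(data.frame(covariate = covariate,
                      beta1 = unname(cf["W"]), beta2 = unname(cf["x"]),
                      beta3 = unname(b3), se3 = Inf, or3 = unname(exp(b3)),
                      ci3_low = 0, ci3_high = Inf, p3 = 1, converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  z <- b3 / se3
  p3 <- 2 * stats::pnorm(-abs(z))
  data.frame(covariate = covariate,
             beta1 = unname(cf["W"]), beta2 = unname(cf["x"]),
             beta3 = unname(b3), se3 = unname(se3), or3 = unname(exp(b3)),
             ci3_low = unname(exp(b3 - 1.96 * se3)),
             ci3_high = unname(exp(b3 + 1.96 * se3)),
             p3 = unname(p3), converged = TRUE,
             stringsAsFactors = FALSE)
}

#' Univariable interaction screen over all covariates
#'
#' Fits [fit_interaction_logistic()] once per covariate (factors expanded to
#' reference-level indicator columns first), then applies the Bonferroni
#' correction — `alpha` divided by the number of tests — and, for
#' volcano-plot colouring, Benjamini-Hochberg FDR flags at the same level.
#'
#' @param data a [trial_data].
#' @param alpha familywise level, default 0.05.
#' @return object of class `interaction_screen`: a list with `results` (one
#'   row per test), `bonferroni_threshold`, `alpha`, `n_tests`.
#' @export
run_screen <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "trial_data"), ncol(data$X) >= 1)
  dat <- expand_factors_reference(data)
  res <- do.call(rbind, lapply(names(dat$X), function(nm) {
    fit_interaction_logistic(dat, nm)
  }))
  K <- nrow(res)
  thr <- alpha / K
  res$bonferroni_significant <- res$p3 < thr
  res$fdr_q <- stats::p.adjust(res$p3, method = "BH")
  res$fdr_significant <- res$fdr_q < alpha
  structure(list(results = res, bonferroni_threshold = thr,
                 alpha = alpha, n_tests = K),
            class = "interaction_screen")
}

## reference-level dummy expansion for the unpenalised screen
expand_factors_reference <- function(data) {
  out <- list()
  for (j in seq_along(data$X)) {
    nm <- names(data$X)[j]
    col <- data$X[[j]]
    if (is.factor(col)) {
      lv <- levels(col)
      for (l in lv[-1]) out[[paste0(nm, ".", l)]] <- as.numeric(col == l)
    } else {
      out[[nm]] <- col
    }
  }
  data$X <- as.data.frame(out, check.names = FALSE)
  data$meta <- infer_meta(data$X)
  data
}

#' @export
print.interaction_screen <- function(x, ...) {
  cat(sprintf("interaction_screen: %d tests, Bonferroni threshold p < %.3g\n",
              x$n_tests, x$bonferroni_threshold))
  sig <- x$results[x$results$bonferroni_significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("  Bonferroni-significant interactions:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s: OR %.3f [%.3f, %.3f], p = %.2g\n",
                  sig$covariate[i], sig$or3[i], sig$ci3_low[i],
                  sig$ci3_high[i], sig$p3[i]))
    }
  } else cat("  no Bonferroni-significant interactions\n")
  invisible(x)
}

#' Volcano-plot table for an interaction screen
#'
#' Monotone transform of the screen results: one row per covariate with the
#' interaction log odds ratio, `-log10(p)` (capped at `p_floor` for p-values
#' of exactly zero) and both significance flags, in the input row order. No
#' refitting occurs.
#'
#' @param screen an `interaction_screen`.
#' @param p_floor smallest p-value represented (default 1e-300).
#' @return data frame with columns `covariate`, `log_or`, `neg_log10_p`,
#'   `bonferroni_significant`, `fdr_significant`.
#' @export
volcano_table <- function(screen, p_floor = 1e-300) {
  stopifnot(inherits(screen, "interaction_screen"))
  r <- screen$results
  data.frame(covariate = r$covariate,
             log_or = r$beta3,
             neg_log10_p = -log10(pmax(r$p3, p_floor)),
             bonferroni_significant = r$bonferroni_significant,
             fdr_significant = r$fdr_significant,
             stringsAsFactors = FALSE)
}
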