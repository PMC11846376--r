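#' Configuration of the synthetic trial data-generating process
#'
#' Describes a two-arm trial with a prognostic covariate X1, a continuous
#' effect modifier X2 (distributed like maximum serum potassium, mmol/L) and
#' a binary 28-day-survival outcome from a logistic model in which the
#' treatment effect changes across the threshold-defined subgroup
#' `S = 1{X2 > true_threshold}`:
#'
#' \deqn{logit P(Y=1) = \beta_0 + \beta_{x1} X1 + \beta_w W + \beta_{ws} W S.}
#'
#' @param n_participants number of participants per generated trial.
#' @param treat_prob randomisation probability for treatment (default 0.5).
#' @param x1_mean,x1_sd distribution of the prognostic covariate X1.
#' @param x2_mean,x2_sd distribution of the effect modifier X2 in its raw
#'   units (defaults 4.58 and 0.937 mmol/L).
#' @param true_threshold subgroup threshold on X2 (default 4.68 mmol/L);
#'   membership uses the strict inequality `X2 > true_threshold`.
#' @param beta0,beta_x1,beta_w,beta_ws logistic-model coefficients on the
#'   log-odds scale. [calibrate_dgp()] solves for `beta0`, `beta_w`,
#'   `beta_ws` from marginal targets.
#' @param seed integer seed; generation is fully reproducible from it. The
#'   RNG is R's Mersenne-Twister with inversion sampling for normals
#'   (`kind = "Mersenne-Twister", normal.kind = "Inversion"`), pinned in the
#'   config so datasets are bit-reproducible across platforms.
#'
#' @return An object of class `dgp_config`.
#' @export
dgp_config <- function(n_participants = 1000, treat_prob = 0.5,
                       x1_mean = 0, x1_sd = 1,
                       x2_mean = 4.58, x2_sd = 0.937,
                       true_threshold = 4.68,
                       beta0 = 1, beta_x1 = 0.5, beta_w = 0, beta_ws = 0,
                       seed = 1L) {
  stopifnot(x1_sd > 0, x2_sd > 0, treat_prob > 0, treat_prob < 1)
  structure(list(
    n_participants = as.integer(n_participants), treat_prob = treat_prob,
    x1_mean = x1_mean, x1_sd = x1_sd, x2_mean = x2_mean, x2_sd = x2_sd,
    true_threshold = true_threshold,
    beta0 = beta0, beta_x1 = beta_x1, beta_w = beta_w, beta_ws = beta_ws,
    seed = as.integer(seed),
    rng = c(kind = "Mersenne-Twister", normal.kind = "Inversion")
  ), class = "dgp_config")
}

#' @export
print.dgp_config <- function(x, ...) {
  cat(sprintf(paste0(
    "dgp_config: n=%d, P(W=1)=%.2f\n",
    "  X1 ~ N(%.3g, %.3g^2); X2 ~ N(%.3g, %.3g^2); subgroup X2 > %.3g\n",
    "  logit P(Y=1) = %.4f + %.4f X1 + %.4f W + %.4f W*S\n"),
    x$n_participants, x$treat_prob, x$x1_mean, x$x1_sd, x$x2_mean, x$x2_sd,
    x$true_threshold, x$beta0, x$beta_x1, x$beta_w, x$beta_ws))
  invisible(x)
}

## Marginal survival under the logistic model, integrating X1 out over its
## normal distribution by adaptive quadrature (deterministic, no Monte Carlo).
marginal_survival <- function(shift, beta_x1, x1_mean, x1_sd) {
  stats::integrate(function(z) {
    stats::plogis(shift + beta_x1 * z) * stats::dnorm(z, x1_mean, x1_sd)
  }, lower = x1_mean - 10 * x1_sd, upper = x1_mean + 10 * x1_sd,
  rel.tol = 1e-10)$value
}

solve_shift <- function(target, beta_x1, x1_mean, x1_sd, what) {
  if (target <= 0 || target >= 1) {
    stop("calibration target infeasible for the logistic link (", what,
         " = ", target, " outside (0, 1))")
  }
  stats::uniroot(function(s) {
    marginal_survival(s, beta_x1, x1_mean, x1_sd) - target
  }, interval = c(-40, 40), tol = 1e-12)$root
}

#' Calibrate the outcome model to marginal trial targets
#'
#' Solves for `(beta0, beta_w, beta_ws)` so that the generated trial has a
#' given control-arm survival and given within-subgroup marginal risk
#' differences. Because the subgroup indicator S does not enter the control
#' arm, the three targets decouple into three one-dimensional root-finding
#' problems on the marginal survival curve, solved by numeric quadrature
#' over the X1 distribution — no simulation is involved and the result is
#' exact to quadrature tolerance.
#'
#' The defaults reproduce a VANISH-like trial: control-arm 28-day survival
#' 72.5\% and subgroup risk differences +0.069 (serum potassium at or below
#' the threshold) and -0.257 (above it).
#'
#' @param control_survival target P(Y=1 | W=0).
#' @param rd_low target risk difference E[Y|W=1,S=0] - E[Y|W=0,S=0] in the
#'   low-X2 subgroup.
#' @param rd_high target risk difference in the high-X2 subgroup (S=1).
#' @param config a [dgp_config] supplying the covariate distributions, the
#'   threshold and the (caller-fixed) prognostic strength `beta_x1`.
#' @return The config with `beta0`, `beta_w`, `beta_ws` replaced by the
#'   calibrated values.
#' @export
calibrate_dgp <- function(control_survival = 0.725, rd_low = 0.069,
                          rd_high = -0.257, config = dgp_config()) {
  stopifnot(inherits(config, "dgp_config"),
            abs(rd_low) < 1, abs(rd_high) < 1)
  b1 <- config$beta_x1
  beta0 <- solve_shift(control_survival, b1, config$x1_mean, config$x1_sd,
                       "control-arm survival")
  ## treated, S = 0: survival = control + rd_low
  s_low <- solve_shift(control_survival + rd_low, b1,
                       config$x1_mean, config$x1_sd, "treated low-subgroup survival")
  beta_w <- s_low - beta0
  ## treated, S = 1: survival = control + rd_high
  s_high <- solve_shift(control_survival + rd_high, b1,
                        config$x1_mean, config$x1_sd, "treated high-subgroup survival")
  beta_ws <- s_high - beta0 - beta_w
  config$beta0 <- beta0
  config$beta_w <- beta_w
  config$beta_ws <- beta_ws
  config
}

#' True marginal quantities implied by a DGP configuration
#'
#' Deterministic quadrature versions of the quantities the generator is
#' calibrated to: control-arm survival, the two subgroup risk differences,
#' the subgroup prevalence and the marginal average treatment effect.
#'
#' @param config a [dgp_config].
#' @return named list with `control_survival`, `rd_low`, `rd_high`,
#'   `prevalence_high`, `ate`.
#' @export
dgp_truth <- function(config) {
  p0 <- marginal_survival(config$beta0, config$beta_x1,
                          config$x1_mean, config$x1_sd)
  p1_low <- marginal_survival(config$beta0 + config$beta_w, config$beta_x1,
                              config$x1_mean, config$x1_sd)
  p1_high <- marginal_survival(config$beta0 + config$beta_w + config$beta_ws,
                               config$beta_x1, config$x1_mean, config$x1_sd)
  prev <- 1 - stats::pnorm((config$true_threshold - config$x2_mean) / config$x2_sd)
  list(control_survival = p0,
       rd_low = p1_low - p0,
       rd_high = p1_high - p0,
       prevalence_high = prev,
       ate = (1 - prev) * (p1_low - p0) + prev * (p1_high - p0))
}

#' Generate one synthetic trial
#'
#' Draws treatment, covariates and outcome from the configured process:
#' `W ~ Bernoulli(treat_prob)`, `X1 ~ N(x1_mean, x1_sd^2)`,
#' `X2 ~ N(x2_mean, x2_sd^2)`, and
#' `Y ~ Bernoulli(plogis(beta0 + beta_x1*X1 + beta_w*W + beta_ws*W*S))`
#' with `S = 1{X2 > true_threshold}`.
#'
#' @param config a [dgp_config].
#' @return a [trial_data] with covariates `X1`, `X2`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  n <- config$n_participants
  if (n < 2) stop("n_participants must be at least 2")
  withr_seed(config$seed, {
    W <- stats::rbinom(n, 1, config$treat_prob)
    X1 <- stats::rnorm(n, config$x1_mean, config$x1_sd)
    X2 <- stats::rnorm(n, config$x2_mean, config$x2_sd)
    S <- as.numeric(X2 > config$true_threshold)
    eta <- config$beta0 + config$beta_x1 * X1 + config$beta_w * W +
      config$beta_ws * W * S
    Y <- stats::rbinom(n, 1, stats::plogis(eta))
  })
  trial_data(Y, W, data.frame(X1 = X1, X2 = X2))
}

## Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
## caller's state afterwards; the bindings made by expr land in the caller.
withr_seed <- function(seed, expr) {
  env <- parent.frame()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  eval(substitute(expr), env)
}

#' Generate a richer VANISH-like trial to exercise preprocessing
#'
#' Produces a trial with many mixed-type baseline covariates (continuous,
#' binary, multi-level categorical), optional injected missingness (MCAR or
#' MAR on a named observed column) and optional pairwise-correlated
#' continuous covariates, emulating the messiness of real critical-care
#' baseline tables. The outcome follows the same logistic model as
#' [generate_trial()] driven by the first continuous covariate (prognostic)
#' and `X2` (modifier).
#'
#' @param n participants.
#' @param n_covariates number of baseline covariates besides `X2`; kinds
#'   cycle continuous / binary / categorical (3 levels).
#' @param missing_spec named list: column name -> either a single fraction
#'   (MCAR) or `list(fraction =, mechanism = "MAR", depends_on = <column>)`
#'   where missingness probability increases with the (observed) value of
#'   `depends_on` while averaging the requested fraction.
#' @param correlated_pairs list of `list(i, j, r)` (continuous covariate
#'   indices and target Pearson correlation, |r| <= 0.99).
#' @param config a [dgp_config] for the outcome model and X2 distribution.
#' @param seed integer seed.
#' @return a [trial_data].
#' @export
generate_vanishlike <- function(n = 408, n_covariates = 20,
                                missing_spec = list(),
                                correlated_pairs = list(),
                                config = calibrate_dgp(),
                                seed = 1L) {
  stopifnot(n >= 2, n_covariates >= 1)
  kinds <- rep(c("continuous", "binary", "categorical"),
               length.out = n_covariates)
  cont_idx <- which(kinds == "continuous")
  for (p in correlated_pairs) {
    if (abs(p[[3]]) > 0.99) stop("requested |r| > 0.99 is infeasible")
    if (!(p[[1]] %in% cont_idx) || !(p[[2]] %in% cont_idx)) {
      stop("correlated pairs must reference continuous covariate indices")
    }
  }
  withr_seed(seed, {
    W <- stats::rbinom(n, 1, config$treat_prob)
    X2 <- stats::rnorm(n, config$x2_mean, config$x2_sd)
    cols <- vector("list", n_covariates)
    names(cols) <- sprintf("V%02d", seq_len(n_covariates))
    for (j in seq_len(n_covariates)) {
      cols[[j]] <- switch(kinds[j],
        continuous = stats::rnorm(n),
        binary = stats::rbinom(n, 1, stats::runif(1, 0.1, 0.5)),
        categorical = factor(sample(c("a", "b", "c"), n, replace = TRUE,
                                    prob = c(0.5, 0.3, 0.2))))
    }
    ## impose requested correlations among standard-normal continuous columns:
    ## redraw the second member of each pair as r*x_i + sqrt(1-r^2)*noise
    for (p in correlated_pairs) {
      i <- p[[1]]; j <- p[[2]]; r <- p[[3]]
      cols[[j]] <- r * cols[[i]] + sqrt(1 - r^2) * stats::rnorm(n)
    }
    prog <- if (length(cont_idx)) cols[[cont_idx[1]]] else rep(0, n)
    S <- as.numeric(X2 > config$true_threshold)
    eta <- config$beta0 + config$beta_x1 * prog + config$beta_w * W +
      config$beta_ws * W * S
    Y <- stats::rbinom(n, 1, stats::plogis(eta))
    X <- cbind(data.frame(X2 = X2), as.data.frame(cols))
    ## inject missingness last so the MAR driver is always observed
    for (nm in names(missing_spec)) {
      if (!nm %in% names(X)) stop("missing_spec names unknown column: ", nm)
      sp <- missing_spec[[nm]]
      if (is.numeric(sp)) sp <- list(fraction = sp, mechanism = "MCAR")
      frac <- sp$fraction
      stopifnot(frac >= 0, frac < 1)
      if (identical(sp$mechanism, "MAR")) {
        drv <- X[[sp$depends_on]]
        if (is.factor(drv)) drv <- as.numeric(drv)
        rk <- rank(drv, ties.method = "average") / n
        pm <- pmin(0.95, pmax(0, frac * 2 * rk))  # increases with driver, mean ~ frac
        idx <- which(stats::runif(n) < pm)
      } else {
        idx <- sample.int(n, round(frac * n))
      }
      X[[nm]][idx] <- NA
    }
  })
  trial_data(Y, W, X)
}

#' Dichotomise a continuous covariate at a threshold
#'
#' Appends a binary indicator `1{x > threshold}` (strict inequality: a value
#' exactly at the threshold maps to 0) while retaining the original column;
#' the threshold is recorded in the new column's metadata.
#'
#' @param data a [trial_data].
#' @param column name of a continuous covariate.
#' @param threshold cut point in the column's units.
#' @param name optional name for the indicator column (default
#'   `<column>_gt_<threshold>`).
#' @return the augmented [trial_data].
#' @export
dichotomize <- function(data, column, threshold, name = NULL) {
  stopifnot(inherits(data, "trial_data"))
  if (!column %in% names(data$X)) stop("unknown column: ", column)
  kind <- data$meta$kind[match(column, data$meta$name)]
  if (kind != "continuous") stop("column ", column, " is not continuous")
  if (is.null(name)) name <- sprintf("%s_gt_%g", column, threshold)
  ind <- as.numeric(data$X[[column]] > threshold)
  data$X[[name]] <- ind
  data$meta <- rbind(data$meta, data.frame(
    name = name, kind = "binary", center = NA_real_, scale = NA_real_,
    missing_frac = mean(is.na(ind)), derived_score = FALSE,
    stringsAsFactors = FALSE))
  attr(data$meta, "thresholds") <-
    c(attr(data$meta, "thresholds"), stats::setNames(threshold, name))
  data
}

#' Read or write a generator configuration
#'
#' Configurations serialise to JSON or YAML (by file extension) so a study
#' can freeze and re-load the exact process that produced a dataset.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @param config a [dgp_config] (for writing).
#' @return `read_dgp_config()` returns a [dgp_config];
#'   `write_dgp_config()` returns `path` invisibly.
#' @export
read_dgp_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals$rng <- NULL
  do.call(dgp_config, vals)
}

#' @rdname read_dgp_config
#' @export
write_dgp_config <- function(config, path) {
  stopifnot(inherits(config, "dgp_config"))
  vals <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path, precision = 15)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
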