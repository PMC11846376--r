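#' Nuisance estimates for the partially linear model
#'
#' Estimates the propensity p(X) = E[W|X] and the treatment-free mean
#' outcome m(X) = E[Y|X] with regression random forests (W on X, and Y on X
#' excluding W), taking out-of-bag predictions so each participant's
#' nuisance values come only from trees whose bootstrap excluded them. The
#' residuals W - p(X) and Y - m(X) drive the causal trees.
#'
#' In a randomised trial the propensity is known by design;
#' `fix_propensity` short-circuits the propensity forest with that constant
#' (e.g. 0.5 for 1:1 randomisation).
#'
#' @param data a complete-case (post-imputation) [trial_data].
#' @param n_trees trees per nuisance forest, default 500.
#' @param seed integer seed.
#' @param fix_propensity optional constant in (0, 1) used as p(X).
#' @param clip propensity clipping bounds, default `c(0.01, 0.99)`, keeping
#'   the doubly-robust score denominators away from zero.
#' @param min_node minimum leaf size of the nuisance forests; the default
#'   `max(5, n/25)` smooths the conditional-mean estimates, which for a
#'   binary outcome are badly overfit by deep trees.
#' @return list of class `cf_nuisance`: `p_hat`, `m_hat`, `w_resid`,
#'   `y_resid`, `source`, `clipped` (logical per row).
#' @export
fit_nuisance <- function(data, n_trees = 500L, seed = 1L,
                         fix_propensity = NULL, clip = c(0.01, 0.99),
                         min_node = NULL) {
  stopifnot(inherits(data, "trial_data"))
  if (any(vapply(data$X, anyNA, logical(1)))) {
    stop("covariates contain missing values; impute first")
  }
  Xdf <- data$X
  if (is.null(min_node)) min_node <- max(5L, round(length(data$Y) / 25))
  m_fit <- ranger::ranger(x = Xdf, y = data$Y, num.trees = n_trees,
                          seed = seed, num.threads = 1, verbose = FALSE,
                          min.node.size = min_node)
  m_hat <- m_fit$predictions  # out-of-bag
  if (anyNA(m_hat)) {
    stop("some rows were in-bag for every outcome tree; increase n_trees")
  }
  if (is.null(fix_propensity)) {
    p_fit <- ranger::ranger(x = Xdf, y = data$W, num.trees = n_trees,
                            seed = seed + 1L, num.threads = 1, verbose = FALSE,
                            min.node.size = min_node)
    p_raw <- p_fit$predictions
    if (anyNA(p_raw)) {
      stop("some rows were in-bag for every propensity tree; increase n_trees")
    }
    source <- "forest"
  } else {
    stopifnot(fix_propensity > 0, fix_propensity < 1)
    p_raw <- rep(fix_propensity, length(data$W))
    source <- "fixed_known"
  }
  clipped <- p_raw < clip[1] | p_raw > clip[2]
  p_hat <- pmin(pmax(p_raw, clip[1]), clip[2])
  structure(list(p_hat = p_hat, m_hat = m_hat,
                 w_resid = data$W - p_hat, y_resid = data$Y - m_hat,
                 source = source, clipped = clipped),
            class = "cf_nuisance")
}
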