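# Shared fixtures, built in code. The calibrated configuration solves for
# the outcome-model coefficients once per test run.
vanish_dgp <- calibrate_dgp(control_survival = 0.725, rd_low = 0.069,
                            rd_high = -0.257)

null_dgp <- calibrate_dgp(control_survival = 0.5, rd_low = 0, rd_high = 0)

# small complete two-covariate trial for structural tests
small_trial <- function(n = 200, seed = 1, dgp = vanish_dgp) {
  cfg <- dgp
  cfg$n_participants <- as.integer(n)
  cfg$seed <- as.integer(seed)
  generate_trial(cfg)
}

# Monte-Carlo estimate of the marginal quantities of a DGP, independent of
# the quadrature route used by calibrate_dgp()/dgp_truth()
mc_truth <- function(cfg, n = 2e5, seed = 99) {
  c2 <- cfg
  c2$n_participants <- as.integer(n)
  c2$seed <- as.integer(seed)
  d <- generate_trial(c2)
  S <- as.numeric(d$X$X2 > cfg$true_threshold)
  list(control_survival = mean(d$Y[d$W == 0]),
       rd_low = mean(d$Y[d$W == 1 & S == 0]) - mean(d$Y[d$W == 0 & S == 0]),
       rd_high = mean(d$Y[d$W == 1 & S == 1]) - mean(d$Y[d$W == 0 & S == 1]))
}

# build a causal_forest-shaped object by hand (for post-estimation tests
# that need full control over trees / nuisance / CATEs)
fake_forest <- function(trees, data, tau_oob, p_hat, m_hat,
                        feature_names = names(data$X)) {
  nu <- structure(list(p_hat = p_hat, m_hat = m_hat,
                       w_resid = data$W - p_hat, y_resid = data$Y - m_hat,
                       source = "fixed_known",
                       clipped = rep(FALSE, length(data$Y))),
                  class = "cf_nuisance")
  structure(list(trees = trees, tau_oob = tau_oob,
                 oob_count = rep(length(trees), length(data$Y)),
                 nuisance = nu, data = data, feature_names = feature_names,
                 params = list(n_trees = length(trees))),
            class = "causal_forest")
}

# a leaf-only tree whose root splits `var` at `thr`, with all rows as
# estimate members split by the threshold
fake_tree <- function(var, thr, data) {
  x <- data$X[[var]]
  vi <- match(var, names(data$X))
  lo <- which(x <= thr)
  hi <- which(x > thr)
  list(root = 1L, var = c(vi, NA_integer_, NA_integer_),
       threshold = c(thr, NA_real_, NA_real_),
       left = c(2L, NA_integer_, NA_integer_),
       right = c(3L, NA_integer_, NA_integer_),
       depth = c(0L, 1L, 1L),
       members = list(integer(0), lo, hi),
       grow_idx = integer(0), est_idx = seq_along(data$Y))
}

## replicate the grower's split search in plain R: one-step pseudo-outcome
## leaf means, midpoint thresholds, child floor, arm constraints
oracle_best_split <- function(X, wr, yr, W, rows, min_node = 5, min_arm = 1,
                              alpha = 0.1) {
  n <- length(rows)
  wrr <- wr[rows]; yrr <- yr[rows]
  tauP <- sum(wrr * yrr) / sum(wrr^2)
  vP <- mean(wrr^2)
  rho <- wrr * (yrr - wrr * tauP) / vP
  floorc <- max(min_node, ceiling(alpha * n))
  best <- list(crit = 0, var = NA, thr = NA)
  for (v in seq_len(ncol(X))) {
    x <- X[rows, v]
    for (t in sort(unique(x))) {
      L <- x <= t
      nL <- sum(L); nR <- n - nL
      if (nL < floorc || nR < floorc) next
      if (sum(W[rows][L]) < min_arm || sum(1 - W[rows][L]) < min_arm) next
      if (sum(W[rows][!L]) < min_arm || sum(1 - W[rows][!L]) < min_arm) next
      d <- mean(rho[L]) - mean(rho[!L])
      crit <- nL * nR * d^2
      if (crit > best$crit) {
        xs <- sort(x)
        best <- list(crit = crit, var = v,
                     thr = mean(c(max(x[x <= t]), min(x[x > t]))))
      }
    }
  }
  best
}
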