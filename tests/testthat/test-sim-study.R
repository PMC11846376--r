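test_that("aggregation reproduces hand-computed threshold metrics", {
  reps <- data.frame(seed = 1:3, modal_variable = "X2",
                     mean_threshold = c(4.6, 4.7, 4.8),
                     cf_dfp = 1, cf_dfp_p = .01,
                     univ_continuous_p = c(.01, .2, .03),
                     univ_dichot_p = c(.04, .06, .5),
                     lasso_kept_continuous = c(TRUE, TRUE, FALSE),
                     lasso_p_continuous = c(.01, .04, NA),
                     lasso_kept_dichot = TRUE, lasso_p_dichot = .2,
                     gate_low = .1, gate_high = -.2,
                     stringsAsFactors = FALSE)
  rep <- aggregate_replicates(reps, true_threshold = 4.68)
  expect_equal(rep$pct_modal_correct, 100)
  expect_equal(rep$threshold_mean, 4.7)
  expect_equal(rep$threshold_sd, 0.1)
  expect_equal(rep$threshold_mse_vs_true,
               mean((c(4.6, 4.7, 4.8) - 4.68)^2))
  ## internal consistency: population MSE = population variance + bias^2
  n <- 3
  expect_equal(rep$threshold_mse_vs_true,
               rep$threshold_sd^2 * (n - 1) / n +
                 (rep$threshold_mean - 4.68)^2,
               tolerance = 1e-10)
  expect_equal(rep$power_univ_continuous, 100 * 2 / 3)
  expect_equal(rep$power_univ_dichot, 100 * 1 / 3)
  expect_equal(rep$lasso_retention_continuous, 100 * 2 / 3)
  expect_equal(rep$power_lasso_continuous, 100 * 2 / 3)
})

test_that("identical replicates collapse to zero spread", {
  reps <- data.frame(seed = 1:2, modal_variable = "X2",
                     mean_threshold = c(4.7, 4.7),
                     cf_dfp = 1, cf_dfp_p = .01,
                     univ_continuous_p = .01, univ_dichot_p = .01,
                     lasso_kept_continuous = TRUE, lasso_p_continuous = .01,
                     lasso_kept_dichot = TRUE, lasso_p_dichot = .01,
                     gate_low = .1, gate_high = -.2,
                     stringsAsFactors = FALSE)
  rep <- aggregate_replicates(reps)
  expect_equal(rep$threshold_sd, 0)
  expect_equal(rep$threshold_mse_vs_true, (4.7 - 4.68)^2)
})

test_that("the report is invariant to replicate order and covariate relabelling", {
  set.seed(37)
  reps <- data.frame(seed = 1:20,
                     modal_variable = sample(c("X2", "X1"), 20, TRUE,
                                             prob = c(.8, .2)),
                     mean_threshold = rnorm(20, 4.68, 0.1),
                     cf_dfp = 1, cf_dfp_p = .01,
                     univ_continuous_p = runif(20),
                     univ_dichot_p = runif(20),
                     lasso_kept_continuous = TRUE,
                     lasso_p_continuous = runif(20),
                     lasso_kept_dichot = TRUE, lasso_p_dichot = runif(20),
                     gate_low = .1, gate_high = -.2,
                     stringsAsFactors = FALSE)
  a <- aggregate_replicates(reps)
  b <- aggregate_replicates(reps[sample(20), ])
  a$replicates <- b$replicates <- NULL
  expect_equal(a, b)
  ## relabelling the non-modifier covariate leaves the hit rate unchanged
  reps2 <- reps
  reps2$modal_variable[reps2$modal_variable == "X1"] <- "Xother"
  expect_equal(aggregate_replicates(reps2)$pct_modal_correct,
               a$pct_modal_correct)
})

test_that("a replicate is reproducible from its seed and tolerates the null process", {
  r1 <- run_replicate(vanish_dgp, seed = 77,
                      methods = list(n_trees = 60, nuisance_trees = 60,
                                     n_lambda = 15))
  r2 <- run_replicate(vanish_dgp, seed = 77,
                      methods = list(n_trees = 60, nuisance_trees = 60,
                                     n_lambda = 15))
  expect_identical(r1, r2)
  expect_equal(r1$modal_variable, "X2")
  ## a null replicate records whatever modal variable arises, without error
  r0 <- run_replicate(null_dgp, seed = 78,
                      methods = list(n_trees = 60, nuisance_trees = 60,
                                     n_lambda = 15))
  expect_true(r0$modal_variable %in% c("X1", "X2", NA))
  expect_true(all(vapply(
    r0[c("univ_continuous_p", "univ_dichot_p")],
    function(p) is.na(p) || (p >= 0 && p <= 1), logical(1))))
})

test_that("a small study end-to-end populates every report field", {
  rep <- run_simulation(vanish_dgp, n_reps = 3, seed = 91,
                        methods = list(n_trees = 500, nuisance_trees = 300,
                                       n_lambda = 15))
  expect_s3_class(rep, "simulation_report")
  expect_equal(rep$n_reps, 3)
  expect_false(is.na(rep$threshold_mean))
  expect_false(is.na(rep$power_univ_continuous))
  expect_false(is.na(rep$power_lasso_continuous))
  expect_length(rep$threshold_95_range, 2)
  ## single-replicate sanity band for the recovered threshold: truth 4.68
  ## +/- 4.5 of the measured cross-replicate SD (~0.1)
  expect_true(all(rep$replicates$mean_threshold > 4.23 &
                    rep$replicates$mean_threshold < 5.13))
})

test_that("serial and forked execution produce identical reports", {
  a <- run_simulation(vanish_dgp, n_reps = 2, seed = 93, cores = 1,
                      methods = list(n_trees = 40, nuisance_trees = 40,
                                     n_lambda = 10))
  b <- run_simulation(vanish_dgp, n_reps = 2, seed = 93, cores = 2,
                      methods = list(n_trees = 40, nuisance_trees = 40,
                                     n_lambda = 10))
  expect_equal(a$replicates, b$replicates)
})
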