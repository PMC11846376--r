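make_missing_trial <- function() {
  set.seed(11)
  n <- 100
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X$a[1:31] <- NA  # 31%
  X$b[1:29] <- NA  # 29%
  trial_data(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5), X)
}

test_that("the missingness filter drops at the cut and never touches Y/W", {
  d <- make_missing_trial()
  res <- filter_high_missingness(d)
  expect_setequal(names(res$data$X), c("b", "c"))
  expect_equal(res$report$removed_for_missingness$name, "a")
  expect_equal(res$report$removed_for_missingness$fraction, 0.31)
  expect_length(res$data$Y, 100)
  ## identity on complete data, and idempotence
  res2 <- filter_high_missingness(res$data)
  expect_identical(res2$data$X, res$data$X)
  ## exact boundary: 30% missing is dropped
  d$X$c[1:30] <- NA
  expect_true("c" %in%
    filter_high_missingness(d)$report$removed_for_missingness$name)
})

test_that("the correlation filter is strict and drops the least informative member", {
  set.seed(2)
  n <- 300
  base <- rnorm(n)
  X <- data.frame(p = base, q = base, r = rnorm(n))
  d <- trial_data(rbinom(n, 1, .5), rbinom(n, 1, .5), X)
  res <- filter_correlated(d)
  ## duplicated pair: exactly one dropped (the later column on a tie)
  expect_setequal(names(res$data$X), c("p", "r"))
  expect_equal(res$report$removed_for_correlation$dropped, "q")
  ## r below the cut keeps both
  X2 <- data.frame(p = base, q = 0.62 * base + sqrt(1 - 0.62^2) * rnorm(n))
  stopifnot(abs(cor(X2$p, X2$q)) < 0.7)
  d2 <- trial_data(d$Y, d$W, X2)
  expect_equal(ncol(filter_correlated(d2)$data$X), 2)
  ## idempotence
  expect_identical(filter_correlated(res$data)$data$X, res$data$X)
})

test_that("three mutually correlated columns lose the two most-missing ones", {
  set.seed(4)
  n <- 400
  base <- rnorm(n)
  X <- data.frame(u = base + 0.1 * rnorm(n),
                  v = base + 0.1 * rnorm(n),
                  w = base + 0.1 * rnorm(n))
  X$v[1:40] <- NA  # 10% missing
  X$w[1:80] <- NA  # 20% missing
  d <- trial_data(rbinom(n, 1, .5), rbinom(n, 1, .5), X)
  cm <- cor(as.matrix(X), use = "pairwise.complete.obs")
  stopifnot(all(abs(cm[upper.tri(cm)]) > 0.7))
  res <- filter_correlated(d)
  expect_equal(names(res$data$X), "u")
  expect_setequal(res$report$removed_for_correlation$dropped, c("v", "w"))
})

test_that("encoding one-hots every level and standardises with the sample SD", {
  d <- trial_data(c(0, 1, 0), c(1, 0, 1),
                  data.frame(cat = factor(c("a", "b", "c")),
                             num = c(1, 2, 3)))
  enc <- encode_and_scale(d)$data
  expect_setequal(names(enc$X), c("cat.a", "cat.b", "cat.c", "num"))
  expect_equal(enc$X$cat.a, c(1, 0, 0))
  expect_equal(enc$X$num, c(-1, 0, 1))  # sample SD of (1,2,3) is 1
  i <- match("num", enc$meta$name)
  expect_equal(enc$meta$center[i], 2)
  expect_equal(enc$meta$scale[i], 1)
  ## standardisation invariant
  expect_lt(abs(mean(enc$X$num)), 1e-8)
  expect_lt(abs(sd(enc$X$num) - 1), 1e-8)
})

test_that("standardised thresholds back-transform to raw units", {
  set.seed(7)
  d <- trial_data(rbinom(50, 1, .5), rbinom(50, 1, .5),
                  data.frame(k = rnorm(50, 4.58, 0.937)))
  enc <- encode_and_scale(d)$data
  i <- match("k", enc$meta$name)
  ## algebraic inverse: z maps back to mean + z * sd
  z <- (4.68 - enc$meta$center[i]) / enc$meta$scale[i]
  expect_equal(unscale_threshold(enc$meta, "k", z), 4.68, tolerance = 1e-12)
  ## the canonical potassium example: 0.106 SD above a 4.58/0.937 scale
  meta <- data.frame(name = "k", kind = "continuous", center = 4.58,
                     scale = 0.937, missing_frac = 0, derived_score = FALSE)
  expect_equal(unscale_threshold(meta, "k", 0.106), 4.58 + 0.106 * 0.937)
})

test_that("zero-variance continuous columns are dropped with a note", {
  d <- trial_data(c(0, 1), c(1, 0), data.frame(flat = c(2, 2), ok = c(1, 5)))
  res <- encode_and_scale(d)
  expect_equal(names(res$data$X), "ok")
  expect_match(res$report$notes, "zero-variance")
})

test_that("all imputation methods are the identity on complete data", {
  d <- small_trial(n = 50)
  for (m in c("missforest", "mean", "complete_case", "ipw")) {
    res <- impute(d, m, seed = 1)
    expect_identical(res$data$X, d$X, label = m)
    expect_equal(res$report$iterations_run, 0L)
  }
})

test_that("complete-case analysis keeps exactly the fully observed rows", {
  ## synthetic stand-in shaped like the trial's missingness profile:
  ## 408 participants of whom 153 have at least one missing covariate
  set.seed(13)
  n <- 408
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  incomplete <- sample(n, 153)
  third <- split(incomplete, rep(1:3, length.out = 153))
  X$a[third[[1]]] <- NA
  X$b[third[[2]]] <- NA
  X$c[third[[3]]] <- NA
  d <- trial_data(rbinom(n, 1, .5), rbinom(n, 1, .5), X)
  res <- impute(d, "complete_case")
  expect_equal(n_participants(res$data), 255)
  expect_false(anyNA(res$data$X))
})

test_that("ipw weights complete cases by inverse completeness probability", {
  set.seed(17)
  n <- 500
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  ## completeness depends on the observed column a
  p_miss <- plogis(-1 + X$a)
  X$b[runif(n) < p_miss] <- NA
  d <- trial_data(rbinom(n, 1, .5), rbinom(n, 1, .5), X)
  res <- impute(d, "ipw")
  keep <- complete.cases(X)
  expect_equal(n_participants(res$data), sum(keep))
  expect_true(all(res$data$weights >= 1))
  ## rows with large a (likelier to be missing) get larger weights
  expect_gt(cor(res$data$X$a, res$data$weights), 0)
})

test_that("iterative forest imputation recovers a masked deterministic relation", {
  set.seed(3)
  n <- 1000
  xa <- rnorm(n)
  xb <- 2 * xa
  X <- data.frame(xa = xa, xb = xb, xc = rnorm(n))
  mask <- sample(n, 0.2 * n)
  X$xb[mask] <- NA
  d <- trial_data(rbinom(n, 1, .5), rbinom(n, 1, .5), X)
  res <- impute(d, "missforest", seed = 4)
  expect_lt(sqrt(mean((res$data$X$xb[mask] - xb[mask])^2)), 0.2)
  ## observed entries preserved exactly; trace recorded
  expect_identical(res$data$X$xb[-mask], xb[-mask])
  expect_identical(res$data$X$xa, xa)
  expect_gt(length(res$report$convergence_trace), 0)
})

test_that("mean imputation then standardisation leaves imputed entries at zero", {
  set.seed(5)
  X <- data.frame(a = rnorm(60))
  X$a[1:10] <- NA
  d <- trial_data(rbinom(60, 1, .5), rbinom(60, 1, .5), X)
  imp <- impute(d, "mean")$data
  enc <- encode_and_scale(imp)$data
  expect_equal(enc$X$a[1:10], rep(0, 10), tolerance = 1e-12)
})
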