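# Gaussian mixture fitting, model selection and the log-likelihood-ratio
# separation measure.

test_that("single-component fit is the ML closed form", {
  fit <- fit_gaussian_mixture(c(1, 2, 3, 4, 5), K = 1)
  expect_equal(fit$means, 3)
  expect_equal(fit$sds, sqrt(2), tolerance = 1e-12)
  expect_equal(fit$weights, 1)
  # BIC from the closed-form Gaussian log-likelihood, p = 2 parameters
  n <- 5
  ll <- sum(dnorm(1:5, 3, sqrt(2), log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-12)
  expect_equal(fit$bic, 2 * ll - 2 * log(n), tolerance = 1e-12)
})

test_that("MAP variance update matches the stated formula", {
  set.seed(42)
  x <- rnorm(20, 5, 0.7)
  fit <- fit_gaussian_mixture(x, K = 1, lambda = 1, beta = 6)
  expect_equal(fit$means, mean(x), tolerance = 1e-12)
  expect_equal(fit$sds^2, (sum((x - mean(x))^2) + 6) / (length(x) + 1),
               tolerance = 1e-12)
})

test_that("two well-separated bulks are recovered", {
  set.seed(1)
  x <- c(rnorm(16, 0, 1), rnorm(16, 8, 1))
  fit <- fit_gaussian_mixture(x, K = 2, seed = 1)
  mu <- sort(fit$means)
  expect_lt(abs(mu[1] - 0), 0.5)
  expect_lt(abs(mu[2] - 8), 0.5)
  expect_true(all(abs(fit$weights - 0.5) < 0.15))
})

test_that("fit invariants hold: weights, posteriors, assignments, sorting", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- c(rnorm(20, 0, 1), rnorm(12, 6, 0.5))
    K <- sample(1:3, 1)
    fit <- tryCatch(fit_gaussian_mixture(x, K = K, seed = seed),
                    condspec_degenerate_error = function(e) NULL)
    if (is.null(fit)) next  # no non-singular K-component solution exists
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_true(all(fit$weights > 0))
    expect_true(all(fit$sds > 0))
    expect_equal(rowSums(fit$posteriors), rep(1, length(x)), tolerance = 1e-9)
    expect_equal(fit$assignments, max.col(fit$posteriors, ties.method = "first"))
    expect_true(all(diff(fit$weights) < 1e-12))  # sorted by decreasing weight
    expect_true(is.finite(fit$bic))
  }
})

test_that("EM objective is monotone non-decreasing across iterations", {
  for (seed in 1:15) {
    set.seed(seed)
    x <- c(rnorm(18), rnorm(14, 5, 2))
    for (prior in list(c(0, 0), c(1, 6))) {
      fit <- fit_gaussian_mixture(x, K = 2, lambda = prior[1], beta = prior[2],
                                  seed = seed)
      tr <- fit$trace
      if (length(tr) > 1) {
        expect_true(all(diff(tr) >= -1e-7 * (1 + abs(tr[-length(tr)]))))
      }
    }
  }
})

test_that("permuting the initialization leaves the sorted fit unchanged", {
  set.seed(11)
  x <- c(rnorm(16, 0, 1), rnorm(16, 7, 1.3))
  pooled <- sd(x)
  base <- condspec:::em_run(x, c(0.5, 0.5), c(0, 7), rep(pooled, 2), 0, 0)
  perm <- condspec:::em_run(x, c(0.5, 0.5), c(7, 0), rep(pooled, 2), 0, 0)
  o1 <- order(base$mu); o2 <- order(perm$mu)
  expect_equal(base$mu[o1], perm$mu[o2], tolerance = 1e-6)
  expect_equal(base$sd[o1], perm$sd[o2], tolerance = 1e-6)
  expect_equal(base$w[o1], perm$w[o2], tolerance = 1e-6)
})

test_that("prior (0,0) equals the pure ML fit", {
  set.seed(3)
  x <- c(rnorm(20), rnorm(12, 4))
  f1 <- fit_gaussian_mixture(x, K = 2, lambda = 0, beta = 0, seed = 3)
  # closed-form check at K=1 as the anchored ML reference
  f0 <- fit_gaussian_mixture(x, K = 1, lambda = 0, beta = 0)
  expect_equal(f0$sds, sd(x) * sqrt((length(x) - 1) / length(x)),
               tolerance = 1e-12)
  expect_gte(f1$loglik, f0$loglik)  # richer model fits no worse under ML
})

test_that("degenerate inputs are rejected or floored as specified", {
  expect_error(fit_gaussian_mixture(c(1, 1, 1), K = 2),
               class = "condspec_degenerate_error")
  expect_error(fit_gaussian_mixture(3, K = 1),
               class = "condspec_degenerate_error")
  expect_error(fit_gaussian_mixture(c(1, NA, 2), K = 1),
               class = "condspec_validation_error")
  expect_error(fit_gaussian_mixture(1:5, K = 4),
               class = "condspec_validation_error")
  # constant profile: K=1 via the variance floor
  fit <- fit_gaussian_mixture(rep(2.5, 10), K = 1)
  expect_equal(fit$K, 1L)
  expect_equal(fit$means, 2.5)
  expect_gt(fit$sds, 0)
})

test_that("BIC selection picks the generating K on clear cases", {
  # constant profile: higher K cannot improve the penalized fit
  expect_equal(select_mixture_model(rep(1, 32))$K, 1L)
  # quick seeded versions of the selection simulations (full versions in
  # the acceptance suite)
  k1 <- vapply(1:20, function(s) {
    set.seed(s); select_mixture_model(rnorm(32), seed = s)$K
  }, integer(1))
  expect_gte(sum(k1 == 1L), 17)
  k2 <- vapply(1:20, function(s) {
    set.seed(s); select_mixture_model(c(rnorm(16), rnorm(16, 10)), seed = s)$K
  }, integer(1))
  expect_gte(sum(k2 == 2L), 19)
})

test_that("the ML fit matches mclust's EM at fixed K", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(5)
  x <- c(rnorm(16, 0, 1), rnorm(16, 9, 1))
  ours <- fit_gaussian_mixture(x, K = 2, seed = 5)
  mc <- suppressWarnings(
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  )
  expect_equal(ours$loglik, mc$loglik, tolerance = 1e-4)
  expect_equal(sort(ours$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("absolute log-likelihood ratio matches closed forms", {
  expect_equal(loglik_ratio_abs(10, 10, 1, 0, 1), 50, tolerance = 1e-12)
  expect_equal(loglik_ratio_abs(3.7, 2, 1.5, 2, 1.5), 0)
  expect_equal(loglik_ratio_abs(0, 0, 1, 0, 2), log(2), tolerance = 1e-12)
  expect_error(loglik_ratio_abs(0, 0, 0, 0, 1),
               class = "condspec_validation_error")
})
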