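# Outlier-component rules, null construction and the two-step procedure.

test_that("step_params validates its thresholds", {
  p <- step_params()
  expect_s3_class(p, "step_params")
  expect_error(step_params(per = 0), class = "condspec_validation_error")
  expect_error(step_params(per = 1), class = "condspec_validation_error")
  expect_error(step_params(md = -1), class = "condspec_validation_error")
  expect_error(step_params(lambda = -1), class = "condspec_validation_error")
  expect_error(step_params(kmax = 4), class = "condspec_validation_error")
})

test_that("main component follows weight with the stated tie-breaks", {
  f <- make_fit(c(0.7, 0.3), c(0, 5), c(1, 1),
                data = c(rnorm(22), rnorm(10, 5)),
                assignments = rep(1:2, c(22, 10)))
  expect_equal(main_component(f), 1L)
  f1 <- fit_gaussian_mixture(rnorm(20), K = 1)
  expect_equal(main_component(f1), 1L)
  # equal weights: larger hard-assignment count wins
  f2 <- make_fit(c(0.5, 0.5), c(0, 5), c(1, 1),
                 data = c(rnorm(17), rnorm(15, 5)),
                 assignments = rep(1:2, c(17, 15)))
  expect_equal(main_component(f2), 1L)
  f3 <- make_fit(c(0.5, 0.5), c(5, 0), c(1, 1),
                 data = c(rnorm(15, 5), rnorm(17)),
                 assignments = rep(1:2, c(15, 17)))
  expect_equal(main_component(f3), 2L)
})

test_that("the three screening rules flag exactly as stated", {
  # small, separated component: rule I + rule II
  set.seed(1)
  f <- make_fit(c(0.94, 0.06), c(0, 10), c(1, 1),
                data = c(rnorm(30), 9.8, 10.1),
                assignments = rep(1:2, c(30, 2)))
  p <- step_params(per = 0.1, md = 1.3, mlk = 10, rsd = 0.1)
  expect_equal(flag_outlier_components(f, p), 2L)
  # minimum log-likelihood ratio at x = 9.8 is (9.8^2 - 0.2^2)/2 = 48
  expect_equal(min(loglik_ratio_abs(c(9.8, 10.1), 10, 1, 0, 1)), 48,
               tolerance = 1e-12)

  # rule I fails: medians too close
  f2 <- make_fit(c(0.95, 0.05), c(0, 0.5), c(1, 1),
                 data = c(rnorm(30), 0.45, 0.55),
                 assignments = rep(1:2, c(30, 2)))
  expect_length(flag_outlier_components(f2, p), 0)

  # small, widely spread component: rule III
  set.seed(2)
  f3 <- make_fit(c(0.93, 0.07), c(0, 3), c(1, 15),
                 data = c(rnorm(30), 2.5, 3.5),
                 assignments = rep(1:2, c(30, 2)))
  p3 <- step_params(per = 0.1, md = 1.3, mlk = 300, rsd = 0.1)
  expect_equal(flag_outlier_components(f3, p3), 2L)

  # single component: empty set
  expect_length(flag_outlier_components(fit_gaussian_mixture(rnorm(20), 1), p), 0)
})

test_that("flagging agrees with a brute-force rule evaluation", {
  for (seed in 1:200) {
    fit <- random_fit(seed)
    set.seed(seed + 5e5)
    p <- step_params(per = runif(1, 0.05, 0.5), md = runif(1, 0, 3),
                     mlk = runif(1, 0, 50), rsd = runif(1, 0, 2))
    expect_equal(sort(flag_outlier_components(fit, p)),
                 sort(brute_flag(fit, p)),
                 info = paste("seed", seed))
  }
})

test_that("raising md or per moves flags monotonically", {
  for (seed in 1:60) {
    fit <- random_fit(seed)
    set.seed(seed + 9e5)
    base <- step_params(per = runif(1, 0.1, 0.4), md = runif(1, 0, 2),
                        mlk = runif(1, 0, 30), rsd = runif(1, 0, 1.5))
    f0 <- flag_outlier_components(fit, base)
    # raising md never adds flags
    stricter_md <- step_params(per = base$per, md = base$md + 0.8,
                               mlk = base$mlk, rsd = base$rsd)
    expect_true(all(flag_outlier_components(fit, stricter_md) %in% f0))
    # lowering per never adds flags
    stricter_per <- step_params(per = base$per / 2, md = base$md,
                                mlk = base$mlk, rsd = base$rsd)
    expect_true(all(flag_outlier_components(fit, stricter_per) %in% f0))
  }
})

test_that("the main component is never flagged", {
  for (seed in 1:60) {
    fit <- random_fit(seed)
    set.seed(seed + 7e5)
    p <- step_params(per = runif(1, 0.05, 0.9), md = 0, mlk = 0, rsd = 2)
    expect_false(main_component(fit) %in% flag_outlier_components(fit, p))
  }
})

test_that("build_null renormalizes and never returns an empty model", {
  f <- make_fit(c(0.9, 0.1), c(0, 8), c(1, 1),
                data = c(rnorm(28), rnorm(4, 8)),
                assignments = rep(1:2, c(28, 4)))
  n1 <- build_null(f, excluded = 2L)
  expect_equal(n1$weights, 1)
  expect_equal(n1$means, 0)

  f3 <- make_fit(c(0.6, 0.3, 0.1), c(0, 4, 9), c(1, 1, 1),
                 data = c(rnorm(19), rnorm(10, 4), rnorm(3, 9)),
                 assignments = rep(1:3, c(19, 10, 3)))
  n3 <- build_null(f3, excluded = 3L)
  expect_equal(n3$weights, c(2 / 3, 1 / 3), tolerance = 1e-12)

  # single component, nothing excluded: unchanged
  f1 <- fit_gaussian_mixture(rnorm(20, 5, 0.5), K = 1)
  n0 <- build_null(f1)
  expect_equal(n0$means, f1$means)
  expect_equal(n0$sds, f1$sds)
  expect_equal(n0$weights, 1)

  # excluding everything falls back to the main component alone
  nf <- build_null(f3, excluded = 1:3)
  expect_length(nf$weights, 1)
  expect_equal(sum(nf$weights), 1)
  for (seed in 1:40) {
    fit <- random_fit(seed)
    nn <- build_null(fit, excluded = seq_len(fit$K)[-main_component(fit)])
    expect_gte(length(nn$retained), 1)
    expect_equal(sum(nn$weights), 1, tolerance = 1e-9)
  }
})

test_that("detect_step handles flat, spiked and over-excluded profiles", {
  # identical values: single component, all p-values equal
  r <- detect_step(rep(4, 32), step_params(kmax = 1))
  expect_equal(r$fit$K, 1L)
  expect_length(r$excluded_components, 0)
  expect_true(all(abs(r$p_two - r$p_two[1]) < 1e-12))

  # one value far out: provisionally flagged
  set.seed(21)
  x <- c(rnorm(31, 5, 0.5), 5 + 8 * 0.5)
  r2 <- detect_step(x, step_params(beta = 6, kmax = 1), alpha = 0.05 / 32)
  expect_true(32L %in% r2$provisional_outliers)

  # excluding all but two conditions cannot support a fit over the rest
  expect_error(detect_step(rnorm(10), step_params(), exclude_conditions = 1:9),
               class = "condspec_degenerate_error")
  expect_error(detect_step(rnorm(10), step_params(), exclude_conditions = 1:11),
               class = "condspec_validation_error")
})

test_that("two-step detection refines the null and is idempotent when clean", {
  # pure Gaussian profile: the two steps agree and nothing is flagged
  set.seed(31)
  x <- rnorm(32, 7, 0.6)
  r <- run_two_step(x, seed = 31)
  expect_lt(abs(r$null$means[1] - r$step1$null$means[1]), 0.3)
  expect_true(all(r$p_two > 1e-4))

  # two spiked conditions are flagged and the refined null recovers the
  # background mean
  set.seed(32)
  bg <- rnorm(30, 8, 0.5)
  x2 <- c(bg, 8 + 6 * 0.5, 8 + 6 * 0.5 + 0.2)
  r2 <- run_two_step(x2, seed = 32)
  expect_true(all(c(31L, 32L) %in% r2$step1$provisional_outliers))
  expect_lt(abs(r2$null$means[which.max(r2$null$weights)] - 8), 0.2)
  expect_true(all(r2$p_two[31:32] < 1e-6))
  expect_true(all(r2$direction[31:32] == 1L))

  # same params in both steps and no provisional outliers: identical steps
  set.seed(33)
  x3 <- rnorm(32)
  sp <- step_params(per = 0.1, beta = 0, kmax = 1)
  r3 <- run_two_step(x3, step1 = sp, step2 = sp, seed = 33)
  if (length(r3$step1$provisional_outliers) == 0) {
    expect_equal(r3$step2$p_two, r3$step1$p_two, tolerance = 1e-12)
    expect_equal(r3$step2$null$means, r3$step1$null$means, tolerance = 1e-12)
  }
})

test_that("the robust screen reverts on large flagged structures", {
  # a secondary bulk of ~10 shifted conditions must not be peeled
  set.seed(41)
  x <- c(rnorm(22, 5, 0.25), rnorm(10, 7, 0.25))
  flags <- condspec:::robust_screen(x, cut = 3.6, cap = 4L)
  expect_length(flags, 0)
  # while a genuine 2-spike set is
  set.seed(42)
  y <- c(rnorm(30, 5, 0.25), 6.6, 6.8)
  flags2 <- condspec:::robust_screen(y, cut = 3.6, cap = 4L)
  expect_true(all(c(31L, 32L) %in% flags2))
})
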