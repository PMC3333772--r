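# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive results from first principles (step-up formulas,
# quadrature, brute-force rule evaluation) rather than calling the package
# code they check.

# Benjamini-Hochberg step-up, written directly from the formula.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Benjamini-Yekutieli: BH with the harmonic-sum inflation c(m).
brute_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * cm * ps / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail probability of a Gaussian mixture by numerical quadrature,
# component-wise with finite limits so that very tight components (near
# delta functions on the scale of the mixture) are not missed by the
# adaptive grid.
quad_tail_up <- function(weights, means, sds, x) {
  total <- 0
  for (k in seq_along(weights)) {
    hi <- means[k] + 12 * sds[k]
    if (x >= hi) next
    total <- total + weights[k] * stats::integrate(
      function(t) stats::dnorm(t, means[k], sds[k]),
      lower = x, upper = hi,
      rel.tol = 1e-12, abs.tol = 1e-14, subdivisions = 400L)$value
  }
  total
}

# Build a mixture_fit object directly from component parameters and a
# hard assignment, bypassing EM — for exercising the outlier rules on
# exactly specified configurations.
make_fit <- function(weights, means, sds, data, assignments) {
  n <- length(data)
  K <- length(weights)
  post <- matrix(0, n, K)
  post[cbind(seq_len(n), assignments)] <- 1
  structure(list(
    K = K, weights = weights, means = means, sds = sds,
    loglik = NA_real_, objective = NA_real_, bic = NA_real_,
    posteriors = post, assignments = as.integer(assignments),
    trace = NULL, converged = TRUE,
    n = n, data = data, lambda = 0, beta = 0
  ), class = "mixture_fit")
}

# Brute-force re-implementation of the outlier-component rules, written
# against the rule statements rather than the package code: rule I gates on
# the median gap to the main component; a small component (assigned
# fraction below per) is flagged when it is well separated (minimum
# absolute log-density ratio above mlk) or much wider than the main
# component (sd ratio main/candidate below rsd). A component with no
# assigned values is flagged iff its weight is below per and rule I holds
# on its mean.
brute_flag <- function(fit, params) {
  if (fit$K == 1L) return(integer(0))
  counts <- tabulate(fit$assignments, fit$K)
  med_all <- median(fit$data)
  ord <- order(-fit$weights, -counts, abs(fit$means - med_all))
  main <- ord[1L]
  med_main <- median(fit$data[fit$assignments == main])
  out <- integer(0)
  for (k in seq_len(fit$K)) {
    if (k == main) next
    vals <- fit$data[fit$assignments == k]
    if (length(vals) == 0L) {
      if (fit$weights[k] < params$per &&
          abs(fit$means[k] - med_main) > params$md) out <- c(out, k)
      next
    }
    if (abs(median(vals) - med_main) <= params$md) next
    if (length(vals) / fit$n >= params$per) next
    llr <- abs(dnorm(vals, fit$means[k], fit$sds[k], log = TRUE) -
                 dnorm(vals, fit$means[main], fit$sds[main], log = TRUE))
    if (min(llr) > params$mlk ||
        fit$sds[main] / fit$sds[k] < params$rsd) out <- c(out, k)
  }
  out
}

# Random fitted mixture on synthetic data, for property tests.
random_fit <- function(seed) {
  set.seed(seed)
  K <- sample(1:3, 1)
  n <- sample(20:40, 1)
  mu <- sort(runif(K, 0, 12))
  sds <- runif(K, 0.1, 2)
  w <- as.vector(stats::rmultinom(1, n, rep(1 / K, K))) / n
  cnt <- round(w * n)
  cnt[1] <- n - sum(cnt[-1])
  if (any(cnt < 1)) return(random_fit(seed + 10000L))
  x <- unlist(lapply(seq_len(K), function(k) rnorm(cnt[k], mu[k], sds[k])))
  select_mixture_model(x, Kmax = 3, lambda = 1, beta = 0, seed = seed)
}

random_null <- function(seed) {
  set.seed(seed)
  K <- sample(1:3, 1)
  w <- runif(K, 0.2, 1)
  structure(list(means = runif(K, -5, 15), sds = runif(K, 0.05, 3),
                 weights = w / sum(w), retained = seq_len(K)),
            class = "null_model")
}
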