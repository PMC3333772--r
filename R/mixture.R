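# Univariate Gaussian mixture fitting (1-3 components) by EM, with an
# optional inverse-gamma MAP penalty on component variances, and BIC model
# selection. This is the model underlying each gene's null distribution.

SD_FLOOR <- 1e-3   # log2 units; absolute floor (constant profiles, K = 1)
# Minimum sd for a component in a multi-component fit. A "component"
# tighter than ~3% on the raw scale is below array technical noise and is
# invariably a likelihood spike over a few near-coincident values; EM
# starts converging there are discarded as singular.
MIN_COMPONENT_SD <- 0.05
EM_TOL <- 1e-8     # relative change in the (penalized) objective
EM_MAX_ITER <- 500L
# Seeded random restarts in addition to the deterministic quantile init.
# Zero by default: restarts systematically discover near-degenerate
# likelihood spikes (2-3 near-coincident values captured by a tight
# component) that BIC then rewards, biasing selection toward spurious extra
# components; the single quantile-based start behaves like a single
# hierarchical-init run and selects the generating K reliably.
EM_RESTARTS <- 0L

#' Fit a univariate Gaussian mixture by (MAP-)EM
#'
#' Fits a `K`-component Gaussian mixture to a gene's expression values across
#' conditions. With `lambda = 0, beta = 0` this is maximum likelihood; with a
#' nonzero prior the M-step variance update becomes
#' \deqn{\sigma_k^2 \leftarrow \frac{\sum_i r_{ik}(x_i-\mu_k)^2 + \beta}{\sum_i r_{ik} + \lambda},}
#' the MAP update under an inverse-gamma prior on each component variance.
#' The penalty shrinks near-singular component variances upward, which
#' stabilises the fit when a component captures only a handful of conditions.
#'
#' Initialisation is deterministic: component means start at the
#' K-quantiles of the data with pooled sd and equal weights (random
#' restarts, controlled by `seed`, are available internally but off by
#' default; see the package vignette). Component standard deviations are
#' floored at `1e-3` log2 units in every M-step; a K >= 2 start whose
#' component collapses onto that floor is discarded as singular.
#'
#' @param x numeric vector of log2 expression values (one per condition).
#' @param K number of components, 1, 2 or 3.
#' @param lambda nonnegative pseudo-count of the variance prior.
#' @param beta nonnegative variance pseudo-sum (squared log2 units).
#' @param seed integer seed controlling the random restarts.
#' @return an object of class `mixture_fit`: a list with elements `K`,
#'   `weights`, `means`, `sds` (components sorted by decreasing weight, ties
#'   by increasing mean), `loglik` (unpenalized data log-likelihood),
#'   `objective` (penalized), `bic` (`2*loglik - (3K-1)*log(n)`; larger is
#'   better), `posteriors` (n x K), `assignments` (maximum-posterior
#'   component per value), `trace` (objective per EM iteration of the winning
#'   start), `converged`, `n`, `data`.
#' @examples
#' fit <- fit_gaussian_mixture(c(1, 2, 3, 4, 5), K = 1)
#' fit$means  # 3
#' fit$sds    # sqrt(2): ML (biased, /n) standard deviation
#' @export
fit_gaussian_mixture <- function(x, K, lambda = 0, beta = 0, seed = 1L) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop_degenerate("need at least 2 values, got %d", length(x))
  if (!all(is.finite(x))) stop_validation("expression values must all be finite")
  if (!K %in% 1:3) stop_validation("K must be 1, 2 or 3, got %s", format(K))
  if (lambda < 0 || beta < 0) stop_validation("lambda and beta must be nonnegative")
  n <- length(x)
  n_distinct <- length(unique(x))
  if (n_distinct < K) {
    if (K == 1L) {
      # all values identical: the variance floor (or beta) defines sigma
      sigma2 <- if (lambda + n > 0) beta / (n + lambda) else 0
      sd1 <- max(sqrt(sigma2), SD_FLOOR)
      return(finish_fit(x, w = 1, mu = x[1L], sd = sd1, lambda, beta,
                        trace = NULL, converged = TRUE))
    }
    stop_degenerate("K = %d components but only %d distinct value(s)", K, n_distinct)
  }

  if (K == 1L) {
    mu <- mean(x)
    sigma2 <- (sum((x - mu)^2) + beta) / (n + lambda)
    sd1 <- max(sqrt(sigma2), SD_FLOOR)
    return(finish_fit(x, w = 1, mu = mu, sd = sd1, lambda, beta,
                      trace = NULL, converged = TRUE))
  }

  starts <- em_starts(x, K, seed)
  best <- NULL
  for (st in starts) {
    run <- tryCatch(
      em_run(x, st$w, st$mu, st$sd, lambda, beta),
      condspec_degenerate_error = function(e) NULL
    )
    if (is.null(run)) next
    if (is.null(best) || run$objective > best$objective) best <- run
  }
  if (is.null(best)) {
    stop_degenerate("all EM starts collapsed for K = %d (n = %d)", K, n)
  }
  finish_fit(x, best$w, best$mu, best$sd, lambda, beta,
             trace = best$trace, converged = best$converged)
}

# Initial parameter sets, deterministic: a quantile-based start (component
# means at the K-quantiles of the data) and a hierarchical-clustering start
# (Ward linkage on the 1-D values), which proposes separated clusters —
# including small outlying ones — that the quantile start never sees. Both
# start from the pooled sd: group-wise start variances steer EM into
# overfitted tight-component optima on homogeneous data. Optional seeded
# random restarts (EM_RESTARTS > 0) are kept for experimentation.
em_starts <- function(x, K, seed) {
  n <- length(x)
  pooled <- max(stats::sd(x) * sqrt((n - 1) / n), SD_FLOOR)
  qmu <- as.numeric(stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE))
  starts <- list(list(w = rep(1 / K, K), mu = qmu, sd = rep(pooled, K)))
  cl <- stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = K)
  sizes <- tabulate(cl, K)
  if (all(sizes > 0L)) {
    hmu <- vapply(seq_len(K), function(k) mean(x[cl == k]), numeric(1))
    starts[[length(starts) + 1L]] <-
      list(w = sizes / n, mu = hmu, sd = rep(pooled, K))
  }
  if (EM_RESTARTS > 0L) {
    ux <- unique(x)
    with_seed(seed, {
      for (r in seq_len(EM_RESTARTS)) {
        mu <- sort(sample(ux, K))
        starts[[length(starts) + 1L]] <-
          list(w = rep(1 / K, K), mu = mu, sd = rep(pooled, K))
      }
    })
  }
  starts
}

# log-sum-exp over matrix rows
row_lse <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

# Penalized objective: data loglik plus the log variance-prior kernel
# -beta/(2 sigma^2) - (lambda/2) log sigma^2 per component.
em_objective <- function(loglik, sd, lambda, beta) {
  if (lambda == 0 && beta == 0) return(loglik)
  loglik + sum(-beta / (2 * sd^2) - (lambda / 2) * log(sd^2))
}

# One EM run from a given start (compiled inner loop). A K >= 2 start is
# degenerate when a component loses all responsibility or collapses onto
# the variance floor (a singular spike carries no usable density model).
em_run <- function(x, w, mu, sd, lambda, beta) {
  out <- .em_run_cpp(x, w, mu, sd, lambda, beta,
                     EM_TOL, EM_MAX_ITER, MIN_COMPONENT_SD,
                     allow_floor = FALSE)
  if (isTRUE(out$degenerate)) {
    stop_degenerate("EM component collapsed (empty or singular component)")
  }
  list(w = out$w, mu = out$mu, sd = out$sd, objective = out$objective,
       trace = out$trace, converged = out$converged)
}

# Sort components, compute final posteriors/assignments/BIC, build the object.
finish_fit <- function(x, w, mu, sd, lambda, beta, trace, converged) {
  n <- length(x)
  K <- length(w)
  ord <- order(-w, mu)
  w <- w[ord]; mu <- mu[ord]; sd <- sd[ord]
  w <- w / sum(w)
  L <- vapply(seq_len(K),
              function(k) stats::dnorm(x, mu[k], sd[k], log = TRUE) + log(w[k]),
              numeric(n))
  if (K == 1L) L <- matrix(L, nrow = n)
  lse <- row_lse(L)
  loglik <- sum(lse)
  post <- exp(L - lse)
  assign <- max.col(post, ties.method = "first")
  p_free <- 3L * K - 1L
  structure(list(
    K = K, weights = w, means = mu, sds = sd,
    loglik = loglik,
    objective = em_objective(loglik, sd, lambda, beta),
    bic = 2 * loglik - p_free * log(n),
    posteriors = post, assignments = assign,
    trace = trace, converged = converged,
    n = n, data = x, lambda = lambda, beta = beta
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: K = %d, n = %d, BIC = %.3f\n",
              x$K, x$n, x$bic))
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits mixtures with `K = 1..Kmax` components (skipping any `K` exceeding
#' the number of distinct values) and returns the fit maximizing
#' `BIC = 2*loglik - (3K-1)*log(n)`; ties break toward fewer components.
#'
#' @inheritParams fit_gaussian_mixture
#' @param Kmax maximum number of components (1 to 3).
#' @return a `mixture_fit` (see [fit_gaussian_mixture()]).
#' @export
select_mixture_model <- function(x, Kmax = 3L, lambda = 0, beta = 0, seed = 1L) {
  if (!Kmax %in% 1:3) stop_validation("Kmax must be 1, 2 or 3")
  x <- as.numeric(x)
  best <- NULL
  for (K in seq_len(Kmax)) {
    fit <- tryCatch(
      fit_gaussian_mixture(x, K, lambda = lambda, beta = beta, seed = seed),
      condspec_degenerate_error = function(e) NULL
    )
    if (is.null(fit)) {
      if (K == 1L) stop_degenerate("cannot fit even a single component (n = %d)", length(x))
      next
    }
    if (is.null(best) || fit$bic > best$bic) best <- fit
  }
  best
}

#' Absolute Gaussian log-likelihood ratio
#'
#' `|log phi(x; mean_a, sd_a) - log phi(x; mean_b, sd_b)|` for a value `x`
#' under two Gaussian components; the separation measure used when deciding
#' whether a small mixture component is an outlier.
#'
#' @param x expression value(s).
#' @param mean_a,sd_a,mean_b,sd_b parameters of the two components; both sds
#'   must be strictly positive.
#' @return nonnegative numeric vector, same length as `x`.
#' @export
loglik_ratio_abs <- function(x, mean_a, sd_a, mean_b, sd_b) {
  if (sd_a <= 0 || sd_b <= 0) stop_validation("component sds must be positive")
  abs(stats::dnorm(x, mean_a, sd_a, log = TRUE) -
        stats::dnorm(x, mean_b, sd_b, log = TRUE))
}
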